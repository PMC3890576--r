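#' Simulate IRIL genotypes by gene drop
#'
#' Simulates the breeding scheme of an intermated recombinant inbred line
#' population: the F1 of two fully homozygous parents is selfed to an F2 of
#' `n_lines` individuals, the population is then randomly pair-mated for
#' `n_intermating_generations`, and finally each individual founds a line that
#' is selfed by single-seed descent for `n_selfing_generations`.  Meioses
#' follow the Haldane model (crossovers without interference, recombination
#' fraction `haldane_r()` of the inter-marker distance); chromosomes assort
#' independently.  Residual heterozygous calls are retained as `"H"`.
#'
#' @param map A genetic map as returned by [simulate_genetic_map()] (or read
#'   with [read_map()]); markers are simulated at its positions.
#' @param spec The [sim_spec()] describing population size and generations.
#' @return A wide tibble: column `line` plus one column per marker (in map
#'   order) with calls in `"A"` (parent-A/B73 homozygote), `"B"`
#'   (parent-B/Mo17), `"H"` (heterozygous).
#' @examples
#' spec <- sim_spec(n_chromosomes = 1, chrom_lengths = 50,
#'                  n_markers_per_chrom = 6, n_lines = 20, seed = 1)
#' geno <- simulate_iril_genotypes(simulate_genetic_map(spec), spec)
#' dim(geno)
#' @export
simulate_iril_genotypes <- function(map, spec) {
  stopifnot(inherits(spec, "iril_sim_spec"))
  map <- validate_map(map)
  if (spec$n_lines < 2) abort("`n_lines` must be at least 2.")
  if (!is.null(spec$seed)) set.seed(spec$seed + 1L)
  m <- nrow(map)
  n <- spec$n_lines
  # recombination fraction between adjacent markers; independent assortment
  # (r = 1/2) across chromosome boundaries
  r <- if (m > 1L) {
    ifelse(map$chrom[-1L] != map$chrom[-m], 0.5, haldane_r(diff(map$pos_cm)))
  } else {
    numeric(0)
  }
  h1 <- matrix(1L, n, m) # F1: one haplotype from each parent
  h2 <- matrix(0L, n, m)
  g1 <- .meiosis(h1, h2, r)
  g2 <- .meiosis(h1, h2, r)
  h1 <- g1
  h2 <- g2 # F2
  for (g in seq_len(spec$n_intermating_generations)) {
    mo <- sample.int(n, n, replace = TRUE)
    fa <- sample.int(n, n, replace = TRUE)
    clash <- which(fa == mo)
    while (length(clash)) {
      fa[clash] <- sample.int(n, length(clash), replace = TRUE)
      clash <- which(fa == mo)
    }
    g1 <- .meiosis(h1[mo, , drop = FALSE], h2[mo, , drop = FALSE], r)
    g2 <- .meiosis(h1[fa, , drop = FALSE], h2[fa, , drop = FALSE], r)
    h1 <- g1
    h2 <- g2
  }
  for (g in seq_len(spec$n_selfing_generations)) {
    g1 <- .meiosis(h1, h2, r)
    g2 <- .meiosis(h1, h2, r)
    h1 <- g1
    h2 <- g2
  }
  calls <- matrix("H", n, m)
  calls[h1 == 1L & h2 == 1L] <- "A"
  calls[h1 == 0L & h2 == 0L] <- "B"
  colnames(calls) <- map$marker
  dplyr::bind_cols(
    tibble::tibble(line = sprintf("L%04d", seq_len(n))),
    tibble::as_tibble(calls)
  )
}

# one gamete per row of (h1, h2): random starting haplotype, switch between
# adjacent markers with probability r[j]
.meiosis <- function(h1, h2, r) {
  n <- nrow(h1)
  m <- ncol(h1)
  phase <- matrix(0L, n, m)
  cur <- rbinom(n, 1L, 0.5)
  phase[, 1L] <- cur
  for (j in seq_len(m - 1L)) {
    cur <- (cur + rbinom(n, 1L, r[j])) %% 2L
    phase[, j + 1L] <- cur
  }
  out <- h1
  out[phase == 1L] <- h2[phase == 1L]
  out
}
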