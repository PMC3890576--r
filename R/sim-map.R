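#' Simulate a genetic map
#'
#' Builds a marker map for the genome described by a [sim_spec()]: markers are
#' spaced evenly (default) or uniformly at random along each chromosome, with
#' strictly increasing centimorgan positions, a synthetic physical coordinate
#' (monotone in cM) and contiguous bin labels used as cofactor sampling strata
#' (the role the IBM2 bins play on the real map).
#'
#' @param spec A [sim_spec()].
#' @param spacing `"even"` for equal spacing from 0 to the chromosome length,
#'   `"random"` for uniformly random interior positions with anchored ends.
#' @param bin_size_cm Approximate bin width in cM (default 10).
#' @param bp_per_cm Synthetic physical scale used to derive base-pair
#'   coordinates from cM positions.
#' @return A tibble with columns `marker`, `chrom`, `pos_cm`, `bp`, `bin`,
#'   ordered by chromosome and position.
#' @examples
#' map <- simulate_genetic_map(sim_spec(n_chromosomes = 1, chrom_lengths = 100,
#'                                      n_markers_per_chrom = 11, seed = 1))
#' map$pos_cm # 0, 10, ..., 100
#' @export
simulate_genetic_map <- function(spec, spacing = c("even", "random"),
                                 bin_size_cm = 10, bp_per_cm = 5e5) {
  stopifnot(inherits(spec, "iril_sim_spec"))
  spacing <- match.arg(spacing)
  if (bin_size_cm <= 0) abort("`bin_size_cm` must be positive.")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  chroms <- purrr::map(seq_len(spec$n_chromosomes), function(cc) {
    len <- spec$chrom_lengths[cc]
    m <- spec$n_markers_per_chrom[cc]
    pos <- if (spacing == "even" || m < 3) {
      seq(0, len, length.out = m)
    } else {
      c(0, sort(runif(m - 2L, 0, len)), len)
    }
    # ties have probability zero but would break the strict-ordering invariant
    while (anyDuplicated(pos)) {
      pos <- c(0, sort(runif(m - 2L, 0, len)), len)
    }
    n_bins <- max(1L, ceiling(len / bin_size_cm))
    bin_idx <- pmin(floor(pos / bin_size_cm) + 1L, n_bins)
    tibble::tibble(
      marker = sprintf("c%dm%02d", cc, seq_len(m)),
      chrom = cc,
      pos_cm = pos,
      bp = as.integer(round(pos * bp_per_cm)) + 1L,
      bin = sprintf("%d.%02d", cc, bin_idx)
    )
  })
  dplyr::bind_rows(chroms)
}
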