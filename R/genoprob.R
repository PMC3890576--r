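#' Conditional genotype probabilities on a scan grid
#'
#' Lays a pseudomarker grid over every chromosome (every `step_cm`
#' centimorgans, always including the marker positions themselves) and
#' computes, per line and grid position, the probability of the parent-A
#' genotype conditional on the nearest informative (homozygous, non-missing)
#' flanking markers, under the two-state RIL transition model with Haldane
#' distances (optionally scaled by a map-expansion factor).  At an observed
#' homozygous marker the probability is exactly 0 or 1; at an observed
#' heterozygous marker it is 0.5.
#'
#' @param genotypes Wide genotype tibble (QC'd; imputed or not).
#' @param map Map tibble.
#' @param step_cm Grid step in cM (default 2, the scan resolution used for
#'   the emulated study).
#' @param expansion Map-expansion factor for the transition distances.
#' @return An object of class `iril_genoprob`: list with `grid` (tibble
#'   `chrom`, `pos_cm`, `marker` -- `NA` for pseudomarkers), `prob_a`
#'   (lines x positions matrix), `lines`, `step_cm`, `expansion`.
#'   [tidy()] returns the long line-by-position tibble.
#' @export
compute_genotype_probabilities <- function(genotypes, map, step_cm = 2,
                                           expansion = 1) {
  if (step_cm <= 0) abort("`step_cm` must be positive.")
  map <- validate_map(map)
  calls <- geno_calls(genotypes)
  mk <- colnames(calls)
  if (!all(mk %in% map$marker)) {
    abort("all genotyped markers must be on the map.")
  }
  map <- map[map$marker %in% mk, ]
  grid <- purrr::map_dfr(unique(map$chrom), function(cc) {
    mpos <- map$pos_cm[map$chrom == cc]
    if (!length(mpos)) abort("empty chromosome on the map.")
    pos <- sort(unique(c(seq(min(mpos), max(mpos), by = step_cm),
                         max(mpos), mpos)))
    mi <- match(round(pos, 9), round(mpos, 9))
    tibble::tibble(chrom = cc, pos_cm = pos,
                   marker = map$marker[map$chrom == cc][mi])
  })
  n <- nrow(calls)
  prob <- matrix(0.5, n, nrow(grid),
                 dimnames = list(rownames(calls), NULL))
  for (cc in unique(grid$chrom)) {
    gj <- which(grid$chrom == cc)
    mj <- which(map$chrom == cc)
    sub <- calls[, map$marker[mj], drop = FALSE]
    pos <- map$pos_cm[mj]
    qpos <- grid$pos_cm[gj]
    for (i in seq_len(n)) {
      inf <- which(sub[i, ] %in% c("A", "B"))
      prob[i, gj] <- .flank_prob_a(pos[inf], as.integer(sub[i, inf] == "A"),
                                   qpos, expansion)
    }
    # observed heterozygous markers carry probability 1/2 by definition
    het_mk <- map$marker[mj]
    at_marker <- which(!is.na(grid$marker[gj]))
    for (j in at_marker) {
      mcol <- grid$marker[gj[j]]
      het <- sub[, mcol] == "H"
      if (any(het)) prob[het, gj[j]] <- 0.5
    }
  }
  structure(
    list(grid = grid, prob_a = prob, lines = rownames(calls),
         step_cm = step_cm, expansion = expansion),
    class = "iril_genoprob"
  )
}

#' Expected dosage on the scan grid
#'
#' @param probs An `iril_genoprob` object.
#' @return Lines-by-positions matrix of `E[x] = 2 P(A) - 1` in `[-1, 1]`.
#' @export
grid_dosage <- function(probs) {
  stopifnot(inherits(probs, "iril_genoprob"))
  2 * probs$prob_a - 1
}

#' @export
print.iril_genoprob <- function(x, ...) {
  cat(sprintf("<iril_genoprob> %d lines x %d positions (%d chromosomes, step %g cM)\n",
              length(x$lines), nrow(x$grid), length(unique(x$grid$chrom)),
              x$step_cm))
  invisible(x)
}

#' @export
tidy.iril_genoprob <- function(x, ...) {
  grid <- x$grid
  tibble::tibble(
    line = rep(x$lines, times = nrow(grid)),
    chrom = rep(grid$chrom, each = length(x$lines)),
    pos_cm = rep(grid$pos_cm, each = length(x$lines)),
    marker = rep(grid$marker, each = length(x$lines)),
    prob_a = as.vector(x$prob_a),
    dosage = 2 * as.vector(x$prob_a) - 1
  )
}
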