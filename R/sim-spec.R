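#' Specify a synthetic IRIL study
#'
#' Bundles every parameter of the synthetic-data generator: the genome
#' (chromosomes, lengths, marker counts), the breeding scheme (F2 from a
#' biparental cross, random intermating, single-seed-descent selfing), the
#' trait architecture (additive QTL effects, polygenic and error variance,
#' replication effects) and data-corruption settings (missing calls,
#' segregation distortion).  Defaults emulate the study conditions of the
#' maize IBM Fe-homeostasis trial: 85 IRILs, 3 replications, intermating
#' before selfing, heritabilities in the moderate-to-high range.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in cM (recycled to
#'   `n_chromosomes`).
#' @param n_markers_per_chrom Markers per chromosome (recycled).
#' @param n_lines Number of IRILs to generate.
#' @param n_intermating_generations Random-intermating generations between the
#'   F2 and the start of selfing (IBM-style map expansion; default 4).
#' @param n_selfing_generations Single-seed-descent selfing generations
#'   (default 8; residual heterozygosity about `0.5^8`).
#' @param qtl_effects Data frame with columns `chrom`, `pos_cm`, `effect`:
#'   additive QTL effects in trait units, sign convention parent-A
#'   (B73) homozygote `= +effect`, parent-B (Mo17) `= -effect`.  `NULL` for
#'   no simulated QTL.
#' @param polygenic_variance Variance of the per-line polygenic deviation
#'   (trait units squared).
#' @param error_variance Residual (pot) variance \eqn{\sigma^2_e} of a single
#'   replication record (trait units squared).
#' @param rep_effects Fixed replication effects \eqn{r_k}, recycled to
#'   `n_replications`.
#' @param grand_mean Grand mean \eqn{\mu} in trait units.
#' @param n_replications Number of replications `b` (must be at least 2 so
#'   that \eqn{\sigma^2_e} is estimable; default 3 as in the emulated trial).
#' @param missing_rate Fraction of genotype calls masked to missing by
#'   [inject_missing_and_distortion()].
#' @param distortion Data frame with columns `marker`, `freq_a` giving
#'   markers to distort and their target parent-A allele frequencies, or
#'   `NULL`.
#' @param seed Integer seed making every simulation stage deterministic, or
#'   `NULL` to use the current RNG state.
#' @return A validated list of class `iril_sim_spec`.
#' @examples
#' spec <- sim_spec(n_chromosomes = 2, chrom_lengths = 100,
#'                  n_markers_per_chrom = 11, n_lines = 50, seed = 1)
#' spec$n_lines
#' @export
sim_spec <- function(n_chromosomes = 10,
                     chrom_lengths = 150,
                     n_markers_per_chrom = 20,
                     n_lines = 85,
                     n_intermating_generations = 4,
                     n_selfing_generations = 8,
                     qtl_effects = NULL,
                     polygenic_variance = 0,
                     error_variance = 1,
                     rep_effects = 0,
                     grand_mean = 0,
                     n_replications = 3,
                     missing_rate = 0,
                     distortion = NULL,
                     seed = NULL) {
  if (n_chromosomes < 1) abort("`n_chromosomes` must be positive.")
  chrom_lengths <- rep_len(as.numeric(chrom_lengths), n_chromosomes)
  n_markers_per_chrom <- rep_len(as.integer(n_markers_per_chrom), n_chromosomes)
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive.")
  if (any(n_markers_per_chrom < 1)) {
    abort("each chromosome needs at least 1 marker.")
  }
  if (n_lines < 2) abort("`n_lines` must be at least 2.")
  if (n_intermating_generations < 0 || n_selfing_generations < 0) {
    abort("generation counts must be non-negative.")
  }
  if (n_replications < 2) {
    abort("`n_replications` must be at least 2 so that sigma_e^2 is estimable.")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    abort("`missing_rate` must lie in [0, 1].")
  }
  if (!is.null(qtl_effects)) {
    qtl_effects <- tibble::as_tibble(qtl_effects)
    stopifnot(all(c("chrom", "pos_cm", "effect") %in% names(qtl_effects)))
    if (!all(is.finite(qtl_effects$effect))) abort("QTL effects must be finite.")
    len <- chrom_lengths[match(qtl_effects$chrom, seq_len(n_chromosomes))]
    if (anyNA(len) || any(qtl_effects$pos_cm < 0 | qtl_effects$pos_cm > len)) {
      abort("QTL positions must lie on their chromosome.")
    }
  }
  if (!is.null(distortion)) {
    distortion <- tibble::as_tibble(distortion)
    stopifnot(all(c("marker", "freq_a") %in% names(distortion)))
    if (any(distortion$freq_a < 0 | distortion$freq_a > 1)) {
      abort("distorted allele frequencies must lie in [0, 1].")
    }
  }
  if (polygenic_variance < 0 || error_variance < 0) {
    abort("variance components must be non-negative.")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_lengths = chrom_lengths,
      n_markers_per_chrom = n_markers_per_chrom,
      n_lines = as.integer(n_lines),
      n_intermating_generations = as.integer(n_intermating_generations),
      n_selfing_generations = as.integer(n_selfing_generations),
      qtl_effects = qtl_effects,
      polygenic_variance = polygenic_variance,
      error_variance = error_variance,
      rep_effects = rep_len(as.numeric(rep_effects), n_replications),
      grand_mean = grand_mean,
      n_replications = as.integer(n_replications),
      missing_rate = missing_rate,
      distortion = distortion,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "iril_sim_spec"
  )
}

#' @export
print.iril_sim_spec <- function(x, ...) {
  cat("<iril_sim_spec>\n")
  cat(sprintf("  genome: %d chromosomes, %s markers, %s cM\n",
              x$n_chromosomes,
              paste(unique(x$n_markers_per_chrom), collapse = "/"),
              paste(unique(x$chrom_lengths), collapse = "/")))
  cat(sprintf("  breeding: F2 + %d intermating + %d selfing generations, %d lines\n",
              x$n_intermating_generations, x$n_selfing_generations, x$n_lines))
  cat(sprintf("  trait: %d QTL, polygenic var %.3g, error var %.3g, b = %d\n",
              if (is.null(x$qtl_effects)) 0L else nrow(x$qtl_effects),
              x$polygenic_variance, x$error_variance, x$n_replications))
  invisible(x)
}
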