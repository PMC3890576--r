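#' Simulate replicated phenotypes with known QTL architecture
#'
#' Generates one record per line and replication under the analysis model
#' \deqn{y_{ik} = \mu + \sum_q a_q x_{iq} + u_i + r_k + e_{ik},}
#' where \eqn{x_{iq}} is the dosage at the marker nearest each simulated QTL
#' (+1 for the parent-A homozygote, -1 for parent-B, 0 for heterozygous or
#' missing calls), \eqn{u_i \sim N(0, \sigma^2_{poly})} is a polygenic line
#' deviation, \eqn{r_k} the fixed replication effect and
#' \eqn{e_{ik} \sim N(0, \sigma^2_e)} the pot error (each phenotype record is
#' understood as the mean of the plants grown in one pot).
#'
#' @param genotypes Wide genotype tibble from [simulate_iril_genotypes()].
#' @param map The genetic map the genotypes were simulated on.
#' @param spec The [sim_spec()] holding the trait architecture.
#' @param trait,regime Labels stamped on the records.
#' @return Long tibble with columns `line`, `rep`, `regime`, `trait`, `value`.
#' @examples
#' spec <- sim_spec(n_chromosomes = 1, chrom_lengths = 50,
#'                  n_markers_per_chrom = 6, n_lines = 20,
#'                  qtl_effects = data.frame(chrom = 1, pos_cm = 20, effect = 1),
#'                  error_variance = 0.5, seed = 1)
#' map <- simulate_genetic_map(spec)
#' pheno <- simulate_phenotypes(simulate_iril_genotypes(map, spec), map, spec)
#' head(pheno)
#' @export
simulate_phenotypes <- function(genotypes, map, spec,
                                trait = "trait1", regime = "deficient") {
  stopifnot(inherits(spec, "iril_sim_spec"))
  map <- validate_map(map)
  calls <- geno_calls(genotypes)
  n <- nrow(calls)
  if (n != spec$n_lines) {
    abort(sprintf("genotype matrix has %d lines but the spec expects %d.",
                  n, spec$n_lines))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed + 2L)
  genetic <- rep(0, n)
  if (!is.null(spec$qtl_effects) && nrow(spec$qtl_effects) > 0) {
    for (q in seq_len(nrow(spec$qtl_effects))) {
      qq <- spec$qtl_effects[q, ]
      on_chr <- map[map$chrom == qq$chrom, ]
      if (nrow(on_chr) == 0) abort("QTL chromosome absent from the map.")
      causal <- on_chr$marker[which.min(abs(on_chr$pos_cm - qq$pos_cm))]
      if (!causal %in% colnames(calls)) {
        abort(sprintf("causal marker '%s' absent from the genotypes.", causal))
      }
      x <- .dosage_code(calls[, causal])
      genetic <- genetic + qq$effect * x
    }
  }
  u <- if (spec$polygenic_variance > 0) {
    rnorm(n, 0, sqrt(spec$polygenic_variance))
  } else {
    rep(0, n)
  }
  b <- spec$n_replications
  reps <- sprintf("R%d", seq_len(b))
  e <- if (spec$error_variance > 0) {
    matrix(rnorm(n * b, 0, sqrt(spec$error_variance)), n, b)
  } else {
    matrix(0, n, b)
  }
  y <- spec$grand_mean + genetic + u +
    matrix(spec$rep_effects, n, b, byrow = TRUE) + e
  tibble::tibble(
    line = rep(rownames(calls), times = b),
    rep = rep(reps, each = n),
    regime = regime,
    trait = trait,
    value = as.vector(y)
  )
}

#' Mask genotype calls and distort marker segregation
#'
#' Test-fixture generator for the quality-control stage: masks calls to
#' missing (`"-"`) uniformly at random at `spec$missing_rate`, and for every
#' row of `spec$distortion` resamples that marker's calls as parent-A with
#' the stated allele frequency (and parent-B otherwise), emulating distorted
#' segregation.  Seed-deterministic via `spec$seed`.
#'
#' @param genotypes Wide genotype tibble.
#' @param spec The [sim_spec()] holding `missing_rate` and `distortion`.
#' @return A genotype tibble of the same shape.
#' @export
inject_missing_and_distortion <- function(genotypes, spec) {
  stopifnot(inherits(spec, "iril_sim_spec"))
  calls <- geno_calls(genotypes)
  if (!is.null(spec$seed)) set.seed(spec$seed + 3L)
  if (!is.null(spec$distortion) && nrow(spec$distortion) > 0) {
    unknown <- setdiff(spec$distortion$marker, colnames(calls))
    if (length(unknown)) {
      abort(sprintf("distortion markers not in the genotypes: %s",
                    paste(unknown, collapse = ", ")))
    }
    for (q in seq_len(nrow(spec$distortion))) {
      mk <- spec$distortion$marker[q]
      fa <- spec$distortion$freq_a[q]
      calls[, mk] <- ifelse(rbinom(nrow(calls), 1L, fa) == 1L, "A", "B")
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < spec$missing_rate,
                   nrow(calls), ncol(calls))
    calls[mask] <- "-"
  }
  dplyr::bind_cols(
    tibble::tibble(line = rownames(calls)),
    tibble::as_tibble(calls)
  )
}

#' Write simulated truth to a JSON file
#'
#' Records the ground truth of a simulation (QTL positions and effects,
#' variance components, design and seed) so downstream parameter-recovery
#' analyses can be audited.
#'
#' @param spec A [sim_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(spec, path) {
  stopifnot(inherits(spec, "iril_sim_spec"))
  truth <- list(
    qtl = if (is.null(spec$qtl_effects)) list() else spec$qtl_effects,
    polygenic_variance = spec$polygenic_variance,
    error_variance = spec$error_variance,
    grand_mean = spec$grand_mean,
    rep_effects = spec$rep_effects,
    n_lines = spec$n_lines,
    n_replications = spec$n_replications,
    n_intermating_generations = spec$n_intermating_generations,
    n_selfing_generations = spec$n_selfing_generations,
    seed = spec$seed
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
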