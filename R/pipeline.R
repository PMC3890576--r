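#' Run the full IRIL analysis pipeline
#'
#' Orchestrates every stage for each trait-by-regime combination in the
#' phenotype table: segregation-distortion QC and flanking-marker
#' imputation; adjusted entry means, variance components, heritability and
#' KS normality per trait; partial-correlation trait network per regime;
#' then for each trait the cofactor selection, composite-interval scan,
#' permutation threshold, peak calling, Bayesian credible intervals,
#' simultaneous multi-QTL fit and candidate-gene interval counts.  All
#' randomized stages are seeded deterministically from `seed`, so rerunning
#' with the same inputs and configuration reproduces every output.
#'
#' @param map Map tibble (with `bin` column for cofactor selection and `bp`
#'   for physical intervals).
#' @param genotypes Wide genotype tibble.
#' @param phenotypes Long phenotype tibble (`line`, `rep`, `regime`,
#'   `trait`, `value`).
#' @param annotation Optional gene annotation tibble; when `NULL` the
#'   `genes` column of the QTL tables is reported as `NA` (missing, not 0).
#' @param step_cm Scan grid step in cM.
#' @param n_perm Permutations per trait and regime.
#' @param alpha Experiment-wise type-I error for the LOD threshold.
#' @param window_cm Cofactor exclusion window for the scan.
#' @param n_repeats,n_final_candidates Cofactor-selection settings (see
#'   [select_cofactors()]).
#' @param distortion_alpha Significance level of the segregation-distortion
#'   filter.
#' @param min_peak_separation_cm Peak-merging separation.
#' @param ci_prob Posterior mass of the credible intervals.
#' @param expansion Map-expansion factor for transition probabilities.
#' @param network_lambda Shrinkage for the partial-correlation network.
#' @param seed Integer seed for all randomized stages.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV/CSV files.
#' @return A list of class `iril_pipeline`: `h2` (heritability report
#'   tibble), `aem` (named by regime, wide AEM tibbles), `networks` (named
#'   by regime), `qtl_tables` (named by regime, QTL record tibbles in the
#'   [read_qtl_table()] layout), `scans`, `qc_report`, `summaries`, and the
#'   configuration under `config`.
#' @export
run_pipeline <- function(map, genotypes, phenotypes, annotation = NULL,
                         step_cm = 2, n_perm = 1000, alpha = 0.05,
                         window_cm = 10, n_repeats = 1000,
                         n_final_candidates = 100, distortion_alpha = 0.001,
                         min_peak_separation_cm = 30, ci_prob = 0.95,
                         expansion = 1, network_lambda = 0, seed = 1,
                         out_dir = NULL) {
  stopifnot(step_cm > 0, n_perm >= 20, alpha > 0, alpha < 1, window_cm > 0)
  map <- validate_map(map)
  phenotypes <- validate_phenotypes(phenotypes)
  seed <- as.integer(seed)

  qc <- test_segregation_distortion(genotypes, alpha = distortion_alpha)
  imp <- impute_missing(qc$genotypes, map, expansion = expansion)
  probs <- compute_genotype_probabilities(imp$genotypes, map,
                                          step_cm = step_cm,
                                          expansion = expansion)
  regimes <- unique(phenotypes$regime)
  traits <- unique(phenotypes$trait)

  herit <- heritability_report(phenotypes)
  aem_by_regime <- list()
  networks <- list()
  qtl_tables <- list()
  scans <- list()

  for (rg in regimes) {
    fits <- herit$fits[paste(traits, rg, sep = ".")]
    fits <- fits[!vapply(fits, is.null, TRUE)]
    aem_wide <- aem_table(fits)
    aem_by_regime[[rg]] <- aem_wide
    networks[[rg]] <- if (length(fits) >= 3) {
      partial_correlation_network(aem_wide, lambda = network_lambda)
    } else {
      NULL
    }
    records <- list()
    for (ti in seq_along(fits)) {
      fit <- fits[[ti]]
      tr <- fit$trait
      trait_seed <- seed + 1000L * match(rg, regimes) + ti
      aem_one <- fit$aem
      cof <- select_cofactors(imp$genotypes, aem_one, map,
                              n_repeats = n_repeats,
                              n_final_candidates = n_final_candidates,
                              seed = trait_seed,
                              dosage = imp$dosage)
      thr <- permutation_threshold(probs, aem_one, cof$cofactors,
                                   n_perm = n_perm, alpha = alpha,
                                   window_cm = window_cm,
                                   seed = trait_seed + 500L)
      sc <- mqm_scan(probs, aem_one, cof$cofactors, window_cm = window_cm,
                     threshold = as.numeric(thr))
      scans[[paste(tr, rg, sep = ".")]] <- sc
      peaks <- call_qtl_peaks(sc, as.numeric(thr),
                              min_peak_separation_cm = min_peak_separation_cm)
      if (!nrow(peaks)) next
      fitq <- fit_multi_qtl(probs, aem_one, peaks)
      qtl <- fitq$qtl
      ci <- purrr::map_dfr(seq_len(nrow(qtl)), function(q) {
        bayes_credible_interval(sc, qtl$chrom[q], qtl$pos_cm[q], map,
                                prob = ci_prob)
      })
      genes <- purrr::map_int(seq_len(nrow(ci)), function(q) {
        if (is.null(annotation) || is.na(ci$phys_lo[q])) {
          return(NA_integer_)
        }
        nrow(genes_in_interval(annotation, ci$chrom[q],
                               ci$phys_lo[q], ci$phys_hi[q]))
      })
      peak_lods <- qtl_peak_lod(peaks, qtl)
      records[[tr]] <- tibble::tibble(
        trait = tr, qtl = seq_len(nrow(.env$qtl)),
        chrom = as.character(.env$qtl$chrom), pos_cm = .env$qtl$pos_cm,
        add = .env$qtl$add, add_censored = FALSE,
        r2_pct = .env$qtl$r2_pct, r2_censored = FALSE,
        ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
        marker_lo = ci$marker_lo, marker_hi = ci$marker_hi,
        phys_lo = ci$phys_lo, phys_hi = ci$phys_hi,
        genes = genes, total_r2_pct = fitq$total_r2_pct,
        lod = peak_lods, threshold = as.numeric(thr)
      )
    }
    qtl_tables[[rg]] <- if (length(records)) {
      dplyr::bind_rows(records)
    } else {
      tibble::tibble()
    }
  }
  summaries <- purrr::map(qtl_tables, summarize_qtl_table)
  out <- structure(
    list(h2 = herit$h2, aem = aem_by_regime, networks = networks,
         qtl_tables = qtl_tables, scans = scans, qc_report = qc$report,
         summaries = summaries,
         config = list(step_cm = step_cm, n_perm = n_perm, alpha = alpha,
                       window_cm = window_cm, n_repeats = n_repeats,
                       n_final_candidates = n_final_candidates,
                       distortion_alpha = distortion_alpha,
                       min_peak_separation_cm = min_peak_separation_cm,
                       ci_prob = ci_prob, expansion = expansion,
                       network_lambda = network_lambda, seed = seed)),
    class = "iril_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

qtl_peak_lod <- function(peaks, qtl) {
  peaks$lod[match(paste(qtl$chrom, qtl$pos_cm),
                  paste(peaks$chrom, peaks$pos_cm))]
}

#' Write all pipeline outputs to a directory
#'
#' @param result An `iril_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "iril_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$h2, file.path(out_dir, "heritability.tsv"))
  readr::write_tsv(result$qc_report, file.path(out_dir, "qc_report.tsv"))
  for (rg in names(result$aem)) {
    readr::write_csv(result$aem[[rg]],
                     file.path(out_dir, sprintf("aem_%s.csv", rg)))
    if (!is.null(result$networks[[rg]])) {
      readr::write_tsv(tidy(result$networks[[rg]]),
                       file.path(out_dir, sprintf("network_%s.tsv", rg)))
    }
    render_qtl_table(result$qtl_tables[[rg]],
                     file.path(out_dir, sprintf("qtl_%s.tsv", rg)))
  }
  jsonlite::write_json(result$config,
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.iril_pipeline <- function(x, ...) {
  cat("<iril_pipeline>\n")
  for (rg in names(x$qtl_tables)) {
    s <- x$summaries[[rg]]
    cat(sprintf("  %s: %d QTL across %d traits\n", rg, s$n_qtl,
                length(unique(x$qtl_tables[[rg]]$trait))))
  }
  invisible(x)
}
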