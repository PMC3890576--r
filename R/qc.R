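#' Test and filter segregation distortion
#'
#' In a biparental inbred population every marker is expected to segregate
#' 1:1 between the two parental allele classes.  For each marker the counts
#' of `A` and `B` calls (heterozygous and missing calls excluded) are tested
#' with a 1-df chi-square goodness-of-fit against 1:1, and markers with
#' `p < alpha` are removed, mirroring the distortion filter applied to the
#' IBM map before QTL mapping (there at `alpha = 0.001`).  Markers with no
#' informative calls are excluded with status `"no_data"` rather than tested.
#'
#' @param genotypes Wide genotype tibble.
#' @param alpha Significance level below which a marker is excluded.
#' @return A list with `report` (tibble: `marker`, `n_a`, `n_b`, `chisq`,
#'   `p`, `status` in kept/excluded/no_data) and `genotypes` (the filtered
#'   matrix).  Filtering is idempotent.
#' @examples
#' spec <- sim_spec(n_chromosomes = 1, chrom_lengths = 50,
#'                  n_markers_per_chrom = 6, n_lines = 40, seed = 2)
#' geno <- simulate_iril_genotypes(simulate_genetic_map(spec), spec)
#' test_segregation_distortion(geno)$report
#' @export
test_segregation_distortion <- function(genotypes, alpha = 0.001) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  calls <- geno_calls(genotypes)
  if (nrow(calls) < 2) abort("need at least 2 lines.")
  n_a <- colSums(calls == "A")
  n_b <- colSums(calls == "B")
  n <- n_a + n_b
  chisq <- unname(ifelse(n > 0, (n_a - n_b)^2 / n, NA_real_))
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  status <- dplyr::case_when(
    n == 0 ~ "no_data",
    p < alpha ~ "excluded",
    TRUE ~ "kept"
  )
  report <- tibble::tibble(
    marker = colnames(calls),
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    chisq = chisq,
    p = p,
    status = status
  )
  keep <- report$marker[report$status == "kept"]
  geno_kept <- dplyr::select(tibble::as_tibble(genotypes),
                             "line", dplyr::all_of(keep))
  list(report = report, genotypes = geno_kept)
}

#' Impute missing genotype calls from flanking markers
#'
#' Replaces each missing call by its conditional expected dosage
#' `E[x] = 2 P(A) - 1` given the nearest non-missing homozygous flanking
#' markers on the same chromosome, under the two-state RIL transition model
#' (`ril_transition()` of the Haldane distance, optionally scaled by a map
#' expansion factor).  At chromosome ends the single available flank is
#' used; a line with no informative call on a chromosome gets dosage 0 for
#' that chromosome with a warning.  Observed calls are never altered.  Hard
#' calls (`A`/`B`) are written back only where `|E[x]|` exceeds
#' `hard_call_threshold`; elsewhere the fractional dosage is retained for
#' regression.
#'
#' @param genotypes Wide genotype tibble (QC-filtered).
#' @param map Map tibble covering the markers.
#' @param expansion Map-expansion factor applied to distances.
#' @param hard_call_threshold `|E[x]|` above which a missing call is
#'   replaced by a hard call (default 0.98).
#' @return A list with `genotypes` (hard calls filled in) and `dosage`
#'   (numeric lines-by-markers matrix in `[-1, 1]`, observed calls coded
#'   +1/-1/0, missing calls as fractional expectations).
#' @export
impute_missing <- function(genotypes, map, expansion = 1,
                           hard_call_threshold = 0.98) {
  map <- validate_map(map)
  calls <- geno_calls(genotypes)
  mk <- colnames(calls)
  missing_from_map <- setdiff(mk, map$marker)
  if (length(missing_from_map)) {
    abort(sprintf("markers absent from the map: %s",
                  paste(head(missing_from_map, 5), collapse = ", ")))
  }
  map <- map[match(mk, map$marker), ] # genotype column order
  dos <- matrix(.dosage_code(calls), nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  bare_lines <- character(0)
  for (cc in unique(map$chrom)) {
    jj <- which(map$chrom == cc)
    pos <- map$pos_cm[jj]
    sub <- calls[, jj, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      miss <- which(sub[i, ] == "-")
      if (!length(miss)) next
      inf <- which(sub[i, ] %in% c("A", "B"))
      if (!length(inf)) {
        bare_lines <- c(bare_lines, rownames(sub)[i])
        next # dosage already 0
      }
      pa <- .flank_prob_a(pos[inf], as.integer(sub[i, inf] == "A"),
                          pos[miss], expansion)
      dos[i, jj[miss]] <- 2 * pa - 1
    }
  }
  if (length(bare_lines)) {
    warn(sprintf(
      "%d line/chromosome combinations had no informative call; dosage set to 0 (lines: %s).",
      length(bare_lines), paste(unique(bare_lines), collapse = ", ")
    ))
  }
  hard <- calls
  fill <- calls == "-" & abs(dos) > hard_call_threshold
  hard[fill & dos > 0] <- "A"
  hard[fill & dos < 0] <- "B"
  list(
    genotypes = dplyr::bind_cols(tibble::tibble(line = rownames(hard)),
                                 tibble::as_tibble(hard)),
    dosage = dos
  )
}
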