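#' Forward-backward stepwise selection by BIC
#'
#' Greedy model search over candidate predictor columns for a linear model
#' with intercept: at each step the single addition or deletion that most
#' lowers \eqn{BIC = n \ln(RSS/n) + k \ln(n)} (`k` = number of selected
#' predictors) is applied, until no move improves it.  Ties are broken
#' toward the lower column index; rank-deficient additions (collinear
#' candidates) are skipped.
#'
#' @param x Numeric candidate matrix (observations x candidates) with
#'   column names; candidates should be de-duplicated.
#' @param y Numeric response.
#' @return List with `selected` (column names, possibly empty), `bic` of
#'   the final model, and `bic_null` of the intercept-only model.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("m", 1:4)))
#' y <- x[, 2] * 2 + rnorm(50, sd = 0.1)
#' stepwise_bic(x, y)$selected
#' @export
stepwise_bic <- function(x, y) {
  x <- as.matrix(x)
  n <- length(y)
  if (n <= 2) abort("need more than 2 observations.")
  if (nrow(x) != n) abort("`x` and `y` sizes disagree.")
  p <- ncol(x)
  bic_of <- function(cols) {
    z <- cbind(1, x[, cols, drop = FALSE])
    qz <- qr(z)
    if (qz$rank < ncol(z)) {
      return(NA_real_) # collinear: not a valid move
    }
    rss <- sum(qr.resid(qz, y)^2)
    n * log(rss / n) + length(cols) * log(n)
  }
  cur <- integer(0)
  cur_bic <- bic_of(cur)
  bic_null <- cur_bic
  repeat {
    best_bic <- cur_bic
    best_cols <- NULL
    for (j in seq_len(p)) { # additions first, in index order: ties go low
      if (j %in% cur) next
      cand <- bic_of(c(cur, j))
      if (!is.na(cand) && cand < best_bic - 1e-10) {
        best_bic <- cand
        best_cols <- c(cur, j)
      }
    }
    for (j in cur) {
      cand <- bic_of(setdiff(cur, j))
      if (!is.na(cand) && cand < best_bic - 1e-10) {
        best_bic <- cand
        best_cols <- setdiff(cur, j)
      }
    }
    if (is.null(best_cols)) break
    cur <- best_cols
    cur_bic <- best_bic
  }
  list(selected = if (length(cur)) colnames(x)[sort(cur)] else character(0),
       bic = cur_bic, bic_null = bic_null)
}

#' Randomized bin-based cofactor selection
#'
#' Selects marker cofactors for the composite-interval scan when there are
#' far more markers than lines, by the three-stage randomized procedure:
#' (1) for each of `n_repeats` repetitions, draw one random marker per map
#' bin and run forward-backward stepwise selection by BIC on this thinned
#' set; (2) let `m*` be the rounded mean number of cofactors selected per
#' repetition and keep the `m*` bins with the highest selection frequency;
#' (3) draw up to `n_final_candidates` markers at random from those bins and
#' run one final stepwise-BIC selection, which yields the cofactor set.
#'
#' @param genotypes Wide genotype tibble (post-QC; missing calls count as
#'   dosage 0 unless `dosage` is supplied).
#' @param aem Per-line trait values: tibble with `line` and a value column
#'   (`aem` or `value`); lines with missing values are dropped.
#' @param map Map tibble with a `bin` column assigning every marker to a
#'   sampling stratum.
#' @param n_repeats Stage-1 repetitions (default 1000 as in the emulated
#'   analysis; scale down for quick runs).
#' @param n_final_candidates Markers drawn from the retained bins for the
#'   final selection (default 100; truncated with a warning when it is not
#'   well below the number of lines).
#' @param seed Optional integer seed for the randomized stages.
#' @param dosage Optional precomputed dosage matrix (lines x markers), e.g.
#'   the fractional dosages from [impute_missing()].
#' @return An object of class `iril_cofactors`: list with `cofactors`
#'   (marker names), `bin_frequency` (tibble `bin`, `frequency`), `m_star`,
#'   `selected_bins`, `n_repeats`.
#' @export
select_cofactors <- function(genotypes, aem, map, n_repeats = 1000,
                             n_final_candidates = 100, seed = NULL,
                             dosage = NULL) {
  map <- validate_map(map)
  if (!"bin" %in% names(map) || all(is.na(map$bin))) {
    abort("cofactor selection needs a `bin` column on the map.")
  }
  if (!is.null(seed)) set.seed(seed)
  aem <- tibble::as_tibble(aem)
  val_col <- intersect(c("aem", "value"), names(aem))[1]
  if (is.na(val_col) || !"line" %in% names(aem)) {
    abort("`aem` needs columns `line` and `aem` (or `value`).")
  }
  aem <- aem[!is.na(aem[[val_col]]), ]
  if (is.null(dosage)) dosage <- geno_dosage(genotypes)
  lines <- intersect(rownames(dosage), aem$line)
  if (length(lines) <= 2) abort("need more than 2 lines with phenotype data.")
  x <- dosage[lines, , drop = FALSE]
  y <- aem[[val_col]][match(lines, aem$line)]
  map <- map[map$marker %in% colnames(x), ]
  bins <- split(map$marker, map$bin)
  if (!length(bins)) abort("no bins defined for the genotyped markers.")

  counts <- integer(n_repeats)
  hits <- setNames(numeric(length(bins)), names(bins))
  for (rep_i in seq_len(n_repeats)) {
    picked <- vapply(bins, function(mm) mm[sample.int(length(mm), 1L)], "")
    sel <- stepwise_bic(x[, picked, drop = FALSE], y)$selected
    counts[rep_i] <- length(sel)
    if (length(sel)) {
      sel_bins <- names(picked)[match(sel, picked)]
      hits[sel_bins] <- hits[sel_bins] + 1
    }
  }
  freq <- hits / n_repeats
  bin_frequency <- tibble::tibble(bin = names(freq), frequency = unname(freq)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$bin)
  m_star <- as.integer(round(mean(counts)))

  cofactors <- character(0)
  selected_bins <- character(0)
  if (m_star > 0) {
    selected_bins <- bin_frequency$bin[seq_len(min(m_star, nrow(bin_frequency)))]
    pool <- unlist(bins[selected_bins], use.names = FALSE)
    n_cand <- min(n_final_candidates, length(pool))
    if (n_cand >= length(lines) - 1) {
      n_cand <- length(lines) - 2L
      warn(sprintf("final candidate count truncated to %d (only %d lines).",
                   n_cand, length(lines)))
    }
    cand <- if (n_cand < length(pool)) sort(sample(pool, n_cand)) else sort(pool)
    cofactors <- stepwise_bic(x[, cand, drop = FALSE], y)$selected
  }
  structure(
    list(cofactors = cofactors, bin_frequency = bin_frequency,
         m_star = m_star, selected_bins = selected_bins,
         n_repeats = n_repeats, mean_selected = mean(counts)),
    class = "iril_cofactors"
  )
}

#' @export
print.iril_cofactors <- function(x, ...) {
  cat(sprintf("<iril_cofactors> m* = %d (mean %.2f over %d repetitions); %d cofactors: %s\n",
              x$m_star, x$mean_selected, x$n_repeats, length(x$cofactors),
              paste(x$cofactors, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.iril_cofactors <- function(x, ...) x$bin_frequency
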