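#' Composite-interval multiple-QTL genome scan
#'
#' Haley-Knott regression scan: at every grid position the phenotype is
#' regressed on the expected dosage `E[x]` at that position plus the dosages
#' of the selected marker cofactors, excluding any cofactor lying within
#' `window_cm` of the test position on the same chromosome (so a cofactor
#' never absorbs the signal it sits on).  The reduced model keeps the same
#' included cofactors without the test position, and
#' \deqn{LOD = (n/2) \log_{10}(RSS_{reduced} / RSS_{full}).}
#' At a fully observed marker this equals the exact single-marker regression
#' LOD.  Positions with constant dosage (after adjusting for cofactors) get
#' LOD 0.
#'
#' @param probs An `iril_genoprob` grid from
#'   [compute_genotype_probabilities()].
#' @param aem Per-line trait values (tibble `line` + `aem`/`value` column);
#'   lines missing from either input are dropped.
#' @param cofactors Character vector of cofactor marker names (must be on
#'   the grid), e.g. from [select_cofactors()]; may be empty.
#' @param window_cm Exclusion window around the test position in cM
#'   (default 10).
#' @param threshold Optional genome-wide LOD threshold to attach (e.g. from
#'   [permutation_threshold()]).
#' @return A tibble of class `iril_scan` with columns `chrom`, `pos_cm`,
#'   `marker`, `lod` and attributes `n`, `cofactors`, `window_cm`,
#'   `threshold`.
#' @export
mqm_scan <- function(probs, aem, cofactors = character(), window_cm = 10,
                     threshold = NULL) {
  prep <- .scan_prepare(probs, aem, cofactors)
  lod <- .hk_lod_matrix(prep$dos, probs$grid, prep$cof_cols, window_cm,
                        cbind(prep$y))
  out <- tibble::tibble(
    chrom = probs$grid$chrom,
    pos_cm = probs$grid$pos_cm,
    marker = probs$grid$marker,
    lod = as.vector(lod)
  )
  if (inherits(cofactors, "iril_cofactors")) cofactors <- cofactors$cofactors
  structure(out, class = c("iril_scan", class(out)),
            n = length(prep$y), cofactors = cofactors,
            window_cm = window_cm, threshold = threshold)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Determines the experiment-wise type-I error threshold for the scan:
#' the phenotype vector is permuted across lines (leaving the genotype
#' matrix and the cofactor set intact), the full composite-interval scan is
#' rerun, and the genome-wide maximum LOD is recorded; the threshold is the
#' empirical `1 - alpha` quantile (linear-interpolation / type-7 quantile)
#' of those maxima.  The emulated analysis used 1000 permutations per trait
#' and regime at `alpha = 0.05`.
#'
#' @inheritParams mqm_scan
#' @param n_perm Number of permutations (at least 20).
#' @param alpha Experiment-wise type-I error rate.
#' @param seed Optional integer seed for the permutations.
#' @return The LOD threshold (scalar) with attributes `max_lods` (the
#'   permutation distribution of genome-wide maxima), `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(probs, aem, cofactors = character(),
                                  n_perm = 1000, alpha = 0.05,
                                  window_cm = 10, seed = NULL) {
  if (n_perm < 20) abort("`n_perm` must be at least 20 for a usable quantile.")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  if (!is.null(seed)) set.seed(seed)
  prep <- .scan_prepare(probs, aem, cofactors)
  n <- length(prep$y)
  ymat <- vapply(seq_len(n_perm), function(i) prep$y[sample.int(n)],
                 numeric(n))
  lod <- .hk_lod_matrix(prep$dos, probs$grid, prep$cof_cols, window_cm, ymat)
  max_lods <- apply(lod, 2, max)
  thr <- quantile(max_lods, probs = 1 - alpha, type = 7, names = FALSE)
  structure(thr, max_lods = max_lods, n_perm = n_perm, alpha = alpha)
}

# shared input matching for scan functions
.scan_prepare <- function(probs, aem, cofactors) {
  stopifnot(inherits(probs, "iril_genoprob"))
  if (inherits(cofactors, "iril_cofactors")) cofactors <- cofactors$cofactors
  aem <- tibble::as_tibble(aem)
  val_col <- intersect(c("aem", "value"), names(aem))[1]
  if (is.na(val_col) || !"line" %in% names(aem)) {
    abort("`aem` needs columns `line` and `aem` (or `value`).")
  }
  aem <- aem[!is.na(aem[[val_col]]), ]
  lines <- intersect(probs$lines, aem$line)
  if (length(lines) < 3) abort("need at least 3 lines with phenotype data.")
  dos <- grid_dosage(probs)[match(lines, probs$lines), , drop = FALSE]
  y <- aem[[val_col]][match(lines, aem$line)]
  cof_cols <- integer(0)
  if (length(cofactors)) {
    cof_cols <- match(cofactors, probs$grid$marker)
    if (anyNA(cof_cols)) {
      abort(sprintf("cofactor markers not on the grid: %s",
                    paste(cofactors[is.na(cof_cols)], collapse = ", ")))
    }
  }
  list(dos = dos, y = y, cof_cols = cof_cols)
}

# LOD matrix (positions x phenotype columns) for the Haley-Knott scan.
# Positions sharing the same included-cofactor set are processed together:
# by Frisch-Waugh-Lovell, after residualising y and the test dosage on the
# included cofactors, LOD = -(n/2) log10(1 - r^2) with r the residual
# correlation; this is algebraically identical to the two-RSS form.
.hk_lod_matrix <- function(dos, grid, cof_cols, window_cm, ymat) {
  n <- nrow(dos)
  np <- nrow(grid)
  lod <- matrix(0, np, ncol(ymat))
  if (length(cof_cols)) {
    cpos <- grid$pos_cm[cof_cols]
    cchr <- grid$chrom[cof_cols]
    excl_key <- vapply(seq_len(np), function(p) {
      paste(which(cchr == grid$chrom[p] &
                    abs(cpos - grid$pos_cm[p]) < window_cm), collapse = ",")
    }, "")
  } else {
    excl_key <- rep("", np)
  }
  for (key in unique(excl_key)) {
    cols <- which(excl_key == key)
    excluded <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    use <- setdiff(seq_along(cof_cols), excluded)
    z <- cbind(rep(1, n), dos[, cof_cols[use], drop = FALSE])
    qz <- qr(z)
    yres <- qr.resid(qz, ymat)
    gres <- qr.resid(qz, dos[, cols, drop = FALSE])
    css <- colSums(gres^2)
    rss <- colSums(yres^2)
    num <- crossprod(gres, yres)^2 # |cols| x K
    r2 <- num / outer(pmax(css, .Machine$double.xmin),
                      pmax(rss, .Machine$double.xmin))
    r2[css < 1e-10, ] <- 0
    r2[, rss < 1e-10] <- 0
    r2 <- pmin(r2, 1 - 1e-15)
    lod[cols, ] <- -(n / 2) * log10(1 - r2)
  }
  lod
}

#' @export
print.iril_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("<iril_scan> %d positions on %d chromosomes, n = %d, %d cofactors%s\n",
              nrow(x), length(unique(x$chrom)), attr(x, "n"),
              length(attr(x, "cofactors")),
              if (is.null(thr)) "" else sprintf(", threshold %.2f", thr)))
  NextMethod()
}
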