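#' Call QTL peaks from a scan profile
#'
#' Local maxima of the LOD profile with `lod >= threshold` are peak
#' candidates; candidates on the same chromosome closer than
#' `min_peak_separation_cm` are merged to the higher peak (ties broken
#' toward the lower cM position).
#'
#' @param scan An `iril_scan` tibble from [mqm_scan()].
#' @param threshold Genome-wide LOD threshold; defaults to the threshold
#'   attached to the scan.
#' @param min_peak_separation_cm Minimum separation between distinct peaks
#'   on one chromosome (default 30 cM).
#' @return Tibble of peaks: `chrom`, `pos_cm`, `marker`, `lod` (possibly
#'   zero rows).
#' @export
call_qtl_peaks <- function(scan, threshold = NULL,
                           min_peak_separation_cm = 30) {
  threshold <- threshold %||% attr(scan, "threshold")
  if (is.null(threshold)) abort("no `threshold` given or attached to the scan.")
  out <- purrr::map_dfr(unique(scan$chrom), function(cc) {
    sub <- scan[scan$chrom == cc, ]
    lod <- sub$lod
    k <- length(lod)
    left <- c(-Inf, lod[-k])
    right <- c(lod[-1], -Inf)
    is_peak <- lod >= left & lod >= right & lod >= threshold
    # plateaus: keep only the first (lowest-cM) point of a run of equal LOD
    if (any(is_peak)) {
      idx <- which(is_peak)
      drop <- idx[c(FALSE, diff(idx) == 1 & diff(lod[idx]) == 0)]
      is_peak[drop] <- FALSE
    }
    pk <- sub[is_peak, ]
    while (nrow(pk) > 1 && any(diff(pk$pos_cm) < min_peak_separation_cm)) {
      j <- which(diff(pk$pos_cm) < min_peak_separation_cm)[1]
      loser <- if (pk$lod[j] >= pk$lod[j + 1]) j + 1L else j
      pk <- pk[-loser, ]
    }
    pk
  })
  tibble::as_tibble(out)[c("chrom", "pos_cm", "marker", "lod")]
}

#' Bayesian credible interval for a QTL location
#'
#' Treats `10^LOD`, normalised over the peak's chromosome grid, as a
#' posterior for the QTL location and takes the smallest contiguous set of
#' grid positions containing the peak whose posterior mass reaches `prob`
#' (grown greedily from the peak toward the higher-mass neighbour).  The
#' interval endpoints are then expanded outward to the nearest flanking
#' marker positions, whose physical (`bp`) coordinates give the physical
#' interval, as in the reporting convention of the emulated study.
#'
#' @param scan An `iril_scan` tibble.
#' @param chrom Chromosome of the peak.
#' @param peak_cm Peak position in cM (nearest grid point is used).
#' @param map Map tibble (for flanking markers and physical coordinates).
#' @param prob Posterior mass of the interval (default 0.95).
#' @return One-row tibble: `chrom`, `peak_cm`, `ci_grid_lo`, `ci_grid_hi`
#'   (grid endpoints), `ci_lo`, `ci_hi` (flanking-marker positions),
#'   `marker_lo`, `marker_hi`, `phys_lo`, `phys_hi` (bp, `NA` when the map
#'   has no physical coordinates).
#' @export
bayes_credible_interval <- function(scan, chrom, peak_cm, map, prob = 0.95) {
  if (prob <= 0 || prob > 1) abort("`prob` must lie in (0, 1].")
  map <- validate_map(map)
  sub <- scan[scan$chrom == chrom, ]
  if (!nrow(sub)) abort("no scan positions on that chromosome.")
  lod <- sub$lod
  pos <- sub$pos_cm
  if (diff(range(lod)) < 1e-8) {
    warn("flat LOD profile; returning the whole chromosome.")
    lo <- 1L
    hi <- length(pos)
  } else {
    w <- 10^(lod - max(lod))
    w <- w / sum(w)
    ipk <- which.min(abs(pos - peak_cm))
    lo <- hi <- ipk
    mass <- w[ipk]
    while (mass < prob && (lo > 1L || hi < length(w))) {
      wl <- if (lo > 1L) w[lo - 1L] else -Inf
      wr <- if (hi < length(w)) w[hi + 1L] else -Inf
      if (wl >= wr) {
        lo <- lo - 1L
        mass <- mass + w[lo]
      } else {
        hi <- hi + 1L
        mass <- mass + w[hi]
      }
    }
  }
  mpos <- map$pos_cm[map$chrom == chrom]
  mnames <- map$marker[map$chrom == chrom]
  if (!length(mpos)) abort("no markers on that chromosome in the map.")
  li <- findInterval(pos[lo] + 1e-9, mpos)
  li <- max(li, 1L)
  hi_idx <- findInterval(pos[hi] - 1e-9, mpos) + 1L
  hi_idx <- min(hi_idx, length(mpos))
  bp <- if ("bp" %in% names(map)) map$bp[map$chrom == chrom] else rep(NA, length(mpos))
  tibble::tibble(
    chrom = chrom, peak_cm = pos[which.min(abs(pos - peak_cm))],
    prob = prob,
    ci_grid_lo = pos[lo], ci_grid_hi = pos[hi],
    ci_lo = mpos[li], ci_hi = mpos[hi_idx],
    marker_lo = mnames[li], marker_hi = mnames[hi_idx],
    phys_lo = bp[li], phys_hi = bp[hi_idx]
  )
}

#' Simultaneous multi-QTL fit
#'
#' Joint regression of the phenotype on the expected dosages at all called
#' peak positions.  The additive effect of each QTL is the coefficient on
#' the `{-1, +1}` dosage (half the difference between the two homozygote
#' class means; positive = parent-A/B73 allele increases the trait); the
#' per-QTL explained variance is the drop-one increase in residual sum of
#' squares over the total sum of squares, and the total explained variance
#' is the model R-squared.
#'
#' @param probs An `iril_genoprob` grid.
#' @param aem Per-line trait values (tibble `line` + `aem`/`value`).
#' @param peaks Tibble of peaks (`chrom`, `pos_cm`), e.g. from
#'   [call_qtl_peaks()].
#' @return Object of class `iril_qtl_fit`: list with `qtl` (tibble `chrom`,
#'   `pos_cm`, `add`, `r2_pct`), `total_r2_pct`, `n`.  [tidy()] returns the
#'   per-QTL table, [glance()] the totals.
#' @export
fit_multi_qtl <- function(probs, aem, peaks) {
  if (!nrow(peaks)) abort("need at least one peak.")
  prep <- .scan_prepare(probs, aem, character())
  grid <- probs$grid
  cols <- vapply(seq_len(nrow(peaks)), function(q) {
    on_chr <- which(grid$chrom == peaks$chrom[q])
    if (!length(on_chr)) abort("peak chromosome absent from the grid.")
    on_chr[which.min(abs(grid$pos_cm[on_chr] - peaks$pos_cm[q]))]
  }, integer(1))
  x <- prep$dos[, cols, drop = FALSE]
  keep <- seq_len(ncol(x))
  qz <- qr(cbind(1, x))
  while (qz$rank < length(keep) + 1L) {
    warn("collinear peak dosages; dropping the later peak.")
    keep <- keep[-length(keep)]
    qz <- qr(cbind(1, x[, keep, drop = FALSE]))
  }
  y <- prep$y
  n <- length(y)
  xk <- x[, keep, drop = FALSE]
  fit <- lm.fit(cbind(`(Intercept)` = 1, xk), y)
  rss_full <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2_pct <- vapply(seq_along(keep), function(q) {
    z <- cbind(1, xk[, -q, drop = FALSE])
    rss_red <- sum(qr.resid(qr(z), y)^2)
    100 * (rss_red - rss_full) / tss
  }, numeric(1))
  qtl <- tibble::tibble(
    chrom = peaks$chrom[keep],
    pos_cm = grid$pos_cm[cols[keep]],
    add = unname(fit$coefficients[-1]),
    r2_pct = r2_pct
  )
  structure(
    list(qtl = qtl, total_r2_pct = 100 * (1 - rss_full / tss), n = n),
    class = "iril_qtl_fit"
  )
}

#' @export
print.iril_qtl_fit <- function(x, ...) {
  cat(sprintf("<iril_qtl_fit> %d QTL, n = %d, total r2 = %.1f%%\n",
              nrow(x$qtl), x$n, x$total_r2_pct))
  print(x$qtl)
  invisible(x)
}

#' @export
tidy.iril_qtl_fit <- function(x, ...) x$qtl

#' @export
glance.iril_qtl_fit <- function(x, ...) {
  tibble::tibble(n_qtl = nrow(x$qtl), total_r2_pct = x$total_r2_pct, n = x$n)
}

#' Genes overlapping a physical interval
#'
#' Returns the annotation rows whose gene spans overlap the closed physical
#' interval `[start_bp, end_bp]` on `chrom` (any overlap; 1-based inclusive
#' coordinates).
#'
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param chrom Chromosome label.
#' @param start_bp,end_bp Interval bounds in bp (inclusive).
#' @return Tibble of overlapping genes (possibly zero rows).
#' @export
genes_in_interval <- function(annotation, chrom, start_bp, end_bp) {
  if (is.null(annotation)) abort("no annotation supplied.")
  ann <- tibble::as_tibble(annotation)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(ann))) {
    abort(sprintf("annotation needs columns %s.", paste(need, collapse = ", ")))
  }
  ann[ann$chrom == chrom & ann$start <= end_bp & ann$end >= start_bp, ]
}
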