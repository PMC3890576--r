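#' Read a QTL summary table
#'
#' Parses a tab-separated QTL table in the layout used by the package's
#' reports (and by the transcribed published summary tables shipped under
#' `inst/extdata/`): one row per QTL with columns `trait`, `qtl`, `chrom`,
#' `pos_cm`, `add`, `r2_pct`, `ci_lo`, `ci_hi`, `marker_lo`, `marker_hi`,
#' `phys_lo`, `phys_hi`, `genes`, plus one `Total` row per trait carrying
#' the simultaneous-fit total explained variance in `r2_pct`.  Effects and
#' variance percentages printed as censored values (`< 0.1`, `- < 0.1`) are
#' parsed to numeric `+-0.05` with a censoring flag so that rendering
#' round-trips losslessly.
#'
#' @param path TSV file path.
#' @return Tibble of QTL records with numeric columns, logical
#'   `add_censored` / `r2_censored`, and `total_r2_pct` repeated on every
#'   row of a trait.
#' @examples
#' t2 <- read_qtl_table(system.file("extdata", "table2_qtl_deficient.tsv",
#'                                  package = "irilqtl"))
#' summarize_qtl_table(t2)
#' @export
read_qtl_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("QTL table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("trait", "qtl", "chrom", "pos_cm", "add", "r2_pct",
            "ci_lo", "ci_hi", "marker_lo", "marker_hi",
            "phys_lo", "phys_hi", "genes")
  if (!all(need %in% names(raw))) {
    abort(sprintf("QTL table needs columns %s.", paste(need, collapse = ", ")))
  }
  totals <- raw[raw$qtl == "Total", ]
  total_map <- setNames(as.numeric(totals$r2_pct), totals$trait)
  rec <- raw[raw$qtl != "Total", ]
  add_parsed <- .parse_printed(rec$add)
  r2_parsed <- .parse_printed(rec$r2_pct)
  tibble::tibble(
    trait = rec$trait,
    qtl = as.integer(rec$qtl),
    chrom = rec$chrom,
    pos_cm = as.numeric(rec$pos_cm),
    add = add_parsed$value,
    add_censored = add_parsed$censored,
    r2_pct = r2_parsed$value,
    r2_censored = r2_parsed$censored,
    ci_lo = as.numeric(rec$ci_lo),
    ci_hi = as.numeric(rec$ci_hi),
    marker_lo = rec$marker_lo,
    marker_hi = rec$marker_hi,
    phys_lo = as.numeric(rec$phys_lo),
    phys_hi = as.numeric(rec$phys_hi),
    genes = as.integer(rec$genes),
    total_r2_pct = unname(total_map[rec$trait])
  )
}

# printed effect/variance values: plain numbers or the censored forms
# "< 0.1" and "- < 0.1"; censored magnitudes are represented as 0.05
.parse_printed <- function(x) {
  x <- stringr::str_trim(x)
  censored <- stringr::str_detect(x, "<")
  neg <- stringr::str_detect(x, "^-")
  value <- suppressWarnings(as.numeric(x))
  value[censored] <- ifelse(neg[censored], -0.05, 0.05)
  list(value = value, censored = censored)
}

.format_printed <- function(value, censored, digits = 1) {
  out <- formatC(value, format = "f", digits = digits)
  out[censored & value >= 0] <- "< 0.1"
  out[censored & value < 0] <- "- < 0.1"
  out
}

#' Write a QTL summary table
#'
#' Renders QTL records (as returned by [read_qtl_table()] or assembled by
#' [run_pipeline()]) to the tab-separated report layout: positions,
#' additive effects, explained variances and interval bounds at one
#' decimal, physical coordinates as integers, one `Total` row per trait
#' carrying the simultaneous-fit total.  `read_qtl_table(render_qtl_table(x))`
#' reproduces `x` at the printed precision.
#'
#' @param tbl QTL record tibble (the `total_r2_pct` column feeds the Total
#'   rows; censoring flags are optional).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
render_qtl_table <- function(tbl, path) {
  tbl <- tibble::as_tibble(tbl)
  if (!nrow(tbl)) {
    readr::write_tsv(tibble::tibble(
      trait = character(), qtl = character(), chrom = character(),
      pos_cm = character(), add = character(), r2_pct = character(),
      ci_lo = character(), ci_hi = character(), marker_lo = character(),
      marker_hi = character(), phys_lo = character(), phys_hi = character(),
      genes = character()
    ), path)
    return(invisible(path))
  }
  add_cen <- tbl$add_censored %||% rep(FALSE, nrow(tbl))
  r2_cen <- tbl$r2_censored %||% rep(FALSE, nrow(tbl))
  fmt_int <- function(x) ifelse(is.na(x), "", formatC(x, format = "d"))
  rows <- tibble::tibble(
    trait = tbl$trait,
    qtl = as.character(tbl$qtl),
    chrom = as.character(tbl$chrom),
    pos_cm = formatC(tbl$pos_cm, format = "f", digits = 1),
    add = .format_printed(tbl$add, add_cen),
    r2_pct = .format_printed(tbl$r2_pct, r2_cen),
    ci_lo = formatC(tbl$ci_lo, format = "f", digits = 1),
    ci_hi = formatC(tbl$ci_hi, format = "f", digits = 1),
    marker_lo = tbl$marker_lo,
    marker_hi = tbl$marker_hi,
    phys_lo = fmt_int(tbl$phys_lo),
    phys_hi = fmt_int(tbl$phys_hi),
    genes = fmt_int(tbl$genes)
  )
  out <- purrr::map_dfr(unique(tbl$trait), function(tr) {
    block <- rows[rows$trait == tr, ]
    total <- tbl$total_r2_pct[tbl$trait == tr][1]
    dplyr::bind_rows(block, tibble::tibble(
      trait = tr, qtl = "Total", chrom = "", pos_cm = "", add = "",
      r2_pct = formatC(total, format = "f", digits = 1),
      ci_lo = "", ci_hi = "", marker_lo = "", marker_hi = "",
      phys_lo = "", phys_hi = "", genes = ""
    ))
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Summarize a QTL table
#'
#' Computes the headline summary of a QTL report: number of QTL, number
#' whose trait-increasing allele comes from parent B/Mo17 (negative
#' additive effect under the B73 = +1 coding), extrema of the
#' simultaneous-fit totals and single-QTL explained variances, confidence
#' interval widths (cM, at the printed one-decimal precision) and gene
#' counts.
#'
#' @param tbl QTL record tibble from [read_qtl_table()] or a pipeline run.
#' @return One-row tibble: `n_qtl`, `n_mo17_increasing`, `max_total_r2`,
#'   `min_total_r2`, `max_single_r2`, `max_ci_width_cm`, `min_ci_width_cm`,
#'   `max_genes`, `min_genes`.  An empty table yields zero counts and `NA`
#'   extrema.
#' @export
summarize_qtl_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!nrow(tbl)) {
    return(tibble::tibble(
      n_qtl = 0L, n_mo17_increasing = 0L, max_total_r2 = NA_real_,
      min_total_r2 = NA_real_, max_single_r2 = NA_real_,
      max_ci_width_cm = NA_real_, min_ci_width_cm = NA_real_,
      max_genes = NA_integer_, min_genes = NA_integer_
    ))
  }
  width <- round(tbl$ci_hi - tbl$ci_lo, 1)
  totals <- tbl$total_r2_pct[!duplicated(tbl$trait)]
  tibble::tibble(
    n_qtl = nrow(tbl),
    n_mo17_increasing = sum(tbl$add < 0),
    max_total_r2 = max(totals, na.rm = TRUE),
    min_total_r2 = min(totals, na.rm = TRUE),
    max_single_r2 = max(tbl$r2_pct, na.rm = TRUE),
    max_ci_width_cm = max(width, na.rm = TRUE),
    min_ci_width_cm = min(width, na.rm = TRUE),
    max_genes = if (all(is.na(tbl$genes))) NA_integer_ else max(tbl$genes, na.rm = TRUE),
    min_genes = if (all(is.na(tbl$genes))) NA_integer_ else min(tbl$genes, na.rm = TRUE)
  )
}

#' Read a heritability table
#'
#' Parses the tab-separated trait/heritability layout (`trait`,
#' `abbreviation`, `unit`, one `H2_<regime>` column per regime), the format
#' of the shipped transcription of the published Table 1.
#'
#' @param path TSV file path.
#' @return Tibble with one row per trait.
#' @export
read_heritability_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("heritability table not found: %s", path))
  readr::read_tsv(path, show_col_types = FALSE)
}
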