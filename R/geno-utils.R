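GENO_CODES <- c("A", "B", "H", "-")

# wide genotype tibble (line + marker columns) -> character matrix with
# line rownames; validates the four-symbol alphabet
geno_calls <- function(genotypes) {
  df <- as.data.frame(genotypes)
  if (!"line" %in% names(df)) abort("genotypes need a `line` column.")
  if (anyDuplicated(df$line)) abort("duplicate line identifiers.")
  mk <- setdiff(names(df), "line")
  if (length(mk) == 0) abort("genotypes contain no marker columns.")
  calls <- as.matrix(df[mk])
  mode(calls) <- "character"
  bad <- which(!(calls %in% GENO_CODES | is.na(calls)), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "invalid genotype code '%s' for line '%s', marker '%s' (allowed: %s).",
      calls[bad[1, 1], bad[1, 2]], df$line[bad[1, 1]], mk[bad[1, 2]],
      paste(GENO_CODES, collapse = " ")
    ))
  }
  calls[is.na(calls)] <- "-"
  rownames(calls) <- df$line
  calls
}

.dosage_code <- function(x) {
  out <- rep(0, length(x))
  out[x == "A"] <- 1
  out[x == "B"] <- -1
  out
}

#' Genotype dosage matrix
#'
#' Converts genotype calls to the numeric dosage coding used throughout the
#' mapping engine: `+1` for the parent-A (B73) homozygote, `-1` for parent-B
#' (Mo17), `0` for heterozygous or missing calls.  With this convention a
#' positive additive effect means the B73 allele increases the trait, so
#' Mo17-contributed trait-increasing alleles appear as negative effects.
#'
#' @param genotypes Wide genotype tibble (`line` column + marker columns).
#' @return Numeric matrix, lines as rows (rownames), markers as columns.
#' @export
geno_dosage <- function(genotypes) {
  calls <- geno_calls(genotypes)
  dos <- matrix(.dosage_code(calls), nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  dos
}

# check/normalise a map tibble: required columns, unique names, strictly
# increasing positions within chromosome after sorting
validate_map <- function(map) {
  map <- tibble::as_tibble(map)
  need <- c("marker", "chrom", "pos_cm")
  if (!all(need %in% names(map))) {
    abort(sprintf("map needs columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$marker)) {
    abort(sprintf("duplicate marker names in the map: %s",
                  paste(unique(map$marker[duplicated(map$marker)]),
                        collapse = ", ")))
  }
  map <- dplyr::arrange(map, .data$chrom, .data$pos_cm)
  ties <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(tie = anyDuplicated(.data$pos_cm) > 0)
  if (any(ties$tie)) {
    abort("marker positions must be strictly increasing within a chromosome.")
  }
  map
}
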