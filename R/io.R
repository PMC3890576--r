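#' Read and write genetic maps
#'
#' Maps are tab-separated tables with columns `marker`, `chrom`, `pos_cm` and
#' optionally `bp` (physical coordinate) and `bin` (cofactor sampling
#' stratum, e.g. an IBM2 bin label).  Reading validates uniqueness of marker
#' names and strictly increasing positions within each chromosome and returns
#' the markers sorted in map order.
#'
#' @param path File path.
#' @param map A map tibble.
#' @return `read_map()` returns a map tibble; `write_map()` returns `path`
#'   invisibly.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("map file not found: %s", path))
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           bin = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  validate_map(map)
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  readr::write_tsv(validate_map(map), path)
  invisible(path)
}

#' Read and write genotype matrices
#'
#' Genotype files are comma-separated with lines as rows: a `line` column
#' followed by one column per marker, calls coded `A` / `B` / `H` / `-`
#' (parent-A homozygote, parent-B homozygote, heterozygous, missing).
#' Reading validates the code alphabet (an unknown code raises an error
#' naming the offending line and marker), requires every marker to be on the
#' map, and reorders the marker columns to map order.
#'
#' @param path File path.
#' @param map Map tibble the markers must belong to.
#' @param genotypes Wide genotype tibble.
#' @return `read_genotypes()` returns a wide genotype tibble;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, map) {
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  map <- validate_map(map)
  geno <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (!"line" %in% names(geno)) abort("genotype file needs a `line` column.")
  mk <- setdiff(names(geno), "line")
  missing_from_map <- setdiff(mk, map$marker)
  if (length(missing_from_map)) {
    abort(sprintf("markers in the genotype file but not on the map: %s",
                  paste(head(missing_from_map, 5), collapse = ", ")))
  }
  geno <- geno[c("line", intersect(map$marker, mk))]
  geno_calls(geno) # validates codes, duplicates
  geno
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  geno_calls(genotypes)
  readr::write_csv(genotypes, path)
  invisible(path)
}

#' Read and write long-format phenotype tables
#'
#' Phenotype tables are comma-separated long records with columns `line`,
#' `rep`, `regime`, `trait`, `value`; at most one record per
#' (line, rep, regime, trait) combination.
#'
#' @param path File path.
#' @param pheno Long phenotype tibble.
#' @return `read_phenotypes()` returns a phenotype tibble;
#'   `write_phenotypes()` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  pheno <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             line = readr::col_character(),
                             rep = readr::col_character(),
                             regime = readr::col_character(),
                             trait = readr::col_character(),
                             value = readr::col_double()
                           ))
  validate_phenotypes(pheno)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(validate_phenotypes(pheno), path)
  invisible(path)
}

validate_phenotypes <- function(pheno) {
  pheno <- tibble::as_tibble(pheno)
  need <- c("line", "rep", "regime", "trait", "value")
  if (!all(need %in% names(pheno))) {
    abort(sprintf("phenotypes need columns %s.", paste(need, collapse = ", ")))
  }
  key <- paste(pheno$line, pheno$rep, pheno$regime, pheno$trait, sep = "\r")
  if (anyDuplicated(key)) {
    abort("at most one record per (line, rep, regime, trait) is allowed.")
  }
  pheno
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `start`, `end`; coordinates
#' are 1-based inclusive base pairs (matching the closed physical intervals
#' reported for QTL confidence intervals).
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(ann))) {
    abort(sprintf("annotation needs columns %s.", paste(need, collapse = ", ")))
  }
  ann
}
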