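# Shared fixture builders.  Everything is generated in code under fixed
# seeds; the standard small setting is a 2-chromosome genome with markers
# every 10 cM, enough for linkage structure without slowing the suite.

small_genome_spec <- function(seed, n_lines = 100, effect = 1,
                              qtl = data.frame(chrom = 1, pos_cm = 50,
                                               effect = effect),
                              error_variance = 3, polygenic_variance = 0,
                              n_chromosomes = 2, chrom_lengths = 100,
                              n_markers_per_chrom = 11, ...) {
  sim_spec(
    n_chromosomes = n_chromosomes, chrom_lengths = chrom_lengths,
    n_markers_per_chrom = n_markers_per_chrom, n_lines = n_lines,
    qtl_effects = qtl, polygenic_variance = polygenic_variance,
    error_variance = error_variance, seed = seed, ...
  )
}

small_dataset <- function(seed, ...) {
  spec <- small_genome_spec(seed, ...)
  map <- simulate_genetic_map(spec)
  geno <- simulate_iril_genotypes(map, spec)
  pheno <- simulate_phenotypes(geno, map, spec)
  list(spec = spec, map = map, geno = geno, pheno = pheno)
}

# genotype tibble from an explicit call matrix (markers as columns)
geno_from_matrix <- function(calls, lines = sprintf("L%03d", seq_len(nrow(calls)))) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("mk%02d", seq_len(ncol(calls)))
  }
  out <- tibble::as_tibble(calls)
  dplyr::bind_cols(tibble::tibble(line = lines), out)
}

# single-marker recombinant fraction between the two markers of a
# two-marker genotype set, among fully homozygous lines
recombinant_fraction <- function(geno) {
  calls <- as.matrix(geno[-1])
  hom <- calls[, 1] %in% c("A", "B") & calls[, 2] %in% c("A", "B")
  mean(calls[hom, 1] != calls[hom, 2])
}

# balanced phenotype table from per-line genetic values
pheno_from_values <- function(values, b = 3, rep_effects = rep(0, b),
                              sigma_e = 0, trait = "t", regime = "d",
                              lines = sprintf("L%03d", seq_along(values))) {
  n <- length(values)
  tibble::tibble(
    line = rep(lines, times = b),
    rep = rep(sprintf("R%d", seq_len(b)), each = n),
    regime = regime,
    trait = trait,
    value = rep(values, times = b) +
      rep(rep_effects, each = n) +
      rnorm(n * b, 0, sigma_e)
  )
}
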