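# enumeration oracle for a three-point conditional probability: joint over
# (left, x, right) genotypes under the two-state chain, then condition
enum_prob_a <- function(left, d1, right, d2) {
  states <- c(1, 0)
  joint <- function(s) {
    t1 <- ril_transition(d1)
    t2 <- ril_transition(d2)
    p_l <- 0.5
    p_1 <- if (s == left) 1 - t1 else t1
    p_2 <- if (right == s) 1 - t2 else t2
    p_l * p_1 * p_2
  }
  num <- joint(1)
  num / (num + joint(0))
}

test_that("genotype probabilities honour observed markers and symmetry", {
  map <- tibble::tibble(marker = c("m1", "m2", "m3"), chrom = 1,
                        pos_cm = c(0, 10, 20))
  geno <- geno_from_matrix(rbind(c("A", "A", "A"),
                                 c("A", "-", "B"),
                                 c("B", "H", "B")),
                           lines = c("L1", "L2", "L3"))
  names(geno)[-1] <- map$marker
  pr <- compute_genotype_probabilities(geno, map, step_cm = 5)
  expect_equal(pr$grid$pos_cm, seq(0, 20, by = 5))
  at <- function(line, pos) unname(pr$prob_a[line, which(pr$grid$pos_cm == pos)])
  expect_equal(at("L1", 0), 1)
  expect_equal(at("L3", 0), 0)
  expect_equal(at("L3", 10), 0.5) # heterozygous call
  expect_gt(at("L1", 5), 0.9) # interior of an A...A interval
  expect_equal(at("L2", 10), 0.5) # midway between A and B flanks
  expect_true(all(pr$prob_a >= 0 & pr$prob_a <= 1))
})

test_that("conditional probabilities match the enumeration oracle", {
  geometries <- list(
    list(left = 1, d1 = 4, right = 1, d2 = 6),
    list(left = 1, d1 = 10, right = 0, d2 = 10),
    list(left = 0, d1 = 2, right = 1, d2 = 18),
    list(left = 0, d1 = 7, right = 0, d2 = 3),
    list(left = 1, d1 = 1, right = 0, d2 = 29),
    list(left = 0, d1 = 15, right = 1, d2 = 15)
  )
  for (gm in geometries) {
    map <- tibble::tibble(marker = c("mL", "mR"), chrom = 1,
                          pos_cm = c(0, gm$d1 + gm$d2))
    call_of <- function(s) if (s == 1) "A" else "B"
    geno <- geno_from_matrix(rbind(c(call_of(gm$left), call_of(gm$right))),
                             lines = "L1")
    names(geno)[-1] <- map$marker
    pr <- compute_genotype_probabilities(geno, map, step_cm = gm$d1)
    got <- unname(pr$prob_a[1, which(abs(pr$grid$pos_cm - gm$d1) < 1e-9)])
    expect_equal(got, enum_prob_a(gm$left, gm$d1, gm$right, gm$d2),
                 tolerance = 1e-12)
  }
})

test_that("stepwise BIC selects exact predictors and handles edge cases", {
  set.seed(71)
  x <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("m", 1:6)))
  y <- x[, 3]
  expect_equal(stepwise_bic(x, y)$selected, "m3")
  res0 <- stepwise_bic(x[, 0, drop = FALSE], rnorm(50))
  expect_equal(res0$selected, character(0))
  expect_equal(res0$bic, res0$bic_null)
})

test_that("stepwise BIC matches exhaustive best-subset search", {
  set.seed(72)
  for (i in 1:20) {
    n <- 40
    p <- sample(3:8, 1)
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("m", 1:p)))
    k_true <- sample(0:2, 1)
    beta <- numeric(p)
    if (k_true > 0) beta[sample(p, k_true)] <- runif(k_true, 0.5, 1.5)
    y <- drop(x %*% beta) + rnorm(n)
    got <- stepwise_bic(x, y)
    # exhaustive oracle over all subsets, same BIC definition
    best_bic <- Inf
    best_set <- character(0)
    for (sz in 0:p) {
      for (cols in as.list(as.data.frame(utils::combn(p, sz)))) {
        z <- cbind(1, x[, cols, drop = FALSE])
        rss <- sum(lm.fit(z, y)$residuals^2)
        bic <- n * log(rss / n) + sz * log(n)
        if (bic < best_bic - 1e-10) {
          best_bic <- bic
          best_set <- colnames(x)[cols]
        }
      }
    }
    expect_equal(sort(got$selected), sort(best_set))
    expect_equal(got$bic, best_bic, tolerance = 1e-10)
  }
})

test_that("cofactor selection recovers simulated QTL bins", {
  sim <- small_dataset(73, n_lines = 200, effect = 1, error_variance = 3)
  fit <- fit_trait_model(sim$pheno)
  cof <- select_cofactors(sim$geno, fit$aem, sim$map, n_repeats = 200,
                          seed = 100)
  # the causal bin (chrom 1, 50 cM -> bin 1.05 or 1.06) must rank first
  expect_true(cof$bin_frequency$bin[1] %in% c("1.05", "1.06"))
  expect_gte(cof$m_star, 1)
  sel_pos <- sim$map$pos_cm[match(cof$cofactors, sim$map$marker)]
  sel_chr <- sim$map$chrom[match(cof$cofactors, sim$map$marker)]
  expect_true(any(sel_chr == 1 & abs(sel_pos - 50) <= 15))
})

test_that("cofactor selection stays near-empty for pure noise", {
  sim <- small_dataset(74, n_lines = 200, qtl = NULL, error_variance = 3)
  fit <- fit_trait_model(sim$pheno)
  cof <- select_cofactors(sim$geno, fit$aem, sim$map, n_repeats = 100,
                          seed = 101)
  expect_lte(cof$mean_selected, 1)
  expect_lte(length(cof$cofactors), 1)
})

test_that("two unlinked QTL both surface in the top bins", {
  qtl2 <- data.frame(chrom = c(1, 2), pos_cm = c(50, 50), effect = c(1, 1))
  sim <- small_dataset(75, n_lines = 200, qtl = qtl2, error_variance = 2)
  fit <- fit_trait_model(sim$pheno)
  cof <- select_cofactors(sim$geno, fit$aem, sim$map, n_repeats = 200,
                          seed = 102)
  expect_true(abs(cof$m_star - 2) <= 1)
  top2_chr <- substr(cof$bin_frequency$bin[1:2], 1, 1)
  expect_setequal(top2_chr, c("1", "2"))
})

test_that("scan LOD at observed markers equals the regression oracle", {
  sim <- small_dataset(76, n_lines = 80, effect = 0.7, error_variance = 2)
  fit <- fit_trait_model(sim$pheno)
  probs <- compute_genotype_probabilities(sim$geno, sim$map)
  sc <- mqm_scan(probs, fit$aem)
  y <- fit$aem$aem[match(probs$lines, fit$aem$line)]
  dos <- geno_dosage(sim$geno)
  n <- length(y)
  for (mk in c("c1m02", "c1m06", "c2m09")) {
    x <- dos[, mk]
    rss1 <- sum(lm.fit(cbind(1, x), y)$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    lod_oracle <- (n / 2) * log10(rss0 / rss1)
    expect_equal(sc$lod[which(sc$marker == mk)], lod_oracle,
                 tolerance = 1e-10)
  }
  expect_true(all(sc$lod >= 0))
})

test_that("the cofactor exclusion window follows the scan position", {
  sim <- small_dataset(77, n_lines = 120, effect = 0.8, error_variance = 2)
  fit <- fit_trait_model(sim$pheno)
  probs <- compute_genotype_probabilities(sim$geno, sim$map)
  cof <- "c1m06" # marker at 50 cM on chromosome 1
  sc <- mqm_scan(probs, fit$aem, cofactors = cof, window_cm = 10)
  y <- fit$aem$aem[match(probs$lines, fit$aem$line)]
  dos_grid <- grid_dosage(probs)
  n <- length(y)
  manual_lod <- function(pos, with_cofactor) {
    j <- which(probs$grid$chrom == 1 & probs$grid$pos_cm == pos)
    x <- dos_grid[, j]
    c_dos <- dos_grid[, which(probs$grid$marker == cof)]
    zf <- if (with_cofactor) cbind(1, c_dos, x) else cbind(1, x)
    zr <- if (with_cofactor) cbind(1, c_dos) else cbind(1, numeric(n))
    rss_f <- sum(lm.fit(zf, y)$residuals^2)
    rss_r <- sum(lm.fit(zr, y)$residuals^2)
    (n / 2) * log10(rss_r / rss_f)
  }
  at <- function(pos) sc$lod[sc$chrom == 1 & sc$pos_cm == pos]
  # inside the 10 cM window (42-58): cofactor excluded from both models
  expect_equal(at(42), manual_lod(42, FALSE), tolerance = 1e-10)
  expect_equal(at(58), manual_lod(58, FALSE), tolerance = 1e-10)
  # outside the window: cofactor kept in both models
  expect_equal(at(66), manual_lod(66, TRUE), tolerance = 1e-10)
  expect_equal(at(30), manual_lod(30, TRUE), tolerance = 1e-10)
  # at the cofactor itself the LOD is the plain single-marker LOD
  expect_equal(at(50), manual_lod(50, FALSE), tolerance = 1e-10)
})

test_that("permutation thresholds are deterministic and quantile-monotone", {
  sim <- small_dataset(78, n_lines = 60, qtl = NULL)
  fit <- fit_trait_model(sim$pheno)
  probs <- compute_genotype_probabilities(sim$geno, sim$map, step_cm = 10)
  t1 <- permutation_threshold(probs, fit$aem, n_perm = 50, seed = 9)
  t2 <- permutation_threshold(probs, fit$aem, n_perm = 50, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  maxes <- attr(t1, "max_lods")
  t_all <- permutation_threshold(probs, fit$aem, n_perm = 50, alpha = 1,
                                 seed = 9)
  expect_equal(as.numeric(t_all), min(maxes))
  t01 <- permutation_threshold(probs, fit$aem, n_perm = 50, alpha = 0.01,
                               seed = 9)
  expect_gte(as.numeric(t01), as.numeric(t1))
  # type-7 quantile definition
  expect_equal(as.numeric(t1), quantile(maxes, 0.95, type = 7, names = FALSE))
  expect_error(permutation_threshold(probs, fit$aem, n_perm = 10), "20")
})

test_that("peak calling finds, separates and merges local maxima", {
  profile <- tibble::tibble(
    chrom = 1,
    pos_cm = seq(0, 100, by = 2),
    marker = NA_character_,
    lod = 0.1
  )
  expect_equal(nrow(call_qtl_peaks(profile, threshold = 3)), 0)
  # two clear maxima 60 cM apart
  profile$lod <- 4 * exp(-(profile$pos_cm - 20)^2 / 50) +
    5 * exp(-(profile$pos_cm - 80)^2 / 50)
  pk <- call_qtl_peaks(profile, threshold = 3)
  expect_equal(pk$pos_cm, c(20, 80))
  # closer than the separation: merged to the higher peak
  profile$lod <- 4 * exp(-(profile$pos_cm - 40)^2 / 50) +
    5 * exp(-(profile$pos_cm - 60)^2 / 50)
  pk2 <- call_qtl_peaks(profile, threshold = 3, min_peak_separation_cm = 30)
  expect_equal(pk2$pos_cm, 60)
})

test_that("credible intervals concentrate and expand to flanking markers", {
  map <- tibble::tibble(marker = paste0("m", 1:6), chrom = 1,
                        pos_cm = seq(0, 100, by = 20),
                        bp = as.integer(seq(0, 100, by = 20) * 1e5 + 1))
  profile <- tibble::tibble(chrom = 1, pos_cm = seq(0, 100, by = 2),
                            marker = NA_character_, lod = 0)
  profile$lod[profile$pos_cm == 50] <- 6 # >99% of 10^LOD mass at one point
  ci <- bayes_credible_interval(profile, 1, 50, map)
  expect_equal(ci$ci_grid_lo, 50)
  expect_equal(ci$ci_grid_hi, 50)
  expect_equal(ci$marker_lo, "m3") # 40 cM
  expect_equal(ci$marker_hi, "m4") # 60 cM
  expect_equal(ci$phys_lo, 40 * 1e5 + 1)
  # flat profile: whole chromosome with a warning
  profile$lod <- 1
  expect_warning(ci_flat <- bayes_credible_interval(profile, 1, 50, map),
                 "flat")
  expect_equal(ci_flat$ci_lo, 0)
  expect_equal(ci_flat$ci_hi, 100)
})

test_that("multi-QTL fits agree with refit oracles and the sign convention", {
  qtl3 <- data.frame(chrom = c(1, 1, 2), pos_cm = c(20, 80, 50),
                     effect = c(1, -0.8, 0.6))
  sim <- small_dataset(79, n_lines = 300, qtl = qtl3, error_variance = 2)
  fit <- fit_trait_model(sim$pheno)
  probs <- compute_genotype_probabilities(sim$geno, sim$map)
  peaks <- tibble::tibble(chrom = qtl3$chrom, pos_cm = qtl3$pos_cm)
  fq <- fit_multi_qtl(probs, fit$aem, peaks)
  # sign convention: the Mo17-increasing QTL carries a negative effect
  expect_lt(fq$qtl$add[2], 0)
  expect_gt(fq$qtl$add[1], 0)
  expect_lt(max(abs(fq$qtl$add - qtl3$effect)), 0.35)
  # drop-one oracle
  y <- fit$aem$aem[match(probs$lines, fit$aem$line)]
  dos <- grid_dosage(probs)
  cols <- vapply(seq_len(3), function(q) {
    j <- which(probs$grid$chrom == qtl3$chrom[q])
    j[which.min(abs(probs$grid$pos_cm[j] - qtl3$pos_cm[q]))]
  }, integer(1))
  x <- dos[, cols]
  tss <- sum((y - mean(y))^2)
  rss_full <- sum(lm.fit(cbind(1, x), y)$residuals^2)
  expect_equal(fq$total_r2_pct, 100 * (1 - rss_full / tss), tolerance = 1e-10)
  for (q in 1:3) {
    rss_red <- sum(lm.fit(cbind(1, x[, -q]), y)$residuals^2)
    expect_equal(fq$qtl$r2_pct[q], 100 * (rss_red - rss_full) / tss,
                 tolerance = 1e-10)
  }
  # single QTL: total equals the scan r2 at that position
  f1 <- fit_multi_qtl(probs, fit$aem, peaks[3, ])
  sc <- mqm_scan(probs, fit$aem)
  lod_at <- sc$lod[cols[3]]
  expect_equal(f1$total_r2_pct,
               100 * (1 - 10^(-2 * lod_at / length(y))), tolerance = 1e-8)
})

test_that("collinear peaks are dropped with a warning", {
  sim <- small_dataset(80, n_lines = 50, effect = 1, error_variance = 1)
  fit <- fit_trait_model(sim$pheno)
  probs <- compute_genotype_probabilities(sim$geno, sim$map)
  peaks <- tibble::tibble(chrom = c(1, 1), pos_cm = c(50, 50))
  expect_warning(fq <- fit_multi_qtl(probs, fit$aem, peaks), "collinear")
  expect_equal(nrow(fq$qtl), 1)
})

test_that("gene-interval queries use closed-interval overlap", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    chrom = c("1", "1", "1", "1", "2"),
    start = c(100, 300, 500, 900, 100),
    end = c(200, 400, 600, 1000, 200)
  )
  expect_equal(nrow(genes_in_interval(ann[0, ], "1", 1, 1e6)), 0)
  hit <- genes_in_interval(ann, "1", 150, 550)
  expect_equal(hit$gene_id, c("g1", "g2", "g3"))
  # boundary touch counts (closed interval)
  expect_equal(genes_in_interval(ann, "1", 200, 250)$gene_id, "g1")

  # brute-force oracle on random toy annotations
  set.seed(81)
  big <- tibble::tibble(
    gene_id = paste0("g", 1:1000),
    chrom = sample(c("1", "2"), 1000, replace = TRUE),
    start = sample.int(1e6, 1000)
  )
  big$end <- big$start + sample.int(5e4, 1000)
  lo <- 2.5e5
  hi <- 4e5
  got <- genes_in_interval(big, "1", lo, hi)$gene_id
  want <- character(0)
  for (i in seq_len(1000)) {
    if (big$chrom[i] == "1" && big$start[i] <= hi && big$end[i] >= lo) {
      want <- c(want, big$gene_id[i])
    }
  }
  expect_equal(got, want)
})
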