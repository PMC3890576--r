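test_that("balanced least-squares means reduce to arithmetic line means", {
  set.seed(51)
  ph <- pheno_from_values(rnorm(40), b = 3, rep_effects = c(1, -0.5, -0.5),
                          sigma_e = 1)
  fit <- fit_trait_model(ph)
  means <- tapply(ph$value, ph$line, mean)
  expect_equal(fit$aem$aem, as.numeric(means[fit$aem$line]))
  # stored heritability always satisfies the entry-mean formula
  expect_equal(fit$H2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2 / fit$b))
})

test_that("unbalanced least-squares means adjust for replication effects", {
  set.seed(52)
  g <- rnorm(30)
  ph <- pheno_from_values(g, b = 3, rep_effects = c(2, 0, -2), sigma_e = 0.3)
  ph_unbal <- ph[-c(5, 40, 41, 88), ]
  fit <- fit_trait_model(ph_unbal)
  # oracle: lm coefficients with sum-to-zero replication contrasts
  d <- ph_unbal
  d$line_f <- factor(d$line)
  d$rep_f <- factor(d$rep)
  m <- lm(value ~ line_f + rep_f, data = d,
          contrasts = list(rep_f = "contr.sum"))
  co <- coef(m)
  aem_oracle <- co[1] + c(0, co[grep("line_f", names(co))])
  expect_equal(fit$aem$aem, unname(aem_oracle), tolerance = 1e-10)
})

test_that("adjusted entry means are location-equivariant", {
  set.seed(53)
  ph <- pheno_from_values(rnorm(25), b = 3, sigma_e = 0.5)
  ph2 <- dplyr::mutate(ph, value = value + 7)
  f1 <- fit_trait_model(ph)
  f2 <- fit_trait_model(ph2)
  expect_equal(f2$aem$aem, f1$aem$aem + 7)
  expect_equal(f2$sigma_g2, f1$sigma_g2)
  expect_equal(f2$sigma_e2, f1$sigma_e2)
  expect_equal(f2$H2, f1$H2)
})

test_that("REML variance components match oracles on balanced and unbalanced data", {
  set.seed(54)
  g <- rnorm(60, 0, sqrt(2))
  ph <- pheno_from_values(g, b = 3, rep_effects = c(0.5, -0.2, -0.3),
                          sigma_e = 1)
  fit <- fit_trait_model(ph)
  d <- ph
  d$line_f <- factor(d$line)
  d$rep_f <- factor(d$rep)
  a <- stats::anova(lm(value ~ line_f + rep_f, data = d))
  ms_e <- a["Residuals", "Mean Sq"]
  sg_anova <- (a["line_f", "Mean Sq"] - ms_e) / 3
  expect_equal(fit$sigma_g2, sg_anova, tolerance = 1e-10)
  expect_equal(fit$sigma_e2, ms_e, tolerance = 1e-10)
  # independent REML route: lme4's own optimizer
  m <- lme4::lmer(value ~ rep_f + (1 | line_f), data = d, REML = TRUE)
  expect_equal(fit$sigma_g2, as.numeric(lme4::VarCorr(m)$line_f),
               tolerance = 1e-5)
  expect_equal(fit$sigma_e2, sigma(m)^2, tolerance = 1e-5)

  # unbalanced data use the numerical REML path; lme4 is the oracle
  ph_u <- ph[-c(2, 61, 130, 131), ]
  fit_u <- fit_trait_model(ph_u)
  d_u <- ph_u
  d_u$line_f <- factor(d_u$line)
  d_u$rep_f <- factor(d_u$rep)
  m_u <- lme4::lmer(value ~ rep_f + (1 | line_f), data = d_u, REML = TRUE)
  expect_equal(fit_u$sigma_g2, as.numeric(lme4::VarCorr(m_u)$line_f),
               tolerance = 1e-4)
  expect_equal(fit_u$sigma_e2, sigma(m_u)^2, tolerance = 1e-4)
})

test_that("negative genotypic variance estimates truncate to zero", {
  set.seed(55)
  # no genetic signal, tiny n: (MS_G - MS_E)/b frequently negative
  found <- FALSE
  for (i in 1:20) {
    ph <- pheno_from_values(rep(0, 8), b = 3, sigma_e = 1)
    fit <- fit_trait_model(ph)
    expect_gte(fit$sigma_g2, 0)
    expect_true(fit$H2 >= 0 && fit$H2 <= 1)
    if (fit$truncated) found <- TRUE
  }
  expect_true(found)
})

test_that("degenerate and missing-line phenotypes are handled", {
  ph <- pheno_from_values(rep(1, 10), b = 3)
  fit <- fit_trait_model(ph) # constant trait
  expect_equal(fit$sigma_g2, 0)
  expect_equal(fit$sigma_e2, 0)
  expect_true(is.na(fit$H2))
  expect_true(is.na(fit$ks_p))

  set.seed(56)
  ph2 <- pheno_from_values(rnorm(10), b = 3, sigma_e = 0.1)
  ph2$value[ph2$line == "L003"] <- NA # line present but unobserved
  expect_message(fit2 <- fit_trait_model(ph2), "L003")
  expect_true(is.na(fit2$aem$aem[fit2$aem$line == "L003"]))
})

test_that("KS normality equals the brute-force sup statistic", {
  set.seed(57)
  x <- rexp(60) # skewed so the statistic is informative
  stat <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$statistic
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  sup <- max(pmax(abs(seq_len(n) / n - pnorm(z)),
                  abs((seq_len(n) - 1) / n - pnorm(z))))
  expect_equal(unname(stat), sup, tolerance = 1e-12)

  set.seed(58)
  expect_gt(ks_normality(rnorm(1000)), 0.05)
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("partial correlations equal the residual-regression oracle", {
  set.seed(59)
  n <- 50
  p <- 5
  sigma <- 0.5 * diag(p) + 0.5
  x <- matrix(rnorm(n * p), n) %*% chol(sigma)
  colnames(x) <- paste0("t", 1:p)
  aem <- dplyr::bind_cols(tibble::tibble(line = sprintf("L%02d", 1:n)),
                          tibble::as_tibble(x))
  net <- partial_correlation_network(aem)
  edges <- tidy(net)
  for (k in seq_len(nrow(edges))) {
    a <- edges$trait_a[k]
    b <- edges$trait_b[k]
    rest <- setdiff(colnames(x), c(a, b))
    ra <- lm.fit(cbind(1, x[, rest]), x[, a])$residuals
    rb <- lm.fit(cbind(1, x[, rest]), x[, b])$residuals
    expect_equal(edges$partial_r[k], cor(ra, rb), tolerance = 1e-10)
  }
  # pearson side of the edge list matches cor()
  cm <- cor(x)
  expect_equal(edges$pearson_r[1], cm["t1", "t2"])
})

test_that("collider structure yields a negative partial correlation", {
  set.seed(60)
  n <- 200
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 0.5)
  aem <- tibble::tibble(line = sprintf("L%03d", 1:n),
                        t1 = x1, t2 = x2, t3 = x3)
  expect_lt(abs(cor(x1, x2)), 0.15) # marginally near-independent
  edges <- tidy(partial_correlation_network(aem))
  expect_lt(edges$partial_r[edges$trait_a == "t1" & edges$trait_b == "t2"],
            -0.5)
})

test_that("independent traits give near-zero partial correlations", {
  set.seed(61)
  n <- 300
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("t", 1:4)))
  aem <- dplyr::bind_cols(tibble::tibble(line = sprintf("L%03d", 1:n)),
                          tibble::as_tibble(x))
  edges <- tidy(partial_correlation_network(aem))
  expect_true(all(abs(edges$partial_r) < 3 / sqrt(n - 4)))
})

test_that("singular correlation matrices demand shrinkage", {
  set.seed(62)
  n <- 6
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("t", 1:8)))
  aem <- dplyr::bind_cols(tibble::tibble(line = sprintf("L%d", 1:n)),
                          tibble::as_tibble(x))
  expect_error(partial_correlation_network(aem), "shrink|complete lines")
  net <- partial_correlation_network(aem, lambda = 0.5)
  expect_true(all(abs(tidy(net)$partial_r) <= 1))
})

test_that("heritability report and AEM table assemble across traits", {
  set.seed(63)
  ph <- dplyr::bind_rows(
    pheno_from_values(rnorm(20, 0, 1.2), sigma_e = 1, trait = "t1"),
    pheno_from_values(rnorm(20, 0, 0.8), sigma_e = 1, trait = "t2"),
    pheno_from_values(rnorm(20, 0, 1.2), sigma_e = 1, trait = "t1",
                      regime = "s"),
    pheno_from_values(rnorm(20, 0, 0.8), sigma_e = 1, trait = "t2",
                      regime = "s")
  )
  rep <- heritability_report(ph)
  expect_equal(sort(names(rep$h2)), sort(c("trait", "H2_d", "H2_s")))
  expect_equal(nrow(rep$h2), 2)
  wide <- aem_table(rep$fits[c("t1.d", "t2.d")])
  expect_equal(names(wide), c("line", "t1", "t2"))
  expect_equal(nrow(wide), 20)
})
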