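#' Fit the per-regime trait model
#'
#' Fits the two-way model \eqn{y_{ik} = \mu + g_i + r_k + e_{ik}} to one
#' trait in one regime.  Adjusted entry means (AEM) are the least-squares
#' means of the fixed-effects fit (genotype and replication both fixed); for
#' complete balanced data they reduce to the per-line arithmetic means.
#' Variance components are estimated by REML with genotype random and
#' replication fixed, and broad-sense heritability on an entry-mean basis is
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / b)} with `b` the
#' number of replications.  For complete balanced data the REML estimates
#' coincide with the ANOVA moment estimators
#' \eqn{\hat\sigma^2_g = (MS_G - MS_E)/b}, \eqn{\hat\sigma^2_e = MS_E}.
#' A Kolmogorov-Smirnov normality check of the AEM is attached.
#'
#' @param pheno Long phenotype tibble (`line`, `rep`, `regime`, `trait`,
#'   `value`).
#' @param trait,regime Which trait and regime to fit (may be omitted when
#'   the table contains a single one).
#' @return An object of class `iril_trait_fit` with elements `aem` (tibble
#'   `line`, `aem`), `mu_hat`, `rep_effects`, `sigma_g2`, `sigma_e2`, `b`,
#'   `H2`, `ks_p`, `truncated` (`TRUE` when the genotypic variance estimate
#'   hit the zero boundary) and `n_lines`.  [tidy()] returns the AEM table,
#'   [glance()] a one-row component summary.
#' @examples
#' spec <- sim_spec(n_chromosomes = 1, chrom_lengths = 50,
#'                  n_markers_per_chrom = 6, n_lines = 30,
#'                  polygenic_variance = 2, error_variance = 1, seed = 3)
#' map <- simulate_genetic_map(spec)
#' pheno <- simulate_phenotypes(simulate_iril_genotypes(map, spec), map, spec)
#' fit <- fit_trait_model(pheno)
#' glance(fit)
#' @export
fit_trait_model <- function(pheno, trait = NULL, regime = NULL) {
  pheno <- validate_phenotypes(pheno)
  trait <- trait %||% unique(pheno$trait)
  regime <- regime %||% unique(pheno$regime)
  if (length(trait) != 1 || length(regime) != 1) {
    abort("specify a single `trait` and `regime`.")
  }
  all_lines <- sort(unique(pheno$line))
  df <- pheno[pheno$trait == trait & pheno$regime == regime &
                !is.na(pheno$value), ]
  if (length(unique(df$line)) < 2) abort("need data on at least 2 lines.")
  if (length(unique(df$rep)) < 2) abort("need at least 2 replications with data.")
  df$line_f <- factor(df$line)
  df$rep_f <- factor(df$rep)
  b <- nlevels(df$rep_f)

  # least-squares means: additive fixed-effects fit, predictions averaged
  # over the replication levels
  fit_fixed <- lm(value ~ line_f + rep_f, data = df)
  grid <- expand.grid(line_f = levels(df$line_f), rep_f = levels(df$rep_f))
  pred <- matrix(predict(fit_fixed, newdata = grid), nlevels(df$line_f), b)
  aem_values <- rowMeans(pred)
  aem <- tibble::tibble(line = all_lines,
                        aem = aem_values[match(all_lines, levels(df$line_f))])
  dropped <- setdiff(all_lines, levels(df$line_f))
  if (length(dropped)) {
    inform(sprintf("no observations for %d line(s) (%s); AEM reported as NA.",
                   length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  mu_hat <- mean(aem_values)
  rep_effects <- tibble::tibble(rep = levels(df$rep_f),
                                effect = colMeans(pred) - mean(pred))

  if (var(df$value) < .Machine$double.eps) {
    vc <- list(sigma_g2 = 0, sigma_e2 = 0, truncated = TRUE)
  } else {
    vc <- .reml_line_variance(df)
  }
  H2 <- if (vc$sigma_g2 + vc$sigma_e2 / b > 0) {
    vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2 / b)
  } else {
    NA_real_
  }
  aem_obs <- aem$aem[!is.na(aem$aem)]
  degenerate <- length(aem_obs) > 0 &&
    sd(aem_obs) <= sqrt(.Machine$double.eps) * max(1, abs(mean(aem_obs)))
  ks_p <- if (length(aem_obs) >= 8 && !degenerate) {
    ks_normality(aem_obs)
  } else {
    NA_real_
  }
  structure(
    list(trait = trait, regime = regime, aem = aem, mu_hat = mu_hat,
         rep_effects = rep_effects, sigma_g2 = vc$sigma_g2,
         sigma_e2 = vc$sigma_e2, b = b, H2 = H2, ks_p = ks_p,
         truncated = vc$truncated, n_lines = nlevels(df$line_f)),
    class = "iril_trait_fit"
  )
}

# REML for y ~ rep (fixed) + (1 | line).  For complete balanced data the
# REML solution is available in closed form and equals the ANOVA moment
# estimators (sigma_e2 = MS_E, sigma_g2 = (MS_G - MS_E)/b) whenever the
# latter is non-negative, with the boundary fit sigma_g2 = 0 otherwise;
# that path is exact.  Unbalanced data go through lme4's modular interface
# with a 1-D optimisation of theta = sigma_g/sigma_e.
.reml_line_variance <- function(df) {
  tab <- table(df$line_f, df$rep_f)
  if (all(tab == 1L)) {
    a <- stats::anova(lm(value ~ line_f + rep_f, data = df))
    ms_g <- a["line_f", "Mean Sq"]
    ms_e <- a["Residuals", "Mean Sq"]
    b <- nlevels(df$rep_f)
    sg <- (ms_g - ms_e) / b
    if (sg >= 0) {
      return(list(sigma_g2 = sg, sigma_e2 = ms_e, truncated = FALSE))
    }
    m0 <- lm(value ~ rep_f, data = df)
    sigma_e2 <- sum(m0$residuals^2) / m0$df.residual
    return(list(sigma_g2 = 0, sigma_e2 = sigma_e2, truncated = TRUE))
  }
  .reml_line_variance_lme4(df)
}

.reml_line_variance_lme4 <- function(df) {
  parsed <- lme4::lFormula(value ~ rep_f + (1 | line_f), data = df,
                           REML = TRUE,
                           control = lme4::lmerControl(
                             check.nobs.vs.nlev = "ignore",
                             check.nobs.vs.nRE = "ignore"))
  devfun <- do.call(lme4::mkLmerDevfun, parsed)
  opt <- optimize(devfun, interval = c(0, 1e3), tol = 1e-12)
  theta <- opt$minimum
  if (devfun(0) <= opt$objective) theta <- 0
  dev <- devfun(theta) # leave devfun environment at the optimum
  mod <- lme4::mkMerMod(environment(devfun),
                        list(par = theta, fval = dev, feval = NA_integer_,
                             conv = 0L, message = ""),
                        parsed$reTrms, fr = parsed$fr)
  sigma_e2 <- sigma(mod)^2
  sigma_g2 <- theta^2 * sigma_e2
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, truncated = theta == 0)
}

#' Kolmogorov-Smirnov normality check
#'
#' Computes the KS statistic `sup |ECDF - Normal CDF|` against a normal
#' distribution with mean and standard deviation estimated from the sample,
#' with the p-value from the asymptotic KS distribution.  Because the
#' reference parameters are estimated from the same sample the p-value is
#' conservative in the Lilliefors sense; it is used as a descriptive screen
#' of the adjusted entry means, as in the emulated analysis.
#'
#' @param x A numeric vector (at least 8 values) or an `iril_trait_fit`,
#'   whose AEM are tested.
#' @return The p-value (`NA` for degenerate all-equal input).
#' @export
ks_normality <- function(x) {
  if (inherits(x, "iril_trait_fit")) x <- x$aem$aem
  x <- x[!is.na(x)]
  if (length(x) < 8) abort("need at least 8 values.")
  if (sd(x) == 0) {
    return(NA_real_)
  }
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$p.value
}

#' @export
print.iril_trait_fit <- function(x, ...) {
  cat(sprintf("<iril_trait_fit> %s / %s: %d lines, b = %d\n",
              x$trait, x$regime, x$n_lines, x$b))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g, H2 = %.3f%s, KS p = %.3g\n",
              x$sigma_g2, x$sigma_e2, x$H2,
              if (x$truncated) " (boundary)" else "", x$ks_p))
  invisible(x)
}

#' @export
tidy.iril_trait_fit <- function(x, ...) {
  dplyr::mutate(x$aem, trait = x$trait, regime = x$regime,
                .before = "line")
}

#' @export
glance.iril_trait_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, regime = x$regime,
                 n_lines = x$n_lines, b = x$b,
                 sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, H2 = x$H2,
                 ks_p = x$ks_p, truncated = x$truncated)
}

#' Heritability report across traits and regimes
#'
#' Fits [fit_trait_model()] for every trait-by-regime combination present in
#' the phenotype table and assembles the entry-mean heritabilities as one
#' row per trait with one `H2` column per regime (the layout of a classical
#' heritability summary table).
#'
#' @param pheno Long phenotype tibble.
#' @return A list with `fits` (named list of `iril_trait_fit`; names are
#'   `trait.regime`) and `h2` (wide tibble, one `H2_<regime>` column per
#'   regime).
#' @export
heritability_report <- function(pheno) {
  pheno <- validate_phenotypes(pheno)
  combos <- dplyr::distinct(pheno, .data$trait, .data$regime)
  fits <- purrr::pmap(combos, function(trait, regime) {
    fit_trait_model(pheno, trait, regime)
  })
  names(fits) <- paste(combos$trait, combos$regime, sep = ".")
  h2 <- purrr::map_dfr(fits, glance) |>
    dplyr::select("trait", "regime", "H2") |>
    tidyr::pivot_wider(names_from = "regime", values_from = "H2",
                       names_prefix = "H2_")
  list(fits = fits, h2 = h2)
}

#' Adjusted entry means in wide format
#'
#' @param fits A list of `iril_trait_fit` objects for one regime.
#' @return Wide tibble: `line` plus one column per trait holding its AEM.
#' @export
aem_table <- function(fits) {
  if (inherits(fits, "iril_trait_fit")) fits <- list(fits)
  long <- purrr::map_dfr(fits, tidy)
  if (length(unique(long$regime)) > 1) {
    abort("AEM tables are per regime; got fits from several regimes.")
  }
  tidyr::pivot_wider(long[c("line", "trait", "aem")],
                     names_from = "trait", values_from = "aem")
}
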