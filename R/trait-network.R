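#' Pairwise Pearson correlations between traits
#'
#' @param aem Wide AEM tibble from [aem_table()] (`line` column plus one
#'   column per trait), or any data frame shaped that way.
#' @return Long tibble of unordered trait pairs with their Pearson `r`
#'   (pairwise-complete observations).
#' @export
trait_correlations <- function(aem) {
  x <- .aem_matrix(aem)
  r <- cor(x, use = "pairwise.complete.obs")
  .cor_edges(r, "pearson_r")
}

#' Partial-correlation trait network
#'
#' Estimates the Gaussian graphical model of the traits: the correlation
#' matrix `R` of the adjusted entry means is (optionally) shrunk toward the
#' identity, inverted, and the precision matrix `Omega` standardised to
#' partial correlations
#' \deqn{\rho_{ab \cdot rest} = -\Omega_{ab} / \sqrt{\Omega_{aa}\Omega_{bb}},}
#' the correlation between each pair of traits after removing the linear
#' effect of all remaining traits.  Edges with `|partial_r|` below `cutoff`
#' are dropped from the exported edge list.
#'
#' @param aem Wide AEM tibble (`line` + trait columns); only complete lines
#'   are used.
#' @param lambda Shrinkage weight toward the identity in `[0, 1)`; default 0
#'   (appropriate when the number of complete lines exceeds the number of
#'   traits + 1).  A singular correlation matrix at `lambda = 0` raises an
#'   error suggesting shrinkage.
#' @param cutoff Minimum `|partial_r|` for an edge to be retained.
#' @return An object of class `iril_trait_network`: list with `edges`
#'   (tibble `trait_a`, `trait_b`, `partial_r`, `pearson_r`), `nodes`,
#'   `lambda`, `n` (lines used).  [tidy()] returns the edge list.
#' @examples
#' set.seed(1)
#' aem <- tibble::tibble(line = sprintf("L%02d", 1:40),
#'                       t1 = rnorm(40), t2 = rnorm(40))
#' aem$t3 <- aem$t1 + aem$t2 + rnorm(40, sd = 0.5)
#' tidy(partial_correlation_network(aem))
#' @export
partial_correlation_network <- function(aem, lambda = 0, cutoff = 0) {
  x <- .aem_matrix(aem)
  if (ncol(x) < 3) abort("need at least 3 traits for partial correlations.")
  if (lambda < 0 || lambda >= 1) abort("`lambda` must lie in [0, 1).")
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  p <- ncol(x)
  if (lambda == 0 && nrow(x) < p + 2) {
    abort("need at least p + 2 complete lines for lambda = 0; consider shrinkage.")
  }
  r <- cor(x)
  r_shrunk <- (1 - lambda) * r + lambda * diag(p)
  omega <- tryCatch(
    solve(r_shrunk),
    error = function(e) {
      abort(paste("correlation matrix is singular; increase `lambda` to",
                  "shrink toward the identity."))
    }
  )
  d <- sqrt(diag(omega))
  prho <- -omega / tcrossprod(d)
  diag(prho) <- 1
  edges <- .cor_edges(prho, "partial_r")
  edges$pearson_r <- .cor_edges(r, "pearson_r")$pearson_r
  edges <- edges[abs(edges$partial_r) >= cutoff, ]
  structure(
    list(edges = edges, nodes = colnames(x), lambda = lambda, n = nrow(x)),
    class = "iril_trait_network"
  )
}

.aem_matrix <- function(aem) {
  df <- as.data.frame(aem)
  if ("line" %in% names(df)) {
    rownames(df) <- df$line
    df$line <- NULL
  }
  as.matrix(df)
}

.cor_edges <- function(r, value_name) {
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble::tibble(
    trait_a = rownames(r)[idx[, 1]],
    trait_b = colnames(r)[idx[, 2]],
    value = r[idx]
  )
  names(out)[3] <- value_name
  out
}

#' @export
print.iril_trait_network <- function(x, ...) {
  cat(sprintf("<iril_trait_network> %d traits, %d edges, lambda = %g, n = %d\n",
              length(x$nodes), nrow(x$edges), x$lambda, x$n))
  invisible(x)
}

#' @export
tidy.iril_trait_network <- function(x, ...) x$edges

#' @export
glance.iril_trait_network <- function(x, ...) {
  tibble::tibble(n_traits = length(x$nodes), n_edges = nrow(x$edges),
                 lambda = x$lambda, n = x$n)
}
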