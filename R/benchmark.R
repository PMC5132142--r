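# Two-stage benchmark: case-only trend tests for every marker pair,
# combined into one global p-value by Fisher's method.

#' Case-only trend test for one marker pair
#'
#' Regresses marker `Ga` on marker `Gb` (plus covariates) among the cases
#' only and returns the two-sided Wald p-value for the `Gb` slope, using the
#' t reference distribution with `d - k - 2` degrees of freedom. Within
#' cases, association between two markers signals interaction on the
#' log-odds scale -- but only when the markers are uncorrelated in the
#' general population; otherwise the test is anticonservative.
#'
#' @param ga,gb Numeric genotype columns (0/1/2), length n.
#' @param y Binary phenotype (1 = case).
#' @param covariates Optional covariate matrix (n x k).
#' @return A list with `beta`, `se`, `statistic`, `df`, `p_value`.
#' @export
case_only_trend_test <- function(ga, gb, y, covariates = NULL) {
  d <- .check_phenotype(y, length(ga))
  if (length(gb) != length(ga)) stop("marker columns must have equal length")
  cases <- y == 1
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (d < k + 3L) stop("need at least k + 3 cases for the trend test")
  ga_c <- ga[cases]
  gb_c <- gb[cases]
  if (var(gb_c) == 0) {
    stop("marker Gb has zero variance among cases")
  }
  dat <- if (k > 0L) {
    data.frame(ga = ga_c, as.matrix(covariates)[cases, , drop = FALSE],
               gb = gb_c)
  } else {
    data.frame(ga = ga_c, gb = gb_c)
  }
  fit <- lm(ga ~ ., data = dat)
  if (any(is.na(coef(fit)))) stop("collinear design among cases")
  sm <- summary(fit)$coefficients
  row <- sm["gb", ]
  list(beta = unname(row["Estimate"]), se = unname(row["Std. Error"]),
       statistic = unname(row["t value"]), df = fit$df.residual,
       p_value = unname(row["Pr(>|t|)"]))
}

#' Case-only trend p-values for all marker pairs
#'
#' Runs [case_only_trend_test()] over all `p(p-1)/2` pairs, with the
#' lower-index marker as the response. Without covariates the Wald t
#' statistic of a simple regression is symmetric in the two markers (it is
#' the correlation t test), so the direction convention is immaterial there;
#' with covariates the two directions differ slightly.
#'
#' @inheritParams case_only_trend_test
#' @param g Genotype matrix, subjects x markers.
#' @return A data frame of class `pairwise_pvalues` with columns `i`, `j`,
#'   `marker_i`, `marker_j`, `beta`, `se`, `p_value`.
#' @export
pairwise_caseonly_pvalues <- function(g, y, covariates = NULL) {
  .check_genotypes(g, min_n = 3L, min_p = 2L)
  d <- .check_phenotype(y, nrow(g))
  p <- ncol(g)
  ids <- .marker_ids(g)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]

  if (is.null(covariates)) {
    # vectorized over pairs through the case cross-product matrix
    X <- g[y == 1, , drop = FALSE]
    X <- sweep(X, 2L, colMeans(X))
    C <- crossprod(X)
    dg <- diag(C)
    if (any(dg == 0)) {
      stop("markers with zero variance among cases: ",
           paste(ids[dg == 0], collapse = ", "))
    }
    df <- d - 2L
    a <- idx[, 1L]; b <- idx[, 2L]
    Cab <- C[cbind(a, b)]
    beta <- Cab / dg[b]                    # slope of Ga on Gb
    rss <- pmax(dg[a] - Cab^2 / dg[b], 0)
    se <- sqrt(rss / df / dg[b])
    tstat <- ifelse(se > 0, beta / se, Inf)
    pv <- 2 * pt(-abs(tstat), df)
    out <- data.frame(i = a, j = b, marker_i = ids[a], marker_j = ids[b],
                      beta = beta, se = se, p_value = pv)
  } else {
    rows <- lapply(seq_len(nrow(idx)), function(r) {
      a <- idx[r, 1L]; b <- idx[r, 2L]
      fit <- case_only_trend_test(g[, a], g[, b], y, covariates)
      data.frame(i = a, j = b, marker_i = ids[a], marker_j = ids[b],
                 beta = fit$beta, se = fit$se, p_value = fit$p_value)
    })
    out <- do.call(rbind, rows)
  }
  class(out) <- c("pairwise_pvalues", "data.frame")
  out
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum(log p)` referred to the chi-square distribution with `2m`
#' degrees of freedom. Valid when the component p-values are independent
#' and uniform under the null.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.2, 0.8, 0.05))
fisher_combine <- function(pvals) {
  if (length(pvals) < 1L || anyNA(pvals)) {
    stop("need at least one non-missing p-value")
  }
  if (any(pvals > 1)) stop("p-values above 1 are invalid")
  if (any(pvals <= 0)) {
    warning("p-values at or below 0 clamped to 1e-300")
    pvals <- pmax(pvals, 1e-300)
  }
  x <- -2 * sum(log(pvals))
  pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Two-stage global interaction test (benchmark method)
#'
#' The comparison method for the global epistasis test: a case-only trend
#' test per marker pair, all `p(p-1)/2` p-values combined by Fisher's
#' method into one global p-value. Accurate when markers are independent in
#' the population; severely anticonservative otherwise, because the
#' case-only p-values are then neither uniform nor independent.
#'
#' @inheritParams pairwise_caseonly_pvalues
#' @param return_pairs If `TRUE`, attach the per-pair table as attribute
#'   `"pairs"`.
#' @return The combined global p-value.
#' @export
benchmark_global_test <- function(g, y, covariates = NULL,
                                  return_pairs = FALSE) {
  tab <- pairwise_caseonly_pvalues(g, y, covariates)
  out <- fisher_combine(tab$p_value)
  if (return_pairs) attr(out, "pairs") <- tab
  out
}
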