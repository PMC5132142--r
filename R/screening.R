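# Screening: marginal-association marker filter and BH FDR utilities.

#' Filter markers by marginal association
#'
#' Ranks markers by the Wald p-value of the marker coefficient in a
#' one-marker regression on the phenotype (logistic for a binary phenotype,
#' linear for a continuous one; covariates included in every fit) and keeps
#' the `k` smallest. Under the null of no interaction, the marginal
#' association statistic is asymptotically independent of downstream
#' interaction test statistics, which is what makes it a valid
#' screening-testing filter; the function itself only implements the
#' operational ranking contract.
#'
#' @param g Genotype matrix, subjects x markers.
#' @param y Phenotype: binary 0/1 or continuous.
#' @param k Number of markers to retain (at least 1; capped at `ncol(g)`).
#' @param covariates Optional covariate matrix.
#' @param type `"auto"` detects binary vs continuous from the values of `y`;
#'   override with `"binary"` or `"continuous"`.
#' @return An object of class `filter_result`: list with `kept_ids`,
#'   `kept_idx` (columns of `g`, in increasing p-value order, ties broken by
#'   input marker order), `marginal_p` (all markers), `marginal_beta`,
#'   `threshold_rank`.
#' @export
marginal_filter <- function(g, y, k, covariates = NULL,
                            type = c("auto", "binary", "continuous")) {
  .check_genotypes(g)
  type <- match.arg(type)
  if (k < 1) stop("'k' must be at least 1")
  if (length(y) != nrow(g) || anyNA(y)) {
    stop("phenotype must match subject count with no missing values")
  }
  if (type == "auto") {
    type <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  ids <- .marker_ids(g)
  p <- ncol(g)
  k <- min(as.integer(k), p)
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)

  pv <- numeric(p)
  bt <- numeric(p)
  for (j in seq_len(p)) {
    dat <- if (is.null(cv)) data.frame(y = y, marker = g[, j])
           else data.frame(y = y, cv, marker = g[, j])
    res <- tryCatch({
      if (type == "binary") {
        fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
        if (!fit$converged) stop("nonconvergent")
        sm <- summary(fit)$coefficients
        c(sm["marker", "Estimate"], sm["marker", "Pr(>|z|)"])
      } else {
        fit <- lm(y ~ ., data = dat)
        sm <- summary(fit)$coefficients
        c(sm["marker", "Estimate"], sm["marker", "Pr(>|t|)"])
      }
    }, error = function(e) c(NA_real_, NA_real_))
    if (anyNA(res)) {
      warning("marginal fit failed for marker ", ids[j],
              " (separation or degenerate column); assigning p = 1")
      res <- c(0, 1)
    }
    bt[j] <- res[1L]
    pv[j] <- res[2L]
  }
  ord <- order(pv)  # stable: ties keep input marker order
  kept <- ord[seq_len(k)]
  structure(list(kept_ids = ids[kept], kept_idx = kept,
                 marginal_p = setNames(pv, ids),
                 marginal_beta = setNames(bt, ids),
                 threshold_rank = k),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Marginal-association filter: kept", x$threshold_rank, "of",
      length(x$marginal_p), "markers\n")
  cat("  best:", paste(utils::head(x$kept_ids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment with the running-minimum monotonicity
#' correction, delegated to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values, elementwise at least as large as the input p-values.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvals, method = "BH")
}
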