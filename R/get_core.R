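# GET core: partitioned correlation matrices, the greatest-root statistic,
# Johnstone's centering/scaling, and the assembled test.

#' Case and control correlation matrices
#'
#' Splits the genotype matrix by the binary phenotype and computes the
#' Pearson correlation matrix within cases and within controls, each
#' partition mean-centered and standardized on its own rows. Off-diagonal
#' entries estimate the genotypic linkage-disequilibrium measure within each
#' subpopulation. With covariates, each marker is first residualized on an
#' intercept plus the covariates by least squares within its partition, and
#' the residuals are correlated, giving partial correlation matrices.
#'
#' @param g Numeric matrix, subjects x markers, entries 0/1/2 (additive
#'   allele counts), no missing values.
#' @param y Binary phenotype vector (0 = control, 1 = case), length `nrow(g)`.
#' @param covariates Optional numeric matrix of covariates, subjects x k.
#' @param drop_degenerate If `TRUE`, markers with zero variance within
#'   either partition are dropped with a warning instead of raising an error.
#'   Dropping changes the marker count `p` and hence the test's centering
#'   and scaling constants, so the default is a hard error.
#' @return An object of class `partitioned_correlations`: a list with
#'   elements `s_case`, `s_control` (p x p correlation matrices), `d` (case
#'   count), `n` (total subjects), `partial` (logical) and `marker_ids`.
#' @export
#' @examples
#' g <- simulate_genotypes(genotype_model(p = 6, maf = 0.3), n = 200, seed = 1)
#' y <- rbinom(200, 1, 0.5)
#' pc <- partitioned_correlations(g, y)
#' dim(pc$s_case)
partitioned_correlations <- function(g, y, covariates = NULL,
                                     drop_degenerate = FALSE) {
  .check_genotypes(g, min_n = 4L, min_p = 2L)
  d <- .check_phenotype(y, nrow(g))
  n <- nrow(g)
  if (d < 2L || n - d < 2L) {
    stop("partition too small: need at least 2 cases and 2 controls, got d = ",
         d, ", n - d = ", n - d)
  }
  ids <- .marker_ids(g)
  case_rows <- y == 1
  g1 <- g[case_rows, , drop = FALSE]
  g0 <- g[!case_rows, , drop = FALSE]

  partial <- FALSE
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match subject count")
    if (ncol(covariates) > 0L) {
      partial <- TRUE
      g1 <- .residualize(g1, covariates[case_rows, , drop = FALSE])
      g0 <- .residualize(g0, covariates[!case_rows, , drop = FALSE])
    }
  }

  v1 <- .col_vars(g1)
  v0 <- .col_vars(g0)
  degenerate <- v1 <= 0 | v0 <= 0
  if (any(degenerate)) {
    if (!drop_degenerate) {
      stop("markers with zero variance within a phenotype partition: ",
           paste(ids[degenerate], collapse = ", "),
           " (set drop_degenerate = TRUE to drop them)")
    }
    warning("dropping ", sum(degenerate),
            " zero-variance marker(s): ", paste(ids[degenerate], collapse = ", "))
    keep <- !degenerate
    if (sum(keep) < 2L) stop("fewer than 2 markers remain after dropping")
    g1 <- g1[, keep, drop = FALSE]
    g0 <- g0[, keep, drop = FALSE]
    ids <- ids[keep]
  }

  structure(list(s_case = .name_cor(cor(g1), ids),
                 s_control = .name_cor(cor(g0), ids),
                 d = d, n = n, partial = partial, marker_ids = ids),
            class = "partitioned_correlations")
}

.col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x * x) - n * mu^2) / (n - 1)
}

.residualize <- function(x, covs) {
  qrX <- qr(cbind(1, covs))
  if (qrX$rank < ncol(covs) + 1L) {
    stop("covariate matrix is rank deficient within a phenotype partition")
  }
  qr.resid(qrX, x)
}

.name_cor <- function(s, ids) {
  dimnames(s) <- list(ids, ids)
  s
}

#' @export
print.partitioned_correlations <- function(x, ...) {
  cat("Partitioned sample correlation matrices",
      if (x$partial) "(partial, covariate-adjusted)" else "", "\n")
  cat("  markers:", length(x$marker_ids),
      " cases:", x$d, " controls:", x$n - x$d, "\n")
  invisible(x)
}

#' Greatest-root statistic of the case/control correlation pair
#'
#' Largest eigenvalue of `(d S1 + (n-d) S0)^{-1} (n-d) S0`, the classical
#' greatest-root statistic for comparing two covariance structures. Computed
#' through the symmetric generalized eigenproblem via a Cholesky reduction
#' of the weighted sum, never by explicit inversion.
#'
#' @param pc A `partitioned_correlations` object.
#' @return The largest eigenvalue, a scalar strictly inside (0, 1).
#' @export
greatest_root <- function(pc) {
  .root_spectrum(pc)[1L]
}

# full spectrum of (d S1 + m S0)^{-1} m S0 via the Cholesky-reduced
# symmetric form; eigenvalues of the case-oriented companion
# (d S1 + m S0)^{-1} d S1 are 1 minus these, reversed.
.root_spectrum <- function(pc) {
  stopifnot(inherits(pc, "partitioned_correlations"))
  d <- pc$d
  m <- pc$n - pc$d
  B <- d * pc$s_case + m * pc$s_control
  A <- m * pc$s_control
  R <- tryCatch(chol(B), error = function(e) {
    stop("weighted correlation sum is numerically singular; ",
         "filter collinear or degenerate markers before testing")
  })
  # M = L^{-1} A L^{-T} with B = L L^T shares eigenvalues with B^{-1} A
  Linv_A <- forwardsolve(t(R), A)
  M <- forwardsolve(t(R), t(Linv_A))
  eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
}

#' Centering and scaling constants for the logit greatest root
#'
#' Johnstone's trigonometric constants under which the logit of the
#' greatest-root statistic converges to the Tracy-Widom law of order 1:
#' with `N = n1 + n2 - 1`,
#' \deqn{\sin^2(\gamma/2) = (\min(p, n2) - 1/2)/N,\quad
#'       \sin^2(\phi/2) = (\max(p, n2) - 1/2)/N,}
#' \deqn{\mu = 2 \log \tan((\phi+\gamma)/2),\quad
#'       \sigma^3 = \frac{16}{N^2}\,
#'       \frac{1}{\sin^2(\phi+\gamma)\,\sin\phi\,\sin\gamma}.}
#'
#' The constants are not symmetric in `(n1, n2)`: the group entering the
#' numerator of the greatest root (here the controls) plays the role of
#' `n2`. With `n1 = n2` both labelings coincide.
#'
#' @param p Number of markers.
#' @param n1 Sample size of the first group (cases, `d`).
#' @param n2 Sample size of the second group (controls, `n - d`).
#' @return Named numeric vector `c(mu, sigma)` with `sigma > 0`.
#' @export
centering_and_scaling <- function(p, n1, n2) {
  if (any(c(p, n1, n2) < 2)) stop("p, n1 and n2 must all be at least 2")
  N <- n1 + n2 - 1
  r_gamma <- (min(p, n2) - 0.5) / N
  r_phi <- (max(p, n2) - 0.5) / N
  if (r_phi >= 1) {
    stop("angle parameters undefined: (max(p, n2) - 0.5)/(n1 + n2 - 1) = ",
         signif(r_phi, 4), " >= 1")
  }
  if (r_gamma + r_phi >= 1) {
    stop("angle parameters out of domain: p must be smaller than n1 ",
         "(ratio sum = ", signif(r_gamma + r_phi, 4), " >= 1)")
  }
  gam <- 2 * asin(sqrt(r_gamma))
  phi <- 2 * asin(sqrt(r_phi))
  mu <- 2 * log(tan((phi + gam) / 2))
  sigma3 <- (16 / N^2) / (sin(phi + gam)^2 * sin(phi) * sin(gam))
  c(mu = mu, sigma = sigma3^(1 / 3))
}

#' Global epistasis test
#'
#' Tests the global null hypothesis that the population correlation matrix
#' of the markers among cases equals the one among controls -- equivalently,
#' that the pairwise LD structure is identical in the two subpopulations, as
#' it is when no marker pair interacts on the log-odds scale. The statistic
#' is the logit of the greatest root of the two-matrix function of the
#' partitioned sample correlation matrices, centered and scaled with
#' Johnstone's constants and referred to the upper tail of the Tracy-Widom
#' law of order 1.
#'
#' The greatest root has two orientations, depending on which partition's
#' weighted matrix forms the numerator: `"case"` uses the largest eigenvalue
#' of `(d S1 + (n-d) S0)^{-1} d S1` with Johnstone roles
#' `(p, n1 = n - d, n2 = d)`; `"control"` uses
#' `(d S1 + (n-d) S0)^{-1} (n-d) S0` with roles `(p, n1 = d, n2 = n - d)`.
#' Under the null and a balanced design the two calibrations coincide; under
#' case/control sampling the interaction-induced LD distortion loads
#' predominantly on the case partition, and the case orientation is the
#' markedly more sensitive test. It is the default, and is the orientation
#' whose operating characteristics the simulation harness reproduces.
#'
#' A significant result indicates that some interaction exists among the
#' tested markers; the test does not identify which pair drives it. The
#' Tracy-Widom approximation is asymptotic and degrades for `n/p < 5`
#' (a warning is issued); accuracy deviations are in the conservative
#' direction.
#'
#' @inheritParams partitioned_correlations
#' @param orientation Which partition forms the numerator of the greatest
#'   root: `"case"` (default) or `"control"`; see Details.
#' @return An object of class `get_result`: a list with `lambda1`, `mu`,
#'   `sigma`, `statistic` (T), `p_value`, `p` (marker count), `n1` (cases),
#'   `n2` (controls), `orientation`.
#' @export
#' @examples
#' gm <- genotype_model(p = 10, maf = 0.3)
#' g <- simulate_genotypes(gm, n = 400, seed = 7)
#' y <- simulate_phenotype(g, simulation_model(beta0 = 0, p = 10), seed = 8)
#' get_test(g, y)
get_test <- function(g, y, covariates = NULL, drop_degenerate = FALSE,
                     orientation = c("case", "control")) {
  orientation <- match.arg(orientation)
  pc <- partitioned_correlations(g, y, covariates = covariates,
                                 drop_degenerate = drop_degenerate)
  p <- length(pc$marker_ids)
  n1 <- pc$d
  n2 <- pc$n - pc$d
  if (p > min(n1, n2)) {
    warning("marker count p = ", p, " exceeds min(cases, controls) = ",
            min(n1, n2), "; the Tracy-Widom approximation may be unreliable")
  }
  if (pc$n / p < 5) {
    warning("n/p = ", signif(pc$n / p, 3),
            " < 5: the null approximation degrades in this regime")
  }
  spectrum <- .root_spectrum(pc)
  if (orientation == "case") {
    lambda1 <- 1 - spectrum[p]          # largest root, case numerator
    ms <- centering_and_scaling(p, n2, n1)
  } else {
    lambda1 <- spectrum[1L]             # largest root, control numerator
    ms <- centering_and_scaling(p, n1, n2)
  }
  lambda1 <- min(max(lambda1, 1e-12), 1 - 1e-12)
  statistic <- (qlogis(lambda1) - ms[["mu"]]) / ms[["sigma"]]
  structure(list(lambda1 = lambda1, mu = ms[["mu"]], sigma = ms[["sigma"]],
                 statistic = statistic, p_value = tw1_sf(statistic),
                 p = p, n1 = n1, n2 = n2, orientation = orientation),
            class = "get_result")
}

#' @export
print.get_result <- function(x, digits = 4, ...) {
  cat("Global epistasis test (greatest root vs Tracy-Widom order 1)\n")
  cat(sprintf("  markers p = %d, cases = %d, controls = %d\n",
              x$p, x$n1, x$n2))
  cat(sprintf("  lambda1 = %s, mu = %s, sigma = %s\n",
              signif(x$lambda1, digits), signif(x$mu, digits),
              signif(x$sigma, digits)))
  cat(sprintf("  T = %s, p-value = %s\n",
              signif(x$statistic, digits), signif(x$p_value, digits)))
  invisible(x)
}

#' @export
as.data.frame.get_result <- function(x, ...) {
  data.frame(lambda1 = x$lambda1, mu = x$mu, sigma = x$sigma,
             T = x$statistic, p_value = x$p_value,
             p = x$p, d = x$n1, n = x$n1 + x$n2)
}

#' Write a GET result to disk
#'
#' @param x A `get_result`.
#' @param file Output path.
#' @param format `"tsv"` (single header + single row) or `"json"`.
#' @return `file`, invisibly.
#' @export
write_get_result <- function(x, file, format = c("tsv", "json")) {
  stopifnot(inherits(x, "get_result"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(x), file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
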