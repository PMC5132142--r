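# Tracy-Widom law of order 1 (GOE edge distribution).
#
# F1 is evaluated from a table of CDF values precomputed by integrating the
# Painleve II equation q'' = t q + 2 q^3 with the Hastings-McLeod boundary
# condition q(t) ~ Ai(t) as t -> +Inf, together with the integrals needed by
# the Tracy-Widom determinantal formulas:
#
#   F2(s) = exp( -int_s^Inf (x - s) q(x)^2 dx )
#   F1(s) = sqrt( F2(s) ) * exp( -(1/2) int_s^Inf q(x) dx )
#
# The table ships with the package as a two-column text resource and is
# interpolated with a monotone (Hyman-filtered) cubic spline; outside the
# tabulated range [-12, 8] the CDF is clamped to 0/1, where the untabulated
# tail mass is below 1e-6.

.tw1_env <- new.env(parent = emptyenv())

.tw1_table_path <- function() {
  system.file("extdata", "tw1_cdf.tsv", package = "epiget", mustWork = TRUE)
}

.tw1_load <- function() {
  if (!is.null(.tw1_env$cdf_fun)) {
    return(invisible(NULL))
  }
  tab <- utils::read.table(.tw1_table_path(), header = TRUE, sep = "\t",
                           colClasses = "numeric")
  if (any(diff(tab$cdf) <= 0)) {
    stop("shipped TW1 table is not strictly increasing; regenerate it")
  }
  .tw1_env$grid <- tab$grid
  .tw1_env$cdf <- tab$cdf
  .tw1_env$cdf_fun <- stats::splinefun(tab$grid, tab$cdf, method = "hyman")
  invisible(NULL)
}

#' Tracy-Widom order-1 distribution function
#'
#' CDF of the Tracy-Widom law of order 1 (orthogonal ensemble), the limiting
#' law of the scaled largest eigenvalue of real Wishart-type random matrices
#' and the null reference for the global epistasis test statistic.
#'
#' @param t Numeric vector of quantiles (finite).
#' @return `F1(t)`, a probability in `[0, 1]` for each element of `t`.
#'   Values below/above the tabulated range `[-12, 8]` are clamped to 0/1;
#'   the tail mass outside that range is below 1e-6.
#' @seealso [tw1_sf()], [tw1_quantile()], [tw1_build_table()]
#' @export
#' @examples
#' tw1_cdf(0.9793)  # ~0.95, the standard 5% genome-scan threshold
tw1_cdf <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric")
  }
  .tw1_load()
  out <- numeric(length(t))
  lo <- t < .tw1_env$grid[1L]
  hi <- t > .tw1_env$grid[length(.tw1_env$grid)]
  mid <- !lo & !hi
  out[lo] <- 0
  out[hi] <- 1
  if (any(mid)) {
    out[mid] <- pmin(1, pmax(0, .tw1_env$cdf_fun(t[mid])))
  }
  out
}

#' Tracy-Widom order-1 survival function
#'
#' `1 - tw1_cdf(t)`; the upper-tail probability used as the GET p-value.
#'
#' @inheritParams tw1_cdf
#' @return `1 - F1(t)` for each element of `t`.
#' @export
tw1_sf <- function(t) {
  1 - tw1_cdf(t)
}

#' Tracy-Widom order-1 quantile function
#'
#' Inverse of [tw1_cdf()], solved by bisection on the monotone interpolant.
#'
#' @param q Probabilities strictly inside `(0, 1)`.
#' @return Quantiles `t` with `tw1_cdf(t)` equal to `q` to within 1e-6.
#' @export
#' @examples
#' round(tw1_quantile(c(0.95, 0.99)), 3)
tw1_quantile <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("'q' must be numeric in (0, 1)")
  }
  .tw1_load()
  grid <- .tw1_env$grid
  vapply(q, function(qi) {
    stats::uniroot(function(x) .tw1_env$cdf_fun(x) - qi,
                   lower = grid[1L], upper = grid[length(grid)],
                   tol = 1e-9)$root
  }, numeric(1))
}

# Airy Ai and Ai' for x > 0 via modified Bessel functions:
#   Ai(x)  =  (1/pi) sqrt(x/3) K_{1/3}(z),   z = (2/3) x^(3/2)
#   Ai'(x) = -(x / (pi sqrt(3))) K_{2/3}(z)
.airy_ai <- function(x) {
  z <- (2 / 3) * x^1.5
  sqrt(x / 3) / pi * besselK(z, 1 / 3)
}

.airy_ai_prime <- function(x) {
  z <- (2 / 3) * x^1.5
  -x / (pi * sqrt(3)) * besselK(z, 2 / 3)
}

# Initial state of the augmented Painleve II system at t0 (large positive),
# where the Hastings-McLeod solution coincides with Ai to working precision.
#   q, q'           : Airy values
#   R  = int_t^Inf q^2        (closed form: Ai'(t)^2 - t Ai(t)^2)
#   E  = int_t^Inf (x - t) q^2  (numerical quadrature of the Airy tail)
#   I1 = int_t^Inf q            (numerical quadrature)
.tw1_initial_state <- function(t0) {
  E0 <- stats::integrate(function(x) (x - t0) * .airy_ai(x)^2,
                         lower = t0, upper = Inf, rel.tol = 1e-12)$value
  I10 <- stats::integrate(.airy_ai, lower = t0, upper = Inf,
                          rel.tol = 1e-12)$value
  c(q = .airy_ai(t0),
    qp = .airy_ai_prime(t0),
    R = .airy_ai_prime(t0)^2 - t0 * .airy_ai(t0)^2,
    E = E0,
    I1 = I10)
}

.tw1_deriv <- function(t, state, parms) {
  list(c(state[["qp"]],
         t * state[["q"]] + 2 * state[["q"]]^3,
         -state[["q"]]^2,
         -state[["R"]],
         -state[["q"]]))
}

#' Rebuild the Tracy-Widom order-1 CDF table
#'
#' Integrates the Painleve II equation with the Hastings-McLeod boundary
#' condition from the Airy regime downwards and evaluates the order-1
#' Tracy-Widom CDF on a regular grid. This is the generator for the table
#' shipped in `inst/extdata/tw1_cdf.tsv`; end users never need to call it.
#'
#' @param lower,upper Grid end points (statistic scale).
#' @param step Grid spacing.
#' @param file Optional path; when given, the table is written there as TSV.
#' @return A data frame with columns `grid` and `cdf`, ascending in `grid`.
#' @export
tw1_build_table <- function(lower = -12, upper = 8, step = 0.01, file = NULL) {
  stopifnot(lower < upper, step > 0)
  t0 <- max(upper, 8)
  times <- c(t0, seq(upper, lower, by = -step))
  sol <- deSolve::lsoda(.tw1_initial_state(t0), times, .tw1_deriv,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
  sol <- sol[-1L, , drop = FALSE]  # drop the Airy anchor point
  cdf <- exp(-(sol[, "E"] + sol[, "I1"]) / 2)
  out <- data.frame(grid = rev(sol[, "time"]), cdf = rev(cdf))
  # guard against double-precision flatlining deep in the tails
  if (any(diff(out$cdf) <= 0)) {
    stop("integrated CDF not strictly increasing; tighten tolerances")
  }
  if (!is.null(file)) {
    dat <- data.frame(grid = sprintf("%.3f", out$grid),
                      cdf = sprintf("%.12e", out$cdf))
    utils::write.table(dat, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
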