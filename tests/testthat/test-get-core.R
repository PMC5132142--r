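make_data <- function(n = 120, p = 6, seed = 1, rho = 0) {
  g <- simulate_genotypes(genotype_model(p = p, maf = 0.4, rho = rho),
                          n = n, seed = seed)
  y <- rep(c(1L, 0L), length.out = n)
  list(g = g, y = y)
}

test_that("partitioned correlations: perfect correlation and structure", {
  d <- make_data()
  g <- cbind(d$g, dup = d$g[, 1])  # identical marker copy
  pc <- partitioned_correlations(g, d$y)
  expect_equal(pc$s_case[1, ncol(g)], 1.0)
  expect_equal(pc$s_control[1, ncol(g)], 1.0)
  expect_equal(diag(pc$s_case), rep(1, ncol(g)), ignore_attr = TRUE)
  expect_true(isSymmetric(pc$s_control))
  expect_true(all(abs(pc$s_case) <= 1 + 1e-12))
  expect_equal(pc$d, sum(d$y))
})

test_that("covariate adjustment matches the partial-correlation oracle", {
  set.seed(42)
  n <- 600
  covs <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  d <- make_data(n = n, p = 4, seed = 5)
  y <- d$y
  pc <- partitioned_correlations(d$g, y, covariates = covs)
  expect_true(pc$partial)
  # oracle: inverse-covariance partial correlation among cases
  cases <- y == 1
  oracle <- partial_cor_oracle(d$g[cases, ], covs[cases, ])
  expect_equal(unname(pc$s_case), oracle, tolerance = 1e-8)
  # covariates independent of markers: partial ~ plain, O(1/sqrt(n))
  plain <- partitioned_correlations(d$g, y)
  expect_lt(max(abs(pc$s_case - plain$s_case)), 5 / sqrt(n))
})

test_that("degenerate markers error by default and drop on request", {
  d <- make_data(n = 40, p = 3, seed = 2)
  g <- cbind(d$g, mono = rep(0L, 40))
  expect_error(partitioned_correlations(g, d$y), "mono")
  expect_warning(pc <- partitioned_correlations(g, d$y,
                                                drop_degenerate = TRUE),
                 "dropping")
  expect_equal(length(pc$marker_ids), 3)
  expect_error(partitioned_correlations(d$g, c(1L, rep(0L, 39))),
               "partition too small")
})

test_that("greatest root: closed-form identities", {
  s <- diag(4)
  pc <- structure(list(s_case = s, s_control = s, d = 50, n = 100,
                       partial = FALSE, marker_ids = paste0("M", 1:4)),
                  class = "partitioned_correlations")
  expect_equal(greatest_root(pc), 0.5)
  # any shared correlation matrix: lambda1 = (n - d)/n regardless of S
  set.seed(7)
  s2 <- random_corr(5)
  pc2 <- structure(list(s_case = s2, s_control = s2, d = 30, n = 100,
                        partial = FALSE, marker_ids = paste0("M", 1:5)),
                   class = "partitioned_correlations")
  expect_equal(greatest_root(pc2), 70 / 100, tolerance = 1e-12)
})

test_that("greatest root matches brute-force inversion on random pairs", {
  set.seed(11)
  for (rep in 1:5) {
    s1 <- random_corr(5)
    s0 <- random_corr(5)
    d <- sample(20:80, 1)
    n <- d + sample(20:80, 1)
    pc <- structure(list(s_case = s1, s_control = s0, d = d, n = n,
                         partial = FALSE, marker_ids = paste0("M", 1:5)),
                    class = "partitioned_correlations")
    brute <- max(Re(eigen(solve(d * s1 + (n - d) * s0) %*%
                            ((n - d) * s0))$values))
    expect_equal(greatest_root(pc), brute, tolerance = 1e-10)
  }
})

test_that("centering/scaling matches an independent transcription", {
  # second, separate coding of the trigonometric constants
  oracle <- function(p, n1, n2) {
    N <- n1 + n2 - 1
    gam <- 2 * asin(sqrt((min(p, n2) - 0.5) / N))
    phi <- 2 * asin(sqrt((max(p, n2) - 0.5) / N))
    c(2 * log(sin((phi + gam) / 2) / cos((phi + gam) / 2)),
      ((16 / N^2) / (sin(phi + gam)^2 * sin(phi) * sin(gam)))^(1 / 3))
  }
  for (args in list(c(10, 100, 100), c(50, 500, 500), c(50, 2000, 2000),
                    c(20, 300, 150))) {
    got <- centering_and_scaling(args[1], args[2], args[3])
    expect_equal(unname(got), oracle(args[1], args[2], args[3]),
                 tolerance = 1e-12)
  }
  expect_gt(centering_and_scaling(50, 500, 500)[["sigma"]], 0)
})

test_that("centering/scaling asymmetry and domain errors", {
  a <- centering_and_scaling(10, 200, 100)
  b <- centering_and_scaling(10, 100, 200)
  expect_false(isTRUE(all.equal(a, b)))              # labeling matters
  expect_equal(centering_and_scaling(10, 150, 150),
               centering_and_scaling(10, 150, 150))  # and is deterministic
  expect_error(centering_and_scaling(300, 100, 100), "domain|angle")
  expect_error(centering_and_scaling(1, 100, 100), "at least 2")
})

test_that("get_test chains components and is permutation invariant", {
  d <- make_data(n = 400, p = 8, seed = 3)
  res <- get_test(d$g, d$y)
  expect_s3_class(res, "get_result")
  expect_gt(res$lambda1, 0); expect_lt(res$lambda1, 1)
  expect_equal(res$p_value, tw1_sf(res$statistic))
  expect_equal(res$statistic,
               (qlogis(res$lambda1) - res$mu) / res$sigma)
  # marker permutation leaves the result unchanged
  perm <- sample(ncol(d$g))
  res_p <- get_test(d$g[, perm], d$y)
  expect_equal(res_p$statistic, res$statistic, tolerance = 1e-12)
  # subject permutation within phenotype class leaves it unchanged
  idx <- seq_along(d$y)
  idx[d$y == 1] <- sample(idx[d$y == 1])
  res_s <- get_test(d$g[idx, ], d$y[idx])
  expect_equal(res_s$statistic, res$statistic, tolerance = 1e-12)
})

test_that("relabeling cases and controls changes the statistic", {
  d <- make_data(n = 401, p = 8, seed = 4)   # odd n: unbalanced split
  y <- c(rep(1L, 180), rep(0L, 221))
  a <- get_test(d$g, y)
  b <- get_test(d$g, 1L - y)
  expect_false(isTRUE(all.equal(a$statistic, b$statistic)))
})

test_that("identical case and control partitions hit the closed form", {
  set.seed(9)
  half <- simulate_genotypes(genotype_model(p = 5, maf = 0.4), n = 100)
  g <- rbind(half, half)                     # exact copies
  y <- rep(c(1L, 0L), each = 100)
  res <- get_test(g, y)                      # S1 = S0, balanced
  ms <- centering_and_scaling(5, 100, 100)
  expect_equal(res$statistic,
               (qlogis(0.5) - ms[["mu"]]) / ms[["sigma"]],
               tolerance = 1e-9)
  # control orientation: same closed form when balanced
  res_c <- get_test(g, y, orientation = "control")
  expect_equal(res_c$statistic, res$statistic, tolerance = 1e-9)
})

test_that("the two orientations are complementary roots", {
  d <- make_data(n = 300, p = 6, seed = 13)
  y <- c(rep(1L, 120), rep(0L, 180))
  pc <- partitioned_correlations(d$g, y)
  res_ctrl <- get_test(d$g, y, orientation = "control")
  expect_equal(res_ctrl$lambda1, greatest_root(pc), tolerance = 1e-12)
  res_case <- get_test(d$g, y, orientation = "case")
  # case root = 1 - smallest control-oriented eigenvalue
  expect_lt(res_case$lambda1, 1); expect_gt(res_case$lambda1, 0)
  expect_gt(res_case$lambda1 + res_ctrl$lambda1, 1 - 1e-9)  # top roots sum > 1
})

test_that("low n/p triggers a warning, and output round-trips to disk", {
  d <- make_data(n = 60, p = 20, seed = 6)
  expect_warning(res <- get_test(d$g, d$y), "n/p")
  tf <- tempfile(fileext = ".tsv")
  write_get_result(res, tf)
  back <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(back$p_value, res$p_value, tolerance = 1e-12)
  tj <- tempfile(fileext = ".json")
  write_get_result(res, tj, format = "json")
  expect_equal(jsonlite::read_json(tj)$lambda1, res$lambda1,
               tolerance = 1e-12)
})
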