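# Experiment harness: type-I-error and power grids, the five-SNP worked
# example, and the Tracy-Widom calibration study.
#
# Reproducibility scheme: every replicate draws its RNG seed as
# derive_seed(master_seed, cell_id, replicate, attempt), so a report is a
# pure function of (grid, reps, master seed) regardless of execution order,
# and a rare failing replicate (e.g. a degenerate marker at small n) can be
# regenerated deterministically (up to 3 attempts, counted in the report).

#' Run one simulation cell
#'
#' Simulates `reps` case/control data sets under one design (copula
#' genotypes + logistic phenotype + balanced subsampling) and applies the
#' global epistasis test and/or the two-stage benchmark to each, recording
#' rejection rates at level `alpha`. Interaction pairs, when requested, are
#' drawn uniformly without replacement from the eligible pair set, fresh
#' for every replicate.
#'
#' @param n_subjects Data set size after subsampling (split evenly into
#'   cases and controls).
#' @param p Number of SNPs.
#' @param rho Latent copula correlation between SNPs.
#' @param maf Allele-frequency law passed to [genotype_model()].
#' @param beta0 Intercept log-odds of the phenotype model.
#' @param marginal_idx,marginal_beta Markers carrying marginal effects and
#'   their common coefficient.
#' @param interaction_pool Marker indices eligible for interaction pairs
#'   (`NULL` for none).
#' @param n_interactions Number of pairs drawn per replicate.
#' @param interaction_beta Log-odds interaction coefficient.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @param cell_id Integer folded into the per-replicate seed stream.
#' @param alpha Nominal test level.
#' @param methods Which tests to run: subset of `c("get", "benchmark")`.
#' @param keep_pvalues If `TRUE`, attach the per-replicate p-value matrix.
#' @return A one-row data frame with the design, rejection rates, binomial
#'   MC standard errors, failure count and the master seed.
#' @export
run_simulation_cell <- function(n_subjects, p = 50, rho = 0,
                                maf = c(0.25, 0.75), beta0,
                                marginal_idx = integer(),
                                marginal_beta = 0,
                                interaction_pool = NULL,
                                n_interactions = 0,
                                interaction_beta = 0,
                                reps = 1000, seed = 1, cell_id = 1,
                                alpha = 0.05,
                                methods = c("get", "benchmark"),
                                keep_pvalues = FALSE) {
  stopifnot(reps >= 1, n_subjects >= 4)
  methods <- match.arg(methods, several.ok = TRUE)
  n_cases <- n_subjects %/% 2
  n_controls <- n_subjects - n_cases
  gm <- genotype_model(p = p, maf = maf, rho = rho)
  pair_set <- if (!is.null(interaction_pool) && n_interactions > 0) {
    t(utils::combn(interaction_pool, 2))
  } else NULL

  pv <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("get", "benchmark")))
  failures <- 0L
  for (r in seq_len(reps)) {
    for (attempt in 1:3) {
      res <- tryCatch({
        set.seed(derive_seed(seed, cell_id, r, attempt))
        interactions <- NULL
        if (!is.null(pair_set)) {
          pick <- pair_set[sample.int(nrow(pair_set), n_interactions), ,
                           drop = FALSE]
          interactions <- data.frame(i = pick[, 1L], j = pick[, 2L],
                                     beta = interaction_beta)
        }
        sm <- simulation_model(beta0 = beta0, p = p,
                               marginal_idx = marginal_idx,
                               marginal_beta = marginal_beta,
                               interactions = interactions)
        dat <- simulate_case_control(gm, sm, n_cases, n_controls)
        out <- c(get = NA_real_, benchmark = NA_real_)
        if ("get" %in% methods) {
          out["get"] <- get_test(dat$genotypes, dat$phenotype)$p_value
        }
        if ("benchmark" %in% methods) {
          out["benchmark"] <- benchmark_global_test(dat$genotypes,
                                                    dat$phenotype)
        }
        out
      }, error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      failures <- failures + 1L
    } else {
      pv[r, ] <- res
    }
  }

  ok <- !is.na(pv[, 1L]) | !is.na(pv[, 2L])
  used <- sum(ok)
  rate <- function(col) {
    if (!col %in% methods || used == 0L) return(NA_real_)
    mean(pv[ok, col] < alpha)
  }
  r_get <- rate("get")
  r_bm <- rate("benchmark")
  out <- data.frame(cell_id = cell_id, n = n_subjects, p = p, rho = rho,
                    beta0 = beta0,
                    marginal = length(marginal_idx) > 0,
                    n_interactions = n_interactions,
                    reps = reps, used = used, failures = failures,
                    alpha = alpha,
                    get_rate = r_get,
                    get_se = sqrt(r_get * (1 - r_get) / used),
                    benchmark_rate = r_bm,
                    benchmark_se = sqrt(r_bm * (1 - r_bm) / used),
                    seed = seed)
  if (keep_pvalues) attr(out, "pvalues") <- pv
  out
}

#' Type-I-error simulation grid
#'
#' All 20 null cells: subjects in {250, 500, 1000, 2000, 4000} crossed with
#' copula correlation {0, 0.1} and two coefficient settings (no marginal
#' effects with `beta0 = -5`, or marginal effects `log(1.15)` on the first
#' ten SNPs with `beta0 = -2`); 50 SNPs with MAF ~ U(0.25, 0.75), no
#' interactions, balanced case/control subsampling.
#'
#' @param reps Replicates per cell.
#' @param seed Master seed.
#' @param alpha Nominal level.
#' @param cells Optional integer subset of cell ids (1-20) to run.
#' @param methods Tests to run per replicate.
#' @return Data frame with one row per cell (rates, MC standard errors,
#'   failure counts); master seed attached as attribute `"master_seed"`.
#' @export
run_type1_grid <- function(reps = 1000, seed = 1, alpha = 0.05,
                           cells = NULL, methods = c("get", "benchmark")) {
  grid <- expand.grid(n = c(250, 500, 1000, 2000, 4000),
                      rho = c(0, 0.1),
                      marginal = c(TRUE, FALSE))
  grid$cell_id <- seq_len(nrow(grid))
  if (!is.null(cells)) grid <- grid[grid$cell_id %in% cells, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gl <- grid[i, ]
    run_simulation_cell(
      n_subjects = gl$n, rho = gl$rho,
      beta0 = if (gl$marginal) -2 else -5,
      marginal_idx = if (gl$marginal) 1:10 else integer(),
      marginal_beta = if (gl$marginal) log(1.15) else 0,
      reps = reps, seed = seed, cell_id = gl$cell_id,
      alpha = alpha, methods = methods)
  })
  out <- do.call(rbind, rows)
  attr(out, "master_seed") <- seed
  out
}

# eligible interaction pools for the three power models, given p markers
.power_model_design <- function(model, p = 50) {
  switch(as.character(model),
         "1" = list(beta0 = -3, marginal_idx = 1:10,
                    marginal_beta = log(1.15), pool = 1:10),
         "2" = list(beta0 = -3, marginal_idx = 1:10,
                    marginal_beta = log(1.15), pool = 6:p),
         "3" = list(beta0 = -1, marginal_idx = integer(),
                    marginal_beta = 0, pool = 1:p),
         stop("model must be 1, 2 or 3"))
}

#' Power simulation grid
#'
#' The 15 power cells: subjects in {250, 500, 1000, 2000, 4000} crossed with
#' three coefficient models, independent SNPs (`rho = 0`), five interaction
#' pairs at `log(2)` drawn fresh per replicate from each model's eligible
#' pair set: model 1 pairs among the main-effect SNPs 1-10, model 2 pairs
#' among the non-main-effect SNPs 6-50, model 3 pairs among all SNPs with
#' no marginal effects anywhere.
#'
#' @inheritParams run_type1_grid
#' @param cells Optional subset of cell ids (1-15).
#' @return Data frame with one row per cell.
#' @export
run_power_grid <- function(reps = 1000, seed = 1, alpha = 0.05,
                           cells = NULL, methods = c("get", "benchmark")) {
  grid <- expand.grid(n = c(250, 500, 1000, 2000, 4000), model = 1:3)
  grid$cell_id <- 100L + seq_len(nrow(grid))
  if (!is.null(cells)) {
    grid <- grid[grid$cell_id %in% c(cells, 100L + cells), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gl <- grid[i, ]
    des <- .power_model_design(gl$model)
    cell <- run_simulation_cell(
      n_subjects = gl$n, beta0 = des$beta0,
      marginal_idx = des$marginal_idx, marginal_beta = des$marginal_beta,
      interaction_pool = des$pool, n_interactions = 5,
      interaction_beta = log(2),
      reps = reps, seed = seed, cell_id = gl$cell_id,
      alpha = alpha, methods = methods)
    cell$model <- gl$model
    cell
  })
  out <- do.call(rbind, rows)
  attr(out, "master_seed") <- seed
  out
}

#' Averaged partitioned correlations for the five-SNP worked example
#'
#' Replicates the illustrative design: five SNPs at MAF 0.25 with latent
#' copula correlation 0.1, phenotype from
#' `logit P(Y=1|G) = -1 + log(1.5) G1 + log(1.5) G2 + log(3) G1 G2`,
#' 500 cases and 500 controls subsampled per data set, and the case and
#' control sample correlation matrices averaged over the replicates. The
#' interacting pair shows a case/control correlation gap an order of
#' magnitude larger than the background pairs.
#'
#' @param reps Number of replicated data sets (20 in the worked example).
#' @param seed Master seed.
#' @return A list with `s_case_mean`, `s_control_mean`, `interacting_gap`
#'   (absolute case/control difference for the SNP1-SNP2 entry),
#'   `background_gap` (mean absolute difference over the other nine pairs)
#'   and `reps`.
#' @export
run_table1_demo <- function(reps = 20, seed = 1) {
  stopifnot(reps >= 1)
  gm <- genotype_model(p = 5, maf = 0.25, rho = 0.1)
  sm <- simulation_model(beta0 = -1, p = 5, marginal_idx = 1:2,
                         marginal_beta = log(1.5),
                         interactions = data.frame(i = 1, j = 2,
                                                   beta = log(3)))
  acc1 <- acc0 <- matrix(0, 5, 5)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 999, r, 1))
    dat <- simulate_case_control(gm, sm, 500, 500)
    pc <- partitioned_correlations(dat$genotypes, dat$phenotype)
    acc1 <- acc1 + pc$s_case
    acc0 <- acc0 + pc$s_control
  }
  s1 <- acc1 / reps
  s0 <- acc0 / reps
  off <- which(upper.tri(s1), arr.ind = TRUE)
  gaps <- abs(s1[off] - s0[off])
  interacting <- abs(s1[1, 2] - s0[1, 2])
  background <- mean(gaps[!(off[, 1L] == 1 & off[, 2L] == 2)])
  list(s_case_mean = s1, s_control_mean = s0,
       interacting_gap = interacting, background_gap = background,
       reps = reps)
}

#' Null calibration of the statistic against the Tracy-Widom law
#'
#' Simulates two collections of null data sets (no interactions, MAF 0.25,
#' independent SNPs): one without any effects (intercept 0) and one with a
#' marginal association of `log(1.5)` for the first five SNPs (intercept
#' -1, offsetting the mean marginal contribution so prevalence stays near
#' one half in both collections; the case count is the Bernoulli draw, no
#' subsampling). For each collection
#' the empirical distribution of the statistic T is compared to the
#' Tracy-Widom order-1 law: Kolmogorov-Smirnov distance, and the empirical
#' rejection rate at the TW 0.95 quantile (expected at or conservatively
#' below 0.05).
#'
#' @param reps Data sets per collection.
#' @param n,p Subjects and SNPs per data set.
#' @param seed Master seed.
#' @param marginal_beta Marginal log-odds effect for the second collection.
#' @return A list of two collection reports (`no_effects`, `marginal`),
#'   each with elements `statistics`, `ks_distance`, `tail_rate` (rejection
#'   at the TW 0.95 quantile), `tail_se` and `tail_deviation`
#'   (`tail_rate - 0.05`; negative = conservative).
#' @export
run_calibration <- function(reps = 2500, n = 500, p = 100, seed = 1,
                            marginal_beta = log(1.5)) {
  if (reps < 1) stop("empty report: 'reps' must be at least 1")
  q95 <- tw1_quantile(0.95)
  gm <- genotype_model(p = p, maf = 0.25, rho = 0)
  one_collection <- function(cell_id, marginal_idx, beta0) {
    sm <- simulation_model(beta0 = beta0, p = p, marginal_idx = marginal_idx,
                           marginal_beta = marginal_beta)
    stats_t <- numeric(reps)
    for (r in seq_len(reps)) {
      for (attempt in 1:3) {
        res <- tryCatch({
          set.seed(derive_seed(seed, cell_id, r, attempt))
          g <- .sim_geno_raw(n, rep(0.25, p), 0)
          y <- simulate_phenotype(g, sm)
          get_test(g, y)$statistic
        }, error = function(e) NULL)
        if (!is.null(res)) break
      }
      stats_t[r] <- if (is.null(res)) NA_real_ else res
    }
    stats_t <- stats_t[!is.na(stats_t)]
    tail_rate <- mean(stats_t > q95)
    ks <- suppressWarnings(ks.test(stats_t, tw1_cdf)$statistic)
    list(statistics = stats_t, ks_distance = unname(ks),
         tail_rate = tail_rate,
         tail_se = sqrt(tail_rate * (1 - tail_rate) / length(stats_t)),
         tail_deviation = tail_rate - 0.05)
  }
  # the marginal collection's intercept offsets the mean marginal
  # contribution (5 * log(1.5) * E[G] ~ 1), keeping prevalence near 1/2
  list(no_effects = one_collection(2001L, integer(), beta0 = 0),
       marginal = one_collection(2002L, 1:5, beta0 = -1),
       tw_q95 = q95, reps = reps, n = n, p = p, seed = seed)
}
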