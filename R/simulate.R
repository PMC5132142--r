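# Genotype and phenotype simulators: correlated Binomial(2, MAF) SNPs via a
# Gaussian copula with exchangeable latent correlation, logistic phenotype
# models with marginal and pairwise-interaction effects, pool-then-subsample
# case/control designs, and a configurable disease-architecture generator.

#' Genotype model specification
#'
#' @param p Number of SNPs.
#' @param maf Allele frequency law: a single value, a length-2 range for
#'   per-SNP uniform draws (one draw per SNP per data set), or a length-`p`
#'   vector of fixed frequencies. Values must lie in (0, 1); following the
#'   usual simulation convention the full range (including values above 0.5)
#'   is taken literally.
#' @param rho Exchangeable latent Gaussian-copula correlation in `[0, 1)`.
#' @return An object of class `genotype_model`.
#' @export
#' @examples
#' genotype_model(p = 50, maf = c(0.25, 0.75), rho = 0.1)
genotype_model <- function(p, maf = 0.25, rho = 0) {
  stopifnot(p >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("'rho' must be a single value in [0, 1)")
  }
  if (!is.numeric(maf) || any(maf <= 0) || any(maf >= 1)) {
    stop("'maf' values must lie strictly inside (0, 1)")
  }
  if (!length(maf) %in% c(1L, 2L, p)) {
    stop("'maf' must be a single value, a length-2 range, or length p")
  }
  structure(list(p = as.integer(p), maf = maf, rho = rho),
            class = "genotype_model")
}

.draw_mafs <- function(model) {
  if (length(model$maf) == 2L && model$p != 2L) {
    runif(model$p, model$maf[1L], model$maf[2L])
  } else if (length(model$maf) == 1L) {
    rep(model$maf, model$p)
  } else {
    model$maf
  }
}

# uniform-to-genotype map: the Binomial(2, maf) quantile function written as
# two threshold comparisons, P(G = 0) = (1-m)^2, P(G <= 1) = 1 - m^2
.u_to_geno <- function(u, mafs, n, p) {
  t0 <- rep((1 - mafs)^2, each = n)
  t1 <- rep(1 - mafs^2, each = n)
  g <- (u > t0) + (u > t1)
  dim(g) <- c(n, p)
  g
}

# raw generator without identifiers; mafs drawn beforehand (once per data set)
.sim_geno_raw <- function(n, mafs, rho) {
  p <- length(mafs)
  if (rho == 0) {
    u <- runif(n * p)
  } else {
    z <- sqrt(rho) * rnorm(n) + sqrt(1 - rho) * rnorm(n * p)
    u <- pnorm(z)
  }
  .u_to_geno(u, mafs, n, p)
}

#' Simulate additive-coded genotypes through a Gaussian copula
#'
#' Draws latent standard-normal rows with exchangeable correlation `rho`,
#' maps each column through the standard-normal CDF and then through the
#' Binomial(2, MAF) quantile function, producing correlated 0/1/2 allele
#' counts under Hardy-Weinberg marginals. A latent `rho` of 0.1 yields a
#' genotype-scale Pearson correlation of about 0.1.
#'
#' @param model A [genotype_model()].
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x p` integer matrix with marker column names; the allele
#'   frequencies used are attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "genotype_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mafs <- .draw_mafs(model)
  g <- .sim_geno_raw(n, mafs, model$rho)
  dimnames(g) <- list(paste0("S", seq_len(n)), paste0("SNP", seq_len(model$p)))
  attr(g, "maf") <- mafs
  g
}

#' Logistic phenotype model specification
#'
#' Linear predictor on the log-odds scale:
#' `beta0 + sum_i marginal[i] * G_i + sum_(i,j) beta_ij * G_i * G_j`.
#'
#' @param beta0 Intercept log-odds.
#' @param p Number of markers the model refers to.
#' @param marginal Either a length-`p` coefficient vector or a named
#'   shorthand via `marginal_idx`/`marginal_beta`.
#' @param marginal_idx,marginal_beta Indices and common coefficient for
#'   markers with marginal effects (used when `marginal` is `NULL`).
#' @param interactions Data frame with columns `i`, `j`, `beta` listing
#'   pairwise interaction terms (distinct pairs, `i != j`), or `NULL`.
#' @return An object of class `simulation_model`.
#' @export
#' @examples
#' # worked five-SNP example: marginal log(1.5) on SNPs 1-2, interaction log 3
#' simulation_model(beta0 = -1, p = 5, marginal_idx = 1:2,
#'                  marginal_beta = log(1.5),
#'                  interactions = data.frame(i = 1, j = 2, beta = log(3)))
simulation_model <- function(beta0, p, marginal = NULL,
                             marginal_idx = integer(), marginal_beta = 0,
                             interactions = NULL) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  if (is.null(marginal)) {
    marginal <- numeric(p)
    marginal[marginal_idx] <- marginal_beta
  }
  if (length(marginal) != p) stop("'marginal' must have length p")
  if (is.null(interactions)) {
    interactions <- data.frame(i = integer(), j = integer(), beta = numeric())
  }
  stopifnot(all(c("i", "j", "beta") %in% names(interactions)))
  if (nrow(interactions) > 0L) {
    if (any(interactions$i == interactions$j)) {
      stop("interaction pairs must involve two distinct markers")
    }
    key <- paste(pmin(interactions$i, interactions$j),
                 pmax(interactions$i, interactions$j))
    if (anyDuplicated(key)) stop("interaction pairs must be distinct")
    if (any(c(interactions$i, interactions$j) > p)) {
      stop("interaction indices exceed marker count")
    }
    if (any(!is.finite(interactions$beta))) stop("coefficients must be finite")
  }
  structure(list(beta0 = beta0, p = as.integer(p), marginal = marginal,
                 interactions = interactions),
            class = "simulation_model")
}

.linear_predictor <- function(g, model) {
  eta <- rep(model$beta0, nrow(g))
  nz <- which(model$marginal != 0)
  if (length(nz) > 0L) {
    eta <- eta + g[, nz, drop = FALSE] %*% model$marginal[nz]
  }
  if (nrow(model$interactions) > 0L) {
    for (r in seq_len(nrow(model$interactions))) {
      eta <- eta + model$interactions$beta[r] *
        g[, model$interactions$i[r]] * g[, model$interactions$j[r]]
    }
  }
  as.numeric(eta)
}

#' Simulate a binary phenotype from the logistic interaction model
#'
#' One Bernoulli draw per subject with success probability
#' `plogis(linear predictor)`.
#'
#' @param g Genotype matrix.
#' @param model A [simulation_model()] with `p == ncol(g)`.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of length `nrow(g)`.
#' @export
simulate_phenotype <- function(g, model, seed = NULL) {
  stopifnot(inherits(model, "simulation_model"))
  if (model$p != ncol(g)) stop("model refers to ", model$p,
                               " markers but g has ", ncol(g))
  if (!is.null(seed)) set.seed(seed)
  prob <- plogis(.linear_predictor(g, model))
  as.integer(runif(nrow(g)) < prob)
}

#' Subsample a case/control data set from a simulated pool
#'
#' Uniform sampling without replacement within each phenotype class,
#' followed by a random permutation of the output rows.
#'
#' @param g Pool genotype matrix.
#' @param y Pool phenotype.
#' @param n_cases,n_controls Requested class counts.
#' @param seed Optional integer seed.
#' @return A list with elements `genotypes` and `phenotype`.
#' @export
subsample_case_control <- function(g, y, n_cases, n_controls, seed = NULL) {
  if (length(y) != nrow(g)) stop("phenotype length must match pool rows")
  if (!is.null(seed)) set.seed(seed)
  cases <- which(y == 1)
  controls <- which(y == 0)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop("insufficient cases/controls in pool: have ", length(cases), "/",
         length(controls), ", need ", n_cases, "/", n_controls,
         " (pool prevalence ", signif(mean(y), 3), ")")
  }
  pick <- c(sample(cases, n_cases), sample(controls, n_controls))
  pick <- sample(pick)
  list(genotypes = g[pick, , drop = FALSE], phenotype = as.integer(y[pick]))
}

#' Simulate a complete case/control data set
#'
#' Grows a pool of subjects in blocks of `10 * (n_cases + n_controls)` until
#' both class counts are met (capped at `100 *` the target size), then
#' subsamples a balanced-by-request data set. Allele frequencies are drawn
#' once per data set. When the phenotype model has no genotype-dependent
#' terms at all, genotypes are independent of case status, and the pool is
#' bypassed: genotypes are drawn directly for the sampled subjects -- an
#' exact distributional identity, not an approximation.
#'
#' @param gen_model A [genotype_model()].
#' @param sim_model A [simulation_model()].
#' @param n_cases,n_controls Requested class counts.
#' @param seed Optional integer seed.
#' @param pool_block,pool_cap Pool growth block size and hard cap
#'   (multiples of `n_cases + n_controls`).
#' @return A list with `genotypes`, `phenotype`, `maf`.
#' @export
simulate_case_control <- function(gen_model, sim_model, n_cases, n_controls,
                                  seed = NULL, pool_block = 10,
                                  pool_cap = 100) {
  stopifnot(inherits(gen_model, "genotype_model"),
            inherits(sim_model, "simulation_model"),
            n_cases >= 1, n_controls >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_target <- n_cases + n_controls
  mafs <- .draw_mafs(gen_model)

  null_model <- all(sim_model$marginal == 0) &&
    nrow(sim_model$interactions) == 0L
  if (null_model) {
    # genotypes independent of phenotype: draw them for the sample directly
    g <- .sim_geno_raw(n_target, mafs, gen_model$rho)
    y <- sample(rep(c(1L, 0L), c(n_cases, n_controls)))
    colnames(g) <- paste0("SNP", seq_len(gen_model$p))
    return(list(genotypes = g, phenotype = y, maf = mafs))
  }

  block <- pool_block * n_target
  cap <- pool_cap * n_target
  g_pool <- NULL
  y_pool <- integer()
  total <- 0L
  while (total < cap) {
    nb <- min(block, cap - total)
    gb <- .sim_geno_raw(nb, mafs, gen_model$rho)
    yb <- simulate_phenotype(gb, sim_model)
    g_pool <- rbind(g_pool, gb)
    y_pool <- c(y_pool, yb)
    total <- total + nb
    if (sum(y_pool) >= n_cases && sum(y_pool == 0L) >= n_controls) break
  }
  if (sum(y_pool) < n_cases || sum(y_pool == 0L) < n_controls) {
    stop("pool cap of ", cap, " subjects reached with only ", sum(y_pool),
         " cases and ", sum(y_pool == 0L), " controls (pool prevalence ",
         signif(mean(y_pool), 3), ")")
  }
  out <- subsample_case_control(g_pool, y_pool, n_cases, n_controls)
  colnames(out$genotypes) <- paste0("SNP", seq_len(gen_model$p))
  out$maf <- mafs
  out
}

#' Disease risk-architecture specification
#'
#' A configurable architecture in the style of published per-disease
#' simulation models: known risk SNPs with per-SNP odds ratios, binary
#' environmental exposures with prevalences and odds ratios, a block of
#' null SNPs, and optional gene-gene interaction terms among the risk SNPs.
#' All variables are generated independently (no gene-environment terms and
#' no inter-variable correlation).
#'
#' @param risk_snps Data frame with columns `maf` and `or` (odds ratio > 0).
#' @param exposures Data frame with columns `prevalence` and `or`, or `NULL`.
#' @param n_null Number of null SNPs with no phenotype association.
#' @param null_maf Length-2 range for null-SNP allele frequencies.
#' @param gxg Data frame with columns `i`, `j` (indices into the risk SNPs)
#'   and `beta` (log-odds interaction effect), or `NULL`.
#' @param beta0 Intercept log-odds.
#' @return An object of class `disease_architecture`.
#' @export
disease_architecture <- function(risk_snps, exposures = NULL, n_null = 50,
                                 null_maf = c(0.05, 0.95), gxg = NULL,
                                 beta0 = -2) {
  stopifnot(is.data.frame(risk_snps), all(c("maf", "or") %in% names(risk_snps)))
  if (any(risk_snps$or <= 0)) stop("odds ratios must be positive")
  if (!is.null(exposures)) {
    stopifnot(all(c("prevalence", "or") %in% names(exposures)))
    if (any(exposures$or <= 0)) stop("odds ratios must be positive")
  }
  if (!is.null(gxg) && nrow(gxg) > 0L) {
    stopifnot(all(c("i", "j", "beta") %in% names(gxg)))
    if (any(gxg$i == gxg$j) || any(c(gxg$i, gxg$j) > nrow(risk_snps))) {
      stop("gxg pairs must index distinct risk SNPs")
    }
  }
  structure(list(risk_snps = risk_snps, exposures = exposures,
                 n_null = as.integer(n_null), null_maf = null_maf,
                 gxg = gxg, beta0 = beta0),
            class = "disease_architecture")
}

#' Simulate a disease-architecture case/control data set
#'
#' Risk SNPs, exposures and null SNPs are generated independently; the
#' binary outcome follows the logistic risk model implied by the
#' architecture; cases and controls are then pool-subsampled to the
#' requested balance as in [simulate_case_control()].
#'
#' @param arch A [disease_architecture()].
#' @param n_cases,n_controls Requested class counts.
#' @param seed Optional integer seed.
#' @inheritParams simulate_case_control
#' @return A list with `genotypes` (risk SNPs first, then null SNPs),
#'   `covariates` (exposure matrix or `NULL`), `phenotype`.
#' @export
simulate_disease <- function(arch, n_cases, n_controls, seed = NULL,
                             pool_block = 10, pool_cap = 100) {
  stopifnot(inherits(arch, "disease_architecture"))
  if (!is.null(seed)) set.seed(seed)
  n_target <- n_cases + n_controls
  n_risk <- nrow(arch$risk_snps)
  n_exp <- if (is.null(arch$exposures)) 0L else nrow(arch$exposures)
  null_mafs <- runif(arch$n_null, arch$null_maf[1L], arch$null_maf[2L])

  gen_block <- function(nb) {
    g_risk <- .sim_geno_raw(nb, arch$risk_snps$maf, 0)
    g_null <- if (arch$n_null > 0L) .sim_geno_raw(nb, null_mafs, 0) else NULL
    e <- if (n_exp > 0L) {
      matrix(rbinom(nb * n_exp, 1L, rep(arch$exposures$prevalence, each = nb)),
             nb, n_exp)
    } else NULL
    eta <- arch$beta0 + as.numeric(g_risk %*% log(arch$risk_snps$or))
    if (n_exp > 0L) eta <- eta + as.numeric(e %*% log(arch$exposures$or))
    if (!is.null(arch$gxg) && nrow(arch$gxg) > 0L) {
      for (r in seq_len(nrow(arch$gxg))) {
        eta <- eta + arch$gxg$beta[r] *
          g_risk[, arch$gxg$i[r]] * g_risk[, arch$gxg$j[r]]
      }
    }
    y <- as.integer(runif(nb) < plogis(eta))
    list(g = cbind(g_risk, g_null), e = e, y = y)
  }

  block <- pool_block * n_target
  cap <- pool_cap * n_target
  g_pool <- NULL; e_pool <- NULL; y_pool <- integer(); total <- 0L
  while (total < cap) {
    nb <- min(block, cap - total)
    bl <- gen_block(nb)
    g_pool <- rbind(g_pool, bl$g)
    if (n_exp > 0L) e_pool <- rbind(e_pool, bl$e)
    y_pool <- c(y_pool, bl$y)
    total <- total + nb
    if (sum(y_pool) >= n_cases && sum(y_pool == 0L) >= n_controls) break
  }
  if (sum(y_pool) < n_cases || sum(y_pool == 0L) < n_controls) {
    stop("pool cap of ", cap, " subjects reached with only ", sum(y_pool),
         " cases and ", sum(y_pool == 0L), " controls (pool prevalence ",
         signif(mean(y_pool), 3), ")")
  }
  cases <- sample(which(y_pool == 1L), n_cases)
  controls <- sample(which(y_pool == 0L), n_controls)
  pick <- sample(c(cases, controls))
  g_out <- g_pool[pick, , drop = FALSE]
  colnames(g_out) <- c(paste0("RISK", seq_len(n_risk)),
                       if (arch$n_null > 0L) paste0("NULL", seq_len(arch$n_null)))
  list(genotypes = g_out,
       covariates = if (n_exp > 0L) e_pool[pick, , drop = FALSE] else NULL,
       phenotype = as.integer(y_pool[pick]))
}
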