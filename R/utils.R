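# internal helpers shared across modules

.MINSTD <- 2147483647  # 2^31 - 1

# Deterministic per-replicate seed stream: fold the master seed and any
# number of index components through minstd LCG steps. Order-independent
# across cells/replicates so parallel execution reproduces serial results.
derive_seed <- function(master, ...) {
  parts <- c(...)
  s <- (abs(as.numeric(master)) %% .MINSTD)
  for (x in parts) {
    s <- (s * 48271 + as.numeric(x) + 1) %% .MINSTD
  }
  as.integer(s %% (.MINSTD - 1)) + 1L
}

.check_genotypes <- function(g, min_n = 1L, min_p = 1L) {
  if (!is.matrix(g) || !is.numeric(g)) {
    stop("genotypes must be a numeric matrix of 0/1/2 allele counts")
  }
  if (anyNA(g)) {
    stop("genotype matrix contains missing values; resolve missingness upstream")
  }
  if (!all(g %in% c(0, 1, 2))) {
    stop("genotype matrix entries must all be 0, 1 or 2 (additive coding)")
  }
  if (nrow(g) < min_n) stop("too few subjects: need at least ", min_n)
  if (ncol(g) < min_p) stop("too few markers: need at least ", min_p)
  invisible(g)
}

.check_phenotype <- function(y, n) {
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("phenotype must be binary 0/1 with no missing values")
  }
  if (length(y) != n) {
    stop("phenotype length (", length(y), ") does not match subject count (", n, ")")
  }
  d <- sum(y)
  if (d == 0 || d == length(y)) {
    stop("phenotype must contain both cases and controls")
  }
  as.integer(d)
}

.marker_ids <- function(g) {
  if (!is.null(colnames(g))) colnames(g) else paste0("SNP", seq_len(ncol(g)))
}
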