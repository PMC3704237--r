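# Shared fixtures and independent oracles for the test suite.

# A small, fast simulation configuration.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_sires = 8, daughters_per_sire = 6, records_per_daughter = 2,
         n_htd = 40, n_snps = 12, n_qtl = 0, seed = 42),
    list(...)
  )
  do.call(sim_config, args)
}

# Build a geno_matrix by hand from a dosage matrix.
make_geno <- function(calls, chrom = NULL, pos = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("S%04d", seq_len(n))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("snp%05d", seq_len(m))
  map <- tibble::tibble(
    snp = colnames(calls),
    chrom = if (is.null(chrom)) as.character(rep_len(1:29, m)) else as.character(chrom),
    pos = if (is.null(pos)) as.integer(seq_len(m) * 1000L) else as.integer(pos),
    allele1 = "A", allele2 = "B", counted_allele = "B"
  )
  reactnorm:::new_geno_matrix(calls, map)
}

# Random variance components for oracle-equality sweeps.
random_components <- function(mode, scale = 1e4) {
  list(Gs = random_cov2(0.1 * scale),
       Gd = if (mode == "heterogeneous") random_cov2(0.3 * scale)
            else matrix(0.3 * scale * stats::runif(1, 0.5, 2), 1, 1),
       sigma2_e = if (mode == "heterogeneous") stats::runif(10, 0.5, 1.5) * scale
                  else stats::runif(1, 0.5, 1.5) * scale)
}

# Random valid 2x2 covariance (for oracle-equality sweeps).
random_cov2 <- function(scale = 1) {
  v0 <- stats::runif(1, 0.5, 2) * scale
  v1 <- stats::runif(1, 0.05, 0.5) * scale
  rho <- stats::runif(1, -0.9, 0.9)
  matrix(c(v0, rho * sqrt(v0 * v1), rho * sqrt(v0 * v1), v1), 2, 2)
}

# Random acyclic pedigree: founders plus layered descendants whose parents
# are drawn from earlier individuals.
random_pedigree <- function(n_founders = 5, n_descendants = 20) {
  ids <- sprintf("P%03d", seq_len(n_founders + n_descendants))
  sire <- dam <- rep("0", n_founders + n_descendants)
  for (i in (n_founders + 1):(n_founders + n_descendants)) {
    pool <- ids[seq_len(i - 1)]
    parents <- sample(pool, 2)
    if (stats::runif(1) < 0.15) parents[2] <- "0"  # some unknown dams
    sire[i] <- parents[1]; dam[i] <- parents[2]
  }
  tibble::tibble(id = ids, sire = sire, dam = dam)
}

# Independent dense GLS/REML oracle for the single-SNP mixed model
# y = mu + x b + u + e, u ~ N(0, A s2u), e ~ N(0, I s2e): grid search over
# the variance ratio with a dense V solve (no eigendecomposition).
gls_snp_oracle <- function(y, x, A) {
  n <- length(y)
  X <- cbind(1, x)
  crit <- function(ld) {
    V <- exp(ld) * A + diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    sig2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
    ll <- -0.5 * ((n - 2) * (log(sig2) + 1 + log(2 * pi)) +
                    as.numeric(determinant(V)$modulus) +
                    as.numeric(determinant(XtViX)$modulus))
    list(ll = ll, beta = beta[2])
  }
  grid <- seq(-25, 15, by = 0.05)
  lls <- vapply(grid, function(g) crit(g)$ll, numeric(1))
  best <- grid[which.max(lls)]
  fine <- seq(best - 0.05, best + 0.05, by = 1e-4)
  lls2 <- vapply(fine, function(g) crit(g)$ll, numeric(1))
  best2 <- fine[which.max(lls2)]
  c(crit(best2), list(log_delta = best2))
}
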