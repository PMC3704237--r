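#' Minor allele frequency of one SNP
#'
#' @param calls Integer vector of 0/1/2 allele-copy counts, `NA` = missing.
#' @return `min(f, 1 - f)` with `f` the counted-allele frequency over
#'   non-missing calls.
#' @examples
#' compute_maf(c(2, 2, 1, 1))
#' @export
compute_maf <- function(calls) {
  ok <- !is.na(calls)
  if (!any(ok)) {
    abort("all calls missing; allele frequency undefined.",
          class = "reactnorm_domain_error")
  }
  f <- sum(calls[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Call rate of one SNP
#'
#' @param calls Integer vector of calls, `NA` = missing.
#' @return Fraction of non-missing calls.
#' @export
compute_call_rate <- function(calls) {
  if (length(calls) == 0) abort("no calls.", class = "reactnorm_domain_error")
  mean(!is.na(calls))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square (no continuity
#' correction) of observed genotype counts against the Hardy-Weinberg
#' expectations \eqn{n p^2, 2 n p q, n q^2} with the allele frequency
#' estimated from the counts.  A monomorphic SNP is defined to have p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return P-value.
#' @examples
#' hwe_test(30, 40, 30)  # chi-square 4, p ~= 0.0455
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("no genotypes.", class = "reactnorm_domain_error")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

hwe_test_calls <- function(calls) {
  ok <- !is.na(calls)
  hwe_test(sum(calls[ok] == 2), sum(calls[ok] == 1), sum(calls[ok] == 0))
}

#' Remove individuals with excessive genotype missingness
#'
#' Individuals with strictly more than `max_missing` missing calls are
#' removed; the order of survivors is preserved.
#'
#' @param geno A `geno_matrix`.
#' @param max_missing Missingness threshold (default 0.10).
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`
#'   (tibble: id, missingness, pass).
#' @export
filter_individuals <- function(geno, max_missing = 0.10) {
  stopifnot(inherits(geno, "geno_matrix"))
  miss <- rowMeans(is.na(geno$calls))
  pass <- miss <= max_missing
  if (!any(pass)) {
    abort("all individuals removed by the missingness filter.",
          class = "reactnorm_qc_error")
  }
  report <- tibble(id = rownames(geno$calls), missingness = miss, pass = pass)
  geno$calls <- geno$calls[pass, , drop = FALSE]
  if (!is.null(geno$complete)) geno$complete <- geno$complete[pass, , drop = FALSE]
  list(genotypes = geno, report = report)
}

#' SNP quality-control filter
#'
#' Removes SNPs with minor allele frequency below `maf_min`, call rate
#' below `call_rate_min`, Hardy-Weinberg p-value below `hwe_alpha`, unknown
#' genomic position, or a sex-chromosome label.  All comparisons are
#' strict, and every failure reason is recorded.  Individual filtering is
#' expected to have been applied first, so per-SNP statistics are computed
#' on the surviving individuals.
#'
#' @param geno A `geno_matrix`.
#' @param maf_min,call_rate_min,hwe_alpha Thresholds; set a threshold to 0
#'   to disable the corresponding filter.
#' @param sex_chroms Chromosome labels treated as sex chromosomes.
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`
#'   (tibble: snp, maf, call_rate, hwe_p, known_position, autosomal, pass,
#'   reasons).
#' @export
filter_snps <- function(geno, maf_min = 0.03, call_rate_min = 0.90,
                        hwe_alpha = 0.001, sex_chroms = c("X", "Y", "XY", "30")) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  map <- geno$map
  m <- ncol(calls)
  call_rate <- colMeans(!is.na(calls))
  maf <- vapply(seq_len(m), function(k) {
    if (call_rate[k] == 0) NA_real_ else compute_maf(calls[, k])
  }, numeric(1))
  hwe_p <- vapply(seq_len(m), function(k) {
    if (call_rate[k] == 0) NA_real_ else hwe_test_calls(calls[, k])
  }, numeric(1))
  known_pos <- !is.na(map$pos) & map$pos > 0
  autosomal <- !(toupper(map$chrom) %in% toupper(sex_chroms)) & !is.na(map$chrom)

  reasons <- vapply(seq_len(m), function(k) {
    r <- character()
    if (is.na(maf[k]) || maf[k] < maf_min) r <- c(r, "low_maf")
    if (call_rate[k] < call_rate_min) r <- c(r, "low_call_rate")
    if (!is.na(hwe_p[k]) && hwe_p[k] < hwe_alpha) r <- c(r, "hwe_deviation")
    if (!known_pos[k]) r <- c(r, "unknown_position")
    if (!autosomal[k]) r <- c(r, "sex_chromosome")
    paste(r, collapse = ";")
  }, character(1))
  pass <- reasons == ""

  report <- tibble(
    snp = map$snp, maf = maf, call_rate = call_rate, hwe_p = hwe_p,
    known_position = known_pos, autosomal = autosomal,
    pass = pass, reasons = reasons
  )
  geno$calls <- calls[, pass, drop = FALSE]
  if (!is.null(geno$complete)) geno$complete <- geno$complete[, pass, drop = FALSE]
  geno$map <- map[pass, , drop = FALSE]
  list(genotypes = geno, report = report)
}

#' Impute sporadic missing genotypes by the modal genotype class
#'
#' Each missing call is replaced by the most frequent observed genotype
#' class at that SNP.  Ties are broken toward the class nearest the
#' expected dosage `2f` (with `f` the counted-allele frequency); a residual
#' tie goes to the smaller class.  Non-missing calls are never changed.
#'
#' @param geno A `geno_matrix` (normally post-QC).
#' @return The `geno_matrix` with no missing calls.
#' @export
impute_sporadic <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  for (k in seq_len(ncol(calls))) {
    x <- calls[, k]
    na <- is.na(x)
    if (!any(na)) next
    if (all(na)) {
      abort(paste0("SNP ", geno$map$snp[k], " has no observed calls; ",
                   "it should have failed the call-rate filter."),
            class = "reactnorm_qc_error")
    }
    obs <- x[!na]
    counts <- vapply(0:2, function(g) sum(obs == g), integer(1))
    modal <- which(counts == max(counts)) - 1L
    if (length(modal) > 1) {
      f <- sum(obs) / (2 * length(obs))
      d <- abs(modal - 2 * f)
      modal <- modal[d == min(d)]
      modal <- min(modal)
    }
    calls[na, k] <- modal
  }
  geno$calls <- calls
  geno
}

#' Recode genotypes so the counted allele is the more frequent one
#'
#' Flips the dosage coding (`x -> 2 - x`) at every SNP whose counted-allele
#' frequency is below one half, so that after recoding each genotype counts
#' copies of the major allele.  Frequencies are computed on the full matrix
#' passed in, so the coding is fixed *before* any discovery/validation
#' split and effect signs are comparable across sets.  The recoding is
#' recorded in the map (`counted_allele`, `counted_freq`).
#'
#' @param geno A `geno_matrix`.
#' @return The recoded `geno_matrix`.
#' @export
recode_counted_allele <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  map <- geno$map
  freq <- vapply(seq_len(ncol(calls)), function(k) {
    x <- calls[, k]
    sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, numeric(1))
  flip <- !is.na(freq) & freq < 0.5
  calls[, flip] <- 2L - calls[, flip]
  if (!is.null(geno$complete)) geno$complete[, flip] <- 2L - geno$complete[, flip]
  map$counted_allele <- ifelse(flip, map$allele1, map$counted_allele)
  map$counted_freq <- ifelse(flip, 1 - freq, freq)
  geno$calls <- calls
  geno$map <- map
  geno
}

#' Full genotype quality control
#'
#' Applies, in order: individual missingness filtering, SNP filtering
#' (computed on the surviving individuals), modal imputation of sporadic
#' missing calls, and recoding to count the major allele.
#'
#' @inheritParams filter_individuals
#' @inheritParams filter_snps
#' @param impute Impute remaining sporadic missing calls (default `TRUE`).
#' @return List with `genotypes` and the two QC `report`s.
#' @export
run_genotype_qc <- function(geno, max_missing = 0.10, maf_min = 0.03,
                            call_rate_min = 0.90, hwe_alpha = 0.001,
                            impute = TRUE) {
  ind <- filter_individuals(geno, max_missing = max_missing)
  snp <- filter_snps(ind$genotypes, maf_min = maf_min,
                     call_rate_min = call_rate_min, hwe_alpha = hwe_alpha)
  g <- snp$genotypes
  if (impute) g <- impute_sporadic(g)
  g <- recode_counted_allele(g)
  list(genotypes = g, individual_report = ind$report, snp_report = snp$report)
}
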