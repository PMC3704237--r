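test_that("per-SNP statistics match hand computations", {
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 1, 1)), 0.25)
  expect_equal(compute_maf(c(1, 1, 1, 1)), 0.5)
  expect_equal(compute_maf(c(2, NA, 0)), 0.5)
  expect_error(compute_maf(c(NA, NA)), class = "reactnorm_domain_error")

  expect_equal(compute_call_rate(0:2), 1)
  expect_equal(compute_call_rate(c(1:9, NA)), 0.9)
  expect_equal(compute_call_rate(rep(NA_integer_, 4)), 0)

  expect_equal(hwe_test(25, 50, 25), 1)
  expect_equal(hwe_test(30, 40, 30), stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(hwe_test(50, 0, 50), 0.001)
  expect_equal(hwe_test(10, 0, 0), 1)  # monomorphic
})

test_that("individual filter removes strictly-above-threshold missingness", {
  set.seed(1)
  calls <- matrix(rbinom(20 * 100, 2, 0.4), 20, 100)
  calls[1, 1:11] <- NA   # 11% missing -> removed
  calls[2, 1:10] <- NA   # exactly 10% -> retained
  g <- make_geno(calls)
  res <- filter_individuals(g, max_missing = 0.10)
  expect_equal(nrow(res$genotypes$calls), 19)
  expect_false(res$report$pass[1])
  expect_true(res$report$pass[2])
  # no missing data: identity
  clean <- make_geno(matrix(rbinom(50, 2, 0.5), 5, 10))
  expect_identical(filter_individuals(clean)$genotypes$calls, clean$calls)
  allmiss <- make_geno(matrix(NA_integer_, 3, 4))
  expect_error(filter_individuals(allmiss), class = "reactnorm_qc_error")
})

test_that("SNP filter removes each violation for its recorded reason", {
  set.seed(2)
  n <- 200
  clean <- rbinom(n, 2, 0.4)
  low_maf <- rbinom(n, 2, 0.01)
  low_cr <- clean; low_cr[1:30] <- NA                      # call rate 0.85
  hwe_bad <- rep(c(0, 2), n / 2)                            # no heterozygotes
  calls <- cbind(clean, low_maf, low_cr, hwe_bad, clean, clean, clean)
  g <- make_geno(calls, chrom = c(1, 2, 3, 4, 5, 6, "X"),
                 pos = c(100, 200, 300, 400, NA, 600, 700))
  res <- filter_snps(g)
  expect_equal(sum(res$report$pass), 2)
  expect_equal(res$report$reasons[res$report$pass], c("", ""))
  expect_equal(res$report$reasons[2], "low_maf")
  expect_equal(res$report$reasons[3], "low_call_rate")
  expect_equal(res$report$reasons[4], "hwe_deviation")
  expect_equal(res$report$reasons[5], "unknown_position")
  expect_equal(res$report$reasons[7], "sex_chromosome")

  # pass flags exactly reproduce survivorship
  expect_identical(res$genotypes$map$snp, res$report$snp[res$report$pass])

  # idempotence
  res2 <- filter_snps(res$genotypes)
  expect_identical(res2$genotypes$calls, res$genotypes$calls)

  # thresholds at 0 disable the statistical filters
  res0 <- filter_snps(g, maf_min = 0, call_rate_min = 0, hwe_alpha = 0)
  expect_equal(res0$report$reasons[2:4], c("", "", ""))
})

test_that("modal imputation fills missing calls with the stated tie rule", {
  g <- make_geno(matrix(c(2, 2, 2, NA,
                          0, 0, 1, NA,
                          1, 1, 2, 2), 4, 3))
  out <- impute_sporadic(g)
  expect_false(anyNA(out$calls))
  expect_equal(out$calls[4, 1], 2)  # mode
  expect_equal(out$calls[4, 2], 0)  # mode
  # non-missing calls unchanged
  expect_identical(out$calls[1:3, ], g$calls[1:3, ])

  # tie case [0,0,2,2,NA]: classes {0,2} tie, 2f = 1 equidistant, smaller wins
  gt <- make_geno(matrix(c(0, 0, 2, 2, NA), 5, 1))
  expect_equal(impute_sporadic(gt)$calls[5, 1], 0)

  # no missing: identity
  expect_identical(impute_sporadic(make_geno(matrix(0:2, 3, 1)))$calls,
                   matrix(0:2, 3, 1, dimnames = list(sprintf("S%04d", 1:3), "snp00001")))

  gbad <- make_geno(matrix(NA_integer_, 3, 1))
  expect_error(impute_sporadic(gbad), class = "reactnorm_qc_error")
})

test_that("counted-allele recoding counts the major allele and flips signs only", {
  calls <- cbind(rbinom(100, 2, 0.2), rbinom(100, 2, 0.8))
  g <- make_geno(calls)
  out <- recode_counted_allele(g)
  expect_true(all(out$map$counted_freq >= 0.5))
  expect_equal(out$calls[, 1], 2 - calls[, 1], ignore_attr = TRUE)
  expect_equal(out$calls[, 2], calls[, 2], ignore_attr = TRUE)
  expect_equal(out$map$counted_allele[1], "A")
  expect_equal(out$map$counted_allele[2], "B")
})
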