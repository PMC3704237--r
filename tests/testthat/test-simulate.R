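test_that("genotype simulation respects frequencies, missingness, and the seed", {
  g0 <- simulate_genotypes(tiny_config(missing_rate = 0))
  expect_false(anyNA(g0$calls))
  expect_true(all(g0$calls %in% 0:2))

  # fixed f = 0.5: mean dosage 1 within binomial tolerance
  g <- simulate_genotypes(sim_config(n_sires = 10000, n_snps = 5,
                                     maf_range = c(0.5, 0.5), seed = 9))
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(g$calls) - 1) < 4 * se))

  gm <- simulate_genotypes(tiny_config(missing_rate = 0.2, seed = 5))
  rate <- mean(is.na(gm$calls))
  expect_gt(rate, 0.1); expect_lt(rate, 0.3)

  expect_identical(simulate_genotypes(tiny_config(seed = 3)),
                   simulate_genotypes(tiny_config(seed = 3)))
  expect_false(identical(simulate_genotypes(tiny_config(seed = 3))$calls,
                         simulate_genotypes(tiny_config(seed = 4))$calls))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "reactnorm_config_error")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), class = "reactnorm_config_error")
  expect_error(sim_config(rho_s = 1.2), class = "reactnorm_config_error")
  expect_error(sim_config(missing_rate = 1), class = "reactnorm_config_error")
  expect_error(sim_config(n_qtl = 0, qtl_var_fraction = 0.5),
               class = "reactnorm_config_error")
  expect_error(sim_config(residual_class_variances = rep(1, 7)),
               class = "reactnorm_config_error")
})

test_that("pedigree simulation builds a two-generation half-sib structure", {
  cfg <- sim_config(n_sires = 100, n_snps = 2, seed = 7)
  ped <- simulate_pedigree(cfg, n_grandsires = 10)
  gs <- ped$id[ped$sire == "0" & grepl("^GS", ped$id)]
  expect_length(gs, 10)
  sires <- ped[grepl("^S", ped$id), ]
  expect_equal(nrow(sires), 100)
  expect_true(all(sires$sire %in% gs))
  expect_true(all(sires$dam == "0"))
  # ~10 sons per grandsire
  expect_equal(mean(table(sires$sire)), 10)
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
})

test_that("sire effect moments match the configured covariance", {
  # purely polygenic
  cfg <- sim_config(n_sires = 5000, n_snps = 10, n_qtl = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  tr <- simulate_sire_effects(cfg, g)
  s <- cbind(tr$sires$s0, tr$sires$s1)
  mc_se <- sqrt(2 / 5000)  # relative MC error of a variance
  expect_lt(abs(var(s[, 1]) / cfg$sigma_s0_sq - 1), 3 * mc_se)
  expect_lt(abs(var(s[, 2]) / cfg$sigma_s1_sq - 1), 3 * mc_se)
  expect_lt(abs(cor(s[, 1], s[, 2]) - 0.79), 0.02)

  # QTL part calibrated to its variance fraction
  cfgq <- sim_config(n_sires = 3000, n_snps = 100, n_qtl = 20,
                     qtl_var_fraction = 0.4, seed = 32)
  gq <- simulate_genotypes(cfgq)
  trq <- simulate_sire_effects(cfgq, gq)
  expect_equal(nrow(trq$qtl), 20)
  qvar <- var(trq$sires$qtl0)
  expect_lt(abs(qvar / (0.4 * cfgq$sigma_s0_sq) - 1), 0.05)
  svar <- var(trq$sires$s0)
  expect_lt(abs(svar / cfgq$sigma_s0_sq - 1), 3 * sqrt(2 / 3000) + 0.05)

  # degenerate correlation: slope proportional to intercept
  cfg1 <- sim_config(n_sires = 200, n_snps = 5, n_qtl = 0, rho_s = 1,
                     sigma_s0_sq = 4, sigma_s1_sq = 4, seed = 33)
  tr1 <- simulate_sire_effects(cfg1, simulate_genotypes(cfg1))
  expect_gt(cor(tr1$sires$s0, tr1$sires$s1), 0.999)

  expect_error(
    simulate_sire_effects(
      sim_config(n_snps = 10, n_qtl = 2, qtl_var_fraction = 1.5), g),
    class = "reactnorm_config_error")
})

test_that("daughter records follow the generative reaction-norm model", {
  # all variances (essentially) zero, no regression: records equal mu
  cfg0 <- tiny_config(sigma_s0_sq = 0, sigma_s1_sq = 0, rho_s = 0,
                      sigma_d0_sq = 0, sigma_d1_sq = 0, rho_d = 0,
                      residual_class_variances = rep(1e-24, 10),
                      b_fixed = 0, mu = 700)
  sim0 <- simulate_dataset(cfg0)
  expect_true(all(abs(sim0$records$yield - 700) < 1e-9))

  # per-decile residual sample variances match the configured values
  rv <- seq(5000, 14000, length.out = 10)
  cfgr <- sim_config(n_sires = 50, daughters_per_sire = 60,
                     records_per_daughter = 2, n_htd = 3000, n_snps = 2,
                     n_qtl = 0, sigma_s0_sq = 0, sigma_s1_sq = 0, rho_s = 0,
                     sigma_d0_sq = 0, sigma_d1_sq = 0, rho_d = 0,
                     residual_class_variances = rv, b_fixed = 0, seed = 13)
  simr <- simulate_dataset(cfgr)
  for (k in c(1, 5, 10)) {
    e <- simr$records$yield[simr$records$res_class == k] - cfgr$mu
    n_k <- length(e)
    # chi-square 99.9% band for a sample variance
    band <- rv[k] * stats::qchisq(c(5e-4, 1 - 5e-4), n_k - 1) / (n_k - 1)
    expect_gt(var(e), band[1]); expect_lt(var(e), band[2])
  }

  # daughter effect moments
  cfgd <- sim_config(n_sires = 60, daughters_per_sire = 100, n_snps = 2,
                     n_qtl = 0, seed = 14)
  simd <- simulate_dataset(cfgd)
  d <- simd$truth$daughters
  mc <- 3 * sqrt(2 / nrow(d))
  expect_lt(abs(var(d$d0) / cfgd$sigma_d0_sq - 1), mc)
  expect_lt(abs(var(d$d1) / cfgd$sigma_d1_sq - 1), mc)
  expect_lt(abs(cor(d$d0, d$d1) - cfgd$rho_d), 0.05)

  # reproducibility of the full dataset
  expect_identical(simulate_dataset(tiny_config(seed = 8))$records,
                   simulate_dataset(tiny_config(seed = 8))$records)
})

test_that("multiplicative mode produces positive yields with pure-scaling GxE", {
  cfg <- sim_config_multiplicative(n_sires = 50, daughters_per_sire = 200,
                                   records_per_daughter = 2, n_htd = 2000,
                                   n_snps = 2, n_qtl = 0, seed = 15)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$records$yield > 0))

  # pure scaling: sire means in top vs bottom environment deciles do not
  # re-rank (log scale)
  recs <- sim$records
  recs$logy <- log(recs$yield)
  qs <- stats::quantile(recs$env, c(0.1, 0.9))
  bottom <- recs[recs$env <= qs[1], ]
  top <- recs[recs$env >= qs[2], ]
  mb <- tapply(bottom$logy, bottom$sire, mean)
  mt <- tapply(top$logy, top$sire, mean)
  common <- intersect(names(mb), names(mt))
  expect_gt(cor(mb[common], mt[common]), 0.9)
})
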