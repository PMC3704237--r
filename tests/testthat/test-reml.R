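# The blocked likelihood is checked against a naive dense-matrix
# implementation of the same restricted likelihood (built from the full
# n x n covariance); the dense code path shares nothing with the blocked
# kernel beyond the data-preparation step.

test_that("blocked REML equals the dense oracle across random instances", {
  set.seed(101)
  for (i in 1:6) {
    cfg <- tiny_config(n_sires = sample(4:6, 1),
                       daughters_per_sire = sample(3:5, 1),
                       records_per_daughter = sample(1:3, 1),
                       seed = 100 + i)
    sim <- simulate_dataset(cfg)
    recs <- sim$records
    A <- build_numerator_relationship(sim$pedigree, unique(recs$sire))
    for (mode in c("heterogeneous", "homogeneous")) {
      comp <- random_components(mode)
      l_fast <- reml_loglikelihood(recs, comp, mode = mode)
      l_dense <- reactnorm:::reml_loglik_dense(recs, comp, mode = mode)
      expect_equal(l_fast, l_dense, tolerance = 1e-9)
    }
    comp <- random_components("heterogeneous")
    expect_equal(reml_loglikelihood(recs, comp, sire_relationship = A),
                 reactnorm:::reml_loglik_dense(recs, comp,
                                               sire_relationship = A),
                 tolerance = 1e-9)
  }
})

test_that("REML log-likelihood is invariant to record order", {
  sim <- simulate_dataset(tiny_config(seed = 55))
  comp <- random_components("heterogeneous")
  recs <- sim$records
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(reml_loglikelihood(recs, comp),
               reml_loglikelihood(shuffled, comp), tolerance = 1e-10)
})

test_that("vanishing random effects reduce REML to weighted least squares", {
  sim <- simulate_dataset(tiny_config(seed = 56))
  recs <- sim$records
  eps <- 1e-9
  s2 <- runif(10, 0.8, 1.2) * 1e4
  comp <- list(Gs = diag(c(eps, eps)), Gd = diag(c(eps, eps)), sigma2_e = s2)
  l <- reml_loglikelihood(recs, comp)
  # direct weighted-least-squares restricted likelihood on X = [1, env]
  prep <- reactnorm:::prep_reml_data(recs, "heterogeneous")
  w <- 1 / s2[prep$rclass]
  X <- prep$X; y <- prep$y; n <- length(y)
  XtWX <- crossprod(X * w, X)
  beta <- solve(XtWX, crossprod(X * w, y))
  rss <- sum(w * (y - X %*% beta)^2)
  l_wls <- -0.5 * ((n - 2) * log(2 * pi) + sum(log(s2[prep$rclass])) +
                     as.numeric(determinant(XtWX)$modulus) + rss)
  expect_equal(l, l_wls, tolerance = 1e-5)
})

test_that("BLUP solutions equal the dense mixed-model-equation solve", {
  sim <- simulate_dataset(tiny_config(seed = 57))
  recs <- sim$records
  comp <- reactnorm:::normalize_components(random_components("heterogeneous"),
                                           "heterogeneous")
  prep <- reactnorm:::prep_reml_data(recs, "heterogeneous")
  sol <- reactnorm:::reml_eval(prep, comp, want_blups = TRUE)
  dor <- reactnorm:::blup_dense(recs, comp, "heterogeneous")
  expect_equal(sol$beta, dor$beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(sol$u), unname(dor$u[prep$sire_levels, ]),
               tolerance = 1e-8)
})

test_that("the REML fit recovers a null sire slope as a boundary estimate", {
  cfg <- sim_config(n_sires = 60, daughters_per_sire = 30, n_htd = 300,
                    n_snps = 2, n_qtl = 0, sigma_s1_sq = 0, rho_s = 0,
                    seed = 58)
  sim <- simulate_dataset(cfg)
  fit <- fit_reaction_norm(sim$records, se = FALSE)
  # per-sire slope sampling variance ~ residual/(records * var(env)) ~ 110;
  # a null slope variance estimate should stay within ~3 MC SEs of zero
  mc_bound <- 3 * sqrt(2 / cfg$n_sires) * 110
  expect_lt(fit$Gs[2, 2], mc_bound)
  expect_true(all(abs(fit$sire_estimates$es) < sqrt(cfg$sigma_s0_sq)))
  # ES shrunk far below the intercept spread
  expect_lt(var(fit$sire_estimates$es), 0.05 * var(fit$sire_estimates$gp))
})

test_that("reported log-likelihood trace is non-decreasing", {
  sim <- simulate_dataset(tiny_config(n_sires = 10, seed = 59))
  fit <- fit_reaction_norm(sim$records, se = FALSE)
  expect_true(all(diff(fit$loglik_trace) >= 0))
  expect_equal(max(fit$loglik_trace), fit$loglik, tolerance = 1e-6)
})

test_that("environment shifts re-parameterize the model exactly", {
  # shifting E by c maps (s0, s1) -> (s0 - c s1, s1): the likelihood is
  # invariant under the matched covariance transform, and BLUPs map by the
  # same matrix, so re-centering the environment restores the original
  # intercept estimates
  sim <- simulate_dataset(tiny_config(n_sires = 10, seed = 60))
  recs <- sim$records
  comp <- list(Gs = matrix(c(2000, 150, 150, 20), 2),
               Gd = matrix(c(7000, 300, 300, 50), 2),
               sigma2_e = seq(2, 3.5, length.out = 10) * 1e4)
  cshift <- 3
  M <- matrix(c(1, 0, -cshift, 1), 2, 2)
  shifted <- recs; shifted$env <- shifted$env + cshift
  comp2 <- comp
  comp2$Gs <- M %*% comp$Gs %*% t(M)
  comp2$Gd <- M %*% comp$Gd %*% t(M)
  expect_equal(reml_loglikelihood(recs, comp),
               reml_loglikelihood(shifted, comp2), tolerance = 1e-10)

  prep1 <- reactnorm:::prep_reml_data(recs, "heterogeneous")
  prep2 <- reactnorm:::prep_reml_data(shifted, "heterogeneous")
  n1 <- reactnorm:::normalize_components(comp, "heterogeneous")
  n2 <- reactnorm:::normalize_components(comp2, "heterogeneous")
  u1 <- reactnorm:::reml_eval(prep1, n1, want_blups = TRUE)$u
  u2 <- reactnorm:::reml_eval(prep2, n2, want_blups = TRUE)$u
  expect_equal(u2, t(M %*% t(u1)), tolerance = 1e-8)
  # ES (slope) predictions are unchanged by the shift
  expect_equal(u2[, 2], u1[, 2], tolerance = 1e-8)
})

test_that("predict_sire_effects re-solves BLUPs for new records", {
  sim <- simulate_dataset(tiny_config(n_sires = 10, seed = 61))
  fit <- fit_reaction_norm(sim$records, se = FALSE)
  expect_identical(predict_sire_effects(fit), fit$sire_estimates)
  half <- sim$records[sim$records$daughter %in%
                        unique(sim$records$daughter)[1:30], ]
  est <- predict_sire_effects(fit, half)
  comp <- list(Gs = fit$Gs, Gd = fit$Gd, sigma2_e = fit$sigma2_e)
  dor <- reactnorm:::blup_dense(half, comp, "heterogeneous")
  expect_equal(est$gp, unname(dor$u[est$sire, "gp"]), tolerance = 1e-8)
  expect_equal(est$es, unname(dor$u[est$sire, "es"]), tolerance = 1e-8)
})

test_that("identifiability preconditions are enforced", {
  sim <- simulate_dataset(tiny_config(seed = 62))
  one_sire <- sim$records[sim$records$sire == sim$records$sire[1], ]
  expect_error(fit_reaction_norm(one_sire), class = "reactnorm_domain_error")
  const_env <- sim$records; const_env$env <- 1
  expect_error(fit_reaction_norm(const_env), class = "reactnorm_domain_error")
  incomplete <- sim$records; incomplete$yield[1] <- NA
  expect_error(fit_reaction_norm(incomplete), class = "reactnorm_domain_error")
})
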