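test_that("mean-model solutions match a dense mixed-model/GLS oracle", {
  ph <- make_toy_pheno(n_sires = 3, n_prog = 4, n_cg = 2, seed = 42)
  set.seed(1)
  phi <- runif(nrow(ph), 0.5, 2)
  s2s <- 3.7
  fit <- fit_mean_model(ph, phi, s2s)
  oracle <- dense_mme_oracle(ph, phi, s2s)
  expect_equal(unname(fit$s), unname(oracle$s), tolerance = 1e-8)
  expect_equal(unname(fit$b), unname(oracle$b), tolerance = 1e-8)
  expect_equal(fit$h, oracle$h, tolerance = 1e-8)
  expect_equal(unname(fit$pev), unname(oracle$pev), tolerance = 1e-8)
  expect_equal(fit$residuals, oracle$residuals, tolerance = 1e-8)

  # GLS oracle built from the full covariance matrix V = Z G Z' + R
  sire <- factor(ph$sire_id)
  Z <- model.matrix(~ 0 + sire)
  V <- Z %*% (diag(3) * s2s) %*% t(Z) + diag(phi)
  age_s <- (ph$age - mean(ph$age)) / sd(ph$age)
  df <- data.frame(cg = factor(ph$cg), sex = factor(ph$sex), age_s = age_s)
  X <- model.matrix(~ 0 + cg + sex:age_s + sex:I(age_s^2), df)
  b_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, ph$y))
  expect_equal(unname(fit$b), as.numeric(b_gls), tolerance = 1e-8)
})

test_that("ridge limits of the sire variance behave as expected", {
  ph <- make_toy_pheno(n_sires = 4, n_prog = 6, seed = 7)
  # sigma2_s -> 0: all sire solutions shrink to zero, residuals equal WLS
  fit0 <- fit_mean_model(ph, phi = 1, sigma2_s = 1e-10)
  expect_lt(max(abs(fit0$s)), 1e-6)
  ols <- dense_mme_oracle(ph, rep(1, nrow(ph)), 1e-10)
  expect_equal(fit0$residuals, ols$residuals, tolerance = 1e-6)
  # sigma2_s -> Inf: sire effects absorb family means (up to fixed effects)
  fitI <- fit_mean_model(ph, phi = 1, sigma2_s = 1e10)
  fam_res <- tapply(fitI$residuals, ph$sire_id, mean)
  expect_lt(max(abs(fam_res)), 1e-6)
})

test_that("working response has the stated fixed point and plug-in values", {
  ph <- make_toy_pheno(n_sires = 3, n_prog = 5, seed = 11)
  fit <- fit_mean_model(ph, phi = 1, sigma2_s = 2)
  # fixed point: e^2 = (1 - h) phi  =>  psi = log(phi)
  fake <- fit
  fake$residuals <- sqrt((1 - fit$h) * 2.5)
  wr <- working_response(fake, 2.5)
  expect_equal(wr$psi, rep(log(2.5), length(wr$psi)))
  # plug-in: e = 0, h = 0, phi = 1 -> psi = -1, weight 0.5
  fake$residuals <- rep(0, length(fit$h))
  fake$h <- rep(0, length(fit$h))
  wr2 <- working_response(fake, 1)
  expect_equal(wr2$psi, rep(-1, length(wr2$psi)))
  expect_equal(wr2$weight, rep(0.5, length(wr2$weight)))
  # saturated record
  fake$h[1] <- 1
  expect_error(working_response(fake, 1), "saturated")
})

test_that("working response is an asymptotically unbiased log-variance estimate", {
  # large homogeneous family: E[psi] should approach the true log variance
  eta <- log(550)
  cfg <- sim_config(n_sires = 20, progeny_min = 5000, progeny_max = 5000,
                    n_cg = 5, sigma2_cg = 0, eta0 = eta,
                    beta_age = c(F = 0.2, M = 0.25), seed = 12)
  truth <- structure(list(sire_ids = sprintf("s%02d", 1:20),
                          A_m = rep(0, 20), A_v = rep(0, 20)),
                     class = "sim_truth")
  ph <- simulate_progeny(truth, cfg)
  fit <- fit_mean_model(ph, phi = exp(eta), sigma2_s = 1)
  wr <- working_response(fit, exp(eta))
  expect_lt(abs(mean(wr$psi) - eta), 0.02)
})

test_that("rmv_zero constrains the covariance and decouples the mean part", {
  cfg <- sim_config(n_sires = 60, progeny_min = 30, progeny_max = 80,
                    n_chr = 1, snps_per_chr = 40, n_qtl_mean = 5,
                    n_qtl_var = 5, seed = 13)
  st <- simulate_study(cfg)
  fit <- fit_dhglm(st$pheno, "rmv_zero")
  expect_identical(fit$cov_s_sv, 0)
  expect_identical(fit$r_mv, 0)
  # decoupling: mean part equals a stand-alone weighted sire model refit
  # with the converged phi and sigma2_s
  mf <- fit_mean_model(st$pheno, fit$phi, fit$sigma2_s)
  expect_equal(unname(mf$s), unname(fit$mean_part$s), tolerance = 1e-8)
  expect_equal(mf$residuals, fit$mean_part$residuals, tolerance = 1e-8)
})

test_that("null variance-heterogeneity data yield near-zero sigma2_sv", {
  hits <- 0L
  for (r in 1:4) {
    cfg <- sim_config(n_sires = 120, progeny_min = 80, progeny_max = 80,
                      n_chr = 1, snps_per_chr = 30, n_qtl_mean = 5,
                      n_qtl_var = 0, sigma2_sv = 0, r_mv = 0,
                      seed = 200 + r)
    st <- simulate_study(cfg)
    # EM creeps near the sigma2_sv = 0 boundary; a loose phi tolerance is
    # plenty for the magnitude check below
    fit <- fit_dhglm(st$pheno, "rmv_free", tol = 1e-3, tol_vc = 1e-3,
                     max_iter = 60)
    if (fit$sigma2_sv <= 0.01 * var(fit$psi)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("reliabilities are monotone in progeny count and bounded", {
  cfg <- sim_config(n_sires = 80, progeny_min = 20, progeny_max = 500,
                    n_chr = 1, snps_per_chr = 30, n_qtl_mean = 5,
                    n_qtl_var = 3, seed = 14)
  st <- simulate_study(cfg)
  fit <- fit_dhglm(st$pheno, "rmv_free", max_iter = 60)
  rel <- reliabilities(fit)
  expect_true(all(rel$r2_m >= 0 & rel$r2_m < 1))
  big <- rel$n_progeny >= quantile(rel$n_progeny, 0.8)
  small <- rel$n_progeny <= quantile(rel$n_progeny, 0.2)
  expect_gt(min(rel$r2_m[big]), max(rel$r2_m[small]) - 0.05)
  expect_gt(mean(rel$r2_m[big]), mean(rel$r2_m[small]))
  expect_gt(mean(rel$r2_v[big]), mean(rel$r2_v[small]))
  expect_gt(cor(rel$n_progeny, rel$r2_m, method = "spearman"), 0.9)
})

test_that("free-mode fit recovers a strong mean/variance genetic correlation", {
  cfg <- sim_config(n_sires = 250, progeny_min = 120, progeny_max = 120,
                    n_chr = 1, snps_per_chr = 60, n_qtl_mean = 8,
                    n_qtl_var = 4, seed = 15)
  st <- simulate_study(cfg)
  fit <- fit_dhglm(st$pheno, "rmv_free")
  expect_true(fit$converged)
  expect_lt(abs(fit$r_mv - 0.76), 0.2)
  expect_lt(abs(fit$sigma2_s / (cfg$sigma2_s / 4) - 1), 0.35)
  expect_lt(abs(fit$sigma2_sv / (cfg$sigma2_sv / 4) - 1), 0.45)
  expect_gt(cor(fit$mean_part$s, st$truth$A_m), 0.85)
  expect_gt(cor(fit$var_part$s, st$truth$A_v), 0.6)
})
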