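test_that("R diagonal construction follows the response kind", {
  rsp <- data.frame(sire_id = c("a", "b"), n_progeny = c(411L, 100L),
                    w_m = c(2, 4), w_v = c(1, 2), w_v_r0 = c(0.5, 1),
                    dEBV_m = 0, dEBV_v = 0, dEBV_v_r0 = 0, lnvar = 6)
  expect_equal(unname(build_r_diag(rsp, "dEBV_m")), c(0.5, 0.25))
  expect_equal(unname(build_r_diag(rsp, "lnvar"))[1], 1 / 411,
               tolerance = 1e-12)
  rsp$w_v[1] <- 0
  expect_error(build_r_diag(rsp, "dEBV_v"), "non-positive")
})

test_that("posterior inclusion matches exact enumeration on a tiny instance", {
  set.seed(11)
  n <- 25; M <- 3
  Z <- matrix(rbinom(n * M, 2, 0.4), n, M)
  y <- rnorm(n) + 0.5 * scale(Z[, 2])[, 1]
  s2a <- 0.3; s2e <- 1.2; pi0 <- 0.7
  # pin the variances with enormous prior degrees of freedom
  cfg <- bayesc_config(pi = pi0, chain_length = 120000, burn_in = 20000,
                       thin = 10, nu_a = 1e9, nu_e = 1e9, S_a = s2a,
                       S_e = s2e, seed = 2)
  res <- run_bayesc(y, Z, 1, cfg)
  # exact posterior over all delta configurations, flat prior on mu
  Zc <- scale(Z, scale = FALSE)
  logml <- function(d) {
    V <- s2e * diag(n)
    if (any(d == 1)) V <- V + s2a * tcrossprod(Zc[, d == 1, drop = FALSE])
    Vi <- solve(V)
    A <- sum(Vi)
    P <- Vi - (Vi %*% rep(1, n) %*% t(rep(1, n)) %*% Vi) / A
    as.numeric(-0.5 * determinant(V)$modulus - 0.5 * log(A) -
                 0.5 * t(y) %*% P %*% y)
  }
  configs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lp <- apply(configs, 1, function(d)
    logml(d) + sum(d) * log(1 - pi0) + sum(1 - d) * log(pi0))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  pip_exact <- colSums(configs * w)
  expect_lt(max(abs(res$pip - pip_exact)), 0.02)
})

test_that("pi = 0 limit reproduces the closed-form ridge solution", {
  set.seed(9)
  n <- 50; M <- 20
  Z <- matrix(rbinom(n * M, 2, 0.4), n, M)
  a_true <- rnorm(M, 0, 0.3)
  y <- as.numeric(scale(Z, scale = FALSE) %*% a_true) + rnorm(n)
  cfg <- bayesc_config(pi = 0, chain_length = 20000, burn_in = 4000,
                       thin = 5, seed = 5)
  res <- run_bayesc(y, Z, 1, cfg)
  expect_true(all(res$pip == 1))
  Zc <- scale(Z, scale = FALSE)
  lam <- mean(res$s2e_chain) / mean(res$s2a_chain)
  ridge <- solve(crossprod(Zc) + diag(lam, M), crossprod(Zc, y - mean(y)))
  expect_gt(cor(as.numeric(ridge), res$ahat), 0.99)
  expect_lt(max(abs(ridge - res$ahat)), 0.06)
})

test_that("incremental-score (Gram) path and direct path give identical chains", {
  set.seed(17)
  n <- 60; M <- 40
  Z <- matrix(rbinom(n * M, 2, 0.3), n, M)
  y <- rnorm(n) + 0.4 * scale(Z[, 7])[, 1]
  r <- runif(n, 0.5, 2)
  cfgA <- bayesc_config(pi = 0.9, chain_length = 4000, burn_in = 500,
                        thin = 5, seed = 4, use_gram = TRUE)
  cfgB <- bayesc_config(pi = 0.9, chain_length = 4000, burn_in = 500,
                        thin = 5, seed = 4, use_gram = FALSE)
  a <- run_bayesc(y, Z, r, cfgA)
  b <- run_bayesc(y, Z, r, cfgB)
  expect_equal(a$pip, b$pip, tolerance = 1e-12)
  expect_equal(a$ahat, b$ahat, tolerance = 1e-10)
  expect_equal(a$s2e_chain, b$s2e_chain, tolerance = 1e-10)
})

test_that("scaling the response scales effects and variances exactly", {
  set.seed(19)
  n <- 40; M <- 15
  Z <- matrix(rbinom(n * M, 2, 0.35), n, M)
  y <- rnorm(n)
  k <- 3.7
  cfg <- function() bayesc_config(pi = 0.95, chain_length = 3000,
                                  burn_in = 500, thin = 5, seed = 8)
  a <- run_bayesc(y, Z, 1, cfg())
  b <- run_bayesc(k * y, Z, 1, cfg())
  expect_equal(b$ahat, k * a$ahat, tolerance = 1e-8)
  expect_equal(b$s2e_chain, k^2 * a$s2e_chain, tolerance = 1e-8)
  expect_equal(b$pip, a$pip)
})

test_that("uniform weights are equivalent to an unweighted run", {
  set.seed(23)
  n <- 40; M <- 10
  Z <- matrix(rbinom(n * M, 2, 0.3), n, M)
  y <- rnorm(n)
  cfg <- function(se) bayesc_config(pi = 0.9, chain_length = 3000,
                                    burn_in = 500, thin = 5,
                                    S_a = 0.2, S_e = se, seed = 31)
  a <- run_bayesc(y, Z, r_diag = 1, cfg(1))
  # R = c*I with the residual prior scale rescaled by 1/c reproduces the
  # unweighted run exactly, with sigma2_e draws divided by c
  b <- run_bayesc(y, Z, r_diag = 2, cfg(0.5))
  expect_equal(a$pip, b$pip)
  expect_equal(a$ahat, b$ahat, tolerance = 1e-8)
  expect_equal(b$s2e_chain, a$s2e_chain / 2, tolerance = 1e-8)
})

test_that("zero-variance SNP columns are flagged and forced out", {
  set.seed(29)
  Z <- cbind(rbinom(30, 2, 0.4), rep(1, 30), rbinom(30, 2, 0.3))
  res <- run_bayesc(rnorm(30), Z, 1,
                    bayesc_config(chain_length = 2000, burn_in = 200,
                                  thin = 5, seed = 1))
  expect_equal(res$zero_var_snps, 2L)
  expect_equal(res$pip[2], 0)
  expect_equal(res$ahat[2], 0)
})

test_that("Geweke diagnostic is calibrated on iid chains and detects trends", {
  set.seed(37)
  z <- replicate(200, geweke_z(rnorm(5000)))
  rej <- mean(abs(z) > 1.96)
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
  # linear trend of 5 sd over the chain is flagged
  trend <- rnorm(5000) + seq(0, 5, length.out = 5000)
  expect_gt(abs(geweke_z(trend)), 1.96)
  expect_error(geweke_z(rep(1, 500)), "degenerate")
  expect_error(geweke_z(rnorm(50)), "at least 100")
})
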