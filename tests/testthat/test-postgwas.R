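test_that("Bayes factor follows the posterior-to-prior odds ratio", {
  expect_equal(bayes_factor(0.001, 0.001), 1)
  expect_equal(bayes_factor(0, 0.001), 0)
  expect_equal(bayes_factor(0.5, 0.001), 1 / (0.001 / 0.999))
  expect_equal(bayes_factor(0.5, 0.001), 999)
  # strictly increasing in p
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(bayes_factor(p, 0.001)) > 0))
  # p = 1 capping
  expect_message(bf1 <- bayes_factor(1, 0.001, n_kept = 999), "capped")
  expect_equal(bf1, (0.999 / 0.001) / (0.001 / 0.999))
  expect_error(bayes_factor(1, 0.001), "n_kept")
  expect_error(bayes_factor(0.5, 0), "prior_inclusion")
  expect_equal(as.character(bf_class(c(1, 5, 50))),
               c("none", "suggestive", "strong"))
})

test_that("window ids follow the Chr_Mb convention", {
  w <- window_id(c(22L, 8L, 10L), c(51.60e6, 67.46e6, 74.34e6))
  expect_equal(w$label, c("Chr22_52", "Chr8_68", "Chr10_75"))
  expect_equal(window_id(1L, 1)$window_index, 0)
  expect_equal(window_id(1L, 1e6)$window_index, 0)   # 1-based bp inclusive
  expect_equal(window_id(1L, 1e6 + 1)$window_index, 1)
})

test_that("window variance partitioning concentrates and distributes correctly", {
  set.seed(41)
  n <- 10000
  map <- data.frame(snp_id = sprintf("s%d", 1:4), chr = 1L,
                    bp = c(2e5, 5e5, 3.2e6, 7.1e6))
  Z <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  # single causal SNP: its window takes 100%
  a <- c(0, 0.5, 0, 0)
  ws <- window_variance(Z, a, map)
  expect_equal(ws$pct[1], 100)
  expect_equal(ws$label[1], "Chr1_1")
  expect_true(all(ws$pct[-1] == 0))

  # two unlinked SNPs with equal MAF and |effect| in different windows
  p <- 0.25
  Z2 <- matrix(rbinom(n * 2, 2, p), n, 2)
  map2 <- data.frame(snp_id = c("a", "b"), chr = 1L, bp = c(1e5, 5.5e6))
  ws2 <- window_variance(Z2, c(0.4, -0.4), map2)
  expect_lt(max(abs(ws2$pct - 50)), 2)

  # all-zero effects warn and report zeros
  expect_warning(ws0 <- window_variance(Z, rep(0, 4), map), "zero")
  expect_true(all(ws0$pct == 0))
})

test_that("window shares are additive under linkage equilibrium", {
  cfg <- sim_config(n_sires = 2000, n_chr = 3, snps_per_chr = 150,
                    chr_length_bp = 20e6, seed = 43)
  g <- simulate_genotypes(cfg)
  set.seed(44)
  a <- rnorm(450, 0, 0.1) * rbinom(450, 1, 0.2)
  ws <- window_variance(g$codes, a, g$map)
  expect_gt(sum(ws$pct), 95)
  expect_lt(sum(ws$pct), 105)
  # translation of the response leaves shares untouched (effects given),
  # relabelling sires leaves them untouched (rows exchangeable)
  ws2 <- window_variance(g$codes[sample(2000), ], a, g$map)
  expect_equal(sort(ws2$pct), sort(ws$pct))
  # the "windows" denominator normalises to exactly 100
  ws3 <- window_variance(g$codes, a, g$map, denominator = "windows")
  expect_equal(sum(ws3$pct), 100)
})

test_that("top-window overlap has set semantics and is symmetric", {
  s <- data.frame(chr = 1L, window_index = 0:29,
                  label = sprintf("Chr1_%d", 1:30),
                  n_snps = 5L, pct = 30:1)
  expect_equal(top_windows_overlap(s, s, K = 20)$n_shared, 20L)
  s2 <- s
  s2$pct[10:11] <- s$pct[11:10]   # swap two ranks inside the top K
  expect_equal(top_windows_overlap(s, s2, K = 20)$n_shared, 20L)
  # disjoint genomes
  s3 <- s
  s3$chr <- 2L
  s3$label <- sprintf("Chr2_%d", 1:30)
  expect_equal(top_windows_overlap(s, s3, K = 20)$n_shared, 0L)
  # symmetry
  set.seed(45)
  s4 <- s
  s4$pct <- sample(s$pct)
  expect_equal(top_windows_overlap(s, s4, K = 10)$n_shared,
               top_windows_overlap(s4, s, K = 10)$n_shared)
  # K larger than the window count is clipped
  expect_warning(o <- top_windows_overlap(s[1:5, ], s[1:5, ], K = 20),
                 "clipped")
  expect_equal(o$K, 5L)
})

test_that("response correlations report r, SE and degenerate pairs", {
  x <- rnorm(30)
  df <- data.frame(dEBV_m = x, dEBV_v = -x, dEBV_v_r0 = rnorm(30),
                   lnvar = rep(1, 30))
  cc <- response_correlations(df)
  expect_equal(cc$r["dEBV_m", "dEBV_m"], 1)
  expect_equal(cc$r["dEBV_m", "dEBV_v"], -1)
  expect_true(is.na(cc$r["dEBV_m", "lnvar"]))  # zero variance pair
  r <- cc$r["dEBV_m", "dEBV_v_r0"]
  expect_equal(cc$se["dEBV_m", "dEBV_v_r0"], sqrt((1 - r^2) / 28))
})

test_that("scale-effect test compares mean- and variance-standardised effects", {
  # boundary: equal standardised effects are NOT beyond scale
  r <- scale_effect_test(3, 6, mean_trait = 300, mean_resid_var = 600)
  expect_equal(r$std_mean, 0.01)
  expect_equal(r$std_var, 0.01)
  expect_false(r$beyond_scale)
  expect_true(scale_effect_test(3, 12.1, 300, 600)$beyond_scale)
  expect_error(scale_effect_test(1, 1, -5, 600), "mean_trait")

  # contrast of architectures: pure scale (variance tracks the mean) versus
  # direct log-variance effects
  set.seed(47)
  n_snp <- 40
  a_m <- rnorm(n_snp, 0, 1)
  mean_trait <- 300; mean_s2e <- 600
  # pure scale: sd proportional to mean shift => var effect ~ 2*mean*CV^2
  a_v_scale <- 2 * a_m * mean_s2e / mean_trait * 0.5
  flag_scale <- scale_effect_test(a_m, a_v_scale, mean_trait,
                                  mean_s2e)$beyond_scale
  a_v_direct <- rnorm(n_snp, 0, 1) * mean_s2e / 50
  flag_direct <- scale_effect_test(a_m, a_v_direct, mean_trait,
                                   mean_s2e)$beyond_scale
  expect_lte(mean(flag_scale), 0.2)
  expect_gte(mean(flag_direct), 0.6)
})

test_that("genotype summaries track class means and dispersion direction", {
  codes <- rep(0:2, each = 20)
  expect_equal(genotype_summary(codes, codes)$mean, c(0, 1, 2))
  gs <- genotype_summary(rep(5, 60), codes)
  expect_true(all(gs$mean == 5))
  expect_error(genotype_summary(rnorm(10), rep(1, 10)), "monomorphic")

  # a variance-raising allele: carriers of code 2 have larger mean and
  # spread of the family log-variance than code 0 homozygotes
  set.seed(48)
  n <- 600
  g <- rbinom(n, 2, 0.4)
  a_v <- 0.5
  lnvar <- 6 + a_v * g + rnorm(n, 0, 0.1 + 0.1 * g)
  gs2 <- genotype_summary(lnvar, g)
  expect_lt(gs2$mean[1], gs2$mean[3])
  expect_lt(gs2$sd[1], gs2$sd[3])
  empty <- genotype_summary(lnvar[g != 2], g[g != 2])
  expect_equal(empty$n[3], 0L)
})
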