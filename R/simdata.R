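# Synthetic half-sib study generator.
#
# The generator emulates a progeny-test design for a growth trait: a few
# hundred genotyped sires, each with a large group of phenotyped (but not
# genotyped) progeny, contemporary-group and age-by-sex fixed effects, and
# sire genetic effects on both the trait mean and the log residual variance.

#' Configuration for the synthetic half-sib study generator
#'
#' Holds every knob of the generator. Defaults emulate a yearling-weight
#' progeny test: 423 sires, 50-800 progeny per sire, trait mean around
#' 280 kg, baseline residual variance around 600 kg^2, sire-scale variance
#' ratio around 5% on both the mean and the log-variance part, and a strong
#' positive genetic correlation (0.76) between the two.
#'
#' @param n_sires number of genotyped sires.
#' @param progeny_min,progeny_max bounds on progeny group size per sire.
#' @param progeny_mean optional target mean progeny group size. When `NULL`
#'   (default) group sizes are log-uniform on `[progeny_min, progeny_max]`;
#'   otherwise they are drawn from a truncated log-normal whose mean is
#'   calibrated to the target (use e.g. `progeny_max = 10180,
#'   progeny_mean = 411` for a full-scale design).
#' @param n_chr,snps_per_chr,chr_length_bp genome layout; SNPs are placed
#'   uniformly along each chromosome.
#' @param maf_range range of allele frequencies drawn per SNP; must lie in
#'   (0, 0.5].
#' @param ld_rho probability that a SNP copies its left neighbour's genotype
#'   per sire (simple block-LD mode); 0 gives linkage equilibrium.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param n_qtl_mean,n_qtl_var number of QTL with effects on the trait mean
#'   and on the log residual variance (disjoint SNP sets).
#' @param a_m,a_v optional QTL effect standard deviations (kg, log-variance
#'   units). When `NULL`, effects are scaled so the QTL explain
#'   `qtl_prop_m`/`qtl_prop_v` of the corresponding genetic variance.
#' @param qtl_prop_m,qtl_prop_v proportion of genetic variance assigned to
#'   QTL when `a_m`/`a_v` are `NULL`.
#' @param sigma2_s variance of sire total genetic values on the mean scale
#'   (kg^2); progeny receive half the sire value, so the sire-model variance
#'   component is `sigma2_s / 4`.
#' @param sigma2_sv variance of sire total genetic values on the log
#'   residual variance scale.
#' @param r_mv genetic correlation between the mean and log-variance genetic
#'   values.
#' @param mu trait mean (kg).
#' @param eta0 baseline log residual variance; `exp(eta0)` is the residual
#'   variance (kg^2) of a family with zero variance-scale genetic value.
#' @param n_cg number of contemporary groups, assigned uniformly at random.
#' @param sigma2_cg variance of contemporary-group effects (kg^2).
#' @param age_range range of animal age at measurement (days).
#' @param beta_age,beta_age2 named vectors (`F`, `M`) of linear and quadratic
#'   regression coefficients on centred age, nested within sex.
#' @param seed integer seed; every `simulate_*` call derives its stream from
#'   it so the generator is reproducible end to end.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_sires = 50, snps_per_chr = 100, seed = 1)
#' geno <- simulate_genotypes(cfg)
#' truth <- simulate_truth(geno, cfg)
#' pheno <- simulate_progeny(truth, cfg)
sim_config <- function(n_sires = 423,
                       progeny_min = 50, progeny_max = 800,
                       progeny_mean = NULL,
                       n_chr = 3, snps_per_chr = 400, chr_length_bp = 50e6,
                       maf_range = c(0.02, 0.5),
                       ld_rho = 0, missing_rate = 0,
                       n_qtl_mean = 20, n_qtl_var = 10,
                       a_m = NULL, a_v = NULL,
                       qtl_prop_m = 0.2, qtl_prop_v = 0.2,
                       sigma2_s = 130, sigma2_sv = 0.2, r_mv = 0.76,
                       mu = 280, eta0 = log(600),
                       n_cg = 50, sigma2_cg = 100,
                       age_range = c(300, 420),
                       beta_age = c(F = 0.20, M = 0.25),
                       beta_age2 = c(F = -0.001, M = -0.001),
                       seed = NULL) {
  cfg <- list(
    n_sires = as.integer(n_sires),
    progeny_min = as.integer(progeny_min),
    progeny_max = as.integer(progeny_max),
    progeny_mean = progeny_mean,
    n_chr = as.integer(n_chr), snps_per_chr = as.integer(snps_per_chr),
    chr_length_bp = chr_length_bp,
    maf_range = maf_range, ld_rho = ld_rho, missing_rate = missing_rate,
    n_qtl_mean = as.integer(n_qtl_mean), n_qtl_var = as.integer(n_qtl_var),
    a_m = a_m, a_v = a_v,
    qtl_prop_m = qtl_prop_m, qtl_prop_v = qtl_prop_v,
    sigma2_s = sigma2_s, sigma2_sv = sigma2_sv, r_mv = r_mv,
    mu = mu, eta0 = eta0,
    n_cg = as.integer(n_cg), sigma2_cg = sigma2_cg,
    age_range = age_range, beta_age = beta_age, beta_age2 = beta_age2,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sires >= 1, cfg$n_chr >= 1, cfg$snps_per_chr >= 1)
  if (abs(cfg$r_mv) > 1) stop("invalid r_mv: |r_mv| must be <= 1")
  if (cfg$sigma2_s < 0 || cfg$sigma2_sv < 0 || cfg$sigma2_cg < 0)
    stop("variances must be non-negative")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$progeny_min < 0 || cfg$progeny_max < cfg$progeny_min)
    stop("invalid progeny count range")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  invisible(cfg)
}

# Offset the user seed per stage so each simulate_* call has its own
# reproducible stream while the same cfg always regenerates the same study.
set_stage_seed <- function(cfg, stage) {
  if (!is.null(cfg$seed)) {
    offset <- c(genotypes = 0L, truth = 1L, progeny = 2L)[[stage]]
    set.seed(as.integer(cfg$seed) %% 2000000000L + offset)
  }
  invisible(NULL)
}

#' Simulate sire genotypes
#'
#' Draws a per-SNP allele frequency from `cfg$maf_range` and sire genotypes
#' as binomial(2, p) counts of the B allele (Hardy-Weinberg). With
#' `cfg$ld_rho > 0` each SNP copies its left neighbour's genotype per sire
#' with that probability, producing blocky within-chromosome LD.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] with `n_sires` rows.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set_stage_seed(cfg, "genotypes")
  n <- cfg$n_sires
  m_chr <- cfg$snps_per_chr
  M <- cfg$n_chr * m_chr
  p <- runif(M, cfg$maf_range[1], cfg$maf_range[2])
  codes <- matrix(rbinom(n * M, 2L, rep(p, each = n)), nrow = n, ncol = M)
  if (cfg$ld_rho > 0) {
    for (c_i in seq_len(cfg$n_chr)) {
      off <- (c_i - 1L) * m_chr
      for (j in seq_len(m_chr - 1L)) {
        copy <- runif(n) < cfg$ld_rho
        codes[copy, off + j + 1L] <- codes[copy, off + j]
      }
    }
  }
  if (cfg$missing_rate > 0) {
    codes[runif(n * M) < cfg$missing_rate] <- NA_integer_
  }
  map <- data.frame(
    snp_id = sprintf("snp%d_%d", rep(seq_len(cfg$n_chr), each = m_chr),
                     rep(seq_len(m_chr), cfg$n_chr)),
    chr = rep(seq_len(cfg$n_chr), each = m_chr),
    bp = rep(round(seq(1, cfg$chr_length_bp, length.out = m_chr)), cfg$n_chr),
    stringsAsFactors = FALSE
  )
  geno_matrix(codes, map, sire_ids = sprintf("sire%04d", seq_len(n)))
}

#' Simulate true genetic effects on the mean and the log residual variance
#'
#' Samples QTL positions (without replacement, disjoint sets for the two
#' scales), QTL allele-substitution effects, and jointly normal polygenic
#' deviations `(u_m, u_v)` whose covariance is chosen so that the *total*
#' genetic values `A_m = Z a_m + u_m` and `A_v = Z a_v + u_v` have variances
#' `sigma2_s`, `sigma2_sv` and covariance `r_mv * sqrt(sigma2_s * sigma2_sv)`
#' in expectation. QTL contributions are computed from realised genotype
#' frequencies, so the polygenic share is reduced accordingly; since the QTL
#' sets are disjoint, all of the cross-scale covariance is carried by the
#' polygenic part, which bounds the feasible `r_mv` at
#' `sqrt((1 - qtl share m) * (1 - qtl share v))`.
#'
#' @param geno a [geno_matrix()] of sire genotypes.
#' @param cfg a [sim_config()].
#' @return An object of class `sim_truth`: list with `qtl` (data.frame of
#'   snp_id, scale, effect), per-SNP effect vectors `a_m`, `a_v`, polygenic
#'   deviations `u_m`, `u_v`, and total genetic values `A_m`, `A_v`.
#' @export
simulate_truth <- function(geno, cfg) {
  validate_sim_config(cfg)
  set_stage_seed(cfg, "truth")
  M <- ncol(geno$codes)
  if (cfg$n_qtl_mean + cfg$n_qtl_var > M)
    stop("n_qtl_mean + n_qtl_var exceeds the number of SNPs")
  codes <- geno$codes
  codes[is.na(codes)] <- rep(colMeans(codes, na.rm = TRUE),
                             each = nrow(codes))[is.na(codes)]
  p_hat <- colMeans(codes) / 2
  het <- 2 * p_hat * (1 - p_hat)

  idx <- sample.int(M, cfg$n_qtl_mean + cfg$n_qtl_var)
  idx_m <- idx[seq_len(cfg$n_qtl_mean)]
  idx_v <- setdiff(idx, idx_m)

  draw_effects <- function(idx_q, scale_sd, prop, sigma2) {
    a <- numeric(M)
    if (length(idx_q) == 0L) return(a)
    raw <- rnorm(length(idx_q))
    if (is.null(scale_sd)) {
      # scale so realised sum of 2p(1-p)a^2 equals prop * sigma2 exactly
      tv <- sum(het[idx_q] * raw^2)
      if (tv > 0 && sigma2 > 0) raw <- raw * sqrt(prop * sigma2 / tv)
      else raw <- raw * 0
    } else {
      raw <- raw * scale_sd
    }
    a[idx_q] <- raw
    a
  }
  a_m <- draw_effects(idx_m, cfg$a_m, cfg$qtl_prop_m, cfg$sigma2_s)
  a_v <- draw_effects(idx_v, cfg$a_v, cfg$qtl_prop_v, cfg$sigma2_sv)

  var_qm <- sum(het * a_m^2)
  var_qv <- sum(het * a_v^2)
  var_um <- cfg$sigma2_s - var_qm
  var_uv <- cfg$sigma2_sv - var_qv
  if (var_um < -1e-8 || var_uv < -1e-8)
    stop("QTL effects imply more variance than sigma2_s / sigma2_sv")
  var_um <- max(var_um, 0)
  var_uv <- max(var_uv, 0)
  cov_uv <- cfg$r_mv * sqrt(cfg$sigma2_s * cfg$sigma2_sv)
  if (abs(cov_uv) > sqrt(var_um * var_uv) + 1e-12)
    stop("impossible covariance: |r_mv| too large for the polygenic share ",
         "left after the QTL (reduce qtl_prop or |r_mv|)")

  n <- nrow(codes)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  u_m <- sqrt(var_um) * z1
  if (var_um > 0 && var_uv > 0) {
    rho_u <- cov_uv / sqrt(var_um * var_uv)
    u_v <- sqrt(var_uv) * (rho_u * z1 + sqrt(max(0, 1 - rho_u^2)) * z2)
  } else {
    u_v <- sqrt(var_uv) * z2
  }

  zc <- sweep(codes, 2, 2 * p_hat)  # centred dosage
  A_m <- as.numeric(zc %*% a_m) + u_m
  A_v <- as.numeric(zc %*% a_v) + u_v

  qtl <- data.frame(
    snp_id = geno$map$snp_id[c(idx_m, idx_v)],
    scale = rep(c("mean", "var"), c(length(idx_m), length(idx_v))),
    effect = c(a_m[idx_m], a_v[idx_v]),
    stringsAsFactors = FALSE
  )
  structure(list(qtl = qtl, a_m = a_m, a_v = a_v,
                 u_m = u_m, u_v = u_v, A_m = A_m, A_v = A_v,
                 sire_ids = geno$sire_ids, map = geno$map),
            class = "sim_truth")
}

# mean of a log-normal truncated to [a, b]
truncated_lnorm_mean <- function(meanlog, sdlog, a, b) {
  la <- (log(a) - meanlog) / sdlog
  lb <- (log(b) - meanlog) / sdlog
  num <- pnorm(lb - sdlog) - pnorm(la - sdlog)
  den <- pnorm(lb) - pnorm(la)
  exp(meanlog + sdlog^2 / 2) * num / den
}

draw_progeny_counts <- function(cfg, n) {
  a <- max(cfg$progeny_min, 1L)
  b <- cfg$progeny_max
  if (cfg$progeny_min == cfg$progeny_max)
    return(rep(cfg$progeny_min, n))
  if (is.null(cfg$progeny_mean)) {
    lo <- if (cfg$progeny_min == 0) 0.25 else a
    cnt <- round(exp(runif(n, log(lo), log(b))))
  } else {
    sdlog <- 1
    f <- function(m) truncated_lnorm_mean(m, sdlog, a, b) - cfg$progeny_mean
    meanlog <- uniroot(f, lower = log(a) - 5, upper = log(b) + 5)$root
    x <- exp(rnorm(n, meanlog, sdlog))
    # redraw outside the bounds (truncation)
    while (any(bad <- x < a | x > b))
      x[bad] <- exp(rnorm(sum(bad), meanlog, sdlog))
    cnt <- round(x)
  }
  pmin(pmax(cnt, cfg$progeny_min), cfg$progeny_max)
}

#' Simulate progeny phenotype records
#'
#' Each progeny record is
#' `y = mu + cg + b1(sex) * age_c + b2(sex) * age_c^2 + A_m/2 + e`,
#' with `age_c` the age centred at the middle of `age_range` and
#' `e ~ Normal(0, exp(eta0 + A_v/2))` for the record's sire. The sire
#' transmits half of his genetic value on both scales; Mendelian-sampling
#' variation is absorbed into the residual, as in a sire model.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()].
#' @return A phenotype `data.frame` with columns `animal_id`, `sire_id`,
#'   `cg`, `sex`, `age`, `y`.
#' @export
simulate_progeny <- function(truth, cfg) {
  validate_sim_config(cfg)
  set_stage_seed(cfg, "progeny")
  n_s <- length(truth$sire_ids)
  counts <- draw_progeny_counts(cfg, n_s)
  if (any(counts == 0L))
    warning(sum(counts == 0L), " sire(s) drew zero progeny and are absent ",
            "from the phenotype table")
  n <- sum(counts)
  sire <- rep(truth$sire_ids, counts)
  sire_idx <- rep(seq_len(n_s), counts)
  cg_eff <- rnorm(cfg$n_cg, 0, sqrt(cfg$sigma2_cg))
  cg <- sample.int(cfg$n_cg, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  age_c <- age - mean(cfg$age_range)
  b1 <- cfg$beta_age[sex]
  b2 <- cfg$beta_age2[sex]
  resid_sd <- sqrt(exp(cfg$eta0 + truth$A_v[sire_idx] / 2))
  y <- cfg$mu + cg_eff[cg] + b1 * age_c + b2 * age_c^2 +
    truth$A_m[sire_idx] / 2 + rnorm(n, 0, resid_sd)
  data.frame(
    animal_id = sprintf("an%07d", seq_len(n)),
    sire_id = sire,
    cg = sprintf("cg%03d", cg),
    sex = sex,
    age = age,
    y = y,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_truth()]
#' and [simulate_progeny()] with one config.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `geno`, `truth`, `pheno` and the `cfg`.
#' @export
simulate_study <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  truth <- simulate_truth(geno, cfg)
  pheno <- simulate_progeny(truth, cfg)
  list(geno = geno, truth = truth, pheno = pheno, cfg = cfg)
}
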