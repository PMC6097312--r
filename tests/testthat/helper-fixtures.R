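# In-code fixtures shared across test files.

# Small phenotype table with full manual control (used by the dense-oracle
# tests, where the model matrices are rebuilt by hand).
make_toy_pheno <- function(n_sires = 3, n_prog = 4, n_cg = 2, seed = 42,
                           sd_y = 10) {
  set.seed(seed)
  n <- n_sires * n_prog
  data.frame(
    animal_id = sprintf("a%03d", seq_len(n)),
    sire_id = rep(sprintf("s%02d", seq_len(n_sires)), each = n_prog),
    cg = rep(sprintf("c%d", seq_len(n_cg)), length.out = n),
    sex = rep(c("M", "F"), each = ceiling(n / 2))[seq_len(n)],
    age = runif(n, 300, 420),
    y = rnorm(n, 280, sd_y),
    stringsAsFactors = FALSE
  )
}

# Dense mixed-model-equation oracle for the univariate weighted sire model:
# builds the full coefficient matrix explicitly and returns solutions,
# leverages and PEV.
dense_mme_oracle <- function(pheno, phi, sigma2_s) {
  sire <- factor(pheno$sire_id)
  q <- nlevels(sire)
  age_s <- (pheno$age - mean(pheno$age)) / sd(pheno$age)
  df <- data.frame(cg = factor(pheno$cg), sex = factor(pheno$sex),
                   age_s = age_s)
  X <- if (nlevels(df$sex) > 1)
    model.matrix(~ 0 + cg + sex:age_s + sex:I(age_s^2), df)
  else model.matrix(~ 0 + cg + age_s + I(age_s^2), df)
  Z <- model.matrix(~ 0 + sire)
  TT <- cbind(X, Z)
  W <- diag(1 / phi)
  C <- t(TT) %*% W %*% TT
  p <- ncol(X)
  C[p + seq_len(q), p + seq_len(q)] <-
    C[p + seq_len(q), p + seq_len(q)] + diag(q) / sigma2_s
  sol <- solve(C, t(TT) %*% W %*% pheno$y)
  Cinv <- solve(C)
  H <- TT %*% Cinv %*% t(TT) %*% W
  list(b = sol[seq_len(p)], s = sol[p + seq_len(q)], h = diag(H),
       pev = diag(Cinv)[p + seq_len(q)],
       residuals = pheno$y - as.numeric(TT %*% sol))
}

# Hand-enumerable QC fixture: 10 SNPs of which 2 are monomorphic, 1
# grossly violates HWE, and one adjacent pair is an exact duplicate, so
# exactly 6 SNPs survive (2 MAF + 1 HWE + 1 LD removals).
make_qc_fixture <- function(n = 100, seed = 3) {
  set.seed(seed)
  draw_hwe <- function(p) rbinom(n, 2, p)
  codes <- cbind(
    snpA = draw_hwe(0.3),
    snpB = rep(0, n),                        # monomorphic (MAF)
    snpC = draw_hwe(0.4),
    snpD = NA,                               # duplicate of snpC (LD)
    snpE = c(rep(0, n / 2), rep(2, n / 2)),  # no heterozygotes (HWE)
    snpF = draw_hwe(0.25),
    snpG = rep(2, n),                        # monomorphic (MAF)
    snpH = draw_hwe(0.35),
    snpI = draw_hwe(0.45),
    snpJ = draw_hwe(0.2)
  )
  codes[, "snpD"] <- codes[, "snpC"]
  map <- data.frame(snp_id = colnames(codes), chr = 1L,
                    bp = seq(1e5, 1e6, length.out = 10))
  geno_matrix(codes, map)
}
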