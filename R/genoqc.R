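# Chip-style SNP quality control: sex-chromosome removal, sire call-rate
# filter, MAF, Hardy-Weinberg chi-square test, and r^2-based LD pruning in
# sliding windows of consecutive SNPs.

#' Minor allele frequency
#'
#' `min(f, 1 - f)` where `f` is the B-allele frequency over non-missing
#' calls. All-missing SNPs return `NA` (flagged for removal by the MAF
#' filter in [apply_qc()]).
#'
#' @param codes numeric vector of 0/1/2 codes for one SNP, or a matrix with
#'   SNPs in columns.
#' @return MAF in `[0, 0.5]` per SNP.
#' @export
compute_maf <- function(codes) {
  if (is.matrix(codes)) {
    f <- colMeans(codes, na.rm = TRUE) / 2
  } else {
    f <- mean(codes, na.rm = TRUE) / 2
  }
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts against
#' the expected Hardy-Weinberg proportions at the estimated allele
#' frequency. Monomorphic SNPs return `p = 1` by convention (they carry no
#' HWE information and are caught by the MAF filter).
#'
#' @param n_AA,n_AB,n_BB genotype counts (code 0, 1, 2).
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)   # total heterozygote deficit: p ~ 1.5e-23
hwe_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  stopifnot(all(n >= 1))
  p <- (2 * n_BB + n_AB) / (2 * n)
  mono <- p <= 0 | p >= 1
  e_AA <- n * (1 - p)^2
  e_AB <- n * 2 * p * (1 - p)
  e_BB <- n * p^2
  chi2 <- ifelse(mono, 0,
                 (n_AA - e_AA)^2 / pmax(e_AA, .Machine$double.xmin) +
                 (n_AB - e_AB)^2 / pmax(e_AB, .Machine$double.xmin) +
                 (n_BB - e_BB)^2 / pmax(e_BB, .Machine$double.xmin))
  ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Pairwise genotype correlation r-squared
#'
#' Squared Pearson correlation of additive codes over pairwise-complete
#' sires; the usual chip-QC LD measure. If either SNP has zero variance the
#' value is undefined and returned as 0 (so pruning never acts on it).
#'
#' @param codes_a,codes_b numeric vectors of 0/1/2 codes.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(codes_a, codes_b) {
  ok <- !is.na(codes_a) & !is.na(codes_b)
  if (sum(ok) < 2) return(0)
  a <- codes_a[ok]; b <- codes_b[ok]
  if (var(a) == 0 || var(b) == 0) return(0)
  cor(a, b)^2
}

#' Apply the SNP quality-control pipeline
#'
#' Filters are applied in the order sex chromosomes, sire call rate, MAF,
#' HWE, LD pruning; each SNP is attributed to the first filter that removed
#' it, so the per-filter counts add up to the total removed. LD pruning
#' scans each chromosome in map order and drops a candidate SNP when its
#' r-squared with any of the previous `ld_window - 1` *retained* SNPs
#' exceeds `ld_r2_max` (the later SNP of a correlated pair is always the one
#' removed).
#'
#' @param geno a [geno_matrix()]; map must be sorted by (chr, bp).
#' @param maf_min remove SNPs with MAF strictly below this (0 disables).
#' @param hwe_p_min remove SNPs with HWE p-value strictly below this
#'   (0 disables).
#' @param ld_r2_max prune SNPs with r-squared strictly above this
#'   (1 disables).
#' @param ld_window number of consecutive retained SNPs forming the pruning
#'   window.
#' @param callrate_min remove sires with call rate strictly below this
#'   (0 disables). There is no per-SNP call-rate filter.
#' @param sex_chr integer chromosome codes treated as sex chromosomes
#'   (`NULL` disables).
#' @return list with `geno` (filtered [geno_matrix()]) and `report`, a
#'   one-row data.frame of class `qc_report` with per-filter counts.
#' @export
apply_qc <- function(geno, maf_min = 0.02, hwe_p_min = 1e-5,
                     ld_r2_max = 0.99, ld_window = 100L,
                     callrate_min = 0.90, sex_chr = c(30L, 31L)) {
  stopifnot(inherits(geno, "geno_matrix"))
  ord <- order(geno$map$chr, geno$map$bp)
  if (!identical(ord, seq_len(nrow(geno$map))))
    stop("map must be sorted by (chr, bp)")
  n_input <- nrow(geno$map)
  removed <- rep(NA_character_, n_input)  # first filter that removed each SNP

  # 1. sex chromosomes
  if (!is.null(sex_chr)) {
    hit <- geno$map$chr %in% sex_chr
    removed[hit] <- "sex_chr"
  }

  # 2. sire call rate (computed over currently retained SNPs)
  keep_snp <- is.na(removed)
  cr <- rowMeans(!is.na(geno$codes[, keep_snp, drop = FALSE]))
  keep_sire <- cr >= callrate_min
  n_removed_sires <- sum(!keep_sire)
  codes <- geno$codes[keep_sire, , drop = FALSE]
  if (nrow(codes) == 0L) stop("no sires survive the call-rate filter")

  # 3. MAF (all-missing SNPs have undefined MAF and are removed here)
  maf <- compute_maf(codes)
  hit <- keep_snp & (is.na(maf) | (maf_min > 0 & maf < maf_min))
  removed[hit] <- "maf"
  keep_snp <- is.na(removed)

  # 4. HWE
  if (hwe_p_min > 0) {
    idx <- which(keep_snp)
    if (length(idx)) {
      cnt0 <- colSums(codes[, idx, drop = FALSE] == 0, na.rm = TRUE)
      cnt1 <- colSums(codes[, idx, drop = FALSE] == 1, na.rm = TRUE)
      cnt2 <- colSums(codes[, idx, drop = FALSE] == 2, na.rm = TRUE)
      p_hwe <- hwe_test(cnt0, cnt1, cnt2)
      removed[idx[p_hwe < hwe_p_min]] <- "hwe"
      keep_snp <- is.na(removed)
    }
  }

  # 5. LD pruning within chromosomes, sliding window of retained SNPs
  if (ld_r2_max < 1) {
    for (chr in unique(geno$map$chr)) {
      idx <- which(keep_snp & geno$map$chr == chr)
      if (length(idx) < 2) next
      x <- codes[, idx, drop = FALSE]
      xc <- sweep(x, 2, colMeans(x, na.rm = TRUE))
      xc[is.na(xc)] <- 0  # pairwise-complete approximated by zero-filling
      retained <- integer(0)
      for (k in seq_along(idx)) {
        lo <- max(1L, length(retained) - (ld_window - 2L))
        win <- retained[seq(lo, length.out = length(retained) - lo + 1L)]
        prune <- FALSE
        if (length(win)) {
          num <- as.numeric(crossprod(xc[, win, drop = FALSE], xc[, k]))
          den <- sqrt(colSums(xc[, win, drop = FALSE]^2) * sum(xc[, k]^2))
          r2 <- ifelse(den > 0, (num / den)^2, 0)
          prune <- any(r2 > ld_r2_max)
        }
        if (prune) removed[idx[k]] <- "ld" else retained <- c(retained, k)
      }
    }
    keep_snp <- is.na(removed)
  }

  if (!any(keep_snp)) stop("no SNPs survive QC")
  out <- geno_matrix(codes[, keep_snp, drop = FALSE],
                     geno$map[keep_snp, , drop = FALSE],
                     geno$sire_ids[keep_sire])
  report <- data.frame(
    n_input_snps = n_input,
    n_removed_sex_chr = sum(removed == "sex_chr", na.rm = TRUE),
    n_removed_maf = sum(removed == "maf", na.rm = TRUE),
    n_removed_hwe = sum(removed == "hwe", na.rm = TRUE),
    n_removed_ld = sum(removed == "ld", na.rm = TRUE),
    n_removed_callrate_sires = n_removed_sires,
    n_output_snps = sum(keep_snp)
  )
  class(report) <- c("qc_report", "data.frame")
  list(geno = out, report = report)
}
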