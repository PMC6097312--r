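# Inferential summaries of the sampler output: Bayes factors, 1-Mb window
# variance partitioning, top-window overlaps, response correlations, the
# scale-effect test and per-genotype summaries.

#' Bayes factor of SNP inclusion
#'
#' `BF = (p / (1 - p)) / (prior / (1 - prior))`: posterior odds of a SNP
#' having a non-zero effect over its prior odds. A posterior probability of
#' exactly 1 is capped at `1 - 1/(n_kept + 1)` so the ratio stays finite
#' (logged via a message when it happens). BF > 3 is read as suggestive and
#' BF > 20 as strong evidence.
#'
#' @param p posterior inclusion probability (vector allowed).
#' @param prior_inclusion prior inclusion probability, in (0, 1).
#' @param n_kept number of kept posterior samples (needed to cap `p = 1`).
#' @return Bayes factor(s), `>= 0`.
#' @export
#' @examples
#' bayes_factor(0.5, 0.001)   # 999 * ... posterior odds 1 over prior odds
bayes_factor <- function(p, prior_inclusion, n_kept = NULL) {
  stopifnot(prior_inclusion > 0, prior_inclusion < 1,
            all(p >= 0), all(p <= 1))
  capped <- p >= 1
  if (any(capped)) {
    if (is.null(n_kept))
      stop("p = 1 requires n_kept to cap the posterior odds")
    message("bayes_factor: capped ", sum(capped),
            " posterior probability(ies) of 1 at 1 - 1/(n_kept + 1)")
    p[capped] <- 1 - 1 / (n_kept + 1)
  }
  (p / (1 - p)) / (prior_inclusion / (1 - prior_inclusion))
}

#' Classify Bayes factors
#'
#' @param bf Bayes factors.
#' @return factor with levels `none`, `suggestive` (BF > 3), `strong`
#'   (BF > 20).
#' @export
bf_class <- function(bf) {
  cut(bf, breaks = c(-Inf, 3, 20, Inf),
      labels = c("none", "suggestive", "strong"))
}

#' 1-Mb window index and label
#'
#' Windows are non-overlapping megabase bins of physical position:
#' `floor((bp - 1) / 1e6)` (0-based index). Labels follow the `Chr<k>_<Mb>`
#' convention where `<Mb>` is the 1-based megabase bin, so a SNP at 51.6 Mb
#' on chromosome 22 falls in `Chr22_52`.
#'
#' @param chr,bp chromosome and 1-based position vectors.
#' @return data.frame with `window_index` and `label`.
#' @export
window_id <- function(chr, bp) {
  idx <- floor((bp - 1) / 1e6)
  data.frame(window_index = idx,
             label = sprintf("Chr%s_%d", chr, idx + 1),
             stringsAsFactors = FALSE)
}

#' Genetic variance explained by 1-Mb windows
#'
#' For each non-overlapping 1-Mb window `w`, computes the window genomic
#' values `g_w = Z_w a_w` over individuals and reports
#' `pct = 100 * Var(g_w) / Var(g)` with `g` the total genomic value
#' (`denominator = "total"`, default) or with the sum of window variances as
#' denominator (`denominator = "windows"`).
#'
#' @param Z genotype matrix (individuals x SNPs) or [geno_matrix()]; columns
#'   are centred internally.
#' @param a_hat per-SNP (posterior mean) allele substitution effects.
#' @param map SNP map aligned with the columns of `Z`.
#' @param bf optional per-SNP Bayes factors used to report each window's top
#'   SNP.
#' @param denominator `"total"` or `"windows"`.
#' @return data.frame of class `window_summary`, sorted by `pct` decreasing:
#'   `chr`, `window_index`, `label`, `n_snps`, `pct`, and when `bf` is given
#'   `top_snp_id`, `top_snp_bf`.
#' @export
window_variance <- function(Z, a_hat, map, bf = NULL,
                            denominator = c("total", "windows")) {
  denominator <- match.arg(denominator)
  if (inherits(Z, "geno_matrix")) { map <- Z$map; Z <- Z$codes }
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) == length(a_hat), ncol(Z) == nrow(map))
  cm <- colMeans(Z, na.rm = TRUE)
  nas <- which(is.na(Z))
  if (length(nas)) Z[nas] <- cm[((nas - 1L) %/% nrow(Z)) + 1L]
  Zc <- sweep(Z, 2L, colMeans(Z))

  wid <- window_id(map$chr, map$bp)
  key <- paste(map$chr, wid$window_index)
  g_tot <- as.numeric(Zc %*% a_hat)
  groups <- split(seq_along(a_hat), key)
  rows <- lapply(groups, function(ix) {
    g_w <- as.numeric(Zc[, ix, drop = FALSE] %*% a_hat[ix])
    r <- data.frame(chr = map$chr[ix[1]],
                    window_index = wid$window_index[ix[1]],
                    label = wid$label[ix[1]],
                    n_snps = length(ix), var_w = var(g_w),
                    stringsAsFactors = FALSE)
    if (!is.null(bf)) {
      top <- ix[which.max(bf[ix])]
      r$top_snp_id <- map$snp_id[top]
      r$top_snp_bf <- bf[top]
    }
    r
  })
  out <- do.call(rbind, rows)
  den <- if (denominator == "total") var(g_tot) else sum(out$var_w)
  if (!is.finite(den) || den <= 0) {
    warning("all SNP effects are zero; window percentages set to 0")
    out$pct <- 0
  } else {
    out$pct <- 100 * out$var_w / den
  }
  out$var_w <- NULL
  out <- out[order(-out$pct, out$chr, out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_summary", "data.frame")
  out
}

#' Overlap of top-K windows between two analyses
#'
#' Counts the windows present in both top-K sets (by percent of genetic
#' variance, ties at rank K broken by chromosome then window index,
#' deterministically). Set semantics: rank order within the top K is
#' ignored.
#'
#' @param summaries_a,summaries_b [window_variance()] results.
#' @param K top-window count (default 20; clipped with a warning when a
#'   list is shorter).
#' @param response_a,response_b optional response vectors over the same
#'   sires; when given, their Pearson correlation is reported alongside.
#' @return list of class `overlap_report`: `K`, `n_shared`,
#'   `shared_windows`, and `response_cor` (NA when responses not supplied).
#' @export
top_windows_overlap <- function(summaries_a, summaries_b, K = 20L,
                                response_a = NULL, response_b = NULL) {
  top_k <- function(s, K) {
    s <- s[order(-s$pct, s$chr, s$window_index), , drop = FALSE]
    s$label[seq_len(min(K, nrow(s)))]
  }
  K_eff <- min(K, nrow(summaries_a), nrow(summaries_b))
  if (K_eff < K)
    warning("K clipped to ", K_eff, " (fewer windows than requested)")
  ta <- top_k(summaries_a, K_eff)
  tb <- top_k(summaries_b, K_eff)
  shared <- intersect(ta, tb)
  rc <- if (!is.null(response_a) && !is.null(response_b))
    cor(response_a, response_b, use = "pairwise.complete.obs") else NA_real_
  structure(list(K = K_eff, n_shared = length(shared),
                 shared_windows = shared, response_cor = rc),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Top-", x$K, " window overlap: ", x$n_shared, " shared",
      if (length(x$shared_windows))
        paste0(" (", paste(x$shared_windows, collapse = ", "), ")"),
      "\n", sep = "")
  if (!is.na(x$response_cor))
    cat(sprintf("  response correlation: %.3f\n", x$response_cor))
  invisible(x)
}

#' Pairwise Pearson correlations between response variables
#'
#' Pairwise-complete correlations with the large-sample standard error
#' `sqrt((1 - r^2) / (n - 2))`. Pairs with fewer than 3 complete sires or a
#' zero-variance member are reported as `NA`.
#'
#' @param responses a [assemble_responses()] result (or any data.frame whose
#'   response columns are given in `cols`).
#' @param cols columns to correlate.
#' @return list with matrices `r`, `se`, `n`.
#' @export
response_correlations <- function(responses,
                                  cols = c("dEBV_m", "dEBV_v",
                                           "dEBV_v_r0", "lnvar")) {
  cols <- intersect(cols, names(responses))
  k <- length(cols)
  r <- se <- nmat <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- responses[[cols[i]]]; y <- responses[[cols[j]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    rij <- cor(x[ok], y[ok])
    r[i, j] <- rij
    se[i, j] <- sqrt((1 - rij^2) / (n - 2))
  }
  list(r = r, se = se, n = nmat)
}

#' Scale-effect test for shared mean/variance associations
#'
#' Standardises a SNP's absolute effect on the mean response by the trait
#' mean and its absolute effect on the variance response by the mean
#' residual variance. If an apparent variance effect were a pure scale
#' effect the standardised mean effect would be at least as large; a
#' strictly larger standardised variance effect flags an effect on the
#' residual variance beyond scale.
#'
#' @param a_mean,a_var SNP effects on the mean and variance responses
#'   (vectors allowed).
#' @param mean_trait mean of the trait (positive).
#' @param mean_resid_var mean residual variance (positive).
#' @return data.frame with `std_mean`, `std_var`, `beyond_scale`.
#' @export
scale_effect_test <- function(a_mean, a_var, mean_trait, mean_resid_var) {
  stopifnot(mean_trait > 0, mean_resid_var > 0)
  std_mean <- abs(a_mean) / mean_trait
  std_var <- abs(a_var) / mean_resid_var
  data.frame(std_mean = std_mean, std_var = std_var,
             beyond_scale = std_var > std_mean)
}

#' Response summary by genotype class at one SNP
#'
#' Per-genotype (0/1/2) count, mean, quartiles and SD of a response --
#' the numbers behind a genotype box plot.
#'
#' @param response response values per sire.
#' @param codes genotype codes (0/1/2, `NA` allowed) at one SNP for the same
#'   sires.
#' @return data.frame with one row per genotype class (empty classes have
#'   `n = 0` and `NA` summaries).
#' @export
genotype_summary <- function(response, codes) {
  stopifnot(length(response) == length(codes))
  if (length(unique(codes[!is.na(codes)])) < 2)
    stop("SNP is monomorphic in the summarised sires")
  do.call(rbind, lapply(0:2, function(g) {
    x <- response[!is.na(codes) & codes == g & !is.na(response)]
    if (!length(x))
      return(data.frame(genotype = g, n = 0L, mean = NA_real_,
                        q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                        sd = NA_real_))
    data.frame(genotype = g, n = length(x), mean = mean(x),
               q25 = unname(quantile(x, 0.25)), median = median(x),
               q75 = unname(quantile(x, 0.75)),
               sd = if (length(x) > 1) sd(x) else NA_real_)
  }))
}
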