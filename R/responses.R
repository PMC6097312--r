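# GWAS response variables built from DHGLM output: deregressed EBV for the
# mean (dEBV_m) and for the residual variance under a free genetic
# correlation (dEBV_v), plus two alternatives computed under a zero
# correlation constraint: dEBV_v_r0 and the log sample variance of the
# mean-model residuals per sire family (lnvar).

#' Deregress an EBV (no-parent-information form)
#'
#' `dEBV = EBV / r2`, which undoes the BLUP shrinkage, with GWAS weight
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)` so that sires with more
#' reliable EBV carry more weight. This is the founder (no parent average)
#' variant of the standard deregression; `c` is the fraction of genetic
#' variance not captured by the markers.
#'
#' @param ebv EBV vector.
#' @param r2 reliabilities in `[0, 1]`; entries with `r2 = 0` return `NA`
#'   (excluded, with a message).
#' @param h2 heritability of the response scale, in (0, 1).
#' @param c fraction of genetic variance not accounted for by markers, in
#'   `[0, 1)`; default 0.5.
#' @return data.frame with `debv` and `w`.
#' @export
#' @examples
#' deregress(10, 0.5, h2 = 0.3)            # dEBV = 20
#' deregress(1, r2 = 1, h2 = 0.3, c = 0)   # w = (1 - h2) / h2
deregress <- function(ebv, r2, h2, c = 0.5) {
  stopifnot(h2 > 0, h2 < 1, c >= 0, c < 1, all(r2 >= 0), all(r2 <= 1))
  zero <- r2 == 0
  if (any(zero))
    message("deregress: ", sum(zero), " sire(s) with zero reliability excluded")
  debv <- ifelse(zero, NA_real_, ebv / r2)
  denom <- c + (1 - r2) / r2
  # shrinkage-free limit (r2 = 1 with c = 0): weight reduces to (1-h2)/h2
  denom[denom == 0] <- 1
  w <- ifelse(zero, NA_real_, (1 - h2) / (denom * h2))
  data.frame(debv = debv, w = w)
}

#' Log sample variance of residuals per sire family
#'
#' `lnvar_i = log( sum_j (e_ij - mean_i)^2 / (n_i - 1) )`, natural log,
#' n-1 denominator. Families with fewer than 2 progeny or zero residual
#' variance are excluded with a message.
#'
#' @param residuals per-progeny residuals from the mean model.
#' @param sire_id sire of each record.
#' @return data.frame with `sire_id`, `n_progeny`, `lnvar` (excluded sires
#'   absent).
#' @export
ln_residual_variance <- function(residuals, sire_id) {
  stopifnot(length(residuals) == length(sire_id))
  sire <- factor(sire_id)
  n <- as.integer(table(sire))
  v <- as.numeric(tapply(residuals, sire, var))
  few <- n < 2
  if (any(few))
    message("ln_residual_variance: ", sum(few),
            " sire(s) with < 2 progeny excluded")
  degen <- !few & !is.na(v) & v <= 0
  if (any(degen))
    message("ln_residual_variance: ", sum(degen),
            " degenerate family(ies) with zero variance excluded")
  keep <- !few & !degen
  data.frame(sire_id = levels(sire)[keep], n_progeny = n[keep],
             lnvar = log(v[keep]), stringsAsFactors = FALSE)
}

#' Assemble the four GWAS response variables
#'
#' From a free-correlation fit: `dEBV_m` (mean part) and `dEBV_v` (variance
#' part), both deregressed with part-specific reliability and heritability.
#' From the zero-correlation fit: `dEBV_v_r0` (deregressed variance-part
#' EBV) and `lnvar` (log sample variance of the mean-model residuals per
#' family, weighted by progeny count in the GWAS). Heritabilities default to
#' the sire-model identity `h2 = 4 s2 / (4 s2 + mean residual variance)`
#' computed from each fit's own components.
#'
#' @param fit_free a [fit_dhglm()] result with `mode = "rmv_free"`.
#' @param fit_zero a [fit_dhglm()] result with `mode = "rmv_zero"`.
#' @param h2_m,h2_v optional heritabilities for the weight formula.
#' @param c deregression `c` parameter, see [deregress()].
#' @return object of class `sire_responses`: data.frame with columns
#'   `sire_id`, `n_progeny`, `dEBV_m`, `w_m`, `dEBV_v`, `w_v`, `dEBV_v_r0`,
#'   `w_v_r0`, `lnvar`, `w_lnvar`, and a `stats` attribute with the
#'   descriptive table (N, mean, SD, min, max per response).
#' @export
assemble_responses <- function(fit_free, fit_zero, h2_m = NULL, h2_v = NULL,
                               c = 0.5) {
  stopifnot(inherits(fit_free, "dhglm_fit"), inherits(fit_zero, "dhglm_fit"))
  if (fit_free$mode != "rmv_free" || fit_zero$mode != "rmv_zero")
    stop("fit_free must be an rmv_free fit and fit_zero an rmv_zero fit")
  common <- intersect(fit_free$mean_part$sire_ids, fit_zero$mean_part$sire_ids)
  dropped <- length(union(fit_free$mean_part$sire_ids,
                          fit_zero$mean_part$sire_ids)) - length(common)
  if (dropped > 0)
    message("assemble_responses: ", dropped,
            " sire(s) present in only one fit excluded")

  h2_m <- h2_m %||% (4 * fit_free$sigma2_s /
                       (4 * fit_free$sigma2_s + mean(fit_free$phi)))
  tau_v <- 2 / (1 - fit_free$var_part$h)
  h2_v <- h2_v %||% (4 * fit_free$sigma2_sv /
                       (4 * fit_free$sigma2_sv + mean(tau_v)))

  rel_free <- reliabilities(fit_free)
  rel_zero <- reliabilities(fit_zero)
  i_f <- match(common, rel_free$sire_id)
  i_z <- match(common, rel_zero$sire_id)

  dm <- deregress(fit_free$mean_part$s[i_f], rel_free$r2_m[i_f], h2_m, c)
  dv <- deregress(fit_free$var_part$s[i_f], rel_free$r2_v[i_f], h2_v, c)
  h2_v0 <- 4 * fit_zero$sigma2_sv /
    (4 * fit_zero$sigma2_sv + mean(2 / (1 - fit_zero$var_part$h)))
  dv0 <- deregress(fit_zero$var_part$s[i_z], rel_zero$r2_v[i_z], h2_v0, c)

  lv <- ln_residual_variance(fit_zero$mean_part$residuals,
                             fit_zero$mean_part$sire_ids[
                               fit_zero$mean_part$sire_idx])
  out <- data.frame(
    sire_id = common,
    n_progeny = rel_free$n_progeny[i_f],
    dEBV_m = dm$debv, w_m = dm$w,
    dEBV_v = dv$debv, w_v = dv$w,
    dEBV_v_r0 = dv0$debv, w_v_r0 = dv0$w,
    lnvar = lv$lnvar[match(common, lv$sire_id)],
    stringsAsFactors = FALSE
  )
  out$w_lnvar <- out$n_progeny
  stats_tab <- do.call(rbind, lapply(
    c("dEBV_m", "dEBV_v", "dEBV_v_r0", "lnvar"), function(nm) {
      x <- out[[nm]][!is.na(out[[nm]])]
      data.frame(response = nm, N = length(x), mean = mean(x), sd = sd(x),
                 min = min(x), max = max(x), stringsAsFactors = FALSE)
    }))
  attr(out, "stats") <- stats_tab
  attr(out, "h2") <- c(h2_m = h2_m, h2_v = h2_v, h2_v_r0 = h2_v0)
  class(out) <- c("sire_responses", "data.frame")
  out
}

#' Descriptive statistics of a response set
#'
#' @param x a [assemble_responses()] result.
#' @return the descriptive-statistics data.frame stored with the responses.
#' @export
response_stats <- function(x) {
  stopifnot(inherits(x, "sire_responses"))
  attr(x, "stats")
}
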