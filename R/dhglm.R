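# Bivariate sire DHGLM: a mean model for the trait and a dispersion model
# (log link) for its residual variance, coupled through a 2x2 sire
# (co)variance matrix and iterated to joint convergence.
#
# The mixed-model equations are solved by absorbing the fixed effects: with
# X the fixed design, Z the sire incidence and W the record weights, the
# random-effect block of the inverse coefficient matrix is
#   D = (Z'WZ + Ginv x I - Z'WX (X'WX)^-1 X'WZ)^-1,
# dense but only (parts * n_sires)^2, from which solutions, per-record
# leverages and per-sire prediction-error (co)variances all follow without
# ever forming the full inverse.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-effect and sire design shared by both parts of the model:
# contemporary group (no intercept) plus linear and quadratic age nested
# within sex. Age is centred and scaled internally for conditioning; fitted
# values are invariant to this.
build_design <- function(pheno) {
  need <- c("animal_id", "sire_id", "cg", "sex", "age", "y")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  sire <- factor(pheno$sire_id)
  cg <- factor(pheno$cg)
  sex <- factor(pheno$sex)
  age_sd <- sd(pheno$age)
  age_s <- (pheno$age - mean(pheno$age)) / if (age_sd > 0) age_sd else 1
  df <- data.frame(cg = cg, sex = sex, age_s = age_s, age2_s = age_s^2)
  X <- if (nlevels(sex) > 1)
    Matrix::sparse.model.matrix(~ 0 + cg + sex:age_s + sex:age2_s, df)
  else
    Matrix::sparse.model.matrix(~ 0 + cg + age_s + age2_s, df)
  list(X = X, sire = sire, sire_idx = as.integer(sire),
       q = nlevels(sire), sire_ids = levels(sire),
       n_progeny = as.integer(table(sire)))
}

# Solve the (possibly stacked) weighted mixed-model equations.
# X: n x p sparse fixed design (shared by parts); sire_idx: record -> sire;
# resp/wts: per-part response and weight (1 / residual variance) vectors;
# G0: parts x parts sire (co)variance matrix.
# Returns solutions plus the pieces needed for leverages and PEV.
solve_mme <- function(X, sire_idx, q, resp, wts, G0) {
  k <- length(resp)
  p <- ncol(X)
  n <- nrow(X)
  G0 <- as.matrix(G0)
  Ginv <- solve(G0)
  Zsp <- Matrix::sparseMatrix(i = seq_len(n), j = sire_idx, x = 1,
                              dims = c(n, q))
  Finv <- vector("list", k); K <- vector("list", k); M <- vector("list", k)
  rhs_b <- vector("list", k); ru_adj <- vector("list", k)
  zwz <- vector("list", k)
  for (a in seq_len(k)) {
    W <- wts[[a]]
    Xw <- Matrix::Diagonal(x = W) %*% X
    Fa <- as.matrix(Matrix::crossprod(X, Xw))
    ch <- tryCatch(chol(Fa), error = function(e) NULL)
    if (is.null(ch)) {
      d <- diag(qr.R(qr(Fa)))
      bad <- colnames(Fa)[which.min(abs(d))]
      stop("singular fixed-effect block (level '", bad,
           "' confounded or empty)")
    }
    Finv[[a]] <- chol2inv(ch)
    M[[a]] <- as.matrix(Matrix::crossprod(Zsp, Xw))      # q x p
    K[[a]] <- M[[a]] %*% Finv[[a]]                       # q x p
    zwz[[a]] <- rowsum_by(W, sire_idx, q)
    rb <- as.numeric(Matrix::crossprod(Xw, resp[[a]]))
    ru <- rowsum_by(W * resp[[a]], sire_idx, q)
    rhs_b[[a]] <- rb
    ru_adj[[a]] <- as.numeric(ru - K[[a]] %*% rb)
  }
  # random-effect Schur complement: parts x parts blocks of size q; the
  # within-part block is Z'WZ - Z'WX (X'WX)^-1 X'WZ, the cross-part
  # coupling enters only through Ginv.
  S <- matrix(0, k * q, k * q)
  for (a in seq_len(k)) {
    ia <- (a - 1L) * q + seq_len(q)
    S[ia, ia] <- diag(zwz[[a]], q) - tcrossprod(K[[a]], M[[a]])
    for (b in seq_len(k)) {
      ib <- (b - 1L) * q + seq_len(q)
      S[ia, ib] <- S[ia, ib] + diag(Ginv[a, b], q)
    }
  }
  S <- (S + t(S)) / 2
  chS <- chol(S)
  D <- chol2inv(chS)
  u <- D %*% unlist(ru_adj)
  u <- matrix(as.numeric(u), nrow = q, ncol = k)
  b <- vector("list", k)
  for (a in seq_len(k))
    b[[a]] <- as.numeric(Finv[[a]] %*% rhs_b[[a]] - t(K[[a]]) %*% u[, a])
  list(b = b, u = u, D = D, Finv = Finv, K = K, q = q, k = k,
       Zsp = Zsp, X = X)
}

rowsum_by <- function(x, g, q) {
  out <- numeric(q)
  tmp <- rowsum(x, g)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

# Per-record leverage of part `a`: h_j = w_j * t_j' Cinv t_j where t_j picks
# the record's fixed-effect row and sire column. Uses the identity
# t'Cinv t = x'Finv x + (Kx - z)' D_aa (Kx - z).
record_leverage <- function(sol, a, sire_idx, w) {
  q <- sol$q
  ia <- (a - 1L) * q + seq_len(q)
  Daa <- sol$D[ia, ia]
  X <- sol$X
  n <- nrow(X)
  A <- sol$Finv[[a]] + crossprod(sol$K[[a]], Daa %*% sol$K[[a]])
  quad <- numeric(n)
  chunk <- max(1L, floor(4e6 / ncol(X)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Xc <- X[s:e, , drop = FALSE]
    XA <- as.matrix(Xc %*% A)
    quad[s:e] <- Matrix::rowSums(XA * Xc)
  }
  L <- Daa %*% sol$K[[a]]                                # q x p
  Xt <- methods::as(X, "TsparseMatrix")
  vals <- Xt@x * L[cbind(sire_idx[Xt@i + 1L], Xt@j + 1L)]
  cross <- rowsum_by(vals, Xt@i + 1L, n)
  dzz <- diag(Daa)[sire_idx]
  w * (quad - 2 * cross + dzz)
}

new_mixed_fit <- function(sol, a, des, resp, w, sigma2_s, phi) {
  q <- sol$q
  ia <- (a - 1L) * q + seq_len(q)
  fitted <- as.numeric(sol$X %*% sol$b[[a]]) + sol$u[des$sire_idx, a]
  res <- resp - fitted
  h <- record_leverage(sol, a, des$sire_idx, w)
  structure(list(
    b = setNames(sol$b[[a]], colnames(sol$X)),
    s = setNames(sol$u[, a], des$sire_ids),
    residuals = res, h = h,
    pev = setNames(diag(sol$D)[ia], des$sire_ids),
    sigma2_s = sigma2_s, phi = phi,
    sire_ids = des$sire_ids, n_progeny = des$n_progeny,
    sire_idx = des$sire_idx
  ), class = "mixed_fit")
}

#' Fit the weighted sire mixed model for the trait mean
#'
#' Solves the mixed-model equations for
#' `y = X b + Z s + e`, `Var(e_j) = phi_j`, `s ~ N(0, sigma2_s I)`, with
#' fixed effects contemporary group and linear/quadratic age nested within
#' sex. Returns solutions, residuals, per-record leverages (hat-matrix
#' diagonal) and per-sire prediction error variances.
#'
#' @param pheno phenotype data.frame (see [read_phenotypes()]).
#' @param phi per-record residual variances (scalar or length-n vector).
#' @param sigma2_s sire variance component.
#' @return object of class `mixed_fit`.
#' @export
fit_mean_model <- function(pheno, phi, sigma2_s) {
  stopifnot(all(phi > 0), sigma2_s > 0)
  des <- build_design(pheno)
  phi <- rep_len(phi, nrow(pheno))
  w <- 1 / phi
  sol <- solve_mme(des$X, des$sire_idx, des$q, list(pheno$y), list(w),
                   matrix(sigma2_s, 1, 1))
  new_mixed_fit(sol, 1L, des, pheno$y, w, sigma2_s, phi)
}

#' Linearised working response for the dispersion model
#'
#' Converts squared residuals of the mean model into the working variable
#' `psi_j = log(phi_j) + e_j^2 / ((1 - h_j) phi_j) - 1`, the standard
#' first-order linearisation of the log residual variance. The record's
#' dispersion-model residual variance is fixed at `2 / (1 - h_j)` (the
#' asymptotic variance of a scaled chi-square with one degree of freedom),
#' i.e. record weight `(1 - h_j) / 2`.
#'
#' @param fit a `mixed_fit` from [fit_mean_model()] (or the mean part of a
#'   [fit_dhglm()] result).
#' @param phi per-record residual variances used in that fit.
#' @return list with `psi` and `weight` vectors.
#' @export
working_response <- function(fit, phi) {
  phi <- rep_len(phi, length(fit$residuals))
  h <- fit$h
  if (any(h >= 1)) stop("saturated record: leverage >= 1")
  psi <- log(phi) + fit$residuals^2 / ((1 - h) * phi) - 1
  list(psi = psi, weight = (1 - h) / 2)
}

bend_psd <- function(G, floor = 1e-8) {
  e <- eigen(G, symmetric = TRUE)
  if (all(e$values > floor)) return(G)
  v <- pmax(e$values, floor)
  e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
}

#' Fit the bivariate sire DHGLM
#'
#' Iterates (i) a joint solve of the stacked mean/dispersion mixed-model
#' equations given the current fitted residual variances `phi`, (ii) update
#' of the working response `psi` and its weights from the mean-model
#' residuals and leverages, (iii) an EM-REML update of the 2x2 sire
#' (co)variance matrix (covariance pinned to zero when
#' `mode = "rmv_zero"`), and (iv) update of `phi = exp(X b_v + Z s_v)`,
#' until `max |delta log phi| < tol` and the relative change of all variance
#' components is below `tol_vc`.
#'
#' @param pheno phenotype data.frame with columns `animal_id`, `sire_id`,
#'   `cg`, `sex`, `age`, `y`.
#' @param mode `"rmv_free"` estimates the genetic covariance between mean
#'   and log residual variance; `"rmv_zero"` constrains it to zero, which
#'   decouples the two parts.
#' @param init optional list with starting values `sigma2_s`, `sigma2_sv`,
#'   `cov_s_sv`, `phi`.
#' @param tol convergence tolerance on `max |delta log phi|`.
#' @param tol_vc relative convergence tolerance on variance components.
#' @param max_iter maximum outer iterations; on hitting it the best fit is
#'   returned with `converged = FALSE`.
#' @return object of class `dhglm_fit`: `mean_part` and `var_part`
#'   (`mixed_fit` objects), variance components `sigma2_s`, `sigma2_sv`,
#'   `cov_s_sv`, `r_mv`, fitted per-record variances `phi`, working
#'   response `psi`, `converged`, `n_iter` and an iteration `trace`.
#' @export
fit_dhglm <- function(pheno, mode = c("rmv_free", "rmv_zero"), init = NULL,
                      tol = 1e-6, tol_vc = 1e-5, max_iter = 100L) {
  mode <- match.arg(mode)
  des <- build_design(pheno)
  if (des$q < 2) stop("need at least 2 sires")
  y <- pheno$y
  n <- length(y)
  q <- des$q

  # fixed-effects-only start for phi
  w1 <- rep(1, n)
  Xw <- des$X
  F0 <- as.matrix(Matrix::crossprod(Xw))
  b0 <- tryCatch(solve(F0, as.numeric(Matrix::crossprod(Xw, y))),
                 error = function(e)
                   stop("singular fixed-effect block in initialisation"))
  r0 <- y - as.numeric(des$X %*% b0)
  phi <- rep(init$phi %||% var(r0), n)
  sigma2_s <- init$sigma2_s %||% 0.05 * var(y)

  # bootstrap psi from a univariate mean fit
  mf <- fit_mean_model(pheno, phi, sigma2_s)
  wr <- working_response(mf, phi)
  psi <- wr$psi
  tau_w <- wr$weight
  sigma2_sv <- init$sigma2_sv %||% 0.05 * var(psi)
  cov_s_sv <- if (mode == "rmv_zero") 0 else init$cov_s_sv %||% 0
  G0 <- matrix(c(sigma2_s, cov_s_sv, cov_s_sv, sigma2_sv), 2, 2)
  eta_ref <- mean(log(phi))

  trace <- list()
  converged <- FALSE
  sol <- NULL
  for (iter in seq_len(max_iter)) {
    G0 <- bend_psd(G0)
    sol <- solve_mme(des$X, des$sire_idx, q, list(y, psi),
                     list(1 / phi, tau_w), G0)
    fitted_m <- as.numeric(des$X %*% sol$b[[1]]) + sol$u[des$sire_idx, 1]
    e_m <- y - fitted_m
    h <- record_leverage(sol, 1L, des$sire_idx, 1 / phi)
    h <- pmin(h, 1 - 1e-10)
    psi <- log(phi) + e_m^2 / ((1 - h) * phi) - 1
    tau_w <- (1 - h) / 2

    # EM-REML update of the sire (co)variance matrix
    U <- sol$u
    iq <- seq_len(q)
    pev11 <- sum(diag(sol$D)[iq])
    pev22 <- sum(diag(sol$D)[q + iq])
    pev12 <- sum(sol$D[cbind(iq, q + iq)])
    G_new <- (crossprod(U) + matrix(c(pev11, pev12, pev12, pev22), 2, 2)) / q
    if (mode == "rmv_zero") G_new[1, 2] <- G_new[2, 1] <- 0

    # dispersion-model fitted values -> new phi
    log_phi_new <- as.numeric(des$X %*% sol$b[[2]]) + sol$u[des$sire_idx, 2]
    log_phi_new <- pmin(pmax(log_phi_new, eta_ref - 12), eta_ref + 12)
    d_phi <- max(abs(log_phi_new - log(phi)))
    # change measured against the dominant variance scale so a component
    # collapsing to zero cannot stall the convergence declaration
    rel_g <- max(abs(G_new - G0)) / max(abs(G0), 1e-10)
    phi <- exp(log_phi_new)
    G0 <- G_new
    trace[[iter]] <- c(iter = iter, max_dlogphi = d_phi, rel_vc = rel_g,
                       sigma2_s = G0[1, 1], sigma2_sv = G0[2, 2],
                       cov_s_sv = G0[1, 2])
    if (d_phi < tol && rel_g < tol_vc) { converged <- TRUE; break }
  }
  if (!converged)
    warning("DHGLM did not converge in ", max_iter,
            " iterations (max |delta log phi| = ",
            signif(trace[[length(trace)]]["max_dlogphi"], 3), ")")

  # final solve with the converged phi so the reported solutions, residuals
  # and leverages are consistent with the reported variance components
  sol <- solve_mme(des$X, des$sire_idx, q, list(y, psi),
                   list(1 / phi, tau_w), bend_psd(G0))
  mean_part <- new_mixed_fit(sol, 1L, des, y, 1 / phi, G0[1, 1], phi)
  var_part <- new_mixed_fit(sol, 2L, des, psi, tau_w, G0[2, 2], 1 / tau_w)
  r_mv <- if (G0[1, 1] > 0 && G0[2, 2] > 0)
    G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]) else 0
  structure(list(
    mean_part = mean_part, var_part = var_part,
    sigma2_s = G0[1, 1], sigma2_sv = G0[2, 2], cov_s_sv = G0[1, 2],
    r_mv = r_mv, phi = phi, psi = psi,
    mode = mode, converged = converged, n_iter = length(trace),
    trace = as.data.frame(do.call(rbind, trace))
  ), class = "dhglm_fit")
}

#' @export
print.dhglm_fit <- function(x, ...) {
  cat("Sire DHGLM fit (", x$mode, "), ", length(x$mean_part$s), " sires, ",
      length(x$phi), " records\n", sep = "")
  cat(sprintf("  sigma2_s = %.4g  sigma2_sv = %.4g  cov = %.4g  r_mv = %.3f\n",
              x$sigma2_s, x$sigma2_sv, x$cov_s_sv, x$r_mv))
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' Per-sire reliabilities of the DHGLM breeding values
#'
#' `r^2 = 1 - PEV / sigma2` for each part of the model.
#'
#' @param fit a [fit_dhglm()] result.
#' @return data.frame with `sire_id`, `n_progeny`, `r2_m`, `r2_v`.
#' @export
reliabilities <- function(fit) {
  stopifnot(inherits(fit, "dhglm_fit"))
  if (fit$sigma2_s <= 0 || fit$sigma2_sv <= 0)
    stop("reliability undefined: a sire variance component is zero")
  data.frame(
    sire_id = fit$mean_part$sire_ids,
    n_progeny = fit$mean_part$n_progeny,
    r2_m = pmax(0, pmin(1 - fit$mean_part$pev / fit$sigma2_s, 1)),
    r2_v = pmax(0, pmin(1 - fit$var_part$pev / fit$sigma2_sv, 1)),
    stringsAsFactors = FALSE
  )
}
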