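#' Specification of the growth-poverty system
#'
#' Describes which share variable enters the poverty equation, whether
#' country controls and a direct share term are included, the estimator,
#' and the instrument and control column names. The polarity of the
#' adjustment factor follows the share variable: degrading-land shares
#' attenuate growth by `(1 - s/100)`, improving-land shares amplify it by
#' `(1 + s/100)`.
#'
#' The two-equation system estimated is
#' \deqn{P:\; \gamma(H) = \beta_0 + \beta_1 (1 \mp s/100)\, g +
#'   [\theta s] + \Gamma'Z + \varepsilon}
#' \deqn{G:\; g = \delta_0 + \delta_1 \gamma(\mu) + \Lambda'W + \nu}
#' where `g` is the (endogenous) growth index column, instrumented by the
#' exogenous variables and their interactions with the adjustment factor.
#'
#' @param share_variable `"d1"`, `"d2"`, `"i1"` or `"i2"`.
#' @param include_controls include the `controls_P` columns in the poverty
#'   equation.
#' @param include_direct_term include the share itself as a regressor
#'   (the direct channel).
#' @param estimator `"ols"`, `"2sls"`, `"sur"` or `"3sls"`.
#' @param instruments column names of the excluded exogenous instruments
#'   (the growth-equation `W` variables); default `c("w1", "w2")`, the
#'   synthetic generator's exogenous controls.
#' @param controls_P,controls_G control column names for the two
#'   equations; defaults `c("z1", "z2")` and the instruments.
#' @param growth_index column holding the endogenous growth index
#'   (default `"g"`; falls back to `"gamma_mu"` when absent, which makes
#'   the growth equation a pure measurement link).
#' @param income_growth column holding annualized income growth.
#' @return a `model_spec` list.
#' @export
model_spec <- function(share_variable = "d1", include_controls = FALSE,
                       include_direct_term = FALSE, estimator = "3sls",
                       instruments = c("w1", "w2"),
                       controls_P = c("z1", "z2"), controls_G = instruments,
                       growth_index = "g", income_growth = "gamma_mu") {
  estimator <- match.arg(tolower(estimator),
                         c("ols", "2sls", "sur", "3sls"))
  share_variable <- match.arg(share_variable, c("d1", "d2", "i1", "i2"))
  structure(list(share_variable = share_variable,
                 polarity = share_polarity(share_variable),
                 include_controls = include_controls,
                 include_direct_term = include_direct_term,
                 estimator = estimator, instruments = instruments,
                 controls_P = controls_P, controls_G = controls_G,
                 growth_index = growth_index,
                 income_growth = income_growth),
            class = "model_spec")
}

# design matrices for the two equations + instrument matrix.
# rows with any NA in a used column are dropped (listwise deletion).
build_system <- function(panel, spec, separate_interaction = FALSE) {
  s <- panel[[spec$share_variable]]
  if (is.null(s)) {
    abort_landpov(sprintf("panel lacks share column '%s'",
                          spec$share_variable), "landpov_input_error")
  }
  gcol <- if (!is.null(panel[[spec$growth_index]])) spec$growth_index
          else spec$income_growth
  g <- panel[[gcol]]
  gm <- panel[[spec$income_growth]]
  adj <- if (spec$polarity == "DAL") 1 - s / 100 else 1 + s / 100

  zP <- if (spec$include_controls) {
    as.matrix(panel[, intersect(spec$controls_P, names(panel)),
                    drop = FALSE])
  } else NULL
  wG <- as.matrix(panel[, intersect(spec$controls_G, names(panel)),
                        drop = FALSE])

  if (separate_interaction) {
    sg <- (if (spec$polarity == "DAL") -1 else 1) * (s / 100) * g
    X1 <- cbind(`(Intercept)` = 1, g = g, share_x_g = sg, share = s)
  } else {
    X1 <- cbind(`(Intercept)` = 1, adj_growth = adj * g)
    if (spec$include_direct_term) X1 <- cbind(X1, share = s)
  }
  if (!is.null(zP) && ncol(zP)) X1 <- cbind(X1, zP)

  X2 <- cbind(`(Intercept)` = 1, income_growth = gm)
  if (ncol(wG)) X2 <- cbind(X2, wG)

  Zi <- cbind(`(Intercept)` = 1, income_growth = gm, wG, share = s)
  if (separate_interaction) {
    # instruments for the separated interaction term (s/100)*g
    sgm <- (if (spec$polarity == "DAL") -1 else 1) * (s / 100) * gm
    Zi <- cbind(Zi, share_x_income = sgm)
    if (ncol(wG)) {
      sw <- (if (spec$polarity == "DAL") -1 else 1) * (s / 100) * wG
      colnames(sw) <- paste0("share_x_", colnames(wG))
      Zi <- cbind(Zi, sw)
    }
  } else {
    Zi <- cbind(Zi, adj_x_income = adj * gm)
    if (ncol(wG)) {
      aw <- adj * wG
      colnames(aw) <- paste0("adj_x_", colnames(wG))
      Zi <- cbind(Zi, aw)
    }
  }
  if (!is.null(zP) && ncol(zP)) Zi <- cbind(Zi, zP)

  keep <- stats::complete.cases(cbind(panel$gamma_H, g, X1, X2, Zi))
  list(y1 = panel$gamma_H[keep], X1 = X1[keep, , drop = FALSE],
       y2 = g[keep], X2 = X2[keep, , drop = FALSE],
       Z = Zi[keep, , drop = FALSE], n = sum(keep))
}

# rank check naming the collinear columns
check_rank <- function(X, what = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort_landpov(sprintf("%s matrix is rank deficient; collinear: %s",
                          what, paste(dropped, collapse = ", ")),
                  "landpov_singularity_error")
  }
  qrX
}

ols_core <- function(y, X) {
  qrX <- check_rank(X)
  b <- qr.coef(qrX, y)
  resid <- y - drop(X %*% b)
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  V <- s2 * solve(crossprod(X))
  list(coef = b, vcov = V, resid = resid)
}

tsls_core <- function(y, X, Z) {
  if (ncol(Z) < ncol(X)) {
    abort_landpov(sprintf(
      "under-identified: %d instruments for %d regressors",
      ncol(Z), ncol(X)), "landpov_identification_error")
  }
  check_rank(Z, "instrument")
  check_rank(X)
  PZX <- Z %*% solve(crossprod(Z), crossprod(Z, X))
  XX <- crossprod(PZX, X)
  b <- solve(XX, crossprod(PZX, y))
  resid <- y - drop(X %*% b)
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  V <- s2 * solve(crossprod(PZX))
  list(coef = drop(b), vcov = V, resid = resid, Xhat = PZX)
}

as_system_fit <- function(est, eqs, sigma, n, spec) {
  coefs <- do.call(rbind, lapply(names(eqs), function(eq) {
    e <- eqs[[eq]]
    se <- sqrt(diag(e$vcov))
    data.frame(equation = eq, term = names(e$coef),
               estimate = unname(e$coef), se = unname(se),
               t = unname(e$coef / se), stringsAsFactors = FALSE)
  }))
  rownames(coefs) <- NULL
  structure(list(estimator = est, coefficients = coefs,
                 vcov = lapply(eqs, `[[`, "vcov"), sigma = sigma,
                 n_obs = n, spec = spec),
            class = "system_fit")
}

#' @export
print.system_fit <- function(x, ...) {
  cat(sprintf("<system_fit> %s, n = %d\n", toupper(x$estimator), x$n_obs))
  print(transform(x$coefficients,
                  estimate = round(estimate, 4), se = round(se, 4),
                  t = round(t, 2)), row.names = FALSE)
  if (!is.null(x$sigma)) {
    cat("residual covariance:\n"); print(round(x$sigma, 4))
  }
  invisible(x)
}

#' Extract a named structural coefficient from a system fit
#'
#' @param fit a `system_fit`.
#' @param what one of `"beta0"`, `"beta1"`, `"theta"`, `"delta0"`,
#'   `"delta1"`.
#' @param value return the estimate (default), `"se"` or `"t"`.
#' @return scalar.
#' @export
coef_of <- function(fit, what, value = "estimate") {
  map <- list(beta0 = c("P", "(Intercept)"), beta1 = c("P", "adj_growth"),
              theta = c("P", "share"), delta0 = c("G", "(Intercept)"),
              delta1 = c("G", "income_growth"))
  key <- map[[what]]
  row <- fit$coefficients[fit$coefficients$equation == key[1] &
                            fit$coefficients$term == key[2], ]
  if (nrow(row) == 0L) return(NA_real_)
  row[[value]]
}

#' Fit the poverty equation by ordinary least squares
#'
#' Single-equation least squares of the poverty growth rate on the
#' adjusted-growth regressor (plus optional direct share term and
#' controls), with classical standard errors. The growth equation is also
#' fit by OLS so that `delta1` is always available.
#'
#' @param panel analysis panel data frame.
#' @param spec a [model_spec()].
#' @return a `system_fit`.
#' @export
fit_ols <- function(panel, spec = model_spec(estimator = "ols")) {
  sys <- build_system(panel, spec)
  eqP <- ols_core(sys$y1, sys$X1)
  eqG <- ols_core(sys$y2, sys$X2)
  sigma <- stats::cov(cbind(P = eqP$resid, G = eqG$resid)) *
    (sys$n - 1) / sys$n
  as_system_fit("ols", list(P = eqP, G = eqG), sigma, sys$n, spec)
}

#' Fit the poverty equation by two-stage least squares
#'
#' The endogenous adjusted-growth regressor is projected on the instrument
#' set (exogenous income growth, the `W` instruments, the share, and their
#' interactions with the adjustment factor); second-stage coefficients
#' carry the usual IV covariance. The growth equation, whose regressors
#' are all exogenous, is fit by OLS.
#'
#' @inheritParams fit_ols
#' @return a `system_fit`.
#' @export
fit_2sls <- function(panel, spec = model_spec(estimator = "2sls")) {
  sys <- build_system(panel, spec)
  eqP <- tsls_core(sys$y1, sys$X1, sys$Z)
  eqG <- ols_core(sys$y2, sys$X2)
  sigma <- stats::cov(cbind(P = eqP$resid, G = eqG$resid)) *
    (sys$n - 1) / sys$n
  as_system_fit("2sls", list(P = eqP, G = eqG), sigma, sys$n, spec)
}

# stacked GLS given per-equation design (or projected design) matrices
stacked_gls <- function(ys, Xs, Vs, sigma) {
  si <- solve(sigma)
  k <- length(ys)
  p <- vapply(Xs, ncol, integer(1))
  A <- matrix(0, sum(p), sum(p))
  c_vec <- numeric(sum(p))
  off <- cumsum(c(0L, p))
  for (i in seq_len(k)) {
    ri <- (off[i] + 1L):off[i + 1L]
    for (j in seq_len(k)) {
      rj <- (off[j] + 1L):off[j + 1L]
      A[ri, rj] <- si[i, j] * crossprod(Vs[[i]], Xs[[j]])
      c_vec[ri] <- c_vec[ri] + si[i, j] * crossprod(Vs[[i]], ys[[j]])
    }
  }
  b <- solve(A, c_vec)
  V <- solve(A)
  split_idx <- rep(seq_len(k), p)
  list(b = split(b, split_idx), V = V, off = off, p = p)
}

#' Fit the two-equation system by SUR or 3SLS
#'
#' Three-stage least squares: (1) per-equation 2SLS using the common
#' instrument set; (2) residual covariance `sigma` estimated from the
#' stacked stage-1 residuals with denominator `n` (no degrees-of-freedom
#' correction); (3) generalized least squares on the stacked system with
#' every design matrix replaced by its instrument projection. Seemingly
#' unrelated regressions (`fit_sur`) is the special case that treats all
#' regressors as exogenous: stage 1 is OLS and no projection is applied.
#'
#' With a diagonal `sigma` and a common instrument set, 3SLS reproduces
#' per-equation 2SLS exactly; SUR with diagonal `sigma` reproduces OLS.
#'
#' @inheritParams fit_ols
#' @param sigma optional fixed 2x2 residual covariance (rows/cols P, G);
#'   bypasses stage 2. Used mainly for degenerate-limit checks.
#' @param diagonal_sigma force the off-diagonal of the estimated residual
#'   covariance to zero.
#' @return a `system_fit`.
#' @export
fit_system_3sls <- function(panel, spec = model_spec(estimator = "3sls"),
                            sigma = NULL, diagonal_sigma = FALSE) {
  sys <- build_system(panel, spec)
  st1P <- tsls_core(sys$y1, sys$X1, sys$Z)
  st1G <- tsls_core(sys$y2, sys$X2, sys$Z)
  if (is.null(sigma)) {
    E <- cbind(st1P$resid, st1G$resid)
    sigma <- crossprod(E) / sys$n
    if (diagonal_sigma) sigma[1, 2] <- sigma[2, 1] <- 0
  }
  dimnames(sigma) <- list(c("P", "G"), c("P", "G"))
  if (abs(det(sigma)) < 1e-12 * prod(diag(sigma) + 1e-300)) {
    abort_landpov(
      "residual covariance is singular; consider SUR or per-equation 2SLS",
      "landpov_estimation_error")
  }
  gls <- stacked_gls(list(sys$y1, sys$y2),
                     list(sys$X1, sys$X2),
                     list(st1P$Xhat, st1G$Xhat), sigma)
  eqs <- finalize_system(gls, sys)
  as_system_fit("3sls", eqs, sigma, sys$n, spec)
}

#' @rdname fit_system_3sls
#' @export
fit_sur <- function(panel, spec = model_spec(estimator = "sur"),
                    sigma = NULL, diagonal_sigma = FALSE) {
  sys <- build_system(panel, spec)
  st1P <- ols_core(sys$y1, sys$X1)
  st1G <- ols_core(sys$y2, sys$X2)
  if (is.null(sigma)) {
    E <- cbind(st1P$resid, st1G$resid)
    sigma <- crossprod(E) / sys$n
    if (diagonal_sigma) sigma[1, 2] <- sigma[2, 1] <- 0
  }
  dimnames(sigma) <- list(c("P", "G"), c("P", "G"))
  gls <- stacked_gls(list(sys$y1, sys$y2), list(sys$X1, sys$X2),
                     list(sys$X1, sys$X2), sigma)
  eqs <- finalize_system(gls, sys)
  as_system_fit("sur", eqs, sigma, sys$n, spec)
}

finalize_system <- function(gls, sys) {
  bP <- gls$b[[1]]; bG <- gls$b[[2]]
  names(bP) <- colnames(sys$X1); names(bG) <- colnames(sys$X2)
  VP <- gls$V[(gls$off[1] + 1L):gls$off[2],
              (gls$off[1] + 1L):gls$off[2], drop = FALSE]
  VG <- gls$V[(gls$off[2] + 1L):gls$off[3],
              (gls$off[2] + 1L):gls$off[3], drop = FALSE]
  list(P = list(coef = bP, vcov = VP,
                resid = sys$y1 - drop(sys$X1 %*% bP)),
       G = list(coef = bG, vcov = VG,
                resid = sys$y2 - drop(sys$X2 %*% bG)))
}

#' Fit the system with the estimator named in the spec
#'
#' @inheritParams fit_ols
#' @return a `system_fit`.
#' @export
fit_model <- function(panel, spec = model_spec()) {
  switch(spec$estimator,
         ols = fit_ols(panel, spec),
         `2sls` = fit_2sls(panel, spec),
         sur = fit_sur(panel, spec),
         `3sls` = fit_system_3sls(panel, spec))
}

#' Test direct versus indirect share channels
#'
#' Refits the poverty equation with the interaction channel and the direct
#' channel entered separately — regressors `g`, the share-growth
#' interaction `(∓s/100)·g`, and the share itself — and Wald-tests, on the
#' asymptotic chi-squared reference, (a) H0: the direct coefficient
#' `theta = 0` and (b) H0: the interaction coefficient `= 0` (the share
#' would enter only directly). The report states which channel the data
#' support at `alpha`.
#'
#' @param panel analysis panel data frame.
#' @param spec a [model_spec()]; the estimator is used for the refit
#'   (`"ols"` fits by OLS, anything else by 2SLS with the extended
#'   instrument set).
#' @param alpha test level for the verdict (default 0.05).
#' @return list with `wald` (data frame: hypothesis, statistic, df,
#'   p_value) and `supported_channel` (`"indirect-only"`,
#'   `"direct-only"`, `"both"` or `"neither"`).
#' @export
test_restrictions <- function(panel, spec = model_spec(estimator = "2sls"),
                              alpha = 0.05) {
  s <- panel[[spec$share_variable]]
  if (!is.null(s) && stats::sd(s, na.rm = TRUE) == 0) {
    abort_landpov("share column has zero variance",
                  "landpov_input_error")
  }
  sys <- build_system(panel, spec, separate_interaction = TRUE)
  eq <- if (spec$estimator == "ols") ols_core(sys$y1, sys$X1)
        else tsls_core(sys$y1, sys$X1, sys$Z)
  wald_one <- function(term) {
    i <- match(term, colnames(sys$X1))
    stat <- eq$coef[i]^2 / eq$vcov[i, i]
    data.frame(hypothesis = sprintf("%s = 0", term), statistic = stat,
               df = 1L, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  wald <- rbind(wald_one("share"), wald_one("share_x_g"))
  rownames(wald) <- NULL
  direct <- wald$p_value[1] < alpha
  indirect <- wald$p_value[2] < alpha
  verdict <- if (indirect && !direct) "indirect-only"
             else if (direct && !indirect) "direct-only"
             else if (direct && indirect) "both" else "neither"
  list(wald = wald, supported_channel = verdict)
}
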