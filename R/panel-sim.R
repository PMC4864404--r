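#' Configuration for a synthetic survey panel
#'
#' Parameters of the structural data-generating process used to validate
#' the growth-poverty estimators. The system is
#' \deqn{g_j = \delta_0 + \delta_1 \gamma(\mu_j) + \Lambda'W_j + \nu_j}
#' \deqn{\gamma(H_j) = \beta_0 + \beta_1 (1 \mp s_j/100) g_j +
#'   \theta s_j + \Gamma'Z_j + \varepsilon_j}
#' with minus for a degrading-land share and plus for an improving-land
#' share, and cross-equation error correlation `error_corr` making the
#' growth index `g` endogenous in the poverty equation. The exogenous
#' `W` variables are the instruments.
#'
#' Default coefficients are the no-controls estimates of the fitted d1
#' system (`beta1 = -2.15`, `delta1 = 0.54`); `beta0 = -4.86` and
#' `delta0 = 0` place the structural means of the poverty growth rate and
#' the growth index at the sample descriptives (-7.70 %/yr given mean
#' income growth 3.36 %/yr). Share distributions default to the published
#' sample moments: d1 27.11 (21.04), d2 5.02 (4.43), i1 31.89 (21.05),
#' i2 13.45 (18.83), truncated to \[0, 100\].
#'
#' @param n_countries number of countries (panel rows).
#' @param beta0,beta1,delta0,delta1 structural coefficients.
#' @param theta_direct direct-effect coefficient of the share (0 under the
#'   accepted indirect-only model).
#' @param lambda,gamma_z coefficients on the exogenous `W` (growth
#'   equation) and `Z` (poverty equation) controls.
#' @param error_sd_P,error_sd_G standard deviations of the poverty- and
#'   growth-equation errors.
#' @param error_corr cross-equation error correlation, in (-1, 1).
#' @param share_distributions data frame `variable`, `mean`, `sd` for
#'   `d1`, `d2`, `i1`, `i2`.
#' @param mean_income_growth,sd_income_growth mean and SD of annualized
#'   income growth, percent per year.
#' @param share_variable which share enters the structural poverty
#'   equation (`"d1"`, `"d2"`, `"i1"`, `"i2"`).
#' @param spell_length_range integer range of spell lengths in years.
#' @param seed integer RNG seed, or `NULL`.
#' @return a `panel_config` list.
#' @export
panel_config <- function(n_countries = 83, beta0 = -4.86, beta1 = -2.15,
                         delta0 = 0, delta1 = 0.54, theta_direct = 0,
                         lambda = c(0.8, -0.5), gamma_z = c(0.5, -0.3),
                         error_sd_P = 3, error_sd_G = 1, error_corr = 0.5,
                         share_distributions = default_share_distributions(),
                         mean_income_growth = 3.36, sd_income_growth = 3.52,
                         share_variable = "d1",
                         spell_length_range = c(2L, 11L), seed = NULL) {
  if (abs(error_corr) >= 1) {
    abort_landpov("|error_corr| must be < 1", "landpov_parameter_error")
  }
  if (any(spell_length_range < 1)) {
    abort_landpov("spell lengths must be >= 1 year",
                  "landpov_parameter_error")
  }
  share_variable <- match.arg(share_variable, c("d1", "d2", "i1", "i2"))
  structure(list(
    n_countries = as.integer(n_countries), beta0 = beta0, beta1 = beta1,
    delta0 = delta0, delta1 = delta1, theta_direct = theta_direct,
    lambda = lambda, gamma_z = gamma_z, error_sd_P = error_sd_P,
    error_sd_G = error_sd_G, error_corr = error_corr,
    share_distributions = share_distributions,
    mean_income_growth = mean_income_growth,
    sd_income_growth = sd_income_growth, share_variable = share_variable,
    spell_length_range = as.integer(spell_length_range), seed = seed),
    class = "panel_config")
}

#' @rdname panel_config
#' @export
default_share_distributions <- function() {
  data.frame(variable = c("d1", "d2", "i1", "i2"),
             mean = c(27.11, 5.02, 31.89, 13.45),
             sd = c(21.04, 4.43, 21.05, 18.83),
             stringsAsFactors = FALSE)
}

#' Polarity of a spatial-distribution share
#'
#' Degrading-land shares (`d1`, `d2`) attenuate growth via `(1 - s/100)`;
#' improving-land shares (`i1`, `i2`) amplify it via `(1 + s/100)`.
#'
#' @param share_variable `"d1"`, `"d2"`, `"i1"` or `"i2"` (or a polarity
#'   tag `"DAL"`/`"IAL"` passed through).
#' @return `"DAL"` or `"IAL"`.
#' @export
share_polarity <- function(share_variable) {
  if (share_variable %in% c("DAL", "IAL")) return(share_variable)
  pre <- substr(share_variable, 1, 1)
  if (pre == "d") return("DAL")
  if (pre == "i") return("IAL")
  abort_landpov(sprintf("unknown share variable or polarity: %s",
                        share_variable), "landpov_parameter_error")
}

rnorm_trunc <- function(n, mean, sd, lower = 0, upper = 100) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic cross-country survey panel
#'
#' Draws shares, controls, income growth and correlated structural errors
#' from a [panel_config()], builds the endogenous growth index and the
#' poverty growth rate from the structural system, and back-computes raw
#' spell fields (survey years and endpoint headcounts/incomes) consistent
#' with the generated growth rates, so that spell construction and
#' annualization round-trip exactly:
#' `H1 = H0 * exp(spell_years * gamma_H / 100)` with `H0` uniform on
#' \[5, 95\], and likewise for mean income around a 100 $/month base.
#'
#' @param config a [panel_config()].
#' @return list with `panel` (data frame: country, spell fields, growth
#'   rates, shares, `g`, instruments `w1`, `w2`, controls `z1`, `z2`) and
#'   `truth` (list of every coefficient, the error covariance, the share
#'   variable and its polarity, and the instrument names).
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_countries
  pol <- share_polarity(config$share_variable)

  with_seed(config$seed, {
    sd_tab <- config$share_distributions
    shares <- lapply(seq_len(nrow(sd_tab)), function(i) {
      rnorm_trunc(n, sd_tab$mean[i], sd_tab$sd[i])
    })
    names(shares) <- sd_tab$variable

    w <- matrix(stats::rnorm(n * length(config$lambda)), n)
    z <- matrix(stats::rnorm(n * length(config$gamma_z)), n)
    gamma_mu <- stats::rnorm(n, config$mean_income_growth,
                             config$sd_income_growth)

    u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
    nu <- config$error_sd_G * u1
    eps <- config$error_sd_P *
      (config$error_corr * u1 + sqrt(1 - config$error_corr^2) * u2)

    s <- shares[[config$share_variable]]
    adj <- if (pol == "DAL") 1 - s / 100 else 1 + s / 100
    g <- config$delta0 + config$delta1 * gamma_mu +
      drop(w %*% config$lambda) + nu
    gamma_H <- config$beta0 + config$beta1 * adj * g +
      config$theta_direct * s + drop(z %*% config$gamma_z) + eps

    years <- sample(seq(config$spell_length_range[1],
                        config$spell_length_range[2]), n, replace = TRUE)
    H0 <- stats::runif(n, 5, 95)
    H1 <- H0 * exp(years * gamma_H / 100)
    mu0 <- stats::rlnorm(n, log(100), 0.8)
    mu1 <- mu0 * exp(years * gamma_mu / 100)

    panel <- data.frame(
      country = sprintf("SC%03d", seq_len(n)),
      t0 = 2000L, t1 = 2000L + years,
      welfare_type = "consumption",
      H0 = H0, H1 = H1, mu0 = mu0, mu1 = mu1, spell_years = years,
      gamma_H = gamma_H, gamma_mu = gamma_mu,
      d1 = shares$d1, d2 = shares$d2, i1 = shares$i1, i2 = shares$i2,
      g = g, stringsAsFactors = FALSE)
    for (k in seq_along(config$lambda)) panel[[paste0("w", k)]] <- w[, k]
    for (k in seq_along(config$gamma_z)) panel[[paste0("z", k)]] <- z[, k]

    sig <- matrix(c(config$error_sd_P^2,
                    rep(config$error_corr * config$error_sd_P *
                          config$error_sd_G, 2),
                    config$error_sd_G^2), 2, 2,
                  dimnames = list(c("P", "G"), c("P", "G")))
    truth <- list(beta0 = config$beta0, beta1 = config$beta1,
                  delta0 = config$delta0, delta1 = config$delta1,
                  theta_direct = config$theta_direct,
                  lambda = config$lambda, gamma_z = config$gamma_z,
                  error_cov = sig,
                  share_variable = config$share_variable, polarity = pol,
                  instruments = paste0("w", seq_along(config$lambda)))
    list(panel = panel, truth = truth)
  })
}
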