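# Direct matrix-formula oracles, written independently of the package's
# estimator internals, for the degenerate-limit equivalences.
oracle_ols <- function(y, X) solve(crossprod(X), crossprod(X, y))
oracle_2sls <- function(y, X, Z) {
  Xh <- Z %*% solve(crossprod(Z), crossprod(Z, X))
  solve(crossprod(Xh, X), crossprod(Xh, y))
}

sim40 <- function(seed, ...) {
  generate_panel(panel_config(n_countries = 40, seed = seed, ...))$panel
}

test_that("OLS matches the normal-equations oracle at n = 40", {
  p <- sim40(101)
  spec <- model_spec("d1", estimator = "ols")
  fit <- fit_ols(p, spec)
  X <- cbind(1, (1 - p$d1 / 100) * p$g)
  b <- oracle_ols(p$gamma_H, X)
  expect_equal(coef_of(fit, "beta0"), b[1], tolerance = 1e-10)
  expect_equal(coef_of(fit, "beta1"), b[2], tolerance = 1e-10)
  expect_equal(coef_of(fit, "delta1"),
               oracle_ols(p$g, cbind(1, p$gamma_mu, p$w1, p$w2))[2],
               tolerance = 1e-10)
})

test_that("2SLS matches the projection oracle and its degenerate OLS limit", {
  p <- sim40(103)
  spec <- model_spec("d1", estimator = "2sls")
  fit <- fit_2sls(p, spec)
  adj <- 1 - p$d1 / 100
  X <- cbind(1, adj * p$g)
  Z <- cbind(1, p$gamma_mu, p$w1, p$w2, p$d1, adj * p$gamma_mu,
             adj * p$w1, adj * p$w2)
  b <- oracle_2sls(p$gamma_H, X, Z)
  expect_equal(coef_of(fit, "beta1"), b[2], tolerance = 1e-10)

  # when the endogenous column is itself exogenous (growth index absent,
  # the adjusted regressor lies in the instrument span) 2SLS collapses
  # to OLS exactly
  q <- p[, setdiff(names(p), "g")]
  f2 <- fit_2sls(q, spec)
  fo <- fit_ols(q, model_spec("d1", estimator = "ols"))
  expect_equal(coef_of(f2, "beta1"), coef_of(fo, "beta1"),
               tolerance = 1e-10)
  expect_equal(coef_of(f2, "beta0"), coef_of(fo, "beta0"),
               tolerance = 1e-10)
})

test_that("3SLS with diagonal sigma equals per-equation 2SLS", {
  p <- sim40(105)
  spec <- model_spec("d1")
  f3 <- fit_system_3sls(p, spec, diagonal_sigma = TRUE)
  f2 <- fit_2sls(p, model_spec("d1", estimator = "2sls"))
  for (what in c("beta0", "beta1", "delta0", "delta1")) {
    expect_equal(coef_of(f3, what), coef_of(f2, what), tolerance = 1e-8,
                 label = what)
  }
})

test_that("SUR with diagonal sigma equals per-equation OLS", {
  p <- sim40(107)
  fs <- fit_sur(p, model_spec("d1", estimator = "sur"),
                diagonal_sigma = TRUE)
  fo <- fit_ols(p, model_spec("d1", estimator = "ols"))
  for (what in c("beta0", "beta1", "delta0", "delta1")) {
    expect_equal(coef_of(fs, what), coef_of(fo, what), tolerance = 1e-8,
                 label = what)
  }
})

test_that("identification and rank failures raise informative errors", {
  p <- sim40(109)
  p$dup <- p$d1  # duplicate regressor column
  spec_dup <- model_spec("d1", estimator = "ols",
                         include_direct_term = TRUE,
                         include_controls = TRUE,
                         controls_P = c("dup", "z1"))
  expect_error(fit_ols(p, spec_dup), "collinear",
               class = "landpov_singularity_error")

  # order condition: fewer instruments than regressors
  X <- cbind(1, p$g, p$d1)
  Z <- cbind(1, p$gamma_mu)
  expect_error(landpov:::tsls_core(p$gamma_H, X, Z),
               class = "landpov_identification_error")
})

test_that("endogeneity biases OLS but not 2SLS at n = 500", {
  sim <- generate_panel(panel_config(n_countries = 500,
                                     error_corr = 0.6, seed = 111))
  fo <- fit_ols(sim$panel, model_spec("d1", estimator = "ols"))
  f2 <- fit_2sls(sim$panel, model_spec("d1", estimator = "2sls"))
  truth <- sim$truth$beta1
  expect_gt(abs(coef_of(fo, "beta1") - truth),
            2 * coef_of(fo, "beta1", "se"))
  expect_lt(abs(coef_of(f2, "beta1") - truth),
            2 * coef_of(f2, "beta1", "se"))
})

test_that("3SLS recovers both structural slopes within 2 SE at n = 500", {
  sim <- generate_panel(panel_config(n_countries = 500, seed = 113))
  f3 <- fit_system_3sls(sim$panel, model_spec("d1"))
  expect_lt(abs(coef_of(f3, "beta1") - sim$truth$beta1),
            2 * coef_of(f3, "beta1", "se"))
  expect_lt(abs(coef_of(f3, "delta1") - sim$truth$delta1),
            2 * coef_of(f3, "delta1", "se"))
  expect_true(all(eigen(f3$sigma, only.values = TRUE)$values > 0))
  expect_equal(f3$sigma[1, 2], f3$sigma[2, 1])
  # reported t equals estimate / se
  expect_equal(f3$coefficients$t,
               f3$coefficients$estimate / f3$coefficients$se)
})

test_that("restriction test separates direct and indirect channels", {
  sim <- generate_panel(panel_config(n_countries = 500, seed = 115))
  res <- test_restrictions(sim$panel, model_spec("d1",
                                                 estimator = "2sls"))
  expect_equal(res$supported_channel, "indirect-only")
  expect_gt(res$wald$p_value[res$wald$hypothesis == "share = 0"], 0.05)
  expect_lt(res$wald$p_value[res$wald$hypothesis == "share_x_g = 0"],
            0.05)

  sim_dir <- generate_panel(panel_config(n_countries = 500,
                                         theta_direct = 0.5, seed = 117))
  res_dir <- test_restrictions(sim_dir$panel,
                               model_spec("d1", estimator = "2sls"))
  expect_lt(res_dir$wald$p_value[res_dir$wald$hypothesis == "share = 0"],
            0.05)

  flat <- sim$panel
  flat$d1 <- 10
  expect_error(test_restrictions(flat, model_spec("d1",
                                                  estimator = "2sls")),
               class = "landpov_input_error")
})

test_that("fit_model dispatches on the spec estimator", {
  p <- sim40(119)
  expect_equal(fit_model(p, model_spec("d1", estimator = "ols"))$estimator,
               "ols")
  expect_equal(fit_model(p, model_spec("d1"))$estimator, "3sls")
})
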