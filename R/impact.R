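#' Growth adjusted for the spatial distribution of rural population
#'
#' The channel through which the land distribution modifies the
#' poverty-growth link: income growth scaled by `(1 - s/100)` for a
#' degrading-land share and `(1 + s/100)` for an improving-land share.
#'
#' @param share share of rural population, percent, in \[0, 100\].
#' @param growth income growth, percent per year.
#' @param polarity `"DAL"`, `"IAL"`, or a share-variable name.
#' @return adjusted growth, percent per year.
#' @export
adjusted_growth <- function(share, growth, polarity) {
  if (any(share < 0 | share > 100)) {
    abort_landpov("share must lie in [0, 100]", "landpov_parameter_error")
  }
  pol <- share_polarity(polarity)
  if (pol == "DAL") (1 - share / 100) * growth
  else (1 + share / 100) * growth
}

#' Marginal poverty impact of income growth at a given share
#'
#' The total derivative of the poverty growth rate with respect to income
#' growth implied by the two-equation system, evaluated at a share level:
#' `beta1 * delta1 * (1 -/+ share/100) * growth` (minus for degrading,
#' plus for improving land), in percent per year. With `beta1 < 0` and
#' `delta1, growth > 0` the value is negative — growth reduces poverty —
#' and its magnitude shrinks as the degrading-land share rises.
#'
#' @param beta1 adjusted-growth coefficient of the poverty equation.
#' @param delta1 income-growth coefficient of the growth equation.
#' @param share share of rural population, percent.
#' @param polarity `"DAL"`, `"IAL"`, or a share-variable name.
#' @param growth income growth, percent per year (evaluated at the sample
#'   mean, 3.36, in the published schedules).
#' @return poverty growth rate, percent per year.
#' @export
marginal_impact <- function(beta1, delta1, share, polarity, growth) {
  beta1 * delta1 * adjusted_growth(share, growth, polarity)
}

#' Evaluation points around a sample mean
#'
#' `(mean - m*sd, mean, mean + m*sd)` with multiplier `m` (1 by default;
#' one half for the remote improving-land share, whose wide dispersion
#' would otherwise push the low point to zero), clipped below at 0 and
#' rounded half-up to 0.1 for display — the row labels of the published
#' impact schedule.
#'
#' @param mean,sd sample mean and standard deviation of a share, percent.
#' @param multiplier half-width in standard deviations (default 1).
#' @return named numeric vector `low`, `mid`, `high`.
#' @export
evaluation_points <- function(mean, sd, multiplier = 1) {
  if (sd < 0) {
    abort_landpov("sd must be non-negative", "landpov_parameter_error")
  }
  pts <- c(low = mean - multiplier * sd, mid = mean,
           high = mean + multiplier * sd)
  round_half_up(pmax(pts, 0), 1)
}

#' Impact schedule over share variables and parameter columns
#'
#' For each share variable, evaluation points are taken at the panel's
#' sample mean +/- SD (+/- SD/2 for `i2`) and the marginal impact is
#' evaluated for each fitted parameter column (without and with controls).
#' Fits may be `system_fit` objects (coefficients extracted with
#' [coef_of()]) or plain `list(beta1 =, delta1 =)` pairs. A share variable
#' with no fit is reported as an absent row rather than an error.
#'
#' @param fits named list: `fits[[share_variable]]` is a named list of
#'   parameter columns (e.g. `no_controls`, `with_controls`), each a
#'   `system_fit` or a `list(beta1, delta1)`.
#' @param moments data frame `variable`, `mean`, `sd` giving the share
#'   sample moments (e.g. from [describe_panel()]).
#' @param growth income growth at which to evaluate, percent per year.
#' @return data frame: `share_variable`, `point`, `share`, one impact
#'   column per parameter column, and `range` formatted
#'   `"low% to high%"`.
#' @export
impact_table <- function(fits, moments, growth = 3.36) {
  rows <- lapply(names(fits), function(sv) {
    m <- moments[moments$variable == sv, ]
    if (nrow(m) == 0L || is.null(fits[[sv]])) {
      return(data.frame(share_variable = sv, point = "absent",
                        share = NA_real_, range = NA_character_,
                        stringsAsFactors = FALSE))
    }
    mult <- if (sv == "i2") 0.5 else 1
    pts <- evaluation_points(m$mean, m$sd, mult)
    cols <- fits[[sv]]
    out <- data.frame(share_variable = sv,
                      point = names(pts), share = unname(pts),
                      stringsAsFactors = FALSE)
    for (cn in names(cols)) {
      f <- cols[[cn]]
      b1 <- if (inherits(f, "system_fit")) coef_of(f, "beta1") else f$beta1
      d1 <- if (inherits(f, "system_fit")) coef_of(f, "delta1") else f$delta1
      out[[cn]] <- marginal_impact(b1, d1, out$share, sv, growth)
    }
    impact_cols <- setdiff(names(out), c("share_variable", "point", "share"))
    vals <- round_half_up(as.matrix(out[impact_cols]), 2)
    out$range <- apply(vals, 1L, function(v) {
      sprintf("%.2f%% to %.2f%%", v[which.min(abs(v))], v[which.max(abs(v))])
    })
    out
  })
  res <- do.call(rbind, lapply(rows, function(r) {
    for (nm in setdiff(unlist(lapply(rows, names)), names(r))) {
      r[[nm]] <- if (nm == "range") NA_character_ else NA_real_
    }
    r[, unique(unlist(lapply(rows, names)))]
  }))
  rownames(res) <- NULL
  res
}

# ------------------------------------------------------------------
# Published reference values bundled for arithmetic cross-checks.
# ------------------------------------------------------------------

#' Published reference values of the global 2000 tabulation and the
#' fitted system
#'
#' Reference numbers from the published global analysis these tools
#' re-implement, bundled so that arithmetic (share recomputation, world
#' totals, evaluation points, impact schedules) can be cross-checked
#' without external data.
#'
#' `reference_moments()` returns the descriptive statistics of the
#' 83-country estimation sample (mean / median / SD of the initial
#' headcount rate, the two growth rates and the four shares).
#' `reference_estimates()` returns the 3SLS coefficient columns
#' (`beta1`, `delta1`, without and with controls) per share variable.
#' `reference_population_2000()` returns the regional rural-population
#' tabulation for epoch 2000 in millions, one block per land-class table
#' (`DAL`, `IAL`), with the printed share columns. The developing and
#' world share cells of the degrading-land block are stored as recomputed
#' from their own population columns (the printed table transposes those
#' two header cells).
#'
#' @return data frames; see details.
#' @export
reference_moments <- function() {
  data.frame(
    variable = c("H0", "gamma_H", "gamma_mu", "d1", "d2", "i1", "i2"),
    mean = c(46.41, -7.70, 3.36, 27.11, 5.02, 31.89, 13.45),
    median = c(42.85, -4.26, 3.32, 22.44, 3.81, 29.6, 5.21),
    sd = c(29.56, 10.28, 3.52, 21.04, 4.43, 21.05, 18.83),
    stringsAsFactors = FALSE)
}

#' @rdname reference_moments
#' @export
reference_estimates <- function() {
  data.frame(
    share_variable = rep(c("d1", "d2", "i1", "i2"), each = 2),
    controls = rep(c("no_controls", "with_controls"), 4),
    beta1 = c(-2.15, -2.51, -2.31, -2.91, -2.36, -2.92, -2.30, -2.86),
    t_beta1 = c(-3.83, -4.39, -4.72, -6.42, -4.66, -6.11, -4.34, -5.60),
    delta1 = c(0.54, 0.58, 0.52, 0.57, 0.34, 0.37, 0.38, 0.41),
    t_delta1 = c(8.91, 7.05, 12.62, 10.90, 11.55, 9.70, 10.11, 8.47),
    stringsAsFactors = FALSE)
}

#' @rdname reference_moments
#' @export
reference_population_2000 <- function() {
  dal <- data.frame(
    table = "DAL",
    region = c("EAP", "ECA", "LAC", "MENA", "SA", "SSA",
               "Developing", "Developed", "World"),
    rural_pop = c(1398.4, 173.8, 294.1, 195.6, 1090.4, 554.6,
                  3706.8, 404.7, 4111.5),
    pop_class = c(710.3, 67.0, 38.3, 43.7, 285.2, 114.1,
                  1258.7, 72.6, 1331.3),
    share_class = c(50.8, 38.5, 13.0, 22.3, 26.2, 20.6,
                    34.0, 17.9, 32.4),
    pop_remote = c(125.2, 6.2, 5.6, 5.4, 27.4, 32.4, 202.2, 3.2, 205.4),
    share_remote = c(9.0, 3.6, 1.9, 2.8, 2.5, 5.8, 5.5, 0.8, 5.0),
    stringsAsFactors = FALSE)
  ial <- data.frame(
    table = "IAL",
    region = dal$region,
    rural_pop = dal$rural_pop,
    pop_class = c(398.7, 66.7, 90.6, 28.1, 641.8, 114.8,
                  1340.7, 196.4, 1537.1),
    share_class = c(28.5, 38.4, 30.8, 14.4, 58.9, 20.7,
                    36.2, 48.5, 37.4),
    pop_remote = c(67.9, 6.6, 9.3, 1.7, 37.3, 32.5, 155.3, 9.0, 164.3),
    share_remote = c(4.9, 3.8, 3.2, 0.9, 3.4, 5.9, 4.2, 2.2, 4.0),
    stringsAsFactors = FALSE)
  rbind(dal, ial)
}
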