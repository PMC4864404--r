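#' Annualized change in the log of a positive quantity
#'
#' `100 * (log(x1) - log(x0)) / years`, in percent per year. This is the
#' growth measure used for both the headcount poverty rate and survey mean
#' income. Non-positive endpoints (a headcount of exactly zero cannot be
#' log-differenced) yield `NA` rather than an error, so the affected
#' country can be dropped for that variable.
#'
#' @param x0,x1 endpoint values (> 0 for a defined rate).
#' @param years spell length in years (> 0).
#' @return growth rate in percent per year, or `NA`.
#' @export
annualized_log_growth <- function(x0, x1, years) {
  if (any(years <= 0)) {
    abort_landpov("years must be positive", "landpov_parameter_error")
  }
  out <- ifelse(x0 > 0 & x1 > 0, 100 * (log(x1) - log(x0)) / years,
                NA_real_)
  unname(out)
}

#' Select the longest comparable survey spell for one country
#'
#' Given a country's survey records, picks the initial survey as the
#' earliest at or after the window start (the target initial year, 2000,
#' or the soonest subsequent year) and the final survey as the one
#' maximizing the spell length among surveys using the same welfare
#' indicator. Ties between welfare indicators are broken by the earlier
#' initial year, then by preferring consumption over income. Returns
#' `NULL` (with a message in the `reason` attribute) when no compatible
#' pair exists. Spells shorter than 2 or longer than 11 years generate a
#' warning but are kept.
#'
#' @param surveys data frame with columns `country`, `year`,
#'   `welfare_type` (`"consumption"` or `"income"`), `H`, `mu` (and
#'   optionally `gini`).
#' @param window length-2 numeric, first and last admissible survey year
#'   (default `c(2000, 2012)`).
#' @return one-row data frame (`country`, `t0`, `t1`, `welfare_type`,
#'   `H0`, `H1`, `mu0`, `mu1`, `spell_years`) or `NULL`.
#' @export
select_spell <- function(surveys, window = c(2000, 2012)) {
  s <- surveys[surveys$year >= window[1] & surveys$year <= window[2], ]
  if (nrow(s) < 2L) {
    message(sprintf("excluding %s: fewer than two surveys in window",
                    surveys$country[1] %||% "?"))
    return(NULL)
  }
  candidates <- lapply(c("consumption", "income"), function(wt) {
    st <- s[s$welfare_type == wt, ]
    if (nrow(st) < 2L) return(NULL)
    st <- st[order(st$year), ]
    first <- st[1L, ]
    last <- st[nrow(st), ]
    if (last$year <= first$year) return(NULL)
    data.frame(country = first$country, t0 = first$year, t1 = last$year,
               welfare_type = wt, H0 = first$H, H1 = last$H,
               mu0 = first$mu, mu1 = last$mu,
               spell_years = last$year - first$year,
               stringsAsFactors = FALSE)
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) {
    message(sprintf("excluding %s: no two surveys share a welfare indicator",
                    s$country[1]))
    return(NULL)
  }
  cand <- do.call(rbind, candidates)
  # longest spell; then earlier start; then consumption first
  cand <- cand[order(-cand$spell_years, cand$t0,
                     cand$welfare_type != "consumption"), ]
  spell <- cand[1L, ]
  if (spell$spell_years < 2 || spell$spell_years > 11) {
    warning(sprintf("spell for %s is %d years, outside the typical 2-11",
                    spell$country, spell$spell_years))
  } else if (spell$spell_years == 2) {
    warning(sprintf("spell for %s is 2 years, at the lower bound of the typical 2-11",
                    spell$country))
  }
  rownames(spell) <- NULL
  spell
}

#' Build the cross-country analysis panel
#'
#' Joins selected spells with the year-2000 spatial-distribution shares
#' and country controls, and computes the annualized log growth rates of
#' the headcount rate (`gamma_H`) and of survey mean income (`gamma_mu`).
#' Countries missing from the shares table are excluded (recorded in the
#' `excluded` attribute); missing individual share or control values are
#' kept as `NA` and drop out of affected model fits by listwise deletion.
#'
#' @param spells data frame of spells (rows as returned by
#'   [select_spell()]).
#' @param shares data frame: `country`, `d1`, `d2`, `i1`, `i2` (percent).
#' @param controls optional data frame keyed by `country`; all non-key
#'   columns are carried through.
#' @return data frame, one row per retained country, with an `excluded`
#'   attribute naming dropped countries and reasons.
#' @export
build_panel <- function(spells, shares, controls = NULL) {
  missing <- setdiff(spells$country, shares$country)
  keep <- !(spells$country %in% missing)
  panel <- spells[keep, , drop = FALSE]
  panel$gamma_H <- annualized_log_growth(panel$H0, panel$H1,
                                         panel$spell_years)
  panel$gamma_mu <- annualized_log_growth(panel$mu0, panel$mu1,
                                          panel$spell_years)
  idx <- match(panel$country, shares$country)
  for (cl in c("d1", "d2", "i1", "i2")) panel[[cl]] <- shares[[cl]][idx]
  if (!is.null(controls)) {
    cidx <- match(panel$country, controls$country)
    for (cl in setdiff(names(controls), "country")) {
      panel[[cl]] <- controls[[cl]][cidx]
    }
  }
  rownames(panel) <- NULL
  attr(panel, "excluded") <- if (length(missing)) {
    data.frame(country = missing, reason = "no shares available")
  } else NULL
  panel
}

#' Descriptive statistics of the key panel variables
#'
#' Mean, median and sample standard deviation (n-1 denominator) for the
#' initial headcount rate, the two growth rates and the four shares —
#' the layout of a cross-country descriptives table.
#'
#' @param panel data frame from [build_panel()] (or any frame holding the
#'   listed columns).
#' @param variables columns to describe; defaults to the key variables
#'   present.
#' @return data frame `variable`, `mean`, `median`, `sd`, `n`.
#' @export
describe_panel <- function(panel,
                           variables = intersect(
                             c("H0", "gamma_H", "gamma_mu",
                               "d1", "d2", "i1", "i2"), names(panel))) {
  if (nrow(panel) < 2L) {
    abort_landpov("at least two records are required",
                  "landpov_input_error")
  }
  do.call(rbind, lapply(variables, function(v) {
    x <- panel[[v]][!is.na(panel[[v]])]
    data.frame(variable = v, mean = mean(x), median = stats::median(x),
               sd = stats::sd(x), n = length(x))
  }))
}
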