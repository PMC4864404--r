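test_that("annualized log growth has its closed-form values", {
  expect_equal(annualized_log_growth(50, 50, 7), 0)
  expect_equal(annualized_log_growth(10, 10 * exp(1), 1), 100)
  # median headcount fell 42.85 -> 27.86 over the median 8-year spell
  expect_equal(round(annualized_log_growth(42.85, 27.86, 8), 2), -5.38)
  # zero endpoints are undefined, not errors
  expect_true(is.na(annualized_log_growth(0, 10, 5)))
  expect_true(is.na(annualized_log_growth(10, 0, 5)))
  expect_error(annualized_log_growth(10, 20, 0),
               class = "landpov_parameter_error")
})

test_that("spell selection prefers the longest same-indicator pair", {
  surveys <- data.frame(
    country = "A",
    year = c(2000, 2005, 2011),
    welfare_type = c("consumption", "income", "consumption"),
    H = c(40, 35, 25), mu = c(90, 110, 140))
  spell <- select_spell(surveys)
  expect_equal(spell$t0, 2000)
  expect_equal(spell$t1, 2011)
  expect_equal(spell$welfare_type, "consumption")
  expect_equal(spell$spell_years, 11)
  expect_equal(spell$H0, 40); expect_equal(spell$H1, 25)
})

test_that("spell selection edge cases: exclusion, short spells, ties", {
  single <- data.frame(country = "B", year = 2004,
                       welfare_type = "income", H = 20, mu = 100)
  expect_message(expect_null(select_spell(single)), "excluding")

  two_inc <- data.frame(country = "C", year = c(2001, 2003),
                        welfare_type = "income", H = c(30, 25),
                        mu = c(80, 95))
  expect_warning(spell <- select_spell(two_inc), "2 years")
  expect_equal(spell$spell_years, 2)
  expect_equal(spell$welfare_type, "income")

  # equal-length spells: consumption preferred
  tie <- data.frame(country = "D", year = c(2000, 2008, 2000, 2008),
                    welfare_type = rep(c("income", "consumption"),
                                       each = 2),
                    H = c(30, 20, 31, 21), mu = c(80, 120, 82, 118))
  expect_equal(select_spell(tie)$welfare_type, "consumption")

  # surveys outside the window are ignored
  windowed <- data.frame(country = "E", year = c(1995, 2002, 2009),
                         welfare_type = "consumption",
                         H = c(50, 40, 30), mu = c(70, 90, 110))
  sp <- select_spell(windowed)
  expect_equal(c(sp$t0, sp$t1), c(2002, 2009))
})

test_that("build_panel joins shares, excludes unmatched, keeps NA flags", {
  spells <- data.frame(country = c("A", "B", "C"),
                       t0 = 2000, t1 = 2008,
                       welfare_type = "consumption",
                       H0 = c(40, 30, 20), H1 = c(25, 22, 15),
                       mu0 = c(90, 100, 110), mu1 = c(130, 140, 150),
                       spell_years = 8)
  shares <- data.frame(country = c("A", "B"), d1 = c(30, NA),
                       d2 = c(5, 4), i1 = c(20, 25), i2 = c(3, 6))
  panel <- build_panel(spells, shares)
  expect_equal(nrow(panel), 2L)
  expect_equal(attr(panel, "excluded")$country, "C")
  expect_true(is.na(panel$d1[panel$country == "B"]))
  expect_equal(panel$gamma_H,
               annualized_log_growth(c(40, 30), c(25, 22), 8))
})

test_that("generator raw spell fields round-trip through annualization", {
  sim <- generate_panel(panel_config(n_countries = 40, seed = 13))
  rebuilt <- build_panel(
    sim$panel[, c("country", "t0", "t1", "welfare_type",
                  "H0", "H1", "mu0", "mu1", "spell_years")],
    sim$panel[, c("country", "d1", "d2", "i1", "i2")])
  expect_equal(rebuilt$gamma_H, sim$panel$gamma_H, tolerance = 1e-12)
  expect_equal(rebuilt$gamma_mu, sim$panel$gamma_mu, tolerance = 1e-12)
})

test_that("panel descriptives use the n-1 sample standard deviation", {
  df <- data.frame(H0 = c(1, 2, 3), gamma_H = c(4, 4, 4))
  desc <- describe_panel(df, variables = c("H0", "gamma_H"))
  expect_equal(desc$mean, c(2, 4))
  expect_equal(desc$median, c(2, 4))
  expect_equal(desc$sd, c(1, 0))
  expect_error(describe_panel(df[1, , drop = FALSE]),
               class = "landpov_input_error")
})
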