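test_that("generate_field is deterministic and standardized", {
  f1 <- generate_field(c(32, 32), smoothing_scale = 4, seed = 11)
  f2 <- generate_field(c(32, 32), smoothing_scale = 4, seed = 11)
  expect_identical(f1$values, f2$values)
  expect_equal(mean(f1$values), 0, tolerance = 1e-12)
  expect_equal(stats::sd(f1$values), 1, tolerance = 1e-12)
  expect_error(generate_field(c(32, 32), smoothing_scale = -1),
               class = "landpov_parameter_error")
})

test_that("smoothing scale controls the lag-1 autocorrelation", {
  lag1 <- function(field) {
    v <- field$values
    stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  rough <- generate_field(c(64, 64), smoothing_scale = 0, seed = 21)
  smooth <- generate_field(c(64, 64), smoothing_scale = 8, seed = 21)
  expect_lt(abs(lag1(rough)), 0.1)
  expect_gt(lag1(smooth), 0.5)
})

test_that("travel time matches the uniform-cost closed form", {
  cost <- grid_layer(matrix(1, 7, 9), kind = "travel_time")
  city <- c(4, 5)
  tt <- compute_travel_time(cost, matrix(city, 1))
  expect_equal(tt$values, uniform_travel_oracle(7, 9, city),
               tolerance = 1e-12)
  # a 4-step rook path on unit cost takes 4 hours; the city cell takes 0
  expect_equal(tt$values[4, 9], 4)
  expect_equal(tt$values[4, 5], 0)
})

test_that("travel time superposes over cities and obeys the triangle rule", {
  set.seed(31)
  cost <- grid_layer(matrix(runif(120, 0.5, 2), 10, 12),
                     kind = "travel_time")
  c1 <- matrix(c(2, 3), 1); c2 <- matrix(c(9, 10), 1)
  both <- compute_travel_time(cost, rbind(c1, c2))
  t1 <- compute_travel_time(cost, c1)
  t2 <- compute_travel_time(cost, c2)
  expect_equal(both$values, pmin(t1$values, t2$values), tolerance = 1e-12)
  # adding a city never increases any cell's time
  expect_true(all(both$values <= t1$values + 1e-12))
})

test_that("nodata barriers isolate cells and empty city lists error", {
  v <- matrix(1, 5, 5)
  v[, 3] <- NA  # wall splits the grid
  cost <- grid_layer(v, kind = "travel_time")
  tt <- compute_travel_time(cost, matrix(c(3, 1), 1))
  expect_true(all(is.infinite(tt$values[, 4:5])))
  expect_true(all(is.na(tt$values[, 3])))
  expect_true(all(is.finite(tt$values[, 1:2])))
  expect_error(compute_travel_time(cost, matrix(numeric(0), 0, 2)),
               class = "landpov_parameter_error")
  expect_no_error(compute_travel_time(grid_layer(matrix(0.5, 2, 2)),
                                      matrix(c(1, 1), 1)))
  expect_error(
    compute_travel_time(grid_layer(matrix(c(1, -1, 1, 1), 2, 2)),
                        matrix(c(1, 1), 1)),
    class = "landpov_parameter_error")
})

test_that("default landscape satisfies the generator contract", {
  stack <- generate_landscape(landscape_config(seed = 42))
  report <- validate_stack(stack)
  expect_false(any(report$fatal))

  zone <- stack$layers$country_zone$values
  expect_false(any(is.na(zone)))
  expect_setequal(unique(as.vector(zone)), 1:6)

  pop <- stack$layers$population_2000$values
  expect_equal(sum(pop), 1e6, tolerance = 1e-9)
  urb <- stack$layers$urban_mask$values
  expect_equal(sum(pop[urb == 1]) / sum(pop), 0.3, tolerance = 1e-9)
  pop10 <- stack$layers$population_2010$values
  expect_equal(sum(pop10) / sum(pop), 1.13, tolerance = 1e-9)

  # identical seed reproduces the stack exactly
  again <- generate_landscape(landscape_config(seed = 42))
  expect_identical(stack$layers$npp_trend$values,
                   again$layers$npp_trend$values)
  expect_identical(stack$layers$travel_time$values,
                   again$layers$travel_time$values)
})

test_that("degrading_fraction is honoured on agricultural cells", {
  cfg0 <- landscape_config(degrading_fraction = 0, seed = 5)
  st0 <- generate_landscape(cfg0)
  agri0 <- st0$layers$agri_mask$values == 1
  expect_true(all(st0$layers$npp_trend$values[agri0] >= 0))

  cfg <- landscape_config(nrows = 128, ncols = 128,
                          degrading_fraction = 0.4, seed = 6)
  st <- generate_landscape(cfg)
  agri <- st$layers$agri_mask$values == 1
  frac <- mean(st$layers$npp_trend$values[agri] < 0)
  expect_lt(abs(frac - 0.4), 0.02)
})

test_that("landscape config rejects invalid parameters", {
  expect_error(landscape_config(agri_fraction = 1.2),
               class = "landpov_parameter_error")
  expect_error(landscape_config(travel_cost_range = c(0, 1)),
               class = "landpov_parameter_error")
  expect_error(generate_landscape(landscape_config(nrows = 2, ncols = 2,
                                                   n_countries = 5)),
               class = "landpov_parameter_error")
})
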