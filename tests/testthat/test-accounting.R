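test_that("toy tabulation reproduces the hand-enumerated shares", {
  stack <- toy_stack(pop_per_cell = 10)
  labels <- classify_land(stack)
  tab <- tabulate_country(labels, stack$layers$population_2000,
                          stack$layers$urban_mask,
                          stack$layers$country_zone)
  expect_equal(tab$rural_pop, 160)
  expect_equal(tab$pop_DAL, 30)
  expect_equal(tab$pop_DAL_remote, 20)
  expect_equal(tab$d1, 18.75)
  expect_equal(tab$d2, 12.5)
  expect_true(tab$shares_defined)
  # share identity: d1 + i1 shares recover the agricultural rural pop
  expect_equal((tab$d1 + tab$i1) * tab$rural_pop / 100,
               tab$pop_DAL + tab$pop_IAL)
})

test_that("zero rural population flags shares undefined, no error", {
  stack <- toy_stack(pop_per_cell = 10)
  labels <- classify_land(stack)
  zero_pop <- grid_layer(matrix(0, 4, 4), kind = "population")
  tab0 <- tabulate_country(labels, zero_pop, stack$layers$urban_mask,
                           stack$layers$country_zone)
  expect_equal(tab0$rural_pop, 0)
  expect_false(tab0$shares_defined)
  expect_true(is.na(tab0$d1))

  all_urban <- grid_layer(matrix(1, 4, 4), kind = "mask")
  tabu <- tabulate_country(labels, stack$layers$population_2000,
                           all_urban, stack$layers$country_zone)
  expect_equal(tabu$rural_pop, 0)
})

test_that("regional aggregation sums populations and recomputes shares", {
  stack <- generate_landscape(landscape_config(nrows = 32, ncols = 32,
                                               n_countries = 7, seed = 9))
  labels <- classify_land(stack)
  tab <- tabulate_country(labels, stack$layers$population_2000,
                          stack$layers$urban_mask,
                          stack$layers$country_zone)
  reg <- compute_region_table(tab, stack$region_map)
  world <- reg[reg$region == "World", ]
  # conservation: country sums equal the world row, exactly
  for (cl in c("rural_pop", "pop_DAL", "pop_DAL_remote", "pop_IAL",
               "pop_IAL_remote")) {
    expect_equal(world[[cl]], sum(tab[[cl]]), label = cl)
  }
  # developing + developed = world
  dev <- reg[reg$region %in% c("Developing", "Developed"), ]
  expect_equal(sum(dev$pop_DAL), world$pop_DAL)
  # shares are the ratio of the summed populations, not country averages
  expect_equal(world$d1, 100 * world$pop_DAL / world$rural_pop)
  # share orderings inherited from the label partition
  ok <- reg$rural_pop > 0
  expect_true(all(reg$d2[ok] <= reg$d1[ok] + 1e-12))
  expect_true(all(reg$i2[ok] <= reg$i1[ok] + 1e-12))
  expect_true(all(reg$d1[ok] + reg$i1[ok] <= 100 + 1e-12))

  expect_error(compute_region_table(tab, stack$region_map[-1, ]),
               class = "landpov_config_error")
})

test_that("single-region aggregate equals the summed country rows", {
  stack <- toy_stack()
  labels <- classify_land(stack)
  tab <- tabulate_country(labels, stack$layers$population_2000,
                          stack$layers$urban_mask,
                          stack$layers$country_zone)
  reg <- compute_region_table(tab, stack$region_map)
  expect_equal(reg$pop_DAL[reg$region == "EAP"], sum(tab$pop_DAL))
})

test_that("epoch change is elementwise percent change with NA at zero base", {
  t0 <- data.frame(zone_id = 1:3, rural_pop = c(100, 50, 0),
                   pop_DAL = c(10, 0, 0))
  t1 <- data.frame(zone_id = 1:3, rural_pop = c(113, 50, 5),
                   pop_DAL = c(11, 2, 0))
  chg <- epoch_change(t0, t1)
  expect_equal(chg$rural_pop, c(13, 0, NA))
  expect_equal(chg$pop_DAL, c(10, NA, NA))
  expect_error(epoch_change(t0, t1[c(2, 1, 3), ]),
               class = "landpov_input_error")
})

test_that("density change summarizes per-class deltas", {
  stack <- toy_stack(pop_per_cell = 10)
  labels <- classify_land(stack)
  same <- density_change(stack$layers$population_2000,
                         stack$layers$population_2000, labels)
  expect_true(all(same$summary$mean == 0))

  plus10 <- grid_layer(stack$layers$population_2000$values + 10,
                       kind = "population")
  up <- density_change(stack$layers$population_2000, plus10, labels,
                       cell_area = 1)
  expect_equal(up$summary$mean, c(10, 10))
  expect_equal(up$summary$n, c(3L, 5L))

  half_area <- density_change(stack$layers$population_2000, plus10,
                              labels, cell_area = 2)
  expect_equal(half_area$summary$mean, c(5, 5))
  expect_error(density_change(stack$layers$population_2000, plus10,
                              labels, cell_area = 0),
               class = "landpov_parameter_error")
})

test_that("growing synthetic population raises density on both classes", {
  stack <- generate_landscape(landscape_config(nrows = 32, ncols = 32,
                                               n_countries = 3,
                                               pop_growth_2000_2010 = 0.13,
                                               seed = 15))
  labels <- classify_land(stack)
  dens <- density_change(stack$layers$population_2000,
                         stack$layers$population_2010, labels)
  expect_true(all(dens$summary$mean > 0))
})
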