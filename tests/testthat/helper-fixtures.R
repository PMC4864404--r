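# 4 x 4 toy stack with 8 agricultural cells, 3 degrading (2 of those
# remote), all other layers benign: the hand-enumerable classification is
# DAL_REM 2, DAL_ACC 1, IAL_ACC 5, IAL_REM 0, EXCLUDED 8.
toy_stack <- function(pop_per_cell = 10) {
  m <- function(x) matrix(x, 4, 4, byrow = TRUE)
  npp <- m(c(-5, -3, 2, 9,
             -1, 4, 7, 9,
             3, 6, 9, 9,
             9, 9, 9, 1))
  agri <- m(c(1, 1, 1, 0,
              1, 1, 0, 0,
              1, 1, 0, 0,
              0, 0, 0, 1))
  tt <- m(c(6, 2, 1, 1,
            7, 3, 1, 1,
            2, 2, 1, 1,
            1, 1, 1, 5))    # remote: (1,1), (2,1); cell (4,4) is 5h remote
  urban <- m(rep(0, 16))
  pop <- m(rep(pop_per_cell, 16))
  zone <- m(rep(1, 16))
  layer_stack(list(
    npp_trend = grid_layer(npp, kind = "npp_trend"),
    agri_mask = grid_layer(agri, kind = "mask"),
    urban_mask = grid_layer(urban, kind = "mask"),
    travel_time = grid_layer(tt, kind = "travel_time"),
    population_2000 = grid_layer(pop, kind = "population"),
    population_2010 = grid_layer(pop * 1.13, kind = "population"),
    country_zone = grid_layer(zone, kind = "zone")
  ), data.frame(zone_id = 1, country = "Toyland", region = "EAP"))
}

# expected toy label counts (cell (4,4): agri, improving, 5 h -> IAL_REM)
toy_label_counts <- c(EXCLUDED = 8L, DAL_ACC = 1L, DAL_REM = 2L,
                      IAL_ACC = 4L, IAL_REM = 1L)

# closed-form travel time on a uniform-cost grid: 8-neighbour moves with
# step cost c (rook) and c*sqrt(2) (diagonal) give
# c * (max(dr,dc) + (sqrt(2)-1) * min(dr,dc)) to a single city
uniform_travel_oracle <- function(nr, nc, city, cost = 1) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- abs(rows - city[1]); dc <- abs(cols - city[2])
  cost * (pmax(dr, dc) + (sqrt(2) - 1) * pmin(dr, dc))
}

# moments of a N(mean, sd) variable clamped to [lower, upper] (the
# configured share distribution of the panel generator), plus the
# central fourth moment needed for the standard error of the sample SD
clamped_normal_moments <- function(mean, sd, lower = 0, upper = 100) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd, lower.tail = FALSE)
  raw <- function(k) {
    lower^k * p_lo + upper^k * p_hi +
      stats::integrate(function(x) x^k * stats::dnorm(x, mean, sd),
                       lower, upper)$value
  }
  m1 <- raw(1)
  cen <- function(k) {
    lower_c <- (lower - m1)^k * p_lo
    upper_c <- (upper - m1)^k * p_hi
    lower_c + upper_c +
      stats::integrate(function(x) (x - m1)^k * stats::dnorm(x, mean, sd),
                       lower, upper)$value
  }
  v <- cen(2)
  c(mean = m1, sd = sqrt(v), mu4 = cen(4))
}

# large-sample SE of the sample SD for a distribution with variance v and
# central fourth moment mu4
se_of_sd <- function(mom, n) {
  v <- mom[["sd"]]^2
  sqrt((mom[["mu4"]] - v^2) / (4 * v * n))
}
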