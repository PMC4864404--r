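#' Configuration for a synthetic landscape
#'
#' Parameters of the simulated study region. Defaults emulate, at desk
#' scale, the qualitative structure of the global inputs the analysis was
#' designed for: a spatially autocorrelated productivity-trend surface, an
#' agricultural extent covering roughly 40% of land, just under half of
#' agricultural cells degrading, population clustered around market
#' cities holding about 30% of people in urban cells, and a decade of 13%
#' population growth.
#'
#' @param nrows,ncols grid size in cells.
#' @param n_countries number of country zones (nearest-seed partition).
#' @param n_cities_per_country market cities seeded per country.
#' @param smoothing_scale spatial autocorrelation length, cells.
#' @param agri_fraction target fraction of cells that are agricultural.
#' @param degrading_fraction target fraction of agricultural cells with a
#'   negative productivity trend.
#' @param urban_pop_share fraction of total population in urban cells.
#' @param pop_total total persons on the grid (epoch 2000).
#' @param travel_cost_range length-2, min and max per-cell crossing cost in
#'   hours.
#' @param pop_growth_2000_2010 fractional population growth over the
#'   decade.
#' @param urban_radius_cells cells around each city flagged urban.
#' @param seed integer RNG seed (`NULL` for the session stream).
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(nrows = 64, ncols = 64, n_countries = 6,
                             n_cities_per_country = 1, smoothing_scale = 6,
                             agri_fraction = 0.4, degrading_fraction = 0.45,
                             urban_pop_share = 0.3, pop_total = 1e6,
                             travel_cost_range = c(0.25, 2),
                             pop_growth_2000_2010 = 0.13,
                             urban_radius_cells = 1.5, seed = NULL) {
  cfg <- list(nrows = as.integer(nrows), ncols = as.integer(ncols),
              n_countries = as.integer(n_countries),
              n_cities_per_country = as.integer(n_cities_per_country),
              smoothing_scale = smoothing_scale,
              agri_fraction = agri_fraction,
              degrading_fraction = degrading_fraction,
              urban_pop_share = urban_pop_share, pop_total = pop_total,
              travel_cost_range = travel_cost_range,
              pop_growth_2000_2010 = pop_growth_2000_2010,
              urban_radius_cells = urban_radius_cells, seed = seed)
  fr <- c(cfg$agri_fraction, cfg$degrading_fraction, cfg$urban_pop_share)
  if (any(fr < 0 | fr > 1)) {
    abort_landpov("fractions must lie in [0, 1]", "landpov_parameter_error")
  }
  if (cfg$nrows < 1 || cfg$ncols < 1 || cfg$n_countries < 1 ||
      cfg$n_cities_per_country < 1) {
    abort_landpov("sizes must be >= 1", "landpov_parameter_error")
  }
  if (any(cfg$travel_cost_range <= 0)) {
    abort_landpov("travel costs must be positive", "landpov_parameter_error")
  }
  class(cfg) <- "landscape_config"
  cfg
}

#' Spatially autocorrelated Gaussian random field
#'
#' White noise convolved (circularly, via FFT) with an isotropic Gaussian
#' kernel of standard deviation `smoothing_scale` cells, then standardized
#' to zero mean and unit variance. `smoothing_scale = 0` returns
#' standardized white noise. Deterministic given `seed`.
#'
#' @param shape length-2 integer, (nrows, ncols).
#' @param smoothing_scale kernel standard deviation in cells (>= 0).
#' @param seed integer seed, or `NULL`.
#' @return a [grid_layer()] of kind `"generic"`.
#' @export
generate_field <- function(shape, smoothing_scale = 4, seed = NULL) {
  if (length(shape) != 2L || any(shape < 1)) {
    abort_landpov("shape must be two positive integers",
                  "landpov_parameter_error")
  }
  if (smoothing_scale < 0) {
    abort_landpov("smoothing_scale must be >= 0", "landpov_parameter_error")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  noise <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  f <- smooth_field(noise, smoothing_scale)
  grid_layer((f - mean(f)) / stats::sd(f))
}

# circular Gaussian smoothing of a matrix via FFT
smooth_field <- function(m, scale) {
  if (scale <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # wrap-around distance along each axis
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- outer(exp(-dr^2 / (2 * scale^2)), exp(-dc^2 / (2 * scale^2)))
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
}

#' Cumulative travel time to the nearest market city
#'
#' Minimal travel time from every cell to its nearest city over 8-neighbour
#' moves on a per-cell cost surface (hours to cross a cell). A step between
#' adjacent cells costs the mean of the two cells' crossing costs, times
#' sqrt(2) for diagonal moves. City cells get 0; cells cut off by `NA`
#' barriers get `Inf`. Shortest paths are computed with Dijkstra's
#' algorithm on the implied lattice graph.
#'
#' @param cost [grid_layer()] of per-cell crossing cost in hours
#'   (positive or `NA`).
#' @param cities matrix or data frame with columns `row`, `col` (1-based),
#'   or a list of length-2 index vectors.
#' @return a [grid_layer()] of kind `"travel_time"` on the cost geometry.
#' @export
compute_travel_time <- function(cost, cities) {
  cities <- as_city_matrix(cities)
  if (nrow(cities) == 0L) {
    abort_landpov("at least one city is required", "landpov_parameter_error")
  }
  v <- cost$values
  if (any(v <= 0, na.rm = TRUE)) {
    abort_landpov("all travel costs must be positive or NA",
                  "landpov_parameter_error")
  }
  nr <- nrow(v); nc <- ncol(v)
  idx <- function(r, c) (c - 1L) * nr + r
  valid <- !is.na(v)

  # undirected lattice edges: right, down, down-right, down-left
  edges <- list()
  wts <- list()
  add_edges <- function(r1, c1, r2, c2, diag) {
    ok <- valid[cbind(r1, c1)] & valid[cbind(r2, c2)]
    if (!any(ok)) return()
    w <- (v[cbind(r1, c1)[ok, , drop = FALSE]] +
          v[cbind(r2, c2)[ok, , drop = FALSE]]) / 2
    if (diag) w <- w * sqrt(2)
    edges[[length(edges) + 1L]] <<- cbind(idx(r1[ok], c1[ok]),
                                          idx(r2[ok], c2[ok]))
    wts[[length(wts) + 1L]] <<- w
  }
  rs <- rep(seq_len(nr), times = nc)
  cs <- rep(seq_len(nc), each = nr)
  right <- cs < nc
  add_edges(rs[right], cs[right], rs[right], cs[right] + 1L, FALSE)
  down <- rs < nr
  add_edges(rs[down], cs[down], rs[down] + 1L, cs[down], FALSE)
  dr <- rs < nr & cs < nc
  add_edges(rs[dr], cs[dr], rs[dr] + 1L, cs[dr] + 1L, TRUE)
  dl <- rs < nr & cs > 1L
  add_edges(rs[dl], cs[dl], rs[dl] + 1L, cs[dl] - 1L, TRUE)

  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(t(em)),
                           weight = unlist(wts))
  }
  city_idx <- idx(cities[, 1L], cities[, 2L])
  d <- igraph::distances(g, v = city_idx, algorithm = "dijkstra")
  tt <- matrix(apply(d, 2L, min), nr, nc)
  tt[!valid] <- NA_real_
  grid_layer(tt, cell_size = cost$cell_size, origin = cost$origin,
             nodata = cost$nodata, kind = "travel_time")
}

as_city_matrix <- function(cities) {
  if (is.data.frame(cities)) cities <- as.matrix(cities[, c("row", "col")])
  if (is.list(cities)) cities <- do.call(rbind, cities)
  if (is.null(cities) || length(cities) == 0L) {
    return(matrix(integer(0), 0, 2))
  }
  if (!is.matrix(cities)) cities <- matrix(cities, ncol = 2)
  storage.mode(cities) <- "integer"
  cities
}

#' Generate a synthetic landscape stack
#'
#' Builds the seven analysis layers of a [layer_stack()] from a
#' [landscape_config()]:
#' country zones are the nearest-seed partition of the grid among
#' `n_countries` random seed points; the agricultural mask thresholds a
#' smoothed random field at the `agri_fraction` quantile; the productivity
#' trend is a second smoothed field shifted so the configured fraction of
#' agricultural cells is negative, scaled to gC/m2/yr; one market city per
#' country sits at the country's population-potential maximum; cells within
#' `urban_radius_cells` of a city are urban and are scaled to hold
#' `urban_pop_share` of the population; population is a log-normal surface
#' concentrated near cities and normalized to `pop_total`; the 2010
#' population applies the configured growth with multiplicative noise; and
#' travel time is the cost-distance to the nearest city
#' ([compute_travel_time()]) over a smoothly varying cost surface spanning
#' `travel_cost_range`.
#'
#' Countries are assigned round-robin to the six developing regions; when
#' more than six countries are requested the last one is assigned to the
#' developed (`DEV`) group so world/developing/developed aggregation paths
#' are exercised.
#'
#' @param config a [landscape_config()].
#' @return a [layer_stack()]; the city locations are attached as attribute
#'   `cities` (data frame `zone_id`, `row`, `col`).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$nrows; nc <- config$ncols
  if (config$n_countries > nr * nc) {
    abort_landpov("more countries than cells", "landpov_parameter_error")
  }
  seed <- config$seed

  # country zones: nearest seed point (substream 1)
  seeds <- with_seed(seed, {
    cells <- sample.int(nr * nc, config$n_countries)
    cbind(row = (cells - 1L) %% nr + 1L, col = (cells - 1L) %/% nr + 1L)
  }, offset = 1L)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- vapply(seq_len(config$n_countries), function(k) {
    as.vector((rows - seeds[k, 1])^2 + (cols - seeds[k, 2])^2)
  }, numeric(nr * nc))
  zone <- matrix(max.col(-d2, ties.method = "first"), nr, nc)

  agri_field <- generate_field(c(nr, nc), config$smoothing_scale,
                               seed = if (is.null(seed)) NULL else seed + 2L)
  agri <- (agri_field$values >=
           stats::quantile(agri_field$values, 1 - config$agri_fraction)) * 1

  npp_field <- generate_field(c(nr, nc), config$smoothing_scale,
                              seed = if (is.null(seed)) NULL else seed + 3L)
  agri_vals <- npp_field$values[agri == 1]
  shift <- if (length(agri_vals)) {
    if (config$degrading_fraction == 0) {
      min(agri_vals)  # all agricultural cells end >= 0
    } else {
      stats::quantile(agri_vals, config$degrading_fraction, names = FALSE)
    }
  } else 0
  npp <- (npp_field$values - shift) * 15  # ~gC/m2/yr scale

  # population potential: smooth field, log-normal surface (substream 4)
  pot_field <- generate_field(c(nr, nc), config$smoothing_scale,
                              seed = if (is.null(seed)) NULL else seed + 4L)
  pot <- exp(pot_field$values)

  # cities at each country's potential maximum (ties: first cell)
  n_cities <- config$n_cities_per_country
  city_list <- lapply(seq_len(config$n_countries), function(k) {
    in_k <- which(zone == k)
    ord <- in_k[order(pot[in_k], decreasing = TRUE)]
    take <- ord[seq_len(min(n_cities, length(ord)))]
    cbind(zone_id = k, row = (take - 1L) %% nr + 1L,
          col = (take - 1L) %/% nr + 1L)
  })
  cities <- as.data.frame(do.call(rbind, city_list))

  # urban mask: fixed radius around cities
  urban <- matrix(0, nr, nc)
  for (i in seq_len(nrow(cities))) {
    near <- (rows - cities$row[i])^2 + (cols - cities$col[i])^2 <=
      config$urban_radius_cells^2
    urban[near] <- 1
  }

  # population 2000: potential boosted near cities, split so that urban
  # cells hold urban_pop_share of the total
  cdist2 <- Reduce(pmin, lapply(seq_len(nrow(cities)), function(i) {
    (rows - cities$row[i])^2 + (cols - cities$col[i])^2
  }))
  pop <- pot * exp(-sqrt(cdist2) / max(4, config$smoothing_scale))
  su <- sum(pop[urban == 1]); sr <- sum(pop[urban == 0])
  if (su > 0) {
    pop[urban == 1] <- pop[urban == 1] / su * config$urban_pop_share
  }
  if (sr > 0) {
    pop[urban == 0] <- pop[urban == 0] / sr * (1 - config$urban_pop_share)
  }
  pop2000 <- pop / sum(pop) * config$pop_total

  noise <- with_seed(seed,
                     matrix(stats::rlnorm(nr * nc, 0, 0.05), nr, nc),
                     offset = 5L)
  pop2010 <- pop2000 * (1 + config$pop_growth_2000_2010) * noise
  pop2010 <- pop2010 / sum(pop2010) *
    (config$pop_total * (1 + config$pop_growth_2000_2010))

  # travel cost surface spanning travel_cost_range
  cost_field <- generate_field(c(nr, nc), config$smoothing_scale,
                               seed = if (is.null(seed)) NULL else seed + 6L)
  u <- stats::pnorm(cost_field$values)  # ~uniform(0,1)
  cost <- grid_layer(config$travel_cost_range[1] +
                       u * diff(config$travel_cost_range),
                     kind = "travel_time")
  travel <- compute_travel_time(cost, cities[, c("row", "col")])

  region_pool <- c("EAP", "ECA", "LAC", "MENA", "SA", "SSA")
  region <- region_pool[(seq_len(config$n_countries) - 1L) %%
                          length(region_pool) + 1L]
  if (config$n_countries > length(region_pool)) {
    region[config$n_countries] <- "DEV"
  }
  region_map <- data.frame(
    zone_id = seq_len(config$n_countries),
    country = sprintf("C%02d", seq_len(config$n_countries)),
    region = region, stringsAsFactors = FALSE)

  stack <- layer_stack(list(
    npp_trend = grid_layer(npp, kind = "npp_trend"),
    agri_mask = grid_layer(agri, kind = "mask"),
    urban_mask = grid_layer(urban, kind = "mask"),
    travel_time = travel,
    population_2000 = grid_layer(pop2000, kind = "population"),
    population_2010 = grid_layer(pop2010, kind = "population"),
    country_zone = grid_layer(zone, kind = "zone")
  ), region_map)
  attr(stack, "cities") <- cities
  stack
}
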