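#' Tabulate rural population by land class and country
#'
#' Rural cells are those not flagged urban with a valid population value.
#' For each country zone the function sums rural population overall and on
#' each land class, and derives the four spatial-distribution shares as
#' percentages of rural population:
#' `d1` (all degrading agricultural land, DAL), `d2` (remote DAL),
#' `i1` (all improving agricultural land, IAL), `i2` (remote IAL).
#' Zones with zero rural population get `NA` shares and
#' `shares_defined = FALSE` rather than a division error.
#'
#' @param labels a `land_class_grid` from [classify_land()].
#' @param population [grid_layer()] of persons per cell.
#' @param urban_mask [grid_layer()] 0/1 urban extent.
#' @param country_zone [grid_layer()] of zone ids.
#' @return data frame, one row per zone: `zone_id`, `rural_pop`,
#'   `pop_DAL`, `pop_DAL_remote`, `pop_IAL`, `pop_IAL_remote`, `d1`, `d2`,
#'   `i1`, `i2`, `shares_defined`.
#' @export
tabulate_country <- function(labels, population, urban_mask, country_zone) {
  for (layer in list(population, urban_mask, country_zone)) {
    if (!identical(dim(layer$values), dim(labels$labels))) {
      abort_landpov("tabulation layers are not aligned with the labels",
                    "landpov_alignment_error")
    }
  }
  pop <- population$values
  urb <- urban_mask$values
  zone <- country_zone$values
  lab <- labels$labels

  rural <- !is.na(pop) & (is.na(urb) | urb != 1) & !is.na(zone)
  zones <- sort(unique(as.vector(zone[!is.na(zone)])))

  sum_class <- function(sel) {
    vapply(zones, function(z) sum(pop[sel & zone == z & rural]), numeric(1))
  }
  rural_pop <- vapply(zones, function(z) sum(pop[rural & zone == z]),
                      numeric(1))
  dal_acc <- sum_class(lab == LAND_CLASSES[["DAL_ACC"]])
  dal_rem <- sum_class(lab == LAND_CLASSES[["DAL_REM"]])
  ial_acc <- sum_class(lab == LAND_CLASSES[["IAL_ACC"]])
  ial_rem <- sum_class(lab == LAND_CLASSES[["IAL_REM"]])

  pop_DAL <- dal_acc + dal_rem
  pop_IAL <- ial_acc + ial_rem
  defined <- rural_pop > 0
  share <- function(p) ifelse(defined, 100 * p / rural_pop, NA_real_)
  data.frame(zone_id = zones, rural_pop = rural_pop, pop_DAL = pop_DAL,
             pop_DAL_remote = dal_rem, pop_IAL = pop_IAL,
             pop_IAL_remote = ial_rem,
             d1 = share(pop_DAL), d2 = share(dal_rem),
             i1 = share(pop_IAL), i2 = share(ial_rem),
             shares_defined = defined)
}

#' Aggregate country tabulations to regions, developing, developed, world
#'
#' Sums the population columns over member countries of each region
#' present, then adds `Developing` (the six developing regions),
#' `Developed` (`DEV`) and `World` rows. Share columns are recomputed from
#' the summed populations, never averaged over countries, so each printed
#' share is exactly its population ratio.
#'
#' @param tabs country table from [tabulate_country()].
#' @param region_map data frame `zone_id`, `country`, `region`.
#' @return data frame with the same population and share columns plus
#'   `region` and `n_countries`.
#' @export
compute_region_table <- function(tabs, region_map) {
  unmapped <- setdiff(tabs$zone_id, region_map$zone_id)
  if (length(unmapped)) {
    abort_landpov(paste0("zone id(s) not in region_map: ",
                         paste(unmapped, collapse = ", ")),
                  "landpov_config_error")
  }
  tabs$region <- region_map$region[match(tabs$zone_id, region_map$zone_id)]
  pop_cols <- c("rural_pop", "pop_DAL", "pop_DAL_remote", "pop_IAL",
                "pop_IAL_remote")
  agg_rows <- function(sel, name) {
    sums <- colSums(tabs[sel, pop_cols, drop = FALSE])
    out <- data.frame(region = name, n_countries = sum(sel))
    out[pop_cols] <- as.list(sums)
    out
  }
  developing <- c("EAP", "ECA", "LAC", "MENA", "SA", "SSA")
  regions <- intersect(c(developing, "DEV"), unique(tabs$region))
  rows <- lapply(regions, function(r) agg_rows(tabs$region == r, r))
  rows <- c(rows, list(
    agg_rows(tabs$region %in% developing, "Developing"),
    agg_rows(tabs$region == "DEV", "Developed"),
    agg_rows(rep(TRUE, nrow(tabs)), "World")))
  out <- do.call(rbind, rows)
  out$d1 <- ifelse(out$rural_pop > 0, 100 * out$pop_DAL / out$rural_pop, NA)
  out$d2 <- ifelse(out$rural_pop > 0,
                   100 * out$pop_DAL_remote / out$rural_pop, NA)
  out$i1 <- ifelse(out$rural_pop > 0, 100 * out$pop_IAL / out$rural_pop, NA)
  out$i2 <- ifelse(out$rural_pop > 0,
                   100 * out$pop_IAL_remote / out$rural_pop, NA)
  rownames(out) <- NULL
  out
}

#' Percent change between two epoch tabulations
#'
#' For each zone (or region) and each population column, the percent
#' change `100 * (x2010 - x2000) / x2000`. Where the 2000 value is zero
#' the change is `NA` (undefined), never an error.
#'
#' @param tab_2000,tab_2010 matching tables from [tabulate_country()] or
#'   [compute_region_table()] for the two epochs.
#' @return data frame of percent changes with the id column preserved.
#' @export
epoch_change <- function(tab_2000, tab_2010) {
  id_col <- if ("zone_id" %in% names(tab_2000)) "zone_id" else "region"
  if (!identical(tab_2000[[id_col]], tab_2010[[id_col]])) {
    abort_landpov("epoch tables cover different zones", "landpov_input_error")
  }
  pop_cols <- intersect(c("rural_pop", "pop_DAL", "pop_DAL_remote",
                          "pop_IAL", "pop_IAL_remote"), names(tab_2000))
  out <- tab_2000[, id_col, drop = FALSE]
  for (cl in pop_cols) {
    x0 <- tab_2000[[cl]]; x1 <- tab_2010[[cl]]
    out[[cl]] <- ifelse(x0 > 0, 100 * (x1 - x0) / x0, NA_real_)
  }
  out
}

#' Population-density change on degrading and improving land
#'
#' Per-cell change in persons per km2 between the two epochs, summarized
#' separately over DAL and IAL cells (accessible + remote): count, mean,
#' median, and histogram counts over `breaks`.
#'
#' @param pop_2000,pop_2010 [grid_layer()] population layers.
#' @param labels a `land_class_grid`.
#' @param cell_area cell area in km2 (> 0).
#' @param breaks histogram break points (passed to [graphics::hist()]
#'   semantics via [base::cut()]); default 9 equal-width bins.
#' @return list with `summary` (data frame: `class`, `n`, `mean`,
#'   `median`) and `histogram` (data frame: `class`, `bin`, `count`).
#' @export
density_change <- function(pop_2000, pop_2010, labels, cell_area = 1,
                           breaks = NULL) {
  if (cell_area <= 0) {
    abort_landpov("cell_area must be positive", "landpov_parameter_error")
  }
  delta <- (pop_2010$values - pop_2000$values) / cell_area
  lab <- labels$labels
  sel <- list(
    DAL = lab %in% LAND_CLASSES[c("DAL_ACC", "DAL_REM")],
    IAL = lab %in% LAND_CLASSES[c("IAL_ACC", "IAL_REM")])
  vals <- lapply(sel, function(s) delta[s & !is.na(delta)])
  summary <- do.call(rbind, lapply(names(vals), function(k) {
    v <- vals[[k]]
    data.frame(class = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  }))
  all_v <- unlist(vals)
  if (is.null(breaks)) {
    breaks <- if (length(all_v) && diff(range(all_v)) > 0) {
      seq(min(all_v), max(all_v), length.out = 10)
    } else c(-1, 0, 1)
  }
  histogram <- do.call(rbind, lapply(names(vals), function(k) {
    ct <- table(cut(vals[[k]], breaks, include.lowest = TRUE))
    data.frame(class = k, bin = names(ct), count = as.integer(ct))
  }))
  list(summary = summary, histogram = histogram)
}
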