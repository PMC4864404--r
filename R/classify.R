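#' Five-way land classification codes
#'
#' Integer codes used in a land-class grid: 0 excluded (non-agricultural or
#' missing data), 1 degrading accessible, 2 degrading remote, 3 improving
#' accessible, 4 improving remote.
#'
#' @format named integer vector.
#' @export
LAND_CLASSES <- c(EXCLUDED = 0L, DAL_ACC = 1L, DAL_REM = 2L,
                  IAL_ACC = 3L, IAL_REM = 4L)

#' Degrading / improving trend masks
#'
#' Agricultural land is degrading when the productivity trend is strictly
#' negative and improving when it is non-negative (an exactly-zero trend is
#' improving). Missing cells appear in neither mask.
#'
#' @param npp_trend [grid_layer()] of productivity change (gC/m2/yr).
#' @return list of two 0/1/NA matrices, `degrading` and `improving`.
#' @export
classify_trend <- function(npp_trend) {
  v <- npp_trend$values
  list(degrading = (v < 0) * 1, improving = (v >= 0) * 1)
}

#' Remote / accessible masks from a travel-time surface
#'
#' A cell has market access when travel time to the nearest market city is
#' strictly below `threshold_hours`; otherwise (including unreachable
#' `Inf` cells) it is remote. The default threshold is five hours.
#'
#' @param travel_time [grid_layer()] of hours.
#' @param threshold_hours positive remoteness threshold.
#' @return list of two 0/1/NA matrices, `remote` and `accessible`.
#' @export
classify_remoteness <- function(travel_time, threshold_hours = 5) {
  if (threshold_hours <= 0) {
    abort_landpov("threshold_hours must be positive",
                  "landpov_parameter_error")
  }
  v <- travel_time$values
  list(remote = (v >= threshold_hours) * 1,
       accessible = (v < threshold_hours) * 1)
}

#' Classify agricultural land by trend and market access
#'
#' Crosses the degrading/improving trend split with the remote/accessible
#' travel-time split on agricultural cells. A cell is excluded when it is
#' not agricultural or when any needed layer (`agri_mask`, `npp_trend`,
#' `travel_time`) is missing there; excluded cells take part in no
#' tabulation.
#'
#' @param stack a [layer_stack()].
#' @param threshold_hours remoteness threshold in hours (default 5).
#' @return a `land_class_grid`: list with `labels` (integer matrix coded as
#'   [LAND_CLASSES]) and `threshold_hours`.
#' @export
classify_land <- function(stack, threshold_hours = 5) {
  ref <- stack$layers$npp_trend
  for (nm in c("agri_mask", "travel_time")) {
    if (!same_geometry(stack$layers[[nm]], ref)) {
      abort_landpov(sprintf("layer '%s' is not aligned", nm),
                    "landpov_alignment_error")
    }
  }
  agri <- stack$layers$agri_mask$values
  npp <- stack$layers$npp_trend$values
  tt <- stack$layers$travel_time$values

  labels <- matrix(LAND_CLASSES[["EXCLUDED"]], nrow(npp), ncol(npp))
  ok <- !is.na(agri) & agri == 1 & !is.na(npp) & !is.na(tt)
  deg <- npp < 0
  rem <- tt >= threshold_hours
  labels[ok & deg & !rem] <- LAND_CLASSES[["DAL_ACC"]]
  labels[ok & deg & rem] <- LAND_CLASSES[["DAL_REM"]]
  labels[ok & !deg & !rem] <- LAND_CLASSES[["IAL_ACC"]]
  labels[ok & !deg & rem] <- LAND_CLASSES[["IAL_REM"]]
  structure(list(labels = labels, threshold_hours = threshold_hours),
            class = "land_class_grid")
}

#' @export
print.land_class_grid <- function(x, ...) {
  counts <- table(factor(x$labels, levels = LAND_CLASSES,
                         labels = names(LAND_CLASSES)))
  cat(sprintf("<land_class_grid> %d x %d, threshold %g h\n",
              nrow(x$labels), ncol(x$labels), x$threshold_hours))
  print(counts)
  invisible(x)
}

#' Write / read a land-class grid as a coded CSV raster
#'
#' Serialized as an integer raster with the [LAND_CLASSES] code map; the
#' threshold is stored in the companion layer metadata slot `nodata = -1`
#' is reserved, so codes 0-4 round-trip exactly.
#'
#' @param lcg a `land_class_grid` from [classify_land()].
#' @param path file path.
#' @return `write_labels_csv` returns `path` invisibly; `read_labels_csv`
#'   returns a `land_class_grid` (threshold taken from `threshold_hours`).
#' @param threshold_hours threshold recorded on read.
#' @export
write_labels_csv <- function(lcg, path) {
  write_grid_csv(grid_layer(lcg$labels, nodata = -1), path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path, threshold_hours = 5) {
  layer <- read_grid_csv(path)
  structure(list(labels = layer$values, threshold_hours = threshold_hours),
            class = "land_class_grid")
}
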