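#' Georeferenced single-variable grid layer
#'
#' A `grid_layer` is a plain numeric matrix with georeferencing metadata:
#' the length of a cell edge (`cell_size`, same unit for x and y), the
#' coordinates of the top-left corner of cell (1,1) (`origin`), and the
#' sentinel written for missing cells on disk (`nodata`; in memory missing
#' cells are always `NA`). Row 1 is the northernmost row, so y decreases
#' with the row index while x increases with the column index. Cell areas
#' are treated as uniform; there is no latitude correction.
#'
#' The `kind` tag records the variable semantics and drives validation:
#' \describe{
#'   \item{`npp_trend`}{change in net primary productivity, gC/m2/yr}
#'   \item{`mask`}{0/1 indicator}
#'   \item{`travel_time`}{hours, non-negative (may be `Inf` for
#'     unreachable cells)}
#'   \item{`population`}{persons per cell, non-negative}
#'   \item{`zone`}{positive integer zone (country) identifier}
#'   \item{`generic`}{no domain restriction}
#' }
#'
#' @param values numeric matrix of cell values (`NA` = missing).
#' @param cell_size positive scalar, cell edge length.
#' @param origin numeric length-2, (x, y) of the top-left grid corner.
#' @param nodata scalar sentinel used when the layer is written to disk.
#' @param kind one of `"npp_trend"`, `"mask"`, `"travel_time"`,
#'   `"population"`, `"zone"`, `"generic"`.
#' @param check if `TRUE` (default) a domain violation is an error; pass
#'   `FALSE` to construct a deliberately invalid layer for
#'   [validate_stack()] to report on.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, cell_size = 1, origin = c(0, 0),
                       nodata = -9999, kind = "generic", check = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(cell_size) == 1L, cell_size > 0, length(origin) == 2L)
  kind <- match.arg(kind,
    c("generic", "npp_trend", "mask", "travel_time", "population", "zone"))
  layer <- structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         kind = kind),
    class = "grid_layer")
  if (check) check_layer_domain(layer)
  layer
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %s, %d x %d cells, cell_size %g, origin (%g, %g), %d NA\n",
              x$kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

# domain violations raise 'landpov_validation_error' with the offending index
check_layer_domain <- function(layer) {
  v <- layer$values
  ok <- switch(layer$kind,
    mask        = is.na(v) | v == 0 | v == 1,
    population  = is.na(v) | v >= 0,
    travel_time = is.na(v) | v >= 0,
    zone        = is.na(v) | (v >= 1 & v == floor(v)),
    TRUE)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort_landpov(
      sprintf("%s layer violates its domain at cell (%d, %d): value %g",
              layer$kind, bad[1], bad[2], v[bad[1], bad[2]]),
      "landpov_validation_error")
  }
  invisible(layer)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write / read a grid layer as plain-text CSV raster
#'
#' The on-disk format is a two-line header (field names, then values for
#' `nrows, ncols, cell_size, origin_x, origin_y, nodata`) followed by the
#' cell values row-major, one grid row per line. `NA` cells are written as
#' the nodata sentinel.
#'
#' @param layer a [grid_layer()].
#' @param path file path.
#' @param kind semantic tag to attach on read (see [grid_layer()]).
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns a [grid_layer()].
#' @export
write_grid_csv <- function(layer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("nrows,ncols,cell_size,origin_x,origin_y,nodata", con)
  writeLines(paste(nrow(layer$values), ncol(layer$values), layer$cell_size,
                   layer$origin[1], layer$origin[2], layer$nodata, sep = ","),
             con)
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  v[is.infinite(v)] <- layer$nodata  # Inf only arises for travel time
  writeLines(apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = ",")), con)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, kind = "generic") {
  if (!file.exists(path)) {
    abort_landpov(sprintf("raster file not found: %s", path),
                  "landpov_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 3L) {
    abort_landpov(sprintf("malformed raster file: %s", path),
                  "landpov_io_error")
  }
  hdr <- as.numeric(strsplit(lines[2L], ",", fixed = TRUE)[[1L]])
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- as.numeric(strsplit(lines[2L + r], ",", fixed = TRUE)[[1L]])
    if (length(row) != nc) {
      abort_landpov(sprintf("row %d of %s has %d values, expected %d",
                            r, path, length(row), nc), "landpov_io_error")
    }
    vals[r, ] <- row
  }
  vals[vals == hdr[6]] <- NA_real_
  grid_layer(vals, cell_size = hdr[3], origin = c(hdr[4], hdr[5]),
             nodata = hdr[6], kind = kind)
}

#' Resample a layer onto a reference geometry by nearest neighbour
#'
#' Every reference cell takes the value of the source cell whose centre is
#' nearest to its own centre. Nearest-neighbour assignment is used for all
#' layer kinds (masks and zone ids must not be interpolated; population is
#' generated natively on the reference grid in synthetic runs, so its
#' resampling is a real-data concern only). `NA` propagates. A warning is
#' emitted when resampling changes the global sum of a population layer.
#'
#' @param layer source [grid_layer()].
#' @param reference [grid_layer()] supplying the target geometry.
#' @return a [grid_layer()] on the reference geometry.
#' @export
align_to_reference <- function(layer, reference) {
  if (same_geometry(layer, reference)) return(layer)
  nr <- nrow(reference$values); nc <- ncol(reference$values)
  # centres of reference cells
  xs <- reference$origin[1] + (seq_len(nc) - 0.5) * reference$cell_size
  ys <- reference$origin[2] - (seq_len(nr) - 0.5) * reference$cell_size
  # source indices holding those centres
  src_c <- floor((xs - layer$origin[1]) / layer$cell_size) + 1L
  src_r <- floor((layer$origin[2] - ys) / layer$cell_size) + 1L
  if (all(src_c < 1L | src_c > ncol(layer$values)) ||
      all(src_r < 1L | src_r > nrow(layer$values))) {
    abort_landpov("layer extent does not overlap the reference extent",
                  "landpov_alignment_error")
  }
  out <- matrix(NA_real_, nr, nc)
  rr <- src_r >= 1L & src_r <= nrow(layer$values)
  cc <- src_c >= 1L & src_c <= ncol(layer$values)
  out[rr, cc] <- layer$values[src_r[rr], src_c[cc], drop = FALSE]
  aligned <- grid_layer(out, cell_size = reference$cell_size,
                        origin = reference$origin, nodata = layer$nodata,
                        kind = layer$kind)
  if (layer$kind == "population") {
    s0 <- sum(layer$values, na.rm = TRUE)
    s1 <- sum(aligned$values, na.rm = TRUE)
    if (abs(s1 - s0) > 0) {
      warning(sprintf(
        "resampling changed the global population sum by %.6g (%.6g -> %.6g)",
        s1 - s0, s0, s1))
    }
  }
  aligned
}

LAYER_KINDS <- c(npp_trend = "npp_trend", agri_mask = "mask",
                 urban_mask = "mask", travel_time = "travel_time",
                 population_2000 = "population",
                 population_2010 = "population", country_zone = "zone")

#' Bundle of mutually aligned analysis layers
#'
#' A `layer_stack` holds the seven layers the classifier and the
#' tabulations need (`npp_trend`, `agri_mask`, `urban_mask`, `travel_time`,
#' `population_2000`, `population_2010`, `country_zone`) plus a
#' `region_map` data frame (`zone_id`, `country`, `region`) assigning each
#' zone id to one of the six developing regions (`EAP`, `ECA`, `LAC`,
#' `MENA`, `SA`, `SSA`) or the developed group (`DEV`).
#'
#' @param layers named list of [grid_layer()] objects, one per name above.
#' @param region_map data frame with columns `zone_id`, `country`,
#'   `region`.
#' @param check if `TRUE` (default) misaligned layers are an error; pass
#'   `FALSE` to let [validate_stack()] report the misalignment instead.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(layers, region_map, check = TRUE) {
  missing <- setdiff(names(LAYER_KINDS), names(layers))
  if (length(missing)) {
    abort_landpov(paste0("stack is missing layer(s): ",
                         paste(missing, collapse = ", ")),
                  "landpov_config_error")
  }
  stopifnot(is.data.frame(region_map),
            all(c("zone_id", "country", "region") %in% names(region_map)))
  ref <- layers$npp_trend
  if (check) {
    for (nm in names(LAYER_KINDS)) {
      if (!same_geometry(layers[[nm]], ref)) {
        abort_landpov(
          sprintf("layer '%s' is not aligned with 'npp_trend'", nm),
          "landpov_alignment_error")
      }
    }
  }
  structure(list(layers = layers[names(LAYER_KINDS)],
                 region_map = region_map),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$layers$npp_trend$values)
  cat(sprintf("<layer_stack> %d x %d cells, %d zones, %d regions\n",
              d[1], d[2], nrow(x$region_map),
              length(unique(x$region_map$region))))
  invisible(x)
}

#' Load a layer stack from CSV rasters on disk
#'
#' Reads the seven named rasters, aligns every layer to the `npp_trend`
#' geometry by nearest neighbour, reads the region map CSV, and returns a
#' validated [layer_stack()]. File names and MD5 checksums are recorded in
#' the `provenance` attribute.
#'
#' @param paths named character vector or list: one path per layer name in
#'   a [layer_stack()] plus `region_map` (CSV with columns `zone_id`,
#'   `country`, `region`).
#' @return a [layer_stack()] with a `provenance` attribute.
#' @export
load_stack <- function(paths) {
  paths <- as.list(paths)
  need <- c(names(LAYER_KINDS), "region_map")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    abort_landpov(paste0("load_stack: missing path(s) for: ",
                         paste(missing, collapse = ", ")),
                  "landpov_config_error")
  }
  layers <- lapply(names(LAYER_KINDS), function(nm) {
    read_grid_csv(paths[[nm]], kind = LAYER_KINDS[[nm]])
  })
  names(layers) <- names(LAYER_KINDS)
  ref <- layers$npp_trend
  layers <- lapply(layers, align_to_reference, reference = ref)
  region_map <- utils::read.csv(paths$region_map, stringsAsFactors = FALSE)
  stack <- layer_stack(layers, region_map)
  files <- unlist(paths[need])
  attr(stack, "provenance") <- data.frame(
    name = need, file = files, md5 = unname(tools::md5sum(files)),
    row.names = NULL)
  stack
}

#' Write a layer stack to a directory of CSV rasters
#'
#' @param stack a [layer_stack()].
#' @param dir output directory (created if absent).
#' @return named vector of the files written, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_grid_csv(stack$layers[[nm]], p)
    p
  }, character(1))
  rm_path <- file.path(dir, "region_map.csv")
  utils::write.csv(stack$region_map, rm_path, row.names = FALSE)
  invisible(c(paths, region_map = rm_path))
}

#' Validate a layer stack and report findings
#'
#' Checks, per layer: missing-cell count, out-of-domain values, and
#' geometric alignment with the reference (`npp_trend`) layer; and that
#' every zone id in `country_zone` appears in the region map. Findings that
#' break an invariant are flagged fatal; the function reports rather than
#' stops.
#'
#' @param stack a [layer_stack()].
#' @return data frame with columns `layer`, `n_nodata`, `finding`,
#'   `fatal`.
#' @export
validate_stack <- function(stack) {
  ref <- stack$layers$npp_trend
  rows <- lapply(names(stack$layers), function(nm) {
    layer <- stack$layers[[nm]]
    v <- layer$values
    finding <- ""
    fatal <- FALSE
    bad <- switch(layer$kind,
      mask        = sum(!(is.na(v) | v == 0 | v == 1)),
      population  = sum(v < 0, na.rm = TRUE),
      travel_time = sum(v < 0, na.rm = TRUE),
      zone        = sum(v < 1 | v != floor(v), na.rm = TRUE),
      0L)
    if (bad > 0) {
      finding <- switch(layer$kind,
        mask = "mask value outside {0,1}",
        sprintf("%d out-of-domain values", bad))
      fatal <- TRUE
    }
    if (!same_geometry(layer, ref)) {
      finding <- paste0(finding, "; not aligned with reference")
      fatal <- TRUE
    }
    data.frame(layer = nm, n_nodata = sum(is.na(v)), finding = finding,
               fatal = fatal, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  zones <- sort(unique(stats::na.omit(as.vector(
    stack$layers$country_zone$values))))
  unmapped <- setdiff(zones, stack$region_map$zone_id)
  if (length(unmapped)) {
    report <- rbind(report, data.frame(
      layer = "region_map", n_nodata = 0L,
      finding = paste0("zone id(s) absent from region_map: ",
                       paste(unmapped, collapse = ", ")),
      fatal = TRUE, stringsAsFactors = FALSE))
  }
  report
}
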