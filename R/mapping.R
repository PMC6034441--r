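#' Construct a validated GPS track
#'
#' @param timestamp seconds (strictly increasing after sorting).
#' @param lat,lon degrees, |lat| <= 90, |lon| <= 180.
#' @return a `gps_track`: data.frame of time-ordered fixes.
#' @export
gps_track <- function(timestamp, lat, lon) {
  .assert(length(timestamp) == length(lat) && length(lat) == length(lon),
          "timestamp, lat, lon must have equal length")
  .assert(length(timestamp) >= 2, "a track needs at least 2 fixes")
  .assert(all(is.finite(timestamp)) && all(abs(lat) <= 90) &&
            all(abs(lon) <= 180), "lat/lon out of bounds")
  o <- order(timestamp)
  df <- data.frame(timestamp = timestamp[o], lat = lat[o], lon = lon[o])
  # duplicate timestamps collapse to the last fix given
  df <- df[!duplicated(df$timestamp, fromLast = TRUE), ]
  .assert(nrow(df) >= 2, "a track needs at least 2 distinct timestamps")
  structure(df, class = c("gps_track", "data.frame"))
}

#' Parse a GPS log CSV
#'
#' Reads a `timestamp,lat,lon` CSV (header required), validates every
#' row, sorts by time and collapses duplicate timestamps to the last
#' fix. Malformed or out-of-range rows are reported with their line
#' number.
#'
#' @param path CSV file path.
#' @return a [gps_track()].
#' @export
parse_gps_log <- function(path) {
  .assert(file.exists(path), "GPS log not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("timestamp", "lat", "lon") %in% names(df)),
          "%s: header must contain timestamp,lat,lon", path)
  for (cn in c("timestamp", "lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("%s: unparseable %s at line %d", path, cn, bad[1] + 1L),
           call. = FALSE)
    df[[cn]] <- v
  }
  bad <- which(abs(df$lat) > 90 | abs(df$lon) > 180)
  if (length(bad) > 0)
    stop(sprintf("%s: lat/lon out of range at line %d (lat=%g, lon=%g)",
                 path, bad[1] + 1L, df$lat[bad[1]], df$lon[bad[1]]),
         call. = FALSE)
  .assert(nrow(df) >= 2, "%s: need at least 2 fixes (got %d)", path, nrow(df))
  gps_track(df$timestamp, df$lat, df$lon)
}

#' Geo-tag tuber records against a GPS track
#'
#' Each record receives the (lat, lon) linearly interpolated between the
#' track fixes bracketing its timestamp (harvester speed is low, so no
#' smoothing is applied). Records outside
#' `[first fix - window_s, last fix + window_s]` are dropped and
#' counted; records inside the window but beyond the track ends take
#' the nearest end fix.
#'
#' @param records data.frame with a `timestamp` column (e.g. from
#'   [measure_tubers()]).
#' @param track a [gps_track()].
#' @param window_s time alignment tolerance, seconds (default 5).
#' @return list with `tagged` (records + lat/lon columns), `n_dropped`,
#'   and `n_input`.
#' @export
tag_records <- function(records, track, window_s = 5) {
  .assert(inherits(track, "gps_track") && nrow(track) >= 2,
          "track must be a gps_track with >= 2 fixes")
  .assert(is.data.frame(records) && "timestamp" %in% names(records),
          "records must be a data.frame with a timestamp column")
  t0 <- track$timestamp[1]; t1 <- track$timestamp[nrow(track)]
  keep <- records$timestamp >= t0 - window_s &
    records$timestamp <= t1 + window_s
  tagged <- records[keep, , drop = FALSE]
  if (nrow(tagged) > 0) {
    tagged$lat <- approx(track$timestamp, track$lat, tagged$timestamp,
                         rule = 2)$y
    tagged$lon <- approx(track$timestamp, track$lon, tagged$timestamp,
                         rule = 2)$y
  } else {
    tagged$lat <- numeric(0); tagged$lon <- numeric(0)
  }
  list(tagged = tagged, n_dropped = sum(!keep), n_input = nrow(records))
}

# local equirectangular projection, metres east/north of (lat0, lon0)
.EARTH_R <- 6371000
.to_local_m <- function(lat, lon, lat0, lon0) {
  list(x = .EARTH_R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
       y = .EARTH_R * (lat - lat0) * pi / 180)
}

#' Bin geo-tagged tuber records onto a field grid
#'
#' Projects records to local metres (equirectangular about the record
#' centroid — fields are far smaller than a degree, so distortion is
#' negligible), then counts records per (size band, grid cell). The
#' grid covers the bounding box of the tagged records padded by one
#' cell.
#'
#' @param tagged data.frame with `lat`, `lon` and `band` columns (the
#'   `tagged` element of [tag_records()]).
#' @param bands band labels ordering the count planes; default: the
#'   levels present in `tagged$band`.
#' @param cell_size_m grid cell size in metres (> 0).
#' @return a `geo_grid`: `counts` array (band x cell_row x cell_col,
#'   row 1 = northernmost), `bands`, `cell_size_m`, the projection
#'   `origin` (lat0, lon0) and the grid's west/south corner
#'   (`x0`, `y0`) in local metres.
#' @export
grid_bin <- function(tagged, bands = NULL, cell_size_m = 5) {
  .assert(cell_size_m > 0, "cell_size_m must be > 0")
  .assert(is.data.frame(tagged) && nrow(tagged) >= 1 &&
            all(c("lat", "lon", "band") %in% names(tagged)),
          "tagged must be a non-empty data.frame with lat, lon, band")
  if (is.null(bands)) bands <- sort(unique(as.character(tagged$band)))
  .assert(all(tagged$band %in% bands), "records contain bands not in `bands`")
  lat0 <- mean(tagged$lat); lon0 <- mean(tagged$lon)
  pm <- .to_local_m(tagged$lat, tagged$lon, lat0, lon0)
  x0 <- floor(min(pm$x) / cell_size_m - 1) * cell_size_m
  y0 <- floor(min(pm$y) / cell_size_m - 1) * cell_size_m
  ncol_ <- floor((max(pm$x) - x0) / cell_size_m) + 2L
  nrow_ <- floor((max(pm$y) - y0) / cell_size_m) + 2L
  ci <- floor((pm$x - x0) / cell_size_m) + 1L
  ryi <- floor((pm$y - y0) / cell_size_m) + 1L   # 1 = southernmost
  ri <- nrow_ - ryi + 1L                          # row 1 = northernmost
  bi <- match(as.character(tagged$band), bands)
  counts <- array(0L, c(length(bands), nrow_, ncol_),
                  dimnames = list(band = bands, NULL, NULL))
  for (k in seq_len(nrow(tagged)))
    counts[bi[k], ri[k], ci[k]] <- counts[bi[k], ri[k], ci[k]] + 1L
  structure(list(counts = counts, bands = bands, cell_size_m = cell_size_m,
                 origin = c(lat = lat0, lon = lon0), x0 = x0, y0 = y0,
                 nrow = nrow_, ncol = ncol_),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("geo_grid: %d x %d cells of %g m, %d band(s), %d record(s)\n",
              x$nrow, x$ncol, x$cell_size_m, length(x$bands), sum(x$counts)))
  for (b in seq_along(x$bands))
    cat(sprintf("  %-8s %d\n", x$bands[b], sum(x$counts[b, , ])))
  invisible(x)
}

# blue -> green -> red ramp on (0, 1]
.heat_ramp <- function(t) {
  m <- colorRamp(c("blue", "green", "red"))(pmin(pmax(t, 0), 1)) / 255
  m
}

#' Render per-band yield heat maps
#'
#' Writes one PNG heat map per size band (cells coloured on a
#' blue-green-red ramp, by default scaled to that band's own maximum
#' count; zero-count cells transparent) plus a single GeoJSON
#' FeatureCollection of cell polygons carrying the per-band counts, for
#' overlay in GIS tools.
#'
#' @param grid a [grid_bin()] result.
#' @param out_dir output directory (created if missing).
#' @param scale_px PNG pixels per grid cell.
#' @param per_band_scale scale each band's colours to its own maximum
#'   (`TRUE`, the default) or to the global maximum across bands.
#' @return invisibly, the paths written (named list: `png` vector,
#'   `geojson`).
#' @export
render_heatmaps <- function(grid, out_dir, scale_px = 12,
                            per_band_scale = TRUE) {
  .assert(inherits(grid, "geo_grid"), "grid must come from grid_bin()")
  .assert(sum(grid$counts) > 0, "grid is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gmax <- max(grid$counts)
  paths <- character(0)
  for (b in seq_along(grid$bands)) {
    cnt <- grid$counts[b, , , drop = TRUE]
    if (is.null(dim(cnt))) cnt <- matrix(cnt, grid$nrow, grid$ncol)
    mx <- if (per_band_scale) max(cnt) else gmax
    rgba <- array(0, c(grid$nrow, grid$ncol, 4))
    if (mx > 0) {
      t <- cnt / mx
      colm <- .heat_ramp(as.vector(t))
      rgba[, , 1] <- matrix(colm[, 1], grid$nrow)
      rgba[, , 2] <- matrix(colm[, 2], grid$nrow)
      rgba[, , 3] <- matrix(colm[, 3], grid$nrow)
      rgba[, , 4] <- (cnt > 0) * 1
    }
    up <- rgba[rep(seq_len(grid$nrow), each = scale_px),
               rep(seq_len(grid$ncol), each = scale_px), , drop = FALSE]
    fn <- file.path(out_dir, sprintf("heatmap_band_%s.png",
                                     gsub("[^A-Za-z0-9+-]", "_", grid$bands[b])))
    png::writePNG(up, fn)
    paths <- c(paths, fn)
  }
  gj <- .grid_geojson(grid)
  gjfn <- file.path(out_dir, "yield_grid.geojson")
  writeLines(gj, gjfn)
  invisible(list(png = paths, geojson = gjfn))
}

# GeoJSON FeatureCollection of grid cell polygons with per-band counts
.grid_geojson <- function(grid) {
  lat0 <- grid$origin[["lat"]]; lon0 <- grid$origin[["lon"]]
  to_ll <- function(x, y) {
    c(lon = lon0 + x / (.EARTH_R * cos(lat0 * pi / 180)) * 180 / pi,
      lat = lat0 + y / .EARTH_R * 180 / pi)
  }
  feats <- list()
  for (r in seq_len(grid$nrow)) {
    for (cc in seq_len(grid$ncol)) {
      tot <- sum(grid$counts[, r, cc])
      if (tot == 0) next
      # row 1 is northernmost
      ys <- grid$y0 + (grid$nrow - r) * grid$cell_size_m
      xw <- grid$x0 + (cc - 1) * grid$cell_size_m
      corners <- list(to_ll(xw, ys), to_ll(xw + grid$cell_size_m, ys),
                      to_ll(xw + grid$cell_size_m, ys + grid$cell_size_m),
                      to_ll(xw, ys + grid$cell_size_m), to_ll(xw, ys))
      props <- as.list(setNames(as.integer(grid$counts[, r, cc]),
                                paste0("count_", grid$bands)))
      props$count_total <- as.integer(tot)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(corners, unname))),
        properties = props)
    }
  }
  jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                   auto_unbox = TRUE, digits = NA)
}
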