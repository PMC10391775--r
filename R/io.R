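# Raster I/O: single-band ESRI ASCII Grid (.asc) with a .prj sidecar carrying
# the CRS identifier. Plain text, lossless for finite values (written at full
# double precision) and for the nodata mask.

.prjPath <- function(path) {
  if (grepl("\\.[A-Za-z0-9]+$", path)) sub("\\.[A-Za-z0-9]+$", ".prj", path)
  else paste0(path, ".prj")
}

#' Read / write a grid layer
#'
#' Rasters are stored as single-band ESRI ASCII Grid files with a `.prj`
#' sidecar holding the projected CRS identifier. Round-trip write-then-read
#' preserves the grid, all finite values (full double precision) and the
#' nodata mask exactly.
#'
#' @param path file path (`.asc`).
#' @return `readGridLayer` returns a [GridLayer-class]; `writeGridLayer`
#'   returns `path` invisibly.
#' @export
readGridLayer <- function(path) {
  if (!file.exists(path)) stop("no such raster: ", path)
  prj <- .prjPath(path)
  if (!file.exists(prj))
    stop("raster has no CRS: missing sidecar ", prj)
  crs <- trimws(readLines(prj, warn = FALSE)[1])
  msg <- .checkCrs(crs)
  if (!is.null(msg)) stop("raster ", path, ": ", msg)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("raster ", path, ": malformed ASCII grid header")
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("raster ", path, ": expected ", nr * nc, " cells, found ",
         length(vals), " (multi-band or truncated input)")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid <- gridSpec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                   hdr$cellsize, nr, nc, crs)
  gridLayer(grid, m)
}

#' @rdname readGridLayer
#' @param layer a [GridLayer-class].
#' @export
writeGridLayer <- function(layer, path) {
  g <- layer@grid
  v <- layer@values
  nodata <- -9999
  while (any(v == nodata, na.rm = TRUE)) nodata <- nodata * 10 - 1
  hdr <- c(sprintf("ncols %d", g@nCols),
           sprintf("nrows %d", g@nRows),
           sprintf("xllcorner %.17g", g@originX),
           sprintf("yllcorner %.17g", g@originY - g@nRows * g@cellSize),
           sprintf("cellsize %.17g", g@cellSize),
           sprintf("NODATA_value %.17g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(g@crs, .prjPath(path))
  invisible(path)
}

# ---- GeoJSON helpers -------------------------------------------------------

.geojsonCrs <- function(gj) {
  if (!is.null(gj$crs) && !is.null(gj$crs$properties$name))
    gj$crs$properties$name
  else NULL
}

.readFeatureCollection <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(path, ": not a GeoJSON FeatureCollection")
  gj
}

.coordsMatrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  storage.mode(m) <- "double"
  m
}

.featureCollection <- function(features, crs) {
  list(type = "FeatureCollection",
       crs = list(type = "name", properties = list(name = crs)),
       features = features)
}

.lineFeature <- function(m, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = "LineString",
                       coordinates = lapply(seq_len(nrow(m)),
                                            function(i) c(m[i, 1], m[i, 2]))))
}

.pointFeature <- function(x, y, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = "Point", coordinates = c(x, y)))
}

.writeGeoJSON <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a classed road network
#'
#' Accepts GeoJSON LineString features with property `road_class` (and
#' optionally `id`). Classes outside the closed set
#' primary/secondary/track/elevated_highway/water_crossing are rejected with
#' the offending feature id.
#'
#' @param path GeoJSON file.
#' @param crs CRS to assume when the file carries none.
#' @return a [RoadNetwork-class].
#' @export
readRoads <- function(path, crs = NULL) {
  gj <- .readFeatureCollection(path)
  fileCrs <- .geojsonCrs(gj)
  crs <- if (!is.null(fileCrs)) fileCrs else crs
  if (is.null(crs)) stop(path, ": no CRS in file and none supplied")
  ids <- character(); classes <- character(); geoms <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id)
          else sprintf("road_%03d", k)
    cls <- f$properties$road_class
    if (is.null(cls))
      stop("road feature '", id, "': missing road_class")
    if (!(cls %in% ROAD_CLASSES))
      stop("road feature '", id, "': unknown road_class '", cls, "'")
    if (f$geometry$type != "LineString")
      stop("road feature '", id, "': geometry must be LineString")
    ids <- c(ids, id); classes <- c(classes, cls)
    geoms <- c(geoms, list(.coordsMatrix(f$geometry$coordinates)))
  }
  roadNetwork(ids, classes, geoms, crs)
}

#' Write a road network as GeoJSON
#' @param roads a [RoadNetwork-class].
#' @param path output file.
#' @export
writeRoads <- function(roads, path) {
  feats <- lapply(seq_along(roads@ids), function(i)
    .lineFeature(roads@geometry[[i]],
                 list(id = roads@ids[i], road_class = roads@roadClass[i])))
  .writeGeoJSON(.featureCollection(feats, roads@crs), path)
}

#' Read permanent waterbodies
#'
#' GeoJSON LineString features with property `avg_width_m` (> 0).
#' @param path GeoJSON file.
#' @param crs fallback CRS.
#' @return a [WaterBodySet-class].
#' @export
readWaterbodies <- function(path, crs = NULL) {
  gj <- .readFeatureCollection(path)
  fileCrs <- .geojsonCrs(gj)
  crs <- if (!is.null(fileCrs)) fileCrs else crs
  if (is.null(crs)) stop(path, ": no CRS in file and none supplied")
  ids <- character(); widths <- numeric(); geoms <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id)
          else sprintf("wb_%03d", k)
    w <- f$properties$avg_width_m
    if (is.null(w) || !is.finite(as.numeric(w)) || as.numeric(w) <= 0)
      stop("waterbody '", id, "': avg_width_m must be a positive number")
    ids <- c(ids, id); widths <- c(widths, as.numeric(w))
    geoms <- c(geoms, list(.coordsMatrix(f$geometry$coordinates)))
  }
  waterBodySet(ids, geoms, widths, crs)
}

#' @rdname readWaterbodies
#' @param wb a [WaterBodySet-class].
#' @export
writeWaterbodies <- function(wb, path) {
  feats <- lapply(seq_along(wb@ids), function(i)
    .lineFeature(wb@geometry[[i]],
                 list(id = wb@ids[i], avg_width_m = wb@avgWidthM[i])))
  .writeGeoJSON(.featureCollection(feats, wb@crs), path)
}

#' Read a facility table
#'
#' GeoJSON Point features with boolean properties `is_delivery`, `is_emoc`,
#' `is_mws`, or CSV with columns `id,name,x,y,is_delivery,is_emoc,is_mws`.
#' Facilities with every flag false are excluded with a warning (count in
#' attribute `"excluded"`).
#'
#' @param path GeoJSON or CSV file.
#' @return validated facility data.frame (id, name, x, y, isDelivery,
#'   isEmoc, isMws).
#' @export
readFacilities <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    fac <- data.frame(id = as.character(d$id), name = as.character(d$name),
                      x = d$x, y = d$y,
                      isDelivery = as.logical(d$is_delivery),
                      isEmoc = as.logical(d$is_emoc),
                      isMws = as.logical(d$is_mws),
                      stringsAsFactors = FALSE)
  } else {
    gj <- .readFeatureCollection(path)
    fac <- do.call(rbind, lapply(seq_along(gj$features), function(k) {
      f <- gj$features[[k]]
      p <- f$properties
      data.frame(id = as.character(p$id),
                 name = if (!is.null(p$name)) as.character(p$name) else
                   as.character(p$id),
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 isDelivery = isTRUE(p$is_delivery),
                 isEmoc = isTRUE(p$is_emoc),
                 isMws = isTRUE(p$is_mws), stringsAsFactors = FALSE)
    }))
  }
  validateFacilities(fac)
}

#' @rdname readFacilities
#' @param fac facility data.frame.
#' @param crs CRS identifier recorded in GeoJSON output.
#' @export
writeFacilities <- function(fac, path, crs = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- data.frame(id = fac$id, name = fac$name, x = fac$x, y = fac$y,
                      is_delivery = fac$isDelivery, is_emoc = fac$isEmoc,
                      is_mws = fac$isMws)
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  feats <- lapply(seq_len(nrow(fac)), function(i)
    .pointFeature(fac$x[i], fac$y[i],
                  list(id = fac$id[i], name = fac$name[i],
                       is_delivery = fac$isDelivery[i],
                       is_emoc = fac$isEmoc[i], is_mws = fac$isMws[i])))
  .writeGeoJSON(.featureCollection(feats, crs), path)
}

#' Read a population point table
#'
#' GeoJSON Point features with property `women` (>= 0), or CSV with columns
#' `id,x,y,women`. Points are the centroids of populated grid cells.
#'
#' @param path GeoJSON or CSV file.
#' @return validated population data.frame (id, x, y, women).
#' @export
readPopulation <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    pop <- data.frame(id = as.character(d$id), x = d$x, y = d$y,
                      women = d$women, stringsAsFactors = FALSE)
  } else {
    gj <- .readFeatureCollection(path)
    pop <- do.call(rbind, lapply(seq_along(gj$features), function(k) {
      f <- gj$features[[k]]
      data.frame(id = as.character(f$properties$id),
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 women = as.numeric(f$properties$women),
                 stringsAsFactors = FALSE)
    }))
  }
  validatePopulation(pop)
}

#' @rdname readPopulation
#' @param pop population data.frame.
#' @param crs CRS identifier recorded in GeoJSON output.
#' @export
writePopulation <- function(pop, path, crs = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(pop[, c("id", "x", "y", "women")], path,
                     row.names = FALSE)
    return(invisible(path))
  }
  feats <- lapply(seq_len(nrow(pop)), function(i)
    .pointFeature(pop$x[i], pop$y[i],
                  list(id = pop$id[i], women = pop$women[i])))
  .writeGeoJSON(.featureCollection(feats, crs), path)
}

# ---- Raster operations -----------------------------------------------------

#' Rasterise buffered polylines onto a grid
#'
#' A cell is marked iff its centre lies within `halfWidthM` of any polyline.
#' With `halfWidthM = 0` the trace is one cell wide: centres within half a
#' cell size of the line are marked.
#'
#' @param x a [RoadNetwork-class], [WaterBodySet-class], or list of
#'   two-column coordinate matrices.
#' @param grid target [GridSpec-class] (same CRS as the geometries).
#' @param halfWidthM buffer half-width in metres (>= 0).
#' @return a [GridLayer-class] of 0/1 values.
#' @export
rasterizeLines <- function(x, grid, halfWidthM = 0) {
  geoms <- if (is(x, "RoadNetwork") || is(x, "WaterBodySet")) x@geometry
           else x
  if (halfWidthM < 0) stop("halfWidthM must be >= 0")
  r <- if (halfWidthM == 0) grid@cellSize / 2 else halfWidthM
  cc <- cellCenters(grid)
  marked <- matrix(FALSE, grid@nRows, grid@nCols)
  cx1 <- cc$x[1, ]; cy1 <- cc$y[, 1]
  for (poly in geoms) {
    # bounding-box prefilter keeps the distance test near the feature
    xr <- range(poly[, 1]) + c(-r, r) - grid@cellSize
    yr <- range(poly[, 2]) + c(-r, r) - grid@cellSize
    cols <- which(cx1 >= xr[1] - grid@cellSize & cx1 <= xr[2] + 2 * grid@cellSize)
    rows <- which(cy1 >= yr[1] - grid@cellSize & cy1 <= yr[2] + 2 * grid@cellSize)
    if (!length(cols) || !length(rows)) next
    px <- rep(cx1[cols], each = length(rows))
    py <- rep(cy1[rows], times = length(cols))
    d <- .distToPolyline(px, py, poly)
    hit <- matrix(d <= r, nrow = length(rows))
    marked[rows, cols] <- marked[rows, cols] | hit
  }
  gridLayer(grid, marked + 0)
}

#' Resample a layer to a finer (or equal) grid
#'
#' Nearest-neighbour assignment by cell-centre lookup: each target cell takes
#' the value of the source cell containing its centre. Values are only
#' copied, never interpolated, so barrier-defining quantities (flood depth)
#' are never smoothed across boundaries. Target centres outside the source
#' grid get `NA`.
#'
#' @param layer source [GridLayer-class].
#' @param targetGrid target [GridSpec-class]; same CRS, cell size <= source.
#' @return a [GridLayer-class] on `targetGrid`.
#' @export
resampleToGrid <- function(layer, targetGrid) {
  src <- layer@grid
  if (src@crs != targetGrid@crs)
    stop("CRS mismatch: source ", src@crs, " vs target ", targetGrid@crs)
  if (targetGrid@cellSize > src@cellSize + 1e-9)
    stop("target grid must be finer than or equal to the source grid")
  if (gridAligned(src, targetGrid)) return(gridLayer(targetGrid, layer@values))
  cx <- targetGrid@originX + (seq_len(targetGrid@nCols) - 0.5) * targetGrid@cellSize
  cy <- targetGrid@originY - (seq_len(targetGrid@nRows) - 0.5) * targetGrid@cellSize
  colIdx <- floor((cx - src@originX) / src@cellSize) + 1L
  rowIdx <- floor((src@originY - cy) / src@cellSize) + 1L
  colOk <- colIdx >= 1L & colIdx <= src@nCols & cx >= src@originX
  rowOk <- rowIdx >= 1L & rowIdx <= src@nRows & cy <= src@originY
  out <- matrix(NA_real_, targetGrid@nRows, targetGrid@nCols)
  if (any(rowOk) && any(colOk)) {
    ri <- rowIdx[rowOk]; ci <- colIdx[colOk]
    out[rowOk, colOk] <- layer@values[ri, ci, drop = FALSE]
  }
  gridLayer(targetGrid, out)
}
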