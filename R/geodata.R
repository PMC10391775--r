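#' Construct a GridSpec
#'
#' @param originX,originY map coordinates of the north-west grid corner (m).
#' @param cellSize cell edge length (m).
#' @param nRows,nCols grid dimensions.
#' @param crs projected CRS identifier (e.g. `"EPSG:32735"`).
#' @return a [GridSpec-class].
#' @examples
#' gridSpec(0, 1000, 50, 20, 30, "EPSG:32735")
#' @export
gridSpec <- function(originX, originY, cellSize, nRows, nCols, crs) {
  new("GridSpec", originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), nRows = as.integer(nRows),
      nCols = as.integer(nCols), crs = as.character(crs))
}

#' Construct a GridLayer
#'
#' @param grid a [GridSpec-class].
#' @param values numeric matrix (`nRows x nCols`), `NA` = nodata.
#' @return a [GridLayer-class].
#' @export
gridLayer <- function(grid, values) {
  storage.mode(values) <- "double"
  new("GridLayer", grid = grid, values = values)
}

#' Are two grids aligned?
#'
#' Two grids are aligned iff every field (origin, cell size, shape, CRS) is
#' equal.
#' @param a,b [GridSpec-class] objects.
#' @return logical.
#' @export
gridAligned <- function(a, b) {
  isTRUE(a@originX == b@originX && a@originY == b@originY &&
         a@cellSize == b@cellSize && a@nRows == b@nRows &&
         a@nCols == b@nCols && a@crs == b@crs)
}

#' Cell centre coordinates
#'
#' @param grid a [GridSpec-class].
#' @return list with matrices `x` and `y` of cell-centre coordinates.
#' @export
cellCenters <- function(grid) {
  cx <- grid@originX + (seq_len(grid@nCols) - 0.5) * grid@cellSize
  cy <- grid@originY - (seq_len(grid@nRows) - 0.5) * grid@cellSize
  list(x = matrix(cx, grid@nRows, grid@nCols, byrow = TRUE),
       y = matrix(cy, grid@nRows, grid@nCols))
}

#' Locate points on a grid
#'
#' Maps map coordinates to (row, col) under the half-open cell ownership
#' convention \code{[x0, x0+cs) x (y0-cs, y0]} with row 1 the northern edge.
#' Points outside the grid get `NA`.
#'
#' @param grid a [GridSpec-class].
#' @param x,y coordinate vectors.
#' @return data.frame with columns `row`, `col` (`NA` outside the grid).
#' @export
pointToCell <- function(grid, x, y) {
  cs <- grid@cellSize
  col <- floor((x - grid@originX) / cs) + 1L
  row <- floor((grid@originY - y) / cs) + 1L
  outside <- x < grid@originX | col > grid@nCols |
    y > grid@originY | row > grid@nRows | row < 1L
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec %d x %d @ %g m, origin (%g, %g), crs %s\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, object@crs))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  cat(sprintf("%s %d x %d @ %g m [%s]\n", class(object),
              object@grid@nRows, object@grid@nCols, object@grid@cellSize,
              object@grid@crs))
  fin <- v[!is.na(v)]
  cat(sprintf("  values: %d nodata; range of valid: [%g, %g]\n",
              sum(is.na(v)),
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
})

setMethod("show", "MonthlyFloodField", function(object) {
  d <- object@depth@values
  cat(sprintf("MonthlyFloodField %s: mean depth %.3f m, max %.3f m, wet cells %d\n",
              object@month, mean(d, na.rm = TRUE), max(d, na.rm = TRUE),
              sum(d > 0, na.rm = TRUE)))
})

setMethod("show", "RoadNetwork", function(object) {
  cat(sprintf("RoadNetwork: %d segments [%s]\n", length(object@ids), object@crs))
  print(table(object@roadClass))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d months, %d road segments, %d facilities, %d population points (%d women)\n",
              length(object@floods), length(object@roads@ids),
              nrow(object@facilities), nrow(object@population),
              sum(object@population$women)))
})

#' Accessors
#'
#' `layerValues` returns the value matrix of a grid layer; `layerGrid` its
#' [GridSpec-class]; `segmentLengths` the per-segment polyline lengths (m);
#' `roadClasses` the per-segment class labels; `segmentIds` the segment ids.
#'
#' @param x a package object.
#' @return see description.
#' @name accessors
#' @export
layerValues <- function(x) x@values

#' @rdname accessors
#' @export
layerGrid <- function(x) x@grid

#' @rdname accessors
#' @export
segmentIds <- function(x) x@ids

#' @rdname accessors
#' @export
roadClasses <- function(x) x@roadClass

#' @rdname accessors
#' @export
segmentLengths <- function(x) {
  vapply(x@geometry, .polylineLength, numeric(1))
}

#' Construct a RoadNetwork
#'
#' @param ids segment ids.
#' @param roadClass per-segment class, drawn from the closed set
#'   primary/secondary/track/elevated_highway/water_crossing.
#' @param geometry list of two-column coordinate matrices.
#' @param crs projected CRS identifier.
#' @return a [RoadNetwork-class].
#' @export
roadNetwork <- function(ids, roadClass, geometry, crs) {
  geometry <- lapply(geometry, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
  })
  new("RoadNetwork", ids = as.character(ids), roadClass = as.character(roadClass),
      geometry = geometry, crs = crs)
}

#' Construct a WaterBodySet
#'
#' @param ids waterbody ids.
#' @param geometry list of two-column coordinate matrices (centrelines).
#' @param avgWidthM average width (m) per waterbody.
#' @param crs projected CRS identifier.
#' @return a [WaterBodySet-class].
#' @export
waterBodySet <- function(ids, geometry, avgWidthM, crs) {
  geometry <- lapply(geometry, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
  })
  new("WaterBodySet", ids = as.character(ids), geometry = geometry,
      avgWidthM = as.numeric(avgWidthM), crs = crs)
}

#' Validate a facility table
#'
#' Enforces the facility contract: logical service flags, at least one flag
#' per facility. Facilities with all flags false are excluded with a warning;
#' the number excluded is attached as attribute `"excluded"`.
#'
#' @param fac data.frame with columns id, name, x, y, isDelivery, isEmoc,
#'   isMws.
#' @return the validated (possibly reduced) data.frame.
#' @export
validateFacilities <- function(fac) {
  need <- c("id", "name", "x", "y", "isDelivery", "isEmoc", "isMws")
  miss <- setdiff(need, names(fac))
  if (length(miss))
    stop("facility table missing columns: ", paste(miss, collapse = ", "))
  fac$id <- as.character(fac$id)
  for (f in c("isDelivery", "isEmoc", "isMws")) fac[[f]] <- as.logical(fac[[f]])
  if (anyDuplicated(fac$id)) stop("duplicate facility ids")
  none <- !(fac$isDelivery | fac$isEmoc | fac$isMws)
  if (any(none)) {
    warning(sprintf("excluding %d facilit%s with no service flag: %s",
                    sum(none), if (sum(none) == 1) "y" else "ies",
                    paste(fac$id[none], collapse = ", ")))
    fac <- fac[!none, , drop = FALSE]
  }
  attr(fac, "excluded") <- sum(none)
  rownames(fac) <- NULL
  fac
}

#' Validate a population table
#'
#' @param pop data.frame with columns id, x, y, women (women >= 0).
#' @return the validated data.frame.
#' @export
validatePopulation <- function(pop) {
  need <- c("id", "x", "y", "women")
  miss <- setdiff(need, names(pop))
  if (length(miss))
    stop("population table missing columns: ", paste(miss, collapse = ", "))
  pop$id <- as.character(pop$id)
  pop$women <- as.numeric(pop$women)
  bad <- which(!is.finite(pop$women) | pop$women < 0)
  if (length(bad))
    stop("negative or non-finite women count for points: ",
         paste(pop$id[bad], collapse = ", "))
  rownames(pop) <- NULL
  pop
}
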