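#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib floodAccess, .registration = TRUE
NULL

ROAD_CLASSES <- c("primary", "secondary", "track", "elevated_highway",
                  "water_crossing")

SERVICE_CLASSES <- c("delivery", "emoc", "mws", "any")

ROAD_STATES <- c("dry", "wet", "flooded", "deeply_flooded", "impassable")

ACCESS_BINS <- c("<=60 min", "61-120 min", ">120 min", "unreachable")

REFERRAL_CATEGORIES <- c("no_delivery_access", "site_cannot_refer",
                         "referral_late", "referral_timely")

# geographic (degree-unit) CRS identifiers are rejected everywhere: the model
# works in metres and never reprojects
.isGeographicCrs <- function(crs) {
  grepl("(^|:)4326$|(^|:)4269$|longlat|latlong|degree|CRS84", crs,
        ignore.case = TRUE)
}

.checkCrs <- function(crs) {
  if (length(crs) != 1L || is.na(crs) || !nzchar(crs))
    return("crs must be a single non-empty string")
  if (.isGeographicCrs(crs))
    return(sprintf("geographic (degree) CRS '%s' not supported; use a projected metric CRS", crs))
  NULL
}

#' GridSpec: geometry of a regular raster grid
#'
#' Describes a north-up regular grid in a projected metric CRS. `originX`,
#' `originY` are the map coordinates of the grid's north-west corner; row 1 is
#' the northern row. A point belongs to the cell containing it under the
#' half-open convention \code{[x0, x0+cs) x (y0-cs, y0]}.
#'
#' @slot originX,originY north-west corner, metres.
#' @slot cellSize cell edge length, metres (> 0).
#' @slot nRows,nCols grid dimensions (>= 1).
#' @slot crs CRS identifier string (projected; geographic CRS rejected).
#' @export
setClass("GridSpec",
  representation(originX = "numeric", originY = "numeric",
                 cellSize = "numeric", nRows = "integer", nCols = "integer",
                 crs = "character"))

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msgs <- c(msgs, "nRows must be >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msgs <- c(msgs, "nCols must be >= 1")
  msgs <- c(msgs, .checkCrs(object@crs))
  if (length(msgs)) msgs else TRUE
})

#' GridLayer: a single-band raster
#'
#' A numeric matrix tied to a [GridSpec-class]. `NA` is the nodata sentinel;
#' its meaning (impassable, unreachable, no data) is layer semantics.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix, `nRows x nCols`; `NA` = nodata.
#' @export
setClass("GridLayer",
  representation(grid = "GridSpec", values = "matrix"))

setValidity("GridLayer", function(object) {
  g <- object@grid
  v <- object@values
  if (!is.numeric(v) && !is.logical(v))
    return("values must be a numeric or logical matrix")
  if (nrow(v) != g@nRows || ncol(v) != g@nCols)
    return(sprintf("values is %dx%d but grid is %dx%d",
                   nrow(v), ncol(v), g@nRows, g@nCols))
  TRUE
})

#' MonthlyFloodField: depth and velocity rasters for one month
#'
#' @slot month month label, e.g. `"2018-03"`.
#' @slot depth floodwater depth (m), a [GridLayer-class].
#' @slot velocity floodwater velocity (m s^-1), aligned with `depth`.
#' @export
setClass("MonthlyFloodField",
  representation(month = "character", depth = "GridLayer",
                 velocity = "GridLayer"))

setValidity("MonthlyFloodField", function(object) {
  msgs <- character()
  if (length(object@month) != 1L || !nzchar(object@month))
    msgs <- c(msgs, "month must be a single non-empty label")
  if (!gridAligned(object@depth@grid, object@velocity@grid))
    msgs <- c(msgs, "depth and velocity grids are not aligned")
  d <- object@depth@values; v <- object@velocity@values
  if (any(d < 0, na.rm = TRUE)) msgs <- c(msgs, "negative flood depth")
  if (any(v < 0, na.rm = TRUE)) msgs <- c(msgs, "negative flood velocity")
  if (length(msgs)) msgs else TRUE
})

#' ImpedanceSurface: per-cell walking traversal time
#'
#' A [GridLayer-class] whose values are walking traversal times in seconds
#' per metre; `NA` marks impassable cells (permanent water, floodwater above
#' the walking depth limit), which are excluded from all routing.
#' @export
setClass("ImpedanceSurface", contains = "GridLayer")

setValidity("ImpedanceSurface", function(object) {
  if (any(object@values <= 0, na.rm = TRUE))
    return("tau must be > 0 on passable cells")
  TRUE
})

#' CostSurface: accumulated travel time to the nearest source
#'
#' Per-cell minimum walking time (seconds) from a source set of facilities,
#' with the id of the facility attaining the minimum. `NA` seconds =
#' unreachable.
#'
#' @slot grid the [GridSpec-class].
#' @slot seconds numeric matrix of accumulated times; 0 at source cells.
#' @slot nearestIndex integer matrix indexing into `sourceIds`; `NA` where
#'   unreachable.
#' @slot sourceIds facility ids of the sources, sorted lexicographically
#'   (ties for nearest are broken toward the lexicographically smaller id).
#' @slot serviceClass one of `"delivery"`, `"emoc"`, `"mws"`, `"any"`.
#' @slot droppedSources ids of facilities dropped because their cell was
#'   impassable in the month's surface.
#' @export
setClass("CostSurface",
  representation(grid = "GridSpec", seconds = "matrix",
                 nearestIndex = "matrix", sourceIds = "character",
                 serviceClass = "character", droppedSources = "character"))

setValidity("CostSurface", function(object) {
  g <- object@grid
  if (nrow(object@seconds) != g@nRows || ncol(object@seconds) != g@nCols)
    return("seconds matrix does not match grid")
  if (!identical(dim(object@seconds), dim(object@nearestIndex)))
    return("seconds and nearestIndex differ in shape")
  if (any(object@seconds < 0, na.rm = TRUE))
    return("negative accumulated time")
  fin <- !is.na(object@seconds)
  if (any(fin & is.na(object@nearestIndex)))
    return("nearestIndex undefined on a reachable cell")
  if (!(length(object@serviceClass) == 1L &&
        object@serviceClass %in% SERVICE_CLASSES))
    return("serviceClass must be one of delivery/emoc/mws/any")
  TRUE
})

#' RoadNetwork: classed road polylines
#'
#' @slot ids segment ids (unique).
#' @slot roadClass one of primary, secondary, track, elevated_highway,
#'   water_crossing per segment.
#' @slot geometry list of two-column coordinate matrices (>= 2 vertices).
#' @slot crs CRS identifier.
#' @export
setClass("RoadNetwork",
  representation(ids = "character", roadClass = "character",
                 geometry = "list", crs = "character"))

setValidity("RoadNetwork", function(object) {
  n <- length(object@ids)
  if (length(object@roadClass) != n || length(object@geometry) != n)
    return("ids, roadClass and geometry lengths differ")
  if (anyDuplicated(object@ids))
    return("duplicate segment ids")
  bad <- setdiff(unique(object@roadClass), ROAD_CLASSES)
  if (length(bad))
    return(sprintf("unknown road_class: %s", paste(bad, collapse = ", ")))
  for (i in seq_len(n)) {
    m <- object@geometry[[i]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 2L)
      return(sprintf("segment '%s': polyline needs >= 2 coordinate pairs",
                     object@ids[i]))
  }
  msgs <- .checkCrs(object@crs)
  if (length(msgs)) msgs else TRUE
})

#' WaterBodySet: permanent waterbody centrelines with average widths
#'
#' @slot ids waterbody ids.
#' @slot geometry list of two-column coordinate matrices.
#' @slot avgWidthM average width (m, > 0) per waterbody; the barrier buffer
#'   is half this width either side of the centreline.
#' @slot crs CRS identifier.
#' @export
setClass("WaterBodySet",
  representation(ids = "character", geometry = "list",
                 avgWidthM = "numeric", crs = "character"))

setValidity("WaterBodySet", function(object) {
  n <- length(object@ids)
  if (length(object@geometry) != n || length(object@avgWidthM) != n)
    return("ids, geometry and avgWidthM lengths differ")
  if (any(!is.finite(object@avgWidthM)) || any(object@avgWidthM <= 0))
    return("avgWidthM must be > 0")
  msgs <- .checkCrs(object@crs)
  if (length(msgs)) msgs else TRUE
})

#' SpeedRules: road speeds under flood states, with hazard thresholds
#'
#' Per-road-class driving speeds (km h^-1) in the dry, wet, flooded and
#' deeply-flooded states, plus the depth/velocity thresholds separating the
#' states. Classes in `exempt` (the elevated causeway) always drive at their
#' dry speed. A segment is impassable when max depth >= `dMax` or max
#' velocity >= `vMax`.
#'
#' @slot speeds data.frame with columns roadClass, dry, wet, flooded,
#'   deeplyFlooded.
#' @slot dWet,dFlooded,dMax depth thresholds (m), strictly increasing.
#' @slot vMax velocity threshold (m s^-1).
#' @slot exempt road classes exempt from flood rules.
#' @export
setClass("SpeedRules",
  representation(speeds = "data.frame", dWet = "numeric",
                 dFlooded = "numeric", dMax = "numeric", vMax = "numeric",
                 exempt = "character"))

setValidity("SpeedRules", function(object) {
  sp <- object@speeds
  need <- c("roadClass", "dry", "wet", "flooded", "deeplyFlooded")
  if (!all(need %in% names(sp)))
    return("speeds must have columns roadClass, dry, wet, flooded, deeplyFlooded")
  nonex <- !(sp$roadClass %in% object@exempt)
  if (any(sp$dry[nonex] < sp$wet[nonex]))
    return("dry speed must be >= wet speed for non-exempt classes")
  if (!(object@dWet < object@dFlooded && object@dFlooded < object@dMax))
    return("depth thresholds must be strictly increasing")
  if (object@vMax <= 0) return("vMax must be > 0")
  TRUE
})

#' FloodedRoadNetwork: a road network with monthly flood states
#'
#' @slot network the underlying [RoadNetwork-class].
#' @slot month month label.
#' @slot state per-segment state (dry/wet/flooded/deeply_flooded/impassable).
#' @slot speedKmh per-segment effective speed; 0 iff impassable.
#' @slot samples data.frame (id, maxDepth, maxVelocity, nSamples).
#' @export
setClass("FloodedRoadNetwork",
  representation(network = "RoadNetwork", month = "character",
                 state = "character", speedKmh = "numeric",
                 samples = "data.frame"))

setValidity("FloodedRoadNetwork", function(object) {
  n <- length(object@network@ids)
  if (length(object@state) != n || length(object@speedKmh) != n)
    return("state/speed length does not match network")
  bad <- setdiff(unique(object@state), ROAD_STATES)
  if (length(bad)) return(sprintf("unknown state: %s", paste(bad, collapse = ", ")))
  imp <- object@state == "impassable"
  if (any(xor(imp, object@speedKmh == 0)))
    return("impassable <-> speed 0 violated")
  TRUE
})

#' RoutingGraph: the monthly driving graph
#'
#' Nodes are split-segment endpoints and intersections plus one node per
#' snapped facility (the facility-road connector contributes zero minutes);
#' edge weights are driving minutes. Impassable segments are removed before
#' the graph is built.
#'
#' @slot graph an igraph object with edge attribute `minutes`.
#' @slot month month label.
#' @slot facilityNode named integer: graph vertex per snapped facility id.
#' @slot disconnected ids of facilities beyond snap tolerance this month.
#' @slot snapToleranceM snap tolerance used (m).
#' @export
setClass("RoutingGraph",
  representation(graph = "ANY", month = "character",
                 facilityNode = "integer", disconnected = "character",
                 snapToleranceM = "numeric"))

#' SyntheticScene: a complete generated study scene
#'
#' @slot floods list of [MonthlyFloodField-class] (13 months).
#' @slot roads a [RoadNetwork-class].
#' @slot waterbodies a [WaterBodySet-class].
#' @slot facilities facility table (id, name, x, y, isDelivery, isEmoc, isMws).
#' @slot population population table (id, x, y, women).
#' @slot config the generating configuration (list, includes the seed).
#' @export
setClass("SyntheticScene",
  representation(floods = "list", roads = "RoadNetwork",
                 waterbodies = "WaterBodySet", facilities = "data.frame",
                 population = "data.frame", config = "list"))
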