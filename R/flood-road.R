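#' Default flood speed rules for the road network
#'
#' Driving speeds (km h^-1) per road class under the flood states, with the
#' vehicular-stability thresholds: a segment is wet when 0 < depth <= 0.01 m,
#' flooded when 0.01 < depth < 0.1 m, deeply flooded when 0.1 <= depth
#' < 0.5 m, and impassable when depth >= 0.5 m or velocity >= 1.0 m s^-1.
#' The elevated highway (causeway) is exempt and always drives at its dry
#' speed. Every entry is overridable.
#'
#' @param speeds data.frame of per-class speeds (columns roadClass, dry, wet,
#'   flooded, deeplyFlooded).
#' @param dWet,dFlooded,dMax depth thresholds (m).
#' @param vMax velocity threshold (m s^-1).
#' @param exempt classes exempt from flood rules.
#' @return a [SpeedRules-class].
#' @note The printed wet speed for water crossings (5 km h^-1) is below
#'   their flooded speed (8 km h^-1); kept as published.
#' @export
speedRules <- function(speeds = NULL, dWet = 0.01, dFlooded = 0.1,
                       dMax = 0.5, vMax = 1.0,
                       exempt = "elevated_highway") {
  if (is.null(speeds))
    speeds <- data.frame(
      roadClass = c("primary", "secondary", "track", "elevated_highway",
                    "water_crossing"),
      dry = c(80, 50, 30, 120, 15),
      wet = c(26.7, 16.7, 10, NA, 5),
      flooded = c(8, 8, 8, NA, 8),
      deeplyFlooded = c(5, 5, 5, NA, 5),
      stringsAsFactors = FALSE)
  new("SpeedRules", speeds = speeds, dWet = dWet, dFlooded = dFlooded,
      dMax = dMax, vMax = vMax, exempt = exempt)
}

#' Sample flood depth and velocity along a road segment
#'
#' The polyline is sampled at points spaced at most half the flood cell size
#' apart (endpoints included); the maxima over all sample points are
#' returned. Sample points outside the flood grid are treated as depth 0.
#'
#' @param geometry two-column coordinate matrix of the segment polyline.
#' @param flood a [MonthlyFloodField-class].
#' @return list with `maxDepth` (m), `maxVelocity` (m s^-1), `nSamples`.
#' @export
sampleSegmentFlood <- function(geometry, flood) {
  grid <- flood@depth@grid
  spacing <- grid@cellSize / 2
  pts <- .densifyPolyline(geometry, spacing)
  cells <- pointToCell(grid, pts[, 1], pts[, 2])
  ok <- !is.na(cells$row)
  d <- rep(0, nrow(pts)); v <- rep(0, nrow(pts))
  if (any(ok)) {
    idx <- cbind(cells$row[ok], cells$col[ok])
    dd <- flood@depth@values[idx]; vv <- flood@velocity@values[idx]
    d[ok] <- ifelse(is.na(dd), 0, dd)
    v[ok] <- ifelse(is.na(vv), 0, vv)
  }
  list(maxDepth = max(d), maxVelocity = max(v), nSamples = nrow(pts))
}

# Points along a polyline at most `spacing` apart, endpoints and vertices
# included.
.densifyPolyline <- function(m, spacing) {
  out <- list(m[1, , drop = FALSE])
  for (i in seq_len(nrow(m) - 1L)) {
    a <- m[i, ]; b <- m[i + 1L, ]
    L <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(L / spacing))
    t <- seq_len(k) / k
    out[[length(out) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                     a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Classify a segment's flood state and effective speed
#'
#' Applies the conditional speed rules: the elevated highway is always dry at
#' its dry speed; otherwise depth >= `dMax` or velocity >= `vMax` means
#' impassable (speed 0), then decreasing depth maps to deeply_flooded
#' (depth >= `dFlooded`), flooded (depth > `dWet`), wet (depth > 0) and dry.
#'
#' @param sample a [sampleSegmentFlood()] result (or list with `maxDepth`,
#'   `maxVelocity`).
#' @param roadClass the segment's class.
#' @param rules a [SpeedRules-class].
#' @return list with `state` and `speedKmh`.
#' @export
classifySegment <- function(sample, roadClass, rules = speedRules()) {
  row <- match(roadClass, rules@speeds$roadClass)
  if (is.na(row)) stop("unknown road class '", roadClass, "'")
  sp <- rules@speeds[row, ]
  if (roadClass %in% rules@exempt)
    return(list(state = "dry", speedKmh = sp$dry))
  d <- sample$maxDepth; v <- sample$maxVelocity
  if (d >= rules@dMax || v >= rules@vMax)
    list(state = "impassable", speedKmh = 0)
  else if (d >= rules@dFlooded)
    list(state = "deeply_flooded", speedKmh = sp$deeplyFlooded)
  else if (d > rules@dWet)
    list(state = "flooded", speedKmh = sp$flooded)
  else if (d > 0)
    list(state = "wet", speedKmh = sp$wet)
  else
    list(state = "dry", speedKmh = sp$dry)
}

#' Apply a month's flood field to the road network
#'
#' Samples every segment against the flood depth/velocity rasters and
#' classifies it under the speed rules.
#'
#' @param roads a [RoadNetwork-class].
#' @param flood a [MonthlyFloodField-class], or `NULL` for the dry network.
#' @param rules a [SpeedRules-class].
#' @return a [FloodedRoadNetwork-class].
#' @export
applyFloodToNetwork <- function(roads, flood = NULL, rules = speedRules()) {
  n <- length(roads@ids)
  state <- character(n); speed <- numeric(n)
  md <- numeric(n); mv <- numeric(n); ns <- integer(n)
  for (i in seq_len(n)) {
    s <- if (is.null(flood)) list(maxDepth = 0, maxVelocity = 0, nSamples = 0L)
         else sampleSegmentFlood(roads@geometry[[i]], flood)
    cl <- classifySegment(s, roads@roadClass[i], rules)
    state[i] <- cl$state; speed[i] <- cl$speedKmh
    md[i] <- s$maxDepth; mv[i] <- s$maxVelocity; ns[i] <- s$nSamples
  }
  new("FloodedRoadNetwork", network = roads,
      month = if (is.null(flood)) "dry" else flood@month,
      state = state, speedKmh = speed,
      samples = data.frame(id = roads@ids, maxDepth = md, maxVelocity = mv,
                           nSamples = ns, stringsAsFactors = FALSE))
}

setMethod("show", "FloodedRoadNetwork", function(object) {
  cat(sprintf("FloodedRoadNetwork %s: %d segments\n", object@month,
              length(object@state)))
  print(table(factor(object@state, levels = ROAD_STATES)))
})
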