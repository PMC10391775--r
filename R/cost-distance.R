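#' Build a facility source set for a service class
#'
#' Selects facilities offering the requested service, locates them on the
#' impedance grid, and drops (with a report) any facility whose cell is
#' impassable in the month's surface or which lies outside the grid. Sources
#' are sorted lexicographically by id so nearest-facility ties resolve
#' deterministically.
#'
#' @param facilities validated facility table.
#' @param serviceClass `"delivery"`, `"emoc"`, `"mws"`, or `"any"` (any
#'   facility regardless of service).
#' @param surface the month's [ImpedanceSurface-class].
#' @return list with `ids`, `row`, `col` (valid sources) and `dropped`
#'   (ids sited on impassable or out-of-grid cells).
#' @export
sourceSet <- function(facilities, serviceClass, surface) {
  serviceClass <- match.arg(serviceClass, SERVICE_CLASSES)
  keep <- switch(serviceClass,
                 delivery = facilities$isDelivery,
                 emoc = facilities$isEmoc,
                 mws = facilities$isMws,
                 any = rep(TRUE, nrow(facilities)))
  fac <- facilities[keep, , drop = FALSE]
  fac <- fac[order(fac$id), , drop = FALSE]
  cells <- pointToCell(surface@grid, fac$x, fac$y)
  ok <- !is.na(cells$row)
  passable <- rep(FALSE, nrow(fac))
  passable[ok] <- !is.na(surface@values[cbind(cells$row[ok], cells$col[ok])])
  list(ids = fac$id[passable],
       row = cells$row[passable], col = cells$col[passable],
       dropped = fac$id[!passable],
       serviceClass = serviceClass)
}

#' Accumulated-cost surface from a source set
#'
#' Exact multi-source shortest paths over the grid move graph with
#' 16-neighbour connectivity: 4 orthogonal, 4 diagonal and 8 knight moves.
#' The cost of a move between adjacent cells a and b is
#' `L * (tau_a + tau_b) / 2` with `L = cellSize * {1, sqrt(2), sqrt(5)}`.
#' Knight moves are admissible only when both interior cells crossed by the
#' straight centre-to-centre segment are passable, so one-cell-wide barriers
#' cannot be tunnelled through. Impassable cells have no incident moves.
#'
#' @param surface an [ImpedanceSurface-class].
#' @param sources a [sourceSet()] list (>= 1 valid source).
#' @return a [CostSurface-class]: seconds from the nearest source (0 at
#'   source cells, `NA` unreachable) and the id of that source per cell.
#' @export
accumulateCost <- function(surface, sources) {
  if (length(sources$ids) == 0L) stop("no reachable sources")
  res <- .gridCostDijkstra(surface@values, surface@grid@cellSize,
                           as.integer(sources$row), as.integer(sources$col))
  new("CostSurface", grid = surface@grid, seconds = res$seconds,
      nearestIndex = res$nearest, sourceIds = sources$ids,
      serviceClass = sources$serviceClass,
      droppedSources = sources$dropped)
}

# All-unreachable surface for months in which every facility of a class sits
# on an impassable cell (deep-flood months); keeps the 13-month loop total.
.unreachableCostSurface <- function(grid, sources) {
  nr <- grid@nRows; nc <- grid@nCols
  new("CostSurface", grid = grid,
      seconds = matrix(NA_real_, nr, nc),
      nearestIndex = matrix(NA_integer_, nr, nc),
      sourceIds = character(), serviceClass = sources$serviceClass,
      droppedSources = sources$dropped)
}

#' Sample accumulated times at points
#'
#' Each point takes the value of its containing cell. Points on impassable or
#' disconnected cells are reported unreachable; points outside the grid get a
#' per-point error entry (the run continues).
#'
#' @param cost a [CostSurface-class].
#' @param points data.frame with columns id, x, y (e.g. a population table).
#' @return data.frame (id, seconds, nearestFacility, status) where status is
#'   `"ok"`, `"unreachable"` or `"out_of_bounds"`.
#' @export
sampleTimes <- function(cost, points) {
  cells <- pointToCell(cost@grid, points$x, points$y)
  n <- nrow(points)
  seconds <- rep(NA_real_, n)
  nearest <- rep(NA_character_, n)
  status <- rep("out_of_bounds", n)
  ok <- !is.na(cells$row)
  idx <- cbind(cells$row[ok], cells$col[ok])
  s <- cost@seconds[idx]
  lab <- cost@nearestIndex[idx]
  seconds[ok] <- s
  nearest[ok][!is.na(lab)] <- cost@sourceIds[lab[!is.na(lab)]]
  status[ok] <- ifelse(is.na(s), "unreachable", "ok")
  data.frame(id = as.character(points$id), seconds = seconds,
             nearestFacility = nearest, status = status,
             stringsAsFactors = FALSE)
}

#' Classify walking times against the 2-hour threshold
#'
#' Bins: `<=60 min`, `61-120 min` (timely access ends at an inclusive
#' 2 hours: 7200 s is timely), `>120 min`, `unreachable` (`NA` input).
#'
#' @param seconds numeric vector of walking times (`NA` = unreachable).
#' @return factor with levels `<=60 min`, `61-120 min`, `>120 min`,
#'   `unreachable`.
#' @export
classifyThreshold <- function(seconds) {
  if (any(seconds < 0, na.rm = TRUE)) stop("negative travel time")
  bin <- ifelse(is.na(seconds), "unreachable",
         ifelse(seconds <= 3600, "<=60 min",
         ifelse(seconds <= 7200, "61-120 min", ">120 min")))
  factor(bin, levels = ACCESS_BINS)
}

setMethod("show", "CostSurface", function(object) {
  fin <- object@seconds[!is.na(object@seconds)]
  cat(sprintf("CostSurface [%s]: %d sources (%d dropped), %d/%d cells reachable\n",
              object@serviceClass, length(object@sourceIds),
              length(object@droppedSources), length(fin),
              length(object@seconds)))
  if (length(fin))
    cat(sprintf("  minutes: median %.1f, max %.1f\n",
                stats::median(fin) / 60, max(fin) / 60))
})
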