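# Independent oracles and small fixture builders shared across the suite.

testGrid <- function(nRows, nCols, cellSize = 10, crs = "EPSG:32735") {
  gridSpec(0, nRows * cellSize, cellSize, nRows, nCols, crs)
}

uniformSurface <- function(nRows, nCols, tau = 1.2, cellSize = 10) {
  new("ImpedanceSurface", grid = testGrid(nRows, nCols, cellSize),
      values = matrix(tau, nRows, nCols))
}

surfaceFrom <- function(tauMatrix, cellSize = 10) {
  new("ImpedanceSurface",
      grid = testGrid(nrow(tauMatrix), ncol(tauMatrix), cellSize),
      values = tauMatrix)
}

srcList <- function(row, col, ids = sprintf("s%02d", seq_along(row)),
                    serviceClass = "any") {
  o <- order(ids)
  list(ids = ids[o], row = row[o], col = col[o], dropped = character(0),
       serviceClass = serviceClass)
}

floodField <- function(grid, depth, velocity = NULL, month = "2018-03") {
  if (is.null(velocity)) velocity <- depth * 0
  new("MonthlyFloodField", month = month,
      depth = gridLayer(grid, depth), velocity = gridLayer(grid, velocity))
}

# Oracle for the 16-neighbour accumulated-cost problem: builds the move graph
# explicitly (vectorised shifts, independent of the package's C++ engine) and
# runs igraph Dijkstra from the sources. Returns the per-cell minimum over
# sources as a matrix (NA = unreachable).
oracleAccumulatedCost <- function(tau, cellSize, srcRow, srcCol) {
  nr <- nrow(tau); nc <- ncol(tau)
  cellId <- function(r, c) (c - 1L) * nr + r
  moves <- list(
    c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1),
    c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)), c(1, -1, sqrt(2)), c(1, 1, sqrt(2)),
    c(-1, -2, sqrt(5)), c(-1, 2, sqrt(5)), c(1, -2, sqrt(5)), c(1, 2, sqrt(5)),
    c(-2, -1, sqrt(5)), c(-2, 1, sqrt(5)), c(2, -1, sqrt(5)), c(2, 1, sqrt(5)))
  edges <- list()
  for (mv in moves) {
    dr <- mv[1]; dc <- mv[2]; len <- mv[3] * cellSize
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    R1 <- rep(r1, times = length(c1)); C1 <- rep(c1, each = length(r1))
    R2 <- R1 + dr; C2 <- C1 + dc
    ok <- !is.na(tau[cbind(R1, C1)]) & !is.na(tau[cbind(R2, C2)])
    if (abs(dr) + abs(dc) == 3) {
      # knight: both crossed interior cells must be passable
      if (abs(dc) == 2) {
        i1 <- cbind(R1, C1 + sign(dc)); i2 <- cbind(R1 + sign(dr), C1 + sign(dc))
      } else {
        i1 <- cbind(R1 + sign(dr), C1); i2 <- cbind(R1 + sign(dr), C1 + sign(dc))
      }
      ok <- ok & !is.na(tau[i1]) & !is.na(tau[i2])
    }
    if (!any(ok)) next
    w <- len * (tau[cbind(R1, C1)[ok, , drop = FALSE]] +
                tau[cbind(R2, C2)[ok, , drop = FALSE]]) / 2
    edges[[length(edges) + 1L]] <-
      data.frame(from = cellId(R1[ok], C1[ok]), to = cellId(R2[ok], C2[ok]),
                 weight = w)
  }
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to),
               weight = ed$weight),
    directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(nr * nc))))
  src <- as.character(cellId(srcRow, srcCol))
  d <- igraph::distances(g, v = src, mode = "out",
                         weights = igraph::E(g)$weight)
  best <- apply(d, 2, min)
  best[is.infinite(best)] <- NA_real_
  matrix(best[as.character(seq_len(nr * nc))], nr, nc)
}

# Exhaustive simple-path enumeration oracle for shortest driving minutes on a
# small undirected edge list.
enumShortestMinutes <- function(edges, from, to) {
  best <- Inf
  visit <- function(node, dist, visited) {
    if (dist >= best) return(invisible())
    if (node == to) { best <<- dist; return(invisible()) }
    for (i in seq_len(nrow(edges))) {
      nb <- NA
      if (edges$from[i] == node && !(edges$to[i] %in% visited))
        nb <- edges$to[i]
      else if (edges$to[i] == node && !(edges$from[i] %in% visited))
        nb <- edges$from[i]
      if (!is.na(nb)) visit(nb, dist + edges$minutes[i], c(visited, nb))
    }
  }
  visit(from, 0, from)
  best
}

# A two-facility straight-road fixture for referral tests: one delivery site
# at the west end, one EmOC at the east end of a single classed road.
straightRoadScene <- function(lengthM = 10000, roadClass = "primary",
                              crs = "EPSG:32735") {
  roads <- roadNetwork("r1", roadClass,
                       list(cbind(c(0, lengthM), c(500, 500))), crs)
  fac <- validateFacilities(data.frame(
    id = c("del1", "emoc1"), name = c("Delivery", "EmOC"),
    x = c(0, lengthM), y = c(500, 500),
    isDelivery = c(TRUE, FALSE), isEmoc = c(FALSE, TRUE),
    isMws = c(FALSE, FALSE)))
  list(roads = roads, facilities = fac)
}
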