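test_that("a single dry primary road gives the arithmetic drive time", {
  sc <- straightRoadScene(10000, "primary")
  dry <- applyFloodToNetwork(sc$roads, NULL)
  g <- buildGraph(dry, sc$facilities)
  od <- odMatrix(g, "del1", "emoc1")
  expect_equal(od["del1", "emoc1"], 10 / 80 * 60)  # 7.5 min
})

test_that("the same road wet drives at 26.7 km/h", {
  sc <- straightRoadScene(10000, "primary")
  grid <- testGrid(2, 20, cellSize = 500)
  depth <- matrix(0.005, 2, 20)
  wet <- applyFloodToNetwork(sc$roads, floodField(grid, depth))
  expect_equal(wet@state, "wet")
  g <- buildGraph(wet, sc$facilities)
  od <- odMatrix(g, "del1", "emoc1")
  expect_equal(od["del1", "emoc1"], 10 / 26.7 * 60, tolerance = 1e-12)
})

test_that("facilities snap within tolerance and disconnect beyond it", {
  roads <- roadNetwork("r1", "primary", list(cbind(c(0, 10000), c(0, 0))),
                       "EPSG:32735")
  fac <- validateFacilities(data.frame(
    id = c("near", "far", "emoc1"),
    name = c("n", "f", "e"),
    x = c(3000, 5000, 10000), y = c(50, 5000, -10),
    isDelivery = c(TRUE, TRUE, FALSE),
    isEmoc = c(FALSE, FALSE, TRUE), isMws = FALSE))
  g <- buildGraph(applyFloodToNetwork(roads, NULL), fac,
                  snapToleranceM = 250)
  expect_true("near" %in% names(g@facilityNode))
  expect_identical(g@disconnected, "far")
  rr <- referralResults(g, fac)
  expect_identical(rr$status[rr$siteId == "far"], "disconnected")
  # snapped mid-segment: 7 km at 80 km/h, connector contributes 0 minutes
  expect_equal(rr$minutes[rr$siteId == "near"], 7 / 80 * 60)
})

test_that("OD matrix matches exhaustive path enumeration on small graphs", {
  set.seed(202)
  crs <- "EPSG:32735"
  for (rep in 1:5) {
    # random planar-ish lattice: 9 nodes on a 3x3 grid, random subset of edges
    nodes <- expand.grid(x = c(0, 4000, 8000), y = c(0, 4000, 8000))
    # orthogonal lattice edges only, so graph nodes coincide with lattice
    # nodes and exhaustive enumeration over the lattice is a valid oracle
    cand <- list()
    for (i in 1:8) for (j in (i + 1):9) {
      d <- sqrt(sum((nodes[i, ] - nodes[j, ])^2))
      if (d <= 4000 + 1) cand[[length(cand) + 1L]] <- c(i, j)
    }
    keep <- sort(sample(length(cand), sample(7:length(cand), 1)))
    classes <- c("primary", "secondary", "track")
    ids <- sprintf("e%02d", seq_along(keep))
    geoms <- lapply(cand[keep], function(e)
      cbind(c(nodes$x[e[1]], nodes$x[e[2]]), c(nodes$y[e[1]], nodes$y[e[2]])))
    cls <- sample(classes, length(keep), replace = TRUE)
    roads <- roadNetwork(ids, cls, geoms, crs)
    fac <- validateFacilities(data.frame(
      id = c("o1", "o2", "d1"), name = c("o1", "o2", "d1"),
      x = c(0, 8000, 8000), y = c(0, 0, 8000),
      isDelivery = c(TRUE, TRUE, FALSE),
      isEmoc = c(FALSE, FALSE, TRUE), isMws = FALSE))
    net <- applyFloodToNetwork(roads, NULL)
    g <- buildGraph(net, fac, snapToleranceM = 10)
    if (length(g@disconnected)) next  # facility node not on this random net
    od <- odMatrix(g, c("o1", "o2"), "d1")
    # oracle: enumerate simple paths on the same node lattice
    speed <- net@speedKmh
    edges <- do.call(rbind, lapply(seq_along(keep), function(k) {
      e <- cand[keep][[k]]
      L <- sqrt(sum((nodes[e[1], ] - nodes[e[2], ])^2))
      data.frame(from = e[1], to = e[2], minutes = L * 60 / (speed[k] * 1000))
    }))
    expect_equal(od["o1", "d1"], enumShortestMinutes(edges, 1, 9),
                 tolerance = 1e-9)
    expect_equal(od["o2", "d1"], enumShortestMinutes(edges, 3, 9),
                 tolerance = 1e-9)
  }
})

test_that("crossing segments split the graph at their intersection", {
  crs <- "EPSG:32735"
  # X-shaped crossing with facilities at three arms; routing must use the
  # intersection node rather than polyline endpoints
  roads <- roadNetwork(c("ns", "we"), c("primary", "primary"),
                       list(cbind(c(500, 500), c(0, 1000)),
                            cbind(c(0, 1000), c(500, 500))), crs)
  fac <- validateFacilities(data.frame(
    id = c("a", "e"), name = c("a", "e"), x = c(500, 1000), y = c(0, 500),
    isDelivery = c(TRUE, FALSE), isEmoc = c(FALSE, TRUE), isMws = FALSE))
  g <- buildGraph(applyFloodToNetwork(roads, NULL), fac)
  od <- odMatrix(g, "a", "e")
  expect_equal(od["a", "e"], (500 + 500) / 1000 / 80 * 60)
})

test_that("flood-severed components yield Inf and a golden-hour boundary is timely", {
  sc <- straightRoadScene(80000, "primary")  # 80 km at 80 km/h = 60.0 min
  dry <- applyFloodToNetwork(sc$roads, NULL)
  g <- buildGraph(dry, sc$facilities)
  rr <- referralResults(g, sc$facilities)
  expect_equal(rr$minutes, 60)
  expect_identical(rr$status, "timely")

  # sever the road: one deeply-flooded point exceeding the depth criterion
  grid <- testGrid(2, 80, cellSize = 1000)
  depth <- matrix(0, 2, 80)
  depth[, 40] <- 0.6
  cut <- applyFloodToNetwork(sc$roads, floodField(grid, depth))
  expect_identical(cut@state, "impassable")
  g2 <- buildGraph(cut, sc$facilities)
  rr2 <- referralResults(g2, sc$facilities)
  expect_identical(rr2$status, "disconnected")
  expect_true(is.infinite(rr2$minutes))
})

test_that("self-EmOC sites never refer by road; ties break lexicographically", {
  expect_identical(closestEmoc(c(b = 10, a = 10, c = 12)),
                   list(emocId = "a", minutes = 10))
  expect_identical(closestEmoc(c(a = Inf, b = Inf)),
                   list(emocId = NA_character_, minutes = Inf))
  roads <- roadNetwork("r", "primary", list(cbind(c(0, 1000), c(0, 0))),
                       "EPSG:32735")
  fac <- validateFacilities(data.frame(
    id = c("both", "e2"), name = c("x", "y"), x = c(0, 1000), y = c(0, 0),
    isDelivery = c(TRUE, FALSE), isEmoc = c(TRUE, TRUE), isMws = FALSE))
  rr <- referralResults(buildGraph(applyFloodToNetwork(roads, NULL), fac),
                        fac)
  expect_identical(rr$status, "self_emoc")
  expect_equal(rr$minutes, 0)
  fac2 <- fac; fac2$isEmoc <- FALSE
  expect_error(buildGraph(applyFloodToNetwork(roads, NULL), fac2), "EmOC")
})

test_that("an all-zero flood reproduces the dry driving network exactly", {
  scene <- generateScene(synthConfig(seed = 3, nRows = 40L, nCols = 60L,
                                     cellSize = 50))
  grid <- scene@floods[[1]]@depth@grid
  zero <- floodField(grid, matrix(0, 40, 60))
  dry <- applyFloodToNetwork(scene@roads, NULL)
  z <- applyFloodToNetwork(scene@roads, zero)
  expect_identical(dry@state, z@state)
  expect_identical(dry@speedKmh, z@speedKmh)
})
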