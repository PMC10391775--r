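test_that("raster round-trip preserves grid, values and nodata mask exactly", {
  g <- testGrid(3, 3, cellSize = 10)
  v <- matrix(1.2, 3, 3)
  v[2, 3] <- NA  # sentinel cell
  v[1, 1] <- 1 / 3  # non-terminating decimal must survive bit-exactly
  layer <- gridLayer(g, v)
  path <- file.path(withr::local_tempdir(), "layer.asc")
  writeGridLayer(layer, path)
  back <- readGridLayer(path)
  expect_true(gridAligned(layerGrid(back), g))
  expect_identical(layerValues(back), v)
})

test_that("rasters without a CRS or with a geographic CRS are rejected", {
  g <- testGrid(2, 2)
  path <- file.path(withr::local_tempdir(), "layer.asc")
  writeGridLayer(gridLayer(g, matrix(1, 2, 2)), path)
  file.remove(sub("\\.asc$", ".prj", path))
  expect_error(readGridLayer(path), "no CRS")
  writeLines("EPSG:4326", sub("\\.asc$", ".prj", path))
  expect_error(readGridLayer(path), "geographic")
  expect_error(gridSpec(0, 100, 10, 2, 2, "EPSG:4326"), "geographic")
})

test_that("truncated or multi-band cell payloads are format errors", {
  g <- testGrid(2, 2)
  path <- file.path(withr::local_tempdir(), "layer.asc")
  writeGridLayer(gridLayer(g, matrix(1, 2, 2)), path)
  lines <- readLines(path)
  writeLines(c(lines, lines[7:8]), path)  # duplicate band
  expect_error(readGridLayer(path), "expected 4 cells")
})

test_that("vector readers enforce the closed road-class set and attributes", {
  dir <- withr::local_tempdir()
  roads <- roadNetwork(c("a", "b"), c("primary", "track"),
                       list(cbind(c(0, 100), c(0, 0)),
                            cbind(c(0, 100, 200), c(0, 50, 50))),
                       "EPSG:32735")
  path <- file.path(dir, "roads.geojson")
  writeRoads(roads, path)
  back <- readRoads(path)
  expect_identical(segmentIds(back), c("a", "b"))
  expect_identical(roadClasses(back), c("primary", "track"))
  expect_equal(segmentLengths(back), c(100, sqrt(100^2 + 50^2) + 100))

  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$features[[2]]$properties$road_class <- "footpath"
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(readRoads(path), "'b'.*footpath")
})

test_that("facility validation excludes flagless facilities with a count", {
  fac <- data.frame(id = c("f1", "f2", "f3"), name = c("a", "b", "c"),
                    x = 1:3, y = 1:3,
                    isDelivery = c(TRUE, FALSE, FALSE),
                    isEmoc = c(FALSE, TRUE, FALSE),
                    isMws = FALSE)
  expect_warning(out <- validateFacilities(fac), "f3")
  expect_identical(out$id, c("f1", "f2"))
  expect_identical(attr(out, "excluded"), 1L)
  expect_error(validatePopulation(
    data.frame(id = "p1", x = 0, y = 0, women = -2)), "negative")
})

test_that("facility and population tables round-trip through CSV and GeoJSON", {
  dir <- withr::local_tempdir()
  fac <- validateFacilities(data.frame(
    id = c("f1", "f2"), name = c("A", "B"), x = c(10.5, 20), y = c(5, 7.25),
    isDelivery = c(TRUE, FALSE), isEmoc = c(FALSE, TRUE), isMws = FALSE))
  for (ext in c("csv", "geojson")) {
    p <- file.path(dir, paste0("fac.", ext))
    writeFacilities(fac, p, crs = "EPSG:32735")
    back <- readFacilities(p)
    expect_equal(back[names(fac)], fac, ignore_attr = TRUE)
  }
  pop <- validatePopulation(data.frame(id = "p1", x = 3.5, y = 9, women = 12))
  p <- file.path(dir, "pop.csv")
  writePopulation(pop, p)
  expect_equal(readPopulation(p), pop, ignore_attr = TRUE)
})

test_that("rasterizeLines matches a point-in-buffer brute force", {
  g <- testGrid(5, 5, cellSize = 10)  # centres at 5,15,...,45
  line <- list(cbind(c(-10, 60), c(25, 25)))  # through row-3 centres
  hit0 <- layerValues(rasterizeLines(line, g, 0)) > 0
  expect_equal(which(rowSums(hit0) > 0), 3)
  expect_true(all(hit0[3, ]))

  # half-width 1.5 cells: brute force over all 25 centres
  hw <- 15
  hit <- layerValues(rasterizeLines(line, g, hw)) > 0
  cc <- cellCenters(g)
  brute <- matrix(abs(cc$y - 25) <= hw, 5, 5)
  expect_identical(hit, brute)
  expect_equal(sum(rowSums(hit) > 0), 3)

  empty <- rasterizeLines(list(), g, 10)
  expect_true(all(layerValues(empty) == 0))
})

test_that("rasterizeLines is invariant to collinear vertex densification", {
  g <- testGrid(8, 8, cellSize = 10)
  sparse <- list(cbind(c(0, 80), c(12, 63)))
  t <- seq(0, 1, by = 0.05)
  dense <- list(cbind(0 + t * 80, 12 + t * (63 - 12)))
  expect_identical(layerValues(rasterizeLines(sparse, g, 14)),
                   layerValues(rasterizeLines(dense, g, 14)))
})

test_that("resampleToGrid is exact nearest-neighbour centre lookup", {
  crs <- "EPSG:32735"
  coarse <- gridSpec(0, 200, 100, 2, 2, crs)
  vals <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  layer <- gridLayer(coarse, vals)

  expect_identical(layerValues(resampleToGrid(layer, coarse)), vals)

  one <- gridLayer(gridSpec(0, 100, 100, 1, 1, crs), matrix(0.3, 1, 1))
  fine <- gridSpec(0, 100, 10, 10, 10, crs)
  expect_true(all(layerValues(resampleToGrid(one, fine)) == 0.3))

  # brute-force centre lookup on the 2x2 case
  target <- gridSpec(0, 200, 25, 8, 8, crs)
  out <- layerValues(resampleToGrid(layer, target))
  cc <- cellCenters(target)
  for (i in seq_len(8)) for (j in seq_len(8)) {
    sr <- floor((200 - cc$y[i, j]) / 100) + 1
    sc <- floor(cc$x[i, j] / 100) + 1
    expect_identical(out[i, j], vals[sr, sc])
  }
  # value set preserved
  expect_true(all(unique(as.vector(out)) %in% as.vector(vals)))

  bad <- gridSpec(0, 200, 25, 8, 8, "EPSG:32736")
  expect_error(resampleToGrid(layer, bad), "CRS mismatch")
})

test_that("pointToCell follows the half-open ownership convention", {
  g <- testGrid(4, 4, cellSize = 10)  # y top = 40
  # x in [x0, x0+cs), y in (y0-cs, y0]
  res <- pointToCell(g, c(0, 10, 9.999, 5, 5, 40), c(40, 40, 40, 30, 29.999, 5))
  expect_identical(res$col, c(1L, 2L, 1L, 1L, 1L, NA_integer_))
  expect_identical(res$row, c(1L, 1L, 1L, 2L, 2L, NA_integer_))
})
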