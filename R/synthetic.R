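# Seeded generator for a complete synthetic floodplain scene: a parametric
# 13-month floodwave over a meandering channel, a classed road lattice with
# one elevated causeway, flagged facilities and a clustered population. The
# generator emulates the statistical structure the access models assume
# (single-peak seasonal inundation, low velocities, EmOC concentrated near
# the main roads) so the full pipeline is testable without external data.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Defaults mirror the study conditions: a 13-month hydrological year
#' (2017-10 to 2018-10) with the flood peak in March (`peakMonthIndex = 5`,
#' zero-based), up to 2 m of floodwater around a 200 m-wide permanent
#' channel, velocities proportional to depth and capped at 0.6 m s^-1 (flood
#' velocities on the plain stay low), 75 facilities (65 delivery, 10 EmOC,
#' 33 MWS), and 8,130 women of reproductive age spread over 25 clusters.
#'
#' @param seed integer RNG seed; all placements are reproducible from it.
#' @param nRows,nCols,cellSize grid shape (default 200 x 300 at 50 m).
#' @param originX,originY north-west corner.
#' @param crs projected CRS identifier.
#' @param months ordered vector of 13 month labels.
#' @param peakMonthIndex zero-based index of the flood-peak month.
#' @param maxDepthM peak channel-adjacent depth (m).
#' @param channelWidthM permanent channel width (m).
#' @param channelPath channel centreline (two-column matrix); default a
#'   gentle north-south meander through the domain centre.
#' @param velocityScale velocity = `velocityScale * depth`, capped at
#'   0.6 m s^-1.
#' @param nFacilities,nDelivery,nEmoc,nMws facility counts and service flags.
#' @param nPopulationClusters,womenTotal population structure; generated
#'   per-point integer counts sum exactly to `womenTotal`.
#' @param floodAmplitude multiplier on the seasonal weight (0 = flood-free
#'   scene; 1 = default conditions).
#' @return a list of class `synthConfig`.
#' @export
synthConfig <- function(seed = 1L, nRows = 200L, nCols = 300L, cellSize = 50,
                        originX = 0, originY = nRows * cellSize,
                        crs = "EPSG:32735",
                        months = format(seq(as.Date("2017-10-01"),
                                            by = "month", length.out = 13),
                                        "%Y-%m"),
                        peakMonthIndex = 5L, maxDepthM = 2.0,
                        channelWidthM = 200, channelPath = NULL,
                        velocityScale = 0.25,
                        nFacilities = 75L, nDelivery = 65L, nEmoc = 10L,
                        nMws = 33L, nPopulationClusters = 25L,
                        womenTotal = 8130L, floodAmplitude = 1) {
  stopifnot(length(months) == 13L, peakMonthIndex >= 1L,
            peakMonthIndex < 13L, maxDepthM > 0, channelWidthM > 0,
            floodAmplitude >= 0)
  W <- nCols * cellSize; H <- nRows * cellSize
  if (is.null(channelPath)) {
    ys <- seq(originY, originY - H, by = -cellSize * 5)
    xs <- originX + W / 2 +
      0.04 * W * sin(2 * pi * (originY - ys) / H)
    channelPath <- cbind(xs, ys)
  }
  grid <- gridSpec(originX, originY, cellSize, nRows, nCols, crs)
  structure(list(seed = as.integer(seed), grid = grid, months = months,
                 peakMonthIndex = as.integer(peakMonthIndex),
                 maxDepthM = maxDepthM, channelWidthM = channelWidthM,
                 channelPath = channelPath, velocityScale = velocityScale,
                 nFacilities = as.integer(nFacilities),
                 nDelivery = as.integer(nDelivery), nEmoc = as.integer(nEmoc),
                 nMws = as.integer(nMws),
                 nPopulationClusters = as.integer(nPopulationClusters),
                 womenTotal = as.integer(womenTotal),
                 floodAmplitude = floodAmplitude),
            class = "synthConfig")
}

# Unimodal seasonal weight: 0 at the first month, 1 at the peak,
# piecewise-cosine rise and fall (0 again at the last month).
.seasonalWeight <- function(m, peak, nMonths = 13L) {
  if (m <= peak) (1 - cos(pi * m / peak)) / 2
  else (1 + cos(pi * (m - peak) / (nMonths - 1L - peak))) / 2
}

#' Generate the 13-month parametric floodwave
#'
#' Depth at a cell in month m is
#' `maxDepthM * s_m * max(0, 1 - d/W_m)^2` where `d` is the distance to the
#' channel centreline, `W_m = channelWidthM * (1 + 40 s_m)` the monthly
#' inundation half-width, and `s_m` the unimodal seasonal weight (0 in the
#' first month, 1 at the peak). Channel cells (`d < channelWidthM/2`) always
#' hold at least 0.2 m (the permanent-water analogue). Velocity is
#' `velocityScale * depth`, capped at 0.6 m s^-1. Deterministic given the
#' config.
#'
#' @param config a [synthConfig()].
#' @return list of 13 [MonthlyFloodField-class] objects.
#' @export
generateFloodwave <- function(config) {
  grid <- config$grid
  cc <- cellCenters(grid)
  d <- matrix(.distToPolyline(as.vector(cc$x), as.vector(cc$y),
                              config$channelPath),
              grid@nRows, grid@nCols)
  channel <- d < config$channelWidthM / 2
  lapply(seq_along(config$months), function(k) {
    s <- .seasonalWeight(k - 1L, config$peakMonthIndex) * config$floodAmplitude
    Wm <- config$channelWidthM * (1 + 40 * s)
    depth <- if (s > 0)
      config$maxDepthM * s * pmax(1 - d / Wm, 0)^2
    else matrix(0, grid@nRows, grid@nCols)
    depth[channel] <- pmax(depth[channel], 0.2)
    vel <- pmin(config$velocityScale * depth, 0.6)
    new("MonthlyFloodField", month = config$months[k],
        depth = gridLayer(grid, depth), velocity = gridLayer(grid, vel))
  })
}

# Channel centreline x at a given y (the default path is monotone in y).
.channelXatY <- function(config, y) {
  cp <- config$channelPath
  stats::approx(cp[, 2], cp[, 1], xout = y, rule = 2)$y
}

#' Generate the synthetic road network and waterbodies
#'
#' One primary road along each valley margin, a lattice of tracks crossing
#' the floodplain with water-crossing segments where they span the channel,
#' one elevated causeway crossing the channel mid-domain, and short secondary
#' spurs toward the margin settlements. The channel itself is emitted as the
#' permanent waterbody. Deterministic given the config.
#'
#' @param config a [synthConfig()].
#' @return list with `roads` ([RoadNetwork-class]) and `waterbodies`
#'   ([WaterBodySet-class]).
#' @export
generateRoadsAndWaterbodies <- function(config) {
  g <- config$grid
  W <- g@nCols * g@cellSize; H <- g@nRows * g@cellSize
  x0 <- g@originX; yT <- g@originY; yB <- yT - H
  xW <- x0 + 0.10 * W; xE <- x0 + 0.90 * W
  ids <- character(); cls <- character(); geo <- list()
  add <- function(id, class, m) {
    ids <<- c(ids, id); cls <<- c(cls, class); geo <<- c(geo, list(m))
  }
  add("primary_w", "primary", cbind(c(xW, xW), c(yT - 0.02 * H, yB + 0.02 * H)))
  add("primary_e", "primary", cbind(c(xE, xE), c(yT - 0.02 * H, yB + 0.02 * H)))
  yCause <- yT - 0.5 * H
  add("causeway", "elevated_highway", cbind(c(xW, xE), c(yCause, yCause)))
  span <- config$channelWidthM
  for (f in c(0.15, 0.30, 0.70, 0.85)) {
    y <- yT - f * H
    cx <- .channelXatY(config, y)
    tag <- sprintf("track_%02d", round(f * 100))
    add(paste0(tag, "_w"), "track", cbind(c(xW, cx - span), c(y, y)))
    add(paste0(tag, "_x"), "water_crossing",
        cbind(c(cx - span, cx + span), c(y, y)))
    add(paste0(tag, "_e"), "track", cbind(c(cx + span, xE), c(y, y)))
  }
  for (f in c(0.20, 0.80)) {
    y <- yT - f * H
    add(sprintf("spur_w_%02d", round(f * 100)), "secondary",
        cbind(c(xW, xW - 0.05 * W), c(y, y)))
    add(sprintf("spur_e_%02d", round(f * 100)), "secondary",
        cbind(c(xE, xE + 0.05 * W), c(y, y)))
  }
  roads <- roadNetwork(ids, cls, geo, g@crs)
  wb <- waterBodySet("channel", list(config$channelPath),
                     config$channelWidthM, g@crs)
  list(roads = roads, waterbodies = wb)
}

#' Generate facilities and population
#'
#' EmOC facilities sit off-floodplain within snapping reach of the primary
#' roads (the urban margins); delivery sites are scattered near the road
#' lattice, with a handful placed remotely (no road connection, as in rural
#' networks); standalone maternity waiting shelters fill the remainder.
#' Population is drawn as clustered points snapped to cell centres with
#' integer women counts that sum exactly to `womenTotal` (largest-remainder
#' rounding).
#'
#' @param config a [synthConfig()].
#' @param roads the scene's [RoadNetwork-class] (placement reference).
#' @return list with `facilities` and `population` data.frames.
#' @export
generateFacilitiesAndPopulation <- function(config, roads = NULL) {
  if (is.null(roads)) roads <- generateRoadsAndWaterbodies(config)$roads
  g <- config$grid
  W <- g@nCols * g@cellSize; H <- g@nRows * g@cellSize
  x0 <- g@originX; yT <- g@originY
  xW <- x0 + 0.10 * W; xE <- x0 + 0.90 * W
  nF <- config$nFacilities

  # service flags: EmOC split between co-located (delivery+EmOC) and
  # standalone; MWS mostly co-located with delivery sites
  isDelivery <- seq_len(nF) <= config$nDelivery
  nEmocShared <- min(7L, config$nEmoc)
  emocIdx <- c(seq_len(nEmocShared),
               config$nDelivery + seq_len(config$nEmoc - nEmocShared))
  isEmoc <- seq_len(nF) %in% emocIdx
  # facilities that are neither delivery nor EmOC become standalone MWS so
  # every facility carries at least one service flag
  mwsAlone <- setdiff(which(!isDelivery), emocIdx)
  nMwsShared <- max(0L, config$nMws - length(mwsAlone))
  mwsShared <- if (nMwsShared > 0)
    seq.int(config$nDelivery - nMwsShared + 1L, config$nDelivery)
  else integer(0)
  isMws <- seq_len(nF) %in% c(mwsShared, mwsAlone)

  fac <- .withSeed(config$seed + 101L, {
    x <- numeric(nF); y <- numeric(nF)
    # EmOC: alternate margins, hugging the primary roads
    for (j in seq_along(emocIdx)) {
      i <- emocIdx[j]
      xr <- if (j %% 2 == 0) xE else xW
      x[i] <- xr + stats::runif(1, -100, 100)
      y[i] <- yT - stats::runif(1, 0.08, 0.92) * H
    }
    # delivery sites: near a random road vertex-to-vertex piece
    pieces <- .explodeSegments(roads@geometry)
    others <- setdiff(which(isDelivery), emocIdx)
    remote <- sample(others, 6L)
    for (i in others) {
      k <- sample.int(nrow(pieces), 1)
      t <- stats::runif(1)
      px <- pieces[k, 1] + t * (pieces[k, 3] - pieces[k, 1])
      py <- pieces[k, 2] + t * (pieces[k, 4] - pieces[k, 2])
      off <- if (i %in% remote) stats::runif(1, 1000, 3000) else
        abs(stats::rnorm(1, 0, 60))
      ang <- stats::runif(1, 0, 2 * pi)
      x[i] <- px + off * cos(ang); y[i] <- py + off * sin(ang)
    }
    # standalone MWS and anything unplaced: scattered over the plain
    rest <- which(x == 0 & y == 0)
    x[rest] <- x0 + stats::runif(length(rest), 0.05, 0.95) * W
    y[rest] <- yT - stats::runif(length(rest), 0.05, 0.95) * H
    x <- pmin(pmax(x, x0 + g@cellSize), x0 + W - g@cellSize)
    y <- pmin(pmax(y, yT - H + g@cellSize), yT - g@cellSize)
    data.frame(id = sprintf("fac%03d", seq_len(nF)),
               name = sprintf("Facility %d", seq_len(nF)),
               x = x, y = y, isDelivery = isDelivery, isEmoc = isEmoc,
               isMws = isMws, stringsAsFactors = FALSE)
  })

  pop <- .withSeed(config$seed + 202L, {
    nCl <- config$nPopulationClusters
    cx <- x0 + stats::runif(nCl, 0.03, 0.97) * W
    cy <- yT - stats::runif(nCl, 0.03, 0.97) * H
    wCl <- stats::rgamma(nCl, shape = 2)
    ptsPerCl <- 30L
    px <- rep(cx, each = ptsPerCl) + stats::rnorm(nCl * ptsPerCl, 0, 400)
    py <- rep(cy, each = ptsPerCl) + stats::rnorm(nCl * ptsPerCl, 0, 400)
    px <- pmin(pmax(px, x0 + g@cellSize / 2), x0 + W - g@cellSize / 2)
    py <- pmin(pmax(py, yT - H + g@cellSize / 2), yT - g@cellSize / 2)
    w <- rep(wCl, each = ptsPerCl) * stats::rgamma(nCl * ptsPerCl, shape = 1.5)
    # snap to cell centroids and aggregate duplicates
    cells <- pointToCell(g, px, py)
    key <- paste(cells$row, cells$col)
    agg <- rowsum(w, key)
    rc <- do.call(rbind, strsplit(rownames(agg), " "))
    row <- as.integer(rc[, 1]); col <- as.integer(rc[, 2])
    ord <- order(row, col)
    row <- row[ord]; col <- col[ord]; w <- agg[ord]
    women <- .largestRemainder(w, config$womenTotal)
    keep <- women > 0
    data.frame(id = sprintf("pop%04d", seq_len(sum(keep))),
               x = g@originX + (col[keep] - 0.5) * g@cellSize,
               y = g@originY - (row[keep] - 0.5) * g@cellSize,
               women = women[keep], stringsAsFactors = FALSE)
  })
  list(facilities = validateFacilities(fac), population = validatePopulation(pop))
}

# Integer apportionment preserving the exact total.
.largestRemainder <- function(w, total) {
  exact <- w / sum(w) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the complete synthetic scene
#'
#' @param config a [synthConfig()].
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(config = synthConfig()) {
  rw <- generateRoadsAndWaterbodies(config)
  fp <- generateFacilitiesAndPopulation(config, rw$roads)
  new("SyntheticScene", floods = generateFloodwave(config), roads = rw$roads,
      waterbodies = rw$waterbodies, facilities = fp$facilities,
      population = fp$population, config = unclass(config))
}

#' Write a scene to disk in the package's native formats
#'
#' Monthly depth/velocity ASCII grids, roads and waterbodies GeoJSON,
#' facility and population CSVs, plus a JSON manifest listing the files and
#' the generating seed.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (f in scene@floods) {
    dp <- file.path(dir, sprintf("depth_%s.asc", f@month))
    vp <- file.path(dir, sprintf("velocity_%s.asc", f@month))
    writeGridLayer(f@depth, dp); writeGridLayer(f@velocity, vp)
    files <- c(files, dp, vp)
  }
  rp <- file.path(dir, "roads.geojson"); writeRoads(scene@roads, rp)
  wp <- file.path(dir, "waterbodies.geojson")
  writeWaterbodies(scene@waterbodies, wp)
  fp <- file.path(dir, "facilities.csv"); writeFacilities(scene@facilities, fp)
  pp <- file.path(dir, "population.csv"); writePopulation(scene@population, pp)
  files <- c(files, rp, wp, fp, pp)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = scene@config$seed,
                            months = scene@config$months,
                            files = basename(files)),
                       mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
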