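#' Walking impedance parameters
#'
#' Walking speeds are parametrised for reduced mobility in late pregnancy:
#' 4 km h^-1 on roads, 3 km h^-1 off-road. Cells whose floodwater depth
#' exceeds `walkDepthLimit` (default 1 cm, strict) are impassable on foot.
#'
#' @param vOnRoad on-road walking speed, km h^-1.
#' @param vOffRoad off-road walking speed, km h^-1.
#' @param walkDepthLimit flood depth (m) above which a cell is impassable;
#'   depth exactly at the limit stays passable.
#' @return a named list of class `impedanceParams`.
#' @export
impedanceParams <- function(vOnRoad = 4, vOffRoad = 3, walkDepthLimit = 0.01) {
  stopifnot(vOnRoad > 0, vOffRoad > 0, walkDepthLimit >= 0)
  structure(list(vOnRoad = vOnRoad, vOffRoad = vOffRoad,
                 walkDepthLimit = walkDepthLimit),
            class = "impedanceParams")
}

.kmhToSecPerM <- function(kmh) 3600 / (kmh * 1000)

#' Build the monthly walking impedance surface
#'
#' Layers, in priority order: (1) background at the off-road speed; (2) cells
#' traced by any road (one-cell-wide rasterisation) at the on-road speed;
#' (3) cells within any permanent waterbody buffer (half the average width
#' either side of the centreline) impassable; (4) cells whose resampled flood
#' depth strictly exceeds the walking depth limit impassable. Barriers win
#' over roads; roads win over background.
#'
#' @param grid target [GridSpec-class].
#' @param roads a [RoadNetwork-class] (CRS must match `grid`).
#' @param waterbodies a [WaterBodySet-class].
#' @param flood a [MonthlyFloodField-class], or `NULL` for the dry baseline.
#' @param params an [impedanceParams()] list.
#' @return an [ImpedanceSurface-class]: traversal time in s m^-1, `NA` =
#'   impassable.
#' @export
buildImpedance <- function(grid, roads, waterbodies, flood = NULL,
                           params = impedanceParams()) {
  if (roads@crs != grid@crs)
    stop("roads CRS (", roads@crs, ") does not match grid CRS (", grid@crs, ")")
  if (waterbodies@crs != grid@crs)
    stop("waterbodies CRS (", waterbodies@crs, ") does not match grid CRS (",
         grid@crs, ")")
  tau <- matrix(.kmhToSecPerM(params$vOffRoad), grid@nRows, grid@nCols)
  if (length(roads@ids)) {
    onRoad <- rasterizeLines(roads, grid, 0)@values > 0
    tau[onRoad] <- .kmhToSecPerM(params$vOnRoad)
  }
  for (i in seq_along(waterbodies@ids)) {
    wb <- rasterizeLines(waterbodies@geometry[i], grid,
                         waterbodies@avgWidthM[i] / 2)@values > 0
    tau[wb] <- NA_real_
  }
  if (!is.null(flood)) {
    if (flood@depth@grid@crs != grid@crs)
      stop("flood CRS (", flood@depth@grid@crs, ") does not match grid CRS (",
           grid@crs, ")")
    depth <- resampleToGrid(flood@depth, grid)@values
    tau[!is.na(depth) & depth > params$walkDepthLimit] <- NA_real_
  }
  new("ImpedanceSurface", grid = grid, values = tau)
}

#' Dry-season baseline impedance
#'
#' Identical to [buildImpedance()] with no flood layer: only permanent
#' waterbodies act as barriers.
#'
#' @inheritParams buildImpedance
#' @return an [ImpedanceSurface-class].
#' @export
dryBaseline <- function(grid, roads, waterbodies, params = impedanceParams()) {
  buildImpedance(grid, roads, waterbodies, flood = NULL, params = params)
}
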