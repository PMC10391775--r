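#' Assign women to their nearest reachable delivery site
#'
#' Every population point is assigned to the delivery site with the minimum
#' finite walking time in the month's cost surface, or to none if the point
#' is unreachable (including points sitting on flooded cells).
#'
#' @param cost the month's delivery-site [CostSurface-class].
#' @param population validated population table.
#' @return list with `assignments` (data.frame id, siteId or `NA`, seconds,
#'   women) and `served` (named vector of women totals per site).
#' @export
assignWomen <- function(cost, population) {
  s <- sampleTimes(cost, population)
  assignments <- data.frame(id = population$id,
                            siteId = s$nearestFacility,
                            seconds = s$seconds,
                            women = population$women,
                            stringsAsFactors = FALSE)
  ok <- !is.na(assignments$siteId)
  served <- if (any(ok))
    tapply(assignments$women[ok], assignments$siteId[ok], sum)
  else stats::setNames(numeric(0), character(0))
  list(assignments = assignments, served = served)
}

#' Monthly walking-access summary
#'
#' Women counts and percentages per walking-time bin (<=60 min, 61-120 min,
#' >120 min, unreachable) for each service class. Bin counts partition the
#' total women exactly; percentages are stored unrounded.
#'
#' @param costList named list of [CostSurface-class] objects (one per
#'   service class).
#' @param population validated population table.
#' @param month month label.
#' @return data.frame (month, service, bin, women, pct).
#' @export
accessSummary <- function(costList, population, month) {
  total <- sum(population$women)
  out <- lapply(names(costList), function(cls) {
    s <- sampleTimes(costList[[cls]], population)
    bins <- classifyThreshold(s$seconds)
    women <- vapply(ACCESS_BINS, function(b)
      sum(population$women[bins == b]), numeric(1))
    data.frame(month = month, service = cls, bin = ACCESS_BINS,
               women = as.numeric(women), pct = 100 * women / total,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-weighted referral coverage
#'
#' Couples the walking and driving models: each woman is mapped to
#' `no_delivery_access` (cannot walk to any delivery site),
#' `site_cannot_refer` (her site has no road path to EmOC),
#' `referral_late` (> 1 h drive) or `referral_timely` (<= 1 h, or the site
#' itself provides EmOC). Categories partition the women total exactly. Also
#' counts serving delivery sites: accessed by at least one woman, able to
#' refer, and able to refer timely.
#'
#' @param assignment an [assignWomen()] result.
#' @param referrals a [referralResults()] table for the month.
#' @param month month label.
#' @return list with `categories` (data.frame month, category, women, pct)
#'   and `sites` (data.frame month, sitesAccessed, sitesAbleToRefer,
#'   sitesTimely).
#' @export
referralCategories <- function(assignment, referrals, month) {
  a <- assignment$assignments
  unknown <- setdiff(stats::na.omit(unique(a$siteId)), referrals$siteId)
  if (length(unknown))
    stop("assignments reference unknown delivery sites: ",
         paste(unknown, collapse = ", "))
  status <- referrals$status[match(a$siteId, referrals$siteId)]
  cat <- ifelse(is.na(a$siteId), "no_delivery_access",
         ifelse(status == "disconnected", "site_cannot_refer",
         ifelse(status == "late", "referral_late", "referral_timely")))
  total <- sum(a$women)
  women <- vapply(REFERRAL_CATEGORIES, function(k)
    sum(a$women[cat == k]), numeric(1))
  categories <- data.frame(month = month, category = REFERRAL_CATEGORIES,
                           women = as.numeric(women),
                           pct = 100 * women / total,
                           stringsAsFactors = FALSE)
  rownames(categories) <- NULL
  accessed <- names(assignment$served)[assignment$served > 0]
  rs <- referrals[referrals$siteId %in% accessed, , drop = FALSE]
  sites <- data.frame(month = month,
                      sitesAccessed = length(accessed),
                      sitesAbleToRefer = sum(rs$status != "disconnected"),
                      sitesTimely = sum(rs$status %in%
                                          c("timely", "self_emoc")))
  list(categories = categories, sites = sites)
}

#' Run the full monthly coupled pipeline
#'
#' For each month: build the walking impedance surface, compute accumulated
#' cost to each service class (delivery, EmOC, MWS and any facility),
#' summarise walking access; apply the flood speed rules to the road network,
#' build the driving graph, compute delivery-to-EmOC referrals; couple the
#' two through the population-weighted referral categories. A month in which
#' every facility of a class sits on flooded cells yields an all-unreachable
#' cost surface for that class (not a failure).
#'
#' @param scene a [SyntheticScene-class] (or any list-like with elements
#'   `floods`, `roads`, `waterbodies`, `facilities`, `population`).
#' @param months subset of month labels to run (default: all).
#' @param params walking [impedanceParams()].
#' @param rules driving [speedRules()].
#' @param snapToleranceM facility-road snap tolerance (m).
#' @param goldenHourMin timely-referral threshold (min, inclusive).
#' @param serviceClasses walking service classes to evaluate.
#' @param outDir optional output directory for summary/result CSVs and the
#'   resolved run manifest.
#' @param saveIntermediates also write monthly impedance and cost rasters
#'   (requires `outDir`).
#' @return list with `access` (monthly access summary), `referral`
#'   (categories), `sites` (serving-site counts), and `months` (per-month
#'   detail: referral results, assignments, OD matrix, dropped sources).
#' @export
runPipeline <- function(scene, months = NULL, params = impedanceParams(),
                        rules = speedRules(), snapToleranceM = 250,
                        goldenHourMin = 60,
                        serviceClasses = c("delivery", "emoc", "mws", "any"),
                        outDir = NULL, saveIntermediates = FALSE) {
  floods <- if (is(scene, "SyntheticScene")) scene@floods else scene$floods
  roads <- if (is(scene, "SyntheticScene")) scene@roads else scene$roads
  wb <- if (is(scene, "SyntheticScene")) scene@waterbodies else scene$waterbodies
  fac <- if (is(scene, "SyntheticScene")) scene@facilities else scene$facilities
  pop <- if (is(scene, "SyntheticScene")) scene@population else scene$population
  grid <- floods[[1]]@depth@grid
  labels <- vapply(floods, function(f) f@month, character(1))
  if (!is.null(months)) {
    miss <- setdiff(months, labels)
    if (length(miss)) stop("unknown months: ", paste(miss, collapse = ", "))
    floods <- floods[labels %in% months]
    labels <- labels[labels %in% months]
  }
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  accessRows <- list(); catRows <- list(); siteRows <- list()
  detail <- list()
  emocIds <- sort(fac$id[fac$isEmoc])
  delIds <- sort(fac$id[fac$isDelivery])
  for (k in seq_along(floods)) {
    fl <- floods[[k]]; mon <- labels[k]
    imp <- buildImpedance(grid, roads, wb, fl, params)
    costs <- list(); dropped <- list()
    for (cls in serviceClasses) {
      ss <- sourceSet(fac, cls, imp)
      costs[[cls]] <- if (length(ss$ids)) accumulateCost(imp, ss)
                      else .unreachableCostSurface(grid, ss)
      dropped[[cls]] <- ss$dropped
    }
    accessRows[[mon]] <- accessSummary(costs, pop, mon)

    net <- applyFloodToNetwork(roads, fl, rules)
    graph <- buildGraph(net, fac, snapToleranceM)
    rr <- referralResults(graph, fac, goldenHourMin)
    od <- odMatrix(graph, delIds, emocIds)

    asg <- assignWomen(costs[["delivery"]], pop)
    rc <- referralCategories(asg, rr, mon)
    catRows[[mon]] <- rc$categories
    siteRows[[mon]] <- rc$sites
    detail[[mon]] <- list(referrals = rr, assignments = asg$assignments,
                          od = od, droppedSources = dropped,
                          networkState = net@state)
    if (!is.null(outDir)) {
      utils::write.csv(rr, file.path(outDir,
        sprintf("referral_results_%s.csv", mon)), row.names = FALSE)
      odOut <- od; odOut[is.infinite(odOut)] <- NA
      utils::write.csv(odOut, file.path(outDir,
        sprintf("od_matrix_%s.csv", mon)), na = "inf")
      if (saveIntermediates) {
        writeGridLayer(imp, file.path(outDir,
          sprintf("impedance_%s.asc", mon)))
        for (cls in serviceClasses)
          writeGridLayer(gridLayer(grid, costs[[cls]]@seconds),
            file.path(outDir, sprintf("cost_%s_%s.asc", cls, mon)))
      }
    }
  }
  access <- do.call(rbind, accessRows); rownames(access) <- NULL
  referral <- do.call(rbind, catRows); rownames(referral) <- NULL
  sites <- do.call(rbind, siteRows); rownames(sites) <- NULL
  if (!is.null(outDir)) {
    fmt <- function(d) { d$pct <- round(d$pct, 1); d }
    utils::write.csv(fmt(access), file.path(outDir, "access_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(fmt(referral), file.path(outDir, "referral_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(sites, file.path(outDir, "serving_sites.csv"),
                     row.names = FALSE)
    manifest <- list(months = labels,
                     params = unclass(params),
                     snapToleranceM = snapToleranceM,
                     goldenHourMin = goldenHourMin,
                     womenTotal = sum(pop$women),
                     packageVersion =
                       as.character(utils::packageVersion("floodAccess")))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(access = access, referral = referral, sites = sites, months = detail)
}
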