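smallScene <- function(seed = 5)
  generateScene(synthConfig(seed = seed, nRows = 60L, nCols = 90L,
                            cellSize = 50))

test_that("women are conserved across every access and referral breakdown", {
  scene <- smallScene()
  res <- runPipeline(scene, months = c("2017-10", "2018-01", "2018-03"))
  total <- sum(scene@population$women)
  sums <- tapply(res$access$women,
                 list(res$access$month, res$access$service), sum)
  expect_true(all(sums == total))
  catSums <- tapply(res$referral$women, res$referral$month, sum)
  expect_true(all(catSums == total))
  pctSums <- tapply(res$access$pct, list(res$access$month,
                                         res$access$service), sum)
  expect_true(all(abs(pctSums - 100) < 1e-9))
})

test_that("no_delivery_access equals the walking-unreachable delivery bin exactly", {
  scene <- smallScene()
  res <- runPipeline(scene, months = c("2017-12", "2018-03", "2018-06"))
  for (m in unique(res$access$month)) {
    unr <- res$access$women[res$access$month == m &
                            res$access$service == "delivery" &
                            res$access$bin == "unreachable"]
    nda <- res$referral$women[res$referral$month == m &
                              res$referral$category == "no_delivery_access"]
    expect_identical(unr, nda)
  }
})

test_that("women on unreachable cells are assigned to no site; totals conserved", {
  tau <- matrix(1.2, 5, 5)
  tau[, 3] <- NA
  surf <- surfaceFrom(tau)
  cost <- accumulateCost(surf, srcList(3L, 1L, ids = "west"))
  pop <- validatePopulation(data.frame(
    id = c("p1", "p2"), x = c(5, 45), y = c(25, 25), women = c(10, 7)))
  asg <- assignWomen(cost, pop)
  expect_identical(asg$assignments$siteId, c("west", NA_character_))
  expect_equal(sum(asg$served) +
                 sum(pop$women[is.na(asg$assignments$siteId)]),
               sum(pop$women))
})

test_that("assignment matches per-source minima on a three-facility fixture", {
  set.seed(12)
  tau <- matrix(stats::runif(400, 0.8, 2.5), 20, 20)
  surf <- surfaceFrom(tau)
  fac <- validateFacilities(data.frame(
    id = c("fB", "fA", "fC"), name = c("b", "a", "c"),
    x = c(15, 185, 95), y = c(195, 15, 105),
    isDelivery = TRUE, isEmoc = FALSE, isMws = FALSE))
  ss <- sourceSet(fac, "delivery", surf)
  cost <- accumulateCost(surf, ss)
  pop <- validatePopulation(data.frame(
    id = sprintf("p%d", 1:6),
    x = c(25, 175, 95, 55, 145, 5), y = c(25, 185, 95, 155, 65, 105),
    women = 1))
  asg <- assignWomen(cost, pop)$assignments
  for (i in seq_len(nrow(pop))) {
    per <- vapply(seq_along(ss$ids), function(k) {
      s1 <- accumulateCost(surf, srcList(ss$row[k], ss$col[k],
                                         ids = ss$ids[k]))
      sampleTimes(s1, pop[i, ])$seconds
    }, numeric(1))
    expect_equal(asg$seconds[i], min(per), tolerance = 1e-12)
    winners <- ss$ids[per <= min(per) + 1e-12]
    expect_identical(asg$siteId[i], sort(winners)[1])
  }
})

test_that("severing the only road moves exactly that site's women to site_cannot_refer", {
  crs <- "EPSG:32735"
  grid <- gridSpec(0, 2000, 50, 40, 120, crs)  # 6 km x 2 km
  roads <- roadNetwork("r1", "primary",
                       list(cbind(c(500, 5500), c(1000, 1000))), crs)
  wb <- waterBodySet("w", list(cbind(c(-100, -90), c(-100, -90))), 1, crs)
  fac <- validateFacilities(data.frame(
    id = c("del1", "emoc1"), name = c("d", "e"),
    x = c(500, 5500), y = c(1000, 1000),
    isDelivery = c(TRUE, FALSE), isEmoc = c(FALSE, TRUE), isMws = FALSE))
  pop <- validatePopulation(data.frame(
    id = c("p1", "p2"), x = c(600, 700), y = c(900, 1100),
    women = c(40, 2)))
  surf <- dryBaseline(grid, roads, wb)
  cost <- accumulateCost(surf, sourceSet(fac, "delivery", surf))
  asg <- assignWomen(cost, pop)

  dryNet <- applyFloodToNetwork(roads, NULL)
  rrDry <- referralResults(buildGraph(dryNet, fac), fac)
  dry <- referralCategories(asg, rrDry, "dry")
  expect_equal(dry$categories$women[dry$categories$category ==
                                      "referral_timely"], 42)

  depth <- matrix(0, 40, 120)
  depth[, 60] <- 0.7  # one impassable column severs the road
  cutNet <- applyFloodToNetwork(roads, floodField(grid, depth))
  rrCut <- referralResults(buildGraph(cutNet, fac), fac)
  cut <- referralCategories(asg, rrCut, "cut")
  expect_equal(cut$categories$women[cut$categories$category ==
                                      "site_cannot_refer"], 42)
  expect_equal(cut$categories$women[cut$categories$category ==
                                      "referral_timely"], 0)
  expect_equal(sum(cut$categories$women), 42)
  expect_equal(cut$categories$pct[cut$categories$category ==
                                    "site_cannot_refer"], 100)
})

test_that("unknown site references are a consistency error", {
  asg <- list(assignments = data.frame(id = "p1", siteId = "ghost",
                                       seconds = 10, women = 5),
              served = c(ghost = 5))
  rr <- data.frame(siteId = "real", status = "timely",
                   nearestEmoc = "e", minutes = 10)
  expect_error(referralCategories(asg, rr, "m"), "ghost")
})

test_that("pipeline reruns are bit-identical and write their outputs", {
  scene <- smallScene(seed = 21)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  r1 <- runPipeline(scene, months = c("2017-10", "2018-03"), outDir = dir1)
  r2 <- runPipeline(scene, months = c("2017-10", "2018-03"), outDir = dir2)
  expect_identical(r1$access, r2$access)
  expect_identical(r1$referral, r2$referral)
  expect_identical(readLines(file.path(dir1, "access_summary.csv")),
                   readLines(file.path(dir2, "access_summary.csv")))
  expect_true(file.exists(file.path(dir1, "referral_summary.csv")))
  expect_true(file.exists(file.path(dir1, "od_matrix_2018-03.csv")))
  expect_true(file.exists(file.path(dir1, "referral_results_2017-10.csv")))
  expect_true(file.exists(file.path(dir1, "run_manifest.json")))
  expect_error(runPipeline(scene, months = "1999-01"), "unknown months")
})
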