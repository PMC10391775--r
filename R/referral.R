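#' Build the monthly driving graph
#'
#' Impassable segments are removed, remaining segments are exploded into
#' straight pieces and split at every mutual intersection (crossings and
#' endpoint-on-interior junctions), and each facility offering delivery or
#' EmOC is snapped to the nearest point on the passable network if within
#' `snapToleranceM`; the snap point becomes the facility's node (the
#' facility-road connector contributes zero minutes). Facilities beyond
#' tolerance are marked road-disconnected for the month. Edge weights are
#' driving minutes at the segment's flood-conditioned speed.
#'
#' @param network a [FloodedRoadNetwork-class].
#' @param facilities validated facility table (>= 1 EmOC required).
#' @param snapToleranceM snap tolerance in metres (default 250).
#' @return a [RoutingGraph-class].
#' @export
buildGraph <- function(network, facilities, snapToleranceM = 250) {
  if (!any(facilities$isEmoc))
    stop("no EmOC facility present; referral model needs >= 1 destination")
  keep <- network@speedKmh > 0
  roads <- network@network
  edges <- NULL
  if (any(keep)) {
    pieces <- .explodeSegments(roads@geometry[keep])
    speeds <- network@speedKmh[keep][pieces[, 5]]
    edges <- .splitAtIntersections(pieces[, 1:4, drop = FALSE], speeds)
  }

  fac <- facilities[facilities$isDelivery | facilities$isEmoc, , drop = FALSE]
  fac <- fac[order(fac$id), , drop = FALSE]
  snapped <- list()
  disconnected <- character()
  for (i in seq_len(nrow(fac))) {
    p <- c(fac$x[i], fac$y[i])
    hit <- .snapToEdges(p, edges, snapToleranceM)
    if (is.null(hit)) {
      disconnected <- c(disconnected, fac$id[i])
    } else {
      edges <- hit$edges
      snapped[[fac$id[i]]] <- c(hit$x, hit$y)
    }
  }

  g <- .edgesToIgraph(edges)
  facilityNode <- integer(0)
  if (length(snapped)) {
    keys <- vapply(snapped, function(p) .nodeKey(p[1], p[2]), character(1))
    facilityNode <- match(keys, igraph::V(g)$name)
    names(facilityNode) <- names(snapped)
  }
  new("RoutingGraph", graph = g, month = network@month,
      facilityNode = facilityNode, disconnected = disconnected,
      snapToleranceM = snapToleranceM)
}

.nodeKey <- function(x, y) sprintf("%.6f_%.6f", x, y)

# Split straight pieces at all pairwise intersection points. Works on a
# matrix with columns x1,y1,x2,y2 plus a parallel speed vector.
.splitAtIntersections <- function(pieces, speeds, eps = 1e-6) {
  n <- nrow(pieces)
  cuts <- vector("list", n)  # t parameters per piece
  for (i in seq_len(max(0, n - 1L))) {
    a1 <- pieces[i, 1:2]; a2 <- pieces[i, 3:4]
    for (j in seq.int(i + 1L, n)) {
      b1 <- pieces[j, 1:2]; b2 <- pieces[j, 3:4]
      # cheap bbox rejection
      if (max(a1[1], a2[1]) < min(b1[1], b2[1]) - eps ||
          min(a1[1], a2[1]) > max(b1[1], b2[1]) + eps ||
          max(a1[2], a2[2]) < min(b1[2], b2[2]) - eps ||
          min(a1[2], a2[2]) > max(b1[2], b2[2]) + eps) next
      p <- .segIntersect(a1, a2, b1, b2)
      if (is.null(p)) next
      La <- sqrt(sum((a2 - a1)^2)); Lb <- sqrt(sum((b2 - b1)^2))
      if (La > 0) {
        t <- sum((p - a1) * (a2 - a1)) / La^2
        if (t > eps && t < 1 - eps) cuts[[i]] <- c(cuts[[i]], t)
      }
      if (Lb > 0) {
        u <- sum((p - b1) * (b2 - b1)) / Lb^2
        if (u > eps && u < 1 - eps) cuts[[j]] <- c(cuts[[j]], u)
      }
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a1 <- pieces[i, 1:2]; a2 <- pieces[i, 3:4]
    ts <- sort(unique(c(0, cuts[[i]], 1)))
    xs <- a1[1] + ts * (a2[1] - a1[1])
    ys <- a1[2] + ts * (a2[2] - a1[2])
    k <- length(ts) - 1L
    out[[i]] <- cbind(xs[seq_len(k)], ys[seq_len(k)],
                      xs[seq_len(k) + 1L], ys[seq_len(k) + 1L],
                      rep(speeds[i], k))
  }
  do.call(rbind, out)
}

# Snap point p to the nearest edge within tolerance; splits that edge at the
# projection so the snap point is a graph node. Returns NULL if out of reach.
.snapToEdges <- function(p, edges, tol) {
  if (is.null(edges) || nrow(edges) == 0L) return(NULL)
  best <- list(d = Inf, i = NA_integer_, t = NA_real_)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1:2]; b <- edges[i, 3:4]
    L2 <- sum((b - a)^2)
    t <- if (L2 == 0) 0 else min(1, max(0, sum((p - a) * (b - a)) / L2))
    q <- a + t * (b - a)
    d <- sqrt(sum((p - q)^2))
    if (d < best$d) best <- list(d = d, i = i, t = t)
  }
  if (best$d > tol) return(NULL)
  i <- best$i; t <- best$t
  a <- edges[i, 1:2]; b <- edges[i, 3:4]
  q <- a + t * (b - a)
  if (t > 1e-9 && t < 1 - 1e-9) {
    sp <- edges[i, 5]
    edges <- rbind(edges[-i, , drop = FALSE],
                   c(a[1], a[2], q[1], q[2], sp),
                   c(q[1], q[2], b[1], b[2], sp))
  }
  list(edges = edges, x = q[1], y = q[2])
}

.edgesToIgraph <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  from <- .nodeKey(edges[, 1], edges[, 2])
  to <- .nodeKey(edges[, 3], edges[, 4])
  len <- sqrt((edges[, 3] - edges[, 1])^2 + (edges[, 4] - edges[, 2])^2)
  keep <- len > 1e-9
  minutes <- len[keep] * 60 / (edges[keep, 5] * 1000)
  df <- data.frame(from = from[keep], to = to[keep], minutes = minutes,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Origin-destination driving-time matrix
#'
#' Exact shortest-path minutes between facilities on the monthly graph
#' (Dijkstra, one run per destination over the undirected graph). Pairs with
#' no connecting path, and any facility disconnected from the road network,
#' get `Inf`.
#'
#' @param graph a [RoutingGraph-class].
#' @param origins,destinations facility id vectors (e.g. delivery sites and
#'   EmOC sites).
#' @return numeric matrix of minutes, rows = origins, columns = destinations.
#' @export
odMatrix <- function(graph, origins, destinations) {
  m <- matrix(Inf, length(origins), length(destinations),
              dimnames = list(origins, destinations))
  oNode <- graph@facilityNode[origins]
  dNode <- graph@facilityNode[destinations]
  okO <- !is.na(oNode); okD <- !is.na(dNode)
  if (any(okO) && any(okD)) {
    d <- igraph::distances(graph@graph, v = oNode[okO], to = dNode[okD],
                           weights = igraph::E(graph@graph)$minutes,
                           algorithm = "dijkstra")
    m[okO, okD] <- d
  }
  m
}

#' Closest EmOC for one delivery site
#'
#' Minimum over a row of the OD matrix; ties broken toward the
#' lexicographically smaller EmOC id.
#'
#' @param odRow named numeric vector of minutes to each EmOC site.
#' @return list with `emocId` (`NA` if no path) and `minutes` (`Inf` if no
#'   path).
#' @export
closestEmoc <- function(odRow) {
  if (!length(odRow) || all(is.infinite(odRow)))
    return(list(emocId = NA_character_, minutes = Inf))
  best <- min(odRow)
  ids <- sort(names(odRow)[odRow == best])
  list(emocId = ids[1], minutes = best)
}

#' Classify monthly referral capability of delivery sites
#'
#' Delivery sites that themselves provide EmOC are `self_emoc` (0 minutes; no
#' road referral assumed). Otherwise the closest-EmOC drive time is
#' classified against the inclusive golden hour: `timely` (<= 60 min),
#' `late`, or `disconnected` (no path, including sites off the road network).
#'
#' @param graph a [RoutingGraph-class] for the month.
#' @param facilities validated facility table.
#' @param goldenHourMin timely-referral threshold in minutes (default 60,
#'   inclusive).
#' @return data.frame (siteId, status, nearestEmoc, minutes) for every
#'   delivery site.
#' @export
referralResults <- function(graph, facilities, goldenHourMin = 60) {
  del <- facilities[facilities$isDelivery, , drop = FALSE]
  del <- del[order(del$id), , drop = FALSE]
  emoc <- sort(facilities$id[facilities$isEmoc])
  od <- odMatrix(graph, del$id, emoc)
  status <- character(nrow(del))
  nearest <- rep(NA_character_, nrow(del))
  minutes <- numeric(nrow(del))
  for (i in seq_len(nrow(del))) {
    if (del$isEmoc[i]) {
      status[i] <- "self_emoc"; minutes[i] <- 0; nearest[i] <- del$id[i]
      next
    }
    ce <- closestEmoc(stats::setNames(as.numeric(od[i, ]), colnames(od)))
    minutes[i] <- ce$minutes
    nearest[i] <- ce$emocId
    status[i] <- if (is.infinite(ce$minutes)) "disconnected"
                 else if (ce$minutes <= goldenHourMin) "timely" else "late"
  }
  data.frame(siteId = del$id, status = status, nearestEmoc = nearest,
             minutes = minutes, stringsAsFactors = FALSE)
}

setMethod("show", "RoutingGraph", function(object) {
  cat(sprintf("RoutingGraph %s: %d nodes, %d edges, %d snapped facilities, %d disconnected\n",
              object@month, igraph::vcount(object@graph),
              igraph::ecount(object@graph), length(object@facilityNode),
              length(object@disconnected)))
})
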