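# Planar geometry primitives (projected metric coordinates throughout).

.polylineLength <- function(m) {
  dx <- diff(m[, 1]); dy <- diff(m[, 2])
  sum(sqrt(dx * dx + dy * dy))
}

# Minimum distance from each point (px, py) to a polyline. Vectorised over
# points, loops over polyline segments.
.distToPolyline <- function(px, py, poly) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly) - 1L)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1L, 1]; by <- poly[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dx <- px - ax; dy <- py - ay
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Nearest point on a polyline to point p; returns list(dist, x, y, seg, t).
.projectToPolyline <- function(p, poly) {
  best <- list(dist = Inf, x = NA_real_, y = NA_real_, seg = NA_integer_,
               t = NA_real_)
  for (i in seq_len(nrow(poly) - 1L)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1L, 1]; by <- poly[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) 0 else min(1, max(0, ((p[1] - ax) * vx + (p[2] - ay) * vy) / L2))
    qx <- ax + t * vx; qy <- ay + t * vy
    d <- sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
    if (d < best$dist) best <- list(dist = d, x = qx, y = qy, seg = i, t = t)
  }
  best
}

# Proper or touching intersection of segments (a1,a2) and (b1,b2).
# Returns c(x, y) or NULL. Collinear overlaps return NULL (the network
# builder treats shared vertices as nodes anyway).
.segIntersect <- function(a1, a2, b1, b2, eps = 1e-9) {
  r <- a2 - a1; s <- b2 - b1
  denom <- r[1] * s[2] - r[2] * s[1]
  scale <- max(abs(r), abs(s), 1)
  if (abs(denom) < eps * scale * scale) return(NULL)
  q <- b1 - a1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
  a1 + min(1, max(0, t)) * r
}

# Cut a polyline's piecewise segments into elementary straight pieces.
# Returns matrix with columns x1, y1, x2, y2 and the owning feature index.
.explodeSegments <- function(geoms) {
  out <- vector("list", length(geoms))
  for (k in seq_along(geoms)) {
    m <- geoms[[k]]
    n <- nrow(m) - 1L
    out[[k]] <- cbind(m[seq_len(n), 1], m[seq_len(n), 2],
                      m[seq_len(n) + 1L, 1], m[seq_len(n) + 1L, 2],
                      rep(k, n))
  }
  do.call(rbind, out)
}
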