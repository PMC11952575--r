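# Planar polygon primitives used throughout: polygons are n x 2 numeric
# matrices of vertices in file order, implicitly closed (last connects to
# first), coordinates in micrometres.

#' Signed polygon area (shoelace formula)
#'
#' @param poly numeric matrix with columns x, y; vertices in order, open ring.
#' @return Signed area; positive for counter-clockwise vertex order.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area in square micrometres
#' @param poly vertex matrix (x, y).
#' @return Nonnegative area.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(poly))

#' Polygon perimeter
#' @param poly vertex matrix (x, y).
#' @return Total boundary length.
#' @export
polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(sqrt((xs - x)^2 + (ys - y)^2))
}

#' Polygon centroid (area-weighted)
#' @param poly vertex matrix (x, y).
#' @return Length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Second-order area moments about the centroid; used for the best-fit
# ellipse (elongation feature). Standard closed forms from the shoelace
# decomposition into triangles.
polygon_second_moments <- function(poly) {
  c0 <- polygon_centroid(poly)
  x <- poly[, 1] - c0[1]; y <- poly[, 2] - c0[2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  ixx <- sum(cr * (y^2 + y * ys + ys^2)) / 12
  iyy <- sum(cr * (x^2 + x * xs + xs^2)) / 12
  ixy <- sum(cr * (x * ys + 2 * x * y + 2 * xs * ys + xs * y)) / 24
  a <- sum(cr) / 2
  s <- if (a < 0) -1 else 1
  list(ixx = s * ixx, iyy = s * iyy, ixy = s * ixy, area = abs(a))
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' Vectorized over query points. A point lying exactly on a polygon edge or
#' vertex is reported as inside: transcripts sitting on a nucleus outline
#' count as nuclear evidence.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly vertex matrix (x, y), open ring.
#' @param eps boundary tolerance in coordinate units.
#' @return Logical vector, one per query point.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- length(px)
  vx <- poly[, 1]; vy <- poly[, 2]
  m <- length(vx)
  inside <- logical(n)
  on_edge <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: point within eps of segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      on_edge <- on_edge | d2 <= eps * eps
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps * eps)
    }
    # even-odd ray crossing (horizontal ray to +x)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# TRUE if the (closed) polygon ring has no two non-adjacent edges that
# properly intersect. O(V^2); vertices per boundary polygon are few.
polygon_is_simple <- function(poly) {
  m <- nrow(poly)
  if (m < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:m, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    sign(round(v, 12))
  }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (j == i + 1 || (i == 1 && j == m)) next  # adjacent edges share a vertex
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4) return(FALSE)
    }
  }
  TRUE
}

# Clip a convex or simple polygon to the half-plane a*x + b*y <= c
# (Sutherland-Hodgman). Returns a vertex matrix, possibly with 0 rows.
clip_halfplane <- function(poly, a, b, c) {
  m <- nrow(poly)
  outx <- numeric(0); outy <- numeric(0)
  fi <- a * poly[, 1] + b * poly[, 2] - c
  j <- m
  for (i in seq_len(m)) {
    cur_in <- fi[i] <= 1e-12
    prev_in <- fi[j] <= 1e-12
    if (cur_in != prev_in) {
      t <- fi[j] / (fi[j] - fi[i])
      outx <- c(outx, poly[j, 1] + t * (poly[i, 1] - poly[j, 1]))
      outy <- c(outy, poly[j, 2] + t * (poly[i, 2] - poly[j, 2]))
    }
    if (cur_in) {
      outx <- c(outx, poly[i, 1]); outy <- c(outy, poly[i, 2])
    }
    j <- i
  }
  cbind(x = outx, y = outy)
}

#' Bounded Voronoi tessellation of a rectangle
#'
#' Computes the Voronoi cell of each seed point clipped to the rectangle
#' `[0, width] x [0, height]` by successive half-plane cuts against the
#' perpendicular bisectors to all other seeds. Cells are convex and tile the
#' rectangle exactly.
#'
#' @param x,y seed coordinates.
#' @param width,height rectangle extent.
#' @return List of vertex matrices, one convex polygon per seed.
#' @export
bounded_voronoi <- function(x, y, width, height) {
  n <- length(x)
  rect <- cbind(x = c(0, width, width, 0), y = c(0, 0, height, height))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      # keep points closer to seed i than seed j: bisector half-plane
      a <- x[j] - x[i]; b <- y[j] - y[i]
      c <- (x[j]^2 - x[i]^2 + y[j]^2 - y[i]^2) / 2
      poly <- clip_halfplane(poly, a, b, c)
      if (nrow(poly) < 3) break
    }
    out[[i]] <- poly
  }
  out
}

# Shrink a polygon linearly toward an anchor point (defaults to its
# centroid); scale in (0, 1] keeps the result inside a convex polygon.
scale_polygon <- function(poly, scale, anchor = polygon_centroid(poly)) {
  cbind(x = anchor[1] + scale * (poly[, 1] - anchor[1]),
        y = anchor[2] + scale * (poly[, 2] - anchor[2]))
}

# Distance from query points to a polygon: 0 inside (even-odd, boundary
# inclusive), else min distance to the boundary segments. Vectorized over
# points.
points_polygon_distance <- function(px, py, poly) {
  m <- nrow(poly)
  best <- rep(Inf, length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    best <- pmin(best, d2)
    j <- i
  }
  out <- sqrt(best)
  out[point_in_polygon(px, py, poly)] <- 0
  out
}

# Uniform samples inside a polygon by rejection from its bounding box.
sample_in_polygon <- function(n, poly) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  outx <- numeric(0); outy <- numeric(0)
  guard <- 0
  while (length(outx) < n) {
    m <- max(2 * (n - length(outx)), 16)
    cx <- stats::runif(m, bx[1], bx[2])
    cy <- stats::runif(m, by[1], by[2])
    keep <- point_in_polygon(cx, cy, poly)
    outx <- c(outx, cx[keep]); outy <- c(outy, cy[keep])
    guard <- guard + 1
    if (guard > 1000) stop("rejection sampling failed: degenerate polygon?")
  }
  cbind(x = outx[seq_len(n)], y = outy[seq_len(n)])
}
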