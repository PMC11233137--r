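#' Polygonal regions on a planar landscape
#'
#' A region is a named, simple (non-self-intersecting), implicitly closed
#' polygon stored counter-clockwise in abstract planar map units. Regions
#' encode population ranges and habitable patches of a [world()].
#'
#' @param name Region name (used when serializing to WKT).
#' @param coords Two-column numeric matrix (or data frame) of vertices,
#'   ordered along the boundary; the closing vertex must not be repeated.
#' @return An object of class `popscape_region`.
#' @examples
#' sq <- region("square", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' region_area(sq)
#' @export
region <- function(name, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2 || nrow(coords) < 3)
    stop("a region needs a two-column matrix with at least 3 vertices", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("region coordinates must be finite", call. = FALSE)
  # drop a repeated closing vertex if the caller supplied one
  n <- nrow(coords)
  if (isTRUE(all(coords[1, ] == coords[n, ]))) coords <- coords[-n, , drop = FALSE]
  if (signed_area(coords) < 0) coords <- coords[rev(seq_len(nrow(coords))), , drop = FALSE]
  if (abs(signed_area(coords)) <= 0)
    stop("region '", name, "' has zero area", call. = FALSE)
  if (!is_simple_polygon(coords))
    stop("region '", name, "' has a self-intersecting boundary", call. = FALSE)
  structure(list(name = as.character(name), coords = coords),
            class = "popscape_region")
}

#' @export
print.popscape_region <- function(x, ...) {
  cat(sprintf("<region '%s'> %d vertices, area %.6g\n",
              x$name, nrow(x$coords), region_area(x)))
  invisible(x)
}

#' Circular region discretized as a regular polygon
#'
#' Circles are represented as regular polygons (64 vertices by default, which
#' keeps the area error below 0.2%); all landscape geometry is polygonal.
#'
#' @param name Region name.
#' @param center Numeric `c(x, y)`.
#' @param radius Circle radius in map units.
#' @param vertices Number of polygon vertices.
#' @export
region_circle <- function(name, center, radius, vertices = 64) {
  stopifnot(radius > 0, vertices >= 8)
  theta <- 2 * pi * (seq_len(vertices) - 1) / vertices
  region(name, cbind(center[1] + radius * cos(theta),
                     center[2] + radius * sin(theta)))
}

# shoelace signed area; positive for counter-clockwise vertex order
signed_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of a region (shoelace formula)
#' @param r A [region()].
#' @export
region_area <- function(r) abs(signed_area(r$coords))

# O(V^2) segment-intersection test for polygon simplicity; adjacent edges
# sharing a vertex are allowed to touch.
is_simple_polygon <- function(coords) {
  n <- nrow(coords)
  if (n < 4) return(TRUE)
  seg <- function(i) rbind(coords[i, ], coords[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(s1, s2) {
  d1 <- cross2(s2[2, ] - s2[1, ], s1[1, ] - s2[1, ])
  d2 <- cross2(s2[2, ] - s2[1, ], s1[2, ] - s2[1, ])
  d3 <- cross2(s1[2, ] - s1[1, ], s2[1, ] - s1[1, ])
  d4 <- cross2(s1[2, ] - s1[1, ], s2[2, ] - s1[1, ])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Define a planar world with binary habitability
#'
#' The world is an axis-aligned rectangular extent in abstract planar map
#' units. Habitability is binary: if no habitable regions are given, the
#' entire extent is habitable; otherwise only points inside at least one of
#' the regions are. Supplied regions are clipped to the extent.
#'
#' @param xrange,yrange Numeric length-2 vectors giving the extent.
#' @param regions List of [region()] objects forming the habitable set
#'   (empty list: the whole extent is habitable).
#' @return An object of class `popscape_world`.
#' @examples
#' w <- world(xrange = c(0, 100), yrange = c(0, 100))
#' @export
world <- function(xrange = c(0, 1), yrange = c(0, 1), regions = list()) {
  if (!(xrange[2] > xrange[1]) || !(yrange[2] > yrange[1]))
    stop("degenerate world extent", call. = FALSE)
  if (inherits(regions, "popscape_region")) regions <- list(regions)
  w <- structure(list(xmin = xrange[1], xmax = xrange[2],
                      ymin = yrange[1], ymax = yrange[2],
                      habitable = list()),
                 class = "popscape_world")
  w$habitable <- lapply(regions, function(r) {
    cl <- clip_polygon_rect(r$coords, w$xmin, w$xmax, w$ymin, w$ymax)
    if (is.null(cl))
      stop("habitable region '", r$name, "' lies entirely outside the world extent",
           call. = FALSE)
    region(r$name, cl)
  })
  w
}

#' @export
print.popscape_world <- function(x, ...) {
  cat(sprintf("<world> extent [%g, %g] x [%g, %g], %s\n",
              x$xmin, x$xmax, x$ymin, x$ymax,
              if (length(x$habitable) == 0) "fully habitable"
              else sprintf("%d habitable region(s)", length(x$habitable))))
  invisible(x)
}

world_diagonal <- function(w) sqrt((w$xmax - w$xmin)^2 + (w$ymax - w$ymin)^2)

#' Point-in-region test (closed-set convention)
#'
#' Even-odd ray-casting test; points on the boundary count as inside, so the
#' habitable set is closed and rejection sampling terminates on thin regions.
#'
#' @param p Numeric `c(x, y)` or a two-column matrix of points.
#' @param r A [region()].
#' @return Logical vector, one element per point.
#' @export
point_in_region <- function(p, r) {
  p <- to_points(p)
  pip_cpp(p[, 1], p[, 2], r$coords[, 1], r$coords[, 2], 1e-9)
}

to_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 2, byrow = length(p) > 2) else as.matrix(p)
}

#' Habitability test for points of a world
#' @param w A [world()].
#' @param p Point(s) as for [point_in_region()].
#' @return Logical vector.
#' @export
is_habitable <- function(w, p) {
  p <- to_points(p)
  inx <- p[, 1] >= w$xmin & p[, 1] <= w$xmax & p[, 2] >= w$ymin & p[, 2] <= w$ymax
  if (length(w$habitable) == 0) return(inx)
  hab <- rep(FALSE, nrow(p))
  for (r in w$habitable) hab <- hab | point_in_region(p, r)
  inx & hab
}

#' Uniform sampling of points on the habitable part of a region
#'
#' Bounding-box rejection sampling on the intersection of the region with the
#' world's habitable set. Errors when the intersection is (effectively) empty.
#'
#' @param w A [world()].
#' @param r A [region()].
#' @param n Number of points.
#' @return An `n` x 2 matrix of coordinates.
#' @export
sample_point_uniform <- function(w, r, n = 1) {
  bb <- apply(r$coords, 2, range)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  consecutive_rejects <- 0
  while (filled < n) {
    m <- max(2L * (n - filled), 64L)
    cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                  stats::runif(m, bb[1, 2], bb[2, 2]))
    ok <- point_in_region(cand, r) & is_habitable(w, cand)
    k <- sum(ok)
    if (k > 0) {
      take <- min(k, n - filled)
      out[filled + seq_len(take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
      filled <- filled + take
      consecutive_rejects <- 0
    } else {
      consecutive_rejects <- consecutive_rejects + m
      if (consecutive_rejects > 1e5)
        stop("could not place a point in region '", r$name,
             "': intersection with the habitable area looks degenerate or empty",
             call. = FALSE)
    }
  }
  out
}

#' Translate a region by a fixed offset
#' @param r A [region()].
#' @param dx,dy Offsets in map units.
#' @export
translate_region <- function(r, dx, dy) {
  region(r$name, cbind(r$coords[, 1] + dx, r$coords[, 2] + dy))
}

# distance from the centroid to the nearest boundary edge: an upper bound on
# how far a (convex) region can be contracted before collapsing
region_inradius <- function(r) {
  cen <- region_centroid(r)
  coords <- r$coords
  n <- nrow(coords)
  dmin <- Inf
  j <- n
  for (i in seq_len(n)) {
    a <- coords[j, ]; b <- coords[i, ]
    ab <- b - a
    t <- min(1, max(0, sum((cen - a) * ab) / sum(ab^2)))
    dmin <- min(dmin, sqrt(sum((cen - (a + t * ab))^2)))
    j <- i
  }
  dmin
}

region_centroid <- function(r) {
  x <- r$coords[, 1]; y <- r$coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Grow or shrink a region by a distance
#'
#' Offsets the boundary outward (`d > 0`) or inward (`d < 0`) along vertex
#' angle-bisectors (exact for convex regions up to the polygonal
#' discretization), then clips the result to the world extent and, when the
#' world has a single habitable region, to that region as well.
#'
#' @param r A [region()].
#' @param d Offset distance in map units (negative contracts; its magnitude
#'   must stay below the region's inradius).
#' @param w A [world()].
#' @export
buffer_region <- function(r, d, w) {
  if (d < 0 && -d >= region_inradius(r))
    stop("negative buffer collapses region '", r$name, "' to zero area", call. = FALSE)
  coords <- if (d == 0) r$coords else offset_polygon(r$coords, d)
  if (is.null(coords) || abs(signed_area(coords)) <= 0)
    stop("negative buffer collapses region '", r$name, "' to zero area", call. = FALSE)
  coords <- clip_polygon_rect(coords, w$xmin, w$xmax, w$ymin, w$ymax)
  if (is.null(coords))
    stop("buffered region '", r$name, "' falls outside the world extent", call. = FALSE)
  if (length(w$habitable) == 1) {
    coords <- clip_polygon_convex(coords, w$habitable[[1]]$coords)
    if (is.null(coords))
      stop("buffered region '", r$name, "' has no habitable area", call. = FALSE)
  }
  out <- region(r$name, coords)
  if (d < 0 && region_area(out) >= region_area(r))
    stop("negative buffer collapses region '", r$name, "' to zero area", call. = FALSE)
  out
}

# miter offsetting along outward vertex bisectors (CCW polygon)
offset_polygon <- function(coords, d) {
  n <- nrow(coords)
  prev <- coords[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- coords[c(2:n, 1), , drop = FALSE]
  e1 <- coords - prev     # incoming edge
  e2 <- nxt - coords      # outgoing edge
  norm <- function(v) v / pmax(sqrt(rowSums(v^2)), 1e-300)
  # outward normal of a CCW edge (dx, dy) is (dy, -dx)
  n1 <- norm(cbind(e1[, 2], -e1[, 1]))
  n2 <- norm(cbind(e2[, 2], -e2[, 1]))
  u <- norm(n1 + n2)
  cosh2 <- pmax(rowSums(u * n1), 0.05)  # cap the miter at sharp vertices
  out <- coords + u * (d / cosh2)
  if (abs(signed_area(out)) <= 0) return(NULL)
  if (signed_area(out) < 0) return(NULL)  # inward offset flipped the polygon
  if (!is_simple_polygon(out)) return(NULL)
  out
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
clip_polygon_rect <- function(coords, xmin, xmax, ymin, ymax) {
  clip_halfplane <- function(pts, inside, intersect) {
    if (is.null(pts) || nrow(pts) == 0) return(NULL)
    n <- nrow(pts)
    out <- matrix(NA_real_, 2 * n, 2)
    k <- 0L
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prv <- pts[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi_ <- inside(prv)
      if (ci) {
        if (!pi_) { k <- k + 1L; out[k, ] <- intersect(prv, cur) }
        k <- k + 1L; out[k, ] <- cur
      } else if (pi_) {
        k <- k + 1L; out[k, ] <- intersect(prv, cur)
      }
    }
    if (k < 3) return(NULL)
    dedupe_vertices(out[seq_len(k), , drop = FALSE])
  }
  ix <- function(a, b, t) a + t * (b - a)
  coords <- clip_halfplane(coords, function(p) p[1] >= xmin,
    function(a, b) ix(a, b, (xmin - a[1]) / (b[1] - a[1])))
  coords <- clip_halfplane(coords, function(p) p[1] <= xmax,
    function(a, b) ix(a, b, (xmax - a[1]) / (b[1] - a[1])))
  coords <- clip_halfplane(coords, function(p) p[2] >= ymin,
    function(a, b) ix(a, b, (ymin - a[2]) / (b[2] - a[2])))
  coords <- clip_halfplane(coords, function(p) p[2] <= ymax,
    function(a, b) ix(a, b, (ymax - a[2]) / (b[2] - a[2])))
  if (!is.null(coords) && abs(signed_area(coords)) <= 0) return(NULL)
  coords
}

# Sutherland-Hodgman against an arbitrary convex CCW clip polygon
clip_polygon_convex <- function(subject, clip) {
  n <- nrow(clip)
  pts <- subject
  for (i in seq_len(n)) {
    if (is.null(pts)) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    dxy <- b - a
    side <- function(p) dxy[1] * (p[2] - a[2]) - dxy[2] * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      den <- dxy[1] * (q[2] - p[2]) - dxy[2] * (q[1] - p[1])
      t <- (dxy[1] * (a[2] - p[2]) - dxy[2] * (a[1] - p[1])) / den
      p + t * (q - p)
    }
    m <- nrow(pts)
    out <- matrix(NA_real_, 2 * m, 2)
    k <- 0L
    for (j in seq_len(m)) {
      cur <- pts[j, ]; prv <- pts[if (j == 1) m else j - 1, ]
      ci <- side(cur); pi_ <- side(prv)
      if (ci) {
        if (!pi_) { k <- k + 1L; out[k, ] <- inter(prv, cur) }
        k <- k + 1L; out[k, ] <- cur
      } else if (pi_) {
        k <- k + 1L; out[k, ] <- inter(prv, cur)
      }
    }
    pts <- if (k < 3) NULL else dedupe_vertices(out[seq_len(k), , drop = FALSE])
  }
  if (!is.null(pts) && abs(signed_area(pts)) <= 0) return(NULL)
  pts
}

dedupe_vertices <- function(coords, eps = 1e-12) {
  n <- nrow(coords)
  nxt <- coords[c(2:n, 1), , drop = FALSE]
  keep <- rowSums((coords - nxt)^2) > eps^2
  out <- coords[keep, , drop = FALSE]
  if (nrow(out) < 3) return(NULL)
  out
}

# deterministic grid probe for "positive habitable area" checks
habitable_fraction <- function(w, r, grid = 24) {
  bb <- apply(r$coords, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = grid)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = grid)
  pts <- cbind(rep(gx, times = grid), rep(gy, each = grid))
  ok <- point_in_region(pts, r) & is_habitable(w, pts)
  mean(ok)
}

has_habitable_area <- function(w, r) {
  if (habitable_fraction(w, r) > 0) return(TRUE)
  # fall back to the centroid and vertices for very thin regions
  probes <- rbind(region_centroid(r), r$coords)
  any(point_in_region(probes, r) & is_habitable(w, probes))
}

#' Serialize a region to WKT POLYGON text
#' @param r A [region()].
#' @return A WKT string (closed ring, counter-clockwise).
#' @export
region_to_wkt <- function(r) {
  coords <- rbind(r$coords, r$coords[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.17g %.17g", coords[, 1], coords[, 2]), collapse = ", "))
}

#' Parse a WKT POLYGON string into a region
#' @param name Region name.
#' @param wkt WKT `POLYGON ((...))` text (single ring).
#' @export
wkt_to_region <- function(name, wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\)\\s*$", "", body)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  coords <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  region(name, coords)
}
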