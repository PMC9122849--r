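# Planar geometry for the optional polygon input path. Geometries must be in
# a planar, meter-based coordinate system; no reprojection is attempted.

shoelace_area <- function(xy) {
  # signed area; xy is an n x 2 matrix, ring implicitly closed
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

point_in_polygon <- function(px, py, xy) {
  # even-odd ray casting, vectorized over query points
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

dist_point_segments <- function(p, xy) {
  # min distance from point p to the closed ring's segments
  a <- xy
  b <- xy[c(seq_len(nrow(xy))[-1L], 1L), , drop = FALSE]
  dx <- b[, 1L] - a[, 1L]; dy <- b[, 2L] - a[, 2L]
  len2 <- dx^2 + dy^2
  t <- ((p[1L] - a[, 1L]) * dx + (p[2L] - a[, 2L]) * dy) / ifelse(len2 == 0, 1, len2)
  t <- pmin(1, pmax(0, t))
  qx <- a[, 1L] + t * dx; qy <- a[, 2L] + t * dy
  sqrt(min((p[1L] - qx)^2 + (p[2L] - qy)^2))
}

regular_ngon <- function(center, radius, k) {
  theta <- 2 * pi * (seq_len(k) - 1L) / k
  cbind(center[1L] + radius * cos(theta), center[2L] + radius * sin(theta))
}

clip_convex <- function(subject, clip) {
  # Sutherland-Hodgman: clip subject ring against convex ring (CCW)
  out <- subject
  k <- nrow(clip)
  for (i in seq_len(k)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == k) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    side <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])  # >= 0 inside
    n <- nrow(out)
    prev <- c(n, seq_len(n - 1L))
    side_prev <- side[prev]
    keep <- side >= 0
    cross_in <- keep & side_prev < 0    # entering: add intersection then vertex
    cross_out <- !keep & side_prev >= 0 # leaving: add intersection only
    t_num <- side_prev
    t_den <- side_prev - side
    t <- ifelse(t_den == 0, 0, t_num / t_den)
    ix <- out[prev, 1L] + t * (out[, 1L] - out[prev, 1L])
    iy <- out[prev, 2L] + t * (out[, 2L] - out[prev, 2L])
    # assemble output preserving order
    pieces <- vector("list", n)
    for (v in seq_len(n)) {
      if (cross_in[v]) {
        pieces[[v]] <- rbind(c(ix[v], iy[v]), out[v, ])
      } else if (keep[v]) {
        pieces[[v]] <- out[v, , drop = FALSE]
      } else if (cross_out[v]) {
        pieces[[v]] <- matrix(c(ix[v], iy[v]), 1L)
      }
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) out <- matrix(numeric(0), 0L, 2L)
  }
  out
}

check_polygon <- function(poly, i) {
  if (!is.list(poly) || is.null(poly$class) || is.null(poly$xy)) {
    stop("polygon ", i, ": expected list(class = <chr>, xy = <n x 2 matrix>)",
         call. = FALSE)
  }
  xy <- as.matrix(poly$xy)
  if (!is.numeric(xy) || ncol(xy) != 2L || nrow(xy) < 3L || anyNA(xy) ||
      any(!is.finite(xy))) {
    stop("polygon ", i, ": degenerate or non-planar geometry", call. = FALSE)
  }
  if (abs(shoelace_area(xy)) <= 0) {
    stop("polygon ", i, ": zero-area geometry", call. = FALSE)
  }
  if (!poly$class %in% setdiff(landcover_classes(), "other")) {
    stop("polygon ", i, ": unknown class '", poly$class, "'", call. = FALSE)
  }
  list(class = as.character(poly$class), xy = xy)
}

#' Landscape composition from labelled polygons
#'
#' Intersects each class polygon with the disc of radius `radius` around
#' `center` and reports class areas as proportions of the disc; area not
#' covered by any polygon is assigned to `"other"`. Distances are the
#' Euclidean distance from the center to the nearest forest / urban polygon
#' (0 if the center lies inside one, `NA` if the class is absent).
#'
#' The disc is represented by a regular `n_arc`-gon, and polygons are clipped
#' against it exactly (Sutherland-Hodgman); proportions use the polygonal
#' disc area as denominator, so the arc discretization cancels to first
#' order. If polygons overlap, the later-listed polygon wins: a warning is
#' raised and areas are re-measured on a fine point grid where each point is
#' assigned to the last polygon containing it.
#'
#' @param polygons List of `list(class =, xy =)` entries; `xy` is an
#'   `n x 2` vertex matrix in meters, ring closed implicitly.
#' @param center Numeric length-2 center point (meters).
#' @param radius Disc radius in meters (default 500, the study design).
#' @param landscape_id Identifier for the output row.
#' @param n_arc Vertices of the polygonal disc (default 720).
#' @param grid_n Grid resolution per axis for the overlap fallback
#'   (default 301).
#' @return One-row data.frame in the [landscape_composition()] layout.
#' @export
composition_from_polygons <- function(polygons, center = c(0, 0), radius = 500,
                                      landscape_id = "L1", n_arc = 720L,
                                      grid_n = 301L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive number of meters", call. = FALSE)
  }
  polygons <- lapply(seq_along(polygons),
                     function(i) check_polygon(polygons[[i]], i))
  disc <- regular_ngon(center, radius, n_arc)
  disc_area <- abs(shoelace_area(disc))

  # overlap probe on a grid restricted to the disc
  gx <- seq(center[1L] - radius, center[1L] + radius, length.out = grid_n)
  gy <- seq(center[2L] - radius, center[2L] + radius, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gy)
  in_disc <- (pts$x - center[1L])^2 + (pts$y - center[2L])^2 <= radius^2
  pts <- pts[in_disc, ]
  member <- vapply(polygons,
                   function(p) point_in_polygon(pts$x, pts$y, p$xy),
                   logical(nrow(pts)))
  if (length(polygons) == 0L) member <- matrix(FALSE, nrow(pts), 0L)
  overlap <- nrow(pts) > 0L && any(rowSums(member) > 1L)

  classes <- landcover_classes()
  areas <- stats::setNames(numeric(length(classes)), classes)
  if (!overlap) {
    for (p in polygons) {
      ring <- p$xy
      if (shoelace_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
      clipped <- clip_convex(ring, disc)
      if (nrow(clipped) >= 3L) {
        areas[p$class] <- areas[p$class] + abs(shoelace_area(clipped))
      }
    }
    prop <- areas / disc_area
  } else {
    warning("overlapping polygons: later-listed class wins; areas measured ",
            "on a ", grid_n, "-per-axis grid", call. = FALSE)
    last <- apply(member, 1L, function(m) if (any(m)) max(which(m)) else NA_integer_)
    cls <- vapply(polygons, `[[`, "", "class")
    counts <- table(factor(cls[last], levels = classes))
    prop <- as.numeric(counts) / nrow(pts)
    names(prop) <- classes
  }
  prop["other"] <- max(0, 1 - sum(prop[setdiff(classes, "other")]))

  class_dist <- function(cl) {
    of_cl <- Filter(function(p) p$class == cl, polygons)
    if (length(of_cl) == 0L) return(NA_real_)
    if (any(vapply(of_cl, function(p)
      point_in_polygon(center[1L], center[2L], p$xy), logical(1L)))) return(0)
    min(vapply(of_cl, function(p) dist_point_segments(center, p$xy), numeric(1L)))
  }
  data.frame(landscape_id = landscape_id, t(prop),
             dist_forest_m = class_dist("forest"),
             dist_urban_m = class_dist("urban"),
             row.names = NULL, stringsAsFactors = FALSE)
}
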