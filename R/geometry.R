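#' Closed planar contour
#'
#' Ordered 2D points (cm) tracing a closed, simple curve (closure implicit:
#' last point is not a repeat of the first). Contours are canonically stored
#' counter-clockwise; clockwise input is reversed.
#'
#' @param points n x 2 numeric matrix (cm), n >= 8.
#' @return n x 2 matrix of class \code{contour_2d}.
#' @export
contour <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 8L || any(!is.finite(points)))
    stop("contour needs a finite n x 2 matrix with n >= 8")
  if (sum(abs(points[1, ] - points[nrow(points), ])) < 1e-12)
    points <- points[-nrow(points), , drop = FALSE]
  if (polygon_area_signed(points) < 0)
    points <- points[nrow(points):1, , drop = FALSE]
  structure(points, class = c("contour_2d", "matrix"))
}

polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#' @param p contour or n x 2 matrix.
#' @return unsigned area (cm^2).
#' @export
polygon_area <- function(p) abs(polygon_area_signed(as.matrix(p)))

#' Polygon perimeter
#' @param p contour or n x 2 matrix (closed implicitly).
#' @return perimeter (cm).
#' @export
polygon_perimeter <- function(p) {
  p <- as.matrix(p)
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Area centroid of a simple polygon (internal)
polygon_centroid <- function(p) {
  p <- as.matrix(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Ventricle short-axis slice
#'
#' @param inner,outer \code{\link{contour}} objects (endocardial and
#'   epicardial borders); inner area must be smaller.
#' @param z long-axis position (cm).
#' @return object of class \code{ventricle_slice}.
#' @export
ventricle_slice <- function(inner, outer, z) {
  if (!inherits(inner, "contour_2d")) inner <- contour(inner)
  if (!inherits(outer, "contour_2d")) outer <- contour(outer)
  if (polygon_area(inner) >= polygon_area(outer))
    stop("inner contour area must be smaller than outer")
  structure(list(inner = inner, outer = outer, z = as.numeric(z)),
            class = "ventricle_slice")
}

#' Contour stack
#'
#' Ordered short-axis slices with their spacing, the geometric substrate for
#' volumes, wall thickness, curvature and the pre-shrink process.
#'
#' @param slices list of \code{\link{ventricle_slice}} objects, z strictly
#'   monotone (base to apex).
#' @param spacing slice spacing (cm); each slice contributes a disk of this
#'   thickness to Simpson (disk-summation) volumes. Default: mean z increment.
#' @param label free-text frame label (e.g. "diastole", "systole",
#'   "in-vivo").
#' @return object of class \code{contour_stack}.
#' @export
contour_stack <- function(slices, spacing = NULL, label = "in-vivo") {
  z <- vapply(slices, function(s) s$z, 0)
  if (length(slices) < 2L) stop("contour stack needs >= 2 slices")
  dz <- diff(z)
  if (any(dz <= 0) && any(dz >= 0) && !(all(dz > 0) || all(dz < 0)))
    stop("slice z positions must be strictly monotone")
  if (any(dz == 0)) stop("slice z positions must be strictly monotone")
  if (is.null(spacing)) spacing <- mean(abs(dz))
  structure(list(slices = slices, spacing = spacing, label = label),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat("contour_stack:", length(x$slices), "slices, spacing",
      signif(x$spacing, 4), "cm, label:", x$label, "\n")
  cat("  inner volume:", signif(stack_volume(x, "inner"), 5), "cm^3;",
      "wall volume:", signif(stack_volume(x, "outer") -
                               stack_volume(x, "inner"), 5), "cm^3\n")
  invisible(x)
}

#' Resample a contour to equal arc-length spacing
#'
#' Points are placed at equal arc length along the closed polyline, starting
#' at the contour's crossing of the +x ray from its centroid (the package's
#' common start-point convention, which index-aligns meridians across slices).
#'
#' @param c a \code{\link{contour}}.
#' @param n number of points (default 100, the per-slice nodal count used
#'   throughout).
#' @return resampled \code{contour}.
#' @export
resample_contour <- function(c, n = 100) {
  if (!inherits(c, "contour_2d")) c <- contour(c)
  if (n < 8) stop("n must be >= 8")
  p <- unclass(c)
  L <- polygon_perimeter(p)
  if (L < 1e-12) stop("degenerate contour: zero perimeter")
  ctr <- polygon_centroid(p)
  q <- rbind(p, p[1, ])
  seg <- diff(q)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  # arc-length position of the +x axis crossing from the centroid
  s0 <- NA_real_
  yy <- q[, 2] - ctr[2]
  for (i in seq_len(nrow(q) - 1)) {
    y1 <- yy[i]; y2 <- yy[i + 1]
    if ((y1 <= 0 && y2 > 0) || (y1 == 0 && y2 == 0)) { # CCW upward crossing
      t <- if (y2 == y1) 0 else -y1 / (y2 - y1)
      xc <- q[i, 1] + t * seg[i, 1]
      if (xc > ctr[1]) { s0 <- cum[i] + t * seglen[i]; break }
    }
  }
  if (is.na(s0)) s0 <- 0
  s <- (s0 + L * (seq_len(n) - 1) / n) %% L
  xs <- stats::approx(cum, q[, 1], xout = s, rule = 2)$y
  ys <- stats::approx(cum, q[, 2], xout = s, rule = 2)$y
  contour(cbind(xs, ys))
}

# Resample both borders of every slice (internal convenience)
resample_stack <- function(s, n = 100) {
  slices <- lapply(s$slices, function(sl)
    ventricle_slice(resample_contour(sl$inner, n),
                    resample_contour(sl$outer, n), sl$z))
  contour_stack(slices, s$spacing, s$label)
}

#' Simpson-method (disk summation) stack volume
#'
#' The cardiology "Simpson" rule: the sum of slice cross-sectional areas times
#' the slice spacing. Areas are shoelace polygon areas.
#'
#' @param s a \code{\link{contour_stack}}.
#' @param surface \code{"inner"} (cavity) or \code{"outer"}
#'   (cavity + wall).
#' @return volume (cm^3).
#' @export
stack_volume <- function(s, surface = c("inner", "outer")) {
  surface <- match.arg(surface)
  areas <- vapply(s$slices, function(sl) polygon_area(sl[[surface]]), 0)
  sum(areas) * s$spacing
}

#' Wall thickness of a slice
#'
#' Thickness at each inner (endocardial) point is the distance to the outer
#' contour along the inner outward normal (nearest ray intersection). Points
#' whose normal ray misses the outer polygon fall back to the nearest-vertex
#' distance and are flagged.
#'
#' @param s a \code{\link{ventricle_slice}} (contours are resampled to
#'   \code{n} points internally).
#' @param n nodal points per contour (default 100).
#' @return list with \code{per_point} thickness (cm), \code{mean}, and
#'   logical \code{fallback} flags.
#' @export
wall_thickness <- function(s, n = 100) {
  inner <- unclass(resample_contour(s$inner, n))
  outer <- unclass(resample_contour(s$outer, n))
  m <- nrow(inner)
  # central-difference tangents, outward normals (CCW contour)
  nxt <- inner[c(2:m, 1), ]; prv <- inner[c(m, 1:(m - 1)), ]
  tang <- nxt - prv
  tl <- sqrt(rowSums(tang^2))
  nrm <- cbind(tang[, 2], -tang[, 1]) / tl
  oq <- rbind(outer, outer[1, ])
  a <- oq[-nrow(oq), ]; b <- oq[-1, ]
  ab <- b - a
  th <- numeric(m); fb <- logical(m)
  for (i in seq_len(m)) {
    p0 <- inner[i, ]; d <- nrm[i, ]
    # solve p0 + t d = a + u ab for every outer segment
    den <- d[1] * (-ab[, 2]) - d[2] * (-ab[, 1])
    rhs1 <- a[, 1] - p0[1]; rhs2 <- a[, 2] - p0[2]
    tpar <- (rhs1 * (-ab[, 2]) - rhs2 * (-ab[, 1])) / den
    upar <- (d[1] * rhs2 - d[2] * rhs1) / den
    ok <- is.finite(tpar) & tpar > 1e-9 & upar >= -1e-9 & upar <= 1 + 1e-9
    if (any(ok)) {
      th[i] <- min(tpar[ok])
    } else {
      th[i] <- sqrt(min(rowSums((outer - rep(p0, each = nrow(outer)))^2)))
      fb[i] <- TRUE
    }
  }
  list(per_point = th, mean = mean(th), fallback = fb)
}

# Least-squares (Kasa) circle fit; returns curvature 1/R, 0 if collinear
circle_fit_curvature <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
  if (is.null(sol)) return(0)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(0)
  1 / sqrt(r2)
}

#' Circumferential curvature of a contour
#'
#' Unsigned curvature at each point from a least-squares circle fit over a
#' sliding window of neighbouring points.
#'
#' @param c a resampled \code{\link{contour}}.
#' @param window window width in points (odd, default 7).
#' @return list with \code{per_point} (1/cm) and \code{mean}.
#' @export
circumferential_curvature <- function(c, window = 7) {
  p <- as.matrix(c)
  m <- nrow(p)
  h <- window %/% 2
  kap <- numeric(m)
  for (i in seq_len(m)) {
    idx <- ((i - h - 1):(i + h - 1)) %% m + 1
    kap[i] <- circle_fit_curvature(p[idx, 1], p[idx, 2])
  }
  list(per_point = kap, mean = mean(kap))
}

#' Longitudinal curvature of a contour stack
#'
#' After resampling every inner contour to a common point count (index-aligned
#' meridians via the shared start-point convention), each meridian j is the
#' polyline of point j across slices. Its points are expressed as (distance
#' from the long axis, z) and an unsigned sliding-window circle-fit curvature
#' is computed in that meridional plane.
#'
#' @param s a \code{\link{contour_stack}} with >= 3 slices.
#' @param n points per contour (default 100).
#' @param window sliding window in slices (default 5, clamped to the slice
#'   count).
#' @return list with \code{per_point} (slices x n matrix, 1/cm) and
#'   \code{mean}.
#' @export
longitudinal_curvature <- function(s, n = 100, window = 5) {
  if (length(s$slices) < 3L) stop("longitudinal curvature needs >= 3 slices")
  inner <- lapply(s$slices, function(sl) unclass(resample_contour(sl$inner, n)))
  z <- vapply(s$slices, function(sl) sl$z, 0)
  ctrs <- t(vapply(inner, polygon_centroid, numeric(2)))
  axis_xy <- colMeans(ctrs)
  m <- length(inner)
  w <- min(window, m)
  if (w < 3) w <- 3
  h <- w %/% 2
  kap <- matrix(0, m, n)
  rho <- vapply(inner, function(p)
    sqrt((p[, 1] - axis_xy[1])^2 + (p[, 2] - axis_xy[2])^2), numeric(n))
  rho <- t(rho)                           # slices x points
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      i0 <- max(1, min(i - h, m - w + 1))
      idx <- i0:(i0 + w - 1)
      kap[i, j] <- circle_fit_curvature(rho[idx, j], z[idx])
    }
  }
  list(per_point = kap, mean = mean(kap))
}

#' Quarter partition of a slice
#'
#' Splits the (resampled) inner contour into 4 contiguous index sets of equal
#' inner-wall circumferential arc length.
#'
#' @param s a \code{\link{ventricle_slice}}.
#' @param n points per contour (default 100).
#' @return list of 4 integer index vectors (disjoint cover of 1..n).
#' @export
quarter_partition <- function(s, n = 100) {
  inner <- unclass(resample_contour(s$inner, n))
  q <- rbind(inner, inner[1, ])
  seglen <- sqrt(rowSums(diff(q)^2))
  spos <- c(0, cumsum(seglen))[seq_len(n)]    # arc position of each point
  L <- sum(seglen)
  qt <- pmin(floor(spos / (L / 4)) + 1L, 4L)
  lapply(1:4, function(k) which(qt == k))
}

#' Two-layer fiber orientation specification
#'
#' @param epi_angle epicardial fiber angle (degrees from circumferential,
#'   default -60).
#' @param endo_angle endocardial fiber angle (degrees, default +80).
#' @param boundary_frac transmural depth fraction splitting the two layers
#'   (default 0.5).
#' @return object of class \code{fiber_layer_spec}.
#' @export
fiber_layer_spec <- function(epi_angle = -60, endo_angle = 80,
                             boundary_frac = 0.5) {
  stopifnot(epi_angle > -90, epi_angle <= 90,
            endo_angle > -90, endo_angle <= 90,
            boundary_frac > 0, boundary_frac < 1)
  structure(list(epi_angle = epi_angle, endo_angle = endo_angle,
                 boundary_frac = boundary_frac),
            class = "fiber_layer_spec")
}

#' Assign two-layer fiber directions on a contour stack
#'
#' At every inner-contour nodal point the local frame is (circumferential
#' tangent, longitudinal direction, transmural outward normal); the fiber
#' vector lies in the wall tangent plane at the layer's angle from the
#' circumferential direction.
#'
#' @param s a \code{\link{contour_stack}}.
#' @param spec a \code{\link{fiber_layer_spec}}.
#' @param n points per contour (default 100).
#' @return list per slice with \code{endo} and \code{epi} n x 3 unit-vector
#'   matrices and the transmural \code{normal} matrix.
#' @export
assign_fibers <- function(s, spec = fiber_layer_spec(), n = 100) {
  stopifnot(inherits(spec, "fiber_layer_spec"))
  lapply(s$slices, function(sl) {
    inner <- unclass(resample_contour(sl$inner, n))
    m <- nrow(inner)
    nxt <- inner[c(2:m, 1), ]; prv <- inner[c(m, 1:(m - 1)), ]
    tang <- nxt - prv
    tl <- sqrt(rowSums(tang^2))
    if (any(tl == 0)) stop("missing normals: degenerate tangent")
    that <- cbind(tang / tl, 0)                      # circumferential
    nhat <- cbind(tang[, 2] / tl, -tang[, 1] / tl, 0) # transmural outward
    lhat <- cbind(0, 0, 1)[rep(1, m), , drop = FALSE] # longitudinal (n x t)
    mk <- function(ang) {
      a <- ang * pi / 180
      v <- cos(a) * that + sin(a) * lhat
      v / sqrt(rowSums(v^2))
    }
    list(endo = mk(spec$endo_angle), epi = mk(spec$epi_angle), normal = nhat)
  })
}

#' Read a contour stack from JSON
#'
#' Schema: \code{{"spacing_cm": s, "label": l, "slices": [{"z": z,
#' "inner": [[x,y],...], "outer": [[x,y],...]}]}}.
#'
#' @param path JSON file path.
#' @return a \code{\link{contour_stack}}.
#' @export
read_contour_stack <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(x, i) {
    m <- if (is.array(x) && length(dim(x)) == 3L) x[i, , ] else x[[i]]
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.numeric(m), ncol = 2L)
  }
  slices <- vector("list", length(j$slices$z))
  for (i in seq_along(slices)) {
    slices[[i]] <- ventricle_slice(contour(pick(j$slices$inner, i)),
                                   contour(pick(j$slices$outer, i)),
                                   j$slices$z[i])
  }
  contour_stack(slices, spacing = j$spacing_cm, label = j$label %||% "in-vivo")
}

#' Write a contour stack to JSON
#'
#' @param s a \code{\link{contour_stack}}.
#' @param path output file path.
#' @export
write_contour_stack <- function(s, path) {
  j <- list(spacing_cm = s$spacing, label = s$label,
            slices = list(
              z = vapply(s$slices, function(sl) sl$z, 0),
              inner = lapply(s$slices, function(sl)
                unname(as.matrix(sl$inner))),
              outer = lapply(s$slices, function(sl)
                unname(as.matrix(sl$outer)))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour stack from per-slice CSV
#'
#' Long format with columns \code{slice}, \code{z}, \code{surface}
#' ("inner"/"outer"), \code{x}, \code{y}.
#'
#' @param path CSV file path.
#' @param spacing optional slice spacing (cm).
#' @return a \code{\link{contour_stack}}.
#' @export
read_contour_stack_csv <- function(path, spacing = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("slice", "z", "surface", "x", "y") %in% names(d)))
  slices <- lapply(sort(unique(d$slice)), function(k) {
    di <- d[d$slice == k & d$surface == "inner", ]
    do <- d[d$slice == k & d$surface == "outer", ]
    ventricle_slice(contour(cbind(di$x, di$y)), contour(cbind(do$x, do$y)),
                    di$z[1])
  })
  contour_stack(slices, spacing = spacing)
}

#' Slice-level geometric metrics table
#'
#' Convenience wrapper producing per-slice wall thickness, circumferential
#' curvature and areas, plus stack-level longitudinal curvature.
#'
#' @param s a \code{\link{contour_stack}}.
#' @param n points per contour (default 100).
#' @return data.frame, one row per slice, with attribute \code{lcur_mean}.
#' @export
stack_metrics <- function(s, n = 100) {
  rows <- lapply(seq_along(s$slices), function(i) {
    sl <- s$slices[[i]]
    wt <- wall_thickness(sl, n)
    cc <- circumferential_curvature(resample_contour(sl$inner, n))
    data.frame(slice = i, z = sl$z,
               inner_area_cm2 = polygon_area(sl$inner),
               outer_area_cm2 = polygon_area(sl$outer),
               wt_cm = wt$mean, ccur_1cm = cc$mean)
  })
  out <- do.call(rbind, rows)
  lc <- if (length(s$slices) >= 3) longitudinal_curvature(s, n)$mean else NA_real_
  attr(out, "lcur_mean") <- lc
  out
}
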