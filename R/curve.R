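#' Construct a simulated premyofibril curve
#'
#' Builds the geometric substrate for the swarm simulations: a fourth-order
#' (degree 4, five control points) Bezier curve whose arclength matches a
#' prescribed length \code{length} and whose shape follows a circular arc of
#' radius \code{radius}. The curve is delivered in the aligned frame used by
#' the dynamics: both endpoints on the horizontal axis, the start point at the
#' origin, and the vertical coordinate a single-valued function \code{y(x)}.
#'
#' The control points are placed by a least-squares fit of the degree-4
#' Bezier to a dense sampling of the target circular arc (the arc subtends an
#' angle \code{length / radius}), with the two end control points pinned to
#' the arc endpoints. The realized arclength and radius of curvature are then
#' verified against the request: both must agree to within 1\%.
#'
#' @param length target arclength \eqn{L_c} in micrometres; must be positive.
#' @param radius target radius of curvature \eqn{R_c} in micrometres, or
#'   \code{Inf} for a straight (horizontal) fibre. Finite radii require
#'   \code{length <= pi * radius} (the arc may not exceed a half circle).
#' @return An object of class \code{myofibril_curve}: a list with the five
#'   \code{control_points} (micrometres, aligned frame), the requested
#'   \code{L_c} and \code{R_c}, the \code{realized_length} and
#'   \code{realized_radius}, the horizontal extent \code{x_end}, an
#'   \code{arclength_table} (curve parameter, x, cumulative arclength), and an
#'   interpolating function \code{yfun} giving \code{y(x)}.
#' @examples
#' fib <- myofibril_curve(40, Inf)          # straight 40 um fibre
#' arc <- myofibril_curve(20, 20)           # strongly curved arc
#' arc$realized_length
#' @export
myofibril_curve <- function(length, radius = Inf) {
  stopifnot(is.numeric(length), length(length) == 1L, length > 0,
            is.numeric(radius), length(radius) == 1L)
  if (is.finite(radius)) {
    if (radius <= 0) stop("radius of curvature must be positive (or Inf for a straight fibre)")
    if (length > pi * radius + 1e-9)
      stop(sprintf(paste0("infeasible curve: arclength %.3g exceeds a half circle of radius %.3g ",
                          "(need length <= pi * radius)"), length, radius))
  }

  if (!is.finite(radius)) {
    cp <- cbind(seq(0, length, length.out = 5), rep(0, 5))
  } else {
    cp <- fit_bezier_to_arc(length, radius)
  }
  crv <- new_myofibril_curve(cp, spec_length = length, spec_radius = radius)

  if (abs(crv$realized_length - length) > 0.01 * length)
    stop("Bezier fit failed: realized arclength deviates more than 1% from the target")
  if (is.finite(radius)) {
    dev <- max_arc_deviation(crv, length, radius)
    if (dev > 0.01 * radius)
      stop("Bezier fit failed: curve deviates more than 1% of the radius from the target arc")
  }
  crv
}

# Least-squares degree-4 Bezier fit to a circular arc of arclength L and
# radius R, expressed in the aligned frame (chord on the x-axis, bulge up).
fit_bezier_to_arc <- function(L, R) {
  theta <- L / R
  half <- theta / 2
  chord <- 2 * R * sin(half)
  centre <- c(chord / 2, -R * cos(half))
  alpha <- seq(-half, half, length.out = 401L)
  q <- cbind(centre[1] + R * sin(alpha), centre[2] + R * cos(alpha))
  tt <- (alpha + half) / theta           # uniform in arclength along the arc
  B <- bernstein_matrix(tt, 4L)
  p0 <- q[1, ]; p4 <- q[nrow(q), ]
  rhs <- q - outer(B[, 1], p0) - outer(B[, 5], p4)
  mid <- qr.solve(B[, 2:4], rhs)
  rbind(p0, mid, p4)
}

bernstein_matrix <- function(t, degree) {
  sapply(0:degree, function(i) choose(degree, i) * t^i * (1 - t)^(degree - i))
}

bezier_point <- function(cp, t) {
  bernstein_matrix(t, nrow(cp) - 1L) %*% cp
}

bezier_deriv <- function(cp, t) {
  d <- nrow(cp) - 1L
  dcp <- d * (cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])
  bernstein_matrix(t, d - 1L) %*% dcp
}

# Core constructor: takes 5 aligned control points and derives the lookup
# tables the dynamics need. Enforces monotone x(t) and bounded slope.
new_myofibril_curve <- function(control_points, spec_length = NA_real_,
                                spec_radius = NA_real_) {
  cp <- unname(as.matrix(control_points))
  stopifnot(nrow(cp) == 5L, ncol(cp) == 2L)
  tt <- seq(0, 1, length.out = 4001L)
  pts <- bezier_point(cp, tt)
  if (any(diff(pts[, 1]) <= 0))
    stop("curve is not single-valued: x(t) must be strictly increasing in the aligned frame")
  slope <- diff(pts[, 2]) / diff(pts[, 1])
  if (max(abs(slope)) > 10)
    stop("curve is too strongly curved for the lateral update scheme (|dy/dx| > 10)")

  speed <- function(t) {
    d <- bezier_deriv(cp, t)
    sqrt(d[, 1]^2 + d[, 2]^2)
  }
  arclen <- stats::integrate(speed, 0, 1, rel.tol = 1e-10)$value
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cumlen <- c(0, cumsum(seg))
  cumlen <- cumlen * (arclen / cumlen[length(cumlen)])  # quadrature-calibrated

  straight <- max(abs(pts[, 2])) < 1e-9 * max(1, abs(pts[nrow(pts), 1]))
  realized_radius <- if (straight) Inf else kasa_circle_radius(pts)

  yfun <- stats::splinefun(pts[, 1], pts[, 2], method = "fmm")
  structure(list(
    control_points = cp,
    L_c = spec_length,
    R_c = spec_radius,
    realized_length = arclen,
    realized_radius = realized_radius,
    x_start = pts[1, 1],
    x_end = pts[nrow(pts), 1],
    arclength_table = data.frame(t = tt, x = pts[, 1], s = cumlen),
    yfun = yfun
  ), class = "myofibril_curve")
}

# Algebraic (Kasa) circle fit; returns the fitted radius.
kasa_circle_radius <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

max_arc_deviation <- function(crv, L, R) {
  theta <- L / R
  half <- theta / 2
  chord <- 2 * R * sin(half)
  centre <- c(chord / 2, -R * cos(half))
  pts <- bezier_point(crv$control_points, seq(0, 1, length.out = 801L))
  max(abs(sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2) - R))
}

#' Align a curve with the horizontal axis
#'
#' Computes the rigid transform (rotation + translation) taking the curve's
#' start point to the origin and its end point onto the positive x-axis, and
#' returns the transformed curve together with the transform. Curves built by
#' \code{\link{myofibril_curve}} are already aligned, in which case the
#' transform is the identity.
#'
#' @param x a \code{myofibril_curve}, or a 5x2 matrix of control points in an
#'   arbitrary planar frame.
#' @return A list with components \code{curve} (the aligned
#'   \code{myofibril_curve}) and \code{transform} (class \code{axis_transform},
#'   with rotation matrix \code{R} and offset \code{t}).
#' @export
align_to_axis <- function(x) {
  cp <- if (inherits(x, "myofibril_curve")) x$control_points else as.matrix(x)
  stopifnot(nrow(cp) == 5L, ncol(cp) == 2L)
  v <- cp[5, ] - cp[1, ]
  ang <- atan2(v[2], v[1])
  R <- rbind(c(cos(-ang), -sin(-ang)), c(sin(-ang), cos(-ang)))
  tr <- structure(list(R = R, t = as.numeric(-R %*% cp[1, ])),
                  class = "axis_transform")
  cp2 <- apply_transform(tr, cp)
  crv <- new_myofibril_curve(cp2,
                             spec_length = if (inherits(x, "myofibril_curve")) x$L_c else NA_real_,
                             spec_radius = if (inherits(x, "myofibril_curve")) x$R_c else NA_real_)
  list(curve = crv, transform = tr)
}

#' Apply or invert a rigid axis transform
#'
#' @param transform an \code{axis_transform} from \code{\link{align_to_axis}}.
#' @param points an n x 2 matrix (or length-2 vector) of planar points.
#' @return Transformed n x 2 matrix.
#' @export
apply_transform <- function(transform, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  out <- t(transform$R %*% t(p)) + rep(transform$t, each = nrow(p))
  dimnames(out) <- NULL
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Ri <- t(transform$R)
  structure(list(R = Ri, t = as.numeric(-Ri %*% transform$t)),
            class = "axis_transform")
}

#' Evaluate a point on the aligned curve
#'
#' Returns the on-curve points \code{(x, y(x))} for horizontal coordinates
#' \code{x} in the aligned frame. Coordinates outside the fibre extent are an
#' error; the swarm engine clamps before calling (absorbing boundaries).
#'
#' @param curve a \code{myofibril_curve}.
#' @param x numeric vector of horizontal coordinates (micrometres).
#' @return An \code{length(x)} x 2 matrix of planar points.
#' @export
point_on_curve <- function(curve, x) {
  stopifnot(inherits(curve, "myofibril_curve"))
  if (any(x < curve$x_start - 1e-9 | x > curve$x_end + 1e-9))
    stop("x outside the fibre extent; clamp to [x_start, x_end] first")
  out <- cbind(x, curve$yfun(x))
  dimnames(out) <- NULL
  out
}

# Points uniform in arclength along the curve; s in [0, realized_length].
points_at_arclength <- function(curve, s) {
  tab <- curve$arclength_table
  x <- stats::approx(tab$s, tab$x, xout = pmin(pmax(s, 0), max(tab$s)))$y
  cbind(x, curve$yfun(x))
}

#' @export
print.myofibril_curve <- function(x, ...) {
  shape <- if (is.finite(x$realized_radius))
    sprintf("arc, radius %.3g um", x$realized_radius) else "straight"
  cat(sprintf("Myofibril curve (%s): arclength %.4g um, x-extent [%.3g, %.3g]\n",
              shape, x$realized_length, x$x_start, x$x_end))
  invisible(x)
}

#' Export / import a curve as JSON
#'
#' The JSON carries the control points and the length/radius request, which is
#' sufficient to rebuild the lookup tables exactly.
#'
#' @param curve a \code{myofibril_curve}.
#' @param path file path.
#' @export
curve_to_json <- function(curve, path) {
  obj <- list(control_points = unname(curve$control_points),
              L_c = curve$L_c, R_c = curve$R_c,
              realized_length = curve$realized_length)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname curve_to_json
#' @export
curve_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Rc <- obj$R_c
  if (is.null(Rc) || is.na(Rc) || identical(Rc, "Inf")) Rc <- Inf
  new_myofibril_curve(matrix(unlist(obj$control_points), ncol = 2),
                      spec_length = obj$L_c, spec_radius = as.numeric(Rc))
}

#' Export a sampled polyline of the curve as CSV
#'
#' @param curve a \code{myofibril_curve}.
#' @param path file path for a two-column CSV (x_um, y_um).
#' @param n number of samples.
#' @export
curve_to_csv <- function(curve, path, n = 200L) {
  x <- seq(curve$x_start, curve$x_end, length.out = n)
  utils::write.csv(data.frame(x_um = x, y_um = curve$yfun(x)),
                   path, row.names = FALSE)
  invisible(path)
}
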