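#' Energy model parameters
#'
#' Bundles the parameters of the pairwise cluster interaction energy and of
#' the recruitment rule: the Lennard-Jones well depth \code{epsilon} (energy
#' units; it scales the objective uniformly and defaults to 1), the ideal
#' equilibrium inter-cluster distance \code{r_m} (micrometres; 1.1 um is the
#' cardiac value, 0.7 skeletal, 1.8 flight muscle), and the cluster searching
#' distance \code{d_th} (micrometres): recruitment of a new cluster into a
#' myofibril segment is only considered when the segment's neighbour distance
#' exceeds \code{d_th}.
#'
#' @param epsilon well depth, > 0.
#' @param r_m ideal inter-cluster distance in micrometres, > 0.
#' @param d_th minimum segment length for recruitment, >= 0.
#' @return An object of class \code{energy_params}.
#' @export
energy_params <- function(epsilon = 1, r_m = 1.1, d_th = 0.5) {
  stopifnot(epsilon > 0, r_m > 0, d_th >= 0)
  structure(list(epsilon = epsilon, r_m = r_m, d_th = d_th),
            class = "energy_params")
}

# Smallest inter-cluster distance the potential is evaluated at; below this
# the Lennard-Jones repulsion is effectively a hard-core divergence.
.min_eval_dist <- 1e-6

#' Lennard-Jones pairwise potential
#'
#' \deqn{V(r) = \epsilon[(r_m/r)^{12} - 2 (r_m/r)^6]}
#' with well depth \eqn{\epsilon} at the minimum \eqn{V(r_m) = -\epsilon} and
#' zero crossing at \eqn{r = r_m 2^{-1/6}}.
#'
#' @param r inter-cluster distance(s), micrometres; must exceed 1e-6.
#' @param params an \code{\link{energy_params}} object.
#' @return Potential energy, same length as \code{r}.
#' @examples
#' p <- energy_params(r_m = 1.1)
#' lennard_jones(1.1, p)   # -1 at the well minimum
#' @export
lennard_jones <- function(r, params) {
  if (any(r < .min_eval_dist))
    stop("lennard_jones: distance below the 1e-6 um evaluation guard (coincident clusters)")
  s6 <- (params$r_m / r)^6
  params$epsilon * (s6^2 - 2 * s6)
}

# Internal: pairwise energy of an n x 2 point matrix. With collision = "inf"
# a coincident pair yields +Inf instead of an error (used by the engine,
# where absorbing boundaries can transiently stack clusters).
pair_energy <- function(pts, params, collision = c("error", "inf")) {
  collision <- match.arg(collision)
  n <- nrow(pts)
  if (n < 2L) return(0)
  d <- stats::dist(pts)
  if (any(d < .min_eval_dist)) {
    if (collision == "inf") return(Inf)
    stop("coincident clusters: pairwise distance below 1e-6 um")
  }
  sum(lennard_jones(as.numeric(d), params))
}

#' Configuration energy
#'
#' Sum of the Lennard-Jones potential over all unordered cluster pairs,
#' including the two fixed fibre-endpoint clusters, which anchor the pattern
#' but never move.
#'
#' @param x_interior numeric vector of interior cluster x-coordinates in the
#'   aligned frame (may be empty).
#' @param curve the \code{\link{myofibril_curve}} the clusters live on.
#' @param params an \code{\link{energy_params}} object.
#' @return Total pairwise energy (energy units of \code{epsilon}).
#' @export
configuration_energy <- function(x_interior, curve, params) {
  pts <- config_points(curve, x_interior)
  pair_energy(pts, params, collision = "error")
}

# All cluster points of a configuration, endpoints included, sorted by x.
config_points <- function(curve, x_interior) {
  x <- sort(c(curve$x_start, as.numeric(x_interior), curve$x_end))
  out <- cbind(x, curve$yfun(x))
  dimnames(out) <- NULL
  out
}

#' Partition the fibre into myofibril segments
#'
#' Segments are the intervals between consecutive clusters of the optimal
#' swarm configuration under the pseudo-ordering (ascending x in the aligned
#' frame), with the fibre endpoints as the outermost bounds. Ties in x are
#' broken by the original cluster order.
#'
#' @param x_interior interior cluster x-coordinates of the configuration.
#' @param curve the \code{\link{myofibril_curve}}.
#' @return A data frame with one row per segment: \code{x1}, \code{x2}
#'   (segment bounds in x) and \code{length} (2D Euclidean distance between
#'   the bounding on-curve clusters).
#' @export
partition_segments <- function(x_interior, curve) {
  x <- c(curve$x_start,
         as.numeric(x_interior)[order(as.numeric(x_interior))],
         curve$x_end)
  y <- curve$yfun(x)
  n <- length(x)
  data.frame(x1 = x[-n], x2 = x[-1],
             length = sqrt(diff(x)^2 + diff(y)^2))
}

#' Energetic cost-benefit of a recruitment candidate
#'
#' Evaluates the change in energy from adding a candidate cluster at
#' horizontal position \code{s_x} to the optimal configuration, given
#' candidates already accepted this iteration. The segment-occupancy
#' indicator restricts recruitment to one cluster per myofibril segment per
#' iteration: a candidate whose segment already holds an earlier accepted
#' candidate contributes nothing and its cost-benefit is zero.
#'
#' @param s_x candidate x-coordinate (aligned frame).
#' @param accepted_x x-coordinates of candidates already accepted this
#'   iteration (earlier proposals), possibly empty.
#' @param g_interior interior cluster x-coordinates of the optimal
#'   configuration.
#' @param curve the \code{\link{myofibril_curve}}.
#' @param params an \code{\link{energy_params}} object.
#' @param segments optional precomputed \code{\link{partition_segments}}
#'   result for \code{g_interior}.
#' @return The cost-benefit energy: negative values are favourable.
#' @export
cost_benefit <- function(s_x, accepted_x, g_interior, curve, params,
                         segments = NULL) {
  if (is.null(segments)) segments <- partition_segments(g_interior, curve)
  seg_of <- function(x) {
    i <- findInterval(x, segments$x1, rightmost.closed = TRUE)
    max(1L, min(i, nrow(segments)))
  }
  k_seg <- seg_of(s_x)
  occupied <- length(accepted_x) > 0 &&
    any(vapply(accepted_x, seg_of, integer(1)) == k_seg)
  if (occupied) return(0)
  s_pt <- point_on_curve(curve, s_x)
  g_pts <- config_points(curve, g_interior)
  e <- sum(lennard_jones(sqrt((g_pts[, 1] - s_pt[1])^2 +
                              (g_pts[, 2] - s_pt[2])^2), params))
  if (length(accepted_x) > 0) {
    a_pts <- point_on_curve(curve, accepted_x)
    e <- e + sum(lennard_jones(sqrt((a_pts[, 1] - s_pt[1])^2 +
                                    (a_pts[, 2] - s_pt[2])^2), params))
  }
  e
}

#' Objective function value
#'
#' The swarm objective: the configuration energy of the current state plus
#' the summed cost-benefit of the accepted recruitment proposals.
#'
#' @inheritParams configuration_energy
#' @param proposals optional data frame with columns \code{E} (cost-benefit)
#'   and \code{accepted} (0/1) for this iteration's recruitment candidates.
#' @return Objective value in energy units.
#' @export
objective_value <- function(x_interior, curve, params, proposals = NULL) {
  e <- configuration_energy(x_interior, curve, params)
  if (!is.null(proposals) && nrow(proposals) > 0)
    e <- e + sum(proposals$E * proposals$accepted)
  e
}
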