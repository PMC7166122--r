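#' Average inter-cluster distance across simulations
#'
#' For each configuration the inter-cluster distances are the 2D Euclidean
#' distances between consecutive on-curve clusters under the pseudo-ordering
#' (ascending x in the aligned frame), endpoints included. These are averaged
#' over the gaps of a configuration, over the \code{S} configurations of a
#' simulation, and finally over simulations.
#'
#' @param sims a \code{pso_simulation} or a list of them (replicate runs).
#' @return A list with \code{d_sk} (per-simulation means), \code{d_bar}
#'   (across-simulation mean) and \code{sd} (across-simulation standard
#'   deviation).
#' @export
mean_intercluster_distance <- function(sims) {
  sims <- as_sim_list(sims)
  d_sk <- vapply(sims, function(s) {
    if (ncol(s$swarm_positions) + 2L < 2L)
      stop("configuration has fewer than 2 clusters")
    mean(swarm_row_spacings(s$swarm_positions, s$curve))
  }, numeric(1))
  list(d_sk = d_sk, d_bar = mean(d_sk),
       sd = if (length(d_sk) > 1) stats::sd(d_sk) else NA_real_)
}

as_sim_list <- function(sims) {
  if (inherits(sims, "pso_simulation")) list(sims) else sims
}

# Nearest-neighbour distances: gamma_i = min_{j != i} |x_i - x_j| (2D).
nn_distances <- function(pts) {
  if (is.null(dim(pts))) pts <- cbind(as.numeric(pts), 0)
  n <- nrow(pts)
  stopifnot(n >= 2L)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

# Spacing coefficient of variation: population SD of the nearest-neighbour
# distances over their mean. guard errors on coincident points (the public
# uniformity contract); without it coincident pairs simply inflate lambda.
lambda_cov <- function(pts, guard = FALSE) {
  g <- nn_distances(pts)
  if (guard && any(g < .min_eval_dist))
    stop("coincident points in uniformity computation")
  gbar <- mean(g)
  sqrt(mean((g - gbar)^2)) / gbar
}

#' Uniformity of a cluster pattern
#'
#' An adjusted coefficient-of-variation measure: with nearest-neighbour
#' distances \eqn{\gamma_i} and their spacing COV
#' \eqn{\lambda = sd(\gamma)/mean(\gamma)} (population SD), the uniformity is
#' \deqn{u = (\lambda_{rand} - \lambda) / \lambda_{rand} = 1 - \lambda/\lambda_{rand},}
#' clamped to [0, 1]. \eqn{u = 1} corresponds to exactly equally spaced
#' points; \eqn{u = 0} to spacing as irregular as the random calibration
#' level \eqn{\lambda_{rand}} (see \code{\link{calibrate_lambda_rand}}).
#' Because \eqn{\lambda_{rand}} is a maximum over finitely many random sets,
#' \eqn{\lambda > \lambda_{rand}} can occur; such values clamp to 0.
#'
#' @param points an n x 2 matrix of planar points (n >= 3), or a numeric
#'   vector of positions on a straight fibre.
#' @param lambda_rand positive calibration constant.
#' @return Uniformity in [0, 1].
#' @examples
#' uniformity(seq(0, 40, length.out = 30), lambda_rand = 0.5)  # exactly 1
#' @export
uniformity <- function(points, lambda_rand) {
  stopifnot(lambda_rand > 0)
  if (is.null(dim(points))) points <- cbind(as.numeric(points), 0)
  stopifnot(nrow(points) >= 3L)
  u <- 1 - lambda_cov(points, guard = TRUE) / lambda_rand
  min(max(u, 0), 1)
}

.lambda_cache <- new.env(parent = emptyenv())

#' Calibrate the random-pattern spacing level
#'
#' Draws \code{n_sets} independent sets of \code{n_points} points uniformly
#' distributed in arclength along the curve and returns the maximum spacing
#' COV \eqn{\lambda} among them. This is the normalization constant
#' \eqn{\lambda_{rand}} of \code{\link{uniformity}}: the most irregular
#' spacing level expected from that many random points on the fibre.
#' Results are cached per (curve, n_points, n_sets, seed) when a seed is
#' given.
#'
#' @param curve a \code{\link{myofibril_curve}}.
#' @param n_points number of points per random set (>= 3).
#' @param n_sets number of random sets (default 60).
#' @param seed optional integer seed making the calibration reproducible.
#' @return The calibration constant \eqn{\lambda_{rand} > 0}.
#' @export
calibrate_lambda_rand <- function(curve, n_points, n_sets = 60L, seed = NULL) {
  stopifnot(n_points >= 3L, n_sets >= 1L)
  key <- NULL
  if (!is.null(seed)) {
    key <- paste(signif(sum(curve$control_points * seq_len(10)), 12),
                 curve$realized_length, n_points, n_sets, seed, sep = "|")
    hit <- .lambda_cache[[key]]
    if (!is.null(hit)) return(hit)
    set.seed(as.integer(seed))
  }
  L <- curve$realized_length
  lam <- vapply(seq_len(n_sets), function(i) {
    lambda_cov(points_at_arclength(curve, stats::runif(n_points, 0, L)))
  }, numeric(1))
  out <- max(lam)
  if (!is.null(key)) .lambda_cache[[key]] <- out
  out
}

#' Average uniformity across simulations
#'
#' Computes the uniformity of every configuration's final cluster pattern
#' (endpoints included), averages over the configurations of each simulation
#' and then over simulations. The calibration \eqn{\lambda_{rand}} is
#' computed per cluster count actually present. Unconverged individual
#' configurations can carry effectively coincident clusters (absorbing
#' boundaries stack them at a fibre end); their near-zero nearest-neighbour
#' distances inflate \eqn{\lambda} and the uniformity clamps toward 0 rather
#' than erroring.
#'
#' @inheritParams mean_intercluster_distance
#' @param n_sets random sets for the calibration (default 60).
#' @param seed seed for the calibration draws.
#' @return A list with \code{u_sk} (per-simulation means), \code{u_bar}
#'   (across-simulation mean) and the \code{lambda_rand} values used, named
#'   by cluster count.
#' @export
swarm_uniformity <- function(sims, n_sets = 60L, seed = 1L) {
  sims <- as_sim_list(sims)
  lr_used <- list()
  u_sk <- vapply(sims, function(s) {
    n <- ncol(s$swarm_positions) + 2L
    lr <- calibrate_lambda_rand(s$curve, n, n_sets = n_sets, seed = seed)
    lr_used[[as.character(n)]] <<- lr
    u <- apply(s$swarm_positions, 1, function(xrow) {
      lam <- lambda_cov(config_points(s$curve, xrow))
      min(max(1 - lam / lr, 0), 1)
    })
    mean(u)
  }, numeric(1))
  list(u_sk = u_sk, u_bar = mean(u_sk), lambda_rand = lr_used)
}

#' Rescale a grid of mean distances relative to the ideal distance
#'
#' Each cell's deviation from \code{r_m} is divided by the grid-wide maximum
#' absolute deviation, giving values in [-1, 1]. If every cell equals
#' \code{r_m} exactly, the rescaled grid is defined as all zeros (with a
#' warning).
#'
#' @param d_bar numeric vector or matrix of mean inter-cluster distances.
#' @param r_m ideal distance (micrometres).
#' @return Rescaled deviations, same shape as \code{d_bar}.
#' @export
rescaled_distance <- function(d_bar, r_m) {
  dev <- d_bar - r_m
  m <- max(abs(dev))
  if (m == 0) {
    warning("all grid cells equal r_m exactly; rescaled distance set to 0")
    return(dev)
  }
  dev / m
}

#' Ranking of a parameter grid
#'
#' Scores each parameter pair by the product of its average uniformity and a
#' Gaussian weight prioritizing rescaled distances near zero:
#' \deqn{R = \bar u \exp(-\bar d_T^2 / (2\sigma^2)),}
#' where \eqn{\sigma} is the standard deviation of the rescaled-distance
#' collection over the same grid. Optionally normalized to a maximum of 1.
#' The high-rank mask flags cells above \code{mean(R) + sd(R)} (the default)
#' or above a fixed \code{threshold} on the normalized ranking.
#'
#' @param u_bar grid (vector or matrix) of average uniformities.
#' @param d_T congruent grid of rescaled distances (see
#'   \code{\link{rescaled_distance}}).
#' @param normalize divide by the grid maximum (when positive).
#' @param threshold optional fixed high-rank cutoff on the normalized
#'   ranking, e.g. 0.56; \code{NULL} uses mean + SD.
#' @return A list with the ranking grid \code{R}, logical \code{high_rank}
#'   mask, \code{sigma} and the cutoff used.
#' @export
ranking_grid <- function(u_bar, d_T, normalize = TRUE, threshold = NULL) {
  stopifnot(length(u_bar) == length(d_T))
  sigma <- stats::sd(as.numeric(d_T))
  if (is.na(sigma) || sigma == 0) {
    warning("zero spread in rescaled distances; Gaussian factor degenerates")
    w <- ifelse(d_T == 0, 1, 0)
  } else {
    w <- exp(-d_T^2 / (2 * sigma^2))
  }
  R <- u_bar * w
  if (normalize && max(R) > 0) R <- R / max(R)
  cut <- if (is.null(threshold)) mean(R) + stats::sd(as.numeric(R)) else threshold
  high <- R > cut
  list(R = R, high_rank = high, sigma = sigma, cutoff = cut)
}
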