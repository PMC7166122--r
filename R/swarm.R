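#' Swarm parameters for the adapted PSO
#'
#' @param S swarm size: number of candidate cluster configurations (>= 2).
#'   Convergence of PSO benefits from a reasonably large population; the
#'   convergence experiments use 60.
#' @param c1 cognitive acceleration coefficient, in [0, 4]: attraction of
#'   each configuration toward its own best solution.
#' @param c2 social acceleration coefficient, in [0, 4]: attraction toward
#'   the swarm-wide best configuration.
#' @param omega_min,omega_max inertia weight bounds; the inertia decays
#'   linearly from \code{omega_max} at iteration 0 to \code{omega_min} at
#'   \code{T_max}.
#' @param T_max maximum number of iterations.
#' @param dt time step in iteration units.
#' @return An object of class \code{swarm_params}.
#' @export
swarm_params <- function(S = 60L, c1 = 2, c2 = 2,
                         omega_min = 0.4, omega_max = 0.9,
                         T_max = 200L, dt = 1) {
  stopifnot(S >= 2, c1 >= 0, c1 <= 4, c2 >= 0, c2 <= 4,
            omega_min > 0, omega_min <= omega_max, omega_max <= 1.2,
            T_max >= 1, dt > 0)
  structure(list(S = as.integer(S), c1 = c1, c2 = c2,
                 omega_min = omega_min, omega_max = omega_max,
                 T_max = as.integer(T_max), dt = dt),
            class = "swarm_params")
}

#' Linearly decaying inertia weight
#'
#' \deqn{\omega(t) = \omega_{max} - (\omega_{max} - \omega_{min})\, t / T_{max}}
#'
#' @param t iteration counter, 0 <= t <= T_max.
#' @param swarm a \code{\link{swarm_params}} object.
#' @return The inertia weight at iteration \code{t}.
#' @export
inertia_weight <- function(t, swarm) {
  stopifnot(all(t >= 0), all(t <= swarm$T_max))
  swarm$omega_max - (swarm$omega_max - swarm$omega_min) * t / swarm$T_max
}

# Velocity update rule; R1, R2 are fresh uniform(0,1) draws per cluster.
pso_velocity <- function(v, r, p, g, w, c1, c2, R1, R2) {
  w * v + R1 * c1 * (p - r) + R2 * c2 * (g - r)
}

# Energy of one candidate point against a set of cluster points; +Inf when
# the candidate collides with an existing cluster (always rejected).
.pt_energy <- function(s_pt, pts, params) {
  d <- sqrt((pts[, 1] - s_pt[1])^2 + (pts[, 2] - s_pt[2])^2)
  if (any(d < .min_eval_dist)) return(Inf)
  sum(lennard_jones(d, params))
}

#' Run one adapted-PSO premyofibril simulation
#'
#' Evolves a swarm of \code{S} candidate alpha-actinin cluster configurations
#' on a myofibril curve. Each iteration applies the standard PSO update cycle
#' (velocity with linearly decaying inertia, position restricted to the
#' curve, personal/global best bookkeeping) followed by an energy state
#' transition: every segment of the optimal configuration longer than
#' \code{d_th} proposes one uniformly placed candidate cluster, and candidates
#' whose energetic cost-benefit is negative are recruited into the optimal
#' configuration, with a corresponding randomly placed cluster added to every
#' individual configuration.
#'
#' Movement is one-dimensional along the aligned horizontal axis; the
#' vertical coordinate is slaved to the curve. Absorbing boundaries reset any
#' cluster predicted beyond a fibre endpoint to that endpoint with zero
#' velocity. Initialization places the two fixed endpoint clusters plus one
#' interior cluster uniformly at random per configuration, with zero
#' velocities and personal bests equal to the initial positions.
#'
#' @param curve a \code{\link{myofibril_curve}}.
#' @param energy an \code{\link{energy_params}} object.
#' @param swarm a \code{\link{swarm_params}} object.
#' @param seed integer seed for the run's single random generator, or
#'   \code{NULL} to continue from the current RNG state. The same seed and
#'   parameters reproduce the run bit-for-bit.
#' @return An object of class \code{pso_simulation}: the final optimal
#'   configuration (\code{g_interior}, interior cluster x-coordinates, plus
#'   \code{f_g}), the final positions of all configurations
#'   (\code{swarm_positions}, one row per configuration), a per-iteration
#'   \code{history} data frame (\code{t}, \code{n_clusters}, \code{f_g},
#'   \code{mean_spacing}), and the full parameter/seed metadata.
#' @examples
#' fib <- myofibril_curve(10, Inf)
#' sim <- run_simulation(fib, energy_params(r_m = 1.1),
#'                       swarm_params(S = 10, T_max = 30), seed = 1)
#' sim
#' @export
run_simulation <- function(curve, energy = energy_params(),
                           swarm = swarm_params(), seed = NULL) {
  stopifnot(inherits(curve, "myofibril_curve"),
            inherits(energy, "energy_params"),
            inherits(swarm, "swarm_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  S <- swarm$S
  x0 <- curve$x_start
  x1 <- curve$x_end
  yfun <- curve$yfun

  row_energy <- function(xrow) {
    x <- c(x0, xrow, x1)
    pair_energy(cbind(x, yfun(x)), energy, collision = "inf")
  }

  # --- initialization: endpoints + one uniformly random interior cluster ---
  xs <- matrix(stats::runif(S, x0, x1), nrow = S, ncol = 1)
  vs <- matrix(0, S, 1)
  ps <- xs
  fp <- apply(xs, 1, row_energy)
  kb <- which.min(fp)
  g <- ps[kb, ]
  fg <- fp[kb]

  Tm <- swarm$T_max
  hist_n <- integer(Tm)
  hist_f <- numeric(Tm)
  hist_d <- numeric(Tm)

  for (it in seq_len(Tm)) {
    t_now <- it - 1L
    w <- inertia_weight(t_now, swarm)
    N <- ncol(xs)

    # velocity + position updates (Eq. cycle), absorbing boundaries
    R1 <- matrix(stats::runif(S * N), S, N)
    R2 <- matrix(stats::runif(S * N), S, N)
    G <- matrix(g, S, N, byrow = TRUE)
    vs <- pso_velocity(vs, xs, ps, G, w, swarm$c1, swarm$c2, R1, R2)
    xs <- xs + vs * swarm$dt
    out <- xs < x0
    xs[out] <- x0; vs[out] <- 0
    out <- xs > x1
    xs[out] <- x1; vs[out] <- 0
    for (k in seq_len(S)) {          # keep rank correspondence geometric
      o <- order(xs[k, ])
      xs[k, ] <- xs[k, o]
      vs[k, ] <- vs[k, o]
    }

    # personal / global best updates (strict improvement only)
    fr <- apply(xs, 1, row_energy)
    imp <- fr < fp
    if (any(imp)) {
      ps[imp, ] <- xs[imp, , drop = FALSE]
      fp[imp] <- fr[imp]
    }
    kb <- which.min(fp)
    if (fp[kb] < fg) {
      g <- ps[kb, ]
      fg <- fp[kb]
    }

    # --- energy state transition: per-segment recruitment into g ---
    segs <- partition_segments(g, curve)
    eligible <- which(segs$length > energy$d_th)
    if (length(eligible) > 0) {
      g_pts <- config_points(curve, g)
      acc_x <- numeric(0)
      acc_seg <- integer(0)
      for (i in eligible) {
        sx <- stats::runif(1, segs$x1[i], segs$x2[i])
        s_pt <- c(sx, yfun(sx))
        E <- .pt_energy(s_pt, g_pts, energy)
        if (length(acc_x) > 0)
          E <- E + .pt_energy(s_pt, cbind(acc_x, yfun(acc_x)), energy)
        if (is.finite(E) && E < 0) {
          acc_x <- c(acc_x, sx)
          acc_seg <- c(acc_seg, i)
        }
      }
      if (length(acc_x) > 0) {
        g <- sort(c(g, acc_x))
        for (j in seq_along(acc_x)) {
          i <- acc_seg[j]
          newx <- stats::runif(S, segs$x1[i], segs$x2[i])
          xs <- cbind(xs, newx, deparse.level = 0)
          vs <- cbind(vs, 0, deparse.level = 0)
          # p = r for the recruited cluster
          ps <- cbind(ps, newx, deparse.level = 0)
        }
        dimnames(xs) <- dimnames(vs) <- dimnames(ps) <- NULL
        for (k in seq_len(S)) {
          o <- order(xs[k, ])
          xs[k, ] <- xs[k, o]
          vs[k, ] <- vs[k, o]
          ps[k, ] <- sort(ps[k, ])
        }
        fp <- apply(ps, 1, row_energy)
        fg <- row_energy(g)
      }
    }

    hist_n[it] <- length(g) + 2L
    hist_f[it] <- fg
    hist_d[it] <- mean(swarm_row_spacings(xs, curve))
  }

  structure(list(
    curve = curve,
    energy = energy,
    swarm = swarm,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    g_interior = g,
    f_g = fg,
    swarm_positions = xs,
    history = data.frame(t = seq_len(Tm), n_clusters = hist_n,
                         f_g = hist_f, mean_spacing = hist_d),
    metadata = list(
      endpoint_clusters_in_energy = TRUE,
      acceptance_rule = "E_k < 0, proposals evaluated left-to-right",
      random_draws = "uniform(0,1) per cluster per iteration",
      best_matching = "clusters matched by pseudo-order rank",
      recruited_best_init = "p = r, v = 0 for recruited clusters only"
    )
  ), class = "pso_simulation")
}

# Mean nearest-consecutive (pseudo-ordered) 2D spacing per configuration row.
swarm_row_spacings <- function(xs, curve) {
  S <- nrow(xs)
  xall <- cbind(curve$x_start, xs, curve$x_end)
  yall <- matrix(curve$yfun(xall), nrow = S)
  n <- ncol(xall)
  dx <- xall[, -1, drop = FALSE] - xall[, -n, drop = FALSE]
  dy <- yall[, -1, drop = FALSE] - yall[, -n, drop = FALSE]
  rowMeans(sqrt(dx^2 + dy^2))
}

#' @export
print.pso_simulation <- function(x, ...) {
  cat("Adapted-PSO premyofibril simulation\n")
  cat(sprintf("  fibre: %.4g um (%s), S = %d, T_max = %d, seed = %s\n",
              x$curve$realized_length,
              if (is.finite(x$curve$realized_radius))
                sprintf("R_c ~ %.3g um", x$curve$realized_radius) else "straight",
              x$swarm$S, x$swarm$T_max,
              ifelse(is.na(x$seed), "none", x$seed)))
  cat(sprintf("  energy: epsilon = %.3g, r_m = %.3g um, d_th = %.3g um\n",
              x$energy$epsilon, x$energy$r_m, x$energy$d_th))
  cat(sprintf("  final: %d clusters, f(g) = %.5g, mean spacing %.4g um\n",
              length(x$g_interior) + 2L, x$f_g,
              utils::tail(x$history$mean_spacing, 1)))
  invisible(x)
}

#' @export
summary.pso_simulation <- function(object, ...) {
  h <- object$history
  out <- list(
    n_clusters = utils::tail(h$n_clusters, 1),
    f_g = object$f_g,
    mean_spacing = utils::tail(h$mean_spacing, 1),
    g_spacings = diff(c(object$curve$x_start, object$g_interior,
                        object$curve$x_end)),
    iterations = nrow(h),
    recruitment_iterations = sum(diff(c(3L, h$n_clusters)) > 0)
  )
  class(out) <- "summary.pso_simulation"
  out
}

#' @export
print.summary.pso_simulation <- function(x, ...) {
  cat(sprintf("Final clusters: %d after %d iterations (%d recruitment events)\n",
              x$n_clusters, x$iterations, x$recruitment_iterations))
  cat(sprintf("f(g) = %.5g; swarm mean spacing = %.4g um\n",
              x$f_g, x$mean_spacing))
  cat("Optimal-configuration gap summary (um):\n")
  print(summary(x$g_spacings))
  invisible(x)
}

#' Plot a simulation's convergence history
#'
#' Three panels: cluster count, objective value of the optimal configuration,
#' and swarm-average inter-cluster spacing against iteration, plus the final
#' optimal pattern on the fibre.
#'
#' @param x a \code{pso_simulation}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.pso_simulation <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$t, h$n_clusters, type = "s", xlab = "iteration",
       ylab = "clusters", main = "Cluster count", ...)
  plot(h$t, h$f_g, type = "l", xlab = "iteration",
       ylab = "f(g)", main = "Objective", ...)
  plot(h$t, h$mean_spacing, type = "l", xlab = "iteration",
       ylab = "mean spacing (um)", main = "Inter-cluster distance", ...)
  graphics::abline(h = x$energy$r_m, lty = 2)
  pts <- config_points(x$curve, x$g_interior)
  xx <- seq(x$curve$x_start, x$curve$x_end, length.out = 200)
  plot(xx, x$curve$yfun(xx), type = "l", asp = 1, xlab = "x (um)",
       ylab = "y (um)", main = "Final optimal pattern")
  graphics::points(pts, pch = 19, cex = 0.7)
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' Emits \code{trajectory.csv} (t, n_clusters, f_g, mean_spacing),
#' \code{final_configuration.csv} (x_um, y_um of the optimal configuration)
#' and \code{metadata.json} (all parameters, seed, and interpretive choices)
#' into \code{dir}.
#'
#' @param sim a \code{pso_simulation}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- file.path(dir, "trajectory.csv")
  utils::write.csv(sim$history, traj, row.names = FALSE)
  pts <- config_points(sim$curve, sim$g_interior)
  fin <- file.path(dir, "final_configuration.csv")
  utils::write.csv(data.frame(x_um = pts[, 1], y_um = pts[, 2]),
                   fin, row.names = FALSE)
  meta <- file.path(dir, "metadata.json")
  jsonlite::write_json(list(
    curve = list(L_c = sim$curve$L_c, R_c = sim$curve$R_c,
                 realized_length = sim$curve$realized_length),
    energy = unclass(sim$energy),
    swarm = unclass(sim$swarm),
    seed = sim$seed,
    interpretive_choices = sim$metadata
  ), meta, digits = NA, auto_unbox = TRUE, null = "null", na = "null")
  invisible(c(trajectory = traj, final = fin, metadata = meta))
}
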