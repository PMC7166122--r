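#' Convergence experiment: replicate runs on one fibre
#'
#' Runs \code{n_sim} independently seeded simulations with identical
#' parameters and collects the per-iteration cluster count, objective value
#' and swarm-average spacing, plus final-pattern metrics. A run is flagged as
#' converged when its swarm-average spacing changes by less than 1\% over the
#' final 20 iterations.
#'
#' @param curve a \code{\link{myofibril_curve}}.
#' @param energy an \code{\link{energy_params}} object.
#' @param swarm a \code{\link{swarm_params}} object.
#' @param n_sim number of replicate simulations (default 10).
#' @param seed top-level seed; run \code{i} uses \code{seed + i - 1}.
#' @return An object of class \code{pso_convergence}: the list of
#'   simulations, a long-format \code{history} data frame with a \code{run}
#'   column, per-run final spacings/counts, the across-run mean distance
#'   (\code{d_bar}) and a logical \code{converged} vector.
#' @export
convergence_experiment <- function(curve, energy = energy_params(),
                                   swarm = swarm_params(), n_sim = 10L,
                                   seed = 1L) {
  stopifnot(n_sim >= 1L)
  sims <- lapply(seq_len(n_sim), function(i) {
    run_simulation(curve, energy, swarm, seed = seed + i - 1L)
  })
  hist <- do.call(rbind, lapply(seq_along(sims), function(i) {
    cbind(run = i, sims[[i]]$history)
  }))
  converged <- vapply(sims, function(s) {
    d <- s$history$mean_spacing
    n <- length(d)
    if (n < 21L) return(FALSE)
    tail20 <- d[(n - 20L):n]
    (max(tail20) - min(tail20)) < 0.01 * d[n]
  }, logical(1))
  met <- mean_intercluster_distance(sims)
  structure(list(
    simulations = sims,
    history = hist,
    d_sk = met$d_sk,
    d_bar = met$d_bar,
    sd = met$sd,
    final_counts = vapply(sims, function(s) length(s$g_interior) + 2L,
                          integer(1)),
    converged = converged,
    energy = energy, swarm = swarm, n_sim = n_sim, seed = seed
  ), class = "pso_convergence")
}

#' @export
print.pso_convergence <- function(x, ...) {
  cat(sprintf("Convergence experiment: %d runs (seed %d)\n", x$n_sim, x$seed))
  cat(sprintf("  r_m = %.3g um, d_th = %.3g um, S = %d, T_max = %d\n",
              x$energy$r_m, x$energy$d_th, x$swarm$S, x$swarm$T_max))
  cat(sprintf("  mean final distance = %.4g +/- %.3g um; clusters %s; %d/%d converged\n",
              x$d_bar, x$sd,
              paste(range(x$final_counts), collapse = "-"),
              sum(x$converged), x$n_sim))
  invisible(x)
}

#' Define a parameter-grid sweep
#'
#' Describes one of the model's two-parameter explorations: the recruitment
#' sweep over (\code{d_th}, \code{r_m}), the fibre-shape sweep over
#' (\code{L_c}, \code{R_c}) and the behaviour sweep over (\code{c1},
#' \code{c2}). The returned plan is consumed by \code{\link{grid_sweep}}.
#'
#' @param experiment one of \code{"dth_rm"}, \code{"shape"},
#'   \code{"behavior"}.
#' @param p1,p2 numeric vectors of grid values for the two varied parameters
#'   (in the order named by \code{experiment}; for \code{"shape"} these are
#'   \code{L_c} and \code{R_c}, where \code{Inf} means straight).
#' @param curve fixed fibre for the non-shape sweeps.
#' @param energy,swarm baseline parameter objects; the swept pair overrides
#'   the corresponding fields cell by cell.
#' @param n_sim replicate simulations per grid cell.
#' @param seed top-level seed; each run's seed is derived from the cell and
#'   replicate indices only, so results are independent of execution order.
#' @return An object of class \code{sweep_plan}.
#' @export
sweep_plan <- function(experiment = c("dth_rm", "shape", "behavior"),
                       p1, p2, curve = NULL,
                       energy = energy_params(), swarm = swarm_params(),
                       n_sim = 10L, seed = 1L) {
  experiment <- match.arg(experiment)
  if (experiment != "shape" && is.null(curve))
    stop("non-shape sweeps need a fixed curve")
  if (experiment == "behavior" && (any(p1 < 0 | p1 > 4) || any(p2 < 0 | p2 > 4)))
    stop("acceleration coefficients must lie in [0, 4]")
  structure(list(experiment = experiment, p1 = p1, p2 = p2, curve = curve,
                 energy = energy, swarm = swarm,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "sweep_plan")
}

# Deterministic per-(cell, replicate) seed, independent of execution order.
cell_seed <- function(seed, cell, rep) {
  as.integer((seed + 7919 * cell + 104729 * rep) %% .Machine$integer.max)
}

#' Run a parameter-grid sweep
#'
#' For every cell of the plan's \code{p1 x p2} grid, runs \code{n_sim}
#' seeded simulations, aggregates the mean inter-cluster distance and mean
#' uniformity, then derives the rescaled distance, the ranking and the
#' high-rank mask over the grid. Cells whose runs fail are recorded as
#' \code{NA} and excluded from the grid-level statistics.
#'
#' @param plan a \code{\link{sweep_plan}}.
#' @param rank_threshold optional fixed cutoff on the normalized ranking for
#'   the high-rank mask; \code{NULL} uses mean + SD.
#' @return An object of class \code{pso_sweep}: a \code{cells} data frame
#'   (p1, p2, d_bar, u_bar, d_T, R, high_rank) plus the ranking metadata.
#' @export
grid_sweep <- function(plan, rank_threshold = NULL) {
  stopifnot(inherits(plan, "sweep_plan"))
  grid <- expand.grid(p1 = plan$p1, p2 = plan$p2, KEEP.OUT.ATTRS = FALSE)
  nsim <- plan$n_sim
  res <- lapply(seq_len(nrow(grid)), function(cell) {
    ep <- plan$energy
    sp <- plan$swarm
    crv <- plan$curve
    v1 <- grid$p1[cell]; v2 <- grid$p2[cell]
    ok <- TRUE
    msg <- NULL
    tryCatch({
      if (plan$experiment == "dth_rm") {
        ep <- energy_params(ep$epsilon, r_m = v2, d_th = v1)
      } else if (plan$experiment == "behavior") {
        sp <- swarm_params(sp$S, c1 = v1, c2 = v2, sp$omega_min,
                           sp$omega_max, sp$T_max, sp$dt)
      } else {
        crv <- myofibril_curve(v1, v2)
      }
      sims <- lapply(seq_len(nsim), function(r) {
        run_simulation(crv, ep, sp, seed = cell_seed(plan$seed, cell, r))
      })
      d <- mean_intercluster_distance(sims)$d_bar
      u <- swarm_uniformity(sims, seed = cell_seed(plan$seed, cell, 0L))$u_bar
      list(d_bar = d, u_bar = u, ok = TRUE)
    }, error = function(e) list(d_bar = NA_real_, u_bar = NA_real_,
                                ok = FALSE, msg = conditionMessage(e)))
  })
  grid$d_bar <- vapply(res, `[[`, numeric(1), "d_bar")
  grid$u_bar <- vapply(res, `[[`, numeric(1), "u_bar")
  ok <- !is.na(grid$d_bar)
  grid$d_T <- NA_real_
  grid$R <- NA_real_
  grid$high_rank <- NA
  rk <- NULL
  if (any(ok)) {
    grid$d_T[ok] <- rescaled_distance(grid$d_bar[ok], plan$energy$r_m)
    rk <- ranking_grid(grid$u_bar[ok], grid$d_T[ok],
                       threshold = rank_threshold)
    grid$R[ok] <- rk$R
    grid$high_rank[ok] <- rk$high_rank
  }
  structure(list(cells = grid, plan = plan,
                 sigma = if (is.null(rk)) NA_real_ else rk$sigma,
                 cutoff = if (is.null(rk)) NA_real_ else rk$cutoff,
                 failed = sum(!ok)),
            class = "pso_sweep")
}

#' @export
print.pso_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s): %d x %d grid, %d sims/cell\n",
              x$plan$experiment, length(x$plan$p1), length(x$plan$p2),
              x$plan$n_sim))
  if (x$failed > 0) cat(sprintf("  %d cell(s) failed\n", x$failed))
  cat(sprintf("  high-rank cells: %d (cutoff %.3g)\n",
              sum(x$cells$high_rank, na.rm = TRUE), x$cutoff))
  invisible(x)
}

#' Biologically valid area of a sweep
#'
#' Flags grid cells whose mean inter-cluster distance lies inside the range
#' observed experimentally for a muscle cell type, and reports the flagged
#' area as a fraction of the evaluable parameter space. Default ranges:
#' cardiac z-body to z-line spacing 1.2-2 um, flight muscle 1.7-3.2 um; the
#' skeletal range has no published numbers and defaults to 0.5-1.4 um as a
#' package choice (configurable).
#'
#' @param sweep a \code{pso_sweep}.
#' @param cell_type one of \code{"cardiac"}, \code{"flight"},
#'   \code{"skeletal"}, or \code{NULL} to use \code{range} directly.
#' @param range numeric length-2 vector overriding the cell-type range.
#' @return A list with the per-cell logical \code{valid} flags, the
#'   \code{fraction} of valid cells, the range used, and the number of
#'   missing cells excluded.
#' @export
validity_area <- function(sweep, cell_type = "cardiac", range = NULL) {
  stopifnot(inherits(sweep, "pso_sweep"))
  if (is.null(range)) {
    range <- switch(match.arg(cell_type, c("cardiac", "flight", "skeletal")),
                    cardiac = c(1.2, 2.0),
                    flight = c(1.7, 3.2),
                    skeletal = c(0.5, 1.4))
  }
  stopifnot(length(range) == 2L, range[1] < range[2])
  d <- sweep$cells$d_bar
  ok <- !is.na(d)
  valid <- ok & d >= range[1] & d <= range[2]
  list(valid = valid,
       fraction = if (any(ok)) sum(valid) / sum(ok) else NA_real_,
       range = range, missing = sum(!ok))
}

#' Compare metric groups by ANOVA and Tukey-Kramer
#'
#' One-way analysis of variance across groups followed by Tukey-Kramer
#' post-hoc pairwise comparisons (which accommodate unequal group sizes);
#' pairs with adjusted p < \code{alpha} are flagged significant. This is a
#' thin wrapper over \code{stats::aov} and \code{stats::TukeyHSD}.
#'
#' @param values numeric vector of metric values.
#' @param groups factor (or coercible) of the same length.
#' @param alpha significance level (default 0.05).
#' @return A list with the ANOVA p-value (\code{anova_p}), a data frame of
#'   pairwise comparisons (\code{pairs}: pair, diff, p_adj, significant), and
#'   \code{alpha}.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 replicates")
  if (stats::var(values) == 0)
    return(list(anova_p = NA_real_, pairs = NULL, alpha = alpha,
                note = "zero variance everywhere: groups incomparable"))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(anova_p = an[["Pr(>F)"]][1], pairs = pairs, alpha = alpha)
}
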