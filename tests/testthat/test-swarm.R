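test_that("the inertia weight decays linearly between its bounds", {
  sp <- swarm_params(T_max = 200, omega_min = 0.4, omega_max = 0.9)
  expect_equal(inertia_weight(0, sp), 0.9)
  expect_equal(inertia_weight(200, sp), 0.4)
  expect_equal(inertia_weight(100, sp), (0.9 + 0.4) / 2)
  tt <- 0:200
  expect_equal(diff(inertia_weight(tt, sp)), rep(-0.5 / 200, 200))
  expect_error(inertia_weight(201, sp))
})

test_that("the velocity rule reproduces its arithmetic with fixed draws", {
  # v = 0, p - r = 1, g - r = 2, c1 = c2 = 2, draws fixed at 0.5 -> 3
  expect_equal(premyoswarm:::pso_velocity(v = 0, r = 0, p = 1, g = 2, w = 0.7,
                                          c1 = 2, c2 = 2, R1 = 0.5, R2 = 0.5),
               3)
  # c1 = c2 = 0 with unit inertia leaves the velocity unchanged
  expect_equal(premyoswarm:::pso_velocity(0.37, 5, 9, 1, 1, 0, 0, 0.1, 0.9),
               0.37)
  # converged fixed point: v = 0 and p = r = g stays at rest
  expect_equal(premyoswarm:::pso_velocity(0, 2, 2, 2, 0.9, 2, 2, 0.3, 0.8), 0)
})

test_that("parameter validation rejects out-of-range swarm settings", {
  expect_error(swarm_params(S = 1))
  expect_error(swarm_params(c1 = 5))
  expect_error(swarm_params(omega_min = 0))
  expect_error(swarm_params(omega_min = 0.9, omega_max = 0.4))
  expect_error(swarm_params(T_max = 0))
})

test_that("simulations are bit-reproducible under a fixed seed", {
  fib <- straight_fibre(8)
  ep <- energy_params(r_m = 1.1, d_th = 0.5)
  s1 <- run_simulation(fib, ep, quick_swarm(), seed = 33)
  s2 <- run_simulation(fib, ep, quick_swarm(), seed = 33)
  expect_identical(s1$g_interior, s2$g_interior)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$swarm_positions, s2$swarm_positions)
  s3 <- run_simulation(fib, ep, quick_swarm(), seed = 34)
  expect_false(identical(s3$history, s1$history))
})

test_that("the engine honours its dynamical invariants", {
  fib <- straight_fibre(8)
  sim <- run_simulation(fib, energy_params(r_m = 1.1, d_th = 0.5),
                        quick_swarm(S = 20, T_max = 60), seed = 5)
  h <- sim$history
  # global-best monotonicity, with strict drops at recruitment iterations
  expect_true(all(diff(h$f_g) <= 1e-9))
  grew <- diff(h$n_clusters) > 0
  expect_true(any(grew))
  expect_true(all(diff(h$f_g)[grew] < 0))
  # recruitment only ever adds clusters
  expect_true(all(diff(h$n_clusters) >= 0))
  # synchronized growth: every configuration matches g's cluster count
  expect_equal(ncol(sim$swarm_positions), length(sim$g_interior))
  # boundary safety: all positions within the fibre extent
  expect_true(all(sim$swarm_positions >= fib$x_start - 1e-12))
  expect_true(all(sim$swarm_positions <= fib$x_end + 1e-12))
  expect_true(all(sim$g_interior >= fib$x_start &
                  sim$g_interior <= fib$x_end))
})

test_that("no recruitment occurs when every gap is at or below d_th", {
  # 0.4 um fibre with d_th = 0.5: the single segment is never eligible
  fib <- myofibril_curve(0.4, Inf)
  sim <- run_simulation(fib, energy_params(r_m = 0.3, d_th = 0.5),
                        quick_swarm(S = 6, T_max = 10), seed = 2)
  expect_true(all(sim$history$n_clusters == 3L))
})

test_that("a wide gap recruits a midpoint-region cluster into every member", {
  # On a 3 r_m fibre the energy optimum parks the initial interior cluster
  # r_m from one end, leaving a 2 r_m gap; midpoint-region candidates there
  # have E < 0 and are recruited, growing every configuration in sync.
  fib <- myofibril_curve(3.3, Inf)
  sim <- run_simulation(fib, energy_params(r_m = 1.1, d_th = 0.5),
                        quick_swarm(S = 12, T_max = 60), seed = 4)
  expect_gte(utils::tail(sim$history$n_clusters, 1), 4L)
  expect_equal(ncol(sim$swarm_positions), length(sim$g_interior))
  # the recruited pattern sits near equal r_m spacing
  expect_equal(diff(c(0, sim$g_interior, 3.3)), rep(1.1, 3), tolerance = 0.1)
})

test_that("one-iteration runs execute exactly one update cycle", {
  fib <- straight_fibre(8)
  sim <- run_simulation(fib, energy_params(r_m = 1.1, d_th = 0.5),
                        quick_swarm(S = 6, T_max = 1), seed = 9)
  expect_equal(nrow(sim$history), 1L)
})

test_that("simulation outputs round-trip to trajectory and metadata files", {
  fib <- straight_fibre(8)
  sim <- run_simulation(fib, energy_params(r_m = 1.1, d_th = 0.5),
                        quick_swarm(S = 6, T_max = 15), seed = 12)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_true(all(file.exists(paths)))
  traj <- read.csv(paths[["trajectory"]])
  expect_equal(traj, sim$history)
  meta <- jsonlite::read_json(paths[["metadata"]], simplifyVector = TRUE)
  expect_equal(meta$seed, 12)
  expect_equal(meta$energy$r_m, 1.1)
  fin <- read.csv(paths[["final"]])
  expect_equal(nrow(fin), length(sim$g_interior) + 2L)
  expect_equal(fin$x_um, sort(fin$x_um))
})

test_that("summary and plot methods run on a simulation object", {
  fib <- straight_fibre(8)
  sim <- run_simulation(fib, energy_params(r_m = 1.1, d_th = 0.5),
                        quick_swarm(S = 6, T_max = 15), seed = 1)
  s <- summary(sim)
  expect_s3_class(s, "summary.pso_simulation")
  expect_equal(s$n_clusters, utils::tail(sim$history$n_clusters, 1))
  expect_output(print(sim), "premyofibril simulation")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sim))
})
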