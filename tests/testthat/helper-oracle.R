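# Independent oracles: deliberately written without reference to the package
# internals (own Lennard-Jones arithmetic, brute-force scans), so they can
# cross-check the implementation.

oracle_lj <- function(r, rm, eps = 1) eps * ((rm / r)^12 - 2 * (rm / r)^6)

# Exhaustive grid minimization of the total pairwise energy of n <= 3
# interior clusters on a straight fibre of length L with fixed endpoint
# clusters at 0 and L. Grid step 0.01 um.
oracle_grid_min <- function(L, rm, step = 0.01) {
  g <- seq(step, L - step, by = step)
  M <- length(g)
  best <- list(E = Inf, x = numeric(0))
  e_end <- oracle_lj(L, rm)
  A <- oracle_lj(g, rm) + oracle_lj(L - g, rm)   # interior vs both endpoints
  E1 <- e_end + A
  i <- which.min(E1)
  if (E1[i] < best$E) best <- list(E = E1[i], x = g[i])
  jk <- utils::combn(M, 2L)
  B2 <- A[jk[1, ]] + A[jk[2, ]] + oracle_lj(g[jk[2, ]] - g[jk[1, ]], rm)
  E2 <- e_end + B2
  i <- which.min(E2)
  if (E2[i] < best$E) best <- list(E = E2[i], x = g[jk[, i]])
  for (i1 in seq_len(M - 2L)) {
    sel <- jk[1, ] > i1
    j <- jk[1, sel]; k <- jk[2, sel]
    E3 <- e_end + A[i1] + B2[sel] +
      oracle_lj(g[j] - g[i1], rm) + oracle_lj(g[k] - g[i1], rm)
    ib <- which.min(E3)
    if (E3[ib] < best$E)
      best <- list(E = E3[ib], x = c(g[i1], g[j[ib]], g[k[ib]]))
  }
  best
}

# Brute-force cost-benefit of adding a candidate at s_x to a straight-fibre
# configuration: candidate interacts with every existing cluster (endpoints
# included) and with every earlier accepted candidate, unless its segment is
# already occupied by an earlier candidate (then 0).
oracle_cost_benefit <- function(s_x, accepted_x, interior_x, L, rm, eps = 1) {
  bounds <- sort(c(0, interior_x, L))
  seg <- function(x) findInterval(x, bounds, rightmost.closed = TRUE)
  if (length(accepted_x) > 0 && any(seg(accepted_x) == seg(s_x))) return(0)
  all_x <- c(bounds, accepted_x)
  sum(oracle_lj(abs(all_x - s_x), rm, eps))
}

# Brute-force nearest-neighbour distances over an all-pairs scan.
oracle_nn <- function(pts) {
  if (is.null(dim(pts))) pts <- cbind(pts, 0)
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    min(sqrt((pts[-i, 1] - pts[i, 1])^2 + (pts[-i, 2] - pts[i, 2])^2))
  }, numeric(1))
}

# Permutation test for a difference in group means (two groups).
oracle_perm_test <- function(a, b, n_perm = 2000, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  stat <- replicate(n_perm, {
    idx <- sample(length(pool), na)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  mean(stat >= obs - 1e-12)
}
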