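# Shared helpers for the branchrd test suite. Fixtures are built in code;
# nothing is read from disk.

# Always run the whole suite: the scenario-level acceptance blocks report
# several expected failures at reduced problem sizes, and the default
# progress reporter would otherwise stop before the unit suites run.
options(testthat.progress.max_fails = Inf)

# Independent brute-force peak scan: for every strictly-higher-than-both-
# neighbours plateau (not touching the profile ends), walk outward on each
# side to the nearest sample exceeding the peak (or the end) and take the
# minimum en route; prominence is height above the higher of the two
# flanking minima. Written as plain loops, independent of find_peaks().
brute_force_peaks <- function(x, prominence = 0.1) {
  n <- length(x)
  if (n < 3L) return(0L)
  rng <- max(x) - min(x)
  if (rng == 0) return(0L)
  count <- 0L
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (j < n && i > 1L && x[i - 1L] < x[i] && x[j + 1L] < x[i]) {
      lmin <- x[i - 1L]
      k <- i - 1L
      while (k >= 1L && x[k] <= x[i]) {
        if (x[k] < lmin) lmin <- x[k]
        k <- k - 1L
      }
      rmin <- x[j + 1L]
      k <- j + 1L
      while (k <= n && x[k] <= x[i]) {
        if (x[k] < rmin) rmin <- x[k]
        k <- k + 1L
      }
      if (x[i] - max(lmin, rmin) > prominence * rng) count <- count + 1L
    }
    i <- j + 1L
  }
  count
}

# Random positive parameter set for property-style checks.
random_params <- function() {
  rd_params(c = runif(1, 0.01, 0.2), mu = runif(1, 0.05, 0.8),
            nu = runif(1, 0.01, 0.2), rho_A = runif(1, 0, 0.1),
            rho_H = runif(1, 0, 0.01), c0 = runif(1, 0.005, 0.05),
            gamma = runif(1, 0.01, 0.1), epsilon = runif(1, 0, 0.1),
            d = runif(1, 0.001, 0.02), e = runif(1, 0.05, 0.3),
            f = runif(1, 2, 20), D_A = runif(1, 0.02, 0.1),
            D_H = runif(1, 0.15, 0.4), D_S = runif(1, 0.02, 0.1))
}

# Side-branching test shape: straight trunk with two perpendicular lateral
# arms attached in its proximal half.
side_branch_fixture <- function(dim = c(44, 44, 52), r = 2.5) {
  cx <- dim[1] / 2; cy <- dim[2] / 2
  z0 <- 6
  segs <- rbind(
    c(cx, cy, z0, cx, cy, z0 + 38, r),                  # trunk
    c(cx, cy, z0 + 10, cx + 12, cy, z0 + 10, r),        # lateral arm 1
    c(cx, cy, z0 + 18, cx, cy + 12, z0 + 18, r))        # lateral arm 2
  make_fixture(fixture_spec("capsules", dim = dim, segments = segs))
}

# Terminal-fork test shape: long trunk whose only branch point sits in the
# distal quarter, with symmetric short daughter arms.
tip_fork_fixture <- function(dim = c(44, 44, 52), r = 2.5) {
  make_fixture(fixture_spec("y_tube", dim = dim, radius = r,
                            trunk_length = 30, arm_length = 8))
}
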