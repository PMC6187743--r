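# Homogeneous steady states, the analytic Jacobian, and the dispersion
# relation of the linearized reaction-diffusion operator.

test_that("clamped-Y0 steady state matches the closed forms", {
  p <- rd_params()  # c = 0.04, mu = 0.3, nu = 0.03, c0 = 0.02, gamma = 0.02
  ss <- steady_state(p)
  expect_equal(ss$S_star, 1)
  expect_equal(ss$A_star, 0.1)
  expect_equal(ss$H_star, 0.04 * 0.03 * 1 / 0.3^2)  # 0.0133...
  expect_equal(ss$Y_star, 0)
  expect_lt(ss$residual, 1e-12)
  expect_equal(ss$Y_residual, p$d * ss$A_star)  # consistency note
})

test_that("zero substrate production gives the degenerate H* = 0 state", {
  p <- rd_params(c0 = 0)
  ss <- steady_state(p)
  expect_equal(ss$S_star, 0)
  expect_equal(ss$A_star, p$nu / p$mu)
  expect_equal(ss$H_star, 0)
  expect_true(ss$degenerate)
  expect_error(rd_jacobian(p, ss), "H\\*")
})

test_that("full steady state solves all four equations and decouples correctly", {
  p <- rd_params()
  ss <- steady_state(p, "full")
  r <- rd_reaction_rates(ss$A_star, ss$H_star, ss$S_star, ss$Y_star, p)
  expect_lt(max(abs(c(r$dA, r$dH, r$dS, r$dY))), 1e-10)
  # weak coupling: full state close to the clamped one (d A* is small)
  s0 <- steady_state(p)
  expect_equal(ss$A_star, s0$A_star, tolerance = 0.1)
  expect_equal(ss$H_star, s0$H_star, tolerance = 0.1)
  expect_equal(ss$S_star, s0$S_star, tolerance = 0.1)

  # fully decoupled Y: full solution equals clamped solution with Y* = 0
  pd <- rd_params(rho_A = 0, rho_H = 0, epsilon = 0, d = 0)
  sd <- steady_state(pd, "full")
  sc <- steady_state(pd)
  expect_equal(sd$A_star, sc$A_star, tolerance = 1e-8)
  expect_equal(sd$H_star, sc$H_star, tolerance = 1e-8)
  expect_equal(sd$Y_star, 0, tolerance = 1e-10)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    x <- c(A = runif(1, 0.05, 2), H = runif(1, 0.05, 2),
           S = runif(1, 0.05, 2), Y = runif(1, 0.05, 2))
    J <- branchrd:::jacobian_at(p, x[1], x[2], x[3], x[4])
    hstep <- 1e-6
    for (j in 1:4) {
      xp <- x; xm <- x
      xp[j] <- x[j] + hstep
      xm[j] <- x[j] - hstep
      rp <- rd_reaction_rates(xp[1], xp[2], xp[3], xp[4], p)
      rm <- rd_reaction_rates(xm[1], xm[2], xm[3], xm[4], p)
      fd <- (c(rp$dA, rp$dH, rp$dS, rp$dY) -
             c(rm$dA, rm$dH, rm$dS, rm$dY)) / (2 * hstep)
      scale <- pmax(abs(J[, j]), 1)
      expect_lt(max(abs(J[, j] - fd) / scale), 1e-6)
    }
  }
})

test_that("Jacobian structural entries are exact", {
  p <- rd_params()
  ss <- steady_state(p)
  J <- rd_jacobian(p, ss)
  expect_identical(J["dS", "A"], 0)
  expect_identical(J["dS", "H"], 0)
  expect_equal(J["dH", "Y"], p$rho_H)
  # at the clamped state c A* S*/H* = mu, so d(dA)/dA = 2mu - mu = +mu
  expect_equal(J["dA", "A"], p$mu)
})

test_that("dispersion relation has the right limits", {
  p <- rd_params()
  disp <- dispersion(p, q_max = 6, n_q = 300)
  J <- rd_jacobian(p, steady_state(p))
  lam0 <- max(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(disp$data$re_lambda_max[1], lam0)
  expect_equal(disp$data$q[1], 0)
  # diffusion dominates at large q: monotone decrease beyond the peak
  tail_part <- disp$data$re_lambda_max[disp$data$q > disp$q_peak + 1]
  expect_true(all(diff(tail_part) < 0))
})

test_that("seeded Fourier modes grow at the rate the dispersion relation predicts", {
  # periodic pseudo-1D domain: perturb the full fixed point along the
  # leading eigenvector at wavenumber q and compare the measured
  # exponential growth rate of the mode amplitude with Re lambda(q)
  p <- rd_params()
  ss <- steady_state(p, "full")
  nx <- 64; h <- 0.25
  dom <- rd_domain(nx, 4, 4, h = h, boundary = "periodic")
  kmode <- 3
  q <- 2 * pi * kmode / (nx * h)
  J <- rd_jacobian(p, ss)
  M <- J - q^2 * diag(c(p$D_A, p$D_H, p$D_S, 0))
  eg <- eigen(M)
  lead <- which.max(Re(eg$values))
  lam <- Re(eg$values[lead])
  vec <- Re(eg$vectors[, lead])
  vec <- vec / max(abs(vec))

  amp0 <- 1e-6
  xcoord <- (seq_len(nx) - 1) * h
  wave <- cos(q * xcoord)
  base <- rd_initialize(dom, rd_init("uniform", A0 = ss$A_star,
                                     H0 = ss$H_star, S0 = ss$S_star,
                                     fluctuation = 0), p)
  base$Y[] <- ss$Y_star
  flds <- c("A", "H", "S", "Y")
  for (i in 1:4)
    base[[flds[i]]] <- base[[flds[i]]] + amp0 * vec[i] *
      array(wave, dim = c(nx, 4, 4))

  mode_amp <- function(st) {
    prof <- apply(st$A, 1, mean)
    2 * abs(sum(prof * exp(-2i * pi * kmode * (seq_len(nx) - 1) / nx))) / nx
  }
  dt <- 0.04
  n1 <- 250  # 10 time units, well inside the linear regime
  st1 <- rd_step(base, p, rd_stepper(dt = dt, n_steps = n1), dom)
  st2 <- rd_step(st1, p, rd_stepper(dt = dt, n_steps = n1), dom)
  rate <- log(mode_amp(st2) / mode_amp(st1)) / (n1 * dt)
  expect_equal(rate, lam, tolerance = 0.05 * max(abs(lam), 0.01))
})

test_that("strict Turing flag is reported from the q = 0 sign, not assumed", {
  # the canonical parameter sets leave the homogeneous state unstable even
  # at q = 0 (the A-H trace is mu - nu > 0), so patterning is front-driven
  # rather than classical Turing; the flag must say so rather than claim
  # instability of the Turing type
  for (pars in list(rd_params(),                          # side-branching
                    rd_params(mu = 0.8, nu = 0.08),       # tip-splitting
                    rd_params(mu = 0.48, nu = 0.06))) {   # gradient set
    disp <- dispersion(pars)
    expect_gt(disp$data$re_lambda_max[1], 0)
    expect_false(disp$turing_unstable)
    expect_true(all(is.finite(disp$data$re_lambda_max)))
  }
})
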