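# Local reaction kinetics, the discrete Laplacian, and the Euler stepper.

test_that("reaction rates reproduce hand-computed values", {
  p <- rd_params()  # c = 0.04, mu = 0.3
  r <- rd_reaction_rates(1, 1, 1, 0, p)
  expect_equal(r$dA, 0.04 * 1 * 1 / 1 - 0.3 * 1 + 0)  # -0.26
  expect_equal(r$dA, -0.26)

  # zero-activator rest point: A = 0, Y = 0, S = c0/gamma
  r0 <- rd_reaction_rates(0, 0, p$c0 / p$gamma, 0, p)
  expect_equal(r0$dA, 0)
  expect_equal(r0$dH, 0)
  expect_equal(r0$dS, 0)
  expect_equal(r0$dY, 0)
})

test_that("nonzero Y roots of the local Y-equation match the quadratic oracle", {
  # -eY + Y^2/(1+fY^2) = 0  <=>  f e Y^2 - Y + e = 0 for Y > 0
  p <- rd_params()  # e = 0.1, f = 10
  roots <- sort(Re(polyroot(c(p$e, -1, p$f * p$e))))
  expect_equal(roots, c((1 - sqrt(0.6)) / 2, (1 + sqrt(0.6)) / 2))
  for (y in roots) {
    r <- rd_reaction_rates(0, 1, 1, y, p)
    expect_lt(abs(r$dY), 1e-12)
  }
})

test_that("Y dynamics with A clamped at 0 is bistable around the quadratic roots", {
  p <- rd_params()
  lo <- (1 - sqrt(0.6)) / 2    # repeller
  hi <- (1 + sqrt(0.6)) / 2    # upper attractor
  evolve_Y <- function(y0, t_end = 400, dt = 0.01) {
    y <- y0
    for (i in seq_len(t_end / dt))
      y <- y + dt * (-p$e * y + y^2 / (1 + p$f * y^2))
    y
  }
  expect_equal(evolve_Y(lo * 1.05), hi, tolerance = 1e-6)
  expect_equal(evolve_Y(lo * 0.95), 0, tolerance = 1e-6)
  expect_equal(evolve_Y(1), hi, tolerance = 1e-6)
})

test_that("Laplacian matches the 7-point stencil by hand", {
  dom <- rd_domain(5, 5, 5, h = 1)
  u <- array(3.2, c(5, 5, 5))
  expect_true(all(rd_laplacian(u, dom) == 0))

  u <- array(0, c(5, 5, 5))
  u[3, 3, 3] <- 1
  L <- rd_laplacian(u, dom)
  expect_equal(L[3, 3, 3], -6)
  expect_equal(L[2, 3, 3], 1)
  expect_equal(L[4, 3, 3], 1)
  expect_equal(L[3, 2, 3], 1)
  expect_equal(L[3, 3, 4], 1)
  expect_equal(sum(L), 0)  # discrete conservation

  # affine ramp: zero in the interior, mirror condition at the x faces
  ramp <- array(rep(seq_len(5), 25), c(5, 5, 5))
  L <- rd_laplacian(ramp, dom)
  expect_true(all(abs(L[2:4, , ]) < 1e-12))
  expect_equal(L[1, 3, 3], 1)   # ghost = boundary value
  expect_equal(L[5, 3, 3], -1)

  expect_error(rd_laplacian(array(0, c(4, 5, 5)), dom), "shape")
})

test_that("pure Neumann diffusion conserves each field's total mass", {
  p0 <- rd_params(c = 0, mu = 0, nu = 0, rho_A = 0, rho_H = 0, c0 = 0,
                  gamma = 0, epsilon = 0, d = 0, e = 0, f = 1)
  dom <- rd_domain(10, 9, 8)
  set.seed(42)
  st <- rd_initialize(dom, rd_init("uniform", A0 = 1, H0 = 1, S0 = 1,
                                   fluctuation = 0), p0)
  st$A <- array(runif(720), dim = c(10, 9, 8))
  st$H <- array(runif(720), dim = c(10, 9, 8))
  st$S <- array(runif(720), dim = c(10, 9, 8))
  before <- c(sum(st$A), sum(st$H), sum(st$S))
  out <- rd_step(st, p0, rd_stepper(dt = 0.5, n_steps = 1000), dom)
  after <- c(sum(out$A), sum(out$H), sum(out$S))
  expect_equal(after, before, tolerance = 1e-10)
})

test_that("zero-diffusion voxel trajectory matches a high-accuracy ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- rd_params(D_A = 0, D_H = 0, D_S = 0)
  dom <- rd_domain(3, 3, 3)
  y0 <- c(A = 0.2, H = 0.05, S = 1, Y = 0.3)
  st <- rd_initialize(dom, rd_init("uniform", A0 = y0["A"], H0 = y0["H"],
                                   S0 = y0["S"], fluctuation = 0), p)
  st$Y[] <- y0["Y"]
  out <- rd_step(st, p, rd_stepper(dt = 0.04, n_steps = 1000), dom)

  rhs <- function(t, y, parms) {
    r <- rd_reaction_rates(y[1], y[2], y[3], y[4], p)
    list(c(r$dA, r$dH, r$dS, r$dY))
  }
  sol <- deSolve::ode(y0, c(0, 1000 * 0.04), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ref <- sol[2, c("A", "H", "S", "Y")]
  got <- c(out$A[2, 2, 2], out$H[2, 2, 2], out$S[2, 2, 2], out$Y[2, 2, 2])
  expect_equal(got, unname(ref), tolerance = 0.01)
})

test_that("a uniform state at the full fixed point is preserved by stepping", {
  p <- rd_params()
  ss <- steady_state(p, "full")
  dom <- rd_domain(6, 6, 6)
  st <- rd_initialize(dom, rd_init("uniform", A0 = ss$A_star, H0 = ss$H_star,
                                   S0 = ss$S_star, fluctuation = 0), p)
  st$Y[] <- ss$Y_star
  out <- rd_step(st, p, rd_stepper(dt = 0.04, n_steps = 1), dom)
  for (f in c("A", "H", "S", "Y")) {
    rel <- abs(out[[f]] - st[[f]]) / pmax(abs(st[[f]]), 1e-30)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("Y is purely local: no diffusion of the differentiation marker", {
  # freeze A (mu = rho_A = c = 0 keeps dA = 0 when A = 0): a lone Y voxel
  # must evolve exactly like the scalar ODE and never spread
  p <- rd_params(c = 0, mu = 0, rho_A = 0, d = 0.008)
  dom <- rd_domain(7, 7, 7)
  st <- rd_initialize(dom, rd_init("uniform", A0 = 0, H0 = 1, S0 = 1,
                                   fluctuation = 0), p)
  st$Y[4, 4, 4] <- 1
  out <- rd_step(st, p, rd_stepper(dt = 0.1, n_steps = 500), dom)
  expect_equal(sum(out$Y > 0), 1L)
  y <- 1
  for (i in 1:500) y <- y + 0.1 * (-p$e * y + y^2 / (1 + p$f * y^2))
  expect_equal(out$Y[4, 4, 4], y)
})

test_that("stepping is deterministic and n_steps = 0 is the identity", {
  p <- rd_params()
  dom <- rd_domain(8, 8, 8)
  ini <- rd_init("seeded", seed_radius = 2, rng_seed = 7)
  r1 <- rd_run(p, dom, ini, rd_stepper(dt = 0.04, n_steps = 50))
  r2 <- rd_run(p, dom, ini, rd_stepper(dt = 0.04, n_steps = 50))
  expect_identical(r1$final$A, r2$final$A)
  expect_identical(r1$final$Y, r2$final$Y)

  r0 <- rd_run(p, dom, ini, rd_stepper(dt = 0.04, n_steps = 0))
  expect_identical(r0$final$A, r0$initial$A)
  expect_identical(r0$final$t, r0$initial$t)
})

test_that("unstable dt is refused unless explicitly overridden", {
  p <- rd_params()  # D_H = 0.26 -> bound = 1/(6*0.26) at h = 1
  dom <- rd_domain(5, 5, 5)
  st <- rd_initialize(dom, rd_init("uniform", fluctuation = 0), p)
  expect_error(rd_step(st, p, rd_stepper(dt = 0.7, n_steps = 1), dom),
               "stability bound")
  expect_silent(rd_step(st, p, rd_stepper(dt = 0.7, n_steps = 1,
                                          allow_unstable_dt = TRUE), dom))
})

test_that("mirror symmetry: zero fluctuation and a centered seed stay symmetric", {
  p <- rd_params()
  dom <- rd_domain(15, 15, 15, h = 0.25)
  ini <- rd_init("seeded", seed_center = c(8, 8, 8), seed_radius = 2,
                 fluctuation = 0)
  run <- rd_run(p, dom, ini, rd_stepper(dt = 0.04, n_steps = 400))
  for (f in c("A", "H", "S", "Y")) {
    x <- run$final[[f]]
    expect_lt(max(abs(x - x[15:1, , ])), 1e-8)
    expect_lt(max(abs(x - x[, 15:1, ])), 1e-8)
    expect_lt(max(abs(x - x[, , 15:1])), 1e-8)
  }
})
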