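#' Model parameters of the four-field branching reaction-diffusion system
#'
#' Bundles the 14 reaction and diffusion constants of the
#' activator/inhibitor/substrate/differentiation-marker model:
#'
#' \deqn{\partial A/\partial t = c A^2 S / H - \mu A + D_A \nabla^2 A + \rho_A Y}
#' \deqn{\partial H/\partial t = c A^2 S - \nu H + D_H \nabla^2 H + \rho_H Y}
#' \deqn{\partial S/\partial t = c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S}
#' \deqn{\partial Y/\partial t = d A - e Y + Y^2 / (1 + f Y^2)}
#'
#' All quantities are dimensionless. Defaults are the canonical
#' side-branching parameter set used throughout the package's scenarios.
#'
#' @param c autocatalysis rate of the activator.
#' @param mu first-order degradation rate of A.
#' @param nu first-order degradation rate of H.
#' @param rho_A secretion rate of A by differentiated (Y) cells.
#' @param rho_H secretion rate of H by differentiated (Y) cells.
#' @param c0 production rate of the substrate S.
#' @param gamma first-order degradation rate of S.
#' @param epsilon consumption rate of S by Y cells.
#' @param d Y production coefficient from A.
#' @param e first-order degradation rate of Y.
#' @param f saturation constant in the Y self-activation term.
#' @param D_A,D_H,D_S diffusion coefficients of A, H and S. Y does not
#'   diffuse. A lateral-inhibition (Turing) mechanism requires the inhibitor
#'   to spread faster than the activator, so a warning is emitted when
#'   `D_A >= D_H`.
#'
#' @return An object of class `rd_params` (a named list of the 14 constants).
#' @examples
#' p <- rd_params()                # side-branching defaults
#' p2 <- rd_params(mu = 0.8, nu = 0.08)  # tip-splitting regime
#' @export
rd_params <- function(c = 0.04, mu = 0.3, nu = 0.03, rho_A = 0.03,
                      rho_H = 0.0001, c0 = 0.02, gamma = 0.02,
                      epsilon = 0.042, d = 0.008, e = 0.1, f = 10,
                      D_A = 0.1, D_H = 0.26, D_S = 0.06) {
  p <- list(c = c, mu = mu, nu = nu, rho_A = rho_A, rho_H = rho_H,
            c0 = c0, gamma = gamma, epsilon = epsilon, d = d, e = e, f = f,
            D_A = D_A, D_H = D_H, D_S = D_S)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$D_H > 0 && p$D_A >= p$D_H)
    warning("D_A >= D_H: the inhibitor should diffuse faster than the ",
            "activator for lateral inhibition (Turing) patterning",
            call. = FALSE)
  structure(p, class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat("<rd_params> four-field reaction-diffusion constants\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Simulation domain: a regular 3D grid
#'
#' @param nx,ny,nz grid extents in voxels (each at least 3).
#' @param h grid spacing (dimensionless length).
#' @param boundary `"zero_flux"` (mirror/Neumann, the default: a closed
#'   simulation box) or `"periodic"`.
#' @return An object of class `rd_domain`.
#' @examples
#' rd_domain(64, 64, 32)
#' @export
rd_domain <- function(nx = 64L, ny = 64L, nz = 32L, h = 1,
                      boundary = c("zero_flux", "periodic")) {
  boundary <- match.arg(boundary)
  dims <- c(nx = nx, ny = ny, nz = nz)
  if (any(dims < 3L)) stop("grid extents must all be >= 3", call. = FALSE)
  if (!is.numeric(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), h = h, boundary = boundary),
            class = "rd_domain")
}

#' @export
print.rd_domain <- function(x, ...) {
  cat(sprintf("<rd_domain> %d x %d x %d, h = %g, %s boundaries\n",
              x$nx, x$ny, x$nz, x$h, x$boundary))
  invisible(x)
}

domain_dim <- function(domain) c(domain$nx, domain$ny, domain$nz)

#' Initial-condition specification
#'
#' Three initialization modes:
#' * `"seeded"`: a small sphere of differentiated cells (`Y = seed_Y_value`)
#'   at `seed_center` models the initial bud; `Y = 0` elsewhere.
#' * `"gradient"`: no differentiated cells anywhere (`Y = 0`); the activator
#'   varies affinely from `gradient_low` to `gradient_high` along
#'   `gradient_axis`, modelling an externally imposed morphogen gradient.
#' * `"uniform"`: no seed and no gradient.
#'
#' In every mode A and H receive independent multiplicative fluctuations
#' drawn uniformly from `[-fluctuation, +fluctuation]`, seeded by
#' `rng_seed`, so two specifications with the same seed produce
#' bit-identical states. Baselines `A0`, `H0`, `S0` default to the
#' homogeneous `Y = 0` steady state of the reaction system (see
#' [steady_state()]), so the fluctuation perturbs a near-stationary
#' background.
#'
#' @param mode `"seeded"`, `"gradient"` or `"uniform"`.
#' @param seed_center voxel coordinate (length-3, 1-based) of the bud
#'   center; `NULL` means the domain center.
#' @param seed_radius radius of the seeded bud, in voxels.
#' @param seed_Y_value Y concentration inside the seed.
#' @param A0,H0,S0 baseline concentrations; `NULL` defers to the
#'   homogeneous steady state computed from the model parameters.
#' @param fluctuation relative fluctuation amplitude on A and H, in
#'   `[0, 1)`.
#' @param rng_seed integer seed for the fluctuation RNG.
#' @param gradient_axis `"x"`, `"y"` or `"z"`.
#' @param gradient_low,gradient_high activator concentrations at the two
#'   ends of the gradient axis (`gradient_low <= gradient_high`).
#' @return An object of class `rd_init`.
#' @examples
#' rd_init()                                  # centered bud, 5% fluctuation
#' rd_init("gradient", gradient_low = 0.001, gradient_high = 2.9)
#' @export
rd_init <- function(mode = c("seeded", "gradient", "uniform"),
                    seed_center = NULL, seed_radius = 2, seed_Y_value = 1,
                    A0 = NULL, H0 = NULL, S0 = NULL, fluctuation = 0.05,
                    rng_seed = 1L, gradient_axis = c("z", "x", "y"),
                    gradient_low = 0.001, gradient_high = 2.9) {
  mode <- match.arg(mode)
  gradient_axis <- match.arg(gradient_axis)
  if (fluctuation < 0 || fluctuation >= 1)
    stop("fluctuation must be in [0, 1)", call. = FALSE)
  if (gradient_low > gradient_high)
    stop("gradient_low must not exceed gradient_high", call. = FALSE)
  if (seed_radius <= 0) stop("seed_radius must be > 0", call. = FALSE)
  structure(list(mode = mode, seed_center = seed_center,
                 seed_radius = seed_radius, seed_Y_value = seed_Y_value,
                 A0 = A0, H0 = H0, S0 = S0, fluctuation = fluctuation,
                 rng_seed = as.integer(rng_seed),
                 gradient_axis = gradient_axis,
                 gradient_low = gradient_low,
                 gradient_high = gradient_high),
            class = "rd_init")
}

#' Time-stepping configuration
#'
#' Explicit Euler with a 7-point Laplacian. The diffusion-stability bound for
#' this stencil is `dt <= h^2 / (6 * max(D_A, D_H, D_S))`; exceeding it
#' without `allow_unstable_dt = TRUE` is an error at run time.
#'
#' @param dt time increment per step.
#' @param n_steps number of Euler updates to take.
#' @param snapshot_every store a full field snapshot every this many steps
#'   (0 disables snapshots; the final state is always returned).
#' @param H_floor small positive clamp applied to H in the A-equation
#'   denominator; clamp events are counted and reported in the run log.
#' @param allow_unstable_dt set `TRUE` to override the stability bound.
#' @return An object of class `rd_stepper`.
#' @export
rd_stepper <- function(dt = 0.5, n_steps = 1000L, snapshot_every = 0L,
                       H_floor = 1e-8, allow_unstable_dt = FALSE) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (H_floor <= 0) stop("H_floor must be > 0", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 snapshot_every = as.integer(snapshot_every),
                 H_floor = H_floor,
                 allow_unstable_dt = isTRUE(allow_unstable_dt)),
            class = "rd_stepper")
}

check_dt_stable <- function(stepper, params, domain) {
  bound <- domain$h^2 / (6 * max(params$D_A, params$D_H, params$D_S))
  if (stepper$dt > bound && !stepper$allow_unstable_dt)
    stop(sprintf(paste0("dt = %g exceeds the explicit-Euler diffusion ",
                        "stability bound h^2/(6 max D) = %g; reduce dt or ",
                        "set allow_unstable_dt = TRUE"),
                 stepper$dt, bound), call. = FALSE)
  invisible(bound)
}
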