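#' Local reaction rates of the four-field system
#'
#' Evaluates the reaction terms (diffusion excluded) of the model at given
#' concentrations. All arguments are recycled elementwise, so whole fields
#' can be passed directly.
#'
#' @param A,H,S,Y concentrations (scalars or arrays of a common shape).
#' @param params an [rd_params()] object.
#' @param H_floor clamp applied to H in the A-equation denominator before
#'   division.
#' @return A list with components `dA`, `dH`, `dS`, `dY` (same shape as the
#'   inputs) and an attribute `clamp_count`, the number of H values that were
#'   below `H_floor`.
#' @examples
#' rd_reaction_rates(1, 1, 1, 0, rd_params())
#' @export
rd_reaction_rates <- function(A, H, S, Y, params, H_floor = 1e-8) {
  stopifnot(inherits(params, "rd_params"))
  if (!all(is.finite(A), is.finite(H), is.finite(S), is.finite(Y)))
    stop("non-finite concentration passed to rd_reaction_rates", call. = FALSE)
  clamped <- H < H_floor
  Hc <- pmax(H, H_floor)
  autocat <- params$c * A^2 * S
  dA <- autocat / Hc - params$mu * A + params$rho_A * Y
  dH <- autocat - params$nu * H + params$rho_H * Y
  dS <- params$c0 - params$gamma * S - params$epsilon * Y * S
  dY <- params$d * A - params$e * Y + Y^2 / (1 + params$f * Y^2)
  for (nm in c("dA", "dH", "dS", "dY")) {
    v <- get(nm)
    if (!all(is.finite(v)))
      stop("non-finite reaction rate in term ", nm, call. = FALSE)
  }
  structure(list(dA = dA, dH = dH, dS = dS, dY = dY),
            clamp_count = sum(clamped))
}

#' Discrete Laplacian on the simulation grid
#'
#' 7-point second-difference stencil scaled by `1/h^2`. Zero-flux boundaries
#' use mirror ghost voxels (ghost value equals the boundary value), so a
#' constant field maps to zero everywhere and total mass is conserved under
#' pure diffusion; the periodic option wraps.
#'
#' @param field a 3D numeric array matching the domain's grid.
#' @param domain an [rd_domain()] object.
#' @return An array of the same shape.
#' @export
rd_laplacian <- function(field, domain) {
  stopifnot(inherits(domain, "rd_domain"))
  dm <- domain_dim(domain)
  if (!identical(dim(field), as.integer(dm)))
    stop("field shape ", paste(dim(field), collapse = "x"),
         " does not match domain ", paste(dm, collapse = "x"), call. = FALSE)
  laplacian_cpp(field, as.integer(dm), domain$h,
                domain$boundary == "periodic")
}

#' Build the initial field state
#'
#' Realizes an [rd_init()] specification on a domain: places the Y seed or
#' the activator gradient, sets the baselines (defaulting to the homogeneous
#' `Y = 0` steady state of `params`) and applies the multiplicative
#' fluctuations to A and H from the seeded RNG.
#'
#' @param domain an [rd_domain()].
#' @param init an [rd_init()].
#' @param params an [rd_params()]; used only to derive default baselines.
#' @return An object of class `rd_state`: list with 3D arrays `A`, `H`, `S`,
#'   `Y`, plus `step = 0` and `t = 0`.
#' @examples
#' st <- rd_initialize(rd_domain(16, 16, 16), rd_init(), rd_params())
#' range(st$Y)
#' @export
rd_initialize <- function(domain, init = rd_init(), params = rd_params()) {
  stopifnot(inherits(domain, "rd_domain"), inherits(init, "rd_init"))
  dm <- domain_dim(domain)
  if (is.null(init$A0) || is.null(init$H0) || is.null(init$S0)) {
    ss <- steady_state(params)  # Y = 0 homogeneous background
    init$A0 <- init$A0 %||% ss$A_star
    init$H0 <- init$H0 %||% ss$H_star
    init$S0 <- init$S0 %||% ss$S_star
  }
  A0 <- init$A0
  H0 <- init$H0
  S0 <- init$S0

  A <- array(A0, dm)
  H <- array(H0, dm)
  S <- array(S0, dm)
  Y <- array(0, dm)

  if (init$mode == "seeded") {
    ctr <- init$seed_center %||% ceiling(dm / 2)
    if (length(ctr) != 3L) stop("seed_center must have length 3", call. = FALSE)
    r <- init$seed_radius
    if (any(ctr - r < 1) || any(ctr + r > dm))
      stop("seed sphere extends outside the domain", call. = FALSE)
    ax <- seq_len(dm[1]) - ctr[1]
    ay <- seq_len(dm[2]) - ctr[2]
    az <- seq_len(dm[3]) - ctr[3]
    d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
    Y[d2 <= r^2] <- init$seed_Y_value
  } else if (init$mode == "gradient") {
    axis <- match(init$gradient_axis, c("x", "y", "z"))
    nax <- dm[axis]
    ramp <- if (nax > 1)
      init$gradient_low +
        (init$gradient_high - init$gradient_low) * (seq_len(nax) - 1) / (nax - 1)
    else rep(mean(c(init$gradient_low, init$gradient_high)), nax)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    A <- aperm(array(ramp, dm[perm]), order(perm))
  }

  if (init$fluctuation > 0) {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(rng_state))
        assign(".Random.seed", rng_state, envir = globalenv())
    })
    set.seed(init$rng_seed)
    n <- prod(dm)
    A <- A * (1 + array(runif(n, -init$fluctuation, init$fluctuation), dm))
    H <- H * (1 + array(runif(n, -init$fluctuation, init$fluctuation), dm))
  }

  structure(list(A = A, H = H, S = S, Y = Y, step = 0L, t = 0),
            class = "rd_state")
}

#' @export
print.rd_state <- function(x, ...) {
  cat(sprintf("<rd_state> %s grid, step %d (t = %g)\n",
              paste(dim(x$A), collapse = " x "), x$step, x$t))
  for (f in c("A", "H", "S", "Y"))
    cat(sprintf("  %s: [%.4g, %.4g]\n", f, min(x[[f]]), max(x[[f]])))
  invisible(x)
}

#' Advance the state by explicit-Euler steps
#'
#' One call to the compiled kernel: A, H and S receive reaction plus
#' diffusion, Y receives reaction only (differentiated cells neither move
#' nor diffuse). Aborts with a diagnostic naming the step, voxel and field
#' on the first non-finite value.
#'
#' @param state an `rd_state`.
#' @param params an [rd_params()].
#' @param stepper an [rd_stepper()]; `n_steps` of it are taken.
#' @param domain an [rd_domain()].
#' @return The advanced `rd_state`, with attributes `clamp_count`,
#'   `snapshots` (list, possibly empty) and `snapshot_log` (tibble of
#'   per-snapshot field ranges).
#' @export
rd_step <- function(state, params, stepper, domain) {
  stopifnot(inherits(state, "rd_state"), inherits(params, "rd_params"),
            inherits(stepper, "rd_stepper"), inherits(domain, "rd_domain"))
  check_dt_stable(stepper, params, domain)
  dm <- as.integer(domain_dim(domain))
  if (!identical(dim(state$A), dm))
    stop("state shape does not match domain", call. = FALSE)
  if (stepper$n_steps == 0L) {
    attr(state, "clamp_count") <- 0
    attr(state, "snapshots") <- list()
    attr(state, "snapshot_log") <- empty_snapshot_log()
    return(state)
  }
  res <- rd_run_cpp(state$A, state$H, state$S, state$Y, dm, domain$h,
                    domain$boundary == "periodic", unclass(params),
                    stepper$dt, stepper$n_steps, stepper$snapshot_every,
                    stepper$H_floor)
  out <- structure(list(A = res$A, H = res$H, S = res$S, Y = res$Y,
                        step = state$step + stepper$n_steps,
                        t = state$t + stepper$n_steps * stepper$dt),
                   class = "rd_state")
  attr(out, "clamp_count") <- res$clamp_count
  attr(out, "snapshots") <- lapply(res$snapshots, function(s) {
    structure(list(A = s$A, H = s$H, S = s$S, Y = s$Y,
                   step = state$step + s$step,
                   t = state$t + s$step * stepper$dt),
              class = "rd_state")
  })
  attr(out, "snapshot_log") <- snapshot_log_tbl(res, state, stepper)
  out
}

empty_snapshot_log <- function() {
  tibble::tibble(step = integer(), t = numeric(),
                 A_min = numeric(), A_max = numeric(),
                 H_min = numeric(), H_max = numeric(),
                 S_min = numeric(), S_max = numeric(),
                 Y_min = numeric(), Y_max = numeric())
}

snapshot_log_tbl <- function(res, state, stepper) {
  st <- res$snapshot_stats
  if (is.null(st) || nrow(st) == 0L) return(empty_snapshot_log())
  steps <- state$step + res$snapshot_steps
  tibble::tibble(step = as.integer(steps),
                 t = state$t + res$snapshot_steps * stepper$dt,
                 A_min = st[, 1], A_max = st[, 2],
                 H_min = st[, 3], H_max = st[, 4],
                 S_min = st[, 5], S_max = st[, 6],
                 Y_min = st[, 7], Y_max = st[, 8])
}

#' Run a full simulation
#'
#' Initializes a state from the specification (unless an explicit `state` is
#' supplied, e.g. when resuming from a checkpoint) and advances it for
#' `stepper$n_steps` updates. Runs are deterministic given the four
#' configuration objects, including the fluctuation RNG seed.
#'
#' @param params an [rd_params()].
#' @param domain an [rd_domain()].
#' @param init an [rd_init()]; ignored when `state` is given.
#' @param stepper an [rd_stepper()].
#' @param state optional `rd_state` to continue from.
#' @return An object of class `rd_run`: list with `final` (the end
#'   `rd_state`), `initial`, `snapshots`, `log` (tibble of per-snapshot
#'   field ranges), `clamp_count`, and the four configs. `tidy()` returns
#'   the log; `glance()` a one-row run summary.
#' @examples
#' run <- rd_run(rd_params(), rd_domain(16, 16, 8),
#'               rd_init(seed_radius = 2), rd_stepper(n_steps = 10))
#' glance(run)
#' @export
rd_run <- function(params = rd_params(), domain = rd_domain(),
                   init = rd_init(), stepper = rd_stepper(), state = NULL) {
  initial <- state %||% rd_initialize(domain, init, params)
  final <- rd_step(initial, params, stepper, domain)
  structure(list(final = strip_attrs(final),
                 initial = initial,
                 snapshots = attr(final, "snapshots"),
                 log = attr(final, "snapshot_log"),
                 clamp_count = attr(final, "clamp_count"),
                 params = params, domain = domain, init = init,
                 stepper = stepper),
            class = "rd_run")
}

strip_attrs <- function(state) {
  attr(state, "clamp_count") <- NULL
  attr(state, "snapshots") <- NULL
  attr(state, "snapshot_log") <- NULL
  state
}

#' @export
print.rd_run <- function(x, ...) {
  cat(sprintf("<rd_run> %d steps (dt = %g) on %d x %d x %d grid\n",
              x$stepper$n_steps, x$stepper$dt,
              x$domain$nx, x$domain$ny, x$domain$nz))
  cat(sprintf("  H-floor clamps: %g; snapshots kept: %d\n",
              x$clamp_count, length(x$snapshots)))
  print(x$final)
  invisible(x)
}

#' @rdname rd_run
#' @param x an `rd_run` object.
#' @param ... unused.
#' @export
tidy.rd_run <- function(x, ...) x$log

#' @rdname rd_run
#' @export
glance.rd_run <- function(x, ...) {
  tibble::tibble(n_steps = x$stepper$n_steps, dt = x$stepper$dt,
                 t_final = x$final$t,
                 nx = x$domain$nx, ny = x$domain$ny, nz = x$domain$nz,
                 clamp_count = x$clamp_count,
                 Y_max = max(x$final$Y),
                 A_max = max(x$final$A),
                 min_field_value = min(min(x$final$A), min(x$final$H),
                                       min(x$final$S), min(x$final$Y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
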