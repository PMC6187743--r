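#' Homogeneous steady states of the reaction system
#'
#' Computes a spatially uniform fixed point of the local (diffusion-free)
#' reaction system.
#'
#' In `"clamped_Y0"` mode (the default) the differentiation marker is held
#' at zero and the first three equations give the closed forms
#' `S* = c0 / gamma`, `A* = nu / mu`, `H* = c nu S* / mu^2`. This is the
#' undifferentiated background state whose small fluctuations the Turing
#' instability amplifies. The Y-equation residual `d A*` at this point is
#' returned as `Y_residual` (a consistency note, not part of the accepted
#' residual).
#'
#' In `"full"` mode a Newton iteration with the analytic Jacobian solves all
#' four equations simultaneously, including the weak couplings through
#' `rho_A`, `rho_H`, `epsilon` and `d`.
#'
#' @param params an [rd_params()].
#' @param mode `"clamped_Y0"` or `"full"`.
#' @param initial_guess optional length-4 positive numeric `(A, H, S, Y)`
#'   starting point for the full mode; defaults to the clamped solution with
#'   Y seeded at `d A* / e`.
#' @param tol residual tolerance for acceptance (max absolute local rate).
#' @param max_iter Newton iteration cap for the full mode.
#' @return An object of class `rd_steady`: list with `A_star`, `H_star`,
#'   `S_star`, `Y_star`, `residual`, `mode`, `degenerate` (flag set when
#'   `H* = 0` invalidates the A-equation linearization) and, in clamped
#'   mode, `Y_residual`.
#' @examples
#' steady_state(rd_params())
#' @export
steady_state <- function(params, mode = c("clamped_Y0", "full"),
                         initial_guess = NULL, tol = 1e-10,
                         max_iter = 100L) {
  stopifnot(inherits(params, "rd_params"))
  mode <- match.arg(mode)
  if (params$mu <= 0 || params$gamma <= 0)
    stop("mu and gamma must be positive for a steady state", call. = FALSE)

  S0 <- params$c0 / params$gamma
  A0 <- params$nu / params$mu
  H0 <- params$c * params$nu * S0 / params$mu^2

  if (mode == "clamped_Y0") {
    r <- rd_reaction_rates(A0, H0, S0, 0, params)
    residual <- max(abs(c(r$dA, r$dH, r$dS)))
    # H0 = 0 (e.g. c0 = 0) makes the A-equation division degenerate; the
    # closed forms remain exact limits because cA^2 S / H -> mu A.
    degenerate <- H0 <= 0
    if (degenerate) residual <- 0
    out <- list(A_star = A0, H_star = H0, S_star = S0, Y_star = 0,
                residual = residual, mode = mode,
                degenerate = degenerate, Y_residual = abs(r$dY))
    return(structure(out, class = "rd_steady"))
  }

  x <- initial_guess %||% c(A0, H0, S0, params$d * A0 / params$e)
  if (length(x) != 4L || any(x < 0))
    stop("initial_guess must be 4 non-negative values (A, H, S, Y)",
         call. = FALSE)
  for (it in seq_len(max_iter)) {
    r <- rd_reaction_rates(x[1], x[2], x[3], x[4], params)
    fx <- c(r$dA, r$dH, r$dS, r$dY)
    if (max(abs(fx)) < tol) break
    J <- jacobian_at(params, x[1], x[2], x[3], x[4])
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in full steady-state Newton iteration",
           call. = FALSE)
    # damped update keeping the iterate non-negative
    lam <- 1
    repeat {
      xn <- x - lam * step
      if (all(xn[c(1, 3)] >= 0) && xn[2] > 0) break
      lam <- lam / 2
      if (lam < 1e-8) { xn <- pmax(x - lam * step, 1e-12); break }
    }
    x <- xn
  }
  x <- unname(x)
  r <- rd_reaction_rates(x[1], x[2], x[3], x[4], params)
  residual <- max(abs(c(r$dA, r$dH, r$dS, r$dY)))
  if (residual >= tol)
    stop(sprintf(paste0("full steady-state iteration did not converge: ",
                        "residual %.3g at (A, H, S, Y) = (%.6g, %.6g, ",
                        "%.6g, %.6g)"), residual, x[1], x[2], x[3], x[4]),
         call. = FALSE)
  structure(list(A_star = x[1], H_star = x[2], S_star = x[3], Y_star = x[4],
                 residual = residual, mode = mode, degenerate = x[2] <= 0),
            class = "rd_steady")
}

#' @export
print.rd_steady <- function(x, ...) {
  cat(sprintf("<rd_steady> mode = %s%s\n", x$mode,
              if (isTRUE(x$degenerate)) " (degenerate: H* = 0)" else ""))
  cat(sprintf("  A* = %.6g  H* = %.6g  S* = %.6g  Y* = %.6g\n",
              x$A_star, x$H_star, x$S_star, x$Y_star))
  cat(sprintf("  residual = %.3g\n", x$residual))
  invisible(x)
}

#' @export
tidy.rd_steady <- function(x, ...) {
  tibble::tibble(field = c("A", "H", "S", "Y"),
                 value = c(x$A_star, x$H_star, x$S_star, x$Y_star))
}

# Analytic Jacobian of the local reaction system at an arbitrary point.
jacobian_at <- function(params, A, H, S, Y) {
  p <- params
  denom <- 1 + p$f * Y^2
  J <- matrix(0, 4, 4,
              dimnames = list(c("dA", "dH", "dS", "dY"),
                              c("A", "H", "S", "Y")))
  J["dA", "A"] <- 2 * p$c * A * S / H - p$mu
  J["dA", "H"] <- -p$c * A^2 * S / H^2
  J["dA", "S"] <- p$c * A^2 / H
  J["dA", "Y"] <- p$rho_A
  J["dH", "A"] <- 2 * p$c * A * S
  J["dH", "H"] <- -p$nu
  J["dH", "S"] <- p$c * A^2
  J["dH", "Y"] <- p$rho_H
  J["dS", "S"] <- -p$gamma - p$epsilon * Y
  J["dS", "Y"] <- -p$epsilon * S
  J["dY", "A"] <- p$d
  J["dY", "Y"] <- -p$e + 2 * Y / denom^2
  J
}

#' Jacobian of the reaction system at a steady state
#'
#' Analytic 4x4 matrix of partial derivatives of the local reaction rates
#' with respect to `(A, H, S, Y)`, evaluated at a fixed point. This is the
#' linearization whose eigenvalues, shifted by the diffusion operator,
#' decide Turing instability.
#'
#' @param params an [rd_params()].
#' @param steady an `rd_steady` from [steady_state()].
#' @return A 4x4 numeric matrix (rows: equations; columns: variables).
#' @export
rd_jacobian <- function(params, steady) {
  stopifnot(inherits(params, "rd_params"), inherits(steady, "rd_steady"))
  if (steady$H_star <= 0)
    stop("H* <= 0: the A-equation linearization is undefined", call. = FALSE)
  jacobian_at(params, steady$A_star, steady$H_star, steady$S_star,
              steady$Y_star)
}

#' Turing dispersion relation
#'
#' For each spatial wavenumber `q` on `[0, q_max]`, computes the leading
#' real part among the eigenvalues of `J - q^2 diag(D_A, D_H, D_S, 0)`,
#' where `J` is the reaction Jacobian at the homogeneous steady state. The
#' state is Turing-unstable when it is stable to uniform perturbations
#' (`Re lambda_max(0) < 0`) yet some finite wavenumber grows
#' (`Re lambda_max(q) > 0`). Y enters as a non-diffusing fourth variable.
#'
#' @param params an [rd_params()].
#' @param steady optional `rd_steady`; defaults to the clamped-Y0 state.
#' @param q_max largest wavenumber (default `pi`, the grid Nyquist limit at
#'   unit spacing).
#' @param n_q number of q samples (the grid starts at exactly 0).
#' @return An object of class `rd_dispersion`: list with `data` (tibble of
#'   `q`, `re_lambda_max`), `turing_unstable`, `q_peak`, `lambda_peak` and
#'   the steady state used. `tidy()` returns the tibble; `autoplot()` draws
#'   the relation.
#' @examples
#' disp <- dispersion(rd_params())
#' disp$turing_unstable
#' @export
dispersion <- function(params, steady = NULL, q_max = pi, n_q = 200L) {
  stopifnot(inherits(params, "rd_params"))
  steady <- steady %||% steady_state(params)
  J <- rd_jacobian(params, steady)
  D <- c(params$D_A, params$D_H, params$D_S, 0)
  qs <- seq(0, q_max, length.out = n_q)
  lam <- vapply(qs, function(q) {
    max(Re(eigen(J - q^2 * diag(D), only.values = TRUE)$values))
  }, numeric(1))
  ipk <- which.max(lam)
  structure(list(data = tibble::tibble(q = qs, re_lambda_max = lam),
                 turing_unstable = lam[1] < 0 && any(lam[-1] > 0),
                 q_peak = qs[ipk], lambda_peak = lam[ipk],
                 steady = steady, params = params),
            class = "rd_dispersion")
}

#' @export
print.rd_dispersion <- function(x, ...) {
  cat(sprintf("<rd_dispersion> %d wavenumbers on [0, %.4g]\n",
              nrow(x$data), max(x$data$q)))
  cat(sprintf("  turing_unstable = %s; q_peak = %.4g (Re lambda = %.4g)\n",
              x$turing_unstable, x$q_peak, x$lambda_peak))
  invisible(x)
}

#' @rdname dispersion
#' @param x an `rd_dispersion` object.
#' @param ... unused.
#' @export
tidy.rd_dispersion <- function(x, ...) x$data

#' @rdname dispersion
#' @export
glance.rd_dispersion <- function(x, ...) {
  tibble::tibble(turing_unstable = x$turing_unstable, q_peak = x$q_peak,
                 lambda_peak = x$lambda_peak,
                 re_lambda_at_0 = x$data$re_lambda_max[1])
}

#' @rdname dispersion
#' @param object an `rd_dispersion` object.
#' @export
autoplot.rd_dispersion <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$q, .data$re_lambda_max)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data[which.max(object$data$re_lambda_max), ],
                        colour = "red") +
    ggplot2::labs(x = "wavenumber q",
                  y = expression(Re ~ lambda[max](q)),
                  title = sprintf("Dispersion relation (Turing unstable: %s)",
                                  object$turing_unstable)) +
    ggplot2::theme_minimal()
}
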