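#' Built-in simulation scenarios
#'
#' Pre-configured parameter sets for the canonical in-silico experiments:
#' side-branching growth from a seeded bud, tip-splitting with transverse
#' profile observation, multi-round tip bifurcation, substrate-consumption
#' (epsilon) contrast, and the external activator-gradient fabrication
#' setup with its two uniform controls. Each scenario pins the full set of
#' reaction constants for its regime; run lengths, the time step and the
#' domain inherit package defaults and are recorded in the report.
#'
#' @param name scenario name; see Details.
#' @param rng_seed fluctuation seed for the realization.
#' @details Available scenarios:
#' * `"fig1_side_branching"`, `"fig2_side_branching"`: side-branching sets.
#' * `"fig4_tip_splitting"`: tip-splitting with observation (snapshot)
#'   stages for transverse A/H profiles.
#' * `"fig5_tip_splitting"`: long tip-splitting run for multi-round
#'   bifurcation.
#' * `"fig6_eps_short"`, `"fig6_eps_long"`: high/low substrate consumption.
#' * `"fig8_gradient"`, `"fig8_uniform_low"`, `"fig8_uniform_high"`:
#'   gradient fabrication and its uniform-activator controls (no seeded
#'   bud).
#' @return A `scenario_spec` list: `name`, `params`, `domain`, `init`,
#'   `stepper`, `profile_steps`.
#' @export
builtin_scenario <- function(name = c("fig1_side_branching",
                                      "fig2_side_branching",
                                      "fig4_tip_splitting",
                                      "fig5_tip_splitting",
                                      "fig6_eps_short", "fig6_eps_long",
                                      "fig8_gradient", "fig8_uniform_low",
                                      "fig8_uniform_high"),
                             rng_seed = 1L) {
  name <- match.arg(name)
  # resolved-grid study conditions: h = 0.25 resolves the activator core,
  # dt = 0.04 sits at the diffusion stability bound (see the vignette)
  dom <- rd_domain(64, 64, 32, h = 0.25)
  seeded <- function(n_steps, params, snapshot_every = 0L,
                     profile_steps = NULL)
    list(name = name, params = params, domain = dom,
         init = rd_init("seeded", rng_seed = rng_seed),
         stepper = rd_stepper(dt = 0.04, n_steps = n_steps,
                              snapshot_every = snapshot_every),
         profile_steps = profile_steps)
  spec <- switch(name,
    fig1_side_branching = seeded(100000, rd_params()),
    fig2_side_branching = seeded(100000, rd_params(mu = 0.38, nu = 0.04,
                                                   gamma = 0.03)),
    fig4_tip_splitting = seeded(150000, rd_params(mu = 0.8, nu = 0.08),
                                snapshot_every = 25000L,
                                profile_steps = c(100000, 125000, 150000)),
    fig5_tip_splitting = seeded(150000, rd_params(mu = 0.48, nu = 0.06)),
    fig6_eps_short = seeded(150000, rd_params(mu = 0.8, nu = 0.08,
                                              epsilon = 0.084)),
    fig6_eps_long = seeded(150000, rd_params(mu = 0.8, nu = 0.08,
                                             epsilon = 0.032)),
    fig8_gradient = ,
    fig8_uniform_low = ,
    fig8_uniform_high = {
      p <- rd_params(mu = 0.48, nu = 0.06)
      init <- switch(name,
        fig8_gradient = rd_init("gradient", rng_seed = rng_seed),
        fig8_uniform_low = rd_init("uniform", A0 = 0.001,
                                   rng_seed = rng_seed),
        fig8_uniform_high = rd_init("uniform", A0 = 2.9,
                                    rng_seed = rng_seed))
      list(name = name, params = p, domain = dom, init = init,
           stepper = rd_stepper(dt = 0.04, n_steps = 100000),
           profile_steps = NULL)
    })
  structure(spec, class = "scenario_spec")
}

#' Run a scenario and bundle its morphometrics
#'
#' Executes a built-in (or hand-built) scenario for one or more fluctuation
#' seeds, then thresholds, skeletonizes and classifies the final structure.
#' For scenarios with `profile_steps`, transverse A/H profiles through the
#' distal tip are extracted at the matching snapshots and their peak counts
#' recorded.
#'
#' @param scenario a scenario name (see [builtin_scenario()]) or a
#'   `scenario_spec`.
#' @param seeds integer vector of fluctuation seeds (one run each).
#' @param domain optional [rd_domain()] overriding the scenario's; model
#'   reaction constants are never overridden.
#' @param n_steps optional override of the run length.
#' @param Ya differentiation threshold for tissue extraction.
#' @param keep_runs keep the full `rd_run` objects in the report (memory!).
#' @return A `scenario_report`: list with `name`, `summary` (tibble: one
#'   row per seed with label, branch counts, generation depth, max Y),
#'   `results` (per-seed list: `region`, `structure`, `pattern`,
#'   `separations`, `profiles`, optionally `run`), and `majority_label`.
#' @export
run_scenario <- function(scenario, seeds = 1L, domain = NULL,
                         n_steps = NULL, Ya = 0.5, keep_runs = FALSE) {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  results <- list()
  rows <- list()
  for (s in seeds) {
    init <- scenario$init
    init$rng_seed <- as.integer(s)
    dom <- domain %||% scenario$domain
    stepper <- scenario$stepper
    if (!is.null(n_steps)) stepper$n_steps <- as.integer(n_steps)
    run <- rd_run(scenario$params, dom, init, stepper)
    region <- extract_tissue(run$final$Y, Ya)
    root_hint <- if (init$mode == "seeded")
      init$seed_center %||% ceiling(domain_dim(dom) / 2)
    else domain_dim(dom) / 2
    struct <- skeletonize_region(region, root_hint = root_hint)
    pat <- classify_pattern(region, struct)
    seps <- bifurcation_separations(struct)
    profiles <- scenario_profiles(scenario, run, Ya, root_hint)
    res <- list(seed = s, region = region, structure = struct,
                pattern = pat, separations = seps, profiles = profiles)
    if (keep_runs) res$run <- run
    results[[as.character(s)]] <- res
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seed = s, label = pat$label,
      volume_fraction = region$volume_fraction,
      n_branch_points = struct$n_branch_points, n_tips = struct$n_tips,
      max_generation = struct$max_generation,
      n_separations = nrow(seps),
      mean_separation = if (nrow(seps)) mean(seps$separation) else NA_real_,
      Y_max = max(run$final$Y), clamp_count = run$clamp_count)
  }
  summary <- dplyr::bind_rows(rows)
  lab <- names(sort(table(summary$label), decreasing = TRUE))[1]
  structure(list(name = scenario$name, scenario = scenario,
                 summary = summary, results = results,
                 majority_label = lab),
            class = "scenario_report")
}

scenario_profiles <- function(scenario, run, Ya, root_hint) {
  if (is.null(scenario$profile_steps) || length(run$snapshots) == 0L)
    return(NULL)
  snap_steps <- vapply(run$snapshots, `[[`, integer(1), "step")
  out <- list()
  for (st in scenario$profile_steps) {
    i <- which.min(abs(snap_steps - st))
    snap <- run$snapshots[[i]]
    reg <- extract_tissue(snap$Y, Ya)
    if (reg$n_components == 0L) next
    struct <- skeletonize_region(reg, root_hint = root_hint)
    if (nrow(struct$coords) == 0L) next
    line <- auto_profile_line(reg, struct)
    prof <- extract_profile(snap, line$from, line$to)
    out[[as.character(snap_steps[i])]] <-
      list(step = snap_steps[i], profile = prof,
           peaks_A = count_peaks(prof$A), peaks_H = count_peaks(prof$H))
  }
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s (%d seed(s)); majority label: %s\n",
              x$name, nrow(x$summary), x$majority_label))
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @export
tidy.scenario_report <- function(x, ...) x$summary

#' Sweep the mu-nu degradation-rate plane
#'
#' Runs one (or several, for majority voting) seeded simulation per grid
#' cell of activator/inhibitor degradation rates and classifies the final
#' pattern, mapping out the five-regime phase diagram: spillover at small
#' mu, no-branch at small nu, parent-only, side-branching, and
#' tip-splitting toward large mu and nu. Failed cells are recorded as
#' `UNDETERMINED` with the error message; the sweep continues.
#'
#' @param mu_values,nu_values grid coordinates (each length >= 2).
#' @param params base [rd_params()]; `mu` and `nu` are replaced per cell.
#' @param domain sweep domain (default 48 x 48 x 24, a reduced box that
#'   keeps whole-plane sweeps tractable).
#' @param n_steps steps per cell.
#' @param seeds fluctuation seeds per cell (label by majority).
#' @param Ya differentiation threshold.
#' @param dt time step.
#' @return A `sweep_result`: list with `cells` (tibble: `mu`, `nu`,
#'   `label`, metrics), `fractions` (per-label area fractions, summing
#'   to 1), `no_branch_boundary` (per-mu largest nu labelled `NO_BRANCH`).
#'   `autoplot()` draws the phase diagram.
#' @export
run_sweep <- function(mu_values, nu_values, params = rd_params(),
                      domain = rd_domain(48, 48, 24, h = 0.25),
                      n_steps = 50000L, seeds = 1L, Ya = 0.5, dt = 0.04) {
  stopifnot(length(mu_values) >= 2L, length(nu_values) >= 2L)
  grid <- tidyr::expand_grid(mu = mu_values, nu = nu_values)
  stepper <- rd_stepper(dt = dt, n_steps = n_steps)
  rows <- purrr::pmap(grid, function(mu, nu) {
    p <- params
    p$mu <- mu; p$nu <- nu
    cell <- tryCatch({
      labs <- character(0)
      nbp <- vf <- maxgen <- numeric(0)
      for (s in seeds) {
        run <- rd_run(p, domain, rd_init("seeded", rng_seed = s), stepper)
        region <- extract_tissue(run$final$Y, Ya)
        struct <- skeletonize_region(region)
        pat <- classify_pattern(region, struct)
        labs <- c(labs, pat$label)
        nbp <- c(nbp, struct$n_branch_points)
        vf <- c(vf, region$volume_fraction)
        maxgen <- c(maxgen, struct$max_generation)
      }
      tibble::tibble(mu = mu, nu = nu,
                     label = names(sort(table(labs), decreasing = TRUE))[1],
                     volume_fraction = mean(vf),
                     n_branch_points = mean(nbp),
                     max_generation = max(maxgen), note = NA_character_)
    }, error = function(e) {
      tibble::tibble(mu = mu, nu = nu, label = "UNDETERMINED",
                     volume_fraction = NA_real_, n_branch_points = NA_real_,
                     max_generation = NA_real_,
                     note = conditionMessage(e))
    })
    cell
  })
  cells <- dplyr::bind_rows(rows)
  fractions <- cells |>
    dplyr::count(.data$label) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  nb <- cells |>
    dplyr::filter(.data$label == "NO_BRANCH") |>
    dplyr::group_by(.data$mu) |>
    dplyr::summarise(nu_max_no_branch = max(.data$nu), .groups = "drop")
  structure(list(cells = cells, fractions = fractions,
                 no_branch_boundary = nb,
                 domain = domain, n_steps = n_steps, seeds = seeds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells (%s)\n", nrow(x$cells),
              paste(dim(table(x$cells$mu, x$cells$nu)), collapse = " x ")))
  print(as.data.frame(x$fractions))
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) x$cells

#' @export
glance.sweep_result <- function(x, ...) {
  tidyr::pivot_wider(x$fractions[, c("label", "fraction")],
                     names_from = "label", values_from = "fraction")
}

#' @rdname run_sweep
#' @param object a `sweep_result`.
#' @param ... unused.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$mu, .data$nu, fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = expression(mu ~ "(activator degradation)"),
                  y = expression(nu ~ "(inhibitor degradation)"),
                  fill = "pattern") +
    ggplot2::theme_minimal()
}

#' Compare bifurcation separations across substrate-consumption rates
#'
#' Runs the tip-splitting scenario at each substrate-consumption rate
#' `epsilon` and several fluctuation seeds, and measures the mean arc
#' separation between consecutive bifurcation points. Lower consumption
#' leaves more substrate ahead of the growing tip, so the stalk runs longer
#' before splitting: mean separation should decrease as epsilon increases.
#'
#' @param eps_values numeric vector of epsilon values (>= 2).
#' @param seeds fluctuation seeds per epsilon.
#' @param params base [rd_params()] (epsilon replaced per run).
#' @param domain,n_steps,dt,Ya run configuration.
#' @return An `eps_comparison`: list with `runs` (tibble: `epsilon`,
#'   `seed`, `n_branch_points`, `n_separations`, `mean_separation`; runs
#'   with fewer than 2 branch points are kept but flagged `excluded`) and
#'   `summary` (per-epsilon mean of mean separations over included runs).
#' @export
compare_epsilon <- function(eps_values = c(0.084, 0.032), seeds = 1:3,
                            params = rd_params(mu = 0.8, nu = 0.08),
                            domain = rd_domain(48, 48, 24, h = 0.25),
                            n_steps = 150000L, dt = 0.04, Ya = 0.5) {
  stopifnot(length(eps_values) >= 2L)
  stepper <- rd_stepper(dt = dt, n_steps = n_steps)
  rows <- list()
  for (eps in eps_values) {
    p <- params
    p$epsilon <- eps
    for (s in seeds) {
      run <- rd_run(p, domain, rd_init("seeded", rng_seed = s), stepper)
      region <- extract_tissue(run$final$Y, Ya)
      struct <- skeletonize_region(region)
      seps <- bifurcation_separations(struct)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        epsilon = eps, seed = s,
        n_branch_points = struct$n_branch_points,
        n_separations = nrow(seps),
        mean_separation = if (nrow(seps)) mean(seps$separation) else NA_real_,
        excluded = struct$n_branch_points < 2L)
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$epsilon) |>
    dplyr::summarise(mean_separation = mean(.data$mean_separation),
                     n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$epsilon)
  structure(list(runs = runs, summary = summary), class = "eps_comparison")
}

#' @export
print.eps_comparison <- function(x, ...) {
  cat("<eps_comparison> mean bifurcation separation by epsilon\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @export
tidy.eps_comparison <- function(x, ...) x$runs

#' @export
glance.eps_comparison <- function(x, ...) {
  s <- x$summary[order(x$summary$epsilon), ]
  tibble::tibble(
    eps_min = s$epsilon[1], eps_max = s$epsilon[nrow(s)],
    separation_at_eps_min = s$mean_separation[1],
    separation_at_eps_max = s$mean_separation[nrow(s)],
    monotone_decreasing = !is.unsorted(rev(s$mean_separation),
                                       strictly = FALSE))
}
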