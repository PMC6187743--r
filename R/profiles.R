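#' Sample concentration fields along a straight line
#'
#' Trilinear interpolation of one or more fields at uniformly spaced points
#' on the segment from `from` to `to` (voxel coordinates, 1-based; voxel
#' centers sit on integer coordinates, so sampling on integers reproduces
#' voxel values exactly).
#'
#' @param state an `rd_state`, an `rd_run` (its final state), or a named
#'   list of 3D arrays.
#' @param from,to length-3 endpoints, inside the domain.
#' @param n_samples number of samples (at least 2).
#' @param fields names of the fields to sample (default A and H, the
#'   activator/inhibitor pair whose transverse peak structure signals tip
#'   splitting).
#' @return A tibble of class `profile_line` with column `k` (arc-length
#'   coordinate along the line, starting at 0) and one column per field;
#'   attributes `from` and `to` record the line.
#' @export
extract_profile <- function(state, from, to, n_samples = 201L,
                            fields = c("A", "H")) {
  if (inherits(state, "rd_run")) state <- state$final
  flds <- state[fields]
  if (any(vapply(flds, is.null, logical(1))))
    stop("missing field(s): ",
         paste(fields[vapply(flds, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  dm <- dim(flds[[1]])
  from <- as.numeric(from); to <- as.numeric(to)
  if (length(from) != 3L || length(to) != 3L)
    stop("from and to must be length-3 coordinates", call. = FALSE)
  L <- sqrt(sum((to - from)^2))
  if (L == 0) stop("degenerate (zero-length) profile line", call. = FALSE)
  for (p in list(from, to))
    if (any(p < 1) || any(p > dm))
      stop("profile line endpoint outside the domain", call. = FALSE)
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(from[1] + tt * (to[1] - from[1]),
               from[2] + tt * (to[2] - from[2]),
               from[3] + tt * (to[3] - from[3]))
  out <- tibble::tibble(k = tt * L)
  for (nm in fields) out[[nm]] <- trilinear(flds[[nm]], pts)
  class(out) <- c("profile_line", class(out))
  attr(out, "from") <- from
  attr(out, "to") <- to
  out
}

trilinear <- function(field, pts) {
  dm <- dim(field)
  p0 <- pmin(pmax(floor(pts), 1), matrix(rep(dm - 1L, each = nrow(pts)),
                                         ncol = 3))
  w <- pts - p0
  v <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    keep <- wt > 0
    if (!any(keep)) next
    idx <- cbind(p0[keep, 1] + dx, p0[keep, 2] + dy, p0[keep, 3] + dz)
    v[keep] <- v[keep] + wt[keep] * field[idx]
  }
  v
}

#' Place a transverse profile line through the distal tip of a structure
#'
#' Finds the tip farthest (in arc length) from the root, estimates the local
#' stalk axis from the skeleton a few voxels back from the tip, then scans
#' directions perpendicular to that axis for the widest chord of the tissue
#' mask through the tip. The returned segment spans that widest transverse
#' chord plus a margin, mirroring how a line "crossing the largest width
#' through the tip" is drawn on the stalk's symmetry plane.
#'
#' @param region a `tissue_region`.
#' @param structure the matching `branch_structure` (computed if omitted).
#' @param margin extra length (voxels) beyond the chord on each side.
#' @param n_angles number of transverse directions scanned.
#' @return List with `from`, `to` (line endpoints), `tip` (tip coordinate)
#'   and `axis` (unit stalk direction), suitable for [extract_profile()].
#' @export
auto_profile_line <- function(region, structure = NULL, margin = 6,
                              n_angles = 36L) {
  stopifnot(inherits(region, "tissue_region"))
  if (is.null(structure)) structure <- skeletonize_region(region)
  if (nrow(structure$coords) == 0L)
    stop("empty skeleton: no tip to profile", call. = FALSE)
  dm <- dim(region$mask)

  droot <- structure$nodes$dist_from_root
  tips <- which(structure$nodes$degree <= 1L)
  if (length(tips) == 0L) tips <- seq_len(nrow(structure$nodes))
  tip_node <- tips[which.max(droot[tips])]
  tip <- as.numeric(structure$nodes[tip_node, c("x", "y", "z")])

  # local axis: tip minus a skeleton voxel ~5 steps back along the skeleton
  co <- structure$voxel_coords
  d2 <- rowSums(sweep(co, 2, tip)^2)
  tipvox <- which.min(d2)
  vd <- suppressWarnings(igraph::distances(structure$voxel_graph, v = tipvox,
                                           weights = NA))[1, ]
  back <- which(is.finite(vd) & vd >= 4 & vd <= 8)
  if (length(back) == 0L) back <- which(is.finite(vd) & vd > 0)
  axis <- if (length(back)) tip - colMeans(co[back, , drop = FALSE])
          else c(0, 0, 1)
  nn <- sqrt(sum(axis^2))
  axis <- if (nn > 0) axis / nn else c(0, 0, 1)

  # orthonormal transverse basis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- pracma_cross(axis, ref); u <- u / sqrt(sum(u^2))
  v <- pracma_cross(axis, u)

  chord_len <- function(ctr, dir) {
    len <- function(sgn) {
      s <- 0
      repeat {
        p <- round(ctr + sgn * (s + 0.5) * dir)
        if (any(p < 1) || any(p > dm) || !region$mask[p[1], p[2], p[3]]) break
        s <- s + 0.5
      }
      s
    }
    len(1) + len(-1)
  }
  # probe a few setbacks behind the apex: the rounded cap narrows to a
  # point, while the widest transverse chord sits slightly proximal
  best <- NULL; bestw <- -1; bestc <- tip
  for (setback in seq(0, 6, by = 1)) {
    ctr <- tip - setback * axis
    if (any(ctr < 1) || any(ctr > dm)) next
    for (th in seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]) {
      dir <- cos(th) * u + sin(th) * v
      wdt <- chord_len(ctr, dir)
      if (wdt > bestw) { bestw <- wdt; best <- dir; bestc <- ctr }
    }
  }
  half <- bestw / 2 + margin
  clip <- function(p) pmin(pmax(p, 1), dm)
  list(from = unname(clip(bestc - half * best)),
       to = unname(clip(bestc + half * best)),
       tip = unname(tip), center = unname(bestc),
       axis = unname(axis), width = bestw)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Find and count prominent peaks in a 1D profile
#'
#' A peak is a local maximum (plateaus count once; samples touching the
#' profile ends are not peaks) whose prominence -- its height above the
#' higher of the two flanking minima, where each flank extends to the
#' nearest sample exceeding the peak or to the profile end -- is larger than
#' `prominence * (max - min)` of the profile.
#'
#' @param values numeric profile.
#' @param prominence relative prominence threshold in `[0, 1]`
#'   (default 0.1).
#' @return `find_peaks()`: tibble with `index` (plateau center), `value` and
#'   `prominence` (absolute units) of every qualifying peak.
#'   `count_peaks()`: the number of such peaks (0 for profiles shorter than
#'   3 samples or with zero range).
#' @examples
#' x <- dnorm(seq(-4, 4, length.out = 101))
#' count_peaks(x)
#' @export
count_peaks <- function(values, prominence = 0.1) {
  nrow(find_peaks(values, prominence))
}

#' @rdname count_peaks
#' @export
find_peaks <- function(values, prominence = 0.1) {
  stopifnot(prominence >= 0)
  out <- tibble::tibble(index = integer(), value = numeric(),
                        prominence = numeric())
  n <- length(values)
  if (n < 3L) return(out)
  rng <- max(values) - min(values)
  if (rng == 0) return(out)
  thr <- prominence * rng

  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  for (i in seq_len(m)) {
    if (i == 1L || i == m) next          # boundary plateaus are not peaks
    v <- r$values[i]
    if (r$values[i - 1L] >= v || r$values[i + 1L] >= v) next
    # flanking minima out to the nearest higher sample (or profile end)
    left <- values[seq_len(starts[i] - 1L)]
    higher_l <- which(left > v)
    lmin <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L,
                             length(left))])
    right <- values[seq.int(ends[i] + 1L, n)]
    higher_r <- which(right > v)
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) else
                              length(right))])
    prom <- v - max(lmin, rmin)
    if (prom > thr) {
      ctr <- as.integer(floor((starts[i] + ends[i]) / 2))
      out <- dplyr::bind_rows(out, tibble::tibble(index = ctr, value = v,
                                                  prominence = prom))
    }
  }
  out
}

#' @export
#' @rdname extract_profile
#' @param object a `profile_line`.
#' @param ... unused.
autoplot.profile_line <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"k",
                              names_to = "field", values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$concentration,
                                     colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along axis k", y = "concentration") +
    ggplot2::theme_minimal()
}
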