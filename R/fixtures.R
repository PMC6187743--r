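#' Synthetic 3D test volumes
#'
#' Deterministic voxelizations of analytic shapes used to validate the
#' morphometric pipeline against known topology: a solid `"sphere"`
#' (no-branch ball), a straight `"cylinder"` (parent stalk: 2 tips, 0 branch
#' points), a `"y_tube"` (one symmetric bifurcation: 1 branch point,
#' 3 tips), a `"double_y"` (each daughter splits again: 3 branch points,
#' 4 second-generation tips) and `"capsules"`, an arbitrary union of
#' thick segments given as a matrix.
#'
#' A voxel belongs to the shape when its center lies within `radius` of the
#' shape's medial segment set. Shapes are centered in the domain; the trunk
#' of the tube shapes runs along +z and arms open at `arm_angle` in the x-z
#' plane (the second split of `double_y` opens in the y direction, keeping
#' the arms clear of one another).
#'
#' @param shape one of `"sphere"`, `"cylinder"`, `"y_tube"`, `"double_y"`,
#'   `"capsules"`.
#' @param dim grid extents (length 3).
#' @param radius tube/sphere radius in voxels.
#' @param length cylinder length in voxels.
#' @param trunk_length,arm_length,arm2_length segment lengths of the tube
#'   shapes; `arm_length` is also the arc separation between the two
#'   bifurcations of `double_y`.
#' @param arm_angle half-opening angle of each split, radians.
#' @param center shape center (sphere/cylinder); `NULL` = domain center.
#' @param segments for `"capsules"`: matrix with columns
#'   `x1,y1,z1,x2,y2,z2,r`.
#' @return A `fixture_spec` object; pass it to [make_fixture()].
#' @export
fixture_spec <- function(shape = c("sphere", "cylinder", "y_tube",
                                   "double_y", "capsules"),
                         dim = c(48, 48, 48), radius = 8, length = 40,
                         trunk_length = 16, arm_length = 12,
                         arm2_length = 9, arm_angle = pi / 4,
                         center = NULL, segments = NULL) {
  shape <- match.arg(shape)
  structure(list(shape = shape, dim = as.integer(dim), radius = radius,
                 length = length, trunk_length = trunk_length,
                 arm_length = arm_length, arm2_length = arm2_length,
                 arm_angle = arm_angle, center = center,
                 segments = segments),
            class = "fixture_spec")
}

#' Voxelize a fixture specification
#'
#' @param spec a [fixture_spec()].
#' @return A logical 3D array of the requested dimensions. Identical specs
#'   produce identical volumes. Geometry extending outside the domain is an
#'   error.
#' @examples
#' vol <- make_fixture(fixture_spec("sphere", radius = 6, dim = c(20, 20, 20)))
#' sum(vol) / (4 / 3 * pi * 6^3)  # close to 1
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  dm <- spec$dim
  ctr <- spec$center %||% (dm / 2)
  segs <- switch(spec$shape,
    sphere = matrix(c(ctr, ctr, spec$radius), 1, 7),
    cylinder = {
      a <- c(ctr[1], ctr[2], ctr[3] - spec$length / 2)
      b <- c(ctr[1], ctr[2], ctr[3] + spec$length / 2)
      matrix(c(a, b, spec$radius), 1, 7)
    },
    y_tube = y_tube_segments(spec, dm, double = FALSE),
    double_y = y_tube_segments(spec, dm, double = TRUE),
    capsules = {
      if (is.null(spec$segments)) stop("capsules shape needs a segments matrix",
                                       call. = FALSE)
      spec$segments
    })
  lo <- pmin(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE]) - segs[, 7]
  hi <- pmax(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE]) + segs[, 7]
  if (any(lo < 1) || any(sweep(hi, 2, dm, `>`)))
    stop("fixture geometry extends outside the domain", call. = FALSE)

  vol <- array(FALSE, dm)
  gx <- seq_len(dm[1]); gy <- seq_len(dm[2]); gz <- seq_len(dm[3])
  pts <- NULL
  for (r in seq_len(nrow(segs))) {
    a <- segs[r, 1:3]; b <- segs[r, 4:6]; rad <- segs[r, 7]
    # restrict to the segment's bounding box for speed
    ix <- gx[gx >= a[1] - rad - 1 & gx <= b[1] + rad + 1 |
             gx >= b[1] - rad - 1 & gx <= a[1] + rad + 1]
    iy <- gy[gy >= a[2] - rad - 1 & gy <= b[2] + rad + 1 |
             gy >= b[2] - rad - 1 & gy <= a[2] + rad + 1]
    iz <- gz[gz >= a[3] - rad - 1 & gz <= b[3] + rad + 1 |
             gz >= b[3] - rad - 1 & gz <= a[3] + rad + 1]
    if (!length(ix) || !length(iy) || !length(iz)) next
    grid <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    d2 <- point_segment_dist2(grid, a, b)
    inside <- grid[d2 <= rad^2, , drop = FALSE]
    if (nrow(inside)) vol[inside] <- TRUE
  }
  vol
}

point_segment_dist2 <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2, a)
  tt <- if (len2 > 0) pmin(pmax(ap %*% ab / len2, 0), 1) else rep(0, nrow(pts))
  proj <- sweep(tt %*% t(ab), 2, a, `+`)
  rowSums((pts - proj)^2)
}

y_tube_segments <- function(spec, dm, double) {
  r <- spec$radius
  base <- c(dm[1] / 2, dm[2] / 2,
            max(r + 1, dm[3] / 2 - (spec$trunk_length +
                                      spec$arm_length * cos(spec$arm_angle)) / 2))
  top <- base + c(0, 0, spec$trunk_length)
  dirs <- list(c(sin(spec$arm_angle), 0, cos(spec$arm_angle)),
               c(-sin(spec$arm_angle), 0, cos(spec$arm_angle)))
  segs <- rbind(c(base, top, r))
  for (d1 in dirs) {
    end1 <- top + spec$arm_length * d1
    segs <- rbind(segs, c(top, end1, r))
    if (double) {
      # second split opens in the y direction, perpendicular to the first
      for (sg in c(1, -1)) {
        d2 <- cos(spec$arm_angle) * d1 + sin(spec$arm_angle) * c(0, sg, 0)
        segs <- rbind(segs, c(end1, end1 + spec$arm2_length * d2, r))
      }
    }
  }
  segs
}
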