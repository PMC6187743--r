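# Tissue extraction, skeleton topology, pattern classification and
# bifurcation separations, validated on analytic fixtures of known shape.

test_that("tissue extraction handles empty and full fields", {
  Y <- array(0, c(10, 10, 10))
  reg <- extract_tissue(Y)
  expect_equal(reg$volume_fraction, 0)
  expect_equal(reg$n_components, 0L)

  reg1 <- extract_tissue(array(1, c(6, 6, 6)))
  expect_equal(reg1$volume_fraction, 1)
  expect_equal(reg1$n_components, 1L)
})

test_that("sphere fixture is a single near-isotropic component", {
  vol <- make_fixture(fixture_spec("sphere", radius = 8, dim = c(64, 64, 64)))
  expect_lt(abs(sum(vol) - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.05)
  reg <- extract_tissue(vol)
  expect_equal(reg$n_components, 1L)
  expect_lt(reg$principal_axis_ratio, 1.15)
  expect_gt(reg$sphericity, 0.9)
})

test_that("cylinder fixture is elongated per the second-moment closed form", {
  vol <- make_fixture(fixture_spec("cylinder", radius = 3, length = 40,
                                   dim = c(48, 48, 48)))
  reg <- extract_tissue(vol)
  expect_equal(reg$n_components, 1L)
  # closed form: axial variance L^2/12 vs radial r^2/4 -> ratio
  # sqrt((40^2/12)/(3^2/4)) ~ 7.7, far above the elongation bound
  expect_gt(reg$principal_axis_ratio, 4)
  expect_lt(reg$sphericity, 0.85)
})

test_that("skeleton topology of the designed fixtures is exact", {
  cyl <- extract_tissue(make_fixture(fixture_spec("cylinder", radius = 3,
                                                  length = 40,
                                                  dim = c(48, 48, 48))))
  sk <- skeletonize_region(cyl)
  expect_equal(sk$n_branch_points, 0L)
  expect_equal(sk$n_tips, 2L)

  y <- extract_tissue(make_fixture(fixture_spec("y_tube", radius = 3,
                                                dim = c(48, 48, 48))))
  sky <- skeletonize_region(y, root_hint = c(24, 24, 1))
  expect_equal(sky$n_branch_points, 1L)
  expect_equal(sky$n_tips, 3L)

  yy <- extract_tissue(make_fixture(fixture_spec("double_y", radius = 2.5,
                                                 dim = c(56, 56, 56))))
  skyy <- skeletonize_region(yy, root_hint = c(28, 28, 1))
  expect_equal(skyy$n_branch_points, 3L)
  expect_equal(skyy$n_tips, 5L)  # trunk base plus the 4 second-round arms
  expect_equal(skyy$max_generation, 2L)
  expect_equal(sum(skyy$edges$generation == 2L), 4L)  # 4 second-round arms
})

test_that("skeleton topology is invariant under axis permutation", {
  vol <- make_fixture(fixture_spec("y_tube", radius = 3, dim = c(48, 48, 48)))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    sk <- skeletonize_region(extract_tissue(aperm(vol, perm)))
    expect_equal(sk$n_branch_points, 1L)
    expect_equal(sk$n_tips, 3L)
  }
})

test_that("double-Y separations equal the constructed arm length", {
  arm <- 12
  vol <- make_fixture(fixture_spec("double_y", radius = 2.5, arm_length = arm,
                                   dim = c(56, 56, 56)))
  sk <- skeletonize_region(extract_tissue(vol), root_hint = c(28, 28, 1))
  seps <- bifurcation_separations(sk)
  expect_equal(nrow(seps), 2L)
  expect_true(all(abs(seps$separation - arm) <= 2))
  expect_true(is.finite(attr(seps, "root_to_first")))
})

test_that("separations are empty for a single bifurcation and invariant to axis order", {
  y <- make_fixture(fixture_spec("y_tube", radius = 3, dim = c(48, 48, 48)))
  sk <- skeletonize_region(extract_tissue(y), root_hint = c(24, 24, 1))
  expect_equal(nrow(bifurcation_separations(sk)), 0L)

  yy <- make_fixture(fixture_spec("double_y", radius = 2.5,
                                  dim = c(56, 56, 56)))
  s1 <- sort(bifurcation_separations(
    skeletonize_region(extract_tissue(yy), root_hint = c(28, 28, 1)))$separation)
  yyp <- aperm(yy, c(3, 1, 2))
  s2 <- sort(bifurcation_separations(
    skeletonize_region(extract_tissue(yyp), root_hint = c(1, 28, 28)))$separation)
  # sequential directional thinning places junction voxels with up to a
  # voxel of axis-dependent jitter; arc lengths agree to that discretization
  expect_equal(length(s1), length(s2))
  expect_true(all(abs(s1 - s2) <= 1.5))
})

test_that("classifier labels the designed shapes per the decision cascade", {
  full <- extract_tissue(array(1, c(16, 16, 16)))
  expect_equal(classify_pattern(full)$label, "SPATIAL_SPILLOVER")

  ball <- extract_tissue(make_fixture(fixture_spec("sphere", radius = 8,
                                                   dim = c(64, 64, 64))))
  expect_equal(classify_pattern(ball)$label, "NO_BRANCH")

  cyl <- extract_tissue(make_fixture(fixture_spec("cylinder", radius = 3,
                                                  length = 40,
                                                  dim = c(48, 48, 48))))
  expect_equal(classify_pattern(cyl)$label, "PARENT_ONLY")

  side <- extract_tissue(side_branch_fixture())
  sk_side <- skeletonize_region(side, root_hint = c(22, 22, 6))
  expect_equal(classify_pattern(side, sk_side)$label, "SIDE_BRANCHING")

  fork <- extract_tissue(tip_fork_fixture())
  sk_fork <- skeletonize_region(fork, root_hint = c(22, 22, 1))
  expect_equal(classify_pattern(fork, sk_fork)$label, "TIP_SPLITTING")

  empty <- extract_tissue(array(0, c(8, 8, 8)))
  expect_equal(classify_pattern(empty)$label, "UNDETERMINED")
})

test_that("classifier is deterministic and total on arbitrary masks", {
  set.seed(5)
  for (i in 1:10) {
    Y <- array(runif(12^3), c(12, 12, 12))
    reg <- extract_tissue(Y, Ya = 0.7)
    p1 <- classify_pattern(reg)
    p2 <- classify_pattern(reg)
    expect_identical(p1$label, p2$label)
    expect_true(p1$label %in% c("SPATIAL_SPILLOVER", "NO_BRANCH",
                                "PARENT_ONLY", "SIDE_BRANCHING",
                                "TIP_SPLITTING", "UNDETERMINED"))
  }
})

test_that("fixture generation is deterministic and validates geometry", {
  s <- fixture_spec("sphere", radius = 6, dim = c(20, 20, 20))
  expect_identical(make_fixture(s), make_fixture(s))
  expect_error(make_fixture(fixture_spec("sphere", radius = 15,
                                         dim = c(20, 20, 20))),
               "outside the domain")
})
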