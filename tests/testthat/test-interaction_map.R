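template_frame <- function() {
  tpl <- tetraloop_template()
  reference_frame(tpl$backbone, tpl$positions, tpl$atom_names)
}

test_that("reference_frame is orthonormal, right-handed and equivariant", {
  fr <- template_frame()
  expect_equal(t(fr$axes) %*% fr$axes, diag(3), tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)

  tpl <- tetraloop_template()
  R <- ribomotif:::quaternion_to_rotation(c(0.8, 0.2, -0.4, 0.4) /
                                            sqrt(sum(c(0.8, 0.2, -0.4, 0.4)^2)))
  moved <- sweep(tpl$backbone %*% t(R), 2, c(5, -2, 7), "+")
  fr2 <- reference_frame(moved, tpl$positions, tpl$atom_names)
  expect_equal(fr2$origin, as.vector(R %*% fr$origin) + c(5, -2, 7),
               tolerance = 1e-9)
  expect_equal(fr2$axes, R %*% fr$axes, tolerance = 1e-9)

  # sign convention stable under small jitter
  set.seed(13)
  for (i in 1:10) {
    fr3 <- reference_frame(tpl$backbone +
                             matrix(rnorm(72, 0, 0.1), ncol = 3),
                           tpl$positions, tpl$atom_names)
    expect_true(all(colSums(fr3$axes * fr$axes) > 0.9))
  }
  expect_error(reference_frame(cbind(0:5, 0, 0), rep(1:2, each = 3),
                               rep("P", 6)), "collinear")
})

test_that("spherical projection follows the angle conventions", {
  fr <- list(origin = c(0, 0, 0), axes = diag(3))
  expect_equal(project_to_sphere(rbind(c(0, 0, 2)), fr)$theta, 0)
  p <- project_to_sphere(rbind(c(1, 1, 0)), fr)
  expect_equal(p$theta, pi / 2)
  expect_equal(p$phi, pi / 4)
  # the phi = pi boundary maps to -pi
  expect_equal(project_to_sphere(rbind(c(-3, 0, 0)), fr)$phi, -pi)
  expect_error(project_to_sphere(rbind(c(0, 0, 0)), fr), "origin")
})

test_that("choose_step matches brute force and handles edge cases", {
  deg <- pi / 180
  cands <- rev(seq(0.5, 30, by = 0.5)) * deg
  intf <- list(data.frame(theta = c(90, 90) * deg, phi = c(5, 17) * deg))
  expect_equal(choose_step(intf, cands), brute_choose_step(intf, cands))
  # with the grid anchored at phi = -pi, the cells first split at 28 deg
  expect_equal(choose_step(intf, cands), 28 * deg, tolerance = 1e-12)

  # single-atom interfaces are vacuously separable at the largest step
  singles <- list(data.frame(theta = 1, phi = 0),
                  data.frame(theta = 2, phi = 1))
  expect_equal(choose_step(singles, cands), 30 * deg)

  dup <- list(data.frame(theta = c(1, 1), phi = c(0.5, 0.5)))
  expect_warning(step <- choose_step(dup, cands), "smallest")
  expect_equal(step, 0.5 * deg)

  set.seed(31)
  rand <- lapply(1:4, function(i)
    data.frame(theta = runif(12, 0.2, pi - 0.2),
               phi = runif(12, -pi, pi - 0.01)))
  expect_equal(choose_step(rand, cands), brute_choose_step(rand, cands))
})

test_that("build_map conserves counts and records per-interface cells", {
  intf <- list(data.frame(theta = 1.0, phi = 0.5),
               data.frame(theta = 1.0, phi = 0.5))
  grid <- build_map(intf, 0.1)
  expect_equal(grid$cells$count, 2)

  expect_equal(nrow(build_map(list(), 0.1)$cells), 0)

  set.seed(8)
  intfs <- lapply(1:5, function(i)
    data.frame(theta = runif(20, 0, pi), phi = runif(20, -pi, pi - 1e-6)))
  g <- build_map(intfs, 0.2)
  expect_equal(sum(g$cells$count), 100)
})

test_that("amino-acid classes and the majority rule behave as specified", {
  expect_equal(aa_class(c("ARG", "SER", "PRO", "PHE", "ASP", "GLY", "XYZ")),
               c("positive", "polar", "proline", "aromatic", "negative",
                 "hydrophobic", "unknown"))

  mk <- function(classes) {
    grid <- build_map(list(data.frame(theta = rep(1, length(classes)),
                                      phi = rep(0.5, length(classes)),
                                      class = classes)), 0.3)
    property_map(grid)$class
  }
  expect_equal(mk(rep("positive", 3)), "positive")
  expect_equal(mk(c("positive", "positive", "aromatic", "aromatic")), "gap")
  expect_equal(mk(c("positive", "positive", "positive", "polar", "polar")),
               "positive")
  # half is not a strict majority; unknown atoms only dilute
  expect_equal(mk(c("positive", "positive", "polar", "proline")), "gap")
  expect_equal(mk(c("positive", "positive", "unknown", "unknown",
                    "unknown")), "gap")
})

test_that("backbone regions are disjoint with majority/tie assignment", {
  bb <- data.frame(theta = c(1, 1, 1, 1.5), phi = c(0.1, 0.1, 0.1, 0.1),
                   position = c(2, 2, 3, 3))
  reg <- mark_regions(bb, 0.3)
  expect_equal(reg$region[reg$i == floor(1 / 0.3)], 2)  # majority wins

  tie <- data.frame(theta = c(1, 1), phi = c(0.1, 0.1), position = c(4, 2))
  expect_equal(mark_regions(tie, 0.3)$region, 2)  # ties to lower position

  tpl <- tetraloop_template()
  fr <- reference_frame(tpl$backbone, tpl$positions, tpl$atom_names)
  pr <- project_to_sphere(tpl$backbone, fr)
  pr$position <- tpl$positions
  reg4 <- mark_regions(pr, 10 * pi / 180)
  expect_setequal(unique(reg4$region), 1:4)
  expect_false(anyDuplicated(paste(reg4$i, reg4$j)) > 0)
})

test_that("the map pipeline is invariant under rigid motion of the scene", {
  sc <- make_tetraloop_scene(synthetic_spec(seed = 17, n_tetraloops = 3))
  res1 <- run_map(sc$model, sc$annotations)

  set.seed(99)
  R <- ribomotif:::random_rotation()
  m2 <- sc$model
  xyz <- as.matrix(m2$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, c(30, -12, 4), "+")
  m2$atoms[, c("x", "y", "z")] <- xyz
  res2 <- run_map(m2, sc$annotations)

  expect_equal(res2$step, res1$step)
  expect_equal(res2$grid$cells, res1$grid$cells, tolerance = 1e-6)
  expect_equal(res2$coverage, res1$coverage)
})
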