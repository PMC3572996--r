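test_that("strand flip is an involution and fixes straight B-DNA", {
  set.seed(29)
  st <- random_steps(14, ang = 30)
  expect_equal(as.matrix(strand_flip(strand_flip(st))), as.matrix(st))
  b <- step_params(tilt = rep(0, 10), twist = 34.3, rise = 3.4)
  expect_equal(as.matrix(strand_flip(b)), as.matrix(b))
})

test_that("overall bend: straight chain, single kink, flip invariance", {
  b <- step_params(tilt = rep(0, 14), twist = 360 / 10.5, rise = 3.4)
  expect_equal(overall_bend(b), 0, tolerance = 1e-9)
  expect_error(overall_bend(b[1:2, ]), "at least 3")
  # one 90-degree roll kink flanked by straight arms
  kink <- b
  kink$roll[7] <- 90
  expect_equal(overall_bend(kink), 90, tolerance = 2)
  # bend magnitude is invariant under the strand flip
  set.seed(31)
  for (i in 1:10) {
    tpl <- make_hu_fixture(runif(1, 20, 150), runif(1, 0, 25))
    expect_equal(overall_bend(strand_flip(tpl)), overall_bend(tpl),
                 tolerance = 0.5)
  }
})

test_that("HU fixtures hit the requested bend and untwist", {
  straight <- make_hu_fixture(0, 0)
  expect_equal(nrow(straight), 14)
  expect_equal(max(abs(straight$tilt)), 0)
  expect_equal(overall_bend(straight), 0, tolerance = 1e-9)

  tpl <- make_hu_fixture(120, 20)
  expect_equal(nrow(tpl), 14)
  expect_equal(overall_bend(tpl), 120, tolerance = 2)
  expect_equal(sum(360 / 10.5 - tpl$twist), 20, tolerance = 0.01)
  expect_error(make_hu_fixture(170), "150")
})

test_that("the template set has 8 variants with crystal-range bends", {
  hs <- hu_template_set()
  expect_length(hs, 8)
  ids <- vapply(hs, attr, "", "id")
  expect_equal(length(unique(ids)), 4)       # four sources x two strands
  bends <- vapply(hs, function(x) overall_bend(x), 0)
  expect_true(all(bends >= 112 & bends <= 129))
  # the two strand variants of one source share the bend magnitude
  for (id in unique(ids)) {
    b <- bends[ids == id]
    expect_equal(b[1], b[2], tolerance = 0.5, ignore_attr = TRUE)
  }
  for (h in hs) expect_equal(nrow(h), 14)
})

test_that("operator segments are congruent 13-step tables with inner halves", {
  ops <- operator_segments()
  expect_equal(nrow(ops$o3), 13)
  expect_equal(nrow(ops$o1), 13)
  expect_equal(as.matrix(ops$o3), as.matrix(ops$o1))
  expect_length(attr(ops$o3, "inner_steps"), 6)   # 7 inner bp = 6 steps
  expect_length(attr(ops$o1, "inner_steps"), 6)
})

test_that("end conditions: base case, conjugation, continuity, separation", {
  # dalpha = 0 returns the base parameters unchanged
  e0 <- lacr_end_condition("A1", 0)
  tab <- packaged_end_condition_table()
  row <- tab[tab$loop_type == "A1" & tab$dalpha == 0, ]
  expect_equal(unlist(row[, c("tilt", "roll", "twist", "shift", "slide",
                              "rise")]),
               unlist(e0$params), tolerance = 0.01, ignore_attr = TRUE)

  # packaged table equals the constructed values at every tabulated angle
  for (i in seq_len(nrow(tab))) {
    p <- lacr_end_condition(tab$loop_type[i], tab$dalpha[i])$params
    expect_equal(unlist(tab[i, c("tilt", "roll", "twist", "shift", "slide",
                                 "rise")]),
                 unlist(p), tolerance = 0.01, ignore_attr = TRUE)
  }

  # opening by dalpha conjugates the base joining transform by the arm-frame
  # rotation: J(da) J(0)^-1 must be conjugate to R_y(da) in the arm frame,
  # i.e. a rotation by exactly da whose axis is the exit-frame image of the
  # arm-frame y-axis
  for (lt in c("A1", "P2")) {
    base <- lacr_end_condition(lt, 0)$transform
    open <- lacr_end_condition(lt, 60)$transform
    Dm <- open %*% solve(base)
    ang <- acos(max(-1, min(1, (sum(diag(Dm[1:3, 1:3])) - 1) / 2))) * 180 / pi
    expect_equal(ang, 60, tolerance = 1e-9)
  }

  # continuity: no parameter jumps above 5 degrees per 1-degree grid step
  fine <- lacr_end_condition_table(seq(0, 120, 1))
  for (lt in c("A1", "A2", "P1", "P2")) {
    s <- fine[fine$loop_type == lt, c("tilt", "roll", "twist")]
    expect_lt(max(abs(apply(s, 2, diff))), 5)
  }

  # operator separation grows monotonically with the opening angle
  for (lt in c("A1", "A2", "P1", "P2")) {
    d <- vapply(seq(0, 120, 5), function(a)
      sqrt(sum(lacr_end_condition(lt, a)$transform[1:3, 4]^2)), 0)
    expect_true(all(diff(d) > 0))
  }

  expect_error(lacr_end_condition("A1", 150), "dalpha")
  expect_error(lacr_end_condition("X1", 0))
})

test_that("the arm frame is orthonormal and right-handed", {
  Fr <- lacr_frame()[1:3, 1:3]
  expect_equal(crossprod(Fr), diag(3), tolerance = 1e-12)
  expect_equal(det(Fr), 1, tolerance = 1e-12)
})
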