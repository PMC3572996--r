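test_that("generator matrices match the axis-angle oracle and round-trip", {
  # trivial identity and pure twist + rise cases
  expect_equal(params_to_transform(c(0, 0, 0, 0, 0, 0)), diag(4))
  A <- params_to_transform(c(0, 0, 34.2857, 0, 0, 3.4))
  expect_equal(A[1:3, 4], c(0, 0, 3.4), tolerance = 1e-12)
  expect_equal(A[3, 3], 1, tolerance = 1e-12)
  th <- 34.2857 * pi / 180
  expect_equal(A[1:3, 1:3], rodrigues(c(0, 0, 1), th), tolerance = 1e-12)

  set.seed(101)
  worst_or <- worst_rt <- 0
  for (i in 1:2000) {
    p <- random_steps(1)
    A <- params_to_transform(p)
    B <- oracle_transform(p$tilt, p$roll, p$twist, p$shift, p$slide, p$rise)
    worst_or <- max(worst_or, max(abs(A - B)))
    q <- transform_to_params(A)
    worst_rt <- max(worst_rt, max(abs(as.matrix(p) - as.matrix(q))))
    # rotation block orthonormal with det +1
    R <- A[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  }
  expect_lt(worst_or, 1e-9)
  expect_lt(worst_rt, 1e-9)
})

test_that("transform round-trips run through 1e4 random draws", {
  set.seed(7)
  n <- 1e4
  p <- random_steps(n)
  m <- as.matrix(p)
  worst <- 0
  for (i in seq_len(n)) {
    q <- transform_to_params(params_to_transform(m[i, ]))
    worst <- max(worst, max(abs(m[i, ] - as.matrix(q))))
  }
  expect_lt(worst, 1e-9)
})

test_that("degenerate and invalid inputs error", {
  expect_error(params_to_transform(c(NA, 0, 0, 0, 0, 0)), "finite")
  # 180-degree bend about an in-plane axis
  A <- diag(4)
  A[1:3, 1:3] <- rodrigues(c(0, 1, 0), pi)
  expect_error(transform_to_params(A), "degenerate")
})

test_that("compose equals the naive serial product and handles phasing", {
  expect_equal(compose_transforms(list()), diag(4))
  expect_equal(compose_transforms(rep(list(diag(4)), 5)), diag(4))
  # 21 B-DNA steps: two full turns, pure rise
  steps <- step_params(tilt = rep(0, 21), twist = 360 / 10.5, rise = 3.4)
  A <- steps_to_transform(steps)
  expect_equal(A[1:3, 1:3], diag(3), tolerance = 1e-9)
  expect_equal(A[1:3, 4], c(0, 0, 71.4), tolerance = 1e-9)
  # random list vs brute-force pairwise product
  set.seed(11)
  ts <- lapply(1:17, function(i) params_to_transform(random_steps(1)))
  brute <- diag(4)
  for (t in ts) brute <- brute %*% t
  expect_equal(compose_transforms(ts), brute, tolerance = 1e-9)
  # associativity on a split
  left <- compose_transforms(ts[1:8]) %*% compose_transforms(ts[9:17])
  expect_equal(left, brute, tolerance = 1e-9)
})

test_that("chain-direction consistency: strand flip gives the inverse", {
  set.seed(13)
  st <- random_steps(9, ang = 45)
  Afwd <- steps_to_transform(st)
  Arev <- steps_to_transform(strand_flip(st))
  Fx <- diag(4); Fx[2, 2] <- -1; Fx[3, 3] <- -1
  expect_equal(Arev, Fx %*% solve(Afwd) %*% Fx, tolerance = 1e-9)
})

test_that("end metrics: identity, pure twist, single bend", {
  m <- end_metrics(diag(4))
  expect_equal(m$r_norm, 0)
  expect_equal(m$gamma, 0)
  expect_equal(m$phi, 0)
  # pure net twist reduces the algebraic sum to (-180, 180]
  steps <- step_params(tilt = rep(0, 10), twist = 40, rise = 3.4)
  m <- end_metrics(steps_to_transform(steps))
  expect_equal(m$gamma, 0, tolerance = 1e-9)
  expect_equal(m$phi, 40, tolerance = 1e-9)   # 400 deg -> 40
  expect_equal(m$r_norm, 34, tolerance = 1e-9)
  # a single 90-degree roll step bends the normal by 90 degrees
  m <- end_metrics(params_to_transform(c(0, 90, 0, 0, 0, 3.4)))
  expect_equal(m$gamma, 90, tolerance = 1e-9)
})

test_that("pure-twist phi matches the algebraic sum over random chains", {
  set.seed(17)
  for (i in 1:20) {
    tw <- runif(12, -170, 170)
    m <- end_metrics(steps_to_transform(
      step_params(tilt = rep(0, 12), twist = tw, rise = 3.4)))
    want <- ((sum(tw) + 180) %% 360) - 180
    if (want <= -180) want <- want + 360
    expect_equal(m$phi, want, tolerance = 1e-8)
  }
})

test_that("step energy: rest state, closed form, equipartition, flip", {
  e <- elastic_params()
  rest <- step_params(twist = 360 / 10.5, rise = 3.4)
  expect_equal(step_energy(rest, e), 0)
  # one standard deviation in tilt costs exactly 1/2 kT
  p <- rest; p$tilt <- e$sigma[["tilt"]]
  expect_equal(step_energy(p, e), 0.5, tolerance = 1e-12)
  # equipartition: three active modes give <psi> = 1.5 kT
  set.seed(19)
  s <- sample_steps(1e5, e)
  expect_equal(mean(step_energy(s, e)), 1.5, tolerance = 0.02 / 1.5)
  # invariance under the direction-reversal parameter rule
  st <- s[1:50, ]
  expect_equal(step_energy(strand_flip(st), e),
               rev(step_energy(st, e)), tolerance = 1e-12)
})

test_that("step-parameter files round-trip and reject malformed input", {
  set.seed(23)
  st <- random_steps(14)
  f <- withr::local_tempfile(fileext = ".par")
  write_step_params(st, f, comment = c("synthetic template", "test"))
  back <- read_step_params(f)
  expect_equal(as.matrix(back), as.matrix(st), tolerance = 1e-4)
  expect_equal(nrow(back), 14)

  bad <- withr::local_tempfile(fileext = ".par")
  writeLines(c("2", "0 0 3.4 0 0 34.3", "0 0 3.4 0 0"), bad)
  expect_error(read_step_params(bad), "line 3")
  writeLines(c("2", "0 0 3.4 0 0 34.3", "0 0 3.4 0 x 34.3"), bad)
  expect_error(read_step_params(bad), "non-numeric")
  writeLines(c("3", "0 0 3.4 0 0 34.3"), bad)
  expect_error(read_step_params(bad), "declares")
})
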