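test_that("Gaussian step draws have the configured moments", {
  e <- elastic_params()
  frozen <- elastic_params()
  frozen$sigma[] <- 0
  set.seed(37)
  s0 <- sample_steps(20, frozen)
  expect_equal(as.matrix(s0),
               matrix(rep(frozen$intrinsic, each = 20), 20, 6,
                      dimnames = list(NULL, colnames(as.matrix(s0)))))
  n <- 1e5
  s <- sample_steps(n, e)
  # mean twist within 3 standard errors of 34.286 deg
  se_tw <- e$sigma[["twist"]] / sqrt(n)
  expect_lt(abs(mean(s$twist) - 360 / 10.5), 3 * se_tw)
  # per-mode variances within 3 SE of sigma^2 (chi-square SE ~ s^2 sqrt(2/n))
  for (m in c("tilt", "roll", "twist")) {
    v <- var(s[[m]])
    expect_lt(abs(v - e$sigma[[m]]^2), 3 * e$sigma[[m]]^2 * sqrt(2 / n))
  }
  expect_equal(unique(s$rise), 3.4)
  expect_equal(unique(s$shift), 0)
})

test_that("HU placement: calibration is exact and density 0 is empty", {
  expect_equal(nrow(place_hu(100, density = 0)), 0)
  # the DP expectation equals the target after calibration
  p <- calibrate_hu_prob(149, 1.0)
  expect_equal(loopmc:::expected_placements(149, p, 14), 1.0,
               tolerance = 1e-9)
  # empirical mean over many draws: 150 deformable bp at default density
  # carries one dimer on average
  set.seed(41)
  counts <- loopmc:::cpp_place_counts(149L, p, 14L, 1e5L, integer(0))
  expect_equal(mean(counts), 1.0, tolerance = 0.02)
  # unreachable occupancy errors out
  expect_error(calibrate_hu_prob(30, 5), "unreachable")
})

test_that("placement process matches exhaustive enumeration on a toy chain", {
  n <- 30L; f <- 5L; p <- 0.08
  exact <- enumerate_scan_counts(n, p, f)
  set.seed(43)
  draws <- loopmc:::cpp_place_counts(n, p, f, 2e5L, integer(0))
  emp <- table(factor(draws, levels = names(exact))) / length(draws)
  expect_equal(as.numeric(emp), as.numeric(exact), tolerance = 0.01)
  # exact mean from enumeration agrees with the DP used for calibration
  mean_exact <- sum(as.integer(names(exact)) * exact)
  expect_equal(loopmc:::expected_placements(n, p, f), mean_exact,
               tolerance = 1e-9)
  # footprints never overlap and stay inside the window
  pl <- place_hu(60, density = 1 / 30)
  if (nrow(pl) > 1) expect_true(all(diff(pl$start) >= 14))
  if (nrow(pl) > 0) expect_true(all(pl$start >= 1 & pl$start + 13 <= 60))
})

test_that("match_loop honours each closure threshold and picks best window", {
  conds <- list(lacr_end_condition("A1", 0), lacr_end_condition("P1", 0),
                lacr_end_condition("A2", 0), lacr_end_condition("P2", 0))
  crit <- closure_criteria()
  # composite equal to the inverse of the A1 joining transform matches A1
  # with zero deviations
  comp <- solve(conds[[1]]$transform)
  m <- match_loop(comp, conds, crit)
  expect_equal(m$loop_type, "A1")
  expect_equal(m$deviation, 0, tolerance = 1e-9)
  expect_equal(m$metrics$r_norm, 0, tolerance = 1e-9)

  # perturbing the position by 10 A (inside the 15 A bound) still matches
  set.seed(47)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  shift <- diag(4); shift[1:3, 4] <- 10 * dir
  m <- match_loop(shift %*% comp, conds, crit)
  expect_equal(m$loop_type, "A1")
  expect_equal(m$metrics$r_norm, 10, tolerance = 1e-6)

  # violating only the twist bound rejects (cos phi = 0.97 < 0.98); the
  # residual rotation is applied to the closed composite so r and gamma
  # stay exactly zero
  tw <- diag(4)
  tw[1:3, 1:3] <- rodrigues(c(0, 0, 1), acos(0.97))
  expect_null(match_loop(tw %*% comp, conds, crit))
  # ... but passes once the twist window is widened
  m <- match_loop(tw %*% comp, conds, closure_criteria(15, 0.98, 0.96))
  expect_equal(m$loop_type, "A1")
  expect_equal(m$metrics$cos_phi, 0.97, tolerance = 1e-9)
})

test_that("acceptance fraction is 1 when every window is wide open", {
  cfg <- sampler_config(40, hu_density = 0, mode = "direct", samples = 500,
                        seed = 49,
                        criteria = closure_criteria(1e6, -0.999, -0.999))
  e <- run_cyclization_ensemble(cfg)
  expect_equal(e$accepted, 500)
  expect_equal(e$J, j_normalization(cfg$criteria), tolerance = 1e-9)
})

test_that("zero-variance chains never close into minicircles", {
  e0 <- elastic_params()
  e0$sigma[] <- 0
  cfg <- sampler_config(105, hu_density = 0, mode = "direct", samples = 2000,
                        seed = 51, elastic = e0)
  ens <- run_cyclization_ensemble(cfg)
  expect_equal(ens$accepted, 0)
  expect_equal(ens$J, 0)
})

test_that("identical seed and config reproduce a direct run bit-for-bit", {
  cfg <- sampler_config(60, mode = "direct", samples = 2e4, seed = 53,
                        criteria = closure_criteria(60, 0.5, 0.5))
  a <- run_loop_ensemble(cfg)
  b <- run_loop_ensemble(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$J, b$J)
  expect_gt(a$accepted, 0)
})

test_that("chain-length bookkeeping rejects too-short loops", {
  expect_error(run_loop_ensemble(sampler_config(13, samples = 10)),
               "deformable")
  expect_error(run_cyclization_ensemble(sampler_config(10, samples = 10)),
               "n_bp")
})

test_that("tolerance widening never decreases acceptance (monotonicity)", {
  base <- sampler_config(70, hu_density = 1 / 150, mode = "direct",
                         samples = 3e4, seed = 57,
                         criteria = closure_criteria(25, 0.9, 0.9))
  a0 <- run_loop_ensemble(base)$accepted
  for (crit in list(closure_criteria(40, 0.9, 0.9),
                    closure_criteria(25, 0.7, 0.9),
                    closure_criteria(25, 0.9, 0.7))) {
    cfg <- base
    cfg$criteria <- crit
    expect_gte(run_loop_ensemble(cfg)$accepted, a0)
  }
})

test_that("half-chain combination agrees with direct sampling (loop, HU)", {
  crit <- closure_criteria(40, 0.9, 0.9)
  d <- run_loop_ensemble(sampler_config(90, mode = "direct", samples = 3e5,
                                        seed = 59, criteria = crit))
  h <- run_loop_ensemble(sampler_config(90, mode = "halfchain", n_half = 3000,
                                        seed = 61, criteria = crit))
  expect_gt(d$accepted, 0)
  expect_gt(h$accepted, 0)
  expect_lt(abs(d$J - h$J), 3 * sqrt(d$se^2 + h$se^2))
})
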