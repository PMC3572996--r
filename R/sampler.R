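# Configurational sampling: Gaussian step draws, random non-overlapping HU
# placement, loop/cyclization acceptance, and the direct and half-chain
# pairwise-combination ensemble drivers (compiled kernels in src/).

#' Closure criteria
#'
#' Tolerances that classify a configuration as looped/closed: end-to-end
#' distance below `r_max`, and cosines of the net bend and end-to-end twist
#' at least `cos_gamma_min` and `cos_phi_min`. Defaults are the standard
#' bounds (15 A, 0.98, 0.98).
#'
#' @param r_max Radial bound in Angstroms (> 0).
#' @param cos_gamma_min,cos_phi_min Cosine bounds in (-1, 1].
#' @return An object of class `closure_criteria`.
#' @export
closure_criteria <- function(r_max = 15, cos_gamma_min = 0.98,
                             cos_phi_min = 0.98) {
  stopifnot(r_max > 0,
            cos_gamma_min > -1, cos_gamma_min <= 1,
            cos_phi_min > -1, cos_phi_min <= 1)
  structure(list(r_max = r_max, cos_gamma_min = cos_gamma_min,
                 cos_phi_min = cos_phi_min), class = "closure_criteria")
}

#' Sample fluctuating base-pair steps
#'
#' Independent Gaussian draws about the intrinsic values for the fluctuating
#' modes (tilt, roll, twist); frozen modes stay at their rest values.
#'
#' @param n Number of steps (>= 0).
#' @param e An [elastic_params()] object.
#' @return An `n` x 6 step table.
#' @export
sample_steps <- function(n, e = elastic_params()) {
  stopifnot(inherits(e, "elastic_params"), n >= 0)
  if (n == 0) return(step_params()[0, ])
  draw <- function(mode) {
    if (e$sigma[mode] > 0)
      stats::rnorm(n, e$intrinsic[mode], e$sigma[mode])
    else rep(e$intrinsic[[mode]], n)
  }
  step_params(tilt = draw("tilt"), roll = draw("roll"), twist = draw("twist"),
              shift = draw("shift"), slide = draw("slide"), rise = draw("rise"))
}

# Exact expected footprint count of the scan-and-place process on a window
# of n steps with per-position attempt probability p (footprint f): dynamic
# programme over suffix expectations.
expected_placements <- function(n, p, footprint) {
  if (n < footprint || p <= 0) return(0)
  # e[i] = expected count of the scan starting at position i; zero beyond
  # the last admissible start n - footprint + 1
  e <- numeric(n + footprint + 2)
  for (i in seq(n - footprint + 1, 1))
    e[i] <- p * (1 + e[i + footprint]) + (1 - p) * e[i + 1]
  e[1]
}

#' Calibrate the HU placement probability
#'
#' Solves (exactly, by root-finding on the dynamic-programme expectation,
#' not by simulation) for the per-position attempt probability of the
#' sequential scan-and-place process so that the mean number of
#' non-overlapping footprints on a window of `n_steps` steps equals
#' `target`.
#'
#' @param n_steps Window length in steps.
#' @param target Desired mean footprint count.
#' @param footprint Footprint length in steps (default 14).
#' @return The attempt probability in [0, 1).
#' @export
calibrate_hu_prob <- function(n_steps, target, footprint = HU_FOOTPRINT) {
  stopifnot(target >= 0, n_steps >= 0)
  if (target == 0 || n_steps < footprint) {
    if (target > 0) stop("window too short for any footprint")
    return(0)
  }
  emax <- expected_placements(n_steps, 1 - 1e-12, footprint)
  if (target >= emax)
    stop("target occupancy ", target, " unreachable on ", n_steps, " steps")
  stats::uniroot(function(p) expected_placements(n_steps, p, footprint) - target,
                 c(0, 1 - 1e-9), tol = 1e-12)$root
}

#' Randomly place HU footprints on a deformable window
#'
#' One draw of the sequential scan-and-place process: positions are visited
#' 5' to 3'; at each position not covered by an earlier footprint a dimer is
#' placed with the calibrated attempt probability, occupying `footprint`
#' consecutive steps, and its template variant is drawn uniformly from the
#' supplied set.
#'
#' @param n_steps Window length (steps).
#' @param density Target dimers per bp (default 1/150); the mean count is
#'   `(n_steps + 1) * density`.
#' @param templates List of HU templates ([hu_template_set()]), used only
#'   for the variant labels.
#' @param prob Optional pre-calibrated attempt probability (overrides
#'   `density`).
#' @return A `data.frame` with columns `start` (1-based first step) and
#'   `variant`; zero rows when nothing is placed.
#' @export
place_hu <- function(n_steps, density = 1 / 150,
                     templates = hu_template_set(), prob = NULL) {
  stopifnot(density >= 0)
  f <- HU_FOOTPRINT
  p <- if (is.null(prob)) {
    target <- (n_steps + 1) * density
    if (target > 0 && n_steps >= f) calibrate_hu_prob(n_steps, target, f) else 0
  } else prob
  starts <- integer(0); vars <- integer(0)
  i <- 1
  while (i <= n_steps) {
    if (p > 0 && i <= n_steps - f + 1 && stats::runif(1) < p) {
      starts <- c(starts, i)
      vars <- c(vars, sample.int(max(length(templates), 1), 1))
      i <- i + f
    } else i <- i + 1
  }
  data.frame(start = starts, variant = vars)
}

#' Test a composite transform against a set of end conditions
#'
#' Composes an accumulated chain transform with each candidate joining
#' transform and applies the closure criteria. If several
#' (loop type, dalpha) windows are satisfied the single minimum-deviation
#' one is returned (deviation = `r/r_max + (1 - cos g)/(1 - cos g_min) +
#' (1 - cos f)/(1 - cos f_min)`), with the multiplicity logged.
#'
#' @param composite 4x4 accumulated chain transform.
#' @param conditions List of `end_condition` objects.
#' @param criteria A [closure_criteria()] object.
#' @return `NULL` if no condition matches, else a list with `loop_type`,
#'   `dalpha`, `metrics`, `deviation`, `multiplicity`.
#' @export
match_loop <- function(composite, conditions, criteria = closure_criteria()) {
  stopifnot(inherits(criteria, "closure_criteria"))
  if (inherits(conditions, "end_condition")) conditions <- list(conditions)
  best <- NULL
  mult <- 0L
  for (cond in conditions) {
    m <- end_metrics(composite %*% cond$transform)
    ok <- m$r_norm < criteria$r_max &&
      m$cos_gamma >= criteria$cos_gamma_min &&
      m$cos_phi >= criteria$cos_phi_min
    if (!ok) next
    dev <- m$r_norm / criteria$r_max +
      (1 - m$cos_gamma) / (1 - criteria$cos_gamma_min) +
      (1 - m$cos_phi) / (1 - criteria$cos_phi_min)
    mult <- mult + 1L
    if (is.null(best) || dev < best$deviation)
      best <- list(loop_type = cond$loop_type, dalpha = cond$dalpha,
                   metrics = m, deviation = dev)
  }
  if (is.null(best)) return(NULL)
  best$multiplicity <- mult
  best
}

#' Sampler configuration
#'
#' Bundles everything one ensemble run needs. `n_bp` is the chain length in
#' base pairs: for loops, the number of base pairs between the centres of
#' the bound operators (7 rigid bp from each operator's inner half plus
#' `n_bp - 14` deformable bp); for cyclization, the minicircle size.
#'
#' @param n_bp Chain length in bp.
#' @param hu_density HU dimers per bp of deformable DNA (default 1/150;
#'   0 disables HU).
#' @param mode `"direct"` or `"halfchain"`.
#' @param samples Direct-mode trial count.
#' @param n_half Half-chain count per side (half-chain mode samples
#'   `n_half^2` effective configurations).
#' @param seed Integer seed (every run is reproducible from it).
#' @param dalpha_max,dalpha_step Opening-angle grid for deformable-repressor
#'   runs; `dalpha_max = 0` is the rigid V-shaped assembly.
#' @param loop_types Loop orientations to test.
#' @param criteria A [closure_criteria()] object.
#' @param elastic An [elastic_params()] object.
#' @param hu_source,operator_source Template sources (see
#'   [hu_template_set()], [operator_segments()]).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_bp, hu_density = 1 / 150,
                           mode = c("direct", "halfchain"),
                           samples = 1e5, n_half = 1e4, seed = 1,
                           dalpha_max = 0, dalpha_step = 2,
                           loop_types = LOOP_TYPES,
                           criteria = closure_criteria(),
                           elastic = elastic_params(),
                           hu_source = "synthetic",
                           operator_source = "synthetic") {
  mode <- match.arg(mode)
  stopifnot(hu_density >= 0, dalpha_max >= 0, dalpha_step > 0)
  structure(list(n_bp = as.integer(n_bp), hu_density = hu_density,
                 mode = mode, samples = samples, n_half = as.integer(n_half),
                 seed = as.integer(seed), dalpha_max = dalpha_max,
                 dalpha_step = dalpha_step, loop_types = loop_types,
                 criteria = criteria, elastic = elastic,
                 hu_source = hu_source, operator_source = operator_source),
            class = "sampler_config")
}

# Internal: shared machinery for the two ensemble kinds.
run_ensemble_internal <- function(config, kind = c("loop", "cyclization")) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "sampler_config"))
  e <- config$elastic
  sig <- e$sigma[c("tilt", "roll", "twist")] * DEG
  intr <- e$intrinsic
  intr[c("tilt", "roll", "twist")] <- intr[c("tilt", "roll", "twist")] * DEG
  cr <- config$criteria

  if (kind == "loop") {
    n_deform <- config$n_bp - 13L  # deformable steps between rigid halves
    if (n_deform < 1)
      stop("n_bp = ", config$n_bp,
           " leaves no deformable steps between the rigid operator halves")
    ops <- operator_segments(config$operator_source)
    pre_steps <- as_step_matrix(ops$o3)[attr(ops$o3, "inner_steps"), ,
                                        drop = FALSE]
    suf_steps <- as_step_matrix(ops$o1)[attr(ops$o1, "inner_steps"), ,
                                        drop = FALSE]
    prefix <- steps_to_transform(pre_steps)
    suffix <- steps_to_transform(suf_steps)
    gaussian_join <- FALSE
    deform_bp <- config$n_bp - 14L
    dalpha <- seq(0, config$dalpha_max, by = config$dalpha_step)
    if (config$dalpha_max == 0) dalpha <- 0
    conds <- list()
    for (lt in config$loop_types)
      for (a in dalpha)
        conds[[length(conds) + 1L]] <-
          lacr_end_condition(lt, a, dalpha_limit = max(120, config$dalpha_max))
  } else {
    n_deform <- config$n_bp - 1L  # plus one Gaussian joining step
    if (config$n_bp < 15)
      stop("cyclization needs n_bp >= 15")
    prefix <- suffix <- diag(4)
    gaussian_join <- TRUE
    deform_bp <- config$n_bp
    idc <- structure(list(loop_type = "circle", dalpha = 0,
                          transform = diag(4)), class = "end_condition")
    conds <- list(idc)
  }

  n1 <- n_deform %/% 2L
  n2 <- n_deform - n1
  hu <- list()
  p1 <- p2 <- 0
  if (config$hu_density > 0) {
    hu_list <- hu_template_set(config$hu_source)
    hu <- lapply(hu_list, function(s) {
      m <- as_step_matrix(s)
      m[, c("tilt", "roll", "twist")] <- m[, c("tilt", "roll", "twist")] * DEG
      m
    })
    target_total <- deform_bp * config$hu_density
    if (n1 >= HU_FOOTPRINT)
      p1 <- calibrate_hu_prob(n1, target_total * n1 / n_deform)
    if (n2 >= HU_FOOTPRINT)
      p2 <- calibrate_hu_prob(n2, target_total * n2 / n_deform)
  }
  cond_mats <- lapply(conds, `[[`, "transform")

  set.seed(config$seed)
  if (config$mode == "direct") {
    raw <- cpp_direct_ensemble(prefix, suffix, n1, n2, unname(sig),
                               unname(intr), hu, p1, p2, cond_mats,
                               cr$r_max, cr$cos_gamma_min, cr$cos_phi_min,
                               config$samples, gaussian_join)
  } else {
    raw <- cpp_halfchain_ensemble(prefix, suffix, n1, n2, unname(sig),
                                  unname(intr), hu, p1, p2, cond_mats,
                                  cr$r_max, cr$cos_gamma_min, cr$cos_phi_min,
                                  config$n_half, gaussian_join)
  }
  accepted <- data.frame(
    loop_type = vapply(conds, `[[`, "", "loop_type")[raw$cond],
    dalpha = vapply(conds, `[[`, 0, "dalpha")[raw$cond],
    hu_count = raw$hu_count, multiplicity = raw$multiplicity,
    r = raw$r, cos_gamma = raw$cos_gamma, cos_phi = raw$cos_phi,
    phi = raw$phi / DEG, deviation = raw$dev,
    stringsAsFactors = FALSE)
  if (config$mode == "halfchain") {
    accepted$i <- raw$i
    accepted$j <- raw$j
  } else {
    accepted$trial <- raw$trial
  }

  jf <- j_factor(nrow(accepted), raw$samples, cr)
  if (config$mode == "halfchain" && nrow(accepted) > 0) {
    jf["se"] <- halfchain_se(accepted$i, accepted$j, raw$n_half) *
      j_normalization(cr)
  }
  res <- list(kind = kind, n_bp = config$n_bp, mode = config$mode,
              samples = raw$samples, accepted = nrow(accepted),
              J = unname(jf["J"]), se = unname(jf["se"]),
              records = accepted, config = config, seed = config$seed)
  if (config$mode == "direct") {
    res$placements <- raw$hu_starts
    res$placement_variants <- raw$hu_variants
  }
  summ <- if (nrow(accepted) > 0) ensemble_summary(accepted) else NULL
  res$f_loop <- summ$f_loop
  res$f_hu <- summ$f_hu
  res$dalpha_mean <- summ$dalpha_mean
  structure(res, class = "loop_ensemble")
}

# U-statistic standard error of the half-chain acceptance fraction: the same
# half chain enters M pairings, so the binomial error is inflated by the
# between-half variance of the row and column acceptance counts.
halfchain_se <- function(i, j, n_half) {
  M <- as.numeric(n_half)
  A <- length(i)
  p <- A / M^2
  ai <- tabulate(i, nbins = n_half) / M
  aj <- tabulate(j, nbins = n_half) / M
  v <- sum((ai - p)^2) / M^2 + sum((aj - p)^2) / M^2 + p * (1 - p) / M^2
  sqrt(v)
}

#' Run a repressor-mediated looping ensemble
#'
#' Builds chains of `n_bp` base pairs between operator centres - rigid
#' inner operator halves at both ends, Gaussian deformable steps (with
#' randomly placed HU templates) in between - and scores closure against the
#' repressor end conditions for the configured loop orientations and
#' opening-angle grid. `mode = "direct"` enumerates full chains;
#' `mode = "halfchain"` generates two half-ensembles and combines them
#' pairwise (an effective `n_half^2` sample) via spatial hashing.
#'
#' @param config A [sampler_config()] object.
#' @return A `loop_ensemble` object: J factor with standard error, accepted
#'   records (loop type, dalpha, HU count, closure deviations), loop-type
#'   fractions, HU histogram, and the config echo.
#' @export
run_loop_ensemble <- function(config) run_ensemble_internal(config, "loop")

#' Run a cyclization (minicircle) ensemble
#'
#' All `n_bp` steps are deformable (plus a Gaussian-sampled joining step);
#' closure is tested against the identity end condition with the same
#' criteria machinery as looping.
#'
#' @param config A [sampler_config()] object.
#' @return A `loop_ensemble` object (see [run_loop_ensemble()]).
#' @export
run_cyclization_ensemble <- function(config)
  run_ensemble_internal(config, "cyclization")

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf("%s ensemble: N = %d bp, %s mode\n", x$kind, x$n_bp, x$mode))
  cat(sprintf("  samples %.3g, accepted %d, J = %.4g M (SE %.2g)\n",
              x$samples, x$accepted, x$J, x$se))
  if (!is.null(x$f_loop)) {
    cat("  f_loop:",
        paste(sprintf("%s %.3f", names(x$f_loop), x$f_loop), collapse = ", "),
        "\n")
  }
  invisible(x)
}
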