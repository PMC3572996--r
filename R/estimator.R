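# Observables: J factors with Monte-Carlo errors, persistence length from
# bending correlations, loop-type / HU-uptake / opening-angle summaries, and
# the twisted-wormlike-chain closed-form reference.

AVOGADRO <- 6.02214076e23
A3_PER_L <- 1e27

#' J-factor normalization constant
#'
#' Converts an acceptance fraction into a molar J factor: the reciprocal of
#' the phase-space volume admitted by the closure windows,
#' `1/(N_A V_r) * 4pi / (2pi (1 - cos g_max)) * 2pi / (2 phi_max)` with
#' `V_r = (4/3) pi r_max^3` converted to litres. With the default criteria
#' (15 A, 0.98, 0.98) the constant is about 184.5 M.
#'
#' @param criteria A [closure_criteria()] object.
#' @return Normalization in molar units (M).
#' @export
j_normalization <- function(criteria = closure_criteria()) {
  stopifnot(inherits(criteria, "closure_criteria"))
  v_l <- (4 / 3) * pi * criteria$r_max^3 / A3_PER_L
  ang <- 2 / (1 - criteria$cos_gamma_min)
  phi_max <- acos(criteria$cos_phi_min)
  tw <- pi / phi_max
  1 / (AVOGADRO * v_l) * ang * tw
}

#' J factor from acceptance counts
#'
#' `J = f_acc * j_normalization(criteria)` with a binomial standard error
#' propagated through the constant. (For half-chain ensembles the driver
#' replaces the SE with the U-statistic estimate, which accounts for the
#' reuse of each half chain across pairings.)
#'
#' @param accepted Number of accepted configurations.
#' @param samples Number of (effective) sampled configurations (> 0).
#' @param criteria A [closure_criteria()] object.
#' @return Named vector `c(J = , se = )` in molar units.
#' @export
j_factor <- function(accepted, samples, criteria = closure_criteria()) {
  if (samples <= 0) stop("samples must be positive")
  norm <- j_normalization(criteria)
  p <- accepted / samples
  c(J = norm * p, se = norm * sqrt(p * (1 - p) / samples))
}

#' Persistence length from bending correlations
#'
#' Simulates unconstrained chains under the elastic model and fits the
#' exponential decay of the mean cosine of the bend angle between base-pair
#' normals, `<cos Theta(k)> = exp(-k h / l_p)`, over contour separations up
#' to `fit_max_frac * l_p` (weighted through the origin in log space). Rigid
#' chains (no decay) return a divergence flag instead of a number.
#'
#' @param elastic An [elastic_params()] object.
#' @param n_chains Number of chains (>= 1e4 recommended).
#' @param n_steps Steps per chain (>= 100 recommended).
#' @param kmax Largest step separation entering the fit (defaults to half
#'   the nominal persistence length).
#' @return Object of class `persistence_fit`: list with `lp` (A; `NA` when
#'   diverged), `diverged`, `correlation` (per-k mean cosines), `n_chains`,
#'   `n_steps`.
#' @export
persistence_length <- function(elastic = elastic_params(), n_chains = 1e4,
                               n_steps = 200, kmax = NULL) {
  stopifnot(inherits(elastic, "elastic_params"), n_chains >= 1, n_steps >= 10)
  h <- elastic$intrinsic[["rise"]]
  if (is.null(kmax)) {
    sb <- elastic$sigma[["tilt"]] * DEG
    lp_nom <- if (sb > 0) h / sb^2 else Inf
    kmax <- if (is.finite(lp_nom)) max(10L, min(n_steps - 1L,
                                                floor(lp_nom / (2 * h))))
            else min(n_steps - 1L, 50L)
  }
  sig <- elastic$sigma[c("tilt", "roll", "twist")] * DEG
  intr <- elastic$intrinsic
  intr[c("tilt", "roll", "twist")] <- intr[c("tilt", "roll", "twist")] * DEG
  corr <- cpp_bend_correlation(as.integer(n_chains), as.integer(n_steps),
                               unname(sig), unname(intr), as.integer(kmax))
  k <- seq_len(kmax)
  if (all(corr > 1 - 1e-8) || any(corr <= 0)) {
    return(structure(list(lp = NA_real_, diverged = all(corr > 1 - 1e-8),
                          correlation = corr, n_chains = n_chains,
                          n_steps = n_steps), class = "persistence_fit"))
  }
  slope <- sum(k * log(corr)) / sum(k^2)
  structure(list(lp = -h / slope, diverged = FALSE, correlation = corr,
                 n_chains = n_chains, n_steps = n_steps),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  if (x$diverged) cat("persistence fit: no decay (rigid chain)\n")
  else cat(sprintf("persistence length %.1f A (%d chains x %d steps)\n",
                   x$lp, x$n_chains, x$n_steps))
  invisible(x)
}

#' Summaries of accepted loops
#'
#' Loop-type fractions, HU-uptake histogram, and opening-angle statistics of
#' a set of accepted-loop records.
#'
#' @param accepted A `data.frame` of accepted records (from a
#'   `loop_ensemble`) with columns `loop_type`, `hu_count`, `dalpha`.
#' @return List with `f_loop` (fractions over A1/A2/P1/P2, summing to 1),
#'   `f_hu` (fractions by dimer count), `dalpha_mean`, `dalpha_hist`.
#' @export
ensemble_summary <- function(accepted) {
  if (is.null(accepted) || nrow(accepted) == 0)
    stop("no accepted loops to summarize")
  n <- nrow(accepted)
  types <- intersect(LOOP_TYPES, unique(accepted$loop_type))
  if (length(types) == 0) types <- unique(accepted$loop_type)
  f_loop <- vapply(types, function(t) sum(accepted$loop_type == t) / n, 0)
  cnt <- table(factor(accepted$hu_count,
                      levels = 0:max(accepted$hu_count, 0)))
  f_hu <- as.numeric(cnt) / n
  names(f_hu) <- names(cnt)
  list(f_loop = f_loop, f_hu = f_hu,
       dalpha_mean = mean(accepted$dalpha),
       dalpha_hist = table(accepted$dalpha) / n)
}

# Matrix log of a near-identity pose: (V^{-1} r, axis-angle vector).
se3_log <- function(A) {
  R <- A[1:3, 1:3]
  r <- A[1:3, 4]
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  th <- acos(ct)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w <- if (th < 1e-10) v / 2 else th / (2 * sin(th)) * v
  W <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  thn <- sqrt(sum(w^2))
  Vinv <- if (thn < 1e-8) diag(3) - W / 2
  else {
    a <- sin(thn) / thn
    b <- (1 - cos(thn)) / thn^2
    diag(3) - W / 2 + (1 / thn^2) * (1 - a / (2 * b)) * (W %*% W)
  }
  c(as.numeric(Vinv %*% r), w)
}

#' Closed-form ring-closure J of the twisted fluctuating chain
#'
#' Analytic saddle-point evaluation of the cyclization J factor, in the
#' Shimada-Yamakawa framework but computed exactly for the discrete chain:
#' the saddle is the uniformly bent, helically phased circle (which closes
#' the discrete chain exactly), contributing `exp(-E_circle)` with
#' `E_circle = 2 pi^2 l_p / L` plus the twist-mismatch penalty for each
#' candidate linking number; the Gaussian fluctuation integral over the six
#' closure constraints is evaluated exactly from the constraint Jacobian,
#' with the flat circle-phase orbit integrated as a collective coordinate;
#' and the leading anharmonic coil correction `exp(0.246 L/l_p)` is applied
#' when `anharmonic = TRUE`. Nearest linking numbers (`Lk0 - 1, Lk0, Lk0 +
#' 1`) are summed. The computation involves no sampling and serves as an
#' independent oracle for the Monte-Carlo machinery.
#'
#' @param n_bp Chain length in bp (the circle has `n_bp` steps).
#' @param elastic An [elastic_params()] object.
#' @param anharmonic Apply the leading coil correction (default `TRUE`).
#' @return J factor in molar units.
#' @export
wlc_ring_closure_j <- function(n_bp, elastic = elastic_params(),
                               anharmonic = TRUE) {
  n <- as.integer(n_bp)
  stopifnot(n >= 30)
  h <- elastic$intrinsic[["rise"]]
  tw0 <- elastic$intrinsic[["twist"]] * DEG
  sb <- elastic$sigma[["tilt"]] * DEG
  st <- elastic$sigma[["twist"]] * DEG
  stopifnot(sb > 0, st > 0)
  lk0 <- round(n * tw0 / (2 * pi))
  total <- 0
  for (lk in lk0 + (-1:1)) {
    if (lk < 1) next
    twc <- 2 * pi * lk / n
    cum <- cumsum(c(0, rep(twc, n)))[seq_len(n)] + twc / 2
    gam <- 2 * pi / n
    ang <- cbind(gam * sin(cum), gam * cos(cum), rep(twc, n))
    ec <- n * gam^2 / (2 * sb^2) + n * (twc - tw0)^2 / (2 * st^2)
    steps <- cbind(ang, 0, 0, h)
    xi_of <- function(s) {
      raw <- cpp_steps_to_frames(s)
      A <- diag(4)
      A[1:3, 1:3] <- matrix(raw[n + 1, 1:9], 3, 3, byrow = TRUE)
      A[1:3, 4] <- raw[n + 1, 10:12]
      se3_log(A)
    }
    d <- 1e-6
    J6 <- matrix(0, 6, 3 * n)
    for (k in seq_len(3 * n)) {
      i <- (k - 1) %/% 3 + 1
      j <- (k - 1) %% 3 + 1
      sp <- steps; sp[i, j] <- sp[i, j] + d
      sm <- steps; sm[i, j] <- sm[i, j] - d
      J6[, k] <- (xi_of(sp) - xi_of(sm)) / (2 * d)
    }
    tau <- as.numeric(t(cbind(gam * cos(cum), -gam * sin(cum), 0)))
    ell <- 2 * pi * sqrt(sum(tau^2))
    J7 <- rbind(J6, tau / sqrt(sum(tau^2)))
    Cv <- rep(c(sb^2, sb^2, st^2), n)
    S7 <- J7 %*% (Cv * t(J7))
    rho <- exp(-ec) * ell * (2 * pi)^-3.5 / sqrt(det(S7))
    total <- total + rho
  }
  jm <- 8 * pi^2 * total * A3_PER_L / AVOGADRO
  if (anharmonic) {
    lp <- h / sb^2
    jm <- jm * exp(0.246 * n * h / lp)
  }
  jm
}
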