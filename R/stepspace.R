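# Rigid base-pair-step algebra: the six step parameters, their generator
# matrices, chain composition, end-to-end closure metrics, and the quadratic
# elastic energy. Interfaces use degrees and Angstroms throughout; radians
# appear only inside function bodies.

DEG <- pi / 180

#' Base-pair step parameters
#'
#' Constructs a table of rigid-body base-pair-step parameters. Each row holds
#' the six coordinates relating one base-pair frame to the next: three angles
#' (tilt, roll, twist, in degrees) and three displacements (shift, slide,
#' rise, in Angstroms).
#'
#' @param tilt,roll,twist Angular parameters in degrees.
#' @param shift,slide,rise Translational parameters in Angstroms.
#' @return A `data.frame` with columns `tilt, roll, twist, shift, slide, rise`.
#' @export
#' @examples
#' step_params(twist = 360 / 10.5, rise = 3.4)
step_params <- function(tilt = 0, roll = 0, twist = 0,
                        shift = 0, slide = 0, rise = 0) {
  p <- data.frame(tilt = tilt, roll = roll, twist = twist,
                  shift = shift, slide = slide, rise = rise)
  if (!all(is.finite(as.matrix(p))))
    stop("step parameters must be finite")
  p
}

step_cols <- c("tilt", "roll", "twist", "shift", "slide", "rise")

# Coerce a 6-vector, one-row data frame, or n x 6 table to an n x 6 matrix
# with the canonical column order.
as_step_matrix <- function(p) {
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) != 6) stop("a single step needs exactly 6 parameters")
    p <- matrix(p, nrow = 1, dimnames = list(NULL, step_cols))
  } else if (is.data.frame(p)) {
    if (!all(step_cols %in% names(p)))
      stop("step table must have columns ", paste(step_cols, collapse = ", "))
    p <- as.matrix(p[, step_cols])
  } else if (is.matrix(p)) {
    if (ncol(p) != 6) stop("step matrix must have 6 columns")
    colnames(p) <- step_cols
  } else stop("cannot interpret step parameters")
  if (!all(is.finite(p))) stop("step parameters must be finite")
  p
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Generator matrix of one base-pair step
#'
#' Converts the six rigid-body parameters of a base-pair step into the 4x4
#' homogeneous transform relating the frame of base pair n to that of base
#' pair n+1. The mid-step-frame convention of the 3DNA standard is used: the
#' net rotation is `Rz(omega/2 - phi) Ry(Gamma) Rz(omega/2 + phi)` with bend
#' `Gamma = sqrt(tilt^2 + roll^2)` and phase `phi = atan2(tilt, roll)`, and
#' the displacement is the (shift, slide, rise) vector expressed in the
#' mid-step frame. Parameters are therefore independent of chain direction:
#' reading the chain backwards negates tilt and shift only.
#'
#' @param p One step: a 6-vector or one-row table from [step_params()].
#' @return A 4x4 homogeneous matrix (rotation block + displacement).
#' @export
params_to_transform <- function(p) {
  p <- as_step_matrix(p)
  if (nrow(p) != 1) stop("params_to_transform expects a single step")
  tl <- p[1, "tilt"] * DEG; ro <- p[1, "roll"] * DEG; tw <- p[1, "twist"] * DEG
  gam <- sqrt(tl^2 + ro^2)
  phi <- atan2(tl, ro)
  R <- rot_z(tw / 2 - phi) %*% rot_y(gam) %*% rot_z(tw / 2 + phi)
  Tm <- rot_z(tw / 2 - phi) %*% rot_y(gam / 2) %*% rot_z(phi)
  r <- Tm %*% c(p[1, "shift"], p[1, "slide"], p[1, "rise"])
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- r
  A
}

#' Recover step parameters from a generator matrix
#'
#' Exact inverse of [params_to_transform()]. The rotation block is factored as
#' a ZYZ product; a rotation by 180 degrees about an in-plane axis makes that
#' factorization singular and raises an error.
#'
#' @param a A 4x4 homogeneous transform.
#' @return A one-row step-parameter `data.frame`.
#' @export
transform_to_params <- function(a) {
  stopifnot(is.matrix(a), all(dim(a) == c(4, 4)))
  R <- a[1:3, 1:3]
  check_rotation(R)
  sg <- sqrt(R[1, 3]^2 + R[2, 3]^2)
  if (R[3, 3] < -1 + 1e-9)
    stop("degenerate geometry: 180-degree bend about an in-plane axis")
  if (sg < 1e-12) {
    # pure twist about z
    alpha <- 0
    gamma <- atan2(R[2, 1], R[1, 1])
    gam <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
    gam <- atan2(sg, R[3, 3])
  }
  tw <- alpha + gamma
  phi <- (gamma - alpha) / 2
  # The ZYZ branch cuts can shift tw by a full turn; restoring it shifts the
  # bend phase by half a turn (the (Gamma, phi) <-> (Gamma, phi + pi)
  # ambiguity), so the two are corrected together.
  if (tw > pi) { tw <- tw - 2 * pi; phi <- phi + pi }
  if (tw <= -pi) { tw <- tw + 2 * pi; phi <- phi + pi }
  phi <- atan2(sin(phi), cos(phi))
  tl <- gam * sin(phi)
  ro <- gam * cos(phi)
  Tm <- rot_z(tw / 2 - phi) %*% rot_y(gam / 2) %*% rot_z(phi)
  d <- crossprod(Tm, a[1:3, 4])
  step_params(tilt = tl / DEG, roll = ro / DEG, twist = tw / DEG,
              shift = d[1], slide = d[2], rise = d[3])
}

check_rotation <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("rotation block is not orthonormal with determinant +1")
  invisible(R)
}

# Polar re-orthonormalization for long serial products (D-S4 style repair).
orthonormalize <- function(A) {
  s <- svd(A[1:3, 1:3])
  A[1:3, 1:3] <- s$u %*% t(s$v)
  A
}

#' Serial product of step transforms
#'
#' Left-to-right product of a list of 4x4 homogeneous generator matrices,
#' i.e. the accumulated transform of a chain of base-pair steps. The empty
#' list composes to the identity. Long products are re-orthonormalized by
#' polar decomposition when the rotation block drifts beyond 1e-9.
#'
#' @param transforms List of 4x4 matrices (ordered 5' to 3').
#' @return A 4x4 homogeneous matrix.
#' @export
compose_transforms <- function(transforms) {
  A <- Reduce(`%*%`, transforms, accumulate = FALSE, right = FALSE,
              init = diag(4))
  drift <- max(abs(crossprod(A[1:3, 1:3]) - diag(3)))
  if (drift > 1e-9) A <- orthonormalize(A)
  A
}

#' Transform of a whole step list
#'
#' Convenience wrapper: converts an n x 6 step table to its accumulated
#' 4x4 transform.
#'
#' @param steps Step table ([step_params()] rows).
#' @return A 4x4 homogeneous matrix.
#' @export
steps_to_transform <- function(steps) {
  m <- as_step_matrix(steps)
  compose_transforms(lapply(seq_len(nrow(m)), function(i)
    params_to_transform(m[i, ])))
}

#' End-to-end closure metrics of an accumulated transform
#'
#' Measures how far an accumulated chain transform is from perfect closure:
#' the end-to-end vector `r`, the bend `gamma` between the first and last
#' base-pair normals, and the residual end-to-end twist `phi`. The net
#' rotation is factored as (bend about the common perpendicular of the two
#' normals) followed by (twist about the normal); `phi` is the twist part,
#' which for pure-twist chains equals the algebraic twist sum reduced to
#' (-180, 180].
#'
#' @param a A 4x4 accumulated transform.
#' @return A list of class `closure_metrics` with elements `r` (3-vector, A),
#'   `r_norm`, `gamma` and `phi` (degrees), and `cos_gamma`, `cos_phi`.
#' @export
end_metrics <- function(a) {
  stopifnot(is.matrix(a), all(dim(a) == c(4, 4)))
  R <- a[1:3, 1:3]
  r <- a[1:3, 4]
  cg <- max(-1, min(1, R[3, 3]))
  gam <- acos(cg)
  zz <- R[, 3]
  ax <- c(-zz[2], zz[1], 0)     # e_z x z'
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    Rtw <- R
  } else {
    ax <- ax / s
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    Rb <- diag(3) + sin(gam) * K + (1 - cos(gam)) * (K %*% K)
    Rtw <- crossprod(Rb, R)
  }
  phi <- atan2(Rtw[2, 1] - Rtw[1, 2], Rtw[1, 1] + Rtw[2, 2])
  structure(list(r = r, r_norm = sqrt(sum(r^2)),
                 gamma = gam / DEG, phi = phi / DEG,
                 cos_gamma = cg, cos_phi = cos(phi)),
            class = "closure_metrics")
}

#' Elastic parameters of the ideal fluctuating duplex
#'
#' Intrinsic values and Gaussian fluctuation widths of the six step
#' parameters for an ideal, inextensible, naturally straight B-DNA chain.
#' Bending (tilt and roll) is isotropic with standard deviation
#' `sqrt(rise / persistence)` radians per step, which makes the simulated
#' bending-correlation persistence length equal to `persistence`; twisting is
#' independent with its own width; the translations are frozen at the B-form
#' rest values (0, 0, rise).
#'
#' @param persistence Target bending persistence length in Angstroms.
#' @param twist_sd Twist fluctuation width in degrees per step.
#' @param rise Intrinsic rise in Angstroms.
#' @param helical_repeat Intrinsic repeat in bp/turn (sets intrinsic twist).
#' @return An object of class `elastic_params`: list with `intrinsic` and
#'   `sigma` 6-vectors (degrees / Angstroms; `sigma = 0` marks frozen modes).
#' @export
elastic_params <- function(persistence = 500, twist_sd = 4.3,
                           rise = 3.4, helical_repeat = 10.5) {
  stopifnot(persistence > 0, twist_sd >= 0, rise > 0, helical_repeat > 0)
  sb <- sqrt(rise / persistence) / DEG
  structure(list(
    intrinsic = c(tilt = 0, roll = 0, twist = 360 / helical_repeat,
                  shift = 0, slide = 0, rise = rise),
    sigma = c(tilt = sb, roll = sb, twist = twist_sd,
              shift = 0, slide = 0, rise = 0)),
    class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat("elastic base-pair-step model\n")
  cat(sprintf("  intrinsic: twist %.4f deg, rise %.2f A (%.2f bp/turn)\n",
              x$intrinsic["twist"], x$intrinsic["rise"],
              360 / x$intrinsic["twist"]))
  cat(sprintf("  sigma: tilt/roll %.4f deg, twist %.4f deg; translations frozen\n",
              x$sigma["tilt"], x$sigma["twist"]))
  invisible(x)
}

#' Elastic energy of one base-pair step
#'
#' Quadratic deformation energy `psi = 1/2 sum f_i (theta_i - theta0_i)^2`
#' in units of kT, with diagonal stiffnesses `f_i = 1 / sigma_i^2` for the
#' fluctuating modes. Frozen modes (sigma = 0) carry no energy term.
#'
#' @param p One step (6-vector or one-row table).
#' @param e An [elastic_params()] object.
#' @return Energy in kT (non-negative; zero at the rest state).
#' @export
step_energy <- function(p, e) {
  stopifnot(inherits(e, "elastic_params"))
  m <- as_step_matrix(p)
  active <- e$sigma > 0
  dev <- sweep(m[, step_cols, drop = FALSE], 2, e$intrinsic[step_cols])
  z <- sweep(dev[, active, drop = FALSE], 2, e$sigma[active], "/")
  as.numeric(0.5 * rowSums(z^2))
}

#' Read a 3DNA-style step-parameter file
#'
#' Plain-text format: optional '#' comment lines, a header line with the step
#' count, then one line per step with six whitespace-separated values in the
#' order shift, slide, rise, tilt, roll, twist (the usual *.par column
#' order).
#'
#' @param path File to read.
#' @return A step-parameter `data.frame`.
#' @export
read_step_params <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 1) stop("no data in step-parameter file: ", path)
  hdr <- suppressWarnings(as.integer(trimws(lines[idx[1]])))
  if (is.na(hdr))
    stop("line ", idx[1], ": header must be the step count")
  body <- idx[-1]
  if (length(body) != hdr)
    stop("header declares ", hdr, " steps but file has ", length(body))
  vals <- matrix(NA_real_, hdr, 6)
  for (k in seq_along(body)) {
    f <- strsplit(trimws(lines[body[k]]), "\\s+")[[1]]
    if (length(f) != 6)
      stop("line ", body[k], ": expected 6 columns, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("line ", body[k], ": non-numeric field")
    vals[k, ] <- v
  }
  step_params(tilt = vals[, 4], roll = vals[, 5], twist = vals[, 6],
              shift = vals[, 1], slide = vals[, 2], rise = vals[, 3])
}

#' Write a 3DNA-style step-parameter file
#'
#' @param steps Step table.
#' @param path Output file.
#' @param comment Optional character vector written as '#' header lines.
#' @return `path`, invisibly.
#' @export
write_step_params <- function(steps, path, comment = NULL) {
  m <- as_step_matrix(steps)
  out <- character(0)
  if (!is.null(comment)) out <- paste("#", comment)
  out <- c(out, as.character(nrow(m)))
  out <- c(out, apply(m[, c("shift", "slide", "rise",
                            "tilt", "roll", "twist"), drop = FALSE], 1,
                      function(v) paste(sprintf("%10.4f", v), collapse = " ")))
  writeLines(out, path)
  invisible(path)
}
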