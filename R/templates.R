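# Protein-bound DNA geometry: 14-step HU bending templates, 13-step operator
# segments, and the joining-step end conditions that close a loop against the
# tetrameric repressor in one of four orientations (A1/A2/P1/P2) at an
# opening angle dalpha.
#
# Crystal-derived step parameters are not redistributable here, so the
# package ships *synthetic* stand-ins generated from documented geometric
# models; every such artifact is labelled "synthetic" in file names and
# headers. The machinery (strand flips, bend measurement, end-condition
# construction) is identical for synthetic and user-supplied crystal tables.

LOOP_TYPES <- c("A1", "A2", "P1", "P2")
HU_FOOTPRINT <- 14L   # protein-bound steps per bound dimer
OPERATOR_STEPS <- 13L # steps bound to each repressor headpiece
RIGID_INNER_BP <- 7L  # inner-half operator bp counted inside the loop

#' Reverse a step list along the chain
#'
#' Applies the standard direction-reversal rule for base-pair step
#' parameters: the step order is reversed and tilt and shift change sign
#' (roll, twist, slide, rise are chain-direction independent in the mid-step
#' convention). Applying the flip twice restores the input.
#'
#' @param steps Step table.
#' @return Step table of the same size.
#' @export
strand_flip <- function(steps) {
  m <- as_step_matrix(steps)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[, "tilt"] <- -m[, "tilt"]
  m[, "shift"] <- -m[, "shift"]
  as.data.frame(m)
}

# Local helical axis of one step: the rotation axis of its generator,
# oriented along the direction of positive twist advance.
local_helical_axis <- function(p) {
  A <- params_to_transform(p)
  R <- A[1:3, 1:3]
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0, 1))  # identity step: take the normal
  v <- v / n
  if (v[3] < 0) v <- -v
  v
}

#' Overall bend of a protein-bound DNA template
#'
#' Angle between the entry and exit helical-axis directions of a step list:
#' each terminal direction is the average of the local helical axes of the
#' two outermost steps, expressed in the global frame of the chain.
#'
#' @param steps Step table with at least 3 steps.
#' @return Bend angle in degrees.
#' @export
overall_bend <- function(steps) {
  m <- as_step_matrix(steps)
  n <- nrow(m)
  if (n < 3) stop("overall_bend needs at least 3 steps")
  frames <- reconstruct_frames(m)
  axis_global <- function(i) frames$axes[, , i] %*% local_helical_axis(m[i, ])
  a1 <- axis_global(1) + axis_global(2)
  a2 <- axis_global(n - 1) + axis_global(n)
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- a2 / sqrt(sum(a2^2))
  acos(max(-1, min(1, sum(a1 * a2)))) / DEG
}

#' Synthetic HU bending template
#'
#' Builds a 14-step protein-bound template that bends the helix by
#' `total_bend` degrees and unwinds it by `net_untwist` degrees, emulating
#' the sharp, kinked deformation an HU dimer imposes. The bend is spread as
#' a planar arc over the ten core steps (3-12) by phasing tilt/roll against
#' the accumulated helical twist; the terminal two steps at each end stay at
#' the B-form rest state so the flanking helical axes are well defined. The
#' untwist is distributed evenly over the same core steps. The deflection
#' amplitude is solved numerically so that [overall_bend()] of the result
#' matches the request to well within 2 degrees.
#'
#' @param total_bend Requested overall bend in degrees, in [0, 150].
#' @param net_untwist Total twist deficit in degrees (shared over the core).
#' @param id Template identifier stored in the `id` attribute.
#' @return A 14-row step table with attributes `id`, `variant`, `bend`.
#' @export
make_hu_fixture <- function(total_bend, net_untwist = 0, id = "HU-synthetic") {
  if (!is.finite(total_bend) || total_bend < 0 || total_bend > 150)
    stop("total_bend must be in [0, 150] degrees")
  core <- 3:12
  build <- function(b) {
    tw0 <- 360 / 10.5
    tw <- rep(tw0, HU_FOOTPRINT)
    tw[core] <- tw0 - net_untwist / length(core)
    tilt <- roll <- rep(0, HU_FOOTPRINT)
    # accumulated twist to the mid-frame of each core step sets the phase
    # that keeps the per-step deflections in a common bending plane
    cum <- cumsum(c(0, tw))[seq_len(HU_FOOTPRINT)] + tw / 2
    ph <- cum[core] * DEG
    roll[core] <- b * cos(ph)
    tilt[core] <- b * sin(ph)
    step_params(tilt = tilt, roll = roll, twist = tw, rise = 3.4)
  }
  if (total_bend < 1e-9) {
    out <- build(0)
  } else {
    f <- function(b) overall_bend(build(b)) - total_bend
    b <- stats::uniroot(f, c(0, 20), extendInt = "upX", tol = 1e-8)$root
    out <- build(b)
  }
  attr(out, "id") <- id
  attr(out, "variant") <- "fwd"
  attr(out, "bend") <- overall_bend(out)
  out
}

# The four synthetic source templates: bends chosen inside the 112-129 deg
# range characteristic of crystal HU-DNA complexes, with untwists of the
# order seen in those kinked structures. Fixed once; see the methods
# vignette.
hu_synthetic_specs <- function() {
  data.frame(id = c("HUsynA", "HUsynB", "HUsynC", "HUsynD"),
             bend = c(113, 118, 123, 128),
             untwist = c(15, 18, 21, 24))
}

#' The eight HU template variants
#'
#' Returns the full set of HU-bound DNA templates used by the sampler: each
#' source template in both strand orientations (a bound dimer can sit on
#' either strand), giving eight variants. With `source = "synthetic"` the
#' four packaged synthetic templates are used; a directory of 3DNA-style
#' `.par` files (14 steps each) can be supplied instead.
#'
#' @param source `"synthetic"` or a directory containing `*.par` templates.
#' @return A list of `hu_template` objects (step tables with `id`,
#'   `variant`, `bend` attributes).
#' @export
hu_template_set <- function(source = "synthetic") {
  if (identical(source, "synthetic")) {
    sp <- hu_synthetic_specs()
    base <- lapply(seq_len(nrow(sp)), function(i)
      make_hu_fixture(sp$bend[i], sp$untwist[i], id = sp$id[i]))
  } else {
    files <- sort(list.files(source, pattern = "\\.par$", full.names = TRUE))
    if (length(files) == 0) stop("no .par templates found in ", source)
    base <- lapply(files, function(f) {
      s <- read_step_params(f)
      if (nrow(s) != HU_FOOTPRINT)
        stop("HU template ", f, " must have exactly ", HU_FOOTPRINT, " steps")
      attr(s, "id") <- sub("\\.par$", "", basename(f))
      attr(s, "variant") <- "fwd"
      attr(s, "bend") <- overall_bend(s)
      s
    })
  }
  out <- list()
  for (b in base) {
    r <- strand_flip(b)
    attr(r, "id") <- attr(b, "id")
    attr(r, "variant") <- "rev"
    attr(r, "bend") <- overall_bend(r)
    out <- c(out, list(b, r))
  }
  names(out) <- vapply(out, function(x)
    paste(attr(x, "id"), attr(x, "variant"), sep = "."), "")
  out
}

#' Operator segments bound to the repressor headpieces
#'
#' The two 13-step DNA segments held rigid by the repressor headpieces. In
#' the absence of a structure with both natural operators the segments are
#' taken congruent (the symmetrized high-affinity operator geometry); the
#' packaged synthetic segments are straight B-form. The inner 7 bp of each
#' segment (6 steps) lie inside the counted loop; the remaining outer steps
#' sit beyond the loop ends, inside the joining condition.
#'
#' @param source `"synthetic"` or a `.par` file with 13 steps.
#' @return A list with `o3` and `o1` step tables, each carrying an
#'   `inner_steps` attribute marking the steps inside the counted loop.
#' @export
operator_segments <- function(source = "synthetic") {
  if (identical(source, "synthetic")) {
    seg <- step_params(tilt = rep(0, OPERATOR_STEPS), roll = 0,
                       twist = 360 / 10.5, rise = 3.4)
  } else {
    if (!file.exists(source)) stop("operator step-parameter file not found: ",
                                   source)
    seg <- read_step_params(source)
    if (nrow(seg) != OPERATOR_STEPS)
      stop("operator segment must have ", OPERATOR_STEPS, " steps")
  }
  inner <- RIGID_INNER_BP - 1L  # steps among the inner 7 bp
  o3 <- seg; attr(o3, "id") <- "O3-side"; attr(o3, "inner_steps") <- seq_len(inner)
  o1 <- seg; attr(o1, "id") <- "O1-side"
  attr(o1, "inner_steps") <- seq.int(OPERATOR_STEPS - inner + 1L, OPERATOR_STEPS)
  list(o3 = o3, o1 = o1)
}

# --- synthetic V-shaped tetramer geometry -------------------------------

# Parameters of the synthetic repressor model (fixed once, documented in the
# methods vignette): arm length from the four-helix-bundle tip to each
# operator centre, the half-angle of the V, and the pitch of the bound
# operators' helical axes out of the inter-arm direction (the bound DNA
# curves away from the headpieces, so loops leave over the open top of the
# V rather than straight across it).
LACR_ARM_LENGTH <- 80
LACR_HALF_ANGLE <- 25
LACR_OPERATOR_PITCH <- 0
LACR_OPERATOR_SKEW <- 0.18  # out-of-V-plane tangent component (both ends);
                            # keeps joining rotations away from the 180-deg
                            # parametrization singularity at every dalpha

#' Intermediate arm frame of the repressor
#'
#' The coordinate frame embedded in one dimeric arm of the V-shaped
#' assembly, about whose y-axis the opening rotation `dalpha` acts. In the
#' synthetic model the origin sits at the tip of the V (where the
#' tetramerization bundle holds the arms), the V lies in the xz-plane with
#' its symmetry axis along z, and y is the V-plane normal oriented so that
#' positive `dalpha` opens the assembly.
#'
#' @return A 4x4 homogeneous matrix (columns = x, y, z axes and origin).
#' @export
lacr_frame <- function() {
  F <- diag(4)
  F[1:3, 1] <- c(1, 0, 0)
  F[1:3, 2] <- c(0, -1, 0)
  F[1:3, 3] <- c(0, 0, -1)
  F
}

# Base-pair frames at the two operator centres of the closed (dalpha = 0)
# synthetic assembly. eps = +1 points the operator toward the V interior.
lacr_operator_frames <- function() {
  b <- LACR_HALF_ANGLE * DEG
  ch <- cos(LACR_OPERATOR_PITCH * DEG)
  sh <- sin(LACR_OPERATOR_PITCH * DEG)
  u1 <- c(sin(b), 0, cos(b))    # arm holding the chain-end operator (O1 side)
  u2 <- c(-sin(b), 0, cos(b))   # arm holding the chain-start operator (O3)
  frame_at <- function(origin, z) {
    z <- z / sqrt(sum(z^2))
    y0 <- c(0, 1, 0)
    x <- c(y0[2] * z[3] - y0[3] * z[2],
           y0[3] * z[1] - y0[1] * z[3],
           y0[1] * z[2] - y0[2] * z[1])
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    A <- diag(4)
    A[1:3, 1] <- x; A[1:3, 2] <- y; A[1:3, 3] <- z; A[1:3, 4] <- origin
    A
  }
  sk <- LACR_OPERATOR_SKEW
  # tangents: in-plane inter-arm component (sign eps: toward/away from the
  # interior) pitched toward the open top of the V, with a common
  # out-of-plane skew
  list(
    start = function(eps) frame_at(LACR_ARM_LENGTH * u2,
                                   eps * ch * c(cos(b), 0, sin(b)) +
                                     sh * c(0, 0, 1) + sk * c(0, 1, 0)),
    end = function(eps) frame_at(LACR_ARM_LENGTH * u1,
                                 eps * ch * c(cos(b), 0, -sin(b)) +
                                   sh * c(0, 0, 1) + sk * c(0, 1, 0)))
}

# eps signs per loop type: eps_start (O3 toward inside = +1 -> "1" types),
# eps_end chosen so A types are antiparallel, P types parallel.
loop_type_signs <- function(loop_type) {
  switch(loop_type,
         A1 = c(start = 1, end = -1),
         A2 = c(start = -1, end = 1),
         P1 = c(start = 1, end = 1),
         P2 = c(start = -1, end = -1),
         stop("unknown loop type: ", loop_type))
}

#' Repressor end condition for one loop orientation and opening angle
#'
#' The joining-step geometry that closes a loop of a given orientation: the
#' homogeneous transform (equivalently six step parameters) expressing the
#' frame of the loop's first base pair, at the centre of the entry operator,
#' in the frame of its last base pair at the centre of the exit operator.
#' Opening by `dalpha` rotates the entry arm rigidly about the y-axis of
#' [lacr_frame()], so the end condition at any angle is the closed-form
#' conjugation of the `dalpha = 0` condition; the construction is continuous
#' in `dalpha` and the implied operator separation grows monotonically with
#' it.
#'
#' @param loop_type One of `"A1", "A2", "P1", "P2"` (antiparallel/parallel,
#'   entry operator pointing toward/away from the assembly interior).
#' @param dalpha Opening angle in degrees, within `[0, dalpha_limit]`.
#' @param dalpha_limit Configurable upper bound (default 120).
#' @return An object of class `end_condition`: list with `loop_type`,
#'   `dalpha`, the 4x4 `transform`, and its `params` step-parameter row.
#' @export
lacr_end_condition <- function(loop_type, dalpha = 0, dalpha_limit = 120) {
  loop_type <- match.arg(loop_type, LOOP_TYPES)
  if (!is.finite(dalpha) || dalpha < 0 || dalpha > dalpha_limit)
    stop("dalpha must be in [0, ", dalpha_limit, "] degrees")
  eps <- loop_type_signs(loop_type)
  fr <- lacr_operator_frames()
  S0 <- fr$start(eps["start"])
  E <- fr$end(eps["end"])
  F <- lacr_frame()
  rot <- diag(4)
  rot[1:3, 1:3] <- F[1:3, 1:3] %*% rot_y(dalpha * DEG) %*% t(F[1:3, 1:3])
  # arm frame origin is the global origin, so no translation conjugation
  S <- rot %*% S0
  J <- solve(E) %*% S
  structure(list(loop_type = loop_type, dalpha = dalpha,
                 transform = J, params = transform_to_params(J)),
            class = "end_condition")
}

#' @export
print.end_condition <- function(x, ...) {
  cat(sprintf("end condition %s at dalpha = %g deg\n", x$loop_type, x$dalpha))
  p <- x$params
  cat(sprintf("  joining step: tilt %.2f roll %.2f twist %.2f deg; r = %.2f A\n",
              p$tilt, p$roll, p$twist, sqrt(sum(x$transform[1:3, 4]^2))))
  invisible(x)
}

#' Tabulated end conditions over a grid of opening angles
#'
#' Evaluates [lacr_end_condition()] on a `dalpha` grid for all four loop
#' orientations and returns the joining-step parameters as a tidy table;
#' the packaged CSV `inst/extdata/lacr_end_conditions_synthetic.csv` is this
#' table at a 10-degree grid.
#'
#' @param dalpha Numeric vector of opening angles (degrees).
#' @return A `data.frame` with columns `loop_type, dalpha, tilt, ..., rise`.
#' @export
lacr_end_condition_table <- function(dalpha = seq(0, 120, by = 10)) {
  rows <- lapply(LOOP_TYPES, function(lt) {
    do.call(rbind, lapply(dalpha, function(a) {
      p <- lacr_end_condition(lt, a)$params
      cbind(data.frame(loop_type = lt, dalpha = a), p)
    }))
  })
  do.call(rbind, rows)
}

#' Packaged synthetic end-condition table
#'
#' Reads the CSV shipped with the package (a synthetic stand-in for a
#' crystal-derived joining-parameter table).
#'
#' @return A `data.frame` as from [lacr_end_condition_table()].
#' @export
packaged_end_condition_table <- function() {
  path <- system.file("extdata", "lacr_end_conditions_synthetic.csv",
                      package = "loopmc")
  if (!nzchar(path)) stop("packaged end-condition table not found")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
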