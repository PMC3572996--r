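# Coordinate reconstruction of sampled configurations and results
# serialization. Base-pair frames and PDB output are 1-based; step indices
# are 1-based throughout the R interfaces.

#' Reconstruct base-pair frames from step parameters
#'
#' Frame n+1 is frame n advanced by the generator of step n; the first frame
#' is the identity at the origin. An empty step list yields the single
#' identity frame.
#'
#' @param steps Step table (possibly zero rows).
#' @return List with `origins` ((n+1) x 3 matrix, A) and `axes`
#'   (3 x 3 x (n+1) array; columns of each slice are the frame x, y, z axes).
#' @export
reconstruct_frames <- function(steps) {
  m <- if (is.null(steps) || (is.data.frame(steps) && nrow(steps) == 0))
    matrix(numeric(0), 0, 6, dimnames = list(NULL, step_cols))
  else as_step_matrix(steps)
  raw <- cpp_steps_to_frames(deg_to_rad_steps(m))
  n1 <- nrow(raw)
  origins <- raw[, 10:12, drop = FALSE]
  colnames(origins) <- c("x", "y", "z")
  axes <- array(0, c(3, 3, n1))
  for (i in seq_len(n1))
    axes[, , i] <- matrix(raw[i, 1:9], 3, 3, byrow = TRUE)
  list(origins = origins, axes = axes)
}

deg_to_rad_steps <- function(m) {
  m[, c("tilt", "roll", "twist")] <- m[, c("tilt", "roll", "twist")] * DEG
  m
}

#' Write a reconstructed structure to disk
#'
#' Writes two plain-text artifacts for one configuration: `<path>.par`, a
#' 3DNA-style step-parameter file re-loadable with [read_step_params()], and
#' `<path>.pdb`, a minimal pseudo-atom trace with one atom per base-pair
#' origin (1-based residue numbering). Annotations tag residues by segment:
#' a named list of 1-based base-pair index vectors (e.g.
#' `list(operator = 1:7, HU = 20:34)`) written to the PDB segment/chain
#' fields so protein footprints are recoverable from the trace.
#'
#' @param steps Step table of the configuration.
#' @param path Output path prefix (without extension).
#' @param annotations Optional named list of base-pair index vectors.
#' @return Invisibly, the two file paths.
#' @export
write_structure <- function(steps, path, annotations = NULL) {
  m <- as_step_matrix(steps)
  par_path <- paste0(path, ".par")
  pdb_path <- paste0(path, ".pdb")
  write_step_params(m, par_path,
                    comment = "loopmc reconstructed configuration")
  fr <- reconstruct_frames(m)
  n <- nrow(fr$origins)
  seg <- rep("DNA", n)
  if (!is.null(annotations))
    for (nm in names(annotations))
      seg[annotations[[nm]]] <- substr(nm, 1, 4)
  con <- file(pdb_path, "w")
  on.exit(close(con))
  writeLines("REMARK   loopmc pseudo-atom trace: one atom per base-pair origin",
             con)
  for (i in seq_len(n)) {
    writeLines(sprintf(
      "ATOM  %5d  CA  BPS A%4d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s C",
      i, i, fr$origins[i, 1], fr$origins[i, 2], fr$origins[i, 3], seg[i]), con)
  }
  writeLines("END", con)
  invisible(c(par = par_path, pdb = pdb_path))
}

#' Read a pseudo-atom trace written by [write_structure()]
#'
#' @param path PDB file path.
#' @return Matrix of atom coordinates (n x 3).
#' @export
read_structure_trace <- function(path) {
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  xyz <- t(vapply(lines, function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))),
    numeric(3)))
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  xyz
}

#' Serialize an ensemble result to JSON
#'
#' Embeds everything needed to reproduce the run: the full configuration
#' echo (chain length, mode, criteria, elastic constants, template sources,
#' grids), the seed, package version, and the summary observables; accepted
#' records are included as a table.
#'
#' @param ens A `loop_ensemble` object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ens, path) {
  stopifnot(inherits(ens, "loop_ensemble"))
  cfg <- ens$config
  out <- list(
    package = "loopmc",
    version = as.character(utils::packageVersion("loopmc")),
    kind = ens$kind,
    config = list(
      n_bp = cfg$n_bp, hu_density = cfg$hu_density, mode = cfg$mode,
      samples = cfg$samples, n_half = cfg$n_half, seed = cfg$seed,
      dalpha_max = cfg$dalpha_max, dalpha_step = cfg$dalpha_step,
      loop_types = cfg$loop_types,
      criteria = unclass(cfg$criteria),
      elastic = lapply(unclass(cfg$elastic), as.list),
      hu_source = cfg$hu_source, operator_source = cfg$operator_source),
    samples = ens$samples, accepted = ens$accepted,
    J = ens$J, se = ens$se,
    f_loop = as.list(ens$f_loop), f_hu = as.list(ens$f_hu),
    dalpha_mean = ens$dalpha_mean,
    records = ens$records)
  # digits = I(17): significant digits sufficient for exact IEEE-754
  # round-trip, so a re-read config reproduces the run bit-for-bit
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Reconstructs a [sampler_config()] from the `config` block of a results
#' file (or a bare config file with the same fields), so a run can be
#' reproduced bit-for-bit in direct mode.
#'
#' @param path JSON file.
#' @return A `sampler_config` object.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- if (!is.null(j$config)) j$config else j
  sampler_config(
    n_bp = cfg$n_bp, hu_density = cfg$hu_density, mode = cfg$mode,
    samples = cfg$samples, n_half = cfg$n_half, seed = cfg$seed,
    dalpha_max = cfg$dalpha_max, dalpha_step = cfg$dalpha_step,
    loop_types = cfg$loop_types,
    criteria = closure_criteria(cfg$criteria$r_max,
                                cfg$criteria$cos_gamma_min,
                                cfg$criteria$cos_phi_min),
    elastic = {
      e <- elastic_params()
      e$intrinsic[] <- unlist(cfg$elastic$intrinsic)
      e$sigma[] <- unlist(cfg$elastic$sigma)
      e
    },
    hu_source = cfg$hu_source, operator_source = cfg$operator_source)
}
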