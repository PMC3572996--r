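# Thermodynamic bridge between looping J factors and gene-repression
# measurements: operator-occupancy partition function, reporter activity,
# and concentration bookkeeping.

#' Repression model constants
#'
#' Binding constants of the repressor for the two operators of the reporter
#' construct and the free repressor (tetramer) concentration. Defaults are
#' the wild-type values used to interpret the expression data: a
#' high-affinity symmetrized upstream operator, the natural promoter-proximal
#' operator, and ten tetramers in a 0.16 um^3 nucleoid.
#'
#' @param K_Osym Binding constant to the upstream operator (1/M).
#' @param K_O2 Binding constant to the promoter-proximal operator (1/M).
#' @param lacr Repressor tetramer concentration (M).
#' @return Object of class `repression_model`.
#' @export
repression_model <- function(K_Osym = 1.3e9, K_O2 = 3.6e7,
                             lacr = molar_concentration(10, 0.16)) {
  stopifnot(K_Osym > 0, K_O2 > 0, lacr > 0)
  structure(list(K_Osym = K_Osym, K_O2 = K_O2, lacr = lacr),
            class = "repression_model")
}

#' Reporter activity from a looping J factor
#'
#' Partition-function expression for the reporter activity E', the ratio of
#' reporter output of a two-operator (loopable) construct to a
#' single-operator construct. Activity is proportional to the probability
#' that the promoter-proximal operator is free; enumerating the states of
#' the two-operator construct (empty; either operator singly bound; both
#' bound by two repressors; both bridged by one looped repressor, weighted
#' by J) gives
#' `E' = (1 + aR)(1 + bR) / (1 + aR + bR + abR^2 + abRJ)`
#' with `a = K_Osym`, `b = K_O2`, `R = [LacR]`. At `J = 0` the numerator
#' factorizes into the denominator and E' = 1 (independent operators, no
#' looping-mediated repression); E' decreases strictly with J.
#'
#' @param J Looping J factor(s), molar, >= 0.
#' @param model A [repression_model()].
#' @return Reporter activity E' in (0, 1].
#' @export
reporter_from_j <- function(J, model = repression_model()) {
  stopifnot(inherits(model, "repression_model"), all(J >= 0))
  a <- model$K_Osym; b <- model$K_O2; R <- model$lacr
  (1 + a * R) * (1 + b * R) /
    (1 + a * R + b * R + a * b * R^2 + a * b * R * J)
}

#' Looping J factor from a measured reporter activity
#'
#' Closed-form inverse of [reporter_from_j()]:
#' `J = (1 + aR)(1 + bR)(1 - E') / (E' a b R)`. Activities above the J = 0
#' ceiling (E' > 1) are unattainable and raise an error.
#'
#' @param Eprime Reporter activity in (0, 1].
#' @param model A [repression_model()].
#' @return J factor(s) in molar units.
#' @export
j_from_reporter <- function(Eprime, model = repression_model()) {
  stopifnot(inherits(model, "repression_model"))
  if (any(Eprime <= 0) || any(Eprime > 1))
    stop("reporter activity must lie in (0, 1]: values above 1 are ",
         "unattainable (the J = 0 ceiling)")
  a <- model$K_Osym; b <- model$K_O2; R <- model$lacr
  (1 + a * R) * (1 + b * R) * (1 - Eprime) / (Eprime * a * b * R)
}

#' Molar concentration from a copy number and volume
#'
#' `n / (N_A V)` with the volume given in cubic micrometres
#' (1 um^3 = 1e-15 L). Ten copies in a 0.16 um^3 nucleoid give 103.8 nM.
#'
#' @param copy_number Molecule count (>= 0).
#' @param volume_um3 Volume in um^3 (> 0).
#' @return Concentration in molar units.
#' @export
molar_concentration <- function(copy_number, volume_um3) {
  stopifnot(copy_number >= 0)
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  copy_number / (AVOGADRO * volume_um3 * 1e-15)
}

#' Convert a table of reporter activities to J factors
#'
#' Tidy wrapper for expression datasets: takes rows of (N, E') and returns
#' rows of (N, J).
#'
#' @param data `data.frame` with columns `N` and `Eprime` (extra columns,
#'   e.g. strain labels, are carried through).
#' @param model A [repression_model()].
#' @return The input with a `J` column appended.
#' @export
convert_expression <- function(data, model = repression_model()) {
  stopifnot(is.data.frame(data), all(c("N", "Eprime") %in% names(data)))
  data$J <- j_from_reporter(data$Eprime, model)
  data
}
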