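# Independent oracles used across the suite. These deliberately avoid the
# package's own construction routes: rotations are composed by Rodrigues'
# axis-angle formula rather than the ZYZ products used internally.

rodrigues <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Mid-step-frame generator built from axis-angle pieces: the net rotation is
# a twist about z split around a bend of magnitude Gamma about an axis in
# the xy-plane at angle phi from y (phi = atan2(tilt, roll)).
oracle_transform <- function(tilt, roll, twist, shift = 0, slide = 0,
                             rise = 0) {
  d <- pi / 180
  gam <- sqrt(tilt^2 + roll^2) * d
  phi <- atan2(tilt, roll)
  tw <- twist * d
  half1 <- rodrigues(c(0, 0, 1), tw / 2 - phi)
  R <- half1 %*% rodrigues(c(0, 1, 0), gam) %*% rodrigues(c(0, 0, 1),
                                                          tw / 2 + phi)
  Tm <- half1 %*% rodrigues(c(0, 1, 0), gam / 2) %*% rodrigues(c(0, 0, 1),
                                                               phi)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- Tm %*% c(shift, slide, rise)
  A
}

random_steps <- function(n, ang = 60, trans = 3) {
  step_params(tilt = runif(n, -ang, ang), roll = runif(n, -ang, ang),
              twist = runif(n, -ang, ang), shift = runif(n, -trans, trans),
              slide = runif(n, -trans, trans), rise = runif(n, -trans, trans))
}

# Exhaustive enumeration of the scan-and-place footprint process on a small
# window: returns the exact probability of each occupancy count.
enumerate_scan_counts <- function(n, p, f) {
  # state: next position i; returns named vector of count probabilities
  memo <- new.env()
  rec <- function(i) {
    key <- as.character(i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n - f + 1) return(c(`0` = 1))
    skip <- rec(i + 1)
    place <- rec(i + f)
    counts <- sort(unique(c(as.integer(names(skip)),
                            as.integer(names(place)) + 1L)))
    out <- vapply(counts, function(k) {
      s <- if (as.character(k) %in% names(skip)) skip[[as.character(k)]] else 0
      q <- if (as.character(k - 1) %in% names(place))
        place[[as.character(k - 1)]] else 0
      (1 - p) * s + p * q
    }, 0)
    names(out) <- counts
    memo[[key]] <- out
    out
  }
  rec(1)
}
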