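#' Design a Butterworth filter as second-order sections
#'
#' Wraps [signal::butter()] and regroups the zero-pole-gain form into a
#' cascade of biquads, which keeps high-order band-pass designs numerically
#' stable near the band edges. `order` is the overall filter order: a
#' band-pass of order 4 has two pole pairs per edge (the MATLAB
#' `butter(2, band)` convention).
#'
#' @param order Overall filter order (even for band-pass designs).
#' @param cutoff_hz Scalar cutoff (low/high-pass) or length-2 band in Hz.
#' @param fs Sampling rate in Hz.
#' @param type One of `"pass"`, `"low"`, `"high"`, `"stop"`.
#' @return An object of class `sos_filter`: list of `Arma` biquad sections.
#' @export
butter_sos <- function(order, cutoff_hz, fs, type = c("pass", "low", "high", "stop")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    bad <- cutoff_hz[cutoff_hz <= 0 | cutoff_hz >= nyq]
    stop("filter edge ", paste(bad, collapse = ", "),
         " Hz outside the open interval (0, ", nyq, ") Hz (fs = ", fs, " Hz)")
  }
  if (type %in% c("pass", "stop")) {
    if (length(cutoff_hz) != 2L) stop("band filters need two cutoff frequencies")
    if (order %% 2L != 0L) stop("band-pass overall order must be even")
    n <- order / 2L
  } else {
    if (length(cutoff_hz) != 1L) stop("low/high-pass filters need one cutoff")
    n <- order
  }
  zpg <- signal::as.Zpg(signal::butter(n, cutoff_hz / nyq, type = type))
  sections <- zpg_to_sos(zpg)
  structure(list(sections = sections, order = order, cutoff_hz = cutoff_hz,
                 fs = fs, type = type),
            class = "sos_filter")
}

# Pair complex-conjugate poles/zeros into real biquad sections. Poles are
# sorted by modulus (closest to the unit circle last) so the most selective
# section runs last; overall gain is applied to the first section.
zpg_to_sos <- function(zpg) {
  pair_up <- function(r) {
    r <- r[order(Mod(r), abs(Im(r)))]
    out <- list()
    while (length(r) > 0L) {
      if (abs(Im(r[1])) > 1e-10) {
        mate <- which.min(abs(r[-1] - Conj(r[1]))) + 1L
        out[[length(out) + 1L]] <- c(r[1], r[mate])
        r <- r[-c(1L, mate)]
      } else if (length(r) > 1L && any(abs(Im(r[-1])) <= 1e-10)) {
        mate <- which(abs(Im(r[-1])) <= 1e-10)[1] + 1L
        out[[length(out) + 1L]] <- c(r[1], r[mate])
        r <- r[-c(1L, mate)]
      } else {
        out[[length(out) + 1L]] <- r[1]
        r <- r[-1L]
      }
    }
    out
  }
  poly_real <- function(roots) Re(poly_from_roots(roots))
  zs <- pair_up(zpg$zero)
  ps <- pair_up(zpg$pole)
  nsec <- max(length(zs), length(ps))
  sections <- vector("list", nsec)
  for (i in seq_len(nsec)) {
    b <- if (i <= length(zs)) poly_real(zs[[i]]) else 1
    a <- if (i <= length(ps)) poly_real(ps[[i]]) else 1
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    if (i == 1L) b <- b * zpg$gain
    sections[[i]] <- list(b = b, a = a)
  }
  sections
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Zero-phase filtering through a second-order-sections cascade
#'
#' Applies each biquad forward-backward ([signal::filtfilt()]), so the net
#' response is zero-phase with squared magnitude. The signal is first
#' odd-extended by about three time constants of the slowest filter corner,
#' which keeps start-up transients out of the returned samples.
#'
#' @param sos An `sos_filter` from [butter_sos()].
#' @param x Numeric signal vector.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  stopifnot(inherits(sos, "sos_filter"))
  n <- length(x)
  padlen <- min(n - 1, max(64, ceiling(3 * sos$fs / min(sos$cutoff_hz))))
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- c(front, x, back)
  for (sec in sos$sections) {
    y <- signal::filtfilt(signal::Arma(b = sec$b, a = sec$a), y)
  }
  y[(padlen + 1):(padlen + n)]
}

#' Causal (single-pass) filtering through a second-order-sections cascade
#' @param sos An `sos_filter` from [butter_sos()].
#' @param x Numeric signal vector.
#' @return Filtered signal, same length as `x`.
#' @export
sos_filter <- function(sos, x) {
  stopifnot(inherits(sos, "sos_filter"))
  for (sec in sos$sections) {
    x <- as.numeric(signal::filter(signal::Arma(b = sec$b, a = sec$a), x))
  }
  x
}
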