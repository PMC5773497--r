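#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak minus scaled undershoot),
#' sampled on a regular grid and normalized to a maximum of 1. With the
#' default parameters the kernel is zero at t = 0 and peaks at about 5 s
#' post-onset.
#'
#' @param params an \linkS4class{HRFParams}.
#' @param dt sampling interval (s), > 0.
#' @return numeric kernel sampled at \code{seq(0, length, by = dt)}, with
#'   the time grid in attribute \code{"time"}.
#' @export
canonicalHrf <- function(params = HRFParams(), dt = 0.1) {
  validObject(params)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stopf("dt must be a single positive number")
  t <- seq(0, params@length, by = dt)
  ## gamma with mode `delay` and dispersion `disp`: shape = delay/disp
  h <- dgamma(t, shape = params@peakDelay / params@peakDispersion,
              scale = params@peakDispersion) -
    params@undershootRatio *
      dgamma(t, shape = params@undershootDelay / params@undershootDispersion,
             scale = params@undershootDispersion)
  h <- h / max(h)
  attr(h, "time") <- t
  h
}

## Convolve unit sticks at `onsets` (s) with the HRF at microtime
## resolution dt, then sample at the nTR acquisition times 0, tr, 2 tr, ...
## Returns a length-nTR regressor.
.stickRegressor <- function(onsets, nTR, tr, hrf = HRFParams(), dt = 0.1) {
  kern <- canonicalHrf(hrf, dt)
  L <- ceiling((nTR - 1L) * tr / dt) + length(kern) + 1L
  u <- numeric(L)
  if (length(onsets)) {
    idx <- round(onsets / dt) + 1L
    if (any(idx < 1L | idx > L)) stopf("onsets fall outside the run")
    for (i in idx) u[i] <- u[i] + 1
  }
  conv <- stats::convolve(u, rev(kern), type = "open")[seq_len(L)]
  si <- round((seq_len(nTR) - 1L) * tr / dt) + 1L
  conv[si]
}

## Legendre polynomial drift columns (orders 1..order) on [-1, 1].
.legendreDrift <- function(nTR, order = 2) {
  if (order < 1L) return(NULL)
  x <- seq(-1, 1, length.out = nTR)
  polys <- list(x, (3 * x^2 - 1) / 2, (5 * x^3 - 3 * x) / 2)
  out <- do.call(cbind, polys[seq_len(min(order, 3L))])
  colnames(out) <- paste0("drift", seq_len(ncol(out)))
  out
}
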