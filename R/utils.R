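#' somnaffect: sleep-stage suppression analysis of affect and memory
#'
#' See the package DESCRIPTION and the methods vignette
#' (`vignette("somnaffect-methods")`) for an overview of the pipeline.
#'
#' @keywords internal
"_PACKAGE"

# deterministic per-participant substream seed: one global seed expands into
# independent substreams by iterating a 31-bit LCG over (seed, salt, index);
# all products stay below 2^53 so the arithmetic is exact in doubles
substream_seed <- function(seed, index, salt = 0L) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (v in c(as.numeric(salt), as.numeric(index), 97)) {
    h <- (h * 69069 + v + 1) %% m
  }
  as.integer(h)
}

with_substream <- function(seed, index, salt, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, index, salt))
  expr
}

# linear convolution via FFT, returning the "same" central part
# (x convolved with an odd-length symmetric kernel, zero delay);
# padding to a 5-smooth length keeps R's mixed-radix FFT fast
fft_filter_same <- function(x, h) {
  nh <- length(h)
  stopifnot(nh %% 2L == 1L)
  half <- (nh - 1L) / 2L
  # reflect-pad to suppress edge transients
  npad <- min(half, length(x) - 1L)
  xp <- c(rev(x[seq_len(npad) + 1L]), x,
          rev(x[length(x) - seq_len(npad)]))
  n <- length(xp) + nh - 1L
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  H <- stats::fft(c(h, numeric(nfft - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(half + npad + 1L):(half + npad + length(x))]
}

# centered moving average (odd window) via cumulative sums, O(n)
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) / 2L
  n <- length(x)
  xp <- c(rev(x[seq_len(min(half, n - 1L)) + 1L]), x,
          rev(x[n - seq_len(min(half, n - 1L))]))
  cs <- cumsum(c(0, xp))
  (cs[(k + 1L):(length(xp) + 1L)] - cs[1:(length(xp) - k + 1L)]) / k
}

# --- circular statistics -------------------------------------------------

#' Circular mean and resultant vector length
#'
#' Direct summation of unit vectors: the circular mean is the argument of
#' the mean resultant vector and the resultant vector length (RVL) its
#' modulus (1 = perfect concentration, ~0 = uniform).
#'
#' @param phases numeric vector of phases in radians.
#' @return `circ_mean`: mean phase in (-pi, pi]; `circ_rvl`: RVL in [0, 1].
#' @export
circ_mean <- function(phases) {
  if (length(phases) == 0L) return(NA_real_)
  wrap_pi(Arg(mean(exp(1i * phases))))
}

#' @rdname circ_mean
#' @export
circ_rvl <- function(phases) {
  if (length(phases) == 0L) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Wrap-aware circular distance (shorter arc)
#' @param a,b phases in radians.
#' @return absolute angular distance in [0, pi].
#' @export
circ_dist <- function(a, b) {
  abs(wrap_pi(a - b))
}

# wrap to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. Used by the synthetic-data module
#' to plant slow-oscillation phases for coupled spindles.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the uniform circle.
#' @return phases in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 5) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(wrap_pi(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(out)
}

#' Expected resultant vector length of a von Mises distribution
#'
#' The population RVL implied by concentration `kappa`: the Bessel-function
#' ratio I1(kappa) / I0(kappa).
#'
#' @param kappa concentration parameter.
#' @return expected RVL in [0, 1).
#' @export
vonmises_rvl <- function(kappa) {
  besselI(kappa, 1) / besselI(kappa, 0)
}

# Hilbert analytic signal via FFT; Arg() of the result is the instantaneous
# phase with 0 at the positive peak of a cosine and +/-pi at its trough
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# corrected Akaike information criterion
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}
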