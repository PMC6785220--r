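# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
ecog_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "ecog_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_invalid <- function(msg) ecog_error("ecog_invalid_argument", msg)

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# Circular mean direction (radians) of a numeric vector of angles.
circ_mean <- function(x) Arg(mean(exp(1i * x)))

# Mean resultant vector length of a set of angles (0 = dispersed, 1 = aligned).
resultant_length <- function(x) Mod(mean(exp(1i * x)))

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Fourier-domain resampling to an arbitrary number of samples
#'
#' Truncates (anti-aliases) or zero-pads the spectrum, so downsampling
#' applies an ideal low-pass at the new Nyquist frequency.
#' @keywords internal
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  m <- min(n, n_out)
  half <- floor((m - 1) / 2)  # strictly below the shared Nyquist
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  # shared Nyquist bin (even m): split to keep the result real
  if (m %% 2 == 0) {
    k <- m / 2 + 1
    if (n_out > n) {               # upsampling: split the old Nyquist bin
      Y[k] <- X[k] / 2
      Y[n_out - m / 2 + 1] <- Conj(X[k]) / 2
    } else {                       # downsampling: fold +/-Nyquist together
      Y[k] <- 2 * Re(X[k])         # m == n_out
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Analytic signal via FFT (Marple method); even-reflection padding
# suppresses boundary artifacts without injecting a DC step (the input
# is narrowband and approximately zero-mean).
analytic_signal <- function(x, pad = TRUE) {
  n0 <- length(x)
  if (pad) {
    npad <- min(n0 - 1, max(64L, ceiling(n0 / 4)))
    x <- c(rev(x[2:(npad + 1)]), x, rev(x[(n0 - npad):(n0 - 1)]))
  } else npad <- 0L
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(h * stats::fft(x), inverse = TRUE) / n
  z[(npad + 1):(npad + n0)]
}

# Apply a real, zero-phase gain |H(f)| in the Fourier domain with
# reflect padding (gain_fun takes frequencies in Hz, returns gain >= 0).
fft_zero_phase_filter <- function(x, fs, gain_fun) {
  n0 <- length(x)
  npad <- min(n0 - 1, max(64L, ceiling(n0 / 4)))
  xp <- c(rev(2 * x[1] - x[2:(npad + 1)]), x,
          rev(2 * x[n0] - x[(n0 - npad):(n0 - 1)]))
  n <- length(xp)
  freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * fs / n
  g <- gain_fun(abs(freqs))
  y <- Re(stats::fft(g * stats::fft(xp), inverse = TRUE)) / n
  y[(npad + 1):(npad + n0)]
}

# Deterministic per-call RNG scoping: runs expr with the given seed (if any)
# and restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
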