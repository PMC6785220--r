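# Traveling-wave quantification: narrowband filtering, instantaneous
# phase, planar projection, spatial phase gradients, phase-gradient
# directionality (PGD), propagation direction/speed, shuffle nulls, and
# circular statistics.

#' Zero-phase Butterworth band-pass filter
#'
#' Two-pass third-order Butterworth magnitude response applied in the
#' Fourier domain (exactly zero phase), band edges `center +/- fwhm/2`,
#' with reflect padding against boundary artifacts.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param sample_rate Hz.
#' @param center,fwhm band center and width, Hz.
#' @return filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, sample_rate, center, fwhm) {
  f1 <- center - fwhm / 2
  f2 <- center + fwhm / 2
  if (f1 <= 0 || f2 >= sample_rate / 2)
    stop_invalid("band must lie strictly inside (0, Nyquist)")
  f0sq <- f1 * f2
  bw <- f2 - f1
  gain <- function(f) {
    u <- ifelse(f > 0, (f^2 - f0sq) / (f * bw), Inf)
    (1 / (1 + u^(2 * 3)))^2       # |H|^2 per pass, squared for two passes
  }
  if (is.matrix(x))
    apply(x, 2, fft_zero_phase_filter, fs = sample_rate, gain_fun = gain)
  else fft_zero_phase_filter(x, sample_rate, gain)
}

#' Instantaneous phase and amplitude (analytic signal)
#'
#' Hilbert-transform phase of a narrowband signal, edge-padded to
#' suppress boundary artifacts.  Cosine convention: phase 0 at a signal
#' peak.
#'
#' @param filtered numeric vector or samples x channels matrix of
#'   band-limited data.
#' @return list of class `phase_field`: `phase` (radians, in (-pi, pi]),
#'   `amplitude`, same shape as the input.
#' @export
instantaneous_phase <- function(filtered) {
  one <- function(v) analytic_signal(v)
  z <- if (is.matrix(filtered)) vapply(seq_len(ncol(filtered)),
                                       function(j) one(filtered[, j]),
                                       complex(nrow(filtered)))
       else one(filtered)
  structure(list(phase = wrap_pi(Arg(z)), amplitude = Mod(z)),
            class = "phase_field")
}

#' Principal-axes projection of electrode positions
#'
#' Projects 3-D electrode coordinates onto the plane spanned by their
#' first two principal axes.  Planar arrays preserve pairwise distances
#' exactly; axis signs are fixed deterministically.
#'
#' @param positions n x 3 matrix of coordinates (mm), or a data.frame
#'   with `x, y, z` columns.
#' @return list of class `plane_projection`: `coords` (n x 2, mm),
#'   `basis` (3 x 2 orthonormal), `center`.
#' @export
project_to_plane <- function(positions) {
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  if (nrow(positions) < 3) stop_invalid("need >= 3 electrodes")
  ctr <- colMeans(positions)
  X <- sweep(positions, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop_invalid("electrode geometry is collinear or degenerate")
  basis <- sv$v[, 1:2, drop = FALSE]
  co <- X %*% basis
  # the principal axes of (near-)square arrays are rotationally
  # degenerate; fix the in-plane rotation to the lattice orientation
  # (axial mean of nearest-neighbour displacement directions, mod 90 deg)
  ang <- vapply(seq_len(nrow(co)), function(i) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2
    d2[i] <- Inf
    j <- which.min(d2)
    atan2(co[j, 2] - co[i, 2], co[j, 1] - co[i, 1])
  }, 0)
  theta <- Arg(sum(exp(4i * ang))) / 4
  M <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  basis <- basis %*% M
  for (j in 1:2) {                      # deterministic axis orientation
    k <- which.max(abs(basis[, j]))
    if (basis[k, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(coords = X %*% basis, basis = basis, center = ctr),
            class = "plane_projection")
}

#' Azimuth of a 3-D vector in a projection plane
#'
#' Maps a direction vector through the same principal-axes basis as the
#' electrode positions, returning its in-plane azimuth in degrees
#' (0 = first principal axis, counterclockwise).
#'
#' @param projection a [project_to_plane()] result.
#' @param vec3 length-3 direction vector.
#' @export
plane_azimuth <- function(projection, vec3) {
  v <- as.vector(t(projection$basis) %*% vec3)
  (atan2(v[2], v[1]) * 180 / pi) %% 360
}

# Interpolation scaffold: regular grid (step_cm) over the projected
# array, with inverse-distance weights from electrodes within 1.5 grid
# steps.  Phases are interpolated through unit vectors to respect
# circularity.
plane_grid <- function(coords_mm, step_cm = 1) {
  h <- step_cm * 10                     # mm
  xr <- range(coords_mm[, 1]); yr <- range(coords_mm[, 2])
  gx <- seq(xr[1], xr[2], by = h)
  gy <- seq(yr[1], yr[2], by = h)
  nodes <- cbind(x = rep(gx, times = length(gy)),
                 y = rep(gy, each = length(gx)))
  W <- matrix(0, nrow(nodes), nrow(coords_mm))
  for (j in seq_len(nrow(nodes))) {
    d <- sqrt((coords_mm[, 1] - nodes[j, 1])^2 +
              (coords_mm[, 2] - nodes[j, 2])^2)
    near <- d < 1e-6
    if (any(near)) { W[j, near] <- 1 / sum(near); next }
    use <- d <= 1.5 * h
    if (any(use)) W[j, use] <- (1 / d[use]^2) / sum(1 / d[use]^2)
  }
  valid <- rowSums(W) > 0
  list(nodes = nodes, W = W, nx = length(gx), ny = length(gy),
       valid = valid, h_mm = h)
}

#' Spatial phase gradients on the principal-axes plane
#'
#' Interpolates instantaneous phases onto a regular grid (default 1 cm
#' step) via inverse-distance weighting of their unit vectors, then
#' takes circular (wrapped) finite differences along both principal
#' directions.  Positive phase shifts lead the oscillation.
#'
#' @param phase numeric vector (one snapshot, one phase per electrode)
#'   or matrix `[time, channel]` in radians.
#' @param coords electrode coordinates: a [project_to_plane()] result or
#'   an n x 2 matrix (mm).
#' @param step_cm grid step in cm.
#' @return list of class `gradient_field`: `gx`, `gy` (matrices
#'   `[time, node]`, rad/cm, NA where invalid), `valid` (node mask),
#'   `nodes` (node coordinates, mm), `grid` (internal scaffold).
#' @export
phase_gradient <- function(phase, coords, step_cm = 1) {
  if (inherits(coords, "plane_projection")) coords <- coords$coords
  if (!is.matrix(phase)) phase <- matrix(phase, nrow = 1)
  grid <- if (is.list(coords) && !is.null(coords$W)) coords
          else plane_grid(coords, step_cm)
  Z <- exp(1i * phase) %*% t(grid$W)        # time x nodes
  gph <- Arg(Z)
  supported <- grid$valid & colSums(abs(t(grid$W)) > 0) > 0
  nx <- grid$nx; ny <- grid$ny
  nt <- nrow(gph)
  h_cm <- grid$h_mm / 10
  node_ok <- matrix(supported, nx, ny)

  # wrapped one-step differences along each axis, averaged fwd/bwd
  gxm <- array(NA_real_, c(nt, nx, ny))
  gym <- array(NA_real_, c(nt, nx, ny))
  P <- array(gph, c(nt, nx, ny))
  dfx <- wrap_pi(P[, -1, , drop = FALSE] - P[, -nx, , drop = FALSE]) / h_cm
  okx <- node_ok[-1, , drop = FALSE] & node_ok[-nx, , drop = FALSE]
  dim(dfx) <- c(nt, (nx - 1) * ny)
  dfx[, !as.vector(okx)] <- NA
  dim(dfx) <- c(nt, nx - 1, ny)
  dfy <- wrap_pi(P[, , -1, drop = FALSE] - P[, , -ny, drop = FALSE]) / h_cm
  oky <- node_ok[, -1, drop = FALSE] & node_ok[, -ny, drop = FALSE]
  dim(dfy) <- c(nt, nx * (ny - 1))
  dfy[, !as.vector(oky)] <- NA
  dim(dfy) <- c(nt, nx, ny - 1)

  avg2 <- function(a, b) {
    s <- ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b)
    cnt <- (!is.na(a)) + (!is.na(b))
    out <- s / cnt
    out[cnt == 0] <- NA
    out
  }
  if (nx >= 2) {
    if (nx > 2)
      gxm[, 2:(nx - 1), ] <- avg2(dfx[, 2:(nx - 1), , drop = FALSE],
                                  dfx[, 1:(nx - 2), , drop = FALSE])
    gxm[, 1, ] <- dfx[, 1, ]
    gxm[, nx, ] <- dfx[, nx - 1, ]
  }
  if (ny >= 2) {
    if (ny > 2)
      gym[, , 2:(ny - 1)] <- avg2(dfy[, , 2:(ny - 1), drop = FALSE],
                                  dfy[, , 1:(ny - 2), drop = FALSE])
    gym[, , 1] <- dfy[, , 1]
    gym[, , ny] <- dfy[, , ny - 1]
  }

  gx <- matrix(gxm, nt, nx * ny)
  gy <- matrix(gym, nt, nx * ny)
  bad <- !supported
  gx[, bad] <- NA; gy[, bad] <- NA
  structure(list(gx = gx, gy = gy, valid = supported,
                 nodes = grid$nodes, grid = grid),
            class = "gradient_field")
}

#' Phase-gradient directionality
#'
#' Ratio of the norm of the mean spatial gradient to the mean gradient
#' norm: 1 for a perfectly aligned planar wave, near 0 for incoherent
#' gradients.
#'
#' @param grad a [phase_gradient()] result.
#' @param sites optional node subset (indices or logical).
#' @return numeric vector, one PGD in `[0, 1]` per time sample.
#' @export
pgd <- function(grad, sites = NULL) {
  gx <- grad$gx; gy <- grad$gy
  if (!is.null(sites)) { gx <- gx[, sites, drop = FALSE]
                         gy <- gy[, sites, drop = FALSE] }
  if (all(is.na(gx))) stop_invalid("no valid gradient sites")
  mgx <- rowMeans(gx, na.rm = TRUE)
  mgy <- rowMeans(gy, na.rm = TRUE)
  mnorm <- rowMeans(sqrt(gx^2 + gy^2), na.rm = TRUE)
  sqrt(mgx^2 + mgy^2) / mnorm
}

#' Wave propagation direction
#'
#' Azimuth of the negated mean gradient (waves travel from phase-leading
#' to phase-lagging sites), degrees in `[0, 360)` within the projection
#' plane; NA where the mean gradient vanishes.
#'
#' @inheritParams pgd
#' @param tol zero-gradient tolerance (rad/cm).
#' @return numeric vector, one direction per time sample.
#' @export
wave_direction <- function(grad, sites = NULL, tol = 1e-9) {
  gx <- grad$gx; gy <- grad$gy
  if (!is.null(sites)) { gx <- gx[, sites, drop = FALSE]
                         gy <- gy[, sites, drop = FALSE] }
  mgx <- rowMeans(gx, na.rm = TRUE)
  mgy <- rowMeans(gy, na.rm = TRUE)
  out <- (atan2(-mgy, -mgx) * 180 / pi) %% 360
  out[sqrt(mgx^2 + mgy^2) < tol] <- NA
  out
}

#' Wave propagation speed
#'
#' `speed = 2 * pi * f / |grad phi|` (the rhythm's mean frequency over
#' the spatial wavenumber); the median gradient magnitude across sites
#' is used for robustness to near-zero-gradient sites.
#'
#' @param freq rhythm mean frequency, Hz.
#' @inheritParams pgd
#' @param summary `"median"` (default) or `"mean"` across sites.
#' @return numeric vector, speed in cm/s per time sample (NA where the
#'   gradient magnitude vanishes).
#' @export
wave_speed <- function(freq, grad, sites = NULL,
                       summary = c("median", "mean")) {
  summary <- match.arg(summary)
  gx <- grad$gx; gy <- grad$gy
  if (!is.null(sites)) { gx <- gx[, sites, drop = FALSE]
                         gy <- gy[, sites, drop = FALSE] }
  gn <- sqrt(gx^2 + gy^2)
  k <- apply(gn, 1, if (summary == "median") stats::median else mean,
             na.rm = TRUE)
  out <- 2 * pi * freq / k
  out[!is.finite(out) | k <= 0] <- NA
  out
}

#' Permutation null for the mean PGD
#'
#' Compares the observed mean PGD (across time) against PGDs from
#' shuffled data: `time_shuffle` permutes each electrode's phase series
#' independently over time (destroying spatial alignment, preserving
#' per-electrode content); `electrode_shuffle` permutes the assignment
#' of phase series to array positions (destroying spatial structure,
#' preserving temporal structure).
#'
#' @param phase matrix `[time, channel]` of instantaneous phases.
#' @param coords [project_to_plane()] result or n x 2 matrix (mm).
#' @param scheme `"time_shuffle"` or `"electrode_shuffle"`.
#' @param n_perm permutations (>= 100).
#' @param step_cm grid step, cm.
#' @param seed optional RNG seed.
#' @return list: observed mean PGD, null distribution, p (plus-one rule).
#' @export
pgd_null <- function(phase, coords, scheme = c("time_shuffle",
                                               "electrode_shuffle"),
                     n_perm = 200, step_cm = 1, seed = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  if (inherits(coords, "plane_projection")) coords <- coords$coords
  grid <- plane_grid(coords, step_cm)
  mean_pgd <- function(ph) mean(pgd(phase_gradient(ph, grid)), na.rm = TRUE)
  observed <- mean_pgd(phase)
  nt <- nrow(phase); nc <- ncol(phase)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ph <- if (scheme == "time_shuffle") {
      apply(phase, 2, function(col) col[sample.int(nt)])
    } else phase[, sample.int(nc), drop = FALSE]
    mean_pgd(ph)
  }, 0))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm), scheme = scheme)
}

#' Directional consistency across trials
#'
#' Mean resultant vector length of the per-trial propagation directions
#' at each site and time: 1 = identical direction on every trial, near 0
#' for uniformly scattered directions.
#'
#' @param directions array `[trial, time, site]` of directions in
#'   degrees (NA allowed; masked).
#' @return matrix `[time, site]` of DC values in `[0, 1]`.
#' @export
directional_consistency <- function(directions) {
  if (length(dim(directions)) != 3) stop_invalid("need a trial x time x site array")
  if (dim(directions)[1] < 2) stop_invalid("need >= 2 trials")
  rad <- directions * pi / 180
  z <- exp(1i * rad)
  apply(z, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else Mod(mean(v))
  })
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * R^2` with the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))`.
#'
#' @param angles radians or degrees (set `degrees = TRUE`).
#' @param degrees interpret input as degrees.
#' @return list: R (resultant length), z, p, n.
#' @export
rayleigh_test <- function(angles, degrees = FALSE) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 5) stop_invalid("need >= 5 angles")
  if (degrees) angles <- angles * pi / 180
  R <- resultant_length(angles)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (R * n)^2)) - (1 + 2 * n))
  list(R = R, z = z, p = min(max(p, 0), 1), n = n)
}

#' Kullback-Leibler divergence between direction distributions
#'
#' Angular histograms (common bins over `[0, 360)`, epsilon-regularized)
#' compared by `KL(A || B) = sum pA * log(pA / pB)` (natural log), with
#' a label-shuffle permutation p-value.
#'
#' @param anglesA,anglesB directions in degrees.
#' @param n_bins histogram bins.
#' @param n_perm label permutations for the null (0 = skip).
#' @param eps regularization added to each bin probability.
#' @param seed optional RNG seed.
#' @return list: kl, p, pA, pB, breaks.
#' @export
direction_kl <- function(anglesA, anglesB, n_bins = 36, n_perm = 1000,
                         eps = 1e-10, seed = NULL) {
  anglesA <- anglesA[!is.na(anglesA)] %% 360
  anglesB <- anglesB[!is.na(anglesB)] %% 360
  breaks <- seq(0, 360, length.out = n_bins + 1)
  probs <- function(a) {
    p <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                  nbins = n_bins) / length(a)
    p <- p + eps
    p / sum(p)
  }
  kl_of <- function(a, b) {
    pa <- probs(a); pb <- probs(b)
    sum(pa * log(pa / pb))
  }
  kl <- kl_of(anglesA, anglesB)
  p <- NA_real_
  if (n_perm > 0) {
    pooled <- c(anglesA, anglesB)
    nA <- length(anglesA)
    null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nA)
      kl_of(pooled[idx], pooled[-idx])
    }, 0))
    p <- (1 + sum(null >= kl)) / (1 + n_perm)
  }
  list(kl = kl, p = p, pA = probs(anglesA), pB = probs(anglesB),
       breaks = breaks)
}

#' Relative phase map against a reference electrode
#'
#' Circular mean over time (and trials, if stacked) of the phase
#' difference between each electrode and a reference electrode; used to
#' visualize the mean spatial progression of rhythmic activity.
#'
#' @param phase matrix `[time, channel]` of instantaneous phases
#'   (concatenate trials along rows to average across trials).
#' @param reference channel index or name (requires column names).
#' @return numeric vector: circular-mean relative phase per electrode,
#'   radians in (-pi, pi] (0 at the reference).
#' @export
relative_phase_map <- function(phase, reference) {
  if (is.character(reference)) {
    reference <- match(reference, colnames(phase))
    if (is.na(reference)) stop_invalid("reference electrode not found")
  }
  if (reference < 1 || reference > ncol(phase))
    stop_invalid("reference electrode not found")
  rel <- phase - phase[, reference]
  out <- apply(rel, 2, circ_mean)
  wrap_pi(out)
}
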