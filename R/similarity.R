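# First-order correlations between spectral features and second-order
# representational similarity across trials.

# Pearson correlation returning NA (with attribute) for constant input.
safe_cor <- function(a, b, method = "pearson") {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}

#' Within-trial temporal correlation between two features
#'
#' Correlates the two features' time courses (each averaged over its own
#' local-maxima electrodes) within each trial over the analysis window.
#'
#' @param featA,featB arrays `[trial, channel, time]` or matrices
#'   `[trial, time]` (already electrode-averaged).
#' @param times time axis, s.
#' @param window analysis window, s.
#' @return numeric, one correlation per trial (NA where a time course is
#'   constant; the count of dropped trials is in `attr(, "n_undefined")`).
#' @export
temporal_correlation <- function(featA, featB, times,
                                 window = c(-0.75, 2.0)) {
  avg <- function(x) if (length(dim(x)) == 3) apply(x, c(1, 3), mean) else x
  A <- avg(featA); B <- avg(featB)
  keep <- times >= window[1] & times <= window[2]
  r <- vapply(seq_len(nrow(A)), function(i)
    safe_cor(A[i, keep], B[i, keep]), 0)
  structure(r, n_undefined = sum(is.na(r)))
}

#' Within-trial spatial correlation between two features
#'
#' Correlates the per-electrode mean activity (over the imagery window)
#' between two features, within each trial, across stimulation-positive
#' electrodes.
#'
#' @param featA,featB arrays `[trial, channel, time]`.
#' @inheritParams temporal_correlation
#' @export
spatial_correlation <- function(featA, featB, times, window = c(0, 2.0)) {
  if (dim(featA)[2] < 3) stop_invalid("need >= 3 electrodes")
  keep <- times >= window[1] & times <= window[2]
  A <- apply(featA[, , keep, drop = FALSE], c(1, 2), mean)
  B <- apply(featB[, , keep, drop = FALSE], c(1, 2), mean)
  r <- vapply(seq_len(nrow(A)), function(i) safe_cor(A[i, ], B[i, ]), 0)
  structure(r, n_undefined = sum(is.na(r)))
}

#' Within-trial spatiotemporal correlation between two features
#'
#' Correlates the flattened electrode x time pattern of each trial.
#'
#' @inheritParams spatial_correlation
#' @export
spatiotemporal_correlation <- function(featA, featB, times,
                                       window = c(-0.75, 2.0)) {
  if (dim(featA)[2] < 3) stop_invalid("need >= 3 electrodes")
  keep <- times >= window[1] & times <= window[2]
  r <- vapply(seq_len(dim(featA)[1]), function(i)
    safe_cor(as.vector(featA[i, , keep]), as.vector(featB[i, , keep])), 0)
  structure(r, n_undefined = sum(is.na(r)))
}

#' Trial-by-trial representational similarity matrix
#'
#' Correlates the activity pattern of every trial pair and returns the
#' vectorized upper triangle (diagonal of autocorrelations excluded).
#'
#' @param patterns matrix `[trial, feature]`: one flattened pattern per
#'   trial (temporal, spatial, or spatiotemporal).
#' @return list of class `similarity_matrix`: `matrix` (trial x trial),
#'   `vector` (upper triangle, length `n*(n-1)/2`).
#' @export
build_rsm <- function(patterns) {
  n <- nrow(patterns)
  if (n < 3) stop_invalid("need >= 3 trials")
  m <- stats::cor(t(patterns))
  structure(list(matrix = m, vector = m[upper.tri(m)]),
            class = "similarity_matrix")
}

#' Second-order (Spearman) representational similarity
#'
#' Rank correlation between two features' trial-pair similarity vectors:
#' similarity in sensitivity to trial-by-trial demands, abstracted from
#' the within-trial patterns themselves.
#'
#' @param rsmA,rsmB `similarity_matrix` objects or plain vectors.
#' @return Spearman rho.
#' @export
rsa_second_order <- function(rsmA, rsmB) {
  va <- if (inherits(rsmA, "similarity_matrix")) rsmA$vector else rsmA
  vb <- if (inherits(rsmB, "similarity_matrix")) rsmB$vector else rsmB
  if (length(va) != length(vb))
    stop_invalid("similarity vectors differ in length (trial sets must match)")
  stats::cor(va, vb, method = "spearman")
}

# JZS (Jeffreys-Zellner-Siow) Bayes factor for a one-sample t-test.
# Marginal likelihood under H1 integrates the noncentral-t density over
# the Cauchy(0, r) effect-size prior; BF01 = f(t | H0) / f(t | H1).
bf01_jzs <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  f0 <- stats::dt(t, nu)
  # suppress the noncentral-t "full precision" notes; the density error
  # involved is far below the quadrature tolerance
  f1 <- suppressWarnings(stats::integrate(function(delta)
    stats::dt(t, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r),
    -Inf, Inf, rel.tol = 1e-9)$value)
  f0 / f1
}

#' Group-level inference with default-prior Bayes factor
#'
#' One-sample t-test of per-participant values against zero, plus the
#' JZS Bayes factor BF01 (evidence for the null; Cauchy prior scale
#' sqrt(2)/2 on the standardized effect).
#'
#' @param values per-participant summary values (e.g. mean correlations).
#' @param mu null value (default 0).
#' @return list of class `group_stats`: t, df, p, bf01, n, mean.
#' @export
group_inference <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop_invalid("need n >= 2 participants")
  if (stats::sd(values) == 0) {
    if (mean(values) != mu)
      ecog_error("ecog_degenerate_input", "zero variance across participants")
    # all values exactly at the null: t = 0 by convention
    return(structure(list(t = 0, df = n - 1, p = 1,
                          bf01 = bf01_jzs(0, n), n = n,
                          mean = mean(values)),
                     class = "group_stats"))
  }
  tt <- stats::t.test(values, mu = mu)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, bf01 = bf01_jzs(unname(tt$statistic), n),
                 n = n, mean = mean(values)),
            class = "group_stats")
}
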