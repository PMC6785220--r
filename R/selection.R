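# Four-step electrode localization: restrict to stimulation-positive
# sites, then mark band-specific local maxima via confidence bounds on
# the across-electrode distribution.

#' Stimulation-positive electrodes
#'
#' Electrodes whose electrical stimulation evoked motor or somatosensory
#' responses of the upper limb (response type `motor`, `somatosensory`,
#' or `both`) mark sensorimotor coverage.
#'
#' @param electrodes data.frame with a `stim_response` column.
#' @return the subset of rows with a sensorimotor response.
#' @export
select_stimulation_positive <- function(electrodes) {
  if (!"stim_response" %in% names(electrodes))
    ecog_error("ecog_schema_error", "electrode table lacks stim_response column")
  sel <- electrodes[electrodes$stim_response %in%
                      c("motor", "somatosensory", "both"), , drop = FALSE]
  if (nrow(sel) == 0)
    ecog_error("ecog_no_coverage",
               "no stimulation-positive electrodes: no sensorimotor coverage")
  sel
}

#' Band-specific local maxima via confidence bounds
#'
#' Selects electrodes whose feature value exceeds the upper limit of the
#' 99% confidence interval of the across-electrode mean
#' (`mean + z[0.995] * SEM`), or falls below the lower limit for
#' lower-tail features such as the 1/f slope (steepest slopes = greatest
#' inhibition).
#'
#' @param values named numeric vector, one value per electrode.
#' @param tail `"upper"` or `"lower"`.
#' @param level confidence level (default 0.99).
#' @param quantile_fun `"normal"` (default, z = 2.576) or `"t"`.
#' @return list of class `selection_result`: selected (names), threshold,
#'   tail, skipped.
#' @export
find_local_maxima <- function(values, tail = c("upper", "lower"),
                              level = 0.99, quantile_fun = c("normal", "t")) {
  tail <- match.arg(tail)
  quantile_fun <- match.arg(quantile_fun)
  n <- length(values)
  nm <- names(values) %||% as.character(seq_len(n))
  if (n < 3) {
    warning("fewer than 3 electrodes: local-maxima selection skipped, ",
            "all electrodes retained")
    return(structure(list(selected = nm, threshold = NA_real_,
                          tail = tail, skipped = TRUE),
                     class = "selection_result"))
  }
  q <- if (quantile_fun == "normal") stats::qnorm(1 - (1 - level) / 2)
       else stats::qt(1 - (1 - level) / 2, df = n - 1)
  sem <- stats::sd(values) / sqrt(n)
  thr <- if (tail == "upper") mean(values) + q * sem else
    mean(values) - q * sem
  sel <- if (tail == "upper") values > thr else values < thr
  structure(list(selected = nm[sel], threshold = thr, tail = tail,
                 skipped = FALSE),
            class = "selection_result")
}

#' Chi-squared goodness-of-fit test on electrode categories
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = k - 1`, for counts
#' of electrodes per anatomical location or stimulation-response type.
#'
#' @param observed non-negative integer counts.
#' @param expected_prop expected proportions (default uniform).
#' @return list: chi2, df, p.
#' @export
category_test <- function(observed,
                          expected_prop = rep(1 / length(observed),
                                              length(observed))) {
  if (length(observed) < 2) stop_invalid("need at least 2 categories")
  if (any(observed < 0)) stop_invalid("counts must be non-negative")
  expected <- sum(observed) * expected_prop / sum(expected_prop)
  if (any(expected <= 0)) stop_invalid("expected counts must be positive")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Overlap and spatial separation between two electrode sets
#'
#' @param setA,setB character vectors of electrode names.
#' @param positions data.frame with `name, x, y, z` (mm).
#' @return list: shared (count of common electrodes), separation_mm
#'   (mean over A of the distance to the nearest electrode in B).
#' @export
overlap_and_separation <- function(setA, setB, positions) {
  if (length(setA) == 0 || length(setB) == 0)
    ecog_error("ecog_undefined_distance", "empty electrode set")
  miss <- setdiff(c(setA, setB), positions$name)
  if (length(miss))
    stop_invalid(paste("positions missing for:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  rownames(xyz) <- positions$name
  pa <- xyz[setA, , drop = FALSE]
  pb <- xyz[setB, , drop = FALSE]
  nearest <- vapply(seq_len(nrow(pa)), function(i)
    min(sqrt(colSums((t(pb) - pa[i, ])^2))), 0)
  list(shared = length(intersect(setA, setB)),
       separation_mm = mean(nearest))
}
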