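#' Healthy-control reference interval on corrected methylation
#'
#' Center and SD are computed from the pooled per-CpG corrected degrees of
#' all control individuals (so the interval is wide enough to contain the
#' control corrected degrees across all CpGs); the interval is
#' `center +/- k * sd`, clipped to \[0,100\].  `aggregate = "means"` instead
#' pools per-individual means.
#'
#' @param controls a [CorrectionResult-class] for the control individuals
#'   (rows of other groups are ignored; at least 2 controls required).
#' @param k SD multiplier (default 3, two-sided alpha 0.0027; see
#'   [kFromAlpha()]).
#' @param aggregate `"pooled"` (default) or `"means"`.
#' @return A [ReferenceInterval-class].
#' @export
controlReferenceInterval <- function(controls, k = 3,
                                     aggregate = c("pooled", "means")) {
  stopifnot(is(controls, "CorrectionResult"), k >= 0)
  aggregate <- match.arg(aggregate)
  tab <- controls@table[controls@table$group == "control", , drop = FALSE]
  vals <- tab$corrected[!is.na(tab$corrected)]
  if (length(unique(tab$id)) < 2L)
    stop("at least 2 control individuals are required")
  if (aggregate == "means")
    vals <- as.numeric(tapply(tab$corrected, tab$id, mean, na.rm = TRUE))
  center <- mean(vals)
  sdv <- stats::sd(vals)
  if (sdv == 0)
    warning("control corrected degrees have zero variance; the reference interval is degenerate")
  new("ReferenceInterval", center = center, sd = sdv, k = k,
      lower = .clip01(center - k * sdv), upper = .clip01(center + k * sdv))
}

#' SD multiplier from a two-sided type-I error
#'
#' `k = qnorm(1 - alpha/2)`; e.g. `alpha = 0.0027` gives `k = 3.000`.
#'
#' @param alpha two-sided type-I error, in (0, 1).
#' @return The multiplier `k`.
#' @export
kFromAlpha <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  stats::qnorm(1 - alpha / 2)
}

#' Classify patients as loss / normal / gain of methylation
#'
#' Each patient's corrected degrees are averaged across non-missing CpGs and
#' compared to the reference interval: below the lower bound is loss of
#' methylation, above the upper bound gain, otherwise normal.  Patients
#' whose per-CpG range crosses an interval bound while their mean does not
#' are flagged `uncertain` (borderline/mosaic presentation).
#'
#' @param patients a [CorrectionResult-class] (typically the `case` group;
#'   all rows are classified).
#' @param interval a [ReferenceInterval-class].
#' @return A [ClassificationResult-class].
#' @export
classifySamples <- function(patients, interval) {
  stopifnot(is(patients, "CorrectionResult"), is(interval, "ReferenceInterval"))
  tab <- patients@table
  ids <- unique(tab$id)
  rows <- lapply(ids, function(id) {
    v <- tab$corrected[tab$id == id]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop("patient ", id, " has no non-missing corrected CpGs")
    mn <- mean(v)
    call <- if (mn < interval@lower) "loss"
            else if (mn > interval@upper) "gain" else "normal"
    crosses <- (min(v) < interval@lower && max(v) >= interval@lower) ||
               (max(v) > interval@upper && min(v) <= interval@upper)
    data.frame(id = id, mean = mn, rangeMin = min(v), rangeMax = max(v),
               call = call, uncertain = crosses, row.names = NULL)
  })
  new("ClassificationResult", table = do.call(rbind, rows), interval = interval)
}
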