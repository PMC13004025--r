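# Quantification formulas for receptor trafficking assays: flow-cytometry
# geometric means (surface expression, internalization, recycling),
# fluorogen-based down-regulation (percent remaining), live-neuron surface
# fluorescence ratios, and cAMP inhibition from luminescence.

#' @noRd
checkPositive <- function(x, what) {
  if (!is.numeric(x) || anyNA(x)) stop(what, " must be numeric and non-NA")
  if (any(x <= 0)) stop(what, " must be strictly positive")
  invisible(x)
}

#' Percent internalization from flow-cytometry geometric means
#'
#' Surface receptor loss after agonist treatment:
#' `(1 - gmInternalized / gmTotal) * 100`, where `gmTotal` is the surface
#' geometric-mean fluorescence of the antagonist-only (total) condition and
#' `gmInternalized` that of the agonist condition. A negative result
#' (surface gain) is returned as-is with a warning rather than clamped,
#' since assay noise is real and silent clamping would hide it.
#'
#' @param gmTotal geometric-mean fluorescence, antagonist-only condition
#'   (strictly positive).
#' @param gmInternalized geometric-mean fluorescence, agonist condition.
#' @return percent internalized (vectorized).
#' @examples
#' internalizationPct(1000, 500)  # 50
#' @export
internalizationPct <- function(gmTotal, gmInternalized) {
  checkPositive(gmTotal, "gmTotal")
  checkPositive(gmInternalized, "gmInternalized")
  out <- (1 - gmInternalized / gmTotal) * 100
  if (any(out < 0))
    warning("negative internalization (surface gain); returning unclamped")
  out
}

#' Percent recycling from flow-cytometry geometric means
#'
#' Surface receptor recovery after sequential agonist and antagonist
#' treatment:
#' `(gmRecycled - gmInternalized) / (gmTotal - gmInternalized) * 100`.
#' Full return to the surface gives 100; no recovery gives 0. The assay
#' precondition is measurable internalization; equal total and internalized
#' means (zero denominator) are an error. Values outside \[0, 100\] are
#' returned with a warning, not clamped.
#'
#' @param gmTotal geometric-mean fluorescence, antagonist-only condition.
#' @param gmInternalized geometric-mean fluorescence, agonist condition.
#' @param gmRecycled geometric-mean fluorescence, agonist-then-antagonist
#'   condition.
#' @return percent recycled (vectorized).
#' @examples
#' recyclingPct(1000, 500, 790)  # 58
#' @export
recyclingPct <- function(gmTotal, gmInternalized, gmRecycled) {
  checkPositive(gmTotal, "gmTotal")
  checkPositive(gmInternalized, "gmInternalized")
  checkPositive(gmRecycled, "gmRecycled")
  denom <- gmTotal - gmInternalized
  if (any(denom == 0))
    stop("gmTotal equals gmInternalized: no measurable internalization, ",
         "recycling is undefined")
  out <- (gmRecycled - gmInternalized) / denom * 100
  if (any(out < 0 | out > 100))
    warning("recycling outside [0, 100]; returning unclamped")
  out
}

#' Percent receptor remaining after agonist treatment
#'
#' Ratio of fluorogen-derived fluorescence after agonist treatment to the
#' untreated control, times 100. Used to quantify receptor down-regulation:
#' delivery to the lysosome quenches the signal, so lower values mean more
#' down-regulation.
#'
#' @param fTreated fluorescence after agonist treatment.
#' @param fUntreated fluorescence without agonist (strictly positive).
#' @return percent remaining (vectorized).
#' @examples
#' percentRemaining(250, 1000)  # 25
#' @export
percentRemaining <- function(fTreated, fUntreated) {
  checkPositive(fUntreated, "fUntreated")
  if (!is.numeric(fTreated) || anyNA(fTreated) || any(fTreated < 0))
    stop("fTreated must be numeric and non-negative")
  fTreated / fUntreated * 100
}

#' Surface fluorescence ratio
#'
#' Per-cell surface signal divided by total signal, in (0, 1]. Normalizes
#' for variation in receptor expression between cells.
#'
#' @param surface surface fluorescence (strictly positive).
#' @param total whole-cell fluorescence (`>= surface`).
#' @return ratio in (0, 1] (vectorized).
#' @export
surfaceRatio <- function(surface, total) {
  checkPositive(surface, "surface")
  checkPositive(total, "total")
  if (any(surface > total)) stop("surface fluorescence exceeds total")
  surface / total
}

#' @noRd
seriesRatio <- function(series, timepoint) {
  stopifnot(is.data.frame(series),
            all(c("timepoint", "surface", "total") %in% names(series)))
  row <- series[series$timepoint == timepoint, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("series is missing timepoint '", timepoint, "'")
  surfaceRatio(row$surface[1], row$total[1])
}

#' Neuron internalization and recycling from a surface-ratio time series
#'
#' For one cell imaged at three timepoints — `baseline`, `post_agonist`
#' (end of agonist treatment) and `post_antagonist` (end of antagonist
#' treatment) — internalization is the change in surface fluorescence ratio
#' from baseline to the end of agonist treatment (negative when receptor is
#' internalized), and recycling is the change from the end of agonist
#' treatment to the end of antagonist treatment (positive when receptor
#' returns to the surface). The pre-antagonist state is the post-agonist
#' state, so "after minus before antagonist" and "after antagonist minus
#' after agonist" coincide.
#'
#' @param series data.frame with columns `timepoint`
#'   (`"baseline"`, `"post_agonist"`, `"post_antagonist"`), `surface`,
#'   `total` for one cell. `neuronInternalization` needs `baseline` and
#'   `post_agonist`; `neuronRecycling` needs `post_agonist` and
#'   `post_antagonist`.
#' @return signed change in surface fluorescence ratio.
#' @examples
#' s <- data.frame(
#'   timepoint = c("baseline", "post_agonist", "post_antagonist"),
#'   surface = c(90, 40, 70), total = c(100, 100, 100))
#' neuronInternalization(s)  # -0.5
#' neuronRecycling(s)        # 0.3
#' @export
neuronInternalization <- function(series) {
  seriesRatio(series, "post_agonist") - seriesRatio(series, "baseline")
}

#' @rdname neuronInternalization
#' @export
neuronRecycling <- function(series) {
  seriesRatio(series, "post_antagonist") - seriesRatio(series, "post_agonist")
}

#' Percent cAMP inhibition from luminescence
#'
#' Opioid-mediated inhibition of stimulated cAMP production:
#' `(1 - lumIsoOpioid / lumIso) * 100`, with `lumIso` the normalized,
#' background-subtracted luminescence under isoproterenol alone and
#' `lumIsoOpioid` under isoproterenol plus opioid agonist.
#'
#' @param lumIso luminescence, isoproterenol only (strictly positive).
#' @param lumIsoOpioid luminescence, isoproterenol plus opioid agonist.
#' @return percent inhibition (vectorized).
#' @examples
#' campInhibitionPct(1000, 200)  # 80
#' @export
campInhibitionPct <- function(lumIso, lumIsoOpioid) {
  checkPositive(lumIso, "lumIso")
  if (!is.numeric(lumIsoOpioid) || anyNA(lumIsoOpioid) ||
      any(lumIsoOpioid < 0))
    stop("lumIsoOpioid must be numeric and non-negative")
  (1 - lumIsoOpioid / lumIso) * 100
}

#' Fold surface expression over a control
#'
#' Simple ratio of condition to control geometric means, used both for
#' total surface expression over a labeled non-expressing parental control
#' and for induced over uninduced surface expression.
#'
#' @param gmCondition geometric-mean fluorescence of the condition.
#' @param gmControl geometric-mean fluorescence of the control (strictly
#'   positive).
#' @return fold change (vectorized).
#' @export
surfaceExpressionFold <- function(gmCondition, gmControl) {
  checkPositive(gmControl, "gmControl")
  if (!is.numeric(gmCondition) || anyNA(gmCondition))
    stop("gmCondition must be numeric and non-NA")
  gmCondition / gmControl
}

#' Geometric mean of per-event fluorescence
#'
#' Helper for computing a geometric-mean fluorescence from raw per-event
#' values. Zero or negative events cannot enter a geometric mean; they are
#' dropped with a warning reporting how many were rejected.
#'
#' @param x numeric vector of per-event fluorescence values.
#' @return geometric mean of the positive values.
#' @export
geometricMean <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) stop("x must be non-empty numeric")
  bad <- is.na(x) | x <= 0
  if (all(bad)) stop("no positive events to average")
  if (any(bad))
    warning(sprintf("rejected %d non-positive event(s)", sum(bad)))
  exp(mean(log(x[!bad])))
}

#' Compute trafficking metrics from a tidy measurement table
#'
#' Reads a tidy table of labeled fluorescence measurements — columns
#' `sample`, `measure`, `value` — and emits every metric whose inputs are
#' present for a sample. Recognized measures: `gm_total`,
#' `gm_internalized`, `gm_recycled` (flow cytometry); `f_treated`,
#' `f_untreated` (fluorogen assay); `lum_iso`, `lum_iso_opioid`
#' (luminescence); `gm_condition`, `gm_control` (surface expression);
#' `surface_<tp>` / `total_<tp>` for `baseline`, `post_agonist`,
#' `post_antagonist` (neuron imaging).
#'
#' @param measurements data.frame with columns `sample`, `measure`,
#'   `value`, or a path to such a TSV.
#' @return data.frame with columns `sample`, `metric`, `value`.
#' @export
metricsFromTable <- function(measurements) {
  if (is.character(measurements))
    measurements <- utils::read.delim(measurements, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "measure", "value") %in% names(measurements)))
  out <- list()
  for (s in unique(measurements$sample)) {
    sub <- measurements[measurements$sample == s, , drop = FALSE]
    get <- function(m) {
      v <- sub$value[sub$measure == m]
      if (length(v)) v[1] else NA_real_
    }
    add <- function(metric, value)
      out[[length(out) + 1L]] <<- data.frame(sample = s, metric = metric,
                                             value = value,
                                             stringsAsFactors = FALSE)
    gmT <- get("gm_total"); gmI <- get("gm_internalized")
    gmR <- get("gm_recycled")
    if (!is.na(gmT) && !is.na(gmI)) {
      add("internalization_pct", internalizationPct(gmT, gmI))
      if (!is.na(gmR)) add("recycling_pct", recyclingPct(gmT, gmI, gmR))
    }
    fT <- get("f_treated"); fU <- get("f_untreated")
    if (!is.na(fT) && !is.na(fU))
      add("percent_remaining", percentRemaining(fT, fU))
    li <- get("lum_iso"); lio <- get("lum_iso_opioid")
    if (!is.na(li) && !is.na(lio))
      add("camp_inhibition_pct", campInhibitionPct(li, lio))
    gc <- get("gm_condition"); gk <- get("gm_control")
    if (!is.na(gc) && !is.na(gk))
      add("surface_expression_fold", surfaceExpressionFold(gc, gk))
    tps <- c("baseline", "post_agonist", "post_antagonist")
    sv <- vapply(paste0("surface_", tps), get, numeric(1))
    tv <- vapply(paste0("total_", tps), get, numeric(1))
    if (all(!is.na(sv)) && all(!is.na(tv))) {
      series <- data.frame(timepoint = tps, surface = sv, total = tv)
      add("neuron_internalization", neuronInternalization(series))
      add("neuron_recycling", neuronRecycling(series))
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), metric = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
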