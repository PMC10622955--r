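# BrainAGE scoring: raw gap = predicted - chronological age, ordinary
# least-squares age-bias residualization, and z-scoring against the control
# group. The age-bias regression removes the well-known regression-to-the-
# mean artefact of age models (young subjects over-, old subjects
# under-predicted); the slope alpha is on the order of 0.13 in cohorts like
# the reference study.

#' Raw brain age gap
#'
#' Predicted age minus chronological age; positive values mean an
#' older-looking brain.
#' @param predicted,chronological Ages in years (vectors recycle).
#' @return Gap in years.
#' @export
raw_gap <- function(predicted, chronological) {
  stopifnot(all(is.finite(predicted)), all(is.finite(chronological)))
  predicted - chronological
}

#' Fit the age-bias model
#'
#' Ordinary least squares of the brain age gap (default) or of the predicted
#' age on chronological age. The fitted coefficients are used by
#' [apply_bias_correction()] to residualize the gap; on the fitting set the
#' corrected gaps then have exactly zero mean and zero correlation with age.
#'
#' With `regressand = "gap"` the slope is the age bias of the gap (the
#' convention under which a slope near 0.13 is plausible); the literal
#' predicted-age-on-age variant is available as `regressand =
#' "predicted_age"`.
#'
#' @param gaps Raw gaps (years) of the fitting population - or predicted ages
#'   when `regressand = "predicted_age"`.
#' @param ages Chronological ages (years); must vary.
#' @param fit_population Metadata tag: `"controls"`, `"training"` or
#'   `"pooled"`.
#' @param regressand `"gap"` (default) or `"predicted_age"`.
#' @return Object of class `bias_model`: `intercept`, `alpha`,
#'   `fit_population`, `regressand`, `n`.
#' @export
fit_bias_model <- function(gaps, ages,
                           fit_population = c("controls", "training",
                                              "pooled"),
                           regressand = c("gap", "predicted_age")) {
  fit_population <- match.arg(fit_population)
  regressand <- match.arg(regressand)
  stopifnot(length(gaps) == length(ages), length(gaps) >= 3)
  if (sd(ages) == 0)
    stop("singular design: ages are constant", call. = FALSE)
  fit <- lm(gaps ~ ages)
  structure(list(intercept = unname(coef(fit)[1]),
                 alpha = unname(coef(fit)[2]),
                 fit_population = fit_population, regressand = regressand,
                 n = length(gaps)),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> %s ~ age: intercept %.4g, alpha %.4g (fit on %s, n = %d)\n",
              x$regressand, x$intercept, x$alpha, x$fit_population, x$n))
  invisible(x)
}

#' Apply the age-bias correction
#'
#' Residualizes the brain age gap: `corrected = raw_gap - (intercept + alpha
#' * chronological_age)`. For a `predicted_age`-regressand model the same
#' residual is formed on the predicted-age scale,
#' `predicted - (intercept + alpha * age)`.
#'
#' @param predicted,chronological Ages in years.
#' @param bias A fitted [fit_bias_model()].
#' @return data.frame of class `brainage_result`: `predicted_age`,
#'   `chronological_age`, `raw_gap`, `corrected_gap`.
#' @export
apply_bias_correction <- function(predicted, chronological, bias) {
  gap <- raw_gap(predicted, chronological)
  expected <- bias$intercept + bias$alpha * chronological
  corrected <- if (bias$regressand == "gap") gap - expected
               else predicted - expected
  structure(data.frame(predicted_age = predicted,
                       chronological_age = chronological,
                       raw_gap = gap, corrected_gap = corrected),
            class = c("brainage_result", "data.frame"))
}

#' Control reference for z-scoring
#'
#' Mean and sample SD (n - 1 denominator) of the control group's corrected
#' gaps.
#' @param control_gaps Corrected gaps (years) of at least 2 controls.
#' @return Object of class `control_reference`: `mean_gap`, `sd_gap`, `n`.
#' @export
control_reference <- function(control_gaps) {
  stopifnot(length(control_gaps) >= 2)
  s <- sd(control_gaps)
  if (!is.finite(s) || s == 0)
    stop("control gaps have zero spread; cannot z-score", call. = FALSE)
  structure(list(mean_gap = mean(control_gaps), sd_gap = s,
                 n = length(control_gaps)),
            class = "control_reference")
}

#' Convert corrected gaps to control-referenced z-scores
#'
#' `(gap - mean_gap) / sd_gap`; the control group itself maps to mean 0,
#' SD 1 under its own reference.
#' @param corrected_gaps Corrected gaps (years).
#' @param reference A [control_reference()].
#' @return Dimensionless z-scores.
#' @export
to_zscore <- function(corrected_gaps, reference) {
  (corrected_gaps - reference$mean_gap) / reference$sd_gap
}

#' Score a cohort end to end
#'
#' Convenience wrapper: raw gaps for everyone, bias model fitted on the
#' requested population (default: the study controls), correction applied to
#' all, z-reference from the controls' corrected gaps.
#'
#' @param predicted,chronological Ages (years) for all study subjects.
#' @param group Character vector; `"control"` rows define the reference.
#' @param fit_population `"controls"` (default) or `"pooled"` (fit the bias
#'   on everyone).
#' @return List: `scores` (data.frame with `raw_gap`, `corrected_gap`,
#'   `z_score`), `bias` ([fit_bias_model()]), `reference`
#'   ([control_reference()]).
#' @export
score_cohort <- function(predicted, chronological, group,
                         fit_population = c("controls", "pooled")) {
  fit_population <- match.arg(fit_population)
  is_ctrl <- group == "control"
  idx <- if (fit_population == "controls") is_ctrl else rep(TRUE, length(group))
  gaps <- raw_gap(predicted, chronological)
  bias <- fit_bias_model(gaps[idx], chronological[idx], fit_population)
  res <- apply_bias_correction(predicted, chronological, bias)
  ref <- control_reference(res$corrected_gap[is_ctrl])
  res$z_score <- to_zscore(res$corrected_gap, ref)
  res$group <- group
  list(scores = res, bias = bias, reference = ref)
}

#' Write / read BrainAGE scores as CSV
#'
#' Columns: `id,predicted_age,chronological_age,group,raw_gap,corrected_gap,
#' z_score`. The bias model serializes to JSON alongside via
#' [save_bias_model()].
#' @param scores data.frame from [score_cohort()] (an `id` column is added
#'   from `ids` if missing).
#' @param path CSV path.
#' @param ids Optional subject ids.
#' @return Invisibly, the path.
#' @export
write_scores <- function(scores, path, ids = NULL) {
  if (!is.null(ids)) scores$id <- ids
  cols <- intersect(c("id", "predicted_age", "chronological_age", "group",
                      "raw_gap", "corrected_gap", "z_score"), names(scores))
  write.csv(scores[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a bias model as JSON
#' @param bias A `bias_model`.
#' @param path JSON path.
#' @return `load_bias_model` returns the `bias_model`.
#' @export
save_bias_model <- function(bias, path) {
  jsonlite::write_json(unclass(bias), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bias_model
#' @export
load_bias_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "bias_model")
}
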