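# The cohort statistics plan: group summaries and pooled-SD effect sizes,
# two-sample and k-group tests, age-adjusted ANCOVA, correlations, the 2x2
# chi-square with odds ratio, ROC/Youden stratification, and the screened
# multivariate logistic model. Standard tests are delegated to stats::; the
# surrounding conventions (pooled SD, no continuity correction, midpoint
# thresholds, screening rules) are fixed here and documented. No
# multiple-testing adjustment is applied across result-table rows, matching
# the analysis this mirrors; pairwise post-hoc p-values inside a single
# k-group comparison use Bonferroni.

#' Group summary
#' @param n Count (>= 2), `mean`, `sd` of one group.
#' @param mean,sd Group mean and sample SD.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

summarize_group <- function(x) group_summary(length(x), mean(x), sd(x))

as_test_result <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, df %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "NA"
              else format(round(x$df, 2)), x$p_value))
  invisible(x)
}

#' Cohen's d with pooled SD
#'
#' `d = (mean_a - mean_b) / s_p` with the pooled sample SD
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`. The
#' sign follows a - b (by convention a is the patient group). The pooled SD
#' is used for all variables, including skewed ones reported alongside
#' rank tests.
#'
#' @param a,b [group_summary()] objects or raw numeric vectors.
#' @return Dimensionless effect size.
#' @export
cohens_d_pooled <- function(a, b) {
  if (is.numeric(a)) a <- summarize_group(a)
  if (is.numeric(b)) b <- summarize_group(b)
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) {
    if (a$mean == b$mean) return(0)
    stop("pooled SD is 0 with unequal means: infinite effect", call. = FALSE)
  }
  (a$mean - b$mean) / sp
}

#' Two-sample t test (summary- or raw-data based)
#'
#' Student's pooled-variance t (df `n_a + n_b - 2`) or Welch's unequal
#' variance variant, two-sided, computable from group summaries alone.
#'
#' @param a,b [group_summary()] objects or raw numeric vectors.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A `test_result` (statistic, df, p_value, method).
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (is.numeric(a)) a <- summarize_group(a)
  if (is.numeric(b)) b <- summarize_group(b)
  if (a$sd == 0 && b$sd == 0)
    stop("zero variance in both groups", call. = FALSE)
  if (variant == "student") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  as_test_result(t, df, 2 * pt(-abs(t), df), paste0(variant, "_t"))
}

#' Mann-Whitney U test
#'
#' Two-sided; exact for small untied samples, normal approximation with tie
#' correction otherwise (the stats::wilcox.test policy). The statistic is
#' the U count for `x`.
#'
#' @param x,y Raw numeric vectors (n >= 3 each).
#' @return A `test_result`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  wt <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
  as_test_result(wt$statistic, NA_real_, wt$p.value, "mann_whitney_u")
}

#' One-way k-group comparison (ANOVA or Kruskal-Wallis)
#'
#' @param groups Named list of raw numeric vectors (each n >= 2).
#' @param variant `"anova"` (F test) or `"kruskal"` (H test).
#' @param pairwise Also run all pairwise follow-ups (Student t or
#'   Mann-Whitney) with Bonferroni-adjusted p-values.
#' @return A `test_result`; with `pairwise`, a `pairwise` data.frame
#'   (`a`, `b`, `p_adj`) is attached.
#' @export
anova_oneway <- function(groups, variant = c("anova", "kruskal"),
                         pairwise = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups),
                       lengths(groups)))
  res <- if (variant == "anova") {
    if (sd(values) == 0) stop("degenerate: all values equal", call. = FALSE)
    av <- anova(lm(values ~ labels))
    as_test_result(av$`F value`[1], av$Df[1], av$`Pr(>F)`[1], "anova_f",
                   df_resid = av$Df[2])
  } else {
    kw <- kruskal.test(values, labels)
    as_test_result(kw$statistic, kw$parameter, kw$p.value, "kruskal_h")
  }
  if (pairwise) {
    cmb <- utils::combn(names(groups), 2)
    praw <- apply(cmb, 2, function(nm) {
      if (variant == "anova") two_sample_t(groups[[nm[1]]],
                                           groups[[nm[2]]])$p_value
      else mann_whitney(groups[[nm[1]]], groups[[nm[2]]])$p_value
    })
    res$pairwise <- data.frame(a = cmb[1, ], b = cmb[2, ],
                               p_adj = pmin(1, praw * ncol(cmb)))
  }
  res
}

#' Age-adjusted group comparison (ANCOVA)
#'
#' Common-slope linear model `value ~ group + age`; the group effect is the
#' partial F with age already in the model, and adjusted group means are the
#' model predictions at the grand mean age.
#'
#' @param values Numeric outcome.
#' @param group_labels Factor-coercible group labels.
#' @param ages Numeric covariate (years).
#' @return List: `adjusted_means` (named), `adjusted_se` (named),
#'   `test` (`test_result` for the group effect), `age_slope`.
#' @export
ancova_age_adjusted <- function(values, group_labels, ages) {
  g <- factor(group_labels)
  if (any(tapply(ages, g, function(a) length(unique(a))) == 1) &&
      length(unique(ages)) == length(levels(g)))
    stop("age is collinear with group; adjustment is not estimable",
         call. = FALSE)
  fit <- lm(values ~ ages + g)
  av <- anova(fit) # sequential; group enters after age = partial for group
  grand <- mean(ages)
  nd <- data.frame(ages = grand, g = factor(levels(g), levels = levels(g)))
  pr <- predict(fit, newdata = nd, se.fit = TRUE)
  list(adjusted_means = setNames(pr$fit, levels(g)),
       adjusted_se = setNames(pr$se.fit, levels(g)),
       test = as_test_result(av["g", "F value"], av["g", "Df"],
                             av["g", "Pr(>F)"], "ancova_f",
                             df_resid = av["Residuals", "Df"]),
       age_slope = unname(coef(fit)["ages"]))
}

#' Correlation test
#'
#' Pearson (or Spearman for non-normal variables), two-sided.
#' @param x,y Numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `test_result` with an `r` element.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method))
  as_test_result(ct$statistic, ct$parameter %||% NA_real_, ct$p.value,
                 method, r = unname(ct$estimate))
}

#' Chi-square test and odds ratio for a 2x2 table
#'
#' Pearson chi-square without continuity correction (two-sided); odds ratio
#' `ad/bc` with the Woolf (log-normal) 95 percent confidence interval.
#'
#' @param table 2x2 integer matrix `rbind(c(a, b), c(d, e))` with rows =
#'   groups, columns = outcome yes/no; all marginals must be positive.
#' @return A `test_result` with `odds_ratio`, `or_ci` (length-2).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in 2x2 table", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  se_log <- sqrt(sum(1 / table))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se_log)
  as_test_result(ct$statistic, ct$parameter, ct$p.value, "chi_square",
                 odds_ratio = unname(or), or_ci = unname(ci))
}

#' ROC analysis with the Youden-index cutoff
#'
#' Candidate thresholds are the midpoints between sorted unique scores
#' (plus open extremes for the degenerate all-positive/all-negative rules).
#' A subject is called positive when `score >= threshold`. The returned
#' cutoff maximizes the Youden index J = sensitivity + specificity - 1;
#' among ties the threshold with higher specificity wins, and remaining
#' ties go to the larger threshold (policy recorded on the result).
#'
#' @param scores Numeric classifier scores (here: BrainAGE z).
#' @param outcome Logical/0-1 outcome (TRUE = event, e.g. low reaction-time
#'   performance); both classes must be present.
#' @return List of class `roc_result`: `threshold`, `youden`, `sensitivity`,
#'   `specificity`, `auc`, `curve` (data.frame threshold,sens,spec,J),
#'   `tie_policy`.
#' @export
roc_youden <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(scores) == length(outcome), !anyNA(scores),
            !anyNA(outcome))
  if (!any(outcome) || all(outcome))
    stop("both outcome classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(scores[outcome] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!outcome] < t), 0)
  J <- sens + spec - 1
  # argmax J; ties -> higher specificity; remaining ties -> larger threshold
  best <- which(J == max(J))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.max(thr[best])]
  # trapezoidal AUC over the empirical ROC curve (the threshold set already
  # includes the degenerate all-positive/all-negative corners (0,0), (1,1))
  ord <- order(1 - spec, sens)
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  structure(list(threshold = thr[best], youden = J[best],
                 sensitivity = sens[best], specificity = spec[best],
                 auc = auc,
                 curve = data.frame(threshold = thr, sens = sens,
                                    spec = spec, J = J),
                 tie_policy = "max J, then max specificity, then max threshold"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> cutoff %.3g (J = %.3f, sens %.2f, spec %.2f, AUC %.3f)\n",
              x$threshold, x$youden, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Univariate screening + multivariate logistic regression
#'
#' Mirrors the risk-factor analysis: each covariate is tested univariately
#' against the binary outcome (Student t for continuous covariates,
#' chi-square for binary ones); covariates with p below `p_enter` are
#' candidates. Collinearity is then screened pairwise among candidates in
#' their given column order: when |r| exceeds `r_exclude`, the later-listed
#' covariate is dropped (order logged). Survivors enter a maximum-likelihood
#' logistic model (IRLS via `glm`), reported with odds ratios, Wald 95
#' percent CIs and p-values.
#'
#' @param data data.frame of numeric/binary covariates.
#' @param outcome Logical/0-1 response (e.g. high BrainAGE).
#' @param p_enter Univariate inclusion threshold (default 0.2).
#' @param r_exclude Pairwise collinearity threshold (default 0.6).
#' @return Object of class `screening_report`: `univariate` (data.frame),
#'   `entered`, `excluded_collinear`, `model` (data.frame with coefficients,
#'   ORs, CIs, p), `separation` flag.
#' @export
screen_and_fit_logistic <- function(data, outcome, p_enter = 0.2,
                                    r_exclude = 0.6) {
  outcome <- as.logical(outcome)
  stopifnot(is.data.frame(data), length(outcome) == nrow(data),
            !anyNA(outcome))
  vars <- names(data)
  uni <- lapply(vars, function(v) {
    x <- data[[v]]
    binary <- length(unique(x[!is.na(x)])) <= 2
    p <- if (binary) {
      tab <- table(factor(outcome, c(FALSE, TRUE)),
                   factor(x > min(x, na.rm = TRUE), c(FALSE, TRUE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
      else chi_square_2x2(tab)$p_value
    } else {
      two_sample_t(x[outcome], x[!outcome])$p_value
    }
    data.frame(variable = v, type = if (binary) "binary" else "continuous",
               p_value = p, stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  candidates <- uni$variable[uni$p_value < p_enter]

  excluded <- character()
  kept <- character()
  for (v in candidates) {
    clash <- vapply(kept, function(k)
      abs(cor(data[[v]], data[[k]], use = "complete.obs")) > r_exclude,
      logical(1))
    if (any(clash)) excluded <- c(excluded, v) else kept <- c(kept, v)
  }

  model_df <- NULL; separation <- FALSE
  if (length(kept) > 0) {
    dd <- data[, kept, drop = FALSE]
    dd$.outcome <- outcome
    fit <- suppressWarnings(glm(.outcome ~ ., data = dd, family = binomial()))
    separation <- !fit$converged || any(abs(coef(fit)[-1]) > 15)
    sm <- summary(fit)$coefficients
    est <- sm[-1, , drop = FALSE] # drop intercept row for the report
    ci_lo <- est[, 1] - qnorm(0.975) * est[, 2]
    ci_hi <- est[, 1] + qnorm(0.975) * est[, 2]
    model_df <- data.frame(variable = rownames(est), b = est[, 1],
                           odds_ratio = exp(est[, 1]),
                           or_ci_low = exp(ci_lo), or_ci_high = exp(ci_hi),
                           p_value = est[, 4], row.names = NULL,
                           stringsAsFactors = FALSE)
    if (separation)
      warning("possible separation: logistic MLE unstable; ",
              "interpret odds ratios with caution", call. = FALSE)
  }
  structure(list(univariate = uni, entered = kept,
                 excluded_collinear = excluded, model = model_df,
                 separation = separation),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> entered:",
      if (length(x$entered)) paste(x$entered, collapse = ", ") else "(none)",
      "\n  excluded (collinear):",
      if (length(x$excluded_collinear))
        paste(x$excluded_collinear, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$model)) print(x$model, digits = 3)
  invisible(x)
}
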