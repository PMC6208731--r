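## Group comparisons and developmental trajectories -------------------------

# Kolmogorov-Smirnov normality gate applied before parametric tests:
# non-normal inputs trigger a warning (the test still runs; with per-case
# means n is small and the parametric tests are the published procedure).
ks_normality_gate <- function(x, what = "values") {
  x <- x[is.finite(x)]
  if (length(x) < 5 || stats::sd(x) == 0) return(invisible(NULL))
  p <- suppressWarnings(
    stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
  if (p < 0.05)
    warning("Kolmogorov-Smirnov gate: ", what,
            " deviate from normality (p = ", signif(p, 3), ")")
  invisible(p)
}

#' One-way group ANOVA within an age band
#'
#' Compares per-case feature values across diagnostic groups, optionally
#' restricted to an age band (e.g. children 3–10 y or adults 30–67 y;
#' teenagers are conventionally excluded from band comparisons and described
#' only).
#'
#' @param data Data frame with the response, a group column and an age
#'   column.
#' @param response Name of the response column.
#' @param group,age Column names (defaults `"group"`, `"age"`).
#' @param band Optional `c(min, max)` age filter in years.
#' @return Object of class `group_anova`: `F`, `p`, `df`, `n`, and a
#'   `means` table (group mean ± SD, n).
#' @export
group_anova <- function(data, response, group = "group", age = "age",
                        band = NULL) {
  d <- data[is.finite(data[[response]]), ]
  if (!is.null(band)) d <- d[d[[age]] >= band[1] & d[[age]] <= band[2], ]
  if (!nrow(d)) stop("no cases in the requested age band")
  g <- factor(d[[group]])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 cases each")
  ks_normality_gate(d[[response]], response)
  fit <- stats::aov(d[[response]] ~ g)
  an <- summary(fit)[[1]]
  means <- do.call(rbind, lapply(split(d[[response]], g), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  means$group <- rownames(means)
  rownames(means) <- NULL
  structure(list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = unname(an$Df), n = nrow(d), response = response,
                 means = means[, c("group", "mean", "sd", "n")]),
            class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("<group_anova> %s: F(%d,%d) = %.3f, p = %.4g (n = %d)\n",
              x$response, x$df[1], x$df[2], x$F, x$p, x$n))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Developmental-trajectory ANCOVA with age as covariate
#'
#' Fits `feature ~ group + age + group:age` by OLS with treatment coding
#' (reference = first factor level, alphabetical unless the group column is
#' already a factor). The group-by-age interaction tests whether the
#' developmental slopes differ between groups; per-group OLS slopes and
#' intercepts (with SE) are reported alongside.
#'
#' @inheritParams group_anova
#' @return Object of class `trajectory_result`: `interaction` (estimate,
#'   SE, t, p), `group_effect_p`, `slopes` (per group: slope, SE, intercept,
#'   p, n), `fit` (the `lm`), `response`.
#' @export
trajectory_ancova <- function(data, response, group = "group", age = "age") {
  d <- data[is.finite(data[[response]]) & is.finite(data[[age]]), ]
  g <- factor(d[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tapply(d[[age]], g, function(a) length(unique(a))) < 2))
    stop("collinear design: at least one group observed at a single age; ",
         "slopes are not identifiable")
  if (any(table(g) < 3)) stop("need >= 3 cases per group")
  ks_normality_gate(stats::residuals(stats::lm(d[[response]] ~ g * d[[age]])),
                    paste(response, "residuals"))
  dd <- data.frame(y = d[[response]], g = g, a = d[[age]])
  fit <- stats::lm(y ~ g * a, data = dd)
  cf <- summary(fit)$coefficients
  int_row <- grep(":a$", rownames(cf))
  an <- stats::anova(fit)
  slopes <- do.call(rbind, lapply(levels(g), function(lv) {
    sub <- dd[dd$g == lv, ]
    sf <- summary(stats::lm(y ~ a, data = sub))$coefficients
    data.frame(group = lv, slope = sf["a", 1], slope_se = sf["a", 2],
               slope_p = sf["a", 4], intercept = sf["(Intercept)", 1],
               n = nrow(sub))
  }))
  structure(list(interaction = list(estimate = cf[int_row, 1][1],
                                    se = cf[int_row, 2][1],
                                    t = cf[int_row, 3][1],
                                    p = cf[int_row, 4][1]),
                 interaction_anova_p = an["g:a", "Pr(>F)"],
                 group_effect_p = an["g", "Pr(>F)"],
                 slopes = slopes, fit = fit, response = response,
                 n = nrow(dd)),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %s ~ group * age (n = %d)\n",
              x$response, x$n))
  cat(sprintf("  interaction (slope difference): %.5g +/- %.3g, p = %.4g\n",
              x$interaction$estimate, x$interaction$se, x$interaction$p))
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Covariate screen over morphometric features
#'
#' Screens each feature against nuisance covariates: Pearson correlation for
#' continuous covariates (PMI and the like), two-group t-test or one-way
#' ANOVA for categorical ones (sex, secondary diagnoses). Unadjusted p
#' values at 95% confidence; constant covariates are skipped with a note.
#' A Benjamini–Hochberg adjusted column is available on request and off by
#' default (published screens use per-test p < 0.05).
#'
#' @param data Data frame with feature and covariate columns.
#' @param features Character vector of feature column names.
#' @param covariates Character vector of covariate column names (default
#'   `c("sex", "pmi", "other_dx")`).
#' @param adjust Apply Benjamini–Hochberg across the table (default FALSE).
#' @return Data frame: `feature`, `covariate`, `type`, `statistic`,
#'   `estimate`, `p` (and `p_adj` if requested), `note`.
#' @export
covariate_screen <- function(data, features,
                             covariates = c("sex", "pmi", "other_dx"),
                             adjust = FALSE) {
  rows <- list()
  for (f in features) {
    y <- data[[f]]
    for (cv in covariates) {
      x <- data[[cv]]
      ok <- is.finite(y) & !is.na(x)
      note <- NA_character_
      if (is.numeric(x) && length(unique(x[ok])) > 2) {
        if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, covariate = cv, type = "correlation",
            statistic = NA_real_, estimate = NA_real_, p = NA_real_,
            note = "constant: skipped")
          next
        }
        ct <- stats::cor.test(x[ok], y[ok])
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, covariate = cv, type = "correlation",
          statistic = unname(ct$statistic), estimate = unname(ct$estimate),
          p = ct$p.value, note = note)
      } else {
        g <- factor(x[ok])
        if (nlevels(g) < 2 || any(table(g) < 2)) {
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, covariate = cv, type = "group",
            statistic = NA_real_, estimate = NA_real_, p = NA_real_,
            note = "constant or singleton level: skipped")
          next
        }
        if (nlevels(g) == 2) {
          tt <- stats::t.test(y[ok] ~ g)
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, covariate = cv, type = "t_test",
            statistic = unname(tt$statistic),
            estimate = unname(diff(rev(tt$estimate))),
            p = tt$p.value, note = note)
        } else {
          an <- summary(stats::aov(y[ok] ~ g))[[1]]
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, covariate = cv, type = "anova",
            statistic = an$`F value`[1], estimate = NA_real_,
            p = an$`Pr(>F)`[1], note = note)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
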