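#' Kaplan-Meier curve for a set of event records
#'
#' Product-limit estimate with a Greenwood confidence band (log scale), via
#' the survival package. The median is the smallest time at which the
#' survival function falls to 0.5 or below; if it never does, the median is
#' reported as not reached beyond the largest observed time (the analysis
#' horizon), mirroring "> horizon" reporting.
#'
#' @param records Data frame with `time_years` (>= 0) and `observed`
#'   (logical), e.g. one event type from [detect_events()].
#' @return List of class `km_curve`: `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n`, `median` (numeric or `NA`), `median_reached`,
#'   `horizon`, `median_label`.
#' @export
km_fit <- function(records) {
  if (is.null(records) || !nrow(records)) stop("empty input", call. = FALSE)
  if (any(records$time_years < 0)) stop("times must be >= 0", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_years, observed) ~ 1,
    data = records, conf.type = "log")
  s <- summary(fit, censored = FALSE)
  horizon <- max(records$time_years)
  drop_idx <- which(fit$surv <= 0.5 + 1e-12)
  median_reached <- length(drop_idx) > 0
  med <- if (median_reached) fit$time[min(drop_idx)] else NA_real_
  qs <- tryCatch(stats::quantile(fit, probs = 0.5, conf.int = TRUE),
                 error = function(e) NULL)
  med_ci <- if (!is.null(qs)) c(unname(unlist(qs$lower)[1]),
                                unname(unlist(qs$upper)[1]))
  else c(NA_real_, NA_real_)
  structure(list(time = s$time, surv = s$surv, lower = s$lower,
                 upper = s$upper, n_risk = s$n.risk, n = nrow(records),
                 median = med, median_reached = median_reached,
                 median_ci = med_ci,
                 horizon = horizon,
                 median_label = if (median_reached) format_score(med) else
                   paste0("not reached (> ", round(horizon, 1), ")")),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, "| events =", sum(!is.na(x$time)),
      "| median =", x$median_label, "\n")
  invisible(x)
}

#' Log-rank test between two groups of event records
#'
#' One-degree-of-freedom chi-square statistic over the pooled risk sets.
#'
#' @param groupA,groupB Data frames with `time_years`, `observed`.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
logrank_test <- function(groupA, groupB) {
  df <- rbind(
    data.frame(time_years = groupA$time_years, observed = groupA$observed,
               group = "A", stringsAsFactors = FALSE),
    data.frame(time_years = groupB$time_years, observed = groupB$observed,
               group = "B", stringsAsFactors = FALSE))
  sd <- survival::survdiff(survival::Surv(time_years, observed) ~ group,
                           data = df)
  stat <- unname(sd$chisq)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE), df = 1)
}

#' Group-difference test with normality-based routing
#'
#' Routing mirrors a standard applied pipeline: Shapiro-Wilk normality on
#' each sample, then (if both are compatible with normality at `alpha`)
#' Levene's test (median-centred) for variance equality choosing between
#' Welch and pooled t-tests; otherwise a Mann-Whitney U test. The route is a
#' pure function of the three sub-test p-values.
#'
#' @param x,y Numeric samples.
#' @param alpha Routing significance level (default 0.05).
#' @return List of class `test_record`: `route` (`"welch_t"`, `"pooled_t"` or
#'   `"mann_whitney"`), `shapiro_p` (length 2), `levene_p` (or `NA`),
#'   `statistic`, `p_value`.
#' @export
group_difference_test <- function(x, y, alpha = 0.05) {
  shapiro_p <- c(x = shapiro_p_safe(x), y = shapiro_p_safe(y))
  normal <- all(shapiro_p >= alpha)
  if (normal) {
    lev <- car::leveneTest(
      c(x, y) ~ factor(rep(c("x", "y"), c(length(x), length(y)))),
      center = stats::median)
    levene_p <- lev[["Pr(>F)"]][1]
    if (levene_p < alpha) {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      route <- "welch_t"
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      route <- "pooled_t"
    }
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    levene_p <- NA_real_
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value
    route <- "mann_whitney"
  }
  structure(list(route = route, shapiro_p = shapiro_p, levene_p = levene_p,
                 statistic = stat, p_value = p, alpha = alpha),
            class = "test_record")
}

shapiro_p_safe <- function(x) {
  if (length(unique(x)) < 3) return(0)  # degenerate: route nonparametric
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value
}

#' Per-year score summaries since diagnosis
#'
#' Bins observations by whole years since diagnosis (`[k, k+1)`), reporting
#' mean, median, a 95\% t confidence interval (only when n >= 2 and the
#' within-bin variance is positive-definite) and n. Empty bins are omitted.
#'
#' @param scores Data frame with `value` and `years_since_dx`.
#' @param horizon_years Upper limit on years since diagnosis (default 10).
#' @return Data frame: `year_bin`, `n`, `mean`, `median`, `ci_low`, `ci_high`.
#' @export
stratified_score_summary <- function(scores, horizon_years = 10) {
  s <- scores[scores$years_since_dx >= 0 &
                scores$years_since_dx < horizon_years, , drop = FALSE]
  if (!nrow(s)) return(data.frame(year_bin = integer(), n = integer(),
                                  mean = numeric(), median = numeric(),
                                  ci_low = numeric(), ci_high = numeric()))
  bin <- floor(s$years_since_dx)
  agg <- lapply(sort(unique(bin)), function(k) {
    v <- s$value[bin == k]
    n <- length(v)
    m <- mean(v)
    if (n >= 2 && stats::sd(v) > 0) {
      half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
      ci <- c(m - half, m + half)
    } else if (n >= 2) {
      ci <- c(m, m)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(year_bin = k, n = n, mean = m, median = stats::median(v),
               ci_low = ci[1], ci_high = ci[2])
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted score progression regression
#'
#' Ordinary least squares of per-visit scores on years since diagnosis plus
#' covariates (age at diagnosis, sex, optionally education), fitting
#' irregularly sampled visit data. Reports the annual slope, the intercept at
#' diagnosis evaluated at the sample's covariate means, model-based and
#' (optionally) patient-cluster-robust standard errors, residual-normality
#' diagnostics, and variance inflation factors with a VIF >= 10 flag.
#'
#' @param table Data frame with the score column, `years_since_dx`, the
#'   covariate columns, and (for cluster-robust errors) `patient_id`.
#' @param score_col Name of the score column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param cluster Cluster-robust standard errors by `patient_id` (default
#'   TRUE when the column is present).
#' @param time_error_var Known variance (years squared) of measurement error
#'   in `years_since_dx`. Year-resolution diagnosis dates analyzed from a
#'   mid-year origin carry a uniform error on (-0.5, 0.5) y, variance 1/12;
#'   the slope is then corrected by regression calibration (divided by the
#'   reliability ratio `1 - time_error_var / Var(t | covariates)`) and the
#'   intercept recentred so the fitted line passes through the sample means.
#'   Default 0 (no correction).
#' @return List of class `progression_fit`: `coefficients`, `se`,
#'   `robust_se`, `slope`, `slope_se`, `intercept_at_dx`,
#'   `intercept_at_dx_se`, `reliability`, `vif`, `vif_flag`,
#'   `residual_normality_p`, `n_obs`, `n_patients`, `model`.
#' @export
fit_progression_model <- function(table, score_col, covariates = character(),
                                  cluster = "patient_id" %in% names(table),
                                  time_error_var = 0) {
  vars <- c("years_since_dx", covariates)
  table <- table[stats::complete.cases(table[, c(score_col, vars)]), ,
                 drop = FALSE]
  fml <- stats::reformulate(vars, response = score_col)
  fit <- stats::lm(fml, data = table)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear covariate(s): ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(fit)
  vc_model <- stats::vcov(fit)
  vc <- if (cluster)
    sandwich::vcovCL(fit, cluster = table$patient_id) else vc_model
  se_model <- sqrt(diag(vc_model))
  se_rob <- sqrt(diag(vc))

  ## intercept at diagnosis: prediction at t = 0, other covariates at their
  ## sample means (sex and other factors enter via the design-matrix mean).
  xbar <- colMeans(X)
  tbar <- xbar[["years_since_dx"]]
  xbar[["years_since_dx"]] <- 0
  intercept_at_dx <- sum(co * xbar)
  intercept_se <- sqrt(drop(t(xbar) %*% vc %*% xbar))

  reliability <- 1
  if (time_error_var > 0) {
    t_resid_var <- if (length(covariates)) {
      stats::var(stats::residuals(stats::lm(
        stats::reformulate(covariates, response = "years_since_dx"),
        data = table)))
    } else stats::var(table$years_since_dx)
    reliability <- max(1 - time_error_var / t_resid_var, 1e-6)
    slope_raw <- co[["years_since_dx"]]
    slope_cal <- slope_raw / reliability
    intercept_at_dx <- intercept_at_dx - (slope_cal - slope_raw) * tbar
    co[["years_since_dx"]] <- slope_cal
    se_rob[["years_since_dx"]] <- se_rob[["years_since_dx"]] / reliability
    se_model[["years_since_dx"]] <- se_model[["years_since_dx"]] / reliability
  }

  vif <- if (length(vars) >= 2) tryCatch({
    v <- car::vif(fit)
    if (is.matrix(v)) stats::setNames(v[, 1], rownames(v)) else v
  }, error = function(e) NULL) else NULL
  vif_flag <- !is.null(vif) && any(vif >= 10)

  res <- stats::residuals(fit)
  res_p <- shapiro_p_safe(res)

  structure(list(
    coefficients = co, se = se_model, robust_se = se_rob,
    slope = unname(co[["years_since_dx"]]),
    slope_se = unname(se_rob[["years_since_dx"]]),
    intercept_at_dx = intercept_at_dx, intercept_at_dx_se = intercept_se,
    reliability = reliability,
    vif = vif, vif_flag = vif_flag, residual_normality_p = res_p,
    n_obs = nrow(table),
    n_patients = if ("patient_id" %in% names(table))
      length(unique(table$patient_id)) else NA_integer_,
    cluster = cluster, score_col = score_col, model = fit),
    class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat("<progression_fit>", x$score_col, "~ years_since_dx + covariates\n")
  cat(sprintf("  slope: %.3f /y (SE %.3f), intercept at dx: %.2f (SE %.3f)\n",
              x$slope, x$slope_se, x$intercept_at_dx, x$intercept_at_dx_se))
  cat("  n_obs:", x$n_obs, "n_patients:", x$n_patients,
      if (x$vif_flag) "| WARNING: VIF >= 10\n" else "\n")
  invisible(x)
}

#' Compare progression slopes between two sources
#'
#' Pooled model with a source-by-time interaction; the slope difference is
#' the interaction coefficient, Wald-tested with cluster-robust standard
#' errors. Also reports the difference of slopes from separate per-source
#' fits.
#'
#' @param table Pooled data frame including a `source` column.
#' @param score_col Score column name.
#' @param covariates Covariate column names.
#' @param cluster Cluster-robust by `patient_id` (default if present).
#' @return List: `slope_diff`, `se`, `statistic`, `p_value`,
#'   `separate_fit_diff`, `slopes` (per source).
#' @export
compare_progression_slopes <- function(table, score_col,
                                       covariates = character(),
                                       cluster = "patient_id" %in% names(table)) {
  stopifnot("source" %in% names(table))
  table$source <- factor(table$source)
  if (nlevels(table$source) != 2)
    stop("exactly two sources required", call. = FALSE)
  rhs <- paste(c("years_since_dx * source", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(score_col, "~", rhs))
  fit <- stats::lm(fml, data = table)
  vc <- if (cluster) sandwich::vcovCL(fit, cluster = table$patient_id) else
    stats::vcov(fit)
  cn <- names(stats::coef(fit))
  int_name <- grep("years_since_dx:source", cn, value = TRUE)
  est <- stats::coef(fit)[[int_name]]
  se <- sqrt(vc[int_name, int_name])
  z <- est / se
  sep <- lapply(split(table, table$source), function(d)
    fit_progression_model(d, score_col, covariates, cluster = cluster))
  slopes <- vapply(sep, `[[`, numeric(1), "slope")
  list(slope_diff = est, se = se, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       separate_fit_diff = unname(slopes[2] - slopes[1]),
       slopes = slopes)
}

#' Score-presence missingness audit
#'
#' Can patient features predict whether a rating score was recorded? Fits a
#' logistic classifier under k-fold cross-validation and reports the pooled
#' out-of-fold AUC. An AUC near 0.5 supports treating score presence as
#' unpredictable from the measured features.
#'
#' @param features Data frame of per-patient covariates (numeric/factor).
#' @param has_score Logical/0-1 outcome vector.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `auc`, `fold_auc`, `n`, `k`.
#' @export
missingness_audit <- function(features, has_score, k = 5, seed = 1L) {
  y <- as.integer(as.logical(has_score))
  stopifnot(nrow(features) == length(y))
  df <- cbind(data.frame(.y = y), features)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), nrow(df)))
  pred <- numeric(nrow(df))
  for (f in seq_len(k)) {
    tr <- df[fold != f, , drop = FALSE]
    te <- df[fold == f, , drop = FALSE]
    m <- stats::glm(.y ~ ., data = tr, family = stats::binomial())
    pred[fold == f] <- stats::predict(m, newdata = te, type = "response")
  }
  roc <- pROC::roc(response = y, predictor = pred, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  fold_auc <- vapply(seq_len(k), function(f) {
    yy <- y[fold == f]
    if (length(unique(yy)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(yy, pred[fold == f], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  list(auc = as.numeric(pROC::auc(roc)), fold_auc = fold_auc,
       n = length(y), k = k)
}
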