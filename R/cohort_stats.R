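#' Built-in cohort dichotomies
#'
#' The grouping contrasts of the study battery. Each entry names the
#' label column, the values forming the first ("high", conventionally
#' more aggressive) group and the reference ("low") group, and whether
#' the contrast is restricted to invasive carcinomas. Lesions whose label
#' is missing or outside the two groups are dropped listwise within the
#' contrast.
#'
#' @return Named list of dichotomy definitions.
#' @export
study_dichotomies <- function() {
  list(
    histopathology = list(var = "histopathology", high = "invasive",
                          low = "DCIS", invasive_only = FALSE,
                          label = "Invasive carcinoma vs DCIS"),
    grade = list(var = "grade", high = "3", low = c("1", "2"),
                 invasive_only = TRUE, label = "Grade 3 vs grades 1-2"),
    histotype = list(var = "histotype", high = "IDC", low = "ILC",
                     invasive_only = TRUE, label = "IDC vs ILC"),
    molecular = list(var = "molecular", high = c("TN", "HER2"),
                     low = "luminal", invasive_only = TRUE,
                     label = "TN/HER2 vs luminal"),
    node = list(var = "node_status", high = "positive", low = "negative",
                invasive_only = TRUE,
                label = "Node positive vs negative"),
    recurrence = list(var = "recurrence_risk",
                      high = c("high", "intermediate"), low = "low",
                      invasive_only = TRUE,
                      label = "High/intermediate vs low recurrence risk")
  )
}

resolve_dichotomy <- function(grouping) {
  if (is.character(grouping)) {
    d <- study_dichotomies()[[grouping]]
    if (is.null(d)) stop("unknown dichotomy '", grouping, "'")
    d
  } else if (is.list(grouping) &&
             all(c("var", "high", "low") %in% names(grouping))) {
    grouping$invasive_only <- isTRUE(grouping$invasive_only)
    grouping$label <- grouping$label %||% grouping$var
    grouping
  } else stop("'grouping' must be a dichotomy name or a list(var, high, low)")
}

#' Compare a kinetic marker between two lesion groups with GEE
#'
#' Gaussian identity-link GEE of the marker on a group indicator over
#' patient clusters with bias-reduced sandwich standard errors (Wald
#' p-value), accounting for multiple lesions per patient. The default
#' working correlation is independence: the sandwich covariance is
#' cluster-aware regardless of the working structure, and with 1-3
#' lesions per patient the exchangeable correlation parameter is
#' estimated from so few within-patient pairs that its noise visibly
#' inflates the test's size (see the methods vignette); exchangeable is
#' retained as a sensitivity option. Medians and IQRs per group are
#' reported descriptively alongside.
#'
#' @param table Cohort data frame (one row per lesion) with columns
#'   `patient_id`, the marker column, and the grouping label column.
#' @param value Marker column to compare, `"ms"` or `"bat"` (any numeric
#'   column name is accepted).
#' @param grouping A name from [study_dichotomies()] or a custom
#'   `list(var=, high=, low=)`.
#' @param corstr Working correlation, passed to [gee_fit()].
#' @param cov_type Sandwich flavor (see [gee_fit()]); the bias-reduced
#'   small-sample correction is the default for reported p-values.
#' @return An object of class `group_comparison`: per-group summaries,
#'   the GEE coefficient for the "high" group, robust SE and p-value.
#' @export
gee_compare <- function(table, value = c("ms", "bat"), grouping,
                        corstr = "independence",
                        cov_type = "bias-reduced") {
  value <- if (is.character(value) && length(value) > 1L)
    match.arg(value) else value
  d <- resolve_dichotomy(grouping)
  df <- table
  if (d$invasive_only) df <- df[df$histopathology %in% "invasive", ]
  g <- df[[d$var]]
  sel <- !is.na(g) & g %in% c(d$high, d$low) & !is.na(df[[value]])
  df <- df[sel, ]
  group <- ifelse(df[[d$var]] %in% d$high, 1, 0)
  if (length(unique(group)) < 2L)
    stop("both groups must be present for '", d$label, "'")
  if (min(table(group)) < 2L)
    stop("need at least 2 lesions per group for '", d$label, "'")
  df$.group <- group
  fml <- stats::as.formula(paste(value, "~ .group"))
  fit <- gee_fit(fml, id = "patient_id", data = df, family = "gaussian",
                 corstr = corstr, cov_type = cov_type)
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sh <- q(df[[value]][group == 1])
  sl <- q(df[[value]][group == 0])
  groups <- data.frame(
    group = c(paste(d$high, collapse = "/"), paste(d$low, collapse = "/")),
    n = c(sum(group == 1), sum(group == 0)),
    median = c(sh[2], sl[2]), q1 = c(sh[1], sl[1]), q3 = c(sh[3], sl[3]),
    stringsAsFactors = FALSE
  )
  structure(
    list(label = d$label, value = value, groups = groups,
         coefficient = unname(fit$coefficients[".group"]),
         robust_se = unname(fit$robust_se[".group"]),
         p_value = unname(fit$p_value[".group"]),
         fit = fit),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s — %s\n", x$label, x$value))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-28s n=%3d  median %.4g (IQR %.4g-%.4g)\n",
                g$group[i], g$n[i], g$median[i], g$q1[i], g$q3[i]))
  cat(sprintf("  GEE coefficient %.4g (robust SE %.4g), P = %.4g\n",
              x$coefficient, x$robust_se, x$p_value))
  invisible(x)
}

#' Two-reader intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation from the two-way ANOVA mean squares, with the
#' F-based 95% confidence interval of McGraw & Wong, and the Cicchetti
#' interpretation band (>= 0.75 excellent, 0.60-0.74 good, 0.40-0.59
#' fair, < 0.40 poor).
#'
#' @param reader1,reader2 Paired measurements of the same lesions by two
#'   readers (equal length, at least 3 pairs).
#' @param conf_level Confidence level of the interval.
#' @return An object of class `icc_result`: `icc`, `ci` (length 2),
#'   `band`, the ANOVA mean squares, and `n`.
#' @export
icc_two_reader <- function(reader1, reader2, conf_level = 0.95) {
  if (length(reader1) != length(reader2))
    stop("readers must supply paired measurements of equal length")
  ok <- stats::complete.cases(reader1, reader2)
  x <- cbind(reader1[ok], reader2[ok])
  n <- nrow(x)
  k <- 2
  if (n < 3L) stop("at least 3 complete pairs are required")
  if (stats::var(as.vector(x)) == 0)
    stop("zero total variance: ICC undefined")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # targets
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # readers
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  a <- 1 - conf_level
  fc <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fc + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fc^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- stats::qf(1 - a / 2, n - 1, v)
  f_l <- stats::qf(1 - a / 2, v, n - 1)
  lower <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  structure(
    list(icc = icc, ci = c(lower, upper), conf_level = conf_level,
         band = cicchetti_band(icc), msr = msr, msc = msc, mse = mse,
         n = n),
    class = "icc_result"
  )
}

#' Cicchetti interpretation band for an ICC
#'
#' @param icc Intraclass correlation coefficient.
#' @return `"excellent"` (0.75-1.00), `"good"` (0.60-0.74), `"fair"`
#'   (0.40-0.59) or `"poor"` (< 0.40).
#' @export
cicchetti_band <- function(icc) {
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI %.3f, %.3f) over %d pairs: %s agreement\n",
              x$icc, round(100 * x$conf_level), x$ci[1], x$ci[2], x$n,
              x$band))
  invisible(x)
}

#' Multivariate logistic GEE model for invasive carcinoma vs DCIS
#'
#' Binomial logit GEE of histopathology (invasive = 1, DCIS = 0) on a set
#' of lesion covariates, with patient clusters, exchangeable working
#' correlation and robust standard errors; by default restricted to
#' non-mass enhancement (NME) lesions with covariates MS, BAT and lesion
#' size. Complete separation is reported via the `separation` flag, not
#' silently repaired.
#'
#' @param table Cohort data frame.
#' @param covariates Covariate column names.
#' @param lesion_type Restrict to this lesion type (`NULL` = all lesions).
#' @param corstr Working correlation.
#' @param cov_type Sandwich flavor (see [gee_fit()]).
#' @return An object of class `logistic_model`: coefficient table,
#'   per-lesion fitted probabilities (aligned with the analyzed subset),
#'   the analyzed subset itself, and flags.
#' @export
gee_logistic <- function(table,
                         covariates = c("ms", "bat", "lesion_size_mm"),
                         lesion_type = "NME", corstr = "independence",
                         cov_type = "bias-reduced") {
  df <- table
  if (!is.null(lesion_type)) df <- df[df$lesion_type %in% lesion_type, ]
  keep <- stats::complete.cases(df[, c("histopathology", "patient_id",
                                       covariates)])
  df <- df[keep, ]
  cls <- unique(df$histopathology)
  if (!all(c("invasive", "DCIS") %in% cls))
    stop("both outcome classes (invasive, DCIS) must be present in the subset")
  df$.y <- as.numeric(df$histopathology == "invasive")
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- gee_fit(fml, id = "patient_id", data = df, family = "binomial",
                 corstr = corstr, cov_type = cov_type)
  coef_table <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    robust_se = unname(fit$robust_se),
    p_value = unname(fit$p_value),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coef_table, fitted = fit$fitted, data = df,
         separation = fit$separation, converged = fit$converged,
         n = fit$n, fit = fit),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic GEE, invasive vs DCIS (n = %d)%s\n", x$n,
              if (x$separation) " [possible separation]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted half; computed from ranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is positive).
#' @return The AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  y <- if (is.factor(labels)) as.numeric(labels) - 1 else as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  y
}

#' DeLong's test for two correlated ROC AUCs
#'
#' Paired nonparametric comparison of the AUCs of two models scored on
#' the same lesions, using the placement-value covariance estimator of
#' DeLong et al. (1988) and a two-sided normal p-value. When the two
#' score vectors give identical placements (e.g. identical models) the
#' variance of the difference is zero and p = 1 by convention.
#'
#' @param scores1,scores2 Paired model scores on identical cases.
#' @param labels Binary labels as in [auc()].
#' @return An object of class `delong_test`: `auc1`, `auc2`, `delta`,
#'   `z`, `p_value`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  if (length(scores1) != length(scores2) ||
      length(scores1) != length(labels))
    stop("scores and labels must be paired vectors of equal length")
  y <- normalize_labels(labels)
  pos <- which(y == 1)
  neg <- which(y == 0)
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  placements <- function(s) {
    X <- s[pos]
    Y <- s[neg]
    cmp <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
  }
  p1 <- placements(scores1)
  p2 <- placements(scores2)
  a1 <- mean(p1$v10)
  a2 <- mean(p2$v10)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a1 - a2
  if (var_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = a1, auc2 = a2, delta = delta, z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f (delta %.3f), P = %.4g\n",
              x$auc1, x$auc2, x$delta, x$p_value))
  invisible(x)
}

#' Run the full study comparison battery on a cohort table
#'
#' Executes, on a cohort table of measured kinetics: the invasive-vs-DCIS
#' contrast and the five invasive-carcinoma dichotomies (grade,
#' histotype, molecular subtype, node status, recurrence risk), each for
#' MS and BAT via [gee_compare()]; the multivariate logistic GEE model
#' (MS + BAT + size) for invasive vs DCIS in NME lesions; and the DeLong
#' comparison of that model's AUC against a size-alone model. Contrasts
#' with p < 0.05 are flagged; no multiplicity adjustment is applied.
#'
#' @param table Cohort data frame with columns `patient_id`, `ms`, `bat`,
#'   `lesion_size_mm`, `lesion_type` and the label columns.
#' @param alpha Significance threshold for flagging.
#' @return An object of class `study_report` with elements `contrasts`
#'   (list over dichotomies, each with `$ms` and `$bat`
#'   `group_comparison`s), `logistic`, `auc_comparison`, and `flagged`.
#' @export
run_study <- function(table, alpha = 0.05) {
  need <- c("patient_id", "ms", "bat", "lesion_size_mm", "lesion_type",
            "histopathology", "grade", "histotype", "molecular",
            "node_status", "recurrence_risk")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  # contrasts that cannot be formed on a given cohort (e.g. a group absent
  # in a small run) are recorded as errors, not fatal
  contrasts <- lapply(names(study_dichotomies()), function(nm) {
    tryCatch(list(ms = gee_compare(table, "ms", nm),
                  bat = gee_compare(table, "bat", nm)),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(contrasts) <- names(study_dichotomies())
  logistic <- tryCatch(gee_logistic(table),
                       error = function(e) list(error = conditionMessage(e)))
  auc_comparison <- if (is.null(logistic$error)) {
    size_fit <- gee_fit(.y ~ lesion_size_mm, id = "patient_id",
                        data = logistic$data, family = "binomial",
                        corstr = "independence", cov_type = "bias-reduced")
    delong_test(logistic$fitted, size_fit$fitted, logistic$data$.y)
  } else list(error = logistic$error)
  flagged <- character(0)
  for (nm in names(contrasts)) {
    if (!is.null(contrasts[[nm]]$error)) next
    for (vv in c("ms", "bat"))
      if (contrasts[[nm]][[vv]]$p_value < alpha)
        flagged <- c(flagged, paste(nm, vv, sep = "."))
  }
  if (is.null(auc_comparison$error) && auc_comparison$p_value < alpha)
    flagged <- c(flagged, "auc_comparison")
  structure(
    list(contrasts = contrasts, logistic = logistic,
         auc_comparison = auc_comparison, flagged = flagged,
         alpha = alpha, n_lesions = nrow(table),
         n_patients = length(unique(table$patient_id))),
    class = "study_report"
  )
}

#' Tidy data frame of the contrasts in a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return One row per (dichotomy, marker) contrast.
#' @export
as.data.frame.study_report <- function(x, ...) {
  rows <- lapply(names(x$contrasts), function(nm) {
    if (!is.null(x$contrasts[[nm]]$error)) return(NULL)
    do.call(rbind, lapply(c("ms", "bat"), function(vv) {
      ct <- x$contrasts[[nm]][[vv]]
      g <- ct$groups
      data.frame(contrast = nm, value = vv, label = ct$label,
                 n = sum(g$n),
                 group_high = g$group[1], n_high = g$n[1],
                 median_high = g$median[1],
                 group_low = g$group[2], n_low = g$n[2],
                 median_low = g$median[2],
                 coefficient = ct$coefficient, robust_se = ct$robust_se,
                 p_value = ct$p_value, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d lesions in %d patients\n",
              x$n_lesions, x$n_patients))
  for (nm in names(x$contrasts)) {
    if (!is.null(x$contrasts[[nm]]$error)) {
      cat(sprintf("  %-38s     [not estimable: %s]\n", nm,
                  x$contrasts[[nm]]$error))
      next
    }
    for (vv in c("ms", "bat")) {
      ct <- x$contrasts[[nm]][[vv]]
      star <- if (ct$p_value < x$alpha) " *" else ""
      cat(sprintf("  %-38s %-3s P = %.4g%s\n", ct$label, vv,
                  ct$p_value, star))
    }
  }
  if (is.null(x$logistic$error)) {
    cat("Logistic model (NME, invasive vs DCIS):\n")
    print(x$logistic$coefficients, row.names = FALSE, digits = 3)
    cat(sprintf("AUC full model %.3f vs size alone %.3f, DeLong P = %.4g\n",
                x$auc_comparison$auc1, x$auc_comparison$auc2,
                x$auc_comparison$p_value))
  } else {
    cat(sprintf("Logistic model not estimable: %s\n", x$logistic$error))
  }
  invisible(x)
}
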