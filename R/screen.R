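#' Two-factor ANOVA for one variable: disease status and dichotomized age
#'
#' Fits a main-effects linear model of a (transformed) variable on
#' disease status (patient vs control) and age dichotomized at 38
#' years, and extracts the status effect: its p-value, partial
#' eta-squared and direction. With main effects only, the Type-III sum
#' of squares for status equals the increase in residual sum of squares
#' when status is dropped from the full model, which is how it is
#' computed here. If one of the age strata is empty the model falls
#' back to one-way ANOVA on status with a warning.
#'
#' @param values Numeric response (typically power-transformed).
#' @param group Factor-like with levels `"patient"` and `"control"`.
#' @param age Age in years; dichotomized as `age <= age_cut` vs above.
#' @param age_cut Dichotomization threshold (default 38).
#' @return A one-row tibble: `eta_p_sq`, `p_MS`, `direction`
#'   (`"up"` if patients higher on the analysis scale), `estimate`
#'   (patient minus control adjusted effect), `n_used`.
#' @export
anova_ms_age <- function(values, group, age, age_cut = 38) {
  keep <- is.finite(values) & !is.na(group) & !is.na(age)
  values <- values[keep]; group <- group[keep]; age <- age[keep]
  ms01 <- as.numeric(group == "patient")
  if (all(ms01 == 0) || all(ms01 == 1)) {
    stop("both patient and control values required")
  }
  old01 <- as.numeric(age > age_cut)
  two_way <- any(old01 == 0) && any(old01 == 1)
  if (!two_way) {
    warning("an age stratum is empty; falling back to one-way ANOVA on status")
    X_full <- cbind(1, ms01)
    X_red <- cbind(rep(1, length(values)))
  } else {
    X_full <- cbind(1, ms01, old01)
    X_red <- cbind(1, old01)
  }
  fit <- stats::lm.fit(X_full, values)
  rss_full <- sum(fit$residuals^2)
  rss_red <- sum(stats::lm.fit(X_red, values)$residuals^2)
  ss_ms <- rss_red - rss_full
  ss_res <- rss_full
  df_res <- length(values) - ncol(X_full)
  fstat <- (ss_ms / 1) / (ss_res / df_res)
  p <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
  est <- unname(fit$coefficients[2])
  tibble::tibble(
    eta_p_sq = ss_ms / (ss_ms + ss_res),
    p_MS = p,
    direction = ifelse(est >= 0, "up", "down"),
    estimate = est,
    n_used = length(values)
  )
}

#' Median and quartiles per group on the original scale
#'
#' @param values Numeric vector on the reporting (untransformed) scale.
#' @param group Group labels.
#' @return A tibble with one row per group: `group`, `n`, `median`,
#'   `q1`, `q3` (linear-interpolation quantiles, R type 7).
#' @examples
#' describe_groups(1:5, rep("control", 5))
#' @export
describe_groups <- function(values, group) {
  keep <- is.finite(values) & !is.na(group)
  sp <- split(values[keep], as.character(group[keep]))
  if (!length(sp)) stop("no groups present")
  if (any(lengths(sp) < 3)) stop("need at least 3 values per group")
  q <- vapply(sp, stats::quantile, numeric(3),
              probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(group = names(sp), n = unname(lengths(sp)),
                 median = unname(q[2, ]), q1 = unname(q[1, ]),
                 q3 = unname(q[3, ]))
}

#' Correlate one variable with disease-severity indices in patients
#'
#' Pearson (default) or Spearman correlation of a transformed variable
#' with each severity index, restricted to patients, with the usual
#' two-sided t-test on n - 2 degrees of freedom. Indices with fewer
#' than `min_pairs` complete pairs are returned as `NA` and flagged.
#'
#' @param values Numeric (transformed) variable over all subjects.
#' @param data Data frame holding `group` and the index columns.
#' @param indices Index column names (default the four standard
#'   severity scores: EDSS, timed 25-foot walk, 9-hole peg test
#'   right/left).
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs Minimum complete pairs per index (default 5).
#' @return A tibble with one row per index: `index`, `r`, `p`, `n`,
#'   `insufficient`.
#' @export
correlate_severity <- function(values, data,
                               indices = c("EDSS", "T25FWT",
                                           "HPT9_R", "HPT9_L"),
                               method = c("pearson", "spearman"),
                               min_pairs = 5) {
  method <- match.arg(method)
  pat <- data$group == "patient"
  r <- p <- rep(NA_real_, length(indices))
  n <- integer(length(indices))
  for (i in seq_along(indices)) {
    ix <- indices[i]
    if (!ix %in% names(data)) next
    x <- values[pat]; y <- data[[ix]][pat]
    ok <- is.finite(x) & is.finite(y)
    n[i] <- sum(ok)
    if (n[i] < min_pairs) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  tibble::tibble(index = indices, r = r, p = p, n = n,
                 insufficient = is.na(r))
}

#' Screen every variable of a case-control table
#'
#' Runs [anova_ms_age()] on the transformed scale, [describe_groups()]
#' on the original scale and [correlate_severity()] per variable, and
#' assembles one tidy row per variable. This is the per-variable stage
#' whose significance-direction codes feed the trend meta-test.
#'
#' @param transformed Table of transformed analysis variables plus
#'   metadata columns (`group`, `age`, severity indices).
#' @param original Optional table on the original scale for the group
#'   descriptive statistics; defaults to `transformed`.
#' @param vars Variables to screen (default: all analysis variables).
#' @param alpha Significance level used for the direction codes.
#' @param cor_method Correlation method for severity indices.
#' @return A `screen_result` tibble: per variable `eta_p_sq`, `p_MS`,
#'   `direction`, `code` (+1/0/-1 at `alpha`), group medians and
#'   quartiles, and one `r_*`/`p_*` column pair per severity index.
#' @export
screen_variables <- function(transformed, original = transformed,
                             vars = NULL, alpha = 0.05,
                             cor_method = "pearson") {
  vars <- vars %||% analysis_vars(transformed)
  severity_present <- any(c("EDSS", "T25FWT", "HPT9_R", "HPT9_L") %in%
                            names(transformed))
  rows <- lapply(vars, function(v) {
    a <- anova_ms_age(transformed[[v]], transformed$group, transformed$age)
    desc <- describe_groups(original[[v]], original$group)
    row <- c(list(variable = v), as.list(a))
    for (stat in c("n", "median", "q1", "q3")) {
      vals <- as.list(desc[[stat]])
      names(vals) <- paste0(stat, "_", desc$group)
      row <- c(row, vals)
    }
    if (severity_present) {
      cors <- correlate_severity(transformed[[v]], transformed,
                                 method = cor_method)
      rp <- c(as.list(cors$r), as.list(cors$p))
      names(rp) <- c(paste0("r_", cors$index), paste0("p_", cors$index))
      row <- c(row, rp)
    }
    row
  })
  res <- dplyr::bind_rows(rows)
  res$code <- ifelse(res$p_MS < alpha,
                     ifelse(res$direction == "up", 1L, -1L), 0L)
  class(res) <- c("screen_result", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' Count significance directions per variable group
#'
#' Reduces screening results to the trend triplets (u/m/d): per
#' declared variable group, the number of variables significantly up,
#' not significant, and significantly down at level `alpha`. Severity
#' correlations can be counted the same way via `on`.
#'
#' @param results A `screen_result` from [screen_variables()].
#' @param groups Named list of character vectors of variable names; a
#'   variable may appear in several groups. Default: one group with
#'   every screened variable.
#' @param alpha Significance level (default 0.05).
#' @param on `"status"` counts the patient-vs-control effect codes;
#'   `"EDSS"`, `"T25FWT"`, `"HPT9_R"` or `"HPT9_L"` counts the severity
#'   correlation signs instead.
#' @return A tibble with one row per group: `group_name`, `n_up`,
#'   `n_null`, `n_down`.
#' @examples
#' \dontrun{
#' code_directions(res, groups = list(total = res$variable))
#' }
#' @export
code_directions <- function(results, groups = NULL, alpha = 0.05,
                            on = "status") {
  groups <- groups %||% list(all = results$variable)
  if (on == "status") {
    p <- results$p_MS
    up <- results$direction == "up"
  } else {
    p <- results[[paste0("p_", on)]]
    up <- results[[paste0("r_", on)]] > 0
    if (is.null(p)) stop("no severity correlations for index ", on)
  }
  purrr::imap_dfr(groups, function(vars, name) {
    i <- match(vars, results$variable)
    if (anyNA(i)) stop("group '", name, "' names unscreened variables")
    pi <- p[i]; upi <- up[i]
    sig <- !is.na(pi) & pi < alpha
    tibble::tibble(group_name = name,
                   n_up = sum(sig & upi),
                   n_null = sum(!sig),
                   n_down = sum(sig & !upi))
  })
}

#' Trend tests for every enzyme panel of a screened table
#'
#' Convenience wrapper: builds the standard variable groups (all
#' variables, unconjugated, conjugated, each steroid class, each ratio
#' panel — whichever apply to the screened variables), counts
#' direction codes and runs [trend_test()] on each triplet.
#'
#' @param results A `screen_result`.
#' @param catalog A `steroid_catalog` used to assign variables to
#'   groups; ratio variables are grouped by their panel.
#' @inheritParams code_directions
#' @return A tibble of trend results, one row per non-empty group,
#'   with a `label` column in `"(u/m/d, p = ...)"` notation.
#' @export
panel_trends <- function(results, catalog = load_catalog(), alpha = 0.05,
                         on = "status") {
  an <- catalog$analytes
  vars <- results$variable
  groups <- list()
  analyte_vars <- intersect(vars, an$abbreviation)
  if (length(analyte_vars)) {
    groups$total_steroids <- analyte_vars
    groups$unconjugated <- intersect(
      analyte_vars, an$abbreviation[!an$conjugated])
    groups$conjugated <- intersect(
      analyte_vars, an$abbreviation[an$conjugated])
    cls <- split(an$abbreviation, an$steroid_class)
    for (k in names(cls)) {
      g <- intersect(analyte_vars, cls[[k]])
      if (length(g)) groups[[paste0("class_", k)]] <- g
    }
  }
  ratio_vars <- intersect(vars, catalog$ratios$name)
  if (length(ratio_vars)) {
    pan <- split(catalog$ratios$name, catalog$ratios$panel)
    for (k in names(pan)) {
      g <- intersect(ratio_vars, pan[[k]])
      if (length(g)) groups[[k]] <- g
    }
  }
  groups <- groups[lengths(groups) > 0]
  counts <- code_directions(results, groups, alpha = alpha, on = on)
  res <- trend_test(counts$n_up, counts$n_null, counts$n_down)
  out <- dplyr::bind_cols(counts["group_name"], res)
  out$label <- format_trend(out)
  out
}
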