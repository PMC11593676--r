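#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' significance level for direction coding (0.05, two-sided), the
#' Box-Cox exponent grid, the severity correlation method, the VIP
#' elimination threshold (1.0), the number of venetian-blind
#' cross-validation folds (7), the Hotelling screening level (0.95)
#' and the ratio panels to model.
#'
#' @param alpha Two-sided significance level for direction codes.
#' @param grid Box-Cox exponent grid.
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param vip_threshold VIP cutoff for predictor elimination.
#' @param cv_folds Venetian-blind folds.
#' @param hotelling_level Confidence level of the score ellipse.
#' @param opls_panels Panels to fit OPLS models on: `"steroids"`
#'   (all analytes jointly) and/or ratio panel names; `NULL` skips the
#'   OPLS stage.
#' @param seed Seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05,
                            grid = seq(-3, 3, by = 0.01),
                            cor_method = "pearson",
                            vip_threshold = 1,
                            cv_folds = 7,
                            hotelling_level = 0.95,
                            opls_panels = "steroids",
                            seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, vip_threshold >= 0, cv_folds >= 2,
            hotelling_level > 0, hotelling_level <= 1)
  structure(list(alpha = alpha, grid = grid, cor_method = cor_method,
                 vip_threshold = vip_threshold, cv_folds = cv_folds,
                 hotelling_level = hotelling_level,
                 opls_panels = opls_panels, seed = seed),
            class = "pipeline_config")
}

#' Read / write a concentration table
#'
#' CSV with columns `subject_id`, `group` (`patient`/`control`),
#' `age`, the severity indices when available, then one column per
#' analyte key. An optional unit declaration row (with
#' `subject_id == "unit"`) immediately after the header gives each
#' analyte's molar unit; on write the unit row is emitted from
#' `attr(data, "units")`.
#'
#' @param file Path to a CSV file.
#' @return A tibble with the unit declarations in `attr(., "units")`.
#' @export
read_concentrations <- function(file) {
  raw <- readr::read_csv(file, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  units <- NULL
  if (nrow(raw) && raw$subject_id[1] == "unit") {
    u <- unlist(raw[1, ])
    units <- u[!is.na(u) & u %in% c("pM", "nM", "µM", "uM")]
    units <- sub("^uM$", "µM", units)
    raw <- raw[-1, ]
  }
  meta_chr <- c("subject_id", "group")
  out <- dplyr::mutate(raw, dplyr::across(-dplyr::any_of(meta_chr),
                                          as.numeric))
  if (!is.null(units)) attr(out, "units") <- units
  out
}

#' @rdname read_concentrations
#' @param data A concentration tibble.
#' @return For the writer: `file`, invisibly.
#' @export
write_concentrations <- function(data, file) {
  units <- attr(data, "units")
  out <- dplyr::mutate(data, dplyr::across(dplyr::everything(),
                                           as.character))
  if (!is.null(units)) {
    urow <- stats::setNames(as.list(rep(NA_character_, ncol(out))),
                            names(out))
    urow$subject_id <- "unit"
    urow[intersect(names(units), names(out))] <-
      units[intersect(names(units), names(out))]
    out <- dplyr::bind_rows(tibble::as_tibble(urow), out)
  }
  readr::write_csv(out, file, na = "")
  invisible(file)
}

#' Run the full steroidomic analysis pipeline
#'
#' Executes, in order: per-variable Box-Cox transformation and
#' standardization; molar-ratio evaluation over every registered
#' panel; per-variable ANOVA screening (status x dichotomized age)
#' with severity correlations; direction coding and per-panel trend
#' tests; and, for the configured panels, OPLS fitting with Hotelling
#' screening, VIP elimination, cross-validated explained variability
#' and an in-sample classification report. Tables missing the
#' severity columns skip the correlation stages with a warning.
#'
#' @param data A concentration table (see [read_concentrations()]) or
#'   a path to one.
#' @param catalog A `steroid_catalog`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, result tables are
#'   written as CSV and a text report in `(u/m/d, p = ...)` notation
#'   is produced.
#' @return A list: `screen` (per-variable results, analytes and
#'   ratios), `trends` (per-panel trend tests), `opls` (per-panel
#'   list: model, inliers, report), `transforms`, `config`.
#' @export
run_pipeline <- function(data, catalog = load_catalog(),
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(data)) data <- read_concentrations(data)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  analyte_vars <- intersect(catalog$analytes$abbreviation, names(data))
  if (!length(analyte_vars)) stop("no catalog analytes found in table")

  ratios <- stage("ratios", evaluate_ratios(data, catalog, panel = "all"))
  ratio_vars <- intersect(catalog$ratios$name, names(ratios))
  ratio_vars <- ratio_vars[vapply(ratio_vars, function(v) {
    x <- ratios[[v]]
    sum(is.finite(x)) >= 8 && stats::sd(x, na.rm = TRUE) > 0
  }, logical(1))]

  tf_analytes <- stage("transform", fit_transforms(data, analyte_vars,
                                                   grid = config$grid))
  tf_ratios <- stage("transform", fit_transforms(ratios, ratio_vars,
                                                 grid = config$grid))
  tr_analytes <- apply_transform(data, tf_analytes)
  tr_ratios <- apply_transform(ratios, tf_ratios)

  screen_a <- stage("screen", screen_variables(
    tr_analytes, data, vars = analyte_vars, alpha = config$alpha,
    cor_method = config$cor_method))
  screen_r <- stage("screen", screen_variables(
    tr_ratios, ratios, vars = ratio_vars, alpha = config$alpha,
    cor_method = config$cor_method))
  screen <- dplyr::bind_rows(
    dplyr::mutate(screen_a, kind = "analyte", .after = "variable"),
    dplyr::mutate(screen_r, kind = "ratio", .after = "variable"))
  class(screen) <- c("screen_result", class(tibble::tibble()))

  trends <- stage("trend", panel_trends(screen, catalog,
                                        alpha = config$alpha))

  opls_fits <- list()
  for (panel in config$opls_panels %||% character()) {
    vars <- if (panel == "steroids") analyte_vars else {
      intersect(ratio_vars, catalog$ratios$name[catalog$ratios$panel == panel])
    }
    if (length(vars) < 2) next
    train <- if (panel == "steroids") tr_analytes else tr_ratios
    train <- dplyr::select(train, dplyr::any_of(
      c("subject_id", "group", vars)))
    train <- train[stats::complete.cases(train[vars]), ]
    fit <- stage(paste0("opls:", panel), fit_opls(
      train, predictors = vars, scale = FALSE))
    hs <- stage(paste0("opls:", panel),
                hotelling_screen(fit, level = config$hotelling_level))
    sel <- stage(paste0("opls:", panel),
                 select_predictors(hs$model, config$vip_threshold))
    kept <- sel$loadings$variable
    inrows <- hs$inliers$inlier
    sel$explained_cv <- stage(paste0("opls:", panel),
                              cross_validated_explained(
                                train[inrows, ], predictors = kept,
                                folds = config$cv_folds))
    opls_fits[[panel]] <- list(model = sel, inliers = hs$inliers,
                               report = classification_report(sel))
  }

  result <- list(screen = screen, trends = trends, opls = opls_fits,
                 transforms = list(analytes = tf_analytes,
                                   ratios = tf_ratios),
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$screen, file.path(out_dir, "screen.csv"))
  readr::write_csv(result$trends, file.path(out_dir, "trends.csv"))
  lines <- c("Per-panel significance-direction trends",
             "=======================================",
             sprintf("%-28s %s", result$trends$group_name,
                     result$trends$label))
  for (panel in names(result$opls)) {
    m <- result$opls[[panel]]$model
    rep <- result$opls[[panel]]$report$summary
    readr::write_csv(opls_variable_summary(m),
                     file.path(out_dir, paste0("opls_", gsub("[^A-Za-z0-9]", "_", panel),
                                               "_variables.csv")))
    readr::write_csv(result$opls[[panel]]$report$per_subject,
                     file.path(out_dir, paste0("opls_", gsub("[^A-Za-z0-9]", "_", panel),
                                               "_subjects.csv")))
    lines <- c(lines, "",
               sprintf("OPLS panel %s: explained variability = %.1f%% (%.1f%% after cross-validation)",
                       panel, m$explained_fit, m$explained_cv),
               sprintf("  %s = %.3g (%.3g-%.3g), n = %d",
                       rep$metric, rep$estimate, rep$lower, rep$upper, rep$n))
  }
  readr::write_lines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
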