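#' Fit an OPLS discriminant model (one predictive + one orthogonal component)
#'
#' Orthogonal projections to latent structures for a two-class
#' response: the predictor variability is split into a single
#' component predictive of class membership and a single component
#' orthogonal to it, `X = Tp Pp' + To Po' + E`, with the response
#' modelled from the predictive score alone. The class response is
#' coded +1 for the positive class (patients) and -1 otherwise.
#' Predictors are centered and unit-variance scaled internally using
#' the training data.
#'
#' The fitted predictive score is mapped to a log-likelihood ratio of
#' class membership (LLR) by a pooled-variance linear discriminant on
#' the score: `llr = (m1 - m0) / s2 * (Tp - (m1 + m0) / 2)`, where
#' `m1`, `m0` are the class means of `Tp` and `s2` its pooled
#' within-class variance. The training decision point therefore maps
#' to `llr = 0`, and `probability = exp(llr) / (1 + exp(llr))`.
#'
#' @param data Data frame with a class column and numeric predictors.
#' @param response Name of the class column (default `"group"`).
#' @param predictors Predictor column names (default: all analysis
#'   variables, see details in [screen_variables()]).
#' @param positive_class Level coded +1 (default `"patient"`).
#' @param n_orth Number of orthogonal components, 0 or 1. The model is
#'   defined with component counts fixed at one predictive plus at
#'   most one orthogonal; requesting more is an error.
#' @param scale Unit-variance scale the predictors (default `TRUE`).
#' @return An object of class `opls` with elements
#'   `scores` (per-subject tibble: `Tp`, `To`, `llr`, `probability`,
#'   `predicted`), `loadings` (per-variable tibble: weight `w`,
#'   loadings `Pp`/`Po`, `vip`, `loading_R`, regression coefficient
#'   `b` on the LLR scale), `c` (response loading),
#'   `explained_fit` (percent response variability explained),
#'   `explained_cv` (`NA` until [cross_validated_explained()] is run),
#'   and the training summaries needed for prediction.
#' @examples
#' set.seed(7)
#' d <- simulate_steroidome(simulation_design(n_patients = 12,
#'                                            n_controls = 12), seed = 7)
#' m <- fit_opls(apply_transform(d$data, fit_transforms(d$data)))
#' glance(m)
#' @export
fit_opls <- function(data, response = "group", predictors = NULL,
                     positive_class = "patient", n_orth = 1,
                     scale = TRUE) {
  if (n_orth > 1) {
    stop("component counts are fixed at one predictive plus at most one ",
         "orthogonal component")
  }
  predictors <- predictors %||% analysis_vars(data)
  cls <- data[[response]]
  if (is.null(cls)) stop("response column '", response, "' not found")
  y <- ifelse(cls == positive_class, 1, -1)
  if (length(unique(y)) < 2) stop("response is constant")
  if (min(table(y)) < 6) stop("need at least 6 subjects per class")
  X <- as.matrix(data[predictors])
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  centers <- colMeans(X)
  scales <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scales == 0)) {
    stop("constant predictor: ",
         paste(predictors[scales == 0], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  core <- opls_core(Xs, y, n_orth = n_orth)
  # orient the predictive component so patients score positive
  if (mean(core$tp[y == 1]) < 0) {
    core$w2 <- -core$w2; core$tp <- -core$tp
    core$pp <- -core$pp; core$c <- -core$c
  }
  lda <- score_lda(core$tp, y)
  llr <- lda$slope * (core$tp - lda$center)
  prob <- stats::plogis(llr)
  # coefficients reproducing llr from standardized predictors
  filt <- if (core$has_orth) {
    core$w2 - drop(crossprod(core$po, core$w2)) * core$w_o
  } else core$w2
  b <- lda$slope * filt
  b0 <- -lda$slope * lda$center
  vip <- sqrt(length(predictors)) * abs(core$w2) / sqrt(sum(core$w2^2))
  loading_R <- drop(stats::cor(Xs, core$tp))
  subj <- if ("subject_id" %in% names(data)) {
    data$subject_id[keep]
  } else as.character(seq_len(sum(keep)))
  yhat <- core$tp * core$c + mean(y)
  explained_fit <- 100 * (1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  structure(list(
    scores = tibble::tibble(
      subject_id = subj,
      class = ifelse(y == 1, positive_class, "other"),
      y = y, Tp = core$tp, To = core$to, llr = llr, probability = prob,
      predicted = ifelse(prob > 0.5, positive_class, "other")),
    loadings = tibble::tibble(
      variable = predictors, w = core$w2, Pp = core$pp, Po = core$po_vec,
      vip = vip, loading_R = loading_R, b = b),
    c = core$c, b0 = b0, llr_slope = lda$slope, llr_center = lda$center,
    has_orth = core$has_orth, w_o = core$w_o, po = core$po,
    E = core$E, F_res = y - yhat,
    explained_fit = explained_fit, explained_cv = NA_real_,
    centers = centers, scales = scales, response = response,
    positive_class = positive_class, n_orth = n_orth, do_scale = scale,
    X = Xs, y_train = y
  ), class = "opls")
}

# core computation on a centered/scaled matrix and +/-1 response
opls_core <- function(Xs, y, n_orth = 1, tol = 1e-10) {
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  t1 <- drop(Xs %*% w)
  pload <- drop(crossprod(Xs, t1)) / sum(t1^2)
  w_o <- pload - drop(crossprod(w, pload)) * w
  has_orth <- n_orth >= 1 && sqrt(sum(w_o^2)) > tol
  if (has_orth) {
    w_o <- w_o / sqrt(sum(w_o^2))
    if (w_o[which.max(abs(w_o))] < 0) w_o <- -w_o
    to <- drop(Xs %*% w_o)
    po <- drop(crossprod(Xs, to)) / sum(to^2)
    Xf <- Xs - tcrossprod(to, po)
  } else {
    w_o <- numeric(p); to <- numeric(n); po <- numeric(p); Xf <- Xs
  }
  w2 <- drop(crossprod(Xf, yc)); w2 <- w2 / sqrt(sum(w2^2))
  tp <- drop(Xf %*% w2)
  pp <- drop(crossprod(Xf, tp)) / sum(tp^2)
  cc <- sum(yc * tp) / sum(tp^2)
  list(w2 = w2, tp = tp, pp = pp, c = cc, w_o = w_o, to = to, po = po,
       po_vec = po, has_orth = has_orth, E = Xf - tcrossprod(tp, pp))
}

# pooled-variance discriminant on the predictive score
score_lda <- function(tp, y) {
  m1 <- mean(tp[y == 1]); m0 <- mean(tp[y == -1])
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  s2 <- (sum((tp[y == 1] - m1)^2) + sum((tp[y == -1] - m0)^2)) /
    (n1 + n0 - 2)
  list(slope = (m1 - m0) / s2, center = (m1 + m0) / 2)
}

#' Variable importance in projection
#'
#' Standard VIP over the predictive component(s):
#' `vip_j = sqrt(p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a)`;
#' with a single predictive component this reduces to
#' `sqrt(p) * |w_j| / ||w||`, so the mean squared VIP is exactly 1.
#'
#' @param model A fitted [fit_opls()] model.
#' @return A tibble `variable`, `vip`.
#' @export
vip_scores <- function(model) {
  dplyr::select(model$loadings, "variable", "vip")
}

#' Drop low-VIP predictors and refit
#'
#' Removes variables with VIP below `threshold` and refits the model
#' once on the retained set (a single elimination pass; the refit VIPs
#' are reported but not used for further pruning).
#'
#' @param model A fitted `opls` model.
#' @param threshold VIP cutoff (default 1); `0` keeps every variable.
#' @return The refitted `opls` model; the retained variable names are
#'   in `model$loadings$variable`.
#' @export
select_predictors <- function(model, threshold = 1) {
  keep <- model$loadings$variable[model$loadings$vip >= threshold]
  if (!length(keep)) {
    stop("threshold ", threshold, " eliminates every predictor; ",
         "use a value below ", signif(max(model$loadings$vip), 3))
  }
  if (length(keep) == nrow(model$loadings)) return(model)
  refit_opls(model, variables = keep)
}

# refit on stored standardized training data (subset of rows/columns)
refit_opls <- function(model, variables = NULL, rows = NULL) {
  variables <- variables %||% model$loadings$variable
  rows <- rows %||% seq_len(nrow(model$X))
  d <- tibble::as_tibble(model$X[rows, variables, drop = FALSE],
                         .name_repair = "minimal")
  names(d) <- variables
  d[[model$response]] <- ifelse(model$y_train[rows] == 1,
                                model$positive_class, "other")
  d$subject_id <- model$scores$subject_id[rows]
  refit <- fit_opls(d, response = model$response, predictors = variables,
                    positive_class = model$positive_class,
                    n_orth = model$n_orth, scale = FALSE)
  # compose standardization so prediction still works from raw data
  refit$centers <- model$centers[variables]
  refit$scales <- model$scales[variables]
  refit$do_scale <- model$do_scale
  refit
}

#' Hotelling T-squared screening of the score space
#'
#' Flags subjects whose (predictive, orthogonal) score pair lies
#' outside the Hotelling T-squared ellipse at the given confidence
#' level, and refits without them (at most `max_rounds` remove-refit
#' rounds).
#'
#' @param model A fitted `opls` model (at least 10 subjects).
#' @param level Confidence level of the ellipse (default 0.95);
#'   `level = 1` flags nothing.
#' @param max_rounds Maximum remove-refit rounds (default 2).
#' @return A list with `model` (refit on inliers), `inliers` (tibble
#'   `subject_id`, `t2`, `inlier` for the original subjects) and
#'   `t2_crit`.
#' @export
hotelling_screen <- function(model, level = 0.95, max_rounds = 2) {
  stopifnot(nrow(model$scores) >= 10)
  orig <- model
  inlier <- rep(TRUE, nrow(orig$scores))
  t2_all <- hotelling_t2(orig)
  t2_crit <- NA_real_
  current <- orig
  for (round in seq_len(max_rounds)) {
    t2 <- hotelling_t2(current)
    n <- length(t2)
    a <- if (current$has_orth) 2 else 1
    t2_crit <- a * (n - 1) / (n - a) * stats::qf(level, a, n - a)
    out <- t2 > t2_crit
    if (!any(out)) break
    inlier[inlier][out] <- FALSE
    current <- refit_opls(orig, rows = which(inlier))
  }
  list(model = current,
       inliers = tibble::tibble(subject_id = orig$scores$subject_id,
                                t2 = t2_all, inlier = inlier),
       t2_crit = t2_crit)
}

hotelling_t2 <- function(model) {
  S <- if (model$has_orth) {
    cbind(model$scores$Tp, model$scores$To)
  } else cbind(model$scores$Tp)
  Sc <- sweep(S, 2, colMeans(S))
  V <- stats::cov(Sc)
  rowSums((Sc %*% solve(V)) * Sc)
}

#' Cross-validated explained response variability
#'
#' Venetian-blind cross-validation: subject `i` goes to fold
#' `((i - 1) mod folds) + 1` in table order. Each fold is predicted
#' from a model fitted on the remaining subjects (including their own
#' centering and scaling), and
#' `explained_cv = 100 * (1 - PRESS / SS_total)`. If some training
#' remainder lacks a class, subjects are re-interleaved by class once
#' (deterministically); if that still fails, an error is raised.
#'
#' @inheritParams fit_opls
#' @param folds Number of venetian blinds (default 7).
#' @return The cross-validated explained variability in percent
#'   (can be negative for uninformative predictors).
#' @export
cross_validated_explained <- function(data, response = "group",
                                      predictors = NULL,
                                      positive_class = "patient",
                                      folds = 7, n_orth = 1) {
  stopifnot(folds >= 2)
  predictors <- predictors %||% analysis_vars(data)
  y <- ifelse(data[[response]] == positive_class, 1, -1)
  X <- as.matrix(data[predictors])
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  assign_folds <- function(ord) ((seq_len(n) - 1) %% folds) + 1
  order1 <- seq_len(n)
  fold <- assign_folds(order1)
  ok <- all(vapply(seq_len(folds), function(f) {
    length(unique(y[order1][fold != f])) == 2
  }, logical(1)))
  if (!ok) {
    # deterministic re-interleave: alternate classes in original order
    i1 <- which(y == 1); i0 <- which(y == -1)
    order1 <- c(i1, i0)[order(c(seq_along(i1) - 0.25, seq_along(i0)))]
    fold <- assign_folds(order1)
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[order1][fold != f])) == 2
    }, logical(1)))
    if (!ok) stop("cannot form folds with both classes in every remainder")
  }
  press <- 0
  for (f in seq_len(folds)) {
    tr <- order1[fold != f]; te <- order1[fold == f]
    if (!length(te)) next
    Xtr <- X[tr, , drop = FALSE]
    centers <- colMeans(Xtr)
    scales <- apply(Xtr, 2, stats::sd)
    scales[scales == 0] <- 1
    Xtrs <- sweep(sweep(Xtr, 2, centers), 2, scales, "/")
    core <- opls_core(Xtrs, y[tr], n_orth = n_orth)
    Xtes <- sweep(sweep(X[te, , drop = FALSE], 2, centers), 2, scales, "/")
    if (core$has_orth) {
      t_o_new <- drop(Xtes %*% core$w_o)
      Xtes <- Xtes - tcrossprod(t_o_new, core$po)
    }
    yhat <- drop(Xtes %*% core$w2) * core$c + mean(y[tr])
    press <- press + sum((y[te] - yhat)^2)
  }
  100 * (1 - press / sum((y - mean(y))^2))
}

#' Predict log-likelihood ratios for new subjects
#'
#' Applies the training standardization, removes the orthogonal
#' component, and maps the predictive score through the fitted LLR
#' link: `probability = exp(llr) / (1 + exp(llr))`, label = positive
#' class iff probability > 0.5.
#'
#' @param model A fitted (optionally VIP-reduced) `opls` model.
#' @param new_data Data frame containing every model variable on the
#'   same scale as the training data.
#' @return A tibble `llr`, `probability`, `predicted` (one row per
#'   subject of `new_data`).
#' @export
predict_llr <- function(model, new_data) {
  vars <- model$loadings$variable
  missing_vars <- setdiff(vars, names(new_data))
  if (length(missing_vars)) {
    stop("model variables absent from new data: ",
         paste(missing_vars, collapse = ", "))
  }
  X <- as.matrix(new_data[vars])
  Xs <- sweep(sweep(X, 2, model$centers[vars]), 2, model$scales[vars], "/")
  llr <- drop(Xs %*% model$loadings$b) + model$b0
  prob <- stats::plogis(llr)
  tibble::tibble(llr = llr, probability = prob,
                 predicted = ifelse(prob > 0.5, model$positive_class,
                                    "other"))
}

#' @export
predict.opls <- function(object, newdata, ...) predict_llr(object, newdata)

#' Per-variable model summary with jackknife t-statistics
#'
#' The export surface of a fitted model: per variable, the component
#' loading expressed as a correlation with the predictive score
#' (`loading_R`), a t-statistic (`loading_R` divided by its jackknife
#' standard error over the venetian-blind cross-validation folds), the
#' LLR-scale regression coefficient `b` and the VIP.
#'
#' @param model A fitted `opls` model.
#' @param folds Venetian-blind folds used for the jackknife (default 7).
#' @return A tibble `variable`, `loading_R`, `t_stat`, `b`, `vip`.
#' @export
opls_variable_summary <- function(model, folds = 7) {
  n <- nrow(model$X)
  fold <- ((seq_len(n) - 1) %% folds) + 1
  used <- sort(unique(fold))
  loads <- vapply(used, function(f) {
    rows <- which(fold != f)
    core <- opls_core(scale(model$X[rows, , drop = FALSE],
                            scale = FALSE),
                      model$y_train[rows], n_orth = model$n_orth)
    l <- drop(stats::cor(model$X[rows, , drop = FALSE], core$tp))
    l * sign(stats::cor(core$tp, model$y_train[rows]))
  }, numeric(nrow(model$loadings)))
  loads <- matrix(loads, nrow = nrow(model$loadings))
  k <- length(used)
  lbar <- rowMeans(loads)
  se <- sqrt((k - 1) / k * rowSums((loads - lbar)^2))
  tibble::tibble(variable = model$loadings$variable,
                 loading_R = model$loadings$loading_R,
                 t_stat = model$loadings$loading_R / pmax(se, 1e-12),
                 b = model$loadings$b,
                 vip = model$loadings$vip)
}

#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to `[0, 1]`.
#'
#' @param p_hat Proportion in `[0, 1]`.
#' @param n Number of subjects (>= 1).
#' @param level Confidence level (default 0.95, z = 1.96).
#' @return A tibble `estimate`, `lower`, `upper`.
#' @examples
#' wald_ci(0.875, 24)  # lower bound 0.743
#' @export
wald_ci <- function(p_hat, n, level = 0.95) {
  stopifnot(all(p_hat >= 0), all(p_hat <= 1))
  if (any(n < 1)) stop("n must be at least 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  tibble::tibble(estimate = p_hat,
                 lower = pmax(0, p_hat - half),
                 upper = pmin(1, p_hat + half))
}

#' In-sample classification report
#'
#' Sensitivity and specificity of the fitted LLR classifier on its
#' training subjects, with Wald confidence intervals.
#'
#' @param model A fitted `opls` model.
#' @param level Confidence level of the Wald intervals.
#' @return A list with `per_subject` (subject, llr, probability,
#'   label) and `summary` (sensitivity/specificity rows with CI and
#'   denominators).
#' @export
classification_report <- function(model, level = 0.95) {
  s <- model$scores
  pos <- s$y == 1
  sens <- mean(s$predicted[pos] == model$positive_class)
  spec <- mean(s$predicted[!pos] != model$positive_class)
  summ <- dplyr::bind_rows(
    dplyr::mutate(wald_ci(sens, sum(pos), level), metric = "sensitivity",
                  n = sum(pos), .before = 1),
    dplyr::mutate(wald_ci(spec, sum(!pos), level), metric = "specificity",
                  n = sum(!pos), .before = 1))
  list(per_subject = dplyr::select(s, "subject_id", "class", "llr",
                                   "probability", "predicted"),
       summary = summ)
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf(
    "<opls> %d subjects x %d predictors; 1 predictive + %d orthogonal component(s)\n",
    nrow(x$scores), nrow(x$loadings), as.integer(x$has_orth)))
  cat(sprintf("explained variability = %.1f%%", x$explained_fit))
  if (!is.na(x$explained_cv)) {
    cat(sprintf(" (%.1f%% after cross-validation)", x$explained_cv))
  }
  cat("\n")
  invisible(x)
}

#' Tidy per-variable summary of an OPLS fit
#'
#' One row per predictor: predictive weight, loadings, VIP,
#' correlation with the predictive score (`loading_R`) and the LLR
#' regression coefficient, mirroring the usual model-summary export.
#'
#' @param x An `opls` model.
#' @param ... Unused.
#' @method tidy opls
#' @export
tidy.opls <- function(x, ...) x$loadings

#' One-row model summary of an OPLS fit
#'
#' @param x An `opls` model.
#' @param ... Unused.
#' @return A tibble with subject counts, explained variability (fit
#'   and, when computed, cross-validated), sensitivity and specificity.
#' @method glance opls
#' @export
glance.opls <- function(x, ...) {
  rep <- classification_report(x)$summary
  tibble::tibble(
    n = nrow(x$scores),
    n_cases = sum(x$scores$y == 1),
    n_controls = sum(x$scores$y == -1),
    n_predictors = nrow(x$loadings),
    explained_fit = x$explained_fit,
    explained_cv = x$explained_cv,
    sensitivity = rep$estimate[rep$metric == "sensitivity"],
    specificity = rep$estimate[rep$metric == "specificity"])
}
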