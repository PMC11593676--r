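#' Fit a Box-Cox power transform to one variable
#'
#' Scans a fixed grid of exponents and picks the one whose Box-Cox
#' transform makes the sample look most Gaussian. The criterion is the
#' Shapiro-Wilk W statistic (maximized) for samples of up to 50
#' observations and the negative Anderson-Darling A statistic for
#' larger samples; both are reported on a "larger is more normal"
#' scale so the selected lambda always attains the stored criterion
#' maximum.
#'
#' @param values Positive numeric vector, at least 8 finite values.
#' @param grid Candidate exponents; default `seq(-3, 3, by = 0.01)`.
#' @param shift Additive offset applied before transforming (default
#'   0). Non-positive values without a sufficient shift are an error.
#' @return A one-row tibble with `lambda`, `shift`, `mean`, `sd`
#'   (moments of the transformed values) and `criterion`.
#' @examples
#' set.seed(1)
#' fit_power_transform(exp(rnorm(100)))$lambda  # close to 0 (log)
#' @export
fit_power_transform <- function(values, grid = seq(-3, 3, by = 0.01),
                                shift = 0) {
  x <- values[is.finite(values)]
  if (length(x) < 8) stop("need at least 8 finite values")
  x <- x + shift
  if (any(x <= 0)) {
    stop("non-positive values; supply a shift > ", -min(x) + shift)
  }
  if (stats::sd(x) == 0) stop("constant input cannot be transformed")
  lx <- log(x)
  crit <- vapply(grid, function(l) normality_criterion(boxcox_core(lx, l)),
                 numeric(1))
  best <- which.max(crit)
  y <- boxcox_core(lx, grid[best])
  tibble::tibble(lambda = grid[best], shift = shift,
                 mean = mean(y), sd = stats::sd(y),
                 criterion = crit[best])
}

# Box-Cox on the log scale: y = (exp(l * lx) - 1) / l, or lx at l = 0
boxcox_core <- function(lx, lambda) {
  if (lambda == 0) lx else (exp(lambda * lx) - 1) / lambda
}

normality_criterion <- function(y) {
  if (!all(is.finite(y)) || stats::sd(y) == 0) return(-Inf)
  if (length(y) <= 50) {
    unname(stats::shapiro.test(y)$statistic)
  } else {
    -unname(nortest::ad.test(y)$statistic)
  }
}

#' Fit power transforms for every analysis variable of a table
#'
#' Applies [fit_power_transform()] column-wise (patients and controls
#' pooled) and collects the per-variable parameters into a
#' `transform_model`.
#'
#' @param data A data frame; `vars` selects the variables to model
#'   (default: all numeric columns except the standard metadata
#'   columns).
#' @inheritParams fit_power_transform
#' @return A `transform_model`: a tibble with one row per variable and
#'   columns `variable`, `lambda`, `shift`, `mean`, `sd`, `criterion`.
#' @export
fit_transforms <- function(data, vars = NULL, grid = seq(-3, 3, by = 0.01)) {
  vars <- vars %||% analysis_vars(data)
  rows <- purrr::map(vars, function(v) {
    dplyr::mutate(fit_power_transform(data[[v]], grid = grid),
                  variable = v, .before = 1)
  })
  structure(dplyr::bind_rows(rows), class = c("transform_model",
                                              class(tibble::tibble())))
}

#' Apply (or invert) a fitted power transform
#'
#' Transforms each modelled variable by
#' `y = (x^lambda - 1) / lambda` (natural log when `lambda = 0`),
#' then optionally standardizes with the stored training mean and
#' standard deviation. `invert_transform()` undoes both steps.
#'
#' @param data A data frame containing the modelled variables;
#'   unmodelled columns pass through unchanged.
#' @param model A `transform_model` from [fit_transforms()], or a
#'   one-row tibble from [fit_power_transform()] plus a `variable`
#'   column.
#' @param standardize Subtract the training mean and divide by the
#'   training sd (default `TRUE`).
#' @return The table with modelled columns replaced by transformed
#'   values.
#' @export
apply_transform <- function(data, model, standardize = TRUE) {
  missing_vars <- setdiff(model$variable, names(data))
  if (length(missing_vars)) {
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "))
  }
  out <- data
  for (i in seq_len(nrow(model))) {
    v <- model$variable[i]
    y <- boxcox_core(log(out[[v]] + model$shift[i]), model$lambda[i])
    if (standardize) y <- (y - model$mean[i]) / model$sd[i]
    out[[v]] <- y
  }
  out
}

#' @rdname apply_transform
#' @param standardized Whether the values being inverted were
#'   standardized (must match the forward call).
#' @export
invert_transform <- function(data, model, standardized = TRUE) {
  out <- data
  for (i in seq_len(nrow(model))) {
    v <- model$variable[i]
    y <- out[[v]]
    if (standardized) y <- y * model$sd[i] + model$mean[i]
    l <- model$lambda[i]
    x <- if (l == 0) exp(y) else (l * y + 1)^(1 / l)
    out[[v]] <- x - model$shift[i]
  }
  out
}

#' @method tidy transform_model
#' @export
tidy.transform_model <- function(x, ...) tibble::as_tibble(unclass(x))

# analysis variables: numeric columns that are not subject metadata
analysis_vars <- function(data) {
  meta <- c("subject_id", "group", "age", "EDSS", "T25FWT",
            "HPT9_R", "HPT9_L")
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
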