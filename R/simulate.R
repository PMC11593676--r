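#' Describe a synthetic steroidome study design
#'
#' Collects the parameters of the case-control generator. Defaults
#' emulate the reference study conditions: 25 female patients and 15
#' age-matched controls around age 39 (quartiles roughly 32-49),
#' 81 analytes with right-skewed positive concentrations whose
#' log-scale baselines come from the registry's control medians and
#' quartiles, pathway-block correlation, conjugates coupled to their
#' unconjugated parents, age-dependent adrenal androgen sulfates, and
#' a plantable group-effect pattern of 5 analytes up and 15 down at
#' one within-group log-SD.
#'
#' @param n_patients,n_controls Subjects per group (each >= 3).
#' @param catalog A `steroid_catalog` (default: packaged catalog).
#' @param age_mean,age_sd,age_range Age distribution (years), normal
#'   truncated to `age_range`.
#' @param block_rho Within-pathway-class correlation of log
#'   concentrations, in `[0, 1)`.
#' @param n_up,n_down Number of analytes with planted positive /
#'   negative group effects (patients vs controls).
#' @param effect_size Planted shift in units of the analyte's
#'   log-scale SD.
#' @param age_slope Log-scale slope per year applied to the
#'   age-dependent subset (the Delta-5 sulfates and free adrenal
#'   androgens DHEA and androstenediol, which decline with age).
#' @param coupling_sd Log-scale SD of the conjugate-around-parent
#'   coupling noise.
#' @param severity_coupling Log-SD units of analyte shift per SD of
#'   the latent severity, applied to the affected analytes with sign
#'   opposite to their group effect (the "counter-regulation"
#'   discordance scenario); set to 0 for none.
#' @return A `simulation_design` list, validated.
#' @export
simulation_design <- function(n_patients = 25, n_controls = 15,
                              catalog = load_catalog(),
                              age_mean = 40, age_sd = 10,
                              age_range = c(20, 65),
                              block_rho = 0.5,
                              n_up = 5, n_down = 15, effect_size = 1,
                              age_slope = -0.015,
                              coupling_sd = 0.3,
                              severity_coupling = 0.3) {
  stopifnot(n_patients >= 3, n_controls >= 3,
            block_rho >= 0, block_rho < 1,
            coupling_sd > 0, effect_size >= 0,
            n_up + n_down <= nrow(catalog$analytes))
  structure(list(
    n_patients = n_patients, n_controls = n_controls, catalog = catalog,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    block_rho = block_rho, n_up = n_up, n_down = n_down,
    effect_size = effect_size, age_slope = age_slope,
    coupling_sd = coupling_sd, severity_coupling = severity_coupling),
    class = "simulation_design")
}

#' Simulate a steroidome case-control dataset
#'
#' Log-normal concentration model: unconjugated analytes (and
#' conjugates without a measured parent) are drawn from a multivariate
#' normal on the log scale with block-exchangeable correlation within
#' steroid classes; conjugated analytes are their parent's log
#' concentration plus a registry-derived offset and coupling noise.
#' Group effects, age slopes and a latent-severity coupling are added
#' on the log scale, and severity indices (EDSS, timed 25-foot walk,
#' 9-hole peg tests) are monotone noisy functions of the latent
#' severity (patients only). Concentrations are returned in each
#' analyte's registry unit, declared in `attr(data, "units")`.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A list: `data` (tibble: `subject_id`, `group`, `age`,
#'   severity indices, one column per analyte), `truth` (planted
#'   per-analyte log shifts and direction, the age-dependent subset,
#'   severity couplings and the latent severity), `design`.
#' @export
simulate_steroidome <- function(design = simulation_design(), seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  an <- design$catalog$analytes
  n <- design$n_patients + design$n_controls
  group <- rep(c("patient", "control"),
               c(design$n_patients, design$n_controls))
  age <- round(truncnorm(n, design$age_mean, design$age_sd,
                         design$age_range))
  med_nM <- to_molar(an$ctrl_median, an$unit)
  sd_log <- (log(to_molar(an$ctrl_q3, an$unit)) -
               log(to_molar(an$ctrl_q1, an$unit))) / (2 * stats::qnorm(0.75))
  names(med_nM) <- names(sd_log) <- an$abbreviation

  base <- an$abbreviation[!an$conjugated |
                            (an$conjugated & is.na(an$parent))]
  coupled <- an$abbreviation[an$conjugated & !is.na(an$parent)]
  parent_of <- stats::setNames(an$parent, an$abbreviation)[coupled]

  # block-exchangeable correlation within steroid class for base analytes
  cls <- stats::setNames(an$steroid_class, an$abbreviation)[base]
  R <- outer(cls, cls, function(a, b) ifelse(a == b, design$block_rho, 0))
  diag(R) <- 1
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * length(base)), n) %*% L
  colnames(Z) <- base

  # planted group effects (log scale, units of each analyte's log SD)
  eff_pool <- sample(an$abbreviation, design$n_up + design$n_down)
  eff_sign <- stats::setNames(rep(0, nrow(an)), an$abbreviation)
  if (design$n_up > 0) eff_sign[eff_pool[seq_len(design$n_up)]] <- 1
  if (design$n_down > 0) eff_sign[eff_pool[design$n_up + seq_len(design$n_down)]] <- -1

  age_subset <- an$abbreviation[
    (an$conjugated & an$steroid_class == "delta5") |
      an$abbreviation %in% c("DHEA", "Adiol")]
  is_pat <- group == "patient"
  severity <- ifelse(is_pat, stats::rnorm(n), NA_real_)

  logc <- matrix(NA_real_, n, nrow(an),
                 dimnames = list(NULL, an$abbreviation))
  add_structure <- function(key, eps) {
    x <- log(med_nM[key]) + eps
    if (key %in% age_subset) x <- x + design$age_slope * (age - 40)
    s <- eff_sign[key]
    if (s != 0) {
      x <- x + is_pat * s * design$effect_size * sd_log[key]
      x <- x + ifelse(is_pat,
                      -s * design$severity_coupling * sd_log[key] * severity,
                      0)
    }
    x
  }
  for (key in base) {
    logc[, key] <- add_structure(key, sd_log[key] * Z[, key])
  }
  for (key in coupled) {
    par <- parent_of[[key]]
    eps <- (logc[, par] - log(med_nM[par])) +
      stats::rnorm(n, sd = design$coupling_sd)
    logc[, key] <- add_structure(key, eps)
  }
  conc_nM <- exp(logc)
  unit_fac <- c(pM = 1e-3, nM = 1, "µM" = 1e3)[an$unit]
  conc <- sweep(conc_nM, 2, unit_fac, "/")

  edss <- pmin(7, pmax(0, round((3.5 + 1.5 * severity +
                                   stats::rnorm(n, sd = 0.5)) * 2) / 2))
  t25 <- exp(log(5) + 0.25 * severity + stats::rnorm(n, sd = 0.15))
  hpt_r <- exp(log(20) + 0.2 * severity + stats::rnorm(n, sd = 0.12))
  hpt_l <- exp(log(21) + 0.2 * severity + stats::rnorm(n, sd = 0.12))

  data <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, age = age,
      EDSS = edss, T25FWT = round(t25, 1),
      HPT9_R = round(hpt_r, 1), HPT9_L = round(hpt_l, 1)),
    tibble::as_tibble(conc))
  attr(data, "units") <- stats::setNames(an$unit, an$abbreviation)
  truth <- list(
    effects = tibble::tibble(
      analyte = an$abbreviation,
      sign = unname(eff_sign),
      log_shift = unname(eff_sign * design$effect_size * sd_log)),
    age_subset = age_subset,
    severity_coupling = design$severity_coupling,
    latent_severity = severity)
  list(data = data, truth = truth, design = design)
}

truncnorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}
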