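test_that("a single predictor equal to the response gives a perfect fit", {
  d <- tibble::tibble(group = rep(c("patient", "control"), each = 10))
  d$x <- ifelse(d$group == "patient", 1, -1) + rnorm(20, sd = 1e-6)
  m <- fit_opls(d, predictors = "x")
  expect_gt(m$explained_fit, 99)
  expect_gt(abs(cor(m$scores$Tp, m$scores$y)), 0.999)
  expect_false(m$has_orth)  # no orthogonal direction exists for p = 1
  expect_true(all(m$scores$predicted[d$group == "patient"] == "patient"))
})

test_that("scores are orthogonal and loading correlations bounded", {
  for (seed in 1:5) {
    sim <- sim_gaussian_cc(seed)
    m <- fit_opls(sim$data)
    tp <- m$scores$Tp - mean(m$scores$Tp)
    to <- m$scores$To - mean(m$scores$To)
    expect_lt(abs(sum(tp * to)), 1e-8)
    expect_true(all(abs(m$loadings$loading_R) <= 1 + 1e-12))
    # coefficients reproduce the fitted llr from standardized predictors
    llr_hat <- drop(m$X %*% m$loadings$b) + m$b0
    expect_lt(max(abs(llr_hat - m$scores$llr)), 1e-8)
  }
})

test_that("predictive weight recovers a planted discriminant direction", {
  # population weight-truth correlation at these conditions is
  # sqrt(84 / 124) ~ 0.82 (signal n * delta / 2 per informative
  # coordinate, variance n); VIP elimination zeroes part of the noise
  # coordinates and improves on that
  rec_raw <- rec_vip <- numeric(100)
  for (seed in 1:100) {
    sim <- sim_gaussian_cc(seed, p = 20, k = 6, delta = 1)
    m <- fit_opls(sim$data)
    rec_raw[seed] <- abs(cor(m$loadings$w, sim$true_direction))
    sel <- select_predictors(m, 1)
    wfull <- stats::setNames(rep(0, 20), paste0("v", 1:20))
    wfull[sel$loadings$variable] <- sel$loadings$w
    rec_vip[seed] <- abs(cor(wfull, sim$true_direction))
  }
  expect_gte(median(rec_raw), 0.78)
  expect_gt(median(rec_vip), median(rec_raw))
})

test_that("the orthogonal component absorbs a strong confound", {
  # exact identity: deflating by the orthogonal component leaves the
  # predictive weight equal to the one-component PLS weight (t_o'y = 0
  # by construction), so the benefit of the filtering shows up in the
  # predictive score, which sheds the confound variation
  cw_o <- cor_opls <- cor_pls <- numeric(40)
  for (seed in 1:40) {
    set.seed(seed)
    n <- 40; p <- 20
    y <- rep(c(1, -1), each = n / 2)
    dirn <- rnorm(p); dirn <- dirn / sqrt(sum(dirn^2))
    conf <- rnorm(p); conf <- conf - sum(conf * dirn) * dirn
    conf <- conf / sqrt(sum(conf^2))
    withc <- outer(y, dirn) + matrix(rnorm(n * p, sd = 0.3), n, p) +
      outer(rnorm(n, sd = 4), conf)
    d <- tibble::as_tibble(as.data.frame(withc))
    d$group <- ifelse(y == 1, "patient", "control")
    m <- fit_opls(d)
    pls1 <- nipals_pls1(std_cols(withc), y)
    flip <- sign(sum(m$loadings$w * pls1$w))
    expect_lt(max(abs(m$loadings$w - flip * pls1$w)), 1e-8)
    cw_o[seed] <- abs(cor(m$w_o, conf))
    cor_opls[seed] <- abs(cor(m$scores$Tp, y))
    cor_pls[seed] <- abs(cor(pls1$t, y))
  }
  expect_gt(median(cw_o), 0.8)
  expect_gt(median(cor_opls), median(cor_pls))
  # orthogonal score variance is dominated by the planted confound:
  # without it the orthogonal component captures little of X
  sim0 <- sim_gaussian_cc(1, p = 20, k = 6, delta = 1)
  m0 <- fit_opls(sim0$data)
  expect_lt(var(m0$scores$To) / sum(apply(m0$X, 2, var)), 0.10)
})

test_that("OPLS reduces to NIPALS PLS when no orthogonal structure exists", {
  set.seed(5)
  n <- 30; p <- 8
  y <- rep(c(1, -1), each = n / 2)
  w_true <- rnorm(p)
  X <- outer(y + rnorm(n, sd = 0.2), w_true)  # rank-1: loadings parallel to w
  Xs <- std_cols(X)
  d <- tibble::as_tibble(as.data.frame(Xs))
  d$group <- ifelse(y == 1, "patient", "control")
  m <- fit_opls(d, scale = FALSE)
  expect_false(m$has_orth)
  oracle <- nipals_pls1(Xs, y)
  flip <- sign(sum(m$loadings$w * oracle$w))
  expect_lt(max(abs(m$loadings$w - flip * oracle$w)), 1e-6)
  expect_lt(max(abs(abs(m$scores$Tp) - abs(oracle$t))), 1e-6)
})

test_that("VIP has unit mean square, symmetry and signal sensitivity", {
  sim <- sim_gaussian_cc(1)
  m <- fit_opls(sim$data)
  expect_equal(mean(vip_scores(m)$vip^2), 1, tolerance = 1e-9)

  # exchangeable variables: all VIP close to 1 by symmetry
  set.seed(2)
  y <- rep(c(1, -1), each = 30)
  X <- outer(y, rep(1, 10)) + matrix(rnorm(600, sd = 0.1), 60, 10)
  d <- tibble::as_tibble(as.data.frame(X))
  d$group <- ifelse(y == 1, "patient", "control")
  vip <- vip_scores(fit_opls(d))$vip
  expect_lt(max(abs(vip - 1)), 0.05)

  # one informative variable among pure noise dominates
  hits <- vapply(1:50, function(seed) {
    sim <- sim_gaussian_cc(seed, p = 20, k = 1, delta = 2)
    v <- vip_scores(fit_opls(sim$data))
    v$variable[which.max(v$vip)] == "v1" && max(v$vip) > 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("VIP elimination keeps planted predictors and guards its bounds", {
  sim <- sim_gaussian_cc(7)
  m <- fit_opls(sim$data)
  expect_identical(select_predictors(m, 0)$loadings$variable,
                   m$loadings$variable)
  expect_error(select_predictors(m, max(m$loadings$vip) + 1),
               "eliminates every predictor")
  retained <- vapply(1:50, function(seed) {
    sim <- sim_gaussian_cc(seed, p = 20, k = 6, delta = 1)
    sel <- select_predictors(fit_opls(sim$data), 1)
    mean(sim$informative %in% sel$loadings$variable)
  }, numeric(1))
  expect_gte(mean(retained), 0.8)
})

test_that("Hotelling screening is calibrated and catches gross outliers", {
  # calibration of the flagging rule itself (single screening pass);
  # the default two remove-refit rounds re-flag ~5% of the refit data
  # by design and are exercised on the planted outlier below
  frac_flagged <- vapply(1:100, function(seed) {
    sim <- sim_gaussian_cc(seed, n1 = 20, n0 = 20, p = 10, k = 0)
    hs <- hotelling_screen(fit_opls(sim$data), max_rounds = 1)
    mean(!hs$inliers$inlier)
  }, numeric(1))
  n <- 40
  expect_gte(mean(frac_flagged <= ceiling(0.05 * n) / n), 0.9)

  caught <- vapply(1:20, function(seed) {
    sim <- sim_gaussian_cc(seed, p = 10, k = 3, delta = 1)
    m <- fit_opls(sim$data)
    # displace one subject 10 SD along both score axes and refit
    d <- sim$data
    d[1, paste0("v", 1:10)] <- d[1, paste0("v", 1:10)] + 10
    hs <- hotelling_screen(fit_opls(d))
    !hs$inliers$inlier[1]
  }, logical(1))
  expect_true(all(caught))

  sim <- sim_gaussian_cc(3)
  hs <- hotelling_screen(fit_opls(sim$data), level = 1)
  expect_true(all(hs$inliers$inlier))
})

test_that("cross-validated explained variability behaves at both extremes", {
  d <- tibble::tibble(group = rep(c("patient", "control"), 12))
  d$x <- ifelse(d$group == "patient", 1, -1)
  d$x2 <- d$x + rnorm(24, sd = 1e-3)
  expect_gt(cross_validated_explained(d, predictors = c("x", "x2")), 95)

  null_cv <- vapply(1:200, function(seed) {
    sim <- sim_gaussian_cc(seed, p = 20, k = 0)
    cross_validated_explained(sim$data)
  }, numeric(1))
  expect_gte(mean(null_cv <= 10), 0.9)

  # optimism: cross-validated never beats the fit on the same data
  for (seed in 1:10) {
    sim <- sim_gaussian_cc(seed, k = 3)
    m <- fit_opls(sim$data)
    cv <- cross_validated_explained(sim$data)
    expect_lte(cv, m$explained_fit + 1e-6)
  }
})

test_that("the LLR link is logistic with the documented limits", {
  sim <- sim_gaussian_cc(1, k = 6, delta = 3)
  m <- fit_opls(sim$data)
  pred <- predict_llr(m, sim$data)
  expect_equal(pred$probability, plogis(pred$llr), tolerance = 1e-12)
  expect_equal(plogis(0), 0.5)
  expect_gt(plogis(20), 1 - 1e-8)
  expect_lt(plogis(-20), 1e-8)
  # strongly separable data classifies perfectly in sample
  rep <- classification_report(m)
  expect_equal(rep$summary$estimate, c(1, 1))
  expect_error(predict_llr(m, tibble::tibble(zz = 1)), "absent")
})

test_that("component counts are fixed at one predictive plus one orthogonal", {
  sim <- sim_gaussian_cc(1)
  expect_error(fit_opls(sim$data, n_orth = 2), "fixed")
  expect_error(fit_opls(dplyr::mutate(sim$data, group = "patient")),
               "constant")
  small <- sim_gaussian_cc(2, n1 = 4, n0 = 4)
  expect_error(fit_opls(small$data), "at least 6")
})

test_that("Wald intervals reproduce the reference proportions", {
  sens <- wald_ci(0.875, 24)
  expect_equal(round(sens$lower, 3), 0.743)
  expect_equal(sens$upper, 1)  # clipped
  spec <- wald_ci(0.75, 12)
  expect_equal(round(spec$lower, 3), 0.505)
  expect_equal(round(spec$upper, 3), 0.995)
  degenerate <- wald_ci(1, 10)
  expect_equal(c(degenerate$lower, degenerate$upper), c(1, 1))
  expect_error(wald_ci(0.5, 0), "at least 1")
})

test_that("the variable summary reports stable loadings as large t", {
  sim <- sim_gaussian_cc(9, k = 6, delta = 2)
  m <- fit_opls(sim$data)
  vs <- opls_variable_summary(m)
  expect_setequal(names(vs), c("variable", "loading_R", "t_stat", "b", "vip"))
  # strongly informative variables have larger |t| than pure noise
  informative <- vs$variable %in% sim$informative
  expect_gt(median(abs(vs$t_stat[informative])),
            median(abs(vs$t_stat[!informative])))
  expect_true(all(is.finite(vs$t_stat)))
})

test_that("tidy and glance expose the model surface", {
  sim <- sim_gaussian_cc(4)
  m <- fit_opls(sim$data)
  td <- tidy(m)
  expect_setequal(names(td),
                  c("variable", "w", "Pp", "Po", "vip", "loading_R", "b"))
  g <- glance(m)
  expect_equal(g$n, 40)
  expect_true(g$explained_fit >= 0 && g$explained_fit <= 100)
})
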