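test_that("the generator is deterministic given a seed", {
  d1 <- simulate_steroidome(simulation_design(), seed = 99)
  d2 <- simulate_steroidome(simulation_design(), seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_concentrations(d1$data, f1)
  write_concentrations(d2$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_steroidome(simulation_design(), seed = 100)
  expect_false(identical(d1$data, d3$data))
})

test_that("concentrations are positive and right-skewed, log-symmetric", {
  d <- simulate_steroidome(simulation_design(n_patients = 250,
                                             n_controls = 250,
                                             n_up = 0, n_down = 0),
                           seed = 4)
  an <- load_catalog()$analytes$abbreviation
  X <- as.matrix(d$data[an])
  expect_true(all(X > 0))
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  raw_skew <- apply(X, 2, skew)
  log_skew <- apply(log(X), 2, skew)
  expect_gte(mean(raw_skew > 0), 0.95)
  expect_lt(median(abs(log_skew)), 0.25)
})

test_that("pathway blocks carry the designed correlation", {
  rho <- 0.5
  d <- simulate_steroidome(simulation_design(n_patients = 1000,
                                             n_controls = 1000,
                                             n_up = 0, n_down = 0,
                                             block_rho = rho), seed = 5)
  cat81 <- load_catalog()
  an <- cat81$analytes
  free_d5 <- an$abbreviation[!an$conjugated & an$steroid_class == "delta5"]
  # exclude the age-dependent members so the check isolates block_rho
  free_d5 <- setdiff(free_d5, c("DHEA", "Adiol"))
  Xl <- log(as.matrix(d$data[free_d5]))
  C <- cor(Xl)
  within <- C[upper.tri(C)]
  expect_lt(abs(mean(within) - rho), 0.1)
  # across blocks: free delta5 vs corticoids uncorrelated
  Xc <- log(as.matrix(d$data[c("F", "E", "B")]))
  between <- cor(Xl, Xc)
  expect_lt(max(abs(between)), 0.15)
})

test_that("conjugates track their parents through the coupling model", {
  d <- simulate_steroidome(simulation_design(n_patients = 500,
                                             n_controls = 500,
                                             n_up = 0, n_down = 0),
                           seed = 6)
  an <- load_catalog()$analytes
  sd_preg <- (log(an$ctrl_q3[an$abbreviation == "Preg"]) -
                log(an$ctrl_q1[an$abbreviation == "Preg"])) /
    (2 * qnorm(0.75))
  expected <- sd_preg / sqrt(sd_preg^2 + 0.3^2)  # coupling_sd = 0.3
  r <- cor(log(d$data$PregS), log(d$data$Preg))
  expect_equal(r, expected, tolerance = 0.1)
})

test_that("ground truth records the planted pattern and severity model", {
  des <- simulation_design(n_up = 5, n_down = 15)
  d <- simulate_steroidome(des, seed = 8)
  expect_equal(sum(d$truth$effects$sign == 1), 5)
  expect_equal(sum(d$truth$effects$sign == -1), 15)
  expect_equal(nrow(d$truth$effects), 81)
  # severity indices exist for patients only
  pat <- d$data$group == "patient"
  expect_true(all(is.finite(d$data$EDSS[pat])))
  expect_true(all(is.na(d$data$EDSS[!pat])))
  # the four indices are monotone in the latent severity (positive cor)
  s <- d$truth$latent_severity[pat]
  for (ix in c("EDSS", "T25FWT", "HPT9_R", "HPT9_L")) {
    expect_gt(cor(s, d$data[[ix]][pat], method = "spearman"), 0.5)
  }
})

test_that("planted direction patterns are recovered by the screening stage", {
  # with per-variable power ~0.85 at n = 25/15 and 2.5% false positives
  # each way, the expected triplet is ~(6/60/14); its trend p-value sits
  # near the 0.05 boundary (the ideal (5/61/15) itself gives 0.026), so
  # the composition oracle puts the significant-down rate near 0.55 --
  # well above the 2.5% null rate but far from certainty
  grid <- seq(-3, 3, by = 0.5)
  out <- vapply(1:40, function(seed) {
    d <- simulate_steroidome(simulation_design(n_up = 5, n_down = 15),
                             seed = seed)
    vars <- intersect(load_catalog()$analytes$abbreviation, names(d$data))
    tr <- apply_transform(d$data, fit_transforms(d$data, vars, grid = grid))
    sc <- screen_variables(tr, d$data, vars = vars)
    cd <- code_directions(sc)
    tt <- trend_test(cd$n_up, cd$n_null, cd$n_down)
    c(down_dominant = cd$n_down > cd$n_up,
      sig_down = tt$p_value < 0.05 && tt$direction == "down")
  }, numeric(2))
  expect_gte(mean(out["down_dominant", ]), 0.8)
  expect_gte(mean(out["sig_down", ]), 0.3)
})

test_that("design validation rejects impossible settings", {
  expect_error(simulation_design(n_patients = 2))
  expect_error(simulation_design(block_rho = 1))
  expect_error(simulation_design(n_up = 60, n_down = 60))
})
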