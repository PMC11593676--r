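# Independent oracles used across the test suite. These are kept
# deliberately naive and separate from the package implementation.

# one-component PLS1 by NIPALS on an already centered/scaled matrix
nipals_pls1 <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(X %*% w)
  p1 <- drop(crossprod(X, t1)) / sum(t1^2)
  c1 <- sum(yc * t1) / sum(t1^2)
  list(w = w, t = t1, p = p1, c = c1)
}

# partial eta-squared for the status factor by explicit sums of squares
# in a two-way main-effects model (Type III == Type II here), computed
# from scratch with model.matrix algebra rather than the package path
brute_eta_p2 <- function(values, ms, agegrp) {
  X_full <- stats::model.matrix(~ factor(ms) + factor(agegrp))
  X_red <- stats::model.matrix(~ factor(agegrp))
  rss <- function(M) {
    fit <- qr.fitted(qr(M), values)
    sum((values - fit)^2)
  }
  ss_ms <- rss(X_red) - rss(X_full)
  ss_res <- rss(X_full)
  ss_ms / (ss_ms + ss_res)
}

# standardize columns of a matrix (training statistics)
std_cols <- function(X) {
  sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, stats::sd), "/")
}

# simple seeded case-control gaussian design: k informative variables
# shifted by delta SD among p total, n1 patients / n0 controls
sim_gaussian_cc <- function(seed, n1 = 20, n0 = 20, p = 20, k = 6,
                            delta = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), c(n1, n0))
  X <- matrix(stats::rnorm((n1 + n0) * p), n1 + n0, p)
  if (k > 0) X[y == 1, seq_len(k)] <- X[y == 1, seq_len(k)] + delta
  colnames(X) <- paste0("v", seq_len(p))
  d <- tibble::as_tibble(X)
  d$group <- ifelse(y == 1, "patient", "control")
  list(data = d, y = y, informative = paste0("v", seq_len(k)),
       true_direction = c(rep(1, k), rep(0, p - k)))
}
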