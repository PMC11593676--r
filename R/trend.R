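#' One-sample signed-rank trend test on significance-direction counts
#'
#' Aggregates a panel of per-variable screening outcomes, coded
#' +1 (significantly higher in patients), 0 (no significant difference)
#' and -1 (significantly lower), into a single meta-statistic: the
#' one-sample Wilcoxon signed-rank test with continuity correction.
#' Zeros are handled by the Pratt convention (they are ranked together
#' with the non-zero codes, occupying the lowest ranks, and then dropped
#' from the rank sums) and the null variance carries the Cureton tie
#' correction for the single tie group formed by the non-zero codes.
#'
#' With `u` ups, `m` nulls and `d` downs (`N = u + m + d`,
#' `k = u + d`), every non-zero code receives the shared mid-rank
#' `m + (k + 1) / 2`, so
#' \deqn{W^+ = u\,(m + (k+1)/2),\quad
#'       \mu = \tfrac{1}{2}\left[\tfrac{N(N+1)}{2} - \tfrac{m(m+1)}{2}\right],}
#' \deqn{\sigma^2 = \frac{N(N+1)(2N+1) - m(m+1)(2m+1)}{24} - \frac{k^3 - k}{48},}
#' and the standardized statistic is
#' `z = (W+ - mu - 0.5 * sign(W+ - mu)) / sigma` (set to 0 when
#' `|W+ - mu| <= 0.5`), referred to the standard normal distribution,
#' two-sided.
#'
#' @param n_up,n_null,n_down Non-negative integer counts of variables
#'   significantly up, not significant, and significantly down.
#'   Vectors are recycled to a common length.
#' @param exact If `TRUE`, replace the normal approximation by exact
#'   enumeration of the permutation distribution of `W+` (sign flips of
#'   the non-zero codes). Intended for methodological comparison only;
#'   the default normal approximation is the reference behaviour.
#'
#' @return A tibble with one row per input triplet and columns
#'   `n_up`, `n_null`, `n_down`, `w_plus`, `mu`, `sigma`, `z`,
#'   `p_value` and `direction` (`"up"`, `"down"` or `"none"`).
#'   When `n_up + n_down == 0` the test is degenerate and returns
#'   `z = 0`, `p_value = 1`, `direction = "none"`.
#' @seealso [signed_rank_general()] for the same statistic on arbitrary
#'   real-valued vectors, used as an internal cross-check.
#' @examples
#' trend_test(5, 61, 15)   # p = 0.026
#' trend_test(0, 4, 3)     # p = 0.102
#' @export
trend_test <- function(n_up, n_null, n_down, exact = FALSE) {
  n <- vctrs_recycle(n_up, n_null, n_down)
  u <- n[[1]]; m <- n[[2]]; d <- n[[3]]
  stopifnot(all(u >= 0), all(m >= 0), all(d >= 0),
            all(u == floor(u)), all(m == floor(m)), all(d == floor(d)))
  N <- u + m + d
  k <- u + d
  rbar <- m + (k + 1) / 2
  w_plus <- u * rbar
  mu <- (N * (N + 1) / 2 - m * (m + 1) / 2) / 2
  sigma2 <- (N * (N + 1) * (2 * N + 1) - m * (m + 1) * (2 * m + 1)) / 24 -
    (k^3 - k) / 48
  sigma <- sqrt(sigma2)
  delta <- w_plus - mu
  z <- ifelse(abs(delta) <= 0.5 | k == 0, 0,
              (delta - 0.5 * sign(delta)) / sigma)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(p, 1)
  if (exact) {
    p <- purrr::pmap_dbl(list(u, m, d), trend_exact_p)
  }
  direction <- dplyr::case_when(
    k == 0 | z == 0 ~ "none",
    delta > 0 ~ "up",
    TRUE ~ "down"
  )
  tibble::tibble(
    n_up = as.integer(u), n_null = as.integer(m), n_down = as.integer(d),
    w_plus = w_plus, mu = mu, sigma = ifelse(k == 0, 0, sigma),
    z = z, p_value = p, direction = direction
  )
}

# exact two-sided p by enumeration over the u+d sign flips; the k
# non-zero codes share one mid-rank so W+ is rbar * (#positives)
trend_exact_p <- function(u, m, d) {
  k <- u + d
  if (k == 0) return(1)
  rbar <- m + (k + 1) / 2
  w_obs <- u * rbar
  mu <- k * rbar / 2
  probs <- stats::dbinom(0:k, k, 0.5)
  w_all <- (0:k) * rbar
  p <- sum(probs[abs(w_all - mu) >= abs(w_obs - mu) - 1e-12])
  min(1, p)
}

#' Signed-rank trend statistic for arbitrary real values
#'
#' Full one-sample Wilcoxon signed-rank computation with Pratt zero
#' handling: absolute values are mid-ranked including zeros, zero ranks
#' are discarded from both rank sums, the null variance is corrected for
#' every tie group among the non-zero absolute values
#' (`- sum(t^3 - t) / 48`), and the normal approximation is continuity
#' corrected by 0.5. [trend_test()] is the closed form of this
#' computation for vectors that only contain the codes +1, 0 and -1.
#'
#' @param values Numeric vector; zeros are allowed, `NA`s are dropped.
#' @return A one-row tibble with the same columns as [trend_test()]
#'   (`n_up`/`n_null`/`n_down` hold the sign counts of `values`).
#' @examples
#' signed_rank_general(c(1, 2, 3))
#' signed_rank_general(rep(c(1, 0, -1), c(5, 61, 15)))  # == trend_test(5, 61, 15)
#' @export
signed_rank_general <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(is.numeric(values), length(values) >= 1)
  N <- length(values)
  zero <- values == 0
  m <- sum(zero)
  k <- N - m
  if (k == 0) {
    return(tibble::tibble(
      n_up = 0L, n_null = as.integer(m), n_down = 0L,
      w_plus = 0, mu = 0, sigma = 0, z = 0, p_value = 1,
      direction = "none"
    ))
  }
  r <- rank(abs(values))              # mid-ranks, zeros occupy the lowest
  w_plus <- sum(r[values > 0])
  mu <- sum(r[!zero]) / 2
  sigma2 <- (N * (N + 1) * (2 * N + 1) - m * (m + 1) * (2 * m + 1)) / 24
  tie_sizes <- table(abs(values[!zero]))
  sigma2 <- sigma2 - sum(tie_sizes^3 - tie_sizes) / 48
  sigma <- sqrt(sigma2)
  stopifnot(sigma > 0)
  delta <- w_plus - mu
  z <- if (abs(delta) <= 0.5) 0 else (delta - 0.5 * sign(delta)) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  tibble::tibble(
    n_up = sum(values > 0), n_null = as.integer(m),
    n_down = sum(values < 0),
    w_plus = w_plus, mu = mu, sigma = sigma, z = z, p_value = p,
    direction = if (z == 0) "none" else if (delta > 0) "up" else "down"
  )
}

#' Format a trend result in panel notation
#'
#' Renders a trend-test row as `"(u/m/d, p = x)"` with the p-value
#' rounded to three decimals, the notation used in panel summaries.
#'
#' @param result A tibble as returned by [trend_test()].
#' @return A character vector, one entry per row.
#' @examples
#' format_trend(trend_test(5, 61, 15))
#' @export
format_trend <- function(result) {
  p <- round(result$p_value, 3)
  ptxt <- ifelse(p < 0.001, "p < 0.001",
                 paste0("p = ", sub("0+$", "", sprintf("%.3f", p))))
  ptxt <- sub("= $", "= 1", sub("\\.$", "", ptxt))
  sprintf("(%d/%d/%d, %s)", result$n_up, result$n_null, result$n_down, ptxt)
}

# minimal common-length recycling for count vectors
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else rep_len(x, n)
  })
}
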