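#' Bayesian change-point analysis of a windowed series
#'
#' Product-partition change-point model (Barry-Hartigan) fitted by Gibbs
#' sampling: at every inter-window boundary the posterior probability of a
#' change in the underlying mean is estimated, together with the posterior
#' mean of the series. Priors are uniform on `[0, p0]` for the change
#' probability and `[0, w0]` for the signal-to-noise ratio, matching the
#' conventional defaults `p0 = w0 = 0.2`, 550 iterations with 50 burn-in.
#'
#' @param values numeric series (windowed H or dxy, masked windows removed
#'   beforehand).
#' @param p0,w0 prior truncation points.
#' @param iterations,burn_in Gibbs sweeps and burn-in sweeps.
#' @param seed optional integer seed (results are deterministic given the
#'   seed).
#' @return A list of class `bcp_result`: `windows` tibble (`index`, `value`,
#'   `post_mean`), `boundaries` tibble (`after_index`, `prob`), settings.
#' @export
bcp_posterior <- function(values, p0 = 0.2, w0 = 0.2, iterations = 550,
                          burn_in = 50, seed = NULL) {
  assert_that(length(values) >= 3, "series length must be >= 3")
  assert_that(!anyNA(values), "remove masked/NA windows before segmentation")
  assert_that(p0 > 0 && p0 <= 1 && w0 > 0 && w0 <= 1, "bad priors")
  assert_that(iterations > burn_in, "iterations must exceed burn_in")
  res <- with_seed_if(seed, cpp_bcp(values, p0, w0, iterations, burn_in))
  structure(
    list(windows = tibble(index = seq_along(values), value = values,
                          post_mean = res$mean),
         boundaries = tibble(after_index = seq_len(length(values) - 1),
                             prob = res$prob),
         settings = list(p0 = p0, w0 = w0, iterations = iterations,
                         burn_in = burn_in, seed = seed)),
    class = "bcp_result")
}

#' @export
print.bcp_result <- function(x, ...) {
  n_hi <- sum(x$boundaries$prob >= 0.5)
  cat(sprintf("<bcp_result> %d windows; %d boundaries with P(change) >= 0.5\n",
              nrow(x$windows), n_hi))
  invisible(x)
}

#' @export
tidy.bcp_result <- function(x, ...) x$boundaries

#' @export
glance.bcp_result <- function(x, ...) {
  tibble(n_windows = nrow(x$windows),
         n_boundaries_50 = sum(x$boundaries$prob >= 0.5),
         max_prob = max(x$boundaries$prob))
}

#' Extract divergence plateaus from a change-point fit
#'
#' Boundaries are inter-window points with posterior change probability at
#' or above `prob_threshold`; segments shorter than `min_windows` are merged
#' into the neighbour with the closer mean. Per-plateau mean divergence is
#' computed on the raw window values, and a moments split time
#' (`(mean - pi_within) / (2 mu)`) is attached when `mu` is given.
#'
#' @param cp a [bcp_posterior()] result.
#' @param prob_threshold posterior probability needed to call a boundary.
#' @param min_windows minimum plateau width in windows.
#' @param mu optional mutation rate for the split-time stand-in.
#' @param pi_within mean within-haplotype-class diversity used by the
#'   split-time estimator (default 0).
#' @return A tibble of class `plateau_set`: one row per plateau with
#'   `plateau`, `start_win`, `end_win`, `n_windows`, `mean_div`, `t_hat`.
#' @export
extract_plateaus <- function(cp, prob_threshold = 0.5, min_windows = 5,
                             mu = NULL, pi_within = 0) {
  assert_that(prob_threshold > 0 && prob_threshold < 1,
              "prob_threshold must be in (0, 1)")
  v <- cp$windows$value
  n <- length(v)
  bnd <- cp$boundaries$after_index[cp$boundaries$prob >= prob_threshold]
  starts <- c(1, bnd + 1)
  ends <- c(bnd, n)
  # merge short segments into the neighbour with the closer mean
  repeat {
    len <- ends - starts + 1
    if (length(starts) <= 1 || all(len >= min_windows)) break
    i <- which(len < min_windows)[1]
    m_i <- mean(v[starts[i]:ends[i]])
    left <- if (i > 1) abs(m_i - mean(v[starts[i - 1]:ends[i - 1]])) else Inf
    right <- if (i < length(starts))
      abs(m_i - mean(v[starts[i + 1]:ends[i + 1]])) else Inf
    if (left <= right) {
      ends[i - 1] <- ends[i]
      starts <- starts[-i]; ends <- ends[-i]
    } else {
      starts[i + 1] <- starts[i]
      starts <- starts[-i]; ends <- ends[-i]
    }
  }
  out <- tibble(plateau = seq_along(starts),
                start_win = as.integer(starts), end_win = as.integer(ends),
                n_windows = as.integer(ends - starts + 1),
                mean_div = vapply(seq_along(starts), function(i)
                  mean(v[starts[i]:ends[i]]), numeric(1)))
  out$t_hat <- if (is.null(mu)) NA_real_ else
    vapply(out$mean_div, function(d)
      moments_split_time(max(d, 0), pi_within, mu)$t_hat, numeric(1))
  class(out) <- c("plateau_set", class(out))
  out
}

#' Deterministic binary segmentation (BIC stopping)
#'
#' A deterministic fallback to the Gibbs sampler: recursively split at the
#' point maximizing the between-segment sum of squares, accepting a split
#' only if it lowers the Gaussian BIC.
#'
#' @param values numeric series.
#' @param min_size minimum segment size.
#' @return Integer boundary positions (change after these indices).
#' @export
binseg_boundaries <- function(values, min_size = 5) {
  n <- length(values)
  bic <- function(x) length(x) * log(max(sum((x - mean(x))^2), 1e-300) /
                                       length(x))
  rec <- function(lo, hi) {
    if (hi - lo + 1 < 2 * min_size) return(integer(0))
    x <- values[lo:hi]
    m <- length(x)
    cs <- cumsum(x); tot <- cs[m]
    i <- min_size:(m - min_size)
    rss <- vapply(i, function(j) {
      sum((x[1:j] - cs[j] / j)^2) +
        sum((x[(j + 1):m] - (tot - cs[j]) / (m - j))^2)
    }, numeric(1))
    j <- i[which.min(rss)]
    full <- bic(x)
    split <- j * log(max(sum((x[1:j] - mean(x[1:j]))^2), 1e-300) / j) +
      (m - j) * log(max(sum((x[(j + 1):m] - mean(x[(j + 1):m]))^2),
                        1e-300) / (m - j)) + 2 * log(n)
    if (split >= full) return(integer(0))
    c(rec(lo, lo + j - 1), lo + j - 1, rec(lo + j, hi))
  }
  sort(rec(1, n))
}
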