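# Analytic null distribution of the median of n i.i.d. Student-t variates.
#
# For odd n the median is the central order statistic and its density has
# the closed form g(t) = C_n F(t)^k (1-F(t))^k f(t), k = (n-1)/2,
# C_n = n!/(k! k!), with F and f the t cdf/pdf. For even n the analogous
# printed expression with C_n = n!/((n/2)! (n/2)!) does not integrate to 1
# (total mass 1/3 at n = 2); here the even-n median is defined - consistently
# with median_t_per_gene - as the mean of the two central order statistics,
# whose exact density is obtained by numerically integrating the joint
# density of those two order statistics. The non-normalizing expression is
# kept, clearly labeled, in median_t_pdf_as_printed() for documentation.

.mtd_cache <- new.env(parent = emptyenv())

# exact integer combinatorics, representable in doubles for n <= 50
factorial_exact <- function(n) {
  if (n <= 1) return(1)
  prod(seq_len(n))
}

#' Null distribution of the median of n i.i.d. t-variates
#'
#' @param n number of probes (i.i.d. t-variates), `>= 1`.
#' @param df degrees of freedom of the underlying Student t
#'   (`= n_A + n_B - 2` in the two-condition test), `>= 1`.
#' @return An object of class `median_t_dist` with fields `n`, `df`, `k`,
#'   `C_n` (the combinatorial constant of the odd-n closed form, or the
#'   printed even-n constant), cached per `(n, df)`.
#' @export
median_t_distribution <- function(n, df) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    pt_validation_error("'n' must be a single integer >= 1")
  }
  if (!is.numeric(df) || length(df) != 1L || df < 1) {
    pt_validation_error("'df' must be >= 1")
  }
  key <- paste(n, df, sep = ":")
  if (!is.null(.mtd_cache[[key]])) return(.mtd_cache[[key]])
  n <- as.integer(n)
  odd <- n %% 2L == 1L
  k <- if (odd) (n - 1L) %/% 2L else n %/% 2L
  c_n <- if (odd) {
    n * choose(2L * k, k)                       # n!/(k! k!), exact for n <= 50
  } else {
    choose(n, k)                                # printed even-n constant
  }
  # constant of the joint density of the two central order statistics
  # (used for the corrected even-n density): n!/((k-1)! (k-1)!)
  log_c_joint <- if (odd) NA_real_ else lfactorial(n) - 2 * lfactorial(k - 1L)
  obj <- structure(list(n = n, df = df, odd = odd, k = k, C_n = c_n,
                        log_C = if (odd) lfactorial(n) - 2 * lfactorial(k)
                                else log(c_n),
                        log_C_joint = log_c_joint),
                   class = "median_t_dist")
  .mtd_cache[[key]] <- obj
  obj
}

#' @export
print.median_t_dist <- function(x, ...) {
  cat(sprintf("median_t_dist: median of n = %d i.i.d. t(%g) variates (C_n = %g)\n",
              x$n, x$df, x$C_n))
  invisible(x)
}

# log F(t), log(1 - F(t)), log f(t) of the underlying t, numerically stable
t_logs <- function(t, df) {
  list(lF = stats::pt(t, df, log.p = TRUE),
       lS = stats::pt(t, df, lower.tail = FALSE, log.p = TRUE),
       lf = stats::dt(t, df, log = TRUE))
}

#' Density of the median of n i.i.d. t-variates
#'
#' Odd n uses the closed form above; even n evaluates the exact density of
#' the mean of the two central order statistics by adaptive quadrature of
#' their joint density. Symmetric about 0 and normalized to total mass 1.
#'
#' @param dist a [median_t_distribution()].
#' @param t numeric vector of evaluation points.
#' @return Vector of density values.
#' @export
median_t_pdf <- function(dist, t) {
  stopifnot(inherits(dist, "median_t_dist"))
  if (dist$odd) {
    l <- t_logs(t, dist$df)
    out <- exp(dist$log_C + dist$k * (l$lF + l$lS) + l$lf)
    out[!is.finite(t)] <- 0
    return(out)
  }
  k <- dist$k
  df <- dist$df
  lc <- dist$log_C_joint
  one <- function(m) {
    if (!is.finite(m)) return(0)
    # median m = (X_(k) + X_(k+1))/2; X_(k) = m - u, X_(k+1) = m + u, u >= 0
    integrand <- function(u) {
      lo <- t_logs(m - u, df)
      hi <- t_logs(m + u, df)
      exp(lc + (k - 1) * (lo$lF + hi$lS) + lo$lf + hi$lf)
    }
    2 * stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                         abs.tol = 1e-12)$value
  }
  vapply(t, one, numeric(1))
}

#' The density expression exactly as printed (documentation only)
#'
#' For odd n this equals [median_t_pdf()]. For even n it is the expression
#' `C_n F(t)^(n/2) (1-F(t))^(n/2) f(t)` with `C_n = n!/((n/2)!)^2`, which
#' does not integrate to 1 (total mass 1/3 at n = 2); it is provided only to
#' document that defect and must not be used for inference.
#'
#' @param n number of variates.
#' @param df degrees of freedom.
#' @param t evaluation points.
#' @return Vector of (for even n, unnormalized) density values.
#' @export
median_t_pdf_as_printed <- function(n, df, t) {
  dist <- median_t_distribution(n, df)
  if (dist$odd) return(median_t_pdf(dist, t))
  l <- t_logs(t, df)
  out <- exp(log(dist$C_n) + dist$k * (l$lF + l$lS) + l$lf)
  out[!is.finite(t)] <- 0
  out
}

#' Cumulative distribution of the median of n i.i.d. t-variates
#'
#' G(t) is obtained by adaptive quadrature of [median_t_pdf()] (absolute
#' tolerance 1e-9), exploiting the symmetry of the density about 0:
#' G(t) = 1/2 + sign(t) * integral of g over (0, |t|).
#'
#' @param dist a [median_t_distribution()].
#' @param t numeric vector.
#' @return Vector of probabilities in `[0, 1]`, nondecreasing in `t`.
#' @export
median_t_cdf <- function(dist, t) {
  stopifnot(inherits(dist, "median_t_dist"))
  one <- function(tt) {
    if (is.nan(tt)) return(NaN)
    if (!is.finite(tt)) return(if (tt > 0) 1 else 0)
    if (tt == 0) return(0.5)
    hi <- abs(tt)
    # piecewise so a huge |t| cannot hide the central peak from the
    # adaptive rule's first coarse pass
    brk <- unique(c(0, 10^(0:18)))
    brk <- c(brk[brk < hi], hi)
    half <- 0
    for (i in seq_len(length(brk) - 1L)) {
      half <- half + stats::integrate(function(u) median_t_pdf(dist, u),
                                      brk[i], brk[i + 1L],
                                      rel.tol = 1e-10, abs.tol = 1e-12,
                                      subdivisions = 200L)$value
    }
    min(max(0.5 + sign(tt) * half, 0), 1)
  }
  vapply(t, one, numeric(1))
}

#' p-value for an observed median t-value
#'
#' `sided = "one"` returns the left-tail mass G(t_m) (the integral of the
#' median-t density for t < t_m); the default `sided = "two"` returns
#' `2 * min(G(t_m), 1 - G(t_m))` since the direction of differential
#' expression is unspecified a priori. Infinite sentinels (zero pooled
#' variance with unequal means) give p = 0.
#'
#' @param dist a [median_t_distribution()].
#' @param t_m observed median t-value(s).
#' @param sided `"two"` (default) or `"one"`.
#' @return p-value(s) in `[0, 1]`.
#' @export
p_value <- function(dist, t_m, sided = c("two", "one")) {
  sided <- match.arg(sided)
  out <- numeric(length(t_m))
  inf <- !is.finite(t_m)
  out[inf] <- 0
  if (any(!inf)) {
    g <- median_t_cdf(dist, t_m[!inf])
    out[!inf] <- if (sided == "two") {
      pmin(pmax(2 * pmin(g, 1 - g), 0), 1)
    } else {
      pmin(pmax(g, 0), 1)
    }
  }
  out
}

# p-values for a vector of median t's with per-gene probe counts; one null
# distribution per distinct probe count.
median_t_p_values <- function(median_ts, n_per_gene, df,
                              sided = c("two", "one")) {
  sided <- match.arg(sided)
  n_per_gene <- n_per_gene[names(median_ts)]
  out <- numeric(length(median_ts))
  names(out) <- names(median_ts)
  for (n in unique(n_per_gene)) {
    sel <- n_per_gene == n
    out[sel] <- p_value(median_t_distribution(n, df), median_ts[sel],
                        sided = sided)
  }
  out
}

#' Monte-Carlo oracle: simulated medians of n i.i.d. t-variates
#'
#' Draws `n_draws` medians of `n` independent Student-t(`df`) variates,
#' reproducibly per seed. Used to validate the analytic density and cdf.
#'
#' @param n number of variates per median, `>= 1`.
#' @param df degrees of freedom.
#' @param n_draws number of medians to simulate.
#' @param seed integer seed.
#' @return Numeric vector of `n_draws` simulated medians.
#' @export
median_t_mc_oracle <- function(n, df, n_draws, seed) {
  if (n < 1 || n != round(n)) pt_validation_error("'n' must be an integer >= 1")
  with_seed(seed, {
    m <- matrix(stats::rt(n_draws * n, df), nrow = n_draws, ncol = n)
  })
  if (n == 1L) return(m[, 1L])
  row_medians(m)
}
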