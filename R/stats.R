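# Closed-form statistics used across modules. These are deliberately written
# from their textbook definitions; the test suite cross-checks them against
# the corresponding base-R routines on random data.

#' Fisher Z transform of a correlation coefficient
#'
#' \code{Z_R = 0.5 * (ln(1 + R) - ln(1 - R))}, the variance-stabilizing
#' transform applied to pairwise Pearson correlations before averaging.
#' Values with \code{|r| > 1 - 1e-6} are clipped to that bound first, so
#' perfectly correlated pairs stay finite instead of mapping to infinity.
#'
#' @param r Numeric vector of correlations in \code{[-1, 1]}.
#' @return Transformed values, same length as \code{r}.
#' @examples
#' fisher_z(0.6)  # 0.5 * log(4) = log(2)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  lim <- 1 - 1e-6
  r <- pmin(pmax(r, -lim), lim)
  0.5 * (log1p(r) - log1p(-r))
}

#' Inverse Fisher Z transform
#'
#' @param z Numeric vector of Fisher-Z values.
#' @return Correlations in \code{(-1, 1)}.
#' @export
fisher_z_inv <- function(z) {
  e <- exp(2 * z)
  (e - 1) / (e + 1)
}

#' One-sample t test from its closed form
#'
#' \code{t = (mean(x) - mu) / (sd(x) / sqrt(n))} with \code{n - 1} degrees of
#' freedom. Used to decide whether a post-odor active-wake bout is
#' hyperactive relative to the undisturbed active-wake baseline.
#'
#' @param x Numeric sample (per-cell bout means in the hyperactivity test).
#' @param mu Null value.
#' @param alternative One of "greater", "less", "two.sided".
#' @return List with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(x, mu, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("one_sample_t needs at least 2 observations")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    # Degenerate sample: decided by the sign of the shift alone.
    t <- if (m == mu) 0 else sign(m - mu) * Inf
  } else {
    t <- (m - mu) / (s / sqrt(n))
  }
  p <- switch(alternative,
    greater   = stats::pt(t, n - 1, lower.tail = FALSE),
    less      = stats::pt(t, n - 1, lower.tail = TRUE),
    two.sided = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  )
  list(t = t, df = n - 1, p = p, mean = m)
}

#' One-way ANOVA from closed-form sums of squares
#'
#' Between/within decomposition: \code{F = MS_between / MS_within} with
#' \code{k - 1} and \code{N - k} degrees of freedom. If the within-group
#' mean square is zero while the between-group mean square is positive the
#' layout is degenerate and reported as such rather than as an infinite F.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `F`, `df1`, `df2`, `p`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- vapply(groups, length, integer(1))
  if (length(groups) < 2 || any(ns < 1)) stop("need >= 2 non-empty groups")
  N <- sum(ns)
  k <- length(groups)
  if (N <= k) stop("no residual degrees of freedom")
  grand <- sum(vapply(groups, sum, numeric(1))) / N
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2
  if (ms_w == 0) {
    if (ms_b == 0) {
      return(list(F = 0, df1 = df1, df2 = df2, p = 1, degenerate = FALSE))
    }
    return(list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                degenerate = TRUE))
  }
  Fv <- ms_b / ms_w
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Two-way ANOVA (factor A x factor B) from classical sums of squares
#'
#' Classical balanced-layout decomposition into main effects, interaction
#' and residual. Used for the group-by-state comparison of synchrony. For
#' unbalanced layouts the classical formulas are only approximate and a
#' warning is issued.
#'
#' @param values Numeric response vector.
#' @param a,b Factors (coerced) of the same length as `values`.
#' @return List with per-term `F`, `df`, `p` plus `degenerate` flag.
#' @export
twoway_anova <- function(values, a, b) {
  ok <- !is.na(values)
  values <- values[ok]
  a <- factor(a[ok])
  b <- factor(b[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("both factors need >= 2 levels")
  n_cell <- table(a, b)
  if (any(n_cell == 0)) stop("every factor combination needs >= 1 observation")
  if (length(unique(as.vector(n_cell))) > 1) {
    warning("unbalanced layout: classical sums of squares are approximate")
  }
  N <- length(values)
  grand <- mean(values)
  mean_a <- tapply(values, a, mean)
  mean_b <- tapply(values, b, mean)
  mean_ab <- tapply(values, list(a, b), mean)
  n_a <- table(a); n_b <- table(b)
  ss_a <- sum(n_a * (mean_a - grand)^2)
  ss_b <- sum(n_b * (mean_b - grand)^2)
  cell_mean_for <- mean_ab[cbind(as.integer(a), as.integer(b))]
  ss_resid <- sum((values - cell_mean_for)^2)
  ss_ab <- sum(n_cell * (sweep(sweep(mean_ab, 1, mean_a), 2, mean_b) + grand)^2)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_resid <- N - nlevels(a) * nlevels(b)
  term <- function(ss, df) {
    if (df_resid <= 0 || ss_resid == 0) {
      return(list(F = NA_real_, df1 = df, df2 = df_resid, p = NA_real_))
    }
    Fv <- (ss / df) / (ss_resid / df_resid)
    list(F = Fv, df1 = df, df2 = df_resid,
         p = stats::pf(Fv, df, df_resid, lower.tail = FALSE))
  }
  list(A = term(ss_a, df_a), B = term(ss_b, df_b),
       AB = term(ss_ab, df_ab),
       degenerate = (df_resid <= 0 || ss_resid == 0))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' \code{D = sup |ECDF_a - ECDF_b|} evaluated over the pooled breakpoints,
#' with the p value from the asymptotic Kolmogorov distribution at
#' \code{lambda = sqrt(n_a n_b / (n_a + n_b)) * D}. Used to compare per-cell
#' peak-frequency distributions before and after odor exposure.
#'
#' @param a,b Numeric samples (per-cell peak frequencies).
#' @return List with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  a <- sort(a[!is.na(a)])
  b <- sort(b[!is.na(b)])
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both samples must be nonempty")
  if (min(n_a, n_b) < 5) {
    warning("fewer than 5 observations in a sample: asymptotic p unreliable")
  }
  pooled <- sort(unique(c(a, b)))
  ecdf_at <- function(x, q) findInterval(q, x) / length(x)
  D <- max(abs(ecdf_at(a, pooled) - ecdf_at(b, pooled)))
  lambda <- sqrt(n_a * n_b / (n_a + n_b)) * D
  p <- kolmogorov_sf(lambda)
  list(D = D, p = p, n_a = n_a, n_b = n_b)
}

# Survival function of the Kolmogorov distribution,
# Q(x) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 x^2).
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(1, max(0, p))
}
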