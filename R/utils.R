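#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov anova cor cov fft filter ks.test lm mad mantelhaen.test
#'   median p.adjust pnorm pt qchisq qnorm quantile rbinom rexp rlnorm rnorm
#'   rpois runif sd setNames t.test var predict coef complete.cases rgamma
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

sm_log <- function(...) {
  message("[seqmem] ", sprintf(...))
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log values.
#' @return log(sum(exp(x))).
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gaussian smoothing of a regularly sampled signal
#'
#' Convolves with a Gaussian kernel truncated at +/- 4 sd; boundaries are
#' handled by reflection so that a constant signal stays constant.
#'
#' @param x numeric vector.
#' @param sd_bins kernel standard deviation in bins.
#' @return smoothed vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  k <- k / sum(k)
  n <- length(x)
  # reflect-pad; for very short signals, recycle the reflection
  lpad <- x[pmin(n, pmax(1, (half + 1):2))]
  rpad <- x[pmax(1, pmin(n, (n - 1):(n - half)))]
  xp <- c(lpad, x, rpad)
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Analytic signal via FFT
#'
#' One-sided spectrum construction: positive frequencies doubled, negative
#' frequencies zeroed (Nyquist and DC kept once).
#'
#' @param x real numeric vector.
#' @return complex vector; `Mod()` is the envelope, `Arg()` the phase.
#' @export
analytic_signal <- function(x) {
  n0 <- length(x)
  # pad (by reflection) to a 2-3-5-smooth length: R's mixed-radix FFT is
  # quadratic in large prime factors
  N <- stats::nextn(n0, c(2L, 3L, 5L))
  if (N > n0) x <- c(x, x[n0 - seq_len(N - n0)])
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- fft(X * h, inverse = TRUE) / n
  a[seq_len(n0)]
}

#' Von Mises density factor normalized to unit mean
#'
#' exp(kappa*cos(theta - mu)) / I0(kappa): multiplying a rate by this factor
#' modulates firing by phase without changing the cycle-averaged rate.
#'
#' @param theta_deg phase in degrees.
#' @param mu_deg preferred phase in degrees.
#' @param kappa concentration (0 = no modulation).
#' @return numeric vector of gain factors (mean 1 over a uniform phase).
#' @export
von_mises_gain <- function(theta_deg, mu_deg, kappa) {
  if (kappa <= 0) return(rep(1, length(theta_deg)))
  exp(kappa * cos((theta_deg - mu_deg) * pi / 180)) / besselI(kappa, 0)
}

circ_mean_deg <- function(theta_deg) {
  (atan2(mean(sin(theta_deg * pi / 180)), mean(cos(theta_deg * pi / 180))) *
     180 / pi) %% 360
}

#' Circular-circular correlation (Jammalamadaka-Sarma) with asymptotic p
#' @param a,b angles in radians.
#' @return list(rho, p)
#' @keywords internal
circ_cor <- function(a, b) {
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(list(rho = 0, p = 1))
  rho <- sum(sa * sb) / den
  n <- length(a)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  if (l22 <= 0) return(list(rho = rho, p = 1))
  z <- sqrt(n * l20 * l02 / l22) * rho
  list(rho = rho, p = 2 * pnorm(-abs(z)))
}

#' Circular-linear correlation with bounded slope fit
#'
#' Finds the slope `a` (in cycles per unit of `t`) maximizing the mean
#' resultant length of `phi - 2*pi*a*t`, then reports the circular-circular
#' correlation between `phi` and the fitted circular variable `2*pi*a*t`.
#'
#' @param phi_deg spike phases in degrees.
#' @param t linear covariate (e.g. time within trial).
#' @param slope_bound maximum |slope| in cycles over the range of `t`.
#' @return list(rho, p, slope_deg_per_unit)
#' @export
circ_lin_cor <- function(phi_deg, t, slope_bound = 2) {
  phi <- phi_deg * pi / 180
  tr <- diff(range(t))
  if (tr == 0 || length(phi) < 5) return(list(rho = NA_real_, p = NA_real_, slope_deg_per_unit = NA_real_))
  res_len <- function(a) {
    z <- phi - 2 * pi * a * t
    sqrt(mean(cos(z))^2 + mean(sin(z))^2)
  }
  grid <- seq(-slope_bound / tr, slope_bound / tr, length.out = 201)
  r <- vapply(grid, res_len, numeric(1))
  a0 <- grid[which.max(r)]
  opt <- stats::optimize(res_len, lower = a0 - 2 * diff(grid[1:2]),
                         upper = a0 + 2 * diff(grid[1:2]), maximum = TRUE)
  a <- opt$maximum
  cc <- circ_cor(phi, (2 * pi * a * t) %% (2 * pi))
  list(rho = sign(a) * abs(cc$rho), p = cc$p,
       slope_deg_per_unit = a * 360)
}

#' Goodman simultaneous confidence intervals for multinomial proportions
#'
#' @param counts vector of category counts.
#' @param conf overall simultaneous confidence level.
#' @return data.frame(count, p_hat, lower, upper)
#' @export
multinomial_ci <- function(counts, conf = 0.95) {
  k <- length(counts); N <- sum(counts)
  if (N == 0) stop("multinomial_ci: zero total count")
  B <- qchisq(1 - (1 - conf) / k, df = 1)
  p <- counts / N
  half <- sqrt(B * (B + 4 * counts * (N - counts) / N))
  lower <- (B + 2 * counts - half) / (2 * (N + B))
  upper <- (B + 2 * counts + half) / (2 * (N + B))
  data.frame(count = counts, p_hat = p,
             lower = pmax(0, lower), upper = pmin(1, upper))
}

#' KL divergence between two discrete distributions (nats)
#'
#' Distributions are floored at `eps` and renormalized before the divergence
#' is taken, so zero bins do not produce infinities.
#'
#' @param p,q probability vectors of equal length.
#' @param eps floor applied to both before renormalization.
#' @return KL(p || q) in nats.
#' @export
kl_divergence <- function(p, q, eps = 1e-12) {
  stopifnot(length(p) == length(q))
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  sum(p * log(p / q))
}

# interpolate a (possibly wrapped) phase series at arbitrary times
interp_phase_deg <- function(t_grid, phase_deg, t_query) {
  un <- unwrap_deg(phase_deg)
  stats::approx(t_grid, un, xout = t_query, rule = 2)$y %% 360
}

unwrap_deg <- function(p) {
  d <- diff(p)
  d <- d - 360 * round(d / 360)
  c(p[1], p[1] + cumsum(d))
}
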