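## Population-moment helpers and the moment-matched samplers behind the
## phantom generator. All shape statistics use population (divide-by-n)
## central moments and the Pearson (non-excess) kurtosis convention, so a
## Gaussian has kurtosis 3.

central_moment <- function(x, k) mean((x - mean(x))^k)

#' Skewness of a pixel collection
#'
#' Third standardized central moment \eqn{m_3 / m_2^{3/2}} with population
#' (divide-by-n) moments. Right-tailed distributions are positive.
#'
#' @param x numeric vector of gray-level values.
#' @return A single number.
#' @export
#' @examples
#' skewness(c(0, 0, 0, 1))  # long right tail, positive
skewness <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= 0) stop("skewness undefined for constant input", call. = FALSE)
  central_moment(x, 3) / m2^1.5
}

#' Kurtosis of a pixel collection
#'
#' Pearson kurtosis \eqn{m_4 / m_2^2} (population moments, not excess):
#' a Gaussian gives 3, a two-point symmetric distribution gives 1.
#'
#' @inheritParams skewness
#' @return A single number, always \eqn{\ge} skewness^2 + 1.
#' @export
kurtosis <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= 0) stop("kurtosis undefined for constant input", call. = FALSE)
  central_moment(x, 4) / m2^2
}

## ---- truncated / clipped normal moment algebra -------------------------

## E[T^k | alpha < T < beta] for standard normal T, k = 0..4, via the
## recursion M_k = (k-1) M_{k-2} + (alpha^{k-1} phi(alpha) - beta^{k-1} phi(beta)) / Z
std_trunc_moments <- function(alpha, beta) {
  Z <- pnorm(beta) - pnorm(alpha)
  if (Z <= 0) return(rep(NA_real_, 5))
  pa <- dnorm(alpha); pb <- dnorm(beta)
  pow <- function(v, k) if (is.finite(v)) v^k else 0  # x^k phi(x) -> 0 at +-Inf
  term <- function(k) (pow(alpha, k - 1) * pa - pow(beta, k - 1) * pb) / Z
  M0 <- 1
  M1 <- (pa - pb) / Z
  M2 <- M0 + term(2)
  M3 <- 2 * M1 + term(3)
  M4 <- 3 * M2 + term(4)
  c(M0, M1, M2, M3, M4)
}

## Raw moments E[Y^k], k = 1..4, of Y = clip(X, a, b) with X ~ N(m, s).
## Clipping puts point masses at a and b plus the truncated interior.
clipped_normal_raw_moments <- function(m, s, a, b) {
  alpha <- if (is.finite(a)) (a - m) / s else -Inf
  beta  <- if (is.finite(b)) (b - m) / s else Inf
  pl <- pnorm(alpha); pu <- 1 - pnorm(beta)
  Z <- 1 - pl - pu
  out <- numeric(4)
  if (Z > 0) {
    M <- std_trunc_moments(alpha, beta)
    for (k in 1:4) {
      j <- 0:k   # binomial expansion of (m + sT)^k
      out[k] <- Z * sum(choose(k, j) * m^(k - j) * s^j * M[j + 1])
    }
  }
  if (pl > 0) out <- out + pl * a^(1:4)
  if (pu > 0) out <- out + pu * b^(1:4)
  out
}

## mean/sd/skewness/kurtosis of clip(X, a, b) for X a two-component normal
## mixture (weights w, means mu, sds sg).
mixture_clipped_shape <- function(w, mu, sg, a = -Inf, b = Inf) {
  r <- w[1] * clipped_normal_raw_moments(mu[1], sg[1], a, b) +
       w[2] * clipped_normal_raw_moments(mu[2], sg[2], a, b)
  m1 <- r[1]
  m2 <- r[2] - m1^2
  m3 <- r[3] - 3 * m1 * r[2] + 2 * m1^3
  m4 <- r[4] - 4 * m1 * r[3] + 6 * m1^2 * r[2] - 3 * m1^4
  if (m2 <= 0) return(c(mean = m1, sd = 0, skewness = NA, kurtosis = NA))
  c(mean = m1, sd = sqrt(m2), skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

## ---- standardized two-component mixture solver -------------------------

## Solve for a two-component normal mixture with mean 0, variance 1 and the
## given skewness/kurtosis. Parameterization enforces the first two moments
## exactly: theta = (logit w, m1, log s1); m2 and s2 follow.
mixture_from_theta <- function(theta) {
  w1 <- plogis(theta[1])
  m1 <- theta[2]
  s1 <- exp(theta[3])
  w2 <- 1 - w1
  m2 <- -w1 * m1 / w2
  s2sq <- (1 - w1 * (m1^2 + s1^2)) / w2 - m2^2
  if (!is.finite(s2sq) || s2sq <= 1e-10) return(NULL)
  list(w = c(w1, w2), mu = c(m1, m2), sg = c(s1, sqrt(s2sq)))
}

## standardized mixture shape (exact closed form, no clipping)
mixture_std_shape <- function(mix) {
  raw3 <- function(m, s) m^3 + 3 * m * s^2
  raw4 <- function(m, s) m^4 + 6 * m^2 * s^2 + 3 * s^4
  g1 <- sum(mix$w * raw3(mix$mu, mix$sg))
  g2 <- sum(mix$w * raw4(mix$mu, mix$sg))
  c(g1, g2)  # mean 0, var 1 by construction
}

## cache: standardized solves keyed by rounded targets
.mix_cache <- new.env(parent = emptyenv())

## Solve the standardized mixture for target (skewness g1, kurtosis g2).
## Feasibility requires g2 > g1^2 + 1 (with a little slack for the mixture
## family); multi-start Nelder-Mead on the 3 free parameters.
solve_mixture_std <- function(g1, g2, cache = TRUE) {
  if (g2 <= g1^2 + 1) {
    stop(sprintf(
      "infeasible moments: kurtosis (%.3f) must exceed skewness^2 + 1 (%.3f)",
      g2, g1^2 + 1), call. = FALSE)
  }
  key <- sprintf("%.5f_%.5f", g1, g2)
  if (cache && !is.null(.mix_cache[[key]])) return(.mix_cache[[key]])
  obj <- function(theta) {
    mix <- mixture_from_theta(theta)
    if (is.null(mix)) return(1e6)
    sh <- mixture_std_shape(mix)
    (sh[1] - g1)^2 + ((sh[2] - g2) / 4)^2
  }
  ## warm start from the nearest previously solved target on a coarse grid
  wkey <- sprintf("w%.2f_%.2f", round(g1 * 4) / 4, round(g2 * 4) / 4)
  best <- NULL
  if (cache && !is.null(.mix_cache[[wkey]])) {
    best <- stats::optim(.mix_cache[[wkey]], obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-12))
  }
  if (is.null(best) || best$value > 1e-10) {
    side <- if (g1 < 0) -1 else 1
    starts <- list(
      c(qlogis(0.15), side * 1.5, log(1.0)),
      c(qlogis(0.10), side * 2.0, log(1.5)),
      c(qlogis(0.30), side * 1.0, log(0.8)),
      c(qlogis(0.05), side * 2.5, log(2.0))
    )
    for (st in starts) {
      fit <- stats::optim(st, obj, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-12) break
    }
  }
  mix <- mixture_from_theta(best$par)
  mix$residual <- best$value
  if (cache) {
    .mix_cache[[key]] <- mix
    .mix_cache[[wkey]] <- best$par
  }
  mix
}

## Solve a two-component mixture whose *post-clipping* mean/sd/skew/kurt
## match the targets on [floor, cap]. Used when the clip mass is
## non-negligible; weighted so mean/sd dominate when the full four-moment
## target is unreachable inside the bounds.
solve_mixture_clipped <- function(mean, sd, g1, g2, floor, cap) {
  std <- solve_mixture_std(g1, g2)
  start <- c(qlogis(std$w[1]), mean + sd * std$mu, log(sd * std$sg))
  obj <- function(par) {
    w1 <- plogis(par[1])
    mu <- par[2:3]; sg <- exp(par[4:5])
    sh <- mixture_clipped_shape(c(w1, 1 - w1), mu, sg, floor, cap)
    if (!is.finite(sh[3])) return(1e6)
    10 * ((sh[1] - mean) / sd)^2 + 10 * ((sh[2] - sd) / sd)^2 +
      (sh[3] - g1)^2 + ((sh[4] - g2) / 4)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
  if (fit$value > 1e-6) {   # one polish pass; some near-floor targets are
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",  # unreachable
                        control = list(maxit = 600, reltol = 1e-12))
  }
  w1 <- plogis(fit$par[1])
  list(w = c(w1, 1 - w1), mu = fit$par[2:3], sg = exp(fit$par[4:5]),
       residual = fit$value)
}

## fraction of mixture mass outside [floor, cap]
mixture_clip_mass <- function(w, mu, sg, floor, cap) {
  lo <- if (is.finite(floor)) sum(w * pnorm((floor - mu) / sg)) else 0
  hi <- if (is.finite(cap)) sum(w * pnorm((cap - mu) / sg, lower.tail = FALSE)) else 0
  lo + hi
}

## draw n values from a two-component normal mixture
sample_mixture <- function(n, w, mu, sg) {
  comp <- sample.int(2L, n, replace = TRUE, prob = w)
  rnorm(n, mean = mu[comp], sd = sg[comp])
}

## ---- skew-normal ------------------------------------------------------

## Azzalini skew-normal: skewness attainable only in (-0.9953, 0.9953).
## delta solved from the target skewness by root finding.
sn_max_skew <- 0.99527  # supremum as delta -> 1

sn_skew_from_delta <- function(delta) {
  mz <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * mz^3 / (1 - mz^2)^1.5
}

sn_delta_from_skew <- function(g1) {
  stopifnot(abs(g1) < sn_max_skew)
  if (g1 == 0) return(0)
  f <- function(d) sn_skew_from_delta(d) - abs(g1)
  d <- uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  sign(g1) * d
}

## n standardized (mean 0, var 1) skew-normal draws with shape delta
sample_skew_normal_std <- function(n, delta) {
  u0 <- rnorm(n); u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  mz <- delta * sqrt(2 / pi)
  (z - mz) / sqrt(1 - mz^2)
}
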