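## Within- vs between-species repeatability (intra-class correlation) of
## regional niche-breadth metrics, via the one-way Gaussian random-intercept
## model  y_ij = mu + a_i + e_ij,  a_i ~ N(0, s2b),  e_ij ~ N(0, s2w).
##
## The REML/ML log-likelihoods of this model reduce, per group i with n_i
## observations, mean ybar_i and within-group sum of squares SSW_i, to
## functions of the variance ratio gamma = s2b/s2w only (mu and s2w profile
## out in closed form), so a fit is a 1-D bounded optimization. This keeps
## the parametric bootstrap (1000 refits per interval) and calibration
## studies cheap.

#' IccResult: repeatability estimate with bootstrap uncertainty
#'
#' @slot R ICC point estimate, \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_w)}.
#' @slot se Parametric-bootstrap standard error.
#' @slot ci Percentile bootstrap interval (2.5%, 97.5%).
#' @slot p Likelihood-ratio p-value for \eqn{\sigma^2_b = 0} (50:50
#'   \eqn{\chi^2_0/\chi^2_1} boundary mixture).
#' @slot sigma2Between,sigma2Within REML variance components.
#' @slot logLik REML log-likelihood at the optimum.
#' @slot nBoot Number of bootstrap refits.
#' @slot boot Bootstrap replicate ICCs.
#' @export
setClass("IccResult",
  representation(R = "numeric", se = "numeric", ci = "numeric", p = "numeric",
                 sigma2Between = "numeric", sigma2Within = "numeric",
                 logLik = "numeric", nBoot = "integer", boot = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@R < -1e-12 || object@R > 1 + 1e-12)
      msg <- c(msg, "R must lie in [0, 1]")
    if (length(object@ci) != 2L || object@ci[1] > object@ci[2] + 1e-12)
      msg <- c(msg, "ci must be (lower, upper) with lower <= upper")
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("show", "IccResult", function(object) {
  cat(sprintf("ICC = %.3f +/- %.3f  [%.3f, %.3f]  P = %s\n",
              object@R, object@se, object@ci[1], object@ci[2],
              format.pval(object@p, digits = 3)))
  cat(sprintf("  sigma2 between = %.4g, within = %.4g  (%d bootstrap refits)\n",
              object@sigma2Between, object@sigma2Within, object@nBoot))
})

checkGrouped <- function(values, groups) {
  stopIfNot(length(values) == length(groups), "values and groups differ in length")
  stopIfNot(all(is.finite(values)), "values must be finite")
  groups <- as.character(groups)
  sizes <- table(groups)
  stopIfNot(length(sizes) >= 2L, "need at least two groups")
  stopIfNot(any(sizes >= 2L), "need at least one group with two observations")
  groups
}

## Per-group sufficient statistics.
groupStats <- function(values, groups) {
  ybar <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  ssw <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  list(ybar = as.numeric(ybar), n = as.numeric(n), ssw = as.numeric(ssw),
       N = length(values))
}

## Profiled log-likelihood at variance ratio gamma; REML or ML.
## Returns list(loglik, mu, s2w).
profileLik <- function(gs, gamma, reml = TRUE) {
  lam <- 1 + gs$n * gamma
  wsum <- sum(gs$n / lam)
  mu <- sum(gs$n * gs$ybar / lam) / wsum
  Q <- sum(gs$ssw) + sum(gs$n * (gs$ybar - mu)^2 / lam)
  N <- gs$N
  if (Q <= 0) return(list(loglik = Inf, mu = mu, s2w = 0))
  if (reml) {
    s2w <- Q / (N - 1)
    ll <- -0.5 * ((N - 1) * (log(2 * pi) + log(s2w) + 1) +
                    sum(log(lam)) + log(wsum))
  } else {
    s2w <- Q / N
    ll <- -0.5 * (N * (log(2 * pi) + log(s2w) + 1) + sum(log(lam)))
  }
  list(loglik = ll, mu = mu, s2w = s2w)
}

#' REML variance components of the one-way random-intercept model
#'
#' Maximizes the REML (or ML) log-likelihood, profiled over the mean and the
#' residual variance, over the ratio \eqn{\gamma = \sigma^2_b/\sigma^2_w}
#' constrained to \eqn{\ge 0}. Unbalanced group sizes are handled natively.
#'
#' @param values Numeric vector of observations (e.g. a parasite's regional
#'   niche-breadth values).
#' @param groups Group labels (e.g. parasite species), same length.
#' @param reml Use REML (default) or ML.
#' @return List with `sigma2Between`, `sigma2Within`, `logLik`, `mu`.
#' @export
fitVarianceComponents <- function(values, groups, reml = TRUE) {
  groups <- checkGrouped(values, groups)
  gs <- groupStats(values, groups)
  if (stats::var(values) < .Machine$double.eps * max(1, mean(values)^2)) {
    warning("all values identical; variance components are degenerate",
            call. = FALSE)
    return(list(sigma2Between = 0, sigma2Within = 0, logLik = NA_real_, mu = mean(values)))
  }
  obj <- function(phi) profileLik(gs, exp(phi), reml)$loglik
  opt <- stats::optimize(obj, interval = c(-18, 18), maximum = TRUE, tol = 1e-10)
  atZero <- profileLik(gs, 0, reml)
  if (atZero$loglik >= opt$objective) {
    gamma <- 0; ll <- atZero$loglik; prof <- atZero
  } else {
    gamma <- exp(opt$maximum); ll <- opt$objective
    prof <- profileLik(gs, gamma, reml)
  }
  list(sigma2Between = gamma * prof$s2w, sigma2Within = prof$s2w,
       logLik = ll, mu = prof$mu)
}

iccPoint <- function(values, groups, reml = TRUE) {
  vc <- suppressWarnings(fitVarianceComponents(values, groups, reml))
  tot <- vc$sigma2Between + vc$sigma2Within
  if (tot <= 0) 0 else vc$sigma2Between / tot
}

#' Repeatability (ICC) with parametric-bootstrap uncertainty
#'
#' Point estimate \eqn{R = \sigma^2_b / (\sigma^2_b + \sigma^2_w)} from REML;
#' standard error and percentile confidence interval from `nBoot` parametric
#' bootstrap refits (data re-simulated from the fitted model and
#' re-estimated); p-value from the likelihood-ratio test of
#' \eqn{\sigma^2_b = 0} against the 50:50 \eqn{\chi^2_0/\chi^2_1} boundary
#' mixture, using ML fits.
#'
#' @inheritParams fitVarianceComponents
#' @param nBoot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param level Confidence level of the percentile interval.
#' @return An [IccResult-class] object.
#' @examples
#' set.seed(1)
#' g <- rep(1:20, each = 3)
#' y <- rnorm(20, sd = 1)[g] + rnorm(60)
#' icc(y, g, nBoot = 99, seed = 1)
#' @export
icc <- function(values, groups, nBoot = 1000L, seed = 1L, level = 0.95,
                reml = TRUE) {
  stopIfNot(nBoot >= 2L, "nBoot must be at least 2")
  groups <- checkGrouped(values, groups)
  vc <- fitVarianceComponents(values, groups, reml)
  tot <- vc$sigma2Between + vc$sigma2Within
  R <- if (tot <= 0) 0 else vc$sigma2Between / tot

  # boundary-corrected LRT (ML vs the single-normal null)
  mlFit <- fitVarianceComponents(values, groups, reml = FALSE)
  N <- length(values)
  s20 <- sum((values - mean(values))^2) / N
  ll0 <- if (s20 > 0) -0.5 * N * (log(2 * pi) + log(s20) + 1) else NA_real_
  lr <- max(0, 2 * (mlFit$logLik - ll0))
  p <- if (is.na(lr)) NA_real_ else if (lr == 0) 1 else
    0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)

  sizes <- tapply(values, groups, length)
  boot <- withSeed(seed, {
    sb <- sqrt(vc$sigma2Between); sw <- sqrt(vc$sigma2Within)
    vapply(seq_len(nBoot), function(b) {
      a <- stats::rnorm(length(sizes), 0, sb)
      ysim <- vc$mu + rep(a, sizes) + stats::rnorm(N, 0, sw)
      iccPoint(ysim, rep(names(sizes), sizes), reml)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  methods::new("IccResult", R = R, se = stats::sd(boot), ci = ci, p = p,
               sigma2Between = vc$sigma2Between, sigma2Within = vc$sigma2Within,
               logLik = vc$logLik, nBoot = as.integer(nBoot), boot = boot)
}
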