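# Count regressions for side-effect burden: median binning of responses,
# negative binomial / Poisson GLM with log link (authored fit: IRLS for the
# coefficients alternating with profile maximum likelihood for the shape
# theta), an overdispersion diagnostic, and the Wilcoxon rank-sum wrapper.

#' Median-bin counts by covariate level
#'
#' Groups observations by unique covariate value (ascending) and replaces
#' each level's raw counts by their median, to damp the influence of
#' extreme observations. Sparse levels at the upper margin are merged
#' downward: sweeping from the largest level, any level with fewer than
#' `min_bin_size` observations is merged into the next lower level and the
#' combined level re-checked, so thin margins cascade into bins of at least
#' `min_bin_size` (the single lowest level may remain smaller). A merged
#' level's covariate value is the observation-weighted mean of its member
#' levels; the median of an even-sized group is the mean of the two central
#' values.
#'
#' @param x numeric covariate values.
#' @param y non-negative counts, same length as `x`.
#' @param min_bin_size minimum observations per (merged) level.
#' @return data frame with columns `x_level`, `median_count`, `n_drugs`.
#' @export
median_bin <- function(x, y, min_bin_size = 5L) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  if (min_bin_size < 1L) stop("min_bin_size must be >= 1", call. = FALSE)
  lev <- sort(unique(x))
  bins <- lapply(lev, function(v) which(x == v))
  i <- length(bins)
  while (i >= 2L) {
    if (length(bins[[i]]) < min_bin_size) {
      bins[[i - 1L]] <- c(bins[[i - 1L]], bins[[i]])
      bins[[i]] <- NULL
    }
    i <- i - 1L
  }
  data.frame(
    x_level = vapply(bins, function(ix) mean(x[ix]), numeric(1)),
    median_count = vapply(bins, function(ix) stats::median(y[ix]), numeric(1)),
    n_drugs = vapply(bins, length, integer(1)))
}

# Round half-up to an integer (binned medians can be half-integral and the
# count likelihood needs integer responses).
round_half_up <- function(x) floor(x + 0.5)

# NB log-likelihood at response y, mean mu, shape theta; `pw` case weights.
nb_loglik <- function(y, mu, theta, pw = rep(1, length(y))) {
  sum(pw * (lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
              theta * log(theta / (theta + mu)) +
              ifelse(y > 0, y * log(mu / (theta + mu)), 0)))
}

pois_loglik <- function(y, mu, pw = rep(1, length(y))) {
  sum(pw * stats::dpois(y, mu, log = TRUE))
}

# One IRLS solve of log mu = X b for fixed working weights family:
# family "poisson": w = mu; "nb": w = mu / (1 + mu / theta).
# `pw` are prior (case) weights multiplying each observation's likelihood.
irls_loglink <- function(X, y, family, theta = NULL, start = NULL,
                         pw = rep(1, length(y)),
                         tol = 1e-10, max_iter = 50L) {
  eta <- if (is.null(start)) log(pmax(y, 0.5)) else drop(X %*% start)
  coef <- start
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- pw * if (family == "poisson") mu else mu / (1 + mu / theta)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    new_coef <- fit$coefficients
    eta_new <- drop(X %*% new_coef)
    if (!is.null(coef) &&
        max(abs(new_coef - coef)) < tol * (1 + max(abs(new_coef)))) {
      coef <- new_coef; eta <- eta_new; break
    }
    coef <- new_coef; eta <- eta_new
  }
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- pw * if (family == "poisson") mu else mu / (1 + mu / theta)
  list(coef = coef, mu = mu, eta = eta, w = w)
}

#' Fit a count GLM with log link
#'
#' Fits `log mu = intercept + beta * x` by maximum likelihood for a
#' negative binomial or Poisson response. The negative binomial shape
#' `theta` is estimated by profile maximum likelihood, alternating with
#' iteratively reweighted least-squares updates of the coefficients until
#' the joint log-likelihood converges (relative change < 1e-8, at most 100
#' outer iterations). With `binning = TRUE` the response is first reduced to
#' per-level medians via [median_bin()] (half-integral medians rounded
#' half-up).
#'
#' The p-value is a two-sided Wald test of beta = 0, with the standard
#' error taken from the Fisher information at the fitted coefficients
#' (conditional on the estimated theta).
#'
#' @param x numeric covariate.
#' @param y non-negative integer counts.
#' @param family `"negative_binomial"` or `"poisson"`.
#' @param binning reduce to median-binned levels before fitting?
#' @param min_bin_size margin-merge threshold passed to [median_bin()].
#' @param theta_fixed optional fixed shape; skips theta estimation
#'   (negative binomial only).
#' @param weight_levels when binning, weight each level's likelihood
#'   contribution by the number of drugs in the level (medians of larger
#'   levels are better estimated); `FALSE` treats every level equally.
#' @return object of class `count_glm`: list with `beta`, `intercept`,
#'   `se_beta`, `wald_p`, `theta` (`NULL` for Poisson), `n_obs_fitted`,
#'   `converged`, `family`, `loglik`, and the fitted `points`.
#' @export
fit_count_glm <- function(x, y, family = c("negative_binomial", "poisson"),
                          binning = TRUE, min_bin_size = 5L,
                          theta_fixed = NULL, weight_levels = TRUE) {
  family <- match.arg(family)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (binning) {
    pts <- median_bin(x, y, min_bin_size)
    xf <- pts$x_level
    yf <- round_half_up(pts$median_count)
    pw <- if (weight_levels) as.numeric(pts$n_drugs) else
      rep(1, nrow(pts))
  } else {
    pts <- data.frame(x_level = x, median_count = y,
                      n_drugs = rep(1L, length(x)))
    xf <- x; yf <- y
    pw <- rep(1, length(x))
  }
  if (length(unique(xf)) < 3L)
    stop("need at least 3 distinct covariate levels to fit", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x = xf)

  converged <- TRUE
  if (family == "poisson") {
    fit <- irls_loglink(X, yf, "poisson", pw = pw)
    ll <- pois_loglik(yf, fit$mu, pw)
    theta <- NULL
  } else {
    theta <- if (!is.null(theta_fixed)) theta_fixed else {
      mu0 <- mean(yf)
      v0 <- stats::var(yf)
      if (is.na(v0) || v0 <= mu0) 100 else mu0^2 / (v0 - mu0)
    }
    fit <- irls_loglink(X, yf, "nb", theta = theta, pw = pw)
    ll <- nb_loglik(yf, fit$mu, theta, pw)
    if (is.null(theta_fixed)) {
      converged <- FALSE
      for (outer in seq_len(100L)) {
        opt <- stats::optimize(
          function(lt) nb_loglik(yf, fit$mu, exp(lt), pw),
          interval = c(log(1e-4), log(1e8)),
          maximum = TRUE, tol = 1e-10)
        theta <- exp(opt$maximum)
        fit <- irls_loglink(X, yf, "nb", theta = theta, start = fit$coef,
                            pw = pw)
        ll_new <- nb_loglik(yf, fit$mu, theta, pw)
        if (abs(ll_new - ll) < 1e-8 * (1 + abs(ll_new))) {
          ll <- ll_new; converged <- TRUE; break
        }
        ll <- ll_new
      }
      if (!converged)
        warning("negative binomial fit did not converge", call. = FALSE)
    }
  }

  info <- crossprod(X, fit$w * X)
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e)
    matrix(NA_real_, 2L, 2L))
  se <- sqrt(vcov[2L, 2L])
  beta <- unname(fit$coef[2L])
  structure(list(
    beta = beta,
    intercept = unname(fit$coef[1L]),
    se_beta = se,
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    theta = theta,
    n_obs_fitted = length(yf),
    converged = converged,
    family = family,
    loglik = ll,
    points = pts), class = "count_glm")
}

#' @export
print.count_glm <- function(x, ...) {
  cat(sprintf("Count GLM (%s, log link), %d observations%s\n",
              x$family, x$n_obs_fitted,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  beta = %.4g (se %.3g), Wald p = %.3g\n",
              x$beta, x$se_beta, x$wald_p))
  if (!is.null(x$theta)) cat(sprintf("  theta = %.4g\n", x$theta))
  invisible(x)
}

#' Overdispersion diagnostic for count data
#'
#' Fits a Poisson GLM on the raw (unbinned) data and reports the Pearson
#' chi-square statistic divided by residual degrees of freedom. Values well
#' above 1 indicate overdispersion; the pipeline selects the negative
#' binomial family when the statistic exceeds 1.5 and Poisson otherwise.
#'
#' @param x numeric covariate.
#' @param y non-negative integer counts.
#' @return list with `dispersion_stat` and `poisson_ok`.
#' @export
overdispersion_check <- function(x, y) {
  fit <- fit_count_glm(x, y, family = "poisson", binning = FALSE)
  mu <- exp(fit$intercept + fit$beta * x)
  df <- length(y) - 2L
  if (df < 1L) {
    warning("too few observations for a stable dispersion estimate",
            call. = FALSE)
    df <- 1L
  }
  stat <- sum((y - mu)^2 / mu) / df
  list(dispersion_stat = stat, poisson_ok = stat <= 1.5)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most 20 observations and
#' there are no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) return(1)   # fully tied: no evidence
  exact <- length(a) <= 20L && length(b) <= 20L &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}
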