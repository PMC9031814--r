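#' Negative-binomial log-link regression of per-gene counts on rates
#'
#' Fits `log E[K] = log(L) + intercept + slope * log(rate) + gamma * DX`
#' by maximum likelihood (negative binomial with shape theta estimated
#' jointly), the baseline from which species-specific deviations in
#' diversity are measured. Genes with a non-positive rate under the chosen
#' proxy are dropped (log undefined) with a message. When the table has no
#' X-linked genes the DX term is omitted and `x_effect` is 0.
#'
#' @param table Data frame joining the per-gene polymorphism table with the
#'   rate summaries: needs the response column, `L`, `is_X`, and the rate
#'   proxy column.
#' @param response `"K"` or `"singletons"` (or `"de_novo"`).
#' @param rate_proxy `"median_bl"`, `"truncated_mean_bl"` or `"mean_bl"`.
#' @return Object of class `nb_fit`: `intercept`, `slope`, `x_effect`,
#'   `theta`, `loglik`, `model_form = "loglink"`, `n`, plus coefficient
#'   standard errors `se` and the dropped-gene count.
#' @export
fit_nb_loglink <- function(table,
                           response = c("K", "singletons", "de_novo"),
                           rate_proxy = c("median_bl", "truncated_mean_bl", "mean_bl")) {
  response <- match.arg(response)
  rate_proxy <- match.arg(rate_proxy)
  y <- table[[response]]
  r <- table[[rate_proxy]]
  keep <- !is.na(r) & r > 0 & !is.na(y)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("fit_nb_loglink: dropped ", n_drop, " gene(s) with non-positive rate")
  d <- data.frame(y = y[keep], lograte = log(r[keep]),
                  L = table$L[keep], DX = as.numeric(table$is_X[keep]))
  if (nrow(d) < 10L) stop("fit_nb_loglink: fewer than 10 usable genes")
  if (all(d$y == 0)) stop("fit_nb_loglink: all-zero response")
  use_dx <- length(unique(d$DX)) > 1L
  fml <- if (use_dx) y ~ lograte + DX + offset(log(L)) else y ~ lograte + offset(log(L))
  fit <- withCallingHandlers(
    MASS::glm.nb(fml, data = d, control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      # near-Poisson data drives theta to very large values; the fit itself
      # is fine, so silence the iteration-limit chatter
      if (grepl("iteration limit|alternation limit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("fit_nb_loglink: IWLS did not converge (iterations = ", fit$iter, ")")
  cf <- coef(fit)
  structure(list(intercept = unname(cf["(Intercept)"]),
                 slope = unname(cf["lograte"]),
                 x_effect = if (use_dx) unname(cf["DX"]) else 0,
                 theta = fit$theta,
                 loglik = as.numeric(logLik(fit)),
                 model_form = "loglink",
                 n = nrow(d), n_dropped = n_drop,
                 se = sqrt(diag(stats::vcov(fit))),
                 response = response, rate_proxy = rate_proxy),
            class = "nb_fit")
}

#' Linear-rate negative-binomial model
#'
#' Alternative mean model `E[K] = L * (alpha + beta * rate) * exp(gamma *
#' DX)` fitted by direct maximization of the negative-binomial likelihood
#' (shape estimated jointly) with multi-start Nelder-Mead plus BFGS polish.
#' A positive intercept `alpha` indicates intraspecific survival of
#' mutations destined for loss on the macroevolutionary scale, so its sign
#' is reported prominently by `print()`. Zero-rate genes are retained (the
#' linear mean is defined there).
#'
#' @inheritParams fit_nb_loglink
#' @param n_starts Number of perturbed method-of-moments starts.
#' @param seed Seed for the start perturbations.
#' @return Object of class `nb_fit` with `model_form = "linear"`; fields as
#'   in [fit_nb_loglink()] plus `alpha_ci`, the 95% profile-likelihood
#'   interval for the intercept.
#' @export
fit_linear_rate_model <- function(table,
                                  response = c("K", "singletons", "de_novo"),
                                  rate_proxy = c("median_bl", "truncated_mean_bl", "mean_bl"),
                                  n_starts = 5L, seed = 1L) {
  response <- match.arg(response)
  rate_proxy <- match.arg(rate_proxy)
  y <- table[[response]]
  r <- table[[rate_proxy]]
  keep <- !is.na(r) & !is.na(y)
  d <- data.frame(y = y[keep], r = r[keep], L = table$L[keep],
                  DX = as.numeric(table$is_X[keep]))
  if (nrow(d) < 10L) stop("fit_linear_rate_model: fewer than 10 usable genes")
  use_dx <- length(unique(d$DX)) > 1L

  nll <- function(par) {
    mu <- d$L * (par[1L] + par[2L] * d$r) * exp(if (use_dx) par[3L] * d$DX else 0)
    if (any(mu <= 0) || !all(is.finite(mu))) return(1e10)
    theta <- exp(par[4L])
    -sum(dnbinom(d$y, mu = mu, size = theta, log = TRUE))
  }
  # method-of-moments start: linear fit of y/L on r, crude moment theta
  mm <- stats::lm.fit(cbind(1, d$r), d$y / d$L)$coefficients
  mu0 <- pmax(d$L * pmax(mm[1L] + mm[2L] * d$r, 1e-8), 1e-8)
  ex <- mean((d$y - mu0)^2 - mu0)
  theta0 <- if (ex > 0) max(mean(mu0^2) / ex, 0.1) else 100
  base <- c(max(mm[1L], 1e-6), mm[2L], 0, log(theta0))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1L) base else base * exp(rnorm(4L, 0, 0.3))
    o <- tryCatch({
      o1 <- optim(start, nll, method = "Nelder-Mead",
                  control = list(maxit = 2000))
      optim(o1$par, nll, method = "BFGS", control = list(maxit = 200))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("fit_linear_rate_model: all optimizer starts failed")
  par <- unname(best$par)
  fit <- structure(list(intercept = par[1L], slope = par[2L],
                        x_effect = if (use_dx) par[3L] else 0,
                        theta = exp(par[4L]),
                        loglik = -best$value,
                        model_form = "linear",
                        n = nrow(d), n_dropped = sum(!keep),
                        response = response, rate_proxy = rate_proxy),
                   class = "nb_fit")
  fit$alpha_ci <- .profile_alpha_ci(nll, par, best$value, use_dx)
  fit
}

# 95% profile-likelihood interval for the linear-model intercept: root of
# 2*(nll_profile(alpha) - nll_min) = qchisq(0.95, 1), other parameters
# re-optimized at each fixed alpha.
.profile_alpha_ci <- function(nll, mle, nll_min, use_dx, level = 0.95) {
  crit <- qchisq(level, 1L) / 2
  prof <- function(alpha) {
    f <- function(p) nll(c(alpha, p[1L], p[2L], p[3L]))
    o <- optim(mle[2:4], f, method = "Nelder-Mead", control = list(maxit = 1000))
    o$value - nll_min - crit
  }
  half <- abs(mle[1L]) * 0.5 + 0.05
  find <- function(dir) {
    lo <- mle[1L]
    hi <- mle[1L] + dir * half
    for (i in 1:12) {
      if (prof(hi) > 0) break
      hi <- mle[1L] + (hi - mle[1L]) * 2
    }
    if (prof(hi) < 0) return(NA_real_)
    uniroot(prof, sort(c(lo, hi)), tol = 1e-6)$root
  }
  c(lower = find(-1), upper = find(1))
}

#' Predicted mean and variance from a fitted diversity model
#'
#' The mean follows the fit's model form; the variance is the
#' negative-binomial identity `mu + mu^2 / theta` (approaching the Poisson
#' variance as theta grows).
#'
#' @param fit An `nb_fit`.
#' @param L Gene length(s).
#' @param rate Long-term rate(s); must be positive for the log-link form.
#' @param is_X Logical, X-linkage indicator(s).
#' @return `data.frame(mu, variance)`.
#' @export
nb_predict <- function(fit, L, rate, is_X = FALSE) {
  stopifnot(inherits(fit, "nb_fit"))
  dx <- as.numeric(is_X)
  mu <- if (fit$model_form == "loglink") {
    stopifnot(all(rate > 0))
    exp(log(L) + fit$intercept + fit$slope * log(rate) + fit$x_effect * dx)
  } else {
    L * (fit$intercept + fit$slope * rate) * exp(fit$x_effect * dx)
  }
  data.frame(mu = mu, variance = mu + mu^2 / fit$theta)
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit %s> %s ~ %s: intercept %.4g, slope %.4g, gamma %.4g, theta %.6g, n %d\n",
              x$model_form, x$response, x$rate_proxy,
              x$intercept, x$slope, x$x_effect, x$theta, x$n))
  if (x$model_form == "linear")
    cat(sprintf("  intercept sign: %s (positive indicates intraspecific survival of\n  mutations destined for loss); 95%% profile CI [%.4g, %.4g]\n",
                if (x$intercept > 0) "positive" else "non-positive",
                x$alpha_ci[1L], x$alpha_ci[2L]))
  invisible(x)
}
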