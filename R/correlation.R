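#' Bias-corrected correlation between rates and diversity
#'
#' Per-gene rate estimates and diversity values both carry sampling noise,
#' which attenuates their observed among-gene (Pearson) correlation. The
#' observed correlation is inflated back by
#' `corrected = raw * sqrt(f_B * f_K)` with
#' `f_B = 1 + mean(vs_b) / VarG(b_hat)` and likewise for K, where `VarG` is
#' the among-gene variance of the observed vector and `mean(vs_*)` the
#' average per-gene sampling variance. Mode `"exact"` instead uses the
#' latent variances `VarG(obs) - mean(vs)` in the denominators (classical
#' disattenuation); the default mode is the plug-in form with observed
#' variances.
#'
#' @param b_hat,k_hat Per-gene observed rate and diversity vectors.
#' @param vs_b,vs_k Per-gene sampling variances (scalars are recycled).
#' @param mode `"plugin"` (default) or `"exact"`.
#' @return `list(raw_r, corrected_r, inflation_B, inflation_K, n_genes,
#'   mode)` of class `corrected_cor`.
#' @export
corrected_correlation <- function(b_hat, k_hat, vs_b, vs_k,
                                  mode = c("plugin", "exact")) {
  mode <- match.arg(mode)
  n <- length(b_hat)
  stopifnot(length(k_hat) == n, n >= 3L)
  vs_b <- rep_len(vs_b, n)
  vs_k <- rep_len(vs_k, n)
  if (any(vs_b < 0) || any(vs_k < 0))
    stop("corrected_correlation: negative sampling variance")
  vb <- var(b_hat)
  vk <- var(k_hat)
  if (vb == 0 || vk == 0)
    stop("corrected_correlation: zero among-gene variance")
  raw <- cor(b_hat, k_hat)
  denom_b <- if (mode == "plugin") vb else vb - mean(vs_b)
  denom_k <- if (mode == "plugin") vk else vk - mean(vs_k)
  if (denom_b <= 0 || denom_k <= 0)
    stop("corrected_correlation: sampling variance exceeds observed variance (exact mode)")
  infl_b <- 1 + mean(vs_b) / denom_b
  infl_k <- 1 + mean(vs_k) / denom_k
  corrected <- raw * sqrt(infl_b * infl_k)
  if (abs(corrected) > 1) {
    warning("corrected_correlation: corrected value ", signif(corrected, 4),
            " clamped to [-1, 1]")
    corrected <- sign(corrected) * 1
  }
  structure(list(raw_r = raw, corrected_r = corrected,
                 inflation_B = infl_b, inflation_K = infl_k,
                 n_genes = n, mode = mode),
            class = "corrected_cor")
}

#' @export
print.corrected_cor <- function(x, ...) {
  cat(sprintf("<corrected_cor> raw r = %.4f, corrected r = %.4f (n = %d, %s)\n",
              x$raw_r, x$corrected_r, x$n_genes, x$mode))
  invisible(x)
}

#' Equilibrium coalescent variance of the number of segregating sites
#'
#' For a neutral equilibrium population sampled at `n` chromosomes,
#' `V(K) = E(K) + E(K)^2 * b_n / a_n^2` with
#' `a_n = sum_{i=1}^{n-1} 1/i` and `b_n = sum_{i=1}^{n-1} 1/i^2`. The first
#' term is mutational (Poisson) noise; the second is the stochasticity of
#' the genealogy.
#'
#' @param expected_K Expected number of segregating sites, `E(K) >= 0`.
#' @param n_chromosomes Sample size in chromosomes, `n >= 2`.
#' @return The variance of K.
#' @export
variance_of_K <- function(expected_K, n_chromosomes) {
  stopifnot(n_chromosomes >= 2L, all(expected_K >= 0))
  i <- seq_len(n_chromosomes - 1L)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  expected_K + expected_K^2 * bn / an^2
}

#' Non-equilibrium variance of the number of segregating sites
#'
#' When the population has its own history, the genealogy term is driven
#' by the coalescent waiting times Tc:
#' `V(K) = E(K) + E(K)^2 * V(Tc) / E(Tc)^2`. This matches the
#' negative-binomial variance identity `V = E + E^2 / theta` with
#' `theta = E(Tc)^2 / V(Tc)`, which motivates the negative-binomial
#' regression baseline.
#'
#' @param expected_K Expected number of segregating sites.
#' @param mean_Tc,var_Tc Mean and variance of the coalescent waiting times.
#' @return The variance of K.
#' @export
variance_of_K_nonequilibrium <- function(expected_K, mean_Tc, var_Tc) {
  stopifnot(mean_Tc > 0, var_Tc >= 0, all(expected_K >= 0))
  expected_K + expected_K^2 * var_Tc / mean_Tc^2
}
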