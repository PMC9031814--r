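#' Parameters of the background-selection diversity model
#'
#' Window diversity is modeled as an intrinsic level `pi0` reduced by the
#' joint hitchhiking effect of selection on the exon windows of the
#' chromosome. Each exon window contributes a factor
#' `1 - U * delta_x * sh / (2 * (sh + R)^2)` where `sh = exp(alpha_sel +
#' beta_sel * r)` is its selective effect as a function of the long-term
#' rate `r` of the gene spanning it, `R` the recombination fraction between
#' the exon window and the target window, `U` the deleterious mutation rate
#' per position per haploid genome, and `delta_x` the window width.
#'
#' @param pi0 Intrinsic diversity, > 0.
#' @param alpha_sel,beta_sel Selective-effect coefficients.
#' @param U Deleterious mutation rate per position per haploid genome
#'   (default 1e-8).
#' @param delta_x Window width in bp (default 1000).
#' @return List of class `bgs_params`.
#' @export
bgs_params <- function(pi0, alpha_sel, beta_sel, U = 1e-8, delta_x = 1000L) {
  stopifnot(pi0 > 0, U >= 0, delta_x >= 1L)
  structure(list(pi0 = pi0, alpha_sel = alpha_sel, beta_sel = beta_sel,
                 U = U, delta_x = delta_x),
            class = "bgs_params")
}

# per-exon-window reduction terms U*dx*sh / (2*(sh+R)^2)
.bgs_terms <- function(R, rates, params) {
  sh <- exp(params$alpha_sel + params$beta_sel * rates)
  params$U * params$delta_x * sh / (2 * (sh + R)^2)
}

#' Predicted window diversity under background selection
#'
#' @param target_cM Genetic-map position (cumulative cM) of the target
#'   window's midpoint.
#' @param exon_windows Data frame with columns `map_cM` (genetic position
#'   of each exon window) and `rate` (long-term rate of the gene spanning
#'   it).
#' @param params A [bgs_params()] object.
#' @param mode `"exp_approx"` (the exponential-sum approximation, also the
#'   form used for fitting) or `"product"` (the exact product over exon
#'   windows, with each bracket clamped to `[0, 1]`; a warning is issued if
#'   a per-window term exceeds 1).
#' @return Predicted nucleotide diversity of the target window.
#' @export
bgs_predict_pi <- function(target_cM, exon_windows, params,
                           mode = c("exp_approx", "product")) {
  mode <- match.arg(mode)
  R <- haldane_fraction(abs(exon_windows$map_cM - target_cM))
  term <- .bgs_terms(R, exon_windows$rate, params)
  if (mode == "product") {
    if (any(term > 1)) {
      warning("bgs_predict_pi: ", sum(term > 1), " per-window term(s) > 1 clamped")
      term <- pmin(term, 1)
    }
    params$pi0 * prod(1 - term)
  } else {
    params$pi0 * exp(-sum(term))
  }
}

# vectorized predictor over many target windows; Rmat is targets x exons
.bgs_predict_matrix <- function(Rmat, rates, params) {
  sh <- exp(params$alpha_sel + params$beta_sel * rates)
  shm <- matrix(sh, nrow = nrow(Rmat), ncol = length(sh), byrow = TRUE)
  S <- rowSums(shm / (shm + Rmat)^2)
  params$pi0 * exp(-params$U * params$delta_x / 2 * S)
}

#' Fit the background-selection model to window diversities
#'
#' Least-squares fit of the exponential form of the model to the observed
#' window diversities of one chromosome x feature stratum. Because `pi0`
#' enters the model linearly, it is profiled out analytically; the
#' remaining two-parameter search over `(alpha_sel, beta_sel)` uses
#' Nelder-Mead from a multi-start grid (`alpha = log(0.01)`, `beta` in
#' `{0, +-10, +-100}`), keeping the start with the lowest residual sum of
#' squares. A flat fit (all reduction factors within 1e-8 of 1, as when
#' the data carry no selection signal) is flagged in the result.
#'
#' @param windows Target windows: data frame with `pi` and `map_cM`.
#' @param exon_windows Exon windows: data frame with `map_cM` and `rate`.
#' @param U,delta_x Model constants, see [bgs_params()].
#' @return List of class `bgs_fit`: `pi0`, `alpha_sel`, `beta_sel`, `rss`,
#'   `n_windows`, `flat` (logical), `convergence`.
#' @export
fit_bgs <- function(windows, exon_windows, U = 1e-8, delta_x = 1000L) {
  y <- windows$pi
  stopifnot(length(y) >= 10L, nrow(exon_windows) >= 1L)
  Rmat <- haldane_fraction(abs(outer(windows$map_cM, exon_windows$map_cM, "-")))
  rates <- exon_windows$rate
  cU <- U * delta_x / 2
  gfun <- function(par) {   # reduction factor exp(-U dx/2 * S_i), pi0-free
    sh <- exp(par[1L] + par[2L] * rates)
    shm <- matrix(sh, nrow = nrow(Rmat), ncol = length(sh), byrow = TRUE)
    exp(-cU * rowSums(shm / (shm + Rmat)^2))
  }
  rss <- function(par) {
    g <- gfun(par)
    pi0 <- sum(y * g) / sum(g * g)   # profiled least-squares pi0
    sum((y - pi0 * g)^2)
  }
  best <- NULL
  for (b0 in c(0, 10, -10, 100, -100)) {
    o <- optim(c(log(0.01), b0), rss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$convergence != 0)
    warning("fit_bgs: optimizer reports convergence code ", best$convergence)
  g <- gfun(best$par)
  pi0 <- sum(y * g) / sum(g * g)
  flat <- max(1 - g) < 1e-8
  if (flat)
    warning("fit_bgs: fitted reduction is flat (no identifiable selection signal)")
  if (pi0 < 0)
    warning("fit_bgs: negative pi0 at the optimum (boundary fit)")
  structure(list(pi0 = pi0, alpha_sel = best$par[1L], beta_sel = best$par[2L],
                 rss = best$value, n_windows = length(y), flat = flat,
                 convergence = best$convergence, U = U, delta_x = delta_x),
            class = "bgs_fit")
}

#' @export
print.bgs_fit <- function(x, ...) {
  cat(sprintf("<bgs_fit> pi0 %.4g, alpha %.4g, beta %.4g, rss %.4g, n %d%s\n",
              x$pi0, x$alpha_sel, x$beta_sel, x$rss, x$n_windows,
              if (x$flat) " [flat]" else ""))
  invisible(x)
}

#' Fit the model for every chromosome x feature stratum
#'
#' @param windows Data frame of target windows with `chrom`, `feature`,
#'   `pi`, `map_cM`.
#' @param exon_windows Per-chromosome exon windows (`chrom`, `map_cM`,
#'   `rate`).
#' @param U,delta_x Model constants.
#' @param min_windows Strata with fewer target windows are skipped.
#' @return Data frame (`chrom`, `feature`, `pi0`, `alpha_sel`, `beta_sel`,
#'   `rss`, `n_windows`), one row per fitted stratum.
#' @export
fit_bgs_table <- function(windows, exon_windows, U = 1e-8, delta_x = 1000L,
                          min_windows = 50L) {
  strata <- unique(windows[!is.na(windows$feature), c("chrom", "feature")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    ch <- strata$chrom[i]; fe <- strata$feature[i]
    w <- windows[windows$chrom == ch & !is.na(windows$feature) &
                 windows$feature == fe, , drop = FALSE]
    if (nrow(w) < min_windows) return(NULL)
    ex <- exon_windows[exon_windows$chrom == ch, , drop = FALSE]
    f <- fit_bgs(w, ex, U = U, delta_x = delta_x)
    data.frame(chrom = ch, feature = fe, pi0 = f$pi0,
               alpha_sel = f$alpha_sel, beta_sel = f$beta_sel,
               rss = f$rss, n_windows = f$n_windows, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Two-way variance decomposition of fitted model parameters
#'
#' Decomposes the variance of one fitted parameter over the chromosome x
#' feature grid into among-chromosome, among-feature, and residual
#' (interaction) components by two-way ANOVA without replication, and
#' returns the two main-effect F-test p-values.
#'
#' @param fit_table Output of [fit_bgs_table()] covering a complete grid
#'   (every chromosome x feature cell present exactly once).
#' @param param `"pi0"`, `"alpha_sel"` or `"beta_sel"`.
#' @return `list(shares = c(chrom, feature, residual), p_chrom, p_feature,
#'   ss = named sums of squares)`; shares sum to 1.
#' @export
anova_decompose_params <- function(fit_table,
                                   param = c("pi0", "alpha_sel", "beta_sel")) {
  param <- match.arg(param)
  tab <- table(fit_table$chrom, fit_table$feature)
  if (any(tab != 1L))
    stop("anova_decompose_params: chromosome x feature grid is incomplete")
  d <- data.frame(value = fit_table[[param]],
                  chrom = factor(fit_table$chrom),
                  feature = factor(fit_table$feature))
  av <- withCallingHandlers(
    stats::anova(aov(value ~ chrom + feature, data = d)),
    warning = function(w) {
      # an exactly additive grid has zero residual SS; the F test is then
      # meaningless but the sums of squares remain valid
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- setNames(av[["Sum Sq"]], rownames(av))
  total <- sum(ss)
  shares <- if (total > 0) {
    c(chrom = unname(ss["chrom"]) / total,
      feature = unname(ss["feature"]) / total,
      residual = unname(ss["Residuals"]) / total)
  } else c(chrom = 0, feature = 0, residual = 0)
  list(shares = shares,
       p_chrom = av["chrom", "Pr(>F)"],
       p_feature = av["feature", "Pr(>F)"],
       ss = ss)
}
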