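#' Lower-tail mid-p deviation of an observed count from its NB baseline
#'
#' Given the predicted mean `mu` and shape `theta` of a gene's
#' segregating-site count, computes the lower-tailed mid-p value
#' `P(X <= K - 1) + 0.5 * P(X = K)` and its standard-normal quantile z.
#' The mid-p convention makes the null distribution of p average exactly
#' 0.5 despite the discreteness of counts, so the z-scores feeding the
#' gene-set test are centered under the null. Values are clamped to
#' `[1e-300, 1 - 1e-16]` before the quantile transform. Negative z marks a
#' diversity deficit (enhanced constraint), positive z an excess (reduced
#' constraint).
#'
#' @param observed_K Observed count(s).
#' @param mu Predicted mean(s), > 0.
#' @param theta NB shape, > 0.
#' @return `data.frame(observed_K, mu, theta, p_lower, z)`.
#' @export
gene_deviation_pvalue <- function(observed_K, mu, theta) {
  stopifnot(all(mu > 0), all(theta > 0))
  p <- pnbinom(observed_K - 1L, mu = mu, size = theta) +
    0.5 * dnbinom(observed_K, mu = mu, size = theta)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  data.frame(observed_K = observed_K, mu = mu, theta = theta,
             p_lower = p, z = qnorm(p))
}

#' Gene-set deviation t test
#'
#' Tests whether the normal-quantile-transformed deviations of a set's
#' member genes are centered away from zero:
#' `t = mean(z) / (sd(z) / sqrt(m))` against a t distribution with `m - 1`
#' degrees of freedom, two-sided. Positive t indicates reduced functional
#' constraint (diversifying selection), negative t enhanced constraint
#' (purifying selection). Degenerate sets with all z equal use `t = 0,
#' p = 1` when the common value is 0, otherwise an sd floor of 1e-12 with
#' a warning.
#'
#' @param z Vector of member-gene z values (length m >= 2).
#' @param set_id Optional identifier carried into the result.
#' @return `data.frame(set_id, m, t_value, p_value)`.
#' @export
gene_set_t_test <- function(z, set_id = NA_character_) {
  m <- length(z)
  if (m < 2L) stop("gene_set_t_test: a set needs at least two genes")
  s <- sd(z)
  if (s == 0) {
    if (all(z == 0)) {
      warning("gene_set_t_test: all z equal 0; t = 0, p = 1")
      return(data.frame(set_id = set_id, m = m, t_value = 0, p_value = 1))
    }
    warning("gene_set_t_test: zero spread among nonzero z; sd floored at 1e-12")
    s <- 1e-12
  }
  tv <- mean(z) / (s / sqrt(m))
  data.frame(set_id = set_id, m = m, t_value = tv,
             p_value = 2 * pt(abs(tv), df = m - 1L, lower.tail = FALSE))
}

#' Gene-set tests for a table of set memberships
#'
#' @param deviations Per-gene deviation table (needs `gene_id` and `z`).
#' @param sets Data frame with `set_id` and `gene_id` membership rows.
#' @param min_size Sets with fewer member genes present in `deviations`
#'   are skipped (default 2).
#' @param fdr False discovery rate for the significance flag
#'   (Benjamini-Hochberg; default 0.01).
#' @return `data.frame(set_id, m, t_value, p_value, significant)`.
#' @export
gene_set_tests <- function(deviations, sets, min_size = 2L, fdr = 0.01) {
  zmap <- setNames(deviations$z, deviations$gene_id)
  res <- lapply(split(sets$gene_id, sets$set_id), function(gids) {
    z <- zmap[gids[gids %in% names(zmap)]]
    if (length(z) < min_size) return(NULL)
    z
  })
  skipped <- sum(vapply(res, is.null, TRUE))
  if (skipped > 0L)
    message("gene_set_tests: skipped ", skipped, " set(s) below minimum size")
  res <- res[!vapply(res, is.null, TRUE)]
  out <- do.call(rbind, Map(function(z, id) gene_set_t_test(z, id),
                            res, names(res)))
  rownames(out) <- NULL
  out$significant <- bh_select(out$p_value, fdr)
  out
}

#' Benjamini-Hochberg selection mask
#'
#' Standard step-up procedure: with `p_(1) <= ... <= p_(m)`, find the
#' largest k with `p_(k) <= fdr * k / m`; everything at or below `p_(k)`
#' is selected.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param fdr Target false discovery rate in (0, 1).
#' @return Logical mask, same length/order as `p_values`.
#' @export
bh_select <- function(p_values, fdr) {
  stopifnot(fdr > 0, fdr < 1)
  p.adjust(p_values, method = "BH") <= fdr
}

#' PCA of per-species diversity plus long-term rate
#'
#' Column-standardized (by default) SVD-based principal component analysis
#' of a genes x columns matrix, typically the proportion of segregating
#' sites of each species together with the long-term rate. Component signs
#' follow the convention that each component's largest-magnitude loading
#' is positive.
#'
#' @param x Complete numeric matrix, >= 2 columns.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return `list(scores, loadings, explained)`; `explained` fractions sum
#'   to 1.
#' @export
pca_species <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2L, !anyNA(x))
  if (standardize) {
    sds <- apply(x, 2L, sd)
    if (any(sds == 0))
      stop("pca_species: constant column(s): ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Correspondence analysis of -log10(p) profiles
#'
#' Standard CA: the matrix is scaled to a correspondence matrix, row and
#' column masses are taken from its margins, and the standardized
#' residuals `(P - r c') / sqrt(r c')` are decomposed by SVD. Row and
#' column principal coordinates are the mass-rescaled singular vectors
#' scaled by the singular values; the total inertia equals the matrix's
#' chi-square statistic divided by its grand total. All-zero rows or
#' columns are dropped with a warning; zero p-values should be floored
#' (e.g. at 1e-300) before the -log10 transform upstream.
#'
#' @param x Non-negative items x species matrix (e.g. `-log10(p)`).
#' @param n_axes Number of axes to return (default
#'   `min(dim) - 1`).
#' @return `list(row_coords, col_coords, inertia, explained,
#'   total_inertia)`.
#' @export
ca_profiles <- function(x, n_axes = NULL) {
  x <- as.matrix(x)
  stopifnot(all(x >= 0))
  rz <- rowSums(x) == 0
  cz <- colSums(x) == 0
  if (any(rz) || any(cz)) {
    warning("ca_profiles: dropping ", sum(rz), " all-zero row(s) and ",
            sum(cz), " all-zero column(s)")
    x <- x[!rz, !cz, drop = FALSE]
  }
  total <- sum(x)
  if (total == 0) stop("ca_profiles: zero grand total")
  P <- x / total
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- (P - outer(r, c_)) / sqrt(outer(r, c_))
  sv <- svd(S)
  k <- min(if (is.null(n_axes)) min(dim(x)) - 1L else n_axes, length(sv$d))
  k <- max(k, 1L)
  d <- sv$d[seq_len(k)]
  # sign convention: the largest-magnitude column coordinate of each axis is
  # positive (columns are the species; stable under row permutation)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    vc <- v[, j] / sqrt(c_)
    s <- sign(vc[which.max(abs(vc))])
    if (s == 0) 1 else s
  }, 0)
  u <- sweep(u, 2L, flip, `*`)
  v <- sweep(v, 2L, flip, `*`)
  row_coords <- sweep(u / sqrt(r), 2L, d, `*`)
  col_coords <- sweep(v / sqrt(c_), 2L, d, `*`)
  dimnames(row_coords) <- list(rownames(x), paste0("Axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(x), paste0("Axis", seq_len(k)))
  list(row_coords = row_coords, col_coords = col_coords,
       inertia = d^2, explained = d^2 / sum(sv$d^2),
       total_inertia = sum(sv$d^2))
}
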