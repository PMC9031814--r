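#' Per-gene branch-length summaries
#'
#' Summarizes the branch multiset of a gene tree into the long-term-rate
#' proxies used throughout the package: the mean branch length, the median
#' (robust against the occasional extremely long terminal branch), and the
#' truncated mean obtained after removing the `truncate_k` longest branches
#' (the remedy for highly conserved genes whose median is 0). The sampling
#' variance of the mean is the Poisson approximation
#' `mean_bl / (M * alignment_length)`.
#'
#' @param tree A [gene_tree()].
#' @param truncate_k Number of longest branches removed for the truncated
#'   mean (default 5). If the tree has `M <= truncate_k` branches the
#'   truncated mean is `NA`, not 0.
#' @return One-row data frame: `gene_id, n_branches, total_bl, mean_bl,
#'   median_bl, truncated_mean_bl, sampling_var_mean`.
#' @export
summarize_branch_lengths <- function(tree, truncate_k = 5L) {
  stopifnot(inherits(tree, "gene_tree"), truncate_k >= 0L)
  b <- tree$branch_lengths
  m <- length(b)
  trunc_mean <- if (m > truncate_k) {
    # ties among the longest broken by stable input order; only the count
    # removed affects the mean
    mean(b[order(b)][seq_len(m - truncate_k)])
  } else NA_real_
  mb <- mean(b)
  data.frame(gene_id = tree$gene_id,
             n_branches = m,
             total_bl = sum(b),
             mean_bl = mb,
             median_bl = median(b),
             truncated_mean_bl = trunc_mean,
             sampling_var_mean = mean_branch_sampling_variance(mb, m, tree$alignment_length),
             stringsAsFactors = FALSE)
}

#' Summarize a collection of gene trees
#'
#' @param trees List of [gene_tree()] objects.
#' @param truncate_k Passed to [summarize_branch_lengths()].
#' @return Data frame with one row per gene.
#' @export
summarize_gene_trees <- function(trees, truncate_k = 5L) {
  out <- do.call(rbind, lapply(trees, summarize_branch_lengths, truncate_k = truncate_k))
  rownames(out) <- NULL
  out
}

#' Sampling variance of a mean branch length
#'
#' Treats the substitution count on each branch as Poisson with mean
#' `branch length x alignment length`, giving
#' `V[mean] = mean_bl / (M * alignment_length)`.
#'
#' @param mean_bl Mean branch length (substitutions/site).
#' @param n_branches Number of branches M.
#' @param alignment_length Alignment length in sites.
#' @return The approximate sampling variance of the mean branch length.
#' @export
mean_branch_sampling_variance <- function(mean_bl, n_branches, alignment_length) {
  stopifnot(n_branches >= 1L, alignment_length >= 1L)
  mean_bl / (n_branches * alignment_length)
}

#' Closed-form gene and branch effects for a branch-length matrix
#'
#' Decomposes scaled branch lengths under the multiplicative model
#' `E[b_ik * L_i] = c * L_i * alpha_i * beta_k`, where `alpha_i` is the
#' gene effect (relative variability, proportional to the gene's neutral
#' fraction), `beta_k` the branch effect (time x mutation rate along branch
#' k up to scale), under the identifiability constraints
#' `sum_i L_i * alpha_i = sum_k beta_k = 1`. For a complete matrix the
#' closed forms below are the maximum-likelihood estimators of the
#' constrained Poisson model; with missing cells the sums are restricted to
#' observed cells (mean-style robustness to missing taxa). The interaction
#' ratio `p_ik = b_ik * L_i / (c * L_i * alpha_i * beta_k)` captures
#' branch-specific shifts of a gene's constraint.
#'
#' @param b_mat Numeric genes x branches matrix of branch lengths
#'   (substitutions/site); `NA` marks a missing cell. Row names are gene
#'   ids, column names branch ids.
#' @param lengths Named numeric vector of gene alignment lengths `L_i`,
#'   names matching `rownames(b_mat)`.
#' @param require_complete If `TRUE`, error on any missing cell.
#' @return An object of class `effects_fit`: list with `scale_c`,
#'   `gene_effects`, `branch_effects`, `interactions` (matrix, `NA` at
#'   missing cells).
#' @export
estimate_gene_branch_effects <- function(b_mat, lengths, require_complete = FALSE) {
  stopifnot(is.matrix(b_mat), nrow(b_mat) >= 1L, ncol(b_mat) >= 1L)
  if (is.null(rownames(b_mat)))
    rownames(b_mat) <- paste0("G", seq_len(nrow(b_mat)))
  if (is.null(colnames(b_mat)))
    colnames(b_mat) <- paste0("B", seq_len(ncol(b_mat)))
  L <- lengths[rownames(b_mat)]
  if (any(is.na(L)) || any(L < 1))
    stop("estimate_gene_branch_effects: missing or invalid gene length")
  if (require_complete && anyNA(b_mat))
    stop("estimate_gene_branch_effects: matrix has missing cells")
  if (any(b_mat < 0, na.rm = TRUE))
    stop("estimate_gene_branch_effects: negative branch length")
  scaled <- b_mat * L                       # N_ik = b_ik * L_i, row-recycled
  denom <- sum(scaled, na.rm = TRUE)        # = c-hat
  if (denom == 0)
    stop("estimate_gene_branch_effects: all branch lengths are zero")
  alpha <- rowSums(b_mat, na.rm = TRUE) / denom
  beta <- colSums(scaled, na.rm = TRUE) / denom
  if (any(alpha == 0))
    warning("estimate_gene_branch_effects: all-zero gene row(s), effect 0: ",
            paste(head(rownames(b_mat)[alpha == 0], 5L), collapse = ", "))
  if (any(beta == 0))
    warning("estimate_gene_branch_effects: all-zero branch column(s), effect 0: ",
            paste(head(colnames(b_mat)[beta == 0], 5L), collapse = ", "))
  pred <- denom * outer(L * alpha, beta)
  inter <- scaled / pred
  inter[is.na(b_mat)] <- NA_real_
  structure(list(scale_c = denom,
                 gene_effects = setNames(as.numeric(alpha), rownames(b_mat)),
                 branch_effects = setNames(as.numeric(beta), colnames(b_mat)),
                 interactions = inter,
                 lengths = setNames(as.numeric(L), rownames(b_mat))),
            class = "effects_fit")
}

#' @export
print.effects_fit <- function(x, ...) {
  cat(sprintf("<effects_fit> %d genes x %d branches, c = %.6g\n",
              length(x$gene_effects), length(x$branch_effects), x$scale_c))
  invisible(x)
}

#' Poisson resampling of a gene tree's branch lengths
#'
#' Evaluates the stochastic variance of branch-length summaries due to the
#' randomness of substitutions: per replicate and branch, a substitution
#' count is drawn from Poisson with mean `branch length x alignment length`
#' and divided back by the alignment length; the mean and median of the
#' resampled branch lengths are returned per replicate.
#'
#' @param tree A [gene_tree()].
#' @param reps Number of replicates.
#' @param seed Integer seed; the same seed gives identical output.
#' @return `data.frame(mean_bl, median_bl)` with `reps` rows.
#' @export
poisson_branch_resample <- function(tree, reps, seed = 1L) {
  stopifnot(inherits(tree, "gene_tree"), reps >= 1L)
  b <- tree$branch_lengths
  l <- tree$alignment_length
  set.seed(seed)
  counts <- matrix(rpois(reps * length(b), lambda = rep(b * l, each = reps)),
                   nrow = reps)
  data.frame(mean_bl = rowMeans(counts) / l,
             median_bl = apply(counts, 1L, median) / l)
}
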