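#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage end to end on generated data: simulate gene
#' trees, summarize long-term rates and fit gene/branch effects, simulate
#' per-species polymorphism tables, compute raw and bias-corrected
#' rate-diversity correlations, fit the negative-binomial diversity
#' baseline per species, fit the background-selection window model on two
#' synthetic chromosomes and decompose its parameters, run the gene-set
#' deviation tests, and ordinate species by PCA (q plus rate) and
#' correspondence analysis of the -log10 p profiles. Stage outputs are
#' written as TSVs under `out_dir` together with a `manifest.json`
#' recording the configuration and seed; outputs are deterministic given
#' the seed, so a rerun reproduces them byte for byte.
#'
#' @param out_dir Output directory (created).
#' @param config A [generator_config()]; its `n_genes` sets the scale.
#' @param n_species Number of simulated species (default 5).
#' @param fdr FDR for the gene-set significance flag (default 0.01).
#' @param rate_proxy Rate proxy for regressions (default `"median_bl"`).
#' @param run_bgs Set `FALSE` to skip the (relatively slow)
#'   background-selection stage.
#' @return Invisibly, a list with each stage's in-memory result.
#' @export
run_pipeline <- function(out_dir, config = generator_config(n_genes = 1467L),
                         n_species = 5L, fdr = 0.01,
                         rate_proxy = "median_bl", run_bgs = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  # simulate + tree-stats
  gen <- gen_gene_trees(config)
  rates <- summarize_gene_trees(gen$trees)
  write_tsv(rates, file.path(out_dir, "rate_summaries.tsv"))
  eff <- estimate_gene_branch_effects(gen$b_matrix, gen$lengths)
  write_tsv(data.frame(gene_id = names(eff$gene_effects),
                       gene_effect = eff$gene_effects),
            file.path(out_dir, "gene_effects.tsv"))
  write_tsv(data.frame(branch_id = names(eff$branch_effects),
                       branch_effect = eff$branch_effects),
            file.path(out_dir, "branch_effects.tsv"))
  res$rates <- rates
  res$effects <- eff

  rate_tab <- data.frame(gene_id = rates$gene_id,
                         rate = rates[[rate_proxy]],
                         L = as.integer(gen$lengths[rates$gene_id]))
  rate_tab <- rate_tab[rate_tab$rate > 0, ]

  # per-species polymorphism, correlation, NB baseline, deviations
  species <- paste0("sp", seq_len(n_species))
  poly <- list(); fits <- list(); dev <- list(); corr_rows <- list()
  for (s in seq_len(n_species)) {
    tab <- gen_gene_polymorphism(config, rate_tab, seed = config$seed + s)
    tab[[rate_proxy]] <- rate_tab$rate
    poly[[species[s]]] <- tab
    fit <- fit_nb_loglink(tab, response = "K", rate_proxy = rate_proxy)
    fits[[species[s]]] <- fit
    pred <- nb_predict(fit, tab$L, tab[[rate_proxy]], tab$is_X)
    dv <- gene_deviation_pvalue(tab$K, pred$mu, fit$theta)
    dv$gene_id <- tab$gene_id
    dev[[species[s]]] <- dv
    vs_b <- rates$sampling_var_mean[match(tab$gene_id, rates$gene_id)]
    vs_k <- pred$variance / tab$L^2
    cc <- corrected_correlation(tab[[rate_proxy]], tab$q, vs_b, vs_k)
    corr_rows[[s]] <- data.frame(species = species[s], raw_r = cc$raw_r,
                                 corrected_r = cc$corrected_r,
                                 inflation_B = cc$inflation_B,
                                 inflation_K = cc$inflation_K,
                                 n = cc$n_genes)
  }
  corr_tab <- do.call(rbind, corr_rows)
  write_tsv(corr_tab, file.path(out_dir, "correlations.tsv"))
  fit_tab <- do.call(rbind, lapply(species, function(sp) {
    f <- fits[[sp]]
    data.frame(species = sp, intercept = f$intercept, slope = f$slope,
               x_effect = f$x_effect, theta = f$theta, loglik = f$loglik,
               n = f$n)
  }))
  write_tsv(fit_tab, file.path(out_dir, "nb_fits.tsv"))
  res$polymorphism <- poly
  res$correlations <- corr_tab
  res$nb_fits <- fits

  # background selection on two chromosomes + decomposition
  if (run_bgs) {
    bcfg <- config
    bcfg$bgs$chrom_length <- min(bcfg$bgs$chrom_length, 2e6)
    bcfg$bgs$n_genes <- min(bcfg$bgs$n_genes, 80L)
    chroms <- lapply(1:2, function(i)
      gen_bgs_windows(bcfg, chrom = paste0("chr", i), seed = config$seed + 100L + i))
    windows <- do.call(rbind, lapply(chroms, `[[`, "windows"))
    exons <- do.call(rbind, lapply(chroms, `[[`, "exon_windows"))
    bgs_tab <- fit_bgs_table(windows, exons,
                             U = bcfg$bgs$U, delta_x = bcfg$bgs$delta_x)
    write_tsv(bgs_tab, file.path(out_dir, "bgs_fits.tsv"))
    decomp <- lapply(c("pi0", "alpha_sel", "beta_sel"), function(p)
      anova_decompose_params(bgs_tab, p))
    names(decomp) <- c("pi0", "alpha_sel", "beta_sel")
    write_tsv(do.call(rbind, lapply(names(decomp), function(p)
      data.frame(param = p, t(decomp[[p]]$shares),
                 p_chrom = decomp[[p]]$p_chrom,
                 p_feature = decomp[[p]]$p_feature))),
      file.path(out_dir, "bgs_decomposition.tsv"))
    res$bgs <- list(fits = bgs_tab, decomposition = decomp)
  }

  # gene-set deviation tests per species
  set_res <- list()
  for (s in seq_len(n_species)) {
    sp <- species[s]
    sets <- gen_gene_sets(config, poly[[sp]], seed = config$seed + 200L + s)
    th <- fits[[sp]]$theta
    dv <- gene_deviation_pvalue(sets$members$K, sets$members$mu, th)
    dv$set_id <- sets$members$set_id
    tests <- do.call(rbind, lapply(split(dv$z, dv$set_id), function(z)
      if (length(z) >= 2L) gene_set_t_test(z) else NULL))
    tests$set_id <- rownames(tests)
    tests$significant <- bh_select(tests$p_value, fdr)
    rownames(tests) <- NULL
    set_res[[sp]] <- tests
  }
  all_sets <- do.call(rbind, lapply(species, function(sp)
    cbind(species = sp, set_res[[sp]])))
  write_tsv(all_sets, file.path(out_dir, "gene_set_results.tsv"))
  res$gene_sets <- set_res

  # ordination: PCA of q + rate; CA of -log10 p over sets x species
  qmat <- do.call(cbind, lapply(species, function(sp)
    poly[[sp]]$q[match(rate_tab$gene_id, poly[[sp]]$gene_id)]))
  colnames(qmat) <- paste0("q_", species)
  pca <- pca_species(cbind(qmat, rate = rate_tab$rate))
  write_tsv(data.frame(component = seq_along(pca$explained),
                       explained = pca$explained),
            file.path(out_dir, "pca_explained.tsv"))
  pmat <- do.call(cbind, lapply(species, function(sp)
    -log10(pmax(set_res[[sp]]$p_value, 1e-300))))
  colnames(pmat) <- species
  rownames(pmat) <- set_res[[1L]]$set_id
  ca <- ca_profiles(pmat)
  write_tsv(data.frame(species = rownames(ca$col_coords), ca$col_coords),
            file.path(out_dir, "ca_species_coords.tsv"))
  res$pca <- pca
  res$ca <- ca

  manifest <- list(package = "divrate",
                   version = as.character(utils::packageVersion("divrate")),
                   seed = config$seed,
                   n_genes = config$n_genes,
                   n_species = n_species,
                   fdr = fdr,
                   rate_proxy = rate_proxy,
                   run_bgs = run_bgs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
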