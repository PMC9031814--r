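#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters of every generator with a single seed that fully
#' determines all output. The defaults emulate the mammalian-scale study
#' conditions: ~14,671 gene trees over a shared topology with 50 branches,
#' gene lengths around 1.5 kb of coding sequence, mean branch lengths
#' around 0.03 substitutions/site, a count model whose slope on log rate
#' is 0.413 with moderate overdispersion, and a background-selection
#' chromosome of 5 Mb with a 1.2 cM/Mb linear map. Test suites typically
#' pass a smaller `n_genes`.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param n_branches Number of branches M of the shared tree topology
#'   (must be even; the topology has `M/2 + 1` tips).
#' @param gene_sdlog,branch_sdlog Log-sd of the lognormal gene/branch
#'   effect draws.
#' @param interaction_sdlog Log-sd of the lognormal gene x branch
#'   interaction perturbation (0 = multiplicative model holds exactly).
#' @param mean_branch_length Target average branch length
#'   (substitutions/site); fixes the overall scale constant.
#' @param length_meanlog,length_sdlog Lognormal parameters of gene length.
#' @param nb_intercept,nb_slope,nb_gamma,theta Count-model parameters:
#'   `K ~ NB(mean = L * exp(nb_intercept + nb_slope * log(rate) +
#'   nb_gamma * DX), shape = theta)`.
#' @param prop_X Fraction of genes placed on the X chromosome.
#' @param singleton_frac Binomial fraction of segregating sites that are
#'   singletons.
#' @param denovo_rate Per-site rate of the de-novo Poisson counts
#'   (independent of gene rate by construction).
#' @param bgs Named list of background-selection generator settings:
#'   `pi0, alpha_sel, beta_sel, U, delta_x, chrom_length, n_genes,
#'   exon_windows_per_gene, cM_per_Mb, noise_sd, rate_meanlog, rate_sdlog`.
#' @param set_sizes,set_deltas Parallel vectors defining gene sets: one
#'   set per element, of the given size, with log-scale constraint shift
#'   delta (0 = null set).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 14671L,
                             n_branches = 50L,
                             gene_sdlog = 0.6,
                             branch_sdlog = 0.5,
                             interaction_sdlog = 0,
                             mean_branch_length = 0.03,
                             length_meanlog = log(1500),
                             length_sdlog = 0.5,
                             nb_intercept = log(0.113),
                             nb_slope = 0.413,
                             nb_gamma = -0.29,
                             theta = 10,
                             prop_X = 0.03,
                             singleton_frac = 0.4,
                             denovo_rate = 1e-3,
                             bgs = list(),
                             set_sizes = rep(10L, 100L),
                             set_deltas = rep(0, 100L)) {
  stopifnot(n_genes >= 1L, n_branches %% 2L == 0L, n_branches >= 2L,
            mean_branch_length > 0, theta > 0,
            length(set_sizes) == length(set_deltas))
  bgs_default <- list(pi0 = 1e-3, alpha_sel = -3, beta_sel = 50,
                      U = 1e-8, delta_x = 1000L,
                      chrom_length = 5e6, n_genes = 150L,
                      exon_windows_per_gene = 4L, cM_per_Mb = 1.2,
                      noise_sd = 1e-4,
                      rate_meanlog = log(0.03), rate_sdlog = 0.5)
  bgs <- utils::modifyList(bgs_default, bgs)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate gene trees under the multiplicative gene x branch model
#'
#' Draws relative gene effects and branch effects from lognormal
#' distributions, normalizes them to the identifiability constraints
#' (`sum L_i alpha_i = sum beta_k = 1`), fixes the scale constant so the
#' average expected branch length matches `mean_branch_length`, and draws
#' per-cell substitution counts `N_ik ~ Poisson(c L_i alpha_i beta_k
#' p_ik)`; branch lengths are `N_ik / L_i`. All genes share one reference
#' topology so branches are identified across genes by their edge index.
#'
#' @param config A [generator_config()].
#' @return List: `trees` (list of [gene_tree()]), `b_matrix` (genes x
#'   branches), `lengths` (named), `topology` (an `ape` phylo), and
#'   `truth` (`alpha`, `beta`, `scale_c`, `interaction`).
#' @export
gen_gene_trees <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$n_branches
  L <- pmax(100L, round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  g <- rlnorm(n, 0, config$gene_sdlog)
  alpha <- g / sum(L * g)
  h <- rlnorm(m, 0, config$branch_sdlog)
  beta <- h / sum(h)
  cc <- config$mean_branch_length / mean(outer(alpha, beta))
  inter <- if (config$interaction_sdlog > 0) {
    s <- config$interaction_sdlog
    matrix(rlnorm(n * m, -s^2 / 2, s), n, m)
  } else matrix(1, n, m)
  lambda <- cc * L * outer(alpha, beta) * inter
  counts <- matrix(rpois(n * m, lambda), n, m)
  b <- counts / L
  gids <- sprintf("G%05d", seq_len(n))
  dimnames(b) <- list(gids, paste0("B", seq_len(m)))
  names(L) <- names(alpha) <- gids
  names(beta) <- colnames(b)
  topo <- ape::rtree(m / 2L + 1L)
  trees <- lapply(seq_len(n), function(i)
    gene_tree(gids[i], b[i, ], topo$tip.label, L[i]))
  names(trees) <- gids
  list(trees = trees, b_matrix = b, lengths = L, topology = topo,
       truth = list(alpha = alpha, beta = beta, scale_c = cc,
                    interaction = inter))
}

#' Write generated gene trees as newick files plus a length sidecar
#'
#' @param gen Output of [gen_gene_trees()].
#' @param dir Output directory (created if absent).
#' @return Character vector of newick paths, invisibly.
#' @export
write_gene_trees <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- gen$topology
  paths <- vapply(names(gen$trees), function(gid) {
    phy <- topo
    phy$edge.length <- gen$b_matrix[gid, ]
    p <- file.path(dir, paste0(gid, ".nwk"))
    ape::write.tree(phy, file = p, digits = 17)
    p
  }, "")
  write_tsv(data.frame(gene_id = names(gen$lengths),
                       alignment_length = as.integer(gen$lengths)),
            file.path(dir, "alignment_lengths.tsv"))
  invisible(paths)
}

#' Generate a per-gene polymorphism table linked to long-term rates
#'
#' Segregating-site counts follow the negative-binomial regression model
#' `K ~ NB(mean = L * exp(a + b log r + gamma DX), shape = theta)`;
#' singleton counts are binomial thinning of K; de-novo counts are
#' Poisson in gene length and independent of the rate, so a fitted
#' de-novo slope is null by construction.
#'
#' @param config A [generator_config()].
#' @param rates Data frame with `gene_id`, `rate` and `L` (e.g. joined
#'   from [gen_gene_trees()] truth or [summarize_gene_trees()] output).
#' @param seed Optional seed overriding `config$seed` (useful for several
#'   species sharing one rate table).
#' @return `data.frame(gene_id, K, singletons, de_novo, L, q, chrom,
#'   is_X, mu)` where `mu` is the generative mean (truth column).
#' @export
gen_gene_polymorphism <- function(config, rates, seed = config$seed) {
  stopifnot(all(rates$rate > 0))
  set.seed(seed)
  n <- nrow(rates)
  is_x <- runif(n) < config$prop_X
  mu <- rates$L * exp(config$nb_intercept +
                      config$nb_slope * log(rates$rate) +
                      config$nb_gamma * is_x)
  K <- rnbinom(n, mu = mu, size = config$theta)
  singles <- rbinom(n, K, config$singleton_frac)
  dn <- rpois(n, rates$L * config$denovo_rate)
  data.frame(gene_id = rates$gene_id, K = K, singletons = singles,
             de_novo = dn, L = rates$L, q = K / rates$L,
             chrom = ifelse(is_x, "chrX", "chr1"), is_X = is_x,
             mu = mu, stringsAsFactors = FALSE)
}

#' Generate a background-selection chromosome of diversity windows
#'
#' Lays genes with consecutive exon windows along a synthetic chromosome,
#' assigns each gene a lognormal long-term rate, builds a linear genetic
#' map, computes the model-predicted diversity of every window, and adds
#' truncated Gaussian noise. Exon windows are labeled `exon`, all other
#' windows `intron` (the chromosome is gene-dense, so nothing is farther
#' than the intergenic rule).
#'
#' @param config A [generator_config()]; settings under `config$bgs`.
#' @param chrom Chromosome name for the output tables.
#' @param seed Optional seed override.
#' @return List: `windows` (`chrom, start, pi, map_cM, feature`),
#'   `exon_windows` (`chrom, start, map_cM, rate`), `map`,
#'   `truth` (the generating [bgs_params()] and the noiseless `pi_true`).
#' @export
gen_bgs_windows <- function(config, chrom = "chr1", seed = config$seed) {
  bg <- config$bgs
  set.seed(seed)
  width <- bg$delta_x
  n_w <- floor(bg$chrom_length / width)
  starts <- (seq_len(n_w) - 1L) * width
  mids <- starts + width / 2
  epg <- bg$exon_windows_per_gene
  gene_start_idx <- sort(sample.int(n_w - epg, bg$n_genes, replace = FALSE))
  rate_gene <- rlnorm(bg$n_genes, bg$rate_meanlog, bg$rate_sdlog)
  # a window spanned by two genes takes the max rate of its genes
  rate_win <- tapply(
    rate_gene[rep(seq_len(bg$n_genes), each = epg)],
    as.vector(t(outer(gene_start_idx, seq_len(epg) - 1L, `+`))),
    max)
  exon_idx <- as.integer(names(rate_win))
  map <- data.frame(position = c(0, bg$chrom_length),
                    cM = c(0, bg$chrom_length * bg$cM_per_Mb / 1e6))
  cM <- interpolate_cM(map, mids)
  params <- bgs_params(bg$pi0, bg$alpha_sel, bg$beta_sel,
                       U = bg$U, delta_x = width)
  Rmat <- haldane_fraction(abs(outer(cM, cM[exon_idx], "-")))
  pi_true <- .bgs_predict_matrix(Rmat, as.numeric(rate_win), params)
  pi_obs <- pmax(pi_true + rnorm(n_w, 0, bg$noise_sd), 0)
  feature <- rep("intron", n_w)
  feature[exon_idx] <- "exon"
  list(windows = data.frame(chrom = chrom, start = starts, pi = pi_obs,
                            map_cM = cM, feature = feature,
                            stringsAsFactors = FALSE),
       exon_windows = data.frame(chrom = chrom, start = starts[exon_idx],
                                 map_cM = cM[exon_idx],
                                 rate = as.numeric(rate_win),
                                 stringsAsFactors = FALSE),
       map = map,
       truth = list(params = params, pi_true = pi_true))
}

#' Generate gene sets with shifted functional constraints
#'
#' Null sets (`delta = 0`) sample member genes as-is; shifted sets
#' resample each member's segregating-site count from a negative binomial
#' whose mean is multiplied by `exp(delta)`, emulating a lineage-specific
#' relaxation (`delta > 0`) or enhancement (`delta < 0`) of constraint.
#'
#' @param config A [generator_config()] (uses `set_sizes`, `set_deltas`,
#'   `theta`).
#' @param genes Polymorphism table carrying the generative mean `mu`
#'   (from [gen_gene_polymorphism()]).
#' @param seed Optional seed override.
#' @return List: `members` long table (`set_id, gene_id, K, mu, L`),
#'   `truth` (`set_id, delta, size`).
#' @export
gen_gene_sets <- function(config, genes, seed = config$seed) {
  stopifnot(all(config$set_sizes >= 2L), "mu" %in% names(genes))
  set.seed(seed)
  n_sets <- length(config$set_sizes)
  ids <- sprintf("S%04d", seq_len(n_sets))
  members <- lapply(seq_len(n_sets), function(s) {
    size <- config$set_sizes[s]
    delta <- config$set_deltas[s]
    pick <- genes[sample.int(nrow(genes), size), , drop = FALSE]
    K <- if (delta != 0) {
      rnbinom(size, mu = pick$mu * exp(delta), size = config$theta)
    } else pick$K
    data.frame(set_id = ids[s], gene_id = pick$gene_id, K = K,
               mu = pick$mu, L = pick$L, stringsAsFactors = FALSE)
  })
  list(members = do.call(rbind, members),
       truth = data.frame(set_id = ids, delta = config$set_deltas,
                          size = config$set_sizes, stringsAsFactors = FALSE))
}

#' Write a toy VCF with per-site AC/AN
#'
#' Emits a minimal VCF v4.2 whose INFO column carries AC and AN, for
#' exercising the VCF reading path.
#'
#' @param variants Data frame with `chrom, pos, alt_allele_count,
#'   total_chromosomes` (and optionally `ref`, `alt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total alleles\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  ref <- if ("ref" %in% names(variants)) variants$ref else rep("A", nrow(variants))
  alt <- if ("alt" %in% names(variants)) variants$alt else rep("G", nrow(variants))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
                     variants$chrom, variants$pos, ref, alt,
                     variants$alt_allele_count, variants$total_chromosomes),
             con)
  invisible(path)
}
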