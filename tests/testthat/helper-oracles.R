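# Independent oracles used across tests. These deliberately avoid the
# package's own closed forms: numerical likelihood maximization, brute-force
# scans, and direct enumeration.

# Constrained Poisson-likelihood maximization for the gene x branch
# multiplicative model, parameterized through softmax weights so the
# identifiability constraints hold exactly at every iterate.
fit_effects_numeric <- function(b_mat, L, restarts = 3L) {
  n <- nrow(b_mat)
  m <- ncol(b_mat)
  N <- b_mat * L
  nll <- function(par) {
    ea <- exp(par[1:n])
    eb <- exp(par[(n + 1):(n + m)])
    alpha <- ea / sum(L * ea)
    beta <- eb / sum(eb)
    cc <- exp(par[n + m + 1])
    lam <- cc * L * outer(alpha, beta)
    -sum(N * log(lam) - lam)
  }
  best <- NULL
  for (s in seq_len(restarts)) {
    start <- if (s == 1L) c(rep(0, n + m), log(sum(N))) else rnorm(n + m + 1, 0, 0.5)
    o <- optim(start, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
    o <- optim(o$par, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ea <- exp(best$par[1:n])
  eb <- exp(best$par[(n + 1):(n + m)])
  list(alpha = ea / sum(L * ea), beta = eb / sum(eb),
       scale_c = exp(best$par[n + m + 1]), nll = best$value)
}

# brute-force per-base recount of segregating sites inside gene intervals
brute_force_gene_K <- function(variants, gene_intervals) {
  seg_pos <- unique(variants$pos[variants$alt_allele_count > 0 &
    variants$alt_allele_count < variants$total_chromosomes])
  count <- 0L
  for (p in seg_pos) {
    inside <- any(variants$chrom[variants$pos == p][1] == gene_intervals$chrom &
                  p > gene_intervals$start & p <= gene_intervals$end)
    if (inside) count <- count + 1L
  }
  count
}

# mean pairwise difference per window by explicit haplotype-pair enumeration
pairwise_pi_oracle <- function(haplotypes, width) {
  n <- nrow(haplotypes)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(haplotypes[i, ] != haplotypes[j, ])
    }
  }
  # per-pair mean difference divided by window width; algebraically equal
  # to the per-site unbiased heterozygosity sum 2p(1-p)n/(n-1) / width
  tot / choose(n, 2) / width
}

# toy variant table builder
toy_variants <- function(pos, ac, an, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             alt_allele_count = as.integer(ac),
             total_chromosomes = as.integer(an),
             is_de_novo = FALSE, stringsAsFactors = FALSE)
}

# small gene tree fixture
toy_tree <- function(b, L = 100L, id = "G1") {
  gene_tree(id, b, paste0("t", seq_len(max(2L, length(b)))), L)
}
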