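test_that("per-gene tabulation counts segregating sites, singletons and q", {
  genes <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                      feature = "exon", gene_id = "G1")
  v <- toy_variants(pos = c(10, 20, 30, 40, 50),
                    ac = c(1, 5, 9, 0, 10), an = 10)
  tab <- tabulate_gene_variation(v, genes)
  # AC=0 and AC=AN are not segregating; AC=1 and AC=AN-1 are singleton sites
  expect_equal(tab$K, 3L)
  expect_equal(tab$singletons, 2L)
  expect_equal(tab$L, 1000L)
  expect_equal(tab$q, 3 / 1000)
  expect_false(tab$is_X)
})

test_that("gene length is the union of intervals and de novo counts attach", {
  genes <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(100L, 120L),
                      feature = "exon", gene_id = "G1")
  dn <- toy_variants(pos = c(10, 80, 500), ac = 1, an = 2)
  tab <- tabulate_gene_variation(toy_variants(60, 1, 10), genes, denovo = dn)
  expect_equal(tab$L, 120L)   # [0,100) U [50,120) = [0,120)
  expect_equal(tab$de_novo, 2L)
})

test_that("tabulated K matches a brute-force per-site recount on random data", {
  set.seed(21)
  genes <- data.frame(chrom = "chr1", start = c(100L, 400L), end = c(250L, 600L),
                      feature = "exon", gene_id = "G1")
  v <- toy_variants(pos = sample(1:700, 200),
                    ac = sample(0:20, 200, replace = TRUE), an = 20)
  tab <- tabulate_gene_variation(v, genes)
  expect_equal(tab$K, brute_force_gene_K(v, genes))
})

test_that("q is invariant to variant record order", {
  genes <- data.frame(chrom = "chr1", start = 0L, end = 500L,
                      feature = "exon", gene_id = "G1")
  set.seed(3)
  v <- toy_variants(pos = 1:50, ac = sample(0:8, 50, TRUE), an = 8)
  t1 <- tabulate_gene_variation(v, genes)
  t2 <- tabulate_gene_variation(v[sample(nrow(v)), ], genes)
  expect_equal(t1$q, t2$q)
})

test_that("window pi matches the unbiased single-site form and zero default", {
  v <- toy_variants(pos = 500, ac = 1, an = 2)
  w <- window_pi(v, chrom_length = 3000L)
  expect_equal(w$pi[1], (2 * 0.25 * 2) / 1000)   # = 0.001
  expect_equal(w$pi[2:3], c(0, 0))
  expect_equal(nrow(w), 3L)
})

test_that("window pi equals explicit haplotype-pair enumeration", {
  set.seed(14)
  n <- 6L
  hap <- matrix(0L, n, 10L)
  for (j in 1:10) hap[sample(n, sample(0:n, 1)), j] <- 1L
  ac <- colSums(hap)
  v <- toy_variants(pos = seq(10, 100, by = 10), ac = ac, an = n)
  w <- window_pi(v[v$alt_allele_count > 0 & v$alt_allele_count < n, ],
                 chrom_length = 1000L)
  # the package pi uses the n/(n-1) unbiased correction of 2p(1-p)
  oracle <- pairwise_pi_oracle(hap, width = 1000L)
  expect_equal(w$pi[1], oracle, tolerance = 1e-12)
})

test_that("summed window pi conserves total per-site heterozygosity", {
  set.seed(2)
  v <- toy_variants(pos = sample(1:5000, 300), ac = sample(1:9, 300, TRUE), an = 10)
  w <- window_pi(v, chrom_length = 5000L)
  p <- v$alt_allele_count / v$total_chromosomes
  het <- 2 * p * (1 - p) * 10 / 9
  expect_equal(sum(w$pi) * 1000, sum(het), tolerance = 1e-10)
})

test_that("window feature assignment follows majority, precedence and distance", {
  feats <- data.frame(
    chrom = "chr1",
    start = c(1000L, 2600L, 2000L, 3000L),
    end = c(2000L, 3000L, 2600L, 3500L),
    feature = c("exon", "exon", "intron", "utr3"),
    gene_id = "G1")
  w <- data.frame(chrom = "chr1", start = c(1000L, 2000L, 150000L, 0L))
  out <- assign_window_feature(w, feats)
  expect_equal(out$feature[1], "exon")            # fully inside an exon
  expect_equal(out$feature[2], "intron")          # 600 bp intron vs 400 bp exon
  expect_equal(out$feature[3], "intergenic")      # ~147 kb from the gene
  expect_true(is.na(out$feature[4]))              # near gene, no annotation
  # exact ties go to the higher-precedence class
  tie <- data.frame(chrom = "chr1",
                    start = c(0L, 500L), end = c(500L, 1000L),
                    feature = c("intron", "exon"), gene_id = "G1")
  out2 <- assign_window_feature(data.frame(chrom = "chr1", start = 0L), tie)
  expect_equal(out2$feature, "exon")
})

test_that("intergenic windows are over 100 kb from every gene by brute force", {
  set.seed(4)
  feats <- data.frame(chrom = "chr1",
                      start = c(50000L, 300000L), end = c(60000L, 310000L),
                      feature = "exon", gene_id = c("G1", "G2"))
  w <- data.frame(chrom = "chr1", start = seq(0L, 500000L, by = 25000L))
  out <- assign_window_feature(w, feats)
  expect_true(all(out$feature %in% c("exon", "utr5", "utr3", "intron", "intergenic") |
                  is.na(out$feature)))
  for (i in which(out$feature == "intergenic")) {
    ws <- out$start[i]; we <- ws + 1000L
    dists <- sapply(1:2, function(g) {
      max(0, feats$start[g] - we, ws - feats$end[g])
    })
    expect_gt(min(dists), 100000L)
  }
})

test_that("recombination fractions come from Haldane on interpolated cM", {
  map <- data.frame(position = c(0L, 10000L, 20000L), cM = c(0, 0.01, 0.05))
  expect_equal(window_recombination(map, 5000, 5000), 0)
  # d = 0.01 cM
  r <- window_recombination(map, 0, 10000)
  expect_equal(r, 0.5 * (1 - exp(-2 * 0.01 / 100)), tolerance = 1e-12)
  expect_equal(r, 9.9990e-05, tolerance = 1e-4)
  # saturation at 0.5 for large distances
  expect_equal(haldane_fraction(1e6), 0.5, tolerance = 1e-12)
  # linear extrapolation beyond the map ends
  expect_equal(interpolate_cM(map, 30000), 0.05 + 0.04, tolerance = 1e-12)
  expect_error(interpolate_cM(map[0, ], 5), "empty map")
})
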