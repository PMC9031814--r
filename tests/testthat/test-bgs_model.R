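test_that("background-selection prediction obeys its analytic limits", {
  ex <- data.frame(map_cM = c(0.1, 0.5, 2.0), rate = c(0.02, 0.05, 0.1))
  p_noU <- bgs_params(1e-3, -3, 50, U = 0)
  expect_equal(bgs_predict_pi(0.3, ex, p_noU, "product"), 1e-3)
  expect_equal(bgs_predict_pi(0.3, ex, p_noU, "exp_approx"), 1e-3)
  # sh -> 0 removes all selection
  p_nosel <- bgs_params(1e-3, -200, 0)
  expect_equal(bgs_predict_pi(0.3, ex, p_nosel, "product"), 1e-3, tolerance = 1e-10)
})

test_that("single-exon closed form and first-order mode agreement hold", {
  # sh = 1, R = 0, U * dx = 1e-5: product term is pi0 * (1 - 1e-5 / 2)
  ex <- data.frame(map_cM = 0, rate = 0)
  p <- bgs_params(1e-3, 0, 1, U = 1e-8, delta_x = 1000L)
  got <- bgs_predict_pi(0, ex, p, "product")
  expect_equal(got, 1e-3 * (1 - 1e-5 / 2), tolerance = 1e-12)
  gexp <- bgs_predict_pi(0, ex, p, "exp_approx")
  expect_equal(gexp / got, 1, tolerance = 1e-9)
})

test_that("product and exponential modes agree to first order on synthetic data", {
  set.seed(5)
  ex <- data.frame(map_cM = runif(200, 0, 5), rate = rlnorm(200, log(0.03), 0.5))
  p <- bgs_params(1e-3, -3, 50)
  targets <- runif(50, 0, 5)
  for (tc in targets[1:10]) {
    terms <- 1e-8 * 1000 * exp(-3 + 50 * ex$rate) /
      (2 * (exp(-3 + 50 * ex$rate) + haldane_fraction(abs(ex$map_cM - tc)))^2)
    if (max(terms) < 1e-2) {
      a <- bgs_predict_pi(tc, ex, p, "product")
      b <- bgs_predict_pi(tc, ex, p, "exp_approx")
      expect_lt(abs(a / b - 1), 1e-3)
    }
  }
})

test_that("prediction is monotone in U and in recombination distance", {
  ex <- data.frame(map_cM = c(0.2, 1.1), rate = c(0.03, 0.06))
  pis <- sapply(c(0, 1e-8, 1e-7, 1e-6), function(u)
    bgs_predict_pi(0.5, ex, bgs_params(1e-3, -3, 50, U = u)))
  expect_true(all(diff(pis) < 0))
  # pushing every exon window farther away raises predicted diversity
  p <- bgs_params(1e-3, -3, 50)
  near <- bgs_predict_pi(0.5, ex, p)
  far <- bgs_predict_pi(0.5, transform(ex, map_cM = map_cM + 50), p)
  expect_gt(far, near)
})

test_that("the fit recovers a noiseless synthetic chromosome near-exactly", {
  cfg <- generator_config(seed = 71, bgs = list(chrom_length = 1e6, n_genes = 40,
                                                noise_sd = 0))
  b <- gen_bgs_windows(cfg)
  w <- b$windows[b$windows$feature == "intron", ]
  fit <- fit_bgs(w, b$exon_windows)
  expect_equal(fit$pi0, 1e-3, tolerance = 0.01)
  expect_false(fit$flat)
})

test_that("the noisy default recovers pi0 and the reduction profile", {
  cfg <- generator_config(seed = 72, bgs = list(chrom_length = 2e6, n_genes = 80))
  b <- gen_bgs_windows(cfg)
  w <- b$windows[b$windows$feature == "intron", ]
  fit <- fit_bgs(w, b$exon_windows)
  expect_equal(fit$pi0, 1e-3, tolerance = 0.1)
  truth <- b$truth$params
  Rm <- haldane_fraction(abs(outer(w$map_cM, b$exon_windows$map_cM, "-")))
  g_true <- divrate:::.bgs_predict_matrix(Rm, b$exon_windows$rate, truth) / truth$pi0
  g_fit <- divrate:::.bgs_predict_matrix(
    Rm, b$exon_windows$rate,
    bgs_params(max(fit$pi0, 1e-12), fit$alpha_sel, fit$beta_sel)) /
    max(fit$pi0, 1e-12)
  expect_lt(sqrt(mean((g_fit / g_true - 1)^2)), 0.1)
})

test_that("a selection-free chromosome is flagged as flat", {
  cfg <- generator_config(seed = 73,
                          bgs = list(chrom_length = 5e5, n_genes = 20,
                                     U = 0, noise_sd = 0))
  b <- gen_bgs_windows(cfg)
  w <- b$windows[b$windows$feature == "intron", ]
  expect_warning(fit <- fit_bgs(w, b$exon_windows, U = 0), "flat")
  expect_true(fit$flat)
  expect_equal(fit$pi0, 1e-3, tolerance = 1e-10)
})

test_that("accepted fits never end above their starting residual sum of squares", {
  cfg <- generator_config(seed = 74, bgs = list(chrom_length = 1e6, n_genes = 40))
  b <- gen_bgs_windows(cfg)
  w <- b$windows[b$windows$feature == "intron", ]
  fit <- fit_bgs(w, b$exon_windows)
  # rss at every documented start is >= the accepted optimum
  Rm <- haldane_fraction(abs(outer(w$map_cM, b$exon_windows$map_cM, "-")))
  for (b0 in c(0, 10, -10, 100, -100)) {
    sh_par <- c(log(0.01), b0)
    sh <- exp(sh_par[1] + sh_par[2] * b$exon_windows$rate)
    shm <- matrix(sh, nrow(Rm), length(sh), byrow = TRUE)
    g <- exp(-1e-8 * 1000 / 2 * rowSums(shm / (shm + Rm)^2))
    pi0 <- sum(w$pi * g) / sum(g * g)
    expect_gte(sum((w$pi - pi0 * g)^2), fit$rss - 1e-15)
  }
})

test_that("two-way decomposition matches hand-computed sums of squares", {
  grid <- expand.grid(chrom = c("c1", "c2", "c3"),
                      feature = c("exon", "intron"),
                      stringsAsFactors = FALSE)
  grid$pi0 <- c(1, 2, 3, 2, 3, 5)
  # hand computation: grand mean 8/3; row (chrom) means 1.5, 2.5, 4;
  # column (feature) means 2, 10/3
  gm <- mean(grid$pi0)
  ss_chrom <- 2 * sum((c(1.5, 2.5, 4) - gm)^2)
  ss_feat <- 3 * sum((c(2, 10 / 3) - gm)^2)
  ss_tot <- sum((grid$pi0 - gm)^2)
  ss_res <- ss_tot - ss_chrom - ss_feat
  dec <- anova_decompose_params(grid, "pi0")
  expect_equal(sum(dec$shares), 1, tolerance = 1e-12)
  expect_equal(unname(dec$shares["chrom"]), ss_chrom / ss_tot, tolerance = 1e-10)
  expect_equal(unname(dec$shares["feature"]), ss_feat / ss_tot, tolerance = 1e-10)
  expect_equal(unname(dec$shares["residual"]), ss_res / ss_tot, tolerance = 1e-10)
})

test_that("feature-only signal gives zero chromosome and residual shares", {
  grid <- expand.grid(chrom = paste0("c", 1:4),
                      feature = c("exon", "utr5", "utr3", "intron"),
                      stringsAsFactors = FALSE)
  grid$alpha_sel <- c(-3, -2, -1, -2.5)[match(grid$feature,
                                              c("exon", "utr5", "utr3", "intron"))]
  dec <- anova_decompose_params(grid, "alpha_sel")
  expect_equal(unname(dec$shares["chrom"]), 0, tolerance = 1e-12)
  expect_equal(unname(dec$shares["residual"]), 0, tolerance = 1e-12)
  expect_equal(unname(dec$shares["feature"]), 1, tolerance = 1e-12)
  expect_error(anova_decompose_params(grid[-1, ], "alpha_sel"), "incomplete")
})

test_that("main-effect p-values are calibrated under a pure-noise grid", {
  set.seed(81)
  reps <- 500L
  pc <- pf <- numeric(reps)
  grid <- expand.grid(chrom = paste0("c", 1:3),
                      feature = c("exon", "utr5", "utr3", "intron"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(reps)) {
    grid$beta_sel <- rnorm(nrow(grid))
    d <- anova_decompose_params(grid, "beta_sel")
    pc[i] <- d$p_chrom
    pf[i] <- d$p_feature
  }
  # rejection rate at 0.05 within the binomial 99.9% band
  band <- qbinom(c(5e-4, 1 - 5e-4), reps, 0.05)
  expect_true(sum(pc < 0.05) >= band[1] && sum(pc < 0.05) <= band[2])
  expect_true(sum(pf < 0.05) >= band[1] && sum(pf < 0.05) <= band[2])
})
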