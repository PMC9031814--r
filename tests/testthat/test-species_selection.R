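test_that("mid-p lower-tail values match the Poisson limit and tail behavior", {
  # theta enormous: NB -> Poisson; K = 0 gives 0.5 * exp(-mu)
  d <- gene_deviation_pvalue(0L, mu = 5, theta = 1e12)
  expect_equal(d$p_lower, 0.5 * dpois(0, 5), tolerance = 1e-6)
  expect_equal(d$z, qnorm(0.5 * exp(-5)), tolerance = 1e-4)
  # K far above mu: p -> 1, z large positive
  d2 <- gene_deviation_pvalue(500L, mu = 5, theta = 10)
  expect_gt(d2$p_lower, 1 - 1e-6)
  expect_gt(d2$z, 4)
  # K far below mu: negative z (enhanced constraint)
  d3 <- gene_deviation_pvalue(0L, mu = 100, theta = 1e6)
  expect_lt(d3$z, -5)
})

test_that("mid-p values average exactly one half over the NB support", {
  for (mu in c(3, 40)) {
    for (theta in c(2, 10)) {
      kmax <- qnbinom(1 - 1e-13, mu = mu, size = theta)
      k <- 0:kmax
      pmf <- dnbinom(k, mu = mu, size = theta)
      midp <- gene_deviation_pvalue(k, mu, theta)$p_lower
      expect_equal(sum(pmf * midp), 0.5, tolerance = 1e-10)
    }
  }
})

test_that("the gene-set t test follows its closed form and conventions", {
  r <- gene_set_t_test(c(-1, 1), "s")
  expect_equal(r$t_value, 0)
  expect_equal(r$p_value, 1)
  # closed form against a worked example
  z <- c(0.3, -0.2, 0.8, 0.1)
  r2 <- gene_set_t_test(z)
  expect_equal(r2$t_value, mean(z) / (sd(z) / 2), tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pt(abs(r2$t_value), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # order invariance
  expect_equal(gene_set_t_test(rev(z))$t_value, r2$t_value)
  # degenerate spreads
  expect_warning(r3 <- gene_set_t_test(c(0, 0, 0)), "t = 0")
  expect_equal(r3$p_value, 1)
  expect_warning(r4 <- gene_set_t_test(c(2, 2)), "floored")
  expect_lt(r4$p_value, 1e-6)
  expect_error(gene_set_t_test(1), "at least two")
})

test_that("Benjamini-Hochberg selection matches the step-up definition", {
  # p = {0.01, 0.02, 0.5}: thresholds 0.0167, 0.0333, 0.05 -> first two pass
  expect_equal(bh_select(c(0.01, 0.02, 0.5), 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(bh_select(rep(1, 5), 0.05), rep(FALSE, 5))
  p <- c(1e-9, runif(999, 0.2, 1))
  expect_true(bh_select(p, 0.01)[1])
  # monotone: everything below the largest passing rank is selected
  set.seed(6)
  p <- runif(200)^2
  mask <- bh_select(p, 0.1)
  if (any(mask)) expect_true(all(mask[p <= max(p[mask])]))
})

test_that("PCA standardizes, orients and decomposes variance correctly", {
  set.seed(10)
  x <- rnorm(100)
  two <- cbind(a = x, b = 2 * x + 3)
  pc <- pca_species(two)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  # loadings match the eigen-decomposition of the correlation matrix
  m <- cbind(rnorm(50), rnorm(50), rnorm(50))
  m[, 2] <- m[, 1] * 0.5 + m[, 2]
  colnames(m) <- c("u", "v", "w")
  pc2 <- pca_species(m)
  ev <- eigen(cor(m))
  expect_equal(abs(pc2$loadings), abs(ev$vectors), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pc2$explained, ev$values / sum(ev$values), tolerance = 1e-10)
  # sign convention: dominant loading of each component is positive
  for (j in 1:3) {
    l <- pc2$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(pca_species(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("correspondence analysis matches an explicit SVD of residuals", {
  x <- matrix(c(20, 5, 2, 4, 25, 3, 1, 6, 30), 3, 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  ca <- ca_profiles(x)
  # hand computation
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  expect_equal(ca$total_inertia, sum(sv$d^2), tolerance = 1e-12)
  # total inertia equals chi-square statistic / grand total
  chi <- suppressWarnings(chisq.test(x))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(x), tolerance = 1e-10)
  rc <- sweep(sv$u[, 1:2] / sqrt(r), 2, sv$d[1:2], `*`)
  expect_equal(abs(unname(ca$row_coords)), abs(rc), tolerance = 1e-10)
  # cross-check axis variances against an independent CA implementation
  mc <- MASS::corresp(x, nf = 2)
  expect_equal(ca$inertia[1:2], unname(mc$cor[1:2]^2), tolerance = 1e-8)
})

test_that("CA handles degenerate and permuted input as specified", {
  # rows proportional to column masses: independence, zero inertia
  x <- outer(c(10, 20, 5), c(0.2, 0.3, 0.5))
  ca <- ca_profiles(x)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  y <- matrix(c(5, 1, 0, 0, 2, 8, 3, 1, 4), 3, 3,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  ca1 <- ca_profiles(y)
  perm <- c(3, 1, 2)
  ca2 <- ca_profiles(y[perm, ])
  expect_equal(ca2$row_coords, ca1$row_coords[perm, ], tolerance = 1e-10)
  yz <- rbind(y, r4 = c(0, 0, 0))
  expect_warning(ca3 <- ca_profiles(yz), "all-zero")
  expect_equal(nrow(ca3$row_coords), 3L)
  expect_error(suppressWarnings(ca_profiles(matrix(0, 2, 2))), "zero grand total")
})

test_that("gene_set_tests joins membership, skips small sets and flags by FDR", {
  set.seed(12)
  dev <- data.frame(gene_id = paste0("G", 1:50), z = rnorm(50))
  dev$z[1:10] <- dev$z[1:10] - 5     # strong deficit set
  sets <- rbind(data.frame(set_id = "low", gene_id = paste0("G", 1:10)),
                data.frame(set_id = "null", gene_id = paste0("G", 11:30)),
                data.frame(set_id = "tiny", gene_id = "G31"))
  expect_message(res <- gene_set_tests(dev, sets, fdr = 0.05), "skipped 1")
  expect_equal(nrow(res), 2L)
  low <- res[res$set_id == "low", ]
  expect_lt(low$t_value, 0)
  expect_true(low$significant)
})
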