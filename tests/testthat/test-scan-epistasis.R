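# Two-locus scan: model fit, interaction tests, SSE thresholds, the
# governing-threshold rules, clustering and the edge-effect rule.

rand_ad <- function(n, seed) {
  set.seed(seed)
  A <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  list(A = A, D = (A == 0) * 1)
}

test_that("the two-locus fit recovers noiseless coefficients exactly", {
  l1 <- rand_ad(60, 1); l2 <- rand_ad(60, 2)
  truth <- c(a1 = 0.3, d1 = -0.2, a2 = 0.1, d2 = 0.4,
             iaa = 0.5, iad = -0.3, ida = 0.2, idd = -0.1)
  y <- truth["a1"] * l1$A + truth["d1"] * l1$D + truth["a2"] * l2$A +
    truth["d2"] * l2$D + truth["iaa"] * l1$A * l2$A +
    truth["iad"] * l1$A * l2$D + truth["ida"] * l1$D * l2$A +
    truth["idd"] * l1$D * l2$D
  f <- two_locus_fit(y, l1$A, l1$D, l2$A, l2$D)
  expect_equal(unname(f$coef[c("A1", "D1", "A2", "D2", "iaa", "iad",
                               "ida", "idd")]),
               unname(truth), tolerance = 1e-9)
  expect_lt(f$SSE, 1e-18)
  # all interactions zero in noiseless data: joint p = 1
  y0 <- 0.3 * l1$A + 0.4 * l2$D
  f0 <- two_locus_fit(y0, l1$A, l1$D, l2$A, l2$D)
  expect_equal(interaction_test(f0)$p_joint, 1)
})

test_that("the two-locus fit equals brute-force least squares on 12 individuals", {
  set.seed(3)
  A1 <- rnorm(12); D1 <- runif(12); A2 <- rnorm(12); D2 <- runif(12)
  y <- rnorm(12)
  X <- cbind(1, A1, D1, A2, D2, A1 * A2, A1 * D2, D1 * A2, D1 * D2)
  o <- ols_oracle(X, y)
  f <- two_locus_fit(y, A1, D1, A2, D2)
  expect_equal(unname(f$coef), unname(o$beta), tolerance = 1e-8)
  expect_equal(f$SSE, o$SSE, tolerance = 1e-8)
})

test_that("aliased interaction columns are dropped and recorded", {
  l1 <- rand_ad(40, 4)
  # second locus identical to the first: interactions alias heavily
  f <- two_locus_fit(rnorm(40), l1$A, l1$D, l1$A, l1$D)
  expect_true(length(f$dropped) > 0)
  tt <- interaction_test(f)
  expect_true(is.finite(tt$p_joint))
})

test_that("the interaction F test is calibrated and powered", {
  set.seed(5)
  n <- 400
  pj <- replicate(150, {
    l1 <- list(A = sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)))
    l1$D <- (l1$A == 0) * 1
    l2 <- list(A = sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)))
    l2$D <- (l2$A == 0) * 1
    y <- 0.3 * l1$A + rnorm(n)
    interaction_test(two_locus_fit(y, l1$A, l1$D, l2$A, l2$D))$pass
  })
  expect_lte(mean(pj), 0.12)  # 0.05 joint + Bonferroni-level coefficient tests
  pow <- replicate(50, {
    l1 <- list(A = sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)))
    l1$D <- (l1$A == 0) * 1
    l2 <- list(A = sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)))
    l2$D <- (l2$A == 0) * 1
    y <- 0.5 * l1$A * l2$A + rnorm(n)
    interaction_test(two_locus_fit(y, l1$A, l1$D, l2$A, l2$D))$pass
  })
  expect_gt(mean(pow), 0.6)
})

test_that("two-locus SSE is nested within the single-locus SSEs", {
  set.seed(6)
  cfg <- sim_config(n_f2 = 150)
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 10)
  y <- rnorm(150)
  ps <- pair_scan(y, g, step = 10)
  sc <- scan_genome(y, g)
  for (k in sample(nrow(ps), 20)) {
    expect_lte(ps$SSE[k], sc$SSE[ps$i[k]] + 1e-8)
    expect_lte(ps$SSE[k], sc$SSE[ps$j[k]] + 1e-8)
  }
})

test_that("pair eligibility excludes close same-chromosome pairs", {
  set.seed(7)
  cfg <- sim_config(chr_lengths = c(`1` = 60, `2` = 40),
                    n_markers_per_chr = 4, n_f2 = 50)
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 5)
  ps <- pair_scan(y = rnorm(50), g, step = 5, min_sep = 20)
  same <- ps$chr1 == ps$chr2
  expect_true(all(abs(ps$pos1[same] - ps$pos2[same]) >= 20))
  expect_true(any(!same))
})

test_that("governing thresholds follow the span and lowest-SSE_specific rules", {
  pairs <- data.frame(i = 1:4, j = 11:14,
                      chr1 = c("1", "1", "2", "3"), pos1 = c(10, 50, 30, 5),
                      chr2 = c("2", "2", "3", "4"), pos2 = c(30, 35, 10, 5),
                      SSE = c(90, 95, 85, 101))
  qtl <- data.frame(chr = c("1", "2"), pos = c(12, 32), F = c(8, 7),
                    span_lo = c(5, 25), span_hi = c(20, 40),
                    sse_specific = c(96, 88))
  out <- apply_thresholds(pairs, qtl, sse_genome = 100)
  # pair 1: pos1 in chr1 span (thr 96) and pos2 in chr2 span (thr 88):
  # lowest applicable specific threshold governs
  expect_equal(out$governing[1], 88)
  # pair 2: only pos2 in chr2 span
  expect_equal(out$governing[2], 88)
  # pair 3: pos1 in chr2 span
  expect_equal(out$governing[3], 88)
  # pair 4: outside all spans: genomewide
  expect_equal(out$governing[4], 100)
  expect_equal(out$retained, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(out$heat[out$retained] > 0))
  expect_true(all(out$heat[!out$retained] <= 0))
  # a specific threshold above SSE_genome is never applied
  qtl2 <- qtl; qtl2$sse_specific <- c(150, 150)
  out2 <- apply_thresholds(pairs, qtl2, sse_genome = 100)
  expect_true(all(out2$governing == 100))
})

test_that("raising alpha never removes a retained pair", {
  set.seed(8)
  cfg <- sim_config(n_f2 = 200)
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 10)
  y <- rnorm(200)
  ps <- pair_scan(y, g, step = 10)
  set.seed(9)
  th <- genomewide_sse_threshold(y, g, n_perm = 120, alpha = 0.05, step = 10)
  set.seed(9)
  th2 <- genomewide_sse_threshold(y, g, n_perm = 120, alpha = 0.10, step = 10)
  r1 <- ps$SSE < th$threshold
  r2 <- ps$SSE < th2$threshold
  expect_true(all(which(r1) %in% which(r2)))
})

test_that("cluster peaks pick the maximum heat value per connected cluster", {
  # two separated clusters on a single chromosome-pair panel
  grid <- list(map = data.frame(chr = rep(c("1", "2"), each = 10),
                                pos = rep(seq(0, 45, by = 5), 2)))
  pairs <- expand.grid(i = 1:10, j = 11:20)
  pairs$chr1 <- "1"; pairs$chr2 <- "2"
  pairs$pos1 <- grid$map$pos[pairs$i]; pairs$pos2 <- grid$map$pos[pairs$j]
  pairs$SSE <- 100
  # cluster A around (i=2..3, j=12..13), peak at (3, 13)
  pairs$SSE[pairs$i %in% 2:3 & pairs$j %in% 12:13] <- 90
  pairs$SSE[pairs$i == 3 & pairs$j == 13] <- 85
  # cluster B at (8, 18)
  pairs$SSE[pairs$i == 8 & pairs$j == 18] <- 88
  out <- apply_thresholds(pairs, NULL, sse_genome = 95)
  peaks <- select_cluster_peaks(out, grid)
  expect_equal(nrow(peaks), 2L)
  expect_setequal(paste(peaks$i, peaks$j), c("3 13", "8 18"))
  expect_false(any(peaks$edge_discarded))
})

test_that("edge-effect fragments beside a span boundary are discarded", {
  grid <- list(map = data.frame(chr = rep(c("1", "2"), each = 10),
                                pos = rep(seq(0, 45, by = 5), 2)))
  pairs <- expand.grid(i = 1:10, j = 11:20)
  pairs$chr1 <- "1"; pairs$chr2 <- "2"
  pairs$pos1 <- grid$map$pos[pairs$i]; pairs$pos2 <- grid$map$pos[pairs$j]
  pairs$SSE <- 100
  # one contiguous low-SSE region straddling the chr1 span boundary at 20:
  # inside the span (pos1 <= 20) SSEs are lower but governed by a strict
  # SSE_specific that removes them; the fragment outside survives SSE_genome
  region <- pairs$j %in% 14:15 & pairs$i %in% 3:6
  pairs$SSE[region & pairs$pos1 <= 20] <- 80   # inside boundary, lower SSE
  pairs$SSE[region & pairs$pos1 > 20] <- 90    # outside fragment
  qtl <- data.frame(chr = "1", pos = 10, F = 9, span_lo = 0, span_hi = 20,
                    sse_specific = 75)
  out <- apply_thresholds(pairs, qtl, sse_genome = 95)
  peaks <- select_cluster_peaks(out, grid)
  frag <- peaks[peaks$pos1 > 20, ]
  expect_true(all(frag$edge_discarded))
})

test_that("locus-specific thresholds strictly correct for a large main effect", {
  set.seed(10)
  cfg <- sim_config(n_f2 = 300, qtl = data.frame(chr = "1", pos = 30,
                                                 a = 0.8, d = 0))
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 5)
  ph <- simulate_phenotype(cr, cfg)
  y <- ph$y - mean(ph$y)
  set.seed(11)
  sg <- genomewide_sse_threshold(y, g, n_perm = 100, step = 5)
  set.seed(11)
  ls <- locus_specific_sse_threshold(y, g, "1", 30, n_perm = 100, step = 5)
  # permutations with the QTL's columns kept explain the main effect, so
  # the locus-specific threshold must sit well below the genomewide one
  expect_lt(ls$threshold, sg$threshold)
})
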