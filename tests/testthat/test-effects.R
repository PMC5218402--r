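# The background-conditional effect decomposition: genotypic values,
# conditional effects (coefficient form vs genotypic-value form), standard
# errors, Holm correction, variance explained, the independent effects
# model and the plot data.

rand_coef <- function() {
  stats::setNames(rnorm(8), c("a1", "d1", "a2", "d2",
                              "iaa", "iad", "ida", "idd"))
}

# conditional effects recomputed from genotypic values in the
# single-locus way: a1(X) = (G_WW,X - G_EE,X)/2, d1(X) = G_EW,X - mean
effects_from_gv <- function(gv) {
  val <- function(g1, g2) gv$value[gv$g1 == g1 & gv$g2 == g2]
  out <- NULL
  for (bg in c("WW", "EW", "EE")) {
    out <- rbind(out,
      data.frame(locus = 1, bg = bg, kind = "a",
                 estimate = (val("WW", bg) - val("EE", bg)) / 2),
      data.frame(locus = 1, bg = bg, kind = "d",
                 estimate = val("EW", bg) - (val("WW", bg) + val("EE", bg)) / 2),
      data.frame(locus = 2, bg = bg, kind = "a",
                 estimate = (val(bg, "WW") - val(bg, "EE")) / 2),
      data.frame(locus = 2, bg = bg, kind = "d",
                 estimate = val(bg, "EW") - (val(bg, "WW") + val(bg, "EE")) / 2))
  }
  out
}

test_that("genotypic values follow the two-locus coefficient algebra", {
  z <- stats::setNames(rep(0, 8), names(rand_coef()))
  gv0 <- genotypic_values(z)
  expect_true(all(gv0$value == 0))
  g1 <- z; g1["a1"] <- 1
  gv1 <- genotypic_values(g1)
  for (g2 in c("EE", "EW", "WW")) {
    expect_equal(gv1$value[gv1$g1 == "WW" & gv1$g2 == g2], 1)
    expect_equal(gv1$value[gv1$g1 == "EW" & gv1$g2 == g2], 0)
    expect_equal(gv1$value[gv1$g1 == "EE" & gv1$g2 == g2], -1)
  }
  g2c <- z; g2c[c("a1", "a2", "iaa")] <- 1
  gv2 <- genotypic_values(g2c)
  expect_equal(gv2$value[gv2$g1 == "WW" & gv2$g2 == "WW"], 3)
  expect_equal(gv2$value[gv2$g1 == "EE" & gv2$g2 == "EE"], -1)
  expect_error(genotypic_values(z[-1]), "missing")
})

test_that("coefficient-form effects equal the genotypic-value recomputation exactly", {
  set.seed(61)
  for (r in 1:1000) {
    cf <- rand_coef()
    eff <- conditional_effects(cf)
    ref <- effects_from_gv(genotypic_values(cf))
    m <- merge(eff, ref, by = c("locus", "bg", "kind"))
    expect_equal(m$estimate.x, m$estimate.y, tolerance = 1e-12)
  }
})

test_that("single conditional effects match the stated combinations", {
  z <- stats::setNames(rep(0, 8), names(rand_coef()))
  cf <- z; cf["a1"] <- 0.1; cf["iaa"] <- 0.2
  eff <- conditional_effects(cf)
  pick <- function(l, b, k) eff$estimate[eff$locus == l & eff$bg == b &
                                           eff$kind == k]
  expect_equal(pick(1, "WW", "a"), 0.3)
  expect_equal(pick(1, "EE", "a"), -0.1)
  expect_equal(pick(1, "EW", "a"), 0.1)
  cf2 <- z; cf2["d2"] <- 0.2; cf2["idd"] <- 0.3
  eff2 <- conditional_effects(cf2)
  expect_equal(eff2$estimate[eff2$locus == 2 & eff2$bg == "EW" &
                               eff2$kind == "d"], 0.5)
})

test_that("linkage-equilibrium averaging returns the single-locus coefficients", {
  # under linkage equilibrium the partner's genotype frequencies are
  # (1/4, 1/2, 1/4); the population single-locus coefficients are then
  # a1 + iad/2 (additive) and d1 + idd/2 (dominance), and the weighted
  # mean of the conditional effects must reproduce them exactly
  set.seed(62)
  w <- c(EE = 0.25, EW = 0.5, WW = 0.25)
  for (r in 1:50) {
    cf <- rand_coef()
    eff <- conditional_effects(cf)
    single <- c(a1 = unname(cf["a1"] + cf["iad"] / 2),
                d1 = unname(cf["d1"] + cf["idd"] / 2),
                a2 = unname(cf["a2"] + cf["ida"] / 2),
                d2 = unname(cf["d2"] + cf["idd"] / 2))
    for (l in 1:2) for (k in c("a", "d")) {
      sub <- eff[eff$locus == l & eff$kind == k, ]
      avg <- sum(w[sub$bg] * sub$estimate)
      expect_equal(avg, single[[paste0(k, l)]], tolerance = 1e-12)
    }
  }
  # empirical confirmation: a single-locus fit on a large F2 sample in
  # linkage equilibrium lands on the averaged conditional effects
  set.seed(162)
  n <- 60000
  A1 <- sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)); D1 <- (A1 == 0) * 1
  A2 <- sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)); D2 <- (A2 == 0) * 1
  cf <- rand_coef()
  y <- cf["a1"] * A1 + cf["d1"] * D1 + cf["a2"] * A2 + cf["d2"] * D2 +
    cf["iaa"] * A1 * A2 + cf["iad"] * A1 * D2 + cf["ida"] * D1 * A2 +
    cf["idd"] * D1 * D2
  f1 <- hk_fit(as.numeric(y), A1, D1)
  expect_lt(abs(f1$a - (cf[["a1"]] + cf[["iad"]] / 2)), 0.03)
  expect_lt(abs(f1$d - (cf[["d1"]] + cf[["idd"]] / 2)), 0.05)
})

test_that("effect standard errors come from the coefficient covariance", {
  V <- diag(0.01, 8)
  rownames(V) <- colnames(V) <- names(rand_coef())
  w <- stats::setNames(c(1, rep(0, 3), 1, rep(0, 3)), names(rand_coef()))
  expect_equal(effect_se(w, V), sqrt(0.02), tolerance = 1e-12)
  expect_equal(round(effect_se(w, V), 4), 0.1414)
  w1 <- stats::setNames(c(1, rep(0, 7)), names(rand_coef()))
  expect_equal(effect_se(w1, V), 0.1)
  expect_error(effect_se(stats::setNames(1, "zz"), V), "cover")
})

test_that("effect SEs agree with a parametric bootstrap on a simulated fit", {
  set.seed(63)
  n <- 600
  A1 <- sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)); D1 <- (A1 == 0) * 1
  A2 <- sample(c(-1, 0, 1), n, TRUE, c(.25, .5, .25)); D2 <- (A2 == 0) * 1
  lin <- 0.3 * A1 + 0.5 * A1 * A2
  boot <- replicate(400, {
    y <- lin + rnorm(n)
    f <- two_locus_fit(y, A1, D1, A2, D2)
    unname(f$coef["A1"] + f$coef["iaa"])   # a1(WW)
  })
  y <- lin + rnorm(n)
  f <- two_locus_fit(y, A1, D1, A2, D2)
  V <- f$vcov
  rownames(V) <- colnames(V) <- c("mu", names(rand_coef()))
  w <- stats::setNames(c(1, 0, 0, 0, 1, 0, 0, 0), names(rand_coef()))
  se <- effect_se(w, V)
  expect_lt(abs(se - sd(boot)) / sd(boot), 0.15)
})

test_that("Holm flags match a hand-rolled step-down", {
  set.seed(64)
  for (r in 1:200) {
    p <- runif(12)^sample(1:3, 1)
    expect_equal(holm_adjust(p, 0.05), holm_oracle(p, 0.05))
  }
  expect_false(any(holm_adjust(rep(1, 12))))
  p <- c(0.001, rep(0.5, 11))
  expect_equal(holm_adjust(p, 0.05)[1], 0.001 < 0.05 / 12)
})

test_that("variance explained is PSS-based and near zero for null terms", {
  set.seed(65)
  cfg <- sim_config(n_f2 = 600, qtl = data.frame(chr = "1", pos = 40,
                                                 a = 0.5, d = 0))
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 5)
  ph <- simulate_phenotype(cr, cfg)
  qtl <- data.frame(chr = c("1", "2"), pos = c(40, 80), F = 9,
                    span_lo = c(30, 70), span_hi = c(50, 90))
  spec <- assemble_model(ph, "y", c("sex", "batch"), "mother", qtl)
  fm <- fit_full_model(spec, g)
  bm <- fit_base_model(ph, "y", c("sex", "batch"))
  pss_base <- unname(bm$fit@devcomp$cmp["pwrss"])
  real <- variance_explained(fm, fm$colmap$locus[["1"]], pss_base)
  null <- variance_explained(fm, fm$colmap$locus[["2"]], pss_base)
  # generating share: a^2/2 over (a^2/2 + mother + residual) ~ 10%
  expect_gt(real, 4)
  expect_lt(abs(real - 100 * 0.125 / 1.225), 6)
  expect_lt(null, 1.5)
})

test_that("the independent effects model ignores pure epistasis but sees additive loci", {
  pairs <- data.frame(chr1 = "1", pos1 = 30, chr2 = "2", pos2 = 70,
                      a1 = 0, d1 = 0, a2 = 0, d2 = 0,
                      iaa = 0.5, iad = 0, ida = 0, idd = 0)
  set.seed(66)
  hits <- numeric(0)
  for (r in 1:25) {
    cfg <- sim_config(n_f2 = 300, pairs = pairs)
    cr <- simulate_cross(cfg)
    g <- true_ad_grid(cr, grid_step = 10)
    ph <- simulate_phenotype(cr, cfg)
    qtl <- data.frame(chr = c("1", "2"), pos = c(30, 70), F = 9,
                      span_lo = c(20, 60), span_hi = c(40, 80))
    bm <- fit_base_model(ph, "y", c("sex", "batch"))
    iem <- independent_effects_model(ph, "y", c("sex", "batch"), "mother",
                                     qtl, g, base_sd = sqrt(bm$sigma2))
    hits <- c(hits, iem$effects$significant)
  }
  expect_lte(mean(hits), 0.16)  # near the nominal test level
  # additive-only locus: Eq-7-style and full-model estimates agree
  set.seed(67)
  cfg <- sim_config(n_f2 = 800, qtl = data.frame(chr = "1", pos = 40,
                                                 a = 0.4, d = 0))
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 5)
  ph <- simulate_phenotype(cr, cfg)
  qtl <- data.frame(chr = "1", pos = 40, F = 20, span_lo = 30, span_hi = 50)
  bm <- fit_base_model(ph, "y", c("sex", "batch"))
  iem <- independent_effects_model(ph, "y", c("sex", "batch"), "mother",
                                   qtl, g, base_sd = sqrt(bm$sigma2))
  expect_true(iem$effects$significant[1])
  expect_lt(abs(iem$effects$a[1] - 0.4), 3 * iem$effects$se_a[1])
  # empty QTL set reduces to the base model
  iem0 <- independent_effects_model(ph, "y", c("sex", "batch"), "mother",
                                    NULL, g, base_sd = 1)
  expect_equal(nrow(iem0$effects), 0L)
  expect_equal(iem0$fit$reml_loglik, bm$reml_loglik, tolerance = 1e-6)
})

test_that("plot data is 9 rows, ordered, and parallel exactly without interaction", {
  cf <- stats::setNames(c(0.3, 0.1, -0.2, 0.4, 0, 0, 0, 0),
                        c("a1", "d1", "a2", "d2", "iaa", "iad", "ida", "idd"))
  pd <- epistasis_plot_data(genotypic_values(cf), denom = 2)
  expect_equal(nrow(pd), 9L)
  expect_equal(levels(pd$g1), c("EE", "EW", "WW"))
  # parallel: the vertical offsets between g2 lines are constant across g1
  wide <- tapply(pd$value, list(pd$g1, pd$g2), identity)
  diffs <- wide[, "WW"] - wide[, "EE"]
  expect_equal(max(diffs) - min(diffs), 0, tolerance = 1e-12)
  # pure iaa: lines cross, anti-symmetric about EW
  cf2 <- cf; cf2[] <- 0; cf2["iaa"] <- 1
  pd2 <- epistasis_plot_data(genotypic_values(cf2))
  wide2 <- tapply(pd2$value, list(pd2$g1, pd2$g2), identity)
  expect_equal(wide2["WW", "WW"], 1)
  expect_equal(wide2["EE", "WW"], -1)
  expect_equal(unname(wide2[, "EW"]), c(0, 0, 0))
})

test_that("triple effects extend the pair identities for a shared locus", {
  # build a fitted model with two pairs sharing locus on chr 1
  set.seed(68)
  cfg <- sim_config(chr_lengths = c(`1` = 100, `2` = 100, `3` = 100),
                    n_markers_per_chr = 6, n_f2 = 700)
  arch <- data.frame(chr1 = c("1", "1"), pos1 = c(30, 30),
                     chr2 = c("2", "3"), pos2 = c(60, 40),
                     a1 = c(0.3, 0), d1 = 0, a2 = 0, d2 = 0,
                     iaa = c(0.5, 0.4), iad = 0, ida = 0, idd = 0)
  cfg$pairs <- arch
  cr <- simulate_cross(cfg)
  g <- true_ad_grid(cr, grid_step = 5)
  ph <- simulate_phenotype(cr, cfg)
  spec <- assemble_model(ph, "y", c("sex", "batch"), "mother", NULL,
                         arch[, c("chr1", "pos1", "chr2", "pos2")])
  fm <- fit_full_model(spec, g)
  te <- triple_effects(fm, 1, 2, base_sd = 1)
  expect_equal(nrow(te), 30L)
  shared <- fm$spec$pairs[[1]]$l1
  expect_equal(sum(te$locus == shared), 18L)
  # the shared locus's a(WW, WW) = a1 + iaa_12 + iaa_13
  cols1 <- epiqtl:::pair_columns(fm, 1)
  cols2 <- epiqtl:::pair_columns(fm, 2)
  want <- unname(fm$beta[cols1["a1"]] + fm$beta[cols1["iaa"]] +
                   fm$beta[cols2["iaa"]])
  got <- te$estimate[te$locus == shared & te$bg == "WWWW" & te$kind == "a"]
  expect_equal(got, want, tolerance = 1e-10)
  # a partner's effects depend only on the shared locus genotype (6 rows)
  p2 <- fm$spec$pairs[[1]]$l2
  expect_equal(sum(te$locus == p2), 6L)
  a2_WW <- te$estimate[te$locus == p2 & te$bg == "WW" & te$kind == "a"]
  expect_equal(a2_WW, unname(fm$beta[cols1["a2"]] + fm$beta[cols1["iaa"]]),
               tolerance = 1e-10)
  expect_error(triple_effects(fm, 1, 1, 1), "share")
})
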