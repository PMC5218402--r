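# Background-conditional representation of epistasis. From the fitted
# two-locus coefficients, genotypic values for the nine genotype
# combinations are computed relative to the mean of the all-homozygote
# classes; additive and dominance effects of each locus are then measured
# separately for every genotype at the partner locus, with standard errors
# from the coefficient covariance, Holm correction within the pair, and
# standardisation by the base model's residual standard deviation.

# F-infinity genotype scores: additive s(EE,EW,WW) = -1, 0, 1; dominance
# h = 1 for EW else 0.
geno_s <- c(EE = -1, EW = 0, WW = 1)
geno_h <- c(EE = 0, EW = 1, WW = 0)

canonical_pair_coefs <- c("a1", "d1", "a2", "d2", "iaa", "iad", "ida", "idd")

# Linear-combination weights (over the 8 pair coefficients) of the
# genotypic value for genotypes (g1, g2)
gv_weights <- function(g1, g2) {
  s1 <- geno_s[g1]; h1 <- geno_h[g1]; s2 <- geno_s[g2]; h2 <- geno_h[g2]
  c(a1 = unname(s1), d1 = unname(h1), a2 = unname(s2), d2 = unname(h2),
    iaa = unname(s1 * s2), iad = unname(s1 * h2), ida = unname(h1 * s2),
    idd = unname(h1 * h2))
}

#' Genotypic values of a two-locus model
#'
#' The nine genotypic values, relative to the mean of the four
#' double-homozygote classes, computed from the 8 genetic coefficients of
#' the two-locus model (e.g. the WW/WW class equals a1' + a2' + iaa).
#'
#' @param coef Named vector with elements `a1`, `d1`, `a2`, `d2`, `iaa`,
#'   `iad`, `ida`, `idd` (missing/NA coefficients are an error).
#' @return data.frame `g1`, `g2` (EE/EW/WW), `value`; attribute `weights`
#'   holds the 9 x 8 linear-combination matrix over the coefficients.
#' @export
genotypic_values <- function(coef) {
  coef <- coef[canonical_pair_coefs]
  if (anyNA(coef)) stop("missing coefficient(s): ",
                        paste(canonical_pair_coefs[is.na(coef)], collapse = ", "))
  gg <- expand.grid(g1 = c("EE", "EW", "WW"), g2 = c("EE", "EW", "WW"),
                    stringsAsFactors = FALSE)
  W <- t(vapply(seq_len(nrow(gg)),
                function(k) gv_weights(gg$g1[k], gg$g2[k]), numeric(8L)))
  colnames(W) <- canonical_pair_coefs
  out <- data.frame(g1 = gg$g1, g2 = gg$g2,
                    value = as.numeric(W %*% coef))
  attr(out, "weights") <- W
  out
}

# Weight vectors (over the 8 pair coefficients) of the 12 conditional
# effects: a_i(X) and d_i(X) for each locus i and partner genotype X.
conditional_effect_weights <- function() {
  eff <- expand.grid(locus = 1:2, bg = c("WW", "EW", "EE"),
                     kind = c("a", "d"), stringsAsFactors = FALSE)
  eff <- eff[order(eff$locus, eff$bg, eff$kind), ]
  W <- matrix(0, nrow(eff), 8L,
              dimnames = list(NULL, canonical_pair_coefs))
  for (k in seq_len(nrow(eff))) {
    s <- geno_s[eff$bg[k]]; h <- geno_h[eff$bg[k]]
    if (eff$locus[k] == 1L) {
      if (eff$kind[k] == "a") {        # a1(X) = a1' + iaa*s(X) + iad*h(X)
        W[k, "a1"] <- 1; W[k, "iaa"] <- s; W[k, "iad"] <- h
      } else {                          # d1(X) = d1' + ida*s(X) + idd*h(X)
        W[k, "d1"] <- 1; W[k, "ida"] <- s; W[k, "idd"] <- h
      }
    } else {
      if (eff$kind[k] == "a") {        # a2(X) = a2' + iaa*s(X) + ida*h(X)
        W[k, "a2"] <- 1; W[k, "iaa"] <- s; W[k, "ida"] <- h
      } else {                          # d2(X) = d2' + iad*s(X) + idd*h(X)
        W[k, "d2"] <- 1; W[k, "iad"] <- s; W[k, "idd"] <- h
      }
    }
  }
  list(effects = eff, W = W)
}

#' Background-conditional additive and dominance effects of a pair
#'
#' The 12 effects (additive and dominance of each locus, conditional on the
#' three genotypes at the partner locus) as linear combinations of the
#' two-locus coefficients, e.g. a1(WW) = a1' + iaa. These equal the
#' effects measured from the genotypic values in the single-locus way
#' (a1(X) = (G_WW,X - G_EE,X)/2 etc.).
#'
#' @param coef Named coefficient vector (see [genotypic_values()]).
#' @param V Optional 8 x 8 coefficient covariance (rows/cols named as
#'   `coef`) for standard errors.
#' @param denom Optional standardisation divisor (the base model's residual
#'   standard deviation).
#' @return data.frame `locus`, `bg`, `kind`, `estimate`, and where
#'   available `se`, `p` (normal t test) and `std_estimate`; attribute
#'   `weights` holds the 12 x 8 combination matrix.
#' @export
conditional_effects <- function(coef, V = NULL, denom = NULL) {
  coef <- coef[canonical_pair_coefs]
  if (anyNA(coef)) stop("missing coefficient(s)")
  cw <- conditional_effect_weights()
  out <- cw$effects
  out$estimate <- as.numeric(cw$W %*% coef)
  if (!is.null(V)) {
    V <- V[canonical_pair_coefs, canonical_pair_coefs]
    out$se <- vapply(seq_len(nrow(cw$W)),
                     function(k) effect_se(cw$W[k, ], V), 0)
    out$p <- 2 * stats::pnorm(abs(out$estimate / out$se), lower.tail = FALSE)
  }
  if (!is.null(denom)) out$std_estimate <- out$estimate / denom
  attr(out, "weights") <- cw$W
  out
}

#' Standard error of a linear combination of model coefficients
#'
#' @param w Named weight vector.
#' @param V Coefficient covariance matrix covering `names(w)`.
#' @return sqrt(w' V w).
#' @export
effect_se <- function(w, V) {
  nm <- names(w)[w != 0]
  if (!all(nm %in% rownames(V))) stop("covariance does not cover: ",
                                      paste(setdiff(nm, rownames(V)),
                                            collapse = ", "))
  v <- as.numeric(t(w[nm]) %*% V[nm, nm, drop = FALSE] %*% w[nm])
  if (v < -1e-12) stop("covariance not positive semi-definite on the effect")
  sqrt(max(v, 0))
}

#' Holm correction for a family of conditional effects
#'
#' Step-down Holm adjustment of the raw p-values; the family is the 12
#' effects of one pair at level 0.05, or the combined effect set of the two
#' pairs sharing a locus at level 0.1.
#'
#' @param p Raw p-values.
#' @param alpha Family-wise level.
#' @return Logical significance flags (same order as `p`).
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") < alpha
}

# Map the model columns of pair k in a full_model_fit to the canonical
# coefficient names; returns named character vector canonical -> column.
pair_columns <- function(fm, k) {
  p <- fm$spec$pairs[[k]]
  l1 <- fm$colmap$locus[[as.character(p$l1)]]
  l2 <- fm$colmap$locus[[as.character(p$l2)]]
  ints <- fm$colmap$pair[[k]]
  stats::setNames(c(l1, l2, ints), canonical_pair_coefs)
}

#' Conditional effects of one pair in a fitted full model
#'
#' Extracts the pair's 8 coefficients and their covariance from the REML
#' fit, computes the 12 background-conditional effects with standard
#' errors, tests them (t tests with the large-df normal approximation),
#' applies the Holm correction within the pair, and standardises by the
#' base model's residual standard deviation. Effects nominally significant
#' at p < `nominal_alpha` before correction are flagged separately and
#' never promoted.
#'
#' @param fm A `full_model_fit`.
#' @param k Pair index in `fm$spec$pairs`.
#' @param base_sd Residual standard deviation of the trait's base model.
#' @param alpha Holm family-wise level (default 0.05).
#' @param nominal_alpha Nominal flag level (default 0.025).
#' @return data.frame as [conditional_effects()] plus `significant`
#'   (Holm-corrected) and `nominal` flags.
#' @export
pair_effects <- function(fm, k, base_sd, alpha = 0.05, nominal_alpha = 0.025) {
  cols <- pair_columns(fm, k)
  if (!all(cols %in% names(fm$beta)))
    stop("pair ", k, " has aliased coefficients (",
         paste(setdiff(cols, names(fm$beta)), collapse = ", "),
         "): effects are not identifiable")
  coef <- stats::setNames(fm$beta[cols], names(cols))
  V <- fm$V[cols, cols]
  dimnames(V) <- list(names(cols), names(cols))
  eff <- conditional_effects(coef, V, denom = base_sd)
  eff$significant <- holm_adjust(eff$p, alpha)
  eff$nominal <- !eff$significant & eff$p < nominal_alpha
  eff
}

#' Conditional effects for a locus interacting with two others
#'
#' For two pairs sharing a locus, the shared locus's additive and dominance
#' effects are conditional on the genotype *pair* at both partners (9
#' combinations), while each partner's effects depend only on the shared
#' locus's genotype (computed as in the two-locus case). All 30 effects are
#' tested together with a Holm correction at level `alpha` (default 0.1,
#' reflecting that terms from two pairs are assessed).
#'
#' @param fm A `full_model_fit`.
#' @param k1,k2 Indices of the two pairs sharing a locus.
#' @param base_sd Base-model residual standard deviation.
#' @param alpha Family-wise level for the combined set (default 0.1).
#' @return data.frame `locus` (lid), `bg` (partner genotype or genotype
#'   pair), `kind`, `estimate`, `se`, `p`, `std_estimate`, `significant`.
#' @export
triple_effects <- function(fm, k1, k2, base_sd, alpha = 0.1) {
  p1 <- fm$spec$pairs[[k1]]; p2 <- fm$spec$pairs[[k2]]
  shared <- intersect(c(p1$l1, p1$l2), c(p2$l1, p2$l2))
  if (length(shared) != 1L)
    stop("pairs must share exactly one locus")
  shared <- shared[1L]
  gts <- c("EE", "EW", "WW")
  rows <- list()
  # orientation helpers: weights of (a_shared, d_shared) given partner
  # genotype, and of the partner's effects given the shared genotype
  pair_w <- function(k, pp) {
    cols <- pair_columns(fm, k)
    shared_first <- pp$l1 == shared
    list(cols = cols, shared_first = shared_first)
  }
  w1 <- pair_w(k1, p1); w2 <- pair_w(k2, p2)
  add_row <- function(locus, bg, kind, wvec) {
    est <- sum(fm$beta[names(wvec)] * wvec)
    se <- effect_se(wvec, fm$V)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus = locus, bg = bg, kind = kind, estimate = est, se = se,
      p = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
      std_estimate = est / base_sd)
  }
  # contribution of pair k's interaction terms to the shared locus's
  # additive/dominance effect given the partner's genotype
  int_w <- function(wk, kind, g) {
    cols <- wk$cols
    s <- geno_s[g]; h <- geno_h[g]
    w <- stats::setNames(numeric(2L), c("x", "y"))
    if (wk$shared_first) {
      if (kind == "a") stats::setNames(c(s, h), cols[c("iaa", "iad")])
      else             stats::setNames(c(s, h), cols[c("ida", "idd")])
    } else {
      if (kind == "a") stats::setNames(c(s, h), cols[c("iaa", "ida")])
      else             stats::setNames(c(s, h), cols[c("iad", "idd")])
    }
  }
  main_col <- function(wk, kind) {
    cols <- wk$cols
    if (wk$shared_first) unname(cols[if (kind == "a") "a1" else "d1"])
    else unname(cols[if (kind == "a") "a2" else "d2"])
  }
  # shared locus: 9 partner-genotype combinations x (a, d)
  for (g1 in gts) for (g2 in gts) for (kind in c("a", "d")) {
    w <- c(stats::setNames(1, main_col(w1, kind)),
           int_w(w1, kind, g1), int_w(w2, kind, g2))
    w <- tapply(w, names(w), sum)  # collapse duplicate columns
    add_row(shared, paste0(g1, g2), kind, w)
  }
  # partners: effects depend only on the shared locus's genotype
  partner_rows <- function(k, wk, pp) {
    partner <- if (wk$shared_first) pp$l2 else pp$l1
    cols <- wk$cols
    for (g in gts) for (kind in c("a", "d")) {
      s <- geno_s[g]; h <- geno_h[g]
      if (wk$shared_first) {
        # partner is locus 2 of pair k: a2(X) = a2' + iaa s + ida h
        w <- if (kind == "a")
          stats::setNames(c(1, s, h), cols[c("a2", "iaa", "ida")])
        else
          stats::setNames(c(1, s, h), cols[c("d2", "iad", "idd")])
      } else {
        w <- if (kind == "a")
          stats::setNames(c(1, s, h), cols[c("a1", "iaa", "iad")])
        else
          stats::setNames(c(1, s, h), cols[c("d1", "ida", "idd")])
      }
      add_row(partner, g, kind, w)
    }
  }
  partner_rows(k1, w1, p1)
  partner_rows(k2, w2, p2)
  out <- do.call(rbind, rows)
  out$significant <- holm_adjust(out$p, alpha)
  rownames(out) <- NULL
  out
}

#' Percentage residual variance explained by a set of model columns
#'
#' Computed as the increase in penalised residual sum of squares (PSS) when
#' the columns are removed from the final model, divided by the PSS of the
#' base model, times 100.
#'
#' @param fm A `full_model_fit`.
#' @param cols Model column names to remove (e.g. a locus's A/D columns, a
#'   pair's interaction columns, or all locus columns).
#' @param pss_base PSS of the trait's base model.
#' @return Percentage (>= 0 up to numerical tolerance; clearly negative
#'   values signal a refit failure and error).
#' @export
variance_explained <- function(fm, cols, pss_base) {
  fit0 <- refit_without(fm, cols)
  pct <- 100 * (fit0$pss - fm$pss) / pss_base
  if (pct < -1e-6 * 100) stop("negative variance explained: refit failure?")
  max(pct, 0)
}

# Refit the full model without the named columns (same data; the columns
# were materialised by fit_full_model).
refit_without <- function(fm, cols) {
  spec <- fm$spec
  all_terms <- c(spec$fixed_terms,
                 unlist(fm$colmap$locus, use.names = FALSE),
                 unlist(fm$colmap$pair, use.names = FALSE))
  keep <- setdiff(all_terms, cols)
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(spec$response, "~", rhs,
                                 "+ (1 |", spec$mother, ")"))
  fit <- lme4::lmer(fml, data = fm$data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  list(fit = fit, pss = unname(fit@devcomp$cmp["pwrss"]),
       reml_loglik = as.numeric(stats::logLik(fit)))
}

# All locus-related columns of a full model fit
all_locus_columns <- function(fm) {
  c(unlist(fm$colmap$locus, use.names = FALSE),
    unlist(fm$colmap$pair, use.names = FALSE))
}

#' Fit and test the independent effects model
#'
#' REML fit of the raw phenotype on the explanatory variables, the maternal
#' random effect and per-locus additive/dominance terms only (no
#' interactions), for the QTL set from the independent analysis. Loci are
#' tested at p < `alpha_joint` (joint F) or p < `alpha_coef` (either
#' coefficient); significant coefficients are standardised by the base
#' model's residual standard deviation.
#'
#' @inheritParams assemble_model
#' @param grid The `ad_grid`.
#' @param base_sd Base-model residual standard deviation.
#' @param alpha_joint,alpha_coef Test levels (0.05 / 0.025).
#' @return list with the `full_model_fit` (`fit`) and `effects`
#'   (data.frame `chr`, `pos`, `p_joint`, `a`, `se_a`, `p_a`, `std_a`, `d`,
#'   `se_d`, `p_d`, `std_d`, `significant`).
#' @export
independent_effects_model <- function(data, response, fixed_terms, mother,
                                      qtl, grid, base_sd,
                                      alpha_joint = 0.05, alpha_coef = 0.025) {
  spec <- assemble_model(data, response, fixed_terms, mother, qtl,
                         pairs = NULL)
  fm <- fit_full_model(spec, grid)
  eff <- NULL
  for (l in spec$indep) {
    cols <- fm$colmap$locus[[as.character(l)]]
    jt <- wald_joint(fm, cols)
    pc <- wald_t(fm, cols)
    se <- sqrt(diag(fm$V)[cols])
    row <- spec$loci[spec$loci$lid == l, ]
    eff <- rbind(eff, data.frame(
      chr = row$chr, pos = row$pos, p_joint = jt$p,
      a = unname(fm$beta[cols[1L]]), se_a = unname(se[1L]),
      p_a = unname(pc[1L]), std_a = unname(fm$beta[cols[1L]] / base_sd),
      d = unname(fm$beta[cols[2L]]), se_d = unname(se[2L]),
      p_d = unname(pc[2L]), std_d = unname(fm$beta[cols[2L]] / base_sd),
      significant = jt$p < alpha_joint || any(pc < alpha_coef)))
  }
  if (is.null(eff))
    eff <- data.frame(chr = character(), pos = numeric(), p_joint = numeric(),
                      a = numeric(), se_a = numeric(), p_a = numeric(),
                      std_a = numeric(), d = numeric(), se_d = numeric(),
                      p_d = numeric(), std_d = numeric(),
                      significant = logical())
  list(fit = fm, effects = eff)
}

#' Plot data for a two-locus epistasis figure
#'
#' Long-format table of standardised genotypic values: genotype at the
#' first locus on the x-axis (ordered EE, EW, WW), one line per genotype at
#' the second locus. Parallel lines correspond to all interaction
#' coefficients being zero.
#'
#' @param gv Result of [genotypic_values()].
#' @param denom Standardisation divisor (base-model residual SD); 1 leaves
#'   values unstandardised.
#' @return data.frame `g1` (ordered factor EE < EW < WW), `g2`, `value`.
#' @export
epistasis_plot_data <- function(gv, denom = 1) {
  out <- data.frame(g1 = factor(gv$g1, levels = c("EE", "EW", "WW"),
                                ordered = TRUE),
                    g2 = factor(gv$g2, levels = c("EE", "EW", "WW")),
                    value = gv$value / denom)
  out[order(out$g2, out$g1), ]
}

#' Plot a two-locus epistasis figure
#'
#' Standardised genotypic values against the genotype at the first locus,
#' lines distinguished by the genotype at the second locus.
#'
#' @param plot_data Result of [epistasis_plot_data()].
#' @param title Optional plot title.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_epistasis <- function(plot_data, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(x = .data$g1, y = .data$value,
                               group = .data$g2, linetype = .data$g2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Genotype at locus 1", y = "Standardised genotypic value",
                  linetype = "Locus 2", title = title) +
    ggplot2::theme_classic()
}
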