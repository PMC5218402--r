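# Assembly and simplification of the full genetic model: raw phenotype on
# explanatory variables, a maternal random effect, additive/dominance terms
# for independent loci and the full 8-coefficient parameterisation for each
# epistatic pair, fitted by REML. Inference on locus terms reuses the
# chi-square approximation of d x F used for the explanatory variables.

#' Match an epistatic pair locus against the putative-QTL list
#'
#' A pair locus and a putative QTL on the same chromosome are taken to be
#' the same locus when they are within `match_dist` cM of each other or the
#' pair locus lies inside the QTL's span; the epistatic-analysis position is
#' then the one fitted.
#'
#' @param chr,pos Pair-locus position.
#' @param qtl Putative-QTL table (`chr`, `pos`, `span_lo`, `span_hi`).
#' @param match_dist Matching distance in cM (default 20).
#' @return Row index into `qtl` of the match, or `NA` if none. With several
#'   matches, the nearest.
#' @export
match_loci <- function(chr, pos, qtl, match_dist = 20) {
  if (is.null(qtl) || !nrow(qtl)) return(NA_integer_)
  same <- which(qtl$chr == chr)
  if (!length(same)) return(NA_integer_)
  d <- abs(qtl$pos[same] - pos)
  hit <- d <= match_dist |
    (pos >= qtl$span_lo[same] & pos <= qtl$span_hi[same])
  if (!any(hit)) return(NA_integer_)
  same[hit][which.min(d[hit])]
}

#' Assemble the full-model specification from scan results
#'
#' Putative QTL and putative epistatic pairs are combined: a pair locus
#' matching a putative QTL (within 20 cM or inside its span) replaces that
#' QTL, keeping the epistatic position; unmatched putative QTL enter as
#' independent loci; similar positions amongst different pairs are kept as
#' separate loci (they are merged at the end of simplification).
#'
#' @param data data.frame with the raw phenotype, covariates and mother.
#' @param response,fixed_terms,mother As in [fit_base_model()].
#' @param qtl Putative-QTL table from [forward_search()].
#' @param pairs Putative epistatic pairs from [find_epistatic_pairs()]
#'   (columns `chr1`, `pos1`, `chr2`, `pos2`), or NULL.
#' @param match_dist Locus-matching distance (cM).
#' @return A `full_model_spec`: list with the data/model fields plus `loci`
#'   (data.frame `lid`, `chr`, `pos`, `qtl_pos`), `indep` (lids), and
#'   `pairs` (list of `list(l1, l2, added)`).
#' @export
assemble_model <- function(data, response, fixed_terms, mother, qtl,
                           pairs = NULL, match_dist = 20) {
  loci <- data.frame(lid = integer(), chr = character(), pos = numeric(),
                     qtl_pos = numeric(), stringsAsFactors = FALSE)
  add_locus <- function(chr, pos, qtl_pos = NA_real_) {
    lid <- nrow(loci) + 1L
    loci <<- rbind(loci, data.frame(lid = lid, chr = as.character(chr),
                                    pos = pos, qtl_pos = qtl_pos))
    lid
  }
  matched_qtl <- integer()
  pair_list <- list()
  if (!is.null(pairs) && nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    lids <- integer(2L)
    for (side in 1:2) {
      chr <- pairs[[paste0("chr", side)]][k]
      pos <- pairs[[paste0("pos", side)]][k]
      m <- match_loci(chr, pos, qtl, match_dist)
      qp <- NA_real_
      if (!is.na(m)) {
        matched_qtl <- union(matched_qtl, m)
        qp <- qtl$pos[m]
      }
      lids[side] <- add_locus(chr, pos, qp)
    }
    pair_list[[k]] <- list(l1 = lids[1L], l2 = lids[2L], added = k)
  }
  indep <- integer()
  if (!is.null(qtl) && nrow(qtl)) for (r in setdiff(seq_len(nrow(qtl)),
                                                    matched_qtl))
    indep <- c(indep, add_locus(qtl$chr[r], qtl$pos[r]))
  spec <- list(data = data, response = response, fixed_terms = fixed_terms,
               mother = mother, loci = loci, indep = indep,
               pairs = pair_list)
  class(spec) <- "full_model_spec"
  spec
}

# Locus ids actually present in the model (independent or in a pair)
active_lids <- function(spec) {
  union(spec$indep, unlist(lapply(spec$pairs, function(p) c(p$l1, p$l2))))
}

# Canonicalize a spec against a grid: loci resolving to the same grid
# column are one locus (identical design columns), and pairs over the same
# locus set are one pair. Prevents rank-deficient fits from bookkeeping
# duplicates; the deliberate 20 cM merge decisions stay in simplify_model.
canonicalize_spec <- function(spec, grid) {
  lids <- sort(active_lids(spec))
  gi <- vapply(lids, function(l) {
    row <- spec$loci[spec$loci$lid == l, ]
    grid_index(grid, row$chr, row$pos)
  }, 0L)
  for (k in seq_along(lids)) {
    first <- lids[match(gi[k], gi)]
    if (first != lids[k]) spec <- swap_locus(spec, lids[k], first)
  }
  spec$indep <- unique(spec$indep)
  if (length(spec$pairs) > 1L) {
    keys <- vapply(spec$pairs, function(p)
      paste(sort(c(p$l1, p$l2)), collapse = "_"), "")
    spec$pairs <- spec$pairs[!duplicated(keys)]
  }
  # a locus fitted inside a pair must not also appear as independent
  in_pair <- unlist(lapply(spec$pairs, function(p) c(p$l1, p$l2)))
  spec$indep <- setdiff(spec$indep, in_pair)
  spec
}

#' Fit the full genetic model by REML
#'
#' Builds locus A/D columns (from the grid position nearest each locus) and
#' pairwise interaction columns, and fits the raw phenotype on the fixed
#' explanatory terms, all locus terms and the maternal random effect with
#' lme4. The penalised residual sum of squares (PSS) is the penalised
#' weighted RSS at the REML solution.
#'
#' @param spec A `full_model_spec`.
#' @param grid The `ad_grid` (individuals matched by id).
#' @return A `full_model_fit`: list with the lme4 `fit`, fixed-effect
#'   estimates `beta` and covariance `V`, `pss`, `reml_loglik`, `sigma2`,
#'   `n`, the column bookkeeping `colmap`, and `spec`.
#' @export
fit_full_model <- function(spec, grid) {
  spec <- canonicalize_spec(spec, grid)
  d <- spec$data
  ridx <- match(d$id, grid$ids)
  if (anyNA(ridx)) stop("individuals absent from the A/D grid: ",
                        paste(utils::head(d$id[is.na(ridx)]), collapse = ", "))
  lids <- sort(active_lids(spec))
  colmap <- list(locus = list(), pair = list())
  locus_terms <- character()
  for (l in lids) {
    row <- spec$loci[spec$loci$lid == l, ]
    gi <- grid_index(grid, row$chr, row$pos)
    an <- paste0("A_", l); dn <- paste0("D_", l)
    d[[an]] <- grid$A[ridx, gi]
    d[[dn]] <- grid$D[ridx, gi]
    colmap$locus[[as.character(l)]] <- c(an, dn)
    locus_terms <- c(locus_terms, an, dn)
  }
  pair_terms <- character()
  for (k in seq_along(spec$pairs)) {
    p <- spec$pairs[[k]]
    a1 <- d[[paste0("A_", p$l1)]]; d1 <- d[[paste0("D_", p$l1)]]
    a2 <- d[[paste0("A_", p$l2)]]; d2 <- d[[paste0("D_", p$l2)]]
    nm <- paste0(c("Iaa_", "Iad_", "Ida_", "Idd_"), k)
    d[[nm[1L]]] <- a1 * a2; d[[nm[2L]]] <- a1 * d2
    d[[nm[3L]]] <- d1 * a2; d[[nm[4L]]] <- d1 * d2
    colmap$pair[[k]] <- nm
    pair_terms <- c(pair_terms, nm)
  }
  rhs_terms <- c(spec$fixed_terms, locus_terms, pair_terms)
  rhs <- if (length(rhs_terms)) paste(rhs_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(spec$response, "~", rhs,
                                 "+ (1 |", spec$mother, ")"))
  d[[spec$mother]] <- factor(d[[spec$mother]])
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(fit = fit, beta = lme4::fixef(fit),
              V = as.matrix(stats::vcov(fit)),
              pss = unname(fit@devcomp$cmp["pwrss"]),
              reml_loglik = as.numeric(stats::logLik(fit)),
              sigma2 = vc$vcov[vc$grp == "Residual"],
              n = nrow(d), colmap = colmap, data = d, spec = spec)
  class(out) <- "full_model_fit"
  out
}

# Wald joint test of a set of fixed-effect columns, with the chi-square
# approximation of d x F (large denominator df).
wald_joint <- function(fm, cols) {
  cols <- intersect(cols, names(fm$beta))
  dd <- length(cols)
  if (!dd) return(list(F = 0, df = 0, p = 1))
  b <- fm$beta[cols]
  V <- fm$V[cols, cols, drop = FALSE]
  Fstat <- as.numeric(crossprod(b, solve(V, b))) / dd
  list(F = Fstat, df = dd,
       p = stats::pchisq(dd * Fstat, dd, lower.tail = FALSE))
}

# Per-coefficient z tests (large-df normal approximation)
wald_t <- function(fm, cols) {
  cols <- intersect(cols, names(fm$beta))
  se <- sqrt(diag(fm$V)[cols])
  z <- fm$beta[cols] / se
  stats::setNames(2 * stats::pnorm(abs(z), lower.tail = FALSE), cols)
}

# Significance of one pair's interaction set in the full model
pair_significance <- function(fm, k, alpha_joint = 0.05, alpha_coef = 0.0125) {
  cols <- fm$colmap$pair[[k]]
  jt <- wald_joint(fm, cols)
  pc <- wald_t(fm, cols)
  list(p_joint = jt$p, p_coef = pc,
       pass = jt$p < alpha_joint || any(pc < alpha_coef))
}

# Replace locus l_old with l_new everywhere in spec's pairs/indep
swap_locus <- function(spec, l_old, l_new) {
  spec$pairs <- lapply(spec$pairs, function(p) {
    if (p$l1 == l_old) p$l1 <- l_new
    if (p$l2 == l_old) p$l2 <- l_new
    p
  })
  spec$indep[spec$indep == l_old] <- l_new
  spec
}

# Refit after changing one locus's position; returns REML log-likelihood
loglik_at <- function(spec, grid, lid, pos) {
  spec$loci$pos[spec$loci$lid == lid] <- pos
  fit_full_model(spec, grid)$reml_loglik
}

#' Simplify the full genetic model
#'
#' Pairs whose interaction set is not significant (joint p >= `alpha_joint`
#' and all coefficient p >= `alpha_coef`) are removed sequentially, worst
#' (highest joint p) first, refitting and retesting after each removal;
#' ties are broken by removing the pair added later. A removed pair's locus
#' that had matched a putative QTL stays in the model as an independent
#' locus unless a similar position (within `match_dist` cM) remains in a
#' surviving pair; if the pair position and the putative-QTL position
#' differ, both are compared in the current model and the one with the
#' higher REML log-likelihood kept (ties keep the epistatic position).
#' After convergence, loci within `match_dist` cM of each other in
#' different surviving pairs are merged into one locus, again choosing the
#' position by log-likelihood.
#'
#' @param spec A `full_model_spec`.
#' @param grid The `ad_grid`.
#' @param alpha_joint,alpha_coef Interaction significance levels.
#' @param match_dist Merge/matching distance in cM (default 20).
#' @param max_iter Safety iteration limit.
#' @return The final `full_model_fit`; its `spec` holds the surviving
#'   loci/pairs.
#' @export
simplify_model <- function(spec, grid, alpha_joint = 0.05,
                           alpha_coef = 0.0125, match_dist = 20,
                           max_iter = 50) {
  for (it in seq_len(max_iter)) {
    fm <- fit_full_model(spec, grid)
    spec <- fm$spec
    if (!length(spec$pairs)) break
    sig <- lapply(seq_along(spec$pairs), function(k) pair_significance(
      fm, k, alpha_joint, alpha_coef))
    fails <- which(!vapply(sig, `[[`, TRUE, "pass"))
    if (!length(fails)) break
    pj <- vapply(sig, `[[`, 0, "p_joint")
    worst_p <- max(pj[fails])
    cand <- fails[pj[fails] >= worst_p - 1e-12]
    added <- vapply(spec$pairs[cand], `[[`, 0L, "added")
    drop_k <- cand[which.max(added)]  # later-added on ties
    dropped <- spec$pairs[[drop_k]]
    spec$pairs[[drop_k]] <- NULL
    fm <- NULL
    for (l in c(dropped$l1, dropped$l2)) {
      row <- spec$loci[spec$loci$lid == l, ]
      still_used <- l %in% active_lids(spec)
      if (still_used) next
      if (is.na(row$qtl_pos)) next  # never matched a putative QTL: drop
      # similar position remaining in a surviving pair?
      rem <- setdiff(active_lids(spec), spec$indep)
      similar <- any(spec$loci$chr[spec$loci$lid %in% rem] == row$chr &
                     abs(spec$loci$pos[spec$loci$lid %in% rem] - row$pos) <=
                       match_dist)
      if (similar) next
      spec$indep <- c(spec$indep, l)
      if (abs(row$qtl_pos - row$pos) > 1e-9) {
        ll_epi <- loglik_at(spec, grid, l, row$pos)
        ll_qtl <- loglik_at(spec, grid, l, row$qtl_pos)
        if (ll_qtl > ll_epi + 1e-9)
          spec$loci$pos[spec$loci$lid == l] <- row$qtl_pos
      }
    }
    if (it == max_iter) stop("simplification did not converge in ",
                             max_iter, " iterations")
  }
  # merge pair-loci within match_dist across different pairs
  repeat {
    pls <- setdiff(active_lids(spec), numeric(0))
    pls <- unique(unlist(lapply(spec$pairs, function(p) c(p$l1, p$l2))))
    merged <- FALSE
    if (length(pls) > 1L) {
      li <- spec$loci[spec$loci$lid %in% pls, ]
      for (a in seq_len(nrow(li) - 1L)) {
        for (b in (a + 1L):nrow(li)) {
          in_same_pair <- any(vapply(spec$pairs, function(p)
            setequal(c(p$l1, p$l2), c(li$lid[a], li$lid[b])), TRUE))
          if (in_same_pair) next
          if (li$chr[a] == li$chr[b] &&
              abs(li$pos[a] - li$pos[b]) <= match_dist &&
              abs(li$pos[a] - li$pos[b]) > 1e-9) {
            sp_a <- swap_locus(spec, li$lid[b], li$lid[a])
            ll_a <- fit_full_model(sp_a, grid)$reml_loglik
            sp_b <- swap_locus(spec, li$lid[a], li$lid[b])
            ll_b <- fit_full_model(sp_b, grid)$reml_loglik
            spec <- if (ll_a >= ll_b) sp_a else sp_b
            merged <- TRUE
            break
          } else if (li$chr[a] == li$chr[b] &&
                     abs(li$pos[a] - li$pos[b]) <= 1e-9 &&
                     li$lid[a] != li$lid[b]) {
            spec <- swap_locus(spec, li$lid[b], li$lid[a])
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  fit_full_model(spec, grid)
}

#' Test independent loci in the final model
#'
#' Loci not in any retained pair are kept as reported independent QTL when
#' the joint (a, d) test has p < `alpha_joint` or either coefficient's t
#' test has p < `alpha_coef`; the rest are dropped and the model refitted.
#'
#' @param fm A `full_model_fit` (post-simplification).
#' @param grid The `ad_grid`.
#' @param alpha_joint Joint-F level (default 0.05).
#' @param alpha_coef Per-coefficient level (default 0.025).
#' @return The refitted `full_model_fit`; attribute `independent_qtl` is a
#'   data.frame of the surviving loci with their test p-values.
#' @export
test_independent_loci <- function(fm, grid, alpha_joint = 0.05,
                                  alpha_coef = 0.025) {
  spec <- fm$spec
  in_pair <- unique(unlist(lapply(spec$pairs, function(p) c(p$l1, p$l2))))
  only_indep <- setdiff(spec$indep, in_pair)
  keep <- data.frame(lid = integer(), chr = character(), pos = numeric(),
                     p_joint = numeric(), p_a = numeric(), p_d = numeric())
  for (l in only_indep) {
    cols <- fm$colmap$locus[[as.character(l)]]
    jt <- wald_joint(fm, cols)
    pc <- wald_t(fm, cols)
    ok <- jt$p < alpha_joint || any(pc < alpha_coef)
    if (ok) {
      row <- spec$loci[spec$loci$lid == l, ]
      keep <- rbind(keep, data.frame(lid = l, chr = row$chr, pos = row$pos,
                                     p_joint = jt$p,
                                     p_a = unname(pc[1L]),
                                     p_d = unname(pc[length(pc)])))
    }
  }
  spec$indep <- c(intersect(spec$indep, in_pair), keep$lid)
  out <- fit_full_model(spec, grid)
  attr(out, "independent_qtl") <- keep
  out
}

#' Cross-age pointwise testing of epistatic pairs
#'
#' Each epistatic pair detected for any trait is added to every other
#' trait's final model (removing any matching independent locus while
#' testing) and its interaction set tested at the usual criteria; pairs
#' passing individually are then, if there are several, evaluated jointly.
#' Significant additions are retained and labelled pointwise-significant.
#'
#' @param fits Named list (by trait) of `full_model_fit`s.
#' @param grids Named list (by trait) of `ad_grid`s (or a single grid).
#' @param alpha_joint,alpha_coef Interaction test levels.
#' @param match_dist Matching distance (cM).
#' @return The updated named list of fits; each gains an attribute
#'   `pointwise` (data.frame of the added pairs, zero rows if none).
#' @export
crossage_pointwise <- function(fits, grids, alpha_joint = 0.05,
                               alpha_coef = 0.0125, match_dist = 20) {
  get_grid <- function(tr) if (inherits(grids, "ad_grid")) grids else grids[[tr]]
  # collect detected pairs with their source trait
  all_pairs <- list()
  for (tr in names(fits)) {
    spec <- fits[[tr]]$spec
    for (p in spec$pairs) {
      r1 <- spec$loci[spec$loci$lid == p$l1, ]
      r2 <- spec$loci[spec$loci$lid == p$l2, ]
      all_pairs[[length(all_pairs) + 1L]] <-
        data.frame(trait = tr, chr1 = r1$chr, pos1 = r1$pos,
                   chr2 = r2$chr, pos2 = r2$pos)
    }
  }
  if (!length(all_pairs)) {
    for (tr in names(fits)) attr(fits[[tr]], "pointwise") <-
        data.frame(trait = character(), chr1 = character(), pos1 = numeric(),
                   chr2 = character(), pos2 = numeric())
    return(fits)
  }
  all_pairs <- unique(do.call(rbind, all_pairs))
  add_pair <- function(spec, pr) {
    lid0 <- max(spec$loci$lid, 0L)
    spec$loci <- rbind(spec$loci,
                       data.frame(lid = lid0 + 1:2,
                                  chr = c(pr$chr1, pr$chr2),
                                  pos = c(pr$pos1, pr$pos2),
                                  qtl_pos = NA_real_))
    # remove matching independent loci while the pair is in the model
    drop <- spec$indep[vapply(spec$indep, function(l) {
      row <- spec$loci[spec$loci$lid == l, ]
      (row$chr == pr$chr1 && abs(row$pos - pr$pos1) <= match_dist) ||
        (row$chr == pr$chr2 && abs(row$pos - pr$pos2) <= match_dist)
    }, TRUE)]
    spec$indep <- setdiff(spec$indep, drop)
    spec$pairs[[length(spec$pairs) + 1L]] <-
      list(l1 = lid0 + 1L, l2 = lid0 + 2L, added = 1000L + length(spec$pairs))
    spec
  }
  for (tr in names(fits)) {
    spec <- fits[[tr]]$spec
    own <- all_pairs$trait == tr
    cand <- all_pairs[!own, , drop = FALSE]
    # skip pairs already represented in this trait's model
    if (nrow(cand) && length(spec$pairs)) {
      present <- vapply(seq_len(nrow(cand)), function(k) {
        any(vapply(spec$pairs, function(p) {
          r1 <- spec$loci[spec$loci$lid == p$l1, ]
          r2 <- spec$loci[spec$loci$lid == p$l2, ]
          (r1$chr == cand$chr1[k] && abs(r1$pos - cand$pos1[k]) <= match_dist &&
             r2$chr == cand$chr2[k] && abs(r2$pos - cand$pos2[k]) <= match_dist) ||
          (r1$chr == cand$chr2[k] && abs(r1$pos - cand$pos2[k]) <= match_dist &&
             r2$chr == cand$chr1[k] && abs(r2$pos - cand$pos1[k]) <= match_dist)
        }, TRUE))
      }, TRUE)
      cand <- cand[!present, , drop = FALSE]
    }
    cand <- unique(cand[, c("chr1", "pos1", "chr2", "pos2")])
    sig_rows <- integer()
    if (nrow(cand)) for (k in seq_len(nrow(cand))) {
      sp <- add_pair(spec, cand[k, ])
      fmk <- fit_full_model(sp, get_grid(tr))
      if (length(fmk$spec$pairs) == length(sp$pairs) &&
          pair_significance(fmk, length(fmk$spec$pairs), alpha_joint,
                            alpha_coef)$pass)
        sig_rows <- c(sig_rows, k)
    }
    if (length(sig_rows) > 1L) {
      # joint evaluation of all individually significant pairs
      sp <- spec
      for (k in sig_rows) sp <- add_pair(sp, cand[k, ])
      fmk <- fit_full_model(sp, get_grid(tr))
      if (length(fmk$spec$pairs) == length(sp$pairs)) {
        first_new <- length(sp$pairs) - length(sig_rows) + 1L
        joint_ok <- vapply(seq_along(sig_rows), function(m) pair_significance(
          fmk, first_new + m - 1L, alpha_joint, alpha_coef)$pass, TRUE)
        sig_rows <- sig_rows[joint_ok]
      }
    }
    if (length(sig_rows)) {
      for (k in sig_rows) spec <- add_pair(spec, cand[k, ])
      fits[[tr]] <- fit_full_model(spec, get_grid(tr))
    }
    pw <- cand[sig_rows, , drop = FALSE]
    pw <- if (nrow(pw)) cbind(trait = tr, pw) else
      data.frame(trait = character(), chr1 = character(), pos1 = numeric(),
                 chr2 = character(), pos2 = numeric())
    attr(fits[[tr]], "pointwise") <- pw
  }
  fits
}

#' Unify QTL across ages
#'
#' Loci from all traits' final models, whether independent or epistatic,
#' are grouped per chromosome by single-linkage clustering at `link_dist`
#' cM; each group is one cross-age QTL. Output mirrors a QTL x trait
#' matrix with epistatic flags.
#'
#' @param loci data.frame with columns `trait`, `chr`, `pos`, `epistatic`
#'   (logical), `pointwise` (logical).
#' @param link_dist Single-linkage distance in cM (default 30).
#' @return data.frame `qtl` (label like "Q3.1"), `chr`, `pos`, `trait`,
#'   `epistatic`, `pointwise`, sorted by chromosome and group.
#' @export
unify_across_ages <- function(loci, link_dist = 30) {
  if (!nrow(loci))
    return(data.frame(qtl = character(), chr = character(), pos = numeric(),
                      trait = character(), epistatic = logical(),
                      pointwise = logical()))
  loci <- loci[order(loci$chr, loci$pos, loci$trait), , drop = FALSE]
  out <- list()
  for (cc in unique(loci$chr)) {
    s <- loci[loci$chr == cc, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > link_dist))
    ngrp <- max(grp)
    lab <- if (ngrp == 1L) paste0("Q", cc) else
      paste0("Q", cc, ".", grp)
    s$qtl <- lab
    out[[cc]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("qtl", "chr", "pos", "trait", "epistatic", "pointwise")]
}
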