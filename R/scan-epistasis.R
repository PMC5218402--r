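# Exhaustive two-locus scan of the adjusted phenotype:
# ytilde = mu + a1'A1 + d1'D1 + a2'A2 + d2'D2
#        + iaa*A1A2 + iad*A1D2 + ida*D1A2 + idd*D1D2 + e
# with residual-sum-of-squares (SSE) significance thresholds from
# permutation (genomewide SSE_genome, and locus-specific SSE_specific for
# positions within a putative QTL's span), heat maps of threshold - SSE,
# cluster peak selection with the span-boundary edge-effect rule, and the
# interaction significance test.

# 9-column design for a pair of positions (interactions are elementwise
# products of the A/D variables)
pair_design <- function(A1, D1, A2, D2) {
  cbind(`(Intercept)` = 1, A1 = A1, D1 = D1, A2 = A2, D2 = D2,
        iaa = A1 * A2, iad = A1 * D2, ida = D1 * A2, idd = D1 * D2)
}

#' Two-locus epistatic model fit
#'
#' Ordinary least squares of the adjusted phenotype on the full 9-parameter
#' two-locus model. Aliased (rank-deficient) columns are dropped and
#' recorded; their coefficients are reported as NA.
#'
#' @param y Adjusted phenotype.
#' @param A1,D1,A2,D2 Additive/dominance variables at the two positions.
#' @return A `two_locus_fit`: list with `coef` (named, length 9), `vcov`
#'   (of the kept columns), `SSE`, `SSE_noint` (nested model without
#'   interaction terms), `df_resid`, `n`, `dropped` (aliased column names).
#' @export
two_locus_fit <- function(y, A1, D1, A2, D2) {
  X <- pair_design(A1, D1, A2, D2)
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  Xk <- X[, sort(keep), drop = FALSE]
  qk <- qr(Xk)
  cf_k <- qr.coef(qk, y)
  rss <- sum(qr.resid(qk, y)^2)
  n <- length(y)
  dfr <- n - qk$rank
  s2 <- rss / dfr
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  dimnames(XtXinv) <- list(colnames(Xk), colnames(Xk))
  cf <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  cf[names(cf_k)] <- cf_k
  X0 <- X[, 1:5, drop = FALSE]
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  out <- list(coef = cf, vcov = s2 * XtXinv, SSE = rss, SSE_noint = rss0,
              df_resid = dfr, n = n, sigma2 = s2, dropped = dropped,
              yss = sum((y - mean(y))^2))
  class(out) <- "two_locus_fit"
  out
}

#' Joint and per-coefficient interaction tests for a two-locus fit
#'
#' The four interaction coefficients are tested jointly by an F test
#' (nested-model comparison against the two-locus model without interaction
#' terms) and individually by t tests. The pair passes if the joint p is
#' below `alpha_joint` (default 0.05) or any coefficient p is below
#' `alpha_coef` (default 0.0125 = 0.05/4, the printed per-coefficient
#' Bonferroni level).
#'
#' @param fit A `two_locus_fit`.
#' @param alpha_joint,alpha_coef Significance levels.
#' @return list with `p_joint`, `p_coef` (named, the four interaction
#'   terms), `pass`, and the joint `F` and its dfs.
#' @export
interaction_test <- function(fit, alpha_joint = 0.05, alpha_coef = 0.0125) {
  iterms <- c("iaa", "iad", "ida", "idd")
  kept <- intersect(iterms, setdiff(names(fit$coef)[!is.na(fit$coef)],
                                    fit$dropped))
  q <- length(kept)
  if (q == 0L) {
    return(list(p_joint = 1, p_coef = stats::setNames(rep(NA_real_, 4), iterms),
                pass = FALSE, F = 0, df1 = 0, df2 = fit$df_resid))
  }
  scale0 <- max(fit$yss, .Machine$double.eps)
  delta <- max(0, fit$SSE_noint - fit$SSE)
  if (fit$SSE < 1e-12 * scale0) {
    # numerically perfect fit: the interactions either contribute nothing
    # beyond the main effects (p = 1) or are required for the perfect fit
    Fstat <- if (delta < 1e-12 * scale0) 0 else Inf
  } else {
    Fstat <- max(0, (delta / q) / fit$sigma2)
  }
  p_joint <- stats::pf(Fstat, q, fit$df_resid, lower.tail = FALSE)
  p_coef <- stats::setNames(rep(NA_real_, 4), iterms)
  for (term in kept) {
    se <- sqrt(fit$vcov[term, term])
    tval <- fit$coef[term] / se
    p_coef[term] <- 2 * stats::pt(abs(tval), fit$df_resid, lower.tail = FALSE)
  }
  pass <- (p_joint < alpha_joint) ||
    any(p_coef < alpha_coef, na.rm = TRUE)
  list(p_joint = p_joint, p_coef = p_coef, pass = pass, F = Fstat,
       df1 = q, df2 = fit$df_resid)
}

# Scan lattice: grid column indices at a coarsened step (cM) per chromosome.
scan_positions <- function(grid, step = 5) {
  idx <- integer()
  for (cc in unique(grid$map$chr)) {
    i <- which(grid$map$chr == cc)
    pos <- grid$map$pos[i]
    want <- seq(min(pos), max(pos), by = step)
    idx <- c(idx, i[vapply(want, function(p) which.min(abs(pos - p)), 0L)])
  }
  unique(idx)
}

# Eligible pairs of scan-lattice indices: all between-chromosome pairs plus
# same-chromosome pairs separated by at least min_sep cM.
eligible_pairs <- function(grid, scan_idx, min_sep = 20) {
  k <- length(scan_idx)
  pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  i <- scan_idx[pr[, 1L]]; j <- scan_idx[pr[, 2L]]
  chr_i <- grid$map$chr[i]; chr_j <- grid$map$chr[j]
  sep_ok <- chr_i != chr_j |
    abs(grid$map$pos[i] - grid$map$pos[j]) >= min_sep
  data.frame(i = i[sep_ok], j = j[sep_ok])
}

#' Two-locus pair scan
#'
#' Fits the 9-parameter model at every eligible pair of scan-lattice
#' positions (all between-chromosome pairs, plus within-chromosome pairs
#' separated by at least `min_sep` cM) and records the SSE.
#'
#' @param y Adjusted phenotype aligned to `grid$ids`.
#' @param grid An `ad_grid`.
#' @param step Scan-lattice spacing in cM (default 5; use 1 for the full
#'   grid).
#' @param min_sep Minimum within-chromosome separation (cM).
#' @return data.frame `i`, `j` (grid column indices), `chr1`, `pos1`,
#'   `chr2`, `pos2`, `SSE`.
#' @export
pair_scan <- function(y, grid, step = 5, min_sep = 20) {
  scan_idx <- scan_positions(grid, step)
  pairs <- eligible_pairs(grid, scan_idx, min_sep)
  sse <- pair_sse_matrix(matrix(y, ncol = 1L), grid, pairs)[, 1L]
  data.frame(i = pairs$i, j = pairs$j,
             chr1 = grid$map$chr[pairs$i], pos1 = grid$map$pos[pairs$i],
             chr2 = grid$map$chr[pairs$j], pos2 = grid$map$pos[pairs$j],
             SSE = sse)
}

# SSE of the 9-parameter model for every pair (rows) and every response
# column of Y. The design is fixed under row permutations of Y, so the SSEs
# for all permutations come from one orthonormal-basis projection per pair.
pair_sse_matrix <- function(Y, grid, pairs) {
  yy <- colSums(Y^2)
  out <- matrix(NA_real_, nrow(pairs), ncol(Y))
  for (k in seq_len(nrow(pairs))) {
    X <- pair_design(grid$A[, pairs$i[k]], grid$D[, pairs$i[k]],
                     grid$A[, pairs$j[k]], grid$D[, pairs$j[k]])
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    out[k, ] <- yy - colSums(crossprod(Q, Y)^2)
  }
  out
}

#' Genomewide SSE threshold for the two-locus scan
#'
#' The adjusted phenotypes are permuted as whole rows against the grid; for
#' each permutation the minimum SSE over all eligible pairs is found by
#' exhaustive search on the scan lattice, and SSE_genome is the empirical
#' `alpha` quantile of these minima. Seed the RNG before calling.
#'
#' @inheritParams pair_scan
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genomewide level (default 0.05).
#' @return list with `threshold` (SSE_genome), per-permutation `min_SSE`,
#'   `n_perm`, `alpha`.
#' @export
genomewide_sse_threshold <- function(y, grid, n_perm = 1000, alpha = 0.05,
                                     step = 5, min_sep = 20) {
  scan_idx <- scan_positions(grid, step)
  pairs <- eligible_pairs(grid, scan_idx, min_sep)
  n <- length(y)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  mins <- apply(pair_sse_matrix(Y, grid, pairs), 2L, min)
  list(threshold = unname(stats::quantile(mins, alpha, type = 7)),
       min_SSE = mins, n_perm = n_perm, alpha = alpha)
}

#' Locus-specific SSE threshold for a putative QTL
#'
#' The putative QTL's A and D variables are held fixed while the partner
#' position's A and D rows are permuted (one joint row permutation) and the
#' interaction variables are rebuilt from the permuted partner. For each
#' permutation the minimum SSE over all partner positions is recorded;
#' SSE_specific is the `alpha` quantile of the minima. This corrects the
#' two-locus test for the marginal effect of the detected locus.
#'
#' @inheritParams pair_scan
#' @param qtl_chr,qtl_pos Position of the putative QTL.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Level (default 0.05).
#' @return list with `threshold` (SSE_specific), per-permutation `min_SSE`.
#' @export
locus_specific_sse_threshold <- function(y, grid, qtl_chr, qtl_pos,
                                         n_perm = 1000, alpha = 0.05,
                                         step = 5, min_sep = 20) {
  qi <- grid_index(grid, qtl_chr, qtl_pos)
  Aq <- grid$A[, qi]; Dq <- grid$D[, qi]
  scan_idx <- scan_positions(grid, step)
  partner_ok <- grid$map$chr[scan_idx] != grid$map$chr[qi] |
    abs(grid$map$pos[scan_idx] - grid$map$pos[qi]) >= min_sep
  partners <- scan_idx[partner_ok]
  n <- length(y)
  yy <- sum(y^2)
  mins <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    best <- Inf
    for (j in partners) {
      X <- pair_design(Aq, Dq, grid$A[perm, j], grid$D[perm, j])
      qx <- qr(X)
      Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
      sse <- yy - sum(crossprod(Q, y)^2)
      if (sse < best) best <- sse
    }
    mins[b] <- best
  }
  list(threshold = unname(stats::quantile(mins, alpha, type = 7)),
       min_SSE = mins, n_perm = n_perm, alpha = alpha)
}

#' Apply genomewide and locus-specific thresholds to a pair scan
#'
#' A pair with either position inside a putative QTL's span is tested
#' against that QTL's SSE_specific; when both positions are inside spans,
#' against the lowest applicable SSE_specific. A locus-specific threshold is
#' only ever applied when it is stricter (lower) than SSE_genome; all other
#' pairs are tested against SSE_genome. The heat value is
#' (governing threshold - SSE), non-negative exactly on retained pairs.
#'
#' @param pairs Result of [pair_scan()].
#' @param qtl Putative-QTL table ([call_putative_qtl()]) with an added
#'   `sse_specific` column (may have zero rows).
#' @param sse_genome Genomewide SSE threshold.
#' @return `pairs` with columns `governing`, `heat`, `retained`, and
#'   `heat_genome` (the SSE_genome - SSE map, for edge-effect inspection).
#' @export
apply_thresholds <- function(pairs, qtl, sse_genome) {
  governing <- rep(sse_genome, nrow(pairs))
  if (!is.null(qtl) && nrow(qtl)) {
    for (r in seq_len(nrow(qtl))) {
      if (is.na(qtl$sse_specific[r])) next
      thr <- min(qtl$sse_specific[r], sse_genome)
      inside <- (pairs$chr1 == qtl$chr[r] & pairs$pos1 >= qtl$span_lo[r] &
                   pairs$pos1 <= qtl$span_hi[r]) |
                (pairs$chr2 == qtl$chr[r] & pairs$pos2 >= qtl$span_lo[r] &
                   pairs$pos2 <= qtl$span_hi[r])
      governing[inside] <- pmin(governing[inside], thr)
    }
  }
  pairs$governing <- governing
  pairs$heat <- governing - pairs$SSE
  pairs$retained <- pairs$SSE < governing
  pairs$heat_genome <- sse_genome - pairs$SSE
  pairs
}

# Connected clusters (8-neighbour on the pair-position lattice, within a
# chromosome-pair panel) over an indicator vector `on` aligned to `pairs`.
pair_clusters <- function(pairs, grid, on) {
  lat_row <- match(pairs$i, sort(unique(c(pairs$i, pairs$j))))
  lat_col <- match(pairs$j, sort(unique(c(pairs$i, pairs$j))))
  panel <- paste(pairs$chr1, pairs$chr2, sep = "|")
  cl <- rep(NA_integer_, nrow(pairs))
  nxt <- 0L
  idx_on <- which(on)
  key <- paste(panel, lat_row, lat_col)
  lookup <- stats::setNames(seq_len(nrow(pairs)), key)
  for (s in idx_on) {
    if (!is.na(cl[s])) next
    nxt <- nxt + 1L
    queue <- s
    cl[s] <- nxt
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nk <- paste(panel[cur], lat_row[cur] + dr, lat_col[cur] + dc)
        nb <- lookup[nk]
        if (!is.na(nb) && on[nb] && is.na(cl[nb])) {
          cl[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  cl
}

#' Select candidate pairs: one peak per cluster, with the edge-effect rule
#'
#' Retained pairs are grouped into connected clusters (8-neighbour
#' connectivity on the pair lattice at scan resolution, within each
#' chromosome-pair panel) and the pair with the highest heat value (lowest
#' SSE beneath its governing threshold) is taken from each cluster. Because
#' the locus-specific threshold applies only inside a QTL-span boundary, a
#' fragment of a genomewide-retained region can survive just outside the
#' boundary while the pairs inside were removed; such a cluster is discarded
#' when the adjoining region across the boundary (retained under SSE_genome
#' in the initial map) contains a pair with a lower absolute SSE.
#'
#' @param pairs Result of [apply_thresholds()].
#' @param grid The `ad_grid` used for the scan.
#' @return The selected rows of `pairs` (one per surviving cluster), with
#'   `cluster` id and `edge_discarded` marking clusters removed by the
#'   edge-effect rule (these rows are returned for inspection but flagged).
#' @export
select_cluster_peaks <- function(pairs, grid) {
  if (!any(pairs$retained)) {
    out <- pairs[integer(), ]
    out$cluster <- integer()
    out$edge_discarded <- logical()
    return(out)
  }
  cl <- pair_clusters(pairs, grid, pairs$retained)
  # initial-map regions: retained under the genomewide threshold alone
  init_on <- pairs$heat_genome > 0
  init_cl <- pair_clusters(pairs, grid, init_on)
  res <- list()
  for (g in sort(unique(cl[!is.na(cl)]))) {
    members <- which(cl == g)
    peak <- members[which.max(pairs$heat[members])]
    # edge-effect check: does this cluster adjoin, across a governing-
    # threshold boundary, initial-map cells that were cut away? If the
    # initial-map region containing the cluster holds a non-retained pair
    # with lower SSE than the cluster's best, the cluster is an edge
    # artefact.
    discard <- FALSE
    init_regions <- unique(init_cl[members])
    init_regions <- init_regions[!is.na(init_regions)]
    if (length(init_regions)) {
      region_cells <- which(init_cl %in% init_regions)
      cut_cells <- region_cells[!pairs$retained[region_cells]]
      if (length(cut_cells) &&
          any(pairs$SSE[cut_cells] < min(pairs$SSE[members])))
        discard <- TRUE
    }
    row <- pairs[peak, , drop = FALSE]
    row$cluster <- g
    row$edge_discarded <- discard
    res[[length(res) + 1L]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full epistatic pair-detection step for one trait
#'
#' Runs the pair scan, applies the genomewide and locus-specific thresholds,
#' selects cluster peaks with the edge-effect rule, and keeps the candidates
#' whose interaction is significant (joint F p < `alpha_joint` or any
#' interaction coefficient p < `alpha_coef`): the putative epistatic pairs.
#'
#' @inheritParams pair_scan
#' @param qtl Putative-QTL table with `sse_specific` (see
#'   [apply_thresholds()]).
#' @param sse_genome Genomewide SSE threshold.
#' @param alpha_joint,alpha_coef Interaction-test levels.
#' @return data.frame of putative epistatic pairs (positions, SSE, the
#'   interaction p-values); attribute `pairs` holds the thresholded scan.
#' @export
find_epistatic_pairs <- function(y, grid, qtl, sse_genome, step = 5,
                                 min_sep = 20, alpha_joint = 0.05,
                                 alpha_coef = 0.0125) {
  sc <- pair_scan(y, grid, step, min_sep)
  sc <- apply_thresholds(sc, qtl, sse_genome)
  cand <- select_cluster_peaks(sc, grid)
  cand <- cand[!cand$edge_discarded, , drop = FALSE]
  keep <- logical(nrow(cand))
  p_joint <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    fit <- two_locus_fit(y, grid$A[, cand$i[k]], grid$D[, cand$i[k]],
                         grid$A[, cand$j[k]], grid$D[, cand$j[k]])
    tt <- interaction_test(fit, alpha_joint, alpha_coef)
    keep[k] <- tt$pass
    p_joint[k] <- tt$p_joint
  }
  out <- cand[keep, , drop = FALSE]
  out$p_joint <- p_joint[keep]
  rownames(out) <- NULL
  attr(out, "pairs") <- sc
  out
}
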