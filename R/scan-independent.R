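# Single-locus Haley-Knott genome scan on the adjusted phenotype:
# ytilde = mu + a*A + d*D + e, with an F ratio for the joint (a, d) test,
# permutation-derived genomewide thresholds, putative-QTL calling with
# spans, and an iterative forward search conditioning on detected loci.

# Columns of conditioning A/D variables for a set of grid indices
cond_columns <- function(grid, cond_idx) {
  if (!length(cond_idx)) return(NULL)
  cbind(grid$A[, cond_idx, drop = FALSE], grid$D[, cond_idx, drop = FALSE])
}

#' Haley-Knott single-position fit
#'
#' Ordinary least squares of the adjusted phenotype on the additive and
#' dominance variables at one position, optionally given conditioning
#' columns (the A/D variables of already-detected QTL). The F ratio is the
#' joint test of (a, d) against the model without them; if A and D are
#' collinear at an uninformative position the test degrees of freedom are
#' reduced accordingly.
#'
#' @param y Adjusted phenotype (no missing values).
#' @param A,D Additive and dominance variables at the tested position.
#' @param cond Optional matrix of conditioning columns.
#' @return list with `mu`, `a`, `d`, `F`, `df` (numerator df actually
#'   used), `SSE`.
#' @export
hk_fit <- function(y, A, D, cond = NULL) {
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), cond)
  X1 <- cbind(X0, A = A, D = D)
  q1 <- qr(X1); q0 <- qr(X0)
  rss1 <- sum(qr.resid(q1, y)^2)
  rss0 <- sum(qr.resid(q0, y)^2)
  df <- q1$rank - q0$rank
  n <- length(y)
  Fstat <- if (df > 0L && q1$rank < n)
    ((rss0 - rss1) / df) / (rss1 / (n - q1$rank)) else 0
  cf <- qr.coef(q1, y)
  list(mu = unname(cf[1L]), a = unname(cf["A"]), d = unname(cf["D"]),
       F = max(0, Fstat), df = df, SSE = rss1)
}

#' Single-locus genome scan
#'
#' Fits the Haley-Knott model at every grid position.
#'
#' @param y Adjusted phenotype aligned to `grid$ids`.
#' @param grid An `ad_grid`.
#' @param cond_idx Grid column indices of conditioning loci (their A and D
#'   enter every position's model).
#' @return data.frame `chr`, `pos`, `a`, `d`, `F`, `SSE`.
#' @export
scan_genome <- function(y, grid, cond_idx = integer()) {
  cond <- cond_columns(grid, cond_idx)
  P <- nrow(grid$map)
  out <- grid$map
  out$a <- out$d <- out$F <- out$SSE <- NA_real_
  for (j in seq_len(P)) {
    f <- hk_fit(y, grid$A[, j], grid$D[, j], cond)
    out$a[j] <- f$a; out$d[j] <- f$d; out$F[j] <- f$F; out$SSE[j] <- f$SSE
  }
  out
}

# Genomewide maximum F per column of a response matrix Y (n x m), shared
# conditioning. Used by the permutation threshold; the BLAS-level projection
# trick makes 1000 permutations cheap.
max_F_per_column <- function(Y, grid, cond_idx = integer()) {
  n <- nrow(Y)
  X0 <- cbind(rep(1, n), cond_columns(grid, cond_idx))
  q0 <- qr(X0)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  yy <- colSums(Y^2)
  rss0 <- yy - colSums(crossprod(Q0, Y)^2)
  maxF <- rep(0, ncol(Y))
  for (j in seq_len(nrow(grid$map))) {
    X1 <- cbind(X0, grid$A[, j], grid$D[, j])
    q1 <- qr(X1)
    Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
    df <- q1$rank - q0$rank
    if (df == 0L) next
    rss1 <- yy - colSums(crossprod(Q1, Y)^2)
    Fj <- ((rss0 - rss1) / df) / (rss1 / (n - q1$rank))
    maxF <- pmax(maxF, Fj)
  }
  maxF
}

#' Genomewide permutation threshold for the single-locus scan
#'
#' The adjusted phenotypes are permuted as whole rows relative to the A/D
#' grid; for each permutation the genomewide maximum F is recorded, and the
#' threshold is the empirical (1 - alpha) quantile of these maxima. Seed
#' the RNG before calling for reproducibility.
#'
#' @inheritParams scan_genome
#' @param n_perm Number of permutations (default 1000; fewer than 100 gives
#'   an unstable tail and warns).
#' @param alpha Genomewide significance level (default 0.05).
#' @return list with `threshold`, the per-permutation `max_F`, `n_perm`,
#'   `alpha`.
#' @export
permutation_threshold <- function(y, grid, n_perm = 1000, alpha = 0.05,
                                  cond_idx = integer()) {
  if (n_perm < 100) warning("fewer than 100 permutations: unstable tail")
  n <- length(y)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  maxF <- max_F_per_column(Y, grid, cond_idx)
  list(threshold = unname(stats::quantile(maxF, 1 - alpha, type = 7)),
       max_F = maxF, n_perm = n_perm, alpha = alpha)
}

#' Call putative QTL and their spans from a scan
#'
#' On each chromosome with any position above the threshold, the position
#' with the highest F ratio is the putative QTL peak. The QTL span is the
#' contiguous supra-threshold stretch containing the peak; supra-threshold
#' stretches separated from it by sub-threshold gaps of at most `gap_max`
#' cM are merged in, the span then running from the lowest to the highest
#' position.
#'
#' @param scan Result of [scan_genome()].
#' @param threshold Genomewide F threshold.
#' @param gap_max Largest sub-threshold gap (cM) merged into a span
#'   (default 10).
#' @return data.frame `chr`, `pos`, `F`, `span_lo`, `span_hi` (one row per
#'   chromosome with a supra-threshold position).
#' @export
call_putative_qtl <- function(scan, threshold, gap_max = 10) {
  res <- list()
  for (cc in unique(scan$chr)) {
    s <- scan[scan$chr == cc, ]
    supra <- which(s$F > threshold)
    if (!length(supra)) next
    peak <- supra[which.max(s$F[supra])]
    # blocks of consecutive supra positions
    brk <- c(0L, which(diff(supra) > 1L), length(supra))
    blocks <- lapply(seq_len(length(brk) - 1L),
                     function(k) supra[(brk[k] + 1L):brk[k + 1L]])
    b_lo <- vapply(blocks, function(b) s$pos[min(b)], 0)
    b_hi <- vapply(blocks, function(b) s$pos[max(b)], 0)
    in_blk <- which(vapply(blocks, function(b) peak %in% b, TRUE))
    lo <- in_blk; hi <- in_blk
    repeat {
      grew <- FALSE
      if (lo > 1L && b_lo[lo] - b_hi[lo - 1L] <= gap_max) { lo <- lo - 1L; grew <- TRUE }
      if (hi < length(blocks) && b_lo[hi + 1L] - b_hi[hi] <= gap_max) { hi <- hi + 1L; grew <- TRUE }
      if (!grew) break
    }
    res[[cc]] <- data.frame(chr = cc, pos = s$pos[peak], F = s$F[peak],
                            span_lo = b_lo[lo], span_hi = b_hi[hi])
  }
  if (!length(res))
    return(data.frame(chr = character(), pos = numeric(), F = numeric(),
                      span_lo = numeric(), span_hi = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Iterative forward search for independent QTL
#'
#' The genome is scanned, putative QTL called, their A/D variables added to
#' the model, and the genome rescanned with the same threshold; new
#' supra-threshold chromosome peaks are added until a round adds nothing.
#' Positions of already-called QTL are frozen; a chromosome that carries a
#' putative QTL can only yield a further peak outside the existing span(s).
#'
#' @inheritParams scan_genome
#' @param threshold Genomewide F threshold (reused in every round).
#' @param gap_max Span gap-merge distance (cM).
#' @param max_rounds Safety limit on conditioning rounds.
#' @return data.frame of putative QTL as in [call_putative_qtl()], with a
#'   `round` column; attribute `scans` holds the per-round scan tables.
#' @export
forward_search <- function(y, grid, threshold, gap_max = 10, max_rounds = 10) {
  qtl <- NULL
  scans <- list()
  for (round in seq_len(max_rounds)) {
    cond_idx <- if (is.null(qtl)) integer() else
      vapply(seq_len(nrow(qtl)),
             function(i) grid_index(grid, qtl$chr[i], qtl$pos[i]), 0L)
    sc <- scan_genome(y, grid, cond_idx)
    scans[[round]] <- sc
    cand <- call_putative_qtl(sc, threshold, gap_max)
    if (!is.null(qtl) && nrow(cand)) {
      keep <- rep(TRUE, nrow(cand))
      for (i in seq_len(nrow(cand))) {
        prev <- qtl[qtl$chr == cand$chr[i], , drop = FALSE]
        if (nrow(prev) && any(cand$pos[i] >= prev$span_lo &
                              cand$pos[i] <= prev$span_hi))
          keep[i] <- FALSE
      }
      cand <- cand[keep, , drop = FALSE]
    }
    if (!nrow(cand)) break
    cand$round <- round
    qtl <- rbind(qtl, cand)
    if (round == max_rounds)
      stop("forward search did not converge in ", max_rounds, " rounds")
  }
  if (is.null(qtl))
    qtl <- data.frame(chr = character(), pos = numeric(), F = numeric(),
                      span_lo = numeric(), span_hi = numeric(),
                      round = integer())
  attr(qtl, "scans") <- scans
  qtl
}
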