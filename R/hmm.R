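# Hidden Markov model for line origin along F2 chromosomes.
#
# Hidden state at a position is the ordered pair (origin of the maternally
# inherited haplotype, origin of the paternally inherited haplotype), each in
# {E, W}; 4 states, ordered EE, EW, WE, WW (maternal origin major). The
# maternal haplotype recombines at female-map rates, the paternal at male-map
# rates, so the two chains have different transition matrices; they are
# coupled only through the emissions (the observed allele pair is unordered).
# EW is pooled across orderings only at output.

# 2-state haplotype transition matrix for recombination fraction r
hap_trans <- function(r) matrix(c(1 - r, r, r, 1 - r), 2L, 2L)

# Emission probability vector (length 4) for one marker given the dam's and
# sire's phasing matrices (rows = consistent (E-allele, W-allele) orderings)
# and the observed unordered allele pair. Unresolved phase is marginalised by
# averaging over the consistent phasings. Missing genotype: all ones.
emission_vec <- function(dam_ph, sire_ph, obs) {
  if (anyNA(obs) || is.null(dam_ph) || is.null(sire_ph))
    return(rep(1, 4L))
  e <- numeric(4L)
  nd <- nrow(dam_ph); ns <- nrow(sire_ph)
  for (i in seq_len(nd)) for (j in seq_len(ns)) {
    # columns 1 = allele inherited when origin is E, 2 = when origin is W
    for (m in 1:2) for (p in 1:2) {
      got <- c(dam_ph[i, m], sire_ph[j, p])
      if ((got[1L] == obs[1L] && got[2L] == obs[2L]) ||
          (got[1L] == obs[2L] && got[2L] == obs[1L]))
        e[2L * (m - 1L) + p] <- e[2L * (m - 1L) + p] + 1
    }
  }
  e / (nd * ns)
}

# Scaled forward-backward over one chromosome for one individual.
# emis: 4 x P matrix (P evaluation positions); Tf, Tm: lists of 2x2
# haplotype transition matrices per interval (female = maternal haplotype,
# male = paternal). Returns 4 x P posterior matrix.
forward_backward <- function(emis, Tf, Tm) {
  P <- ncol(emis)
  Tlist <- vector("list", P - 1L)
  for (k in seq_len(P - 1L)) Tlist[[k]] <- kronecker(Tf[[k]], Tm[[k]])
  fwd <- matrix(0, 4L, P)
  a <- rep(0.25, 4L) * emis[, 1L]
  s <- sum(a)
  if (s <= 0) stop("Mendelian inconsistency: no hidden state is compatible ",
                   "with the observed genotypes")
  fwd[, 1L] <- a / s
  if (P > 1L) for (k in 2L:P) {
    a <- as.vector(crossprod(Tlist[[k - 1L]], fwd[, k - 1L])) * emis[, k]
    s <- sum(a)
    if (s <= 0) stop("Mendelian inconsistency: no hidden state is compatible ",
                     "with the observed genotypes")
    fwd[, k] <- a / s
  }
  bwd <- matrix(0, 4L, P)
  bwd[, P] <- 1
  if (P > 1L) for (k in (P - 1L):1L) {
    b <- as.vector(Tlist[[k]] %*% (bwd[, k + 1L] * emis[, k + 1L]))
    bwd[, k] <- b / sum(b)
  }
  post <- fwd * bwd
  sweep(post, 2L, colSums(post), "/")
}

#' Line-origin posterior probabilities on a cM grid
#'
#' Runs the forward-backward algorithm per F2 individual and chromosome,
#' with the hidden state the ordered pair of line origins of the maternally
#' and paternally inherited haplotypes. Transitions between adjacent
#' evaluation positions use the Haldane recombination fraction of the
#' female-map interval for the maternal haplotype and of the male-map
#' interval for the paternal haplotype. Emissions at markers are computed
#' from the phased F1 parents' alleles, averaging over unresolved phasings;
#' missing genotypes are uninformative. Posteriors are reported at every
#' `grid_step` cM (anchored at 0, through the last marker position rounded
#' up) and collapsed to p(EE), p(EW), p(WW), from which the Haley-Knott
#' regression variables A = p(WW) - p(EE) and D = p(EW) are derived.
#'
#' @param geno Genotype data.frame (F0, F1 and F2 rows; see
#'   [read_genotypes()]).
#' @param ped Pedigree data.frame (see [read_pedigree()]).
#' @param map A `linkage_map` on the Haldane scale.
#' @param grid_step Grid spacing in cM (default 1).
#' @param ids F2 individuals to process (default: all F2 in the pedigree).
#' @return An `ad_grid` object: list with `ids`, `map` (data.frame of
#'   `chr`, `pos`), and n-by-P matrices `A`, `D`, `pEE`, `pEW`, `pWW`.
#' @export
line_origin_posteriors <- function(geno, ped, map, grid_step = 1, ids = NULL) {
  if (attr(map, "map_function") != "haldane")
    stop("map must be on the Haldane scale (see map_to_haldane)")
  if (is.null(ids)) ids <- ped$id[ped$generation == "F2"]
  phased <- phase_f1(ped, geno)
  dam_of <- stats::setNames(ped$dam, ped$id)
  sire_of <- stats::setNames(ped$sire, ped$id)
  gsplit <- split(geno, geno$id)
  chrs <- unique(map$chr)
  n <- length(ids)

  grid_list <- list()
  blocks <- list()
  for (cc in chrs) {
    mk <- map[map$chr == cc, ]
    grid <- seq(0, ceiling(max(mk$sexavg)), by = grid_step)
    evalpos <- sort(unique(c(grid, mk$sexavg)))
    sp <- sex_positions(map, cc, evalpos)
    Tf <- lapply(haldane_recombination(pmax(diff(sp$female), 0)), hap_trans)
    Tm <- lapply(haldane_recombination(pmax(diff(sp$male), 0)), hap_trans)
    midx <- match(mk$sexavg, evalpos)
    gidx <- match(grid, evalpos)
    P <- length(grid)
    pEE <- pEW <- pWW <- matrix(0, n, P)
    for (i in seq_len(n)) {
      ind <- ids[i]
      dph <- phased[[dam_of[ind]]]
      sph <- phased[[sire_of[ind]]]
      g <- gsplit[[ind]]
      emis <- matrix(1, 4L, length(evalpos))
      for (k in seq_along(midx)) {
        mname <- mk$marker[k]
        row <- if (is.null(g)) integer(0) else which(g$marker == mname)
        obs <- if (length(row)) c(g$a1[row[1L]], g$a2[row[1L]]) else c(NA, NA)
        emis[, midx[k]] <- emission_vec(dph[[mname]], sph[[mname]], obs)
      }
      post <- tryCatch(forward_backward(emis, Tf, Tm),
                       error = function(e) stop(conditionMessage(e),
                                                " (individual ", ind,
                                                ", chromosome ", cc, ")",
                                                call. = FALSE))
      pEE[i, ] <- post[1L, gidx]
      pEW[i, ] <- post[2L, gidx] + post[3L, gidx]
      pWW[i, ] <- post[4L, gidx]
    }
    grid_list[[cc]] <- data.frame(chr = cc, pos = grid)
    blocks[[cc]] <- list(pEE = pEE, pEW = pEW, pWW = pWW)
  }
  posmap <- do.call(rbind, grid_list)
  rownames(posmap) <- NULL
  out <- list(ids = ids, map = posmap,
              pEE = do.call(cbind, lapply(blocks, `[[`, "pEE")),
              pEW = do.call(cbind, lapply(blocks, `[[`, "pEW")),
              pWW = do.call(cbind, lapply(blocks, `[[`, "pWW")))
  class(out) <- "ad_grid"
  ad_variables(out)
}

#' Fill the A and D regression variables of a line-origin grid
#'
#' A = p(WW) - p(EE) and D = p(EW), the expected additive and dominance
#' scores under the line-origin posteriors. Posterior normalisation is
#' checked to 1e-9.
#'
#' @param grid An `ad_grid` with posterior matrices `pEE`, `pEW`, `pWW`.
#' @return The grid with `A` and `D` matrices filled.
#' @export
ad_variables <- function(grid) {
  tot <- grid$pEE + grid$pEW + grid$pWW
  if (any(abs(tot - 1) > 1e-9))
    stop("line-origin posteriors are not normalised")
  grid$A <- grid$pWW - grid$pEE
  grid$D <- grid$pEW
  grid
}

#' @export
print.ad_grid <- function(x, ...) {
  cat("Line-origin A/D grid:", length(x$ids), "individuals,",
      nrow(x$map), "positions on", length(unique(x$map$chr)),
      "chromosome(s)\n")
  invisible(x)
}
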