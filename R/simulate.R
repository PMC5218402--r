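# Synthetic F2 line-cross generator. The design template is a cross of a
# small number of line-E founder dams with a few line-W founder sires, an
# F1 generation, and a large F2 mapped with multi-allelic microsatellite-
# style markers that are only partially informative (the two line pools can
# share alleles). Meiosis follows a no-interference (Haldane) model with
# Poisson crossovers at sex-specific rates. Phenotypes are built
# generatively from the same F-infinity model the analysis fits: fixed
# covariates, a maternal random effect, per-locus additive/dominance terms,
# pairwise interaction terms, and Gaussian residual noise.

#' Simulation configuration
#'
#' @param chr_lengths Named numeric vector of chromosome lengths in
#'   sex-averaged cM.
#' @param n_markers_per_chr Markers per chromosome (evenly spaced, first at
#'   0, last at the chromosome end).
#' @param female_expand,male_expand Multipliers carrying the sex-averaged
#'   map to the female and male maps (defaults mirror a female map about
#'   15% longer and a male map 15% shorter than the average).
#' @param n_line_alleles Alleles in each line's private pool per marker.
#' @param shared_prob Probability that a founder allele copy is drawn from
#'   a pool common to both lines (partial informativeness); 0 makes every
#'   marker fully informative.
#' @param missing_rate Probability an F2 marker genotype is missing.
#' @param n_f0_dams,n_f0_sires Line-E founder dams / line-W founder sires.
#' @param n_f1_dams,n_f1_sires F1 parents of the F2.
#' @param n_f2 Number of F2 individuals.
#' @param litter_size Average F2 litter size (per F1 dam mating).
#' @param qtl data.frame of independent loci: `chr`, `pos`, `a`, `d` (F-inf
#'   coefficients, phenotype units), or NULL.
#' @param pairs data.frame of epistatic pairs: `chr1`, `pos1`, `chr2`,
#'   `pos2`, `a1`, `d1`, `a2`, `d2`, `iaa`, `iad`, `ida`, `idd`, or NULL.
#' @param mother_var Maternal variance component.
#' @param resid_var Residual variance.
#' @param mu Intercept; `sex_effect` additive effect of male sex;
#'   `batch_effects` numeric vector of batch deviations (also sets the
#'   number of batches).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chr_lengths = c(`1` = 100, `2` = 100),
                       n_markers_per_chr = 8,
                       female_expand = 1.15, male_expand = 0.85,
                       n_line_alleles = 3, shared_prob = 0.3,
                       missing_rate = 0.05,
                       n_f0_dams = 4, n_f0_sires = 2,
                       n_f1_dams = 20, n_f1_sires = 5,
                       n_f2 = 400, litter_size = 10,
                       qtl = NULL, pairs = NULL,
                       mother_var = 0.1, resid_var = 1,
                       mu = 0, sex_effect = 0.3,
                       batch_effects = c(0, 0.2)) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Study presets
#'
#' `mini`: 2 chromosomes x 100 cM, 8 markers each, 400 F2 — small enough
#' for repeated simulation. `paper_scale`: 18 autosomes totalling about
#' 2800 sex-averaged cM, 178 markers, 1750 genotyped F2 from 17 founder
#' dams and 2 founder sires — the scale of a large pig F2 resource
#' population.
#'
#' @param name "mini" or "paper_scale".
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("mini", "paper_scale"), ...) {
  name <- match.arg(name)
  if (name == "mini") return(sim_config(...))
  lens <- stats::setNames(round(seq(290, 65, length.out = 18)), as.character(1:18))
  lens <- round(lens * 2788 / sum(lens))
  nm <- pmax(5, round(lens / 17))
  nm <- round(nm * 178 / sum(nm))
  sim_config(chr_lengths = lens, n_markers_per_chr = nm,
             n_f0_dams = 17, n_f0_sires = 2,
             n_f1_dams = 59, n_f1_sires = 9,
             n_f2 = 1750, litter_size = 10,
             batch_effects = c(0, 0.2, -0.1, 0.15, 0.05, -0.2), ...)
}

#' Reference architecture for the mini study
#'
#' One locus with an additive main effect (a = 0.4 residual SD on
#' chromosome 1 at 30 cM) that also interacts additive-by-additive
#' (i_aa = 0.5 residual SD) with a second, purely epistatic locus on
#' chromosome 2 at 70 cM — the configuration most often seen in F2
#' epistasis scans, where one pair member carries a detectable marginal
#' effect and the partner is only found through the interaction.
#'
#' @param a Additive main effect at locus 1 (default 0.4).
#' @param iaa Additive-by-additive interaction (default 0.5).
#' @return list with `qtl` and `pairs` data.frames for [sim_config()].
#' @export
mini_architecture <- function(a = 0.4, iaa = 0.5) {
  list(qtl = NULL,
       pairs = data.frame(chr1 = "1", pos1 = 30, chr2 = "2", pos2 = 70,
                          a1 = a, d1 = 0, a2 = 0, d2 = 0,
                          iaa = iaa, iad = 0, ida = 0, idd = 0))
}

# Build the linkage map implied by a config (evenly spaced markers).
sim_map <- function(cfg) {
  rows <- list()
  nm <- rep(cfg$n_markers_per_chr, length.out = length(cfg$chr_lengths))
  for (k in seq_along(cfg$chr_lengths)) {
    cc <- names(cfg$chr_lengths)[k]
    pos <- seq(0, cfg$chr_lengths[k], length.out = nm[k])
    rows[[k]] <- data.frame(chr = cc, marker = paste0("M", cc, "_", seq_along(pos)),
                            female = pos * cfg$female_expand,
                            male = pos * cfg$male_expand, sexavg = pos)
  }
  m <- do.call(rbind, rows)
  linkage_map(m$chr, m$marker, m$female, m$male, m$sexavg,
              map_function = "haldane")
}

# founder allele pools; returns list per marker: list(E=, W=) character
sim_allele_pools <- function(map, cfg) {
  pools <- vector("list", nrow(map))
  names(pools) <- map$marker
  for (m in map$marker) {
    pools[[m]] <- list(E = paste0("e", seq_len(cfg$n_line_alleles)),
                       W = paste0("w", seq_len(cfg$n_line_alleles)),
                       C = c("c1", "c2"))
  }
  pools
}

draw_founder_allele <- function(pool, line, shared_prob) {
  if (stats::runif(1) < shared_prob) sample(pool$C, 1L) else
    sample(pool[[line]], 1L)
}

# A haplotype for one chromosome: marker alleles plus the line-origin
# mosaic (breaks = crossover positions in sex-averaged cM, lines = origin
# label per segment).
new_hap <- function(alleles, breaks = numeric(), lines) {
  list(alleles = alleles, breaks = breaks, lines = lines)
}

line_at <- function(hap, pos) {
  hap$lines[findInterval(pos, hap$breaks) + 1L]
}

# Meiosis for one chromosome: Poisson crossovers on the sex-specific map,
# breakpoints carried back to the sex-averaged coordinate system. Parent
# haplotypes must each be line-constant (true for F0 and F1 parents, the
# only ones bred here).
meiose_chr <- function(haps, map, chr, sex, cfg) {
  sub <- map[map$chr == chr, ]
  L_avg <- max(sub$sexavg)
  expand <- if (sex == "female") cfg$female_expand else cfg$male_expand
  L_sex <- L_avg * expand
  n_x <- stats::rpois(1L, L_sex / 100)
  breaks <- sort(stats::runif(n_x, 0, L_sex)) / expand
  start <- sample(1:2, 1L)
  seg_hap <- (start - 1L + seq_len(length(breaks) + 1L)) %% 2L + 1L
  mpos <- sub$sexavg
  seg_of_marker <- findInterval(mpos, breaks) + 1L
  alleles <- vapply(seq_along(mpos), function(i)
    haps[[seg_hap[seg_of_marker[i]]]]$alleles[i], "")
  lines <- vapply(seg_hap, function(h) haps[[h]]$lines[1L], "")
  # collapse runs of identical line origin
  keep <- c(TRUE, lines[-1L] != lines[-length(lines)])
  new_hap(alleles, breaks[keep[-1L]], lines[keep])
}

meiose <- function(ind, map, sex, cfg) {
  lapply(stats::setNames(nm = unique(map$chr)), function(cc)
    meiose_chr(list(ind$hap1[[cc]], ind$hap2[[cc]]), map, cc, sex, cfg))
}

#' Simulate an F2 line cross
#'
#' Founders are homozygous for line-labelled chromosomes with marker
#' alleles drawn from line-specific pools (sharing alleles with the other
#' line with probability `shared_prob`); F1 are produced from founder
#' matings and F2 from F1 x F1 matings in litters. Gametes carry Poisson
#' crossovers at sex-specific rates (female map for dams, male for sires).
#' Marker genotypes for the F2 have independent missingness.
#'
#' @param cfg A `sim_config`.
#' @return list of class `sim_cross`: `map` (a `linkage_map`), `ped`
#'   (pedigree data.frame), `geno` (long genotype data.frame, F2 rows
#'   subject to missingness), and `f2` (list per F2 id: `hap_m`, `hap_p`,
#'   the line-origin truth).
#' @export
simulate_cross <- function(cfg) {
  map <- sim_map(cfg)
  pools <- sim_allele_pools(map, cfg)
  chrs <- unique(map$chr)
  make_founder <- function(id, line) {
    h <- function() lapply(stats::setNames(nm = chrs), function(cc) {
      mk <- map$marker[map$chr == cc]
      new_hap(vapply(mk, function(m)
        draw_founder_allele(pools[[m]], line, cfg$shared_prob), ""),
        numeric(), line)
    })
    list(id = id, line = line, hap1 = h(), hap2 = h())
  }
  dams0 <- lapply(seq_len(cfg$n_f0_dams), function(i)
    make_founder(paste0("E", i), "E"))
  sires0 <- lapply(seq_len(cfg$n_f0_sires), function(i)
    make_founder(paste0("W", i), "W"))
  ped <- data.frame(id = c(vapply(dams0, `[[`, "", "id"),
                           vapply(sires0, `[[`, "", "id")),
                    sire = NA_character_, dam = NA_character_,
                    generation = "F0",
                    line = c(rep("E", cfg$n_f0_dams), rep("W", cfg$n_f0_sires)),
                    stringsAsFactors = FALSE)
  n_f1 <- cfg$n_f1_dams + cfg$n_f1_sires
  f1 <- vector("list", n_f1)
  ped_rows <- list(ped)
  for (i in seq_len(n_f1)) {
    d0 <- dams0[[sample.int(length(dams0), 1L)]]
    s0 <- sires0[[sample.int(length(sires0), 1L)]]
    f1[[i]] <- list(id = paste0("F1_", i),
                    hap1 = meiose(d0, map, "female", cfg),   # maternal
                    hap2 = meiose(s0, map, "male", cfg))     # paternal
    ped_rows[[i + 1L]] <- data.frame(id = f1[[i]]$id, sire = s0$id,
                                     dam = d0$id, generation = "F1",
                                     line = NA_character_)
  }
  f1_dams <- f1[seq_len(cfg$n_f1_dams)]
  f1_sires <- f1[cfg$n_f1_dams + seq_len(cfg$n_f1_sires)]
  f2 <- vector("list", cfg$n_f2)
  names(f2) <- paste0("F2_", seq_len(cfg$n_f2))
  k <- 0L
  while (k < cfg$n_f2) {
    dam <- f1_dams[[sample.int(length(f1_dams), 1L)]]
    sire <- f1_sires[[sample.int(length(f1_sires), 1L)]]
    litter <- min(cfg$litter_size, cfg$n_f2 - k)
    for (j in seq_len(litter)) {
      k <- k + 1L
      id <- names(f2)[k]
      f2[[k]] <- list(id = id, dam = dam$id, sire = sire$id,
                      hap_m = meiose(dam, map, "female", cfg),
                      hap_p = meiose(sire, map, "male", cfg))
      ped_rows[[length(ped_rows) + 1L]] <-
        data.frame(id = id, sire = sire$id, dam = dam$id,
                   generation = "F2", line = NA_character_)
    }
  }
  ped <- do.call(rbind, ped_rows)
  geno_rows <- list()
  all_markers <- unlist(lapply(chrs, function(cc) map$marker[map$chr == cc]),
                        use.names = FALSE)
  emit <- function(ind_id, hapA, hapB, missing_rate = 0) {
    a1 <- unlist(lapply(chrs, function(cc) hapA[[cc]]$alleles),
                 use.names = FALSE)
    a2 <- unlist(lapply(chrs, function(cc) hapB[[cc]]$alleles),
                 use.names = FALSE)
    if (missing_rate > 0) {
      miss <- stats::runif(length(a1)) < missing_rate
      a1[miss] <- NA; a2[miss] <- NA
    }
    geno_rows[[length(geno_rows) + 1L]] <<-
      data.frame(id = ind_id, marker = all_markers, a1 = a1, a2 = a2,
                 stringsAsFactors = FALSE)
  }
  for (x in c(dams0, sires0)) emit(x$id, x$hap1, x$hap2)
  for (x in f1) emit(x$id, x$hap1, x$hap2)
  for (x in f2) emit(x$id, x$hap_m, x$hap_p, cfg$missing_rate)
  out <- list(map = map, ped = ped, geno = do.call(rbind, geno_rows),
              f2 = f2, cfg = cfg)
  class(out) <- "sim_cross"
  out
}

#' True line-origin genotype of F2 individuals at a position
#'
#' @param cross A `sim_cross`.
#' @param chr,pos Query position.
#' @return Character vector per F2: "EE", "EW" or "WW" (EW pools both
#'   orderings).
#' @export
true_genotype <- function(cross, chr, pos) {
  vapply(cross$f2, function(ind) {
    g <- sort(c(line_at(ind$hap_m[[as.character(chr)]], pos),
                line_at(ind$hap_p[[as.character(chr)]], pos)))
    paste0(g[1L], g[2L])
  }, "")
}

#' A/D grid from the simulation truth
#'
#' Builds an `ad_grid` whose posteriors are 0/1 indicators of the true
#' line-origin genotypes — the noise-free analogue of the HMM output, used
#' to exercise the scans independently of genotyping.
#'
#' @param cross A `sim_cross`.
#' @param grid_step Grid spacing in cM.
#' @return An `ad_grid`.
#' @export
true_ad_grid <- function(cross, grid_step = 1) {
  map <- cross$map
  rows <- list()
  for (cc in unique(map$chr))
    rows[[cc]] <- data.frame(chr = cc,
                             pos = seq(0, ceiling(max(map$sexavg[map$chr == cc])),
                                       by = grid_step))
  posmap <- do.call(rbind, rows)
  rownames(posmap) <- NULL
  n <- length(cross$f2)
  P <- nrow(posmap)
  gEE <- gEW <- gWW <- matrix(0, n, P)
  for (cc in unique(posmap$chr)) {
    jj <- which(posmap$chr == cc)
    pos <- posmap$pos[jj]
    for (i in seq_len(n)) {
      ind <- cross$f2[[i]]
      om <- line_at(ind$hap_m[[cc]], pos)
      op <- line_at(ind$hap_p[[cc]], pos)
      both_e <- om == "E" & op == "E"
      both_w <- om == "W" & op == "W"
      gEE[i, jj] <- both_e
      gWW[i, jj] <- both_w
      gEW[i, jj] <- !(both_e | both_w)
    }
  }
  out <- list(ids = names(cross$f2), map = posmap,
              pEE = gEE, pEW = gEW, pWW = gWW)
  class(out) <- "ad_grid"
  ad_variables(out)
}

# Genetic value of each F2 under the config's architecture (true origins)
genetic_values <- function(cross, cfg) {
  n <- length(cross$f2)
  gv <- numeric(n)
  score <- function(chr, pos) {
    g <- true_genotype(cross, chr, pos)
    list(A = geno_s[g], D = geno_h[g])
  }
  if (!is.null(cfg$qtl) && nrow(cfg$qtl)) for (r in seq_len(nrow(cfg$qtl))) {
    sc <- score(cfg$qtl$chr[r], cfg$qtl$pos[r])
    gv <- gv + cfg$qtl$a[r] * sc$A + cfg$qtl$d[r] * sc$D
  }
  if (!is.null(cfg$pairs) && nrow(cfg$pairs))
    for (r in seq_len(nrow(cfg$pairs))) {
      p <- cfg$pairs[r, ]
      s1 <- score(p$chr1, p$pos1); s2 <- score(p$chr2, p$pos2)
      gv <- gv + p$a1 * s1$A + p$d1 * s1$D + p$a2 * s2$A + p$d2 * s2$D +
        p$iaa * s1$A * s2$A + p$iad * s1$A * s2$D +
        p$ida * s1$D * s2$A + p$idd * s1$D * s2$D
    }
  gv
}

#' Simulate a phenotype for the F2
#'
#' y = mu + sex + batch + genetic value (from the true line origins under
#' the F-infinity architecture) + maternal effect + Gaussian residual.
#'
#' @param cross A `sim_cross`.
#' @param cfg The `sim_config` (its `qtl`/`pairs` architecture is used).
#' @return data.frame `id`, `y`, `sex`, `batch`, `mother`, plus the truth
#'   columns `genetic` and `maternal`.
#' @export
simulate_phenotype <- function(cross, cfg = cross$cfg) {
  n <- length(cross$f2)
  ids <- names(cross$f2)
  mothers <- vapply(cross$f2, `[[`, "", "dam")
  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- sample(seq_along(cfg$batch_effects), n, replace = TRUE)
  mom_levels <- unique(mothers)
  mom_eff <- stats::setNames(stats::rnorm(length(mom_levels), 0,
                                          sqrt(cfg$mother_var)), mom_levels)
  gv <- genetic_values(cross, cfg)
  y <- cfg$mu + cfg$sex_effect * (sex == "M") +
    cfg$batch_effects[batch] + gv + mom_eff[mothers] +
    stats::rnorm(n, 0, sqrt(cfg$resid_var))
  data.frame(id = ids, y = y, sex = sex, batch = factor(batch),
             mother = mothers, genetic = gv,
             maternal = unname(mom_eff[mothers]), stringsAsFactors = FALSE)
}

#' Simulate full animal records for the growth traits
#'
#' Builds weight measurements at the six nominal ages by accumulating
#' interval gains; each elementary interval receives covariate effects, a
#' maternal effect, the genetic value of the focal architecture (for the
#' interval named in `arch_trait`) and residual noise. Later measurement
#' ages vary inside the trait windows; a fraction `died_rate` of animals
#' dies early (weights missing from a random age on).
#'
#' @param cross A `sim_cross`.
#' @param cfg The `sim_config`.
#' @param arch_trait Elementary interval receiving the genetic
#'   architecture: one of "BW", "G_0_21", "G_21_46", "G_46_120",
#'   "G_120_210", "G_210_240".
#' @param died_rate Fraction of animals dying before the endpoint.
#' @return An animal-record data.frame (see [derive_traits()]).
#' @export
simulate_records <- function(cross, cfg = cross$cfg, arch_trait = "G_46_120",
                             died_rate = 0) {
  n <- length(cross$f2)
  ids <- names(cross$f2)
  mothers <- vapply(cross$f2, `[[`, "", "dam")
  sex <- sample(c("F", "M"), n, replace = TRUE)
  batch <- sample(seq_along(cfg$batch_effects), n, replace = TRUE)
  mom_levels <- unique(mothers)
  mom_eff <- stats::setNames(stats::rnorm(length(mom_levels), 0,
                                          sqrt(cfg$mother_var)), mom_levels)
  gv <- genetic_values(cross, cfg)
  gains <- list(BW = 1.2, G_0_21 = 4.1, G_21_46 = 6.0, G_46_120 = 21,
                G_120_210 = 48, G_210_240 = 15)
  sds <- list(BW = 0.2, G_0_21 = 0.8, G_21_46 = 1.5, G_46_120 = 4.5,
              G_120_210 = 9, G_210_240 = 5.5)
  piece <- function(tr) {
    base <- gains[[tr]] + 0.1 * gains[[tr]] * (sex == "M") / 1.2 +
      0.05 * gains[[tr]] * (batch - mean(batch)) +
      sqrt(sds[[tr]]^2) * stats::rnorm(n) +
      (mom_eff[mothers] + if (tr == arch_trait) gv else 0) *
        sds[[tr]] / sqrt(cfg$resid_var)
    pmax(base, 0.05 * gains[[tr]])
  }
  w0 <- piece("BW")
  w21 <- w0 + piece("G_0_21")
  w46 <- w21 + piece("G_21_46")
  w120 <- w46 + piece("G_46_120")
  w210 <- w120 + piece("G_120_210")
  w240 <- w210 + piece("G_210_240")
  rec <- data.frame(id = ids, sex = sex, batch = factor(batch),
                    mother = mothers, parity = sample(1:4, n, replace = TRUE),
                    w0 = w0, w21 = w21, w46 = w46, w120 = w120, w210 = w210,
                    w240 = w240,
                    a120 = sample(119:130, n, replace = TRUE),
                    a210 = sample(209:213, n, replace = TRUE),
                    group_size = sample(6:10, n, replace = TRUE),
                    move_age = ifelse(stats::runif(n) < 0.5,
                                      sample(60:160, n, replace = TRUE), NA),
                    starved = stats::runif(n) < 0.7,
                    n_offspring = sample(8:16, n, replace = TRUE),
                    died = stats::runif(n) < died_rate,
                    stringsAsFactors = FALSE)
  rec$a240 <- rec$a210 + sample(27:34, n, replace = TRUE)
  rec$a240 <- pmin(pmax(rec$a240, 237), 242)
  for (col in c("w120", "w210", "w240"))
    rec[[col]][rec$died] <- NA
  rec
}

#' Write a complete synthetic study bundle to disk
#'
#' Writes the linkage map, pedigree, genotypes, a phenotype table, the
#' true-origin A/D grid, and a truth sidecar (architecture and variance
#' components) as plain tab-delimited text. Deterministic given the RNG
#' state at entry.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named file paths; attribute `cross` holds the
#'   simulated cross.
#' @export
make_fixtures <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cross <- simulate_cross(cfg)
  phe <- simulate_phenotype(cross, cfg)
  grid <- true_ad_grid(cross)
  paths <- c(map = file.path(dir, "map.tsv"),
             pedigree = file.path(dir, "pedigree.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             ad_grid = file.path(dir, "ad_grid.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_linkage_map(cross$map, paths["map"])
  write_pedigree(cross$ped, paths["pedigree"])
  write_genotypes(cross$geno, paths["genotypes"])
  utils::write.table(phe, paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ad_grid(grid, paths["ad_grid"])
  truth <- rbind(
    if (!is.null(cfg$qtl) && nrow(cfg$qtl))
      data.frame(kind = "qtl", chr = cfg$qtl$chr, pos = cfg$qtl$pos,
                 coef = "a_d", value = paste(cfg$qtl$a, cfg$qtl$d, sep = ";")),
    data.frame(kind = "varcomp", chr = NA, pos = NA,
               coef = c("mother_var", "resid_var"),
               value = c(cfg$mother_var, cfg$resid_var)))
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(paths, "cross") <- cross
  invisible(paths)
}
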