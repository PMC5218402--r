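# Independent oracles used across the suite. These deliberately avoid the
# package's inference code paths: the HMM oracle enumerates origin
# configurations exhaustively, the regression oracle solves the normal
# equations directly, and the Holm oracle is a hand-rolled step-down.

# Exhaustive-enumeration posterior oracle for one chromosome and one F2
# individual. Enumerates the origin (E/W) of the maternal and paternal
# haplotype at every evaluation position; transition probabilities come
# from the Haldane map function on the female (maternal) and male
# (paternal) inter-position distances; emissions at markers average over
# the F1 parents' consistent phasings. Returns a 3 x P matrix (pEE, pEW,
# pWW) over the evaluation positions.
oracle_posteriors_one <- function(obs_alleles, dam_geno, sire_geno,
                                  e_dam_alleles, w_dam_alleles,
                                  e_sire_alleles, w_sire_alleles,
                                  female_pos, male_pos) {
  P <- length(female_pos)
  stopifnot(P <= 7)  # 4^P joint configurations
  rf <- 0.5 * (1 - exp(-2 * diff(female_pos) / 100))
  rm_ <- 0.5 * (1 - exp(-2 * diff(male_pos) / 100))
  hap_prob <- function(o, r) {
    pr <- 0.5
    if (P > 1L) for (k in 2:P)
      pr <- pr * if (o[k] == o[k - 1L]) 1 - r[k - 1L] else r[k - 1L]
    pr
  }
  # consistent (E, W) phasings of a parent's genotype at marker k
  phasings <- function(g, epool, wpool) {
    cand <- unique(rbind(g, rev(g)))
    cand[cand[, 1] %in% epool & cand[, 2] %in% wpool, , drop = FALSE]
  }
  emit_one <- function(k, mo, po) {
    obs <- obs_alleles[[k]]
    if (anyNA(obs)) return(1)
    dph <- phasings(dam_geno[[k]], e_dam_alleles[[k]], w_dam_alleles[[k]])
    sph <- phasings(sire_geno[[k]], e_sire_alleles[[k]], w_sire_alleles[[k]])
    tot <- 0
    for (i in seq_len(nrow(dph))) for (j in seq_len(nrow(sph))) {
      da <- dph[i, if (mo == "E") 1 else 2]
      sa <- sph[j, if (po == "E") 1 else 2]
      tot <- tot + all(sort(c(da, sa)) == sort(obs))
    }
    tot / (nrow(dph) * nrow(sph))
  }
  states <- c("E", "W")
  post <- matrix(0, 3, P, dimnames = list(c("EE", "EW", "WW"), NULL))
  total <- 0
  cfgs <- expand.grid(rep(list(states), 2 * P), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cfgs))) {
    m <- unlist(cfgs[r, 1:P]); p <- unlist(cfgs[r, P + 1:P])
    pr <- hap_prob(m, rf) * hap_prob(p, rm_)
    for (k in seq_len(P)) pr <- pr * emit_one(k, m[k], p[k])
    if (pr == 0) next
    total <- total + pr
    for (k in seq_len(P)) {
      g <- paste0(sort(c(m[k], p[k]))[1], sort(c(m[k], p[k]))[2])
      post[g, k] <- post[g, k] + pr
    }
  }
  sweep(post, 2, colSums(post), "/")
}

# Normal-equations least-squares oracle
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), SSE = sum(res^2))
}

# Hand-rolled Holm step-down: reject smallest p against alpha/m, next
# against alpha/(m-1), ... stop at first failure.
holm_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  rej <- logical(m)
  for (k in seq_len(m)) {
    if (p[o[k]] < alpha / (m - k + 1)) rej[o[k]] <- TRUE else break
  }
  rej
}

# Small deterministic F2 fixture used by several HMM tests: one
# chromosome, fully informative markers unless stated.
make_tiny_cross <- function(markers = c(0, 20, 40), informative = TRUE,
                            f2_obs) {
  chr <- rep("1", length(markers))
  mk <- paste0("M", seq_along(markers))
  map <- linkage_map(chr, mk, female = markers * 1.2, male = markers * 0.8,
                     sexavg = markers, map_function = "haldane")
  ped <- data.frame(id = c("E1", "W1", "D", "S", "X"),
                    sire = c(NA, NA, "W1", "W1", "S"),
                    dam = c(NA, NA, "E1", "E1", "D"),
                    generation = c("F0", "F0", "F1", "F1", "F2"),
                    line = c("E", "W", NA, NA, NA),
                    stringsAsFactors = FALSE)
  g <- function(id, a1, a2) data.frame(id = id, marker = mk, a1 = a1, a2 = a2,
                                       stringsAsFactors = FALSE)
  if (informative) {
    geno <- rbind(g("E1", "e1", "e2"), g("W1", "w1", "w2"),
                  g("D", "e1", "w1"), g("S", "e2", "w2"),
                  g("X", f2_obs$a1, f2_obs$a2))
  } else {
    # both lines share allele "s"; partially informative
    geno <- rbind(g("E1", "e1", "s"), g("W1", "w1", "s"),
                  g("D", "e1", "s"), g("S", "s", "w1"),
                  g("X", f2_obs$a1, f2_obs$a2))
  }
  list(map = map, ped = ped, geno = geno, markers = markers, mk = mk)
}
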