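#' Read marker genotypes (long format)
#'
#' Tab-delimited with header `individual  marker  allele1  allele2`; "NA"
#' for a missing genotype (both allele columns). Allele codes are opaque
#' symbols (microsatellite-style, multi-allelic).
#'
#' @param path File path.
#' @return data.frame with columns `id`, `marker`, `a1`, `a2` (character,
#'   NA for missing).
#' @export
read_genotypes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  need <- c("individual", "marker", "allele1", "allele2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("genotype file missing column(s): ",
                         paste(miss, collapse = ", "))
  data.frame(id = x$individual, marker = x$marker, a1 = x$allele1,
             a2 = x$allele2, stringsAsFactors = FALSE)
}

#' @rdname read_genotypes
#' @param geno Genotype data.frame as returned by `read_genotypes()`.
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(individual = geno$id, marker = geno$marker,
                    allele1 = geno$a1, allele2 = geno$a2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a pedigree file
#'
#' Tab-delimited with header `individual  sire  dam  generation  line`;
#' generation is F0, F1 or F2; line (E or W) is given for F0 founders only.
#'
#' @param path File path.
#' @return data.frame with columns `id`, `sire`, `dam`, `generation`, `line`.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  need <- c("individual", "sire", "dam", "generation", "line")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pedigree file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- x$generation == "F0" & is.na(x$line)
  if (any(bad)) stop("F0 founder(s) without a line label: ",
                     paste(x$individual[bad], collapse = ", "))
  data.frame(id = x$individual, sire = x$sire, dam = x$dam,
             generation = x$generation, line = x$line, stringsAsFactors = FALSE)
}

#' @rdname read_pedigree
#' @param ped Pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(individual = ped$id, sire = ped$sire, dam = ped$dam,
                    generation = ped$generation, line = ped$line)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Consistent (E-allele, W-allele) orderings of an F1 genotype {x, y} given
# the F0 parents' allele sets. Returns a 2-column character matrix, one row
# per consistent phasing (0 rows = Mendelian inconsistency).
f1_phasings <- function(f1_alleles, e_alleles, w_alleles) {
  x <- f1_alleles[1L]; y <- f1_alleles[2L]
  cand <- unique(rbind(c(x, y), c(y, x)))
  keep <- cand[, 1L] %in% e_alleles & cand[, 2L] %in% w_alleles
  cand[keep, , drop = FALSE]
}

#' Phase F1 genotypes against their F0 parents
#'
#' For each F1 individual and marker, assigns each allele to the E-line or
#' W-line parent where the assignment is uniquely determined by the parents'
#' allele sets; markers where both orderings are consistent are left
#' unresolved (both phasings are retained and marginalised over in the HMM
#' emissions). An F1 allele pair consistent with neither ordering is a
#' Mendelian inconsistency.
#'
#' @param ped Pedigree data.frame (see [read_pedigree()]).
#' @param geno Genotype data.frame for F0 + F1 individuals.
#' @return A named list (one element per F1 individual) of named lists (one
#'   per genotyped marker), each a phasing matrix with columns (E, W): one
#'   row when resolved, two when unresolved, and an error is thrown on
#'   inconsistency. Markers with a missing genotype in the F1 or either
#'   parent are absent (treated as uninformative).
#' @export
phase_f1 <- function(ped, geno) {
  f1 <- ped$id[ped$generation == "F1"]
  line_of <- stats::setNames(ped$line, ped$id)
  out <- vector("list", length(f1))
  names(out) <- f1
  gsplit <- split(geno, geno$id)
  for (ind in f1) {
    sire <- ped$sire[ped$id == ind]
    dam <- ped$dam[ped$id == ind]
    parents <- c(sire, dam)
    lines <- line_of[parents]
    if (any(is.na(lines)) || !setequal(lines, c("E", "W")))
      stop("F1 ", ind, " does not have one E-line and one W-line parent")
    e_par <- parents[lines == "E"]; w_par <- parents[lines == "W"]
    g_ind <- gsplit[[ind]]; g_e <- gsplit[[e_par]]; g_w <- gsplit[[w_par]]
    res <- list()
    if (!is.null(g_ind)) for (k in seq_len(nrow(g_ind))) {
      mk <- g_ind$marker[k]
      fa <- c(g_ind$a1[k], g_ind$a2[k])
      if (anyNA(fa)) next
      ea <- c(g_e$a1[g_e$marker == mk], g_e$a2[g_e$marker == mk])
      wa <- c(g_w$a1[g_w$marker == mk], g_w$a2[g_w$marker == mk])
      if (length(ea) == 0L || anyNA(ea) || length(wa) == 0L || anyNA(wa)) next
      ph <- f1_phasings(fa, ea, wa)
      if (nrow(ph) == 0L)
        stop("Mendelian inconsistency: F1 ", ind, " at marker ", mk,
             " carries an allele found in neither parent")
      res[[mk]] <- ph
    }
    out[[ind]] <- res
  }
  out
}
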