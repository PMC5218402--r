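# Readers for the tab-delimited phenotype/explanatory-variable layout and
# the pipeline driver chaining the analysis stages: adjust the phenotype,
# single-locus scan with a permutation threshold and forward search,
# two-locus scan with genomewide and locus-specific SSE thresholds, model
# simplification, independent-locus testing, and the effects report.

#' Read a phenotype / explanatory-variable table
#'
#' Tab-delimited with a header; one row per individual with an
#' `individual` column; "NA" for missing. Required columns beyond
#' `individual` can be declared and are checked; extra columns are kept.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return data.frame with `id` first.
#' @export
read_phenotype_table <- function(path, required = character()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!"individual" %in% names(x) && !"id" %in% names(x))
    stop("phenotype table lacks an 'individual' (or 'id') column")
  if ("individual" %in% names(x)) {
    x$id <- as.character(x$individual)
    x$individual <- NULL
  } else x$id <- as.character(x$id)
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, c("id", setdiff(names(x), "id"))]
}

#' Run the complete QTL analysis for one trait
#'
#' Chains the pipeline: (1) base model — REML fit of the explanatory
#' variables with mother as a random effect, backward-selected at p < 0.05,
#' giving the adjusted phenotype; (2) single-locus scan with a genomewide
#' permutation F threshold and iterative forward search; (3) two-locus scan
#' with the genomewide SSE threshold, locus-specific SSE thresholds over
#' the QTL spans, cluster-peak selection with the edge-effect rule, and
#' interaction tests; (4) assembly of the full REML model and sequential
#' simplification; (5) testing of remaining independent loci; (6) the
#' background-conditional effects report with Holm correction,
#' standardisation, and variance explained.
#'
#' @param data data.frame with the raw phenotype, covariates and mother id
#'   (column `id` identifying individuals).
#' @param response Phenotype column.
#' @param candidates Candidate explanatory-variable terms.
#' @param grid An `ad_grid` covering the individuals.
#' @param mother Maternal grouping column (default "mother").
#' @param n_perm Permutations for each threshold (default 1000).
#' @param alpha Genomewide level (default 0.05).
#' @param step Two-locus scan-lattice spacing in cM (default 5).
#' @param gap_max,min_sep,match_dist Span gap-merge, within-chromosome
#'   pair separation, and locus matching/merging distances in cM.
#' @param backward Run backward selection of covariates (default TRUE;
#'   FALSE fits all candidates).
#' @return list of class `qtl_pipeline` with elements `base` (the base
#'   model), `threshold_F`, `qtl` (putative QTL + `sse_specific`),
#'   `sse_genome`, `epi_pairs` (putative epistatic pairs), `final` (the
#'   simplified `full_model_fit`), `independent_qtl`, `effects` (per-pair
#'   conditional effects), and `variance` (percent residual variance
#'   explained by independent, epistatic and all QTL).
#' @export
run_pipeline <- function(data, response, candidates, grid,
                         mother = "mother", n_perm = 1000, alpha = 0.05,
                         step = 5, gap_max = 10, min_sep = 20,
                         match_dist = 20, backward = TRUE) {
  base <- if (backward)
    backward_select(data, response, candidates, mother, alpha = 0.05)
  else fit_base_model(data, response, candidates, mother)
  ytilde <- base$adjusted
  keep <- match(names(ytilde), grid$ids)
  if (anyNA(keep)) stop("adjusted phenotypes for individuals not in grid")
  g <- grid
  g$ids <- grid$ids[keep]
  for (mm in intersect(c("A", "D", "pEE", "pEW", "pWW"), names(grid)))
    g[[mm]] <- grid[[mm]][keep, , drop = FALSE]
  y <- unname(ytilde)

  thr <- permutation_threshold(y, g, n_perm = n_perm, alpha = alpha)
  qtl <- forward_search(y, g, thr$threshold, gap_max = gap_max)
  qtl$sse_specific <- rep(NA_real_, nrow(qtl))
  if (nrow(qtl)) for (r in seq_len(nrow(qtl)))
    qtl$sse_specific[r] <- locus_specific_sse_threshold(
      y, g, qtl$chr[r], qtl$pos[r], n_perm = n_perm, alpha = alpha,
      step = step, min_sep = min_sep)$threshold
  sse_genome <- genomewide_sse_threshold(y, g, n_perm = n_perm,
                                         alpha = alpha, step = step,
                                         min_sep = min_sep)$threshold
  epi <- find_epistatic_pairs(y, g, qtl, sse_genome, step = step,
                              min_sep = min_sep)

  spec <- assemble_model(base$data, response, base$terms, mother, qtl,
                         pairs = if (nrow(epi)) epi else NULL,
                         match_dist = match_dist)
  fm <- simplify_model(spec, g, match_dist = match_dist)
  fm <- test_independent_loci(fm, g)
  base_sd <- sqrt(base$sigma2)
  pss_base <- unname(base$fit@devcomp$cmp["pwrss"])

  effects <- lapply(seq_along(fm$spec$pairs), function(k)
    pair_effects(fm, k, base_sd))
  var_expl <- list()
  locus_cols <- unlist(fm$colmap$locus, use.names = FALSE)
  pair_cols <- unlist(fm$colmap$pair, use.names = FALSE)
  in_pair <- unique(unlist(lapply(fm$spec$pairs, function(p) c(p$l1, p$l2))))
  indep_cols <- unlist(fm$colmap$locus[as.character(
    setdiff(fm$spec$indep, in_pair))], use.names = FALSE)
  epi_cols <- c(unlist(fm$colmap$locus[as.character(in_pair)],
                       use.names = FALSE), pair_cols)
  if (length(c(locus_cols, pair_cols))) {
    var_expl$all <- variance_explained(fm, c(locus_cols, pair_cols), pss_base)
    var_expl$independent <- if (length(indep_cols))
      variance_explained(fm, indep_cols, pss_base) else 0
    var_expl$epistatic <- if (length(epi_cols))
      variance_explained(fm, epi_cols, pss_base) else 0
  } else var_expl <- list(all = 0, independent = 0, epistatic = 0)

  out <- list(base = base, threshold_F = thr$threshold, qtl = qtl,
              sse_genome = sse_genome, epi_pairs = epi, final = fm,
              independent_qtl = attr(fm, "independent_qtl"),
              effects = effects, variance = var_expl,
              settings = list(n_perm = n_perm, alpha = alpha, step = step,
                              gap_max = gap_max, min_sep = min_sep,
                              match_dist = match_dist))
  class(out) <- "qtl_pipeline"
  out
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  cat("QTL pipeline result\n")
  cat("  putative QTL:", nrow(x$qtl), " epistatic pairs:",
      length(x$final$spec$pairs), " independent QTL:",
      nrow(x$independent_qtl), "\n")
  cat(sprintf("  variance explained (%%): all %.1f, independent %.1f, epistatic %.1f\n",
              x$variance$all, x$variance$independent, x$variance$epistatic))
  invisible(x)
}

#' Write the scan and pair tables of a pipeline result
#'
#' Emits tab-delimited artefacts: the single-locus scan, the putative-QTL
#' table, the thresholded pair scan (heat map in long form) and the
#' epistatic-pair table.
#'
#' @param res A `qtl_pipeline` result.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_pipeline_tables <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(qtl = file.path(dir, "putative_qtl.tsv"),
             pairs = file.path(dir, "pair_scan.tsv"),
             epi = file.path(dir, "epistatic_pairs.tsv"))
  utils::write.table(res$qtl, paths["qtl"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pr <- attr(res$epi_pairs, "pairs")
  if (!is.null(pr))
    utils::write.table(pr, paths["pairs"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  utils::write.table(res$epi_pairs, paths["epi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
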