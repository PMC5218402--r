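#' Construct a sex-specific linkage map
#'
#' A linkage map holds, for every marker, its chromosome and its position on
#' the female, male and sex-averaged maps (cM). Positions must be
#' non-decreasing within a chromosome for each sex. Maps built from
#' Kosambi-scale positions should be converted marker-interval by
#' marker-interval with [kosambi_to_haldane()] before interval mapping.
#'
#' @param chr Chromosome label per marker.
#' @param marker Marker names (unique).
#' @param female,male,sexavg Positions in cM per marker.
#' @param map_function Scale the positions are on: "haldane" or "kosambi".
#' @return A data.frame of class `linkage_map` with columns
#'   `chr`, `marker`, `female`, `male`, `sexavg`.
#' @export
linkage_map <- function(chr, marker, female, male, sexavg = (female + male) / 2,
                        map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (anyDuplicated(marker)) stop("duplicated marker names")
  m <- data.frame(chr = as.character(chr), marker = as.character(marker),
                  female = as.numeric(female), male = as.numeric(male),
                  sexavg = as.numeric(sexavg), stringsAsFactors = FALSE)
  m <- m[order(m$chr, m$sexavg), ]
  rownames(m) <- NULL
  for (cc in unique(m$chr)) {
    sub <- m[m$chr == cc, ]
    for (col in c("female", "male", "sexavg"))
      if (is.unsorted(sub[[col]]))
        stop("positions not non-decreasing on chromosome ", cc, " (", col, ")")
  }
  attr(m, "map_function") <- map_function
  class(m) <- c("linkage_map", "data.frame")
  m
}

#' Convert a whole linkage map from Kosambi to Haldane distances
#'
#' Inter-marker distances (not absolute positions) are converted for each
#' sex, then re-accumulated from the first marker of each chromosome.
#'
#' @param map A `linkage_map` on the Kosambi scale.
#' @return A `linkage_map` on the Haldane scale.
#' @export
map_to_haldane <- function(map) {
  if (attr(map, "map_function") == "haldane") return(map)
  out <- map
  for (cc in unique(map$chr)) {
    i <- which(map$chr == cc)
    for (col in c("female", "male", "sexavg")) {
      p <- map[[col]][i]
      out[[col]][i] <- p[1L] + c(0, cumsum(kosambi_to_haldane(diff(p))))
    }
  }
  attr(out, "map_function") <- "haldane"
  out
}

#' Read / write a linkage map file
#'
#' Tab-delimited with header `chromosome  marker  female_cM  male_cM
#' sexavg_cM`.
#'
#' @param path File path.
#' @param map_function Scale of the stored positions.
#' @return A `linkage_map`.
#' @export
read_linkage_map <- function(path, map_function = "haldane") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "marker", "female_cM", "male_cM", "sexavg_cM")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("map file missing column(s): ", paste(miss, collapse = ", "))
  linkage_map(x$chromosome, x$marker, x$female_cM, x$male_cM, x$sexavg_cM,
              map_function = map_function)
}

#' @rdname read_linkage_map
#' @param map A `linkage_map` to write.
#' @export
write_linkage_map <- function(map, path) {
  out <- data.frame(chromosome = map$chr, marker = map$marker,
                    female_cM = map$female, male_cM = map$male,
                    sexavg_cM = map$sexavg)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Interpolate female/male coordinates for arbitrary sex-averaged positions on
# one chromosome. Outside the marker frame the end intervals' expansion
# ratios are carried on (positions before the first marker only arise for
# grids anchored at 0).
sex_positions <- function(map, chr, pos_sexavg) {
  sub <- map[map$chr == chr, ]
  if (nrow(sub) == 0L) stop("no markers on chromosome ", chr)
  interp <- function(col) {
    sa <- sub$sexavg; v <- sub[[col]]
    if (nrow(sub) == 1L) return(v + (pos_sexavg - sa))
    # rule 2 clamps; handle the outside linearly with the nearest interval slope
    out <- stats::approx(sa, v, xout = pos_sexavg, rule = 2)$y
    lo <- pos_sexavg < sa[1L]
    hi <- pos_sexavg > sa[length(sa)]
    if (any(lo)) {
      s <- (v[2L] - v[1L]) / max(sa[2L] - sa[1L], 1e-12)
      out[lo] <- v[1L] + (pos_sexavg[lo] - sa[1L]) * s
    }
    if (any(hi)) {
      n <- length(sa)
      s <- (v[n] - v[n - 1L]) / max(sa[n] - sa[n - 1L], 1e-12)
      out[hi] <- v[n] + (pos_sexavg[hi] - sa[n]) * s
    }
    out
  }
  data.frame(sexavg = pos_sexavg, female = interp("female"), male = interp("male"))
}
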