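#' Convert a Kosambi map distance to the Haldane scale
#'
#' Interval mapping under a no-interference model requires Haldane map
#' distances. A Kosambi distance \eqn{d} (cM) is first converted to a
#' recombination fraction with the inverse Kosambi function
#' \eqn{r = 0.5\,\tanh(2d/100)} and then back to a distance with Haldane's
#' function \eqn{-50\,\log(1 - 2r)}.
#'
#' @param d Numeric vector of Kosambi map distances in cM (non-negative).
#' @return Numeric vector of Haldane distances in cM. For any `d > 0` the
#'   Haldane distance exceeds the Kosambi distance.
#' @examples
#' kosambi_to_haldane(10)   # 10.99 cM
#' @export
kosambi_to_haldane <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distances must be non-negative")
  r <- 0.5 * tanh(2 * d / 100)
  -50 * log1p(-2 * r)
}

#' Haldane map function: distance to recombination fraction
#'
#' @param d Numeric vector of Haldane map distances in cM (non-negative).
#' @return Recombination fraction \eqn{r = 0.5(1 - e^{-2d/100})} in
#'   \eqn{[0, 0.5)}.
#' @examples
#' haldane_recombination(50)  # 0.3161
#' @export
haldane_recombination <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distances must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Convert a position between two linkage maps by interpolation
#'
#' Positions are carried from one map to another using the nearest markers
#' flanking the position that are present on both maps, with linear
#' interpolation between their coordinates. A position coinciding with a
#' shared marker maps to that marker's coordinate. Extrapolation beyond the
#' shared markers is refused.
#'
#' @param pos Position (cM) on the source map.
#' @param chr Chromosome label.
#' @param source_map,target_map [linkage_map] objects.
#' @param sex Which position column to use: "sexavg" (default), "female" or
#'   "male".
#' @return Interpolated position (cM) on the target map.
#' @export
convert_position <- function(pos, chr, source_map, target_map, sex = "sexavg") {
  col <- match.arg(sex, c("sexavg", "female", "male"))
  src <- source_map[source_map$chr == chr, ]
  tgt <- target_map[target_map$chr == chr, ]
  shared <- intersect(src$marker, tgt$marker)
  if (length(shared) == 0L)
    stop("no shared markers on chromosome ", chr)
  sp <- src[[col]][match(shared, src$marker)]
  tp <- tgt[[col]][match(shared, tgt$marker)]
  o <- order(sp)
  sp <- sp[o]; tp <- tp[o]
  at <- which(abs(sp - pos) < 1e-9)
  if (length(at)) return(tp[at[1L]])
  lo <- which(sp < pos)
  hi <- which(sp > pos)
  if (!length(lo) || !length(hi))
    stop("position ", pos, " on chromosome ", chr,
         " is outside the shared-marker interval; refusing to extrapolate")
  l <- max(lo); h <- min(hi)
  tp[l] + (pos - sp[l]) / (sp[h] - sp[l]) * (tp[h] - tp[l])
}
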