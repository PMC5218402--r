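#' Write / read an A/D grid file
#'
#' Tab-delimited, one row per individual with an `individual` column;
#' remaining columns are labelled `chromosome.position.A` and
#' `chromosome.position.D` (position in cM), paired per grid position.
#'
#' @param grid An `ad_grid` object.
#' @param path File path.
#' @export
write_ad_grid <- function(grid, path) {
  P <- nrow(grid$map)
  lab <- paste(grid$map$chr, format(grid$map$pos, trim = TRUE, scientific = FALSE),
               sep = ".")
  out <- matrix(0, length(grid$ids), 2L * P)
  out[, seq(1L, 2L * P, by = 2L)] <- grid$A
  out[, seq(2L, 2L * P, by = 2L)] <- grid$D
  cn <- character(2L * P)
  cn[seq(1L, 2L * P, by = 2L)] <- paste0(lab, ".A")
  cn[seq(2L, 2L * P, by = 2L)] <- paste0(lab, ".D")
  df <- data.frame(individual = grid$ids, out, check.names = FALSE)
  names(df) <- c("individual", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ad_grid
#' @return `read_ad_grid()` returns an `ad_grid` (without posterior
#'   matrices; only `A` and `D` are stored in the file).
#' @export
read_ad_grid <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"individual" %in% names(x)) stop("A/D grid file lacks an 'individual' column")
  ids <- as.character(x$individual)
  cols <- setdiff(names(x), "individual")
  m <- regmatches(cols, regexec("^(.+)\\.([0-9.]+)\\.([AD])$", cols))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable A/D column name(s): ",
                     paste(cols[bad], collapse = ", "))
  info <- data.frame(col = cols,
                     chr = vapply(m, `[`, "", 2L),
                     pos = as.numeric(vapply(m, `[`, "", 3L)),
                     var = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
  acols <- info[info$var == "A", ]
  dcols <- info[info$var == "D", ]
  key <- function(z) paste(z$chr, z$pos)
  if (!setequal(key(acols), key(dcols)))
    stop("unpaired A/D columns: every position needs both an .A and a .D column")
  o <- order(acols$chr, acols$pos)
  acols <- acols[o, ]
  dcols <- dcols[match(key(acols), key(dcols)), ]
  A <- as.matrix(x[, acols$col, drop = FALSE])
  D <- as.matrix(x[, dcols$col, drop = FALSE])
  if (any(A < -1 - 1e-9 | A > 1 + 1e-9))
    stop("A values outside [-1, 1] in ", path)
  if (any(D < -1e-9 | D > 1 + 1e-9))
    stop("D values outside [0, 1] in ", path)
  dimnames(A) <- dimnames(D) <- NULL
  out <- list(ids = ids,
              map = data.frame(chr = acols$chr, pos = acols$pos),
              A = A, D = D)
  class(out) <- "ad_grid"
  out
}

# Column index of the grid position nearest to (chr, pos); errors if the
# chromosome is absent.
grid_index <- function(grid, chr, pos) {
  i <- which(grid$map$chr == as.character(chr))
  if (!length(i)) stop("chromosome ", chr, " not in grid")
  i[which.min(abs(grid$map$pos[i] - pos))]
}
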