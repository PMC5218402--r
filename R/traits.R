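# Growth-trait derivation and inclusion filters.
#
# Animal records are one row per individual with weights at the nominal ages
# (kg): w0, w21, w46, w120, w210, w240; actual measurement ages (days) for
# the later weighings: a120, a210, a240 (the first three are taken at fixed
# ages); and covariates: sex, batch, parity, mother, foster_mother,
# group_size, castrated, castration_age, move_age (NA = not moved), starved,
# n_offspring, n_live_offspring, died (TRUE if the animal died before the
# experimental endpoint).

#' Trait definitions for the growth intervals
#'
#' Birth weight plus weight gain over six age intervals, with the
#' measurement-age and interval-length inclusion windows applied to the
#' later, variable-age weighings.
#'
#' @return A named list, one element per trait, each with `start`, `end`
#'   (nominal ages in days; `NA` start for birth weight), inclusion
#'   `windows` (list of `c(lo, hi)` for first/second measurement age and
#'   interval length, where constrained), and `post46` (whether females of
#'   batches 1-2 are excluded).
#' @export
trait_definitions <- function() {
  list(
    BW        = list(start = NA,  end = 0,   windows = list(), post46 = FALSE),
    G_0_21    = list(start = 0,   end = 21,  windows = list(), post46 = FALSE),
    G_21_46   = list(start = 21,  end = 46,  windows = list(), post46 = FALSE),
    G_46_120  = list(start = 46,  end = 120,
                     windows = list(second = c(119, 130)), post46 = TRUE),
    G_120_210 = list(start = 120, end = 210,
                     windows = list(first = c(119, 130), second = c(209, 213),
                                    interval = c(80, 90)), post46 = TRUE),
    G_46_210  = list(start = 46,  end = 210,
                     windows = list(second = c(205, 213)), post46 = TRUE),
    G_210_240 = list(start = 210, end = 240,
                     windows = list(first = c(207, 211), second = c(237, 242),
                                    interval = c(27, 34)), post46 = TRUE)
  )
}

weight_col <- function(age) paste0("w", age)
age_col <- function(age) if (age %in% c(0, 21, 46)) NULL else paste0("a", age)

# actual measurement age for a nominal age (fixed for 0/21/46)
actual_age <- function(records, age) {
  ac <- age_col(age)
  if (is.null(ac)) rep(age, nrow(records)) else records[[ac]]
}

#' Derive trait values from animal records
#'
#' Birth weight is the day-0 weight; a growth trait is the difference of the
#' two endpoint weights. Individuals missing either endpoint weight are NA
#' for that trait.
#'
#' @param records Animal-record data.frame (see package overview / the
#'   simulator's output).
#' @return data.frame with `id` and one column per trait.
#' @export
derive_traits <- function(records) {
  defs <- trait_definitions()
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  for (tn in names(defs)) {
    d <- defs[[tn]]
    out[[tn]] <- if (is.na(d$start)) records[[weight_col(d$end)]]
      else records[[weight_col(d$end)]] - records[[weight_col(d$start)]]
  }
  out
}

# TRUE where weight declined over the experiment; the final (post-starvation)
# weight is exempt for starved animals.
weight_declined <- function(records) {
  ages <- c(0, 21, 46, 120, 210, 240)
  w <- as.matrix(records[, weight_col(ages)])
  dec <- rep(FALSE, nrow(records))
  for (k in 2:length(ages)) {
    last_is_starved <- (k == length(ages)) &
      !is.na(records$starved) & records$starved
    d <- w[, k] < w[, k - 1L]
    d[is.na(d)] <- FALSE
    dec <- dec | (d & !last_is_starved)
  }
  dec
}

#' Apply a trait's inclusion filters
#'
#' Retains individuals that (i) have both endpoint weights, (ii) meet the
#' trait's measurement-age and interval-length windows, (iii) did not die
#' before the experimental endpoint, (iv) did not lose weight over the
#' course of the experiment (final starvation weight exempt), and (v) for
#' traits measuring growth after day 46, are not females of batches 1-2
#' (different diet).
#'
#' @param records Animal-record data.frame.
#' @param trait Trait name (see [trait_definitions()]).
#' @return Logical inclusion vector aligned to `records`, with a
#'   `counts` attribute recording how many individuals each filter removed.
#' @export
apply_filters <- function(records, trait) {
  d <- trait_definitions()[[trait]]
  if (is.null(d)) stop("unknown trait: ", trait)
  n <- nrow(records)
  keep <- rep(TRUE, n)
  counts <- c()
  step <- function(ok, label) {
    ok[is.na(ok)] <- FALSE
    removed <- sum(keep & !ok)
    keep <<- keep & ok
    counts <<- c(counts, stats::setNames(removed, label))
  }
  have <- !is.na(records[[weight_col(d$end)]])
  if (!is.na(d$start)) have <- have & !is.na(records[[weight_col(d$start)]])
  step(have, "missing_weight")
  if (!is.null(d$windows$first)) {
    a <- actual_age(records, d$start)
    step(a >= d$windows$first[1] & a <= d$windows$first[2], "first_age_window")
  }
  if (!is.null(d$windows$second)) {
    a <- actual_age(records, d$end)
    step(a >= d$windows$second[1] & a <= d$windows$second[2], "second_age_window")
  }
  if (!is.null(d$windows$interval)) {
    iv <- actual_age(records, d$end) - actual_age(records, d$start)
    step(iv >= d$windows$interval[1] & iv <= d$windows$interval[2],
         "interval_window")
  }
  step(!records$died, "died")
  step(!weight_declined(records), "weight_declined")
  if (d$post46)
    step(!(records$sex == "F" & records$batch %in% c(1, 2, "1", "2")),
         "female_batch12")
  attr(keep, "counts") <- counts
  keep
}
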