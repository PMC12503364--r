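## Distal-histidine swing-out event statistics: detection against the
## 7 Angstrom (0.7 nm) threshold, per-treatment counting with
## simulation-time correction, and first-passage-time normalization.

#' Detect a swing-out event in a HisE7 Nepsilon-Fe distance trace
#'
#' A swing-out event is binary per chain-replicate trace: did the
#' distance ever exceed the threshold (strictly greater than 0.7 nm =
#' 7 Angstrom by default) on analyzed frames (t >= equilibration
#' cutoff). Excursion-level detail (maximal runs above threshold) is
#' recorded too, and a return to the down position is scored when,
#' after the first excursion, the trace falls to `down_threshold` or
#' below and stays there for at least `dwell_min` ns (the dwell
#' requirement avoids counting single-frame dips).
#'
#' @param trace a `DistanceTrace`.
#' @param threshold swing-out threshold, nm; exceeding is strict (a
#'   frame at exactly the threshold does not count).
#' @param down_threshold return-to-down threshold, nm.
#' @param dwell_min minimum time (ns) the trace must stay at or below
#'   `down_threshold` for a return to count.
#' @param replicate_id,chain_id labels carried into the record.
#' @param replicate_total_time total simulated time of this replicate,
#'   ns; defaults to the last frame time of the trace.
#' @return list of class `SwingRecord`: `swung_out`,
#'   `first_exceed_time` (ns or NA), `excursions` (data.frame of
#'   start/end ns, `end` NA when still up at the last frame),
#'   `returned_down`, `replicate_total_time`, plus the labels.
#' @export
detect_swing <- function(trace, threshold = 0.7, down_threshold = 0.7,
                         dwell_min = 5, replicate_id = NA, chain_id = NA,
                         replicate_total_time = NULL) {
  av <- analyzed_frames(trace)
  if (!length(av$times)) stop("no analyzed frames (trace entirely before cutoff)")
  up <- av$values > threshold
  total_time <- replicate_total_time %||% max(trace$times)

  excursions <- data.frame(start = numeric(0), end = numeric(0))
  if (any(up)) {
    r <- rle(up)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      open_ended <- ends[k] == length(up)
      excursions <- rbind(excursions, data.frame(
        start = av$times[starts[k]],
        end = if (open_ended) NA_real_ else av$times[ends[k]]))
    }
  }
  swung <- any(up)
  first_t <- if (swung) av$times[which(up)[1]] else NA_real_

  returned <- FALSE
  if (swung) {
    ## frames after the first excursion's last above-threshold frame
    first_run_end <- which(up)[1] + rle(up[which(up)[1]:length(up)])$lengths[1] - 1L
    if (first_run_end < length(up)) {
      tail_idx <- (first_run_end + 1L):length(up)
      down <- av$values[tail_idx] <= down_threshold
      r <- rle(down)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        span <- av$times[tail_idx[ends[k]]] - av$times[tail_idx[starts[k]]]
        if (span >= dwell_min) { returned <- TRUE; break }
      }
    }
  }

  structure(list(replicate_id = replicate_id, chain_id = chain_id,
                 swung_out = swung, first_exceed_time = first_t,
                 excursions = excursions, returned_down = returned,
                 replicate_total_time = total_time),
            class = "SwingRecord")
}

#' @export
print.SwingRecord <- function(x, ...) {
  cat(sprintf("SwingRecord [rep %s, chain %s]: %s", x$replicate_id, x$chain_id,
              if (x$swung_out)
                sprintf("swung out at %.1f ns (%d excursion(s), returned: %s)",
                        x$first_exceed_time, nrow(x$excursions),
                        x$returned_down)
              else "no swing-out"), "\n")
  invisible(x)
}

records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    replicate_id = r$replicate_id, chain_id = r$chain_id,
    swung_out = r$swung_out, first_exceed_time = r$first_exceed_time,
    n_excursions = nrow(r$excursions), returned_down = r$returned_down,
    replicate_total_time = r$replicate_total_time,
    stringsAsFactors = FALSE)))
}

treatment_total_time <- function(records) {
  t <- vapply(records, function(r) r$replicate_total_time, numeric(1))
  id <- vapply(records, function(r) as.character(r$replicate_id), character(1))
  sum(t[!duplicated(id)])
}

#' Count swing-out events for one treatment
#'
#' Raw count = number of chain-replicate records that ever exceeded the
#' threshold (so with 2 alpha chains x 5 replicates the maximum is 10).
#' To account for unequal simulation lengths the count is corrected for
#' the total simulation time (sum over distinct replicates) of the
#' treatment: `normalized = raw * reference_total_time /
#' treatment_total_time`.
#'
#' @param records list of `SwingRecord`s from one treatment.
#' @param reference_total_time ns; the total time the counts are
#'   normalized to (typically the largest treatment total in the
#'   comparison).
#' @param label treatment label (species x protonation state).
#' @return list of class `TreatmentSummary`.
#' @export
count_events <- function(records, reference_total_time, label = "treatment") {
  stopifnot(length(records) > 0)
  total <- treatment_total_time(records)
  if (total <= 0) stop("treatment total simulation time is zero")
  if (reference_total_time <= 0) stop("reference_total_time must be positive")
  raw <- sum(vapply(records, function(r) r$swung_out, logical(1)))
  returned <- sum(vapply(records, function(r) r$returned_down, logical(1)))
  structure(list(label = label,
                 n_chain_replicates = length(records),
                 raw_event_count = raw,
                 returned_down_count = returned,
                 time_correction = reference_total_time / total,
                 normalized_event_count = raw * reference_total_time / total,
                 total_time = total,
                 reference_total_time = reference_total_time),
            class = "TreatmentSummary")
}

#' @export
print.TreatmentSummary <- function(x, ...) {
  cat(sprintf(
    "TreatmentSummary [%s]: %d/%d swing-outs (normalized %.2f; x%.3f time correction), %d returned down\n",
    x$label, x$raw_event_count, x$n_chain_replicates,
    x$normalized_event_count, x$time_correction, x$returned_down_count))
  invisible(x)
}

#' Normalized swing-out (first-passage) times
#'
#' Only records where an event occurred contribute; replicates with no
#' transition are excluded, not zero. Each contributing first-passage
#' time is corrected for differences in simulation length within the
#' treatment (scaled to the longest replicate) and for total simulation
#' time between treatments:
#' `t_norm = t_first * (longest_replicate_time / replicate_total_time)
#'  * (reference_total_time / treatment_total_time)`.
#' Both factors are returned separately so alternative readings of the
#' normalization can be recomputed from the same table.
#'
#' @param records list of `SwingRecord`s from one treatment.
#' @param longest_replicate_time ns; defaults to the longest replicate
#'   among `records`.
#' @param reference_total_time,treatment_total_time ns; default to the
#'   treatment's own total (factors of 1).
#' @return data.frame with one row per contributing record:
#'   `first_exceed_time`, `length_factor`, `time_factor`,
#'   `normalized_time`; zero rows when no events occurred. The mean of
#'   `normalized_time` is the treatment's swing-out time.
#' @export
normalized_swing_times <- function(records,
                                   longest_replicate_time = NULL,
                                   reference_total_time = NULL,
                                   treatment_total_time = NULL) {
  tot <- treatment_total_time %||% sum(
    vapply(records, function(r) r$replicate_total_time, numeric(1))[
      !duplicated(vapply(records, function(r) as.character(r$replicate_id),
                         character(1)))])
  longest <- longest_replicate_time %||%
    max(vapply(records, function(r) r$replicate_total_time, numeric(1)))
  ref <- reference_total_time %||% tot
  contrib <- Filter(function(r) isTRUE(r$swung_out), records)
  if (!length(contrib))
    return(data.frame(replicate_id = character(0), chain_id = character(0),
                      first_exceed_time = numeric(0), length_factor = numeric(0),
                      time_factor = numeric(0), normalized_time = numeric(0)))
  do.call(rbind, lapply(contrib, function(r) {
    lf <- longest / r$replicate_total_time
    tf <- ref / tot
    data.frame(replicate_id = as.character(r$replicate_id),
               chain_id = as.character(r$chain_id),
               first_exceed_time = r$first_exceed_time,
               length_factor = lf, time_factor = tf,
               normalized_time = r$first_exceed_time * lf * tf,
               stringsAsFactors = FALSE)
  }))
}
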