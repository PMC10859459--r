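# Reference-normalized intensity tracks.
#
# The pipeline starts from per-marker log-R intensities (log-scale signal
# summaries produced upstream of this package). Normalization against the
# wild-type reference is subtraction on the log2 scale: a sample at half the
# reference intensity sits at -1.

#' Normalize sample log-R values against a reference
#'
#' Computes `sample - reference` per marker on the log2 scale, so negative
#' values mean weaker signal than the reference. Inputs must cover the same
#' markers in the same order; when both vectors are named the names are
#' checked and mismatches reported. Missing values propagate as `NA`.
#'
#' @param sample_values numeric log-R values, optionally named by marker id.
#' @param reference_values numeric log-R values for the reference sample.
#' @return numeric vector of normalized values, named like the inputs.
#' @examples
#' normalize_against_reference(c(m1 = -1, m2 = 0), c(m1 = 0, m2 = 0))
#' @export
normalize_against_reference <- function(sample_values, reference_values) {
  if (length(sample_values) != length(reference_values)) {
    stop_("sample and reference cover different numbers of markers (%d vs %d)",
          length(sample_values), length(reference_values))
  }
  ns <- names(sample_values)
  nr <- names(reference_values)
  if (!is.null(ns) && !is.null(nr) && !identical(ns, nr)) {
    bad <- unique(c(setdiff(ns, nr), setdiff(nr, ns), ns[ns != nr]))
    stop_("marker mismatch between sample and reference: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  sample_values - reference_values
}

#' Construct a per-chromosome normalized signal track
#'
#' @param position marker positions in bp, strictly increasing.
#' @param value normalized log2-scale intensities (same length).
#' @param chromosome chromosome name.
#' @param sample_id sample label.
#' @param marker_id optional marker ids.
#' @return `data.frame` of class `signal_track` with columns `position`,
#'   `value` (and `marker_id` if given); chromosome and sample are attributes.
#' @export
signal_track <- function(position, value, chromosome = "chr1",
                         sample_id = "sample", marker_id = NULL) {
  if (length(position) != length(value)) {
    stop_("position and value must have equal length")
  }
  if (is.unsorted(position, strictly = TRUE)) {
    stop_("positions must be strictly increasing within a chromosome")
  }
  df <- data.frame(position = position, value = value)
  if (!is.null(marker_id)) df$marker_id <- marker_id
  structure(df, class = c("signal_track", "data.frame"),
            chromosome = chromosome, sample_id = sample_id)
}

#' Split normalized values into per-chromosome signal tracks
#'
#' @param map a `marker_map` (columns `marker_id`, `chromosome`, `position`).
#' @param values normalized values aligned with the rows of `map` (or named
#'   by marker id, in which case they are matched).
#' @param sample_id sample label stored on each track.
#' @return named list of [signal_track()] objects, one per chromosome.
#' @export
signal_tracks <- function(map, values, sample_id = "sample") {
  if (!is.null(names(values))) values <- values[map$marker_id]
  if (length(values) != nrow(map)) {
    stop_("values do not align with the marker map")
  }
  chroms <- unique(map$chromosome)
  out <- lapply(chroms, function(ch) {
    i <- map$chromosome == ch
    signal_track(map$position[i], unname(values[i]), chromosome = ch,
                 sample_id = sample_id, marker_id = map$marker_id[i])
  })
  names(out) <- chroms
  out
}

#' Flag weak-signal markers
#'
#' A marker is "weak" when its normalized value is at or below `threshold`
#' (default -1, i.e. at most half the reference intensity). `NA` values are
#' never flagged.
#'
#' @param track a [signal_track()] or a numeric vector of normalized values.
#' @param threshold log2-scale cut-off, must be negative.
#' @return logical vector, one element per marker.
#' @export
weak_signal_mask <- function(track, threshold = -1) {
  if (threshold >= 0) stop_("threshold must be negative")
  v <- if (is.data.frame(track)) track$value else track
  out <- v <= threshold
  out[is.na(out)] <- FALSE
  out
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s, sample %s: %d markers, %s..%s bp\n",
              attr(x, "chromosome"), attr(x, "sample_id"), nrow(x),
              format(min(x$position)), format(max(x$position))))
  invisible(x)
}
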