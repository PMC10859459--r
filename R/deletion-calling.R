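# Deletion calling: segmentation candidates confirmed by OTV density, with a
# sliding-window fallback over weak/OTV/outlier evidence when segmentation
# finds nothing on a chromosome.

#' Configuration for [call_deletions()]
#'
#' @param weak_threshold per-marker weak-signal cut-off (log2 units, < 0).
#' @param weak_mean_threshold segment-mean cut-off for a candidate segment.
#' @param min_otv_fraction minimum OTV fraction inside a candidate segment
#'   for it to be retained.
#' @param outlier_alpha family-wise significance for the studentized outlier
#'   test (Bonferroni-adjusted per chromosome).
#' @param fallback_window sliding-window width (markers) for the fallback
#'   scan.
#' @param fallback_density minimum evidence density within a window.
#' @param penalty,max_changepoints passed to [binary_segmentation()].
#' @return named list of class `deletion_config`.
#' @export
deletion_config <- function(weak_threshold = -1,
                            weak_mean_threshold = -1,
                            min_otv_fraction = 0.3,
                            outlier_alpha = 0.05,
                            fallback_window = 10,
                            fallback_density = 0.5,
                            penalty = NULL,
                            max_changepoints = 5) {
  structure(list(weak_threshold = weak_threshold,
                 weak_mean_threshold = weak_mean_threshold,
                 min_otv_fraction = min_otv_fraction,
                 outlier_alpha = outlier_alpha,
                 fallback_window = fallback_window,
                 fallback_density = fallback_density,
                 penalty = penalty,
                 max_changepoints = max_changepoints),
            class = "deletion_config")
}

#' Studentized-residual outlier test along a chromosome
#'
#' Fits an ordinary least-squares regression of normalized signal intensity
#' on marker position, computes externally studentized residuals, derives
#' two-sided p-values from a Student t distribution with `n - 3` degrees of
#' freedom, applies a Bonferroni correction (times `n`), and reports markers
#' whose adjusted p-value falls below `alpha`.
#'
#' @param track a [signal_track()] (or data.frame with `position`, `value`).
#' @param alpha family-wise significance level.
#' @return list of class `outlier_report` with `indices` (marker indices
#'   within the track), `studentized_residuals` and `bonferroni_p` for the
#'   flagged markers, plus `n` markers tested.
#' @export
studentized_outliers <- function(track, alpha = 0.05) {
  pos <- track$position
  val <- track$value
  keep <- which(!is.na(val))
  if (length(keep) < 4) {
    stop_("outlier test needs at least 4 non-missing markers")
  }
  fit <- lm(val[keep] ~ pos[keep])
  n <- length(keep)
  # an exact linear fit leaves only floating-point noise in the residuals;
  # studentizing that noise is meaningless, so report no outliers
  if (max(abs(stats::residuals(fit))) <= 1e-8 * max(abs(val[keep]), 1)) {
    return(structure(list(indices = integer(0),
                          studentized_residuals = numeric(0),
                          bonferroni_p = numeric(0), n = n),
                     class = "outlier_report"))
  }
  rs <- rstudent(fit)
  p <- 2 * pt(abs(rs), df = n - 3, lower.tail = FALSE)
  p[is.na(p)] <- 1  # exact fits give 0/0 residuals: nothing to flag
  bonf <- pmin(1, n * p)
  hit <- which(bonf < alpha)
  structure(list(indices = keep[hit],
                 studentized_residuals = unname(rs[hit]),
                 bonferroni_p = unname(bonf[hit]),
                 n = n),
            class = "outlier_report")
}

#' Fraction of OTV calls within a marker interval
#'
#' `NoCall` markers are excluded from the denominator.
#'
#' @param calls character vector of allele calls (A/B/H/OTV/NoCall).
#' @param interval_marker_indices indices of the markers in the interval.
#' @return proportion of OTV calls among called markers in the interval.
#' @export
otv_fraction <- function(calls, interval_marker_indices) {
  if (length(interval_marker_indices) == 0) stop_("empty interval")
  sub <- calls[interval_marker_indices]
  denom <- sum(sub != "NoCall")
  if (denom == 0) stop_("no called markers in interval (all NoCall)")
  sum(sub == "OTV") / denom
}

#' Candidate low-signal segments from a segmentation
#'
#' @param segmentation a [binary_segmentation()] result for the track.
#' @param track the segmented [signal_track()] or its numeric values.
#' @param weak_mean_threshold retain segments whose mean is at or below this
#'   (log2 units).
#' @return `data.frame` with columns `first`, `last`: 1-based inclusive
#'   marker-index ranges of the retained segments.
#' @export
candidate_segments <- function(segmentation, track, weak_mean_threshold = -1) {
  v <- if (is.data.frame(track)) track$value else track
  n <- length(v)
  b <- segment_bounds(n, segmentation$breakpoints)
  keep <- segmentation$segment_means <= weak_mean_threshold
  data.frame(first = b[keep, 1], last = b[keep, 2])
}

#' Sliding-window fallback scan for evidence-dense regions
#'
#' A marker counts as evidence when it is weak-signal, called OTV, or flagged
#' by the outlier test. Windows of `window` consecutive markers with evidence
#' density at least `min_combined_density` are merged into maximal runs; each
#' run is trimmed to its first and last evidence marker.
#'
#' @param track a [signal_track()].
#' @param calls allele calls aligned with the track markers.
#' @param outliers optional [studentized_outliers()] report for the track.
#' @param window window width in markers (>= 3).
#' @param min_combined_density minimum fraction of evidence markers in a
#'   window.
#' @param weak_threshold per-marker weak-signal cut-off.
#' @return `data.frame` with columns `first`, `last` (1-based inclusive
#'   marker indices); zero rows when nothing qualifies.
#' @export
fallback_scan <- function(track, calls, outliers = NULL, window = 10,
                          min_combined_density = 0.5, weak_threshold = -1) {
  if (window < 3) stop_("window must be >= 3")
  v <- if (is.data.frame(track)) track$value else track
  n <- length(v)
  if (length(calls) != n) stop_("calls do not align with the track")
  evidence <- weak_signal_mask(v, weak_threshold) | calls == "OTV"
  if (!is.null(outliers) && length(outliers$indices)) {
    evidence[outliers$indices] <- TRUE
  }
  empty <- data.frame(first = integer(0), last = integer(0))
  if (n < window) return(empty)
  cs <- cumsum(c(0L, as.integer(evidence)))
  starts <- seq_len(n - window + 1L)
  dens <- (cs[starts + window] - cs[starts]) / window
  ok <- dens >= min_combined_density
  if (!any(ok)) return(empty)
  covered <- rep(FALSE, n)
  for (s in starts[ok]) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(i) {
    idx <- firsts[i]:ends[i]
    ev <- idx[evidence[idx]]
    if (!length(ev)) return(NULL)
    data.frame(first = min(ev), last = max(ev))
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Merge marker-index intervals that are adjacent or overlapping.
merge_adjacent <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$first), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv$first[i] <= out$last[k] + 1L) {
      out$last[k] <- max(out$last[k], iv$last[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Deletion size in megabases
#'
#' @param start,end interval bounds in bp, `end >= start`.
#' @return `(end - start) / 1e6`, reported to 0.1 Mb.
#' @examples
#' deletion_size_mb(10e6, 21.6e6)  # 11.6
#' @export
deletion_size_mb <- function(start, end) {
  if (any(end < start)) stop_("end must be >= start")
  round((end - start) / 1e6, 1)
}

#' Call deletions on one chromosome
#'
#' Runs [binary_segmentation()] on the track, keeps low-mean segments
#' ([candidate_segments()]) and retains those whose OTV fraction reaches
#' `min_otv_fraction` (evidence route `"segmentation"`). If no candidate is
#' retained on the chromosome, the sliding-window [fallback_scan()] over
#' weak/OTV/outlier evidence is used instead (route `"fallback"`). Interval
#' bounds are the positions of the first and last supporting markers
#' (1-based inclusive bp). Markers with missing intensity are excluded
#' throughout.
#'
#' @param track a [signal_track()] for one chromosome and sample.
#' @param calls allele calls aligned with the track markers.
#' @param config a [deletion_config()].
#' @return `data.frame` of class `deletion_calls` with columns `chromosome`,
#'   `start`, `end`, `size_mb`, `n_markers`, `n_weak`, `n_otv`, `n_outliers`,
#'   `mean_signal`, `route`.
#' @export
call_deletions <- function(track, calls, config = deletion_config()) {
  stopifnot(is.data.frame(track))
  if (nrow(track) != length(calls)) {
    stop_("track and calls cover different numbers of markers")
  }
  chrom <- attr(track, "chromosome") %||% "chr1"
  keep <- which(!is.na(track$value))
  v <- track$value[keep]
  pos <- track$position[keep]
  cal <- calls[keep]
  n <- length(v)
  empty <- structure(
    data.frame(chromosome = character(0), start = numeric(0), end = numeric(0),
               size_mb = numeric(0), n_markers = integer(0),
               n_weak = integer(0), n_otv = integer(0), n_outliers = integer(0),
               mean_signal = numeric(0), route = character(0),
               stringsAsFactors = FALSE),
    class = c("deletion_calls", "data.frame"))
  if (n < 2) return(empty)

  outliers <- if (n >= 4) {
    studentized_outliers(data.frame(position = pos, value = v),
                         alpha = config$outlier_alpha)
  } else {
    list(indices = integer(0))
  }

  seg <- binary_segmentation(v, penalty = config$penalty,
                             max_changepoints = config$max_changepoints)
  cands <- candidate_segments(seg, v, config$weak_mean_threshold)
  retained <- if (nrow(cands)) {
    ok <- vapply(seq_len(nrow(cands)), function(i) {
      f <- tryCatch(otv_fraction(cal, cands$first[i]:cands$last[i]),
                    error = function(e) NA_real_)
      !is.na(f) && f >= config$min_otv_fraction
    }, logical(1))
    cands[ok, , drop = FALSE]
  } else {
    cands
  }

  if (nrow(retained)) {
    intervals <- merge_adjacent(retained)
    route <- "segmentation"
  } else {
    intervals <- fallback_scan(v, cal, outliers,
                               window = config$fallback_window,
                               min_combined_density = config$fallback_density,
                               weak_threshold = config$weak_threshold)
    route <- "fallback"
  }
  if (!nrow(intervals)) return(empty)

  weak <- weak_signal_mask(v, config$weak_threshold)
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    idx <- intervals$first[i]:intervals$last[i]
    start <- pos[intervals$first[i]]
    end <- pos[intervals$last[i]]
    data.frame(chromosome = chrom, start = start, end = end,
               size_mb = deletion_size_mb(start, end),
               n_markers = length(idx),
               n_weak = sum(weak[idx]),
               n_otv = sum(cal[idx] == "OTV"),
               n_outliers = sum(outliers$indices %in% idx),
               mean_signal = mean(v[idx]),
               route = route,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("deletion_calls", "data.frame"))
}

#' Call deletions genome-wide for one sample
#'
#' Normalizes the sample's intensities against the reference, builds
#' per-chromosome tracks and runs [call_deletions()] on each chromosome
#' independently.
#'
#' @param intensity intensity table: `marker_id` plus one numeric column per
#'   sample (log-R values).
#' @param calls call table with the same shape (values A/B/H/OTV/NoCall).
#' @param map a `marker_map` covering the markers in `intensity`.
#' @param sample_id column to analyse.
#' @param reference_id reference (wild-type) column.
#' @param config a [deletion_config()].
#' @return `data.frame` of class `deletion_calls` with a `sample` column
#'   prepended; zero rows when nothing is called.
#' @export
call_deletions_experiment <- function(intensity, calls, map,
                                      sample_id, reference_id,
                                      config = deletion_config()) {
  for (col in c(sample_id, reference_id)) {
    if (!col %in% names(intensity)) stop_("sample '%s' not in intensity table", col)
  }
  if (!identical(intensity$marker_id, map$marker_id) ||
      !identical(calls$marker_id, map$marker_id)) {
    stop_("intensity, calls and map must cover the same markers in the same order")
  }
  norm <- normalize_against_reference(intensity[[sample_id]],
                                      intensity[[reference_id]])
  tracks <- signal_tracks(map, norm, sample_id = sample_id)
  res <- lapply(names(tracks), function(ch) {
    i <- map$chromosome == ch
    call_deletions(tracks[[ch]], calls[[sample_id]][i], config)
  })
  out <- do.call(rbind, res)
  if (nrow(out)) out <- cbind(sample = sample_id, out)
  else out <- cbind(sample = character(0), out)
  structure(out, class = c("deletion_calls", "data.frame"))
}
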