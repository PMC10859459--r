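# Changes-in-mean segmentation of a normalized signal track.
#
# Cost is the within-segment sum of squared errors (Gaussian likelihood up
# to constants). Breakpoints follow the convention: breakpoint k (0-based)
# splits the signal between elements k-1 and k, i.e. k is the 0-based index
# of the first element of the right-hand segment, so valid breakpoints lie
# in 1..n-1.

segment_bounds <- function(n, breakpoints) {
  starts <- c(1L, breakpoints + 1L)
  ends <- c(breakpoints, n)
  unname(cbind(starts, ends))
}

#' Within-segment squared-error cost of a segmentation
#'
#' @param values numeric signal vector.
#' @param breakpoints integer breakpoints (0-based, strictly increasing,
#'   each in `1..n-1`); `integer(0)` for a single segment.
#' @return total sum over segments of squared deviations from the segment
#'   mean.
#' @examples
#' segment_cost(c(0, 0, 4, 4), 2L)  # 0
#' segment_cost(c(0, 0, 4, 4), integer(0))  # 16
#' @export
segment_cost <- function(values, breakpoints = integer(0)) {
  n <- length(values)
  if (n == 0) stop_("empty signal vector")
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints)) {
    if (any(breakpoints <= 0 | breakpoints >= n)) {
      stop_("breakpoints must lie strictly inside (0, n)")
    }
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      stop_("breakpoints must be strictly increasing")
    }
  }
  b <- segment_bounds(n, breakpoints)
  sum(vapply(seq_len(nrow(b)), function(i) {
    x <- values[b[i, 1]:b[i, 2]]
    sum((x - mean(x))^2)
  }, numeric(1)))
}

# Best single split of x: returns 0-based breakpoint (= size of the left
# part) and the cost reduction it achieves. NULL when x cannot be split.
best_single_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs2[n] - cs[n]^2 / n
  i <- seq_len(n - 1L)
  left <- cs2[i] - cs[i]^2 / i
  right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  reduction <- total - (left + right)
  j <- which.max(reduction)  # ties -> earliest split: deterministic
  list(split = j, reduction = reduction[j])
}

#' Binary segmentation for changes in mean
#'
#' Greedy recursive splitting: at each step the single split (over all
#' current segments) with the largest reduction in squared-error cost is
#' taken, and accepted iff the reduction strictly exceeds `penalty` and the
#' number of changepoints is below `max_changepoints`. Deterministic; ties
#' resolve to the earliest index.
#'
#' The default penalty is `2 * sigma^2 * log(n)` with `sigma` the
#' median-absolute-deviation estimate of the marker-to-marker noise
#' (`mad(diff(values)) / sqrt(2)`), an information-criterion-style default
#' that is robust to the mean shifts being sought.
#'
#' @param values numeric signal vector (length >= 2), no `NA`s.
#' @param penalty minimum cost reduction to accept a split; `NULL` for the
#'   default above.
#' @param max_changepoints cap on the number of accepted breakpoints.
#' @return object of class `segmentation`: list with `breakpoints` (0-based),
#'   `segment_means`, `total_cost` and `penalty`.
#' @export
binary_segmentation <- function(values, penalty = NULL, max_changepoints = 5) {
  n <- length(values)
  if (n == 0) stop_("empty signal vector")
  if (n < 2) stop_("need at least 2 values to segment")
  if (anyNA(values)) stop_("values must not contain NA; drop missing markers first")
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(values)) / sqrt(2)
    penalty <- 2 * sigma^2 * log(n)
  }
  if (penalty < 0) stop_("penalty must be non-negative")

  breakpoints <- integer(0)
  repeat {
    if (length(breakpoints) >= max_changepoints) break
    b <- segment_bounds(n, sort(breakpoints))
    cand <- lapply(seq_len(nrow(b)), function(i) {
      s <- best_single_split(values[b[i, 1]:b[i, 2]])
      if (is.null(s)) return(NULL)
      list(bp = b[i, 1] - 1L + s$split, reduction = s$reduction)
    })
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) break
    reds <- vapply(cand, `[[`, numeric(1), "reduction")
    best <- cand[[which.max(reds)]]
    if (best$reduction <= penalty) break
    breakpoints <- c(breakpoints, best$bp)
  }
  breakpoints <- sort(breakpoints)
  b <- segment_bounds(n, breakpoints)
  means <- vapply(seq_len(nrow(b)), function(i) mean(values[b[i, 1]:b[i, 2]]),
                  numeric(1))
  structure(list(breakpoints = breakpoints, segment_means = means,
                 total_cost = segment_cost(values, breakpoints),
                 penalty = penalty),
            class = "segmentation")
}

#' Exhaustive optimal segmentation with exactly k changepoints
#'
#' Brute-force search over all placements of `k` breakpoints, returning the
#' globally minimal squared-error segmentation. Intended as an independent
#' oracle for small instances; errors out when the search space exceeds
#' 5e5 placements.
#'
#' @param values numeric signal vector.
#' @param k exact number of changepoints (small; typically <= 3).
#' @return object of class `segmentation` (see [binary_segmentation()]).
#' @export
exhaustive_segmentation <- function(values, k) {
  n <- length(values)
  if (n == 0) stop_("empty signal vector")
  if (k < 0 || k > n - 1) stop_("k must lie in 0..n-1")
  if (k > 0 && choose(n - 1, k) > 5e5) {
    stop_("combinatorially infeasible: choose(%d, %d) placements", n - 1, k)
  }
  if (k == 0) {
    best_bp <- integer(0)
    best_cost <- segment_cost(values)
  } else {
    cs <- cumsum(values)
    cs2 <- cumsum(values^2)
    # cost of values[i..j] from cumulative sums
    scost <- function(i, j) {
      s <- cs[j] - if (i > 1) cs[i - 1] else 0
      s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
      s2 - s^2 / (j - i + 1)
    }
    combos <- utils::combn(n - 1L, k)
    best_cost <- Inf
    best_bp <- integer(0)
    for (c_i in seq_len(ncol(combos))) {
      bp <- combos[, c_i]
      b <- segment_bounds(n, bp)
      cost <- 0
      for (s_i in seq_len(nrow(b))) cost <- cost + scost(b[s_i, 1], b[s_i, 2])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best_bp <- bp
      }
    }
  }
  b <- segment_bounds(n, best_bp)
  means <- vapply(seq_len(nrow(b)), function(i) mean(values[b[i, 1]:b[i, 2]]),
                  numeric(1))
  structure(list(breakpoints = as.integer(best_bp), segment_means = means,
                 total_cost = best_cost, penalty = NA_real_),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d changepoint(s) at [%s]; cost %.4g\n",
              length(x$breakpoints), paste(x$breakpoints, collapse = ", "),
              x$total_cost))
  invisible(x)
}
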