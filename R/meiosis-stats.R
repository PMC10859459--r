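# Chiasma accounting from metaphase-I pairing configurations, per-genotype
# summaries, pollen viability, and normality-gated two-group comparisons.

# Chiasmata scored per shape: univalent 0, rod bivalent 1 (one bound arm),
# ring bivalent 2 (both arms), trivalent 2, ring quadrivalent 4, rod/chain
# quadrivalent 3 (arity - 1 for chains).
.shape_cols <- c("n_univalent", "n_rod_bivalent", "n_ring_bivalent",
                 "n_trivalent", "n_ring_quadrivalent", "n_rod_quadrivalent")
.chiasma_weights <- c(n_univalent = 0, n_rod_bivalent = 1, n_ring_bivalent = 2,
                      n_trivalent = 2, n_ring_quadrivalent = 4,
                      n_rod_quadrivalent = 3)
.chromosome_weights <- c(n_univalent = 1, n_rod_bivalent = 2,
                         n_ring_bivalent = 2, n_trivalent = 3,
                         n_ring_quadrivalent = 4, n_rod_quadrivalent = 4)

config_counts <- function(config) {
  cfg <- as.list(config)
  counts <- vapply(.shape_cols, function(f) {
    x <- cfg[[f]] %||% 0
    as.numeric(x[[1]])
  }, numeric(1))
  if (any(counts < 0)) stop_("shape counts must be non-negative")
  counts
}

#' Chiasma count of one meiocyte configuration
#'
#' Scores 0 chiasmata per univalent, 1 per rod bivalent, 2 per ring
#' bivalent, 2 per trivalent, 4 per ring quadrivalent and 3 per rod (chain)
#' quadrivalent; additional complex associations must come with explicit
#' chiasma values in `complex`. The configuration must account for exactly
#' `total` chromosomes.
#'
#' @param config named list / one-row data.frame with counts `n_univalent`,
#'   `n_rod_bivalent`, `n_ring_bivalent`, `n_trivalent`,
#'   `n_ring_quadrivalent`, `n_rod_quadrivalent` (missing fields are 0).
#' @param total somatic chromosome number (42 for hexaploid wheat).
#' @param complex optional `data.frame` with columns `arity` (chromosomes in
#'   the association) and `chiasmata`.
#' @return integer chiasma count.
#' @examples
#' chiasma_count(list(n_ring_bivalent = 21))  # 42
#' @export
chiasma_count <- function(config, total = 42, complex = NULL) {
  counts <- config_counts(config)
  extra_chrom <- if (!is.null(complex)) sum(complex$arity) else 0
  got <- sum(counts * .chromosome_weights) + extra_chrom
  if (got != total) {
    stop_("configuration accounts for %s chromosomes, expected %s", got, total)
  }
  extra_chi <- if (!is.null(complex)) sum(complex$chiasmata) else 0
  sum(counts * .chiasma_weights) + extra_chi
}

#' Summarize a population of meiocyte configurations
#'
#' Computes the mean and sample SD (n-1 denominator) of the chiasma count
#' and of each shape count, and the percentage of cells containing at least
#' one of each shape. With a single cell the SD is reported as 0 and flagged
#' via `sd_defined = FALSE`.
#'
#' @param cells `data.frame` of configurations (one row per cell, columns as
#'   in [gen_meiocytes()]).
#' @param total somatic chromosome number; every cell is checked for
#'   chromosome conservation.
#' @return list of class `meiocyte_summary`: `n_cells`, `sd_defined`, and
#'   `metrics` (data.frame with `metric`, `mean`, `sd`, `pct_cells`).
#' @export
summarize_cells <- function(cells, total = 42) {
  if (is.null(cells) || nrow(cells) == 0) stop_("no cells to summarize")
  m <- as.matrix(cells[, .shape_cols[.shape_cols %in% names(cells)]])
  missing_cols <- setdiff(.shape_cols, colnames(m))
  for (f in missing_cols) m <- cbind(m, matrix(0, nrow(m), 1, dimnames = list(NULL, f)))
  m <- m[, .shape_cols, drop = FALSE]
  conserved <- m %*% .chromosome_weights
  if (any(conserved != total)) {
    stop_("%s cell(s) violate chromosome conservation (total %s expected)",
          sum(conserved != total), total)
  }
  chi <- as.numeric(m %*% .chiasma_weights)
  n <- nrow(m)
  sd_defined <- n > 1
  sd_or0 <- function(x) if (sd_defined) sd(x) else 0
  metrics <- rbind(
    data.frame(metric = "chiasmata", mean = mean(chi), sd = sd_or0(chi),
               pct_cells = NA_real_, stringsAsFactors = FALSE),
    do.call(rbind, lapply(.shape_cols, function(f) {
      x <- m[, f]
      data.frame(metric = sub("^n_", "", f), mean = mean(x), sd = sd_or0(x),
                 pct_cells = 100 * mean(x > 0), stringsAsFactors = FALSE)
    }))
  )
  structure(list(n_cells = n, sd_defined = sd_defined, metrics = metrics),
            class = "meiocyte_summary")
}

#' @export
print.meiocyte_summary <- function(x, ...) {
  cat(sprintf("<meiocyte_summary> %d cell(s)%s\n", x$n_cells,
              if (!x$sd_defined) " (SD undefined, reported as 0)" else ""))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percentage of viable pollen
#'
#' @param n_viable,n_nonviable grain counts; the total must be positive.
#' @return `100 * n_viable / (n_viable + n_nonviable)`.
#' @export
pollen_viability <- function(n_viable, n_nonviable) {
  total <- n_viable + n_nonviable
  if (any(total <= 0)) stop_("total pollen count must be positive")
  100 * n_viable / total
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk normality test to each group. When both groups
#' pass (p >= `alpha_sw`) the groups are compared with a two-sample t-test
#' at significance `alpha_t` (pooled variance by default, Welch via
#' `welch = TRUE`); otherwise a Kruskal-Wallis test at significance
#' `alpha_kw` is used. The route decision and both normality verdicts are
#' reported; swapping the groups changes neither the route nor the
#' significance verdict.
#'
#' @param a,b numeric samples, each of length >= 3 and not constant.
#' @param alpha_t significance level used on the t-test route.
#' @param alpha_kw significance level used on the Kruskal-Wallis route.
#' @param alpha_sw Shapiro-Wilk gate level.
#' @param welch use the unequal-variance t-test instead of pooled.
#' @return list of class `group_comparison`: `test_used` (`"t_test"` or
#'   `"kruskal_wallis"`), `statistic`, `p_value`, `alpha_used`, `normal_a`,
#'   `normal_b`, `shapiro_p`, `significant`.
#' @export
compare_groups <- function(a, b, alpha_t = 0.05, alpha_kw = 0.01,
                           alpha_sw = 0.05, welch = FALSE) {
  for (g in list(a, b)) {
    if (length(g) < 3) stop_("each group needs at least 3 values")
    if (diff(range(g)) == 0) stop_("constant group: normality test undefined")
  }
  sw_a <- shapiro.test(a)$p.value
  sw_b <- shapiro.test(b)$p.value
  normal_a <- sw_a >= alpha_sw
  normal_b <- sw_b >= alpha_sw
  if (normal_a && normal_b) {
    ht <- t.test(a, b, var.equal = !welch)
    test_used <- "t_test"
    alpha_used <- alpha_t
  } else {
    ht <- kruskal.test(list(a, b))
    test_used <- "kruskal_wallis"
    alpha_used <- alpha_kw
  }
  structure(list(test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 alpha_used = alpha_used,
                 normal_a = normal_a, normal_b = normal_b,
                 shapiro_p = c(a = sw_a, b = sw_b),
                 significant = ht$p.value < alpha_used),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g (alpha %.3g)%s\n",
              x$test_used, x$statistic, x$p_value, x$alpha_used,
              if (x$significant) " *" else ""))
  cat(sprintf("  Shapiro-Wilk: a %s (p=%.3g), b %s (p=%.3g)\n",
              if (x$normal_a) "normal" else "non-normal", x$shapiro_p[["a"]],
              if (x$normal_b) "normal" else "non-normal", x$shapiro_p[["b"]]))
  invisible(x)
}
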