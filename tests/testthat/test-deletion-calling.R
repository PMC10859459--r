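test_that("studentized outlier test flags single spikes and nothing on a line", {
  # exactly linear values: no outliers
  tr <- signal_track(1:20 * 100, 0.01 * (1:20))
  expect_length(studentized_outliers(tr)$indices, 0)

  # one marker far below an otherwise near-noiseless track
  set.seed(5)
  v <- rnorm(51, 0, 1e-6)
  v[26] <- -6
  tr <- signal_track(seq(1e5, 51e5, length.out = 51), v)
  rep <- studentized_outliers(tr, alpha = 0.05)
  expect_equal(rep$indices, 26L)
  expect_true(all(rep$bonferroni_p < 0.05))

  expect_error(studentized_outliers(signal_track(1:3, c(0, 1, 0))), "at least 4")
})

test_that("outlier test agrees with the car package's Bonferroni outlier test", {
  skip_if_not_installed("car")
  set.seed(8)
  pos <- sort(sample.int(1e7, 40))
  v <- rnorm(40, 0, 0.3)
  v[12] <- -4
  v[30] <- -3.5
  tr <- signal_track(pos, v)
  mine <- studentized_outliers(tr, alpha = 0.05)
  ref <- car::outlierTest(lm(v ~ pos), cutoff = 0.05, n.max = 40)
  ref_idx <- sort(as.integer(names(ref$rstudent)))
  expect_equal(sort(mine$indices), ref_idx)
  expect_equal(mine$bonferroni_p[order(mine$indices)],
               unname(ref$bonf.p[order(as.integer(names(ref$rstudent)))]),
               tolerance = 1e-8)
})

test_that("Bonferroni correction controls the family-wise false-positive rate", {
  set.seed(17)
  n_rep <- 400
  fp <- 0
  for (i in seq_len(n_rep)) {
    tr <- signal_track(1:50, rnorm(50))
    if (length(studentized_outliers(tr, alpha = 0.05)$indices)) fp <- fp + 1
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fp / n_rep, 0.05 + 3 * mc_se)
})

test_that("OTV fraction excludes NoCall from the denominator", {
  expect_equal(otv_fraction(c("OTV", "OTV", "A", "B"), 1:4), 0.5)
  expect_equal(otv_fraction(c("OTV", "NoCall", "A"), 1:3), 0.5)
  expect_error(otv_fraction(rep("NoCall", 4), 1:4), "NoCall")
  expect_error(otv_fraction(c("A", "B"), integer(0)), "empty")

  fix <- deletion_fixture(seed = 33, n_markers = 200, n_del = 100,
                          otv_inside = 0.6)
  frac <- otv_fraction(fix$exp$calls$mutant, fix$first:fix$last)
  bounds <- binom_bounds(100, 0.6)
  expect_gte(frac, bounds[1] - 0.02)  # NoCall exclusion can nudge the ratio
  expect_lte(frac, bounds[2] + 0.02)
})

test_that("candidate segments are the low-mean segments of a segmentation", {
  x <- c(rnorm(40, 0, 0.05), rnorm(10, -3, 0.05), rnorm(40, 0, 0.05))
  seg <- binary_segmentation(x, penalty = 0.5)
  cands <- candidate_segments(seg, x, weak_mean_threshold = -1)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$first, 41)
  expect_equal(cands$last, 50)

  flat <- binary_segmentation(rnorm(50, 0, 0.1), penalty = 1)
  expect_equal(nrow(candidate_segments(flat, rnorm(50, 0, 0.1), -1)), 0)
})

test_that("fallback scan emits maximal trimmed evidence runs", {
  n <- 100
  v <- rep(0, n)
  calls <- rep("A", n)
  v[48:52] <- -3          # weak signal
  calls[48:52] <- "OTV"   # and OTV-dense
  tr <- signal_track(1:n * 1000, v)
  iv <- fallback_scan(tr, calls, window = 5, min_combined_density = 0.8)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$first, 48)
  expect_equal(iv$last, 52)

  # clean track: nothing
  clean <- fallback_scan(signal_track(1:n * 1000, rep(0, n)), rep("A", n))
  expect_equal(nrow(clean), 0)

  # intervals never overlap and are maximal
  set.seed(9)
  for (i in 1:10) {
    v <- rnorm(n, 0, 0.2)
    calls <- sample(c("A", "OTV"), n, replace = TRUE, prob = c(0.7, 0.3))
    iv <- fallback_scan(signal_track(1:n * 1000, v), calls,
                        window = 5, min_combined_density = 0.6)
    if (nrow(iv) > 1) {
      expect_true(all(iv$first[-1] > iv$last[-nrow(iv)] + 1))
    }
  }
  expect_error(fallback_scan(tr, calls, window = 2), ">= 3")
})

test_that("deletion size in Mb matches the bp arithmetic", {
  expect_equal(deletion_size_mb(10e6, 21.6e6), 11.6)
  expect_equal(deletion_size_mb(5, 5), 0)
  expect_equal(deletion_size_mb(1, 18900001), 18.9)
  expect_error(deletion_size_mb(10, 5), ">= start")
})

test_that("an injected deletion is called once with tight boundaries", {
  fix <- deletion_fixture(seed = 101, n_markers = 100, n_del = 20)
  tr <- mutant_track(fix)
  calls <- call_deletions(tr, fix$exp$calls$mutant)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$route, "segmentation")
  expect_equal(calls$chromosome, "chr1")
  # boundary error at most one inter-marker interval
  expect_lte(abs(match(calls$start, fix$map$position) - fix$first), 1)
  expect_lte(abs(match(calls$end, fix$map$position) - fix$last), 1)
  expect_equal(calls$size_mb, deletion_size_mb(calls$start, calls$end))
  # evidence counts are consistent
  expect_lte(calls$n_weak, calls$n_markers)
  expect_lte(calls$n_otv, calls$n_markers)
  expect_lt(calls$mean_signal, -1)
})

test_that("a short OTV-dense deletion is recovered through the fallback route", {
  n <- 120
  set.seed(55)
  v <- rnorm(n, 0, 0.3)
  calls <- sample(c("A", "B", "H"), n, replace = TRUE)
  # 4 markers: too narrow for the default segmentation penalty to split out
  idx <- 60:63
  v[idx] <- v[idx] - 3
  calls[idx] <- "OTV"
  tr <- signal_track(sort(sample.int(1e8, n)), v)
  cfg <- deletion_config(fallback_window = 4, fallback_density = 0.75,
                         penalty = 50)  # force the segmentation route to fail
  out <- call_deletions(tr, calls, cfg)
  expect_equal(out$route, "fallback")
  expect_equal(nrow(out), 1)
  expect_gte(out$n_otv, 4)
})

test_that("null tracks yield no calls and inconsistent inputs error", {
  map <- gen_marker_map(1, 80, 1e8, seed = 77)
  exp <- gen_array_experiment(map, NULL, noise_sd = 0.3, seed = 78)
  norm <- normalize_against_reference(exp$intensity$mutant,
                                      exp$intensity$reference)
  tr <- signal_tracks(map, norm, "mutant")[[1]]
  expect_equal(nrow(call_deletions(tr, exp$calls$mutant)), 0)
  expect_error(call_deletions(tr, exp$calls$mutant[1:10]),
               "different numbers")
})

test_that("the genome-wide wrapper restricts calls to the deleted chromosome", {
  map <- gen_marker_map(3, 80, 1e8, seed = 88)
  p <- map$position[map$chromosome == "1B"]
  del <- deletion_spec("1B", p[30], p[49])
  exp <- gen_array_experiment(map, del, noise_sd = 0.3, seed = 89)
  res <- call_deletions_experiment(exp$intensity, exp$calls, map,
                                   "mutant", "reference")
  expect_equal(nrow(res), 1)
  expect_equal(res$chromosome, "1B")
  expect_equal(res$sample, "mutant")
  expect_error(
    call_deletions_experiment(exp$intensity, exp$calls, map, "nope", "reference"),
    "not in intensity")
})
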