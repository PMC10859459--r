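# Shared fixture builders. Everything is generated in code; no stored data.

# Exact two-sided binomial bounds: the observed count at the given
# confidence, as a proportion.
binom_bounds <- function(n, p, conf = 0.99) {
  alpha <- (1 - conf) / 2
  qbinom(c(alpha, 1 - alpha), n, p) / n
}

# A one-chromosome experiment with a single injected deletion spanning
# `n_del` markers out of `n_markers`, regular-ish marker spacing.
deletion_fixture <- function(seed, n_markers = 100, n_del = 12, shift = -3,
                             otv_inside = 0.6, noise_sd = 0.3,
                             chrom_len = 1e8) {
  map <- gen_marker_map(1, n_markers, chrom_len, seed = seed)
  i0 <- floor(n_markers / 2) - floor(n_del / 2) + 1
  del <- deletion_spec("chr1", map$position[i0], map$position[i0 + n_del - 1],
                       signal_shift = shift, otv_rate_inside = otv_inside)
  exp <- gen_array_experiment(map, del, noise_sd = noise_sd, seed = seed + 1)
  list(map = map, exp = exp, first = i0, last = i0 + n_del - 1)
}

# Normalized mutant track for a one-chromosome experiment.
mutant_track <- function(fix) {
  norm <- normalize_against_reference(fix$exp$intensity$mutant,
                                      fix$exp$intensity$reference)
  signal_tracks(fix$map, norm, sample_id = "mutant")[[1]]
}

# A valid random meiocyte configuration on `total` chromosomes.
random_configuration <- function(total = 42) {
  pairs <- total / 2
  n_univ_pairs <- sample(0:2, 1)
  n_quad <- sample(0:1, 1)
  left <- pairs - n_univ_pairs - 2 * n_quad
  n_rod <- sample(0:left, 1)
  list(n_univalent = 2 * n_univ_pairs,
       n_rod_bivalent = n_rod,
       n_ring_bivalent = left - n_rod,
       n_ring_quadrivalent = n_quad)
}
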