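# Synthetic inputs for the deletion-calling and cytology pipeline.
#
# Every generator is deterministic for a fixed seed and, where it injects a
# signal (a deletion, a CDS substitution), returns the ground truth alongside
# the data so recovery can be measured.

#' Chromosome names for a simulated genome
#'
#' When `n` is a multiple of 3 the names follow the hexaploid wheat
#' convention (`1A`, `1B`, `1D`, `2A`, ...: homoeologous groups times the A/B/D
#' subgenomes); otherwise plain `chr1..chrN`.
#'
#' @param n number of chromosomes.
#' @return character vector of length `n`.
#' @export
chromosome_names <- function(n) {
  n <- as.integer(n)
  if (n <= 0) stop_("`n` must be positive")
  if (n %% 3L == 0L) {
    paste0(rep(seq_len(n / 3L), each = 3L), c("A", "B", "D"))
  } else {
    paste0("chr", seq_len(n))
  }
}

#' Generate a marker map
#'
#' Draws marker positions uniformly (without replacement) along each
#' chromosome and sorts them, emulating the physical layout of a genotyping
#' SNP array. Positions are 1-based bp; marker ids are unique.
#'
#' @param n_chromosomes number of chromosomes (21 for hexaploid wheat).
#' @param markers_per_chromosome markers to place on each chromosome.
#' @param chromosome_length chromosome length in bp.
#' @param seed RNG seed.
#' @return a `data.frame` (class `marker_map`) with columns `marker_id`,
#'   `chromosome`, `position`, sorted by chromosome then position.
#' @examples
#' map <- gen_marker_map(3, 10, 1e6, seed = 1)
#' @export
gen_marker_map <- function(n_chromosomes, markers_per_chromosome,
                           chromosome_length, seed) {
  if (n_chromosomes < 1 || markers_per_chromosome < 1 || chromosome_length < 1) {
    stop_("all counts must be positive")
  }
  if (markers_per_chromosome > chromosome_length) {
    stop_("cannot place %s markers on a %s bp chromosome",
          markers_per_chromosome, chromosome_length)
  }
  chroms <- chromosome_names(n_chromosomes)
  pos <- with_seed(seed, {
    lapply(chroms, function(ch) sort(sample.int(chromosome_length, markers_per_chromosome)))
  })
  map <- data.frame(
    marker_id = sprintf("AX-%s-%05d", rep(chroms, each = markers_per_chromosome),
                        sequence(rep(markers_per_chromosome, n_chromosomes))),
    chromosome = rep(chroms, each = markers_per_chromosome),
    position = unlist(pos),
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  attr(map, "chromosome_length") <- chromosome_length
  map
}

#' Specify a deletion to inject into a simulated array experiment
#'
#' @param chromosome chromosome name (must exist in the marker map).
#' @param start,end interval in bp, 1-based inclusive, `start < end`.
#' @param signal_shift additive shift on the log2 intensity scale for markers
#'   inside the interval; must be negative. The default -3 corresponds to
#'   near-complete probe loss for a homozygous deletion.
#' @param otv_rate_inside probability that a marker inside the interval is
#'   called OTV (off-target variant) in the mutant sample.
#' @return one-row `data.frame`; rows can be `rbind`ed to inject several
#'   deletions.
#' @export
deletion_spec <- function(chromosome, start, end, signal_shift = -3,
                          otv_rate_inside = 0.6) {
  if (start >= end) stop_("deletion start must be < end")
  if (signal_shift >= 0) stop_("signal_shift must be negative")
  if (otv_rate_inside < 0 || otv_rate_inside > 1) {
    stop_("otv_rate_inside must be in [0, 1]")
  }
  data.frame(chromosome = chromosome, start = start, end = end,
             signal_shift = signal_shift, otv_rate_inside = otv_rate_inside,
             stringsAsFactors = FALSE)
}

#' Simulate a SNP-array experiment with optional injected deletions
#'
#' The reference (wild-type) sample gets per-marker log-R intensities drawn
#' from Normal(0, `noise_sd`); the mutant sample is drawn the same way and
#' then shifted by each deletion's `signal_shift` inside the deleted
#' interval. Allele calls are `A`/`B`/`H` with a small `NoCall` rate; the
#' mutant's calls switch to `OTV` with probability `otv_rate_inside` inside
#' deletions and `otv_rate_background` elsewhere (the reference only sees
#' the background rate).
#'
#' @param map a `marker_map` from [gen_marker_map()].
#' @param deletions `NULL` or a `data.frame` of [deletion_spec()] rows.
#' @param noise_sd Gaussian noise SD on the log2 scale (>= 0).
#' @param otv_rate_background OTV probability outside deletions.
#' @param nocall_rate probability of a missing (`NoCall`) genotype.
#' @param seed RNG seed.
#' @param sample_id,reference_id column names for the two samples.
#' @return list with elements `intensity` (marker_id + one numeric column per
#'   sample), `calls` (same shape, values in A/B/H/OTV/NoCall), `truth`
#'   (injected deletions plus the index range of affected markers) and `map`.
#' @export
gen_array_experiment <- function(map, deletions = NULL, noise_sd = 0.2,
                                 otv_rate_background = 0.02,
                                 nocall_rate = 0.01, seed = 1,
                                 sample_id = "mutant",
                                 reference_id = "reference") {
  if (noise_sd < 0) stop_("noise_sd must be non-negative")
  n <- nrow(map)
  in_del <- rep(FALSE, n)
  shift <- rep(0, n)
  otv_p <- rep(otv_rate_background, n)
  if (!is.null(deletions) && nrow(deletions) > 0) {
    bad <- setdiff(deletions$chromosome, map$chromosome)
    if (length(bad)) stop_("deletion chromosome(s) not in map: %s",
                           paste(bad, collapse = ", "))
    if (any(deletions$start >= deletions$end)) stop_("deletion start must be < end")
    if (any(deletions$signal_shift >= 0)) stop_("signal_shift must be negative")
    for (i in seq_len(nrow(deletions))) {
      hit <- map$chromosome == deletions$chromosome[i] &
        map$position >= deletions$start[i] &
        map$position <= deletions$end[i]
      in_del <- in_del | hit
      shift[hit] <- deletions$signal_shift[i]
      otv_p[hit] <- deletions$otv_rate_inside[i]
    }
  }
  sim <- with_seed(seed, {
    ref_int <- rnorm(n, 0, noise_sd)
    mut_int <- rnorm(n, 0, noise_sd) + shift
    base_ref <- sample(c("A", "B", "H"), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    base_mut <- sample(c("A", "B", "H"), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    ref_otv <- runif(n) < otv_rate_background
    mut_otv <- runif(n) < otv_p
    ref_nc <- runif(n) < nocall_rate
    mut_nc <- runif(n) < nocall_rate
    ref_call <- ifelse(ref_nc, "NoCall", ifelse(ref_otv, "OTV", base_ref))
    mut_call <- ifelse(mut_nc, "NoCall", ifelse(mut_otv, "OTV", base_mut))
    list(ref_int = ref_int, mut_int = mut_int,
         ref_call = ref_call, mut_call = mut_call)
  })
  intensity <- data.frame(marker_id = map$marker_id, stringsAsFactors = FALSE)
  intensity[[reference_id]] <- sim$ref_int
  intensity[[sample_id]] <- sim$mut_int
  calls <- data.frame(marker_id = map$marker_id, stringsAsFactors = FALSE)
  calls[[reference_id]] <- sim$ref_call
  calls[[sample_id]] <- sim$mut_call
  truth <- if (is.null(deletions) || nrow(deletions) == 0) {
    data.frame(chromosome = character(), start = numeric(), end = numeric(),
               signal_shift = numeric(), otv_rate_inside = numeric(),
               first_marker = integer(), last_marker = integer(),
               n_markers = integer(), stringsAsFactors = FALSE)
  } else {
    cbind(deletions, t(vapply(seq_len(nrow(deletions)), function(i) {
      hit <- which(map$chromosome == deletions$chromosome[i] &
                     map$position >= deletions$start[i] &
                     map$position <= deletions$end[i])
      # indices are within the deletion's chromosome, matching per-track calls
      offset <- match(deletions$chromosome[i], map$chromosome) - 1L
      c(first_marker = if (length(hit)) min(hit) - offset else NA_integer_,
        last_marker = if (length(hit)) max(hit) - offset else NA_integer_,
        n_markers = length(hit))
    }, integer(3))))
  }
  list(intensity = intensity, calls = calls, truth = truth, map = map)
}

#' Construct a genotype profile for cytology/fertility simulation
#'
#' A profile holds the per-cell probabilities of observing each alternative
#' pairing shape at metaphase I (the default configuration being all ring
#' bivalents), the target mean chiasma count, and fertility parameters.
#'
#' @param name genotype label.
#' @param p_cell_with_univalents,p_cell_with_rod_bivalents,p_cell_with_multivalents
#'   probabilities in `[0, 1]` that a cell contains at least one of the shape.
#' @param mean_chiasmata target population mean chiasma count (<= total
#'   chromosome number; 42 means all ring bivalents in every cell).
#' @param mean_seeds_per_spike mean grain count per self-pollinated spike.
#' @param pollen_viable_fraction fraction of viable pollen grains.
#' @return a list of class `genotype_profile`.
#' @export
genotype_profile <- function(name,
                             p_cell_with_univalents = 0,
                             p_cell_with_rod_bivalents = 0,
                             p_cell_with_multivalents = 0,
                             mean_chiasmata = 42,
                             mean_seeds_per_spike = 30,
                             pollen_viable_fraction = 0.95) {
  p <- c(p_cell_with_univalents, p_cell_with_rod_bivalents,
         p_cell_with_multivalents, pollen_viable_fraction)
  if (any(p < 0 | p > 1)) stop_("probabilities must lie in [0, 1]")
  if (mean_chiasmata < 0 || mean_seeds_per_spike < 0) {
    stop_("means must be non-negative")
  }
  structure(list(name = name,
                 p_cell_with_univalents = p_cell_with_univalents,
                 p_cell_with_rod_bivalents = p_cell_with_rod_bivalents,
                 p_cell_with_multivalents = p_cell_with_multivalents,
                 mean_chiasmata = mean_chiasmata,
                 mean_seeds_per_spike = mean_seeds_per_spike,
                 pollen_viable_fraction = pollen_viable_fraction),
            class = "genotype_profile")
}

#' Default genotype profiles
#'
#' Profiles for the wild type, the triple mutant (TM, all six gene copies
#' disrupted) and the three single-copy heterozygotes (Htz-A/B/D) of a
#' RecQ4-helicase mutant panel: WT shows 41.68 mean chiasmata and 36
#' seeds/spike, TM 41.03 chiasmata and 8 seeds/spike, Htz-B 7.6% of cells
#' with univalents and 15 seeds/spike, Htz-A 2% multivalent cells and 38
#' seeds/spike, Htz-D 5% univalent and 5% multivalent cells and 32
#' seeds/spike. Where a quantity is not pinned by those observations
#' (rod-bivalent cell fractions for WT/TM, heterozygote chiasma means,
#' pollen fractions) the values are plausible interpolations; see the
#' methods vignette.
#'
#' @return named list of [genotype_profile()] objects.
#' @export
genotype_profiles <- function() {
  list(
    WT = genotype_profile("WT", 0, 0.32, 0, 41.68, 36, 0.95),
    TM = genotype_profile("TM", 0.015, 0.47, 0.116, 41.03, 8, 0.55),
    `Htz-A` = genotype_profile("Htz-A", 0, 0.409, 0.02, 41.5, 38, 0.85),
    `Htz-B` = genotype_profile("Htz-B", 0.076, 0.493, 0.104, 41.1, 15, 0.90),
    `Htz-D` = genotype_profile("Htz-D", 0.05, 0.39, 0.05, 41.4, 32, 0.85)
  )
}

#' Simulate meiocyte pairing configurations
#'
#' Each cell starts from the default configuration (all ring bivalents) and
#' then independently, with the profile's probabilities, receives a pair of
#' univalents, one or more rod bivalents and a multivalent; remaining
#' chromosomes stay in ring bivalents so that the chromosome total is always
#' conserved. The number of rod bivalents in a rod-bearing cell is a shifted
#' Poisson whose mean is calibrated so that the population mean chiasma count
#' converges to the profile's `mean_chiasmata`.
#'
#' Multivalent shapes are drawn from `multi_shapes`, a named probability
#' vector over `ring_quadrivalent`, `rod_quadrivalent` and `trivalent`; a
#' trivalent (3 chromosomes) is completed by one extra univalent to conserve
#' the total.
#'
#' @param profile a [genotype_profile()].
#' @param n_cells number of cells to draw.
#' @param total_chromosomes somatic chromosome count (default 42, hexaploid
#'   wheat); must be even.
#' @param seed RNG seed.
#' @param multi_shapes named probabilities for the multivalent shape.
#' @return `data.frame` with columns `cell_id`, `genotype`, `n_univalent`,
#'   `n_rod_bivalent`, `n_ring_bivalent`, `n_trivalent`,
#'   `n_ring_quadrivalent`, `n_rod_quadrivalent`.
#' @export
gen_meiocytes <- function(profile, n_cells, total_chromosomes = 42, seed = 1,
                          multi_shapes = c(ring_quadrivalent = 1)) {
  stopifnot(inherits(profile, "genotype_profile"))
  if (total_chromosomes <= 0 || total_chromosomes %% 2 != 0) {
    stop_("total_chromosomes must be even and positive")
  }
  if (n_cells < 1) stop_("n_cells must be >= 1")
  shapes <- c("ring_quadrivalent", "rod_quadrivalent", "trivalent")
  if (!all(names(multi_shapes) %in% shapes) || any(multi_shapes < 0)) {
    stop_("multi_shapes must be named probabilities over %s",
          paste(shapes, collapse = "/"))
  }
  multi_shapes <- multi_shapes / sum(multi_shapes)
  p_univ <- profile$p_cell_with_univalents
  p_rod <- profile$p_cell_with_rod_bivalents
  p_multi <- profile$p_cell_with_multivalents

  # Chiasma deficit relative to the all-ring maximum (= total_chromosomes):
  # a univalent pair costs 2, a rod bivalent 1, a rod quadrivalent 1, a
  # trivalent-plus-univalent 2, a ring quadrivalent 0.
  shape_deficit <- c(ring_quadrivalent = 0, rod_quadrivalent = 1, trivalent = 2)
  deficit <- total_chromosomes - profile$mean_chiasmata
  md <- sum(multi_shapes * shape_deficit[names(multi_shapes)])
  need <- deficit - 2 * p_univ - p_multi * md
  if (p_rod == 0) {
    if (need > 1e-8) {
      stop_("profile infeasible: mean_chiasmata %.2f unreachable with p_rod = 0",
            profile$mean_chiasmata)
    }
    mu_rod <- 0
  } else {
    mu_rod <- need / p_rod
    if (mu_rod < 1 - 1e-8) {
      stop_("profile infeasible: would need %.2f rod bivalents per rod-bearing cell",
            mu_rod)
    }
  }

  pairs_total <- total_chromosomes / 2L
  cells <- with_seed(seed, {
    u <- runif(n_cells) < p_univ
    r <- runif(n_cells) < p_rod
    m <- runif(n_cells) < p_multi
    mshape <- sample(names(multi_shapes), n_cells, replace = TRUE,
                     prob = multi_shapes)
    n_rod <- ifelse(r, 1L + rpois(n_cells, max(mu_rod - 1, 0)), 0L)
    list(u = u, m = m, mshape = mshape, n_rod = n_rod)
  })
  n_triv <- as.integer(cells$m & cells$mshape == "trivalent")
  n_rq <- as.integer(cells$m & cells$mshape == "ring_quadrivalent")
  n_dq <- as.integer(cells$m & cells$mshape == "rod_quadrivalent")
  # pair budget: univalent pair 1, each rod 1, any quadrivalent 2,
  # trivalent + companion univalent 2
  fixed_pairs <- as.integer(cells$u) + 2L * (n_rq + n_dq + n_triv)
  n_rod <- pmin(cells$n_rod, pairs_total - fixed_pairs)
  n_ring <- pairs_total - fixed_pairs - n_rod
  out <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    genotype = profile$name,
    n_univalent = 2L * as.integer(cells$u) + n_triv,
    n_rod_bivalent = as.integer(n_rod),
    n_ring_bivalent = as.integer(n_ring),
    n_trivalent = n_triv,
    n_ring_quadrivalent = n_rq,
    n_rod_quadrivalent = n_dq,
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate seeds-per-spike counts
#'
#' Draws grain counts per spike from a Poisson with each profile's mean (or
#' a negative binomial when `dispersion` is given, with `size = dispersion`).
#'
#' @param profiles list of [genotype_profile()] objects.
#' @param n_spikes spikes per genotype.
#' @param seed RNG seed.
#' @param dispersion optional negative-binomial size parameter; `NULL` for
#'   Poisson.
#' @return `data.frame` with columns `genotype`, `spike`, `seeds`.
#' @export
gen_fertility <- function(profiles, n_spikes, seed = 1, dispersion = NULL) {
  if (n_spikes < 1) stop_("n_spikes must be >= 1")
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  means <- vapply(profiles, function(p) p$mean_seeds_per_spike, numeric(1))
  if (any(means < 0)) stop_("mean seeds per spike must be non-negative")
  names_ <- vapply(profiles, function(p) p$name, character(1))
  seeds <- with_seed(seed, {
    unlist(lapply(means, function(mu) {
      if (is.null(dispersion)) rpois(n_spikes, mu)
      else rnbinom(n_spikes, mu = mu, size = dispersion)
    }))
  })
  data.frame(genotype = rep(names_, each = n_spikes),
             spike = rep(seq_len(n_spikes), length(profiles)),
             seeds = seeds, stringsAsFactors = FALSE)
}

#' Generate a CDS with an optional injected SNP
#'
#' Builds a coding sequence of `n_codons` codons: ATG start, random non-stop
#' internal codons, and a stop codon at the end. Optionally replaces one
#' internal codon by `ref_codon` and records the consequence of substituting
#' `alt_base` at offset `alt_base_offset` (1-3) within it; the returned truth
#' is computed by [annotate_cds_snp()] on the generated sequence, so injected
#' variants round-trip through the annotator by construction.
#'
#' @param n_codons codon count including start and stop (>= 3 to inject).
#' @param inject `NULL` or a list with elements `codon_index`, `ref_codon`,
#'   `alt_base_offset`, `alt_base`.
#' @param seed RNG seed.
#' @return list with `cds` (character) and `truth` (an `aa_change`, or `NULL`).
#' @examples
#' g <- gen_cds(1202, inject = list(codon_index = 539, ref_codon = "ACA",
#'                                  alt_base_offset = 1, alt_base = "G"),
#'              seed = 1)
#' g$truth$consequence  # "missense", Thr -> Ala at residue 539
#' @export
gen_cds <- function(n_codons, inject = NULL, seed = 1) {
  if (n_codons < 2) stop_("n_codons must be >= 2")
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  nonstop <- setdiff(all_codons, stops)
  codons <- with_seed(seed, {
    c("ATG",
      if (n_codons > 2) sample(nonstop, n_codons - 2L, replace = TRUE),
      sample(stops, 1))
  })
  truth <- NULL
  if (!is.null(inject)) {
    ci <- inject$codon_index
    rc <- toupper(inject$ref_codon)
    off <- inject$alt_base_offset
    alt <- toupper(inject$alt_base)
    if (ci < 1 || ci > n_codons) stop_("codon_index out of range")
    if (ci == 1) stop_("cannot inject into the start codon")
    if (ci < n_codons && rc %in% stops) {
      stop_("ref_codon would create an internal stop codon")
    }
    if (ci == n_codons && !(rc %in% stops)) {
      stop_("final codon must remain a stop codon")
    }
    if (!(off %in% 1:3)) stop_("alt_base_offset must be 1, 2 or 3")
    codons[ci] <- rc
    cds <- paste(codons, collapse = "")
    pos <- (ci - 1L) * 3L + off
    truth <- annotate_cds_snp(cds, pos, alt)
  }
  list(cds = paste(codons, collapse = ""), truth = truth)
}

#' Generate a synthetic gene annotation
#'
#' Uniformly placed gene models on each chromosome, for exercising the
#' deletion/gene intersection. Purely synthetic: ids carry a `GSYN` prefix.
#'
#' @param chromosomes character vector of chromosome names.
#' @param chromosome_length chromosome length in bp.
#' @param genes_per_chromosome gene count per chromosome.
#' @param seed RNG seed.
#' @param gene_length_range min/max gene length in bp.
#' @return `data.frame` with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, sorted by chromosome then start.
#' @export
gen_gene_annotation <- function(chromosomes, chromosome_length,
                                genes_per_chromosome, seed = 1,
                                gene_length_range = c(1000, 5000)) {
  if (genes_per_chromosome < 1) stop_("genes_per_chromosome must be >= 1")
  with_seed(seed, {
    rows <- lapply(chromosomes, function(ch) {
      start <- sort(sample.int(chromosome_length - max(gene_length_range),
                               genes_per_chromosome))
      len <- sample(gene_length_range[1]:gene_length_range[2],
                    genes_per_chromosome, replace = TRUE)
      data.frame(gene_id = sprintf("GSYN%s%04d", ch, seq_len(genes_per_chromosome)),
                 chromosome = ch, start = start, end = start + len,
                 strand = sample(c("+", "-"), genes_per_chromosome, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic orthogroup table
#'
#' Builds triads: each orthogroup nominally has one member per subgenome,
#' with each member independently present with probability `p_present`.
#'
#' @param n_groups number of orthogroups.
#' @param p_present probability a subgenome member exists.
#' @param seed RNG seed.
#' @param subgenomes subgenome labels.
#' @return `data.frame` with columns `gene_id`, `orthogroup_id`, `subgenome`.
#' @export
gen_orthogroup_table <- function(n_groups, p_present = 1, seed = 1,
                                 subgenomes = c("A", "B", "D")) {
  if (n_groups < 1) stop_("n_groups must be >= 1")
  with_seed(seed, {
    og <- rep(sprintf("OG%06d", seq_len(n_groups)), each = length(subgenomes))
    sg <- rep(subgenomes, n_groups)
    keep <- runif(length(og)) < p_present
    data.frame(gene_id = sprintf("G%s.%s", sub("OG", "", og), sg)[keep],
               orthogroup_id = og[keep], subgenome = sg[keep],
               stringsAsFactors = FALSE)
  })
}
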