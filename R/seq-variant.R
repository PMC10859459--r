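# CDS SNP consequences, CDS/protein length arithmetic, and percent identity
# on externally supplied alignments. Translation uses the standard genetic
# code (Biostrings::GENETIC_CODE).

#' Codon index of a CDS position
#'
#' @param cds_position 1-based nucleotide position(s) within the CDS.
#' @return 1-based codon index, `floor((pos - 1) / 3) + 1`.
#' @examples
#' codon_index(1615)  # 539
#' @export
codon_index <- function(cds_position) {
  if (any(cds_position < 1)) stop_("CDS positions are 1-based; got position < 1")
  as.integer((cds_position - 1) %/% 3 + 1)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop_("cannot translate codon '%s'", codon)
  aa
}

#' Annotate a single-nucleotide substitution in a CDS
#'
#' Maps the substitution to its codon, translates reference and alternate
#' codons with the standard genetic code, and classifies the consequence as
#' `synonymous`, `missense`, `stop_gained`, `stop_lost` or `start_lost`.
#'
#' @param cds coding sequence (character or `Biostrings::DNAString`); length
#'   must be divisible by 3, unambiguous A/C/G/T at the affected codon.
#' @param position 1-based position of the substitution within the CDS.
#' @param alt_base alternate base (A/C/G/T), different from the reference.
#' @return list of class `aa_change` with fields `cds_position`,
#'   `codon_index`, `within_codon_offset`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `consequence`.
#' @examples
#' cds <- paste0("ATG", "ACA", "TAA")
#' annotate_cds_snp(cds, 4, "G")  # Thr -> Ala, missense
#' @export
annotate_cds_snp <- function(cds, position, alt_base) {
  cds <- toupper(as.character(cds))
  len <- nchar(cds)
  if (len %% 3 != 0) stop_("CDS length %d is not divisible by 3", len)
  if (position < 1 || position > len) stop_("position outside the CDS")
  alt_base <- toupper(alt_base)
  if (!alt_base %in% c("A", "C", "G", "T")) {
    stop_("ambiguous or invalid alternate base '%s'", alt_base)
  }
  ci <- codon_index(position)
  off <- as.integer((position - 1) %% 3 + 1)
  ref_codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
  if (!grepl("^[ACGT]{3}$", ref_codon)) {
    stop_("ambiguous base in reference codon '%s'", ref_codon)
  }
  ref_base <- substr(ref_codon, off, off)
  if (ref_base == alt_base) {
    stop_("alternate base equals the reference base '%s' at position %s",
          ref_base, position)
  }
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  consequence <- if (ci == 1L && ref_aa == "M" && alt_aa != "M") {
    "start_lost"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else if (ref_aa == "*") {
    "stop_lost"
  } else if (alt_aa == "*") {
    "stop_gained"
  } else {
    "missense"
  }
  structure(list(cds_position = as.integer(position), codon_index = ci,
                 within_codon_offset = off, ref_codon = ref_codon,
                 alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
                 consequence = consequence),
            class = "aa_change")
}

#' @export
print.aa_change <- function(x, ...) {
  cat(sprintf("<aa_change> c.%d %s>%s (%s>%s) p.%s%d%s [%s]\n",
              x$cds_position,
              substr(x$ref_codon, x$within_codon_offset, x$within_codon_offset),
              substr(x$alt_codon, x$within_codon_offset, x$within_codon_offset),
              x$ref_codon, x$alt_codon,
              x$ref_aa, x$codon_index, x$alt_aa, x$consequence))
  invisible(x)
}

#' Protein length implied by a CDS length
#'
#' The terminal stop codon is excluded: a 3606 nt CDS encodes 1201 amino
#' acids.
#'
#' @param cds_length CDS length in nucleotides; divisible by 3 and >= 6.
#' @return amino-acid count, `cds_length / 3 - 1`.
#' @export
protein_length_from_cds <- function(cds_length) {
  if (any(cds_length %% 3 != 0)) {
    stop_("CDS length must be divisible by 3 (reading-frame violation)")
  }
  if (any(cds_length < 6)) stop_("CDS must hold at least a start and a stop codon")
  as.integer(cds_length / 3 - 1)
}

#' Percent identity of two aligned sequences
#'
#' Computed column-wise on a supplied pairwise alignment: columns where both
#' sequences have a gap are excluded; a residue aligned to a gap counts as a
#' mismatch. With `denominator = "shorter"` the identical-column count is
#' divided by the shorter ungapped sequence length instead.
#'
#' @param aligned_a,aligned_b gapped sequences of equal aligned length
#'   (character or `Biostrings` XString; gap character `-`).
#' @param denominator `"columns"` (default) or `"shorter"`.
#' @return percent identity, reported to 0.1.
#' @examples
#' percent_identity("AC-GT", "ACTGT")  # 80.0
#' @export
percent_identity <- function(aligned_a, aligned_b,
                             denominator = c("columns", "shorter")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(aligned_a))
  b <- toupper(as.character(aligned_b))
  if (nchar(a) != nchar(b)) {
    stop_("aligned lengths differ (%d vs %d)", nchar(a), nchar(b))
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  gap_a <- av == "-"
  gap_b <- bv == "-"
  scored <- !(gap_a & gap_b)
  ident <- sum(av == bv & !gap_a & !gap_b)
  denom <- if (denominator == "columns") {
    sum(scored)
  } else {
    min(sum(!gap_a), sum(!gap_b))
  }
  if (denom == 0) stop_("no scorable columns in the alignment")
  round(100 * ident / denom, 1)
}
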