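# Plain-text readers and writers for the pipeline's tabular formats.
# Intensity/call tables are TSV with marker_id in the first column and one
# column per sample; maps and summaries are TSV; cytology and fertility
# records are CSV; sequences are FASTA; truth records are JSON.

#' @rdname pipeline_io
#' @param map,path,x,calls,truth objects/paths as described per function.
#' @export
write_marker_map <- function(map, path) {
  write.table(map[, c("marker_id", "chromosome", "position")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline file formats
#'
#' `read_marker_map()`/`write_marker_map()` handle the marker map TSV
#' (`marker_id`, `chromosome`, `position`); `read_intensity()` and
#' `read_calls()` handle per-sample TSV tables with `marker_id` in the first
#' column; `read_meiocytes()`/`write_meiocytes()` the meiocyte configuration
#' CSV; `read_fertility()`/`write_fertility()` the seeds-per-spike CSV;
#' `read_cds_fasta()`/`write_cds_fasta()` FASTA via `Biostrings`;
#' `read_truth()`/`write_truth()` the simulation ground-truth JSON; and
#' `write_deletion_calls()`/`export_deletions_bed()` the caller's output
#' (BED is 0-based half-open).
#'
#' @name pipeline_io
#' @return readers return data.frames (or named character for FASTA);
#'   writers return the path invisibly.
NULL

#' @rdname pipeline_io
#' @export
read_marker_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(map))) {
    stop_("marker map must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$marker_id)) stop_("marker ids must be unique")
  for (ch in unique(map$chromosome)) {
    p <- map$position[map$chromosome == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop_("positions on %s are not strictly increasing", ch)
    }
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @rdname pipeline_io
#' @export
write_sample_table <- function(x, path) {
  stopifnot(names(x)[1] == "marker_id")
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_intensity <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "marker_id") stop_("first column must be marker_id")
  x
}

#' @rdname pipeline_io
#' @export
read_calls <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "marker_id") stop_("first column must be marker_id")
  vocab <- c("A", "B", "H", "OTV", "NoCall")
  vals <- unlist(x[-1], use.names = FALSE)
  bad <- setdiff(unique(vals), vocab)
  if (length(bad)) stop_("invalid allele call(s): %s", paste(bad, collapse = ", "))
  x
}

#' @rdname pipeline_io
#' @param cells meiocyte configuration data.frame.
#' @export
write_meiocytes <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_meiocytes <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "genotype", "n_univalent", "n_rod_bivalent",
            "n_ring_bivalent", "n_trivalent", "n_ring_quadrivalent",
            "n_rod_quadrivalent")
  if (!all(need %in% names(x))) {
    stop_("meiocyte table must have columns %s", paste(need, collapse = ", "))
  }
  x
}

#' @rdname pipeline_io
#' @param fertility seeds-per-spike data.frame.
#' @export
write_fertility <- function(fertility, path) {
  write.csv(fertility, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_fertility <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("genotype", "seeds") %in% names(x))) {
    stop_("fertility table must have columns genotype, seeds")
  }
  x
}

#' @rdname pipeline_io
#' @param seqs named character vector of sequences.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cds_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- names(s)
  out
}

#' @rdname pipeline_io
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname pipeline_io
#' @export
write_deletion_calls <- function(calls, path) {
  cols <- c("sample", "chromosome", "start", "end", "size_mb", "n_markers",
            "n_weak", "n_otv", "n_outliers", "mean_signal", "route")
  out <- calls[, intersect(cols, names(calls)), drop = FALSE]
  names(out)[names(out) == "chromosome"] <- "chrom"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
export_deletions_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chromosome,
                    start = calls$start - 1L,  # BED is 0-based half-open
                    end = calls$end,
                    name = sprintf("%s_del_%d",
                                   if ("sample" %in% names(calls)) calls$sample else "del",
                                   seq_len(nrow(calls))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
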