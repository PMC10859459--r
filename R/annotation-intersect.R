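# Intersection of called deletions with gene models and orthogroup tables:
# which genes lie inside each deletion, and how many homoeologous groups are
# lost on one, two or all three subgenomes.

#' Read gene models from a GFF3 file
#'
#' Imports the annotation with `rtracklayer` and keeps features of type
#' `gene` only; coordinates are 1-based inclusive per the GFF3 standard.
#'
#' @param path GFF3 file.
#' @return `data.frame` with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  data.frame(gene_id = as.character(id),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read an orthogroup membership table
#'
#' @param path TSV with columns `gene_id`, `orthogroup_id`, `subgenome`.
#' @return validated `data.frame`.
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "orthogroup_id", "subgenome")
  if (!all(need %in% names(tab))) {
    stop_("orthogroup table must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) stop_("gene ids in orthogroup table must be unique")
  if (!all(tab$subgenome %in% c("A", "B", "D"))) {
    stop_("subgenome labels must be A, B or D")
  }
  tab
}

#' Subgenome of a wheat-style chromosome name
#'
#' Extracts the trailing A/B/D from names like `2B` or `chr2B`.
#'
#' @param chromosome character vector of chromosome names.
#' @return character vector of subgenome labels.
#' @export
subgenome_of <- function(chromosome) {
  sg <- sub("^.*([ABD])$", "\\1", chromosome)
  bad <- !(sg %in% c("A", "B", "D"))
  if (any(bad)) {
    stop_("cannot infer subgenome from chromosome name(s): %s",
          paste(unique(chromosome[bad]), collapse = ", "))
  }
  sg
}

#' Genes inside a deletion interval
#'
#' Returns the ids of genes overlapping the deletion on the same chromosome,
#' sorted by gene start. `mode = "any"` requires at least 1 bp of overlap
#' (the default); `mode = "within"` requires the gene to be fully contained
#' between the deletion borders. Strand is ignored.
#'
#' @param genes gene models: `data.frame` with columns `gene_id`,
#'   `chromosome`, `start`, `end` (1-based inclusive).
#' @param deletion a single called deletion: list or one-row `data.frame`
#'   with `chromosome`, `start`, `end`.
#' @param mode overlap rule, `"any"` or `"within"`.
#' @return character vector of gene ids.
#' @export
genes_in_interval <- function(genes, deletion, mode = c("any", "within")) {
  mode <- match.arg(mode)
  g <- genes[genes$chromosome == deletion$chromosome[[1]], , drop = FALSE]
  if (!nrow(g)) return(character(0))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(g$start, g$end),
    IRanges::IRanges(deletion$start[[1]], deletion$end[[1]]),
    type = mode
  )
  g <- g[S4Vectors::queryHits(hits), , drop = FALSE]
  g$gene_id[order(g$start)]
}

#' Homoeologous orthogroup intersection across subgenomes
#'
#' Given the genes deleted on each subgenome, counts orthogroups affected on
#' one, two or all three of the A/B/D subgenomes. An orthogroup is "deleted
#' on genome G" as soon as at least one of its G-subgenome members is in the
#' deleted list; "triple-deleted" orthogroups are affected on all three.
#' Gene ids absent from the table are reported but not fatal. The summary is
#' independent of the order of the input lists.
#'
#' @param deleted named list mapping subgenome (`A`, `B`, `D`) to the vector
#'   of deleted gene ids on that subgenome.
#' @param table orthogroup table (`gene_id`, `orthogroup_id`, `subgenome`).
#' @return list of class `orthogroup_summary`: `per_genome` (data.frame with
#'   `subgenome`, `n_genes`, `n_orthogroups`), `by_multiplicity` (named
#'   counts for orthogroups deleted on exactly 1/2/3 genomes),
#'   `triple_deleted` (sorted orthogroup ids) and `unknown_gene_ids`.
#' @export
orthogroup_intersection <- function(deleted, table) {
  if (is.null(table) || !nrow(table)) stop_("empty orthogroup table")
  if (!all(names(deleted) %in% c("A", "B", "D"))) {
    stop_("names of `deleted` must be subgenomes A/B/D")
  }
  unknown <- setdiff(unique(unlist(deleted, use.names = FALSE)), table$gene_id)
  if (length(unknown)) {
    warning(sprintf("%d deleted gene id(s) not in the orthogroup table",
                    length(unknown)), call. = FALSE)
  }
  genomes <- c("A", "B", "D")
  ogs <- lapply(genomes, function(g) {
    del <- deleted[[g]] %||% character(0)
    rows <- table$subgenome == g & table$gene_id %in% del
    sort(unique(table$orthogroup_id[rows]))
  })
  names(ogs) <- genomes
  all_hit <- sort(unique(unlist(ogs, use.names = FALSE)))
  mult <- vapply(all_hit, function(og) {
    sum(vapply(genomes, function(g) og %in% ogs[[g]], logical(1)))
  }, integer(1))
  by_mult <- vapply(1:3, function(k) sum(mult == k), integer(1))
  names(by_mult) <- c("1", "2", "3")
  structure(list(
    per_genome = data.frame(
      subgenome = genomes,
      n_genes = vapply(genomes, function(g) length(deleted[[g]] %||% character(0)),
                       integer(1)),
      n_orthogroups = vapply(ogs, length, integer(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    by_multiplicity = by_mult,
    triple_deleted = all_hit[mult == 3L],
    unknown_gene_ids = unknown
  ), class = "orthogroup_summary")
}

#' @export
print.orthogroup_summary <- function(x, ...) {
  cat("<orthogroup_summary>\n")
  print(x$per_genome)
  cat(sprintf("orthogroups deleted on 1/2/3 genomes: %d / %d / %d\n",
              x$by_multiplicity[["1"]], x$by_multiplicity[["2"]],
              x$by_multiplicity[["3"]]))
  if (length(x$unknown_gene_ids)) {
    cat(sprintf("%d gene id(s) not in table\n", length(x$unknown_gene_ids)))
  }
  invisible(x)
}
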