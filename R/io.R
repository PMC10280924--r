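# readers and writers for the plain-text interchange formats
# (GFF3, BED6, FASTA, TSV count matrices, design tables, truth JSON)

#' Write an annotation to GFF3
#'
#' Emits gene/mRNA/exon features (1-based, closed coordinates) with
#' `##sequence-region` pragmas. Output is byte-deterministic for a given
#' annotation.
#'
#' @param annotation a `genome_annotation` object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  tabs <- annotation_tables(annotation)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(annotation$chrom_lengths),
                     as.integer(annotation$chrom_lengths)))
  g <- tabs$genes[order(tabs$genes$chrom, tabs$genes$start), , drop = FALSE]
  feat <- function(chrom, type, start, end, strand, attr)
    sprintf("%s\tcernets\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attr)
  out <- character(0)
  tx <- tabs$transcripts
  ex <- tabs$exons
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    out <- c(out, feat(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                       paste0("ID=", gid)))
    txi <- tx[tx$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      tid <- txi$tx_id[j]
      out <- c(out, feat(txi$chrom[j], "mRNA", txi$start[j], txi$end[j],
                         txi$strand[j], paste0("ID=", tid, ";Parent=", gid)))
      exj <- ex[ex$tx_id == tid, , drop = FALSE]
      exj <- exj[order(exj$start), , drop = FALSE]
      out <- c(out, feat(exj$chrom, "exon", exj$start, exj$end, exj$strand,
                         sprintf("ID=%s.exon%d;Parent=%s", tid,
                                 seq_len(nrow(exj)), tid)))
    }
  }
  writeLines(c(lines, out), path)
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Imports gene/mRNA/exon features via rtracklayer and assembles the
#' `genome_annotation` container used by [classify_circrnas()]. GFF3
#' coordinates are 1-based closed and kept as such in the GRanges.
#'
#' @param path GFF3 file.
#' @return A `genome_annotation` object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  to_df <- function(g, id_col) {
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
               start = BiocGenerics::start(g),
               end = BiocGenerics::end(g),
               strand = as.character(BiocGenerics::strand(g)),
               stringsAsFactors = FALSE)
  }
  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  gdf <- to_df(genes); gdf$gene_id <- as.character(genes$ID)
  parent1 <- function(g) vapply(as.list(g$Parent), function(p) p[1], "")
  tx_gene <- stats::setNames(parent1(txs), as.character(txs$ID))
  edf <- to_df(exons)
  edf$tx_id <- parent1(exons)
  edf$gene_id <- unname(tx_gene[edf$tx_id])
  lens <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(lens)))
    lens <- stats::setNames(tapply(gdf$end, gdf$chrom, max), NULL)
  ann <- build_annotation(gdf, edf[, c("chrom", "start", "end", "strand",
                                       "gene_id", "tx_id")],
                          lens)
  ann
}

#' Write back-splice junctions to BED6
#'
#' BED is 0-based, half-open; the 1-based closed GRanges coordinates are
#' converted on write. Column 5 (score) is 0; strand goes to column 6.
#'
#' @param circs GRanges with a `circ_id` metadata column (or names).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bed6 <- function(circs, path) {
  ids <- S4Vectors::mcols(circs)$circ_id %||% names(circs)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomeInfoDb::seqnames(circs)),
                   BiocGenerics::start(circs) - 1L,
                   BiocGenerics::end(circs),
                   ids,
                   as.character(BiocGenerics::strand(circs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read back-splice junctions from BED6
#'
#' @param path BED file (0-based half-open; converted to 1-based closed
#'   GRanges on read).
#' @return GRanges with a `circ_id` metadata column.
#' @export
read_junctions <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr)$circ_id <- gr$name
  gr
}

#' Read a counts matrix from TSV
#'
#' First column is the feature id, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_counts <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample` and `group`.
#' @return data.frame with `sample` and `group` columns.
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample", "group") %in% names(df)))
    stop("design file must have columns `sample` and `group`", call. = FALSE)
  df
}

#' Read RNA sequences from FASTA
#'
#' DNA alphabets are accepted; T is converted to U so the internal alphabet
#' is always RNA.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::RNAStringSet].
#' @export
read_rna_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(raw))
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGU]", s)
  if (any(bad))
    stop("read_rna_fasta: non-ACGU/T symbol in sequence ",
         names(raw)[bad][1], call. = FALSE)
  out <- Biostrings::RNAStringSet(s)
  names(out) <- names(raw)
  out
}

write_rna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Serialize / read planted ground truth as JSON
#'
#' @param truth a `cerna_truth` object (as carried by a simulated bundle).
#' @param path JSON file path.
#' @return `write_truth()` returns the path; `read_truth()` a `cerna_truth`.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    mrna_ids = truth$mrna_ids,
    mirna_ids = truth$mirna_ids,
    circ_ids = truth$circ_ids,
    planted_triplets = truth$planted_triplets,
    planted_categories = as.list(truth$planted_categories),
    planted_de = as.list(truth$planted_de),
    target_lengths = as.list(truth$target_lengths),
    planted_sites = truth$planted_sites)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mrna_ids = as.character(x$mrna_ids),
    mirna_ids = as.character(x$mirna_ids),
    circ_ids = as.character(x$circ_ids),
    planted_triplets = as.data.frame(x$planted_triplets,
                                     stringsAsFactors = FALSE),
    planted_categories = unlist(x$planted_categories) %||% character(0),
    planted_de = unlist(x$planted_de) %||% character(0),
    target_lengths = unlist(lapply(x$target_lengths, as.integer)),
    planted_sites = lapply(x$planted_sites, as.integer)),
    class = "cerna_truth")
}
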