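#' Simulate a gene annotation
#'
#' Places non-overlapping genes along each chromosome, each carrying one
#' transcript of 1--18 exons (configurable), with exons sorted and contained
#' in the gene bounds and both strands represented. The result is the
#' reference frame against which back-splice junctions are classified.
#'
#' @param config a [sim_config()] object.
#' @return A `genome_annotation` object: GRanges of genes, transcripts and
#'   exons plus chromosome lengths.
#' @examples
#' ann <- simulate_annotation(sim_config(seed = 1, n_genes = 12))
#' ann
#' @export
simulate_annotation <- function(config) {
  config <- validate_sim_config(config)
  with_seed(child_seed(config$seed, "annotation"), {
    n_chrom <- config$n_chromosomes
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    genes_per <- diff(round(seq(0, config$n_genes, length.out = n_chrom + 1)))
    exr <- config$exon_count_range
    exw <- exon_count_weights(exr)
    gene_rows <- vector("list", config$n_genes)
    exon_rows <- vector("list", config$n_genes)
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      pos <- 1L
      for (k in seq_len(genes_per[ci])) {
        gid <- gid + 1L
        n_ex <- sample(seq(exr[1], exr[2]), 1L, prob = exw)
        ex_w <- runif_int(n_ex, 80L, 300L)
        in_w <- if (n_ex > 1L) runif_int(n_ex - 1L, 60L, 500L) else integer(0)
        start <- pos + runif_int(1L, 500L, 3000L)
        ex_starts <- start + cumsum(c(0L, utils::head(ex_w, -1) + in_w))
        ex_ends <- ex_starts + ex_w - 1L
        gend <- ex_ends[n_ex]
        if (gend > config$chrom_length)
          stop("simulate_annotation: cannot pack ", config$n_genes,
               " genes into chromosomes of length ", config$chrom_length,
               " (ran out of room on ", chroms[ci], ")", call. = FALSE)
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("gene_%04d", gid)
        gene_rows[[gid]] <- data.frame(chrom = chroms[ci], start = start,
                                       end = gend, strand = strand,
                                       gene_id = id,
                                       stringsAsFactors = FALSE)
        exon_rows[[gid]] <- data.frame(chrom = chroms[ci], start = ex_starts,
                                       end = ex_ends, strand = strand,
                                       gene_id = id,
                                       tx_id = paste0(id, ".t1"),
                                       stringsAsFactors = FALSE)
        pos <- gend
      }
    }
    genes <- do.call(rbind, gene_rows)
    exons <- do.call(rbind, exon_rows)
    # guarantee both strands are present when there is more than one gene
    if (config$n_genes > 1L && length(unique(genes$strand)) == 1L) {
      flip <- ifelse(genes$strand[1] == "+", "-", "+")
      genes$strand[1] <- flip
      exons$strand[exons$gene_id == genes$gene_id[1]] <- flip
    }
    build_annotation(genes, exons,
                     stats::setNames(rep(config$chrom_length, n_chrom), chroms))
  })
}

# geometric-ish weights over the exon-count support: most transcripts carry
# few exons, the tail reaches the upper bound
exon_count_weights <- function(range) {
  k <- seq(range[1], range[2])
  w <- 0.6 ^ (k - k[1])
  w / sum(w)
}

# assemble the genome_annotation S3 object from plain gene/exon tables
build_annotation <- function(genes, exons, chrom_lengths) {
  mk <- function(df, extra) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
    gr
  }
  tx <- genes
  tx$tx_id <- paste0(tx$gene_id, ".t1")
  ex <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(ex)), ex$tx_id, FUN = seq_along)
  ex$exon_rank <- as.integer(rank)
  structure(list(genes = mk(genes, "gene_id"),
                 transcripts = mk(tx, c("tx_id", "gene_id")),
                 exons = mk(ex, c("tx_id", "gene_id", "exon_rank")),
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons on %d sequences\n",
              length(x$genes), length(x$transcripts), length(x$exons),
              length(unique(as.character(GenomeInfoDb::seqnames(x$genes))))))
  invisible(x)
}

# plain data.frame views used by the generators and the classifier
annotation_tables <- function(annotation) {
  gr_df <- function(gr, cols) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     stringsAsFactors = FALSE)
    for (nm in cols) df[[nm]] <- S4Vectors::mcols(gr)[[nm]]
    df
  }
  list(genes = gr_df(annotation$genes, "gene_id"),
       transcripts = gr_df(annotation$transcripts, c("tx_id", "gene_id")),
       exons = gr_df(annotation$exons, c("tx_id", "gene_id", "exon_rank")))
}

# introns as GRanges (gaps between consecutive exons of each transcript)
annotation_introns <- function(annotation) {
  ex <- annotation_tables(annotation)$exons
  ex <- ex[order(ex$tx_id, ex$start), , drop = FALSE]
  same <- c(FALSE, ex$tx_id[-1] == ex$tx_id[-nrow(ex)])
  if (!any(same)) {
    return(GenomicRanges::GRanges(intron_tx = character(0)))
  }
  i <- which(same)
  starts <- ex$end[i - 1L] + 1L
  ends <- ex$start[i] - 1L
  keep <- ends >= starts
  gr <- GenomicRanges::GRanges(ex$chrom[i][keep],
                               IRanges::IRanges(starts[keep], ends[keep]),
                               strand = ex$strand[i][keep])
  S4Vectors::mcols(gr)$tx_id <- ex$tx_id[i][keep]
  gr
}
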