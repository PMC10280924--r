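#' Classify back-splice junctions against a genome annotation
#'
#' Assigns each circRNA to exactly one of five categories, evaluated in
#' precedence order:
#'
#' 1. **exonic** — both junction ends coincide (within
#'    `boundary_tolerance` nt, default exact) with annotated exon boundaries
#'    of one same-strand transcript;
#' 2. **intronic** — the interval lies fully inside a single intron of a
#'    same-strand transcript;
#' 3. **sense_overlapping** — any other overlap with a same-strand gene;
#' 4. **antisense** — overlap only with opposite-strand gene(s);
#' 5. **intergenic** — no gene overlap (unknown chromosomes fall here).
#'
#' `exon_count` is the number of annotated exons of the best same-strand
#' transcript (largest genomic overlap; ties broken by transcript id) that
#' the interval strictly overlaps; it is 0 for antisense and intergenic
#' records.
#'
#' @param circs GRanges with a `circ_id` metadata column, or a data.frame
#'   with columns `circ_id`, `chrom`, `start` (0-based), `end`, `strand`.
#' @param annotation a `genome_annotation` ([read_annotation()] or
#'   [simulate_annotation()]).
#' @param boundary_tolerance nt of slack allowed when matching junction ends
#'   to exon boundaries (default 0 = exact).
#' @return data.frame: `circ_id`, `chrom`, `start` (0-based), `end`,
#'   `strand`, `length` (genomic span), `category`, `exon_count`.
#' @examples
#' ann <- simulate_annotation(sim_config(seed = 1, n_genes = 10))
#' cj <- simulate_circrnas(ann, sim_config(seed = 1, n_genes = 10), n = 15)
#' cls <- classify_circrnas(cj$granges, ann)
#' table(cls$category)
#' @export
classify_circrnas <- function(circs, annotation, boundary_tolerance = 0) {
  gr <- as_circ_granges(circs)
  n <- length(gr)
  genes <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons

  ov <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  same <- as.character(BiocGenerics::strand(gr))[qh] ==
    as.character(BiocGenerics::strand(genes))[sh]
  has_any <- tabulate(qh, n) > 0
  has_sense <- tabulate(qh[same], n) > 0

  # exonic: start and end both land on exon boundaries of one transcript
  maxgap <- if (boundary_tolerance > 0) boundary_tolerance - 1L else -1L
  pt <- function(g, pos) GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                                                IRanges::IRanges(pos, width = 1L),
                                                strand = BiocGenerics::strand(g))
  hs <- GenomicRanges::findOverlaps(pt(gr, BiocGenerics::start(gr)),
                                    pt(ex, BiocGenerics::start(ex)),
                                    maxgap = maxgap)
  he <- GenomicRanges::findOverlaps(pt(gr, BiocGenerics::end(gr)),
                                    pt(ex, BiocGenerics::end(ex)),
                                    maxgap = maxgap)
  tx_of_exon <- S4Vectors::mcols(ex)$tx_id
  keyA <- unique(paste(S4Vectors::queryHits(hs),
                       tx_of_exon[S4Vectors::subjectHits(hs)]))
  keyB <- unique(paste(S4Vectors::queryHits(he),
                       tx_of_exon[S4Vectors::subjectHits(he)]))
  exonic_idx <- unique(as.integer(sub(" .*", "", intersect(keyA, keyB))))

  # intronic: fully inside one intron of a same-strand transcript
  introns <- annotation_introns(annotation)
  intronic_idx <- if (length(introns)) {
    unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, introns, type = "within")))
  } else integer(0)

  category <- rep("intergenic", n)
  category[has_any & !has_sense] <- "antisense"
  category[has_sense] <- "sense_overlapping"
  category[intersect(intronic_idx, which(has_sense))] <- "intronic"
  category[exonic_idx] <- "exonic"

  # best same-strand transcript and its strictly-overlapped exon count
  exon_count <- integer(n)
  ovt <- GenomicRanges::findOverlaps(gr, tx)
  if (length(ovt)) {
    tq <- S4Vectors::queryHits(ovt); ts <- S4Vectors::subjectHits(ovt)
    w <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(gr)[tq], IRanges::ranges(tx)[ts]))
    tid <- S4Vectors::mcols(tx)$tx_id[ts]
    ord <- order(tq, -w, tid)
    first <- !duplicated(tq[ord])
    best_tx <- stats::setNames(tid[ord][first], tq[ord][first])
    ove <- GenomicRanges::findOverlaps(gr, ex)
    if (length(ove)) {
      ekey <- paste(S4Vectors::queryHits(ove),
                    tx_of_exon[S4Vectors::subjectHits(ove)])
      etab <- table(ekey)
      want <- paste(names(best_tx), best_tx)
      cnt <- as.integer(etab[want])
      cnt[is.na(cnt)] <- 0L
      exon_count[as.integer(names(best_tx))] <- cnt
    }
  }
  exon_count[category %in% c("antisense", "intergenic")] <- 0L

  data.frame(circ_id = S4Vectors::mcols(gr)$circ_id,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             length = BiocGenerics::width(gr),
             category = category,
             exon_count = exon_count,
             stringsAsFactors = FALSE)
}

as_circ_granges <- function(circs) {
  if (inherits(circs, "GRanges")) {
    if (is.null(S4Vectors::mcols(circs)$circ_id))
      S4Vectors::mcols(circs)$circ_id <-
        names(circs) %||% sprintf("circ_%d", seq_along(circs))
    return(circs)
  }
  if (is.data.frame(circs)) {
    gr <- GenomicRanges::GRanges(circs$chrom,
                                 IRanges::IRanges(circs$start + 1L, circs$end),
                                 strand = circs$strand)
    S4Vectors::mcols(gr)$circ_id <- circs$circ_id
    return(gr)
  }
  stop("circs must be a GRanges or a data.frame", call. = FALSE)
}
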