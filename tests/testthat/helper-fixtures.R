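# shared fixtures: small configs and a hand-built toy annotation

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 24L, n_mirnas = 10L, n_circrnas = 14L,
             n_planted_triplets = 5L, ...)
}

null_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 30L, n_mirnas = 12L, n_circrnas = 16L,
             n_planted_triplets = 8L, de_lfc = 0, repression_strength = 0,
             sponge_strength = 0, ...)
}

# one 3-exon gene on the plus strand of chrT:
#   exons 101-200, 301-400, 501-600; introns 201-300, 401-500
toy_annotation <- function(strand = "+") {
  genes <- data.frame(chrom = "chrT", start = 101L, end = 600L,
                      strand = strand, gene_id = "geneT",
                      stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chrT",
                      start = c(101L, 301L, 501L),
                      end = c(200L, 400L, 600L),
                      strand = strand, gene_id = "geneT", tx_id = "geneT.t1",
                      stringsAsFactors = FALSE)
  cernets:::build_annotation(genes, exons, c(chrT = 10000L))
}

toy_circ <- function(start, end, strand = "+", id = "c1") {
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$circ_id <- id
  gr
}

# independent N50 formulation: the largest length L in the multiset whose
# >=L members hold at least half the total
n50_oracle <- function(lengths) {
  tot <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  min(lengths)
}

pair_table_path <- function() {
  system.file("extdata", "mirna_circrna_pairs.tsv", package = "cernets")
}
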