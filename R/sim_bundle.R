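#' Simulate a complete ceRNA fixture bundle
#'
#' Runs every generator stage: annotation, back-splice junctions with planted
#' categories, ground truth (triplets, DE directions, MRE positions),
#' negative-binomial expression, and sequences with planted binding sites.
#' The same configuration always yields the identical bundle.
#'
#' @param config a [sim_config()].
#' @return A `cerna_bundle`: list with `config`, `annotation`,
#'   `circ_junctions` (GRanges), `counts` (mrna/mirna/circ matrices),
#'   `design`, `sequences` (mirna/targets RNAStringSets), `terms`
#'   (synthetic term annotation for the mRNA universe) and `truth`.
#' @examples
#' b <- simulate_bundle(sim_config(seed = 3, n_genes = 20, n_circrnas = 12,
#'                                 n_mirnas = 10, n_planted_triplets = 4))
#' b
#' @export
simulate_bundle <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  ann <- simulate_annotation(config)
  circ <- simulate_circrnas(ann, config)
  truth <- build_truth(ann, circ, config)
  expr <- simulate_expression(truth, config)
  seqs <- plant_binding_sites(truth, config)
  terms <- simulate_term_annotation(truth$mrna_ids,
                                    seed = child_seed(config$seed, "terms"))
  structure(list(config = config, annotation = ann,
                 circ_junctions = circ$granges,
                 counts = expr$counts, design = expr$design,
                 sequences = seqs, terms = terms, truth = truth),
            class = "cerna_bundle")
}

#' @export
print.cerna_bundle <- function(x, ...) {
  cat("cerna_bundle (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  %d genes / %d miRNAs / %d circRNAs, %d samples\n",
              nrow(x$counts$mrna), nrow(x$counts$mirna), nrow(x$counts$circ),
              nrow(x$design)))
  cat(sprintf("  %d planted triplets\n", nrow(x$truth$planted_triplets)))
  invisible(x)
}

#' Simulate a term annotation for enrichment testing
#'
#' Assigns features to synthetic GO-like terms (BP/CC/MF namespaces) at
#' random, so the over-representation stage can be exercised end to end.
#'
#' @param feature_ids features to annotate.
#' @param n_terms number of terms.
#' @param min_size,max_size term size range.
#' @param seed integer seed.
#' @return data.frame with `term_id`, `term_name`, `namespace`, `feature_id`.
#' @export
simulate_term_annotation <- function(feature_ids, n_terms = 15L,
                                     min_size = 3L, max_size = 12L,
                                     seed = 1L) {
  with_seed(seed, {
    ns <- c("BP", "CC", "MF")
    rows <- lapply(seq_len(n_terms), function(i) {
      size <- min(length(feature_ids),
                  runif_int(1L, min_size, max_size))
      data.frame(term_id = sprintf("TERM:%04d", i),
                 term_name = sprintf("synthetic process %d", i),
                 namespace = ns[(i - 1L) %% 3L + 1L],
                 feature_id = sample(feature_ids, size),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a fixture bundle to disk
#'
#' Emits `annotation.gff3`, `circ_junctions.bed`, the three counts TSVs,
#' `design.tsv`, `mirna.fasta`, `targets.fasta`, `terms.tsv`, `truth.json`
#' and a `manifest.json` with md5 checksums. Re-running with the same
#' configuration reproduces identical bytes.
#'
#' @param bundle a `cerna_bundle`.
#' @param dir output directory (created if absent).
#' @return data.frame manifest (file, md5, bytes), invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cerna_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = "annotation.gff3",
             junctions = "circ_junctions.bed",
             mrna = "mrna_counts.tsv", mirna = "mirna_counts.tsv",
             circ = "circ_counts.tsv", design = "design.tsv",
             mirna_fa = "mirna.fasta", targets_fa = "targets.fasta",
             terms = "terms.tsv", truth = "truth.json")
  fp <- function(x) file.path(dir, x)
  write_gff3(bundle$annotation, fp(paths["annotation"]))
  write_bed6(bundle$circ_junctions, fp(paths["junctions"]))
  write_counts(bundle$counts$mrna, fp(paths["mrna"]))
  write_counts(bundle$counts$mirna, fp(paths["mirna"]))
  write_counts(bundle$counts$circ, fp(paths["circ"]))
  write_tsv(bundle$design, fp(paths["design"]))
  write_rna_fasta(bundle$sequences$mirna, fp(paths["mirna_fa"]))
  write_rna_fasta(bundle$sequences$targets, fp(paths["targets_fa"]))
  write_tsv(bundle$terms, fp(paths["terms"]))
  write_truth(bundle$truth, fp(paths["truth"]))
  files <- unname(paths)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(fp(files))),
                         bytes = unname(file.size(fp(files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle from disk
#'
#' Counterpart of [write_bundle()]; also used to feed [cerna_pipeline()] with
#' externally prepared inputs laid out in the same file scheme.
#'
#' @param dir bundle directory.
#' @return A `cerna_bundle` (without `config`; `truth` and `terms` are NULL
#'   when their files are absent).
#' @export
read_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  truth <- if (file.exists(fp("truth.json"))) read_truth(fp("truth.json"))
  terms <- if (file.exists(fp("terms.tsv"))) read_tsv(fp("terms.tsv"))
  structure(list(config = NULL,
                 annotation = read_annotation(fp("annotation.gff3")),
                 circ_junctions = read_junctions(fp("circ_junctions.bed")),
                 counts = list(mrna = read_counts(fp("mrna_counts.tsv")),
                               mirna = read_counts(fp("mirna_counts.tsv")),
                               circ = read_counts(fp("circ_counts.tsv"))),
                 design = read_design(fp("design.tsv")),
                 sequences = list(mirna = read_rna_fasta(fp("mirna.fasta")),
                                  targets = read_rna_fasta(fp("targets.fasta"))),
                 terms = terms, truth = truth),
            class = "cerna_bundle")
}
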