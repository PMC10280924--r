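#' Thresholds for the ceRNA pipeline
#'
#' The conventional screening thresholds: correlation `|r| >= 0.8` at
#' `p < 0.05`; mRNA differential expression at `|log2FC| >= 1`, miRNA and
#' circRNA at fold change > 2 (the same bound on the log2 scale), all at
#' `p < 0.05`; top 50 circRNA--mRNA interactions ranked by ceRNA score; top
#' 200 co-expressed pairs exported for visualisation.
#'
#' @param r_min minimum |Pearson r| in correlation screens.
#' @param corr_p_max correlation p cutoff.
#' @param de_lfc_min minimum |log2FC| for mRNA DE.
#' @param de_fc_min minimum fold change for circRNA/miRNA DE (linear scale).
#' @param de_p_max DE p cutoff (0.05; the occasionally quoted 0.5 is
#'   selectable).
#' @param use_padj filter DE on BH-adjusted p instead of raw p.
#' @param cerna_alpha significance cutoff on the ceRNA score (default 1 =
#'   keep every pair with at least one shared miRNA).
#' @param top_k retained interactions after evidence intersection.
#' @param top_coexpr_export co-expression pairs exported for plotting.
#' @param pseudocount pseudocount for the log2 transform in DE.
#' @param corr_log2 correlate log2(normalized + pseudocount) values rather
#'   than the normalized values themselves (default TRUE, the usual choice
#'   for expression co-expression).
#' @param boundary_tolerance exon-boundary slack (nt) in classification.
#' @return list of thresholds (serialized into every run manifest).
#' @export
cerna_thresholds <- function(r_min = 0.8, corr_p_max = 0.05,
                             de_lfc_min = 1.0, de_fc_min = 2.0,
                             de_p_max = 0.05, use_padj = FALSE,
                             cerna_alpha = 1, top_k = 50,
                             top_coexpr_export = 200, pseudocount = 1,
                             corr_log2 = TRUE, boundary_tolerance = 0) {
  th <- list(r_min = r_min, corr_p_max = corr_p_max,
             de_lfc_min = de_lfc_min, de_fc_min = de_fc_min,
             de_p_max = de_p_max, use_padj = use_padj,
             cerna_alpha = cerna_alpha, top_k = top_k,
             top_coexpr_export = top_coexpr_export,
             pseudocount = pseudocount, corr_log2 = corr_log2,
             boundary_tolerance = boundary_tolerance)
  stopifnot(th$r_min >= 0, th$r_min <= 1,
            th$corr_p_max > 0, th$corr_p_max <= 1,
            th$de_lfc_min >= 0, th$de_fc_min >= 1,
            th$de_p_max > 0, th$de_p_max <= 1,
            th$cerna_alpha > 0, th$cerna_alpha <= 1,
            th$top_k >= 1, th$pseudocount >= 0,
            th$boundary_tolerance >= 0)
  th
}

#' Run the full ceRNA inference pipeline
#'
#' Orchestrates the stages end to end on a bundle (simulated via
#' [simulate_bundle()], or read from disk via [read_bundle()]):
#' classification and catalogue summaries; normalization (CPM for mRNA and
#' miRNA, RPM for back-splice junction counts) and differential expression;
#' directional correlation screens; binding-site prediction over the DE
#' features; hypergeometric ceRNA scoring over shared miRNAs; intersection
#' with positive co-expression; direction-coherent network assembly; and
#' term enrichment of the network mRNAs (when a term annotation is
#' available). Each filter logs before/after counts and the funnel is kept
#' in the result.
#'
#' @param bundle a `cerna_bundle`, or a [sim_config()] (simulated on the
#'   fly), or a directory path (read via [read_bundle()]).
#' @param thresholds a [cerna_thresholds()] list.
#' @param out_dir optional directory; when given, every stage table, the
#'   network files and a `manifest.json` (thresholds + md5 checksums) are
#'   written there.
#' @param verbose log one structured line per filter (default TRUE).
#' @return A `cerna_run` object: stage outputs, the `cernet` network, the
#'   filter `funnel`, thresholds and (when available) planted-truth
#'   recovery.
#' @examples
#' \donttest{
#' run <- cerna_pipeline(sim_config(seed = 1), verbose = FALSE)
#' run
#' }
#' @export
cerna_pipeline <- function(bundle, thresholds = cerna_thresholds(),
                           out_dir = NULL, verbose = TRUE) {
  if (inherits(bundle, "sim_config")) bundle <- simulate_bundle(bundle)
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "cerna_bundle"))
  th <- thresholds
  funnel <- list()
  log_step <- function(stage, before, after) {
    funnel[[length(funnel) + 1L]] <<- data.frame(stage = stage,
                                                 before = before,
                                                 after = after,
                                                 stringsAsFactors = FALSE)
    if (verbose) message(sprintf("[%s] %d -> %d", stage, before, after))
  }

  ## 1. classify junctions + catalogue summaries ---------------------------
  classification <- classify_circrnas(bundle$circ_junctions,
                                      bundle$annotation,
                                      th$boundary_tolerance)
  per_sample <- apply(bundle$counts$circ > 0, 2,
                      function(v) rownames(bundle$counts$circ)[v],
                      simplify = FALSE)
  summaries <- list(categories = category_proportions(classification),
                    lengths = circ_length_stats(classification),
                    chromosomes = per_chromosome_counts(classification),
                    exons = exon_count_histogram(classification),
                    samples = unique_counts(per_sample))

  ## 2. normalize + differential expression --------------------------------
  norm <- list(mrna = normalize_counts(bundle$counts$mrna, "CPM"),
               mirna = normalize_counts(bundle$counts$mirna, "CPM"),
               circ = normalize_counts(bundle$counts$circ, "RPM"))
  lfc_fc <- log2(th$de_fc_min)
  de <- list(
    mrna = de_test(norm$mrna, bundle$design, th$pseudocount,
                   lfc_min = th$de_lfc_min, p_max = th$de_p_max,
                   use_padj = th$use_padj),
    mirna = de_test(norm$mirna, bundle$design, th$pseudocount,
                    lfc_min = lfc_fc, p_max = th$de_p_max,
                    use_padj = th$use_padj),
    circ = de_test(norm$circ, bundle$design, th$pseudocount,
                   lfc_min = lfc_fc, p_max = th$de_p_max,
                   use_padj = th$use_padj))
  de_sets <- list(
    mrna = filter_de(de$mrna, th$de_lfc_min, th$de_p_max, th$use_padj),
    mirna = filter_de(de$mirna, lfc_fc, th$de_p_max, th$use_padj),
    circ = filter_de(de$circ, lfc_fc, th$de_p_max, th$use_padj))
  log_step("DE mRNA", nrow(de$mrna), nrow(de_sets$mrna))
  log_step("DE miRNA", nrow(de$mirna), nrow(de_sets$mirna))
  log_step("DE circRNA", nrow(de$circ), nrow(de_sets$circ))

  ## 3. correlation screens over the DE features ---------------------------
  cmat <- if (isTRUE(th$corr_log2))
    lapply(norm, function(m) log2(m + th$pseudocount)) else norm
  sub <- function(m, ids) m[rownames(m) %in% ids, , drop = FALSE]
  mi <- de_sets$mirna$feature_id
  gg <- de_sets$mrna$feature_id
  cc <- de_sets$circ$feature_id
  corr <- list(
    mirna_mrna = correlate_pairs(sub(cmat$mirna, mi), sub(cmat$mrna, gg),
                                 "miRNA_mRNA", "negative",
                                 th$r_min, th$corr_p_max),
    mirna_circ = correlate_pairs(sub(cmat$mirna, mi), sub(cmat$circ, cc),
                                 "miRNA_circRNA", "negative",
                                 th$r_min, th$corr_p_max),
    circ_mrna = correlate_pairs(sub(cmat$circ, cc), sub(cmat$mrna, gg),
                                "circRNA_mRNA", "positive",
                                th$r_min, th$corr_p_max))
  log_step("corr miRNA-mRNA", length(mi) * length(gg),
           nrow(corr$mirna_mrna))
  log_step("corr miRNA-circRNA", length(mi) * length(cc),
           nrow(corr$mirna_circ))
  log_step("corr circRNA-mRNA (positive)", length(cc) * length(gg),
           nrow(corr$circ_mrna))

  ## 4. binding-site prediction over the DE features -----------------------
  seq_sub <- function(ids) {
    s <- bundle$sequences$targets
    s[names(s) %in% ids]
  }
  mirnas <- bundle$sequences$mirna
  mirnas <- mirnas[names(mirnas) %in% mi]
  binding <- list(circ = predict_binding(mirnas, seq_sub(cc)),
                  mrna = predict_binding(mirnas, seq_sub(gg)))

  ## 5. interaction pairs = negative correlation AND >= 1 MRE --------------
  merge_pairs <- function(cp, bp, target_col) {
    key_c <- paste(cp$id_a, cp$id_b)
    key_b <- paste(bp$mirna_id, bp$target_id)
    hit <- match(key_c, key_b)
    out <- cp[!is.na(hit), , drop = FALSE]
    out <- cbind(out, bp[hit[!is.na(hit)],
                         c("total_score", "total_energy", "max_score",
                           "max_energy", "target_length", "positions",
                           "mre"), drop = FALSE])
    names(out)[names(out) == "id_a"] <- "mirna_id"
    names(out)[names(out) == "id_b"] <- target_col
    rownames(out) <- NULL
    out
  }
  mc_pairs <- merge_pairs(corr$mirna_circ, binding$circ, "circ_id")
  mg_pairs <- merge_pairs(corr$mirna_mrna, binding$mrna, "mrna_id")
  log_step("miRNA-circRNA pairs (corr + MRE)", nrow(corr$mirna_circ),
           nrow(mc_pairs))
  log_step("miRNA-mRNA pairs (corr + MRE)", nrow(corr$mirna_mrna),
           nrow(mg_pairs))

  ## 6. hypergeometric ceRNA score over shared miRNAs ----------------------
  circ_targets <- split(mc_pairs$mirna_id, mc_pairs$circ_id)
  mrna_targets <- split(mg_pairs$mirna_id, mg_pairs$mrna_id)
  universe <- mi
  score <- cerna_score(circ_targets, mrna_targets, universe,
                       alpha = th$cerna_alpha)
  log_step("ceRNA score pairs (x >= 1)",
           length(circ_targets) * length(mrna_targets), nrow(score))

  ## 7. intersect with positive co-expression, rank, truncate --------------
  final_pairs <- intersect_evidence(score, corr$circ_mrna, th$top_k)
  log_step("score x positive-coexpression intersection", nrow(score),
           nrow(final_pairs))

  ## 8. direction-coherent network -----------------------------------------
  dirs <- c(stats::setNames(de_sets$mrna$direction, de_sets$mrna$feature_id),
            stats::setNames(de_sets$mirna$direction, de_sets$mirna$feature_id),
            stats::setNames(de_sets$circ$direction, de_sets$circ$feature_id))
  network <- build_cernet(final_pairs, mc_pairs, mg_pairs, dirs)
  log_step("direction-coherent triplets", nrow(final_pairs),
           nrow(network$triplets))

  ## 9. enrichment of the network mRNAs ------------------------------------
  enrichment <- NULL
  net_mrnas <- unique(network$triplets$mrna_id)
  if (!is.null(bundle$terms) && length(net_mrnas))
    enrichment <- enrich_terms(net_mrnas, rownames(bundle$counts$mrna),
                               bundle$terms)

  ## 10. extras: top co-expressed circRNA-mRNA pairs (for plotting) --------
  co_all <- corr$circ_mrna
  top_coexpr <- utils::head(co_all[order(-abs(co_all$r), co_all$p,
                                         co_all$id_a, co_all$id_b), ,
                                   drop = FALSE],
                            th$top_coexpr_export)
  rownames(top_coexpr) <- NULL

  funnel <- do.call(rbind, funnel)
  recovery <- if (!is.null(bundle$truth))
    triplet_recovery(network, bundle$truth)
  run <- structure(list(classification = classification,
                        summaries = summaries,
                        normalized = norm, de = de, de_sets = de_sets,
                        correlations = corr, binding = binding,
                        mirna_circ_pairs = mc_pairs,
                        mirna_mrna_pairs = mg_pairs,
                        score_pairs = score, final_pairs = final_pairs,
                        network = network, enrichment = enrichment,
                        top_coexpr = top_coexpr, funnel = funnel,
                        thresholds = th, recovery = recovery,
                        seed = bundle$config$seed %||% NA_integer_),
                   class = "cerna_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("ceRNA pipeline run",
      if (!is.na(x$seed)) sprintf(" (bundle seed %d)", x$seed), "\n", sep = "")
  cat(sprintf("  DE: %d mRNA, %d miRNA, %d circRNA\n",
              nrow(x$de_sets$mrna), nrow(x$de_sets$mirna),
              nrow(x$de_sets$circ)))
  cat(sprintf("  screened pairs: %d miRNA-mRNA, %d miRNA-circRNA, %d circRNA-mRNA(+)\n",
              nrow(x$mirna_mrna_pairs), nrow(x$mirna_circ_pairs),
              nrow(x$correlations$circ_mrna)))
  cat(sprintf("  ceRNA score pairs: %d | final pairs: %d | triplets: %d\n",
              nrow(x$score_pairs), nrow(x$final_pairs),
              nrow(x$network$triplets)))
  if (!is.null(x$recovery))
    cat(sprintf("  planted-truth recovery: recall %.2f, precision %.2f\n",
                x$recovery$recall, x$recovery$precision))
  invisible(x)
}

# write every stage table + manifest under out_dir
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_tsv(run$classification, fp("circ_classification.tsv"))
  write_tsv(run$summaries$categories, fp("circ_categories.tsv"))
  write_tsv(run$summaries$lengths, fp("circ_length_stats.tsv"))
  write_tsv(run$de$mrna, fp("de_mrna.tsv"))
  write_tsv(run$de$mirna, fp("de_mirna.tsv"))
  write_tsv(run$de$circ, fp("de_circ.tsv"))
  write_tsv(run$correlations$mirna_mrna, fp("corr_mirna_mrna.tsv"))
  write_tsv(run$correlations$mirna_circ, fp("corr_mirna_circ.tsv"))
  write_tsv(run$correlations$circ_mrna, fp("corr_circ_mrna.tsv"))
  write_pair_table(run$mirna_circ_pairs, fp("pairs_mirna_circ.tsv"))
  write_pair_table(run$mirna_mrna_pairs, fp("pairs_mirna_mrna.tsv"))
  write_tsv(run$score_pairs, fp("cerna_score.tsv"))
  write_tsv(run$final_pairs, fp("cerna_pairs.tsv"))
  write_tsv(run$top_coexpr, fp("top_coexpr_circ_mrna.tsv"))
  export_network(run$network, out_dir)
  if (!is.null(run$enrichment))
    write_tsv(run$enrichment, fp("enrichment.tsv"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(thresholds = run$thresholds,
                   seed = run$seed,
                   funnel = run$funnel,
                   files = data.frame(file = files,
                                      md5 = unname(tools::md5sum(fp(files))),
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery of planted triplets
#'
#' Compares the network's triplets to the planted ground truth.
#'
#' @param network a `cernet` (or a `cerna_run`).
#' @param truth a `cerna_truth`.
#' @return list: `recall`, `precision` (NA when nothing was called),
#'   `n_called`, `n_planted`, `n_true_positive`.
#' @export
triplet_recovery <- function(network, truth) {
  if (inherits(network, "cerna_run")) network <- network$network
  key <- function(df) paste(df$circ_id, df$mirna_id, df$mrna_id)
  called <- unique(key(network$triplets))
  planted <- unique(key(truth$planted_triplets))
  tp <- length(intersect(called, planted))
  list(recall = if (length(planted)) tp / length(planted) else NA_real_,
       precision = if (length(called)) tp / length(called) else NA_real_,
       n_called = length(called), n_planted = length(planted),
       n_true_positive = tp)
}
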