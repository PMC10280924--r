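#' Hypergeometric upper tail for shared-miRNA enrichment
#'
#' Probability of drawing at least `x` shared elements:
#' `p = sum_{i=x}^{min(K,M)} C(K,i) C(N-K,M-i) / C(N,M)` — the upper tail
#' including the observed count. This is the kernel of both the ceRNA score
#' and the Fisher over-representation test.
#'
#' @param N universe size.
#' @param K,M sizes of the two drawn sets (both <= N).
#' @param x observed overlap (0 <= x <= min(K, M)).
#' @return the tail probability.
#' @examples
#' hypergeom_tail(5, 2, 2, 2)   # 1/10
#' hypergeom_tail(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_tail <- function(N, K, M, x) {
  bad <- K > N | M > N | x > pmin(K, M) | x < 0 | N < 0
  if (any(bad))
    stop("hypergeom_tail: inconsistent arguments (need 0 <= x <= min(K,M) <= N)",
         call. = FALSE)
  stats::phyper(x - 1, K, N - K, M, lower.tail = FALSE)
}

#' Hypergeometric ceRNA score for circRNA--mRNA pairs
#'
#' For every circRNA--mRNA pair sharing at least one targeting miRNA, tests
#' whether the overlap of their miRNA sets is larger than expected by chance
#' in the screened miRNA universe. Smaller p means more significantly shared
#' miRNAs between the two candidate ceRNAs.
#'
#' @param circ_targets named list: circRNA id -> character vector of miRNAs
#'   targeting it.
#' @param mrna_targets named list: mRNA id -> miRNAs targeting it.
#' @param universe character vector of candidate miRNAs (the screened set);
#'   all target sets must be subsets of it.
#' @param alpha significance flag cutoff on the score (default 1: all
#'   x >= 1 pairs are kept and flagged significant).
#' @return data.frame ordered by `score_p` then ids: `circ_id`, `mrna_id`,
#'   `shared_mirnas` (comma-separated), `x`, `K`, `M`, `N`, `score_p`,
#'   `significant`.
#' @export
cerna_score <- function(circ_targets, mrna_targets, universe, alpha = 1) {
  all_t <- unique(c(unlist(circ_targets), unlist(mrna_targets)))
  out_of <- setdiff(all_t, universe)
  if (length(out_of))
    stop("cerna_score: target id(s) outside the universe: ",
         paste(utils::head(out_of, 3), collapse = ", "), call. = FALSE)
  N <- length(unique(universe))
  rows <- list()
  for (ci in names(circ_targets)) {
    cset <- unique(circ_targets[[ci]])
    for (gi in names(mrna_targets)) {
      gset <- unique(mrna_targets[[gi]])
      shared <- intersect(cset, gset)
      if (length(shared) == 0L) next
      rows[[paste(ci, gi)]] <- data.frame(
        circ_id = ci, mrna_id = gi,
        shared_mirnas = paste(sort(shared), collapse = ","),
        x = length(shared), K = length(cset), M = length(gset), N = N,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(circ_id = character(0), mrna_id = character(0),
                      shared_mirnas = character(0), x = integer(0),
                      K = integer(0), M = integer(0), N = integer(0),
                      score_p = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$score_p <- hypergeom_tail(df$N, df$K, df$M, df$x)
  df$significant <- df$score_p < alpha | alpha >= 1
  df <- df[order(df$score_p, df$circ_id, df$mrna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Intersect ceRNA-score evidence with positive co-expression
#'
#' Keeps circRNA--mRNA pairs supported by both the shared-miRNA score and a
#' positive expression correlation, merges the correlation statistics in,
#' ranks by score p ascending (ties broken lexicographically by ids) and
#' truncates to the top `top_k`.
#'
#' @param score_pairs data.frame from [cerna_score()] (significant rows are
#'   used when the `significant` column is present).
#' @param coexpr_pairs data.frame of positively correlated circRNA--mRNA
#'   pairs ([correlate_pairs()] output: `id_a` = circRNA, `id_b` = mRNA).
#' @param top_k maximum number of retained interactions (default 50;
#'   `Inf` disables truncation).
#' @return data.frame of final pairs with `coexpr_r`, `coexpr_p` merged in.
#' @export
intersect_evidence <- function(score_pairs, coexpr_pairs, top_k = 50) {
  sp <- score_pairs
  if ("significant" %in% names(sp)) sp <- sp[sp$significant, , drop = FALSE]
  key_s <- paste(sp$circ_id, sp$mrna_id)
  key_c <- paste(coexpr_pairs$id_a, coexpr_pairs$id_b)
  hit <- match(key_s, key_c)
  out <- sp[!is.na(hit), , drop = FALSE]
  m <- hit[!is.na(hit)]
  out$coexpr_r <- coexpr_pairs$r[m]
  out$coexpr_p <- coexpr_pairs$p[m]
  out <- out[order(out$score_p, out$circ_id, out$mrna_id), , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Assemble the direction-coherent ceRNA network
#'
#' A triplet (circRNA, miRNA, mRNA) enters the network iff the circRNA--mRNA
#' pair survived evidence intersection, the miRNA is a screened partner of
#' both (binding plus negative correlation), and the differential-expression
#' directions are coherent with sponging: the miRNA direction is opposite to
#' both the circRNA's and the mRNA's.
#'
#' @param final_pairs data.frame from [intersect_evidence()].
#' @param mirna_circ_pairs data.frame with `mirna_id`, `circ_id` columns
#'   (screened miRNA--circRNA interactions).
#' @param mirna_mrna_pairs data.frame with `mirna_id`, `mrna_id` columns.
#' @param de_directions named character vector: feature id -> "up"/"down".
#' @return A `cernet` object: list of `nodes` (id, type, direction),
#'   `edges` (from, to, relation), `triplets`, and the retained `pairs`.
#' @export
build_cernet <- function(final_pairs, mirna_circ_pairs, mirna_mrna_pairs,
                         de_directions) {
  trip <- list()
  for (i in seq_len(nrow(final_pairs))) {
    ci <- final_pairs$circ_id[i]; gi <- final_pairs$mrna_id[i]
    ms <- intersect(
      mirna_circ_pairs$mirna_id[mirna_circ_pairs$circ_id == ci],
      mirna_mrna_pairs$mirna_id[mirna_mrna_pairs$mrna_id == gi])
    for (mi in ms) {
      need <- c(ci, mi, gi)
      missing <- need[!(need %in% names(de_directions))]
      if (length(missing))
        stop("build_cernet: missing DE direction for ", missing[1],
             call. = FALSE)
      dm <- de_directions[[mi]]; dc <- de_directions[[ci]]
      dg <- de_directions[[gi]]
      opp <- function(a, b) (a == "up" && b == "down") ||
        (a == "down" && b == "up")
      if (opp(dm, dc) && opp(dm, dg))
        trip[[paste(ci, mi, gi)]] <- data.frame(circ_id = ci, mirna_id = mi,
                                                mrna_id = gi,
                                                stringsAsFactors = FALSE)
    }
  }
  triplets <- if (length(trip)) do.call(rbind, trip) else
    data.frame(circ_id = character(0), mirna_id = character(0),
               mrna_id = character(0), stringsAsFactors = FALSE)
  rownames(triplets) <- NULL
  typed <- function(ids, type)
    data.frame(id = ids, type = rep(type, length(ids)),
               stringsAsFactors = FALSE)
  nodes <- unique(rbind(typed(triplets$circ_id, "circRNA"),
                        typed(triplets$mirna_id, "miRNA"),
                        typed(triplets$mrna_id, "mRNA")))
  nodes$direction <- if (nrow(nodes)) unname(de_directions[nodes$id])
    else character(0)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rel <- function(from, to, relation)
    data.frame(from = from, to = to,
               relation = rep(relation, length(from)),
               stringsAsFactors = FALSE)
  edges <- unique(rbind(rel(triplets$circ_id, triplets$mirna_id, "sponges"),
                        rel(triplets$mirna_id, triplets$mrna_id, "targets"),
                        rel(triplets$circ_id, triplets$mrna_id, "ceRNA")))
  edges <- edges[order(edges$relation, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = triplets,
                 pairs = final_pairs),
            class = "cernet")
}

#' @export
print.cernet <- function(x, ...) {
  tt <- table(factor(x$nodes$type, levels = c("circRNA", "miRNA", "mRNA")))
  cat(sprintf("ceRNA network: %d circRNAs, %d miRNAs, %d mRNAs | %d edges, %d triplets\n",
              tt[["circRNA"]], tt[["miRNA"]], tt[["mRNA"]],
              nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' @export
summary.cernet <- function(object, ...) {
  print(object)
  if (nrow(object$triplets)) {
    cat("\nTriplets (circRNA - miRNA - mRNA):\n")
    utils::write.table(object$triplets, sep = "  ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(object)
}

#' Plot a ceRNA network
#'
#' Uses igraph (when installed) with node shape/colour by RNA type.
#'
#' @param x a `cernet`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.cernet <- function(x, ...) {
  if (nrow(x$edges) == 0L) {
    plot.new(); title("empty ceRNA network")
    return(invisible(x))
  }
  if (!requireNamespace("igraph", quietly = TRUE)) {
    message("plot.cernet: install `igraph` to draw the network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(x$edges, directed = TRUE,
                                     vertices = x$nodes)
  cols <- c(circRNA = "#66c2a5", miRNA = "#fc8d62", mRNA = "#8da0cb")
  igraph::plot.igraph(g, vertex.color = cols[x$nodes$type],
                      vertex.label.cex = 0.7, edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Export a ceRNA network to Cytoscape-ready files
#'
#' Writes a SIF file (`source relation target`), an edge TSV and a node TSV
#' (type and DE direction), with byte-deterministic ordering.
#'
#' @param network a `cernet`.
#' @param dir output directory.
#' @param prefix file name prefix (default "cernet").
#' @return named character vector of the written paths, invisibly.
#' @export
export_network <- function(network, dir, prefix = "cernet") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sif = file.path(dir, paste0(prefix, ".sif")),
             edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             nodes = file.path(dir, paste0(prefix, "_nodes.tsv")))
  writeLines(sprintf("%s %s %s", network$edges$from, network$edges$relation,
                     network$edges$to), paths["sif"])
  write_tsv(network$edges, paths["edges"])
  write_tsv(network$nodes, paths["nodes"])
  invisible(paths)
}
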