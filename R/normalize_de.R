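#' Library-size normalization
#'
#' RPM/CPM scale each column to reads per million; FPKM additionally divides
#' by feature length in kilobases. RPM and CPM are the same formula under two
#' of the field's names (back-splice junction reads are conventionally quoted
#' in RPM, gene counts in CPM/FPKM).
#'
#' @param counts numeric matrix (features x samples), non-negative.
#' @param method "RPM", "CPM" or "FPKM".
#' @param feature_lengths named vector of lengths in nt (required for FPKM).
#' @return matrix of normalized values, same dimnames.
#' @examples
#' m <- matrix(c(10, 990, 20, 1980), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' normalize_counts(m * 500, "CPM")
#' @export
normalize_counts <- function(counts, method = c("CPM", "RPM", "FPKM"),
                             feature_lengths = NULL) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "), call. = FALSE)
  out <- sweep(counts, 2, libs, "/") * 1e6
  if (method == "FPKM") {
    if (is.null(feature_lengths))
      stop("FPKM requires feature_lengths", call. = FALSE)
    len <- feature_lengths[rownames(counts)]
    if (any(is.na(len) | len <= 0))
      stop("missing or non-positive length for some features", call. = FALSE)
    out <- out / (len / 1e3)
  }
  out
}

#' Two-group differential expression screen
#'
#' The screening statistic is Welch's t on log2(normalized + pseudocount):
#' `log2fc` is the mean difference (group 1 minus group 2), `p` the
#' two-sided Welch p-value and `padj` its Benjamini--Hochberg adjustment.
#' This deliberately simple test exercises fold-change/p-value threshold
#' logic; the module boundary admits an exact negative-binomial test as a
#' drop-in replacement.
#'
#' @param normalized matrix of normalized values (features x samples).
#' @param design data.frame with `sample`, `group`; at least two samples per
#'   group.
#' @param pseudocount added before log2 (default 1).
#' @param lfc_min,p_max,use_padj thresholds used to label `direction`
#'   (up/down/ns); see [filter_de()].
#' @param group_order optional explicit ordering of the two group labels
#'   (first label is the fold-change numerator).
#' @return data.frame: `feature_id`, `log2fc`, `p`, `padj`, `direction`.
#' @export
de_test <- function(normalized, design, pseudocount = 1,
                    lfc_min = 1, p_max = 0.05, use_padj = FALSE,
                    group_order = NULL) {
  design <- design[match(colnames(normalized), design$sample), , drop = FALSE]
  if (any(is.na(design$sample)))
    stop("design does not cover every sample", call. = FALSE)
  lev <- group_order %||% unique(design$group)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  i1 <- design$group == lev[1]; i2 <- design$group == lev[2]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  x <- log2(normalized + pseudocount)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  n1 <- sum(i1); n2 <- sum(i2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # zero variance in both groups: identical values give p = 1, separated
  # constants give p -> 0
  degen <- !is.finite(p)
  p[degen] <- ifelse(abs(m1 - m2)[degen] < 1e-12, 1, 0)
  res <- data.frame(feature_id = rownames(normalized),
                    log2fc = unname(m1 - m2),
                    p = unname(p),
                    padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  pp <- if (use_padj) res$padj else res$p
  res$direction <- ifelse(abs(res$log2fc) >= lfc_min & pp < p_max,
                          ifelse(res$log2fc > 0, "up", "down"), "ns")
  res
}

#' Filter a differential-expression table at thresholds
#'
#' Keeps features with `|log2fc| >= lfc_min` and p (or BH-adjusted p) below
#' `p_max`, partitioned into up/down.
#'
#' @param results data.frame from [de_test()].
#' @param lfc_min minimum absolute log2 fold change (1 corresponds to the
#'   conventional fold-change > 2).
#' @param p_max p-value cutoff (default 0.05).
#' @param use_padj use the BH-adjusted p instead of the raw p.
#' @return data.frame of passing features with a recomputed `direction`.
#' @export
filter_de <- function(results, lfc_min = 1, p_max = 0.05, use_padj = FALSE) {
  if (nrow(results) == 0L) return(results)
  pp <- if (use_padj) results$padj else results$p
  keep <- abs(results$log2fc) >= lfc_min & pp < p_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
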