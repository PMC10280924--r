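#' Exact p-value for a Pearson correlation
#'
#' Two-sided p from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' referred to Student's t with n - 2 degrees of freedom. With three
#' replicates per group pooled across both groups (n = 6, df = 4) this
#' reproduces published pair p-values exactly.
#'
#' @param r Pearson correlation coefficient(s) in \[-1, 1\].
#' @param n number of paired samples (>= 3).
#' @return p-value(s); `|r| = 1` returns 0 (degenerate, perfectly
#'   collinear).
#' @examples
#' cor_pvalue(-0.9782303, 6)  # ~ 0.000706
#' @export
cor_pvalue <- function(r, n) {
  if (any(n < 3)) stop("cor_pvalue: need n >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("cor_pvalue: |r| > 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t), n - 2)
  p
}

#' Directional cross-class correlation screen
#'
#' Computes Pearson correlations between every row of `mat_a` and every row
#' of `mat_b` across shared samples, with exact t-based p-values, and keeps
#' pairs matching the requested sign at `|r| >= r_min` and `p < p_max`.
#' Constant (zero-variance) rows are excluded from screening and their count
#' reported via the `n_dropped` attribute.
#'
#' @param mat_a,mat_b matrices (features x samples) of normalized expression;
#'   columns are re-aligned by sample id and must contain the same samples.
#' @param pair_kind label for the output (`miRNA_mRNA`, `miRNA_circRNA`,
#'   `circRNA_mRNA`, or any tag).
#' @param sign "negative" or "positive" — the correlation sign screened for.
#' @param r_min minimum |r| (default 0.8; compared with `>=`).
#' @param p_max p-value cutoff (default 0.05, strict `<`).
#' @return data.frame `pair_kind`, `id_a`, `id_b`, `r`, `n`, `p`, ordered by
#'   p ascending, then |r| descending, then ids.
#' @export
correlate_pairs <- function(mat_a, mat_b, pair_kind = "pair",
                            sign = c("negative", "positive"),
                            r_min = 0.8, p_max = 0.05) {
  sign <- match.arg(sign)
  empty <- data.frame(pair_kind = character(0), id_a = character(0),
                      id_b = character(0), r = numeric(0), n = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(mat_a) == 0L || nrow(mat_b) == 0L) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  common <- intersect(colnames(mat_a), colnames(mat_b))
  if (length(common) < length(union(colnames(mat_a), colnames(mat_b))))
    stop("correlate_pairs: sample sets differ between matrices", call. = FALSE)
  mat_a <- mat_a[, common, drop = FALSE]
  mat_b <- mat_b[, common, drop = FALSE]
  n <- length(common)
  if (n < 3) stop("correlate_pairs: need >= 3 shared samples", call. = FALSE)
  const_a <- apply(mat_a, 1, function(v) stats::sd(v) == 0)
  const_b <- apply(mat_b, 1, function(v) stats::sd(v) == 0)
  n_dropped <- sum(const_a) + sum(const_b)
  mat_a <- mat_a[!const_a, , drop = FALSE]
  mat_b <- mat_b[!const_b, , drop = FALSE]
  if (nrow(mat_a) == 0L || nrow(mat_b) == 0L) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  rmat <- stats::cor(t(mat_a), t(mat_b))
  rv <- as.vector(rmat)
  df <- data.frame(pair_kind = pair_kind,
                   id_a = rep(rownames(mat_a), times = ncol(rmat)),
                   id_b = rep(colnames(rmat), each = nrow(rmat)),
                   r = rv, n = n, p = cor_pvalue(rv, n),
                   stringsAsFactors = FALSE)
  keep <- abs(df$r) >= r_min & df$p < p_max &
    if (sign == "negative") df$r < 0 else df$r > 0
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$p, -abs(df$r), df$id_a, df$id_b), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}
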