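# catalogue summary statistics: category proportions, length/N50 summaries,
# per-chromosome and per-sample counts, exon-count histogram

#' Per-category counts and percentages
#'
#' @param x a classified circRNA data.frame (from [classify_circrnas()]) or a
#'   named vector of per-category counts.
#' @param digits decimal places for the percentage (default 2, the usual
#'   reporting precision).
#' @return data.frame `category`, `count`, `percent`, ordered by count
#'   descending then category name; percentages sum to 100 within rounding.
#' @examples
#' category_proportions(c(sense_overlapping = 8970, intergenic = 356,
#'                        exonic = 316, antisense = 151, intronic = 85))
#' @export
category_proportions <- function(x, digits = 2) {
  if (is.data.frame(x)) {
    if (any(is.na(x$category)))
      stop("unclassified record: ",
           paste(utils::head(x$circ_id[is.na(x$category)], 3), collapse = ", "),
           call. = FALSE)
    counts <- table(x$category)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- x
  }
  if (is.null(names(counts)) || any(counts < 0))
    stop("counts must be a named non-negative vector", call. = FALSE)
  df <- data.frame(category = names(counts),
                   count = as.integer(counts),
                   percent = round(100 * as.numeric(counts) / sum(counts),
                                   digits),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$category), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' N50 of a length multiset
#'
#' The length at which the descending cumulative sum of lengths first
#' reaches half the total.
#'
#' @param lengths positive numeric vector.
#' @return the N50 length.
#' @examples
#' n50(c(300, 200, 100))  # 300
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50: empty input", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Length summary of a circRNA catalogue
#'
#' @param x classified data.frame (uses its `length` column) or a numeric
#'   vector of lengths (genomic span, nt).
#' @return one-row data.frame: `count`, `count_ge_200`, `count_ge_500`,
#'   `count_ge_1000`, `n50`, `total_length`, `max_length`, `min_length`,
#'   `mean_length`.
#' @export
circ_length_stats <- function(x) {
  lengths <- if (is.data.frame(x)) x$length else x
  if (length(lengths) == 0L)
    stop("circ_length_stats: empty input", call. = FALSE)
  data.frame(count = length(lengths),
             count_ge_200 = sum(lengths >= 200),
             count_ge_500 = sum(lengths >= 500),
             count_ge_1000 = sum(lengths >= 1000),
             n50 = n50(lengths),
             total_length = sum(lengths),
             max_length = max(lengths),
             min_length = min(lengths),
             mean_length = mean(lengths))
}

#' Mean feature length from reported totals
#'
#' Convenience for recomputing a reported average from a published total
#' length and count.
#'
#' @param total_length summed length (nt).
#' @param count number of features.
#' @param digits rounding (default 2).
#' @return the rounded mean length.
#' @examples
#' mean_feature_length(23522667, 9878)
#' @export
mean_feature_length <- function(total_length, count, digits = 2) {
  if (count <= 0) stop("count must be positive", call. = FALSE)
  round(total_length / count, digits)
}

#' Number of circRNAs per chromosome
#'
#' @param x classified data.frame (or anything with `chrom`), or a GRanges.
#' @return data.frame `chrom`, `count`, ordered count descending then
#'   chromosome name ascending (the deterministic tie rule).
#' @export
per_chromosome_counts <- function(x) {
  chrom <- if (inherits(x, "GRanges"))
    as.character(GenomeInfoDb::seqnames(x)) else x$chrom
  tab <- table(chrom)
  df <- data.frame(chrom = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$chrom), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-sample total and unique circRNA counts
#'
#' "Unique" counts the circRNAs predicted in a sample and in no other
#' sample.
#'
#' @param per_sample_sets named list: sample -> character vector of circRNA
#'   ids detected in that sample.
#' @return data.frame `sample`, `non_unique`, `unique`.
#' @examples
#' unique_counts(list(A = c("c1", "c2", "c3"), B = c("c3", "c4")))
#' @export
unique_counts <- function(per_sample_sets) {
  if (length(per_sample_sets) < 1L)
    stop("unique_counts: need at least one sample", call. = FALSE)
  sets <- lapply(per_sample_sets, unique)
  tab <- table(unlist(sets))
  data.frame(sample = names(sets),
             non_unique = vapply(sets, length, 0L),
             unique = vapply(sets, function(s) sum(tab[s] == 1L), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exon-count histogram of a classified catalogue
#'
#' @param x classified data.frame with an `exon_count` column.
#' @return data.frame `exon_count`, `count` (ascending exon count; totals
#'   equal the input size).
#' @export
exon_count_histogram <- function(x) {
  tab <- table(x$exon_count)
  data.frame(exon_count = as.integer(names(tab)),
             count = as.integer(tab),
             stringsAsFactors = FALSE)
}
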