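#' Benjamini--Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]), with input validation; order-preserving.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_adjust: p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Term over-representation analysis
#'
#' One-sided Fisher test (hypergeometric upper tail) of each term's overlap
#' with a query set against a background, BH-corrected across tested terms.
#' Terms with no query hit are not reported. Annotations are restricted to
#' background members before testing.
#'
#' @param query feature set of interest (must be a subset of `background`).
#' @param background the feature universe.
#' @param annotations data.frame with columns `term_id`, `feature_id` and
#'   optionally `term_name`, `namespace` (long format, one row per
#'   membership; see [read_term_annotation()]).
#' @return data.frame sorted by p ascending: `term_id`, `term_name`,
#'   `namespace`, `k` (query hits), `n` (query size), `K` (term size in
#'   background), `N` (background size), `p`, `fdr`.
#' @export
enrich_terms <- function(query, background, annotations) {
  query <- unique(query); background <- unique(background)
  if (length(setdiff(query, background)))
    stop("enrich_terms: query is not a subset of the background",
         call. = FALSE)
  ann <- annotations[annotations$feature_id %in% background, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  terms <- split(ann, ann$term_id)
  N <- length(background); n <- length(query)
  rows <- lapply(terms, function(d) {
    members <- unique(d$feature_id)
    k <- length(intersect(members, query))
    if (k == 0L) return(NULL)
    data.frame(term_id = d$term_id[1],
               term_name = if ("term_name" %in% names(d)) d$term_name[1] else NA,
               namespace = if ("namespace" %in% names(d)) d$namespace[1] else NA,
               k = k, n = n, K = length(members), N = N,
               p = hypergeom_tail(N, length(members), n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$fdr <- bh_adjust(df$p)
  df <- df[order(df$p, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a feature-to-term annotation
#'
#' Mapping file: two or more TSV columns starting with `feature_id`,
#' `term_id`. An optional term-description file (`term_id`, `term_name`,
#' `namespace`) is joined in.
#'
#' @param mapping_path mapping TSV.
#' @param terms_path optional term-description TSV.
#' @return long-format data.frame for [enrich_terms()].
#' @export
read_term_annotation <- function(mapping_path, terms_path = NULL) {
  map <- read_tsv(mapping_path)
  if (!all(c("feature_id", "term_id") %in% names(map)))
    stop("mapping file needs `feature_id` and `term_id` columns",
         call. = FALSE)
  if (!is.null(terms_path)) {
    info <- read_tsv(terms_path)
    map <- merge(map, info, by = "term_id", all.x = TRUE, sort = FALSE)
  }
  map
}
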