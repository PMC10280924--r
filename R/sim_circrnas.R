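#' Simulate back-splice junctions with known categories
#'
#' Constructs circRNA records that satisfy, by construction, the
#' classification definition of an assigned category (exonic, intronic,
#' sense_overlapping, antisense, intergenic), so the classifier can be tested
#' against planted truth. Category proportions default to the configured
#' `category_props`.
#'
#' @param annotation a `genome_annotation` (typically [simulate_annotation()]).
#' @param config a [sim_config()].
#' @param proportions optional named proportions overriding
#'   `config$category_props`.
#' @param n optional number of circRNAs overriding `config$n_circrnas`.
#' @return A list with `granges` (GRanges with `circ_id`) and `categories`
#'   (named character vector of planted categories).
#' @export
simulate_circrnas <- function(annotation, config, proportions = NULL, n = NULL) {
  config <- validate_sim_config(config)
  props <- proportions %||% config$category_props
  n <- as.integer(n %||% config$n_circrnas)
  if (length(annotation$genes) == 0L)
    stop("simulate_circrnas: empty annotation", call. = FALSE)
  props <- props[props > 0]
  props <- props / sum(props)
  counts <- apportion_counts(props, n)

  with_seed(child_seed(config$seed, "circrnas"), {
    tabs <- annotation_tables(annotation)
    exl <- split(tabs$exons, tabs$exons$tx_id)
    exl <- lapply(exl, function(d) d[order(d$start), , drop = FALSE])
    tx <- tabs$transcripts
    genes <- tabs$genes[order(tabs$genes$chrom, tabs$genes$start), , drop = FALSE]
    parts <- list()
    for (cat in names(counts)) {
      k <- counts[[cat]]
      if (k == 0L) next
      parts[[cat]] <- switch(cat,
        exonic = gen_exonic(k, tx, exl),
        intronic = gen_intronic(k, tx, exl),
        sense_overlapping = gen_sense(k, genes, tabs$exons,
                                      annotation$chrom_lengths),
        antisense = gen_antisense(k, genes),
        intergenic = gen_intergenic(k, genes, annotation$chrom_lengths))
      parts[[cat]]$category <- cat
    }
    df <- do.call(rbind, parts)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    df$circ_id <- sprintf("circRNA_%d", seq_len(nrow(df)))
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$circ_id <- df$circ_id
    list(granges = gr,
         categories = stats::setNames(df$category, df$circ_id))
  })
}

# integer apportionment by largest remainder (deterministic, sums to n)
apportion_counts <- function(props, n) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    ord <- order(-frac, names(props))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

gen_exonic <- function(k, tx, exl) {
  rows <- vector("list", k)
  tids <- sample(names(exl), k, replace = TRUE)
  for (i in seq_len(k)) {
    ex <- exl[[tids[i]]]
    a <- sample.int(nrow(ex), 1L)
    b <- if (a == nrow(ex)) a else sample(a:nrow(ex), 1L)
    rows[[i]] <- data.frame(chrom = ex$chrom[1], start = ex$start[a],
                            end = ex$end[b], strand = ex$strand[1],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

gen_intronic <- function(k, tx, exl) {
  multi <- names(exl)[vapply(exl, nrow, 0L) >= 2L]
  if (length(multi) == 0L)
    stop("simulate_circrnas: category `intronic` unattainable - no multi-exon transcript",
         call. = FALSE)
  rows <- vector("list", k)
  tids <- sample(multi, k, replace = TRUE)
  for (i in seq_len(k)) {
    ex <- exl[[tids[i]]]
    j <- sample.int(nrow(ex) - 1L, 1L)
    istart <- ex$end[j] + 1L
    iend <- ex$start[j + 1L] - 1L
    w <- iend - istart + 1L
    span <- runif_int(1L, 20L, max(20L, w - 2L))
    off <- runif_int(1L, 1L, w - span - 1L)
    rows[[i]] <- data.frame(chrom = ex$chrom[1], start = istart + off,
                            end = istart + off + span - 1L,
                            strand = ex$strand[1], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# sense-overlapping: same-strand gene overlap that is neither exon-bounded
# nor intron-contained. Two flavours: an interval strictly inside one exon
# (endpoints off the exon boundaries), or a read-through past the gene end.
gen_sense <- function(k, genes, exons, chrom_lengths) {
  wide <- exons[exons$end - exons$start + 1L >= 30L, , drop = FALSE]
  if (nrow(wide) == 0L)
    stop("simulate_circrnas: category `sense_overlapping` unattainable - no exon wide enough",
         call. = FALSE)
  n_inner <- ceiling(k * 0.7)
  n_over <- k - n_inner
  pick <- wide[sample.int(nrow(wide), n_inner, replace = TRUE), , drop = FALSE]
  w <- pick$end - pick$start + 1L
  span <- runif_int(n_inner, 20L, pmax(20L, w - 2L))
  off <- runif_int(n_inner, 1L, pmax(1L, w - span - 1L))
  inner <- data.frame(chrom = pick$chrom, start = pick$start + off,
                      end = pick$start + off + span - 1L,
                      strand = pick$strand, stringsAsFactors = FALSE)
  out <- inner
  if (n_over > 0L) {
    # room to the next gene on the same chromosome (any strand)
    nxt <- c(genes$start[-1], NA)
    same_chrom <- c(genes$chrom[-1] == genes$chrom[-nrow(genes)], FALSE)
    room <- ifelse(same_chrom, nxt - genes$end,
                   chrom_lengths[genes$chrom] - genes$end + 1L)
    cand <- which(room >= 3L & genes$end - genes$start >= 3L)
    if (length(cand) == 0L) {
      # no room past any gene end: fall back to the inner-exon flavour
      pick2 <- wide[sample.int(nrow(wide), n_over, replace = TRUE), , drop = FALSE]
      w2 <- pick2$end - pick2$start + 1L
      span2 <- runif_int(n_over, 20L, pmax(20L, w2 - 2L))
      off2 <- runif_int(n_over, 1L, pmax(1L, w2 - span2 - 1L))
      out <- rbind(inner,
                   data.frame(chrom = pick2$chrom, start = pick2$start + off2,
                              end = pick2$start + off2 + span2 - 1L,
                              strand = pick2$strand, stringsAsFactors = FALSE))
    } else {
      gi <- cand[runif_int(n_over, 1L, length(cand))]
      g <- genes[gi, , drop = FALSE]
      ext <- runif_int(n_over, 1L, pmin(200L, room[gi] - 2L))
      start <- runif_int(n_over, g$start + 1L, g$end - 1L)
      out <- rbind(inner, data.frame(chrom = g$chrom, start = start,
                                     end = g$end + ext, strand = g$strand,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

gen_antisense <- function(k, genes) {
  wide <- genes[genes$end - genes$start + 1L >= 120L, , drop = FALSE]
  if (nrow(wide) == 0L)
    stop("simulate_circrnas: category `antisense` unattainable - genes too short",
         call. = FALSE)
  pick <- wide[runif_int(k, 1L, nrow(wide)), , drop = FALSE]
  w <- pick$end - pick$start + 1L
  span <- runif_int(k, 100L, pmin(2000L, w))
  off <- runif_int(k, 0L, w - span)
  data.frame(chrom = pick$chrom, start = pick$start + off,
             end = pick$start + off + span - 1L,
             strand = ifelse(pick$strand == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

gen_intergenic <- function(k, genes, chrom_lengths) {
  gaps <- list()
  for (chrom in names(chrom_lengths)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    bounds <- c(1L, if (nrow(g)) c(rbind(g$start - 1L, g$end + 1L)),
                as.integer(chrom_lengths[[chrom]]))
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends - starts + 1L >= 220L
    if (any(keep))
      gaps[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                  end = ends[keep], stringsAsFactors = FALSE)
  }
  gaps <- do.call(rbind, gaps)
  if (is.null(gaps) || nrow(gaps) == 0L)
    stop("simulate_circrnas: category `intergenic` unattainable - no gap wide enough",
         call. = FALSE)
  gi <- runif_int(k, 1L, nrow(gaps))
  g <- gaps[gi, , drop = FALSE]
  w <- g$end - g$start + 1L
  span <- runif_int(k, 200L, pmin(2000L, w))
  off <- runif_int(k, 0L, w - span)
  data.frame(chrom = g$chrom, start = g$start + off,
             end = g$start + off + span - 1L,
             strand = c("+", "-")[runif_int(k, 1L, 2L)],
             stringsAsFactors = FALSE)
}
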