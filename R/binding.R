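#' Scoring parameters for the MRE scanner
#'
#' The scanner anchors on a perfect Watson--Crick seed match (miRNA
#' positions 2--8) worth `base_score`, then extends 3'-ward along the miRNA
#' (5'-ward on the target): each additional Watson--Crick pair adds
#' `wc_bonus`, each G:U wobble `gu_bonus`; the first mismatch terminates the
#' extension (no gaps). The energy proxy is
#' `-(energy_base + energy_wc * WC + energy_gu * GU)` kcal/mol.
#'
#' @param base_score seed-only score (default 40).
#' @param wc_bonus,gu_bonus per-pair score bonuses in the 3' extension.
#' @param energy_base,energy_wc,energy_gu energy proxy coefficients.
#' @return list of parameters for [scan_binding_sites()].
#' @export
binding_params <- function(base_score = 40, wc_bonus = 5, gu_bonus = 2,
                           energy_base = 7.0, energy_wc = 0.45,
                           energy_gu = 0.2) {
  list(base_score = base_score, wc_bonus = wc_bonus, gu_bonus = gu_bonus,
       energy_base = energy_base, energy_wc = energy_wc,
       energy_gu = energy_gu)
}

check_rna <- function(seq, what) {
  s <- chartr("T", "U", toupper(as.character(seq)))
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) && nchar(bad))
    stop("invalid symbol `", bad, "` in ", what, call. = FALSE)
  s
}

#' Scan a target sequence for miRNA response elements
#'
#' Finds every occurrence of the reverse complement of the miRNA seed
#' (positions 2--8, 1-based from the 5' end) on the target, extends each
#' match 3'-ward along the miRNA, scores it (see [binding_params()]), and
#' resolves overlaps greedily (score descending, then position ascending).
#' T and U are treated as equivalent on input.
#'
#' @param mirna miRNA sequence (character or RNAString), length >= 8.
#' @param target target sequence.
#' @param params list from [binding_params()].
#' @param mirna_id,target_id optional ids attached to the output.
#' @return data.frame of sites ordered by position: `position` (0-based
#'   start of the paired region on the target), `score`, `energy`
#'   (kcal/mol proxy, <= 0), `wc3`, `gu3` (3'-extension pair counts),
#'   `width`, plus the ids.
#' @examples
#' mir <- "UGAGGUAGUAGGUUGUAUAGUU"
#' tgt <- paste0("AAAA", as.character(
#'   Biostrings::reverseComplement(Biostrings::RNAString(mir))), "AAAA")
#' scan_binding_sites(mir, tgt)
#' @export
scan_binding_sites <- function(mirna, target, params = binding_params(),
                               mirna_id = NA_character_,
                               target_id = NA_character_) {
  m <- check_rna(mirna, "miRNA")
  t <- check_rna(target, "target")
  if (nchar(m) < 8L) stop("miRNA must be >= 8 nt", call. = FALSE)
  mc <- strsplit(m, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  seed_rc <- paste(rc_chars(mc[2:8]), collapse = "")
  hits <- gregexpr(seed_rc, t, fixed = TRUE)[[1]]
  hits <- as.integer(hits[hits > 0])
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      position = integer(0), score = numeric(0),
                      energy = numeric(0), wc3 = integer(0), gu3 = integer(0),
                      width = integer(0), stringsAsFactors = FALSE)
  if (length(hits) == 0L) return(empty)
  rows <- lapply(hits, function(s) {
    wc <- 0L; gu <- 0L
    i <- 9L                     # next miRNA base 3' of the seed
    tpos <- s - 1L              # next target base 5' of the seed match
    while (i <= length(mc) && tpos >= 1L) {
      mb <- mc[i]; tb <- tc[tpos]
      if ((mb == "A" && tb == "U") || (mb == "U" && tb == "A") ||
          (mb == "G" && tb == "C") || (mb == "C" && tb == "G")) {
        wc <- wc + 1L
      } else if ((mb == "G" && tb == "U") || (mb == "U" && tb == "G")) {
        gu <- gu + 1L
      } else break
      i <- i + 1L; tpos <- tpos - 1L
    }
    data.frame(mirna_id = mirna_id, target_id = target_id,
               position = (s - 1L) - (wc + gu),
               score = params$base_score + params$wc_bonus * wc +
                 params$gu_bonus * gu,
               energy = -(params$energy_base + params$energy_wc * wc +
                            params$energy_gu * gu),
               wc3 = wc, gu3 = gu, width = 7L + wc + gu,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  # greedy non-overlap: best score first, then leftmost
  sites <- sites[order(-sites$score, sites$position), , drop = FALSE]
  keep <- logical(nrow(sites))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$position[i]; e0 <- s0 + sites$width[i]
    if (!any(s0 < taken_end & e0 > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s0); taken_end <- c(taken_end, e0)
    }
  }
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Aggregate the sites of one miRNA--target pair
#'
#' Totals are sums over sites; `max_score` is the best per-site score and
#' `max_energy` the energy of that maximum-score site (the convention used
#' in published pair tables, where single-site rows make total and max
#' coincide).
#'
#' @param sites data.frame from [scan_binding_sites()] (one pair only).
#' @param target_length target length in nt.
#' @return one-row data.frame in the pair-summary schema: ids,
#'   `total_score`, `total_energy`, `max_score`, `max_energy`,
#'   `target_length`, `positions` (space-separated 0-based), `mre`.
#' @export
aggregate_pair <- function(sites, target_length) {
  if (nrow(sites) == 0L)
    stop("aggregate_pair: no sites to aggregate", call. = FALSE)
  if (length(unique(sites$mirna_id)) > 1L ||
      length(unique(sites$target_id)) > 1L)
    stop("aggregate_pair: sites mix more than one miRNA-target pair",
         call. = FALSE)
  best <- which.max(sites$score)
  data.frame(mirna_id = sites$mirna_id[1],
             target_id = sites$target_id[1],
             total_score = sum(sites$score),
             total_energy = sum(sites$energy),
             max_score = sites$score[best],
             max_energy = sites$energy[best],
             target_length = as.integer(target_length),
             positions = paste(sites$position, collapse = " "),
             mre = nrow(sites),
             stringsAsFactors = FALSE)
}

#' Predict binding summaries for all miRNA--target combinations
#'
#' Runs the scanner over every pair and aggregates pairs with at least one
#' MRE into the pair-summary schema.
#'
#' @param mirnas named character vector or RNAStringSet of miRNAs.
#' @param targets named character vector or RNAStringSet of targets.
#' @param params [binding_params()].
#' @return data.frame of pair summaries (possibly 0 rows), one row per
#'   (miRNA, target) with `mre >= 1`.
#' @export
predict_binding <- function(mirnas, targets, params = binding_params()) {
  mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  targets <- stats::setNames(as.character(targets), names(targets))
  out <- list()
  for (mi in names(mirnas)) {
    for (ti in names(targets)) {
      sites <- scan_binding_sites(mirnas[[mi]], targets[[ti]], params,
                                  mirna_id = mi, target_id = ti)
      if (nrow(sites))
        out[[paste(mi, ti)]] <- aggregate_pair(sites, nchar(targets[[ti]]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      total_score = numeric(0), total_energy = numeric(0),
                      max_score = numeric(0), max_energy = numeric(0),
                      target_length = integer(0), positions = character(0),
                      mre = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an externally produced miRNA--target pair table
#'
#' Accepts the pair-summary TSV schema (ids plus the seven statistic
#' columns; `r` and `p_value` columns are carried through when present), as
#' produced by external binding-site predictors or by [predict_binding()].
#' Rows violating the summary invariants (e.g. an MRE count that does not
#' match the number of listed positions, or total score below max score) are
#' skipped with a warning.
#'
#' @param path TSV file.
#' @return data.frame of validated pair summaries; skipped-row count in the
#'   `n_skipped` attribute.
#' @export
read_pair_table <- function(path) {
  df <- read_tsv(path)
  names(df) <- tolower(gsub("[ .]+", "_", names(df)))
  ren <- c(mirna = "mirna_id", circrna = "target_id", mrna = "target_id",
           target = "target_id", pvalue = "p_value")
  for (nm in names(ren))
    if (nm %in% names(df) && !(ren[[nm]] %in% names(df)))
      names(df)[names(df) == nm] <- ren[[nm]]
  need <- c("mirna_id", "target_id", "total_score", "total_energy",
            "max_score", "max_energy", "target_length", "positions", "mre")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_pair_table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("total_score", "total_energy", "max_score", "max_energy",
                "target_length", "mre")) {
    v <- suppressWarnings(as.numeric(gsub(",", "", df[[col]])))
    if (any(is.na(v)))
      stop("read_pair_table: malformed numeric in `", col, "` at line ",
           which(is.na(v))[1] + 1L, call. = FALSE)
    df[[col]] <- v
  }
  pos_counts <- vapply(strsplit(trimws(as.character(df$positions)),
                                "[ ,;]+"),
                       function(x) sum(nzchar(x)), 0L)
  ok <- df$mre == pos_counts &
    df$total_score >= df$max_score - 1e-9 &
    df$total_energy <= df$max_energy + 1e-9 &
    df$max_energy <= 0 & df$mre >= 1
  if (any(!ok))
    warning(sum(!ok), " row(s) violated pair-summary invariants and were skipped")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' @rdname read_pair_table
#' @param summaries data.frame of pair summaries.
#' @export
write_pair_table <- function(summaries, path) {
  write_tsv(summaries, path)
}
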