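# sequence simulation: miRNAs and target sequences with planted MREs

RNA_LETTERS <- c("A", "C", "G", "U")

random_rna_chars <- function(len) RNA_LETTERS[runif_int(len, 1L, 4L)]

rc_chars <- function(chars) {
  rev(chartr("ACGU", "UGCA", chars))
}

# the planted block for a miRNA: reverse complement of positions 2..(8+ext);
# the scanner's seed complement occupies its rightmost 7 nt
planted_block <- function(mirna_chars, ext) {
  rc_chars(mirna_chars[2:(8L + ext)])
}

# does `mirna` pair with target base `tbase`: Watson-Crick or G:U wobble
pairs_with <- function(mbase, tbase) {
  (mbase == "A" & tbase == "U") | (mbase == "U" & tbase == "A") |
    (mbase == "G" & (tbase == "C" | tbase == "U")) |
    (mbase == "C" & tbase == "G") | (mbase == "U" & tbase == "G")
}

# a base that neither Watson-Crick- nor wobble-pairs with `mbase`
guard_base <- function(mbase) {
  partners <- switch(mbase, A = "U", C = "G", G = c("C", "U"),
                     U = c("A", "G"))
  setdiff(RNA_LETTERS, partners)[1]
}

# Draw miRNA sequences whose seed complements do not collide: no miRNA's
# seed complement may occur inside another miRNA's plantable block (or at a
# non-canonical offset of its own), otherwise planted sites would create
# spurious cross-pair matches.
draw_mirnas <- function(config) {
  ext <- min(config$site_extension, config$mirna_length - 8L)
  for (attempt in seq_len(200L)) {
    seqs <- lapply(seq_len(config$n_mirnas),
                   function(i) random_rna_chars(config$mirna_length))
    seeds <- vapply(seqs, function(s) paste(rc_chars(s[2:8]), collapse = ""), "")
    if (anyDuplicated(seeds)) next
    # the deterministic plantable unit is guard base + block; no seed may
    # occur inside it except the canonical one
    units <- vapply(seqs, function(s) {
      blk <- planted_block(s, ext)
      if (9L + ext <= length(s)) blk <- c(guard_base(s[9L + ext]), blk)
      paste(blk, collapse = "")
    }, "")
    has_guard <- 9L + ext <= config$mirna_length
    ok <- TRUE
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        hits <- gregexpr(seeds[i], units[j], fixed = TRUE)[[1]]
        hits <- hits[hits > 0]
        allowed <- if (i == j) ext + 1L + as.integer(has_guard) else integer(0)
        if (!identical(as.integer(hits), as.integer(allowed)) &&
            !(length(hits) == 0L && length(allowed) == 0L)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) {
      out <- Biostrings::RNAStringSet(vapply(seqs, paste, "", collapse = ""))
      names(out) <- sprintf("mir_%02d", seq_len(config$n_mirnas))
      return(out)
    }
  }
  stop("draw_mirnas: could not draw a collision-free miRNA set", call. = FALSE)
}

#' Plant miRNA binding sites into simulated target sequences
#'
#' Generates miRNA sequences and target sequences (circRNAs and mRNA 3'
#' regions). At each planted position the target carries the reverse
#' complement of the miRNA seed (positions 2--8) preceded by
#' `site_extension` nt of complementary 3' pairing; a guard base terminates
#' the extension so the scanner reports exactly the planted offset.
#' Elsewhere the sequence is random, with accidental seed-complement
#' occurrences (for any miRNA in the bundle) rejected and re-drawn.
#'
#' @param truth a `cerna_truth` carrying target lengths and site positions
#'   (0-based offsets of the site start on the target).
#' @param config a [sim_config()].
#' @return list with `mirna` and `targets`, both named
#'   [Biostrings::RNAStringSet]s.
#' @export
plant_binding_sites <- function(truth, config) {
  config <- validate_sim_config(config)
  with_seed(child_seed(config$seed, "sequences"), {
    mirnas <- draw_mirnas(config)
    mir_chars <- lapply(as.character(mirnas), function(s) strsplit(s, "")[[1]])
    ext <- min(config$site_extension, config$mirna_length - 8L)
    block_len <- 7L + ext
    target_ids <- names(truth$target_lengths)
    # planted sites per target: list of (mirna, pos)
    site_tab <- list()
    for (key in names(truth$planted_sites)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      site_tab[[parts[2]]] <- rbind(site_tab[[parts[2]]],
                                    data.frame(mirna = parts[1],
                                               pos = truth$planted_sites[[key]],
                                               stringsAsFactors = FALSE))
    }
    seeds_rc <- lapply(mir_chars, function(mc) paste(rc_chars(mc[2:8]), collapse = ""))
    targets <- vector("list", length(target_ids))
    names(targets) <- target_ids
    for (tid in target_ids) {
      len <- truth$target_lengths[[tid]]
      sites <- site_tab[[tid]]
      for (redraw in seq_len(100L)) {
        chars <- random_rna_chars(len)
        protected <- logical(len)
        if (!is.null(sites)) {
          for (r in seq_len(nrow(sites))) {
            mc <- mir_chars[[sites$mirna[r]]]
            p0 <- sites$pos[r]           # 0-based site start
            if (p0 + block_len > len)
              stop("plant_binding_sites: site at ", p0, " + block exceeds ",
                   tid, " length ", len, call. = FALSE)
            idx <- (p0 + 1L):(p0 + block_len)
            chars[idx] <- planted_block(mc, ext)
            protected[idx] <- TRUE
            # stop the 3' extension exactly at the planted block
            if (p0 >= 1L && 9L + ext <= length(mc) && !protected[p0]) {
              chars[p0] <- guard_base(mc[9L + ext])
              protected[p0] <- TRUE
            }
          }
        }
        # reject accidental seed complements anywhere off the planted seeds
        clean <- resample_accidental_seeds(chars, protected, seeds_rc,
                                           site_tab[[tid]], ext)
        if (!is.null(clean)) {
          targets[[tid]] <- paste(clean, collapse = "")
          break
        }
        if (redraw == 100L)
          stop("plant_binding_sites: could not clean target ", tid,
               call. = FALSE)
      }
    }
    tset <- Biostrings::RNAStringSet(unlist(targets))
    names(tset) <- target_ids
    list(mirna = mirnas, targets = tset)
  })
}

# re-randomize windows holding accidental seed complements; NULL if a window
# cannot be altered (fully protected), signalling a full redraw
resample_accidental_seeds <- function(chars, protected, seeds_rc, sites, ext) {
  s <- paste(chars, collapse = "")
  for (iter in seq_len(50L)) {
    dirty <- FALSE
    for (mi in seq_along(seeds_rc)) {
      hits <- gregexpr(seeds_rc[[mi]], s, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      if (length(hits) == 0L) next
      allowed <- integer(0)
      if (!is.null(sites)) {
        mine <- sites[sites$mirna == names(seeds_rc)[mi] |
                        sites$mirna == sprintf("mir_%02d", mi), , drop = FALSE]
        # planted seed complement sits `ext` nt right of the site start
        if (nrow(mine)) allowed <- mine$pos + ext + 1L
      }
      bad <- setdiff(as.integer(hits), allowed)
      for (h in bad) {
        win <- h:(h + 6L)
        free <- win[!protected[win]]
        if (length(free) == 0L) return(NULL)
        chars[free] <- random_rna_chars(length(free))
        dirty <- TRUE
      }
    }
    if (dirty) s <- paste(chars, collapse = "") else return(chars)
  }
  NULL
}
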