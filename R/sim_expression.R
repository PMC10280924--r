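# planted ground truth and negative-binomial expression simulation

# Build the ground-truth object: which triplets are planted, the induced DE
# directions (miRNA opposite to both partners), target sequence lengths and
# planted MRE positions. Directions are "up"/"down" for group 1 vs group 2.
build_truth <- function(annotation, circ, config) {
  with_seed(child_seed(config$seed, "truth"), {
    mrna_ids <- annotation_tables(annotation)$genes$gene_id
    mirna_ids <- sprintf("mir_%02d", seq_len(config$n_mirnas))
    circ_ids <- names(circ$categories)
    k <- config$n_planted_triplets
    trip <- data.frame(circ_id = sample(circ_ids, k),
                       mirna_id = sample(mirna_ids, k),
                       mrna_id = sample(mrna_ids, k),
                       stringsAsFactors = FALSE)
    dir_m <- sample(c("up", "down"), k, replace = TRUE)
    opp <- ifelse(dir_m == "up", "down", "up")
    planted_de <- c(stats::setNames(dir_m, trip$mirna_id),
                    stats::setNames(opp, trip$circ_id),
                    stats::setNames(opp, trip$mrna_id))
    target_lengths <- c(
      stats::setNames(runif_int(length(circ_ids),
                                config$circ_seq_length_range[1],
                                config$circ_seq_length_range[2]), circ_ids),
      stats::setNames(runif_int(length(mrna_ids),
                                config$mrna_seq_length_range[1],
                                config$mrna_seq_length_range[2]), mrna_ids))
    block <- 7L + min(config$site_extension, config$mirna_length - 8L)
    planted_sites <- list()
    for (i in seq_len(k)) {
      for (tid in c(trip$circ_id[i], trip$mrna_id[i])) {
        len <- target_lengths[[tid]]
        ns <- config$sites_per_pair
        chunk <- len %/% ns
        if (chunk < block + 4L)
          stop("build_truth: target ", tid, " too short for ", ns,
               " planted sites", call. = FALSE)
        pos <- (seq_len(ns) - 1L) * chunk +
          runif_int(ns, 2L, chunk - block - 2L)
        planted_sites[[paste(trip$mirna_id[i], tid, sep = "|")]] <-
          as.integer(pos)
      }
    }
    structure(list(mrna_ids = mrna_ids, mirna_ids = mirna_ids,
                   circ_ids = circ_ids, planted_triplets = trip,
                   planted_categories = circ$categories,
                   planted_de = planted_de,
                   target_lengths = target_lengths,
                   planted_sites = planted_sites),
              class = "cerna_truth")
  })
}

#' @export
print.cerna_truth <- function(x, ...) {
  cat(sprintf("cerna_truth: %d planted triplets over %d mRNAs, %d miRNAs, %d circRNAs; %d planted site sets\n",
              nrow(x$planted_triplets), length(x$mrna_ids),
              length(x$mirna_ids), length(x$circ_ids),
              length(x$planted_sites)))
  invisible(x)
}

#' Simulate expression counts for a planted ground truth
#'
#' Draws negative-binomial counts for mRNAs, miRNAs and circRNAs across a
#' two-group design. For each planted triplet, per-sample miRNA activity
#' carries the miRNA's group effect; the sponging circRNA attenuates the
#' effective activity multiplicatively (and the measured free-miRNA level is
#' drawn from that attenuated activity); the target mRNA mean is repressed
#' by `2^(-repression_strength * z)`, where `z` is the standardized effective
#' log2 activity. mRNA differential expression is therefore *mediated* by
#' repression: zeroing `repression_strength` removes both the mRNA group
#' effect and all planted correlation signal, and zeroing `sponge_strength`
#' as well decouples the miRNA from the circRNA apart from their opposite
#' group effects. Library sizes vary by +/- 20%.
#'
#' @param truth a `cerna_truth` object (see [simulate_bundle()]).
#' @param config a [sim_config()].
#' @return A list with `counts` (list of three matrices: `mrna`, `mirna`,
#'   `circ`) and `design` (data.frame of sample/group).
#' @export
simulate_expression <- function(truth, config) {
  config <- validate_sim_config(config)
  with_seed(child_seed(config$seed, "expression"), {
    g1 <- config$groups[1]; g2 <- config$groups[2]
    groups <- rep(c(g1, g2), each = config$samples_per_group)
    samples <- paste(groups,
                     rep(seq_len(config$samples_per_group), times = 2),
                     sep = "_")
    design <- data.frame(sample = samples, group = groups,
                         stringsAsFactors = FALSE)
    ns <- length(samples)
    sgn <- ifelse(groups == g1, 0.5, -0.5)
    lo <- config$base_mean_log_range[1]; hi <- config$base_mean_log_range[2]
    base_log <- function(ids) stats::setNames(stats::runif(length(ids), lo, hi), ids)
    b_m <- base_log(truth$mrna_ids)
    b_mi <- base_log(truth$mirna_ids)
    b_c <- base_log(truth$circ_ids)
    dirn <- function(id) {
      d <- truth$planted_de[id]
      if (is.na(d)) 0 else if (d == "up") 1 else -1
    }
    logmu_m <- matrix(rep(b_m, ns), ncol = ns,
                      dimnames = list(truth$mrna_ids, samples))
    logmu_mi <- matrix(rep(b_mi, ns), ncol = ns,
                       dimnames = list(truth$mirna_ids, samples))
    logmu_c <- matrix(rep(b_c, ns), ncol = ns,
                      dimnames = list(truth$circ_ids, samples))
    zscore <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    trip <- truth$planted_triplets
    for (i in seq_len(nrow(trip))) {
      m <- trip$mirna_id[i]; cc <- trip$circ_id[i]; gg <- trip$mrna_id[i]
      alpha <- dirn(m) * config$de_lfc * sgn +
        stats::rnorm(ns, 0, config$activity_sd)
      gamma <- dirn(cc) * config$de_lfc * sgn +
        stats::rnorm(ns, 0, config$activity_sd)
      logmu_c[cc, ] <- b_c[cc] + gamma
      # circRNA sponging attenuates the effective miRNA activity; the
      # measured free-miRNA level is the effective activity
      alpha_eff <- alpha - config$sponge_strength * zscore(gamma)
      logmu_mi[m, ] <- b_mi[m] + alpha_eff
      # targets are repressed in proportion to effective activity
      logmu_m[gg, ] <- b_m[gg] -
        config$repression_strength * zscore(alpha_eff)
    }
    draw <- function(logmu, label) {
      libf <- stats::runif(ns, 0.8, 1.2)
      mu <- 2^logmu * rep(libf, each = nrow(logmu))
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / config$nb_dispersion),
                    nrow = nrow(logmu), dimnames = dimnames(logmu))
      storage.mode(cnt) <- "double"
      cnt
    }
    list(counts = list(mrna = draw(logmu_m),
                       mirna = draw(logmu_mi),
                       circ = draw(logmu_c)),
         design = design)
  })
}
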