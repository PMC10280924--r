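#' Configuration for a synthetic ceRNA fixture bundle
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. The defaults emulate a two-breed ovary RNA-seq design: two groups
#' of three replicates, negative-binomial counts, miRNA-mediated repression of
#' planted mRNA targets and a multiplicative circRNA sponge effect, so that
#' planted triplets show the correlation signs the ceRNA screens expect
#' (miRNA--mRNA r < 0, miRNA--circRNA r < 0, circRNA--mRNA r > 0).
#'
#' @param seed integer root seed; every generator stream is derived from it.
#' @param n_chromosomes,n_genes,n_mirnas,n_circrnas feature universe sizes.
#' @param samples_per_group replicates per group (>= 2; correlation needs
#'   n - 2 >= 1 degrees of freedom).
#' @param groups character pair of group labels (first = "case" group).
#' @param nb_dispersion negative-binomial dispersion (mu--dispersion
#'   parameterization: variance = mu + dispersion * mu^2).
#' @param base_mean_log_range log2 range for baseline feature means.
#' @param repression_strength beta: log2-fold repression of a planted target
#'   mean per standard deviation of effective miRNA activity.
#' @param sponge_strength log2 attenuation of miRNA activity per standard
#'   deviation of the sponging circRNA level.
#' @param n_planted_triplets number of planted circRNA--miRNA--mRNA triplets.
#' @param de_lfc log2 group effect applied to planted miRNAs and circRNAs
#'   (mRNA differential expression is induced through repression).
#' @param mirna_length miRNA length in nt.
#' @param activity_sd standard deviation of per-sample log2 activity noise.
#' @param chrom_length chromosome length available for gene packing (nt).
#' @param exon_count_range inclusive range of exons per transcript.
#' @param category_props named proportions for planted circRNA categories
#'   (exonic, intronic, sense_overlapping, antisense, intergenic).
#' @param sites_per_pair planted MREs per miRNA--target pair.
#' @param site_extension nt of Watson--Crick 3' pairing planted beyond the
#'   seed match.
#' @param circ_seq_length_range,mrna_seq_length_range sequence length ranges
#'   (nt) for circRNA sequences and mRNA 3' regions.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_bundle()]
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 20, n_circrnas = 10,
#'                   n_mirnas = 8, n_planted_triplets = 4)
#' cfg
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       n_genes = 80L,
                       n_mirnas = 30L,
                       n_circrnas = 40L,
                       samples_per_group = 3L,
                       groups = c("X_LC", "D_LC"),
                       nb_dispersion = 0.05,
                       base_mean_log_range = c(4, 9),
                       repression_strength = 2,
                       sponge_strength = 0.5,
                       n_planted_triplets = 20L,
                       de_lfc = 3,
                       mirna_length = 22L,
                       activity_sd = 0.2,
                       chrom_length = 2e6,
                       exon_count_range = c(1L, 18L),
                       category_props = c(sense_overlapping = 0.9081,
                                          intergenic = 0.0360,
                                          exonic = 0.0320,
                                          antisense = 0.0153,
                                          intronic = 0.0086),
                       sites_per_pair = 3L,
                       site_extension = 8L,
                       circ_seq_length_range = c(400L, 1200L),
                       mrna_seq_length_range = c(300L, 800L)) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_circrnas = as.integer(n_circrnas),
              samples_per_group = as.integer(samples_per_group),
              groups = as.character(groups),
              nb_dispersion = nb_dispersion,
              base_mean_log_range = as.numeric(base_mean_log_range),
              repression_strength = repression_strength,
              sponge_strength = sponge_strength,
              n_planted_triplets = as.integer(n_planted_triplets),
              de_lfc = de_lfc,
              mirna_length = as.integer(mirna_length),
              activity_sd = activity_sd,
              chrom_length = as.numeric(chrom_length),
              exon_count_range = as.integer(exon_count_range),
              category_props = category_props,
              sites_per_pair = as.integer(sites_per_pair),
              site_extension = as.integer(site_extension),
              circ_seq_length_range = as.integer(circ_seq_length_range),
              mrna_seq_length_range = as.integer(mrna_seq_length_range))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (f in c("n_chromosomes", "n_genes", "n_mirnas", "n_circrnas",
              "n_planted_triplets", "mirna_length", "sites_per_pair"))
    if (!is_count(cfg[[f]]))
      stop("sim_config: `", f, "` must be a positive integer", call. = FALSE)
  if (!is_count(cfg$samples_per_group, min = 2))
    stop("sim_config: `samples_per_group` must be >= 2 (correlation needs n - 2 >= 1)",
         call. = FALSE)
  if (length(cfg$groups) != 2L || anyDuplicated(cfg$groups))
    stop("sim_config: `groups` must be two distinct labels", call. = FALSE)
  if (!is_number(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    stop("sim_config: `nb_dispersion` must be a positive real", call. = FALSE)
  for (f in c("repression_strength", "sponge_strength"))
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: `", f, "` must be non-negative", call. = FALSE)
  if (!is_number(cfg$de_lfc) || cfg$de_lfc < 0)
    stop("sim_config: `de_lfc` must be non-negative", call. = FALSE)
  if (length(cfg$base_mean_log_range) != 2L ||
      diff(cfg$base_mean_log_range) < 0)
    stop("sim_config: `base_mean_log_range` must be an increasing interval",
         call. = FALSE)
  if (cfg$mirna_length < 8L)
    stop("sim_config: `mirna_length` must be >= 8 (seed is positions 2-8)",
         call. = FALSE)
  if (cfg$n_planted_triplets > min(cfg$n_genes, cfg$n_mirnas, cfg$n_circrnas))
    stop("sim_config: `n_planted_triplets` exceeds the smallest feature universe",
         call. = FALSE)
  props <- cfg$category_props
  valid <- c("exonic", "intronic", "sense_overlapping", "antisense", "intergenic")
  if (is.null(names(props)) || !all(names(props) %in% valid))
    stop("sim_config: `category_props` names must be circRNA categories",
         call. = FALSE)
  if (any(props < 0) || sum(props) <= 0)
    stop("sim_config: `category_props` must be non-negative and sum > 0",
         call. = FALSE)
  if (cfg$exon_count_range[1] < 1L ||
      cfg$exon_count_range[2] < cfg$exon_count_range[1])
    stop("sim_config: invalid `exon_count_range`", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ceRNA bundle configuration\n")
  cat(sprintf("  seed %d | %d chromosomes, %d genes, %d miRNAs, %d circRNAs\n",
              x$seed, x$n_chromosomes, x$n_genes, x$n_mirnas, x$n_circrnas))
  cat(sprintf("  design: %s vs %s, %d + %d samples\n", x$groups[1], x$groups[2],
              x$samples_per_group, x$samples_per_group))
  cat(sprintf("  %d planted triplets | de_lfc %.2g, repression %.2g, sponge %.2g, dispersion %.2g\n",
              x$n_planted_triplets, x$de_lfc, x$repression_strength,
              x$sponge_strength, x$nb_dispersion))
  invisible(x)
}
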