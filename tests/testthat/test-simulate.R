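# synthetic-data generator: determinism, geometry, planted structure

test_that("annotation genes are non-overlapping per chromosome (interval sweep)", {
  cfg <- sim_config(seed = 5, n_genes = 50, n_chromosomes = 2)
  ann <- simulate_annotation(cfg)
  tabs <- cernets:::annotation_tables(ann)
  expect_equal(nrow(tabs$genes), 50L)
  for (chrom in unique(tabs$genes$chrom)) {
    g <- tabs$genes[tabs$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    # brute-force sweep: every start must lie beyond the previous end
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # exons inside gene bounds, sorted, non-overlapping within transcripts
  for (tid in unique(tabs$exons$tx_id)) {
    e <- tabs$exons[tabs$exons$tx_id == tid, ]
    e <- e[order(e$start), ]
    gene <- tabs$genes[tabs$genes$gene_id == e$gene_id[1], ]
    expect_true(all(e$start >= gene$start & e$end <= gene$end))
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
  expect_setequal(unique(tabs$genes$strand), c("+", "-"))
})

test_that("degenerate single-gene single-exon annotation collapses to one span", {
  cfg <- sim_config(seed = 2, n_genes = 1, n_chromosomes = 1,
                    n_circrnas = 1, n_mirnas = 1, n_planted_triplets = 1,
                    exon_count_range = c(1, 1))
  ann <- simulate_annotation(cfg)
  tabs <- cernets:::annotation_tables(ann)
  expect_equal(nrow(tabs$exons), 1L)
  expect_equal(tabs$transcripts$start, tabs$exons$start)
  expect_equal(tabs$transcripts$end, tabs$exons$end)
})

test_that("impossible gene packing raises a sizing error", {
  cfg <- sim_config(seed = 1, n_genes = 40, n_chromosomes = 1,
                    chrom_length = 5000)
  expect_error(simulate_annotation(cfg), "pack")
})

test_that("same seed gives byte-identical GFF3, FASTA and bundle checksums", {
  cfg <- small_config(seed = 9)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  m1 <- write_bundle(simulate_bundle(cfg), d1)
  m2 <- write_bundle(simulate_bundle(cfg), d2)
  expect_identical(m1$md5, m2$md5)
  expect_identical(readLines(file.path(d1, "annotation.gff3")),
                   readLines(file.path(d2, "annotation.gff3")))
  expect_identical(readLines(file.path(d1, "mirna.fasta")),
                   readLines(file.path(d2, "mirna.fasta")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("single-category proportions produce only that category", {
  cfg <- small_config(seed = 3)
  ann <- simulate_annotation(cfg)
  cj <- simulate_circrnas(ann, cfg, proportions = c(intergenic = 1), n = 25)
  expect_true(all(cj$categories == "intergenic"))
  # by construction: no gene overlap
  ov <- GenomicRanges::findOverlaps(cj$granges, ann$genes,
                                    ignore.strand = TRUE)
  expect_length(ov, 0L)
  # exonic circRNAs coincide with exon boundaries of a same-strand transcript
  ce <- simulate_circrnas(ann, cfg, proportions = c(exonic = 1), n = 25)
  tabs <- cernets:::annotation_tables(ann)
  key_s <- paste(tabs$exons$chrom, tabs$exons$strand, tabs$exons$start)
  key_e <- paste(tabs$exons$chrom, tabs$exons$strand, tabs$exons$end)
  gr <- ce$granges
  expect_true(all(paste(GenomeInfoDb::seqnames(gr), BiocGenerics::strand(gr),
                        BiocGenerics::start(gr)) %in% key_s))
  expect_true(all(paste(GenomeInfoDb::seqnames(gr), BiocGenerics::strand(gr),
                        BiocGenerics::end(gr)) %in% key_e))
})

test_that("unattainable category errors name the category", {
  cfg <- sim_config(seed = 4, n_genes = 3, n_chromosomes = 1,
                    n_circrnas = 3, n_mirnas = 2, n_planted_triplets = 1,
                    exon_count_range = c(1, 1))
  ann <- simulate_annotation(cfg)
  expect_error(simulate_circrnas(ann, cfg, proportions = c(intronic = 1)),
               "intronic")
})

test_that("planted sites are recovered by the scanner at exact offsets", {
  cfg <- small_config(seed = 6)
  b <- simulate_bundle(cfg)
  keys <- names(b$truth$planted_sites)
  for (key in keys) {
    ids <- strsplit(key, "|", fixed = TRUE)[[1]]
    sites <- scan_binding_sites(b$sequences$mirna[[ids[1]]],
                                b$sequences$targets[[ids[2]]],
                                mirna_id = ids[1], target_id = ids[2])
    expect_equal(sites$position, sort(b$truth$planted_sites[[key]]),
                 info = key)
  }
  # a pair with no planted sites reports none
  tr <- b$truth$planted_triplets
  other_mirna <- setdiff(b$truth$mirna_ids, tr$mirna_id)[1]
  some_target <- tr$circ_id[1]
  sites0 <- scan_binding_sites(b$sequences$mirna[[other_mirna]],
                               b$sequences$targets[[some_target]])
  expect_equal(nrow(sites0), 0L)
})

test_that("truth JSON round-trips to an equal object", {
  b <- simulate_bundle(small_config(seed = 8))
  path <- tempfile(fileext = ".json")
  write_truth(b$truth, path)
  back <- read_truth(path)
  expect_equal(back$planted_triplets, b$truth$planted_triplets)
  expect_equal(back$planted_de, b$truth$planted_de)
  expect_equal(back$planted_categories, b$truth$planted_categories)
  expect_equal(back$target_lengths, b$truth$target_lengths)
  expect_equal(back$planted_sites, b$truth$planted_sites)
  unlink(path)
})

test_that("a zero-count feature row survives the file round trip", {
  m <- matrix(c(0, 0, 0, 0, 5, 8, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("zero_f", "ok_f"),
                              c("s1", "s2", "s3", "s4")))
  path <- tempfile(fileext = ".tsv")
  cernets:::write_counts(m, path)
  back <- read_counts(path)
  expect_equal(back, m)
  unlink(path)
})

test_that("with repression zeroed, planted-pair correlations vanish", {
  # Monte-Carlo over seeds, scaled to a handful of bundles. At n = 6 even
  # independent pairs have E|r| ~ 0.36, so the null check is on the
  # expected (mean signed) correlation and on the screening pass rate.
  rs <- unlist(lapply(1:6, function(s) {
    cfg <- small_config(seed = s, repression_strength = 0,
                        sponge_strength = 0)
    b <- simulate_bundle(cfg)
    lg <- function(m) log2(normalize_counts(m, "CPM") + 1)
    mi <- lg(b$counts$mirna); mr <- lg(b$counts$mrna)
    tr <- b$truth$planted_triplets
    mapply(function(m, g) stats::cor(mi[m, ], mr[g, ]),
           tr$mirna_id, tr$mrna_id)
  }))
  expect_lt(abs(mean(rs)), 0.3)
  expect_lt(mean(rs <= -0.8), 0.2)
})

test_that("strong repression drives planted miRNA-mRNA r below -0.8", {
  # the stated strong settings: beta = 2, dispersion = 0.05, de_lfc = 2
  rs <- unlist(lapply(1:6, function(s) {
    cfg <- small_config(seed = s, repression_strength = 2,
                        nb_dispersion = 0.05, de_lfc = 2)
    b <- simulate_bundle(cfg)
    lg <- function(m) log2(normalize_counts(m, "CPM") + 1)
    mi <- lg(b$counts$mirna); mr <- lg(b$counts$mrna)
    tr <- b$truth$planted_triplets
    mapply(function(m, g) stats::cor(mi[m, ], mr[g, ]),
           tr$mirna_id, tr$mrna_id)
  }))
  expect_gt(mean(rs <= -0.8), 0.9)
})

test_that("bundle files exist and manifest checksums verify", {
  d <- file.path(tempdir(), "bundle_m")
  manifest <- write_bundle(simulate_bundle(small_config(seed = 12)), d)
  expect_true(all(file.exists(file.path(d, manifest$file))))
  expect_identical(unname(tools::md5sum(file.path(d, manifest$file))),
                   manifest$md5)
  b <- read_bundle(d)
  expect_s3_class(b, "cerna_bundle")
  expect_equal(sort(rownames(b$counts$mrna)), sort(b$truth$mrna_ids))
  unlink(d, recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(samples_per_group = 1), "samples_per_group")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(n_planted_triplets = 100), "universe")
  expect_error(sim_config(mirna_length = 6), "mirna_length")
})
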