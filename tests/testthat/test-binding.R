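# deterministic seed-and-extend MRE scanner and pair-table interop

test_that("a full reverse-complement target yields the stated site", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"          # 22 nt
  rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(mir)))
  target <- paste0("AAAACCA", rc, "CCAA")  # full RC at 0-based offset 7
  sites <- scan_binding_sites(mir, target)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 7L)
  expect_equal(sites$score, 40 + 5 * 14)   # 14 Watson-Crick 3' pairs
  expect_equal(sites$energy, -(7.0 + 0.45 * 14))
  expect_equal(sites$wc3, 14L)
})

test_that("a target without any seed complement yields no site", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_equal(nrow(scan_binding_sites(mir, strsplit(strrep("A", 200), NULL)[[1]] |>
                                         paste(collapse = ""))), 0L)
})

test_that("T/U are equivalent on read and bad symbols error by name", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  seed_rc_dna <- gsub("U", "T", as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(substr(mir, 2, 8)))))
  target_dna <- paste0("AAAA", seed_rc_dna, "AAAA")
  sites <- scan_binding_sites(mir, target_dna)
  expect_equal(nrow(sites), 1L)
  expect_error(scan_binding_sites(mir, "ACGUNACGU"), "N")
  expect_error(scan_binding_sites("ACGU", "ACGUACGU"), ">= 8")
})

test_that("the scanner is deterministic and position-faithful", {
  b <- simulate_bundle(small_config(seed = 51))
  tr <- b$truth$planted_triplets[1, ]
  mir <- as.character(b$sequences$mirna[[tr$mirna_id]])
  tgt <- as.character(b$sequences$targets[[tr$mrna_id]])
  s1 <- scan_binding_sites(mir, tgt)
  s2 <- scan_binding_sites(mir, tgt)
  expect_identical(s1, s2)
  key <- paste(tr$mirna_id, tr$mrna_id, sep = "|")
  expect_equal(s1$position, sort(b$truth$planted_sites[[key]]))
  # sites are reported in target coordinate order and within bounds
  expect_false(is.unsorted(s1$position))
  expect_true(all(s1$position >= 0 & s1$position + s1$width <= nchar(tgt)))
})

test_that("greedy non-overlap keeps the best-scoring of clashing sites", {
  # construct a target where two seed matches overlap via a repeated motif
  mir <- "AGGGGGGGGGGGGGGGGGGGGG"              # seed = positions 2-8: G x7
  target <- strrep("C", 20)                     # C-runs: many overlapping CCCCCCC
  sites <- scan_binding_sites(mir, target)
  # every kept site must be disjoint
  if (nrow(sites) > 1) {
    s <- sites[order(sites$position), ]
    expect_true(all(s$position[-1] >= (s$position + s$width)[-nrow(s)]))
  }
  expect_gt(nrow(sites), 0L)
})

test_that("aggregate_pair sums sites and tracks the max-score site", {
  sites <- data.frame(mirna_id = "m", target_id = "t",
                      position = c(5L, 50L), score = c(10, 20),
                      energy = c(-8, -12), wc3 = 0L, gu3 = 0L, width = 7L,
                      stringsAsFactors = FALSE)
  agg <- aggregate_pair(sites, target_length = 100)
  expect_equal(agg$total_score, 30)
  expect_equal(agg$max_score, 20)
  expect_equal(agg$max_energy, -12)          # energy of the max-score site
  expect_equal(agg$total_energy, -20)
  expect_equal(agg$mre, 2L)
  expect_equal(agg$positions, "5 50")
  one <- aggregate_pair(sites[1, ], 100)
  expect_equal(one$total_score, one$max_score)
  expect_equal(one$total_energy, one$max_energy)
  # brute-force sum property over random site sets
  set.seed(8)
  for (i in 1:10) {
    k <- sample(1:12, 1)
    s <- data.frame(mirna_id = "m", target_id = "t",
                    position = sample(1:1000, k), score = runif(k, 40, 160),
                    energy = -runif(k, 7, 30), wc3 = 0L, gu3 = 0L,
                    width = 7L, stringsAsFactors = FALSE)
    a <- aggregate_pair(s, 2000)
    expect_equal(a$total_score, sum(s$score))
    expect_equal(a$total_energy, sum(s$energy))
    expect_equal(a$max_score, max(s$score))
  }
  bad <- sites; bad$mirna_id <- c("m1", "m2")
  expect_error(aggregate_pair(bad, 100), "mix")
})

test_that("the shipped pair table parses to 12 rows over 9 circRNAs and 8 miRNAs", {
  tab <- read_pair_table(pair_table_path())
  expect_equal(nrow(tab), 12L)
  expect_equal(length(unique(tab$target_id)), 9L)
  expect_equal(length(unique(tab$mirna_id)), 8L)
  # MRE = 1 rows have total == max by construction of the schema
  one_site <- tab[tab$mre == 1, ]
  expect_equal(one_site$total_score, one_site$max_score)
  expect_equal(one_site$total_energy, one_site$max_energy)
})

test_that("pair-table reading validates and skips invariant violations", {
  path <- tempfile(fileext = ".tsv")
  header <- paste(c("mirna_id", "target_id", "total_score", "total_energy",
                    "max_score", "max_energy", "target_length", "positions",
                    "mre"), collapse = "\t")
  writeLines(header, path)
  expect_equal(nrow(read_pair_table(path)), 0L)   # empty file with header
  writeLines(c(header,
               "m1\tt1\t100\t-20\t60\t-10\t500\t5 50\t2",
               "m2\tt2\t100\t-20\t60\t-10\t500\t5 50\t3"), path)  # mre mismatch
  expect_warning(tab <- read_pair_table(path), "skipped")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_skipped"), 1L)
  writeLines(c(header,
               "m1\tt1\tnot_a_number\t-20\t60\t-10\t500\t5\t1"), path)
  expect_error(read_pair_table(path), "line 2")
  unlink(path)
})

test_that("predict_binding aggregates planted pairs with the planted MRE count", {
  b <- simulate_bundle(small_config(seed = 52))
  tr <- b$truth$planted_triplets
  mir <- b$sequences$mirna[tr$mirna_id[1]]
  tgt <- b$sequences$targets[c(tr$circ_id[1], tr$mrna_id[1])]
  got <- predict_binding(mir, tgt)
  expect_equal(nrow(got), 2L)
  expect_equal(sort(unique(got$mre)),
               b$config$sites_per_pair)
  expect_equal(got$target_length,
               unname(b$truth$target_lengths[got$target_id]))
})
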