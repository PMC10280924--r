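# normalization and differential-expression screening

test_that("RPM/CPM and FPKM follow their definitions", {
  m <- matrix(c(10, 999990, 30, 999970), nrow = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  rpm <- normalize_counts(m, "RPM")
  expect_equal(rpm["f1", "s1"], 10)         # count 10 in a 1e6 library
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  fpkm <- normalize_counts(matrix(c(100, 999900), 2,
                                  dimnames = list(c("a", "b"), "s1")),
                           "FPKM", feature_lengths = c(a = 1000, b = 500))
  expect_equal(fpkm["a", "s1"], 100)        # 100*1e9/(1e6*1000)
  z <- matrix(c(0, 0, 5, 7), 2, byrow = TRUE,
              dimnames = list(c("zero", "ok"), c("s1", "s2")))
  expect_equal(unname(normalize_counts(z, "CPM")["zero", ]), c(0, 0))
})

test_that("normalization rejects zero libraries and missing lengths", {
  m <- matrix(c(0, 0, 1, 2), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normalize_counts(m, "CPM"), "zero library")
  m2 <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normalize_counts(m2, "FPKM"), "length")
})

test_that("normalization preserves within-column rank order", {
  set.seed(3)
  m <- matrix(rpois(60, 50), 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  cpm <- normalize_counts(m, "CPM")
  for (j in 1:6) expect_equal(order(cpm[, j]), order(m[, j]))
})

design6 <- data.frame(sample = paste0("s", 1:6),
                      group = rep(c("G1", "G2"), each = 3),
                      stringsAsFactors = FALSE)

test_that("identical group profiles give log2fc 0 and doubling gives 1", {
  base <- matrix(rep(c(8, 16, 32), 6), nrow = 3,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  de0 <- de_test(base, design6, pseudocount = 0)
  expect_equal(de0$log2fc, rep(0, 3))
  doubled <- base
  doubled[, 1:3] <- doubled[, 1:3] * 2
  de2 <- de_test(doubled, design6, pseudocount = 0)
  expect_equal(de2$log2fc, rep(1, 3))
})

test_that("swapping group labels negates log2fc and keeps p", {
  set.seed(11)
  m <- matrix(rnbinom(60, mu = 100, size = 10) + 1, 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  a <- de_test(m, design6)
  b <- de_test(m, design6, group_order = c("G2", "G1"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("BH adjustment is monotone with p ordering", {
  set.seed(4)
  m <- matrix(rnbinom(120, mu = 80, size = 5) + 1, 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  de <- de_test(m, design6)
  expect_true(all(de$padj >= de$p))
  expect_equal(order(de$p), order(de$padj, de$p))
})

test_that("planted DE features are recovered at the stated settings", {
  # planted de_lfc = 2, dispersion 0.05: >= 90% recovery expected
  hits <- unlist(lapply(1:4, function(s) {
    b <- simulate_bundle(small_config(seed = s, de_lfc = 2,
                                      nb_dispersion = 0.05))
    norm <- lapply(b$counts, normalize_counts, method = "CPM")
    de <- list(mrna = filter_de(de_test(norm$mrna, b$design)),
               mirna = filter_de(de_test(norm$mirna, b$design)),
               circ = filter_de(de_test(norm$circ, b$design)))
    planted <- b$truth$planted_de
    found <- c(stats::setNames(de$mrna$direction, de$mrna$feature_id),
               stats::setNames(de$mirna$direction, de$mirna$feature_id),
               stats::setNames(de$circ$direction, de$circ$feature_id))
    recovered <- names(planted)[names(planted) %in% names(found)]
    # recovered features must carry the planted direction
    expect_equal(unname(found[recovered]), unname(planted[recovered]))
    names(planted) %in% names(found)
  }))
  expect_gt(mean(hits), 0.9)
})

test_that("filter_de applies strict threshold boundaries", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2fc = c(0.99, 1.0, -1.4),
                    p = c(0.001, 0.049, 0.05),
                    padj = c(0.003, 0.147, 0.15),
                    direction = "ns", stringsAsFactors = FALSE)
  got <- filter_de(res, lfc_min = 1, p_max = 0.05)
  expect_equal(got$feature_id, "b")          # 0.99 excluded; p = 0.05 excluded
  expect_equal(got$direction, "up")
  expect_equal(nrow(filter_de(res[0, ], 1, 0.05)), 0L)
  padj_only <- filter_de(res, lfc_min = 1, p_max = 0.05, use_padj = TRUE)
  expect_equal(nrow(padj_only), 0L)
})

test_that("de_test validates its design", {
  m <- matrix(1:8, 2, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  bad <- data.frame(sample = paste0("s", 1:4),
                    group = c("G1", "G1", "G1", "G2"))
  expect_error(de_test(m, bad), ">= 2 samples")
})
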