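# hypergeometric ceRNA scoring, evidence intersection, network assembly

test_that("hypergeom_tail matches enumerated anchors", {
  expect_equal(hypergeom_tail(10, 4, 3, 0), 1)       # full mass at x = 0
  expect_equal(hypergeom_tail(5, 2, 2, 2), 1 / 10)   # all C(5,2) draws
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210) # C(5,4)C(5,0)/C(10,4)
  expect_error(hypergeom_tail(5, 6, 2, 1), "inconsistent")
  expect_error(hypergeom_tail(5, 2, 2, 3), "inconsistent")
})

test_that("hypergeom_tail is non-increasing in x at fixed N, K, M", {
  for (N in c(6, 9, 12)) for (K in c(2, 4, N - 1)) for (M in c(2, N %/% 2)) {
    x <- 0:min(K, M)
    p <- hypergeom_tail(N, K, M, x)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("cerna_score emits only sharing pairs with exact probabilities", {
  expect_equal(nrow(cerna_score(list(c1 = "m1"), list(g1 = "m2"),
                                c("m1", "m2"))), 0L)   # disjoint sets
  got <- cerna_score(list(c1 = "m1"), list(g1 = "m1"),
                     paste0("m", 1:4))
  expect_equal(got$x, 1L)
  expect_equal(got$score_p, 1 / 4)                     # N=4, K=M=x=1
  expect_error(cerna_score(list(c1 = "mX"), list(g1 = "m1"),
                           c("m1", "m2")), "universe")
})

test_that("cerna_score orders by p then ids and flags significance", {
  circ <- list(cA = c("m1", "m2", "m3"), cB = "m1")
  mrna <- list(gA = c("m1", "m2", "m3"), gB = "m1")
  got <- cerna_score(circ, mrna, paste0("m", 1:6), alpha = 0.2)
  expect_false(is.unsorted(got$score_p))
  expect_equal(got$circ_id[1], "cA")                   # x=3 strongest
  expect_true(all(got$significant == (got$score_p < 0.2)))
  expect_true(all(got$x <= pmin(got$K, got$M)))
})

test_that("intersect_evidence intersects on pair identity and truncates", {
  sp <- data.frame(circ_id = c("A", "C"), mrna_id = c("B", "D"),
                   x = 1L, K = 1L, M = 1L, N = 5L,
                   score_p = c(0.2, 0.1), stringsAsFactors = FALSE)
  co <- data.frame(id_a = "C", id_b = "D", r = 0.9, n = 6, p = 0.01,
                   stringsAsFactors = FALSE)
  got <- intersect_evidence(sp, co)
  expect_equal(nrow(got), 1L)
  expect_equal(got$circ_id, "C")
  expect_equal(got$coexpr_r, 0.9)
  none <- intersect_evidence(sp, data.frame(id_a = "B", id_b = "C",
                                            r = 1, n = 6, p = 0))
  expect_equal(nrow(none), 0L)
  # truncation to top_k by score_p
  sp2 <- data.frame(circ_id = paste0("c", 1:5), mrna_id = paste0("g", 1:5),
                    score_p = c(0.5, 0.1, 0.3, 0.2, 0.4),
                    stringsAsFactors = FALSE)
  co2 <- data.frame(id_a = paste0("c", 1:5), id_b = paste0("g", 1:5),
                    r = 0.9, n = 6, p = 0.01, stringsAsFactors = FALSE)
  top2 <- intersect_evidence(sp2, co2, top_k = 2)
  expect_equal(top2$circ_id, c("c2", "c4"))
})

test_that("build_cernet assembles a minimal coherent triplet", {
  fp <- data.frame(circ_id = "c1", mrna_id = "g1", score_p = 0.05,
                   stringsAsFactors = FALSE)
  mc <- data.frame(mirna_id = "m1", circ_id = "c1", stringsAsFactors = FALSE)
  mg <- data.frame(mirna_id = "m1", mrna_id = "g1", stringsAsFactors = FALSE)
  dirs <- c(c1 = "down", m1 = "up", g1 = "down")
  net <- build_cernet(fp, mc, mg, dirs)
  expect_equal(nrow(net$triplets), 1L)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$edges$relation, c("sponges", "targets", "ceRNA"))
})

test_that("direction coherence rejects same-direction miRNA partners", {
  fp <- data.frame(circ_id = "c1", mrna_id = "g1", score_p = 0.05,
                   stringsAsFactors = FALSE)
  mc <- data.frame(mirna_id = "m1", circ_id = "c1", stringsAsFactors = FALSE)
  mg <- data.frame(mirna_id = "m1", mrna_id = "g1", stringsAsFactors = FALSE)
  both_up <- build_cernet(fp, mc, mg, c(c1 = "up", m1 = "up", g1 = "down"))
  expect_equal(nrow(both_up$triplets), 0L)
  expect_error(build_cernet(fp, mc, mg, c(c1 = "up", g1 = "down")),
               "m1")
})

test_that("network export is deterministic and round-trips edges", {
  fp <- data.frame(circ_id = c("c1", "c2"), mrna_id = c("g1", "g2"),
                   score_p = c(0.02, 0.04), stringsAsFactors = FALSE)
  mc <- data.frame(mirna_id = c("m1", "m2"), circ_id = c("c1", "c2"),
                   stringsAsFactors = FALSE)
  mg <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
                   stringsAsFactors = FALSE)
  dirs <- c(c1 = "down", c2 = "up", m1 = "up", m2 = "down",
            g1 = "down", g2 = "up")
  net <- build_cernet(fp, mc, mg, dirs)
  d <- file.path(tempdir(), "netout")
  paths <- export_network(net, d)
  expect_equal(length(readLines(paths["sif"])), nrow(net$edges))
  back <- utils::read.delim(paths["edges"], stringsAsFactors = FALSE)
  expect_equal(back, net$edges)
  # empty network: header-only tables, empty SIF
  net0 <- build_cernet(fp[0, ], mc[0, ], mg[0, ], dirs)
  paths0 <- export_network(net0, d, prefix = "empty")
  expect_equal(length(readLines(paths0["sif"])), 0L)
  expect_equal(nrow(utils::read.delim(paths0["nodes"])), 0L)
  unlink(d, recursive = TRUE)
})
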