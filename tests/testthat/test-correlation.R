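# Pearson correlation screening with exact p-values

test_that("cor_pvalue hits the closed-form anchors", {
  expect_equal(cor_pvalue(0, 6), 1)                 # t = 0
  expect_equal(cor_pvalue(1, 6), 0)                 # degenerate
  expect_equal(cor_pvalue(-1, 6), 0)
  # hand-computable vector: x=(1..6), y=(2,1,4,3,6,5):
  # sum(dx*dy) = 14.5, sum(dx^2) = sum(dy^2) = 17.5, so r = 29/35
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(stats::cor(x, y), 29 / 35)
  expect_equal(cor_pvalue(29 / 35, 6),
               2 * stats::pt(-(29 / 35) * sqrt(4 / (1 - (29 / 35)^2)), 4))
})

test_that("cor_pvalue is sign-symmetric and decreasing in |r|", {
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(cor_pvalue(rs, 6), cor_pvalue(-rs, 6))
  p <- cor_pvalue(rs, 6)
  expect_true(all(diff(p) < 0))
  expect_error(cor_pvalue(0.5, 2), "n >= 3")
})

test_that("t-based p agrees in rank with an exhaustive permutation null", {
  set.seed(17)
  x <- rnorm(6)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  perm_idx <- all_perms(1:6)
  perm_p <- function(x, y) {
    r_obs <- abs(stats::cor(x, y))
    rs <- vapply(perm_idx, function(p) abs(stats::cor(x, y[p])), 0)
    mean(rs >= r_obs - 1e-12)
  }
  for (i in 1:5) {
    y1 <- rnorm(6); y2 <- x + rnorm(6, sd = 0.3)
    t_ps <- c(cor_pvalue(stats::cor(x, y1), 6),
              cor_pvalue(stats::cor(x, y2), 6))
    e_ps <- c(perm_p(x, y1), perm_p(x, y2))
    expect_equal(order(t_ps), order(e_ps))
  }
})

mk_mat <- function(v, ids, samples = paste0("s", seq_len(ncol(v)))) {
  dimnames(v) <- list(ids, samples)
  v
}

test_that("correlate_pairs screens sign, threshold and order deterministically", {
  set.seed(5)
  base <- rnorm(6)
  A <- mk_mat(rbind(base, -base + rnorm(6, sd = 0.1)), c("a1", "a2"))
  B <- mk_mat(rbind(base + rnorm(6, sd = 0.05), rnorm(6)), c("b1", "b2"))
  neg <- correlate_pairs(A, B, "t", "negative", r_min = 0.8, p_max = 0.05)
  pos <- correlate_pairs(A, B, "t", "positive", r_min = 0.8, p_max = 0.05)
  expect_true(all(neg$r < 0) && all(pos$r > 0))
  expect_true(all(abs(c(neg$r, pos$r)) >= 0.8))
  expect_true(all(c(neg$p, pos$p) < 0.05))
  expect_true("a1 b1" %in% paste(pos$id_a, pos$id_b))
  # unattainable threshold empties the output
  expect_equal(nrow(correlate_pairs(A, B, "t", "negative", r_min = 1.01)), 0L)
  # ordering: p ascending
  both <- correlate_pairs(A, B, "t", "positive", r_min = 0, p_max = 1)
  expect_false(is.unsorted(both$p))
})

test_that("constant rows are dropped, mismatched samples error", {
  A <- mk_mat(rbind(rep(1, 6), rnorm(6)), c("const", "var"))
  B <- mk_mat(matrix(rnorm(6), 1), "b1")
  got <- correlate_pairs(A, B, "t", "negative", r_min = 0, p_max = 1)
  expect_equal(attr(got, "n_dropped"), 1L)
  expect_false("const" %in% got$id_a)
  B2 <- mk_mat(matrix(rnorm(6), 1), "b1", samples = paste0("x", 1:6))
  expect_error(correlate_pairs(A, B2, "t", "negative"), "sample")
})

test_that("planted sponge pairs appear with negative correlation", {
  b <- simulate_bundle(small_config(seed = 41))
  lg <- function(m) log2(normalize_counts(m, "CPM") + 1)
  pairs <- correlate_pairs(lg(b$counts$mirna), lg(b$counts$mrna),
                           "miRNA_mRNA", "negative", r_min = 0, p_max = 1)
  tr <- b$truth$planted_triplets
  key <- paste(tr$mirna_id, tr$mrna_id)
  hit <- match(key, paste(pairs$id_a, pairs$id_b))
  expect_true(all(!is.na(hit)))
  expect_true(all(pairs$r[hit] < 0))
})
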