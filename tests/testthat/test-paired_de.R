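test_that("paired t-test matches closed form and the stats::t.test oracle", {
  r <- paired_t_test(c(1, -1, 1, -1), rep(0, 4))
  expect_identical(r$statistic, 0)
  expect_identical(r$p_value, 1)

  r <- paired_t_test(c(1, 2, 3, 4), rep(0, 4))
  expect_equal(r$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(r$p_value, 0.03046629, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- paired_t_test(x, y)
    o <- t.test(x, y, paired = TRUE)
    expect_equal(r$statistic, unname(o$statistic))
    expect_equal(r$p_value, o$p.value)
    swapped <- paired_t_test(y, x)
    expect_equal(swapped$statistic, -r$statistic)
    expect_equal(swapped$p_value, r$p_value)
  }

  r <- paired_t_test(rep(2, 5), rep(0, 5))  # zero-variance differences
  expect_true(is.na(r$statistic) && is.na(r$p_value))
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:2), "equal length")
})

test_that("exact Wilcoxon p equals full sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_identical(r$p_value, 0.0625)   # 2/32, all differences positive
  expect_true(r$exact)
  expect_identical(r$p_value, oracle_wilcoxon_enum(c(1, 2, 3, 4, 5)))

  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, sd = 5), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, sd = 5), 3)
    r <- wilcoxon_signed_rank(d, rep(0, n))
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_wilcoxon_enum(d))
    expect_equal(r$p_value,
                 suppressWarnings(wilcox.test(d, exact = TRUE)$p.value))
    swapped <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(swapped$p_value, r$p_value)
  }
})

test_that("Wilcoxon handles zeros, ties, and sparse differences", {
  r <- wilcoxon_signed_rank(rep(1, 5), rep(1, 5))  # all-zero differences
  expect_true(is.na(r$p_value))
  expect_identical(r$n_used, 0L)

  r <- wilcoxon_signed_rank(c(3, 1, 0, 0, 0), rep(0, 5))  # 2 < min_nonzero
  expect_true(is.na(r$p_value))

  # ties in |d| -> normal approximation with tie correction, as in
  # stats::wilcox.test(correct = FALSE)
  d <- c(2, -2, 3, 3, -5, 7, 7, 1, -1, 4)
  r <- wilcoxon_signed_rank(d, rep(0, 10))
  expect_false(r$exact)
  o <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(r$p_value, o$p.value)
  expect_equal(r$statistic, unname(o$statistic))

  # beyond the exact cutoff the normal path engages even without ties
  d <- seq(1, 14) * c(1, -1)
  r <- wilcoxon_signed_rank(d, rep(0, 14))
  expect_false(r$exact)
  expect_equal(r$p_value,
               suppressWarnings(wilcox.test(d, exact = FALSE,
                                            correct = FALSE)$p.value))
})

test_that("Benjamini-Hochberg reproduces step-up hand computations", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.05, 5)), rep(0.05, 5))

  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, p.adjust(p, "BH"))          # independent oracle
    expect_true(all(q >= p))
    # re-application never decreases adjusted values (exact idempotence
    # holds only for flat-tailed adjusted vectors; see methods vignette)
    expect_true(all(benjamini_hochberg(q) >= q - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))      # monotone along sorted p
  }

  p <- c(0.01, NA, 0.04)
  q <- benjamini_hochberg(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_differential_expression satisfies its table invariants", {
  set.seed(61)
  d <- make_design(6)
  np <- 50L
  vals_a <- matrix(2^rnorm(np * 6, 20, 2), np)
  vals_b <- matrix(2^rnorm(np * 6, 20, 2), np)
  drop <- matrix(runif(np * 12) < 0.25, np)
  vals <- cbind(vals_a, vals_b)
  vals[drop] <- 0
  m <- make_paired_intensity(vals[, 1:6], vals[, 7:12], d)
  # plant one protein with all-positive large paired differences
  m$values[np, ] <- c(2^c(26, 27, 26.5, 25.8, 26.2, 27.1), rep(2^20, 6))
  tab <- run_differential_expression(m, d)
  expect_identical(nrow(tab), np)
  for (col in c("t_p", "w_p", "prop_p", "q_t", "q_w", "q_prop")) {
    v <- tab[[col]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  }
  expect_true(all(tab$q_t >= tab$t_p, na.rm = TRUE))
  expect_true(all(tab$q_w >= tab$w_p, na.rm = TRUE))
  expect_true(all(tab$min_rank >= 1 & tab$min_rank <= np))
  expect_true(all(tab$min_rank <= tab$rank_t))
  expect_true(all(tab$min_rank <= tab$rank_w))
  expect_true(all(tab$min_rank <= tab$rank_prop))
  expect_identical(tab$min_rank[np], 1L)  # planted extreme shift

  # a protein observed nowhere: all tests undefined, min_rank = n_proteins
  m$values[1, ] <- 0
  tab2 <- run_differential_expression(m, d)
  expect_true(is.na(tab2$t_p[1]) && is.na(tab2$w_p[1]) &&
                is.na(tab2$prop_p[1]))
  expect_identical(tab2$min_rank[1], np)

  # log2p1 transform shrinks effects but keeps the table contract
  tlog <- run_differential_expression(m, d, transform = "log2p1")
  expect_identical(nrow(tlog), np)
  expect_true(all(abs(tlog$effect) <= 40))
})

test_that("min-rank list is a deterministic permutation", {
  set.seed(71)
  d <- make_design(5)
  vals <- matrix(2^rnorm(30 * 10, 20, 2), 30)
  vals[runif(300) < 0.3] <- 0
  m <- make_paired_intensity(vals[, 1:5], vals[, 6:10], d)
  tab <- run_differential_expression(m, d)
  r <- min_rank_list(tab)
  expect_setequal(r, m$protein_ids)
  expect_identical(length(r), 30L)
  expect_identical(r, min_rank_list(tab[sample(30), ]))  # order-invariant

  tab3 <- data.frame(protein_id = c("B", "A", "C"), min_rank = c(2L, 2L, 1L),
                     prop_p = c(0.5, 0.5, 0.1))
  expect_identical(min_rank_list(tab3), c("C", "A", "B"))  # id tie-break
})

test_that("volcano table drops undefined p and maps p to -log10", {
  tab <- data.frame(protein_id = c("A", "B", "C"), effect = c(1, -2, 3),
                    w_p = c(1, 0.01, NA), t_p = c(0.5, 0.5, 0.5),
                    prop_p = c(NA, NA, NA))
  v <- volcano_table(tab, "wilcoxon")
  expect_identical(nrow(v), 2L)
  expect_equal(v$neg_log10_p, c(0, 2))
  expect_identical(nrow(volcano_table(tab, "t")), 3L)
  expect_error(volcano_table(tab, "proportion"), "no defined")
})
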