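test_that("binarize scores any positive intensity as present", {
  m <- make_intensity(matrix(c(0, 1e-9, 5, 0, 0, 2), nrow = 3))
  a <- binarize(m)
  expect_s3_class(a, "appearance_matrix")
  expect_identical(a$protein_ids, m$protein_ids)
  expect_identical(unname(a$bits[, 1]), c(0L, 1L, 1L))
  expect_identical(unname(a$bits[, 2]), c(0L, 0L, 1L))
  all0 <- binarize(make_intensity(matrix(0, 4, 4)))
  expect_true(all(all0$bits == 0L))
})

test_that("presence counts follow the design pairing", {
  d <- make_design(10)
  bits <- matrix(0L, 3, 20,
                 dimnames = list(NULL, c(d$pairs$sample_a, d$pairs$sample_b)))
  bits[1, ] <- 1L                        # everywhere
  bits[2, "subj03_a"] <- 1L              # one subject, condition A only
  a <- appearance_matrix(c("P1", "P2", "P3"), colnames(bits), bits)
  cc <- condition_presence_counts(a, d)
  expect_identical(cc$k_a, c(10L, 1L, 0L))
  expect_identical(cc$k_b, c(10L, 0L, 0L))
  expect_identical(attr(cc, "n_subjects"), 10L)

  a_small <- appearance_matrix("P1", "subj01_a", matrix(1L))
  expect_error(condition_presence_counts(a_small, d), "absent from matrix")

  extra <- appearance_matrix("P1", c(colnames(bits), "orphan"),
                             cbind(bits[1, , drop = FALSE], 1L))
  expect_warning(condition_presence_counts(extra, d), "orphan")
})

test_that("tables fixture reproduces printed presence counts", {
  fx <- build_tables_fixture()
  cc <- condition_presence_counts(fx$appearance, fx$design)
  expect_identical(cc$k_a[cc$protein_id == "Q16678"], 9L)
  expect_identical(cc$k_b[cc$protein_id == "Q16678"], 0L)
  expect_identical(cc$k_b[cc$protein_id == "P28330"], 6L)
  expect_identical(sum(fx$appearance$bits), 112L)
})

test_that("proportion z-test matches printed p-values and handles degeneracy", {
  # frozen printed values, verified externally before freezing
  cases <- list(list(k = 9, p = 5.23e-5), list(k = 6, p = 3.41e-3),
                list(k = 5, p = 9.82e-3), list(k = 4, p = 2.53e-2))
  for (cs in cases)
    expect_equal(signif(proportion_z_test(cs$k, 10, 0, 10)$p_value, 3), cs$p)

  r <- proportion_z_test(5, 10, 5, 10)
  expect_identical(r$z, 0)
  expect_identical(r$p_value, 1)
  r <- proportion_z_test(10, 10, 10, 10)  # pooled frequency 1
  expect_identical(c(r$z, r$p_value), c(0, 1))
  r <- proportion_z_test(0, 10, 0, 10)
  expect_identical(c(r$z, r$p_value), c(0, 1))

  expect_error(proportion_z_test(1, 0, 0, 10), ">= 1")
  expect_error(proportion_z_test(11, 10, 0, 10), "k <= n")
})

test_that("proportion z-test is symmetric and monotone", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    a <- proportion_z_test(k1, n1, k2, n2)
    b <- proportion_z_test(k2, n2, k1, n1)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$z, -b$z)
  }
  p_seq <- vapply(1:10, function(k) proportion_z_test(k, 10, 0, 10)$p_value, 0)
  expect_true(all(diff(p_seq) < 0))
})

test_that("unique detection applies the >= ceil(fraction*n) + exclusivity rule", {
  fx <- build_tables_fixture()
  u <- detect_unique_proteins(fx$appearance, fx$design, min_fraction = 0.4)
  expect_identical(sum(u$condition == "orbital"), 5L)
  expect_identical(sum(u$condition == "abdominal"), 18L)
  expect_true(all(u$n_present >= 4L))
  # multiset of p-values at 3 significant figures, as printed
  expect_identical(as.vector(table(signif(u$p_value, 3))),
                   c(1L, 3L, 9L, 10L))
  expect_identical(sort(unique(signif(u$p_value, 3))),
                   c(5.23e-5, 3.41e-3, 9.82e-3, 2.53e-2))
  # sorted by descending fraction then id; q-values BH-consistent
  expect_true(all(diff(u$fraction) <= 0))
  expect_true(all(u$q_value >= u$p_value))
  expect_identical(u$protein_id[1], "Q16678")

  d <- make_design(10)
  bits <- matrix(0L, 2, 20,
                 dimnames = list(NULL, c(d$pairs$sample_a, d$pairs$sample_b)))
  bits[1, 1:3] <- 1L            # 3 of 10: below the 4-patient threshold
  bits[2, 1:10] <- 1L           # all of A ...
  bits[2, 11] <- 1L             # ... but present once in B: not exclusive
  a <- appearance_matrix(c("P1", "P2"), colnames(bits), bits)
  expect_identical(nrow(detect_unique_proteins(a, d)), 0L)
  # at a lower threshold the 3/10 protein appears: monotone superset
  u2 <- detect_unique_proteins(a, d, min_fraction = 0.3)
  expect_identical(u2$protein_id, "P1")
})

test_that("lowering min_fraction never removes unique records", {
  set.seed(23)
  sim <- generate_paired_proteome(synthetic_config(n_proteins = 300,
                                                   n_shifted = 5, seed = 23))
  a <- binarize(sim$intensities)
  prev <- character()
  for (f in c(0.9, 0.6, 0.4, 0.2)) {
    ids <- detect_unique_proteins(a, sim$design, min_fraction = f)$protein_id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("per-sample counts equal a brute-force recount", {
  set.seed(5)
  bits <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8)
  a <- appearance_matrix(sprintf("P%d", 1:8), sprintf("S%d", 1:12), bits)
  counts <- per_sample_protein_counts(a)
  brute <- integer(12)
  for (j in 1:12) for (i in 1:8) brute[j] <- brute[j] + bits[i, j]
  expect_identical(unname(counts), brute)
  expect_identical(sum(counts), sum(bits))
  ident <- appearance_matrix(c("a", "b", "c"), c("x", "y", "z"), diag(3))
  expect_identical(unname(per_sample_protein_counts(ident)), rep(1L, 3))
  expect_identical(unname(per_sample_protein_counts(
    appearance_matrix("p", c("s1", "s2"), matrix(0L, 1, 2)))), c(0L, 0L))
})
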