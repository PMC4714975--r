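test_that("D50 matches closed forms", {
  # 10 clones x 10 copies: C = 5, D50 = 50
  t <- make_table(sprintf("AAA%03d", 1:10), rep(10, 10))
  expect_equal(d50(t), 50)
  # one clone at 60 + 40 singles: r1 alone >= J/2, C = 1
  t <- make_table(sprintf("CCC%03d", 1:41), c(60, rep(1, 40)))
  expect_equal(d50(t), 100 / 41)
  # single clonotype
  expect_equal(d50(make_table("AAATTT", 7)), 100)
  # invariance under copy rescaling
  t1 <- make_table(sprintf("GGG%03d", 1:7), c(40, 20, 10, 5, 3, 1, 1))
  t2 <- t1; t2$copies <- t2$copies * 13L
  expect_equal(d50(t1), d50(t2))
  expect_error(d50(make_table(character(0), integer(0))), "empty")
})

test_that("D50 stays in (0, 100] and hits 50 for uniform even-S tables", {
  set.seed(51)
  for (k in 1:20) {
    S <- sample(seq(2, 40, by = 2), 1)
    t <- make_table(sprintf("AA%04d", 1:S), rep(sample(1:20, 1), S))
    expect_equal(d50(t), 50)
  }
  for (k in 1:20) {
    S <- sample(1:30, 1)
    t <- make_table(sprintf("AA%04d", 1:S), sample(1:50, S, replace = TRUE))
    v <- d50(t)
    expect_gt(v, 0); expect_lte(v, 100)
  }
})

test_that("pairwise sharing is set arithmetic on distinct peptides", {
  a <- make_table(sprintf("A%05d", 1:4), c(100, 1, 1, 1),
                  cdr3_aa = c("X", "Y", "Z", "W"))
  b <- make_table(sprintf("C%05d", 1:2), c(5, 5), cdr3_aa = c("X", "Q"))
  s <- pairwise_sharing(a, b)
  expect_equal(unname(s), c(25, 50))
  expect_equal(unname(pairwise_sharing(a, a)), c(100, 100))
  d <- make_table(sprintf("G%05d", 1:3), c(1, 1, 1), cdr3_aa = c("M", "N", "O"))
  expect_equal(unname(pairwise_sharing(a, d)), c(0, 0))
})

test_that("normalized VH usage counts each unique sequence once", {
  t <- make_table(c("AAA111", "AAA222", "AAA333", "CCC111"),
                  c(100, 1, 1, 2),
                  v_call = c("V1-55", "V1-55", "V1-55", "V6-6"))
  u <- vh_usage(t, normalized = TRUE)
  expect_equal(u$pct[u$v_call == "V1-55"], 75)
  expect_equal(u$pct[u$v_call == "V6-6"], 25)
  expect_equal(sum(u$pct), 100, tolerance = 1e-9)
  # copy-weighted mode differs
  raw <- vh_usage(t, normalized = FALSE)
  expect_equal(raw$pct[raw$v_call == "V1-55"], 100 * 102 / 104)
  # chromosomal ordering covers every V in the reference
  ref <- test_ref()
  t2 <- make_table("AAA111", 5, v_call = "V11-1")
  u2 <- vh_usage(t2, ref = ref)
  expect_equal(u2$v_call, segments_of(ref, "V")$id)
  expect_equal(sum(u2$pct), 100)
})

test_that("N-insertion profiles bin unique sequences and sum to 100", {
  t <- make_table(sprintf("A%05d", 1:6), c(50, 1, 1, 1, 1, 1),
                  n_total = c(0, 1, 2, 4, 6, 9))
  np <- n_insertion_profile(t)
  expect_equal(np$pct, c(1, 2, 1, 1, 1) / 6 * 100)
  expect_equal(sum(np$pct), 100, tolerance = 1e-9)
  t0 <- make_table(sprintf("A%05d", 1:5), rep(3, 5), n_total = 0)
  expect_equal(n_insertion_profile(t0)$pct[1], 100)
})

test_that("convergence entropy matches closed forms and bounds", {
  # one recombination: E = 0, first bin
  t1 <- make_table("AAACCC", 10, cdr3_aa = "KR")
  ce <- convergence_entropy(t1)
  expect_equal(ce$peptides$entropy, 0)
  expect_equal(ce$bins$fraction_peptides, c(1, 0, 0, 0))
  # two recombinations at 50/50: E = 1
  t2 <- make_table(c("AAACCC", "AAGCCC"), c(5, 5), cdr3_aa = "KR")
  expect_equal(convergence_entropy(t2)$peptides$entropy, 1)
  # four recombinations at 25% each: E = 2, third bin
  t4 <- make_table(c("AAACCC", "AAGCCC", "AAACCG", "AAACCT"), rep(25, 4),
                   cdr3_aa = "KR")
  ce4 <- convergence_entropy(t4)
  expect_equal(ce4$peptides$entropy, 2)
  expect_equal(ce4$bins$fraction_peptides, c(0, 0, 1, 0))
  # unequal frequencies: 0 <= E <= log2(n); copy-weighting matters
  t5 <- make_table(c("AAACCC", "AAGCCC"), c(90, 10), cdr3_aa = "KR")
  e5 <- convergence_entropy(t5)$peptides$entropy
  expect_lt(e5, 1); expect_gt(e5, 0)
  expect_equal(convergence_entropy(t5, weighting = "unique")$peptides$entropy, 1)
  # bin fractions always sum to 1
  expect_equal(sum(ce4$bins$fraction_peptides), 1)
  expect_equal(sum(ce4$bins$fraction_reads), 1)
})

test_that("entropy respects its log2(n) upper bound on random tables", {
  set.seed(53)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    t <- make_table(sprintf("A%04d%d", k, 1:n), sample(1:50, n, replace = TRUE),
                    cdr3_aa = "PEP")
    ce <- convergence_entropy(t)
    expect_gte(ce$peptides$entropy, 0)
    expect_lte(ce$peptides$entropy, log2(ce$peptides$n_recombinations) + 1e-12)
  }
})

test_that("mutation summary thresholds, rate and eligibility", {
  t <- make_table(sprintf("A%05d", 1:4), rep(10, 4),
                  mutation_count = c(0, 1, 2, 5))
  ms <- mutation_summary(t)
  expect_equal(unname(ms$pct), c(75, 50, 25))
  expect_equal(ms$rate_per_1e4, 1e4 * 8 / (4 * 129))
  # unmutated table
  t0 <- make_table(sprintf("A%05d", 1:3), rep(10, 3), mutation_count = 0)
  expect_equal(unname(mutation_summary(t0)$pct), c(0, 0, 0))
  expect_equal(mutation_summary(t0)$rate_per_1e4, 0)
  # records below the copy floor do not enter
  t2 <- make_table(sprintf("A%05d", 1:2), c(4, 10), mutation_count = c(9, 1))
  ms2 <- mutation_summary(t2)
  expect_equal(ms2$n_eligible, 1)
  expect_equal(unname(ms2$pct[1]), 100)
  # nothing eligible: absent, not zero
  t3 <- make_table("AAACCC", 2, mutation_count = 3L)
  expect_true(all(is.na(mutation_summary(t3)$pct)))
})

test_that("isotype-by-mutation strata behave and sum to 100", {
  t <- make_table(sprintf("A%05d", 1:6), rep(10, 6),
                  mutation_count = c(0, 0, 1, 2, 4, 7),
                  isotype = c("IgM", "IgM", "IgM", "IgG1", "IgM", "IgA"))
  ib <- isotype_by_mutation(t)
  for (s in unique(ib$by_stratum$stratum))
    expect_equal(sum(ib$by_stratum$pct[ib$by_stratum$stratum == s]), 100)
  expect_equal(ib$switched_pct$pct_switched[ib$switched_pct$stratum == "0"], 0)
  expect_equal(ib$switched_pct$pct_switched[ib$switched_pct$stratum == ">=5"], 100)
  # all-IgM table: switched fraction 0 everywhere
  tm <- make_table(sprintf("A%05d", 1:3), rep(10, 3),
                   mutation_count = c(0, 1, 6), isotype = "IgM")
  expect_true(all(isotype_by_mutation(tm)$switched_pct$pct_switched == 0))
})

test_that("switching applied only to mutated clones shows up as enrichment", {
  set.seed(55)
  n <- 200
  mut <- rbinom(n, 1, 0.4)
  iso <- ifelse(mut == 1 & runif(n) < 0.5, "IgG1", "IgM")
  t <- make_table(sprintf("A%05d", 1:n), rep(10, n),
                  mutation_count = mut, isotype = iso)
  ib <- isotype_by_mutation(t)
  mv <- ib$mutated_vs_not
  sw_mut <- unique(mv$pct_switched[mv$group == "mutated"])
  sw_non <- unique(mv$pct_switched[mv$group == "non_mutated"])
  expect_gt(sw_mut, sw_non)
  expect_equal(sw_non, 0)
})
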