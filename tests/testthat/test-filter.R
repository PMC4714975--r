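test_that("V relatedness thresholds are strict at both boundaries", {
  # identical 250-nt pair: 250 matched > 200, 0 mismatches < 6
  g <- build_vh_relatedness(make_v_pair_ref(250, 0))
  expect_true(are_related(g, "Va", "Vb"))
  # exactly 6 mismatches over ~250 matched: not related (< 6 is strict)
  g <- build_vh_relatedness(make_v_pair_ref(256, 6))
  expect_false(are_related(g, "Va", "Vb"))
  # 5 mismatches: related
  g <- build_vh_relatedness(make_v_pair_ref(256, 5))
  expect_true(are_related(g, "Va", "Vb"))
  # alignment covering only ~150 nt: not related (> 200 required)
  g <- build_vh_relatedness(make_v_pair_ref(150, 0))
  expect_false(are_related(g, "Va", "Vb"))
  # exactly 200 matched bases: still not related (strict >)
  g <- build_vh_relatedness(make_v_pair_ref(200, 0))
  expect_false(are_related(g, "Va", "Vb"))
})

test_that("related-read collapsing removes only sub-5% minors", {
  ref2 <- make_v_pair_ref(250, 3)
  graph <- build_vh_relatedness(ref2)
  set.seed(41)
  cdr3 <- rand_dna(30)
  cdr3_var <- cdr3
  substr(cdr3_var, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(cdr3, 7, 7))[1]

  # 40 of 1000 (4%) on a related V, CDR3 within 1 mismatch: removed
  t1 <- make_table(c(cdr3, cdr3_var), c(1000, 40), v_call = c("Va", "Vb"))
  out <- collapse_related_reads(t1, graph)
  expect_equal(nrow(out), 1)
  expect_equal(out$copies, 1000)
  expect_equal(cnt(out), 1000)  # removed counts are dropped, not merged

  # 60 of 1000 (6%): retained
  t2 <- make_table(c(cdr3, cdr3_var), c(1000, 60), v_call = c("Va", "Vb"))
  expect_equal(nrow(collapse_related_reads(t2, graph)), 2)

  # exactly 5%: retained (strictly-below rule)
  t3 <- make_table(c(cdr3, cdr3_var), c(1000, 50), v_call = c("Va", "Vb"))
  expect_equal(nrow(collapse_related_reads(t3, graph)), 2)

  # identical CDR3 but unrelated V genes: both retained
  ref3 <- make_v_pair_ref(250, 40)
  g3 <- build_vh_relatedness(ref3)
  t4 <- make_table(c(cdr3, cdr3), c(1000, 10), v_call = c("Va", "Vb"))
  expect_equal(nrow(collapse_related_reads(t4, g3)), 2)

  # same V call is trivially related: sequencing-error variant removed
  t5 <- make_table(c(cdr3, cdr3_var), c(1000, 10), v_call = "Va")
  expect_equal(nrow(collapse_related_reads(t5, graph)), 1)
})

test_that("singleton CDR3s are removed, two-copy CDR3s kept", {
  t <- make_table(c("AAACCC", "GGGTTT", "ACACAC"), c(1, 2, 7))
  out <- remove_singletons(t)
  expect_equal(sort(out$cdr3_nt), c("ACACAC", "GGGTTT"))
  # a CDR3 seen once in each of two records (total 2) survives
  t2 <- make_table(c("AAACCC", "AAACCC"), c(1, 1), v_call = c("V1-1", "V1-2"))
  expect_equal(nrow(remove_singletons(t2)), 2)
  empty <- t[0, , drop = FALSE]
  expect_equal(nrow(remove_singletons(empty)), 0)
})

test_that("contamination_p matches closed forms and the summation oracle", {
  # lambda = 1: P(X >= 1) = 1 - exp(-1)
  expect_equal(contamination_p(1, 8000, 1 / 8000), 1 - exp(-1), tolerance = 1e-12)
  # no source reads: no contamination possible
  expect_equal(contamination_p(1, 0, 1 / 8000), 0)
  set.seed(43)
  for (k in 1:60) {
    n <- sample(1:20, 1); N <- sample(0:100000, 1)
    expect_lt(abs(contamination_p(n, N, 1 / 8000) -
                    poisson_tail_oracle(n, N, 1 / 8000)), 1e-12)
  }
  expect_error(contamination_p(0, 10, 1 / 8000))
  expect_error(contamination_p(1, 10, 2))
})

test_that("printed-formula variant omits the k=0 term", {
  # summing from k=1 makes P(X >= 1) identically 1
  expect_equal(contamination_p(1, 8000, 1 / 8000, printed_formula = TRUE), 1)
  expect_equal(contamination_p(5, 8000, 1 / 8000, printed_formula = TRUE),
               contamination_p(5, 8000, 1 / 8000) + dpois(0, 1), tolerance = 1e-12)
})

test_that("contamination_p is monotone in n and N", {
  p_n <- vapply(1:15, contamination_p, numeric(1), N = 8000, mu = 1 / 8000)
  expect_true(all(diff(p_n) < 0))
  p_N <- vapply(c(0, 10, 100, 1000, 10000), function(N)
    contamination_p(3, N, 1 / 8000), numeric(1))
  expect_true(all(diff(p_N) > 0))
})

test_that("cross-contamination filter retains real clones and removes low-count sharers", {
  big <- make_table(c("AAACCCGGG", "TTTGGGCCC"), c(8000, 50), sample_id = "S1")
  small <- make_table(c("AAACCCGGG", "CACACAGGG"), c(1, 30), sample_id = "S2")
  res <- filter_cross_contamination(list(S1 = big, S2 = small))
  rep_s2 <- res$report[res$report$sample_id == "S2" &
                         res$report$cdr3_nt == "AAACCCGGG", ]
  # n=1 against N=8000 (lambda 1): P ~ 0.63 -> removed
  expect_equal(rep_s2$verdict, "REMOVE")
  expect_false("AAACCCGGG" %in% res$samples$S2$cdr3_nt)
  # n=8000 in S1 against N=1: vastly above contamination -> retained
  rep_s1 <- res$report[res$report$sample_id == "S1" &
                         res$report$cdr3_nt == "AAACCCGGG", ]
  expect_equal(rep_s1$verdict, "RETAIN")
  # CDR3s unique to one sample are never tested
  expect_false("TTTGGGCCC" %in% res$report$cdr3_nt)
  expect_true("TTTGGGCCC" %in% res$samples$S1$cdr3_nt)
  # n=50 vs N=8000: far beyond Poisson(1) -> retained
  t50 <- make_table("AAACCCGGG", 50, sample_id = "S3")
  res2 <- filter_cross_contamination(list(S1 = big, S3 = t50))
  expect_equal(res2$report$verdict[res2$report$sample_id == "S3"], "RETAIN")
})

test_that("filter stack order is fixed and counts are non-increasing", {
  ref <- test_ref()
  graph <- build_vh_relatedness(ref)
  set.seed(45)
  t1 <- make_table(replicate(6, rand_dna(30)), c(500, 100, 40, 2, 1, 1),
                   sample_id = "S1")
  t2 <- make_table(replicate(4, rand_dna(30)), c(300, 80, 2, 1),
                   sample_id = "S2")
  res <- apply_artifact_filters(list(S1 = t1, S2 = t2), graph)
  log <- res$log
  expect_equal(rownames(log),
               c("input", "after_collapse", "after_singletons",
                 "after_contamination"))
  for (j in seq_len(ncol(log))) expect_true(all(diff(log[, j]) <= 0))
})
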