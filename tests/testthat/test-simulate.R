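test_that("zero insertion rate yields N-free junctions; zero SHM yields no mutations", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 40, n_insertion_rate = 0, shm_rate = 0,
                         reads_per_sample = 200, seed = 3)
  rep1 <- simulate_repertoire(p, ref)
  expect_true(all(rep1$n_total == 0))
  expect_true(all(rep1$n1 == "" & rep1$n2 == ""))
  expect_true(all(rep1$mutation_count == 0))
  expect_true(all(rep1$mutations == ""))
})

test_that("clonotypes round-trip from germline parts plus mutations", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 60, n_insertion_rate = 2.5,
                         shm_rate = 2e-3, reads_per_sample = 300, seed = 4)
  rep1 <- simulate_repertoire(p, ref)
  seg <- ref$segments
  get_seq <- function(id) seg$sequence[match(id, seg$id)]
  amp_start <- 151 - 45  # CDR2 mark minus the FR2 primer offset
  for (i in seq_len(nrow(rep1))) {
    r <- rep1[i, ]
    v <- get_seq(r$v_id); j <- get_seq(r$j_id); cseq <- get_seq(r$isotype)
    d_part <- if (!is.na(r$d_id)) {
      d <- get_seq(r$d_id)
      substr(d, r$d5_del + 1, nchar(d) - r$d3_del)
    } else ""
    germ <- paste0(substr(v, amp_start, nchar(v) - r$v_del), r$p2, r$n2,
                   d_part, r$n1, r$p1,
                   substr(j, r$j_del + 1, nchar(j)), cseq)
    if (nzchar(r$mutations)) {
      chars <- strsplit(germ, "")[[1]]
      for (m in strsplit(r$mutations, ";")[[1]]) {
        f <- strsplit(m, "[:>]")[[1]]  # pos, from, to, class
        expect_identical(chars[as.integer(f[1])], f[2])
        chars[as.integer(f[1])] <- f[3]
      }
      germ <- paste(chars, collapse = "")
    }
    expect_identical(germ, r$full_nt)
  }
  # CDR3 is in the V reading frame and matches the recorded boundaries
  expect_true(all((rep1$cdr3_end - rep1$cdr3_start + 1) %% 3 == 0))
  expect_identical(substr(rep1$full_nt, rep1$cdr3_start, rep1$cdr3_end),
                   rep1$cdr3_nt)
})

test_that("mutations are enriched in DGYW/WRCH hotspot contexts", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 1500, shm_rate = 5e-3, hotspot_bias = 10,
                         reads_per_sample = 3000, seed = 9)
  rep1 <- simulate_repertoire(p, ref)
  muts <- unlist(strsplit(rep1$mutations[nzchar(rep1$mutations)], ";"))
  cls <- vapply(strsplit(muts, ":"), `[`, "", 3)
  obs_hot <- mean(cls != "none")
  # expected background: base-pair fraction of hotspot context in the
  # analysis window, averaged over V segments (brute-force weighting)
  vs <- segments_of(ref, "V")
  base_frac <- mean(vapply(vs$sequence, function(s)
    mean(hotspot_class(s, 151:279) != "none"), numeric(1)))
  expect_gt(obs_hot, base_frac)
  # with bias 10 the enrichment should be substantial, not marginal
  expect_gt(obs_hot, base_frac + 0.15)
})

test_that("emitted runs are byte-identical under a fixed seed", {
  ref <- test_ref()
  bs <- design_barcodes(2, seed = 2)
  p <- simulation_params(n_clonotypes = 10, reads_per_sample = 60,
                         seq_error_rate = 0.01, seed = 5)
  reps <- list(S1 = simulate_repertoire(p, ref, seed = 11))
  d1 <- tempfile(); d2 <- tempfile()
  emit_run(reps, bs, p, d1)
  emit_run(reps, bs, p, d2)
  expect_identical(readLines(file.path(d1, "R1.fastq")),
                   readLines(file.path(d2, "R1.fastq")))
  expect_identical(readLines(file.path(d1, "R2.fastq")),
                   readLines(file.path(d2, "R2.fastq")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a single clonotype of abundance 50 yields 50 read pairs", {
  ref <- test_ref()
  bs <- design_barcodes(1, seed = 2)
  p <- simulation_params(n_clonotypes = 1, reads_per_sample = 50, seed = 6)
  rep1 <- simulate_repertoire(p, ref)
  expect_equal(rep1$abundance, 50)
  d <- tempfile()
  run <- emit_run(list(S1 = rep1), bs, p, d)
  fq <- read_fastq(run$fwd)
  expect_length(fq$id, 50)
  unlink(d, recursive = TRUE)
})

test_that("injected per-base error rate is recovered within 20%", {
  ref <- test_ref()
  bs <- design_barcodes(1, seed = 2)
  p <- simulation_params(n_clonotypes = 40, reads_per_sample = 400,
                         seq_error_rate = 0.01, shm_rate = 0, seed = 8)
  rep1 <- simulate_repertoire(p, ref)
  d <- tempfile()
  run <- emit_run(list(S1 = rep1), bs, p, d)
  fq <- read_fastq(run$fwd)
  clone <- sub("^S1:(C\\d+):.*$", "\\1", fq$id)
  truth <- substr(rep1$full_nt[match(clone, rep1$clone_id)], 1, p$read_length)
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 fq$seq, truth)
  rate <- sum(mism) / sum(nchar(truth))   # ~1e5 bases
  expect_gt(rate, 0.008); expect_lt(rate, 0.012)
  unlink(d, recursive = TRUE)
})

test_that("amplicons that cannot overlap are refused", {
  ref <- test_ref()
  bs <- design_barcodes(1, seed = 2)
  p <- simulation_params(n_clonotypes = 5, reads_per_sample = 25,
                         read_length = 150, seed = 6)
  rep1 <- simulate_repertoire(p, ref)   # amplicons ~330 nt >> 2*150-6
  expect_error(emit_run(list(S1 = rep1), bs, p, tempfile()), "unmergeable")
})

test_that("invalid parameters are rejected", {
  expect_error(simulation_params(shm_rate = 1.5))
  expect_error(simulation_params(abundance_law = 0))
  expect_error(simulation_params(hotspot_bias = 0.5))
  expect_error(simulation_params(seq_error_rate = -0.1))
})
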