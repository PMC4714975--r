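# Builds reads directly from germline parts so expected calls, junctions
# and mutations are known by construction.

build_read <- function(ref, v_id, d_id, j_id, c_id, v_del = 0, d5 = 0, d3 = 0,
                       j_del = 0, n2 = "", n1 = "") {
  seg <- ref$segments
  gs <- function(id) seg$sequence[match(id, seg$id)]
  v <- gs(v_id); d <- gs(d_id); j <- gs(j_id); cc <- gs(c_id)
  paste0(substr(v, 106, nchar(v) - v_del), n2,
         substr(d, d5 + 1, nchar(d) - d3), n1,
         substr(j, j_del + 1, nchar(j)), cc)
}

test_that("segment assignment recovers the constructed rearrangement", {
  ref <- test_ref()
  s <- build_read(ref, "V11-2", "D2", "J1", "IgM",
                  v_del = 2, d5 = 1, d3 = 1, j_del = 2, n2 = "CC", n1 = "AT")
  calls <- assign_segments(s, ref)
  expect_equal(calls$v_call, "V11-2")
  expect_equal(calls$j_call, "J1")
  expect_equal(calls$c_call, "IgM")
  b <- migrate_cdr3(s, calls, ref)
  expect_true(b$cdr3_start < b$cdr3_end)
  junc <- decompose_junction(s, calls$v_call, calls$j_call,
                             b$cdr3_start, b$cdr3_end, ref)
  expect_equal(junc$d_call, "D2")
})

test_that("reads with no J-matching stretch are unmappable", {
  ref <- test_ref()
  v <- segments_of(ref, "V")$sequence[1]
  set.seed(31)
  s <- paste0(substr(v, 106, 288))  # V only, then nothing
  calls <- assign_segments(substr(s, 1, 120), ref)  # V fragment alone
  expect_null(calls)
  expect_null(assign_segments(rand_dna(200), ref))
})

test_that("CDR3 translation and frame handling are correct", {
  expect_equal(translate_nt("GCTCGTGGTGCTTAT"), "ARGAY")
  expect_true(is.na(translate_nt("GCTCGTGGTGCTTA")))   # not a codon multiple
  expect_equal(translate_nt("TGTTGA"), "C*")            # stop retained
})

test_that("a frame-shifted junction is flagged non-productive", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 5, reads_per_sample = 25,
                         n_insertion_rate = 4, seed = 17)
  rep1 <- simulate_repertoire(p, ref)
  r <- rep1[which(rep1$n_total > 0)[1], ]
  # delete one junction base: CDR3 length drops to a non-multiple of 3
  chars <- strsplit(r$full_nt, "")[[1]]
  s <- paste(chars[-(r$cdr3_start + 10L)], collapse = "")
  calls <- assign_segments(s, ref)
  b <- migrate_cdr3(s, calls, ref)
  expect_false(b$productive)
  expect_equal(b$cdr3_aa, "")
})

test_that("junction decomposition recovers deletions, P and N additions", {
  ref <- test_ref()
  seg <- ref$segments
  v <- seg$sequence[seg$id == "V3-1"]; j <- seg$sequence[seg$id == "J2"]
  # untrimmed V and J ends with explicit P additions and known N segments
  p2 <- substr(revcomp(substr(v, nchar(v) - 1, nchar(v))), 1, 2)
  p1 <- substr(revcomp(substr(j, 1, 2)), 2, 2)
  s <- paste0(substr(v, 106, nchar(v)), p2, "GG",
              substr(seg$sequence[seg$id == "D1"], 2, 15), "T", p1,
              j, seg$sequence[seg$id == "IgA"])
  calls <- assign_segments(s, ref)
  b <- migrate_cdr3(s, calls, ref)
  junc <- decompose_junction(s, calls$v_call, calls$j_call,
                             b$cdr3_start, b$cdr3_end, ref)
  expect_equal(junc$v_del, 0)
  expect_equal(junc$j_del, 0)
  expect_equal(junc$p2, p2)
  expect_equal(junc$p1, p1)
  expect_equal(junc$n2, "GG")
  expect_equal(junc$n1, "T")
  expect_equal(junc$n_total, 3)
  expect_equal(calls$c_call, "IgA")
})

test_that("abutting germline ends give zero N", {
  ref <- test_ref()
  s <- build_read(ref, "V5-1", "D3", "J3", "IgM", v_del = 3, d5 = 2,
                  d3 = 2, j_del = 3)
  calls <- assign_segments(s, ref)
  b <- migrate_cdr3(s, calls, ref)
  junc <- decompose_junction(s, calls$v_call, calls$j_call,
                             b$cdr3_start, b$cdr3_end, ref)
  expect_equal(junc$n_total, 0)
})

test_that("junction concatenation reproduces the read exactly", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 80, n_insertion_rate = 3,
                         reads_per_sample = 400, seed = 19)
  rep1 <- simulate_repertoire(p, ref)
  tab <- annotate_sequences(rep1$full_nt, ref, copies = rep1$abundance)
  seg <- ref$segments
  gs <- function(id) seg$sequence[match(id, seg$id)]
  # walk the CDR3 left to right: v-tail, p2, n2, d, n1, p1, j-head must
  # tile it exactly in that order
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    v <- gs(r$v_call); j <- gs(r$j_call)
    cdr3 <- r$cdr3_nt
    expect_part <- function(off, part) {
      if (nchar(part) > 0)
        expect_identical(substr(cdr3, off + 1, off + nchar(part)), part)
      off + nchar(part)
    }
    off <- 0
    off <- expect_part(off, substr(v, seg$cdr3_start[match(r$v_call, seg$id)],
                                   nchar(v) - r$v_del))
    off <- expect_part(off, r$p2)
    off <- off + r$n2_len
    if (!is.na(r$d_call)) {
      d <- gs(r$d_call)
      off <- expect_part(off, substr(d, r$d5_del + 1, nchar(d) - r$d3_del))
    }
    off <- off + r$n1_len
    off <- expect_part(off, r$p1)
    off <- expect_part(off, substr(j, r$j_del + 1,
                                   seg$cdr3_end[match(r$j_call, seg$id)]))
    expect_equal(off, nchar(cdr3))
  }
})

test_that("mutation calling respects window and copy threshold", {
  ref <- test_ref()
  s0 <- build_read(ref, "V6-1", "D2", "J2", "IgM", v_del = 1, j_del = 1)
  chars <- strsplit(s0, "")[[1]]
  flip <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  # two substitutions inside [cdr2_start, cdr3_start) = [46, 175), one in CDR3
  for (pp in c(60, 120, 180)) chars[pp] <- flip(chars[pp])
  s <- paste(chars, collapse = "")
  calls <- assign_segments(s, ref)
  expect_equal(calls$v_call, "V6-1")
  b <- migrate_cdr3(s, calls, ref)
  m10 <- call_mutations(s, calls, b, ref, copies = 10)
  expect_true(m10$evaluated)
  expect_equal(m10$count, 2)
  expect_equal(m10$mutations$seq_pos, c(60, 120))
  # more-than-4-copies rule: 4 copies excluded, 5 included
  expect_false(call_mutations(s, calls, b, ref, copies = 4)$evaluated)
  expect_true(call_mutations(s, calls, b, ref, copies = 5)$evaluated)
})

test_that("hotspot context classification matches the IUPAC motifs", {
  # AGCT matches DGYW (A=D, G, C=Y, T=W) at the C
  expect_equal(hotspot_class("AAGCTA", 4), "DGYW")
  # TACA matches WRCH (T=W, A=R, C, A=H) at the C
  expect_equal(hotspot_class("GTACAG", 4), "WRCH")
  expect_equal(hotspot_class("CCCCCC", 3), "none")
})

test_that("zero-SHM simulations produce zero called mutations at any copy depth", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 60, shm_rate = 0,
                         n_insertion_rate = 3, reads_per_sample = 400, seed = 23)
  rep1 <- simulate_repertoire(p, ref)
  tab <- annotate_sequences(rep1$full_nt, ref, copies = rep(10L, nrow(rep1)))
  expect_true(all(tab$mutation_count == 0))
})

test_that("error-free simulated reads annotate 100% concordantly with truth", {
  ref <- test_ref()
  p <- simulation_params(n_clonotypes = 150, n_insertion_rate = 2.5,
                         reads_per_sample = 1000, seed = 29)
  rep1 <- simulate_repertoire(p, ref)
  tab <- annotate_sequences(rep1$full_nt, ref, copies = rep1$abundance)
  expect_equal(nrow(tab), nrow(rep1))
  key <- match(tab$sequence, rep1$full_nt)
  expect_false(any(is.na(key)))
  expect_equal(tab$v_call, rep1$v_id[key])
  expect_equal(tab$j_call, rep1$j_id[key])
  expect_equal(tab$cdr3_nt, rep1$cdr3_nt[key])
  expect_equal(tab$isotype, rep1$isotype[key])
  expect_equal(tab$n_total, rep1$n_total[key])
  # D calls agree wherever the canonical truth keeps >= 5 matched nt
  expect_equal(tab$d_call, rep1$d_id[key])
})
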