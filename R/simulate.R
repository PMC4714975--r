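# Synthetic V(D)J repertoire and sequencing-run simulator.
#
# A clonotype is assembled as
#   V[amp_start .. len-v_del] + p2 + n2 + D[d5_del+1 .. len-d3_del] +
#   n1 + p1 + J[j_del+1 .. len] + C
# where the amplicon starts 45 nt upstream of CDR2 (the forward primer
# anchor in FR2), p1/p2 are <= 2 nt palindromic mirrors of the untrimmed
# segment end and n1/n2 are nontemplated additions whose lengths follow a
# geometric law. J trimming is chosen so the CDR3 stays in the V reading
# frame. The truth table records the *canonical* (template-maximal)
# junction decomposition of the realized sequence — the decomposition a
# perfect annotator would return — because alternative decompositions of
# the same nucleotide string are indistinguishable by any method.

AMP_OFFSET <- 45L  # amplicon starts this many nt upstream of CDR2

#' Simulation parameters
#'
#' Bundles every knob of the repertoire/sequencing simulator with
#' validation. Defaults describe a single adult-like sample: a few hundred
#' clonotypes under a Zipf clone-size law, adult-level N additions, and an
#' error-free sequencer (error injection is opt-in).
#'
#' @param n_clonotypes Number of distinct clonotypes per repertoire.
#' @param abundance_law Zipf exponent of the clone-size distribution (> 0).
#' @param n_insertion_rate Mean N-segment length per junction (geometric
#'   law); 0 emulates Tdt-negative neonatal repertoires where every
#'   junction is N-free.
#' @param shm_rate Substitutions per bp in the V region upstream of CDR3.
#' @param hotspot_bias Relative mutation rate multiplier at DGYW/WRCH
#'   hotspot positions (>= 1); per-position rates are renormalized so the
#'   average equals `shm_rate`.
#' @param switch_prob Per-clonotype probability of a class-switched
#'   (non-IgM/IgD) isotype.
#' @param seq_error_rate Per-base sequencing error rate.
#' @param read_length Read length of both mates, nt.
#' @param reads_per_sample Target total reads per repertoire.
#' @param seed Integer seed.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_clonotypes = 200, abundance_law = 1.2,
                              n_insertion_rate = 2.5, shm_rate = 0,
                              hotspot_bias = 5, switch_prob = 0.1,
                              seq_error_rate = 0, read_length = 250,
                              reads_per_sample = 2500, seed = 1) {
  p <- list(n_clonotypes = as.integer(n_clonotypes),
            abundance_law = abundance_law,
            n_insertion_rate = n_insertion_rate, shm_rate = shm_rate,
            hotspot_bias = hotspot_bias, switch_prob = switch_prob,
            seq_error_rate = seq_error_rate,
            read_length = as.integer(read_length),
            reads_per_sample = as.integer(reads_per_sample),
            seed = as.integer(seed))
  stopifnot(p$n_clonotypes >= 1, p$abundance_law > 0,
            p$n_insertion_rate >= 0, p$shm_rate >= 0, p$shm_rate <= 1,
            p$switch_prob >= 0, p$switch_prob <= 1,
            p$seq_error_rate >= 0, p$seq_error_rate <= 1,
            p$hotspot_bias >= 1, p$read_length >= 50)
  structure(p, class = "simulation_params")
}

geom_len <- function(n, mean_len) {
  if (mean_len <= 0) return(integer(n))
  rgeom(n, prob = 1 / (1 + mean_len))
}

# Per-position mutation probabilities over the analysis window (CDR2
# start to CDR3 start on the germline V), hotspot-weighted and
# renormalized so the mean equals shm_rate. Mutations are modeled inside
# this window only: it is the stretch the mutation analysis reads, so the
# rate parameter keeps a direct per-bp interpretation there.
mutation_profile <- function(v_seq, shm_rate, hotspot_bias) {
  win_v <- V_CDR2_START:(V_CDR3_START - 1L)         # germline window on V
  hot <- hotspot_class(v_seq, win_v)
  w <- ifelse(hot == "none", 1, hotspot_bias)
  p <- shm_rate * w / mean(w)
  list(p = pmin(p, 0.9), hot = hot)
}

#' Simulate a ground-truth repertoire
#'
#' Draws `n_clonotypes` V(D)J rearrangements with exonuclease trimming,
#' palindromic (P) and nontemplated (N) additions, frame-consistent CDR3s,
#' hotspot-biased somatic hypermutation, class switching, and Zipf clone
#' sizes. All full-length sequences are distinct.
#'
#' @param params A [simulation_params()] object.
#' @param ref A `germline_reference`.
#' @param seed Seed; defaults to `params$seed`.
#' @return data.frame of class `true_repertoire`, one row per clonotype,
#'   with the assembled sequence, canonical junction decomposition, CDR3
#'   coordinates, mutation list and expected abundance.
#' @export
simulate_repertoire <- function(params, ref, seed = params$seed) {
  vs <- segments_of(ref, "V"); ds <- segments_of(ref, "D")
  js <- segments_of(ref, "J"); cs <- segments_of(ref, "C")
  switched_iso <- setdiff(cs$id, c("IgM", "IgD"))
  unswitched <- intersect(c("IgM", "IgD"), cs$id)
  amp_start <- V_CDR2_START - AMP_OFFSET
  cdr3_pos <- V_CDR3_START - amp_start + 1L
  profiles <- lapply(seq_len(nrow(vs)), function(i)
    mutation_profile(vs$sequence[i], params$shm_rate, params$hotspot_bias))
  names(profiles) <- vs$id

  draw_isotype <- function() {
    if (runif(1) < params$switch_prob && length(switched_iso))
      sample(switched_iso, 1L)
    else if (length(unswitched) > 1L)
      sample(unswitched, 1L, prob = c(0.9, 0.1))
    else (unswitched[1] %||% cs$id[1])
  }

  draw_one <- function(id) {
    iso <- draw_isotype()
    c_seq <- cs$sequence[match(iso, cs$id)]
    for (try in 1:30) {
      v <- vs[sample.int(nrow(vs), 1L), ]; d <- ds[sample.int(nrow(ds), 1L), ]
      j <- js[sample.int(nrow(js), 1L), ]
      v_len <- nchar(v$sequence); d_len <- nchar(d$sequence)
      v_del <- sample(0:6, 1L, prob = dgeom(0:6, 0.35))
      d5_del <- sample(0:4, 1L, prob = dgeom(0:4, 0.4))
      d3_del <- sample(0:4, 1L, prob = dgeom(0:4, 0.4))
      p2 <- if (v_del == 0L) {
        k <- sample(0:2, 1L, prob = c(0.5, 0.3, 0.2))
        substr(revcomp(substr(v$sequence, v_len - 1L, v_len)), 1L, k)
      } else ""
      nl <- geom_len(2L, params$n_insertion_rate)
      n2 <- random_dna(nl[1]); n1 <- random_dna(nl[2])
      v_part <- substr(v$sequence, amp_start, v_len - v_del)
      d_part <- substr(d$sequence, d5_del + 1L, d_len - d3_del)
      pre_j <- (9L - v_del) + nchar(p2) + nchar(n2) + nchar(d_part) + nchar(n1)
      # choose j_del (and possibly p1) so the CDR3 length is a multiple of 3
      p1 <- ""
      if (runif(1) < 0.5) {
        k <- sample(0:2, 1L, prob = c(0.5, 0.3, 0.2))
        p1_cand <- substring(revcomp(substr(j$sequence, 1L, 2L)), 3L - k, 2L)
        if ((pre_j + nchar(p1_cand) + J_CDR3_END) %% 3L == 0L) {
          p1 <- p1_cand; j_del <- 0L
        } else j_del <- (pre_j + J_CDR3_END) %% 3L
      } else {
        r <- (pre_j + J_CDR3_END) %% 3L
        j_del <- r + 3L * sample(0:1, 1L)
      }
      j_part <- substr(j$sequence, j_del + 1L, nchar(j$sequence))
      full <- paste0(v_part, p2, n2, d_part, n1, p1, j_part, c_seq)
      cdr3_len <- (9L - v_del) + nchar(p2) + nchar(n2) + nchar(d_part) +
        nchar(n1) + nchar(p1) + (J_CDR3_END - j_del)
      cdr3_nt <- substr(full, cdr3_pos, cdr3_pos + cdr3_len - 1L)
      aa <- translate_nt(cdr3_nt)
      if ((!is.na(aa) && !grepl("*", aa, fixed = TRUE)) || try == 30L) {
        return(list(v = v$id, d = d$id, j = j$id, full = full, isotype = iso,
                    cdr3_start = cdr3_pos, cdr3_end = cdr3_pos + cdr3_len - 1L))
      }
    }
  }

  with_seed(seed, {
    clones <- vector("list", params$n_clonotypes)
    seen <- character(0)
    for (i in seq_len(params$n_clonotypes)) {
      repeat {
        cl <- draw_one(i)
        if (!(cl$full %in% seen)) break
      }
      seen <- c(seen, cl$full)
      clones[[i]] <- cl
    }

    rows <- lapply(seq_along(clones), function(i) {
      cl <- clones[[i]]
      full <- cl$full
      # somatic hypermutation in the V stretch upstream of CDR3
      mut_str <- ""; mut_n <- 0L
      if (params$shm_rate > 0) {
        prof <- profiles[[cl$v]]
        cdr2_pos <- AMP_OFFSET + 1L                 # CDR2 start on amplicon
        win <- cdr2_pos:(cl$cdr3_start - 1L)        # analysis window
        hit <- win[runif(length(win)) < prof$p]
        if (length(hit)) {
          chars <- strsplit(full, "")[[1]]
          recs <- character(length(hit))
          for (k in seq_along(hit)) {
            p <- hit[k]
            from <- chars[p]
            to <- sample(setdiff(DNA_BASES, from), 1L)
            chars[p] <- to
            recs[k] <- sprintf("%d:%s>%s:%s", p, from, to, prof$hot[p - cdr2_pos + 1L])
          }
          full <- paste(chars, collapse = "")
          mut_str <- paste(recs, collapse = ";")
          mut_n <- length(hit)
        }
      }
      junc <- decompose_junction(full, cl$v, cl$j, cl$cdr3_start, cl$cdr3_end, ref)
      cdr3_nt <- substr(full, cl$cdr3_start, cl$cdr3_end)
      aa <- translate_nt(cdr3_nt)
      iso <- cl$isotype
      data.frame(clone_id = sprintf("C%04d", i), v_id = cl$v,
                 d_id = junc$d_call %||% NA_character_, j_id = cl$j,
                 v_del = junc$v_del, d5_del = junc$d5_del,
                 d3_del = junc$d3_del, j_del = junc$j_del,
                 p2 = junc$p2, n2 = junc$n2, n1 = junc$n1, p1 = junc$p1,
                 n_total = nchar(junc$n1) + nchar(junc$n2),
                 full_nt = full, cdr3_nt = cdr3_nt,
                 cdr3_aa = ifelse(is.na(aa), "", aa),
                 cdr3_start = cl$cdr3_start, cdr3_end = cl$cdr3_end,
                 cdr2_start = AMP_OFFSET + 1L,
                 isotype = iso, mutation_count = mut_n, mutations = mut_str,
                 productive = !is.na(aa) && !grepl("\\*", aa),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    # Zipf clone sizes, largest first over a shuffled clone order
    w <- seq_len(nrow(tab))^(-params$abundance_law)
    tab$abundance <- pmax(1L, as.integer(round(params$reads_per_sample * w / sum(w))))
    class(tab) <- c("true_repertoire", "data.frame")
    tab
  })
}

#' Emit a barcoded paired-end sequencing run from simulated repertoires
#'
#' The forward read covers the 5' end of each amplicon; the reverse read
#' starts with the sample barcode followed by the reverse-complemented 3'
#' end (constant region first), as sequenced. Per-base errors are injected
#' at `seq_error_rate`; qualities follow a two-component model (high ~Q35,
#' low ~Q15) with low qualities enriched at injected-error positions.
#'
#' @param repertoires Named list mapping sample id to a `true_repertoire`.
#' @param barcodes A `barcode_set` with at least one code per sample.
#' @param params A [simulation_params()] object.
#' @param dir Output directory for `R1.fastq`, `R2.fastq` and truth tables.
#' @param min_overlap Minimum mate overlap the amplicon geometry must
#'   allow; amplicons violating it abort the run.
#' @param seed Seed; defaults to `params$seed + 1`.
#' @return List with paths `fwd`, `rev`, `truth` (read-level truth
#'   data.frame) and `barcode_map`.
#' @export
emit_run <- function(repertoires, barcodes, params, dir,
                     min_overlap = 30, seed = params$seed + 1L) {
  stopifnot(length(repertoires) >= 1,
            length(barcodes$barcodes) >= length(repertoires))
  if (is.null(names(repertoires)))
    names(repertoires) <- paste0("S", seq_along(repertoires))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rl <- params$read_length
  bc_len <- barcodes$length
  payload <- rl - bc_len

  ids <- character(0); fwd <- character(0); rev <- character(0)
  truth_sample <- character(0); truth_clone <- character(0)
  for (si in seq_along(repertoires)) {
    rep_tab <- repertoires[[si]]
    sname <- names(repertoires)[si]
    bc <- barcodes$barcodes[si]
    lens <- nchar(rep_tab$full_nt)
    ov <- rl + payload - lens
    if (any(ov < min_overlap))
      stop(sprintf("amplicon of %d nt leaves overlap < %d; unmergeable by construction",
                   max(lens), min_overlap))
    idx <- rep(seq_len(nrow(rep_tab)), rep_tab$abundance)
    amp <- rep_tab$full_nt[idx]
    f <- substr(amp, 1L, rl)
    r <- paste0(bc, revcomp(substr(amp, nchar(amp) - payload + 1L, nchar(amp))))
    n <- length(idx)
    ids <- c(ids, sprintf("%s:%s:%05d", sname, rep_tab$clone_id[idx], seq_len(n)))
    fwd <- c(fwd, f); rev <- c(rev, r)
    truth_sample <- c(truth_sample, rep(sname, n))
    truth_clone <- c(truth_clone, rep_tab$clone_id[idx])
  }

  with_seed(seed, {
    inject <- function(seqs) {
      err_pos <- vector("list", length(seqs))
      if (params$seq_error_rate > 0) {
        for (i in seq_along(seqs)) {
          chars <- strsplit(seqs[i], "")[[1]]
          hit <- which(runif(length(chars)) < params$seq_error_rate)
          if (length(hit)) {
            for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
            seqs[i] <- paste(chars, collapse = "")
          }
          err_pos[[i]] <- hit
        }
      }
      qual <- vector("list", length(seqs))
      for (i in seq_along(seqs)) {
        L <- nchar(seqs[i])
        q <- sample(33:40, L, replace = TRUE)
        low <- runif(L) < params$seq_error_rate / 2
        if (length(err_pos[[i]]))
          low[err_pos[[i]]] <- runif(length(err_pos[[i]])) < 0.7
        q[low] <- sample(10:19, sum(low), replace = TRUE)
        qual[[i]] <- q
      }
      list(seq = seqs, qual = qual)
    }
    fr <- inject(fwd); rr <- inject(rev)
    fwd_path <- file.path(dir, "R1.fastq"); rev_path <- file.path(dir, "R2.fastq")
    write_fastq(list(id = ids, seq = fr$seq, qual = fr$qual), fwd_path)
    write_fastq(list(id = ids, seq = rr$seq, qual = rr$qual), rev_path)
    truth <- data.frame(read_id = ids, sample_id = truth_sample,
                        clone_id = truth_clone, stringsAsFactors = FALSE)
    write.table(truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (sname in names(repertoires))
      write.table(repertoires[[sname]],
                  file.path(dir, paste0("truth_", sname, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    list(fwd = fwd_path, rev = rev_path, truth = truth,
         barcode_map = setNames(barcodes$barcodes[seq_along(repertoires)],
                                names(repertoires)))
  })
}
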