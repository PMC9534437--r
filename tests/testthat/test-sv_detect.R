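# helper: minimal alignment-record rows for signal-extraction tests
mk_aln_row <- function(qname, pos, end, left_clip = 0L, right_clip = 0L,
                       seq = strrep("A", 100), cigar = "100M",
                       read_len = nchar(seq), strand = "+",
                       is_supplementary = FALSE) {
  data.frame(qname = qname, flag = 0L, mapped = TRUE, rname = "locus",
             strand = strand, pos = pos, end = end, mapq = 60L,
             cigar = cigar, left_clip = left_clip,
             right_clip = right_clip, read_len = read_len, seq = seq,
             AS = 0L, NM = 0L, is_secondary = FALSE,
             is_supplementary = is_supplementary,
             mean_read_q = 12, stringsAsFactors = FALSE)
}

test_that("clip signals honour the length threshold and allele
           assignment", {
  big_clip <- strrep("C", 12000)
  body <- strrep("A", 5000)
  aln <- rbind(
    mk_aln_row("r1", 1000, 5999, right_clip = 12000L,
               seq = paste0(body, big_clip),
               cigar = "5000M12000S", read_len = 17000L),
    mk_aln_row("r2", 1000, 5999, right_clip = 50L,
               seq = paste0(body, strrep("C", 50)),
               cigar = "5000M50S", read_len = 5050L),
    mk_aln_row("r3", 1000, 5999, seq = body, cigar = "5000M",
               read_len = 5000L))
  sig <- extract_clips(aln, NULL, min_clip_len = 200L)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$read_id, "r1")
  expect_equal(sig$side, "right")
  expect_equal(sig$anchor, 5999L)
  expect_equal(nchar(sig$clip_seq), 12000L)

  # reads not assigned to an allele are excluded
  part <- structure(list(allele1 = "other", allele2 = character(),
                         unassigned = "r1", single_allele = FALSE),
                    class = "PhasePartition")
  expect_equal(nrow(extract_clips(aln, part, 200L)), 0L)
})

test_that("deletion worked example: printed breakpoint geometry is
           recovered from clipped reads", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  hap <- build_haplotype(locus, haplotype_spec(locus, defs, "*5"))
  reads <- simulate_reads(list(hap), locus, n_reads = 30, pools = "A",
                          seed = 3)
  flt <- filter_reads(align_reads(reads, locus))
  clips <- remap_clips(extract_clips(flt, NULL), locus)
  bp <- cluster_breakpoints(clips)
  expect_equal(nrow(bp), 1L)
  expect_gte(bp$support, 3L)
  sv <- classify_sv(bp, locus)
  expect_equal(sv$kind, "DEL")
  expect_lt(abs(sv$length - 12152L), 6L)
  expect_lt(abs(sv$start - synthetic_events()$deletion[1]), 6L)
})

test_that("duplication worked example: tandem-duplication junction is
           classified with the printed length", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  hap <- build_haplotype(locus, haplotype_spec(locus, defs, "*68"))
  reads <- simulate_reads(list(hap), locus, n_reads = 30, pools = "A",
                          seed = 3)
  flt <- filter_reads(align_reads(reads, locus))
  clips <- remap_clips(extract_clips(flt, NULL), locus)
  sv <- classify_sv(cluster_breakpoints(clips), locus)
  # the hybrid head inside the inserted copy can add a genuine second
  # junction cluster; the duplication itself must be there either way
  dup <- sv[sv$kind == "DUP", ]
  expect_equal(nrow(dup), 1L)
  expect_lt(abs(dup$length - 13680L), 6L)
})

test_that("breakpoint clustering equals a brute-force single-linkage
           oracle and applies the support rule", {
  # support boundary: two reads are not enough, three are
  sig <- function(n) data.frame(
    read_id = sprintf("r%d", seq_len(n)), allele = 1L, type = "split",
    side = NA, anchor = 2027L, clip_seq = NA, pos_a = 2027L,
    pos_b = 14179L, stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_breakpoints(sig(2))), 0L)
  bp3 <- cluster_breakpoints(sig(3))
  expect_equal(nrow(bp3), 1L)
  expect_equal(bp3$support, 3L)

  # jittered signals: one cluster at the median, equal to brute force
  withr::with_seed(5, {
    n <- 30
    ja <- sample(-5:5, n, replace = TRUE)
    jb <- sample(-5:5, n, replace = TRUE)
  })
  jit <- data.frame(read_id = sprintf("r%d", 1:30), allele = 1L,
                    type = "split", side = NA, anchor = 0L,
                    clip_seq = NA, pos_a = 5000L + ja,
                    pos_b = 12000L + jb, stringsAsFactors = FALSE)
  bp <- cluster_breakpoints(jit, tolerance = 20)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$pos_a, as.integer(round(median(5000L + ja))))
  expect_equal(bp$pos_b, as.integer(round(median(12000L + jb))))

  # brute-force oracle: all-pairs single linkage via transitive closure
  adj <- outer(seq_len(30), seq_len(30), Vectorize(function(i, j) {
    abs(jit$pos_a[i] - jit$pos_a[j]) <= 20 &&
      abs(jit$pos_b[i] - jit$pos_b[j]) <= 20
  }))
  reach <- adj
  for (k in 1:30) reach <- reach | (reach %*% reach > 0)
  expect_equal(length(unique(apply(reach, 1, paste, collapse = ""))), 1L)

  # two distant clusters stay separate (and match brute force)
  jit2 <- jit
  jit2$pos_a[16:30] <- jit2$pos_a[16:30] + 1000L
  bp2 <- cluster_breakpoints(jit2, tolerance = 20)
  expect_equal(nrow(bp2), 2L)

  # monotonicity: raising min_support never adds breakpoints
  prev <- Inf
  for (ms in 1:6) {
    nbp <- nrow(cluster_breakpoints(jit2, tolerance = 20,
                                    min_support = ms))
    expect_lte(nbp, prev)
    prev <- nbp
  }
})

test_that("SV classification maps junction orientation to DEL/DUP with
           the printed lengths", {
  locus <- fixture_locus()
  bp <- data.frame(allele = 1L, pos_a = 2027L, pos_b = 14179L,
                   support = 37L)
  sv <- classify_sv(bp, locus)
  expect_equal(sv$kind, "DEL")
  expect_equal(sv$length, 12152L)

  bp2 <- data.frame(allele = 2L, pos_a = 24709L, pos_b = 11029L,
                    support = 6L)
  sv2 <- classify_sv(bp2, locus)
  expect_equal(sv2$kind, "DUP")
  expect_equal(sv2$length, 13680L)

  # a duplication spanning parts of both genes is a hybrid insertion
  bp3 <- data.frame(allele = 2L, pos_a = 18000L, pos_b = 6000L,
                    support = 5L)
  expect_equal(classify_sv(bp3, locus)$kind, "HYBRID_INS")

  # zero-length junctions are dropped
  bp0 <- data.frame(allele = 1L, pos_a = 100L, pos_b = 100L,
                    support = 5L)
  expect_equal(nrow(classify_sv(bp0, locus)), 0L)
})

test_that("allele-reference construction splices events and replays the
           simulated truth", {
  locus <- fixture_locus()
  ref <- as.character(locus$sequence)
  L <- nchar(ref)
  ev <- synthetic_events()

  # no events: identity
  id <- build_allele_reference(locus, NULL)
  expect_identical(as.character(id$sequence), ref)
  expect_equal(nrow(id$segment_map), 1L)

  # deletion: shorter by 12,152, two segments, replay oracle
  del <- data.frame(allele = 1L, kind = "DEL", start = ev$deletion[1],
                    end = ev$deletion[2], length = 12152L, support = 3L)
  a1 <- build_allele_reference(locus, del)
  expect_equal(length(a1$sequence), L - 12152L)
  expect_equal(nrow(a1$segment_map), 2L)
  expect_identical(as.character(a1$sequence),
                   paste0(substr(ref, 1, ev$deletion[1] - 1),
                          substr(ref, ev$deletion[2] + 1, L)))
  defs <- fixture_defs()
  h5 <- build_haplotype(locus, haplotype_spec(locus, defs, "*5"))
  expect_identical(as.character(a1$sequence), as.character(h5$sequence))

  # duplication: longer by 13,680, three segments, middle is copy 2
  dup <- data.frame(allele = 2L, kind = "DUP", start = ev$duplication[1],
                    end = ev$duplication[2], length = 13680L,
                    support = 3L)
  a2 <- build_allele_reference(locus, dup)
  expect_equal(length(a2$sequence), L + 13680L)
  expect_equal(nrow(a2$segment_map), 3L)
  expect_equal(a2$segment_map$copy_index, c(1L, 2L, 1L))
  expect_identical(as.character(a2$sequence),
                   paste0(substr(ref, 1, ev$duplication[2]),
                          substr(ref, ev$duplication[1],
                                 ev$duplication[2]),
                          substr(ref, ev$duplication[2] + 1, L)))

  # overlapping events are fatal
  both <- rbind(del, data.frame(allele = 1L, kind = "DEL", start = 14000L,
                                end = 15000L, length = 1001L,
                                support = 3L))
  expect_error(build_allele_reference(locus, both), "overlapping")
})
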