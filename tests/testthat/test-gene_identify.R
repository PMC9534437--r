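test_that("segmentation DP equals brute-force enumeration over all
           labelings", {
  withr::with_seed(41, {
    for (case in 1:20) {
      k <- sample(3:12, 1)
      diag_pos <- sort(sample(50:950, k))
      mism_gene <- sample(1:2, k, replace = TRUE)
      penalty <- sample(c(1, 3, 5), 1)
      prof <- make_profiles(diag_pos, mism_gene)
      segs <- segment_and_assign(prof, switch_penalty = penalty)
      # cost matrix: labelling position i with gene g costs 1 when g is
      # the mismatching source there
      cost <- cbind(as.integer(mism_gene == 1L),
                    as.integer(mism_gene == 2L))
      expect_equal(dp_cost(diag_pos, cost, segs, penalty,
                           prof$genes),
                   brute_force_segmentation(cost, penalty))
    }
  })
})

test_that("pure copies give one segment; swapping the sources swaps
           labels and nothing else", {
  locus <- fixture_mini()
  grefs <- gene_references(locus)
  g2 <- grefs[[2]]
  prof <- mismatch_profiles(c(1L, length(g2)), g2, grefs)
  expect_equal(nrow(prof$profiles[[names(grefs)[2]]]), 0L)
  expect_gt(nrow(prof$profiles[[names(grefs)[1]]]), 20L)
  segs <- segment_and_assign(prof)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$source, names(grefs)[2])
  expect_lte(segs$mismatches_assigned, segs$mismatches_other)

  # symmetry: swapped references swap the winning label
  prof_sw <- mismatch_profiles(c(1L, length(g2)), g2, rev(grefs))
  segs_sw <- segment_and_assign(prof_sw)
  expect_equal(nrow(segs_sw), 1L)
  expect_equal(segs_sw$source, names(grefs)[2])

  gc <- reconstruct_hybrids(segs)
  expect_equal(gc$label, names(grefs)[2])
  expect_length(gc$switches, 0L)
})

test_that("a 50:50 chimera is segmented with the boundary inside the
           true switch gap", {
  locus <- fixture_mini()
  grefs <- gene_references(locus)
  glen <- Biostrings::width(grefs)[1]
  sw <- 400L
  chim <- Biostrings::xscat(Biostrings::subseq(grefs[[1]], 1, sw),
                            Biostrings::subseq(grefs[[2]], sw + 1, glen))
  prof <- mismatch_profiles(c(1L, glen), chim, grefs)
  segs <- segment_and_assign(prof)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$source, names(grefs))
  # boundary falls between the last gene-1 diagnostic before the switch
  # and the first gene-2 diagnostic after it
  expect_lt(abs(segs$end[1] - sw), 60L)

  gc <- reconstruct_hybrids(segs, c(1L, glen))
  expect_match(gc$label, "hybrid")
  expect_length(gc$switches, 1L)

  # an infinite switch penalty forces the single global least-mismatch
  # assignment
  segs_inf <- segment_and_assign(prof, switch_penalty = 1e9)
  expect_equal(nrow(segs_inf), 1L)

  # adjacent same-source segments merge
  two <- rbind(segs[1, ], segs[1, ])
  two$start <- c(1L, 201L); two$end <- c(200L, 400L)
  merged <- reconstruct_hybrids(two)
  expect_equal(nrow(merged$segments), 1L)
})

test_that("gene-copy location counts deletions, duplications and the
           unedited locus correctly", {
  locus <- fixture_mini()
  grefs <- gene_references(locus)
  ref <- as.character(locus$sequence)
  g <- locus$genes

  # unedited: two copies
  ivs <- locate_gene_copies(Biostrings::DNAString(ref), grefs)
  expect_equal(nrow(ivs), 2L)

  # gene-1 deletion: one copy, and it is the gene-2 slot
  del_seq <- paste0(substr(ref, 1, g$start[1] - 101L),
                    substr(ref, g$end[1] + 101L, nchar(ref)))
  ivs_del <- locate_gene_copies(Biostrings::DNAString(del_seq), grefs)
  expect_equal(nrow(ivs_del), 1L)

  # tandem duplication of the gene-2 region: three copies (flanks wide
  # enough that adjacent copies stay beyond the merge gap)
  dup_seq <- paste0(substr(ref, 1, g$end[2] + 400L),
                    substr(ref, g$start[2] - 400L, g$end[2] + 400L),
                    substr(ref, g$end[2] + 401L, nchar(ref)))
  ivs_dup <- locate_gene_copies(Biostrings::DNAString(dup_seq), grefs)
  expect_equal(nrow(ivs_dup), 3L)
})

test_that("copy variants are scored from the probability track and
           exclude paralog bases", {
  locus <- fixture_mini()
  grefs <- gene_references(locus)
  glen <- Biostrings::width(grefs)[1]
  # copy = gene 2 with one planted variant
  g2c <- strsplit(as.character(grefs[[2]]), "")[[1]]
  vpos <- 555L
  g1c <- strsplit(as.character(grefs[[1]]), "")[[1]]
  newb <- setdiff(c("A", "C", "G", "T"), c(g2c[vpos], g1c[vpos]))[1]
  g2c[vpos] <- newb
  copy <- Biostrings::DNAString(paste(g2c, collapse = ""))
  prof <- mismatch_profiles(c(1L, glen), copy, grefs)
  segs <- segment_and_assign(prof, tie_break = names(grefs)[2])
  gc <- reconstruct_hybrids(segs, c(1L, glen))
  expect_equal(gc$label, names(grefs)[2])

  vars <- score_copy_variants(gc, prof, rep(0.99, glen), grefs)
  expect_equal(nrow(vars), 1L)
  expect_equal(vars$pos, vpos)
  expect_equal(vars$alt, newb)
  expect_equal(vars$qual, 20, tolerance = 1e-6)  # -10 log10(1 - 0.99)

  # p = 1 caps at Q60
  vars60 <- score_copy_variants(gc, prof, rep(1, glen), grefs)
  expect_equal(vars60$qual, 60)

  # a pure chimera has no variants: every within-segment difference is
  # the other source's paralog base, not a variant
  sw <- 400L
  chim <- Biostrings::xscat(Biostrings::subseq(grefs[[1]], 1, sw),
                            Biostrings::subseq(grefs[[2]], sw + 1, glen))
  profc <- mismatch_profiles(c(1L, glen), chim, grefs)
  segsc <- segment_and_assign(profc)
  gcc <- reconstruct_hybrids(segsc, c(1L, glen))
  varsc <- score_copy_variants(gcc, profc, rep(0.99, glen), grefs)
  expect_equal(nrow(varsc), 0L)
})

test_that("in-place hybrid replacement is recovered purely from the
           small-variant segmentation (no clip signal)", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  hap <- build_haplotype(locus, haplotype_spec(locus, defs, "*13"))
  reads <- simulate_reads(list(hap), locus, n_reads = 25, pools = "A",
                          seed = 12)
  flt <- filter_reads(align_reads(reads, locus))

  # there is no junction evidence at all
  clips <- remap_clips(extract_clips(flt, NULL), locus)
  expect_equal(nrow(cluster_breakpoints(clips)), 0L)

  # yet segmentation of the gene-2 slot finds the hybrid and its switch
  cons <- first_consensus(reads, build_allele_reference(locus, NULL))
  grefs <- gene_references(locus)
  ivs <- locate_gene_copies(cons, grefs)
  expect_equal(nrow(ivs), 2L)
  iv <- as.integer(ivs[2, ])
  prof <- mismatch_profiles(iv, cons, grefs)
  gc <- reconstruct_hybrids(segment_and_assign(prof), iv)
  expect_match(gc$label, "hybrid")
  expect_equal(gc$sources, locus$genes$gene)
  d13 <- defs[defs$allele == "*13", ]
  expect_gte(gc$switch_local[1], d13$switch_start)
  expect_lte(gc$switch_local[1], d13$switch_end)
})
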