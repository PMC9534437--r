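test_that("haplotype construction replays byte-exactly (oracle)", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  ref <- as.character(locus$sequence)
  L <- nchar(ref)
  ev <- synthetic_events()
  g <- locus$genes

  # *5 whole-gene deletion
  h5 <- build_haplotype(locus, haplotype_spec(locus, defs, "*5"))
  expect_identical(as.character(h5$sequence),
                   paste0(substr(ref, 1, ev$deletion[1] - 1),
                          substr(ref, ev$deletion[2] + 1, L)))
  expect_equal(h5$applied_events$kind, "DEL")
  expect_equal(h5$applied_events$length, 12152L)

  # *4 SNV set applied by hand
  h4 <- build_haplotype(locus, haplotype_spec(locus, defs, "*4"))
  chars <- strsplit(ref, "")[[1]]
  v4 <- defs[defs$allele == "*4", ]$variants[[1]]
  chars[v4$pos + g$start[1] - 1L] <- v4$alt
  expect_identical(as.character(h4$sequence), paste(chars, collapse = ""))

  # *68 hybrid duplication-insertion: oracle spliced by hand
  h68 <- build_haplotype(locus, haplotype_spec(locus, defs, "*68"))
  sw <- 800L  # centre of the *68 switch region 600-1000
  hyb <- paste0(substr(ref, g$start[1], g$start[1] + sw - 1L),
                substr(ref, g$start[2] + sw, g$end[2]))
  copy <- paste0(substr(ref, ev$duplication[1], g$start[2] - 1L), hyb,
                 substr(ref, g$end[2] + 1L, ev$duplication[2]))
  expect_identical(as.character(h68$sequence),
                   paste0(substr(ref, 1, ev$duplication[2]), copy,
                          substr(ref, ev$duplication[2] + 1L, L)))
  expect_equal(h68$applied_events$kind, "DUP")
  expect_equal(h68$applied_events$length, 13680L)

  # *13 in-place hybrid replacement: same length, no DEL/DUP event
  h13 <- build_haplotype(locus, haplotype_spec(locus, defs, "*13"))
  sw13 <- 1600L
  hyb13 <- paste0(substr(ref, g$start[1], g$start[1] + sw13 - 1L),
                  substr(ref, g$start[2] + sw13, g$end[2]))
  expect_identical(as.character(h13$sequence),
                   paste0(substr(ref, 1, g$start[2] - 1L), hyb13,
                          substr(ref, g$end[2] + 1L, L)))
  expect_equal(length(h13$sequence), L)
  expect_equal(h13$applied_events$kind, "HYBRID_REPLACE")

  # empty directive list is the identity
  h1 <- build_haplotype(locus, list(name = "id"))
  expect_identical(as.character(h1$sequence), ref)

  # invalid constructions are fatal
  expect_error(build_haplotype(locus, list(
    name = "x", directives = list(
      list(type = "replace_with_hybrid", gene = g$gene[2],
           switch = 5000L)))), "switch")
  expect_error(build_haplotype(locus, list(
    name = "x", directives = list(
      list(type = "delete", start = 2027L, end = 14178L),
      list(type = "delete", start = 14000L, end = 15000L)))),
    "overlapping")
})

test_that("Cas9 fragmentation follows the cut sites and duplicated
           recognition sites also cut", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  cuts <- default_cut_sites()
  h1 <- build_haplotype(locus, haplotype_spec(locus, defs, "*1"))

  frA <- simulate_fragments(h1, cuts$A, "A")
  expect_equal(nrow(frA), 1L)   # two flanking cuts, one full-locus fragment
  frB <- simulate_fragments(h1, cuts$B, "B")
  expect_equal(nrow(frB), 2L)   # middle cut splits between the genes

  # the duplication copies the middle recognition site: pool B gains a cut
  # and no full-length gene-2 fragment remains
  h68 <- build_haplotype(locus, haplotype_spec(locus, defs, "*68"))
  frB68 <- simulate_fragments(h68, cuts$B, "B")
  expect_equal(nrow(frB68), 3L)
  expect_warning(simulate_fragments(h1, integer(), "A"), "no cut sites")
})

test_that("error injection matches its nominal rates", {
  frag <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb, no homopolymers

  # zero-noise identity
  r0 <- add_errors(frag, error_model(0, 0, 0), seed = 1)
  expect_identical(r0$sequence, frag)
  expect_equal(length(r0$qualities), nchar(frag))

  # mismatch fraction within 3 sigma of the binomial expectation
  em <- error_model(mismatch = 0.05, insertion = 0, deletion = 0)
  r <- add_errors(frag, em, seed = 7)
  n <- nchar(frag)
  observed <- sum(r$edits$op == "mismatch")
  expect_lt(abs(observed - n * 0.05), 3 * sqrt(n * 0.05 * 0.95))

  # homopolymer indel multiplier: deletion rate inside a long run vs the
  # non-homopolymer background, counted over replicates
  run <- strrep("A", 30)
  body <- paste(rep("ACGT", 500), collapse = "")
  seqc <- paste0(body, run, body)
  emh <- error_model(mismatch = 0, insertion = 0, deletion = 0.02,
                     homopolymer_multiplier = 4)
  run_pos <- (nchar(body) + 1):(nchar(body) + 30)
  in_run <- 0L; out_run <- 0L
  for (s in 1:200) {
    ed <- add_errors(seqc, emh, seed = s)$edits
    dels <- ed$pos[ed$op == "del"]
    in_run <- in_run + sum(dels %in% run_pos)
    out_run <- out_run + sum(!dels %in% run_pos)
  }
  rate_in <- in_run / (30 * 200)
  rate_out <- out_run / ((nchar(seqc) - 30) * 200)
  expect_gt(rate_in / rate_out, 2.5)
  expect_lt(rate_in / rate_out, 6)
})

test_that("read simulation is deterministic and hits target coverage", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  h <- build_haplotype(locus, haplotype_spec(locus, defs, "*1"))

  r1 <- simulate_reads(list(h), locus, n_reads = 10, seed = 5)
  r2 <- simulate_reads(list(h), locus, n_reads = 10, seed = 5)
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(as.character(Biostrings::quality(r1)),
                   as.character(Biostrings::quality(r2)))
  r3 <- simulate_reads(list(h), locus, n_reads = 10, seed = 6)
  expect_false(identical(as.character(r1), as.character(r3)))

  # mean depth close to the analytic expectation (error-free, pool A:
  # every read is the full 27,900 bp excision fragment)
  r <- simulate_reads(list(h), locus, n_reads = 30, pools = "A",
                      em = error_model(0, 0, 0), seed = 1,
                      truncation_prob = 0)
  depth <- sum(Biostrings::width(r)) / length(locus$sequence)
  expected <- 30 * 27900 / 28206
  expect_lt(abs(depth - expected) / expected, 0.1)
})

test_that("background reads do not map to the locus", {
  locus <- fixture_locus()
  bg <- simulate_background(200, seed = 3)
  expect_equal(length(simulate_background(0)), 0L)
  aln <- align_reads(bg, locus)
  pri <- aln[aln$mapped & !aln$is_secondary & !aln$is_supplementary, ]
  expect_lt(nrow(pri) / 200, 0.01)
})

test_that("truth files round-trip the applied variants and events", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  haps <- list(build_haplotype(locus, haplotype_spec(locus, defs, "*5")),
               build_haplotype(locus, haplotype_spec(locus, defs, "*4")))
  reads <- simulate_reads(haps, locus, n_reads = 100, seed = 2)
  out <- tempfile("truth")
  files <- write_truth(haps, reads, out)
  expect_length(files, 4L)
  expect_true(all(file.exists(files)))

  fq <- read_reads(files[["fastq"]])
  expect_equal(length(fq), 100L)
  expect_identical(as.character(fq), as.character(reads))

  v <- vcfR::read.vcfR(files[["vcf"]], verbose = FALSE)
  fix <- vcfR::getFIX(v)
  truth_v <- haps[[2]]$applied_variants
  expect_equal(as.integer(fix[, "POS"]), truth_v$pos)
  expect_equal(unname(fix[, "REF"]), truth_v$ref)
  expect_equal(unname(fix[, "ALT"]), truth_v$alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  expect_true(all(gt[, 1] == "0|1"))  # all *4 variants on haplotype 2

  bed <- rtracklayer::import(files[["bed"]])
  expect_equal(length(bed), 1L)
  expect_equal(GenomicRanges::start(bed), haps[[1]]$applied_events$start)
  expect_equal(GenomicRanges::end(bed), haps[[1]]$applied_events$end)
})
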