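test_that("zero-noise consensus reproduces the haplotype exactly,
           including variants and indels", {
  locus <- fixture_mini()
  g1 <- locus$genes[1, ]
  ref <- as.character(locus$sequence)
  # haplotype with SNVs and a 1 bp deletion
  snv_pos <- g1$start + c(100L, 400L)
  vars <- data.frame(
    pos = snv_pos,
    ref = substring(ref, snv_pos, snv_pos),
    alt = ifelse(substring(ref, snv_pos, snv_pos) == "A", "G", "A"))
  hap <- build_haplotype(locus, list(name = "h", variants = vars))
  reads <- perfect_reads(hap$sequence, 20)
  aref <- build_allele_reference(locus, NULL)
  cons <- first_consensus(reads, aref)
  expect_identical(as.character(cons$sequence),
                   as.character(hap$sequence))
  expect_equal(length(cons$probability), length(cons$sequence))
  expect_true(all(cons$probability > 0 & cons$probability <= 1))
  expect_equal(unique(cons$support), 20L)
})

test_that("majority columns carry the Laplace-smoothed probability", {
  withr::with_seed(31, ref <- rand_dna(1000))
  ref_chars <- strsplit(ref, "")[[1]]
  # one column with a 12 A / 8 G split
  p <- 500L
  reads <- vapply(1:20, function(i) {
    ch <- ref_chars
    ch[p] <- if (i <= 12) "A" else "G"
    paste(ch, collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("r%02d", 1:20)
  cons <- first_consensus(dss, Biostrings::DNAString(ref))
  expect_equal(substr(as.character(cons$sequence), p, p), "A")
  expect_equal(cons$probability[p], 13 / 22)
})

test_that("depth-0 regions fall back to the reference at the
           probability floor and are flagged", {
  withr::with_seed(32, ref <- rand_dna(4000))
  # reads covering only the first 2 kb
  reads <- Biostrings::DNAStringSet(rep(substr(ref, 1, 2000), 10))
  names(reads) <- sprintf("r%02d", 1:10)
  cons <- first_consensus(reads, Biostrings::DNAString(ref))
  expect_identical(as.character(cons$sequence), ref)
  gap <- cons$support[2100:4000]
  expect_true(all(gap == 0L))
  expect_true(all(cons$probability[2100:4000] == 0.5))
  expect_true(any(cons$zero_depth$start <= 2100 &
                    cons$zero_depth$end >= 4000))

  # no reads at all: consensus equals the reference, with a warning
  empty <- Biostrings::DNAStringSet()
  expect_warning(c0 <- first_consensus(empty,
                                       Biostrings::DNAString(ref)),
                 "no reads")
  expect_identical(as.character(c0$sequence), ref)
})

test_that("re-assignment recovers reads by allele and removes ambiguous
           ones; every read lands in exactly one set", {
  locus <- fixture_mini()
  ref <- as.character(locus$sequence)
  sites <- c(1200L, 2600L, 4400L)
  alt_of <- function(b) c(A = "G", C = "T", G = "A", T = "C")[b]
  h2_chars <- strsplit(ref, "")[[1]]
  h2_chars[sites] <- alt_of(h2_chars[sites])
  hap2 <- paste(h2_chars, collapse = "")
  cons1 <- first_consensus(perfect_reads(ref, 5),
                           Biostrings::DNAString(ref))
  cons2 <- first_consensus(perfect_reads(hap2, 5),
                           Biostrings::DNAString(hap2))

  r1 <- fragment_reads(ref, n = 8, seed = 4)
  names(r1) <- sprintf("a1_%02d", seq_along(r1))
  r2 <- fragment_reads(hap2, n = 8, seed = 5)
  names(r2) <- sprintf("a2_%02d", seq_along(r2))
  # a read from the shared segment between het sites: ambiguous
  amb <- Biostrings::DNAStringSet(substr(ref, 2700, 4300))
  names(amb) <- "amb"
  reads <- c(Biostrings::DNAStringSet(r1), Biostrings::DNAStringSet(r2),
             amb)
  re <- reassign_reads(reads, cons1, cons2)
  expect_true("amb" %in% re$removed)
  a1_hit <- grepl("^a1_", re$allele1)
  a2_hit <- grepl("^a2_", re$allele2)
  # reads overlapping at least one het site sort to their allele
  expect_gt(sum(a1_hit), 0)
  expect_gt(sum(a2_hit), 0)
  expect_false(any(grepl("^a2_", re$allele1)))
  expect_false(any(grepl("^a1_", re$allele2)))
  # conservation: the three sets partition the read set
  all_ids <- names(reads)
  expect_setequal(c(re$allele1, re$allele2, re$removed), all_ids)
  expect_equal(length(re$allele1) + length(re$allele2) +
                 length(re$removed), length(all_ids))
})

test_that("a further consensus round with unchanged reads is a fixed
           point", {
  locus <- fixture_mini()
  defs <- synthetic_star_table(locus)
  reads <- fragment_reads(as.character(locus$sequence), n = 25,
                          em = error_model(), seed = 9)
  cons1 <- first_consensus(reads, Biostrings::DNAString(
    as.character(locus$sequence)))
  cons2 <- final_consensus(reads, cons1)
  cons3 <- final_consensus(reads, cons2)
  expect_identical(as.character(cons3$sequence),
                   as.character(cons2$sequence))
})

test_that("high-probability columns are empirically accurate", {
  withr::with_seed(33, ref <- rand_dna(1000))
  reads <- fragment_reads(ref, n = 150, min_len = 900L,
                          em = error_model(), seed = 10)
  cons <- first_consensus(reads, Biostrings::DNAString(ref))
  # truth is the reference the reads were drawn from
  cc <- strsplit(as.character(cons$sequence), "")[[1]]
  tc <- strsplit(ref, "")[[1]]
  if (length(cc) == length(tc)) {
    hi <- cons$probability >= 0.99
    if (any(hi)) {
      expect_lte(mean(cc[hi] != tc[hi]), 0.01)
    }
  }
  # overall accuracy at 100X+ should be near-perfect
  d <- utils::adist(as.character(cons$sequence), ref)[1, 1]
  expect_lte(d / nchar(ref), 0.002)
})
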