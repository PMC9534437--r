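test_that("alignment contract holds for error-free on-target reads", {
  locus <- fixture_locus()
  defs <- fixture_defs()
  h <- build_haplotype(locus, haplotype_spec(locus, defs, "*1"))
  reads <- simulate_reads(list(h), locus, n_reads = 20, pools = "A",
                          em = error_model(0, 0, 0), seed = 1,
                          truncation_prob = 0)
  aln <- align_reads(reads, locus)
  pri <- aln[aln$mapped & !aln$is_secondary & !aln$is_supplementary, ]
  covered <- (pri$read_len - pri$left_clip - pri$right_clip) /
    pri$read_len
  expect_gte(mean(covered >= 0.95), 0.99)
  expect_true(all(pri$left_clip < 50 & pri$right_clip < 50))
})

test_that("read filter applies the mean-quality and overlap rules", {
  locus <- fixture_mini()
  s <- as.character(locus$sequence)
  mk <- function(id, q) {
    dss <- Biostrings::DNAStringSet(s)
    names(dss) <- id
    Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(paste(
        vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1)),
        collapse = "")))
  }
  n <- nchar(s)
  # mean quality 7.9: below the threshold, removed
  q79 <- c(rep(7L, round(n * 0.1)), rep(8L, n - round(n * 0.1) -
                                          round(n * 0.1)),
           rep(7L, round(n * 0.1)))
  lowq <- mk("lowq", q79)
  highq <- mk("highq", rep(12L, n))
  reads <- c(lowq, highq)
  aln <- align_reads(reads, locus)
  flt <- filter_reads(aln)
  expect_false("lowq" %in% flt$qname)
  expect_true("highq" %in% flt$qname)

  # off-target reads are removed
  bg <- simulate_background(5, seed = 1)
  aln2 <- align_reads(c(reads, bg), locus)
  flt2 <- filter_reads(aln2)
  expect_false(any(grepl("^bg_", flt2$qname)))

  # empty input stays empty
  expect_equal(nrow(filter_reads(aln[0, ])), 0L)
})

test_that("pileup caller equals the brute-force genotype-likelihood
           oracle on a 1 kb fixture", {
  withr::with_seed(11, {
    ref <- rand_dna(1000)
  })
  ref_chars <- strsplit(ref, "")[[1]]
  # plant: a het site (15/15), a hom-alt site (30 alt), a weak site
  # (29 ref / 1 alt, must stay hom-ref)
  sites <- c(het = 300L, hom = 600L, weak = 900L)
  alt_of <- function(b) c(A = "G", C = "T", G = "A", T = "C")[[b]]
  reads <- vapply(1:30, function(i) {
    ch <- ref_chars
    if (i <= 15) ch[sites["het"]] <- alt_of(ref_chars[sites["het"]])
    ch[sites["hom"]] <- alt_of(ref_chars[sites["hom"]])
    if (i == 1) ch[sites["weak"]] <- alt_of(ref_chars[sites["weak"]])
    paste(ch, collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("r%02d", 1:30)
  locus <- locus_reference("fix1k", ref)
  aln <- align_reads(dss, locus)
  called <- call_small_variants(aln, locus, min_depth = 16,
                                error_rate = 0.05)

  # independent oracle: naive per-read base counts (no package layering)
  # and direct likelihood evaluation at every position
  eps <- 0.05
  counts <- matrix(0L, 4, 1000, dimnames = list(c("A", "C", "G", "T")))
  for (r in reads) {
    rc <- strsplit(r, "")[[1]]
    for (p in seq_len(1000)) {
      counts[rc[p], p] <- counts[rc[p], p] + 1L
    }
  }
  oracle <- list()
  for (p in seq_len(1000)) {
    d <- sum(counts[, p])
    nr <- counts[ref_chars[p], p]
    alts <- counts[setdiff(rownames(counts), ref_chars[p]), p]
    na_ <- max(alts)
    no <- d - nr - na_
    ll <- c(nr * log(1 - eps) + (na_ + no) * log(eps / 3),
            (nr + na_) * log(0.5 * (1 - eps) + 0.5 * eps / 3) +
              no * log(eps / 3),
            na_ * log(1 - eps) + (nr + no) * log(eps / 3))
    g <- which.max(ll)
    if (g > 1 && na_ >= 2) {
      oracle[[length(oracle) + 1L]] <- data.frame(
        pos = p, gt = c("0/0", "0/1", "1/1")[g])
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(called$pos, oracle$pos)
  expect_equal(called$gt, oracle$gt)
  expect_equal(unname(called$gt[called$pos == sites["het"]]), "0/1")
  expect_equal(unname(called$gt[called$pos == sites["hom"]]), "1/1")
  expect_false(sites["weak"] %in% called$pos)
  expect_true(all(called$low_confidence == FALSE))
})

test_that("no reads means no calls", {
  locus <- fixture_mini()
  aln <- align_reads(simulate_background(3, seed = 1), locus)
  flt <- filter_reads(aln)
  v <- call_small_variants(flt, locus)
  expect_equal(nrow(v), 0L)
})

test_that("phasing partitions consistent reads exactly and leaves
           ambiguous reads unassigned", {
  withr::with_seed(21, {
    ref <- rand_dna(2000)
  })
  ref_chars <- strsplit(ref, "")[[1]]
  alt_of <- function(b) c(A = "G", C = "T", G = "A", T = "C")[[b]]
  sites <- c(500L, 1500L)
  hap2 <- ref_chars
  hap2[sites] <- vapply(ref_chars[sites], alt_of, character(1))
  mk_read <- function(chars, id) {
    d <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(d) <- id
    d
  }
  reads <- do.call(c, c(
    lapply(1:10, function(i) mk_read(ref_chars, sprintf("h1_%02d", i))),
    lapply(1:10, function(i) mk_read(hap2, sprintf("h2_%02d", i)))))
  # a read covering no het site, and a 1-1 conflicting read
  no_site <- Biostrings::DNAStringSet(substr(ref, 600, 1400))
  names(no_site) <- "nosite"
  confl <- ref_chars
  confl[sites[1]] <- alt_of(ref_chars[sites[1]])  # hap2 allele at site 1
  reads <- c(reads, no_site, mk_read(confl, "conflict"))

  locus <- locus_reference("fix2k", ref)
  aln <- filter_reads(align_reads(reads, locus))
  v <- call_small_variants(aln, locus, error_rate = 0.05)
  part <- phase_reads(v[v$gt == "0/1", ], aln)

  g1 <- sort(sprintf("h1_%02d", 1:10))
  g2 <- sort(sprintf("h2_%02d", 1:10))
  got <- list(sort(part$allele1), sort(part$allele2))
  expect_true(identical(got, list(g1, g2)) ||
                identical(got, list(g2, g1)))
  expect_true("nosite" %in% part$unassigned)
  expect_true("conflict" %in% part$unassigned)
  expect_false(part$single_allele)

  # no het sites: single-allele mode with a warning
  expect_warning(p0 <- phase_reads(v[0, ], aln), "single-allele")
  expect_true(p0$single_allele)
})
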