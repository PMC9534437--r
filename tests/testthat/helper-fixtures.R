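# Shared fixtures, built in code and cached per test run.

.fix <- new.env()

# full-size study locus (28,206 bp, two 4,382 bp genes at 94% identity)
fixture_locus <- function() {
  if (is.null(.fix$locus)) .fix$locus <- synthetic_locus(seed = 43L)
  .fix$locus
}

fixture_defs <- function() {
  if (is.null(.fix$defs)) .fix$defs <- synthetic_star_table(fixture_locus())
  .fix$defs
}

# small locus for fast unit tests: 6 kb, two 800 bp genes at 94% identity
fixture_mini <- function() {
  if (is.null(.fix$mini)) {
    .fix$mini <- synthetic_locus(locus_length = 6000L, gene_length = 800L,
                                 gene1_start = 1001L, gene2_start = 3501L,
                                 seed = 7L)
  }
  .fix$mini
}

# error-free reads tiling a haplotype: n full-length copies
perfect_reads <- function(hap_seq, n = 15L) {
  s <- as.character(hap_seq)
  dss <- Biostrings::DNAStringSet(rep(s, n))
  names(dss) <- sprintf("pr_%03d", seq_len(n))
  q <- paste(rep(rawToChar(as.raw(20L + 33L)), nchar(s)), collapse = "")
  Biostrings::QualityScaledDNAStringSet(
    dss, Biostrings::PhredQuality(rep(q, n)))
}

# reads as random fragments of a sequence (optionally noisy)
fragment_reads <- function(hap_seq, n = 20L, min_len = 1500L,
                           em = error_model(0, 0, 0), seed = 1L) {
  s <- as.character(hap_seq)
  L <- nchar(s)
  withr::with_seed(seed, {
    starts <- sample(max(1L, L - min_len), n, replace = TRUE)
    ends <- pmin(L, starts + min_len +
                   sample(0:max(1L, L - min_len), n, replace = TRUE))
    seqs <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      res <- add_errors(substr(s, starts[i], ends[i]), em,
                        seed = sample.int(1e6, 1L))
      seqs[i] <- res$sequence
      quals[i] <- paste(vapply(res$qualities, function(q) {
        rawToChar(as.raw(q + 33L))
      }, character(1)), collapse = "")
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("fr_%03d", seq_len(n))
    Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(quals))
  })
}

# independent brute-force two-state segmentation by full enumeration
brute_force_segmentation <- function(cost, penalty) {
  k <- nrow(cost)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    lab <- as.integer(intToBits(mask))[seq_len(k)] + 1L
    c_ <- sum(cost[cbind(seq_len(k), lab)]) +
      penalty * sum(lab[-1] != lab[-k])
    if (c_ < best) best <- c_
  }
  best
}

# cost of a DP segmentation result, for comparison with brute force
dp_cost <- function(diag_pos, cost, segments, penalty, genes) {
  lab <- vapply(diag_pos, function(p) {
    match(segments$source[segments$start <= p & segments$end >= p][1],
          genes)
  }, integer(1))
  sum(cost[cbind(seq_along(diag_pos), lab)]) +
    penalty * sum(lab[-1] != lab[-length(lab)])
}

# synthetic mismatch_profiles object from diagnostic-position labels
make_profiles <- function(diag_pos, mism_gene, copy_len = 1000L,
                          genes = c("g1", "g2")) {
  p1 <- diag_pos[mism_gene == 1L]
  p2 <- diag_pos[mism_gene == 2L]
  prof <- function(p) {
    data.frame(copy_pos = p, gene_pos = p, type = "mismatch",
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  structure(list(profiles = stats::setNames(list(prof(p1), prof(p2)),
                                            genes),
                 identity = c(0.95, 0.95), unclassified = FALSE,
                 copy_interval = c(1L, copy_len), copy_len = copy_len,
                 genes = genes),
            class = "mismatch_profiles")
}
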