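# Read mapping, on-target filtering, pileup small-variant calling, and
# allele splitting. Alignment itself is delegated to minimap2 (the standard
# long-read mapper); everything downstream of the SAM records — the pileup
# genotype-likelihood caller and the greedy margin-based read partitioner —
# is implemented here in a transparent, oracle-checkable form.

# Run minimap2 and return parsed alignment records as a data.frame.
# Soft clips of supplementary alignments are preserved (-Y), secondary
# alignments suppressed, single-threaded for determinism.
mm2_align <- function(query, reference, preset = "map-ont",
                      extra = character()) {
  mm2 <- minimap2_path()
  td <- tempfile("mm2")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qfa <- file.path(td, "query.fa")
  rfa <- file.path(td, "ref.fa")
  if (is.character(query) && length(query) == 1 && file.exists(query)) {
    qss <- read_reads(query)
    qss <- Biostrings::DNAStringSet(qss)
  } else if (methods::is(query, "QualityScaledXStringSet")) {
    S4Vectors::mcols(query) <- NULL
    qss <- Biostrings::DNAStringSet(query)
  } else if (is.character(query)) {
    qss <- Biostrings::DNAStringSet(query)
  } else qss <- query
  if (is.null(names(qss))) names(qss) <- paste0("q", seq_along(qss))
  Biostrings::writeXStringSet(qss, qfa)
  if (methods::is(reference, "DNAString")) {
    reference <- Biostrings::DNAStringSet(list(reference))
    names(reference) <- "ref"
  } else if (is.character(reference)) {
    reference <- Biostrings::DNAStringSet(reference)
    if (is.null(names(reference))) names(reference) <- "ref"
  }
  Biostrings::writeXStringSet(reference, rfa)
  sam <- file.path(td, "out.sam")
  args <- c("-a", "-Y", "--secondary=no", "-t", "1", "-x", preset, extra,
            rfa, qfa, "-o", sam)
  status <- system2(mm2, args, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(sam)) {
    stop("minimap2 failed (exit status ", status, ")", call. = FALSE)
  }
  bam <- suppressWarnings(Rsamtools::asBam(
    sam, file.path(td, "out"), overwrite = TRUE, indexDestination = FALSE))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq",
             "cigar", "seq"),
    tag = c("AS", "NM"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0) {
    return(empty_alignments())
  }
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- b$cigar
  cigar[is.na(cigar)] <- ""
  lc <- rc <- integer(n)
  ref_w <- integer(n)
  if (any(mapped)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[mapped])
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[mapped])
    lc[mapped] <- mapply(function(o, l) {
      if (length(o) > 0 && o[1] == "S") l[1] else 0L
    }, ops, lens)
    rc[mapped] <- mapply(function(o, l) {
      k <- length(o)
      if (k > 0 && o[k] == "S") l[k] else 0L
    }, ops, lens)
    ref_w[mapped] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[mapped])
  }
  data.frame(
    qname = b$qname,
    flag = flag,
    mapped = mapped,
    rname = as.character(b$rname),
    strand = as.character(b$strand),
    pos = b$pos,
    end = ifelse(mapped, b$pos + ref_w - 1L, NA_integer_),
    mapq = b$mapq,
    cigar = cigar,
    left_clip = lc,
    right_clip = rc,
    read_len = b$qwidth,
    seq = as.character(b$seq),
    AS = b$tag$AS %||% rep(NA_integer_, n),
    NM = b$tag$NM %||% rep(NA_integer_, n),
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), mapped = logical(),
             rname = character(), strand = character(), pos = integer(),
             end = integer(), mapq = integer(), cigar = character(),
             left_clip = integer(), right_clip = integer(),
             read_len = integer(), seq = character(), AS = integer(),
             NM = integer(), is_secondary = logical(),
             is_supplementary = logical(), mean_read_q = numeric(),
             stringsAsFactors = FALSE)
}

#' Align reads to the locus reference
#'
#' Maps reads with minimap2 (long-read preset, single-threaded, secondary
#' alignments suppressed, supplementary alignments and soft clips
#' preserved) and returns parsed SAM-compatible records. Mean read quality
#' is attached per read when the input carries qualities.
#'
#' @param reads A `QualityScaledDNAStringSet`, `DNAStringSet`, or FASTQ
#'   path.
#' @param locus_reference A [locus_reference()], or any named sequence set.
#' @param preset minimap2 preset.
#' @return `data.frame` of alignment records (one row per SAM record,
#'   including unmapped reads), with attributes `ref_name` and `ref_len`.
#' @export
align_reads <- function(reads, locus_reference, preset = "map-ont") {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  if (methods::is(locus_reference, "LocusReference")) {
    ref <- Biostrings::DNAStringSet(list(locus_reference$sequence))
    names(ref) <- locus_reference$name
    ref_len <- length(locus_reference$sequence)
  } else {
    ref <- locus_reference
    ref_len <- max(Biostrings::width(ref))
  }
  aln <- mm2_align(reads, ref, preset = preset)
  mq <- mean_read_quality(reads)
  names(mq) <- names(reads)
  aln$mean_read_q <- unname(mq[aln$qname])
  attr(aln, "ref_name") <- names(ref)[1]
  attr(aln, "ref_len") <- ref_len
  aln
}

#' Filter alignments to high-quality on-target reads
#'
#' Keeps reads whose primary alignment overlaps the target region, whose
#' mean basecall quality exceeds `min_read_q` (the standard nanopore
#' pass-read threshold), and whose primary alignment covers at least
#' `min_overlap` of the read length. All records (including supplementary)
#' of a kept read are retained, so clip evidence is never lost.
#'
#' @param alignments Output of [align_reads()].
#' @param region `c(start, end)` target region; default the whole
#'   reference.
#' @param min_read_q Minimum mean read quality (strict inequality).
#' @param min_overlap Minimum fraction of the read length aligned in the
#'   primary record.
#' @return Filtered alignment records.
#' @export
filter_reads <- function(alignments, region = NULL, min_read_q = 8,
                         min_overlap = 0.5) {
  if (nrow(alignments) == 0) return(alignments)
  if (is.null(region)) region <- c(1L, attr(alignments, "ref_len") %||%
                                     max(alignments$end, na.rm = TRUE))
  pri <- alignments$mapped & !alignments$is_secondary &
    !alignments$is_supplementary
  ov_start <- pmax(alignments$pos, region[1])
  ov_end <- pmin(alignments$end, region[2])
  overlaps <- !is.na(ov_start) & ov_start <= ov_end
  aligned_frac <- (alignments$read_len - alignments$left_clip -
                     alignments$right_clip) / alignments$read_len
  q_ok <- is.na(alignments$mean_read_q) |
    alignments$mean_read_q > min_read_q
  keep_read <- alignments$qname[pri & overlaps & q_ok &
                                  aligned_frac >= min_overlap]
  out <- alignments[alignments$qname %in% keep_read & alignments$mapped, ,
                    drop = FALSE]
  attr(out, "ref_name") <- attr(alignments, "ref_name")
  attr(out, "ref_len") <- attr(alignments, "ref_len")
  attr(out, "total_reads") <- length(unique(alignments$qname))
  out
}

# Lay read sequences onto the reference coordinate frame (soft clips and
# insertions removed, deletions gap-filled), for pileup and phasing.
layer_reads <- function(alignments) {
  rows <- alignments[alignments$mapped & !alignments$is_secondary, ,
                     drop = FALSE]
  if (nrow(rows) == 0) {
    return(list(layered = Biostrings::DNAStringSet(), rows = rows))
  }
  layered <- GenomicAlignments::sequenceLayer(
    Biostrings::DNAStringSet(rows$seq), rows$cigar,
    from = "query", to = "reference")
  list(layered = layered, rows = rows)
}

# Per-position base counts (A, C, G, T, -) over the reference frame.
pileup_counts <- function(layer, ref_len) {
  if (length(layer$layered) == 0) {
    m <- matrix(0L, nrow = 5, ncol = ref_len,
                dimnames = list(c("A", "C", "G", "T", "-"), NULL))
    return(m)
  }
  cm <- Biostrings::consensusMatrix(layer$layered,
                                    shift = layer$rows$pos - 1L,
                                    width = ref_len)
  cm[c("A", "C", "G", "T", "-"), , drop = FALSE]
}

# Genotype log-likelihoods for one biallelic site from counts.
# Symmetric per-base error eps; SNV model spreads eps over 3 alt bases,
# indel model is binary.
genotype_loglik <- function(n_ref, n_alt, n_other, eps, snv = TRUE) {
  e <- if (snv) eps / 3 else eps
  ll_rr <- n_ref * log(1 - eps) + (n_alt + n_other) * log(e)
  p_het <- 0.5 * (1 - eps) + 0.5 * e
  ll_ra <- (n_ref + n_alt) * log(p_het) + n_other * log(e)
  ll_aa <- n_alt * log(1 - eps) + (n_ref + n_other) * log(e)
  c(ll_rr, ll_ra, ll_aa)
}

genotype_call <- function(n_ref, n_alt, n_other, eps, snv = TRUE) {
  ll <- genotype_loglik(n_ref, n_alt, n_other, eps, snv)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  g <- which.max(ll)
  qual <- min(60, -10 * log10(max(1 - post[g], 1e-6)))
  list(gt = c("0/0", "0/1", "1/1")[g], qual = qual)
}

# modal element of a character vector (ties -> first after sort)
modal <- function(x) {
  t <- sort(table(x), decreasing = TRUE)
  names(t)[1]
}

#' Call small variants from a pileup
#'
#' Transparent diploid pileup caller: per-position genotype by maximum
#' likelihood over hom-ref / het / hom-alt with a symmetric per-base error
#' rate. SNVs are called from layered base counts; insertions and deletions
#' are collected from alignment gap operations, grouped per site, and
#' genotyped with the same likelihood model, then left-aligned. Variants
#' below `min_depth` are emitted with `low_confidence = TRUE` rather than
#' dropped.
#'
#' @param alignments Filtered alignment records (sorted or not).
#' @param locus_reference A [locus_reference()] (or `DNAString`).
#' @param min_depth Depth below which calls are flagged low-confidence.
#' @param error_rate Symmetric per-base error rate `eps`.
#' @return `data.frame` of variants (`pos`, `ref`, `alt`, `kind`, `gt`,
#'   `depth`, `alt_count`, `qual`, `low_confidence`).
#' @export
call_small_variants <- function(alignments, locus_reference,
                                min_depth = 16L, error_rate = 0.1) {
  refseq <- if (methods::is(locus_reference, "LocusReference")) {
    as.character(locus_reference$sequence)
  } else as.character(locus_reference)
  ref_len <- nchar(refseq)
  layer <- layer_reads(alignments)
  out <- list()
  if (length(layer$layered) > 0) {
    cm <- pileup_counts(layer, ref_len)
    acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
    depth <- colSums(acgt)
    ref_chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
    ref_idx <- match(ref_chars, c("A", "C", "G", "T"))
    n_ref <- acgt[cbind(ref_idx, seq_len(ref_len))]
    alt_cm <- acgt
    alt_cm[cbind(ref_idx, seq_len(ref_len))] <- -1L
    alt_row <- max.col(t(alt_cm), ties.method = "first")
    n_alt <- alt_cm[cbind(alt_row, seq_len(ref_len))]
    n_alt[n_alt < 0] <- 0L
    cand <- which(depth > 0 & n_alt >= 2 & n_alt > depth * 0.15)
    if (length(cand) > 0) {
      eps <- error_rate
      nr <- n_ref[cand]; na_ <- n_alt[cand]
      no <- depth[cand] - nr - na_
      p_het <- 0.5 * (1 - eps) + 0.5 * eps / 3
      ll <- cbind(nr * log(1 - eps) + (na_ + no) * log(eps / 3),
                  (nr + na_) * log(p_het) + no * log(eps / 3),
                  na_ * log(1 - eps) + (nr + no) * log(eps / 3))
      g <- max.col(ll, ties.method = "first")
      post <- exp(ll - apply(ll, 1, max))
      p_best <- post[cbind(seq_along(g), g)] / rowSums(post)
      qual <- pmin(60, -10 * log10(pmax(1 - p_best, 1e-6)))
      keep <- g > 1L
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = cand[keep], ref = ref_chars[cand[keep]],
          alt = c("A", "C", "G", "T")[alt_row[cand[keep]]],
          kind = "SNV", gt = c("0/0", "0/1", "1/1")[g[keep]],
          depth = as.integer(depth[cand[keep]]),
          alt_count = as.integer(n_alt[cand[keep]]), qual = qual[keep],
          low_confidence = depth[cand[keep]] < min_depth,
          stringsAsFactors = FALSE)
      }
    }
    # coverage for indel sites
    cov <- as.integer(IRanges::coverage(
      IRanges::IRanges(layer$rows$pos, layer$rows$end), width = ref_len))

    # deletions from D gap ops
    dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      layer$rows$cigar, ops = "D", pos = layer$rows$pos)
    dl <- unlist(dr)
    if (length(dl) > 0) {
      keys <- paste0(BiocGenerics::start(dl), "_",
                     BiocGenerics::width(dl))
      tab <- table(keys)
      tab <- tab[tab >= 2]
      for (k in names(tab)) {
        a <- as.integer(tab[[k]])
        sw <- as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
        s <- sw[1]; w <- sw[2]
        if (s <= 1L || s + w - 1L > ref_len) next
        d <- cov[s]
        r <- max(d - a, 0L)
        if (a < 2 || a <= d * 0.15) next
        call <- genotype_call(r, a, 0L, error_rate, snv = FALSE)
        if (call$gt == "0/0") next
        nv <- normalize_variant(s - 1L,
                                substr(refseq, s - 1L, s + w - 1L),
                                substr(refseq, s - 1L, s - 1L), refseq)
        out[[length(out) + 1L]] <- data.frame(
          pos = nv$pos, ref = nv$ref, alt = nv$alt, kind = "DEL",
          gt = call$gt, depth = as.integer(d), alt_count = a,
          qual = call$qual, low_confidence = d < min_depth,
          stringsAsFactors = FALSE)
      }
    }
    # insertions from I gap ops
    ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      layer$rows$cigar, ops = "I", pos = layer$rows$pos)
    iq <- GenomicAlignments::cigarRangesAlongQuerySpace(
      layer$rows$cigar, ops = "I", after.soft.clipping = FALSE)
    ins <- list()
    for (i in seq_along(ir)) {
      if (length(ir[[i]]) == 0) next
      anchors <- BiocGenerics::end(ir[[i]])
      seqs <- as.character(Biostrings::extractAt(
        Biostrings::DNAString(layer$rows$seq[i]), iq[[i]]))
      for (j in seq_along(anchors)) {
        ins[[length(ins) + 1L]] <- data.frame(
          anchor = anchors[j], seq = seqs[j], stringsAsFactors = FALSE)
      }
    }
    if (length(ins) > 0) {
      insdf <- do.call(rbind, ins)
      cnt <- table(insdf$anchor)
      anchors <- as.integer(names(cnt))
      ok <- anchors >= 1L & anchors <= ref_len &
        as.integer(cnt) >= 2 & as.integer(cnt) > cov[pmax(anchors, 1L)] *
        0.15
      for (a_pos in anchors[ok]) {
        sub <- insdf[insdf$anchor == a_pos, , drop = FALSE]
        a <- nrow(sub)
        d <- cov[a_pos]
        r <- max(d - a, 0L)
        call <- genotype_call(r, a, 0L, error_rate, snv = FALSE)
        if (call$gt == "0/0") next
        alt_seq <- modal(sub$seq)
        nv <- normalize_variant(a_pos, substr(refseq, a_pos, a_pos),
                                paste0(substr(refseq, a_pos, a_pos),
                                       alt_seq), refseq)
        out[[length(out) + 1L]] <- data.frame(
          pos = nv$pos, ref = nv$ref, alt = nv$alt, kind = "INS",
          gt = call$gt, depth = as.integer(d), alt_count = a,
          qual = call$qual, low_confidence = d < min_depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_variants())
  res <- do.call(rbind, out)
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Split reads into two alleles from their heterozygous sites
#'
#' Greedy margin-based read partition: starting from the read covering the
#' most heterozygous SNV sites, reads are iteratively assigned to the
#' haplotype whose current consensus they match at more het sites (margin
#' of at least one site), and the haplotype consensus is refined each pass
#' until a fixed point (at most `max_passes` passes). Reads with zero
#' margin stay unassigned (they are recovered later against the allele
#' consensus sequences). Het sites connected by no common read form
#' separate phase blocks.
#'
#' @param variants Output of [call_small_variants()].
#' @param alignments Filtered alignment records.
#' @param max_passes Maximum refinement passes per block.
#' @return A `PhasePartition`: list with `allele1`, `allele2`,
#'   `unassigned` (read-id vectors), `het_sites` (with haplotype-1 allele
#'   and block id), and `single_allele` flag.
#' @export
phase_reads <- function(variants, alignments, max_passes = 10L) {
  het <- variants[variants$gt == "0/1" & variants$kind == "SNV", ,
                  drop = FALSE]
  all_reads <- unique(alignments$qname[alignments$mapped])
  if (nrow(het) == 0) {
    warning("no heterozygous sites; single-allele mode")
    return(structure(list(allele1 = all_reads, allele2 = all_reads,
                          unassigned = character(),
                          het_sites = cbind(het, hap1_allele = integer(0),
                                            block = integer(0)),
                          single_allele = TRUE),
                     class = "PhasePartition"))
  }
  layer <- layer_reads(alignments)
  n_sites <- nrow(het)
  # read x site allele observations
  obs <- list()
  for (i in seq_len(nrow(layer$rows))) {
    r <- layer$rows[i, ]
    cover <- which(het$pos >= r$pos & het$pos <= r$end)
    if (length(cover) == 0) next
    b <- substring(as.character(layer$layered[[i]]),
                   het$pos[cover] - r$pos + 1L,
                   het$pos[cover] - r$pos + 1L)
    al <- ifelse(b == het$ref[cover], 0L,
                 ifelse(b == het$alt[cover], 1L, NA_integer_))
    obs[[length(obs) + 1L]] <- data.frame(qname = r$qname, site = cover,
                                          allele = al)
  }
  obs <- do.call(rbind, obs)
  obs <- obs[!is.na(obs$allele), , drop = FALSE]
  reads <- unique(obs$qname)
  M <- matrix(NA_integer_, nrow = length(reads), ncol = n_sites,
              dimnames = list(reads, NULL))
  # a read observed twice at a site (primary + supplementary) keeps the
  # first observation
  first <- !duplicated(paste(obs$qname, obs$site))
  M[cbind(match(obs$qname[first], reads), obs$site[first])] <-
    obs$allele[first]

  # phase blocks: connected components of sites sharing a read
  parent <- seq_len(n_sites)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(M))) {
    s <- which(!is.na(M[r, ]))
    if (length(s) > 1) for (k in s[-1]) {
      a <- find(s[1]); b <- find(k)
      if (a != b) parent[b] <- a
    }
  }
  block <- vapply(seq_len(n_sites), find, integer(1))
  block <- as.integer(factor(block))

  h1 <- rep(NA_integer_, n_sites)
  assign_of <- rep(NA_integer_, length(reads))
  for (bl in unique(block)) {
    sites <- which(block == bl)
    in_block <- which(rowSums(!is.na(M[, sites, drop = FALSE])) > 0)
    if (length(in_block) == 0) next
    seed <- in_block[which.max(rowSums(!is.na(M[in_block, sites,
                                                drop = FALSE])))]
    h1[sites] <- M[seed, sites]
    for (pass in seq_len(max_passes)) {
      m1 <- rowSums(sweep(M[in_block, sites, drop = FALSE], 2, h1[sites],
                          "==") == TRUE, na.rm = TRUE)
      m2 <- rowSums(sweep(M[in_block, sites, drop = FALSE], 2,
                          1L - h1[sites], "==") == TRUE, na.rm = TRUE)
      newa <- ifelse(m1 > m2, 1L, ifelse(m2 > m1, 2L, NA_integer_))
      # refine haplotype consensus at each site
      newh <- h1[sites]
      for (j in seq_along(sites)) {
        col <- M[in_block, sites[j]]
        v0 <- sum(col == 0L & newa == 1L, na.rm = TRUE) +
          sum(col == 1L & newa == 2L, na.rm = TRUE)
        v1 <- sum(col == 1L & newa == 1L, na.rm = TRUE) +
          sum(col == 0L & newa == 2L, na.rm = TRUE)
        if (v0 != v1) newh[j] <- ifelse(v0 > v1, 0L, 1L)
      }
      stable <- identical(newa, assign_of[in_block]) &&
        identical(newh, h1[sites])
      assign_of[in_block] <- newa
      h1[sites] <- newh
      if (stable) break
    }
  }
  a1 <- reads[!is.na(assign_of) & assign_of == 1L]
  a2 <- reads[!is.na(assign_of) & assign_of == 2L]
  un <- setdiff(all_reads, c(a1, a2))
  het$hap1_allele <- h1
  het$block <- block
  structure(list(allele1 = a1, allele2 = a2, unassigned = un,
                 het_sites = het, single_allele = FALSE),
            class = "PhasePartition")
}
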