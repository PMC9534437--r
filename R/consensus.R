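# Per-allele consensus: two rounds of transparent majority-column consensus
# over reads realigned to the allele-adjusted reference, with a per-base
# probability track (Laplace-smoothed majority fraction), majority indel
# voting, and modal length voting in homopolymer runs (the dominant
# nanopore error mode). Between rounds, all on-target reads are
# re-assigned to the allele consensus they match best; ambiguous reads are
# removed.

# Core column-vote consensus of alignment records against `refseq`.
consensus_core <- function(alignments, refseq, hp_min_run = 4L) {
  refseq <- as.character(refseq)
  L <- nchar(refseq)
  ref_chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  layer <- layer_reads(alignments)
  nreads <- nrow(layer$rows)
  if (nreads == 0) {
    return(list(sequence = refseq, probability = rep(0.5, L),
                support = rep(0L, L),
                zero_depth = data.frame(start = 1L, end = L),
                read_ids = character()))
  }
  cm <- pileup_counts(layer, L)
  depth <- colSums(cm)
  cov <- as.integer(IRanges::coverage(
    IRanges::IRanges(layer$rows$pos, layer$rows$end), width = L))

  # insertion events: (record index, anchor, seq)
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    layer$rows$cigar, ops = "I", pos = layer$rows$pos)
  iq <- GenomicAlignments::cigarRangesAlongQuerySpace(
    layer$rows$cigar, ops = "I")
  ins <- list()
  for (i in seq_along(ir)) {
    if (length(ir[[i]]) == 0) next
    anchors <- BiocGenerics::end(ir[[i]])
    seqs <- as.character(Biostrings::extractAt(
      Biostrings::DNAString(layer$rows$seq[i]), iq[[i]]))
    ins[[length(ins) + 1L]] <- data.frame(
      rec = i, anchor = anchors, seq = seqs, stringsAsFactors = FALSE)
  }
  insdf <- if (length(ins) > 0) do.call(rbind, ins) else
    data.frame(rec = integer(), anchor = integer(), seq = character())

  lay_chars <- as.character(layer$layered)
  pure_base <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    grepl(paste0("^", b, "+$"), insdf$seq)
  })
  # homopolymer runs of the reference
  r <- rle(ref_chars)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  hp <- which(r$lengths >= hp_min_run)
  in_hp <- rep(FALSE, L)
  hp_runs <- data.frame(start = run_start[hp], end = run_end[hp],
                        base = r$values[hp])
  for (i in seq_len(nrow(hp_runs))) {
    in_hp[hp_runs$start[i]:hp_runs$end[i]] <- TRUE
  }
  # insertions of the run base at anchors inside (or just before) a run are
  # consumed by the run-length vote
  ins_consumed <- rep(FALSE, nrow(insdf))
  hp_emit <- vector("list", nrow(hp_runs))
  for (i in seq_len(nrow(hp_runs))) {
    s <- hp_runs$start[i]; e <- hp_runs$end[i]; B <- hp_runs$base[i]
    covering <- which(layer$rows$pos <= s & layer$rows$end >= e)
    if (length(covering) == 0) {
      hp_emit[[i]] <- list(seq = strrep(B, e - s + 1L), prob = 0.5,
                           depth = 0L)
      next
    }
    pure_b <- pure_base[[B]]
    segs <- substring(lay_chars[covering],
                      s - layer$rows$pos[covering] + 1L,
                      e - layer$rows$pos[covering] + 1L)
    base_n <- nchar(segs) - nchar(gsub(B, "", segs, fixed = TRUE))
    ins_rel <- insdf[pure_b & insdf$anchor >= s - 1L &
                       insdf$anchor <= e, , drop = FALSE]
    lens <- base_n
    if (nrow(ins_rel) > 0) {
      extra <- tapply(nchar(ins_rel$seq), ins_rel$rec, sum)
      m <- match(covering, as.integer(names(extra)))
      lens <- lens + ifelse(is.na(m), 0L, as.integer(extra)[m])
    }
    ins_consumed[insdf$anchor >= s - 1L & insdf$anchor <= e & pure_b] <- TRUE
    t <- table(lens)
    best <- max(t)
    cand <- as.integer(names(t)[t == best])
    ref_len <- e - s + 1L
    len_out <- if (ref_len %in% cand) ref_len else cand[1]
    hp_emit[[i]] <- list(seq = strrep(B, len_out),
                         prob = (best + 1) / (length(covering) + 2),
                         depth = length(covering))
  }

  # accepted insertions outside homopolymer consumption
  ins_ok <- list()
  if (nrow(insdf) > 0) {
    rest <- insdf[!ins_consumed, , drop = FALSE]
    cnt <- table(rest$anchor)
    anchors <- as.integer(names(cnt))
    ok <- anchors >= 1L & anchors <= L &
      as.integer(cnt) * 2L > cov[pmax(pmin(anchors, L), 1L)]
    for (a in anchors[ok]) {
      sub <- rest[rest$anchor == a, , drop = FALSE]
      d <- cov[a]
      ms <- modal(sub$seq)
      ins_ok[[as.character(a)]] <- list(
        seq = ms, prob = (sum(sub$seq == ms) + 1) / (d + 2), depth = d)
    }
  }

  # vectorised column winners with reference preference on ties
  prefer <- cm + 0
  ridx <- match(ref_chars, rownames(cm))
  has_ref_row <- !is.na(ridx)
  prefer[cbind(ridx[has_ref_row], which(has_ref_row))] <-
    prefer[cbind(ridx[has_ref_row], which(has_ref_row))] + 0.25
  win_row <- max.col(t(prefer), ties.method = "first")
  win_base <- rownames(cm)[win_row]
  win_count <- cm[cbind(win_row, seq_len(L))]
  win_base[depth == 0] <- ref_chars[depth == 0]

  col_emit <- character(L)
  col_prob <- rep(NA_real_, L)
  col_supp <- as.integer(depth)
  keep <- !in_hp & win_base != "-"
  col_emit[keep] <- win_base[keep]
  col_prob[keep] <- ifelse(depth[keep] == 0, 0.5,
                           (win_count[keep] + 1) / (depth[keep] + 2))
  # assemble: per-column token + insertion token, homopolymer runs emitted
  # at their first column
  parts <- col_emit
  probs <- lapply(seq_len(L),
                  function(p) if (keep[p]) col_prob[p] else numeric())
  supps <- lapply(seq_len(L),
                  function(p) if (keep[p]) col_supp[p] else integer())
  for (i in seq_len(nrow(hp_runs))) {
    s <- hp_runs$start[i]
    h <- hp_emit[[i]]
    parts[s] <- h$seq
    probs[[s]] <- rep(h$prob, nchar(h$seq))
    supps[[s]] <- rep(h$depth, nchar(h$seq))
  }
  ins_parts <- character(L); ins_probs <- vector("list", L)
  ins_supps <- vector("list", L)
  for (a in names(ins_ok)) {
    ai <- as.integer(a)
    if (in_hp[ai]) next
    io <- ins_ok[[a]]
    ins_parts[ai] <- io$seq
    ins_probs[[ai]] <- rep(io$prob, nchar(io$seq))
    ins_supps[[ai]] <- rep(io$depth, nchar(io$seq))
  }
  seq_out <- paste(paste0(parts, ins_parts), collapse = "")
  prob_out <- numeric(nchar(seq_out))
  supp_out <- integer(nchar(seq_out))
  k <- 0L
  for (p in seq_len(L)) {
    np <- length(probs[[p]])
    if (np > 0) {
      prob_out[(k + 1L):(k + np)] <- probs[[p]]
      supp_out[(k + 1L):(k + np)] <- supps[[p]]
      k <- k + np
    }
    ni <- length(ins_probs[[p]])
    if (ni > 0) {
      prob_out[(k + 1L):(k + ni)] <- ins_probs[[p]]
      supp_out[(k + 1L):(k + ni)] <- ins_supps[[p]]
      k <- k + ni
    }
  }
  zd <- IRanges::IRanges(depth == 0)
  zero_depth <- data.frame(start = BiocGenerics::start(zd),
                           end = BiocGenerics::end(zd))
  list(sequence = seq_out, probability = prob_out, support = supp_out,
       zero_depth = zero_depth,
       read_ids = unique(layer$rows$qname))
}

new_consensus <- function(allele, core) {
  structure(list(allele = allele,
                 sequence = Biostrings::DNAString(core$sequence),
                 probability = core$probability, support = core$support,
                 zero_depth = core$zero_depth, read_ids = core$read_ids),
            class = "ConsensusAllele")
}

#' @export
print.ConsensusAllele <- function(x, ...) {
  cat(sprintf(
    "ConsensusAllele %s: %d bp, %d reads, mean support %.1fX\n",
    x$allele, length(x$sequence), length(x$read_ids), mean(x$support)))
  invisible(x)
}

# align a read set against an arbitrary sequence and return records
align_to_sequence <- function(reads, sequence, name = "ref",
                              preset = "map-ont") {
  ref <- Biostrings::DNAStringSet(list(
    if (methods::is(sequence, "DNAString")) sequence else
      Biostrings::DNAString(as.character(sequence))))
  names(ref) <- name
  aln <- mm2_align(reads, ref, preset = preset)
  attr(aln, "ref_name") <- name
  attr(aln, "ref_len") <- Biostrings::width(ref)[1]
  aln
}

#' First-round consensus of an allele
#'
#' Realigns the allele's reads against its adjusted reference and emits
#' the majority base per column (ties favour the reference), with majority
#' indel voting, modal run-length voting in homopolymer runs, and a
#' Laplace-smoothed probability per emitted base. Depth-0 columns emit the
#' reference base at the probability floor of 0.5 and are flagged.
#'
#' @param allele_reads `QualityScaledDNAStringSet` of the allele's reads.
#' @param allele_reference An `AlleleReference` (or any sequence).
#' @param hp_min_run Minimum homopolymer run length for length-voting.
#' @return A `ConsensusAllele`.
#' @export
first_consensus <- function(allele_reads, allele_reference,
                            hp_min_run = 4L) {
  seqv <- if (methods::is(allele_reference, "AlleleReference")) {
    allele_reference$sequence
  } else allele_reference
  allele <- if (methods::is(allele_reference, "AlleleReference")) {
    allele_reference$allele
  } else 1L
  if (length(allele_reads) == 0) {
    warning("no reads for allele ", allele,
            "; consensus equals the adjusted reference")
    L <- length(seqv)
    return(new_consensus(allele, list(
      sequence = as.character(seqv), probability = rep(0.5, L),
      support = rep(0L, L), zero_depth = data.frame(start = 1L, end = L),
      read_ids = character())))
  }
  aln <- align_to_sequence(allele_reads, seqv,
                           name = paste0("allele", allele))
  new_consensus(allele, consensus_core(aln, seqv, hp_min_run))
}

#' Re-assign all on-target reads to the better-matching allele consensus
#'
#' Each read is aligned to both first-round consensus sequences and
#' assigned to the one with the strictly better alignment score by at
#' least `min_margin`; reads without a sufficient margin are removed as
#' ambiguous. Previously unassigned reads overlapping a het site are
#' recovered here.
#'
#' @param reads All on-target reads (`QualityScaledDNAStringSet`).
#' @param consensus1,consensus2 First-round `ConsensusAllele` objects.
#' @param min_margin Minimum alignment-score difference.
#' @return List with `allele1`, `allele2`, `removed` (read ids), and
#'   `scores` (per-read score table).
#' @export
reassign_reads <- function(reads, consensus1, consensus2,
                           min_margin = 10L) {
  a1 <- align_to_sequence(reads, consensus1$sequence, name = "c1")
  a2 <- align_to_sequence(reads, consensus2$sequence, name = "c2")
  best_as <- function(aln) {
    pri <- aln[aln$mapped & !aln$is_secondary & !aln$is_supplementary, ,
               drop = FALSE]
    stats::setNames(pri$AS, pri$qname)
  }
  s1 <- best_as(a1); s2 <- best_as(a2)
  ids <- names(reads)
  sc1 <- ifelse(ids %in% names(s1), s1[ids], -Inf)
  sc2 <- ifelse(ids %in% names(s2), s2[ids], -Inf)
  assigned <- ifelse(sc1 - sc2 >= min_margin, 1L,
                     ifelse(sc2 - sc1 >= min_margin, 2L, 0L))
  assigned[is.infinite(sc1) & is.infinite(sc2)] <- 0L
  list(allele1 = ids[assigned == 1L], allele2 = ids[assigned == 2L],
       removed = ids[assigned == 0L],
       scores = data.frame(read_id = ids, score1 = sc1, score2 = sc2,
                           assigned = assigned))
}

#' Final consensus from the re-assigned read set
#'
#' Same column logic as [first_consensus()], applied to the enlarged read
#' set aligned against the first-round consensus. This is the sequence
#' used for gene identification and star-allele calling. With unchanged
#' read sets the operation is idempotent.
#'
#' @param assigned_reads Reads assigned to this allele after
#'   [reassign_reads()].
#' @param consensus The allele's first-round `ConsensusAllele`.
#' @param hp_min_run Minimum homopolymer run length for length-voting.
#' @return A `ConsensusAllele`.
#' @export
final_consensus <- function(assigned_reads, consensus, hp_min_run = 4L) {
  if (length(assigned_reads) == 0) {
    warning("no reads for allele ", consensus$allele,
            "; final consensus equals round-1 consensus")
    return(consensus)
  }
  aln <- align_to_sequence(assigned_reads, consensus$sequence,
                           name = paste0("allele", consensus$allele))
  new_consensus(consensus$allele,
                consensus_core(aln, consensus$sequence, hp_min_run))
}
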