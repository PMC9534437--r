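# Gene-copy and hybrid identification on a final consensus: locate all
# high-identity copies of the two source-gene references, profile their
# mismatches against each source, and assign each stretch to the source
# with the fewest mismatches by an exact dynamic program over
# paralog-diagnostic positions (the only columns that carry source
# signal at ~94% paralog identity). Hybrids are reconstructed by
# concatenating the assigned fragments.

#' Extract the gene reference sequences from a locus
#'
#' @param locus A [locus_reference()] with annotated genes.
#' @return Named `DNAStringSet` of the gene sequences.
#' @export
gene_references <- function(locus) {
  g <- locus$genes
  out <- Biostrings::DNAStringSet(lapply(seq_len(nrow(g)), function(i) {
    Biostrings::subseq(locus$sequence, g$start[i], g$end[i])
  }))
  names(out) <- g$gene
  out
}

#' Locate candidate gene-copy intervals on a consensus
#'
#' Maps each gene reference against the consensus and merges all
#' high-identity hits into non-overlapping candidate copy intervals. The
#' number of intervals is the copy count of the allele: a whole-gene
#' deletion yields one fewer interval, a duplication-insertion one more.
#'
#' @param consensus A `ConsensusAllele` or sequence.
#' @param gene_refs Named `DNAStringSet` from [gene_references()].
#' @param min_identity Minimum alignment identity of a hit.
#' @param min_len_frac Minimum merged-interval length as a fraction of the
#'   shortest gene.
#' @param merge_gap Hits closer than this are merged into one interval.
#' @return `data.frame` of candidate copy intervals (`start`, `end`).
#' @export
locate_gene_copies <- function(consensus, gene_refs, min_identity = 0.9,
                               min_len_frac = 0.5, merge_gap = 300L) {
  seqv <- if (methods::is(consensus, "ConsensusAllele")) {
    consensus$sequence
  } else consensus
  if (length(gene_refs) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  # iterative align-and-mask so that repeated (duplicated) copies are all
  # found: a single alignment pass only reports the best placement of
  # each gene reference
  intervals <- list()
  for (gi in seq_along(gene_refs)) {
    masked <- as.character(seqv)
    for (round in 1:4) {
      aln <- align_to_sequence(gene_refs[gi],
                               Biostrings::DNAString(masked),
                               name = "consensus")
      hits <- aln[aln$mapped & !aln$is_secondary, , drop = FALSE]
      if (nrow(hits) > 0) {
        alen <- hits$end - hits$pos + 1L
        identity <- 1 - hits$NM / alen
        hits <- hits[identity >= min_identity &
                       alen >= 0.25 * Biostrings::width(gene_refs)[gi], ,
                     drop = FALSE]
      }
      if (nrow(hits) == 0) break
      for (k in seq_len(nrow(hits))) {
        intervals[[length(intervals) + 1L]] <- c(hits$pos[k],
                                                 hits$end[k])
        substr(masked, hits$pos[k], hits$end[k]) <-
          strrep("N", hits$end[k] - hits$pos[k] + 1L)
      }
    }
  }
  if (length(intervals) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  iv <- do.call(rbind, intervals)
  merged <- IRanges::reduce(IRanges::IRanges(iv[, 1], iv[, 2]),
                            min.gapwidth = merge_gap)
  min_w <- min(Biostrings::width(gene_refs)) * min_len_frac
  merged <- merged[BiocGenerics::width(merged) >= min_w]
  data.frame(start = BiocGenerics::start(merged),
             end = BiocGenerics::end(merged))
}

# Walk one global pairwise alignment (gene vs copy) into an event profile.
# Events are mismatches and indel runs of the copy relative to the gene,
# with anchored ref/alt tokens in gene-local coordinates.
alignment_profile <- function(gene_seq, copy_seq) {
  al <- Biostrings::pairwiseAlignment(
    pattern = gene_seq, subject = copy_seq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -4),
    gapOpening = 6, gapExtension = 1)
  gp <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sp <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gpos <- cumsum(gp != "-")
  cpos <- cumsum(sp != "-")
  n <- length(gp)
  ev <- list()
  i <- 1L
  while (i <= n) {
    if (gp[i] != "-" && sp[i] != "-") {
      if (gp[i] != sp[i]) {
        ev[[length(ev) + 1L]] <- data.frame(
          copy_pos = cpos[i], gene_pos = gpos[i], type = "mismatch",
          ref = gp[i], alt = sp[i], stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (gp[i] == "-") {          # insertion in the copy
      j <- i
      while (j <= n && gp[j] == "-") j <- j + 1L
      anchor_g <- max(gpos[i] - 0L, 1L)   # gene base before the run
      anchor_c <- max(cpos[i] - 1L, 1L)
      inserted <- paste(sp[i:(j - 1L)], collapse = "")
      anchor_base <- as.character(Biostrings::subseq(gene_seq, anchor_g,
                                                     anchor_g))
      ev[[length(ev) + 1L]] <- data.frame(
        copy_pos = anchor_c + 1L, gene_pos = anchor_g, type = "ins",
        ref = anchor_base, alt = paste0(anchor_base, inserted),
        stringsAsFactors = FALSE)
      i <- j
    } else {                             # deletion in the copy
      j <- i
      while (j <= n && sp[j] == "-") j <- j + 1L
      anchor_g <- max(gpos[i] - 1L, 1L)
      anchor_base <- as.character(Biostrings::subseq(gene_seq, anchor_g,
                                                     anchor_g))
      deleted <- paste(gp[i:(j - 1L)], collapse = "")
      ev[[length(ev) + 1L]] <- data.frame(
        copy_pos = max(cpos[i], 1L), gene_pos = anchor_g, type = "del",
        ref = paste0(anchor_base, deleted), alt = anchor_base,
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  prof <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(copy_pos = integer(), gene_pos = integer(),
               type = character(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  list(profile = prof, score = Biostrings::score(al),
       identity = 1 - nrow(prof) / nchar(as.character(copy_seq)))
}

#' Mismatch profiles of one candidate copy against both source genes
#'
#' Globally aligns each source-gene reference to the copy sequence and
#' returns the aligned event positions (SNVs and small indels, each
#' counted once) per source, in copy-local coordinates, with anchored
#' variant tokens in gene-local coordinates.
#'
#' @param copy_interval `c(start, end)` of the candidate copy on the
#'   consensus.
#' @param consensus A `ConsensusAllele` or sequence.
#' @param gene_refs Named `DNAStringSet` of the source genes.
#' @param min_identity Identity below which the copy is flagged
#'   unclassified for that source.
#' @return List of class `mismatch_profiles`: per gene a profile
#'   data.frame, plus `identity` and `unclassified`.
#' @export
mismatch_profiles <- function(copy_interval, consensus, gene_refs,
                              min_identity = 0.9) {
  seqv <- if (methods::is(consensus, "ConsensusAllele")) {
    consensus$sequence
  } else consensus
  copy_seq <- Biostrings::subseq(seqv, copy_interval[1], copy_interval[2])
  profs <- lapply(seq_along(gene_refs), function(i) {
    alignment_profile(gene_refs[[i]], copy_seq)
  })
  names(profs) <- names(gene_refs)
  identity <- vapply(profs, `[[`, numeric(1), "identity")
  structure(list(profiles = lapply(profs, `[[`, "profile"),
                 identity = identity,
                 unclassified = all(identity < min_identity),
                 copy_interval = as.integer(copy_interval),
                 copy_len = copy_interval[2] - copy_interval[1] + 1L,
                 genes = names(gene_refs)),
            class = "mismatch_profiles")
}

#' Optimal least-mismatch segmentation of a gene copy
#'
#' Exact two-state dynamic program over the paralog-diagnostic positions
#' (copy positions where exactly one source mismatches): each position
#' costs one mismatch if assigned to the source that mismatches there,
#' and each source switch costs `switch_penalty`. The minimizer assigns
#' every stretch to the source with the fewest mismatches; an infinite
#' penalty reduces to the global least-mismatch gene.
#'
#' @param profiles A [mismatch_profiles()] result (two genes).
#' @param switch_penalty Cost of one source switch, in diagnostic
#'   mismatches.
#' @param tie_break Source label used when a copy carries no diagnostic
#'   signal (default the gene whose locus slot the copy occupies, as
#'   supplied by the caller; falls back to the first gene).
#' @return `data.frame` of segments (`start`, `end` in copy-local
#'   coordinates, `source`, `mismatches_assigned`, `mismatches_other`).
#' @export
segment_and_assign <- function(profiles, switch_penalty = 3,
                               tie_break = NULL) {
  genes <- profiles$genes[1:2]
  tie_break <- tie_break %||% genes[1]
  p1 <- profiles$profiles[[genes[1]]]$copy_pos
  p2 <- profiles$profiles[[genes[2]]]$copy_pos
  diag_pos <- sort(union(setdiff(p1, p2), setdiff(p2, p1)))
  L <- profiles$copy_len
  count_in <- function(g, s, e) {
    sum(profiles$profiles[[g]]$copy_pos >= s &
          profiles$profiles[[g]]$copy_pos <= e)
  }
  segment_row <- function(s, e, src) {
    other <- setdiff(genes, src)[1]
    data.frame(start = s, end = e, source = src,
               mismatches_assigned = count_in(src, s, e),
               mismatches_other = count_in(other, s, e),
               stringsAsFactors = FALSE)
  }
  k <- length(diag_pos)
  if (k == 0) {
    return(segment_row(1L, L, tie_break))
  }
  # cost of labelling diagnostic position i with gene g: 1 if g
  # mismatches there
  cost <- cbind(as.integer(diag_pos %in% p1),
                as.integer(diag_pos %in% p2))
  D <- matrix(Inf, nrow = k, ncol = 2)
  back <- matrix(NA_integer_, nrow = k, ncol = 2)
  D[1, ] <- cost[1, ]
  if (k > 1) for (i in 2:k) for (g in 1:2) {
    stay <- D[i - 1, g]
    sw <- D[i - 1, 3 - g] + switch_penalty
    if (stay <= sw) { D[i, g] <- stay + cost[i, g]; back[i, g] <- g }
    else { D[i, g] <- sw + cost[i, g]; back[i, g] <- 3L - g }
  }
  lab <- integer(k)
  # final label: lower cost; tie -> the caller's tie-break gene
  tb <- match(tie_break, genes)
  lab[k] <- if (D[k, 1] < D[k, 2]) 1L else if (D[k, 2] < D[k, 1]) 2L else tb
  if (k > 1) for (i in k:2) lab[i - 1] <- back[i, lab[i]]
  # collapse runs into segments with boundaries midway between adjacent
  # diagnostic positions of different labels
  bounds <- c(1L)
  seg_lab <- lab[1]
  segs <- list()
  for (i in seq_len(k - 1)) {
    if (lab[i + 1] != lab[i]) {
      cut <- as.integer(floor((diag_pos[i] + diag_pos[i + 1]) / 2))
      segs[[length(segs) + 1L]] <- segment_row(
        bounds[length(bounds)], cut, genes[lab[i]])
      bounds <- c(bounds, cut + 1L)
    }
  }
  segs[[length(segs) + 1L]] <- segment_row(bounds[length(bounds)], L,
                                           genes[lab[k]])
  do.call(rbind, segs)
}

#' Reconstruct a gene copy (pure or hybrid) from its segments
#'
#' Adjacent same-source segments are merged; a copy drawing on more than
#' one source is labelled a hybrid with its switch positions, exactly the
#' concatenation of the assigned fragments.
#'
#' @param segments Output of [segment_and_assign()].
#' @param copy_interval `c(start, end)` of the copy on the consensus.
#' @param allele Allele index.
#' @return A `GeneCopy`: list with `allele`, `interval`, `segments`
#'   (consensus coordinates), `label`, `sources`, `switches` (consensus
#'   coordinates of the source switches).
#' @export
reconstruct_hybrids <- function(segments, copy_interval = NULL,
                                allele = 1L) {
  offset <- if (is.null(copy_interval)) 0L else copy_interval[1] - 1L
  merged <- segments[1, , drop = FALSE]
  for (i in seq_len(nrow(segments) - 1L)) {
    s <- segments[i + 1L, ]
    j <- nrow(merged)
    if (s$source == merged$source[j]) {
      merged$end[j] <- s$end
      merged$mismatches_assigned[j] <-
        merged$mismatches_assigned[j] + s$mismatches_assigned
      merged$mismatches_other[j] <-
        merged$mismatches_other[j] + s$mismatches_other
    } else merged <- rbind(merged, s)
  }
  sources <- merged$source
  label <- if (length(sources) == 1) sources else
    paste0("hybrid(", paste(sources, collapse = "::"), ")")
  switches <- if (nrow(merged) > 1) {
    merged$start[-1] + offset
  } else integer()
  out <- merged
  out$start <- out$start + offset
  out$end <- out$end + offset
  structure(list(allele = allele,
                 interval = if (is.null(copy_interval)) {
                   c(min(out$start), max(out$end))
                 } else as.integer(copy_interval),
                 segments = out, label = label, sources = sources,
                 switches = as.integer(switches),
                 switch_local = if (nrow(merged) > 1) {
                   as.integer(merged$start[-1])
                 } else integer()),
            class = "GeneCopy")
}

#' Score the small variants of a gene copy
#'
#' The copy's variants are the profile events of each segment's assigned
#' source within that segment, reported in gene-local coordinates and
#' left-aligned; events matching the other source's diagnostic allele
#' inside a segment are by construction not reported (they are the
#' paralog base, not variants). Quality is derived from the consensus
#' probability track at the variant position,
#' `Q = -10 log10(1 - p)`, capped at 60.
#'
#' @param gene_copy A [reconstruct_hybrids()] result.
#' @param profiles The copy's [mismatch_profiles()].
#' @param probability_track Consensus probability track (full consensus).
#' @param gene_refs Named `DNAStringSet` (for indel normalization).
#' @return `data.frame` of variants: `gene`, `pos` (gene-local), `ref`,
#'   `alt`, `kind`, `qual`.
#' @export
score_copy_variants <- function(gene_copy, profiles, probability_track,
                                gene_refs) {
  offset <- profiles$copy_interval[1] - 1L
  out <- list()
  for (i in seq_len(nrow(gene_copy$segments))) {
    seg <- gene_copy$segments[i, ]
    src <- seg$source
    prof <- profiles$profiles[[src]]
    # segment bounds are consensus coordinates; profiles are copy-local
    sel <- prof[prof$copy_pos >= seg$start - offset &
                  prof$copy_pos <= seg$end - offset, , drop = FALSE]
    if (nrow(sel) == 0) next
    gseq <- as.character(gene_refs[[src]])
    for (j in seq_len(nrow(sel))) {
      v <- normalize_variant(sel$gene_pos[j], sel$ref[j], sel$alt[j],
                             gseq)
      cons_pos <- sel$copy_pos[j] + offset
      p <- probability_track[min(cons_pos, length(probability_track))]
      qv <- if (p >= 1) 60 else min(60, -10 * log10(1 - p))
      out[[length(out) + 1L]] <- data.frame(
        gene = src, pos = v$pos, ref = v$ref, alt = v$alt,
        kind = variant_kind(v$ref, v$alt), qual = qv,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(), qual = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}
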