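# Large-SV breakpoint detection from clipped and split alignments, event
# classification, and construction of an adjusted reference per allele.
#
# All junction evidence is reduced to one representation: a pair of
# reference coordinates (pos_a = first sample base after the junction's
# left anchor, pos_b = reference coordinate the sample continues at).
# Soft clips needing remapping, supplementary (split) alignments, and
# large deletion gap operations all feed this single code path.

#' Extract clip and split-alignment signals
#'
#' One signal per soft clip of at least `min_clip_len` bases on a
#' phased-allele read. Split (supplementary) alignments are converted into
#' equivalent junction signals directly (anchor = primary end, remap =
#' supplementary start), as are deletion gap operations of at least
#' `min_clip_len` bases, so either aligner behaviour feeds one code path.
#' Reads not assigned to an allele are excluded.
#'
#' @param alignments Filtered alignment records.
#' @param partition A [phase_reads()] partition, or `NULL` to treat all
#'   reads as one allele.
#' @param min_clip_len Minimum clip (or gap) length in bases.
#' @return `data.frame` of signals: `read_id`, `allele`, `type`
#'   (`clip`/`split`/`gap`), `side`, `anchor`, `clip_seq`, and for
#'   pre-resolved junctions the breakpoint pair `pos_a`, `pos_b`.
#' @export
extract_clips <- function(alignments, partition = NULL,
                          min_clip_len = 200L) {
  allele_of <- function(q) {
    if (is.null(partition)) return(1L)
    if (q %in% partition$allele1) return(1L)
    if (q %in% partition$allele2) return(2L)
    NA_integer_
  }
  rows <- alignments[alignments$mapped & !alignments$is_secondary, ,
                     drop = FALSE]
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (q in unique(rows$qname)) {
    al <- allele_of(q)
    if (is.na(al)) next
    rr <- rows[rows$qname == q, , drop = FALSE]
    # order segments by query start in the stored (reference-forward)
    # orientation; for same-strand segments this is sample order
    rr <- rr[order(rr$left_clip), , drop = FALSE]
    if (nrow(rr) > 1 && length(unique(rr$strand)) == 1) {
      qstart <- rr$left_clip + 1L
      qend <- rr$read_len - rr$right_clip
      for (i in seq_len(nrow(rr) - 1L)) {
        # microhomology at the junction makes the segments overlap in
        # query space; trim the double-counted bases off the left anchor
        overlap <- max(0L, qend[i] - qstart[i + 1L] + 1L)
        add(read_id = q, allele = al, type = "split", side = NA,
            anchor = rr$end[i] + 1L - overlap, clip_seq = NA,
            pos_a = rr$end[i] + 1L - overlap, pos_b = rr$pos[i + 1L])
      }
    }
    # large deletion gaps within one record
    for (i in seq_len(nrow(rr))) {
      dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        rr$cigar[i], ops = "D", pos = rr$pos[i])[[1]]
      dr <- dr[BiocGenerics::width(dr) >= min_clip_len]
      for (j in seq_along(dr)) {
        add(read_id = q, allele = al, type = "gap", side = NA,
            anchor = BiocGenerics::start(dr)[j], clip_seq = NA,
            pos_a = BiocGenerics::start(dr)[j],
            pos_b = BiocGenerics::end(dr)[j] + 1L)
      }
    }
    # unresolved soft clips (only on the outer ends of the segment chain)
    first <- rr[1, ]; last <- rr[nrow(rr), ]
    if (first$left_clip >= min_clip_len) {
      add(read_id = q, allele = al, type = "clip", side = "left",
          anchor = first$pos,
          clip_seq = substr(first$seq, 1L, first$left_clip),
          pos_a = NA_integer_, pos_b = NA_integer_)
    }
    if (last$right_clip >= min_clip_len) {
      add(read_id = q, allele = al, type = "clip", side = "right",
          anchor = last$end,
          clip_seq = substr(last$seq,
                            last$read_len - last$right_clip + 1L,
                            last$read_len),
          pos_a = NA_integer_, pos_b = NA_integer_)
    }
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(), allele = integer(),
                      type = character(), side = character(),
                      anchor = integer(), clip_seq = character(),
                      pos_a = integer(), pos_b = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Remap clip sequences to the locus
#'
#' Clipped-off sequence ends are re-aligned to the locus; a same-strand
#' remapping resolves the clip into a breakpoint pair. Clips that fail to
#' map (or map inverted) keep `pos_a`/`pos_b` as `NA` and are dropped from
#' clustering.
#'
#' @param clips Output of [extract_clips()].
#' @param locus_reference A [locus_reference()].
#' @param min_mapq Minimum mapping quality of the remapped clip.
#' @return The signal table with breakpoint pairs filled in.
#' @export
remap_clips <- function(clips, locus_reference, min_mapq = 10L) {
  todo <- which(clips$type == "clip" & !is.na(clips$clip_seq))
  if (length(todo) == 0) return(clips)
  qs <- Biostrings::DNAStringSet(clips$clip_seq[todo])
  names(qs) <- paste0("clip", seq_along(todo))
  aln <- mm2_align(qs, Biostrings::DNAStringSet(
    stats::setNames(list(locus_reference$sequence), locus_reference$name)))
  pri <- aln[aln$mapped & !aln$is_secondary & !aln$is_supplementary, ,
             drop = FALSE]
  for (k in seq_along(todo)) {
    i <- todo[k]
    hit <- pri[pri$qname == paste0("clip", k), , drop = FALSE]
    if (nrow(hit) == 0 || hit$mapq[1] < min_mapq ||
        hit$strand[1] != "+") next
    if (clips$side[i] == "right") {
      clips$pos_a[i] <- clips$anchor[i] + 1L
      clips$pos_b[i] <- hit$pos[1] - hit$left_clip[1]
    } else {
      clips$pos_a[i] <- hit$end[1] + hit$right_clip[1] + 1L
      clips$pos_b[i] <- clips$anchor[i]
    }
  }
  clips
}

#' Cluster junction signals into breakpoints
#'
#' Single-linkage clustering of `(pos_a, pos_b)` pairs per allele with a
#' positional tolerance on both coordinates; the reported position is the
#' per-cluster median. Clusters supported by fewer than `min_support`
#' reads are discarded (the breakpoint-support rule).
#'
#' @param clips Signal table with `pos_a`/`pos_b` filled.
#' @param tolerance Positional tolerance in bp on both coordinates.
#' @param min_support Minimum distinct supporting reads per breakpoint.
#' @return `data.frame` of breakpoints: `allele`, `pos_a`, `pos_b`,
#'   `support`.
#' @export
cluster_breakpoints <- function(clips, tolerance = 20L, min_support = 3L) {
  cl <- clips[!is.na(clips$pos_a) & !is.na(clips$pos_b), , drop = FALSE]
  out <- list()
  for (al in unique(cl$allele)) {
    s <- cl[cl$allele == al, , drop = FALSE]
    n <- nrow(s)
    comp <- seq_len(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j &&
          abs(s$pos_a[i] - s$pos_a[j]) <= tolerance &&
          abs(s$pos_b[i] - s$pos_b[j]) <= tolerance) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
    for (cc in unique(comp)) {
      sub <- s[comp == cc, , drop = FALSE]
      support <- length(unique(sub$read_id))
      if (support < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        allele = al,
        pos_a = as.integer(round(stats::median(sub$pos_a))),
        pos_b = as.integer(round(stats::median(sub$pos_b))),
        support = support)
    }
  }
  if (length(out) == 0) {
    return(data.frame(allele = integer(), pos_a = integer(),
                      pos_b = integer(), support = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$allele, -res$support), , drop = FALSE]
}

#' Classify a breakpoint into a structural variant
#'
#' Forward-orientation junctions only: a junction skipping forward
#' (`pos_b > pos_a`) is a deletion of `[pos_a, pos_b)`; a junction jumping
#' back (`pos_b < pos_a`) is a tandem duplication of `[pos_b, pos_a)`. A
#' duplication whose copied interval spans parts of both annotated genes
#' is labelled a hybrid insertion. Zero-length junctions are dropped.
#'
#' @param breakpoints Output of [cluster_breakpoints()].
#' @param locus_reference Optional [locus_reference()]; needed for the
#'   hybrid-insertion label.
#' @return `data.frame` of SVs: `allele`, `kind`, `start`, `end`,
#'   `length`, `support`.
#' @export
classify_sv <- function(breakpoints, locus_reference = NULL) {
  out <- list()
  for (i in seq_len(nrow(breakpoints))) {
    b <- breakpoints[i, ]
    if (b$pos_a == b$pos_b) next
    if (b$pos_b > b$pos_a) {
      kind <- "DEL"; s <- b$pos_a; e <- b$pos_b - 1L
    } else {
      kind <- "DUP"; s <- b$pos_b; e <- b$pos_a - 1L
      if (!is.null(locus_reference) && nrow(locus_reference$genes) >= 2) {
        g <- locus_reference$genes
        spans <- (s <= g$end) & (e >= g$start)
        if (sum(spans) >= 2) kind <- "HYBRID_INS"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      allele = b$allele, kind = kind, start = s, end = e,
      length = e - s + 1L, support = b$support, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(allele = integer(), kind = character(),
                      start = integer(), end = integer(),
                      length = integer(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the adjusted reference for one allele
#'
#' Splices the detected structural variants into the locus sequence:
#' deletions remove their interval; duplications (and hybrid insertions)
#' insert the copied interval immediately after its source in tandem
#' orientation. The segment map records provenance for [liftover()].
#'
#' @param locus_reference A [locus_reference()].
#' @param svs SV table (possibly empty) for this allele; must be
#'   non-overlapping.
#' @param allele Allele index recorded on the result.
#' @return An `AlleleReference`: list with `allele`, `sequence`,
#'   `segment_map`, `events`.
#' @export
build_allele_reference <- function(locus_reference, svs, allele = 1L) {
  refseq <- as.character(locus_reference$sequence)
  L <- nchar(refseq)
  if (is.null(svs) || nrow(svs) == 0) {
    svs <- data.frame(allele = integer(), kind = character(),
                      start = integer(), end = integer(),
                      length = integer(), support = integer())
  }
  svs <- svs[order(svs$start), , drop = FALSE]
  if (nrow(svs) > 1 && any(svs$start[-1] <= svs$end[-nrow(svs)])) {
    stop("overlapping structural variants: ",
         paste(sprintf("%s[%d-%d]", svs$kind, svs$start, svs$end),
               collapse = ", "), call. = FALSE)
  }
  pieces <- list(); seg <- list()
  emit <- function(from, to, copy_index = 1L) {
    if (from > to) return(invisible())
    pieces[[length(pieces) + 1L]] <<- substr(refseq, from, to)
    seg[[length(seg) + 1L]] <<- data.frame(
      r_start = from, r_end = to, copy_index = copy_index,
      width = to - from + 1L)
    invisible()
  }
  pos <- 1L
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    if (sv$kind == "DEL") {
      emit(pos, sv$start - 1L)
      pos <- sv$end + 1L
    } else if (sv$kind %in% c("DUP", "HYBRID_INS")) {
      emit(pos, sv$end)
      emit(sv$start, sv$end, copy_index = 2L)
      pos <- sv$end + 1L
    } else {
      stop("unsupported event kind '", sv$kind, "'", call. = FALSE)
    }
  }
  emit(pos, L)
  segmap <- do.call(rbind, seg)
  segmap$a_end <- cumsum(segmap$width)
  segmap$a_start <- segmap$a_end - segmap$width + 1L
  segmap <- segmap[, c("a_start", "a_end", "r_start", "r_end",
                       "copy_index")]
  structure(list(allele = allele,
                 sequence = Biostrings::DNAString(
                   paste(unlist(pieces), collapse = "")),
                 segment_map = segmap, events = svs),
            class = "AlleleReference")
}
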