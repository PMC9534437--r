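# Locus model: reference sequence, gene annotations, star-allele definitions,
# and coordinate bookkeeping. All internal coordinates are 1-based closed
# (the IRanges convention); BED I/O converts at the boundary via rtracklayer
# and VCF I/O is 1-based by standard.

#' Construct a locus reference
#'
#' A `LocusReference` bundles the sequence of a target locus with its gene
#' annotations. It is the coordinate frame for every downstream stage:
#' alignment, breakpoint detection, allele-reference construction and gene
#' identification all report positions relative to this locus.
#'
#' @param name Contig name of the locus.
#' @param sequence Locus sequence (`DNAString` or character).
#' @param genes `data.frame` with columns `gene`, `start`, `end`, `strand`
#'   (1-based closed, non-overlapping, within the locus).
#' @param region Optional `(contig, start, end)` of the locus in an external
#'   reference frame (e.g. a chromosome); defaults to the locus itself.
#' @return An object of class `LocusReference`.
#' @export
locus_reference <- function(name, sequence, genes = NULL, region = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  len <- length(sequence)
  if (is.null(genes)) {
    genes <- data.frame(gene = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(genes) > 0) {
    stopifnot(all(genes$start <= genes$end))
    if (any(genes$start < 1L) || any(genes$end > len)) {
      stop("gene annotation outside the locus sequence", call. = FALSE)
    }
    genes <- genes[order(genes$start), , drop = FALSE]
    if (nrow(genes) > 1 &&
        any(genes$start[-1] <= genes$end[-nrow(genes)])) {
      stop("gene annotations overlap", call. = FALSE)
    }
  }
  if (is.null(region)) region <- list(contig = name, start = 1L, end = len)
  if (region$end - region$start + 1L != len) {
    stop("region length does not equal sequence length", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, genes = genes,
                 region = region),
            class = "LocusReference")
}

#' @export
print.LocusReference <- function(x, ...) {
  cat(sprintf("LocusReference '%s': %d bp, %d gene(s)\n",
              x$name, length(x$sequence), nrow(x$genes)))
  if (nrow(x$genes) > 0) {
    for (i in seq_len(nrow(x$genes))) {
      cat(sprintf("  %s: %d-%d (%s)\n", x$genes$gene[i], x$genes$start[i],
                  x$genes$end[i], x$genes$strand[i]))
    }
  }
  invisible(x)
}

#' Load a locus reference from FASTA + BED
#'
#' The FASTA must contain a single record holding the locus sequence; the
#' BED6 file annotates the genes within it. An empty BED yields a locus with
#' zero genes (gene identification is then disabled downstream).
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param bed_path Path to a BED6 file of gene annotations (may be empty).
#' @return A [locus_reference()] object.
#' @export
load_reference <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) < 1L) stop("FASTA contains no record", call. = FALSE)
  if (length(seqs) > 1L) {
    stop("FASTA must contain exactly one locus record", call. = FALSE)
  }
  name <- sub("\\s.*", "", names(seqs)[1])
  sequence <- seqs[[1]]
  genes <- data.frame(gene = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!is.null(bed_path) && file.exists(bed_path) &&
      file.info(bed_path)$size > 0) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    if (length(gr) > 0) {
      if (!all(as.character(GenomicRanges::seqnames(gr)) == name)) {
        stop("BED contig does not match the FASTA locus contig '", name,
             "'", call. = FALSE)
      }
      if (any(GenomicRanges::end(gr) > length(sequence))) {
        stop("gene annotation extends beyond the locus sequence",
             call. = FALSE)
      }
      strand <- as.character(GenomicRanges::strand(gr))
      strand[strand == "*"] <- "+"
      genes <- data.frame(
        gene = gr$name %||% paste0("gene", seq_along(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  locus_reference(name, sequence, genes)
}

#' Write a locus reference to FASTA + BED
#'
#' @param locus A [locus_reference()] object.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(locus, fasta_path, bed_path = NULL) {
  seqs <- Biostrings::DNAStringSet(list(locus$sequence))
  names(seqs) <- locus$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    if (nrow(locus$genes) > 0) {
      gr <- GenomicRanges::GRanges(
        seqnames = locus$name,
        ranges = IRanges::IRanges(locus$genes$start, locus$genes$end),
        strand = locus$genes$strand, name = locus$genes$gene,
        score = 0L)
      rtracklayer::export(gr, bed_path, format = "BED")
    } else {
      file.create(bed_path)
    }
  }
  invisible(c(fasta_path, bed_path))
}

# numeric star number of an allele name like "*4" -> 4
star_number <- function(allele) {
  suppressWarnings(as.numeric(sub("^\\*", "", allele)))
}

#' Load star-allele definitions
#'
#' Reads a tab-separated allele-definition table in the package's schema:
#' columns `allele`, `sub_allele`, `variants`, `structural_event`,
#' `source_gene`. `variants` holds semicolon-separated `pos:REF>ALT` tokens
#' in 1-based gene-local coordinates on the source gene's plus strand.
#' `structural_event` is empty, `gene_deletion`, or `hybrid:START-END`
#' where START-END is the gene-local switch region of a hybrid allele.
#'
#' Definitions are returned ordered by star number then sub-allele, one row
#' per definition, with the parsed variants in the list-column `variants`.
#'
#' @param table_path Path to the TSV definition table.
#' @return A `data.frame` of class `star_definitions`.
#' @export
load_star_definitions <- function(table_path) {
  tab <- utils::read.table(table_path, sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE,
                           na.strings = NULL, quote = "")
  required <- c("allele", "sub_allele", "variants", "structural_event")
  if (!all(required %in% names(tab))) {
    stop("definition table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (!"source_gene" %in% names(tab)) tab$source_gene <- ""
  key <- paste(tab$allele, tab$sub_allele)
  if (anyDuplicated(key)) {
    stop("duplicate (allele, sub_allele) rows in definition table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  parse_variants <- function(s, row) {
    s <- trimws(s)
    if (!nzchar(s)) {
      return(data.frame(pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    }
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(toks, regexec("^([0-9]+):([ACGTacgt]+)>([ACGTacgt]+)$",
                                  toks))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad)) {
      stop(sprintf("malformed variant token '%s' in definition table row %d",
                   toks[bad][1], row), call. = FALSE)
    }
    data.frame(pos = as.integer(vapply(m, `[`, character(1), 2L)),
               ref = toupper(vapply(m, `[`, character(1), 3L)),
               alt = toupper(vapply(m, `[`, character(1), 4L)),
               stringsAsFactors = FALSE)
  }
  vars <- lapply(seq_len(nrow(tab)),
                 function(i) parse_variants(tab$variants[i], i))
  ev <- trimws(tab$structural_event)
  ok_ev <- ev == "" | ev == "gene_deletion" |
    grepl("^hybrid:[0-9]+-[0-9]+$", ev)
  if (any(!ok_ev)) {
    stop("malformed structural_event in definition table row ",
         which(!ok_ev)[1], call. = FALSE)
  }
  if (any(ev == "gene_deletion" & vapply(vars, nrow, integer(1)) > 0)) {
    stop("a gene_deletion allele must have no defining variants",
         call. = FALSE)
  }
  switch_start <- switch_end <- rep(NA_integer_, nrow(tab))
  hy <- grepl("^hybrid:", ev)
  if (any(hy)) {
    parts <- regmatches(ev[hy], regexec("^hybrid:([0-9]+)-([0-9]+)$", ev[hy]))
    switch_start[hy] <- as.integer(vapply(parts, `[`, character(1), 2L))
    switch_end[hy] <- as.integer(vapply(parts, `[`, character(1), 3L))
  }
  out <- data.frame(allele = tab$allele, sub_allele = tab$sub_allele,
                    structural_event = ifelse(hy, "hybrid", ev),
                    switch_start = switch_start, switch_end = switch_end,
                    source_gene = tab$source_gene, stringsAsFactors = FALSE)
  out$variants <- vars
  ord <- order(star_number(out$allele), out$sub_allele)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("star_definitions", "data.frame")
  out
}

#' Write star-allele definitions
#'
#' Inverse of [load_star_definitions()]; a written table re-loads to an
#' identical definition set.
#'
#' @param defs A `star_definitions` object.
#' @param table_path Output TSV path.
#' @export
write_star_definitions <- function(defs, table_path) {
  fmt_var <- function(v) {
    if (nrow(v) == 0) return("")
    paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
  }
  ev <- defs$structural_event
  ev[ev == "hybrid"] <- sprintf("hybrid:%d-%d",
                                defs$switch_start[ev == "hybrid"],
                                defs$switch_end[ev == "hybrid"])
  out <- data.frame(allele = defs$allele, sub_allele = defs$sub_allele,
                    variants = vapply(defs$variants, fmt_var, character(1)),
                    structural_event = ev, source_gene = defs$source_gene,
                    stringsAsFactors = FALSE)
  utils::write.table(out, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table_path)
}

#' Convert gene-local defining variants to locus coordinates
#'
#' Gene-local 1-based positions on the plus strand of `gene` are shifted to
#' locus coordinates and left-aligned against the locus sequence.
#'
#' @param locus A [locus_reference()].
#' @param variants `data.frame` with `pos`, `ref`, `alt` (gene-local).
#' @param gene Gene name in `locus$genes`.
#' @return The same table in locus coordinates, normalized.
#' @export
gene_to_locus_variants <- function(locus, variants, gene) {
  g <- locus$genes[locus$genes$gene == gene, , drop = FALSE]
  if (nrow(g) != 1) stop("gene '", gene, "' not annotated on locus",
                         call. = FALSE)
  refseq <- as.character(locus$sequence)
  if (nrow(variants) == 0) return(variants)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    normalize_variant(variants$pos[i] + g$start - 1L,
                      variants$ref[i], variants$alt[i], refseq)
  })
  data.frame(pos = vapply(out, `[[`, integer(1), "pos"),
             ref = vapply(out, `[[`, character(1), "ref"),
             alt = vapply(out, `[[`, character(1), "alt"),
             stringsAsFactors = FALSE)
}

#' Lift a position on an allele-adjusted reference back to locus coordinates
#'
#' Uses the segment map carried by an `AlleleReference` (or any object with
#' a `segment_map` component, e.g. a `SimulatedHaplotype`). Positions inside
#' a duplicated (secondary-copy) segment are mapped to the original copy and
#' flagged `secondary = TRUE`.
#'
#' @param position Integer vector of 1-based positions on the allele
#'   sequence.
#' @param allele_reference Object with a `segment_map` data.frame
#'   (`a_start`, `a_end`, `r_start`, `r_end`, `copy_index`).
#' @return `data.frame` with columns `position` (locus coordinate) and
#'   `secondary`.
#' @export
liftover <- function(position, allele_reference) {
  sm <- allele_reference$segment_map
  alen <- max(sm$a_end)
  if (any(position < 1L | position > alen)) {
    stop("position outside the allele reference (length ", alen, ")",
         call. = FALSE)
  }
  out <- data.frame(position = rep(NA_integer_, length(position)),
                    secondary = rep(FALSE, length(position)))
  for (i in seq_along(position)) {
    p <- position[i]
    j <- which(sm$a_start <= p & p <= sm$a_end)[1]
    out$position[i] <- sm$r_start[j] + (p - sm$a_start[j])
    out$secondary[i] <- sm$copy_index[j] > 1L
  }
  out
}
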