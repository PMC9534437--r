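# Synthetic-data generator: a two-gene paralogous locus, diploid haplotypes
# carrying star-allele variant sets and structural events, Cas9-excised
# fragments in two gRNA pools, and nanopore-like error injection. Every
# downstream stage of the pipeline is testable against the truth records
# this module emits.

#' Default structural-event geometry of the synthetic locus
#'
#' Locus-relative coordinates (1-based closed) of the two large structural
#' events the generator can plant: a whole-gene deletion of 12,152 bp and a
#' tandem hybrid duplication of 13,680 bp. The geometry mirrors the
#' well-characterized CYP2D6 *5 deletion and *68 hybrid-duplication alleles
#' of reference cell line HG01190 (GRCh38 breakpoints shifted to the start
#' of the 28 kb CYP2D6-CYP2D7 target locus).
#'
#' @return List with `deletion` and `duplication`, each `c(start, end)`.
#' @export
synthetic_events <- function() {
  list(deletion = c(2027L, 14178L),     # 12,152 bp, removes gene 1
       duplication = c(11029L, 24708L)) # 13,680 bp, copies gene 2 + flanks
}

#' Default Cas9 cut sites per gRNA pool
#'
#' Pool A cuts upstream and downstream of the whole locus (full-locus
#' fragments); pool B adds a cut between the two genes (two sub-fragments,
#' boosting depth on each gene). Coordinates are locus-relative.
#'
#' @return Named list of integer vectors, one per pool.
#' @export
default_cut_sites <- function() {
  list(A = c(150L, 28050L), B = c(150L, 12800L, 28050L))
}

#' Generate a synthetic two-gene paralogous locus
#'
#' Builds a random locus carrying two gene copies of configurable identity
#' (default 94%, the CYP2D6/CYP2D7 situation): gene 2 is a mutated copy of
#' gene 1. The default geometry places the genes so that the structural
#' events of [synthetic_events()] delete gene 1 or duplicate gene 2 entirely,
#' with breakpoints in unique flanking sequence.
#'
#' @param locus_length Total locus length in bp.
#' @param gene_length Length of each gene copy.
#' @param gene1_start,gene2_start Start positions of the two genes.
#' @param identity Sequence identity between the two gene copies.
#' @param gene_names Names of the two genes.
#' @param contig Contig name.
#' @param seed RNG seed (the locus is deterministic given the seed).
#' @return A [locus_reference()].
#' @export
synthetic_locus <- function(locus_length = 28206L, gene_length = 4382L,
                            gene1_start = 5335L, gene2_start = 16385L,
                            identity = 0.94,
                            gene_names = c("CYP2D6", "CYP2D7"),
                            contig = "locus", seed = 42L) {
  stopifnot(gene1_start + gene_length <= gene2_start,
            gene2_start + gene_length - 1L <= locus_length)
  with_rng(seed, {
    chars <- sample(c("A", "C", "G", "T"), locus_length, replace = TRUE)
    g1 <- chars[gene1_start:(gene1_start + gene_length - 1L)]
    n_mut <- round((1 - identity) * gene_length)
    mut_pos <- sort(sample(gene_length, n_mut))
    g2 <- g1
    g2[mut_pos] <- other_base(g1[mut_pos])
    chars[gene2_start:(gene2_start + gene_length - 1L)] <- g2
    genes <- data.frame(gene = gene_names,
                        start = c(gene1_start, gene2_start),
                        end = c(gene1_start, gene2_start) + gene_length - 1L,
                        strand = c("+", "+"), stringsAsFactors = FALSE)
    locus_reference(contig, paste(chars, collapse = ""), genes)
  })
}

#' Star-allele definition table for a synthetic locus
#'
#' Derives a small PharmVar-style definition set consistent with the gene-1
#' sequence of `locus`: *1 (reference), *2 and *4 (SNV sets), *3 (frameshift
#' deletion), *5 (whole-gene deletion), and the hybrid alleles *68 and *13
#' distinguished by their gene-local switch regions. Reference bases are
#' read from the locus so the definitions always match the sequence the
#' simulator builds haplotypes from.
#'
#' @param locus A [locus_reference()] with two genes.
#' @param path Optional path; if given, the table is also written as TSV.
#' @return A `star_definitions` object.
#' @export
synthetic_star_table <- function(locus, path = NULL) {
  g <- locus$genes[1, ]
  g1 <- as.character(Biostrings::subseq(locus$sequence, g$start, g$end))
  base_at <- function(p) substr(g1, p, p)
  snv_set <- function(pos) {
    data.frame(pos = as.integer(pos),
               ref = vapply(pos, base_at, character(1)),
               alt = unname(transition(vapply(pos, base_at, character(1)))),
               stringsAsFactors = FALSE)
  }
  del_at <- function(p) {
    v <- normalize_variant(p, substr(g1, p, p + 1L), base_at(p), g1)
    data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
               stringsAsFactors = FALSE)
  }
  empty <- data.frame(pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  defs <- data.frame(
    allele = c("*1", "*2", "*3", "*4", "*5", "*13", "*68"),
    sub_allele = "",
    structural_event = c("", "", "", "", "gene_deletion", "hybrid", "hybrid"),
    switch_start = c(NA, NA, NA, NA, NA, 1400L, 600L),
    switch_end = c(NA, NA, NA, NA, NA, 1800L, 1000L),
    source_gene = g$gene, stringsAsFactors = FALSE)
  defs$variants <- list(
    empty,
    snv_set(c(311, 1127, 2173, 2851, 3209, 3790, 4121)),
    del_at(2636L),
    snv_set(c(137, 506, 974, 1662, 1846, 2549, 3183, 3944)),
    empty,
    empty,
    empty)
  ord <- order(star_number(defs$allele), defs$sub_allele)
  defs <- defs[ord, , drop = FALSE]
  rownames(defs) <- NULL
  class(defs) <- c("star_definitions", "data.frame")
  if (!is.null(path)) write_star_definitions(defs, path)
  defs
}

#' Nanopore-like error model
#'
#' Per-base independent substitution/insertion/deletion rates, with indel
#' rates multiplied inside homopolymer runs of at least
#' `homopolymer_min_run` bases (homopolymers are the dominant systematic
#' error mode of nanopore basecalls). Defaults stress the pipeline like
#' R9.4-era data.
#'
#' @param mismatch,insertion,deletion Per-base event probabilities.
#' @param homopolymer_multiplier Indel-rate multiplier inside homopolymer
#'   runs (>= 1).
#' @param homopolymer_min_run Minimum run length counting as a homopolymer.
#' @param quality_mean,quality_sd Per-base phred quality distribution.
#' @return An object of class `error_model`.
#' @export
error_model <- function(mismatch = 0.03, insertion = 0.02, deletion = 0.03,
                        homopolymer_multiplier = 4, homopolymer_min_run = 4L,
                        quality_mean = 12, quality_sd = 3) {
  stopifnot(mismatch >= 0, mismatch < 1, insertion >= 0, insertion < 1,
            deletion >= 0, deletion < 1, homopolymer_multiplier >= 1)
  structure(list(mismatch = mismatch, insertion = insertion,
                 deletion = deletion,
                 homopolymer_multiplier = homopolymer_multiplier,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "error_model")
}

# Error injection on the current RNG stream (no seed handling); returns
# list(sequence, qualities, edits).
inject_errors <- function(fragment_sequence, em) {
  chars <- strsplit(toupper(fragment_sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) {
    return(list(sequence = "", qualities = integer(),
                edits = data.frame(op = character(), pos = integer())))
  }
  r <- rle(chars)
  run_len <- rep(r$lengths, r$lengths)
  hp <- run_len >= em$homopolymer_min_run
  mult <- ifelse(hp, em$homopolymer_multiplier, 1)
  del_p <- pmin(em$deletion * mult, 0.9)
  ins_p <- pmin(em$insertion * mult, 0.9)
  deleted <- stats::runif(n) < del_p
  mism <- stats::runif(n) < em$mismatch & !deleted
  inserted <- stats::runif(n) < ins_p
  out <- chars
  if (any(mism)) out[mism] <- other_base(chars[mism])
  pieces <- ifelse(deleted, "", out)
  # inserted base duplicates the current base (the dominant ONT artifact)
  pieces <- paste0(pieces, ifelse(inserted, chars, ""))
  seq_out <- paste(pieces, collapse = "")
  len <- nchar(seq_out)
  quals <- as.integer(pmin(pmax(round(
    stats::rnorm(len, em$quality_mean, em$quality_sd)), 2L), 40L))
  edits <- data.frame(
    op = c(rep("mismatch", sum(mism)), rep("del", sum(deleted)),
           rep("ins", sum(inserted))),
    pos = c(which(mism), which(deleted), which(inserted)))
  list(sequence = seq_out, qualities = quals, edits = edits)
}

#' Inject nanopore-like errors into a fragment
#'
#' Per-base edits are drawn independently, except in homopolymer runs where
#' the indel rates are multiplied (see [error_model()]). Deterministic for a
#' given seed. The returned record carries the edit list so error rates can
#' be audited directly.
#'
#' @param fragment_sequence Character; the error-free fragment.
#' @param em An [error_model()].
#' @param seed RNG seed.
#' @param id Read identifier.
#' @return List with `id`, `sequence`, `qualities` (integer phred), and
#'   `edits` (data.frame of op/pos on the input fragment).
#' @export
add_errors <- function(fragment_sequence, em = error_model(), seed = 1L,
                       id = "read") {
  res <- with_rng(seed, inject_errors(fragment_sequence, em))
  c(list(id = id), res)
}

# --- haplotype construction ------------------------------------------------

# Build the hybrid occupant of a gene slot: head of gene 1 up to `switch`
# (gene-local), then the tail of `gene`.
hybrid_gene_sequence <- function(locus, gene, switch) {
  g1 <- locus$genes[1, ]
  gs <- locus$genes[locus$genes$gene == gene, , drop = FALSE]
  if (nrow(gs) != 1) stop("gene '", gene, "' not annotated", call. = FALSE)
  g1_len <- g1$end - g1$start + 1L
  g_len <- gs$end - gs$start + 1L
  if (switch < 1L || switch >= min(g1_len, g_len)) {
    stop("hybrid switch point outside gene", call. = FALSE)
  }
  head <- as.character(Biostrings::subseq(locus$sequence, g1$start,
                                          g1$start + switch - 1L))
  tail <- as.character(Biostrings::subseq(locus$sequence, gs$start + switch,
                                          gs$end))
  paste0(head, tail)
}

#' Build a simulated haplotype from structural directives and variants
#'
#' Constructs one haplotype of the locus by splicing structural events and
#' applying small variants, recording full truth: the applied variants and
#' events, a segment map (haplotype interval to reference interval with
#' copy index) for liftover, and the gene structure. Deterministic.
#'
#' Directives (`spec$directives`, each a list with `type`):
#' \describe{
#'   \item{`delete`}{remove reference interval `start..end`.}
#'   \item{`insert_hybrid_copy`}{tandem-duplicate reference interval
#'     `start..end` immediately after `end`; if `switch` is given, the gene
#'     copy inside the inserted interval (`gene`, default the second gene)
#'     is replaced by a gene1-head/gene-tail hybrid switching at the
#'     gene-local position `switch`.}
#'   \item{`replace_with_hybrid`}{replace the occupant of the `gene` slot
#'     in place by the hybrid switching at `switch` (no length change, no
#'     clip-detectable junction).}
#' }
#'
#' @param locus A [locus_reference()].
#' @param spec List with `name`, `directives` (list as above, may be empty)
#'   and `variants` (data.frame `pos`,`ref`,`alt` in locus coordinates).
#' @return An object of class `SimulatedHaplotype`.
#' @export
build_haplotype <- function(locus, spec) {
  refseq <- as.character(locus$sequence)
  L <- nchar(refseq)
  directives <- spec$directives %||% list()
  variants <- spec$variants %||%
    data.frame(pos = integer(), ref = character(), alt = character())

  # resolve directives to reference intervals and validate non-overlap
  iv <- lapply(directives, function(d) {
    if (d$type == "replace_with_hybrid") {
      g <- locus$genes[locus$genes$gene == (d$gene %||%
                                            locus$genes$gene[2]), ,
                       drop = FALSE]
      c(g$start, g$end)
    } else c(as.integer(d$start), as.integer(d$end))
  })
  if (length(iv) > 1) {
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("overlapping structural directives", call. = FALSE)
    }
  }
  ord <- order(vapply(iv, `[`, numeric(1), 1L))
  directives <- directives[ord]

  pieces <- list()      # character pieces
  seg <- list()         # segment map rows
  surgeries <- list()   # hybrid surgery records for gene_structure
  events <- list()
  pos <- 1L
  emit <- function(from, to, copy_index = 1L, override_seq = NULL) {
    if (!is.null(override_seq)) s <- override_seq
    else {
      if (from > to) return(invisible())
      s <- substr(refseq, from, to)
    }
    pieces[[length(pieces) + 1L]] <<- s
    seg[[length(seg) + 1L]] <<- data.frame(
      r_start = from, r_end = to, copy_index = copy_index,
      width = nchar(s))
    invisible()
  }
  for (d in directives) {
    if (d$type == "delete") {
      s <- as.integer(d$start); e <- as.integer(d$end)
      emit(pos, s - 1L)
      events[[length(events) + 1L]] <- data.frame(
        kind = "DEL", start = s, end = e, length = e - s + 1L,
        gene = NA_character_, switch = NA_integer_)
      pos <- e + 1L
    } else if (d$type == "insert_hybrid_copy") {
      s <- as.integer(d$start); e <- as.integer(d$end)
      gene <- d$gene %||% locus$genes$gene[2]
      emit(pos, e)
      copy <- substr(refseq, s, e)
      if (!is.null(d$switch) && !is.na(d$switch)) {
        g <- locus$genes[locus$genes$gene == gene, , drop = FALSE]
        if (g$start < s || g$end > e) {
          stop("hybridized gene not contained in duplicated interval",
               call. = FALSE)
        }
        hyb <- hybrid_gene_sequence(locus, gene, as.integer(d$switch))
        copy <- paste0(substr(copy, 1L, g$start - s),
                       hyb,
                       substr(copy, g$end - s + 2L, nchar(copy)))
        surgeries[[length(surgeries) + 1L]] <- list(
          gene = gene, copy_index = 2L, switch = as.integer(d$switch))
      }
      emit(s, e, copy_index = 2L, override_seq = copy)
      events[[length(events) + 1L]] <- data.frame(
        kind = "DUP", start = s, end = e, length = e - s + 1L,
        gene = gene, switch = as.integer(d$switch %||% NA))
      pos <- e + 1L
    } else if (d$type == "replace_with_hybrid") {
      gene <- d$gene %||% locus$genes$gene[2]
      g <- locus$genes[locus$genes$gene == gene, , drop = FALSE]
      emit(pos, g$start - 1L)
      hyb <- hybrid_gene_sequence(locus, gene, as.integer(d$switch))
      emit(g$start, g$end, copy_index = 1L, override_seq = hyb)
      surgeries[[length(surgeries) + 1L]] <- list(
        gene = gene, copy_index = 1L, switch = as.integer(d$switch))
      events[[length(events) + 1L]] <- data.frame(
        kind = "HYBRID_REPLACE", start = g$start, end = g$end,
        length = g$end - g$start + 1L, gene = gene,
        switch = as.integer(d$switch))
      pos <- g$end + 1L
    } else stop("unknown directive type '", d$type, "'", call. = FALSE)
  }
  emit(pos, L)
  segmap <- do.call(rbind, seg)
  segmap$a_end <- cumsum(segmap$width)
  segmap$a_start <- segmap$a_end - segmap$width + 1L
  segmap <- segmap[, c("a_start", "a_end", "r_start", "r_end", "copy_index")]
  hapseq <- paste(pieces, collapse = "")

  # apply small variants through the segment map (all copies of a region)
  applied <- list()
  if (nrow(variants) > 0) {
    targets <- list()
    for (i in seq_len(nrow(variants))) {
      p <- variants$pos[i]
      hits <- which(segmap$r_start <= p & p <= segmap$r_end)
      for (j in hits) {
        targets[[length(targets) + 1L]] <- data.frame(
          i = i, a_pos = segmap$a_start[j] + (p - segmap$r_start[j]))
      }
      if (length(hits) > 0) applied[[length(applied) + 1L]] <- variants[i, ]
    }
    if (length(targets) > 0) {
      tg <- do.call(rbind, targets)
      tg <- tg[order(-tg$a_pos), , drop = FALSE]
      for (k in seq_len(nrow(tg))) {
        v <- variants[tg$i[k], ]
        a <- tg$a_pos[k]
        have <- substr(hapseq, a, a + nchar(v$ref) - 1L)
        if (have != v$ref) {
          stop(sprintf("variant ref mismatch at %d: expected %s, found %s",
                       v$pos, v$ref, have), call. = FALSE)
        }
        hapseq <- paste0(substr(hapseq, 1L, a - 1L), v$alt,
                         substr(hapseq, a + nchar(v$ref), nchar(hapseq)))
        delta <- nchar(v$alt) - nchar(v$ref)
        if (delta != 0L) {
          shift <- segmap$a_start > a
          segmap$a_start[shift] <- segmap$a_start[shift] + delta
          segmap$a_end[segmap$a_end >= a] <-
            segmap$a_end[segmap$a_end >= a] + delta
        }
      }
    }
  }
  applied_variants <- if (length(applied) > 0) {
    av <- do.call(rbind, applied)
    av[order(av$pos), , drop = FALSE]
  } else data.frame(pos = integer(), ref = character(), alt = character())
  applied_events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(kind = character(), start = integer(), end = integer(),
               length = integer(), gene = character(), switch = integer())

  # gene structure: every gene copy present on the haplotype, labelled
  gene_structure <- list()
  for (gi in seq_len(nrow(locus$genes))) {
    g <- locus$genes[gi, ]
    hits <- which(segmap$r_start <= g$start & g$end <= segmap$r_end)
    for (j in hits) {
      a_start <- segmap$a_start[j] + (g$start - segmap$r_start[j])
      a_end <- a_start + (g$end - g$start)
      label <- g$gene
      sw <- NA_integer_
      for (su in surgeries) {
        if (su$gene == g$gene && su$copy_index == segmap$copy_index[j]) {
          label <- paste0("hybrid(", locus$genes$gene[1], "::", g$gene, ")")
          sw <- su$switch
        }
      }
      gene_structure[[length(gene_structure) + 1L]] <- data.frame(
        label = label, slot = g$gene, a_start = a_start, a_end = a_end,
        copy_index = segmap$copy_index[j], switch = sw)
    }
  }
  gene_structure <- if (length(gene_structure) > 0) {
    gs <- do.call(rbind, gene_structure)
    gs[order(gs$a_start), , drop = FALSE]
  } else data.frame()

  structure(list(name = spec$name %||% "hap",
                 sequence = Biostrings::DNAString(hapseq),
                 reference = locus$sequence,
                 locus_name = locus$name,
                 applied_variants = applied_variants,
                 applied_events = applied_events,
                 segment_map = segmap,
                 gene_structure = gene_structure,
                 spec = spec),
            class = "SimulatedHaplotype")
}

#' Translate star-allele names into a haplotype build spec
#'
#' Resolves each star allele against the definition table: variant sets are
#' converted to locus coordinates; `gene_deletion` becomes a `delete`
#' directive over the locus deletion geometry; hybrid alleles become either
#' a tandem `insert_hybrid_copy` (duplication-insertion, e.g. *68) or an
#' in-place `replace_with_hybrid` (e.g. *13) according to `hybrid_modes`.
#'
#' @param locus A [locus_reference()].
#' @param defs A `star_definitions` table.
#' @param stars Character vector of star alleles carried by this haplotype,
#'   e.g. `c("*4", "*68")`.
#' @param geometry Structural geometry, see [synthetic_events()].
#' @param hybrid_modes Named character vector mapping hybrid allele names to
#'   `"insert"` or `"replace"`.
#' @return A spec list for [build_haplotype()].
#' @export
haplotype_spec <- function(locus, defs, stars,
                           geometry = synthetic_events(),
                           hybrid_modes = c("*68" = "insert",
                                            "*13" = "replace")) {
  directives <- list()
  variants <- data.frame(pos = integer(), ref = character(),
                         alt = character())
  for (star in stars) {
    row <- defs[defs$allele == star, , drop = FALSE]
    if (nrow(row) == 0) stop("star allele '", star,
                             "' not in definition table", call. = FALSE)
    row <- row[1, , drop = FALSE]
    if (row$structural_event == "gene_deletion") {
      directives[[length(directives) + 1L]] <- list(
        type = "delete", start = geometry$deletion[1],
        end = geometry$deletion[2])
    } else if (row$structural_event == "hybrid") {
      sw <- as.integer(round((row$switch_start + row$switch_end) / 2))
      mode <- unname(hybrid_modes[star]) %||% "replace"
      if (is.na(mode)) mode <- "replace"
      if (mode == "insert") {
        directives[[length(directives) + 1L]] <- list(
          type = "insert_hybrid_copy", start = geometry$duplication[1],
          end = geometry$duplication[2], switch = sw,
          gene = locus$genes$gene[2])
      } else {
        directives[[length(directives) + 1L]] <- list(
          type = "replace_with_hybrid", gene = locus$genes$gene[2],
          switch = sw)
      }
    }
    v <- row$variants[[1]]
    if (nrow(v) > 0) {
      src <- if (nzchar(row$source_gene)) row$source_gene else
        locus$genes$gene[1]
      variants <- rbind(variants, gene_to_locus_variants(locus, v, src))
    }
  }
  list(name = paste(stars, collapse = "+"), directives = directives,
       variants = variants, stars = stars)
}

#' Plant background heterozygous SNVs on a simulated diploid
#'
#' Real diploid genomes differ between their haplotypes at roughly one
#' site per kilobase; read-backed phasing rests on exactly those
#' variants. This step plants `n` heterozygous SNVs at intergenic
#' positions (outside every annotated gene plus `margin`), each assigned
#' to one haplotype at random, and records them in the haplotype truth.
#' Positions falling inside a deleted region of their haplotype are
#' dropped for that haplotype.
#'
#' @param haplotypes List of [build_haplotype()] results.
#' @param locus The underlying [locus_reference()].
#' @param n Number of heterozygous sites.
#' @param seed RNG seed.
#' @param margin Exclusion margin around annotated genes (bp).
#' @return The haplotype list with mutated sequences and updated
#'   `applied_variants`.
#' @export
add_background_het <- function(haplotypes, locus, n = 20L, seed = 1L,
                               margin = 50L) {
  if (n == 0L || length(haplotypes) < 2L) return(haplotypes)
  L <- length(locus$sequence)
  ok <- rep(TRUE, L)
  for (i in seq_len(nrow(locus$genes))) {
    ok[max(1L, locus$genes$start[i] - margin):
         min(L, locus$genes$end[i] + margin)] <- FALSE
  }
  refc <- as.character(locus$sequence)
  seqs <- lapply(haplotypes, function(h) as.character(h$sequence))
  with_rng(seed, {
    pos <- sort(sample(which(ok), n))
    hap_ix <- sample(length(haplotypes), n, replace = TRUE)
    for (i in seq_len(n)) {
      p <- pos[i]
      ref <- substr(refc, p, p)
      alt <- other_base(ref)
      h <- haplotypes[[hap_ix[i]]]
      sm <- h$segment_map
      hits <- which(sm$r_start <= p & p <= sm$r_end)
      if (length(hits) == 0) next
      for (j in hits) {
        a <- sm$a_start[j] + (p - sm$r_start[j])
        stopifnot(substr(seqs[[hap_ix[i]]], a, a) == ref)
        substr(seqs[[hap_ix[i]]], a, a) <- alt
      }
      haplotypes[[hap_ix[i]]]$applied_variants <- rbind(
        haplotypes[[hap_ix[i]]]$applied_variants,
        data.frame(pos = p, ref = ref, alt = alt))
    }
  })
  for (k in seq_along(haplotypes)) {
    haplotypes[[k]]$sequence <- Biostrings::DNAString(seqs[[k]])
    av <- haplotypes[[k]]$applied_variants
    haplotypes[[k]]$applied_variants <- av[order(av$pos), , drop = FALSE]
  }
  haplotypes
}

#' Simulate Cas9 excision fragments from a haplotype
#'
#' Cut sites are given in locus (reference) coordinates; each carries an
#' implicit recognition sequence (the reference 21-mer around the cut), and
#' every exact occurrence of that recognition sequence on the haplotype is
#' cut. Structural events that duplicate a recognition site therefore also
#' duplicate the cut, emulating the loss of full-length fragments observed
#' when hybrids re-introduce a gRNA site. Fragments are the intervals
#' between consecutive cuts.
#'
#' @param haplotype A [build_haplotype()] result.
#' @param cut_sites Integer vector of cut positions (reference coordinates).
#' @param pool Pool label attached to the fragments.
#' @param recognition_halfwidth Half-width of the recognition k-mer.
#' @return `data.frame` with `start`, `end` (haplotype coordinates), `pool`.
#' @export
simulate_fragments <- function(haplotype, cut_sites, pool = "A",
                               recognition_halfwidth = 10L) {
  hapseq <- haplotype$sequence
  refseq <- haplotype$reference
  hw <- recognition_halfwidth
  if (length(cut_sites) == 0) {
    warning("no cut sites; returning the full haplotype as one fragment")
    return(data.frame(start = 1L, end = length(hapseq), pool = pool))
  }
  cuts <- integer()
  for (cs in cut_sites) {
    from <- max(1L, cs - hw)
    to <- min(length(refseq), cs + hw)
    kmer <- Biostrings::subseq(refseq, from, to)
    # one mismatch tolerated: a stray SNV in the recognition sequence
    # does not abolish cutting of a 21-mer target
    m <- Biostrings::matchPattern(kmer, hapseq, max.mismatch = 1)
    if (length(m) > 0) {
      cuts <- c(cuts, BiocGenerics::start(m) + (cs - from))
    }
  }
  cuts <- sort(unique(cuts))
  if (length(cuts) < 2L) {
    warning("fewer than two cut sites hit the haplotype; ",
            "returning the full haplotype as one fragment")
    return(data.frame(start = 1L, end = length(hapseq), pool = pool))
  }
  data.frame(start = cuts[-length(cuts)] + 1L, end = cuts[-1], pool = pool,
             stringsAsFactors = FALSE)
}

#' Simulate background (off-target) reads
#'
#' Random-sequence reads that should not map to the locus, emulating the
#' adapter-ligation background of Cas9-targeted enrichment.
#'
#' @param n_reads Number of reads.
#' @param length_distribution Function `n -> integer lengths`; defaults to a
#'   log-normal around 3 kb.
#' @param seed RNG seed.
#' @param em An [error_model()] (only the quality distribution is used).
#' @return A `QualityScaledDNAStringSet` with `truth_hap = "background"`.
#' @export
simulate_background <- function(n_reads, length_distribution = NULL,
                                seed = 1L, em = error_model()) {
  if (n_reads == 0) {
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character()))
    return(out)
  }
  if (is.null(length_distribution)) {
    length_distribution <- function(n) {
      pmax(200L, as.integer(round(stats::rlnorm(n, log(3000), 0.6))))
    }
  }
  with_rng(seed, {
    lens <- length_distribution(n_reads)
    seqs <- vapply(lens, rand_dna, character(1))
    quals <- vapply(lens, function(l) {
      paste(phred_to_char(as.integer(pmin(pmax(round(
        stats::rnorm(l, em$quality_mean, em$quality_sd)), 2L), 40L))),
        collapse = "")
    }, character(1))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("bg_%04d", seq_len(n_reads))
    out <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(quals))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      truth_hap = "background", truth_start = NA_integer_,
      truth_end = NA_integer_, pool = NA_character_,
      strand = NA_character_)
    out
  })
}

#' Simulate a sequencing run over one or two haplotypes
#'
#' Draws Cas9-excised fragments from both gRNA pools per haplotype, applies
#' optional 3'-truncation (pore dropout), injects errors, flips strand at
#' random, and appends background reads. Either `n_reads` or a target
#' `depth` (mean on-locus coverage) controls the read count. Deterministic
#' per seed.
#'
#' @param haplotypes List of [build_haplotype()] results (length 1 or 2).
#' @param locus The [locus_reference()] the haplotypes derive from.
#' @param depth Target mean depth over the locus (ignored if `n_reads` set).
#' @param n_reads Exact number of on-target reads to draw.
#' @param pools Pools to draw from (see [default_cut_sites()]).
#' @param cut_sites Named list of cut-site vectors per pool.
#' @param em An [error_model()].
#' @param seed RNG seed.
#' @param truncation_prob Probability a read is truncated (pore dropout).
#' @param adapter_bias Probability the adapter (read start) is on the 3'
#'   side of the fragment, the side Cas9 leaves accessible.
#' @param n_background Number of background reads appended.
#' @return A `QualityScaledDNAStringSet` with truth columns in `mcols`.
#' @export
simulate_reads <- function(haplotypes, locus, depth = 20, n_reads = NULL,
                           pools = c("A", "B"),
                           cut_sites = default_cut_sites(),
                           em = error_model(), seed = 1L,
                           truncation_prob = 0.1, adapter_bias = 0.8,
                           n_background = 0L) {
  if (methods::is(haplotypes, "SimulatedHaplotype")) {
    haplotypes <- list(haplotypes)
  }
  frag_sets <- lapply(haplotypes, function(h) {
    do.call(rbind, lapply(pools, function(p) {
      simulate_fragments(h, cut_sites[[p]], pool = p)
    }))
  })
  locus_len <- length(locus$sequence)
  target_bases <- depth * locus_len * length(haplotypes) / 2
  with_rng(seed, {
    seqs <- character(); quals <- character()
    hap_ix <- integer(); starts <- integer(); ends <- integer()
    poolv <- character(); strandv <- character()
    total <- 0; i <- 0L
    repeat {
      i <- i + 1L
      if (!is.null(n_reads)) { if (i > n_reads) break }
      else if (total >= target_bases) break
      h <- ((i - 1L) %% length(haplotypes)) + 1L
      fr <- frag_sets[[h]]
      f <- fr[sample(nrow(fr), 1L), ]
      s <- f$start; e <- f$end
      from_3prime <- stats::runif(1) < adapter_bias
      if (stats::runif(1) < truncation_prob) {
        keep <- max(200L, as.integer(round((e - s + 1L) *
                                             stats::runif(1, 0.25, 0.95))))
        if (from_3prime) s <- max(s, e - keep + 1L) else
          e <- min(e, s + keep - 1L)
      }
      frag <- as.character(Biostrings::subseq(haplotypes[[h]]$sequence,
                                              s, e))
      res <- inject_errors(frag, em)
      sq <- res$sequence
      qv <- res$qualities
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      if (strand == "-") {
        sq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sq)))
        qv <- rev(qv)
      }
      seqs <- c(seqs, sq)
      quals <- c(quals, paste(phred_to_char(qv), collapse = ""))
      hap_ix <- c(hap_ix, h); starts <- c(starts, s); ends <- c(ends, e)
      poolv <- c(poolv, f$pool); strandv <- c(strandv, strand)
      total <- total + nchar(sq)
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("read_%04d", seq_along(dss))
    out <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(quals))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      truth_hap = as.character(hap_ix), truth_start = starts,
      truth_end = ends, pool = poolv, strand = strandv)
    if (n_background > 0) {
      bg <- simulate_background(n_background,
                                seed = sample.int(2^30, 1L), em = em)
      out <- c(out, bg)
    }
    out
  })
}

#' Write truth files for a simulated dataset
#'
#' Emits the reads as FASTQ, the applied small variants as a phased VCF,
#' the structural events as BED, and the diplotype as JSON.
#'
#' @param haplotypes List of [build_haplotype()] results.
#' @param reads A `QualityScaledDNAStringSet` from [simulate_reads()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths.
#' @export
write_truth <- function(haplotypes, reads, out_dir) {
  if (methods::is(haplotypes, "SimulatedHaplotype")) {
    haplotypes <- list(haplotypes)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(out_dir, "reads.fastq")
  write_reads(reads, fq)
  locus_name <- haplotypes[[1]]$locus_name

  keys <- lapply(haplotypes, function(h) {
    v <- h$applied_variants
    if (nrow(v) == 0) character() else variant_key(v$pos, v$ref, v$alt)
  })
  all_v <- unique(do.call(rbind, lapply(haplotypes, function(h) {
    h$applied_variants
  })))
  vcf <- file.path(out_dir, "truth.vcf.gz")
  if (!is.null(all_v) && nrow(all_v) > 0) {
    all_v <- all_v[order(all_v$pos), , drop = FALSE]
    k <- variant_key(all_v$pos, all_v$ref, all_v$alt)
    gt1 <- as.integer(k %in% keys[[1]])
    gt2 <- if (length(haplotypes) > 1) as.integer(k %in% keys[[2]]) else gt1
    fix <- cbind(CHROM = locus_name, POS = as.character(all_v$pos),
                 ID = ".", REF = all_v$ref, ALT = all_v$alt, QUAL = ".",
                 FILTER = "PASS", INFO = ".")
    gt <- cbind(FORMAT = "GT:PS", SAMPLE = paste0(gt1, "|", gt2, ":1"))
    v <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               sprintf("##contig=<ID=%s>", locus_name),
                               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                                      "Description=\"Genotype\">"),
                               paste0("##FORMAT=<ID=PS,Number=1,",
                                      "Type=Integer,Description=",
                                      "\"Phase set\">")),
                      fix = fix, gt = gt)
    vcfR::write.vcf(v, vcf)
  } else {
    con <- gzfile(vcf, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s>", locus_name),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", sep = "\t")), con)
    close(con)
  }

  bed <- file.path(out_dir, "truth_events.bed")
  ev <- do.call(rbind, lapply(seq_along(haplotypes), function(i) {
    e <- haplotypes[[i]]$applied_events
    if (nrow(e) == 0) return(NULL)
    e$hap <- i
    e
  }))
  if (!is.null(ev) && nrow(ev) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = locus_name,
      ranges = IRanges::IRanges(ev$start, ev$end),
      name = sprintf("%s_hap%d", ev$kind, ev$hap), score = 0L)
    rtracklayer::export(gr, bed, format = "BED")
  } else file.create(bed)

  dj <- file.path(out_dir, "truth_diplotype.json")
  dip <- lapply(haplotypes, function(h) {
    list(name = h$name, stars = h$spec$stars %||% character())
  })
  names(dip) <- paste0("allele", seq_along(haplotypes))
  jsonlite::write_json(dip, dj, auto_unbox = TRUE, pretty = TRUE)

  c(fastq = fq, vcf = vcf, bed = bed, diplotype = dj)
}

#' Read a FASTQ file into a quality-scaled read set
#'
#' @param path FASTQ path.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_reads <- function(path) {
  # the reader warns about dropping (nonexistent) metadata columns
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Write reads as FASTQ
#'
#' Plain four-line-per-record FASTQ output. (The Biostrings FASTQ writer
#' is limited to records of at most ~20 kb, well below Cas9-excision
#' read lengths, so the records are emitted directly.)
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read_%04d", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1, length(lines), by = 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), by = 4)] <- as.character(reads)
  lines[seq(3, length(lines), by = 4)] <- "+"
  lines[seq(4, length(lines), by = 4)] <-
    as.character(Biostrings::quality(reads))
  writeLines(lines, path)
  invisible(path)
}
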