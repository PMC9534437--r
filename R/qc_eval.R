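# Depth/on-target statistics, deterministic subsampling, truth comparison
# of called variants (phase-aware, invariant to haplotype relabelling),
# and the depth-reliability curve used to characterize the false-positive
# behaviour of small-variant calling below the reliable-depth threshold.

#' On-target and depth statistics
#'
#' Mean depth is total aligned bases within the region divided by the
#' region length; the on-target percentage is the fraction of all reads
#' whose primary alignment overlaps the region.
#'
#' @param alignments [align_reads()] records (including unmapped reads).
#' @param region `c(start, end)`; defaults to the whole reference.
#' @return List: `total_reads`, `on_target_reads`, `mean_depth`,
#'   `pct_on_target`.
#' @export
depth_and_ontarget_stats <- function(alignments, region = NULL) {
  if (is.null(region)) region <- c(1L, attr(alignments, "ref_len"))
  if (is.null(region[1]) || region[2] < region[1]) {
    stop("empty target region", call. = FALSE)
  }
  total <- length(unique(alignments$qname))
  pri <- alignments[alignments$mapped & !alignments$is_secondary &
                      !alignments$is_supplementary, , drop = FALSE]
  ov <- pmin(pri$end, region[2]) - pmax(pri$pos, region[1]) + 1L
  on_ids <- unique(pri$qname[ov > 0])
  seg <- alignments[alignments$mapped & !alignments$is_secondary &
                      alignments$qname %in% on_ids, , drop = FALSE]
  bases <- sum(pmax(0L, pmin(seg$end, region[2]) -
                      pmax(seg$pos, region[1]) + 1L))
  list(total_reads = total, on_target_reads = length(on_ids),
       mean_depth = bases / (region[2] - region[1] + 1L),
       pct_on_target = if (total == 0) 0 else
         100 * length(on_ids) / total)
}

#' Subsample reads
#'
#' Per-read Bernoulli selection, deterministic per seed.
#'
#' @param reads A read set (any subsettable object with names).
#' @param fraction Retention probability in (0, 1].
#' @param seed RNG seed.
#' @return The retained subset.
#' @export
subsample_reads <- function(reads, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(reads)
  keep <- with_rng(seed, stats::runif(length(reads)) < fraction)
  reads[keep]
}

# genotype equivalence ignoring phase: 0|1 == 1|0 == 0/1
gt_unphased <- function(gt) {
  parts <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
}

#' Compare called variants against truth
#'
#' Variants match on (position, ref, alt) and unphased genotype after
#' normalization. Phase agreement is computed per phase block as the best
#' agreement over the two global allele swaps (phasing is only defined up
#' to relabelling within a block).
#'
#' @param called Variant table with `pos`, `ref`, `alt`, `gt`, optionally
#'   phased (`0|1`) with a `block` column.
#' @param truth Truth table in the same schema.
#' @param regions Optional `c(start, end)` restriction.
#' @return List: `concordant`, `discordant_extra`, `discordant_missing`,
#'   `phase_agreement`.
#' @export
compare_variants <- function(called, truth, regions = NULL) {
  restrict <- function(v) {
    if (is.null(regions) || nrow(v) == 0) return(v)
    v[v$pos >= regions[1] & v$pos <= regions[2], , drop = FALSE]
  }
  called <- restrict(called); truth <- restrict(truth)
  ck <- if (nrow(called) > 0) {
    paste(variant_key(called$pos, called$ref, called$alt),
          gt_unphased(called$gt))
  } else character()
  tk <- if (nrow(truth) > 0) {
    paste(variant_key(truth$pos, truth$ref, truth$alt),
          gt_unphased(truth$gt))
  } else character()
  conc <- intersect(ck, tk)
  # phase agreement over matched het variants, per block, swap-invariant
  phase_agreement <- NA_real_
  if (nrow(called) > 0 && nrow(truth) > 0) {
    cm <- called[paste(variant_key(called$pos, called$ref, called$alt),
                       gt_unphased(called$gt)) %in% conc &
                   grepl("\\|", called$gt), , drop = FALSE]
    if (nrow(cm) > 0) {
      tmap <- stats::setNames(truth$gt,
                              variant_key(truth$pos, truth$ref,
                                          truth$alt))
      cm$truth_gt <- tmap[variant_key(cm$pos, cm$ref, cm$alt)]
      cm <- cm[grepl("\\|", cm$truth_gt), , drop = FALSE]
      het <- cm[gt_unphased(cm$gt) == "0/1", , drop = FALSE]
      if (nrow(het) > 0) {
        if (is.null(het$block)) het$block <- 1L
        agree <- 0L
        for (b in unique(het$block)) {
          sub <- het[het$block == b, , drop = FALSE]
          same <- sum(sub$gt == sub$truth_gt)
          agree <- agree + max(same, nrow(sub) - same)
        }
        phase_agreement <- agree / nrow(het)
      }
    }
  }
  list(concordant = length(conc),
       discordant_extra = length(setdiff(ck, tk)),
       discordant_missing = length(setdiff(tk, ck)),
       phase_agreement = phase_agreement)
}

#' Depth-reliability curve
#'
#' Re-runs small-variant calling on subsampled read sets and counts, per
#' subsampling fraction, the calls absent from the full-depth baseline
#' (false positives by definition of the baseline). Used to locate the
#' depth below which spurious variants appear.
#'
#' @param reads Full read set.
#' @param locus_reference A [locus_reference()].
#' @param fractions Subsampling fractions (1.0 is the baseline).
#' @param seed RNG seed.
#' @param min_depth,error_rate Passed to [call_small_variants()].
#' @return `data.frame`: `fraction`, `mean_depth`, `n_calls`,
#'   `false_positives`.
#' @export
depth_reliability_curve <- function(reads, locus_reference,
                                    fractions = c(1, 0.75, 0.5, 0.25),
                                    seed = 1L, min_depth = 16L,
                                    error_rate = 0.1) {
  fractions <- sort(unique(c(1, fractions)), decreasing = TRUE)
  run <- function(subset) {
    aln <- align_reads(subset, locus_reference)
    aln <- filter_reads(aln)
    v <- call_small_variants(aln, locus_reference, min_depth = min_depth,
                             error_rate = error_rate)
    stats <- depth_and_ontarget_stats(aln)
    list(keys = variant_key(v$pos, v$ref, v$alt),
         depth = stats$mean_depth)
  }
  base <- run(reads)
  rows <- list()
  for (f in fractions) {
    r <- if (f == 1) base else
      run(subsample_reads(reads, f, seed = seed + round(1000 * f)))
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, mean_depth = r$depth, n_calls = length(r$keys),
      false_positives = length(setdiff(r$keys, base$keys)))
  }
  do.call(rbind, rows)
}
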