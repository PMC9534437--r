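# End-to-end orchestration: map -> filter -> small variants -> allele
# split -> clip-based breakpoints -> adjusted reference per allele ->
# two-round consensus -> gene/hybrid identification -> star-allele
# diplotype, with every intermediate retained and every threshold
# recorded.

#' Pipeline parameters
#'
#' All thresholds of the genotyping pipeline in one place. Defaults:
#' breakpoints need at least 3 supporting reads; reads need mean quality
#' above 8; 16X mean depth per gene copy marks the reliability limit;
#' clips shorter than 200 bp are ignored (at ~94% paralog identity,
#' shorter clips map ambiguously); breakpoint clustering tolerance 20 bp;
#' read re-assignment needs an alignment-score margin of 10; a source
#' switch during gene segmentation costs 3 diagnostic mismatches.
#'
#' @param min_support Minimum reads supporting a breakpoint.
#' @param min_depth Reliable-depth threshold (flag, not filter).
#' @param min_read_q Minimum mean read quality (strict).
#' @param min_clip_len Minimum clip length feeding SV detection.
#' @param tolerance Breakpoint clustering tolerance (bp).
#' @param min_margin Alignment-score margin for unambiguous assignment.
#' @param switch_penalty Gene-segmentation switch penalty.
#' @param error_rate Pileup caller symmetric per-base error rate.
#' @param min_overlap Minimum aligned fraction of a read to count
#'   on-target.
#' @param min_identity Minimum identity for gene-copy location.
#' @param hp_min_run Minimum homopolymer run length for length-voting.
#' @param preset minimap2 preset.
#' @return Named list of parameters.
#' @export
locustar_params <- function(min_support = 3L, min_depth = 16L,
                            min_read_q = 8, min_clip_len = 200L,
                            tolerance = 20L, min_margin = 10L,
                            switch_penalty = 3, error_rate = 0.1,
                            min_overlap = 0.5, min_identity = 0.9,
                            hp_min_run = 4L, preset = "map-ont") {
  as.list(environment())
}

# per-allele conflict resolution: highest-support SV wins, overlapping
# lower-support events become secondary
select_svs <- function(svs) {
  if (nrow(svs) == 0) return(list(kept = svs, secondary = svs))
  svs <- svs[order(-svs$support), , drop = FALSE]
  kept <- svs[0, ]
  secondary <- svs[0, ]
  for (i in seq_len(nrow(svs))) {
    s <- svs[i, ]
    if (nrow(kept) == 0 ||
        all(s$start > kept$end | s$end < kept$start)) {
      kept <- rbind(kept, s)
    } else secondary <- rbind(secondary, s)
  }
  list(kept = kept[order(kept$start), , drop = FALSE],
       secondary = secondary)
}

# star calls for the copies of one allele
call_allele_stars <- function(copies, svs, locus, defs, final_cons) {
  target_gene <- locus$genes$gene[1]
  calls <- list()
  for (gc in copies) {
    depth_iv <- gc$interval[1]:min(gc$interval[2],
                                   length(final_cons$support))
    mean_depth <- mean(final_cons$support[depth_iv])
    if (length(gc$sources) > 1) {
      sw <- if (length(gc$switch_local) > 0) gc$switch_local[1] else
        NA_integer_
      as_ <- assign_star_allele(gc$variants, "hybrid", defs,
                                detected_switch = sw)
      calls[[length(calls) + 1L]] <- list(
        star = as_$allele, label = gc$label, position = gc$interval[1],
        mean_depth = mean_depth, similarity = as_$similarity,
        extras = as_$extras, missing = as_$missing, in_string = TRUE)
    } else if (gc$sources[1] == target_gene) {
      as_ <- assign_star_allele(gc$variants, target_gene, defs)
      calls[[length(calls) + 1L]] <- list(
        star = as_$allele, label = gc$label, position = gc$interval[1],
        mean_depth = mean_depth, similarity = as_$similarity,
        extras = as_$extras, missing = as_$missing, in_string = TRUE)
    } else {
      calls[[length(calls) + 1L]] <- list(
        star = "", label = gc$label, position = gc$interval[1],
        mean_depth = mean_depth, in_string = FALSE)
    }
  }
  # whole-gene deletion: the target-gene slot is gone
  g1 <- locus$genes[1, ]
  del_hit <- nrow(svs) > 0 &&
    any(svs$kind == "DEL" & svs$start <= g1$start & svs$end >= g1$end)
  has_target <- any(vapply(calls, function(x) isTRUE(x$in_string),
                           logical(1)))
  if (del_hit && !has_target) {
    as_ <- assign_star_allele(empty_variants(), "deleted", defs)
    calls[[length(calls) + 1L]] <- list(
      star = as_$allele, label = "deleted", position = g1$start,
      mean_depth = mean(final_cons$support),
      similarity = as_$similarity, extras = character(),
      missing = character(), in_string = TRUE, deleted = TRUE)
  }
  calls
}

#' Genotype a locus from long reads
#'
#' Runs the full pipeline on a read set: alignment, on-target filtering,
#' pileup small-variant calling, allele splitting, clip-based breakpoint
#' detection and SV classification per allele, adjusted-reference
#' construction, two consensus rounds with ambiguous-read removal, gene
#' and hybrid identification, and star-allele diplotype assignment.
#'
#' @param reads `QualityScaledDNAStringSet` or FASTQ path.
#' @param locus A [locus_reference()].
#' @param star_definitions A `star_definitions` table.
#' @param params [locustar_params()].
#' @return A `locus_genotype` result list with every intermediate:
#'   alignments, variants, partition, breakpoints, SVs, allele
#'   references, both consensus rounds, gene copies, and the
#'   `DiplotypeCall`.
#' @export
genotype_locus <- function(reads, locus, star_definitions,
                           params = locustar_params()) {
  if (is.character(reads) && length(reads) == 1) reads <- read_reads(reads)
  aln <- align_reads(reads, locus, preset = params$preset)
  flt <- filter_reads(aln, min_read_q = params$min_read_q,
                      min_overlap = params$min_overlap)
  stats <- depth_and_ontarget_stats(aln)
  variants <- call_small_variants(flt, locus,
                                  min_depth = params$min_depth,
                                  error_rate = params$error_rate)
  partition <- withCallingHandlers(
    phase_reads(variants, flt),
    warning = function(w) invokeRestart("muffleWarning"))
  single <- isTRUE(partition$single_allele)

  detect <- function(part) {
    cl <- extract_clips(flt, part, min_clip_len = params$min_clip_len)
    cl <- remap_clips(cl, locus)
    bp <- cluster_breakpoints(cl, tolerance = params$tolerance,
                              min_support = params$min_support)
    list(clips = cl, breakpoints = bp, svs = classify_sv(bp, locus))
  }
  build_side <- function(svs_allele, a, ids) {
    sel <- select_svs(svs_allele)
    aref <- build_allele_reference(locus, sel$kept, allele = a)
    cons <- withCallingHandlers(
      first_consensus(reads[names(reads) %in% ids], aref,
                      hp_min_run = params$hp_min_run),
      warning = function(w) invokeRestart("muffleWarning"))
    list(sel = sel, aref = aref, cons = cons)
  }
  det <- detect(partition)
  on_target <- reads[names(reads) %in% unique(flt$qname)]
  alleles <- if (single) 1L else c(1L, 2L)
  aref <- list(); cons1 <- list(); svs <- list(); svs_secondary <- list()
  for (a in alleles) {
    ids <- if (a == 1L) partition$allele1 else partition$allele2
    side <- build_side(det$svs[det$svs$allele == a, , drop = FALSE],
                       a, ids)
    svs[[a]] <- side$sel$kept
    svs_secondary[[a]] <- side$sel$secondary
    aref[[a]] <- side$aref
    cons1[[a]] <- side$cons
  }
  if (single) {
    assignment <- list(allele1 = names(on_target),
                       allele2 = names(on_target),
                       removed = character())
    final <- list(final_consensus(on_target, cons1[[1]],
                                  hp_min_run = params$hp_min_run))
    final[[2]] <- final[[1]]
    aref[[2]] <- aref[[1]]
    svs[[2]] <- svs[[1]]
  } else {
    assignment <- reassign_reads(on_target, cons1[[1]], cons1[[2]],
                                 min_margin = params$min_margin)
    # the cleaned read assignment supersedes the initial phasing for
    # junction evidence: re-detect SVs per allele, rebuild the adjusted
    # references, and finalize the consensus against them
    part2 <- structure(list(allele1 = assignment$allele1,
                            allele2 = assignment$allele2,
                            unassigned = assignment$removed,
                            single_allele = FALSE),
                       class = "PhasePartition")
    det <- detect(part2)
    final <- list()
    for (a in 1:2) {
      ids <- if (a == 1L) assignment$allele1 else assignment$allele2
      side <- build_side(det$svs[det$svs$allele == a, , drop = FALSE],
                         a, ids)
      svs[[a]] <- side$sel$kept
      svs_secondary[[a]] <- side$sel$secondary
      aref[[a]] <- side$aref
      final[[a]] <- side$cons
    }
  }
  clips <- det$clips
  breakpoints <- det$breakpoints

  grefs <- gene_references(locus)
  allele_copies <- list(list(), list())
  allele_calls <- list(list(), list())
  if (length(grefs) >= 2) {
    for (a in 1:2) {
      fc <- final[[a]]
      ivs <- locate_gene_copies(fc, grefs,
                                min_identity = params$min_identity)
      copies <- list()
      for (i in seq_len(nrow(ivs))) {
        iv <- c(ivs$start[i], ivs$end[i])
        prof <- mismatch_profiles(iv, fc, grefs,
                                  min_identity = params$min_identity)
        if (prof$unclassified) next
        # tie-break by the annotated gene slot the copy occupies
        mid <- liftover(min(round(mean(iv)),
                            max(aref[[a]]$segment_map$a_end)),
                        aref[[a]])$position
        slot <- locus$genes$gene[locus$genes$start <= mid &
                                   locus$genes$end >= mid]
        tb <- if (length(slot) == 1) slot else locus$genes$gene[1]
        segs <- segment_and_assign(prof,
                                   switch_penalty =
                                     params$switch_penalty,
                                   tie_break = tb)
        gc <- reconstruct_hybrids(segs, iv, allele = a)
        gc$variants <- score_copy_variants(gc, prof, fc$probability,
                                           grefs)
        copies[[length(copies) + 1L]] <- gc
      }
      allele_copies[[a]] <- copies
      allele_calls[[a]] <- call_allele_stars(copies, svs[[a]], locus,
                                             star_definitions, final[[a]])
    }
  }
  diplotype <- format_diplotype(allele_calls,
                                min_depth = params$min_depth,
                                homozygous = single)
  structure(list(
    params = params, locus = locus, alignments = aln, filtered = flt,
    stats = stats, variants = variants, partition = partition,
    clips = clips, breakpoints = breakpoints, svs = svs,
    svs_secondary = svs_secondary, allele_references = aref,
    consensus_round1 = cons1, assignment = assignment,
    consensus_final = final, gene_copies = allele_copies,
    allele_calls = allele_calls, diplotype = diplotype),
    class = "locus_genotype")
}

#' @export
print.locus_genotype <- function(x, ...) {
  cat(sprintf("locus_genotype: %d reads (%d on-target, %.1fX)\n",
              x$stats$total_reads, x$stats$on_target_reads,
              x$stats$mean_depth))
  cat(sprintf("  small variants: %d (%d het)\n", nrow(x$variants),
              sum(x$variants$gt == "0/1")))
  for (a in 1:2) {
    sv <- x$svs[[a]]
    cat(sprintf("  allele %d SVs: %s\n", a,
                if (nrow(sv) == 0) "none" else
                  paste(sprintf("%s %d bp (support %d)", sv$kind,
                                sv$length, sv$support), collapse = "; ")))
  }
  print(x$diplotype)
  invisible(x)
}

# write phased small variants as VCF (vcfR; 1-based by standard)
write_variants_vcf <- function(variants, partition, locus, path) {
  if (nrow(variants) == 0) {
    con <- gzfile(path, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s>", locus$name),
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "SAMPLE",
                       sep = "\t")), con)
    close(con)
    return(invisible(path))
  }
  gt <- variants$gt
  ps <- rep(".", nrow(variants))
  hs <- partition$het_sites
  if (!is.null(hs) && nrow(hs) > 0) {
    key <- variant_key(hs$pos, hs$ref, hs$alt)
    m <- match(variant_key(variants$pos, variants$ref, variants$alt),
               key)
    phased <- !is.na(m)
    gt[phased] <- ifelse(hs$hap1_allele[m[phased]] == 1L, "1|0", "0|1")
    ps[phased] <- as.character(hs$block[m[phased]])
  }
  fix <- cbind(CHROM = locus$name, POS = as.character(variants$pos),
               ID = ".", REF = variants$ref, ALT = variants$alt,
               QUAL = sprintf("%.0f", variants$qual),
               FILTER = ifelse(variants$low_confidence, "LowDepth",
                               "PASS"),
               INFO = ".")
  gtm <- cbind(FORMAT = "GT:PS", SAMPLE = paste0(gt, ":", ps))
  v <- methods::new("vcfR",
                    meta = c("##fileformat=VCFv4.2",
                             sprintf("##contig=<ID=%s>", locus$name),
                             paste0("##FORMAT=<ID=GT,Number=1,",
                                    "Type=String,Description=",
                                    "\"Genotype\">"),
                             paste0("##FORMAT=<ID=PS,Number=1,",
                                    "Type=String,Description=",
                                    "\"Phase set\">"),
                             paste0("##FILTER=<ID=LowDepth,Description=",
                                    "\"Depth below the reliability ",
                                    "threshold\">")),
                    fix = fix, gt = gtm)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Run the pipeline from a configuration
#'
#' Orchestrates simulate -> genotype -> evaluate. The configuration (a
#' list or a YAML path) names the inputs, thresholds and seed; every
#' intermediate is persisted under `out_dir` and every threshold is
#' recorded in the log. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' Configuration keys: `seed`; `simulate` (optional: `diplotype` — star
#' strings per allele, e.g. `["*5", "*4+*68"]` —, `depth`,
#' `n_background`); `reference` (optional `fasta` + `bed`, otherwise the
#' synthetic locus); `reads` (FASTQ path, when not simulating);
#' `star_table` (TSV path, otherwise the synthetic table); `params`
#' (overrides for [locustar_params()]); `evaluate` (compare calls to
#' simulated truth).
#'
#' @param config List or YAML file path.
#' @param out_dir Output directory.
#' @return The `locus_genotype` result, invisibly; files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  params <- do.call(locustar_params, config$params %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("seed: %d", seed)
  for (p in names(params)) logf("param %s: %s", p, params[[p]])

  # inputs are validated before any alignment work
  if (is.null(config$simulate) && is.null(config$reads)) {
    stop("config must provide either 'simulate' or 'reads'",
         call. = FALSE)
  }
  if (!is.null(config$star_table) && !file.exists(config$star_table)) {
    stop("star table not found: ", config$star_table, call. = FALSE)
  }
  if (!is.null(config$reference$fasta)) {
    locus <- load_reference(config$reference$fasta,
                            config$reference$bed)
  } else {
    locus <- synthetic_locus(seed = config$locus_seed %||% 42L)
  }
  defs <- if (!is.null(config$star_table)) {
    load_star_definitions(config$star_table)
  } else synthetic_star_table(locus)
  write_reference(locus, file.path(out_dir, "locus.fa"),
                  file.path(out_dir, "genes.bed"))
  write_star_definitions(defs, file.path(out_dir, "star_table.tsv"))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    stars <- lapply(sim$diplotype %||% list("*1", "*1"), function(s) {
      strsplit(s, "+", fixed = TRUE)[[1]]
    })
    haps <- lapply(seq_along(stars), function(i) {
      sp <- haplotype_spec(locus, defs, stars[[i]])
      sp$name <- paste(stars[[i]], collapse = "+")
      build_haplotype(locus, sp)
    })
    haps <- add_background_het(haps, locus,
                               n = sim$het_background %||% 20L,
                               seed = seed + 1L)
    reads <- simulate_reads(haps, locus, depth = sim$depth %||% 25,
                            em = do.call(error_model,
                                         sim$error_model %||% list()),
                            seed = seed,
                            n_background = sim$n_background %||% 0L)
    truth_files <- write_truth(haps, reads,
                               file.path(out_dir, "truth"))
    truth <- list(haplotypes = haps, files = truth_files)
    logf("simulated %d reads for diplotype %s", length(reads),
         paste(vapply(haps, `[[`, character(1), "name"),
               collapse = "/"))
  } else {
    reads <- read_reads(config$reads)
  }

  res <- genotype_locus(reads, locus, defs, params)

  # persist intermediates
  utils::write.table(res$breakpoints,
                     file.path(out_dir, "breakpoints.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  all_svs <- do.call(rbind, res$svs[1:2])
  utils::write.table(unique(all_svs),
                     file.path(out_dir, "structural_variants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (a in 1:2) {
    fa <- Biostrings::DNAStringSet(list(res$consensus_final[[a]]$sequence))
    names(fa) <- sprintf("allele%d", a)
    Biostrings::writeXStringSet(
      fa, file.path(out_dir, sprintf("consensus_allele%d.fa", a)))
    utils::write.table(
      data.frame(position = seq_along(res$consensus_final[[a]]$probability),
                 probability = res$consensus_final[[a]]$probability),
      file.path(out_dir, sprintf("consensus_allele%d_prob.tsv", a)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_variants_vcf(res$variants, res$partition, locus,
                     file.path(out_dir, "variants.vcf.gz"))
  gene_report <- lapply(1:2, function(a) {
    lapply(res$gene_copies[[a]], function(gc) {
      list(allele = gc$allele, interval = gc$interval, label = gc$label,
           switches = gc$switches,
           segments = gc$segments,
           variants = gc$variants)
    })
  })
  jsonlite::write_json(gene_report,
                       file.path(out_dir, "gene_structure.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dip <- res$diplotype
  jsonlite::write_json(
    list(diplotype = dip$diplotype, allele1 = dip$allele1,
         allele2 = dip$allele2, flags = dip$flags,
         per_copy = dip$per_copy),
    file.path(out_dir, "diplotype.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  jsonlite::write_json(res$stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("diplotype: %s", dip$diplotype)

  if (isTRUE(config$evaluate) && !is.null(truth)) {
    tv <- do.call(rbind, lapply(truth$haplotypes, function(h) {
      h$applied_variants
    }))
    truth_tab <- if (!is.null(tv) && nrow(tv) > 0) {
      tv <- unique(tv)
      k1 <- with(truth$haplotypes[[1]]$applied_variants,
                 if (length(pos)) variant_key(pos, ref, alt) else
                   character())
      k2 <- if (length(truth$haplotypes) > 1) {
        with(truth$haplotypes[[2]]$applied_variants,
             if (length(pos)) variant_key(pos, ref, alt) else
               character())
      } else k1
      k <- variant_key(tv$pos, tv$ref, tv$alt)
      tv$gt <- paste0(as.integer(k %in% k1), "|",
                      as.integer(k %in% k2))
      tv
    } else cbind(empty_variants()[, c("pos", "ref", "alt")],
                 gt = character())
    called <- res$variants
    cmp <- compare_variants(called, truth_tab)
    jsonlite::write_json(cmp, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logf("evaluation: %d concordant, %d extra, %d missing",
         cmp$concordant, cmp$discordant_extra, cmp$discordant_missing)
  }
  invisible(res)
}
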