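# Star-/sub-allele assignment per gene copy by variant-set lookup, and
# diplotype formatting. Structural labels (whole-gene deletion, hybrid)
# are matched against structural definitions first; sequence-defined
# alleles are ranked by Jaccard similarity of normalized variant sets,
# with a deterministic tie cascade. Extra and missing variants relative
# to the chosen definition are reported verbatim — star nomenclature is
# intrinsically not comprehensive, and the extras are often exactly the
# sub-allele signal.

#' Assign a star allele to one gene copy
#'
#' For a deleted gene slot (`copy_label = "deleted"`) the gene-deletion
#' definition matches structurally. For a hybrid copy, hybrid definitions
#' are matched by whether their gene-local switch region contains the
#' detected switch. For a pure copy, similarity is the Jaccard index
#' between the copy's variant set and each definition's defining set
#' (both normalized; two empty sets count as identical). Ties are broken
#' by fewer missing defining variants, then fewer extras, then lowest
#' star number, then sub-allele.
#'
#' @param copy_variants Variant table of the copy
#'   ([score_copy_variants()]), gene-local coordinates.
#' @param copy_label `"deleted"`, `"hybrid"`, or a gene name.
#' @param definitions A `star_definitions` table.
#' @param detected_switch Gene-local switch position (hybrid copies).
#' @return List with `allele`, `sub_allele`, `similarity`, `extras`,
#'   `missing`.
#' @export
assign_star_allele <- function(copy_variants, copy_label, definitions,
                               detected_switch = NA_integer_) {
  if (nrow(definitions) == 0) {
    stop("empty star-allele definition table", call. = FALSE)
  }
  keys <- if (nrow(copy_variants) > 0) {
    variant_key(copy_variants$pos, copy_variants$ref, copy_variants$alt)
  } else character()
  cand <- list()
  if (identical(copy_label, "deleted")) {
    rows <- which(definitions$structural_event == "gene_deletion")
    if (length(rows) == 0) {
      stop("no gene_deletion allele in the definition table",
           call. = FALSE)
    }
    for (r in rows) {
      cand[[length(cand) + 1L]] <- list(row = r, similarity = 1,
                                        extras = keys,
                                        missing = character())
    }
  } else if (identical(copy_label, "hybrid")) {
    rows <- which(definitions$structural_event == "hybrid")
    if (length(rows) == 0) {
      stop("no hybrid allele in the definition table", call. = FALSE)
    }
    for (r in rows) {
      d <- definitions[r, ]
      sim <- if (!is.na(detected_switch) &&
                 detected_switch >= d$switch_start &&
                 detected_switch <= d$switch_end) 1 else {
        centre <- (d$switch_start + d$switch_end) / 2
        max(0, 1 - abs(detected_switch - centre) / 1000)
      }
      cand[[length(cand) + 1L]] <- list(row = r, similarity = sim,
                                        extras = keys,
                                        missing = character())
    }
  } else {
    rows <- which(definitions$structural_event == "")
    for (r in rows) {
      dv <- definitions$variants[[r]]
      dkeys <- if (nrow(dv) > 0) variant_key(dv$pos, dv$ref, dv$alt) else
        character()
      inter <- length(intersect(keys, dkeys))
      uni <- length(union(keys, dkeys))
      sim <- if (uni == 0) 1 else inter / uni
      cand[[length(cand) + 1L]] <- list(
        row = r, similarity = sim,
        extras = setdiff(keys, dkeys), missing = setdiff(dkeys, keys))
    }
  }
  sims <- vapply(cand, `[[`, numeric(1), "similarity")
  nmiss <- vapply(cand, function(x) length(x$missing), integer(1))
  nextra <- vapply(cand, function(x) length(x$extras), integer(1))
  rows <- vapply(cand, `[[`, integer(1), "row")
  ord <- order(-sims, nmiss, nextra, star_number(definitions$allele[rows]),
               definitions$sub_allele[rows])
  best <- cand[[ord[1]]]
  d <- definitions[best$row, ]
  list(allele = d$allele, sub_allele = d$sub_allele,
       similarity = best$similarity, extras = best$extras,
       missing = best$missing)
}

#' Flag gene copies below the reliable-depth threshold
#'
#' Small-variant calls are considered reliable only from a mean depth of
#' 16X per allele per gene; copies below that are flagged low-confidence
#' but their calls are still emitted (correct star-alleles are routinely
#' recovered below the threshold).
#'
#' @param depths Numeric vector (or data.frame column `mean_depth`) of
#'   per-copy mean depths.
#' @param min_depth Reliability threshold (strict inequality).
#' @return Logical vector: `TRUE` where flagged low-confidence.
#' @export
flag_reliability <- function(depths, min_depth = 16) {
  if (is.data.frame(depths)) depths <- depths$mean_depth
  depths < min_depth
}

#' Format the diplotype call
#'
#' Within an allele, target-gene copies (pure target-gene copies and
#' hybrids) are ordered by locus position and joined with `+`; the two
#' alleles are joined with `/`, ordered by ascending copy count and then
#' star number (so a whole-gene-deletion allele prints first, as in
#' `*5/*4+*68`). Copies of the partner (pseudo)gene are reported in the
#' per-copy table but are not part of the star-allele string.
#'
#' @param allele_calls List of two per-allele call lists, each a list of
#'   copies with `star`, `position`, `mean_depth`, `in_string`.
#' @param min_depth Reliability threshold for depth flags.
#' @param homozygous Set for single-allele mode (both alleles identical).
#' @return A `DiplotypeCall`: list with `allele1`, `allele2`,
#'   `diplotype`, `per_copy` table, `flags`.
#' @export
format_diplotype <- function(allele_calls, min_depth = 16,
                             homozygous = FALSE) {
  allele_string <- function(calls) {
    named <- Filter(function(x) isTRUE(x$in_string), calls)
    if (length(named) == 0) return("*?")
    pos <- vapply(named, function(x) x$position[1], numeric(1))
    stars <- vapply(named, `[[`, character(1), "star")[order(pos)]
    paste(stars, collapse = "+")
  }
  n_copies <- vapply(allele_calls, function(calls) {
    sum(vapply(calls, function(x) isTRUE(x$in_string) &&
                 !isTRUE(x$deleted), logical(1)))
  }, integer(1))
  strings <- vapply(allele_calls, allele_string, character(1))
  primary <- vapply(strings, function(s) {
    star_number(strsplit(s, "+", fixed = TRUE)[[1]][1])
  }, numeric(1))
  ord <- order(n_copies, primary)
  per_copy <- do.call(rbind, lapply(seq_along(allele_calls), function(i) {
    calls <- allele_calls[[i]]
    if (length(calls) == 0) return(NULL)
    do.call(rbind, lapply(calls, function(x) {
      data.frame(allele = i, star = x$star, label = x$label %||% "",
                 position = x$position[1],
                 mean_depth = x$mean_depth %||% NA_real_,
                 similarity = x$similarity %||% NA_real_,
                 n_extras = length(x$extras %||% character()),
                 n_missing = length(x$missing %||% character()),
                 in_string = isTRUE(x$in_string),
                 stringsAsFactors = FALSE)
    }))
  }))
  flags <- character()
  if (!is.null(per_copy) && nrow(per_copy) > 0) {
    low <- flag_reliability(per_copy$mean_depth, min_depth)
    per_copy$low_confidence <- low & !is.na(per_copy$mean_depth)
    if (any(per_copy$low_confidence)) {
      flags <- c(flags, "low_depth")
    }
  }
  if (homozygous) flags <- c(flags, "homozygous")
  structure(list(allele1 = strings[ord[1]], allele2 = strings[ord[2]],
                 diplotype = paste(strings[ord], collapse = "/"),
                 per_copy = per_copy, flags = flags),
            class = "DiplotypeCall")
}

#' @export
print.DiplotypeCall <- function(x, ...) {
  cat("Diplotype:", x$diplotype, "\n")
  if (length(x$flags) > 0) cat("Flags:", paste(x$flags, collapse = ", "),
                               "\n")
  if (!is.null(x$per_copy) && nrow(x$per_copy) > 0) {
    print(x$per_copy, row.names = FALSE)
  }
  invisible(x)
}
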