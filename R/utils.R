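# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#' @noRd
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Random DNA of length n (uniform base composition); caller controls the seed.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute a base with one of the other three (vectorised).
other_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# Transition partner (deterministic alternative base, used for fixture tables).
transition <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}

phred_to_char <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(pmin(pmax(x, 0L), 93L) + 33L)),
         character(1))
}

# Mean phred score per read of a QualityScaledDNAStringSet.
mean_read_quality <- function(reads) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    return(rep(NA_real_, length(reads)))
  }
  ql <- methods::as(Biostrings::quality(reads), "IntegerList")
  vapply(ql, function(x) mean(as.numeric(x)), numeric(1))
}

# Path to the minimap2 binary; alignment is delegated to it (see align_reads).
minimap2_path <- function() {
  p <- Sys.which("minimap2")
  if (!nzchar(p)) {
    stop("minimap2 binary not found on PATH; read alignment requires it. ",
         "Install minimap2 or add it to PATH.", call. = FALSE)
  }
  unname(p)
}

# Left-align and parsimony-trim one variant against a reference sequence
# (character). Coordinates are 1-based. Returns list(pos, ref, alt).
normalize_variant <- function(pos, ref, alt, refseq) {
  ref <- toupper(ref); alt <- toupper(alt)
  last <- function(x) substr(x, nchar(x), nchar(x))
  # trim shared suffix / left-shift indels (vt-style)
  while (nchar(ref) > 1L || nchar(alt) > 1L) {
    if (last(ref) == last(alt)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos <= 1L) {
          stop("cannot left-align variant at contig start")
        }
        b <- substr(refseq, pos - 1L, pos - 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  # trim shared prefix (keep one anchor base for indels)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "SNV",
         ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
}

variant_key <- function(pos, ref, alt) paste0(pos, ":", ref, ">", alt)

# Empty small-variant table (shared schema).
empty_variants <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             kind = character(), gt = character(), depth = integer(),
             alt_count = integer(), qual = numeric(),
             low_confidence = logical(), stringsAsFactors = FALSE)
}
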