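#' Parse a bracketed repeat-structure string
#'
#' Parses STR repeat-structure nomenclature: whitespace-separated
#' tokens, each either `[MOTIF]k` (a repeat block of k units), a bare
#' uppercase motif (a single unit, count 1), or `Nk` (a fixed spacer of
#' k bases).  Lowercase segments -- used in published tables to spell
#' out spacer sequence -- are treated as spacer annotations and
#' normalized to their base length; the original token is preserved so
#' that serialization round-trips.
#'
#' @param text Structure string, e.g. `"[TAGA]11 [CAGA]2 N48 [TAGA]11 [CAGA]4"`.
#' @return Object of class `repeat_structure`: data frame of blocks
#'   with columns `kind` (repeat/single_unit/spacer), `motif`, `count`,
#'   `length_bp`, `raw`; attribute `source_text`.
#' @export
#' @examples
#' parse_repeat_structure("[ATA]13 AAA")
parse_repeat_structure <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(toks)) stop("empty repeat-structure string")
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    m <- regmatches(tok, regexec("^\\[([ACGT]+)\\]([0-9]+)$", tok))[[1]]
    if (length(m)) {
      count <- as.integer(m[3])
      if (count < 1) stop("zero repeat count in token ", i, ": '", tok, "'")
      rows[[i]] <- data.frame(kind = "repeat", motif = m[2], count = count,
                              length_bp = nchar(m[2]) * count, raw = tok,
                              stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(tok, regexec("^N([0-9]+)$", tok))[[1]]
    if (length(m)) {
      len <- as.integer(m[2])
      if (len < 1) stop("zero spacer length in token ", i, ": '", tok, "'")
      rows[[i]] <- data.frame(kind = "spacer", motif = NA_character_,
                              count = NA_integer_, length_bp = len, raw = tok,
                              stringsAsFactors = FALSE)
      next
    }
    if (grepl("^[ACGT]+$", tok)) {
      rows[[i]] <- data.frame(kind = "single_unit", motif = tok, count = 1L,
                              length_bp = nchar(tok), raw = tok,
                              stringsAsFactors = FALSE)
      next
    }
    # lowercase spacer annotations, bare or bracketed
    m <- regmatches(tok, regexec("^\\[([acgt]+)\\]([0-9]+)$", tok))[[1]]
    if (length(m)) {
      rows[[i]] <- data.frame(kind = "spacer", motif = NA_character_,
                              count = NA_integer_,
                              length_bp = nchar(m[2]) * as.integer(m[3]),
                              raw = tok, stringsAsFactors = FALSE)
      next
    }
    if (grepl("^[acgt-]+$", tok)) {
      rows[[i]] <- data.frame(kind = "spacer", motif = NA_character_,
                              count = NA_integer_,
                              length_bp = nchar(gsub("-", "", tok)),
                              raw = tok, stringsAsFactors = FALSE)
      next
    }
    stop("malformed repeat-structure token ", i, ": '", tok, "'")
  }
  st <- do.call(rbind, rows)
  attr(st, "source_text") <- text
  class(st) <- c("repeat_structure", "data.frame")
  st
}

#' Serialize a repeat structure back to its string form
#' @param x A `repeat_structure`.
#' @param ... Unused.
#' @return The structure string (whitespace-normalized).
#' @export
format.repeat_structure <- function(x, ...) paste(x$raw, collapse = " ")

#' @export
print.repeat_structure <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Total base length of a repeat structure
#' @param st A `repeat_structure`.
#' @return Length in bp: repeat counts times motif length, plus single
#'   units, plus spacers.
#' @export
structure_length_bp <- function(st) sum(st$length_bp)

resolve_locus <- function(locus, registry) {
  if (is.data.frame(locus)) locus else get_locus(locus, registry)
}

#' Allele designation from a repeat structure
#'
#' Applies the locus' counted-block rule: the designation is the sum of
#' repeat-block counts plus counted single units (per-locus excluded
#' motifs, e.g. the GTAT interruption at DYS460, are skipped); spacers
#' never count.  Where the locus defines a canonical spacer length, a
#' deviation folds into the designation in base pairs, yielding a
#' microvariant: with repeat unit u and a spacer d bases short of
#' canonical, the designation becomes `floor((c*u - d)/u)` whole
#' repeats with the remainder as the decimal suffix (e.g. DYS448
#' 19.2 from a 4-bp spacer deletion).
#'
#' @param st A `repeat_structure` or structure string.
#' @param locus Locus name or registry row.
#' @param registry A `ystr_registry` (used when `locus` is a name).
#' @return Numeric designation; microvariants carry the suffix as one
#'   decimal (x.y means x whole repeats plus y bases).
#' @export
#' @examples
#' allele_designation("[TAGA]11 [CAGA]2 N48 [TAGA]11 [CAGA]4", "DYS389II")
allele_designation <- function(st, locus, registry = ystr_registry()) {
  if (is.character(st)) st <- parse_repeat_structure(st)
  loc <- resolve_locus(locus, registry)
  excluded <- trimws(strsplit(loc$excluded_single_units, "[;,]")[[1]])
  counted <- sum(st$count[st$kind == "repeat"]) +
    sum(st$kind == "single_unit" & !(st$motif %in% excluded))
  spacer_bp <- sum(st$length_bp[st$kind == "spacer"])
  canon <- loc$canonical_spacer_bp
  if (is.na(canon) || spacer_bp == canon) return(as.numeric(counted))
  u <- loc$unit_length_bp
  bp <- counted * u - (canon - spacer_bp)
  whole <- bp %/% u
  rem <- bp %% u
  whole + rem / 10
}

# repeat-region signature used for variant comparison: counted blocks
# with spacers normalized to Nk
rr_signature <- function(st) {
  paste(ifelse(st$kind == "spacer", paste0("N", st$length_bp),
               ifelse(st$kind == "repeat",
                      paste0("[", st$motif, "]", st$count), st$motif)),
        collapse = " ")
}

#' Construct a sequence-based allele
#'
#' @param locus Locus name or registry row.
#' @param structure A `repeat_structure` or structure string.
#' @param flank_variants Character vector of flanking-region variant
#'   labels (e.g. dbSNP rsIDs or coordinate labels); empty when the
#'   flank matches the reference.
#' @param registry A `ystr_registry`.
#' @return Object of class `ystr_seqallele` with the designation
#'   derived from the structure under the locus rule.
#' @export
sequence_allele <- function(locus, structure, flank_variants = character(),
                            registry = ystr_registry()) {
  if (is.character(structure)) structure <- parse_repeat_structure(structure)
  loc <- resolve_locus(locus, registry)
  obj <- list(locus = loc$locus,
              designation = allele_designation(structure, loc),
              structure = structure,
              flank_variants = sort(unique(flank_variants)))
  class(obj) <- "ystr_seqallele"
  obj
}

#' Classify the relation between two sequence alleles
#'
#' Distinguishes repeat-region (RR) variants -- isoalleles with the
#' same length-based designation but different repeat-region structure
#' -- from flanking-region (FR) variants and plain length differences.
#'
#' @param a,b `ystr_seqallele` objects at the same locus.
#' @return One of `"identical"`, `"length_only"`, `"rr_variant"`,
#'   `"fr_variant"`, `"rr_and_fr"`.
#' @export
classify_variant <- function(a, b) {
  if (!identical(a$locus, b$locus))
    stop("cannot compare sequence alleles across loci (",
         a$locus, " vs ", b$locus, ")")
  same_des <- isTRUE(all.equal(a$designation, b$designation))
  rr_diff <- !identical(rr_signature(a$structure), rr_signature(b$structure))
  fr_diff <- !identical(a$flank_variants, b$flank_variants)
  if (!same_des) return("length_only")
  if (rr_diff && fr_diff) return("rr_and_fr")
  if (rr_diff) return("rr_variant")
  if (fr_diff) return("fr_variant")
  "identical"
}

#' Sequence-based versus length-based gene diversity
#'
#' Compares per-locus gene diversity when alleles are coded by their
#' full sequence (designation plus repeat/flank structure) against the
#' length-based coding of the same samples, quantifying the diversity
#' gained by sequencing.
#'
#' @param ds_seq,ds_len Character matrices or data frames (samples x
#'   loci) of allele keys under each coding; same dimensions and
#'   column names, `NA` for missing.
#' @return Data frame with `locus`, `gd_seq`, `gd_len`,
#'   `increment` (relative); attribute `averages` holds the mean GDs.
#' @export
sequence_vs_length_diversity <- function(ds_seq, ds_len) {
  ds_seq <- as.matrix(ds_seq); ds_len <- as.matrix(ds_len)
  if (!identical(dim(ds_seq), dim(ds_len)) ||
      !identical(colnames(ds_seq), colnames(ds_len)))
    stop("sequence and length datasets must cover the same samples and loci")
  gd_col <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    gene_diversity(as.integer(table(x)))
  }
  out <- data.frame(locus = colnames(ds_seq),
                    gd_seq = apply(ds_seq, 2, gd_col),
                    gd_len = apply(ds_len, 2, gd_col),
                    stringsAsFactors = FALSE)
  out$increment <- (out$gd_seq - out$gd_len) / out$gd_len
  rownames(out) <- NULL
  attr(out, "averages") <- c(gd_seq = mean(out$gd_seq, na.rm = TRUE),
                             gd_len = mean(out$gd_len, na.rm = TRUE))
  out
}

#' Which repeat block mutated, relative to block size
#'
#' For a father-son pair of structures at a compound/complex marker,
#' identifies the variable (repeat) block whose count changed and
#' classifies the event by whether that block carries the largest
#' repeat count among the father's variable blocks (`"larger_unit"`,
#' ties included) or not (`"smaller_unit"`); `"both"` when two or more
#' blocks changed, `"none"` when the structures are identical in
#' counts.
#'
#' @param f,s Father and son `repeat_structure` (or strings).
#' @return One of `"larger_unit"`, `"smaller_unit"`, `"both"`,
#'   `"none"`, or `"not_comparable"` when the block skeletons differ.
#' @export
mutated_unit_class <- function(f, s) {
  if (is.character(f)) f <- parse_repeat_structure(f)
  if (is.character(s)) s <- parse_repeat_structure(s)
  skel <- function(st) paste(st$kind, ifelse(is.na(st$motif), "", st$motif),
                             collapse = "|")
  if (nrow(f) != nrow(s) || !identical(skel(f), skel(s)))
    return("not_comparable")
  rep_i <- which(f$kind == "repeat")
  changed <- rep_i[f$count[rep_i] != s$count[rep_i]]
  if (!length(changed)) return("none")
  if (length(changed) >= 2) return("both")
  if (f$count[changed] >= max(f$count[rep_i])) "larger_unit" else "smaller_unit"
}
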