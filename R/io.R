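# Allele strings follow the one-decimal convention of CE nomenclature:
# "14" and "14.0" are the same allele, "23.2" is an intermediate allele,
# more than one decimal place is invalid.

allele_token_ok <- function(tok) grepl("^[0-9]+(\\.[0-9])?$", tok)

format_allele <- function(x) {
  s <- formatC(x, format = "f", digits = 1)
  sub("\\.0$", "", s)
}

# canonical genotype string: ascending alleles joined by ","
format_genotype <- function(values) {
  paste(format_allele(sort(values)), collapse = ",")
}

parse_genotype_string <- function(s) {
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

# Validate one raw cell against a locus' copy number.
# Returns list(values=numeric or NULL, reason=NA or QC reason, note=NA or note).
validate_cell <- function(raw, copy_number) {
  out <- function(values = NULL, reason = NA_character_, note = NA_character_)
    list(values = values, reason = reason, note = note)
  if (is.na(raw) || !nzchar(trimws(raw))) return(out(reason = "missing"))
  toks <- trimws(strsplit(trimws(raw), ",", fixed = TRUE)[[1]])
  if (!length(toks)) return(out(reason = "missing"))
  for (tok in toks) {
    if (!grepl("^-?[0-9.]+$", tok)) return(out(reason = "non-numeric"))
    if (grepl("^-", tok) || suppressWarnings(as.numeric(tok)) <= 0)
      return(out(reason = "non-positive"))
    if (!allele_token_ok(tok)) return(out(reason = "bad-precision"))
  }
  vals <- as.numeric(toks)
  if (length(vals) == copy_number) return(out(values = vals))
  if (copy_number == 2L && length(vals) == 1L)
    return(out(values = c(vals, vals), note = "homozygous-expansion"))
  out(reason = "bad-copy-count")
}

read_delim_or_xlsx <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.xlsx$", lower)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", lower)) "\t" else ","
    utils::read.csv(path, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
}

qc_row <- function(id, row_tag, locus, raw, reason, severity) {
  data.frame(id = id, row = row_tag, locus = locus,
             raw = ifelse(is.na(raw), "", raw),
             reason = reason, severity = severity,
             stringsAsFactors = FALSE)
}

empty_qc <- function() {
  data.frame(id = character(), row = character(), locus = character(),
             raw = character(), reason = character(), severity = character(),
             stringsAsFactors = FALSE)
}

#' Read a haplotype table
#'
#' Reads the tabular haplotype layout: first column sample
#' identifier, first row locus names, one column per marker; dual-copy
#' genotypes comma-separated (`13,13` homozygote, `13,20` heterozygote).
#' Cells failing validation (non-numeric, non-positive, more than one
#' decimal place, wrong copy count) and empty cells are excluded from
#' all downstream statistics and logged in the QC report -- never
#' imputed.  A single value at a dual-copy marker is expanded to a
#' homozygous pair with an informational QC note.
#'
#' @param path CSV/TSV file or .xlsx workbook.
#' @param registry A `ystr_registry`.
#' @return An object of class `ystr_haplotypes`: list with `samples`,
#'   `loci` (registry names), `geno` (character matrix of canonical
#'   genotype strings, `NA` = excluded/missing) and `qc` (data frame of
#'   QC messages, one per ignored cell; `severity` is "excluded" or
#'   "note").
#' @export
read_haplotypes <- function(path, registry = ystr_registry()) {
  raw <- read_delim_or_xlsx(path)
  if (ncol(raw) < 2) stop("haplotype table needs a sample-ID column and at least one locus")
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- names(raw)[-1]
  idx <- match_locus(hdr, registry)
  if (any(is.na(idx)))
    warning("skipping unknown locus column(s): ",
            paste(hdr[is.na(idx)], collapse = ", "))
  keep <- which(!is.na(idx))
  loci <- registry$locus[idx[keep]]
  qc <- list(empty_qc())
  geno <- matrix(NA_character_, nrow = length(ids), ncol = length(loci),
                 dimnames = list(ids, loci))
  for (k in seq_along(keep)) {
    col <- raw[[keep[k] + 1L]]
    cn <- registry$copy_number[idx[keep[k]]]
    for (r in seq_along(ids)) {
      v <- validate_cell(col[r], cn)
      if (!is.null(v$values)) {
        geno[r, k] <- format_genotype(v$values)
        if (!is.na(v$note))
          qc[[length(qc) + 1L]] <- qc_row(ids[r], "", loci[k], col[r], v$note, "note")
      } else {
        qc[[length(qc) + 1L]] <- qc_row(ids[r], "", loci[k], col[r], v$reason, "excluded")
      }
    }
  }
  structure(list(samples = ids, loci = loci, geno = geno,
                 registry = registry, qc = do.call(rbind, qc)),
            class = "ystr_haplotypes")
}

#' @export
print.ystr_haplotypes <- function(x, ...) {
  cat("Y-STR haplotype dataset:", length(x$samples), "samples x",
      length(x$loci), "markers;",
      sum(x$qc$severity == "excluded"), "cells excluded by QC\n")
  invisible(x)
}

#' Read a father-son pedigree table
#'
#' Reads the tabular pedigree layout: two rows per pedigree
#' sharing one pedigree identifier in the first column, with "P"
#' (father) / "O" (offspring) designators in the second.  An optional
#' `BirthYear` column gives birth years; the father's age at
#' gametogenesis is the son's birth year minus the father's.  Rows
#' without a matching partner are excluded and logged as
#' `unpaired-row`.  Cell validation is shared with [read_haplotypes()];
#' an invalid cell excludes that locus for that pair only (the pair is
#' kept at its other loci).
#'
#' @param path CSV/TSV file or .xlsx workbook.
#' @param registry A `ystr_registry`.
#' @return An object of class `ystr_pairs`: list with `pedigree_id`,
#'   `father_age`, `father` and `son` (canonical genotype-string
#'   matrices, pairs x loci), `loci` and `qc`.
#' @export
read_pairs <- function(path, registry = ystr_registry()) {
  raw <- read_delim_or_xlsx(path)
  if (ncol(raw) < 3) stop("pedigree table needs id, P/O designator and locus columns")
  ids <- trimws(raw[[1]])
  role <- toupper(trimws(raw[[2]]))
  hdr <- names(raw)[-(1:2)]
  by_col <- grepl("^birth[ ._-]?year$", hdr, ignore.case = TRUE)
  birth <- if (any(by_col)) suppressWarnings(as.numeric(raw[[which(by_col)[1] + 2L]])) else NULL
  loc_hdr <- hdr[!by_col]
  idx <- match_locus(loc_hdr, registry)
  if (any(is.na(idx)))
    warning("skipping unknown locus column(s): ",
            paste(loc_hdr[is.na(idx)], collapse = ", "))
  keep_cols <- which(!by_col)[!is.na(idx)]
  loci <- registry$locus[idx[!is.na(idx)]]

  qc <- list(empty_qc())
  bad_role <- !(role %in% c("P", "O"))
  for (r in which(bad_role))
    qc[[length(qc) + 1L]] <- qc_row(ids[r], role[r], "", raw[r, 2], "unpaired-row", "excluded")

  ok <- !bad_role
  ped <- unique(ids[ok])
  keep_ped <- character()
  p_row <- o_row <- integer()
  for (pid in ped) {
    pr <- which(ok & ids == pid & role == "P")
    or <- which(ok & ids == pid & role == "O")
    if (length(pr) == 1L && length(or) == 1L) {
      keep_ped <- c(keep_ped, pid)
      p_row <- c(p_row, pr); o_row <- c(o_row, or)
    } else {
      for (r in c(pr, or))
        qc[[length(qc) + 1L]] <- qc_row(pid, role[r], "", "", "unpaired-row", "excluded")
    }
  }

  n <- length(keep_ped)
  father <- son <- matrix(NA_character_, n, length(loci),
                          dimnames = list(keep_ped, loci))
  for (k in seq_along(loci)) {
    col <- raw[[keep_cols[k] + 2L]]
    cn <- registry$copy_number[match(loci[k], registry$locus)]
    for (j in seq_len(n)) {
      for (side in c("P", "O")) {
        r <- if (side == "P") p_row[j] else o_row[j]
        v <- validate_cell(col[r], cn)
        if (!is.null(v$values)) {
          if (side == "P") father[j, k] <- format_genotype(v$values)
          else son[j, k] <- format_genotype(v$values)
          if (!is.na(v$note))
            qc[[length(qc) + 1L]] <- qc_row(keep_ped[j], side, loci[k], col[r], v$note, "note")
        } else {
          qc[[length(qc) + 1L]] <- qc_row(keep_ped[j], side, loci[k], col[r], v$reason, "excluded")
        }
      }
    }
  }

  father_age <- rep(NA_real_, n)
  if (!is.null(birth)) father_age <- birth[o_row] - birth[p_row]

  structure(list(pedigree_id = keep_ped, father_age = father_age,
                 father = father, son = son, loci = loci,
                 registry = registry, qc = do.call(rbind, qc)),
            class = "ystr_pairs")
}

#' @export
print.ystr_pairs <- function(x, ...) {
  cat("Y-STR father-son pairs:", length(x$pedigree_id), "pairs x",
      length(x$loci), "markers;",
      sum(x$qc$severity == "excluded"), "records excluded by QC\n")
  invisible(x)
}

#' Write a result table
#'
#' Plain-CSV writer with a stable column order, shared by all analysis
#' outputs; `write_table` followed by `utils::read.csv` round-trips
#' values at full precision.
#'
#' @param result A data frame.
#' @param path Output file path.
#' @export
write_table <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

#' Summarize a QC report
#'
#' @param qc QC data frame from [read_haplotypes()] or [read_pairs()].
#' @return Data frame of message counts by reason.
#' @export
qc_counts <- function(qc) {
  if (!nrow(qc)) return(data.frame(reason = character(), n = integer()))
  agg <- as.data.frame(table(reason = qc$reason), stringsAsFactors = FALSE)
  names(agg) <- c("reason", "n")
  agg
}
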