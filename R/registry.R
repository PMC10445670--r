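#' Load the Y-STR locus registry
#'
#' The registry describes the 41 Y-STR loci of the 41-locus multiplex
#' (33 single-copy markers plus the four dual-copy markers DYF387S1a/b,
#' DYF404S1a/b, DYS385a/b and DYS527a/b, each contributing two allele
#' copies per male) together with the combined marker panels used for
#' haplotype projection.  Each entry carries the copy number, the
#' repeat-unit length in bp, a motif-complexity class (simple, compound,
#' complex), a flag for the initially defined rapidly mutating (RM)
#' loci, and the per-locus conventions needed to derive an allele
#' designation from a repeat structure (canonical spacer length,
#' single-unit motifs excluded from the repeat count).
#'
#' The registry ships as editable CSV configuration; pass paths to use a
#' modified registry.  The motif-class assignment for loci whose repeat
#' structure is not spelled out in the shipped structure table is
#' provisional configuration, chosen to be consistent with the pooled
#' per-class mutation rates of the reference mutation-count table.
#'
#' @param loci_path,panels_path,panel_meta_path Optional paths to CSV
#'   files overriding the shipped registry configuration.
#' @return A data frame of class `ystr_registry`, one row per marker
#'   (dual-copy markers are single rows with `copy_number = 2`), with
#'   panel definitions attached as attributes.
#' @export
#' @examples
#' reg <- ystr_registry()
#' sum(reg$copy_number)  # nominal locus count: 41
ystr_registry <- function(loci_path = NULL, panels_path = NULL,
                          panel_meta_path = NULL) {
  ext <- function(f) system.file("extdata", "registry", f, package = "ystrkit")
  if (is.null(loci_path)) loci_path <- ext("loci.csv")
  if (is.null(panels_path)) panels_path <- ext("panels.csv")
  if (is.null(panel_meta_path)) panel_meta_path <- ext("panel_meta.csv")

  loci <- utils::read.csv(loci_path, stringsAsFactors = FALSE)
  need <- c("locus", "copy_number", "unit_length_bp", "motif_class", "rm_flag")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("registry file lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(loci$locus))
    stop("duplicate locus names in registry")
  if (is.null(loci$excluded_single_units)) loci$excluded_single_units <- ""
  loci$excluded_single_units[is.na(loci$excluded_single_units)] <- ""

  panels_long <- utils::read.csv(panels_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(panel_meta_path, stringsAsFactors = FALSE)
  panels <- split(panels_long$locus, panels_long$panel)
  panels[["full"]] <- loci$locus
  for (p in names(panels)) {
    unknown <- setdiff(panels[[p]], loci$locus)
    if (length(unknown))
      stop("panel ", p, " references unknown loci: ",
           paste(unknown, collapse = ", "))
  }

  structure(loci,
            panels = panels,
            panel_meta = meta,
            class = c("ystr_registry", "data.frame"))
}

# Canonical key for case/punctuation-insensitive locus matching.
norm_locus_key <- function(x) {
  x <- toupper(trimws(x))
  gsub("[^A-Z0-9/]", "", x)
}

#' Resolve a locus name against the registry
#'
#' Matching is case-insensitive and ignores punctuation; the "a/b"
#' suffix of dual-copy markers may be dropped or written "ab"
#' (`"dys385"`, `"DYS385ab"` and `"DYS385a/b"` all resolve to the same
#' entry).
#'
#' @param name Locus identifier.
#' @param registry A `ystr_registry`.
#' @return The matching registry row (a one-row data frame).
#' @export
#' @examples
#' get_locus("dys392")$unit_length_bp
get_locus <- function(name, registry = ystr_registry()) {
  i <- match_locus(name, registry)
  if (is.na(i)) {
    near <- agrep(name, registry$locus, max.distance = 0.3,
                  ignore.case = TRUE, value = TRUE)
    stop("unknown locus '", name, "'",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(near, collapse = ", ")))
  }
  registry[i, , drop = FALSE]
}

match_locus <- function(names, registry) {
  keys <- norm_locus_key(registry$locus)
  # accept names with the a/b suffix dropped or fused ("DYS385AB")
  alias <- sub("A/B$", "", keys)
  q <- norm_locus_key(names)
  q2 <- sub("A/?B$", "", q)
  i <- match(q, keys)
  j <- match(q2, alias)
  ifelse(is.na(i), j, i)
}

#' Retrieve a combined Y-STR panel
#'
#' Seven panels are configured by default: `MH` (minimal haplotype, 9
#' loci), `SWGDAM` (11), `Yfiler` (17), `PPY23` (PowerPlex Y23),
#' `YfilerPlus` (27), `Ymax` (29) and `full` (all 41).  Locus counts
#' follow the convention that dual-copy markers count as two loci.
#' `n_l_reported` carries the locus count reported for the panel in the
#' reference population summary, which for `PPY23` differs from the
#' count implied by the standard kit definition; the panel composition
#' is configuration, not code.
#'
#' @param name Panel identifier (case-insensitive).
#' @param registry A `ystr_registry`.
#' @return A list with `name`, `loci` (registry locus names), `n_l`
#'   (sum of copy numbers) and `n_l_reported`.
#' @export
#' @examples
#' ystr_panel("MH")$n_l
ystr_panel <- function(name, registry = ystr_registry()) {
  panels <- attr(registry, "panels")
  meta <- attr(registry, "panel_meta")
  i <- match(tolower(name), tolower(names(panels)))
  if (is.na(i))
    stop("unknown panel '", name, "'; available: ",
         paste(names(panels), collapse = ", "))
  pname <- names(panels)[i]
  loci <- panels[[i]]
  n_l <- sum(registry$copy_number[match(loci, registry$locus)])
  rep_i <- match(tolower(pname), tolower(meta$panel))
  list(name = pname, loci = loci, n_l = n_l,
       n_l_reported = if (is.na(rep_i)) NA_integer_ else meta$n_l_reported[rep_i])
}

#' List configured panel names
#' @param registry A `ystr_registry`.
#' @return Character vector of panel names.
#' @export
ystr_panels <- function(registry = ystr_registry()) {
  names(attr(registry, "panels"))
}

#' Reference per-locus mutation counts
#'
#' Published per-locus mutation accounting for 2,548 Northern Han
#' Chinese father-son pairs typed at the 41-locus kit: allele transfers,
#' sequence-confirmed mutations, step-size breakdown (one-, two-,
#' multi-step) and mutation direction (gains/losses).  Shipped as a
#' plain-text table; used as the printed-counts input for desk-scale
#' rate computations and as the default rate profile of the simulator.
#'
#' @return Data frame with columns locus, transfers, mutations,
#'   one_step, two_step, multi_step, gains, losses.
#' @export
reference_mutation_counts <- function() {
  utils::read.csv(system.file("extdata", "mutation_counts_nhc2548.csv",
                              package = "ystrkit"),
                  stringsAsFactors = FALSE)
}

#' Reference novel repeat-region structures
#'
#' Bracketed repeat-structure strings for the novel repeat-region
#' variant alleles reported from massively parallel sequencing of 308
#' fathers, with their published allele designations.
#'
#' @return Data frame with columns locus, allele, structure.
#' @export
reference_repeat_structures <- function() {
  utils::read.csv(system.file("extdata", "novel_repeat_structures.csv",
                              package = "ystrkit"),
                  stringsAsFactors = FALSE)
}
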