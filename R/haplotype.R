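#' Allele frequencies at one locus
#'
#' Frequencies by mere counting over samples with valid data at the
#' locus.  For dual-copy markers, `mode = "combined"` counts unordered
#' allelic combinations (the genotype, e.g. `13,16`) while
#' `mode = "separated"` counts the individual allele copies (denominator
#' twice the number of samples).
#'
#' @param ds A `ystr_haplotypes` dataset.
#' @param locus Locus identifier.
#' @param mode `"separated"` or `"combined"`.
#' @return Data frame with columns `allele`, `count`, `freq`, plus
#'   attributes `locus`, `mode` and `n_effective` (samples with valid
#'   data).
#' @export
allele_frequencies <- function(ds, locus, mode = c("separated", "combined")) {
  mode <- match.arg(mode)
  loc <- get_locus(locus, ds$registry)
  if (!(loc$locus %in% ds$loci)) stop("locus ", loc$locus, " absent from dataset")
  g <- ds$geno[, loc$locus]
  g <- g[!is.na(g)]
  n_eff <- length(g)
  keys <- if (mode == "combined" || loc$copy_number == 1L) g
          else unlist(strsplit(g, ",", fixed = TRUE))
  tab <- table(keys)
  out <- data.frame(allele = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(suppressWarnings(as.numeric(sub(",.*", "", out$allele))),
                   out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out$freq <- out$count / sum(out$count)
  attr(out, "locus") <- loc$locus
  attr(out, "mode") <- mode
  attr(out, "n_effective") <- n_eff
  out
}

#' Gene diversity
#'
#' Unbiased gene diversity `GD = n/(n-1) * (1 - sum(p_i^2))` computed
#' from the counts of a frequency table; with haplotype frequencies the
#' same quantity is the haplotype diversity (HD).
#'
#' @param ft A frequency table from [allele_frequencies()], or any data
#'   frame with a `count` column, or a bare vector of counts.
#' @return The diversity value in `[0, 1]`.
#' @export
#' @examples
#' gene_diversity(c(2, 1, 1))  # 0.8333...
gene_diversity <- function(ft) {
  counts <- if (is.data.frame(ft)) ft$count else ft
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("gene diversity undefined for fewer than 2 observations")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

haplotype_keys <- function(ds, panel_loci) {
  sub <- ds$geno[, panel_loci, drop = FALSE]
  complete <- !apply(is.na(sub), 1L, any)
  keys <- apply(sub[complete, , drop = FALSE], 1L, paste, collapse = "|")
  list(keys = keys, complete = complete)
}

#' Haplotype summary and forensic parameters over a panel
#'
#' A haplotype is the ordered tuple of canonical genotype strings over
#' the panel loci (dual-copy genotypes as ascending pairs, so the
#' summary is invariant to copy order).  Samples missing any panel
#' locus are excluded and counted.  Reports the sharing spectrum, the
#' number of different haplotypes `N_diff`, the number observed exactly
#' once `N_unique`, the fraction of unique haplotypes
#' `F_UH = N_unique / N_diff`, haplotype diversity `HD` (gene-diversity
#' formula applied to haplotype frequencies) and discrimination
#' capacity `DC = N_diff / n`.  `F_UH` is reported `NA` when fewer than
#' two distinct haplotypes exist.
#'
#' @param ds A `ystr_haplotypes` dataset.
#' @param panel A panel name or the list returned by [ystr_panel()].
#' @return An object of class `ystr_hapsummary`.
#' @export
haplotype_summary <- function(ds, panel = "full") {
  if (is.character(panel)) panel <- ystr_panel(panel, ds$registry)
  missing_loci <- setdiff(panel$loci, ds$loci)
  if (length(missing_loci))
    stop("panel loci absent from dataset: ", paste(missing_loci, collapse = ", "))
  if (!length(panel$loci)) stop("empty panel")
  hk <- haplotype_keys(ds, panel$loci)
  if (!length(hk$keys)) stop("no samples with complete data over the panel")
  counts <- table(hk$keys)
  summary_from_hapcounts(as.integer(counts), panel = panel$name,
                         n_excluded = sum(!hk$complete))
}

summary_from_hapcounts <- function(counts, panel = NA_character_, n_excluded = 0L) {
  n <- sum(counts)
  n_diff <- length(counts)
  spectrum <- table(counts)
  spectrum <- data.frame(multiplicity = as.integer(names(spectrum)),
                         n_haplotypes = as.integer(spectrum))
  n_unique <- sum(counts == 1L)
  structure(list(
    panel = panel, n = n, n_excluded = n_excluded,
    n_diff = n_diff, n_unique = n_unique,
    spectrum = spectrum,
    f_uh = if (n_diff >= 2) n_unique / n_diff else NA_real_,
    hd = if (n >= 2) gene_diversity(counts) else NA_real_,
    dc = n_diff / n), class = "ystr_hapsummary")
}

#' Haplotype summary from a sharing spectrum
#'
#' Recomputes all forensic parameters from a printed sharing spectrum
#' (how many haplotypes were seen once, twice, ...), without access to
#' the underlying dataset.
#'
#' @param multiplicity Integer vector of sharing multiplicities.
#' @param n_haplotypes Number of haplotypes at each multiplicity.
#' @return An object of class `ystr_hapsummary`.
#' @export
#' @examples
#' # 2387 unique, 73 duplicated, 5 tripled haplotypes
#' s <- haplotype_summary_from_spectrum(c(1, 2, 3), c(2387, 73, 5))
#' s$dc
haplotype_summary_from_spectrum <- function(multiplicity, n_haplotypes) {
  stopifnot(length(multiplicity) == length(n_haplotypes),
            all(multiplicity >= 1), all(n_haplotypes >= 0))
  counts <- rep(as.integer(multiplicity), as.integer(n_haplotypes))
  summary_from_hapcounts(counts)
}

#' @export
print.ystr_hapsummary <- function(x, ...) {
  cat("Haplotype summary", if (!is.na(x$panel)) paste0("(panel ", x$panel, ")"), "\n")
  cat(sprintf("  n = %d (%d excluded for missing data)\n", x$n, x$n_excluded))
  cat(sprintf("  N_diff = %d, N_unique = %d\n", x$n_diff, x$n_unique))
  cat(sprintf("  F_UH = %.4f, HD = %.9f, DC = %.4f\n", x$f_uh, x$hd, x$dc))
  invisible(x)
}

#' Shared haplotypes
#'
#' Screens for haplotypes carried by two or more samples over a panel.
#' Output is deterministically ordered by multiplicity (descending)
#' then by haplotype string.
#'
#' @inheritParams haplotype_summary
#' @return Data frame with columns `haplotype`, `multiplicity`,
#'   `samples` (comma-separated sample IDs).
#' @export
shared_haplotype_report <- function(ds, panel = "full") {
  if (is.character(panel)) panel <- ystr_panel(panel, ds$registry)
  hk <- haplotype_keys(ds, panel$loci)
  ids <- ds$samples[hk$complete]
  grp <- split(ids, hk$keys)
  grp <- grp[lengths(grp) >= 2L]
  out <- data.frame(haplotype = names(grp),
                    multiplicity = lengths(grp),
                    samples = vapply(grp, function(s) paste(sort(s), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$multiplicity, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-locus gene diversity table
#'
#' @param ds A `ystr_haplotypes` dataset.
#' @param loci Loci to include (default: all in the dataset).
#' @param mode Frequency mode for dual-copy markers, see
#'   [allele_frequencies()].
#' @return Data frame with columns `locus`, `n_effective`, `gd`.
#' @export
gene_diversity_table <- function(ds, loci = ds$loci, mode = "combined") {
  rows <- lapply(loci, function(l) {
    ft <- allele_frequencies(ds, l, mode = mode)
    data.frame(locus = l, n_effective = attr(ft, "n_effective"),
               gd = if (sum(ft$count) >= 2) gene_diversity(ft) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
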