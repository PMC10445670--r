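# run fn under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Classify alleles into short / moderate / long size classes
#'
#' Alleles sorted by repeat number are cut at cumulative frequencies
#' 0.25 and 0.75 into short (bottom 25%), moderate (middle 50%) and
#' long (top 25%) size classes.  A boundary allele joins the class that
#' contains the majority of its probability mass; exact ties go to
#' moderate.  A single observed allele is moderate.  The rule is
#' rank-based, hence invariant to monotone relabeling of alleles.
#'
#' @param ft Frequency table from [allele_frequencies()] (separated
#'   mode for dual-copy markers), or a data frame with `allele` and
#'   `freq`.
#' @return Named character vector allele -> class.
#' @export
#' @examples
#' ft <- data.frame(allele = 10:13, freq = rep(0.25, 4))
#' classify_allele_sizes(ft)
classify_allele_sizes <- function(ft) {
  a <- suppressWarnings(as.numeric(ft$allele))
  if (anyNA(a)) stop("size classification needs numeric allele labels")
  o <- order(a)
  f <- ft$freq[o] / sum(ft$freq)
  hi <- cumsum(f)
  lo <- c(0, hi[-length(hi)])
  mass <- function(l, u) pmax(0, pmin(hi, u) - pmax(lo, l))
  m <- cbind(short = mass(0, 0.25), moderate = mass(0.25, 0.75),
             long = mass(0.75, 1))
  cls <- apply(m, 1L, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1L) "moderate" else colnames(m)[top]
  })
  stats::setNames(cls, format_allele(a[o]))
}

#' Pooled mutation rates by locus grouping
#'
#' Pools mutations and transfers within groups of loci --
#' `Sum(mutations) / Sum(transfers)`, a transfer-weighted rate, not a
#' mean of locus rates -- for groupings defined in the registry:
#' repeat-unit length, motif complexity class, or the initially defined
#' rapidly-mutating flag.
#'
#' @param per_locus Per-locus data frame with `locus`, `transfers`,
#'   `mutations` (from [mutation_summary()]`$per_locus` or
#'   [mutation_rates_from_counts()]; a `Total` row is ignored).
#' @param grouping `"unit_length"`, `"motif_class"` or `"rm_flag"`.
#' @param registry A `ystr_registry`.
#' @param level Confidence level for the pooled-rate intervals.
#' @return Data frame with `group`, `n_loci` (nominal, dual-copy
#'   markers count twice), `transfers`, `mutations`, `rate`,
#'   `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' rates_by_group(reference_mutation_counts(), "unit_length")
rates_by_group <- function(per_locus,
                           grouping = c("unit_length", "motif_class", "rm_flag"),
                           registry = ystr_registry(), level = 0.95) {
  grouping <- match.arg(grouping)
  per_locus <- per_locus[per_locus$locus != "Total", , drop = FALSE]
  i <- match_locus(per_locus$locus, registry)
  if (anyNA(i))
    stop("loci not in registry: ",
         paste(per_locus$locus[is.na(i)], collapse = ", "))
  key <- switch(grouping,
                unit_length = registry$unit_length_bp[i],
                motif_class = registry$motif_class[i],
                rm_flag = ifelse(registry$rm_flag[i], "RM", "non-RM"))
  rows <- lapply(split(seq_len(nrow(per_locus)), key), function(j) {
    tr <- sum(per_locus$transfers[j]); mu <- sum(per_locus$mutations[j])
    ci <- if (tr >= 1) clopper_pearson(mu, tr, level) else c(NA_real_, NA_real_)
    data.frame(group = as.character(key[j[1]]),
               n_loci = sum(registry$copy_number[i[j]]),
               transfers = tr, mutations = mu,
               rate = if (tr >= 1) mu / tr else NA_real_,
               ci_lower = ci[[1]], ci_upper = ci[[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-locus pattern records
#'
#' Builds the per-locus table underlying the rate-versus-repeat-number
#' analysis: the frequency-weighted mean allele repeat number from the
#' father samples, the estimated rate, and the registry annotations.
#'
#' @param ms A `ystr_mutsummary` from [mutation_summary()].
#' @param pairs The `ystr_pairs` the summary came from (source of
#'   father allele frequencies).
#' @return Data frame with `locus`, `avg_repeat_number`, `rate`,
#'   `motif_class`, `unit_length_bp`, `rm_flag`.
#' @export
locus_pattern_records <- function(ms, pairs) {
  reg <- pairs$registry
  per <- ms$per_locus[ms$per_locus$locus != "Total", , drop = FALSE]
  avg <- vapply(per$locus, function(l) {
    g <- pairs$father[, l]
    vals <- unlist(lapply(g[!is.na(g)], parse_genotype_string))
    if (!length(vals)) NA_real_ else mean(vals)
  }, 0)
  i <- match(per$locus, reg$locus)
  data.frame(locus = per$locus, avg_repeat_number = avg, rate = per$rate,
             motif_class = reg$motif_class[i],
             unit_length_bp = reg$unit_length_bp[i],
             rm_flag = reg$rm_flag[i],
             stringsAsFactors = FALSE)
}

#' Regress mutation rate on mean allele repeat number
#'
#' Ordinary least squares of the per-locus mutation rate (x 10^-3, for
#' comparability of the slope across studies) on the frequency-weighted
#' mean allele repeat number, optionally excluding the initially
#' defined rapidly-mutating loci.
#'
#' @param records From [locus_pattern_records()] (columns
#'   `avg_repeat_number`, `rate`, `rm_flag`).
#' @param exclude_rm Drop loci flagged `rm_flag`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_loci` and the `lm` fit.
#' @export
regress_rate_on_repeats <- function(records, exclude_rm = FALSE) {
  d <- records[!is.na(records$avg_repeat_number) & !is.na(records$rate), ]
  if (exclude_rm) d <- d[!d$rm_flag, ]
  if (nrow(d) < 3) stop("need at least 3 loci for the regression")
  if (length(unique(d$avg_repeat_number)) < 2)
    stop("degenerate predictor: all mean repeat numbers equal")
  fit <- stats::lm(I(rate * 1e3) ~ avg_repeat_number, data = d)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n_loci = nrow(d), fit = fit)
}

#' Pooled mutation rates by allele size class
#'
#' Classifies every usable transfer by the size class of the father's
#' allele (classes from the father-sample allele frequencies at each
#' locus, see [classify_allele_sizes()]) and pools mutations and
#' transfers per class across loci.
#'
#' @param pairs A `ystr_pairs`.
#' @param ms The matching `ystr_mutsummary`; computed when missing.
#' @param level Confidence level.
#' @return List with `rates` (per-class transfers, mutations, rate,
#'   CI), `direction` (per-class gains/losses), and `class_maps`
#'   (per-locus allele -> class).
#' @export
size_class_rates <- function(pairs, ms = mutation_summary(pairs), level = 0.95) {
  reg <- pairs$registry
  class_maps <- list()
  transfers <- mutations <- gains <- losses <-
    stats::setNames(numeric(3), c("short", "moderate", "long"))
  for (l in pairs$loci) {
    g <- pairs$father[, l]
    vals <- lapply(g, function(x) if (is.na(x)) NULL else parse_genotype_string(x))
    flat <- unlist(vals)
    if (length(flat) < 1) next
    tab <- table(format_allele(flat))
    ft <- data.frame(allele = names(tab), freq = as.integer(tab) / sum(tab))
    cmap <- classify_allele_sizes(ft)
    class_maps[[l]] <- cmap
    # transfers: one per father allele copy where the son is also typed
    son_ok <- !is.na(pairs$son[, l])
    for (j in which(!vapply(vals, is.null, TRUE) & son_ok)) {
      for (v in vals[[j]]) {
        cl <- cmap[[format_allele(v)]]
        transfers[cl] <- transfers[cl] + 1
      }
    }
    ev <- ms$events[ms$events$locus == l, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      key <- format_allele(ev$father_allele[r])
      cl <- if (key %in% names(cmap)) cmap[[key]] else "moderate"
      mutations[cl] <- mutations[cl] + 1
      if (ev$direction[r] == "gain") gains[cl] <- gains[cl] + 1
      else losses[cl] <- losses[cl] + 1
    }
  }
  cls <- names(transfers)
  ci <- t(vapply(cls, function(cl) {
    if (transfers[cl] >= 1) clopper_pearson(mutations[cl], transfers[cl], level)
    else c(lower = NA_real_, upper = NA_real_)
  }, c(lower = 0, upper = 0)))
  rates <- data.frame(size_class = cls,
                      transfers = as.integer(transfers),
                      mutations = as.integer(mutations),
                      rate = ifelse(transfers >= 1, mutations / transfers, NA),
                      ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
                      stringsAsFactors = FALSE)
  direction <- data.frame(size_class = cls,
                          gains = as.integer(gains),
                          losses = as.integer(losses),
                          stringsAsFactors = FALSE)
  rownames(rates) <- rownames(direction) <- NULL
  list(rates = rates, direction = direction, class_maps = class_maps)
}

#' Association between allele size class and mutation direction
#'
#' Tests whether longer alleles tend to lose and shorter alleles to
#' gain repeats: a size-class x direction contingency table with
#' Fisher's exact test and the chi-square test (no continuity
#' correction) side by side.
#'
#' @param direction Per-class gains/losses data frame (from
#'   [size_class_rates()]`$direction`).
#' @return List with `table`, `fisher_p`, `chisq`, `chisq_p`,
#'   `dropped` (classes with no events).
#' @export
direction_by_size <- function(direction) {
  tab <- as.matrix(direction[, c("gains", "losses")])
  rownames(tab) <- direction$size_class
  empty <- rowSums(tab) == 0
  tab2 <- tab[!empty, , drop = FALSE]
  if (nrow(tab2) < 2 || any(colSums(tab2) == 0))
    return(list(table = tab, fisher_p = NA_real_, chisq = NA_real_,
                chisq_p = NA_real_, dropped = rownames(tab)[empty]))
  fi <- stats::fisher.test(tab2)
  ch <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE))
  list(table = tab, fisher_p = fi$p.value,
       chisq = unname(ch$statistic), chisq_p = ch$p.value,
       dropped = rownames(tab)[empty])
}

#' Paternal-age analysis of mutation
#'
#' Summarizes father ages at gametogenesis (son's birth year minus
#' father's), compares ages of mutated versus non-mutated pairs with a
#' Welch two-sample t-test, regresses the per-age pooled mutation rate
#' (x 10^-3) on age, and pools rates within the 10-year age intervals
#' <20, 20-30, 30-40, >40 with a chi-square test (no continuity
#' correction) and a Fisher exact test across intervals.
#'
#' @param pairs A `ystr_pairs` with father ages.
#' @param ms The matching `ystr_mutsummary`; computed when missing.
#' @param fisher_seed Seed for the Monte-Carlo Fisher p-value on the
#'   interval table (r x 2 tables can be too large for the exact
#'   network algorithm), so results are reproducible.
#' @return List with `n_with_age`, `n_excluded`, `age_mean`, `age_sd`,
#'   `age_median`, `welch` (t statistic, p, group means; `NA` when a
#'   group is degenerate), `regression` (slope, r_squared, p on the
#'   per-age-year rates), `intervals` (per-interval transfers,
#'   mutations, rate), `chisq`, `chisq_p`, `fisher_p`.
#' @export
age_analysis <- function(pairs, ms = mutation_summary(pairs), fisher_seed = 1L) {
  age <- pairs$father_age
  has <- !is.na(age)
  n_excluded <- sum(!has)
  if (sum(has) < 2) stop("ages available for fewer than 2 pairs")
  age <- age[has]
  ped <- pairs$pedigree_id[has]
  # per-pair usable transfers and mutation counts
  reg <- pairs$registry
  cn <- reg$copy_number[match(pairs$loci, reg$locus)]
  usable <- (!is.na(pairs$father[has, , drop = FALSE])) &
            (!is.na(pairs$son[has, , drop = FALSE]))
  tr <- as.numeric(usable %*% cn)
  mut <- vapply(ped, function(p) sum(ms$events$pedigree_id == p), 0)

  mutated <- mut > 0
  welch <- list(t = NA_real_, p = NA_real_,
                mean_mutated = mean(age[mutated]),
                mean_unmutated = mean(age[!mutated]),
                sd_mutated = stats::sd(age[mutated]),
                sd_unmutated = stats::sd(age[!mutated]))
  if (sum(mutated) >= 2 && sum(!mutated) >= 2 &&
      stats::sd(age[mutated]) > 0 && stats::sd(age[!mutated]) > 0) {
    tt <- stats::t.test(age[mutated], age[!mutated])
    welch$t <- unname(tt$statistic); welch$p <- tt$p.value
  }

  by_age <- split(seq_along(age), age)
  age_rate <- data.frame(
    age = as.numeric(names(by_age)),
    transfers = vapply(by_age, function(j) sum(tr[j]), 0),
    mutations = vapply(by_age, function(j) sum(mut[j]), 0))
  age_rate$rate <- with(age_rate, ifelse(transfers > 0, mutations / transfers, NA))
  regression <- list(slope = NA_real_, r_squared = NA_real_, p_value = NA_real_)
  ok <- age_rate$transfers > 0
  if (sum(ok) >= 3 && length(unique(age_rate$age[ok])) >= 2) {
    fit <- stats::lm(I(rate * 1e3) ~ age, data = age_rate[ok, ],
                     weights = age_rate$transfers[ok])
    sm <- summary(fit)
    regression <- list(slope = unname(stats::coef(fit)[2]),
                       r_squared = sm$r.squared,
                       p_value = unname(sm$coefficients[2, 4]))
  }

  edges <- cut(age, breaks = c(-Inf, 20, 30, 40, Inf),
               labels = c("<20", "20-30", "30-40", ">40"), right = FALSE)
  iv <- lapply(split(seq_along(age), edges), function(j)
    c(transfers = sum(tr[j]), mutations = sum(mut[j])))
  intervals <- data.frame(interval = names(iv),
                          transfers = vapply(iv, `[[`, 0, "transfers"),
                          mutations = vapply(iv, `[[`, 0, "mutations"),
                          stringsAsFactors = FALSE)
  intervals$rate <- with(intervals, ifelse(transfers > 0, mutations / transfers, NA))
  rownames(intervals) <- NULL
  keep <- intervals$transfers > 0
  chisq <- chisq_p <- fisher_p <- NA_real_
  if (sum(keep) >= 2 && sum(intervals$mutations[keep]) > 0) {
    tab <- cbind(intervals$mutations[keep],
                 intervals$transfers[keep] - intervals$mutations[keep])
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chisq <- unname(ch$statistic); chisq_p <- ch$p.value
    fisher_p <- with_preserved_seed(fisher_seed, function()
      tryCatch(stats::fisher.test(tab, simulate.p.value = TRUE,
                                  B = 1e4)$p.value,
               error = function(e) NA_real_))
  }

  list(n_with_age = sum(has), n_excluded = n_excluded,
       age_mean = mean(age), age_sd = stats::sd(age),
       age_median = stats::median(age),
       welch = welch, regression = regression, per_age = age_rate,
       intervals = intervals,
       chisq = chisq, chisq_p = chisq_p, fisher_p = fisher_p)
}
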