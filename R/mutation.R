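# One detected mutation event.  Steps are counted in repeat units;
# a non-integral father-son difference (flanking-indel microvariant,
# e.g. 19 -> 19.2) is still one mutation, with the step rounded to the
# nearest whole unit and flagged non-stepwise in diagnostics.
new_event <- function(f, s) {
  d <- s - f
  step <- round(abs(d))
  data.frame(father_allele = f, son_allele = s, step = as.integer(step),
             direction = if (d > 0) "gain" else "loss",
             nonstepwise = abs(abs(d) - step) > 1e-9,
             stringsAsFactors = FALSE)
}

no_events <- function() {
  data.frame(father_allele = numeric(), son_allele = numeric(),
             step = integer(), direction = character(),
             nonstepwise = logical(), stringsAsFactors = FALSE)
}

#' Compare father and son alleles at a single-copy locus
#'
#' @param f,s Father and son allele (repeat number).
#' @return A one-row event data frame, or a zero-row frame when the
#'   alleles are equal.
#' @export
#' @examples
#' compare_single_copy(14, 15)  # one gain of step 1
compare_single_copy <- function(f, s) {
  if (isTRUE(all.equal(f, s))) return(no_events())
  new_event(f, s)
}

#' Compare father and son genotypes at a dual-copy locus
#'
#' The two allele copies are matched under the copy assignment (of the
#' two possible pairings) that minimizes first the number of mutated
#' copies and then the total step size -- the parsimony reading of the
#' stepwise mutation model.  Ties keep the ascending-order pairing.
#'
#' @param f,s Numeric vectors of length 2 (unordered genotypes).
#' @return Event data frame, one row per mutated copy (0-2 rows).
#' @export
#' @examples
#' compare_dual_copy(c(15, 16), c(16, 17))  # one 2-step event, not two 1-step
compare_dual_copy <- function(f, s) {
  f <- sort(f); s <- sort(s)
  pairings <- list(cbind(f, s), cbind(f, rev(s)))
  score <- function(m) {
    d <- abs(m[, 2] - m[, 1])
    c(sum(d > 1e-9), sum(d))
  }
  sc <- lapply(pairings, score)
  pick <- if (sc[[2]][1] < sc[[1]][1] ||
              (sc[[2]][1] == sc[[1]][1] && sc[[2]][2] < sc[[1]][2] - 1e-9)) 2L else 1L
  m <- pairings[[pick]]
  ev <- lapply(which(abs(m[, 2] - m[, 1]) > 1e-9),
               function(i) new_event(m[i, 1], m[i, 2]))
  if (!length(ev)) no_events() else do.call(rbind, ev)
}

#' Score the nested DYS389 loci
#'
#' The DYS389II amplicon contains the DYS389I repeats, so DYS389II is
#' scored on the adjusted value II - I; DYS389I is scored raw.  All
#' four alleles must be present, otherwise both loci are skipped for
#' the pair.  The raw (unadjusted) DYS389II comparison is also
#' returned for diagnostics.
#'
#' @param f_i,f_ii Father's DYS389I and DYS389II alleles.
#' @param s_i,s_ii Son's DYS389I and DYS389II alleles.
#' @return List with `dys389i`, `dys389ii` (adjusted-scale events) and
#'   `dys389ii_raw` event frames, and `inconsistent` (TRUE when
#'   II < I for either individual; no events are scored then).
#' @export
#' @examples
#' adjust_dys389(13, 29, 14, 30)$dys389ii  # adjusted 16 -> 16: no event
adjust_dys389 <- function(f_i, f_ii, s_i, s_ii) {
  if (f_ii < f_i || s_ii < s_i)
    return(list(dys389i = no_events(), dys389ii = no_events(),
                dys389ii_raw = no_events(), inconsistent = TRUE))
  list(dys389i = compare_single_copy(f_i, s_i),
       dys389ii = compare_single_copy(f_ii - f_i, s_ii - s_i),
       dys389ii_raw = compare_single_copy(f_ii, s_ii),
       inconsistent = FALSE)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from the tails of the binomial distribution, via the
#' beta-quantile closed form; the lower bound is exactly 0 when
#' `k = 0` and the upper bound exactly 1 when `k = n`.
#'
#' @param k Number of successes (mutations).
#' @param n Number of trials (allele transfers).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(32, 2548)  # c(0.0086..., 0.0177...)
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Per-locus mutation summary for father-son pairs
#'
#' Screens every usable father-son transfer for mutations, classifies
#' steps (one-, two-, multi-step with the raw spectrum retained) and
#' directions, and estimates per-locus rates with exact binomial
#' confidence intervals.  Transfers at a dual-copy marker count twice
#' per meiosis; DYS389II is scored on the adjusted II - I value (see
#' [adjust_dys389()]); a missing or invalid genotype on either side
#' skips that locus for that pair only, dropping its transfers.
#'
#' @param pairs A `ystr_pairs` object.
#' @param level Confidence level for the rate intervals.
#' @return An object of class `ystr_mutsummary`: list with `per_locus`
#'   (locus, transfers, mutations, one/two/multi-step, gains, losses,
#'   rate, ci_lower, ci_upper), `total` (the same over all loci),
#'   `events` (one row per mutation with pedigree id), `events_dys389ii_raw`,
#'   `pair_histogram` (pairs by number of mutated loci) and
#'   `frac_discriminated` (share of pairs with at least one mutation).
#' @export
mutation_summary <- function(pairs, level = 0.95) {
  reg <- pairs$registry
  loci <- pairs$loci
  n_pairs <- length(pairs$pedigree_id)
  if (!n_pairs) stop("no usable pairs")
  has389 <- all(c("DYS389I", "DYS389II") %in% loci)

  # vectorized event builder; equals compare_single_copy applied per pair
  ev_rows <- function(ped, locus, f, s) {
    d <- s - f
    keep <- abs(d) > 1e-9
    if (!any(keep)) return(NULL)
    step <- round(abs(d[keep]))
    data.frame(father_allele = f[keep], son_allele = s[keep],
               step = as.integer(step),
               direction = ifelse(d[keep] > 0, "gain", "loss"),
               nonstepwise = abs(abs(d[keep]) - step) > 1e-9,
               pedigree_id = ped[keep], locus = locus,
               stringsAsFactors = FALSE)
  }
  eps <- 1e-9
  events <- list()
  raw389 <- list()
  transfers <- stats::setNames(integer(length(loci)), loci)
  inconsistencies <- character()

  for (l in loci) {
    cn <- reg$copy_number[match(l, reg$locus)]
    if (has389 && l %in% c("DYS389I", "DYS389II")) next
    fcol <- pairs$father[, l]; scol <- pairs$son[, l]
    ok <- !is.na(fcol) & !is.na(scol)
    transfers[l] <- sum(ok) * cn
    if (!any(ok)) next
    ped <- pairs$pedigree_id[ok]
    if (cn == 1L) {
      events[[length(events) + 1L]] <-
        ev_rows(ped, l, as.numeric(fcol[ok]), as.numeric(scol[ok]))
    } else {
      fs <- strsplit(fcol[ok], ",", fixed = TRUE)
      ss <- strsplit(scol[ok], ",", fixed = TRUE)
      f1 <- as.numeric(vapply(fs, `[`, "", 1L))
      f2 <- as.numeric(vapply(fs, `[`, "", 2L))
      s1 <- as.numeric(vapply(ss, `[`, "", 1L))
      s2 <- as.numeric(vapply(ss, `[`, "", 2L))
      # choose between the two copy pairings: fewest mutated copies,
      # then smallest total step (same rule as compare_dual_copy)
      dA1 <- abs(s1 - f1); dA2 <- abs(s2 - f2)
      dB1 <- abs(s2 - f1); dB2 <- abs(s1 - f2)
      nA <- (dA1 > eps) + (dA2 > eps); nB <- (dB1 > eps) + (dB2 > eps)
      pickB <- nB < nA | (nB == nA & dB1 + dB2 < dA1 + dA2 - eps)
      m1 <- ifelse(pickB, s2, s1); m2 <- ifelse(pickB, s1, s2)
      events[[length(events) + 1L]] <- ev_rows(ped, l, f1, m1)
      events[[length(events) + 1L]] <- ev_rows(ped, l, f2, m2)
    }
  }

  if (has389) {
    fi <- suppressWarnings(as.numeric(pairs$father[, "DYS389I"]))
    fii <- suppressWarnings(as.numeric(pairs$father[, "DYS389II"]))
    si <- suppressWarnings(as.numeric(pairs$son[, "DYS389I"]))
    sii <- suppressWarnings(as.numeric(pairs$son[, "DYS389II"]))
    ok <- !is.na(fi) & !is.na(fii) & !is.na(si) & !is.na(sii)
    incons <- ok & (fii < fi | sii < si)
    inconsistencies <- pairs$pedigree_id[incons]
    ok <- ok & !incons
    transfers["DYS389I"] <- transfers["DYS389II"] <- sum(ok)
    ped <- pairs$pedigree_id[ok]
    events[[length(events) + 1L]] <- ev_rows(ped, "DYS389I", fi[ok], si[ok])
    events[[length(events) + 1L]] <-
      ev_rows(ped, "DYS389II", fii[ok] - fi[ok], sii[ok] - si[ok])
    r <- ev_rows(ped, "DYS389II", fii[ok], sii[ok])
    if (!is.null(r)) raw389[[1L]] <- r
  }

  empty_ev <- function() {
    e <- no_events(); e$pedigree_id <- character(); e$locus <- character(); e
  }
  events <- Filter(Negate(is.null), events)
  events <- if (length(events)) do.call(rbind, events) else empty_ev()
  raw389 <- if (length(raw389)) do.call(rbind, raw389) else empty_ev()

  per_locus <- do.call(rbind, lapply(loci, function(l) {
    ev <- events[events$locus == l, , drop = FALSE]
    count_row(l, transfers[[l]], ev, level)
  }))
  total <- count_row("Total", sum(transfers), events, level)

  mut_loci_per_pair <- table(factor(
    vapply(split(events$locus, events$pedigree_id), function(x) length(unique(x)), 0L)))
  pair_histogram <- data.frame(
    n_mutated_loci = as.integer(names(mut_loci_per_pair)),
    n_pairs = as.integer(mut_loci_per_pair))
  n_disc <- length(unique(events$pedigree_id))

  structure(list(per_locus = per_locus, total = total, events = events,
                 events_dys389ii_raw = raw389,
                 pair_histogram = pair_histogram,
                 n_pairs = n_pairs,
                 n_discriminated = n_disc,
                 frac_discriminated = n_disc / n_pairs,
                 dys389_inconsistent = inconsistencies,
                 level = level),
            class = "ystr_mutsummary")
}

count_row <- function(label, transfers, ev, level) {
  k <- nrow(ev)
  ci <- if (transfers >= 1) clopper_pearson(k, transfers, level) else c(NA_real_, NA_real_)
  data.frame(locus = label, transfers = as.integer(transfers), mutations = k,
             one_step = sum(ev$step == 1L), two_step = sum(ev$step == 2L),
             multi_step = sum(ev$step >= 3L),
             gains = sum(ev$direction == "gain"),
             losses = sum(ev$direction == "loss"),
             rate = if (transfers >= 1) k / transfers else NA_real_,
             ci_lower = ci[[1]], ci_upper = ci[[2]],
             stringsAsFactors = FALSE)
}

#' Mutation rates and exact intervals from a printed counts table
#'
#' Computes rates and Clopper-Pearson intervals directly from a
#' per-locus table of allele transfers and mutation counts (as printed
#' in population reports), without the underlying pedigrees.
#'
#' @param counts Data frame with at least `locus`, `transfers`,
#'   `mutations` (the shipped [reference_mutation_counts()] table fits).
#' @param level Confidence level.
#' @return The input with `rate`, `ci_lower`, `ci_upper` appended and a
#'   `Total` row; rates on the raw (per-transfer) scale.
#' @export
#' @examples
#' rates <- mutation_rates_from_counts(reference_mutation_counts())
#' round(subset(rates, locus == "Total")$rate * 1e3, 1)
mutation_rates_from_counts <- function(counts, level = 0.95) {
  stopifnot(all(c("locus", "transfers", "mutations") %in% names(counts)))
  num_cols <- setdiff(names(counts), "locus")
  tot <- counts[1, , drop = FALSE]
  tot$locus <- "Total"
  for (cc in num_cols) tot[[cc]] <- sum(counts[[cc]])
  out <- rbind(counts, tot)
  ci <- t(vapply(seq_len(nrow(out)),
                 function(i) clopper_pearson(out$mutations[i], out$transfers[i], level),
                 c(lower = 0, upper = 0)))
  out$rate <- out$mutations / out$transfers
  out$ci_lower <- ci[, "lower"]
  out$ci_upper <- ci[, "upper"]
  rownames(out) <- NULL
  out
}

#' Report a rate on the conventional x10^-3 scale
#'
#' @param rate Rate(s) on the raw per-transfer scale.
#' @param digits Decimal places after scaling (default 1, the reporting
#'   convention for Y-STR mutation rates).
#' @return Numeric, `rate * 1000` rounded.
#' @export
rate_e3 <- function(rate, digits = 1) round(rate * 1e3, digits)

#' @export
print.ystr_mutsummary <- function(x, ...) {
  cat("Y-STR mutation summary:", x$total$mutations, "mutations in",
      x$total$transfers, "allele transfers from", x$n_pairs, "pairs\n")
  cat(sprintf("  overall rate %.1f x10-3 (%d%% CI %.1f-%.1f)\n",
              rate_e3(x$total$rate), round(100 * x$level),
              rate_e3(x$total$ci_lower), rate_e3(x$total$ci_upper)))
  cat(sprintf("  %d pairs (%.2f%%) carry at least one mutation\n",
              x$n_discriminated, 100 * x$frac_discriminated))
  invisible(x)
}
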