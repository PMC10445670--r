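test_that("size classes cut the frequency spectrum at 25/50/25", {
  ft <- data.frame(allele = 10:13, freq = rep(0.25, 4))
  cls <- classify_allele_sizes(ft)
  expect_equal(unname(cls[c("10", "11", "12", "13")]),
               c("short", "moderate", "moderate", "long"))
  # a single allele is moderate
  expect_equal(unname(classify_allele_sizes(data.frame(allele = 12, freq = 1))),
               "moderate")
})

test_that("size classification is rank-based and mass-faithful", {
  set.seed(21)
  for (rep in 1:15) {
    k <- sample(3:9, 1)
    ft <- data.frame(allele = sort(sample(5:40, k)),
                     freq = as.numeric(prop.table(stats::runif(k))))
    cls <- classify_allele_sizes(ft)
    shifted <- ft; shifted$allele <- shifted$allele + 7
    expect_equal(unname(classify_allele_sizes(shifted)), unname(cls))
    # class masses within one allele's frequency of the 25/50/25 targets
    mass <- tapply(ft$freq, cls[as.character(ft$allele)], sum)
    mass <- ifelse(is.na(mass), 0, mass)
    tol <- max(ft$freq) + 1e-9
    for (nm in names(mass)) {
      target <- c(short = 0.25, moderate = 0.5, long = 0.25)[[nm]]
      expect_lt(abs(mass[[nm]] - target), tol)
    }
  }
})

test_that("pooled group rates are transfer-weighted sums, not means", {
  counts <- reference_mutation_counts()
  by_unit <- rates_by_group(counts, "unit_length")
  r <- function(g) by_unit$rate[by_unit$group == g]
  expect_equal(rate_e3(r("3")), 1.8)
  expect_equal(rate_e3(r("4")), 4.1)
  expect_equal(rate_e3(r("5")), 1.5)
  expect_equal(rate_e3(r("6")), 0.4)
  # pooled rate is bracketed by the min/max locus rate in the group
  reg <- ystr_registry()
  i <- match(counts$locus, reg$locus)
  for (u in unique(reg$unit_length_bp)) {
    sub <- counts[reg$unit_length_bp[i] == u, ]
    pooled <- by_unit$rate[by_unit$group == as.character(u)]
    lr <- sub$mutations / sub$transfers
    expect_gte(pooled, min(lr)); expect_lte(pooled, max(lr))
  }
  # single all-inclusive grouping equals the overall rate
  by_rm <- rates_by_group(counts, "rm_flag")
  expect_equal(sum(by_rm$mutations) / sum(by_rm$transfers),
               sum(counts$mutations) / sum(counts$transfers))
})

test_that("motif-complexity pooled rates reproduce the reference ordering", {
  by_motif <- rates_by_group(reference_mutation_counts(), "motif_class")
  r <- function(g) by_motif$rate[by_motif$group == g]
  expect_equal(rate_e3(r("simple")), 2.7)
  expect_equal(rate_e3(r("compound")), 3.7)
  expect_equal(rate_e3(r("complex")), 5.2)
  expect_true(r("simple") < r("compound") && r("compound") < r("complex"))
})

test_that("rate-on-repeats regression recovers known structure", {
  rec <- data.frame(locus = paste0("L", 1:6),
                    avg_repeat_number = c(10, 12, 14, 16, 18, 20),
                    rate = (0.5 + 0.2 * c(10, 12, 14, 16, 18, 20)) / 1e3,
                    rm_flag = FALSE)
  fit <- suppressWarnings(regress_rate_on_repeats(rec))  # perfect-fit note
  expect_equal(fit$slope, 0.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # simulation oracle: slope within 2 SE of truth ~95% of the time
  set.seed(31)
  hits <- 0L; reps <- 300L
  for (b in seq_len(reps)) {
    x <- seq(8, 30, length.out = 20)
    y <- 1 + 0.25 * x + stats::rnorm(20, 0, 0.8)
    d <- data.frame(locus = paste0("L", 1:20), avg_repeat_number = x,
                    rate = y / 1e3, rm_flag = FALSE)
    f <- regress_rate_on_repeats(d)
    se <- sqrt(stats::vcov(f$fit)[2, 2])
    if (abs(f$slope - 0.25) < 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
  expect_error(regress_rate_on_repeats(rec[1:2, ]), "at least 3")
  rec$avg_repeat_number <- 12
  expect_error(regress_rate_on_repeats(rec), "degenerate")
})

test_that("excluding RM loci drops the flagged loci from the fit", {
  rec <- data.frame(locus = paste0("L", 1:8),
                    avg_repeat_number = c(10, 11, 12, 13, 14, 15, 30, 35),
                    rate = c(1, 1.2, 1.4, 1.6, 1.8, 2.0, 30, 40) / 1e3,
                    rm_flag = c(rep(FALSE, 6), TRUE, TRUE))
  all_fit <- regress_rate_on_repeats(rec)
  no_rm <- suppressWarnings(regress_rate_on_repeats(rec, exclude_rm = TRUE))
  expect_equal(no_rm$n_loci, 6L)
  expect_gt(no_rm$r_squared, all_fit$r_squared - 1e-9)
})

test_that("size-class rates classify transfers by the father's allele", {
  # fathers: allele 10 x2 (short-ish), 12 x4, 14 x2 -> 25/50/25 classes
  ids <- sprintf("P%d", 1:8)
  fa <- c(10, 10, 12, 12, 12, 12, 14, 14)
  so <- fa; so[1] <- 11; so[8] <- 13      # short gain, long loss
  fathers <- lapply(fa, function(a) c(DYS19 = format(a)))
  sons <- lapply(so, function(a) c(DYS19 = format(a)))
  pr <- make_pair_ds(pair_table(ids, fathers, sons))
  sc <- size_class_rates(pr)
  rates <- sc$rates
  expect_equal(sum(rates$transfers), 8L)
  expect_equal(rates$transfers[rates$size_class == "short"], 2L)
  expect_equal(rates$transfers[rates$size_class == "moderate"], 4L)
  expect_equal(rates$transfers[rates$size_class == "long"], 2L)
  expect_equal(rates$mutations[rates$size_class == "short"], 1L)
  dirs <- sc$direction
  expect_equal(dirs$gains[dirs$size_class == "short"], 1L)
  expect_equal(dirs$losses[dirs$size_class == "long"], 1L)
  # margins equal total gains/losses
  expect_equal(sum(dirs$gains), 1L); expect_equal(sum(dirs$losses), 1L)
})

test_that("direction-by-size association is detected when planted", {
  strong <- data.frame(size_class = c("short", "moderate", "long"),
                       gains = c(30, 15, 0), losses = c(0, 15, 30))
  res <- direction_by_size(strong)
  expect_lt(res$fisher_p, 1e-6)
  expect_lt(res$chisq_p, 1e-6)
  # balanced table: no association
  flat <- data.frame(size_class = c("short", "moderate", "long"),
                     gains = c(10, 10, 10), losses = c(10, 10, 10))
  expect_gt(direction_by_size(flat)$fisher_p, 0.99)
  # null calibration: p-values roughly uniform under independence
  set.seed(41)
  ps <- replicate(200, {
    g <- stats::rbinom(3, 40, 0.5)
    direction_by_size(data.frame(size_class = c("s", "m", "l"),
                                 gains = g, losses = 40 - g))$fisher_p
  })
  expect_lte(mean(ps < 0.05), 0.12)
  # empty classes are dropped with a note
  one <- data.frame(size_class = c("short", "long"),
                    gains = c(0, 5), losses = c(0, 5))
  expect_true("short" %in% direction_by_size(one)$dropped)
})

test_that("age analysis reports summaries and a null age effect stays null", {
  set.seed(51)
  reg <- ystr_registry()
  reps <- 60L
  null_ok <- 0L
  for (b in seq_len(reps)) {
    cfg <- sim_config(n_pairs = 120, seed = 1000L + b, age_beta = 0)
    sim <- simulate_pairs(cfg)
    aa <- age_analysis(sim$pairs)
    if (is.na(aa$regression$p_value) || aa$regression$p_value > 0.05)
      null_ok <- null_ok + 1L
  }
  expect_gte(null_ok / reps, 0.85)

  cfg <- sim_config(n_pairs = 200, seed = 9)
  sim <- simulate_pairs(cfg)
  aa <- age_analysis(sim$pairs)
  expect_equal(aa$n_with_age, 200L)
  expect_true(aa$age_mean > 20 && aa$age_mean < 33)
  expect_equal(sum(aa$intervals$mutations), nrow(sim$truth))
  expect_setequal(aa$intervals$interval, c("<20", "20-30", "30-40", ">40"))

  # all fathers the same age: Welch comparison undefined
  df <- pair_table(c("A", "B", "C", "D"),
                   fathers = rep(list(c(DYS19 = "14")), 4),
                   sons = list(c(DYS19 = "15"), c(DYS19 = "14"),
                               c(DYS19 = "14"), c(DYS19 = "15")),
                   birth_p = rep(1975, 4), birth_o = rep(2000, 4))
  aa2 <- age_analysis(make_pair_ds(df))
  expect_true(is.na(aa2$welch$p))
})
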