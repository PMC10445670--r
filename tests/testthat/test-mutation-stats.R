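test_that("single-copy comparison follows the stepwise definition", {
  expect_equal(nrow(compare_single_copy(14, 14)), 0L)
  ev <- compare_single_copy(14, 15)
  expect_equal(ev$direction, "gain"); expect_equal(ev$step, 1L)
  ev <- compare_single_copy(31, 29)
  expect_equal(ev$direction, "loss"); expect_equal(ev$step, 2L)
})

test_that("microvariant differences count as flagged mutations", {
  ev <- compare_single_copy(19, 19.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$step, 0L)          # same whole-repeat count
  expect_true(ev$nonstepwise)
  ev <- compare_single_copy(19, 20.2)
  expect_equal(ev$step, 1L)
  expect_true(ev$nonstepwise)
})

test_that("dual-copy matching minimizes mutated copies then total steps", {
  ev <- compare_dual_copy(c(13, 20), c(13, 21))
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$father_allele, ev$son_allele), c(20, 21))
  ev <- compare_dual_copy(c(13, 13), c(13, 14))
  expect_equal(c(ev$father_allele, ev$son_allele), c(13, 14))
  # one 2-step event beats two 1-step events
  ev <- compare_dual_copy(c(15, 16), c(16, 17))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$step, 2L)
  expect_equal(c(ev$father_allele, ev$son_allele), c(15, 17))
  expect_equal(nrow(compare_dual_copy(c(13, 16), c(16, 13))), 0L)
})

test_that("dual-copy matcher agrees with brute-force pairing enumeration", {
  set.seed(11)
  for (i in 1:500) {
    f <- sample(8:20, 2, replace = TRUE)
    s <- f + sample(c(-2, -1, 0, 0, 0, 1, 2), 2, replace = TRUE)
    s <- pmax(s, 1)
    got <- compare_dual_copy(f, s)
    ref <- dual_bruteforce(f, s)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      o1 <- order(got$father_allele, got$son_allele)
      o2 <- order(ref$father, ref$son)
      expect_equal(got$father_allele[o1], ref$father[o2])
      expect_equal(got$son_allele[o1], ref$son[o2])
    }
  }
})

test_that("DYS389II is scored on the II - I adjusted value", {
  r <- adjust_dys389(13, 29, 13, 30)
  expect_equal(nrow(r$dys389i), 0L)
  expect_equal(nrow(r$dys389ii), 1L)
  expect_equal(c(r$dys389ii$father_allele, r$dys389ii$son_allele), c(16, 17))
  expect_equal(r$dys389ii$direction, "gain")

  # a DYS389I gain moves raw II without an adjusted-II event
  r <- adjust_dys389(13, 29, 14, 30)
  expect_equal(nrow(r$dys389i), 1L)
  expect_equal(r$dys389i$direction, "gain")
  expect_equal(nrow(r$dys389ii), 0L)
  expect_equal(nrow(r$dys389ii_raw), 1L)   # raw comparison retained

  r <- adjust_dys389(13, 29, 13, 29)
  expect_equal(nrow(r$dys389i) + nrow(r$dys389ii), 0L)

  r <- adjust_dys389(13, 12, 13, 29)
  expect_true(r$inconsistent)
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  for (n in c(10, 100, 2548)) for (k in c(0, 1, 5, n %/% 2, n)) {
    got <- clopper_pearson(k, n)
    ref <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-9,
                 label = sprintf("k=%d n=%d", k, n))
  }
  expect_identical(clopper_pearson(0, 50)[["lower"]], 0)
  expect_identical(clopper_pearson(50, 50)[["upper"]], 1)
})

test_that("Clopper-Pearson bounds are monotone in k for fixed n", {
  ci <- t(sapply(0:30, clopper_pearson, n = 30))
  expect_true(all(diff(ci[, "lower"]) >= -1e-12))
  expect_true(all(diff(ci[, "upper"]) >= -1e-12))
})

test_that("mutation summary reproduces a hand-planted fixture exactly", {
  loci <- c("DYS19", "DYS389I", "DYS389II", "DYS385a/b")
  base_f <- c(DYS19 = "14", DYS389I = "13", DYS389II = "29",
              `DYS385a/b` = "13,16")
  fathers <- rep(list(base_f), 10)
  sons <- fathers
  sons[[1]]["DYS19"] <- "15"                    # gain 1
  sons[[2]]["DYS19"] <- "12"                    # loss 2
  sons[[3]]["DYS389I"] <- "14"                  # I gain; raw II unchanged
  sons[[3]]["DYS389II"] <- "30"                 #   -> no adjusted II event
  sons[[4]]["DYS389II"] <- "30"                 # adjusted II gain
  sons[[5]]["DYS385a/b"] <- "13,17"             # dual-copy gain 1
  sons[[6]]["DYS385a/b"] <- "14,17"             # both copies mutated
  sons[[7]]["DYS19"] <- ""                      # missing: transfer dropped
  pr <- make_pair_ds(pair_table(sprintf("F%02d", 1:10), fathers, sons))
  ms <- mutation_summary(pr)

  per <- ms$per_locus
  expect_equal(per$transfers[per$locus == "DYS19"], 9L)
  expect_equal(per$transfers[per$locus == "DYS389I"], 10L)
  expect_equal(per$transfers[per$locus == "DYS385a/b"], 20L)
  expect_equal(per$mutations[per$locus == "DYS19"], 2L)
  expect_equal(per$gains[per$locus == "DYS19"], 1L)
  expect_equal(per$losses[per$locus == "DYS19"], 1L)
  expect_equal(per$two_step[per$locus == "DYS19"], 1L)
  expect_equal(per$mutations[per$locus == "DYS389I"], 1L)
  expect_equal(per$mutations[per$locus == "DYS389II"], 1L)
  expect_equal(per$mutations[per$locus == "DYS385a/b"], 3L)

  # totals conservation
  expect_equal(ms$total$mutations, sum(per$mutations))
  expect_equal(ms$total$transfers, sum(per$transfers))
  expect_equal(ms$total$gains + ms$total$losses, ms$total$mutations)
  expect_equal(ms$total$one_step + ms$total$two_step + ms$total$multi_step,
               ms$total$mutations)

  # pair histogram: six pairs mutated, each at exactly one locus
  # (F06 carries two events but on one locus)
  h <- ms$pair_histogram
  expect_equal(h$n_pairs[h$n_mutated_loci == 1L], 6L)
  expect_equal(ms$n_discriminated, 6L)
  expect_equal(ms$frac_discriminated, 0.6)

  # rates bracket and CI coverage of the point estimate
  expect_true(all(per$ci_lower <= per$rate + 1e-12 &
                  per$rate <= per$ci_upper + 1e-12))
})

test_that("zero mutations give rate 0 with CI lower bound exactly 0", {
  pr <- make_pair_ds(pair_table(c("A", "B"),
                                fathers = list(c(DYS19 = "14"), c(DYS19 = "15")),
                                sons = list(c(DYS19 = "14"), c(DYS19 = "15"))))
  ms <- mutation_summary(pr)
  expect_identical(ms$per_locus$rate, 0)
  expect_identical(ms$per_locus$ci_lower, 0)
})

test_that("rates from a printed counts table carry consistent totals", {
  r <- mutation_rates_from_counts(reference_mutation_counts())
  tot <- r[r$locus == "Total", ]
  per <- r[r$locus != "Total", ]
  expect_equal(tot$mutations, sum(per$mutations))
  expect_equal(tot$transfers, sum(per$transfers))
  expect_equal(tot$gains + tot$losses, tot$mutations)
  expect_equal(per$rate, per$mutations / per$transfers)
})
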