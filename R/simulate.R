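#' Simulation configuration
#'
#' Defines the generative model for synthetic Y-STR populations and
#' father-son pairs: per-locus allele frequency spectra, per-locus
#' mutation rates, a stepwise step-size distribution with a geometric
#' tail, gain/loss probabilities conditional on the father's allele
#' size class, and a truncated-normal father-age distribution with an
#' optional log-linear age effect on the rate.
#'
#' Defaults are a "reference-like" profile: rates are the per-locus
#' point estimates of the shipped reference mutation-count table;
#' spectra are geometric-decay spectra around each locus' typical modal
#' allele (illustrative of real spectra, not a reconstruction of any
#' cohort); the step distribution matches the reference step breakdown
#' (one-step 344/356, two-step 8/356, geometric tail beyond); gain
#' probabilities are size-dependent (0.65/0.50/0.35 for short/
#' moderate/long) so that gains and losses are close to balanced
#' overall while longer alleles tend to lose repeats; father ages are
#' Normal(26.29, 4.21) truncated to [16, 50] years.
#'
#' @param registry A `ystr_registry`.
#' @param n_pairs Number of father-son pairs (or fathers) to simulate.
#' @param rates Named per-locus mutation rates; default from
#'   [reference_mutation_counts()].
#' @param spectra Named list locus -> named numeric vector of allele
#'   probabilities; default geometric-decay spectra.
#' @param step_probs Probabilities of step sizes 1, 2 and >=3.
#' @param multi_geom_p Geometric continuation parameter within the
#'   >=3 tail.
#' @param gain_probs Named probabilities of a repeat gain given the
#'   father allele's size class.
#' @param age_mean,age_sd,age_range Father-age distribution (years).
#' @param age_beta Log-linear age coefficient on the per-transfer rate
#'   (0 = no age effect): `mu * exp(age_beta * (age - age_mean))`.
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return A list of class `ystr_simconfig`.
#' @export
sim_config <- function(registry = ystr_registry(),
                       n_pairs = 2548L,
                       rates = NULL,
                       spectra = NULL,
                       step_probs = c(344, 8, 4) / 356,
                       multi_geom_p = 0.5,
                       gain_probs = c(short = 0.65, moderate = 0.5, long = 0.35),
                       age_mean = 26.29, age_sd = 4.21,
                       age_range = c(16, 50),
                       age_beta = 0,
                       seed = 1L) {
  if (is.null(rates)) {
    rc <- reference_mutation_counts()
    rates <- stats::setNames(rc$mutations / rc$transfers, rc$locus)
  }
  if (is.null(spectra)) spectra <- default_spectra(registry)
  stopifnot(abs(sum(step_probs) - 1) < 1e-9, all(step_probs >= 0),
            all(rates >= 0), all(rates <= 1))
  for (sp in spectra)
    if (abs(sum(sp) - 1) > 1e-9 || any(sp < 0)) stop("invalid allele spectrum")
  cfg <- list(registry = registry, n_pairs = as.integer(n_pairs),
              rates = rates, spectra = spectra, step_probs = step_probs,
              multi_geom_p = multi_geom_p, gain_probs = gain_probs,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              age_beta = age_beta, seed = as.integer(seed))
  class(cfg) <- "ystr_simconfig"
  cfg
}

# geometric-decay spectrum around the registry's modal allele
default_spectra <- function(registry, halfwidth = 3L, decay = 0.45) {
  sp <- list()
  for (i in seq_len(nrow(registry))) {
    modal <- registry$modal_allele[i]
    if (is.null(modal) || is.na(modal)) modal <- 13
    k <- (-halfwidth):halfwidth
    w <- decay^abs(k)
    sp[[registry$locus[i]]] <- stats::setNames(w / sum(w), modal + k)
  }
  sp
}

draw_alleles <- function(spectrum, n) {
  as.numeric(sample(names(spectrum), n, replace = TRUE, prob = spectrum))
}

#' Simulate a male population
#'
#' Draws `n_pairs` independent haplotypes from the configured per-locus
#' allele spectra; dual-copy markers draw two alleles independently
#' (stored unordered).
#'
#' @param cfg A `ystr_simconfig`.
#' @return A `ystr_haplotypes` dataset.
#' @export
simulate_population <- function(cfg) {
  set.seed(cfg$seed)
  reg <- cfg$registry
  n <- cfg$n_pairs
  ids <- sprintf("SIM%05d", seq_len(n))
  loci <- reg$locus
  geno <- matrix(NA_character_, n, length(loci), dimnames = list(ids, loci))
  for (k in seq_along(loci)) {
    sp <- cfg$spectra[[loci[k]]]
    cn <- reg$copy_number[k]
    if (cn == 1L) {
      geno[, k] <- format_allele(draw_alleles(sp, n))
    } else {
      a <- draw_alleles(sp, n); b <- draw_alleles(sp, n)
      geno[, k] <- mapply(function(x, y) format_genotype(c(x, y)), a, b)
    }
  }
  structure(list(samples = ids, loci = loci, geno = geno,
                 registry = reg, qc = empty_qc()),
            class = "ystr_haplotypes")
}

draw_steps <- function(cfg, k) {
  cls <- sample.int(3L, k, replace = TRUE, prob = cfg$step_probs)
  ifelse(cls < 3L, cls, 3L + stats::rgeom(k, cfg$multi_geom_p))
}

# transmit a vector of allele copies father -> son under rate mu
# (per-individual), logging mutated copies; size_key gives the allele
# value used for size-class lookup (differs from the transmitted value
# only for the adjusted DYS389II stretch)
transmit_copies <- function(fa, mu, cfg, size_map, ped, locus, size_key = fa) {
  n <- length(fa)
  so <- fa
  idx <- which(stats::runif(n) < mu)
  if (!length(idx))
    return(list(son = so, events = NULL))
  k <- length(idx)
  steps <- draw_steps(cfg, k)
  keys <- format_allele(size_key[idx])
  cls <- ifelse(keys %in% names(size_map), size_map[keys], "moderate")
  dir <- ifelse(stats::runif(k) < cfg$gain_probs[cls], 1, -1)
  son <- fa[idx] + dir * steps
  flip <- son <= 0  # reflect at zero: repeats stay positive
  son[flip] <- fa[idx][flip] + steps[flip]
  dir[flip] <- 1
  so[idx] <- son
  list(son = so,
       events = data.frame(father_allele = fa[idx], son_allele = son,
                           step = as.integer(steps),
                           direction = ifelse(dir > 0, "gain", "loss"),
                           pedigree_id = ped[idx], locus = locus,
                           stringsAsFactors = FALSE))
}

#' Simulate father-son pairs with known ground truth
#'
#' Draws fathers from the allele spectra and transmits each allele copy
#' to the son, mutating with the per-locus rate (age-modulated when
#' `age_beta` is nonzero), step size from the stepwise distribution and
#' direction from the size-class gain probabilities.  The nested
#' DYS389 pair is simulated coherently: DYS389I and the II-specific
#' stretch (II minus I) mutate independently, and the raw DYS389II
#' allele is their sum, so a DYS389I mutation shifts raw DYS389II
#' without constituting a DYS389II event -- ground truth for DYS389II
#' is logged on the adjusted scale.
#'
#' @param cfg A `ystr_simconfig`.
#' @return List with `pairs` (a `ystr_pairs`) and `truth` (data frame
#'   of planted events: pedigree_id, locus, father_allele, son_allele,
#'   step, direction; DYS389II on the adjusted scale).
#' @export
simulate_pairs <- function(cfg) {
  set.seed(cfg$seed)
  reg <- cfg$registry
  n <- cfg$n_pairs
  ids <- sprintf("P%05d", seq_len(n))
  loci <- reg$locus
  ages <- round(stats::rnorm(n, cfg$age_mean, cfg$age_sd))
  ages <- pmin(pmax(ages, cfg$age_range[1]), cfg$age_range[2])
  age_factor <- exp(cfg$age_beta * (ages - cfg$age_mean))

  size_maps <- lapply(loci, function(l) {
    sp <- cfg$spectra[[l]]
    classify_allele_sizes(data.frame(allele = as.numeric(names(sp)),
                                     freq = as.numeric(sp)))
  })
  names(size_maps) <- loci

  father <- son <- matrix(NA_character_, n, length(loci),
                          dimnames = list(ids, loci))
  truth <- list()
  has389 <- all(c("DYS389I", "DYS389II") %in% loci)

  for (k in seq_along(loci)) {
    l <- loci[k]
    if (has389 && l == "DYS389II") next  # simulated with DYS389I below
    sp <- cfg$spectra[[l]]
    mu <- pmin(1, cfg$rates[[l]] * age_factor)
    cn <- reg$copy_number[k]
    fa1 <- draw_alleles(sp, n)
    t1 <- transmit_copies(fa1, mu, cfg, size_maps[[l]], ids, l)
    truth[[length(truth) + 1L]] <- t1$events
    if (cn == 1L) {
      father[, k] <- format_allele(fa1)
      son[, k] <- format_allele(t1$son)
    } else {
      fa2 <- draw_alleles(sp, n)
      t2 <- transmit_copies(fa2, mu, cfg, size_maps[[l]], ids, l)
      truth[[length(truth) + 1L]] <- t2$events
      father[, k] <- paste(format_allele(pmin(fa1, fa2)),
                           format_allele(pmax(fa1, fa2)), sep = ",")
      son[, k] <- paste(format_allele(pmin(t1$son, t2$son)),
                        format_allele(pmax(t1$son, t2$son)), sep = ",")
    }
    if (has389 && l == "DYS389I") {
      # the II-specific stretch rides on top of the I repeats
      sp2 <- cfg$spectra[["DYS389II"]]
      adj_f <- pmax(1, draw_alleles(sp2, n) - fa1)
      mu2 <- pmin(1, cfg$rates[["DYS389II"]] * age_factor)
      t2 <- transmit_copies(adj_f, mu2, cfg, size_maps[["DYS389II"]],
                            ids, "DYS389II", size_key = adj_f + fa1)
      truth[[length(truth) + 1L]] <- t2$events
      father[, "DYS389II"] <- format_allele(fa1 + adj_f)
      son[, "DYS389II"] <- format_allele(t1$son + t2$son)
    }
  }

  truth <- Filter(Negate(is.null), truth)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(father_allele = numeric(), son_allele = numeric(),
               step = integer(), direction = character(),
               pedigree_id = character(), locus = character(),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$pedigree_id, truth$locus), , drop = FALSE]
  rownames(truth) <- NULL

  pairs <- structure(list(pedigree_id = ids, father_age = ages,
                          father = father, son = son, loci = loci,
                          registry = reg, qc = empty_qc()),
                     class = "ystr_pairs")
  list(pairs = pairs, truth = truth)
}

#' Write simulated data in the tabular input dialect
#'
#' Writes a haplotype table (`samples x loci`) or a pedigree table (two
#' rows per pair, P/O designators, optional birth years) that
#' round-trips through [read_haplotypes()] / [read_pairs()]; useful
#' both as fixtures and as format documentation.
#'
#' @param ds A `ystr_haplotypes`.
#' @param path Output CSV path.
#' @export
write_haplotype_table <- function(ds, path) {
  df <- data.frame(SampleID = ds$samples, ds$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' @rdname write_haplotype_table
#' @param pairs A `ystr_pairs`.
#' @param son_birth_year Birth year assigned to sons (fathers get
#'   `son_birth_year - father_age`), written when ages are present.
#' @export
write_pair_table <- function(pairs, path, son_birth_year = 2000L) {
  n <- length(pairs$pedigree_id)
  rows <- vector("list", 2L * n)
  has_age <- !all(is.na(pairs$father_age))
  for (j in seq_len(n)) {
    p <- data.frame(PedigreeID = pairs$pedigree_id[j], Role = "P",
                    stringsAsFactors = FALSE)
    o <- data.frame(PedigreeID = pairs$pedigree_id[j], Role = "O",
                    stringsAsFactors = FALSE)
    if (has_age) {
      o$BirthYear <- son_birth_year
      p$BirthYear <- son_birth_year - pairs$father_age[j]
    }
    for (l in pairs$loci) {
      p[[l]] <- pairs$father[j, l]
      o[[l]] <- pairs$son[j, l]
    }
    rows[[2 * j - 1L]] <- p; rows[[2 * j]] <- o
  }
  write_table(do.call(rbind, rows), path)
}
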