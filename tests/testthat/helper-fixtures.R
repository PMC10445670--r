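# fixture builders: write a small table to a temp CSV and read it back
# through the package's own readers, so fixtures exercise the IO path

write_fixture_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

make_hap_ds <- function(df, registry = ystr_registry()) {
  suppressWarnings(read_haplotypes(write_fixture_csv(df), registry))
}

make_pair_ds <- function(df, registry = ystr_registry()) {
  suppressWarnings(read_pairs(write_fixture_csv(df), registry))
}

# two-row (father, son) pedigree records from parallel named lists
pair_table <- function(ids, fathers, sons, birth_p = NULL, birth_o = NULL) {
  loci <- names(fathers[[1]])
  rows <- list()
  for (j in seq_along(ids)) {
    p <- c(list(PedigreeID = ids[j], Role = "P"),
           if (!is.null(birth_p)) list(BirthYear = birth_p[j]),
           as.list(fathers[[j]]))
    o <- c(list(PedigreeID = ids[j], Role = "O"),
           if (!is.null(birth_o)) list(BirthYear = birth_o[j]),
           as.list(sons[[j]]))
    rows[[2 * j - 1]] <- as.data.frame(p, check.names = FALSE)
    rows[[2 * j]] <- as.data.frame(o, check.names = FALSE)
  }
  do.call(rbind, rows)
}

# brute-force gene diversity: fraction of unequal ordered pairs,
# scaled by the unbiased factor -- independent of the package formula
gd_bruteforce <- function(values) {
  n <- length(values)
  uneq <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && values[i] != values[j]) uneq <- uneq + 1
  uneq / (n * (n - 1))
}

# brute-force dual-copy matcher: enumerate both copy pairings and pick
# (fewest mutated copies, then smallest total step)
dual_bruteforce <- function(f, s) {
  f <- sort(f); s <- sort(s)
  best <- NULL
  for (perm in list(c(1, 2), c(2, 1))) {
    d <- abs(s[perm] - f)
    key <- c(sum(d > 1e-9), sum(d))
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2] - 1e-9))
      best <- list(key = key, perm = perm)
  }
  idx <- which(abs(s[best$perm] - f) > 1e-9)
  if (!length(idx)) return(data.frame(father = numeric(), son = numeric()))
  data.frame(father = f[idx], son = s[best$perm][idx])
}
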