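# In-code fixtures shared across the suite. Everything is generated at
# test time; nothing is read from disk except round-trip temp files.

# metadata skeleton with all HLA/titer fields missing
blank_md <- function(group, batch = NULL, ids = NULL) {
  n <- length(group)
  if (is.null(batch)) batch <- rep("b1", n)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  md <- data.frame(sample_id = ids, group = group, batch = batch)
  for (h in HLA_COLS) md[[h]] <- NA_integer_
  for (t in TITER_COLS) md[[t]] <- NA_real_
  md
}

# balanced three-group metadata with rotating batches
null_md <- function(n_per_group = c(30, 30, 30), n_batches = 3) {
  group <- rep(GROUP_LEVELS, times = n_per_group)
  batch <- rep_len(sprintf("b%d", seq_len(n_batches)), length(group))
  blank_md(group, batch)
}

# random positive count matrix
rand_counts <- function(n, k, lambda = 50) {
  matrix(stats::rpois(n * k, lambda), n, k,
         dimnames = list(sprintf("S%03d", seq_len(n)),
                         sprintf("t%02d", seq_len(k))))
}

# four-leaf taxonomy: two phyla, one class per leaf pair
toy_taxonomy <- function() {
  data.frame(
    taxon_id = c("t01", "t02", "t03", "t04"),
    kingdom = "Bacteria",
    phylum = c("pA", "pA", "pB", "pB"),
    class = c("cA1", "cA2", "cB1", "cB2"),
    order = c("oA1", "oA2", "oB1", "oB2"),
    family = c("fA1", "fA2", "fB1", "fB2"),
    genus = c("gA1", "gA2", "gB1", "gB2"),
    species = c("sA1", "sA2", "sB1", "sB2"))
}

# cohorts are expensive enough to share across test files
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 1) {
  key <- paste0("co", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(default_cohort_spec(seed))
  .cohort_cache[[key]]
}

# independently coded brute-force BH step-up (oracle for bh_fdr)
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    q[o[i]] <- min(1, running_min)
  }
  q
}

# independently coded pseudo-F (oracle for permanova internals)
brute_force_pseudo_f <- function(d, lab) {
  d2 <- as.matrix(d)^2
  lab <- factor(lab)
  n <- length(lab)
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in levels(lab)) {
    i <- which(lab == g)
    ssw <- ssw + sum(d2[i, i][lower.tri(d2[i, i])]) / length(i)
  }
  ((sst - ssw) / (nlevels(lab) - 1)) / (ssw / (n - nlevels(lab)))
}
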