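# Seeded generator of synthetic cohorts with the statistical structure the
# analysis assumes: a ranked taxonomy, logistic-normal compositions with
# multinomial sequencing depth, planted monotone severity effects, batch
# effects, HLA-by-taxon interactions on disease state, and
# titer-by-disease interactions. Ground truth is returned alongside the
# data so every estimator can be validated by recovery.

#' Specify a synthetic cohort
#'
#' All knobs of the generative model. Group sizes default to the 23/43/82
#' healthy / Asym-UAS / SS-SLE split of the cohort the package emulates;
#' sequencing depth defaults to 32,000 reads/sample. Log-scale taxon
#' baselines are Normal(`base_logmean`, `base_logsd`); every sample adds
#' Normal(0, `sample_logsd`) taxon-level noise, a per-batch-by-taxon
#' offset Normal(0, `batch_effect_sd`), and, for planted taxa, the
#' severity step `sign * delta * s` with s in {-1, 0, +1}; compositions
#' are the softmax of these log abundances and counts are multinomial at
#' Poisson(`seq_depth_mean`) depth.
#'
#' @param n_per_group samples in HC, Asym/UAS, SS/SLE.
#' @param n_phyla,n_classes,n_orders,n_families,n_genera branching targets
#'   per rank (every genus receives at least one leaf).
#' @param n_leaves number of ASV-like leaf taxa in the count table.
#' @param frac_species_assigned fraction of leaves with a species name
#'   (the rest have truncated lineages, as in real reference-database
#'   assignments).
#' @param base_logmean,base_logsd across-taxon baseline log abundance.
#' @param sample_logsd within-taxon across-sample log-scale noise SD.
#' @param seq_depth_mean expected reads per sample.
#' @param n_batches,batch_effect_sd sequencing batches and the SD of the
#'   batch-by-taxon log offsets.
#' @param planted_ordinal data.frame(`taxon` = genus name, `delta` =
#'   log-units per severity step, `sign` = +1/-1) or NULL.
#' @param planted_nonmonotone data.frame(`taxon`, `hc`, `asym_uas`,
#'   `ss_sle` log offsets) or NULL.
#' @param hla_carrier_freq named carrier frequencies for [HLA_COLS]
#'   (anti-Ro mothers only; controls have missing genotypes).
#' @param planted_hla data.frame(`taxon` = genus, `allele`, `log_or`):
#'   after counts are drawn, disease state among anti-Ro mothers is
#'   re-drawn from a logistic model whose linear predictor includes
#'   `log_or * clr(taxon) * carrier`, so the interaction lives on the
#'   outcome scale the estimator models.
#' @param titer_intercept,titer_group_effect,titer_noise_sd titer model
#'   (anti-Ro mothers only; controls have missing titers).
#' @param planted_titer data.frame(`titer`, `taxon` = genus,
#'   `slope_asym_uas`, `slope_ss_sle`): per-group slopes of the titer on
#'   the taxon's clr value.
#' @param pseudocount clr pseudocount used when planting outcome-scale
#'   effects (matched by the default analysis).
#' @param seed integer; same spec + seed gives bit-identical output.
#' @return validated spec, class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = c(23, 43, 82),
                        n_phyla = 13, n_classes = 27, n_orders = 46,
                        n_families = 75, n_genera = 150, n_leaves = 300,
                        frac_species_assigned = 0.65,
                        base_logmean = 0, base_logsd = 1.5,
                        sample_logsd = 1, seq_depth_mean = 32000,
                        n_batches = 3, batch_effect_sd = 0.25,
                        planted_ordinal = NULL,
                        planted_nonmonotone = NULL,
                        hla_carrier_freq = stats::setNames(
                          rep(0.25, 4), HLA_COLS),
                        planted_hla = NULL,
                        titer_intercept = 2, titer_group_effect = 0,
                        titer_noise_sd = 1,
                        planted_titer = NULL,
                        pseudocount = 0.5, seed = 1) {
  spec <- list(n_per_group = n_per_group, n_phyla = n_phyla,
               n_classes = n_classes, n_orders = n_orders,
               n_families = n_families, n_genera = n_genera,
               n_leaves = n_leaves,
               frac_species_assigned = frac_species_assigned,
               base_logmean = base_logmean, base_logsd = base_logsd,
               sample_logsd = sample_logsd,
               seq_depth_mean = seq_depth_mean, n_batches = n_batches,
               batch_effect_sd = batch_effect_sd,
               planted_ordinal = planted_ordinal,
               planted_nonmonotone = planted_nonmonotone,
               hla_carrier_freq = hla_carrier_freq,
               planted_hla = planted_hla,
               titer_intercept = titer_intercept,
               titer_group_effect = titer_group_effect,
               titer_noise_sd = titer_noise_sd,
               planted_titer = planted_titer,
               pseudocount = pseudocount, seed = seed)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with(spec, {
    if (length(n_per_group) != 3 || any(n_per_group < 0))
      stop("n_per_group must be three non-negative sizes")
    if (n_leaves < n_genera)
      stop("n_leaves must be >= n_genera (every genus gets a leaf)")
    if (any(hla_carrier_freq < 0 | hla_carrier_freq > 1))
      stop("carrier frequencies must be in [0, 1]")
    if (!all(names(hla_carrier_freq) == HLA_COLS))
      stop("hla_carrier_freq must be named by HLA_COLS")
    if (frac_species_assigned < 0 || frac_species_assigned > 1)
      stop("frac_species_assigned must be in [0, 1]")
    if (seq_depth_mean <= 0) stop("seq_depth_mean must be positive")
    if (!is.null(planted_hla) &&
        !all(planted_hla$allele %in% HLA_COLS))
      stop("planted_hla$allele must be one of HLA_COLS")
    if (!is.null(planted_titer) &&
        !all(planted_titer$titer %in% TITER_COLS))
      stop("planted_titer$titer must be one of TITER_COLS")
  })
  spec
}

#' The documented default cohort specification
#'
#' The study conditions the package's validation simulations emulate:
#' groups of 23/43/82; 300 ASV-like leaf taxa under a 13-phylum taxonomy
#' with 150 genera (a desk-scale reduction of the 233-genus inventory of
#' the motivating cohort, with roughly 200 species-assigned leaves);
#' 32,000 expected reads per sample; 13 planted monotone genera at
#' delta = 1 log-unit per severity step with both directions represented;
#' two planted HLA-by-genus interactions at log-OR 0.5; and four planted
#' anti-Ro52 IgA titer-by-disease interactions with the slope pattern
#' (-1 in Asym/UAS, 0 in SS/SLE).
#'
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1) {
  genera <- sprintf("g%03d", 1:150)
  cohort_spec(
    planted_ordinal = data.frame(
      taxon = genera[1:13], delta = 1,
      sign = c(rep(1, 7), rep(-1, 6))),
    planted_hla = data.frame(
      taxon = genera[c(1, 8)],
      allele = c("hla_drb1_0301", "hla_dqb1_0602"),
      log_or = 0.5),
    planted_titer = data.frame(
      titer = "ro52_iga", taxon = genera[c(1, 2, 8, 9)],
      slope_asym_uas = -1, slope_ss_sle = 0),
    seed = seed)
}

# Sample a ranked taxonomy: each unit at a rank picks a uniform parent at
# the rank above; every genus is guaranteed at least one leaf.
.generate_taxonomy <- function(spec) {
  nm <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  phy <- nm("p", spec$n_phyla)
  cls <- nm("c", spec$n_classes)
  ord <- nm("o", spec$n_orders)
  fam <- nm("f", spec$n_families)
  gen <- nm("g", spec$n_genera)
  parent <- list(
    cls = sample(phy, spec$n_classes, replace = TRUE),
    ord = sample(cls, spec$n_orders, replace = TRUE),
    fam = sample(ord, spec$n_families, replace = TRUE),
    gen = sample(fam, spec$n_genera, replace = TRUE))
  leaf_genus <- c(gen, sample(gen, spec$n_leaves - spec$n_genera,
                              replace = TRUE))
  leaf_genus <- leaf_genus[sample(spec$n_leaves)]
  has_sp <- stats::runif(spec$n_leaves) < spec$frac_species_assigned
  gi <- match(leaf_genus, gen)
  fi <- match(parent$gen[gi], fam)
  oi <- match(parent$fam[fi], ord)
  ci <- match(parent$ord[oi], cls)
  data.frame(
    taxon_id = sprintf("asv%04d", seq_len(spec$n_leaves)),
    kingdom = "Bacteria",
    phylum = parent$cls[ci],
    class = cls[ci], order = ord[oi], family = fam[fi],
    genus = leaf_genus,
    species = ifelse(has_sp,
                     sprintf("s_%s_%04d", leaf_genus,
                             seq_len(spec$n_leaves)), ""))
}

.leaves_of_genus <- function(tax, genus) {
  idx <- which(tax$genus == genus)
  if (length(idx) == 0)
    stop("planted effect references absent genus '", genus, "'")
  tax$taxon_id[idx]
}

#' Generate a synthetic cohort
#'
#' Runs the generative model of [cohort_spec()] and returns the count
#' table, taxonomy, metadata, a taxonomy-derived bifurcating tree, and the
#' ground truth (planted effect sets plus the latent per-sample
#' composition). Each generation stage draws from its own deterministic
#' sub-seed, so adding a planted effect never perturbs unrelated draws.
#'
#' @param spec a `cohort_spec`.
#' @return list of class `"synthetic_cohort"` with elements `counts`,
#'   `taxonomy`, `metadata`, `tree`, `truth`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  n <- sum(spec$n_per_group)

  set.seed(.stage_seed(spec$seed, 1))
  tax <- .generate_taxonomy(spec)

  set.seed(.stage_seed(spec$seed, 2))
  mu <- stats::rnorm(spec$n_leaves, spec$base_logmean, spec$base_logsd)

  set.seed(.stage_seed(spec$seed, 3))
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(GROUP_LEVELS, times = spec$n_per_group)
  batch <- sample(sprintf("b%d", seq_len(spec$n_batches)), n,
                  replace = TRUE)
  antiro <- group != "HC"
  hla <- sapply(HLA_COLS, function(h) {
    v <- rep(NA_integer_, n)
    v[antiro] <- stats::rbinom(sum(antiro), 1, spec$hla_carrier_freq[h])
    v
  })

  # planted log-scale effects on the leaves of each named genus
  eff <- matrix(0, n, spec$n_leaves,
                dimnames = list(sample_id, tax$taxon_id))
  s <- .severity_score(group)
  if (!is.null(spec$planted_ordinal)) {
    for (i in seq_len(nrow(spec$planted_ordinal))) {
      pe <- spec$planted_ordinal[i, ]
      leaves <- .leaves_of_genus(tax, pe$taxon)
      eff[, leaves] <- eff[, leaves] + s * pe$delta * pe$sign
    }
  }
  if (!is.null(spec$planted_nonmonotone)) {
    for (i in seq_len(nrow(spec$planted_nonmonotone))) {
      pe <- spec$planted_nonmonotone[i, ]
      leaves <- .leaves_of_genus(tax, pe$taxon)
      off <- c(HC = pe$hc, ASYM_UAS = pe$asym_uas,
               SS_SLE = pe$ss_sle)[group]
      eff[, leaves] <- eff[, leaves] + off
    }
  }

  set.seed(.stage_seed(spec$seed, 4))
  batch_off <- matrix(stats::rnorm(spec$n_batches * spec$n_leaves, 0,
                                   spec$batch_effect_sd),
                      spec$n_batches, spec$n_leaves)
  bi <- as.integer(factor(batch, levels = sprintf("b%d",
                                                  seq_len(spec$n_batches))))
  eta <- matrix(mu, n, spec$n_leaves, byrow = TRUE) + eff +
    batch_off[bi, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$n_leaves, 0, spec$sample_logsd),
           n, spec$n_leaves)
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  depth <- stats::rpois(n, spec$seq_depth_mean)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depth[i], pr[i, ])[, 1],
                     numeric(spec$n_leaves)))
  dimnames(counts) <- list(sample_id, tax$taxon_id)

  # outcome-scale HLA interaction: re-draw disease state among anti-Ro
  # mothers from a logistic model with the clr(taxon) x carrier term
  set.seed(.stage_seed(spec$seed, 5))
  if (!is.null(spec$planted_hla) && nrow(spec$planted_hla) > 0) {
    gct <- aggregate_to_level(counts, tax, "genus", quiet = TRUE)
    gclr <- clr_transform(gct, spec$pseudocount)
    n2 <- spec$n_per_group[2]
    n3 <- spec$n_per_group[3]
    lin <- rep(stats::qlogis(n3 / (n2 + n3)), n)
    for (i in seq_len(nrow(spec$planted_hla))) {
      pe <- spec$planted_hla[i, ]
      if (!pe$taxon %in% colnames(gclr))
        stop("planted HLA effect references absent genus '", pe$taxon, "'")
      z <- gclr[, pe$taxon] - mean(gclr[antiro, pe$taxon])
      lin <- lin + pe$log_or * z * hla[, pe$allele]
    }
    newg <- group
    draw <- stats::rbinom(sum(antiro), 1, stats::plogis(lin[antiro]))
    newg[antiro] <- ifelse(draw == 1, "SS_SLE", "ASYM_UAS")
    group <- newg
  }

  # titers: linear in the planted taxa's clr values, per disease group
  set.seed(.stage_seed(spec$seed, 6))
  antiro <- group != "HC"
  titers <- sapply(TITER_COLS, function(tn) {
    v <- rep(NA_real_, n)
    v[antiro] <- spec$titer_intercept +
      spec$titer_group_effect * (group[antiro] == "SS_SLE") +
      stats::rnorm(sum(antiro), 0, spec$titer_noise_sd)
    v
  })
  if (!is.null(spec$planted_titer) && nrow(spec$planted_titer) > 0) {
    gct <- aggregate_to_level(counts, tax, "genus", quiet = TRUE)
    gclr <- clr_transform(gct, spec$pseudocount)
    for (i in seq_len(nrow(spec$planted_titer))) {
      pe <- spec$planted_titer[i, ]
      if (!pe$taxon %in% colnames(gclr))
        stop("planted titer effect references absent genus '",
             pe$taxon, "'")
      z <- gclr[, pe$taxon]
      slope <- ifelse(group == "SS_SLE", pe$slope_ss_sle,
                      pe$slope_asym_uas)
      add <- slope * z
      add[!antiro] <- 0
      titers[, pe$titer] <- titers[, pe$titer] + add
    }
  }
  # floor titers at zero (assay units are non-negative)
  shift <- pmin(0, apply(titers, 2, min, na.rm = TRUE))
  shift[!is.finite(shift)] <- 0
  titers <- sweep(titers, 2, shift)

  md <- data.frame(sample_id = sample_id, group = group, batch = batch,
                   hla, titers, row.names = NULL, check.names = FALSE)
  md <- validate_metadata(md)

  set.seed(.stage_seed(spec$seed, 7))
  tree <- build_tree_from_taxonomy(tax, seed = .stage_seed(spec$seed, 7))

  truth <- list(planted_ordinal = spec$planted_ordinal,
                planted_nonmonotone = spec$planted_nonmonotone,
                planted_hla = spec$planted_hla,
                planted_titer = spec$planted_titer,
                latent_proportions = pr, depth = depth, seed = spec$seed)
  structure(list(counts = counts, taxonomy = tax, metadata = md,
                 tree = tree, truth = truth),
            class = "synthetic_cohort")
}
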