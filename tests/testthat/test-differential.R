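test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), brute_force_bh(p), tolerance = 1e-12)
  }
  # adjusting adjusted values never lowers them
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(bh_fdr(q) >= q - 1e-12))
})

test_that("rank tests find planted monotone and non-monotone signals with
           the right contrast", {
  set.seed(42)
  md <- null_md(c(30, 30, 30))
  s <- rep(c(-1, 0, 1), each = 30)
  # monotone taxon + flat taxa
  Y <- matrix(rnorm(90 * 5), 90, 5,
              dimnames = list(md$sample_id, paste0("t", 1:5)))
  Y[, 1] <- Y[, 1] + 1.2 * s
  r <- taxon_test(rank_columns(Y), md, "ordinal3")
  expect_lt(r$p_value[1], 1e-4)
  expect_gt(r$estimate[1], 0)
  expect_equal(r$direction[1], 1)
  expect_true(all(r$p_fdr >= r$p_value - 1e-12))
  rd <- taxon_test(rank_columns(Y), md, "discrete3")
  expect_lt(rd$p_value[1], 1e-3)

  # the pooled two-group contrast equals testing HC vs a merged label
  r2 <- taxon_test(rank_columns(Y), md, "two_group")
  md_m <- md
  md_m$group[md_m$group == "SS_SLE"] <- "ASYM_UAS"
  r2m <- taxon_test(rank_columns(Y), md_m, "two_group",
                    group_b = "ASYM_UAS")
  expect_equal(r2$p_value, r2m$p_value, tolerance = 1e-12)
})

test_that("the discrete contrast beats the ordinal one on low-high-low
           patterns", {
  set.seed(43)
  md <- null_md(c(30, 30, 30))
  pat <- rep(c(0, 1, 0), each = 30)
  rej_ord <- rej_dis <- 0
  n_sim <- 300
  for (i in seq_len(n_sim)) {
    Y <- matrix(rnorm(90 * 2), 90, 2,
                dimnames = list(md$sample_id, c("sig", "null")))
    Y[, 1] <- Y[, 1] + 0.8 * pat
    rk <- rank_columns(Y)
    rej_ord <- rej_ord + (taxon_test(rk, md, "ordinal3")$p_value[1] < 0.05)
    rej_dis <- rej_dis + (taxon_test(rk, md, "discrete3")$p_value[1] < 0.05)
  }
  expect_gt(rej_dis / n_sim, 0.8)
  expect_gt(rej_dis, rej_ord + 50)
})

test_that("constant-rank taxa get p = 1 with a warning, keeping the family
           size fixed", {
  md <- null_md(c(5, 5, 5))
  Y <- matrix(rnorm(15 * 3), 15, 3,
              dimnames = list(md$sample_id, paste0("t", 1:3)))
  Y[, 2] <- 4
  expect_warning(r <- taxon_test(rank_columns(Y), md, "ordinal3"),
                 "constant ranks")
  expect_equal(r$p_value[2], 1)
  expect_equal(r$estimate[2], 0)
  expect_equal(nrow(r), 3)
})

test_that("TSD follows the gate rule: children are tested only under
           significant parents", {
  # plant a coherent severity signal on every genus of one phylum; the
  # taxonomy stage is seed-deterministic, so it can be inspected first
  tax0 <- generate_cohort(cohort_spec(seed = 4400))$taxonomy
  by_phylum <- table(unique(tax0[c("genus", "phylum")])$phylum)
  target <- names(which.max(by_phylum))
  gsel <- unique(tax0$genus[tax0$phylum == target])
  sp <- cohort_spec(planted_ordinal = data.frame(taxon = gsel,
                                                 delta = 1.2, sign = 1),
                    seed = 4400)
  co <- generate_cohort(sp)
  res <- tsd(co$counts, co$taxonomy, co$metadata, alpha = 0.05)
  ph <- res[res$level == "phylum", ]
  expect_true(ph$gate_open[ph$taxon_id == target])
  open_phyla <- ph$taxon_id[ph$gate_open]
  closed_phyla <- ph$taxon_id[!ph$gate_open]
  cl <- res[res$level == "class", ]
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$parent_id %in% open_phyla))
  expect_false(any(cl$parent_id %in% closed_phyla))
  # sibling-set adjustment: within a family, adjusted >= raw p
  expect_true(all(cl$p_fdr_within_gate >= cl$p_value - 1e-12))
})

test_that("TSD gates are structurally sound and test no more hypotheses
           than flat testing", {
  co <- cached_cohort(1)
  res <- tsd(co$counts, co$taxonomy, co$metadata)
  # every emitted node's parent (at the level above) has an open gate
  lv_idx <- match(res$level, TAX_RANKS)
  for (i in seq_len(nrow(res))) {
    if (lv_idx[i] > min(lv_idx)) {
      par <- res[res$level == TAX_RANKS[lv_idx[i] - 1] &
                   res$taxon_id == res$parent_id[i], ]
      expect_equal(nrow(par), 1)
      expect_true(par$gate_open)
    }
  }
  # within each gate family, gate_open implies adjusted p below alpha
  expect_true(all(res$p_fdr_within_gate[res$gate_open] < 0.05))
  # flat testing would examine every taxon at every level
  flat_n <- sum(sapply(TAX_RANKS[-1], function(lv) {
    agg <- aggregate_to_level(co$counts, co$taxonomy, lv, quiet = TRUE)
    ncol(filter_mean_relabund(agg, 1e-4, quiet = TRUE))
  }))
  expect_lte(nrow(res), flat_n)
})

test_that("the level summary recovers planted genera with their signs and
           the reporting layout", {
  co <- cached_cohort(1)
  s <- summarize_level(co$counts, co$taxonomy, co$metadata)
  expect_equal(names(s),
               c("parent", "taxon", "hc_mean", "hc_sd", "asym_uas_mean",
                 "asym_uas_sd", "ss_sle_mean", "ss_sle_sd",
                 "estimate_ordinal", "p_ordinal", "p_ordinal_fdr",
                 "p_hc_vs_antiro", "p_discrete3", "p_discrete3_fdr"))
  truth <- co$truth$planted_ordinal
  hit <- s$taxon %in% truth$taxon
  expect_gt(sum(hit), 9) # most of the 13 planted genera recovered
  sgn <- truth$sign[match(s$taxon[hit], truth$taxon)]
  expect_equal(sign(s$estimate_ordinal[hit]), sgn)
  expect_true(all(s$p_ordinal_fdr < 0.05))
  # unfiltered summary keeps every genus surviving the abundance filter
  s_all <- summarize_level(co$counts, co$taxonomy, co$metadata,
                           filter_fdr = FALSE)
  expect_gt(nrow(s_all), 100)
})
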