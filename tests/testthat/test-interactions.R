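interaction_cohort <- function(seed) {
  generate_cohort(cohort_spec(
    n_leaves = 60, n_genera = 30, n_phyla = 5, n_classes = 8,
    n_orders = 12, n_families = 20,
    planted_hla = data.frame(taxon = "g010", allele = "hla_drb1_0301",
                             log_or = 0.5),
    planted_titer = data.frame(titer = "ro52_iga", taxon = "g020",
                               slope_asym_uas = -1, slope_ss_sle = 0),
    seed = seed))
}

test_that("HLA interaction odds ratios reconstruct from the Wald pieces
           and ignore reference coding", {
  co <- interaction_cohort(51)
  g <- aggregate_to_level(co$counts, co$taxonomy, "genus", quiet = TRUE)
  h <- hla_by_taxon(g, co$metadata, "hla_drb1_0301", "g010")
  expect_true(h$estimable)
  expect_equal(h$odds_ratio, exp(h$log_or), tolerance = 1e-9)
  se <- (log(h$ci_high) - log(h$ci_low)) / (2 * 1.96)
  expect_equal(h$ci_low, exp(h$log_or - 1.96 * se), tolerance = 1e-9)
  expect_true(h$ci_low <= h$odds_ratio && h$odds_ratio <= h$ci_high)
  expect_gt(h$odds_ratio, 0)
  # flipping the outcome reference flips the sign, not the p-value
  md_flip <- co$metadata
  md_flip$group[md_flip$group == "ASYM_UAS"] <- "tmp"
  md_flip$group[md_flip$group == "SS_SLE"] <- "ASYM_UAS"
  md_flip$group[md_flip$group == "tmp"] <- "SS_SLE"
  h2 <- hla_by_taxon(g, md_flip, "hla_drb1_0301", "g010")
  expect_equal(h2$interaction_p, h$interaction_p, tolerance = 1e-7)
  expect_equal(h2$log_or, -h$log_or, tolerance = 1e-7)
})

test_that("degenerate HLA inputs raise the documented errors", {
  co <- interaction_cohort(52)
  g <- aggregate_to_level(co$counts, co$taxonomy, "genus", quiet = TRUE)
  md <- co$metadata
  md$hla_drb1_1501 <- ifelse(md$group == "HC", NA_integer_, 1L)
  expect_error(hla_by_taxon(g, md, "hla_drb1_1501", "g001"),
               "constant.*stratum")
  md$hla_dqb1_0201 <- NA_integer_
  expect_error(hla_by_taxon(g, md, "hla_dqb1_0201", "g001"), "missing")
  expect_error(hla_by_taxon(g, md, "hla_drb1_0301", "nope"),
               "not in the count table")
})

test_that("proportional-odds coding estimates the product term, with and
           without genotyped controls", {
  co <- interaction_cohort(53)
  g <- aggregate_to_level(co$counts, co$taxonomy, "genus", quiet = TRUE)
  # controls ungenotyped: the ordered outcome degenerates to two levels
  h <- hla_by_taxon(g, co$metadata, "hla_drb1_0301", "g010",
                    outcome_coding = "ordinal3")
  expect_true(h$estimable)
  expect_true(h$interaction_p >= 0 && h$interaction_p <= 1)
  # genotyped controls: full three-level proportional-odds fit
  md3 <- co$metadata
  set.seed(53)
  hc <- md3$group == "HC"
  md3$hla_drb1_0301[hc] <- rbinom(sum(hc), 1, 0.25)
  h3 <- hla_by_taxon(g, md3, "hla_drb1_0301", "g010",
                     outcome_coding = "ordinal3")
  expect_true(h3$estimable)
  expect_true(is.finite(h3$log_or))
})

test_that("titer-by-disease models recover planted per-group slopes", {
  co <- interaction_cohort(54)
  g <- aggregate_to_level(co$counts, co$taxonomy, "genus", quiet = TRUE)
  t <- titer_by_disease(g, co$metadata, "ro52_iga", "g020")
  expect_lt(t$interaction_p, 0.01)
  expect_lt(t$slope_asym_uas, -0.5)
  expect_lt(abs(t$slope_ss_sle), 0.5)
  # identical relationships in both groups: interaction near zero
  md <- co$metadata
  set.seed(54)
  z <- clr_transform(g, 0.5)[, "g005"]
  md$ro52_igg <- ifelse(md$group == "HC", NA, 2 + 0.5 * z + rnorm(nrow(g),
                                                                  0, 0.1))
  t0 <- titer_by_disease(g, md, "ro52_igg", "g005")
  expect_lt(abs(t0$slope_asym_uas - t0$slope_ss_sle), 0.15)
})

test_that("the interaction screen emits one row per pair and flags by the
           reporting threshold", {
  co <- interaction_cohort(55)
  g <- aggregate_to_level(co$counts, co$taxonomy, "genus", quiet = TRUE)
  sc <- screen_interactions(g, co$metadata, "g010")
  expect_equal(nrow(sc$hla), 4)
  expect_equal(nrow(sc$titer), 4)
  expect_equal(names(sc$hla)[1:2], c("allele", "taxon_id"))
  sc_all <- screen_interactions(g, co$metadata, c("g010", "g020"),
                                alpha_report = 1.0)
  expect_equal(nrow(sc_all$hla), 8)
  expect_true(all(sc_all$hla$flagged[sc_all$hla$estimable]))
  expect_true(all(sc_all$titer$flagged))
  expect_error(screen_interactions(g, co$metadata, character(0)), "empty")
})
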