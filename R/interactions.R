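# Effect-modification models: HLA-allele-by-taxon interactions on clinical
# severity, and antibody-titer-by-disease-group interactions.

.clr_column <- function(ct, taxon_id, pseudocount) {
  if (!taxon_id %in% colnames(ct))
    stop("taxon '", taxon_id, "' not in the count table")
  clr_transform(ct, pseudocount)[, taxon_id]
}

#' HLA-allele-by-taxon interaction on clinical severity
#'
#' Does carrying a lupus-risk HLA allele modify the association between a
#' taxon's abundance and disease state? The taxon enters as its clr value
#' (so the odds ratio is per clr unit). Two outcome codings:
#' \itemize{
#'   \item `binary_ssle_vs_asym` (default): logistic regression of
#'     SS/SLE vs Asym/UAS among anti-Ro mothers on
#'     `clr + carrier + clr:carrier`.
#'   \item `ordinal3`: proportional-odds regression of the full ordered
#'     severity outcome on the same terms (samples with missing carrier
#'     status drop out).
#' }
#' The interaction p is the product term's Wald test; the odds ratio is
#' `exp(coef)` with a Wald 95 percent CI. Complete separation or
#' non-convergence is reported as non-estimable, not an error.
#'
#' @param ct count matrix at the reporting level (e.g. genus).
#' @param md sample metadata.
#' @param allele one of [HLA_COLS].
#' @param taxon_id column of `ct`.
#' @param outcome_coding `"binary_ssle_vs_asym"` or `"ordinal3"`.
#' @param pseudocount clr zero replacement.
#' @param min_nonmissing minimum fraction of included samples with carrier
#'   status present.
#' @return one-row data.frame: `allele`, `taxon_id`, `interaction_p`,
#'   `log_or`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `overall_mean_abundance`, `estimable`.
#' @export
hla_by_taxon <- function(ct, md, allele, taxon_id,
                         outcome_coding = c("binary_ssle_vs_asym",
                                            "ordinal3"),
                         pseudocount = 0.5, min_nonmissing = 0.8) {
  outcome_coding <- match.arg(outcome_coding)
  allele <- match.arg(allele, HLA_COLS)
  m <- .match_md(rownames(ct), md)
  z <- .clr_column(ct, taxon_id, pseudocount)
  rel <- ct[, taxon_id] / rowSums(ct)
  overall_mean <- mean(rel)
  if (outcome_coding == "binary_ssle_vs_asym") {
    keep <- m$group %in% c("ASYM_UAS", "SS_SLE")
  } else {
    keep <- rep(TRUE, nrow(m))
  }
  carrier <- m[[allele]][keep]
  if (mean(!is.na(carrier)) < min_nonmissing)
    stop("carrier status missing for > ",
         round(100 * (1 - min_nonmissing)), "% of included samples")
  keep2 <- which(keep)[!is.na(carrier)]
  carrier <- m[[allele]][keep2]
  if (length(unique(carrier)) < 2)
    stop("carrier flag is constant: empty stratum")
  zz <- z[keep2]
  res <- list(coef = NA_real_, se = NA_real_, p = NA_real_,
              estimable = FALSE)
  if (outcome_coding == "binary_ssle_vs_asym") {
    y <- as.integer(m$group[keep2] == "SS_SLE")
    fit <- suppressWarnings(
      stats::glm(y ~ zz * carrier, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if ("zz:carrier" %in% rownames(co)) {
      se <- co["zz:carrier", "Std. Error"]
      # huge Wald SE flags (quasi-)separation: report non-estimable
      if (is.finite(se) && se < 50 && fit$converged)
        res <- list(coef = co["zz:carrier", "Estimate"], se = se,
                    p = co["zz:carrier", "Pr(>|z|)"], estimable = TRUE)
    }
  } else {
    y <- droplevels(factor(m$group[keep2], levels = GROUP_LEVELS,
                           ordered = TRUE))
    if (nlevels(y) < 2) stop("outcome is constant")
    if (nlevels(y) == 2) {
      # only two severity levels carry genotype data (controls are
      # typically ungenotyped): the proportional-odds model reduces to
      # logistic regression on the upper level
      yb <- as.integer(y == levels(y)[2])
      fit <- suppressWarnings(
        stats::glm(yb ~ zz * carrier, family = stats::binomial()))
      co <- summary(fit)$coefficients
      if ("zz:carrier" %in% rownames(co)) {
        se <- co["zz:carrier", "Std. Error"]
        if (is.finite(se) && se < 50 && fit$converged)
          res <- list(coef = co["zz:carrier", "Estimate"], se = se,
                      p = co["zz:carrier", "Pr(>|z|)"], estimable = TRUE)
      }
    } else {
      fit <- try(suppressWarnings(
        MASS::polr(y ~ zz * carrier, Hess = TRUE)), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        co <- summary(fit)$coefficients
        if ("zz:carrier" %in% rownames(co)) {
          est <- co["zz:carrier", "Value"]
          se <- co["zz:carrier", "Std. Error"]
          if (is.finite(se) && se < 50)
            res <- list(coef = est, se = se,
                        p = 2 * stats::pnorm(abs(est / se),
                                             lower.tail = FALSE),
                        estimable = TRUE)
        }
      }
    }
  }
  data.frame(allele = allele, taxon_id = taxon_id,
             interaction_p = res$p, log_or = res$coef,
             odds_ratio = exp(res$coef),
             ci_low = exp(res$coef - 1.96 * res$se),
             ci_high = exp(res$coef + 1.96 * res$se),
             overall_mean_abundance = overall_mean,
             estimable = res$estimable, row.names = NULL)
}

#' Antibody-titer-by-disease-group interaction
#'
#' Among anti-Ro mothers, does the relationship between a taxon's clr
#' abundance and an autoantibody titer differ between Asym/UAS and SS/SLE?
#' Linear model `titer ~ clr + group + clr:group`; the interaction p is
#' the product term's t-test and the per-group fitted lines (intercept and
#' slope) are returned for interaction plots.
#'
#' @param ct count matrix at the reporting level.
#' @param md sample metadata.
#' @param titer_name one of [TITER_COLS].
#' @param taxon_id column of `ct`.
#' @param pseudocount clr zero replacement.
#' @param log_titer model `log(titer + 1)` instead of the raw titer.
#' @return one-row data.frame with `titer`, `taxon_id`, `interaction_p`,
#'   `slope_asym_uas`, `slope_ss_sle`, `intercept_asym_uas`,
#'   `intercept_ss_sle`.
#' @export
titer_by_disease <- function(ct, md, titer_name, taxon_id,
                             pseudocount = 0.5, log_titer = FALSE) {
  titer_name <- match.arg(titer_name, TITER_COLS)
  m <- .match_md(rownames(ct), md)
  z <- .clr_column(ct, taxon_id, pseudocount)
  keep <- m$group %in% c("ASYM_UAS", "SS_SLE") & !is.na(m[[titer_name]])
  g <- factor(m$group[keep], levels = c("ASYM_UAS", "SS_SLE"))
  if (any(table(g) < 3))
    stop("each disease group needs >= 3 titered samples")
  y <- m[[titer_name]][keep]
  if (log_titer) y <- log1p(y)
  zz <- z[keep]
  fit <- stats::lm(y ~ zz * g)
  co <- summary(fit)$coefficients
  b <- stats::coef(fit)
  data.frame(titer = titer_name, taxon_id = taxon_id,
             interaction_p = co["zz:gSS_SLE", "Pr(>|t|)"],
             slope_asym_uas = unname(b["zz"]),
             slope_ss_sle = unname(b["zz"] + b["zz:gSS_SLE"]),
             intercept_asym_uas = unname(b["(Intercept)"]),
             intercept_ss_sle = unname(b["(Intercept)"] + b["gSS_SLE"]),
             row.names = NULL)
}

#' Screen all allele-by-taxon and titer-by-taxon interactions
#'
#' Runs [hla_by_taxon()] for every candidate taxon against every allele
#' and [titer_by_disease()] against every titer, flagging rows below
#' `alpha_report`. No multiplicity adjustment is applied by default (the
#' screen is exploratory); set `adjust = TRUE` to add a BH column.
#'
#' @param ct count matrix at the reporting level.
#' @param md sample metadata.
#' @param candidate_taxa taxa to screen (normally the FDR-significant set
#'   from [summarize_level()]).
#' @param alleles,titers subsets of [HLA_COLS] / [TITER_COLS].
#' @param alpha_report flag threshold.
#' @param adjust add BH-adjusted columns.
#' @param ... passed to the per-pair model functions.
#' @return list with data.frames `hla` and `titer`, each sorted by
#'   interaction p.
#' @export
screen_interactions <- function(ct, md, candidate_taxa,
                                alleles = HLA_COLS, titers = TITER_COLS,
                                alpha_report = 0.05, adjust = FALSE, ...) {
  if (length(candidate_taxa) == 0) stop("empty candidate taxon set")
  hla <- do.call(rbind, lapply(candidate_taxa, function(tx)
    do.call(rbind, lapply(alleles, function(al)
      hla_by_taxon(ct, md, al, tx, ...)))))
  titer <- do.call(rbind, lapply(candidate_taxa, function(tx)
    do.call(rbind, lapply(titers, function(tn)
      titer_by_disease(ct, md, tn, tx)))))
  hla$flagged <- !is.na(hla$interaction_p) &
    hla$interaction_p < alpha_report
  titer$flagged <- titer$interaction_p < alpha_report
  if (adjust) {
    ok <- !is.na(hla$interaction_p)
    hla$interaction_p_fdr <- NA_real_
    hla$interaction_p_fdr[ok] <- bh_fdr(hla$interaction_p[ok])
    titer$interaction_p_fdr <- bh_fdr(titer$interaction_p)
  }
  hla <- hla[order(hla$interaction_p), , drop = FALSE]
  titer <- titer[order(titer$interaction_p), , drop = FALSE]
  rownames(hla) <- rownames(titer) <- NULL
  list(hla = hla, titer = titer)
}
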