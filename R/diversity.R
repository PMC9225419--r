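# Alpha diversity (Shannon H in nats and the effective number e^H) and the
# two-group / ordinal three-group tests applied level by level.

#' Shannon diversity per sample
#'
#' `H = -sum(p_i * log(p_i))` over the sample's nonzero proportions (nats;
#' zeros contribute nothing), and the effective number of equally abundant
#' taxa `eH = exp(H)`. Computed on raw counts, without pseudocount.
#'
#' @param ct count matrix, optionally pre-aggregated.
#' @param tax,level when both given, `ct` is aggregated to `level` first.
#' @return data.frame with `sample_id`, `level`, `H`, `eH`.
#' @export
shannon_diversity <- function(ct, tax = NULL, level = NULL) {
  if (!is.null(level)) {
    if (is.null(tax)) stop("aggregating to a level needs a taxonomy")
    ct <- aggregate_to_level(ct, tax, level, quiet = TRUE)
  }
  tot <- rowSums(ct)
  if (any(tot == 0))
    stop("sample with zero total count: ", rownames(ct)[which(tot == 0)[1]])
  p <- ct / tot
  H <- apply(p, 1, function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  })
  data.frame(sample_id = rownames(ct),
             level = if (is.null(level)) NA_character_ else level,
             H = H, eH = exp(H), row.names = NULL)
}

.match_md <- function(ids, md) {
  md <- validate_metadata(md)
  i <- match(ids, md$sample_id)
  if (anyNA(i)) stop("samples missing from metadata: ",
                     paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  md[i, , drop = FALSE]
}

#' Two-group test of Shannon diversity
#'
#' Welch t-test of H between two (possibly pooled) group sets, or a linear
#' model with sequencing batch as a fixed covariate when `batch_adjust` is
#' set.
#'
#' @param div output of [shannon_diversity()].
#' @param md sample metadata.
#' @param group_a,group_b character vectors of [GROUP_LEVELS] labels; each
#'   side pools its listed groups.
#' @param batch_adjust add batch as a covariate (linear model) instead of
#'   the plain Welch test.
#' @return data.frame with `level`, `contrast`, `estimate` (mean difference
#'   b minus a), `p_value`.
#' @export
diversity_two_group_test <- function(div, md, group_a = "HC",
                                     group_b = c("ASYM_UAS", "SS_SLE"),
                                     batch_adjust = FALSE) {
  m <- .match_md(div$sample_id, md)
  in_a <- m$group %in% group_a
  in_b <- m$group %in% group_b
  if (sum(in_a) < 2 || sum(in_b) < 2)
    stop("each group needs at least 2 samples")
  keep <- in_a | in_b
  H <- div$H[keep]
  g <- ifelse(in_b[keep], 1, 0)
  if (batch_adjust && length(unique(m$batch[keep])) > 1) {
    fit <- stats::lm(H ~ g + factor(m$batch[keep]))
    co <- summary(fit)$coefficients
    est <- co["g", "Estimate"]
    p <- co["g", "Pr(>|t|)"]
  } else {
    if (stats::var(H[g == 1]) + stats::var(H[g == 0]) == 0) {
      est <- mean(H[g == 1]) - mean(H[g == 0])
      p <- if (abs(est) < 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(H[g == 1], H[g == 0])
      est <- unname(diff(rev(tt$estimate)))
      p <- tt$p.value
    }
  }
  data.frame(level = div$level[1], contrast = "two_group",
             estimate = est, p_value = p)
}

#' Ordinal three-group test of Shannon diversity
#'
#' Linear model of H on the severity trend score (HC = -1, Asym/UAS = 0,
#' SS/SLE = +1), with batch as a covariate; the p-value is the t-test of
#' the trend coefficient.
#'
#' @inheritParams diversity_two_group_test
#' @param batch_adjust include the batch covariate (default TRUE).
#' @return data.frame with `level`, `contrast`, `estimate`, `p_value`.
#' @export
diversity_ordinal_test <- function(div, md, batch_adjust = TRUE) {
  m <- .match_md(div$sample_id, md)
  if (!all(GROUP_LEVELS %in% m$group))
    stop("ordinal test needs all three groups present")
  s <- .severity_score(m$group)
  if (batch_adjust && length(unique(m$batch)) > 1) {
    fit <- stats::lm(div$H ~ s + factor(m$batch))
  } else {
    fit <- stats::lm(div$H ~ s)
  }
  co <- summary(fit)$coefficients
  data.frame(level = div$level[1], contrast = "three_group_ordinal",
             estimate = co["s", "Estimate"], p_value = co["s", "Pr(>|t|)"])
}

#' Level-by-level alpha-diversity summary
#'
#' Per-group mean and SD of H with the group's effective number (exp of the
#' group's mean H), plus the two-group healthy-vs-all test, the ordinal
#' three-group trend test, and the direct Asym/UAS vs SS/SLE comparison,
#' for each requested taxonomic level.
#'
#' @param ct count matrix at the base (leaf) level.
#' @param tax taxonomy table.
#' @param md sample metadata.
#' @param levels ranks to summarise (default phylum..species).
#' @param batch_adjust passed to the tests.
#' @return one row per level.
#' @export
diversity_table <- function(ct, tax, md, levels = TAX_RANKS[-1],
                            batch_adjust = FALSE) {
  rows <- lapply(levels, function(lv) {
    dv <- shannon_diversity(ct, tax, lv)
    m <- .match_md(dv$sample_id, md)
    stat <- function(g) {
      h <- dv$H[m$group == g]
      c(mean = mean(h), sd = stats::sd(h), eh = exp(mean(h)))
    }
    hc <- stat("HC"); au <- stat("ASYM_UAS"); ss <- stat("SS_SLE")
    p2 <- diversity_two_group_test(dv, md, batch_adjust = batch_adjust)
    p3 <- diversity_ordinal_test(dv, md, batch_adjust = batch_adjust)
    pa <- diversity_two_group_test(dv, md, group_a = "ASYM_UAS",
                                   group_b = "SS_SLE",
                                   batch_adjust = batch_adjust)
    data.frame(level = lv,
               hc_h_mean = hc["mean"], hc_h_sd = hc["sd"], hc_eh = hc["eh"],
               asym_uas_h_mean = au["mean"], asym_uas_h_sd = au["sd"],
               asym_uas_eh = au["eh"],
               ss_sle_h_mean = ss["mean"], ss_sle_h_sd = ss["sd"],
               ss_sle_eh = ss["eh"],
               p_hc_vs_antiro = p2$p_value,
               p_ordinal = p3$p_value,
               p_asym_vs_ss = pa$p_value,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
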