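# Per-taxon rank-GLM tests (ordinal trend, discrete three-group,
# two-group), Benjamini-Hochberg adjustment, and the taxonomy-gated
# stepdown (TSD) hierarchical testing procedure.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: sort ascending, `q_i = min_{j >= i} p_(j) * m / j`,
#' capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-taxon rank-based group tests
#'
#' Linear model of the column-wise midranks (typically of clr values, see
#' [rank_columns()]) on the group contrast, with sequencing batch as a
#' fixed covariate:
#' \itemize{
#'   \item `ordinal3`: severity trend score (HC = -1, Asym/UAS = 0,
#'     SS/SLE = +1); p from the trend coefficient's t-test.
#'   \item `discrete3`: two group indicators; p from the 2-df F-test,
#'     agnostic to severity ordering.
#'   \item `two_group`: indicator of `group_b` membership vs `group_a`
#'     (each side may pool several labels, e.g. healthy vs all anti-Ro).
#' }
#' Taxa with constant ranks (all ties) get p = 1 with a warning so the FDR
#' family keeps a fixed size.
#'
#' @param ranks rank matrix, samples x taxa (rownames = sample ids).
#' @param md sample metadata.
#' @param contrast one of `"ordinal3"`, `"discrete3"`, `"two_group"`.
#' @param batch include the batch covariate.
#' @param group_a,group_b pooled label sets for `two_group`.
#' @param level optional rank label carried into the output.
#' @return data.frame with `taxon_id`, `level`, `contrast`, `estimate`,
#'   `p_value`, `p_fdr` (BH within this family), `direction`.
#' @export
taxon_test <- function(ranks, md,
                       contrast = c("ordinal3", "discrete3", "two_group"),
                       batch = TRUE, group_a = "HC",
                       group_b = c("ASYM_UAS", "SS_SLE"),
                       level = NA_character_) {
  contrast <- match.arg(contrast)
  m <- .match_md(rownames(ranks), md)
  Y <- as.matrix(ranks)
  if (contrast == "two_group") {
    keep <- m$group %in% c(group_a, group_b)
    if (sum(m$group[keep] %in% group_a) < 2 ||
        sum(m$group[keep] %in% group_b) < 2)
      stop("two_group needs >= 2 samples on each side")
    Y <- Y[keep, , drop = FALSE]
    m <- m[keep, , drop = FALSE]
  } else if (!all(GROUP_LEVELS %in% m$group)) {
    stop("contrast '", contrast, "' needs all three groups present")
  }
  bd <- if (batch) .batch_design(m$batch) else NULL
  if (contrast == "discrete3") {
    g <- factor(m$group, levels = GROUP_LEVELS)
    X1 <- cbind(1, g == "ASYM_UAS", g == "SS_SLE", bd)
    X0 <- cbind(rep(1, nrow(Y)), bd)
    ft <- .lm_matrix_f(Y, X1, X0)
    est <- rep(NA_real_, ncol(Y))
    p <- ft$p_value
    const <- ft$constant
  } else {
    v <- if (contrast == "ordinal3") .severity_score(m$group) else
      as.numeric(m$group %in% group_b)
    X <- cbind(1, v, bd)
    tt <- .lm_matrix_t(Y, X, coef_idx = 2)
    est <- tt$estimate
    p <- tt$p_value
    const <- tt$constant
  }
  if (any(const))
    warning(.fmt_count(sum(const), "taxon"),
            " with constant ranks: p set to 1")
  data.frame(taxon_id = colnames(ranks), level = level, contrast = contrast,
             estimate = unname(est), p_value = unname(p),
             p_fdr = bh_fdr(unname(p)),
             direction = sign(ifelse(is.na(est), 0, est)),
             row.names = NULL)
}

# Map each distinct lineage value at `level` to its value at the rank just
# above. Ambiguous children (same name under several parents) resolve to
# the majority parent with a warning.
.parent_map <- function(tax, level) {
  i <- match(level, TAX_RANKS)
  if (i < 2) return(NULL)
  up <- TAX_RANKS[i - 1]
  ok <- tax[[level]] != "" & tax[[up]] != ""
  pairs <- unique(tax[ok, c(level, up)])
  if (anyDuplicated(pairs[[level]])) {
    warning("lineage value(s) at ", level,
            " map to multiple parents; using the most frequent parent")
    tab <- table(tax[ok, level], tax[ok, up])
    pairs <- data.frame(
      v = rownames(tab),
      p = colnames(tab)[apply(tab, 1, which.max)])
    names(pairs) <- c(level, up)
  }
  stats::setNames(pairs[[up]], pairs[[level]])
}

#' Taxonomy-gated stepdown (TSD) testing
#'
#' Hierarchical multiple testing over the taxonomic tree. All taxa at
#' `start_level` are tested (counts aggregated at that level, clr, ranks,
#' [taxon_test()]) and BH-adjusted across the whole level. Each node whose
#' adjusted p falls below `alpha` opens a gate: its children at the next
#' rank are tested, BH-adjusted only within that sibling set, and the
#' recursion continues until species or until no gate opens. Child tests
#' use counts re-aggregated at the child's own level. Only tested nodes
#' are emitted; a node is never tested unless every ancestor gate is open.
#'
#' @param ct leaf-level count matrix.
#' @param tax taxonomy table.
#' @param md sample metadata.
#' @param contrast passed to [taxon_test()].
#' @param alpha gate threshold on the within-family BH-adjusted p.
#' @param start_level first rank tested (root gate is always open).
#' @param pseudocount clr zero replacement.
#' @param batch include the batch covariate.
#' @param filter_threshold mean-relative-abundance filter applied at each
#'   level before testing (0 disables).
#' @return data.frame with `taxon_id`, `level`, `parent_id`, `p_value`,
#'   `p_fdr_within_gate`, `gate_open`, one row per tested node.
#' @export
tsd <- function(ct, tax, md, contrast = "ordinal3", alpha = 0.05,
                start_level = "phylum", pseudocount = 0.5, batch = TRUE,
                filter_threshold = 1e-4) {
  start_level <- match.arg(start_level, TAX_RANKS)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  tax <- validate_taxonomy(tax)
  levels_run <- TAX_RANKS[seq(match(start_level, TAX_RANKS),
                              length(TAX_RANKS))]
  out <- list()
  open_parents <- NULL # NULL marks the always-open root gate
  for (lv in levels_run) {
    agg <- tryCatch(aggregate_to_level(ct, tax, lv, quiet = TRUE),
                    error = function(e) NULL)
    if (is.null(agg) || ncol(agg) == 0) break
    if (filter_threshold > 0)
      agg <- filter_mean_relabund(agg, filter_threshold, quiet = TRUE)
    pmap <- .parent_map(tax, lv)
    if (is.null(open_parents)) {
      fams <- list(root = colnames(agg))
      parent_of <- stats::setNames(rep(NA_character_, ncol(agg)),
                                   colnames(agg))
    } else {
      parent_of <- pmap[colnames(agg)]
      fams <- split(colnames(agg), parent_of)
      fams <- fams[names(fams) %in% open_parents]
      if (length(fams) == 0) break
    }
    tested <- unlist(fams, use.names = FALSE)
    rk <- rank_columns(clr_transform(agg, pseudocount))
    tt <- taxon_test(rk[, tested, drop = FALSE], md, contrast = contrast,
                     batch = batch, level = lv)
    p <- stats::setNames(tt$p_value, tt$taxon_id)
    lvl_rows <- lapply(fams, function(members) {
      q <- bh_fdr(unname(p[members]))
      data.frame(taxon_id = members, level = lv,
                 parent_id = unname(parent_of[members]),
                 p_value = unname(p[members]),
                 p_fdr_within_gate = q,
                 gate_open = q < alpha, row.names = NULL)
    })
    lvl_df <- do.call(rbind, lvl_rows)
    rownames(lvl_df) <- NULL
    out[[lv]] <- lvl_df
    open_parents <- lvl_df$taxon_id[lvl_df$gate_open]
    if (length(open_parents) == 0) break
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(taxon_id = character(), level = character(),
                      parent_id = character(), p_value = numeric(),
                      p_fdr_within_gate = numeric(), gate_open = logical())
  rownames(res) <- NULL
  .check_tsd_gates(res)
  res
}

# Structural invariant, asserted on every run: no emitted node has a
# non-open ancestor gate at a tested level.
.check_tsd_gates <- function(res) {
  if (nrow(res) == 0) return(invisible(TRUE))
  open <- stats::setNames(res$gate_open, paste(res$level, res$taxon_id))
  lv_idx <- match(res$level, TAX_RANKS)
  first <- min(lv_idx)
  bad <- vapply(seq_len(nrow(res)), function(i) {
    if (lv_idx[i] == first) return(FALSE)
    key <- paste(TAX_RANKS[lv_idx[i] - 1], res$parent_id[i])
    !isTRUE(open[key])
  }, logical(1))
  if (any(bad))
    stop("internal error: TSD emitted a node under a closed gate (",
         res$taxon_id[which(bad)[1]], ")")
  invisible(TRUE)
}

#' Level summary of differential relative abundance
#'
#' The reporting table for one taxonomic level: per-group mean and SD of
#' the (untransformed) relative abundance, the ordinal trend p and its BH
#' adjustment, the pooled healthy-vs-anti-Ro two-group p, and the discrete
#' three-group p with its BH adjustment. Optionally filtered to taxa whose
#' ordinal FDR-adjusted p is below `alpha`.
#'
#' @param ct leaf-level count matrix.
#' @param tax taxonomy table.
#' @param md sample metadata.
#' @param level rank to report (default genus, the primary reporting
#'   level).
#' @param alpha FDR threshold used when `filter_fdr` is TRUE.
#' @param filter_fdr keep only ordinal-FDR-significant taxa.
#' @param pseudocount clr zero replacement.
#' @param batch include the batch covariate.
#' @param filter_threshold mean-relative-abundance filter applied before
#'   testing (0 disables).
#' @return data.frame, one row per taxon, sorted by ordinal p.
#' @export
summarize_level <- function(ct, tax, md, level = "genus", alpha = 0.05,
                            filter_fdr = TRUE, pseudocount = 0.5,
                            batch = TRUE, filter_threshold = 1e-4) {
  level <- match.arg(level, TAX_RANKS)
  tax <- validate_taxonomy(tax)
  agg <- aggregate_to_level(ct, tax, level, quiet = TRUE)
  if (filter_threshold > 0)
    agg <- filter_mean_relabund(agg, filter_threshold, quiet = TRUE)
  m <- .match_md(rownames(agg), md)
  rel <- agg / rowSums(agg)
  rk <- rank_columns(clr_transform(agg, pseudocount))
  t_ord <- taxon_test(rk, md, "ordinal3", batch = batch, level = level)
  t_dis <- taxon_test(rk, md, "discrete3", batch = batch, level = level)
  t_two <- taxon_test(rk, md, "two_group", batch = batch, level = level)
  gstat <- function(g, fun) apply(rel[m$group == g, , drop = FALSE], 2, fun)
  pmap <- .parent_map(tax, level)
  parent <- if (is.null(pmap)) rep(NA_character_, ncol(agg)) else
    unname(pmap[colnames(agg)])
  res <- data.frame(
    parent = parent,
    taxon = colnames(agg),
    hc_mean = gstat("HC", mean), hc_sd = gstat("HC", stats::sd),
    asym_uas_mean = gstat("ASYM_UAS", mean),
    asym_uas_sd = gstat("ASYM_UAS", stats::sd),
    ss_sle_mean = gstat("SS_SLE", mean),
    ss_sle_sd = gstat("SS_SLE", stats::sd),
    estimate_ordinal = t_ord$estimate,
    p_ordinal = t_ord$p_value,
    p_ordinal_fdr = t_ord$p_fdr,
    p_hc_vs_antiro = t_two$p_value,
    p_discrete3 = t_dis$p_value,
    p_discrete3_fdr = t_dis$p_fdr,
    row.names = NULL)
  if (filter_fdr) res <- res[res$p_ordinal_fdr < alpha, , drop = FALSE]
  res <- res[order(res$p_ordinal), , drop = FALSE]
  rownames(res) <- NULL
  res
}
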