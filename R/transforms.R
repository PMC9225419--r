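# Taxonomic aggregation, abundance filters, and the compositional
# transforms (clr, rank-of-clr, tree-based ilr balances, Aitchison
# distance) feeding every downstream test.

#' Aggregate a count table to a taxonomic level
#'
#' Sums the counts of all taxa sharing the same lineage value at `level`.
#' Taxa with no assignment at that level are dropped (and reported); there
#' is no "unclassified" pseudo-taxon, so each level's test family contains
#' only named taxa.
#'
#' @param ct count matrix (samples x taxa).
#' @param tax taxonomy table covering every column of `ct`.
#' @param level one of [TAX_RANKS].
#' @param quiet suppress the dropped-taxa message.
#' @return count matrix with one column per distinct lineage value at
#'   `level`, columns in first-appearance order.
#' @export
aggregate_to_level <- function(ct, tax, level, quiet = FALSE) {
  level <- match.arg(level, TAX_RANKS)
  tax <- validate_taxonomy(tax)
  missing_tax <- setdiff(colnames(ct), tax$taxon_id)
  if (length(missing_tax) > 0)
    stop("taxa absent from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "))
  lin <- tax[[level]][match(colnames(ct), tax$taxon_id)]
  ok <- !is.na(lin) & lin != ""
  if (!any(ok)) stop("no taxon assignable at level '", level, "'")
  if (!quiet && any(!ok))
    message("aggregate_to_level(", level, "): dropped ",
            .fmt_count(sum(!ok), "unassigned taxon"))
  sub <- ct[, ok, drop = FALSE]
  vals <- lin[ok]
  uvals <- unique(vals)
  agg <- t(rowsum(t(sub), group = vals))
  agg <- agg[, uvals, drop = FALSE]
  rownames(agg) <- rownames(ct)
  agg
}

#' Drop taxa whose total count is zero
#'
#' @param ct count matrix.
#' @param quiet suppress the message.
#' @return count matrix without all-zero taxa, order preserved.
#' @export
drop_zero_taxa <- function(ct, quiet = FALSE) {
  tot <- colSums(ct)
  if (all(tot == 0)) stop("all taxa have zero total count")
  if (!quiet && any(tot == 0))
    message("drop_zero_taxa: removed ",
            .fmt_count(sum(tot == 0), "all-zero taxon"))
  ct[, tot > 0, drop = FALSE]
}

#' Filter taxa by mean relative abundance
#'
#' Computes each sample's relative abundances (closure of the counts) and
#' drops taxa whose mean relative abundance across samples falls below
#' `threshold` (default 1e-4, the conventional rare-taxon cutoff).
#'
#' @param ct count matrix.
#' @param threshold in `[0, 1)`.
#' @param quiet suppress the message.
#' @return filtered count matrix, order preserved.
#' @export
filter_mean_relabund <- function(ct, threshold = 1e-4, quiet = FALSE) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  rel <- ct / rowSums(ct)
  keep <- colMeans(rel) >= threshold
  if (!any(keep)) stop("no taxon passes the mean relative abundance filter")
  if (!quiet && any(!keep))
    message("filter_mean_relabund: removed ",
            .fmt_count(sum(!keep), "rare taxon"))
  ct[, keep, drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per sample: adds `pseudocount` to every count, closes to proportions and
#' returns `log(x_i / g(x))` with `g` the geometric mean, so each row sums
#' to zero. The default half-count pseudocount is the conventional zero
#' replacement for sequencing counts.
#'
#' @param ct count matrix.
#' @param pseudocount added to every count; must be positive when zeros are
#'   present.
#' @return samples x taxa clr matrix.
#' @export
clr_transform <- function(ct, pseudocount = 0.5) {
  x <- as.matrix(ct)
  if (any(x == 0) && pseudocount <= 0)
    stop("zero counts present: clr needs a positive pseudocount")
  x <- x + pseudocount
  lp <- log(x / rowSums(x))
  lp - rowMeans(lp)
}

#' Column-wise midranks
#'
#' Ranks samples 1..n within every taxon column, ties receiving the mean of
#' the tied ranks. Used because clr values need not meet the conditional
#' normality assumption of a Gaussian linear model.
#'
#' @param m numeric matrix (samples x taxa).
#' @return matrix of ranks with the same dimnames.
#' @export
rank_columns <- function(m) {
  if (nrow(m) < 2) stop("ranking needs at least 2 samples")
  apply(m, 2, rank, ties.method = "average")
}

#' Build a bifurcating tree from a taxonomy
#'
#' Nests taxa by lineage (kingdom down to species) and resolves every
#' multifurcation into a seeded random bifurcation, with unit branch
#' lengths. This stands in for a sequence-based phylogeny when only
#' taxonomic assignments are available; a user-supplied Newick tree
#' overrides it everywhere a tree is accepted.
#'
#' @param tax taxonomy table.
#' @param seed integer; same seed gives an identical topology.
#' @return an `ape::phylo` bifurcating tree whose leaves are the taxon ids.
#' @export
build_tree_from_taxonomy <- function(tax, seed = 1) {
  tax <- validate_taxonomy(tax)
  ids <- tax$taxon_id
  if (length(ids) < 2) stop("need at least 2 taxa to build a tree")
  if (!all(grepl("^[A-Za-z0-9_.-]+$", ids)))
    stop("taxon ids must be Newick-safe ([A-Za-z0-9_.-])")
  lineage <- as.matrix(tax[TAX_RANKS])
  set.seed(seed)
  build <- function(idx, depth) {
    if (length(idx) == 1) return(paste0(ids[idx], ":1"))
    if (depth > length(TAX_RANKS)) {
      grp <- as.list(idx)
    } else {
      vals <- lineage[idx, depth]
      key <- ifelse(vals == "", paste0(".leaf.", idx), vals)
      grp <- split(idx, key)
    }
    subs <- lapply(grp, build, depth = depth + 1L)
    if (length(subs) > 1) subs <- subs[sample(length(subs))]
    while (length(subs) > 1) {
      merged <- paste0("(", subs[[1]], ",", subs[[2]], "):1")
      subs <- c(list(merged), subs[-(1:2)])
    }
    subs[[1]]
  }
  nwk <- build(seq_along(ids), 1L)
  # strip the root's dangling branch length before terminating
  nwk <- sub(":1$", "", nwk)
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Isometric log-ratio balances over a bifurcating tree
#'
#' One balance per internal node: with left/right leaf sets L and R of
#' sizes r and s, the uniform-weight balance is
#' `sqrt(r*s/(r+s)) * ln(g(x_L)/g(x_R))`, `g` the geometric mean of the
#' closed proportions. The `mean_descendants` weighting multiplies each
#' taxon's contribution by its mean relative abundance across samples,
#' using weighted geometric means and weighted node normalizers; uniform
#' weighting is the exact isometry (balance-space Euclidean distance equals
#' Aitchison distance), the weighted variant is a soft down-weighting of
#' rare parts.
#'
#' @param ct count matrix.
#' @param tree bifurcating `ape::phylo` tree whose leaves are the columns
#'   of `ct`.
#' @param pseudocount zero replacement before closure.
#' @param weighting `"uniform"` or `"mean_descendants"`.
#' @return samples x (n_taxa - 1) balance matrix; columns named by the
#'   tree's node labels (or `nodeNN`).
#' @export
ilr_balances <- function(ct, tree, pseudocount = 0.5,
                         weighting = c("uniform", "mean_descendants")) {
  weighting <- match.arg(weighting)
  if (!ape::is.binary(tree))
    stop("tree is not bifurcating; resolve it first, e.g. with ",
         "build_tree_from_taxonomy()")
  if (!setequal(tree$tip.label, colnames(ct)))
    stop("tree leaf set must equal the count table's taxon set")
  x <- as.matrix(ct)[, tree$tip.label, drop = FALSE] + pseudocount
  if (any(x <= 0)) stop("non-positive values after pseudocount")
  p <- x / rowSums(x)
  lp <- log(p)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (i in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[i, 1]
    ch <- tr$edge[i, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[ch]])
  }
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  nodes <- sort(as.integer(names(kids)))
  w <- if (weighting == "mean_descendants") colMeans(p) else
    rep(1, ntip)
  bal <- matrix(0, nrow(p), length(nodes),
                dimnames = list(rownames(ct), NULL))
  for (j in seq_along(nodes)) {
    ch <- kids[[as.character(nodes[j])]]
    L <- desc[[ch[1]]]
    R <- desc[[ch[2]]]
    wl <- w[L]
    wr <- w[R]
    sl <- sum(wl)
    sr <- sum(wr)
    gl <- (lp[, L, drop = FALSE] %*% wl) / sl
    gr <- (lp[, R, drop = FALSE] %*% wr) / sr
    bal[, j] <- sqrt(sl * sr / (sl + sr)) * (gl - gr)
  }
  labs <- tree$node.label
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs))
    labs <- paste0("node", nodes)
  colnames(bal) <- labs
  bal
}

#' Aitchison distance
#'
#' Pairwise Euclidean distance between the rows of a clr matrix: the
#' natural metric between compositions.
#'
#' @param clr_m clr matrix (samples x taxa), e.g. from [clr_transform()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
aitchison_distance <- function(clr_m) {
  if (nrow(clr_m) < 2) stop("need at least 2 samples")
  as.matrix(stats::dist(clr_m))
}
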