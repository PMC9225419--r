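# Readers, writers and validators for the tabular and tree formats the
# pipeline touches. Dense TSV is the canonical interchange format; a sparse
# triplet dialect is accepted for large simulated tables. All readers
# validate and name the offending record on failure; none silently coerce.

#' Validate a sample-by-taxon count table
#'
#' Checks that `x` is a numeric matrix (or coercible data frame) of
#' non-negative whole numbers with unique sample and taxon identifiers and
#' at least two samples and two taxa.
#'
#' @param x matrix or data.frame, samples in rows, taxa in columns, with
#'   row and column names.
#' @return the validated table as a base matrix.
#' @export
validate_count_table <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("count table must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count table needs sample row names and taxon column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(is.na(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid count at sample '", rownames(m)[bad[1, 1]],
         "', taxon '", colnames(m)[bad[1, 2]],
         "': counts must be non-negative integers")
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("count table needs at least 2 samples and 2 taxa, got ",
         nrow(m), " x ", ncol(m))
  storage.mode(m) <- "double"
  m
}

#' Read a count table
#'
#' @param path file path.
#' @param dialect `"tsv_dense"` (header row of taxon ids, first column of
#'   sample ids) or `"triplet_sparse"` (columns `sample_id`, `taxon_id`,
#'   `count`; unlisted cells are zero).
#' @return validated count matrix, row/column order as in the file (first
#'   appearance order for the triplet dialect).
#' @export
read_count_table <- function(path, dialect = c("tsv_dense", "triplet_sparse")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv_dense") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "taxon_id", "count")
    if (!all(need %in% names(df)))
      stop("triplet file must have columns: ", paste(need, collapse = ", "))
    s <- unique(df$sample_id)
    t <- unique(df$taxon_id)
    m <- matrix(0, length(s), length(t), dimnames = list(s, t))
    m[cbind(match(df$sample_id, s), match(df$taxon_id, t))] <- df$count
  }
  validate_count_table(m)
}

#' Write a count table
#'
#' @param ct count matrix.
#' @param path destination.
#' @param dialect see [read_count_table()].
#' @export
write_count_table <- function(ct, path,
                              dialect = c("tsv_dense", "triplet_sparse")) {
  dialect <- match.arg(dialect)
  ct <- validate_count_table(ct)
  if (dialect == "tsv_dense") {
    df <- data.frame(sample_id = rownames(ct), ct, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(ct != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(sample_id = rownames(ct)[idx[, 1]],
                     taxon_id = colnames(ct)[idx[, 2]],
                     count = ct[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Validate a taxonomy table
#'
#' A taxonomy table has a `taxon_id` column plus the seven ranked lineage
#' columns of [TAX_RANKS]. A missing rank (empty string) implies all lower
#' ranks are missing too, mirroring truncated SILVA-style lineages.
#'
#' @param tax data.frame.
#' @return validated data.frame with missing ranks normalised to `""`.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("taxon_id", TAX_RANKS)
  if (!all(need %in% names(tax)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  tax <- as.data.frame(tax)[need]
  tax$taxon_id <- as.character(tax$taxon_id)
  if (anyDuplicated(tax$taxon_id))
    stop("duplicate taxon_id in taxonomy: ",
         tax$taxon_id[duplicated(tax$taxon_id)][1])
  for (r in TAX_RANKS) {
    tax[[r]] <- as.character(tax[[r]])
    tax[[r]][is.na(tax[[r]])] <- ""
  }
  present <- sapply(TAX_RANKS, function(r) tax[[r]] != "")
  if (is.null(dim(present))) present <- matrix(present, nrow = 1)
  for (i in seq_len(nrow(tax))) {
    p <- present[i, ]
    if (any(p) && any(!p) && max(which(p)) > min(which(!p)))
      stop("gap in lineage for taxon '", tax$taxon_id[i],
           "': rank '", TAX_RANKS[min(which(!p))],
           "' missing but lower rank '",
           TAX_RANKS[max(which(p))], "' present")
  }
  tax
}

#' Read / write a taxonomy table (TSV, 8 columns)
#' @param path file path.
#' @return validated taxonomy data.frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0),
                          colClasses = "character")
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame.
#' @export
write_taxonomy <- function(tax, path) {
  tax <- validate_taxonomy(tax)
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Fixed columns: `sample_id`, `group` (one of [GROUP_LEVELS]), `batch`,
#' the four HLA carrier flags of [HLA_COLS] (0/1/NA) and the four titers of
#' [TITER_COLS] (non-negative, possibly NA). Healthy controls may have all
#' HLA flags and titers missing.
#'
#' @param md data.frame.
#' @return validated data.frame.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "group", "batch", HLA_COLS, TITER_COLS)
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md <- as.data.frame(md)[need]
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1])
  md$group <- as.character(md$group)
  bad <- setdiff(unique(md$group), GROUP_LEVELS)
  if (length(bad) > 0 || anyNA(md$group))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(GROUP_LEVELS, collapse = ", "))
  md$batch <- as.character(md$batch)
  for (h in HLA_COLS) {
    v <- md[[h]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("HLA flag '", h, "' must be 0, 1 or missing")
    md[[h]] <- as.integer(v)
  }
  for (t in TITER_COLS) {
    v <- suppressWarnings(as.numeric(md[[t]]))
    if (any(!is.na(v) & v < 0))
      stop("titer '", t, "' has negative values")
    md[[t]] <- v
  }
  md
}

#' Read / write sample metadata (TSV with fixed column names)
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param md metadata data.frame.
#' @export
write_metadata <- function(md, path) {
  md <- validate_metadata(md)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a taxon tree (Newick)
#'
#' @param path Newick file.
#' @param taxonomy optional taxonomy table; when given, every tree leaf must
#'   be a known `taxon_id` (cross-reference check).
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (!is.null(taxonomy)) {
    taxonomy <- validate_taxonomy(taxonomy)
    unknown <- setdiff(tree$tip.label, taxonomy$taxon_id)
    if (length(unknown) > 0)
      stop("tree leaves absent from taxonomy: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  tree
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Align a count table, taxonomy and metadata on shared identifiers
#'
#' Restricts all three objects to the intersection of their sample and
#' taxon identifiers, preserving the count-table order (the authoritative
#' order for all downstream matrices), and reports what was dropped.
#'
#' @param ct count matrix.
#' @param tax taxonomy data.frame.
#' @param md metadata data.frame.
#' @param quiet suppress the dropped-id messages.
#' @return list with elements `counts`, `taxonomy`, `metadata`.
#' @export
align_inputs <- function(ct, tax, md, quiet = FALSE) {
  ct <- validate_count_table(ct)
  tax <- validate_taxonomy(tax)
  md <- validate_metadata(md)
  keep_s <- rownames(ct)[rownames(ct) %in% md$sample_id]
  keep_t <- colnames(ct)[colnames(ct) %in% tax$taxon_id]
  if (length(keep_s) == 0) stop("no samples shared between counts and metadata")
  if (length(keep_t) == 0) stop("no taxa shared between counts and taxonomy")
  if (!quiet) {
    ds <- nrow(ct) - length(keep_s) + sum(!md$sample_id %in% keep_s)
    dt <- ncol(ct) - length(keep_t) + sum(!tax$taxon_id %in% keep_t)
    if (ds > 0) message("align: dropped ", .fmt_count(ds, "unmatched sample"))
    if (dt > 0) message("align: dropped ", .fmt_count(dt, "unmatched taxon"))
  }
  list(counts = ct[keep_s, keep_t, drop = FALSE],
       taxonomy = tax[match(keep_t, tax$taxon_id), , drop = FALSE],
       metadata = md[match(keep_s, md$sample_id), , drop = FALSE])
}
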