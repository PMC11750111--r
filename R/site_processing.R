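#' Missing-value filter
#'
#' Keeps exactly the features whose number of missing measurements is at most
#' `max_missing`. The study presets correspond to discarding sites absent in
#' more than one biological replicate: 10 of 30 for the 2-condition mating
#' design (3 replicates x 2 conditions x 5 time points) and 5 of 15 for the
#' fusion design.
#'
#' @param x a [quant_table()].
#' @param max_missing maximum allowed missing count per feature, or a preset
#'   `"mating"` (10) / `"fusion"` (5).
#' @return the filtered [quant_table()]; attributes `"n_kept"`/`"n_dropped"`
#'   report the bookkeeping.
#' @export
filter_missing <- function(x, max_missing) {
  stopifnot(inherits(x, "quant_table"))
  if (is.character(max_missing))
    max_missing <- switch(match.arg(max_missing, c("mating", "fusion")),
                          mating = 10L, fusion = 5L)
  if (max_missing >= ncol(x$values))
    stop("max_missing must be smaller than the sample count (", ncol(x$values), ")")
  n_miss <- rowSums(is.na(x$values))
  keep <- n_miss <= max_missing
  out <- subset_quant(x, which(keep))
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Collapse exactly redundant features
#'
#' Phosphopeptides with several phosphorylation possibilities can yield
#' multiple site rows carrying exactly the same measurements. To avoid biasing
#' the multiple-testing correction, rows whose full value vectors (including
#' the missing pattern) are bit-identical are grouped and only one
#' representative (the lexicographically smallest feature_id) is retained for
#' testing; [expand_redundant()] restores the duplicates afterwards.
#'
#' @param x a [quant_table()].
#' @return list with `table` (collapsed [quant_table()]) and `map`, a named
#'   list mapping each representative feature_id to its duplicates' ids
#'   (empty list when all rows are distinct).
#' @export
collapse_redundant <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  v <- x$values
  # exact equality incl. NA pattern: serialize each row to a key
  key <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\r"))
  groups <- split(x$features$feature_id, key)
  map <- list()
  keep_ids <- character(0)
  for (ids in groups) {
    ids <- sort(ids)
    keep_ids <- c(keep_ids, ids[1L])
    if (length(ids) > 1L) map[[ids[1L]]] <- ids[-1L]
  }
  keep <- x$features$feature_id %in% keep_ids
  list(table = subset_quant(x, which(keep)), map = map)
}

#' Re-attach redundant features to per-site results
#'
#' Each duplicate receives a copy of its representative's statistics and
#' labels, so the output covers the original (pre-collapse) feature set.
#'
#' @param stats data.frame of per-site results with a `feature_id` column.
#' @param map redundancy map from [collapse_redundant()].
#' @return data.frame covering representatives and duplicates; duplicates are
#'   flagged in the `redundant_with` column.
#' @export
expand_redundant <- function(stats, map) {
  stopifnot(is.data.frame(stats), "feature_id" %in% names(stats))
  if (length(map) == 0L) {
    stats$redundant_with <- NA_character_
    return(stats)
  }
  missing_rep <- setdiff(names(map), stats$feature_id)
  if (length(missing_rep))
    stop("representatives absent from stats: ",
         paste(missing_rep, collapse = ", "))
  stats$redundant_with <- NA_character_
  extra <- lapply(names(map), function(rep_id) {
    row <- stats[stats$feature_id == rep_id, , drop = FALSE]
    dup <- row[rep(1L, length(map[[rep_id]])), , drop = FALSE]
    dup$feature_id <- map[[rep_id]]
    dup$redundant_with <- rep_id
    dup
  })
  out <- rbind(stats, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Monophosphorylated-site subset
#'
#' Restricts a table to sites detected on monophosphorylated peptides
#' (multiplicity 1), the universe used for kinase-substrate enrichment.
#'
#' @param x a [quant_table()] with a `multiplicity` feature column.
#' @return the subset [quant_table()].
#' @export
monophospho_subset <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  m <- x$features$multiplicity
  if (is.null(m))
    stop("multiplicity not annotated")
  if (anyNA(m))
    stop("multiplicity missing for features: ",
         paste(utils::head(x$features$feature_id[is.na(m)], 5), collapse = ", "))
  subset_quant(x, which(m == 1L))
}
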