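#' Quantitative feature-by-sample table
#'
#' The central container of the pipeline: a features x samples matrix of log2
#' abundances (NA marks a missing measurement) together with feature metadata
#' (protein, residue, position, multiplicity, +/-5 sequence window) and sample
#' metadata (condition, time in minutes, biological replicate). Phosphosite
#' rows carry a residue in {S, T, Y}; proteome rows leave residue/position/
#' multiplicity/window as NA.
#'
#' @param values numeric matrix, features in rows, samples in columns. NA
#'   entries are missing measurements; all non-missing entries must be finite.
#' @param features data.frame with at least `feature_id` (unique); optional
#'   columns `protein_id`, `residue`, `position`, `multiplicity`, `window`.
#' @param samples data.frame with columns `condition`, `time_min`,
#'   `replicate`; the triple must be unique per sample. If NULL, sample keys
#'   are parsed from `colnames(values)` (pattern `<condition>_<time>min_R<rep>`).
#' @return an object of class `quant_table`.
#' @seealso [read_quant_table()], [median_center_by_replicate()]
#' @export
quant_table <- function(values, features = NULL, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(features)) {
    if (is.null(rownames(values)))
      stop("`features` missing and `values` has no rownames")
    features <- data.frame(feature_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$feature_id))
    stop("`features` must have a feature_id column")
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  if (nrow(features) != nrow(values))
    stop("features rows (", nrow(features), ") != value rows (", nrow(values), ")")
  if (is.null(samples)) {
    if (is.null(colnames(values)))
      stop("`samples` missing and `values` has no colnames")
    samples <- parse_sample_keys(colnames(values))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("condition", "time_min", "replicate"))
    if (is.null(samples[[col]])) stop("`samples` must have a ", col, " column")
  samples$condition <- as.character(samples$condition)
  samples$time_min <- as.numeric(samples$time_min)
  samples$replicate <- as.character(samples$replicate)  # canonical key type
  if (nrow(samples) != ncol(values))
    stop("samples rows (", nrow(samples), ") != value columns (", ncol(values), ")")
  key <- paste(samples$condition, samples$time_min, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, time_min, replicate) sample keys")
  if (any(samples$time_min < 0)) stop("negative time_min")
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite values present (use NA for missing)")
  if (!is.null(features$window)) {
    w <- features$window
    bad <- !is.na(w) & nchar(w) != 11L
    if (any(bad))
      stop("windows must have length 11; offending features: ",
           paste(utils::head(features$feature_id[bad], 5), collapse = ", "))
  }
  if (!is.null(features$multiplicity)) {
    m <- features$multiplicity
    if (any(!is.na(m) & m < 1)) stop("multiplicity must be >= 1")
  }
  rownames(values) <- features$feature_id
  colnames(values) <- sample_names(samples)
  structure(list(values = values, features = features, samples = samples),
            class = "quant_table")
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' @export
print.quant_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("quant_table: %d features x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  cond <- table(x$samples$condition)
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(cond), cond), collapse = ", "), "\n")
  cat("  times (min):", paste(sort(unique(x$samples$time_min)), collapse = ", "),
      " replicates:", paste(sort(unique(x$samples$replicate)), collapse = ", "), "\n")
  invisible(x)
}

# canonical sample naming: <condition>_<time>min_R<replicate>
sample_names <- function(samples) {
  sprintf("%s_%smin_R%s", samples$condition, samples$time_min, samples$replicate)
}

#' Parse sample names into sample keys
#'
#' Interprets column headers of the form `<condition>_<time>min_R<rep>`
#' (e.g. `mating_45min_R2`) into a (condition, time_min, replicate) table.
#'
#' @param x character vector of sample names.
#' @return data.frame with columns condition, time_min, replicate.
#' @export
parse_sample_keys <- function(x) {
  m <- regmatches(x, regexec("^(.+)_([0-9]+)min_R([A-Za-z0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("unparseable sample header(s): ", paste(x[bad], collapse = ", "))
  data.frame(condition = vapply(m, `[`, "", 2L),
             time_min = as.numeric(vapply(m, `[`, "", 3L)),
             replicate = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

# subset a quant_table by feature index/logical/id and/or sample index
subset_quant <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$values))
  if (is.character(i)) i <- match(i, x$features$feature_id)
  if (is.null(j)) j <- seq_len(ncol(x$values))
  quant_table(x$values[i, j, drop = FALSE],
              x$features[i, , drop = FALSE],
              x$samples[j, , drop = FALSE])
}
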