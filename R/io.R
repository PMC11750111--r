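#' Read a wide quantification table
#'
#' Two dialects are supported. `"tsv"` is the package's native wide layout:
#' feature-metadata columns (`feature_id`, optionally `protein_id`, `residue`,
#' `position`, `multiplicity`, `window`) followed by one column per sample
#' named `<condition>_<time>min_R<rep>`; `NA` or an empty cell marks a missing
#' measurement. `"supplementary_xlsx"` reads the deposited supplementary-table
#' layout: one sheet per data set holding replicate columns followed by
#' per-time "average" columns; only replicate columns (headers matching the
#' sample-name pattern) are loaded, averages and annotation extras are ignored.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"supplementary_xlsx"`.
#' @param sheet sheet name or index for the xlsx dialect.
#' @return a [quant_table()].
#' @export
read_quant_table <- function(path, dialect = c("tsv", "supplementary_xlsx"),
                             sheet = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, na.strings = c("NA", ""))
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("the supplementary_xlsx dialect requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet),
                        stringsAsFactors = FALSE, check.names = FALSE)
  }
  quant_from_frame(df)
}

quant_from_frame <- function(df) {
  meta_cols <- intersect(
    c("feature_id", "protein_id", "residue", "position", "multiplicity", "window"),
    names(df))
  if (!"feature_id" %in% meta_cols)
    stop("table lacks a feature_id column")
  is_sample <- grepl("^.+_[0-9]+min_R[A-Za-z0-9]+$", names(df))
  sample_cols <- names(df)[is_sample]
  other <- setdiff(names(df), c(meta_cols, sample_cols))
  if (length(sample_cols) == 0L)
    stop("no sample columns matching <condition>_<time>min_R<rep>; ",
         "unrecognized columns: ", paste(utils::head(other, 5), collapse = ", "))
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(values) <- "double"
  features <- df[, meta_cols, drop = FALSE]
  features$feature_id <- as.character(features$feature_id)
  quant_table(values, features, parse_sample_keys(sample_cols))
}

#' Write a quantification table as wide TSV
#'
#' Inverse of [read_quant_table()] for the tsv dialect: feature metadata
#' columns, then one sample column per channel, `NA` for missing cells.
#'
#' @param x a [quant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  out <- cbind(x$features,
               as.data.frame(x$values, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Log2-transform raw intensities
#'
#' @param x a [quant_table()] of raw (non-negative) intensities.
#' @param pseudocount value added before taking log2 (default 0).
#' @return a [quant_table()] with values log2(value + pseudocount); missing
#'   entries stay missing.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "quant_table"))
  v <- x$values
  if (any(v < 0, na.rm = TRUE)) stop("negative intensities cannot be log2-transformed")
  if (pseudocount == 0 && any(v == 0, na.rm = TRUE))
    stop("zero intensities require a positive pseudocount")
  x$values <- log2(v + pseudocount)
  x
}

#' Per-replicate median centering
#'
#' Corrects technical variation between replicates (TMT runs): for every
#' feature and every biological replicate, the median over that feature's
#' non-missing values across all time points of that replicate -- pooling all
#' conditions run in the same multiplex -- is subtracted from each of those
#' values. Afterwards each feature's per-replicate median is exactly zero.
#' A feature entirely missing within a replicate is left untouched there.
#'
#' @param x a [quant_table()] of log2 values.
#' @return the centered [quant_table()], with attribute `"n_untouched"` giving
#'   the number of (feature, replicate) blocks left uncentered because no
#'   value was observed.
#' @export
median_center_by_replicate <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  v <- x$values
  untouched <- 0L
  for (rep in unique(x$samples$replicate)) {
    cols <- which(x$samples$replicate == rep)
    block <- v[, cols, drop = FALSE]
    med <- apply(block, 1L, stats::median, na.rm = TRUE)  # midpoint for even n
    missing_all <- !is.finite(med)
    untouched <- untouched + sum(missing_all)
    med[missing_all] <- 0
    v[, cols] <- block - med
  }
  x$values <- v
  attr(x, "n_untouched") <- untouched
  x
}

#' Principal-component quality control
#'
#' PCA of the samples computed on the sub-table of features with no missing
#' values (complete cases; no imputation), feature-wise mean-centered.
#' Components are ordered by decreasing explained variance.
#'
#' @param x a [quant_table()].
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions), `n_features_used`, and the sample table.
#' @export
pca_qc <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "quant_table"))
  if (ncol(x$values) < 2L) stop("pca_qc needs at least 2 samples")
  complete <- stats::complete.cases(x$values)
  if (sum(complete) < n_components)
    stop("only ", sum(complete), " complete-case features; need >= ", n_components)
  m <- t(x$values[complete, , drop = FALSE])  # samples x features
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       n_features_used = sum(complete),
       samples = x$samples)
}

#' Derive phosphosite sequence windows from protein sequences
#'
#' Fills the `window` feature column with the 11-residue window centered on
#' each phosphosite (positions -5..+5), padding beyond the protein termini
#' with `_`. Proteome rows (no residue/position) are left as NA.
#'
#' @param x a [quant_table()] whose features carry `protein_id` and `position`.
#' @param fasta path to a protein FASTA file; names must match `protein_id`.
#' @param flank residues on each side of the phosphosite (default 5).
#' @return `x` with the `window` column filled.
#' @export
windows_from_fasta <- function(x, fasta, flank = 5L) {
  stopifnot(inherits(x, "quant_table"))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("windows_from_fasta requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  f <- x$features
  win <- rep(NA_character_, nrow(f))
  for (i in seq_len(nrow(f))) {
    if (is.null(f$position) || is.na(f$position[i])) next
    pid <- f$protein_id[i]
    if (!pid %in% names(seqs)) stop("protein not in FASTA: ", pid)
    s <- as.character(seqs[[pid]])
    pos <- f$position[i]
    if (pos < 1L || pos > nchar(s))
      stop("position ", pos, " outside protein ", pid)
    padded <- paste0(strrep("_", flank), s, strrep("_", flank))
    win[i] <- substr(padded, pos, pos + 2L * flank)
  }
  x$features$window <- win
  x
}
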