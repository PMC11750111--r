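#' Kinase-substrate enrichment by Fisher's exact test
#'
#' Tests whether hit phosphosites are enriched for a kinase's known
#' substrates against a background universe (conventionally all
#' monophosphorylated sites quantified after filtering, see
#' [monophospho_subset()]). Fold enrichment is the ratio of the substrate
#' proportion among hits to the substrate proportion in the background.
#'
#' @param hits character vector of hit site keys; must be a subset of
#'   `background`.
#' @param substrate_set character vector of the kinase's substrate site keys.
#' @param background character vector of the background universe.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `fold_enrichment`, `p_value`, and the 2x2 `table`.
#' @export
fisher_enrichment <- function(hits, substrate_set, background,
                              alternative = "two.sided") {
  if (length(hits) == 0L || length(background) == 0L)
    stop("hits and background must be non-empty")
  if (!all(hits %in% background))
    stop("hits must be a subset of the background universe")
  hits <- unique(hits); background <- unique(background)
  sub_bg <- intersect(unique(substrate_set), background)
  if (length(sub_bg) == 0L)
    return(list(fold_enrichment = NA_real_, p_value = 1,
                table = matrix(c(0L, length(hits), 0L,
                                 length(background) - length(hits)), 2L)))
  a <- length(intersect(hits, sub_bg))                 # hit substrates
  b <- length(hits) - a                                # hit non-substrates
  cc <- length(sub_bg) - a                             # non-hit substrates
  d <- length(background) - length(hits) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2L,
                dimnames = list(c("substrate", "other"),
                                c("hit", "non_hit")))
  fold <- (a / length(hits)) / (length(sub_bg) / length(background))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(fold_enrichment = fold, p_value = p, table = tab)
}

#' Load kinase-substrate sets from two-column TSV
#'
#' Expects columns `kinase` and `site` (a site key such as
#' `<protein>_<residue><position>`); duplicate keys within a kinase are
#' de-duplicated.
#'
#' @param path TSV file path.
#' @return named list of character vectors (kinase -> site keys), with a
#'   `counts` attribute.
#' @export
load_substrate_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty substrate file: ", path)
  if (!all(c("kinase", "site") %in% names(df)))
    stop("substrate file needs 'kinase' and 'site' columns")
  bad <- which(is.na(df$site) | df$site == "" | is.na(df$kinase))
  if (length(bad))
    stop("malformed substrate entry at line ", bad[1L] + 1L)
  sets <- lapply(split(df$site, df$kinase), unique)
  attr(sets, "counts") <- vapply(sets, length, 1L)
  sets
}

#' Write kinase-substrate sets as two-column TSV
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_substrate_sets <- function(sets, path) {
  df <- data.frame(kinase = rep(names(sets), lengths(sets)),
                   site = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Position frequency matrix of phosphosite sequence windows
#'
#' Aligns 11-residue windows (positions -5..+5 around the phosphoresidue) and
#' tabulates per-position residue probabilities, the numerical content of a
#' sequence logo. Terminal padding characters (`_`) are excluded from the
#' denominators. `exclude_proline_directed` removes windows with a proline at
#' +1 (the CDK/MAPK-style proline-directed sites) before counting;
#' `exclude_sites` removes named sites (e.g. known substrates of a kinase
#' whose motif would dominate).
#'
#' @param windows character vector of length-11 windows, optionally named by
#'   site key.
#' @param exclude_proline_directed drop windows with P at position +1.
#' @param exclude_sites character vector of site names to drop (matched
#'   against `names(windows)`).
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @return matrix alphabet x 11 (positions -5..+5) of probabilities, with
#'   attribute `"n_windows"` (windows retained).
#' @export
motif_pfm <- function(windows, exclude_proline_directed = FALSE,
                      exclude_sites = NULL, alphabet = AMINO_ACIDS) {
  bad <- nchar(windows) != 11L
  if (any(bad))
    stop("malformed window for site(s): ",
         paste(utils::head(if (is.null(names(windows))) which(bad)
                           else names(windows)[bad], 5), collapse = ", "))
  if (!all(substr(windows, 6L, 6L) %in% c("S", "T")))
    stop("window centers must be S or T")
  if (!is.null(exclude_sites) && length(exclude_sites) && !is.null(names(windows)))
    windows <- windows[!names(windows) %in% exclude_sites]
  if (exclude_proline_directed)
    windows <- windows[substr(windows, 7L, 7L) != "P"]
  pfm <- matrix(0, nrow = length(alphabet), ncol = 11L,
                dimnames = list(alphabet, as.character(-5:5)))
  if (length(windows)) {
    chars <- do.call(rbind, strsplit(windows, ""))
    for (j in seq_len(11L)) {
      col <- chars[, j]
      col <- col[col != "_"]
      if (length(col))
        pfm[, j] <- table(factor(col, levels = alphabet)) / length(col)
    }
  }
  attr(pfm, "n_windows") <- length(windows)
  pfm
}

#' @rdname motif_pfm
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Microscopy screen metrics
#'
#' Percent metrics quantified from micrographs of mating mixtures.
#' Mating efficiency is the percentage of cells engaged in mating (cell pairs
#' or fused zygotes) relative to all cells:
#' `100 * 2(pairs + zygotes) / (individual + 2(pairs + zygotes))`.
#' Fusion efficiency is the percentage of mating-engaged pairs that fused;
#' the default denominator counts all engaged pairs (unfused + fused), the
#' `"unfused_pairs"` option reproduces the literal formula
#' `100 * fused / unfused`. The zygote fraction is
#' `100 * 2 * zygotes / (individual + 2(pairs + zygotes))`.
#'
#' @param n_individual number of unpaired cells.
#' @param n_pairs number of (unfused) mating pairs.
#' @param n_zygotes,n_fused number of fused zygotes.
#' @param denominator `"engaged_pairs"` (default) or `"unfused_pairs"`.
#' @return a percentage in \[0, 100\] (fusion efficiency with the
#'   `"unfused_pairs"` denominator may exceed 100).
#' @export
mating_efficiency <- function(n_individual, n_pairs, n_zygotes) {
  check_counts(n_individual, n_pairs, n_zygotes)
  engaged <- 2 * (n_pairs + n_zygotes)
  if (n_individual + engaged == 0) stop("all counts are zero")
  100 * engaged / (n_individual + engaged)
}

#' @rdname mating_efficiency
#' @export
fusion_efficiency <- function(n_pairs, n_fused,
                              denominator = c("engaged_pairs",
                                              "unfused_pairs")) {
  check_counts(n_pairs, n_fused)
  denominator <- match.arg(denominator)
  den <- if (denominator == "engaged_pairs") n_pairs + n_fused else n_pairs
  if (den == 0) stop("zero denominator for fusion efficiency")
  100 * n_fused / den
}

#' @rdname mating_efficiency
#' @export
zygote_fraction <- function(n_individual, n_pairs, n_fused) {
  check_counts(n_individual, n_pairs, n_fused)
  den <- n_individual + 2 * (n_pairs + n_fused)
  if (den == 0) stop("all counts are zero")
  100 * 2 * n_fused / den
}

check_counts <- function(...) {
  x <- c(...)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  invisible(TRUE)
}
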