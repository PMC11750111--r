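#' Per-replicate log2 fold changes against the baseline time point
#'
#' Within each replicate, the value at the baseline time is subtracted from
#' every time point of the same (condition, replicate) series, so each series
#' starts at 0. A replicate lacking its baseline measurement is dropped for
#' that feature (counted in the `"n_dropped_series"` attribute); missing
#' values elsewhere propagate as missing fold changes at that time only.
#'
#' @param x a [quant_table()].
#' @param baseline_time time (minutes) used as reference, default 0.
#' @return a [quant_table()] of fold changes (same layout; baseline columns
#'   become 0 where observed).
#' @export
fold_changes <- function(x, baseline_time = 0) {
  stopifnot(inherits(x, "quant_table"))
  s <- x$samples
  if (!baseline_time %in% s$time_min)
    stop("baseline time ", baseline_time, " not present")
  v <- x$values
  dropped <- 0L
  for (cond in unique(s$condition)) {
    for (rep in unique(s$replicate[s$condition == cond])) {
      cols <- which(s$condition == cond & s$replicate == rep)
      base_col <- cols[s$time_min[cols] == baseline_time]
      if (length(base_col) != 1L)
        stop("replicate ", rep, " in ", cond, " lacks a unique baseline sample")
      base <- v[, base_col]
      miss <- is.na(base)
      dropped <- dropped + sum(miss)
      v[, cols] <- v[, cols, drop = FALSE] - base   # NA base -> NA series
    }
  }
  x$values <- v
  attr(x, "n_dropped_series") <- dropped
  x
}

#' Interaction test of phosphosite vs protein fold-change slopes
#'
#' Pools the replicate-level fold-change points of the two layers and fits
#' the multiple linear regression
#' `delta ~ layer + time + layer:time`
#' with layer a categorical variable (protein vs phosphosite) and time
#' continuous (minutes). The interaction coefficient b3 is the difference in
#' slope (log2 units per minute) between the phosphosite and its protein; its
#' two-sided t-test p-value is returned. A phosphosite whose change merely
#' mirrors protein abundance has b3 ~ 0.
#'
#' @param protein_delta,phospho_delta data.frames with columns `time` and
#'   `delta` (one row per replicate-level fold-change point; NA deltas are
#'   dropped).
#' @return list with `estimate` (b3), `p_value`, `n_points`; NULL-like result
#'   (`estimate = NA`) when fewer than 3 distinct time points have data in
#'   either layer.
#' @export
covariation_test <- function(protein_delta, phospho_delta) {
  clean <- function(d) d[!is.na(d$delta) & !is.na(d$time), , drop = FALSE]
  pr <- clean(protein_delta); ph <- clean(phospho_delta)
  if (length(unique(pr$time)) < 3L || length(unique(ph$time)) < 3L)
    return(list(estimate = NA_real_, p_value = NA_real_,
                n_points = nrow(pr) + nrow(ph)))
  dat <- rbind(data.frame(delta = pr$delta, time = pr$time, layer = 0),
               data.frame(delta = ph$delta, time = ph$time, layer = 1))
  fit <- stats::lm(delta ~ layer * time, data = dat)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  if (!"layer:time" %in% rownames(cf))
    return(list(estimate = NA_real_, p_value = NA_real_, n_points = nrow(dat)))
  b3 <- unname(cf["layer:time", "Estimate"])
  p <- unname(cf["layer:time", "Pr(>|t|)"])
  if (!is.finite(p)) {
    # perfect (zero-residual) fit: the slope difference is exact
    p <- if (abs(b3) < 1e-12) 1 else 0
  }
  list(estimate = b3, p_value = p, n_points = nrow(dat))
}

#' Label phosphosites as co-varying with or independent of protein levels
#'
#' Interaction p-values over the tested set are BH-adjusted; adjusted p above
#' `alpha` means the site's slope is indistinguishable from the protein's
#' (`covarying`), at or below `alpha` the site changes independently
#' (`independent`). A site whose protein shows no significant change is
#' labelled `independent_no_protein_change` regardless of the test, and a
#' site without protein data `no_protein_data`.
#'
#' Two "% independent" summaries are reported: `pct_independent` uses all
#' significant sites with any protein information (independent +
#' independent_no_protein_change over that denominator), and
#' `pct_independent_tested` restricts the denominator to sites whose protein
#' changed significantly (the tested set).
#'
#' @param results data.frame with feature_id, estimate, p_value (from
#'   [covariation_test()]), and logical `protein_significant` (NA when the
#'   protein was not quantified).
#' @param alpha threshold on the BH-adjusted interaction p (default 0.05).
#' @return list with `results` (labelled data.frame with adj_p_value and
#'   label) and `summary` (counts and the two percentages; NA when a
#'   denominator is empty).
#' @export
classify_covariation <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  res <- results
  lab <- rep(NA_character_, nrow(res))
  adj <- rep(NA_real_, nrow(res))
  no_data <- is.na(res$protein_significant) | is.na(res$p_value)
  not_changing <- !is.na(res$protein_significant) & !res$protein_significant
  tested <- !no_data & !not_changing
  adj[tested] <- bh_adjust(res$p_value[tested])
  lab[tested] <- ifelse(adj[tested] <= alpha, "independent", "covarying")
  lab[not_changing] <- "independent_no_protein_change"
  lab[no_data & !not_changing] <- "no_protein_data"
  res$adj_p_value <- adj
  res$label <- factor(lab, levels = c("covarying", "independent",
                                      "independent_no_protein_change",
                                      "no_protein_data"))
  n <- table(res$label)
  with_info <- sum(n[c("covarying", "independent",
                       "independent_no_protein_change")])
  indep <- sum(n[c("independent", "independent_no_protein_change")])
  pct <- if (with_info > 0) 100 * indep / with_info else NA_real_
  n_tested <- sum(n[c("covarying", "independent")])
  pct_tested <- if (n_tested > 0) 100 * n["independent"] / n_tested else NA_real_
  list(results = res,
       summary = list(n = as.list(n),
                      pct_independent = unname(pct),
                      pct_independent_tested = unname(pct_tested)))
}

#' Run the covariation analysis for a set of significant sites
#'
#' For each listed phosphosite with protein-level data, builds per-replicate
#' fold-change series in both layers (optionally baseline-condition
#' corrected: mating deltas minus matched control deltas) and applies
#' [covariation_test()] and [classify_covariation()].
#'
#' @param phospho,proteome [quant_table()]s sharing the sample design.
#' @param site_ids phosphosite feature_ids to test (the significant set).
#' @param protein_calls data.frame with `protein_id` and logical
#'   `significant` (protein-level change calls).
#' @param condition condition whose fold changes are analyzed.
#' @param baseline_condition optional condition whose matched deltas are
#'   subtracted first (the starvation correction).
#' @param alpha threshold passed to [classify_covariation()].
#' @param baseline_time reference time for [fold_changes()].
#' @return the [classify_covariation()] result.
#' @export
covariation_analysis <- function(phospho, proteome, site_ids, protein_calls,
                                 condition, baseline_condition = NULL,
                                 alpha = 0.05, baseline_time = 0) {
  ph_fc <- fold_changes(phospho, baseline_time)
  pr_fc <- fold_changes(proteome, baseline_time)
  delta_series <- function(fc, id, cond) {
    i <- match(id, fc$features$feature_id)
    cols <- which(fc$samples$condition == cond)
    data.frame(time = fc$samples$time_min[cols],
               replicate = fc$samples$replicate[cols],
               delta = fc$values[i, cols])
  }
  corrected <- function(fc, id) {
    d <- delta_series(fc, id, condition)
    if (is.null(baseline_condition)) return(d[, c("time", "delta")])
    b <- delta_series(fc, id, baseline_condition)
    key <- paste(b$time, b$replicate)
    d$delta <- d$delta - b$delta[match(paste(d$time, d$replicate), key)]
    d[, c("time", "delta")]
  }
  empty <- data.frame(feature_id = character(0), protein_id = character(0),
                      estimate = numeric(0), p_value = numeric(0),
                      protein_significant = logical(0))
  rows <- lapply(site_ids, function(id) {
    i <- match(id, phospho$features$feature_id)
    pid <- phospho$features$protein_id[i]
    j <- match(pid, proteome$features$feature_id)
    psig <- protein_calls$significant[match(pid, protein_calls$protein_id)]
    if (length(psig) == 0L) psig <- NA
    if (is.na(j)) psig <- NA              # protein never quantified
    out <- data.frame(feature_id = id, protein_id = pid,
                      estimate = NA_real_, p_value = NA_real_,
                      protein_significant = psig)
    # the regression is only run for sites whose protein changed significantly
    if (isTRUE(psig)) {
      tst <- covariation_test(corrected(pr_fc, pid), corrected(ph_fc, id))
      out$estimate <- tst$estimate
      out$p_value <- tst$p_value
    }
    out
  })
  classify_covariation(do.call(rbind, c(list(empty), rows)), alpha = alpha)
}
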