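#' Run the full time-course analysis pipeline
#'
#' Composes the stages in analysis order: per-replicate median centering,
#' missing-value filtering (no more than one lost replicate: 10 of 30 values
#' in the mating design, 5 of 15 in the fusion design), collapse of
#' bit-identical redundant sites, moderated linear model with the preset's
#' contrast sets, BH adjustment, a-posteriori re-expansion of duplicates,
#' significance-class labels, monotone profile clustering, and -- when a
#' proteome table is supplied -- the phosphosite-protein covariation
#' analysis.
#'
#' The `mating` preset fits two contrast sets: the control stepwise set
#' (starvation response) and the starvation-corrected difference-of-
#' differences set (mating response), both at BH `alpha`. The `fusion`
#' preset fits the single stepwise set at the stricter default `alpha`
#' (0.001, reflecting the 4-replicate design).
#'
#' @param phospho a phosphoproteome [quant_table()].
#' @param proteome optional proteome [quant_table()] on the same design.
#' @param preset `"mating"` or `"fusion"`.
#' @param alpha BH threshold for the (corrected) response; defaults to 0.05
#'   for mating, 0.001 for fusion.
#' @param alpha_starvation BH threshold for the control stepwise set
#'   (mating preset only).
#' @param normalize run [median_center_by_replicate()] first (set FALSE for
#'   already-centered input).
#' @return object of class `phos_pipeline`: per-site `stats` (expanded to the
#'   original feature set, with class and cluster labels), the underlying
#'   fits, the redundancy map, the covariation results, and `summary` counts.
#' @export
run_pipeline <- function(phospho, proteome = NULL,
                         preset = c("mating", "fusion"),
                         alpha = NULL, alpha_starvation = 0.05,
                         normalize = TRUE) {
  preset <- match.arg(preset)
  if (is.null(alpha)) alpha <- if (preset == "mating") 0.05 else 0.001
  conds <- unique(phospho$samples$condition)
  if (preset == "mating" && length(conds) != 2L)
    stop("mating preset expects 2 conditions, got: ",
         paste(conds, collapse = ", "))
  if (preset == "fusion" && length(conds) != 1L)
    stop("fusion preset expects a single condition")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  # degenerate noiseless input: fall back to the unmoderated fit (no feature
  # can be called significant without an error variance estimate)
  fit_maybe_moderated <- function(tab, design, C) {
    tryCatch(phos_fit(tab, design, C),
             error = function(e) {
               if (grepl("noiseless", conditionMessage(e)))
                 phos_fit(tab, design, C, moderate = FALSE)
               else stop(e)
             })
  }

  if (normalize) {
    phospho <- stage("normalize", median_center_by_replicate(phospho))
    if (!is.null(proteome))
      proteome <- stage("normalize", median_center_by_replicate(proteome))
  }
  n_input <- nrow(phospho$values)
  phospho <- stage("filter", filter_missing(phospho, preset))
  n_filtered <- nrow(phospho$values)
  col <- stage("collapse", collapse_redundant(phospho))
  tab <- col$table
  n_collapsed <- nrow(tab$values)

  design <- design_spec(tab)
  if (preset == "mating") {
    base_cond <- conds[conds != "mating"]
    mate_cond <- conds[conds == "mating"]
    if (length(mate_cond) == 0L) { base_cond <- conds[1L]; mate_cond <- conds[2L] }
    C_starv <- stepwise_contrasts(design, base_cond, prefix = "Ctrl")
    C_diff <- stepwise_contrasts(design, mate_cond, baseline = base_cond)
    fit_starv <- stage("fit", fit_maybe_moderated(tab, design, C_starv))
    fit_mate <- stage("fit", fit_maybe_moderated(tab, design, C_diff))
    stats_starv <- expand_redundant(as_site_stats(fit_starv), col$map)
    stats_mate <- expand_redundant(as_site_stats(fit_mate), col$map)
    classes <- stage("classify",
                     classify_sites(stats_mate, stats_starv,
                                    alpha_mating = alpha,
                                    alpha_starvation = alpha_starvation))
    prof <- mean_profiles(fit_mate, mate_cond, baseline = base_cond)
  } else {
    C_diff <- stepwise_contrasts(design, conds, prefix = "Diff")
    fit_mate <- stage("fit", fit_maybe_moderated(tab, design, C_diff))
    fit_starv <- NULL
    stats_starv <- NULL
    stats_mate <- expand_redundant(as_site_stats(fit_mate), col$map)
    sig <- !is.na(stats_mate$adj_p_value) & stats_mate$adj_p_value <= alpha
    classes <- data.frame(
      feature_id = stats_mate$feature_id,
      class = factor(ifelse(sig, "fusion_significant", "ns"),
                     levels = c("ns", "fusion_significant")),
      stringsAsFactors = FALSE)
    prof <- mean_profiles(fit_mate, conds)
  }

  # expand profiles to duplicates for clustering
  stats <- merge(stats_mate, classes, by = "feature_id", sort = FALSE)
  rep_of <- stats$feature_id
  rep_of[!is.na(stats$redundant_with)] <-
    stats$redundant_with[!is.na(stats$redundant_with)]
  prof_all <- prof[match(rep_of, rownames(prof)), , drop = FALSE]
  sig_idx <- which(stats$class != "ns")
  stats$cluster <- NA_character_
  if (length(sig_idx)) {
    k <- if (preset == "mating") 2L else 3L
    cl <- stage("cluster",
                cluster_profiles(prof_all[sig_idx, , drop = FALSE], k = k))
    stats$cluster[sig_idx] <- as.character(cl)
  }

  covar <- NULL
  if (!is.null(proteome)) {
    proteome_f <- stage("filter", filter_missing(proteome, preset))
    pdesign <- design_spec(proteome_f)
    if (preset == "mating") {
      pfit_s <- stage("fit", phos_fit(proteome_f, pdesign,
                                      stepwise_contrasts(pdesign, base_cond,
                                                         prefix = "Ctrl")))
      pfit_m <- stage("fit", phos_fit(proteome_f, pdesign,
                                      stepwise_contrasts(pdesign, mate_cond,
                                                         baseline = base_cond)))
      psig <- (!is.na(pfit_s$adj_p_value) & pfit_s$adj_p_value <= 0.05) |
        (!is.na(pfit_m$adj_p_value) & pfit_m$adj_p_value <= 0.05)
      pcalls <- data.frame(protein_id = pfit_s$feature_id, significant = psig)
      sig_sites <- stats$feature_id[stats$class %in%
                                      c("mating_specific", "both_different")]
      covar <- stage("covariation",
                     covariation_analysis(phospho, proteome_f, sig_sites,
                                          pcalls, condition = mate_cond,
                                          baseline_condition = base_cond))
    } else {
      pfit <- stage("fit", phos_fit(proteome_f, pdesign,
                                    stepwise_contrasts(pdesign, conds,
                                                       prefix = "Diff")))
      psig <- !is.na(pfit$adj_p_value) & pfit$adj_p_value <= 0.05
      pcalls <- data.frame(protein_id = pfit$feature_id, significant = psig)
      sig_sites <- stats$feature_id[stats$class == "fusion_significant"]
      covar <- stage("covariation",
                     covariation_analysis(phospho, proteome_f, sig_sites,
                                          pcalls, condition = conds))
    }
  }

  counts <- as.list(table(stats$class))
  summary <- list(preset = preset, alpha = alpha,
                  n_input = n_input, n_filtered = n_filtered,
                  n_collapsed = n_collapsed,
                  n_duplicates = n_filtered - n_collapsed,
                  class_counts = counts,
                  n_significant = sum(stats$class != "ns"),
                  pct_independent =
                    if (!is.null(covar)) covar$summary$pct_independent else NA_real_)
  structure(list(stats = stats, classes = classes,
                 fit_response = fit_mate, fit_control = fit_starv,
                 control_stats = stats_starv,
                 redundancy_map = col$map, covariation = covar,
                 profiles = prof, summary = summary,
                 alpha = alpha, preset = preset),
            class = "phos_pipeline")
}

#' @export
print.phos_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf("phos_pipeline (%s preset, BH alpha %.3g)\n", s$preset, s$alpha))
  cat(sprintf("  %d sites -> %d after missing-value filter -> %d tested (%d duplicates re-added)\n",
              s$n_input, s$n_filtered, s$n_collapsed, s$n_duplicates))
  cc <- s$class_counts
  cat("  classes:", paste(sprintf("%s %d", names(cc), unlist(cc)),
                          collapse = ", "), "\n")
  if (!is.na(s$pct_independent))
    cat(sprintf("  %% independent of protein levels: %.1f\n", s$pct_independent))
  invisible(x)
}

#' @export
summary.phos_pipeline <- function(object, ...) object$summary
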