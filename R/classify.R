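#' Classify phosphosites by starvation and mating significance
#'
#' Sites significant on the starvation-corrected (Diff) contrast set are split
#' into those changing only in the presence of a mating partner
#' (`mating_specific`) and those that also change significantly upon
#' starvation but differently with a partner (`both_different`). Sites
#' significant only on the control stepwise contrasts are `starvation_only`;
#' the rest are `ns`.
#'
#' @param mating_stats,starvation_stats data.frames with `feature_id` and
#'   `adj_p_value`, on the same (expanded) feature universe.
#' @param alpha_mating,alpha_starvation BH significance thresholds
#'   (study values: 0.05 for both in the mating design).
#' @return data.frame feature_id + class factor with levels ns,
#'   starvation_only, mating_specific, both_different.
#' @export
classify_sites <- function(mating_stats, starvation_stats,
                           alpha_mating = 0.05, alpha_starvation = 0.05) {
  if (!setequal(mating_stats$feature_id, starvation_stats$feature_id))
    stop("mating and starvation statistics cover different feature sets")
  st <- starvation_stats$adj_p_value[
    match(mating_stats$feature_id, starvation_stats$feature_id)]
  mat_sig <- !is.na(mating_stats$adj_p_value) &
    mating_stats$adj_p_value <= alpha_mating
  stv_sig <- !is.na(st) & st <= alpha_starvation
  cls <- ifelse(mat_sig & stv_sig, "both_different",
         ifelse(mat_sig, "mating_specific",
         ifelse(stv_sig, "starvation_only", "ns")))
  data.frame(feature_id = mating_stats$feature_id,
             class = factor(cls, levels = c("ns", "starvation_only",
                                            "mating_specific",
                                            "both_different")),
             stringsAsFactors = FALSE)
}

#' Monotone profile clustering
#'
#' Groups significant sites by the shape of their (starvation-corrected) mean
#' profile. With `k = 2`, the sign of the net change (last minus first time
#' point) splits sites into increasing and decreasing clusters. With `k = 3`
#' the increasing sites are further split by timing: `early_increase` when at
#' least half the net increase is reached by the second time point,
#' `late_increase` otherwise. A net change of exactly zero is assigned to
#' "increase" (ties are logged via the `"n_ties"` attribute).
#'
#' @param profiles features x timepoints matrix of replicate-averaged
#'   (corrected) mean profiles, columns in time order.
#' @param k 2 or 3.
#' @return factor of cluster labels, one per row of `profiles`.
#' @export
cluster_profiles <- function(profiles, k = 2L) {
  profiles <- as.matrix(profiles)
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  if (ncol(profiles) < 2L) stop("profiles need >= 2 time points")
  first <- profiles[, 1L]
  last <- profiles[, ncol(profiles)]
  net <- last - first
  ties <- sum(net == 0, na.rm = TRUE)
  if (k == 2L) {
    lab <- ifelse(net >= 0, "increase", "decrease")
    out <- factor(lab, levels = c("increase", "decrease"))
  } else {
    second <- profiles[, 2L]
    early <- (second - first) >= net / 2
    lab <- ifelse(net < 0, "decrease",
                  ifelse(early, "early_increase", "late_increase"))
    out <- factor(lab, levels = c("early_increase", "late_increase",
                                  "decrease"))
  }
  attr(out, "n_ties") <- ties
  out
}

#' Replicate-averaged (optionally baseline-corrected) mean profiles
#'
#' Per-feature mean value at each time point of `condition`; when `baseline`
#' is given, the matched baseline-condition means are subtracted time point by
#' time point (the starvation-corrected profile).
#'
#' @param fit a [phos_fit()].
#' @param condition condition to profile.
#' @param baseline optional condition to subtract.
#' @return features x timepoints matrix; columns named by time.
#' @export
mean_profiles <- function(fit, condition, baseline = NULL) {
  stopifnot(inherits(fit, "phos_fit"))
  cells <- fit$design$cells
  times <- sort(unique(cells$time_min[cells$condition == condition]))
  sel <- function(cond) {
    vapply(times, function(t)
      which(cells$condition == cond & cells$time_min == t), 1L)
  }
  prof <- fit$cell_means[, sel(condition), drop = FALSE]
  if (!is.null(baseline)) prof <- prof - fit$cell_means[, sel(baseline), drop = FALSE]
  colnames(prof) <- as.character(times)
  prof
}
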