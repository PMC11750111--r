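#' Design specification from sample keys
#'
#' Builds the group-means design used by [phos_fit()]: one coefficient (cell)
#' per (condition, time) combination, with every sample assigned to exactly
#' one cell. Replicate is deliberately not a model term -- per-replicate
#' median centering has already removed additive replicate effects, and a
#' replicate term would be collinear at the per-feature level.
#'
#' @param samples sample-key data.frame (condition, time_min, replicate) or a
#'   [quant_table()].
#' @return object of class `design_spec`: cell labels, per-sample cell index,
#'   and the (condition, time) layout.
#' @export
design_spec <- function(samples) {
  if (inherits(samples, "quant_table")) samples <- samples$samples
  cells <- unique(samples[, c("condition", "time_min")])
  cells <- cells[order(cells$condition, cells$time_min), , drop = FALSE]
  rownames(cells) <- NULL
  cell_label <- function(cond, t) sprintf("%s.%smin", cond, t)
  labels <- cell_label(cells$condition, cells$time_min)
  assign <- match(cell_label(samples$condition, samples$time_min), labels)
  if (anyNA(assign)) stop("sample not assignable to a design cell")
  structure(list(cells = cells, labels = labels, assign = assign,
                 samples = samples),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec:", length(x$labels), "cells,",
      nrow(x$samples), "samples\n")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Stepwise and difference-of-differences contrast sets
#'
#' `stepwise_contrasts()` builds consecutive-time-point differences within one
#' condition (e.g. `Ctrl_45-0 = Ctrl.45min - Ctrl.0min`). With a `baseline`
#' condition it builds the starvation-corrected difference-of-differences set,
#' e.g. `Diff_45-0 = (Mating.45min - Mating.0min) - (Ctrl.45min - Ctrl.0min)`,
#' which cancels any change shared with the partner-free starvation control
#' and isolates pheromone-driven signal.
#'
#' @param design a [design_spec()].
#' @param condition condition whose time course is differenced.
#' @param baseline optional condition whose matched stepwise differences are
#'   subtracted.
#' @param prefix name prefix for the contrasts (default `"Diff"` when a
#'   baseline is given, else the condition name).
#' @return matrix (cells x contrasts); every column sums to zero.
#' @export
stepwise_contrasts <- function(design, condition, baseline = NULL,
                               prefix = NULL) {
  stopifnot(inherits(design, "design_spec"))
  cells <- design$cells
  times <- sort(unique(cells$time_min[cells$condition == condition]))
  if (length(times) < 2L) stop("condition ", condition, " has < 2 time points")
  if (is.null(prefix)) prefix <- if (is.null(baseline)) condition else "Diff"
  k <- length(times) - 1L
  C <- matrix(0, nrow = length(design$labels), ncol = k,
              dimnames = list(design$labels,
                              sprintf("%s_%s-%s", prefix, times[-1L],
                                      times[-length(times)])))
  idx <- function(cond, t) {
    i <- which(cells$condition == cond & cells$time_min == t)
    if (length(i) != 1L) stop("design cell not found: ", cond, " ", t, "min")
    i
  }
  for (j in seq_len(k)) {
    C[idx(condition, times[j + 1L]), j] <- C[idx(condition, times[j + 1L]), j] + 1
    C[idx(condition, times[j]), j] <- C[idx(condition, times[j]), j] - 1
    if (!is.null(baseline)) {
      C[idx(baseline, times[j + 1L]), j] <- C[idx(baseline, times[j + 1L]), j] - 1
      C[idx(baseline, times[j]), j] <- C[idx(baseline, times[j]), j] + 1
    }
  }
  C
}

#' Moderated per-feature linear model
#'
#' The package's central fitting function. For every feature it estimates the
#' (condition, time) cell means by least squares on the available samples,
#' applies a contrast matrix, shrinks the per-feature residual variances
#' towards a common prior by empirical Bayes, and tests each feature with a
#' joint moderated F statistic across its contrast set (accounting for the
#' correlation between contrast estimates). One Benjamini-Hochberg adjusted
#' p-value per feature is reported.
#'
#' Features with zero residual degrees of freedom are flagged and excluded
#' from moderation and testing. A feature missing an entire design cell is
#' excluded only from the contrasts touching that cell; its F statistic is
#' computed over the remaining contrasts (the effective number is recorded in
#' `df1`).
#'
#' @param x a normalized [quant_table()].
#' @param design a [design_spec()]; defaults to one derived from `x`.
#' @param contrasts cells x contrasts matrix, e.g. from
#'   [stepwise_contrasts()]. Each column must sum to zero.
#' @param moderate logical; `FALSE` skips empirical-Bayes shrinkage and uses
#'   the raw per-feature variances (ordinary F).
#' @return object of class `phos_fit` with components `coefficients`
#'   (features x contrasts), `cell_means`, `cell_n`, `sigma2`, `df_residual`,
#'   `moderation` (d0, s02), `s2_post`, `F`, `df1`, `df2`, `p_value`,
#'   `adj_p_value`, `t` (per-contrast moderated t), and the inputs.
#' @export
phos_fit <- function(x, design = design_spec(x), contrasts, moderate = TRUE) {
  stopifnot(inherits(x, "quant_table"), inherits(design, "design_spec"))
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != length(design$labels))
    stop("contrast matrix rows must match design cells")
  if (any(abs(colSums(contrasts)) > 1e-8))
    stop("contrast columns must sum to zero")
  v <- x$values
  G <- length(design$labels)
  nfeat <- nrow(v)

  # per-cell means and counts, vectorized over features
  means <- matrix(NA_real_, nfeat, G, dimnames = list(rownames(v), design$labels))
  counts <- matrix(0L, nfeat, G, dimnames = dimnames(means))
  rss <- numeric(nfeat)
  for (g in seq_len(G)) {
    cols <- which(design$assign == g)
    block <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(block))
    m <- rowMeans(block, na.rm = TRUE)
    m[n == 0L] <- NA_real_
    means[, g] <- m
    counts[, g] <- n
    resid2 <- (block - m)^2
    rss <- rss + rowSums(resid2, na.rm = TRUE)
  }
  n_obs <- rowSums(counts)
  cells_obs <- rowSums(counts > 0L)
  df <- n_obs - cells_obs
  sigma2 <- ifelse(df > 0, rss / df, NA_real_)

  if (moderate) {
    ok <- df > 0 & !is.na(sigma2) & sigma2 > 0
    if (sum(ok) < 10L) {
      if (all(sigma2[df > 0] == 0, na.rm = TRUE))
        stop("all residual variances are zero; input looks noiseless")
      stop("too few features with positive residual variance for moderation")
    }
    mod <- squeeze_var(sigma2[ok], df[ok])
    d0 <- mod$df_prior; s02 <- mod$var_prior
    s2_post <- ifelse(df > 0,
                      if (is.finite(d0)) (d0 * s02 + df * sigma2) / (d0 + df)
                      else rep(s02, nfeat),
                      NA_real_)
  } else {
    d0 <- 0; s02 <- NA_real_
    s2_post <- sigma2
  }
  df_total <- ifelse(df > 0, d0 + df, NA_real_)

  k <- ncol(contrasts)
  means0 <- means
  means0[is.na(means0)] <- 0
  est <- means0 %*% contrasts          # NA-ed below where a touched cell is empty
  # per-contrast unscaled variance and moderated t
  var_u <- matrix(NA_real_, nfeat, k, dimnames = dimnames(est))
  for (j in seq_len(k)) {
    w <- contrasts[, j]
    nz <- which(w != 0)
    cc <- counts[, nz, drop = FALSE]
    ok_j <- rowSums(cc == 0L) == 0L
    vu <- rowSums(sweep(1 / pmax(cc, 1L), 2L, w[nz]^2, `*`))
    var_u[ok_j, j] <- vu[ok_j]
    est[!ok_j, j] <- NA_real_
  }
  tstat <- est / sqrt(var_u * s2_post)

  # joint moderated F with contrast covariance C' diag(1/n) C
  Fstat <- rep(NA_real_, nfeat); df1 <- rep(NA_real_, nfeat)
  pval <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    if (is.na(df_total[i]) || is.na(s2_post[i]) || s2_post[i] <= 0) next
    use <- which(!is.na(est[i, ]))
    if (length(use) == 0L) next
    Cu <- contrasts[, use, drop = FALSE]
    ninv <- ifelse(counts[i, ] > 0L, 1 / counts[i, ], 0)
    V <- crossprod(Cu, Cu * ninv)      # C' diag(1/n) C
    e <- est[i, use]
    ev <- eigen(V, symmetric = TRUE)
    r <- sum(ev$values > max(ev$values) * 1e-10)
    if (r == 0L) next
    # quadratic form with the Moore-Penrose inverse of the contrast covariance
    proj <- crossprod(ev$vectors[, seq_len(r), drop = FALSE], e)
    quad <- sum(proj^2 / ev$values[seq_len(r)])
    Fstat[i] <- quad / (r * s2_post[i])
    df1[i] <- r
    pval[i] <- stats::pf(Fstat[i], r, df_total[i], lower.tail = FALSE)
  }
  structure(list(coefficients = est, t = tstat, var_unscaled = var_u,
                 cell_means = means, cell_n = counts,
                 sigma2 = sigma2, df_residual = df,
                 moderation = list(df_prior = d0, var_prior = s02,
                                   moderated = moderate),
                 s2_post = s2_post, F = Fstat, df1 = df1, df2 = df_total,
                 p_value = pval, adj_p_value = bh_adjust(pval),
                 contrasts = contrasts, design = design,
                 feature_id = x$features$feature_id, features = x$features),
            class = "phos_fit")
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Moment-matching estimator of the prior degrees of freedom d0 and prior
#' variance s0^2 under the standard hierarchical model where per-feature
#' variances follow a scaled inverse chi-square prior, fitted on the log
#' sample variances via digamma/trigamma matching to a scaled F distribution.
#' d0 may be estimated infinite (variances essentially common), in which case
#' every posterior variance equals s0^2.
#'
#' @param sigma2 per-feature residual variances (positive).
#' @param df per-feature residual degrees of freedom.
#' @param df_prior,var_prior optional known prior; when both are supplied the
#'   estimation step is skipped and only the posterior variances are computed.
#' @return list with `df_prior`, `var_prior`, and `var_post`.
#' @export
squeeze_var <- function(sigma2, df, df_prior = NULL, var_prior = NULL) {
  stopifnot(length(sigma2) == length(df) || length(df) == 1L, all(df > 0))
  if (!is.null(df_prior) && !is.null(var_prior)) {
    d0 <- df_prior; s02 <- var_prior
    var_post <- if (is.finite(d0)) (d0 * s02 + df * sigma2) / (d0 + df)
                else rep(s02, length(sigma2))
    return(list(df_prior = d0, var_prior = s02, var_post = var_post))
  }
  if (all(sigma2 == 0)) stop("all variances zero")
  z <- log(sigma2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.finite(d0)) (d0 * s02 + df * sigma2) / (d0 + df)
              else rep(s02, length(sigma2))
  list(df_prior = d0, var_prior = s02, var_post = var_post)
}

# Newton solve of trigamma(y) = x; x > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values; missing entries are allowed and excluded
#' from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.phos_fit <- function(x, ...) {
  cat(sprintf("phos_fit: %d features, %d design cells, %d contrasts\n",
              length(x$feature_id), ncol(x$cell_means), ncol(x$coefficients)))
  if (isTRUE(x$moderation$moderated))
    cat(sprintf("  empirical Bayes: d0 = %.3g, s0^2 = %.4g\n",
                x$moderation$df_prior, x$moderation$var_prior))
  cat(sprintf("  significant at BH 0.05: %d\n",
              sum(x$adj_p_value <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.phos_fit <- function(object, ...) object$coefficients

#' @export
fitted.phos_fit <- function(object, ...) {
  object$cell_means[, object$design$assign, drop = FALSE]
}

#' @export
residuals.phos_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) stop("supply the quant_table the model was fitted to")
  x$values - fitted(object)
}

#' @export
summary.phos_fit <- function(object, alpha = 0.05, ...) {
  out <- as_site_stats(object)
  structure(list(stats = out, alpha = alpha,
                 n_significant = sum(out$adj_p_value <= alpha, na.rm = TRUE),
                 moderation = object$moderation),
            class = "summary.phos_fit")
}

#' @export
print.summary.phos_fit <- function(x, ...) {
  cat(sprintf("moderated model over %d features; %d significant at BH %.3g\n",
              nrow(x$stats), x$n_significant, x$alpha))
  ord <- order(x$stats$p_value)
  print(utils::head(x$stats[ord, c("feature_id", "F", "p_value", "adj_p_value")],
                    10L), row.names = FALSE)
  invisible(x)
}

#' @export
plot.phos_fit <- function(x, which = c("variances", "pvalues"), ...) {
  which <- match.arg(which)
  if (which == "variances") {
    ok <- x$df_residual > 0
    graphics::plot(sqrt(x$sigma2[ok]), sqrt(x$s2_post[ok]),
                   xlab = "residual SD", ylab = "moderated SD",
                   main = "empirical-Bayes variance shrinkage", ...)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(h = sqrt(x$moderation$var_prior), col = 2, lty = 3)
  } else {
    graphics::hist(x$p_value, breaks = 50, main = "moderated F p-values",
                   xlab = "p", ...)
  }
  invisible(x)
}

#' Per-site statistics table from a fit
#'
#' @param fit a [phos_fit()].
#' @return data.frame with feature_id, contrast estimates, F, df, raw and
#'   BH-adjusted p-values.
#' @export
as_site_stats <- function(fit) {
  stopifnot(inherits(fit, "phos_fit"))
  est <- as.data.frame(fit$coefficients)
  names(est) <- colnames(fit$coefficients)
  cbind(data.frame(feature_id = fit$feature_id, stringsAsFactors = FALSE),
        est,
        data.frame(sigma2 = fit$sigma2, df_residual = fit$df_residual,
                   s2_post = fit$s2_post, F = fit$F, df1 = fit$df1,
                   df2 = fit$df2, p_value = fit$p_value,
                   adj_p_value = fit$adj_p_value))
}
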