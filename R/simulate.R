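#' Simulation configuration
#'
#' Parameters of the synthetic (proteome, phosphoproteome, truth) generator.
#' Defaults emulate the mating time-course design: 3 biological replicates x
#' 2 conditions (partner-free starvation control vs mating mixture) x 5 time
#' points at 45-minute intervals, TMT-like log2 replicate noise, per
#' feature-x-replicate batch offsets (each replicate is a separate multiplex
#' run), and planted effect classes. Effect profiles are monotone
#' piecewise-linear in time: per-interval log2 increments are drawn as
#' half-normals of scale `effect_size_sd` with a random common sign, so a
#' non-null site accumulates on the order of 3 log2 units over 4 intervals at
#' the default scale.
#'
#' @param n_sites number of phosphosites.
#' @param n_proteins number of proteins; default `ceiling(n_sites /
#'   sites_per_protein)`.
#' @param sites_per_protein expected phosphosites per protein.
#' @param replicates number of biological replicates.
#' @param timepoints time points in minutes.
#' @param conditions condition labels; the last one is the
#'   "mating-specific" condition (the one where mating_specific effects
#'   appear). A single condition gives the fusion-style design.
#' @param class_proportions named fractions over null, starvation_only,
#'   mating_specific, both_different; must sum to 1.
#' @param effect_size_sd scale (log2 units) of per-interval profile
#'   increments.
#' @param noise_sd measurement noise SD (log2 units).
#' @param batch_sd SD of per feature-x-replicate additive offsets.
#' @param missing_rate MCAR missing fraction.
#' @param replicate_dropout_rate fraction of features losing one whole
#'   replicate (all its samples) -- exercises the missing-value filter at its
#'   boundary, since one replicate is exactly 10 of 30 values in the mating
#'   design.
#' @param coupled_fraction fraction of phosphosites whose values additionally
#'   track their protein's abundance profile.
#' @param redundancy_rate fraction of sites duplicated into bit-identical
#'   rows (multi-phosphorylation ambiguity).
#' @param n_kinase_sets number of planted kinase substrate sets.
#' @param substrate_enrichment_odds odds multiplier for substrate membership
#'   among mating_specific sites (background membership probability 0.05).
#' @param window_motif optional list(class=, offset=, residue=, prob=) biasing
#'   sequence windows of one class at one position, see [simulate_windows()].
#' @param seed integer seed driving a hierarchical generator: independent
#'   sub-streams for structure, values, missingness and windows.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L,
                       n_proteins = NULL,
                       sites_per_protein = 3,
                       replicates = 3L,
                       timepoints = c(0, 45, 90, 135, 180),
                       conditions = c("control", "mating"),
                       class_proportions = c(null = 0.70,
                                             starvation_only = 0.22,
                                             mating_specific = 0.04,
                                             both_different = 0.04),
                       effect_size_sd = 1.0,
                       noise_sd = 0.25,
                       batch_sd = 0.5,
                       missing_rate = 0.05,
                       replicate_dropout_rate = 0.05,
                       coupled_fraction = 0.2,
                       redundancy_rate = 0.02,
                       n_kinase_sets = 3L,
                       substrate_enrichment_odds = 5,
                       window_motif = NULL,
                       seed = 1L) {
  if (is.null(n_proteins)) n_proteins <- ceiling(n_sites / sites_per_protein)
  cfg <- list(n_sites = as.integer(n_sites), n_proteins = as.integer(n_proteins),
              sites_per_protein = sites_per_protein,
              replicates = as.integer(replicates),
              timepoints = sort(unique(timepoints)), conditions = conditions,
              class_proportions = class_proportions,
              effect_size_sd = effect_size_sd, noise_sd = noise_sd,
              batch_sd = batch_sd, missing_rate = missing_rate,
              replicate_dropout_rate = replicate_dropout_rate,
              coupled_fraction = coupled_fraction,
              redundancy_rate = redundancy_rate,
              n_kinase_sets = as.integer(n_kinase_sets),
              substrate_enrichment_odds = substrate_enrichment_odds,
              window_motif = window_motif, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  need <- c("null", "starvation_only", "mating_specific", "both_different")
  if (!setequal(names(cfg$class_proportions), need))
    stop("class_proportions must be named over: ", paste(need, collapse = ", "))
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  rates <- c(cfg$missing_rate, cfg$replicate_dropout_rate,
             cfg$coupled_fraction, cfg$redundancy_rate,
             cfg$class_proportions)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_sites < 1L || cfg$n_proteins < 1L || cfg$replicates < 1L)
    stop("counts must be positive")
  if (length(cfg$timepoints) < 2L) stop("need at least 2 time points")
  if (anyDuplicated(cfg$conditions) || length(cfg$conditions) < 1L ||
      length(cfg$conditions) > 2L)
    stop("conditions must be 1 or 2 distinct labels")
  if (any(c(cfg$noise_sd, cfg$batch_sd, cfg$effect_size_sd) < 0))
    stop("scales must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d sites / %d proteins; %d replicates x ",
                     "%d conditions x %d timepoints; seed %d\n"),
              x$n_sites, x$n_proteins, x$replicates, length(x$conditions),
              length(x$timepoints), x$seed))
  invisible(x)
}

# deterministic sub-seeds so value/missingness/window streams are independent
sub_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# monotone piecewise-linear profile over timepoints: half-normal increments
# with a common random sign; returns a vector starting at 0
monotone_profile <- function(n_steps, scale) {
  s <- sample(c(-1, 1), 1L)
  c(0, cumsum(s * abs(stats::rnorm(n_steps, 0, scale))))
}

# condition x time true-profile matrix for one feature of a given class
class_profile <- function(class, conditions, timepoints, scale) {
  nt <- length(timepoints)
  prof <- matrix(0, nrow = length(conditions), ncol = nt,
                 dimnames = list(conditions, as.character(timepoints)))
  if (class == "null" || scale == 0) return(prof)
  if (length(conditions) == 1L) {
    prof[1L, ] <- monotone_profile(nt - 1L, scale)
    return(prof)
  }
  base_cond <- conditions[1L]; mate_cond <- conditions[2L]
  if (class == "starvation_only") {
    p <- monotone_profile(nt - 1L, scale)
    prof[base_cond, ] <- p
    prof[mate_cond, ] <- p
  } else if (class == "mating_specific") {
    prof[mate_cond, ] <- monotone_profile(nt - 1L, scale)
  } else if (class == "both_different") {
    prof[base_cond, ] <- monotone_profile(nt - 1L, scale)
    prof[mate_cond, ] <- monotone_profile(nt - 1L, scale)
  }
  prof
}

#' Simulate a (proteome, phosphoproteome, truth) triple
#'
#' Generates the two quantitative layers with the statistical structure the
#' downstream analysis assumes: per-site baselines, per feature-x-replicate
#' batch offsets (removed exactly by per-replicate median centering), planted
#' class profiles (null / starvation_only / mating_specific /
#' both_different), phosphosite-protein coupling (coupled sites add their
#' protein's profile), Gaussian measurement noise, MCAR missingness plus
#' whole-replicate dropout, exact-duplicate redundancy groups, and planted
#' kinase substrate sets enriched among mating_specific sites. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `proteome` and `phospho` ([quant_table()]s) and `truth`,
#'   a list holding the per-feature `sites` table (class, coupled,
#'   redundancy_group, residue), `protein_classes`, `kinase_sets`, and
#'   `profiles` (feature x design-cell matrix of true means).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  seeds <- sub_seeds(config$seed)
  tp <- config$timepoints; conds <- config$conditions
  nt <- length(tp); nc <- length(conds); nr <- config$replicates

  samples <- expand.grid(replicate = seq_len(nr), time_min = tp,
                         condition = conds, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "time_min", "replicate")]
  ns <- nrow(samples)
  cell_of <- paste(samples$condition, samples$time_min)

  # --- structure stream: classes, assignments, coupling, kinase sets
  set.seed(seeds[1L])
  prot_ids <- sprintf("prot%04d", seq_len(config$n_proteins))
  prot_class <- sample(names(config$class_proportions), config$n_proteins,
                       replace = TRUE, prob = config$class_proportions)
  site_prot <- sample(prot_ids, config$n_sites, replace = TRUE)
  site_class <- sample(names(config$class_proportions), config$n_sites,
                       replace = TRUE, prob = config$class_proportions)
  coupled <- stats::runif(config$n_sites) < config$coupled_fraction
  residue <- sample(c("S", "T"), config$n_sites, replace = TRUE,
                    prob = c(0.85, 0.15))
  position <- sample.int(800L, config$n_sites, replace = TRUE)
  site_ids <- sprintf("%s_%s%d", site_prot, residue, position)
  site_ids <- make.unique(site_ids, sep = "x")
  p0 <- 0.05; odds0 <- p0 / (1 - p0)
  odds1 <- odds0 * config$substrate_enrichment_odds
  p1 <- odds1 / (1 + odds1)
  kinase_sets <- list()
  if (config$n_kinase_sets > 0L) {
    for (kk in seq_len(config$n_kinase_sets)) {
      pmem <- ifelse(site_class == "mating_specific", p1, p0)
      kinase_sets[[sprintf("kinase%02d", kk)]] <-
        site_ids[stats::runif(config$n_sites) < pmem]
    }
  }

  # --- profile stream
  set.seed(seeds[2L])
  cell_labels <- as.vector(t(outer(conds, tp, paste)))
  prot_profiles <- matrix(0, config$n_proteins, nc * nt,
                          dimnames = list(prot_ids, cell_labels))
  for (i in seq_len(config$n_proteins))
    prot_profiles[i, ] <- as.vector(t(class_profile(
      prot_class[i], conds, tp, config$effect_size_sd)))
  site_profiles <- matrix(0, config$n_sites, nc * nt,
                          dimnames = list(site_ids, cell_labels))
  for (i in seq_len(config$n_sites))
    site_profiles[i, ] <- as.vector(t(class_profile(
      site_class[i], conds, tp, config$effect_size_sd)))
  site_profiles[coupled, ] <- site_profiles[coupled, , drop = FALSE] +
    prot_profiles[match(site_prot, prot_ids)[coupled], , drop = FALSE]

  # --- value stream: baselines, batch offsets, noise
  set.seed(seeds[3L])
  build_values <- function(profiles, n_feat) {
    base <- stats::rnorm(n_feat, 0, 1)
    batch <- matrix(stats::rnorm(n_feat * nr, 0, config$batch_sd), n_feat, nr)
    col_cell <- match(cell_of, paste(rep(conds, each = nt), rep(tp, nc)))
    v <- profiles[, col_cell, drop = FALSE] +
      base +
      batch[, samples$replicate, drop = FALSE] +
      matrix(stats::rnorm(n_feat * ns, 0, config$noise_sd), n_feat, ns)
    v
  }
  prot_values <- build_values(prot_profiles, config$n_proteins)
  site_values <- build_values(site_profiles, config$n_sites)

  # --- missingness stream
  set.seed(seeds[4L])
  add_missing <- function(v) {
    v[matrix(stats::runif(length(v)) < config$missing_rate, nrow(v))] <- NA
    drop <- stats::runif(nrow(v)) < config$replicate_dropout_rate
    which_rep <- sample.int(nr, nrow(v), replace = TRUE)
    for (i in which(drop)) v[i, samples$replicate == which_rep[i]] <- NA
    v
  }
  prot_values <- add_missing(prot_values)
  site_values <- add_missing(site_values)

  # --- redundancy stream: bit-identical duplicate rows
  set.seed(seeds[5L])
  n_dup <- floor(config$redundancy_rate * config$n_sites)
  redundancy_group <- rep(NA_character_, config$n_sites)
  if (n_dup > 0L) {
    dup_of <- sample.int(config$n_sites, n_dup)
    redundancy_group[dup_of] <- sprintf("rgroup%03d", seq_len(n_dup))
    dup_ids <- paste0(site_ids[dup_of], "_alt")
    site_values <- rbind(site_values, site_values[dup_of, , drop = FALSE])
    site_profiles <- rbind(site_profiles, site_profiles[dup_of, , drop = FALSE])
    rownames(site_values) <- rownames(site_profiles) <- c(site_ids, dup_ids)
    sites <- data.frame(
      feature_id = c(site_ids, dup_ids),
      protein_id = c(site_prot, site_prot[dup_of]),
      residue = c(residue, residue[dup_of]),
      position = c(position, position[dup_of]),
      multiplicity = c(rep(1L, config$n_sites), rep(2L, n_dup)),
      class = c(site_class, site_class[dup_of]),
      coupled = c(coupled, coupled[dup_of]),
      redundancy_group = c(redundancy_group,
                           sprintf("rgroup%03d", seq_len(n_dup))),
      stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(feature_id = site_ids, protein_id = site_prot,
                        residue = residue, position = position,
                        multiplicity = 1L, class = site_class,
                        coupled = coupled,
                        redundancy_group = redundancy_group,
                        stringsAsFactors = FALSE)
  }

  phospho <- quant_table(
    site_values,
    features = sites[, c("feature_id", "protein_id", "residue", "position",
                         "multiplicity")],
    samples = samples)
  proteome <- quant_table(
    prot_values,
    features = data.frame(feature_id = prot_ids, protein_id = prot_ids,
                          stringsAsFactors = FALSE),
    samples = samples)
  truth <- list(sites = sites,
                protein_classes = data.frame(protein_id = prot_ids,
                                             class = prot_class,
                                             stringsAsFactors = FALSE),
                kinase_sets = kinase_sets,
                profiles = site_profiles,
                protein_profiles = prot_profiles,
                config = config,
                window_seed = seeds[6L])
  list(proteome = proteome, phospho = phospho, truth = truth)
}

#' Simulate phosphosite sequence windows
#'
#' Draws an 11-residue window per phosphosite in `truth`: the center is the
#' site's phosphoresidue (S or T), flanks are drawn from background residue
#' frequencies (uniform over the 20 amino acids by default). An optional
#' motif spec plants a residue at a fixed offset with a given probability in
#' the windows of one effect class, e.g.
#' `list(class = "mating_specific", offset = 1, residue = "P", prob = 0.8)`.
#'
#' @param truth truth component of [simulate_experiment()].
#' @param alphabet residue alphabet for the flanks.
#' @param motif_spec optional list(class, offset, residue, prob); offset in
#'   -5..+5, offset 0 is rejected (the center is the phosphoresidue).
#' @param seed optional seed; defaults to the window sub-stream of the
#'   generating seed.
#' @return named character vector (feature_id -> window).
#' @export
simulate_windows <- function(truth, alphabet = AMINO_ACIDS, motif_spec = NULL,
                             seed = truth$window_seed) {
  if (!is.null(motif_spec)) {
    if (motif_spec$offset < -5 || motif_spec$offset > 5 || motif_spec$offset == 0)
      stop("motif offset must be in -5..+5 and non-zero")
    if (is.null(motif_spec$prob) || motif_spec$prob < 0 || motif_spec$prob > 1)
      stop("motif prob must be in [0, 1]")
  }
  set.seed(seed)
  sites <- truth$sites
  n <- nrow(sites)
  mat <- matrix(sample(alphabet, n * 11L, replace = TRUE), n, 11L)
  mat[, 6L] <- sites$residue
  if (!is.null(motif_spec)) {
    col <- 6L + motif_spec$offset
    hit <- sites$class == motif_spec$class &
      stats::runif(n) < motif_spec$prob
    mat[hit, col] <- motif_spec$residue
  }
  windows <- apply(mat, 1L, paste, collapse = "")
  names(windows) <- sites$feature_id
  windows
}

#' Write / read the ground-truth site table as TSV
#'
#' @param truth truth component of [simulate_experiment()].
#' @param path output TSV path.
#' @return `path` invisibly (write); truth site data.frame (read).
#' @export
write_truth <- function(truth, path) {
  df <- truth$sites
  df$kinase_sets <- vapply(df$feature_id, function(id)
    paste(names(truth$kinase_sets)[vapply(truth$kinase_sets,
                                          function(s) id %in% s, TRUE)],
          collapse = ","), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
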