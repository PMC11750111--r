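# small in-code fixtures shared across test files

# quant table with explicit values; samples parsed from column names
make_qt <- function(values, features = NULL, multiplicity = NULL) {
  qt <- quant_table(values, features = features)
  if (!is.null(multiplicity)) qt$features$multiplicity <- multiplicity
  qt
}

# 2-condition, 2-replicate, `nt`-timepoint column names
design_cols <- function(conditions = c("control", "mating"),
                        times = c(0, 45, 90, 135, 180), reps = 1:3) {
  unlist(lapply(conditions, function(cn)
    unlist(lapply(times, function(t) sprintf("%s_%dmin_R%d", cn, t, reps)))))
}

# independent step-up BH oracle: sort, multiply, enforce monotonicity by
# cumulative minimum from the largest p
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher p by hypergeometric enumeration: sum the probabilities of
# all tables (given margins) no more likely than the observed one
fisher_oracle <- function(a, hits, substrates, N) {
  lo <- max(0L, hits + substrates - N)
  hi <- min(hits, substrates)
  probs <- dhyper(lo:hi, substrates, N - substrates, hits)
  obs <- dhyper(a, substrates, N - substrates, hits)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

null_sim_config <- function(seed, n_sites = 10000L, batch_sd = 0, ...) {
  sim_config(n_sites = n_sites,
             class_proportions = c(null = 1, starvation_only = 0,
                                   mating_specific = 0, both_different = 0),
             coupled_fraction = 0, redundancy_rate = 0,
             batch_sd = batch_sd, seed = seed, ...)
}
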