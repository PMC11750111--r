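test_that("TSV round-trip preserves values, masks and metadata", {
  cols <- design_cols(reps = 1:2, times = c(0, 45))
  v <- matrix(rnorm(3 * length(cols)), 3, dimnames = list(NULL, cols))
  v[2, 3] <- NA
  qt <- quant_table(v, features = data.frame(
    feature_id = c("p1_S10", "p1_T20", "p2_S5"),
    protein_id = c("p1", "p1", "p2"),
    residue = c("S", "T", "S"), position = c(10L, 20L, 5L),
    multiplicity = c(1L, 1L, 2L),
    window = c("AAAAASAAAAA", "AAAAATAAAAA", "QQQQQSQQQQQ")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(qt, path)
  back <- read_quant_table(path, dialect = "tsv")
  expect_identical(back$features, qt$features)
  expect_equal(back$values, qt$values)
  expect_identical(is.na(back$values), is.na(qt$values))
  expect_equal(back$samples, qt$samples)
})

test_that("empty cells become mask entries excluded from downstream sums", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tcontrol_0min_R1\tcontrol_45min_R1",
               "f1\t1.5\t", "f2\t\t2.5"), path)
  qt <- read_quant_table(path)
  expect_true(is.na(qt$values["f1", 2]))
  expect_true(is.na(qt$values["f2", 1]))
  expect_equal(sum(qt$values, na.rm = TRUE), 4)
})

test_that("reader rejects duplicate feature ids and bad sample headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tcontrol_0min_R1", "f1\t1", "f1\t2"), path)
  expect_error(read_quant_table(path), "duplicate feature_id")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tnot_a_sample", "f1\t1"), path2)
  expect_error(read_quant_table(path2), "not_a_sample")
})

test_that("supplementary xlsx dialect loads replicate columns only", {
  skip_if_not_installed("readxl")
  # construct a 2-tab workbook mimicking the deposited layout: replicate
  # columns then per-time average columns (to be ignored)
  path <- withr::local_tempfile(fileext = ".xlsx")
  py <- c(
    "import openpyxl",
    "wb = openpyxl.Workbook()",
    "ws = wb.active",
    "ws.title = 'Phosphoproteome'",
    "hdr = ['feature_id', 'protein_id',",
    "       'control_0min_R1', 'control_45min_R1',",
    "       'mating_0min_R1', 'mating_45min_R1',",
    "       'Average 0min', 'Average 45min']",
    "ws.append(hdr)",
    "ws.append(['p1_S10', 'p1', 0.1, 0.4, 0.2, 0.9, 0.15, 0.65])",
    "ws.append(['p2_S5', 'p2', -0.2, None, 0.0, 0.3, -0.1, 0.3])",
    "ws2 = wb.create_sheet('Proteome')",
    "ws2.append(['feature_id', 'control_0min_R1'])",
    "ws2.append(['p1', 1.0])",
    sprintf("wb.save('%s')", path))
  res <- system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(path), "could not build xlsx fixture")
  qt <- read_quant_table(path, dialect = "supplementary_xlsx",
                         sheet = "Phosphoproteome")
  expect_equal(ncol(qt$values), 4L)  # averages dropped
  expect_false(any(grepl("Average", colnames(qt$values))))
  expect_equal(qt$values["p1_S10", "mating_45min_R1"], 0.9)
  expect_true(is.na(qt$values["p2_S5", "control_45min_R1"]))
  pr <- read_quant_table(path, dialect = "supplementary_xlsx", sheet = "Proteome")
  expect_equal(unname(pr$values[1, 1]), 1.0)
})

test_that("log2 transform follows the pseudocount contract", {
  qt <- make_qt(matrix(c(8, 0, NA, 3), 2,
                       dimnames = list(c("a", "b"),
                                       c("control_0min_R1", "control_45min_R1"))))
  out <- log2_transform(qt, pseudocount = 1)
  expect_equal(out$values["b", 1], 0)       # log2(0 + 1)
  expect_true(is.na(out$values["a", 2]))    # masked stays masked
  out0 <- log2_transform(make_qt(matrix(8, 1, 1, dimnames = list("a", "control_0min_R1"))), 0)
  expect_equal(unname(out0$values[1, 1]), 3)
  qneg <- make_qt(matrix(-1, 1, 1, dimnames = list("a", "control_0min_R1")))
  expect_error(log2_transform(qneg), "negative")
})

test_that("median centering zeroes per-replicate medians and is idempotent", {
  cols <- sprintf("control_%dmin_R1", c(0, 45, 90, 135, 180))
  qt <- make_qt(matrix(c(1, 2, 3, 4, 10), 1, dimnames = list("f", cols)))
  out <- median_center_by_replicate(qt)
  expect_equal(unname(out$values[1, ]), c(-2, -1, 0, 1, 7))
  again <- median_center_by_replicate(out)
  expect_equal(again$values, out$values)
})

test_that("centering removes per-replicate additive offsets exactly", {
  profile <- c(0, 0.5, 1, 1.5, 2, 0, 0.2, 0.4, 0.8, 1.0)
  cols_r1 <- design_cols(reps = 1)
  cols_r2 <- design_cols(reps = 2)
  v <- rbind(site = c(profile + 5, profile - 5))
  colnames(v) <- c(cols_r1, cols_r2)
  out <- median_center_by_replicate(quant_table(v))
  centered <- profile - median(profile)
  expect_equal(unname(out$values[1, 1:10]), centered)
  expect_equal(unname(out$values[1, 11:20]), centered)
  # per-feature per-replicate median exactly zero
  expect_equal(median(out$values[1, 1:10]), 0)
})

test_that("a replicate with no observed values is left untouched", {
  cols <- c("control_0min_R1", "control_45min_R1",
            "control_0min_R2", "control_45min_R2")
  v <- matrix(c(1, 2, NA, NA), 1, dimnames = list("f", cols))
  out <- median_center_by_replicate(quant_table(v))
  expect_true(all(is.na(out$values[1, 3:4])))
  expect_equal(unname(out$values[1, 1:2]), c(-0.5, 0.5))
  expect_equal(attr(out, "n_untouched"), 1L)
})

test_that("PCA on rank-1 data explains all variance in PC1", {
  cols <- sprintf("control_%dmin_R1", seq(0, 180, 45))
  grad <- seq_len(5)
  v <- outer(rnorm(20), grad)  # rank-1: feature loading x time gradient
  dimnames(v) <- list(sprintf("f%02d", 1:20), cols)
  pc <- pca_qc(quant_table(v), n_components = 2)
  expect_gt(pc$explained_variance[1], 1 - 1e-10)
  expect_equal(pc$n_features_used, 20L)
})

test_that("PCA variance fractions are non-increasing and sum to <= 1", {
  set.seed(9)
  cols <- design_cols(reps = 1:2)
  v <- matrix(rnorm(50 * length(cols)), 50, dimnames = list(NULL, cols))
  pc <- pca_qc(quant_table(v, features = data.frame(feature_id = sprintf("f%02d", 1:50))),
               n_components = 5)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
})

test_that("permuting sample order permutes PCA scores identically", {
  set.seed(10)
  cols <- design_cols(reps = 1:2)
  v <- matrix(rnorm(40 * length(cols)), 40, dimnames = list(sprintf("f%02d", 1:40), cols))
  qt <- quant_table(v)
  perm <- sample(ncol(v))
  qt2 <- quant_table(v[, perm], samples = qt$samples[perm, ])
  pc1 <- pca_qc(qt, 2)
  pc2 <- pca_qc(qt2, 2)
  # scores are sign-ambiguous per component
  for (k in 1:2)
    expect_equal(abs(pc2$scores[, k]), abs(pc1$scores[perm, k]),
                 ignore_attr = TRUE)
})

test_that("PC1 tracks time and PC2 separates conditions on simulated data", {
  sim <- simulate_experiment(sim_config(
    n_sites = 1500,
    class_proportions = c(null = 0.45, starvation_only = 0.35,
                          mating_specific = 0.1, both_different = 0.1),
    missing_rate = 0.02, replicate_dropout_rate = 0, seed = 21))
  x <- median_center_by_replicate(sim$phospho)
  pc <- pca_qc(x, 2)
  s <- pc$samples
  expect_gt(abs(cor(pc$scores[, 1], s$time_min)), 0.9)
  sep <- abs(mean(pc$scores[s$condition == "mating", 2]) -
               mean(pc$scores[s$condition == "control", 2]))
  spread <- sd(pc$scores[, 2])
  expect_gt(sep, spread)
})

test_that("pca_qc errors when too few complete features remain", {
  cols <- design_cols(reps = 1, times = c(0, 45))
  v <- matrix(c(1, NA, 2, 3), 1, dimnames = list("f", cols))
  expect_error(pca_qc(quant_table(v), 2), "complete-case")
})

test_that("sequence windows derive from FASTA with terminal padding", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MSTAAAKRRSLT"), fa)
  cols <- "control_0min_R1"
  v <- matrix(0, 2, 1, dimnames = list(NULL, cols))
  qt <- quant_table(v, features = data.frame(
    feature_id = c("p1_S2", "p1_S10"), protein_id = "p1",
    residue = "S", position = c(2L, 10L)))
  out <- windows_from_fasta(qt, fa)
  expect_equal(out$features$window[1], "____MSTAAAK")
  expect_equal(out$features$window[2], "AAKRRSLT___")
  expect_equal(substr(out$features$window, 6, 6), c("S", "S"))
})
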