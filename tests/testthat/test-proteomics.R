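test_that("proteinGroups files round-trip with decoy/contaminant hygiene", {
  tab <- make_pg_table(c(sprintf("P%d", 1:6), "REV__X", "CON__Y"),
                       inter = c(1:6 * 1e6, 1e6, 1e6),
                       mito = c(6:1 * 1e6, 1e6, 1e6), E = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(tab, path)
  expect_message(pt <- read_protein_groups(path), "2 contaminant/decoy")
  expect_equal(nrow(pt), 6)
  expect_equal(attr(pt, "n_dropped_decoys"), 2)
  expect_length(attr(pt, "lfq_columns")$interphase, 4)

  # negative intensity -> validation error
  bad <- tab
  bad$`LFQ intensity mitotic_1`[1] <- -5
  expect_error(protein_quant_table(bad), "negative")

  # missing mapped column -> error naming it
  expect_error(protein_quant_table(tab, condition_column_map = list(
    interphase = "LFQ intensity interphase_9",
    mitotic = "LFQ intensity mitotic_1")), "interphase_9")
})

test_that("ratios, zero exclusion and condition-exclusive classification", {
  tab <- protein_quant_table(make_pg_table(
    c("CTTN", "EPN1", "LOWI", "CFL2", "NORM"),
    inter = c(4.62e7, 2e6, 5e5, 0, 1e7),
    mito = c(1.0e6, 0, 0, 3e6, 1e7)))
  r <- compute_ratios(tab)
  expect_equal(r$ratio[r$protein_id == "CTTN"], 46.2)
  expect_equal(round(r$log2_ratio[r$protein_id == "CTTN"], 3), 5.530)
  expect_equal(r$status[r$protein_id == "CTTN"], "ratio_ok")
  expect_equal(r$status[r$protein_id == "EPN1"], "interphase_exclusive")
  expect_equal(r$status[r$protein_id == "LOWI"], "excluded_zero")
  expect_equal(r$status[r$protein_id == "CFL2"], "mitotic_exclusive")
  expect_equal(r$status[r$protein_id == "NORM"], "ratio_ok")
  # log2 defined iff ratio_ok; outlier_call none elsewhere
  expect_true(all(is.finite(r$log2_ratio) == (r$status == "ratio_ok")))
  expect_true(all(r$outlier_call == "none"))
  # partition is exhaustive and exclusive by construction of a single column
  expect_true(all(r$status %in% c("ratio_ok", "excluded_zero",
                                  "interphase_exclusive", "mitotic_exclusive")))
})

test_that("per-condition aggregation happens before division", {
  g <- gen_lfq_table(lfq_gen_spec(n_proteins = 100, dropout_rate = 0.1,
                                  seed = 4))
  pt <- protein_quant_table(g$table)
  r <- compute_ratios(pt)
  # metamorphic: permuting experiment labels leaves every ratio unchanged
  perm <- g$table
  names(perm) <- sub("_1$", "_9", names(perm))
  names(perm) <- sub("_4$", "_1", names(perm))
  names(perm) <- sub("_9$", "_4", names(perm))
  r2 <- compute_ratios(protein_quant_table(perm))
  expect_equal(r2$ratio, r$ratio)
  # rows untouched by dropout recover their true ratio exactly (the shared
  # run factor cancels only when the same experiments survive per condition)
  lfq <- as.matrix(g$table[, grep("^LFQ", names(g$table))])
  complete <- rowSums(lfq == 0) == 0
  tr <- g$truth$true_ratio[match(r$protein_id, g$truth$protein_id)]
  expect_gt(sum(complete), 20)
  expect_equal(r$ratio[complete], tr[complete], tolerance = 1e-9)
})

test_that("Gaussian null fit recovers histogram parameters", {
  # noiseless self-consistency: deterministic Gaussian quantile sample
  x <- qnorm(ppoints(4000), 0.10, 0.80)
  r <- data.frame(protein_id = as.character(seq_along(x)),
                  gene_name = "g", interphase_lfq = 1, mitotic_lfq = 1,
                  ratio = 2^x, log2_ratio = x, status = "ratio_ok",
                  outlier_call = "none")
  f <- fit_gaussian_null(r, bin_width = 0.25)
  expect_equal(f$mu, 0.10, tolerance = 0.01)
  expect_equal(f$sigma, 0.80, tolerance = 0.01)
  expect_equal(f$n_fitted, 4000)

  # Monte-Carlo draws; oracle = sample moments
  set.seed(11)
  x2 <- rnorm(5000, 0.2, 0.8)
  r2 <- r[rep(1, 5000), ]
  r2$log2_ratio <- x2
  f2 <- fit_gaussian_null(r2)
  expect_equal(f2$mu, 0.2, tolerance = 0.05 / 0.2)
  expect_lt(abs(f2$sigma - 0.8), 0.05)
  expect_lt(abs(f2$mu - mean(x2)), 0.05)

  # moments method returns sample moments exactly
  fm <- fit_gaussian_null(r2, method = "moments")
  expect_equal(fm$mu, mean(x2))
  expect_equal(fm$sigma, sd(x2))

  # degenerate: identical ratios
  r3 <- r[1:100, ]
  r3$log2_ratio <- 1
  expect_error(fit_gaussian_null(r3), "degenerate")
  expect_error(fit_gaussian_null(r[1:10, ]), "at least 50")
})

test_that("outliers are called strictly beyond two fitted sigmas", {
  fit <- structure(list(mu = 0, sigma = 0.75), class = "gaussian_fit")
  r <- data.frame(protein_id = c("CTTN", "NSF", "MID", "EDGE"),
                  gene_name = c("CTTN", "NSF", "MID", "EDGE"),
                  interphase_lfq = 1, mitotic_lfq = 1,
                  ratio = c(46.2, 0.077, 1, 2^1.5),
                  log2_ratio = c(log2(46.2), log2(0.077), 0, 1.5),
                  status = "ratio_ok", outlier_call = "none")
  out <- call_outliers(r, fit)
  expect_equal(out$outlier_call,
               c("interphase_enriched", "mitotic_enriched", "none", "none"))
})

test_that("per-experiment consistency re-detects injected outliers", {
  spec <- lfq_gen_spec(
    n_proteins = 2000, null_mu = 0, null_sigma = 0.8,
    outlier_specs = data.frame(protein_id = c("ALLEXP", "ONEEXP"),
                               true_ratio = c(46.2, 46.2),
                               experiments = c("1,2,3,4", "1")),
    seed = 21)
  g <- gen_lfq_table(spec)
  pt <- protein_quant_table(g$table)
  pec <- per_experiment_consistency(pt)
  expect_true("ALLEXP" %in% pec$intersection)
  cons <- pec$consistency
  expect_equal(cons$n_called[cons$protein_id == "ALLEXP"], 4L)
  expect_true("ONEEXP" %in% pec$per_experiment[["1"]])
  expect_false("ONEEXP" %in% pec$intersection)
  # bookkeeping: count equals number of per-experiment sets containing the id
  expect_equal(cons$n_called[cons$protein_id == "ONEEXP"],
               sum(vapply(pec$per_experiment, function(s) "ONEEXP" %in% s,
                          logical(1))))
})

test_that("annotation restricts and labels by reference lists", {
  r <- data.frame(protein_id = c("CTTN", "CLTC", "XYZ"),
                  gene_name = c("CTTN", "CLTC", "XYZ"),
                  interphase_lfq = 1, mitotic_lfq = 1,
                  ratio = c(46.2, 1, 1),
                  log2_ratio = c(log2(46.2), 0, 0),
                  status = "ratio_ok", outlier_call = "none")
  ann <- annotate_ratios(r, list(ccs_core = c("CLTC", "CTTN"),
                                 actin_related = "CTTN"))
  expect_equal(nrow(ann), 2)            # XYZ retained only in the full table
  expect_false("XYZ" %in% ann$protein_id)
  expect_equal(ann$labels[ann$protein_id == "CTTN"], "ccs_core;actin_related")
  expect_equal(ann$protein_id, c("CTTN", "CLTC"))  # ordered by log2 ratio
  expect_error(annotate_ratios(r, list(empty = character(0))), "empty")
})
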