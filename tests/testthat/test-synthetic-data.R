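test_that("noiseless tether traces place the plateau at F/k above baseline", {
  spec <- trace_gen_spec(noise_sd = 0, trap_stiffness = 0.3, true_force = 30)
  g <- gen_tether_trace(spec)
  tr <- g$trace
  # plateau while tethered and tensioned (between formation and toward event)
  plateau <- tr$displacement[tr$time >= 2 & tr$time < 12]
  baseline <- tr$displacement[tr$time >= 12 & tr$time < 14]
  expect_equal(unique(plateau), 100)   # 30 pN / 0.3 pN/nm
  expect_equal(unique(baseline), 0)
  expect_equal(g$truth$apparent_force_pN, 30)

  # a double tether doubles the plateau displacement
  g2 <- gen_tether_trace(trace_gen_spec(noise_sd = 0, trap_stiffness = 0.3,
                                        true_force = 30, tether_count = 2))
  expect_equal(unique(g2$trace$displacement[g2$trace$time >= 2 &
                                            g2$trace$time < 12]), 200)
  expect_equal(g2$truth$apparent_force_pN, 60)

  # drift offset shifts the whole trace
  g3 <- gen_tether_trace(trace_gen_spec(noise_sd = 0, trap_stiffness = 0.3,
                                        true_force = 30, drift_offset = 50))
  expect_equal(g3$trace$displacement, g$trace$displacement + 50)
})

test_that("trace generation is deterministic given the seed", {
  spec <- trace_gen_spec(noise_sd = 10, seed = 42L)
  a <- gen_tether_trace(spec)
  b <- gen_tether_trace(spec)
  expect_identical(a$trace$displacement, b$trace$displacement)
  c <- gen_tether_trace(trace_gen_spec(noise_sd = 10, seed = 43L))
  expect_false(identical(a$trace$displacement, c$trace$displacement))
})

test_that("a schedule without a zero-reference window is flagged in metadata", {
  ev <- data.frame(time_s = 1, event = "tether_formed")
  g <- gen_tether_trace(trace_gen_spec(noise_sd = 0, event_schedule = ev))
  expect_false(g$truth$has_zero_reference)
  expect_false(g$trace$has_zero_reference)
})

test_that("trace spec validation rejects bad schedules and parameters", {
  bad <- data.frame(time_s = c(5, 3), event = c("tether_formed", "stage_away"))
  expect_error(trace_gen_spec(event_schedule = bad), "strictly increasing")
  expect_error(trace_gen_spec(sampling_rate = 0), "sampling_rate")
  expect_error(trace_gen_spec(true_force = -1), "true_force")
})

test_that("LFQ truth records the stated outlier ratios on the log2 scale", {
  spec <- lfq_gen_spec(
    n_proteins = 10,
    outlier_specs = data.frame(protein_id = c("CTTN", "NSF"),
                               true_ratio = c(46.2, 0.077)),
    seed = 3)
  g <- gen_lfq_table(spec)
  # oracle: plain logarithm
  expect_equal(g$truth$true_log2_ratio[g$truth$protein_id == "CTTN"],
               log2(46.2), tolerance = 1e-12)
  expect_equal(round(g$truth$true_log2_ratio[g$truth$protein_id == "CTTN"], 3),
               5.530)
  expect_equal(g$truth$true_log2_ratio[g$truth$protein_id == "NSF"],
               log2(0.077), tolerance = 1e-12)
  expect_equal(round(g$truth$true_log2_ratio[g$truth$protein_id == "NSF"], 3),
               -3.699)
})

test_that("LFQ generator honours dropout, exclusivity and duplicate checks", {
  g <- gen_lfq_table(lfq_gen_spec(n_proteins = 200, dropout_rate = 0, seed = 1))
  lfq_cols <- grep("^LFQ", names(g$table))
  expect_true(all(as.matrix(g$table[, lfq_cols]) > 0))

  ex <- data.frame(protein_id = c("A", "B"),
                   condition = c("interphase", "mitotic"),
                   intensity = c(2e6, 3e6))
  g2 <- gen_lfq_table(lfq_gen_spec(n_proteins = 5, exclusive_specs = ex,
                                   seed = 1))
  a <- g2$table[g2$table$`Protein IDs` == "A", ]
  expect_true(all(a[, grep("interphase", names(a))] == 2e6))
  expect_true(all(a[, grep("mitotic", names(a))] == 0))

  expect_error(lfq_gen_spec(
    outlier_specs = data.frame(protein_id = "A", true_ratio = 2),
    exclusive_specs = data.frame(protein_id = "A", condition = "mitotic",
                                 intensity = 1e7)), "duplicate")
  expect_error(lfq_gen_spec(dropout_rate = 1), "dropout_rate")
  expect_error(lfq_gen_spec(null_sigma = 0), "null_sigma")
})

test_that("generated null log2 ratios match the requested moments", {
  g <- gen_lfq_table(lfq_gen_spec(n_proteins = 5000, null_mu = 0.2,
                                  null_sigma = 0.8, seed = 5))
  x <- g$truth$true_log2_ratio[g$truth$class == "null"]
  # Monte-Carlo error at n = 5000: se(mean) ~ 0.011, se(sd) ~ 0.008
  expect_equal(mean(x), 0.2, tolerance = 0.05 / 0.2)
  expect_equal(sd(x), 0.8, tolerance = 0.05 / 0.8)
})

test_that("synthetic cell images record arithmetic ground truth", {
  spec <- image_gen_spec(cortex_intensity = 200, cytoplasm_intensity = 100,
                         background_intensity = 50, noise_sd = 0)
  g <- gen_cell_image(spec)
  expect_equal(g$truth$f_actin_ratio, 3.0)
  expect_equal(g$truth$g_actin_mean,
               spec$g_intensity - spec$background_intensity)

  g0 <- gen_cell_image(image_gen_spec(puncta_count = 0))
  expect_equal(g0$truth$tf_total, 0)
  expect_true(all(g0$tf == image_gen_spec()$background_intensity))

  gu <- gen_cell_image(image_gen_spec(cortex_intensity = 80,
                                      cytoplasm_intensity = 80,
                                      background_intensity = 40,
                                      noise_sd = 0))
  expect_equal(gu$truth$f_actin_ratio, 1.0)

  expect_error(image_gen_spec(cortex_width = 90, cell_radius = 80),
               "cortex_width")
  expect_error(image_gen_spec(cell_radius = 200, image_size = 256), "fit")
})

test_that("synthetic flow events record sub-gate counts and geometric means", {
  spec <- flow_gen_spec(n_events = 1000, debris_fraction = 0.3, seed = 9)
  g <- gen_flow_events(spec)
  expect_equal(g$truth$n_below_gate, sum(g$events$FSC < 200))
  expect_gte(g$truth$n_below_gate, g$truth$n_debris * 0.99)

  # log-sd 0 makes FL1 exactly the geometric mean
  g2 <- gen_flow_events(flow_gen_spec(
    n_events = 100,
    population_params = data.frame(fraction = 1, fsc_mean = 500, fsc_sd = 50,
                                   fl1_log_mean = log(100), fl1_log_sd = 0),
    seed = 1))
  expect_equal(unname(g2$truth$fl1_geometric_mean["pop1"]), 100)
  expect_true(all(abs(g2$events$FL1 - 100) < 1e-9))

  # disjoint FSC ranges keep population truth separable
  pp <- data.frame(fraction = c(0.5, 0.5), fsc_mean = c(300, 800),
                   fsc_sd = c(10, 10), fl1_log_mean = log(c(50, 500)),
                   fl1_log_sd = c(0.1, 0.1))
  g3 <- gen_flow_events(flow_gen_spec(n_events = 2000,
                                      population_params = pp, seed = 2))
  lo <- g3$events$population == "pop1"
  expect_lt(max(g3$events$FSC[lo]), min(g3$events$FSC[!lo]))
  expect_equal(unname(g3$truth$fl1_geometric_mean), c(50, 500))

  expect_error(flow_gen_spec(population_params = data.frame(
    fraction = 0.5, fsc_mean = 1, fsc_sd = 1, fl1_log_mean = 0,
    fl1_log_sd = 1)), "sum to 1")
})

test_that("all generators are bit-reproducible under a fixed seed", {
  sl <- lfq_gen_spec(n_proteins = 50, seed = 7)
  expect_identical(gen_lfq_table(sl), gen_lfq_table(sl))
  si <- image_gen_spec(noise_sd = 5, seed = 7)
  expect_identical(gen_cell_image(si), gen_cell_image(si))
  sf <- flow_gen_spec(n_events = 500, seed = 7)
  expect_identical(gen_flow_events(sf), gen_flow_events(sf))
})
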