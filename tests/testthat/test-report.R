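prot <- build_protocol()

test_that("the cumulative release curve conserves the event count", {
  ev <- data.frame(onset_frame = c(65, 65, 70, 100),
                   onset_time_s = c(32, 32, 34.5, 49.5))
  cc <- cumulative_curve(ev, prot)
  expect_equal(nrow(cc), prot$n_frames)
  expect_true(all(diff(cc$cumulative) >= 0))
  expect_equal(cc$cumulative[prot$n_frames], 4)
  expect_equal(cc$cumulative[64], 0)
  expect_equal(cc$cumulative[65], 2)
  # restriction to the first 4 bursts ([30, 36) s)
  c4 <- cumulative_curve(ev, prot, first_n_bursts = 4)
  expect_equal(c4$cumulative[prot$n_frames], 3)
})

test_that("the stimulation fusion rate is events per second of the epoch", {
  ev <- data.frame(onset_time_s = c(10, 31, 35, 53.9, 60))
  expect_equal(fusion_rate(ev, prot), 3 / 24)    # only in-epoch events count
  expect_equal(fusion_rate(ev[0, , drop = FALSE], prot), 0)
})

test_that("amplitude histograms are normalized to the event count", {
  set.seed(61)
  peaks <- rlnorm(200, 0, 0.5)
  h <- dff_histogram(peaks, n_bins = 12)
  expect_equal(nrow(h), 12)
  expect_equal(sum(h$fraction), 1)
  expect_error(dff_histogram(numeric(0)), "no events")
})

test_that("test selection follows the normality/variance screening policy", {
  # deterministic constructions: normal quantiles pass the normality
  # screen with certainty, lognormal quantiles fail it
  qn <- qnorm(ppoints(40))
  r <- compare_groups(qn, 0.5 + qn)
  expect_match(r$test, "t-test")
  expect_true(all(r$normal))
  # grossly unequal variances push the t test to the Welch form
  r2 <- compare_groups(qn, 0.5 + 6 * qn)
  expect_equal(r2$test, "Welch t-test")
  # heavy-tailed data fail the normality screen: Mann-Whitney
  r3 <- compare_groups(exp(1.5 * qn), exp(1 + 1.5 * qn))
  expect_equal(r3$test, "Mann-Whitney")
  expect_false(all(r3$normal))
  # three groups: Kruskal-Wallis with Bonferroni pairwise
  set.seed(62)
  r4 <- compare_groups(rnorm(15), rnorm(15, 2), rnorm(15, 4))
  expect_equal(r4$test, "Kruskal-Wallis")
  expect_lt(r4$p_value, 0.01)
  expect_equal(dim(r4$pairwise), c(2, 2))
  expect_error(compare_groups(c(1, 2), rnorm(10)), "insufficient")
})

test_that("a strong group difference is declared significant", {
  set.seed(63)
  r <- compare_groups(rnorm(20, 0, 1), rnorm(20, 3, 1))
  expect_lt(r$p_value, 1e-4)
})

test_that("per-cell summaries count events, early release and secretion status", {
  ev <- data.frame(onset_frame = c(61, 63, 80),
                   onset_time_s = c(30, 31, 39.5),
                   synaptic = c("synaptic", "synaptic", "extra-synaptic"),
                   motility = c("stationary", "moving", "stationary"))
  s <- cell_summary(ev, prot, cell_id = "c1", label = "ctrl", pool_count = 25)
  expect_equal(s$n_events, 3)
  expect_equal(s$n_events_first4bursts, 2)       # onsets in [30, 36) s
  expect_equal(s$fraction_synaptic, 2 / 3)
  expect_equal(s$fraction_stationary_prior_to_fusion, 2 / 3)
  expect_equal(s$fusion_rate_stim, 3 / 24)
  expect_false(s$non_secreting)
  empty <- ev[0, , drop = FALSE]
  s0 <- cell_summary(empty, prot, cell_id = "c2")
  expect_true(s0$non_secreting)
  both <- summarize_cells(rbind(s, s0))
  expect_equal(both$n_cells, 2)
  expect_equal(both$pct_non_secreting, 50)
  expect_equal(both$mean_events, 3)              # non-secreting excluded
})

test_that("the pipeline runs end to end and writes a complete report bundle", {
  out <- tempfile("report")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  rep <- run_pipeline(list(seed = 2, cell_id = "cellA",
                           scene = list(n_vesicles = 15)),
                      out_dir = out)
  expect_s3_class(rep, "dcv_report")
  expect_gt(nrow(rep$events), 0)
  expect_true(all(c("synaptic", "motility", "mode") %in% names(rep$events)))
  expect_equal(rep$summary$cell_id, "cellA")
  expect_equal(rep$cumulative$cumulative[nrow(rep$cumulative)],
               nrow(rep$events))
  expect_true(all(file.exists(file.path(
    out, c("events.csv", "summary.csv", "cumulative.csv", "coloc.json",
           "log.yaml")))))
  # the written log captures the resolved seed for reproducibility
  expect_equal(yaml::read_yaml(file.path(out, "log.yaml"))$seed, 2)
  # identical config reproduces identical events
  rep2 <- run_pipeline(list(seed = 2, cell_id = "cellA",
                            scene = list(n_vesicles = 15)))
  expect_equal(rep$events, rep2$events)
})

test_that("unknown configuration entries are a hard error", {
  expect_error(run_pipeline(list(sede = 1)), "config error")
  expect_error(run_pipeline(42), "config error")
})
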