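prot <- build_protocol()

test_that("dF/F0 uses the mean of the first four frames as baseline", {
  tr <- roi_trace(c(10, 10, 10, 10, 20, 30), frame_interval_s = 0.5)
  expect_equal(dff(tr), c(0, 0, 0, 0, 1, 2))
  expect_error(dff(roi_trace(c(0, 0, 0, 0, 5))), "F0")
})

test_that("ROI traces average the pixel block covering the punctum", {
  frames <- array(0, c(16, 16, 4))
  frames[6, 6, ] <- c(4, 8, 12, 16)   # 0-based (5, 5)
  mv <- movie_from_array(frames)
  # 2x2 ROI at center (5, 5) covers 0-based rows/cols 5:6 -> mean = v/4
  tr <- extract_trace(mv, "cargo", c(5, 5))
  expect_equal(tr$values, c(1, 2, 3, 4))
  expect_error(extract_trace(mv, "cargo", c(15.5, 5)), "bounds")
  expect_error(extract_trace(mv, "nope", c(5, 5)), "unknown channel")
})

test_that("fusion onset is the first frame crossing F0 + 2 sigma", {
  # deterministic construction: flat baseline, step at frame 80, with the
  # baseline noise scale supplied explicitly
  Tn <- prot$n_frames
  v <- rep(100, Tn)
  v[80:Tn] <- 160
  tr <- roi_trace(v, c(10, 10), protocol = prot)
  tr$sigma0 <- 3
  ev <- detect_fusion_phluorin(tr, protocol = prot)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 80)
  expect_equal(ev$onset_time_s, 39.5)
  expect_false(ev$pre_stim)
  expect_equal(ev$peak_dff, 0.6)
  # with noise on top, the first call still lands on the true onset
  set.seed(21)
  vn <- v + rnorm(Tn, 0, 3)
  trn <- roi_trace(vn, c(10, 10), protocol = prot)
  evn <- detect_fusion_phluorin(trn, protocol = prot)
  expect_equal(evn$onset_frame[1], 80)
})

test_that("raising the detection threshold can only remove events", {
  set.seed(22)
  Tn <- prot$n_frames
  v <- rnorm(Tn, 100, 5)
  v[70:Tn] <- v[70:Tn] + 14      # weak event near 2-3 sigma of the ROI mean
  tr <- roi_trace(v, c(0, 0), protocol = prot)
  n_events <- vapply(c(1, 2, 4, 8), function(k)
    nrow(detect_fusion_phluorin(tr, detection_params(k_sigma = k),
                                protocol = prot)), 0L)
  expect_true(all(diff(n_events) <= 0))
})

test_that("slow drifts are not called as fusion (the sudden-rise rule)", {
  Tn <- prot$n_frames
  set.seed(23)
  v <- 100 + (seq_len(Tn) - 1) * 0.8 + rnorm(Tn, 0, 1)  # ramp, no step
  tr <- roi_trace(v, c(0, 0), protocol = prot)
  ev <- detect_fusion_phluorin(tr, protocol = prot)
  expect_equal(nrow(ev), 0)
})

test_that("the refractory window merges rapid re-crossings of one event", {
  Tn <- prot$n_frames
  v <- rep(100, Tn)
  v[80:84] <- 150
  v[87:92] <- 150                # second crossing 7 frames later: refractory
  tr <- roi_trace(v, c(0, 0), protocol = prot)
  tr$sigma0 <- 2
  ev <- detect_fusion_phluorin(tr, protocol = prot)
  expect_equal(ev$onset_frame, 80)
})

test_that("events before stimulation are flagged, events during NH4+ ignored", {
  p2 <- build_protocol(nh4_start_s = 80, nh4_duration_s = 10)
  Tn <- p2$n_frames
  v <- rep(100, Tn)
  v[30:Tn] <- 140                # pre-stim onset (14.5 s)
  v[165:Tn] <- 340               # inside NH4+ epoch: not an event
  tr <- roi_trace(v, c(0, 0), protocol = p2)
  # sigma0 from pre-stim frames would include the pre-stim step itself;
  # supply the baseline noise scale explicitly
  tr$sigma0 <- 2
  ev <- detect_fusion_phluorin(tr, protocol = p2)
  expect_equal(nrow(ev), 1)
  expect_true(ev$pre_stim)
  expect_equal(ev$onset_frame, 30)
})

test_that("persistent and transient events are told apart by the return rule", {
  Tn <- prot$n_frames
  base <- rep(100, Tn)
  pers <- base; pers[80:Tn] <- 160
  tran <- base; tran[80:Tn] <- 100 + 60 * exp(-(0:(Tn - 80)) * 0.5 / 5)
  trp <- roi_trace(pers, c(0, 0), protocol = prot); trp$sigma0 <- 2
  trt <- roi_trace(tran, c(0, 0), protocol = prot); trt$sigma0 <- 2
  ev <- data.frame(onset_frame = 80)
  expect_equal(as.character(classify_event_mode(trp, ev, protocol = prot)),
               "persistent")
  expect_equal(as.character(classify_event_mode(trt, ev, protocol = prot)),
               "transient")
  # event too close to the end cannot be judged: persistent, censored
  late <- classify_event_mode(trp, data.frame(onset_frame = Tn - 1),
                              protocol = prot)
  expect_equal(as.character(late), "persistent")
  expect_true(attr(late, "censored"))
})

test_that("full release is detected despite bleaching, and bleaching alone never fires", {
  set.seed(26)
  Tn <- prot$n_frames
  bl <- exp(-(0:(Tn - 1)) * 0.5 / 200)
  soma <- roi_trace(rpois(Tn, 500 * bl) / 5, protocol = prot)
  # bleach-only punctum
  v0 <- rpois(Tn, (20 + 300) * bl) + rnorm(Tn, 0, 2)
  expect_null(detect_full_release(roi_trace(v0, c(5, 5), protocol = prot),
                                  soma, protocol = prot))
  # programmed disappearance at frame 90
  amp <- rep(300, Tn); amp[90:Tn] <- 0
  v1 <- rpois(Tn, (20 + amp) * bl) + rnorm(Tn, 0, 2)
  ev <- detect_full_release(roi_trace(v1, c(5, 5), protocol = prot),
                            soma, protocol = prot)
  expect_equal(ev$onset_frame, 90)
  expect_equal(ev$mode, "full-release")
  # without a soma reference the exponential-fit fallback still works
  expect_message(
    ev2 <- detect_full_release(roi_trace(v1, c(5, 5), protocol = prot),
                               NULL, protocol = prot),
    "exponential")
  expect_equal(ev2$onset_frame, 90)
})

test_that("movie-level detection localizes a rendered fusion event", {
  set.seed(27)
  Tn <- prot$n_frames
  traj <- list(data.frame(frame = 75:Tn, y_px = 30.3, x_px = 41.7, amp = 300))
  frames <- render_spot_movie(traj, n_frames = Tn, poisson = TRUE, read_sd = 2)
  mv <- movie_from_array(frames)
  ev <- detect_fusion_events(mv, prot)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 75)
  expect_lt(sqrt((ev$y_px - 30.3)^2 + (ev$x_px - 41.7)^2), 2)
  expect_equal(ev$mode, "persistent")
})

test_that("a bright punctum drifting into view is not called a fusion event", {
  set.seed(28)
  Tn <- prot$n_frames
  # constant-brightness punctum translating at 1 px/frame across the field
  traj <- list(data.frame(frame = 1:Tn, y_px = 32,
                          x_px = 2 + (1:Tn) * 0.45, amp = 300))
  frames <- render_spot_movie(traj, n_frames = Tn, poisson = TRUE, read_sd = 2)
  mv <- movie_from_array(frames)
  ev <- detect_fusion_events(mv, prot)
  expect_equal(nrow(ev), 0)
})
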