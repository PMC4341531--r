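prot <- build_protocol()

test_that("nearest-neighbour linking reconstructs parallel trajectories", {
  # two puncta 10 px apart moving in parallel at 1 px/frame
  det <- lapply(1:20, function(t)
    data.frame(y_px = c(10, 20), x_px = c(5 + t, 5 + t)))
  trks <- link_tracks(det)
  expect_equal(length(trks), 2)
  expect_true(all(vapply(trks, nrow, 0L) == 20))
  ys <- sort(vapply(trks, function(tr) tr$y_px[1], 0))
  expect_equal(ys, c(10, 20))
})

test_that("a one-frame detection gap is bridged by interpolation", {
  det <- lapply(1:11, function(t)
    if (t == 6) data.frame(y_px = numeric(0), x_px = numeric(0))
    else data.frame(y_px = 10, x_px = 5 + t))
  trks <- link_tracks(det)
  expect_equal(length(trks), 1)
  tr <- trks[[1]]
  expect_equal(nrow(tr), 11)
  expect_true(tr$interpolated[tr$frame == 6])
  expect_equal(tr$x_px[tr$frame == 6], 11)   # midpoint of 10 and 12
  # a longer gap splits the track
  det2 <- det; det2[[7]] <- det2[[6]]
  expect_equal(length(link_tracks(det2, max_gap_frames = 1)), 2)
})

test_that("directed transport is called moving, localization jitter stationary", {
  # deterministic check at the classifier's displacement threshold:
  # 2 px net over a 10-frame (9-step) window needs > 0.22 px/frame
  run <- data.frame(frame = 1:20, y_px = 10, x_px = 10 + (0:19) * 0.475)
  expect_equal(as.character(classify_motility(run)), "moving")
  crawl <- data.frame(frame = 1:20, y_px = 10, x_px = 10 + (0:19) * 0.1)
  expect_equal(as.character(classify_motility(crawl)), "stationary")
  set.seed(41)
  jit <- data.frame(frame = 1:60, y_px = 10 + rnorm(60, 0, 0.15),
                    x_px = 10 + rnorm(60, 0, 0.15))
  expect_equal(as.character(classify_motility(jit)), "stationary")
})

test_that("motility classification is invariant to path reversal", {
  set.seed(42)
  trks <- simulate_tracks(50, speed_nm_s = 190, speed_sd_nm_s = 30, seed = 42)
  for (tr in trks) {
    rev_tr <- tr[nrow(tr):1, ]
    rev_tr$frame <- tr$frame
    expect_identical(as.character(classify_motility(tr)),
                     as.character(classify_motility(rev_tr)))
  }
})

test_that("mean velocity arithmetic matches hand-computed displacements", {
  # 1 px/frame along the diagonal: sqrt(2) * 200 nm per 0.5 s
  tr <- data.frame(frame = 1:21, y_px = 10 + 0:20, x_px = 10 + 0:20)
  v <- mean_velocity(tr, c(0, 100), prot)
  expect_equal(v, sqrt(2) * 200 / 0.5)
  # direction reversals must not cancel (per-frame speeds, not net drift)
  zig <- data.frame(frame = 1:21, y_px = 10, x_px = 10 + rep(c(1, 0), 11)[1:21])
  expect_equal(mean_velocity(zig, c(0, 100), prot), 200 / 0.5)
  expect_warning(v2 <- mean_velocity(tr, c(80, 90), prot), "window")
  expect_true(is.na(v2))
})

test_that("velocity windows split the recording around stimulation and fusion", {
  w <- velocity_windows(prot)
  expect_equal(w$prestim, c(0, 30))
  expect_equal(w$stim, c(30, 54))
  expect_equal(w$poststim, c(54, 90))
  wf <- velocity_windows(prot, fusion_onset_s = 40)
  expect_equal(wf$stim, c(30, 40))
})

test_that("a kymograph turns transport speed into ridge slope", {
  Tn <- 60
  path <- rbind(c(32, 4), c(32, 60))
  # stationary punctum: vertical ridge, speed ~ 0
  stat <- list(data.frame(frame = 1:Tn, y_px = 32, x_px = 30, amp = 300))
  mv_s <- movie_from_array(render_spot_movie(stat, n_frames = Tn))
  expect_lt(kymograph_ridge_speed(build_kymograph(mv_s, path)), 10)
  # moving at 0.475 px/frame = 190 nm/s
  mov <- list(data.frame(frame = 1:Tn, y_px = 32,
                         x_px = 6 + (0:(Tn - 1)) * 0.475, amp = 300))
  mv_m <- movie_from_array(render_spot_movie(mov, n_frames = Tn))
  sp <- kymograph_ridge_speed(build_kymograph(mv_m, path))
  expect_equal(sp, 190, tolerance = 0.05)
  expect_error(build_kymograph(mv_m, rbind(c(0, 0), c(100, 100))), "bounds")
})

test_that("the 200 nm rule assigns events to synapses with exact tie-breaking", {
  syn <- data.frame(y_px = c(10, 20), x_px = c(10, 10))
  # 1 px = 200 nm exactly at the default pixel size: on the boundary counts
  a <- assign_synaptic(c(11, 10), syn)
  expect_equal(as.character(a), "synaptic")
  expect_equal(attr(a, "synapse_id"), 1L)
  b <- assign_synaptic(c(11.51, 10), syn)       # 302 nm from nearest
  expect_equal(as.character(b), "extra-synaptic")
  expect_true(is.na(attr(b, "synapse_id")))
  # equidistant between synapse 1 and 2: deterministic lowest index
  tie <- assign_synaptic(c(15, 10), syn, radius_nm = 1200)
  expect_equal(attr(tie, "synapse_id"), 1L)
  # no synapses: everything extra-synaptic
  none <- assign_synaptic(rbind(c(1, 1), c(2, 2)),
                          data.frame(y_px = numeric(0), x_px = numeric(0)))
  expect_equal(as.character(none), rep("extra-synaptic", 2))
})

test_that("co-trafficking requires joint motion, proximity and correlated steps", {
  fr <- 1:30
  a <- data.frame(frame = fr, y_px = 10, x_px = 10 + fr * 0.5)
  b <- data.frame(frame = fr, y_px = 11, x_px = 10.5 + fr * 0.5)
  expect_true(detect_cotrafficking(a, b))
  # same motion but 8 px apart: not co-trafficking
  far <- data.frame(frame = fr, y_px = 18, x_px = 10 + fr * 0.5)
  r <- detect_cotrafficking(a, far)
  expect_false(r); expect_match(attr(r, "reason"), "far")
  # both stationary: proximity alone is not co-trafficking
  s1 <- data.frame(frame = fr, y_px = 10, x_px = 10)
  s2 <- data.frame(frame = fr, y_px = 10.5, x_px = 10)
  r2 <- detect_cotrafficking(s1, s2)
  expect_false(r2); expect_match(attr(r2, "reason"), "moving")
  # opposite directions: anti-correlated displacements
  c1 <- data.frame(frame = fr, y_px = 10, x_px = 10 + fr * 0.5)
  c2 <- data.frame(frame = fr, y_px = 10.5, x_px = 25 - fr * 0.5)
  expect_false(detect_cotrafficking(c1, c2))
  # too little temporal overlap
  r3 <- detect_cotrafficking(a[1:5, ], b)
  expect_false(r3); expect_match(attr(r3, "reason"), "overlap")
})

test_that("co-trafficking bookkeeping reports one-decimal percentages", {
  tab <- cotraffic_summary(rep(c(TRUE, FALSE), c(7, 99)))
  expect_equal(tab$n, c(7, 99))
  expect_equal(tab$percent, c(6.6, 93.4))
  expect_equal(sum(tab$n), 106)
})
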