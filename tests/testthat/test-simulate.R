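test_that("the generator is deterministic in its seed", {
  cfg <- scene_config(rng_seed = 5, n_vesicles = 10)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$movie$channels$cargo, b$movie$channels$cargo)
  expect_identical(a$truth$events, b$truth$events)
  c <- simulate_scene(scene_config(rng_seed = 6, n_vesicles = 10))
  expect_false(identical(a$movie$channels$cargo, c$movie$channels$cargo))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_scene(scene_config(rng_seed = 3, n_vesicles = 5)))
  expect_identical(.Random.seed, before)
})

test_that("rendered spots match the closed-form Gaussian PSF", {
  # a single stationary red vesicle, no noise, no bleaching: every frame
  # must equal background + peak-normalized Gaussian at the true position
  cfg <- scene_config(n_vesicles = 1, frac_mobile = 0, reporter = "red",
                      fusion_prob_stationary = 0, n_synapses = 0,
                      poisson_noise = FALSE, read_noise_sd = 0,
                      bleach_tau_s = Inf, soma_extra_photons = 0,
                      rng_seed = 2)
  sim <- simulate_scene(cfg)
  pos <- sim$truth$positions[1, 1, ]
  expected <- add_spot_test(
    matrix(cfg$background_photons, 96, 96), pos[1], pos[2],
    cfg$amp_photons, cfg$psf_sigma_px)
  frame1 <- sim$movie$channels$cargo[, , 1]
  # the generator truncates the spot at 4 sigma; compare inside that box
  expect_lt(max(abs(frame1 - expected)),
            cfg$amp_photons * exp(-16 / 2) + 1e-8)
  # noise-free, bleach-free, stationary: all frames identical
  expect_equal(sim$movie$channels$cargo[, , 90], frame1)
})

test_that("pHluorin cargo is quenched before stimulation and unquenches at fusion", {
  cfg <- scene_config(n_vesicles = 8, frac_mobile = 0,
                      fusion_prob_stationary = 1, frac_transient = 0,
                      poisson_noise = FALSE, read_noise_sd = 0,
                      bleach_tau_s = Inf, rng_seed = 4)
  sim <- simulate_scene(cfg)
  ev <- sim$truth$events[!sim$truth$events$somatic, ]
  expect_gt(nrow(ev), 0)
  prot <- sim$truth$protocol
  # every fusion onset lies inside the stimulation epoch
  expect_true(all(ev$onset_frame %in% stim_frames(prot)))
  for (k in seq_len(nrow(ev))) {
    v <- ev$vesicle[k]
    pos <- sim$truth$positions[v, ev$onset_frame[k], ]
    px <- sim$movie$channels$cargo[round(pos[1]) + 1, round(pos[2]) + 1, ]
    pre <- px[ev$onset_frame[k] - 1]
    post <- px[ev$onset_frame[k]]
    # quenched residual is quench_frac of the full amplitude
    expect_lt(pre, cfg$background_photons + 0.2 * cfg$amp_photons)
    expect_gt(post - pre, 0.5 * (1 - cfg$quench_frac) * cfg$amp_photons)
  }
})

test_that("total fluorescence is conserved without noise, bleaching or fusion", {
  cfg <- scene_config(n_vesicles = 12, frac_mobile = 0.5, reporter = "red",
                      fusion_prob_stationary = 0, fusion_prob_mobile = 0,
                      n_synapses = 0, poisson_noise = FALSE, read_noise_sd = 0,
                      bleach_tau_s = Inf, rng_seed = 8)
  sim <- simulate_scene(cfg)
  totals <- apply(sim$movie$channels$cargo, 3, sum)
  # movers near edges could clip their PSF tails; margins prevent that
  expect_lt(diff(range(totals)) / totals[1], 1e-3)
})

test_that("photobleaching follows the configured exponential", {
  cfg <- scene_config(n_vesicles = 0, n_synapses = 0, poisson_noise = FALSE,
                      read_noise_sd = 0, bleach_tau_s = 300, rng_seed = 1)
  sim <- simulate_scene(cfg)
  totals <- apply(sim$movie$channels$cargo, 3, sum)
  tt <- (seq_along(totals) - 1) * 0.5
  expect_equal(totals / totals[1], exp(-tt / 300), tolerance = 1e-6)
})

test_that("overcrowded scenes are rejected rather than silently overlapped", {
  expect_error(
    simulate_scene(scene_config(image_shape = c(32, 32), n_vesicles = 200,
                                rng_seed = 1)),
    "capacity error")
})

test_that("the transient fraction of simulated events matches its setting", {
  modes <- unlist(lapply(1:8, function(s) {
    sim <- simulate_scene(scene_config(rng_seed = s,
                                       fusion_prob_stationary = 0.9,
                                       fusion_prob_mobile = 0.9))
    sim$truth$events$mode
  }))
  n <- length(modes)
  expect_gt(n, 100)
  frac <- mean(modes == "transient")
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(frac - 0.6), 3 * se + 1e-12)
})

test_that("fixtures round-trip through TIFF/JSON/CSV/YAML bit-exactly", {
  cfg <- scene_config(n_vesicles = 6, image_shape = c(48, 48), rng_seed = 11)
  prot <- build_protocol(movie_duration_s = 40, stim_start_s = 10,
                         n_bursts = 8)
  sim <- simulate_scene(cfg, prot)
  dir <- tempfile("fixture")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  quant <- round(pmin(pmax(sim$movie$channels$cargo, 0), 65535))
  expect_equal(back$movie$channels$cargo, quant)
  expect_equal(back$protocol$stim_duration_s, prot$stim_duration_s)
  expect_equal(back$truth$events$onset_frame, sim$truth$events$onset_frame)
  expect_equal(back$truth$positions, sim$truth$positions, tolerance = 1e-12)
  expect_equal(back$truth$synapses$x_px, sim$truth$synapses$x_px)
  expect_equal(length(back$truth$neurites), length(sim$truth$neurites))
  for (i in seq_along(back$truth$neurites))
    expect_equal(back$truth$neurites[[i]],
                 unname(sim$truth$neurites[[i]]), tolerance = 1e-12)
})
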