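test_that("MVC trapezoid has exact plateau, length, ramp midpoint and baseline", {
  f <- generate_mvc_force(5, 1600, peak = 1500, ramp_s = 1, noise_sd = 0, seed = 1)
  expect_s3_class(f, "force_trace")
  expect_length(f$samples, 8000)
  expect_equal(max(f$samples), 1500)
  # plateau is flat at the peak over its whole extent
  t <- (seq_along(f$samples) - 1) / f$rate
  expect_true(all(f$samples[t >= 1 & t <= 4] == 1500))
  # linear ramp midpoint: t = 0.5 s with a 1 s ramp is exactly peak/2
  expect_equal(f$samples[t == 0.5], 750)
  # starts and ends at baseline
  expect_equal(f$samples[1], 0)
  expect_lt(abs(f$samples[length(f$samples)]), 1500 / 1600 + 1e-12)
})

test_that("MVC generation is seed-deterministic and validates parameters", {
  a <- generate_mvc_force(5, 1600, 1500, 1, noise_sd = 30, seed = 7)
  b <- generate_mvc_force(5, 1600, 1500, 1, noise_sd = 30, seed = 7)
  expect_identical(a, b)
  c <- generate_mvc_force(5, 1600, 1500, 1, noise_sd = 30, seed = 8)
  expect_false(identical(a$samples, c$samples))
  expect_error(generate_mvc_force(duration_s = -1), "positive")
  expect_error(generate_mvc_force(rate = 0), "positive")
  expect_error(generate_mvc_force(peak = 0), "positive")
  expect_error(generate_mvc_force(duration_s = 1.5, ramp_s = 1), "2 \\* ramp_s")
})

test_that("block-mean resampling conserves the trapezoid mean within 0.1%", {
  f <- generate_mvc_force(5, 1600, 1500, 1, noise_sd = 0, seed = 1)
  frames <- resample_force(f, 50)
  expect_length(frames, 250)
  expect_lt(abs(mean(frames) - mean(f$samples)) / mean(f$samples), 1e-3)
})

test_that("interface trajectories are affine in force with the site's gain", {
  ph <- test_phantom()
  n <- 100
  # zero coupling: constant at rest depths
  ph0 <- muscle_phantom(gains = c(vl = 0, rf = 0, mh = 0, vmo = 0))
  traj0 <- interface_trajectory(ph0, "vl", rep(800, n))
  expect_true(all(apply(traj0, 2, function(x) all(x == x[1]))))
  expect_equal(unname(traj0[1, ]), ph0$interface_rest_depths$vl)
  # constant force F: offset exactly gain * F
  traj <- interface_trajectory(ph, "rf", rep(300, n))
  expect_equal(unname(traj[1, ]) - ph$interface_rest_depths$rf,
               rep(ph$gains[["rf"]] * 300, 3))
  # trapezoid, gain 0.001 cm/N, peak 1000 N: plateau displacement 1.0 cm
  ph1 <- muscle_phantom(
    interface_rest_depths = list(vl = c(0.5, 1.5), rf = c(1, 2),
                                 mh = c(1, 2), vmo = c(1, 2)),
    gains = c(vl = 1e-3, rf = 0, mh = 0, vmo = 0))
  f <- generate_mvc_force(5, 1600, 1000, 1, noise_sd = 0, seed = 1)
  tr <- interface_trajectory(ph1, "vl", f)
  expect_equal(max(tr[, 1]) - ph1$interface_rest_depths$vl[1], 1.0)
  # unknown site and out-of-window errors are informative
  expect_error(interface_trajectory(ph, "soleus", rep(0, 3)), "unknown site")
  expect_error(interface_trajectory(ph1, "vl", rep(4000, 3)),
               "site 'vl' leaves the imaging window")
})

test_that("noise-free first-interface depth is perfectly correlated with force", {
  ph <- test_phantom(noise = no_noise())
  f <- generate_mvc_force(5, 50, 1200, 1, noise_sd = 15, seed = 4)
  share <- ph$contribution_weights[["vl"]] * f$samples
  traj <- interface_trajectory(ph, "vl", share)
  expect_gt(abs(stats::cor(traj[, 1], f$samples)), 1 - 1e-12)
})

test_that("noise-free rendering puts every column argmax at the interface", {
  traj <- matrix(2, nrow = 40, ncol = 1) # static interface at 2 cm
  img <- render_mmode(traj, depth_px = 128, noise = no_noise(), seed = 1)
  target <- which.min(abs(img$depth_axis - 2))
  expect_true(all(apply(img$intensities, 2, which.max) == target))
  expect_true(all(img$intensities >= 0))
})

test_that("seed isolates the speckle but never moves the band centres", {
  traj <- matrix(seq(1, 3, length.out = 60), ncol = 1)
  a <- render_mmode(traj, depth_px = 128, noise = noise_spec(1, Inf), seed = 1)
  b <- render_mmode(traj, depth_px = 128, noise = noise_spec(1, Inf), seed = 2)
  expect_false(identical(a$intensities, b$intensities))
  clean <- render_mmode(traj, depth_px = 128, noise = no_noise(), seed = 1)
  # speckle is unit-mean: band argmax agrees with the clean render on most
  # frames, and exactly under a repeat of the same seed
  a2 <- render_mmode(traj, depth_px = 128, noise = noise_spec(1, Inf), seed = 1)
  expect_identical(a$intensities, a2$intensities)
  expect_equal(dim(a$intensities), dim(clean$intensities))
})

test_that("higher SNR tracks the clean render more closely (100 frames)", {
  traj <- matrix(seq(1.2, 2.8, length.out = 100), ncol = 1)
  clean <- render_mmode(traj, depth_px = 128, noise = no_noise(), seed = 1)
  hi <- render_mmode(traj, depth_px = 128, noise = noise_spec(0, 40), seed = 9)
  lo <- render_mmode(traj, depth_px = 128, noise = noise_spec(0, 0), seed = 9)
  corr <- function(img) mean(vapply(seq_len(100), function(t) {
    stats::cor(img$intensities[, t], clean$intensities[, t])
  }, numeric(1)))
  expect_gt(corr(hi), corr(lo))
})

test_that("trial datasets follow the train/train/test structure", {
  ds <- small_dataset(seed = 11)
  expect_identical(vapply(ds$trials, `[[`, "", "role"),
                   c("train", "train", "test"))
  expect_identical(names(ds$trials[[1]]$images),
                   c("clinical", "vl", "rf", "mh", "vmo"))
  # 3 s x 50 Hz
  expect_equal(ncol(ds$trials[[1]]$images$vl$intensities), 150)
  expect_length(ds$trials[[1]]$force_frames, 150)
  expect_equal(nrow(ds$trials[[1]]$images$clinical$intensities), 256)
  expect_equal(nrow(ds$trials[[1]]$images$vl$intensities), 128)
  expect_error(generate_trial_dataset(n_trials = 1), "train\\+test")
})

test_that("dataset generation is a pure function of its seed", {
  a <- small_dataset(seed = 21)
  b <- small_dataset(seed = 21)
  expect_identical(a, b)
  c <- small_dataset(seed = 22)
  expect_false(identical(a$trials[[1]]$images$vl$intensities,
                         c$trials[[1]]$images$vl$intensities))
})

test_that("full 5 s default gives 250 frames and weights must sum to one", {
  ds <- generate_trial_dataset(test_phantom(), seed = 2)
  expect_equal(ncol(ds$trials[[1]]$images$vl$intensities), 250)
  expect_error(
    muscle_phantom(contribution_weights = c(vl = 0.5, rf = 0.5, mh = 0.5,
                                            vmo = 0.5)),
    "sum to 1")
  expect_error(
    muscle_phantom(interface_rest_depths = list(
      vl = c(2, 1), rf = c(1, 2), mh = c(1, 2), vmo = c(1, 2))),
    "strictly increasing")
})
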