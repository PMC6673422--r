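test_that("frame pairs are seeded, deterministic, and carry the analytic truth", {
  p <- motion_scene_params("forward", magnitude = 1.5, frame_size = c(64, 64),
                           seed = 5)
  a <- generate_frame_pair(p)
  b <- generate_frame_pair(p)
  expect_identical(a$frame1$pixels, b$frame1$pixels)
  expect_identical(a$frame2$pixels, b$frame2$pixels)
  # static: identical frames, zero truth
  st <- generate_frame_pair(motion_scene_params("static", seed = 5))
  expect_identical(st$frame1$pixels, st$frame2$pixels)
  expect_true(all(st$truth$u == 0) && all(st$truth$v == 0))
  # forward motion: radial field, outward everywhere off-center, magnitude
  # proportional to radius (linear zoom profile)
  H <- 64; cc <- (H + 1) / 2
  rr <- matrix(seq_len(H), H, H) - cc
  ccm <- t(rr)
  rad <- sqrt(rr^2 + ccm^2)
  outward <- a$truth$u * ccm + a$truth$v * rr       # dot product with radius
  expect_true(all(outward[rad > 0] > 0))
  magr <- sqrt(a$truth$u^2 + a$truth$v^2)
  expect_equal(magr[rad > 0] / rad[rad > 0],
               rep(1.5 / (64 / 4), sum(rad > 0)), tolerance = 1e-9)
  # backward motion points inward
  bk <- generate_frame_pair(motion_scene_params("backward", magnitude = 1,
                                                frame_size = c(64, 64), seed = 5))
  inward <- bk$truth$u * ccm + bk$truth$v * rr
  expect_true(all(inward[rad > 0] < 0))
})

test_that("estimated flow on generated pairs recovers the analytic field", {
  for (s in 1:3) {
    p <- motion_scene_params("forward", magnitude = 1, frame_size = c(72, 72),
                             seed = s, noise_sigma = 0.002)
    fp <- generate_frame_pair(p)
    fl <- compute_flow(fp$frame1, fp$frame2)
    epe <- mean(sqrt((fl$u - fp$truth$u)^2 + (fl$v - fp$truth$v)^2))
    expect_lt(epe, 0.3)
  }
})

test_that("degraded frames have the constructed feature signatures", {
  cl <- generate_degraded_frame("clean", seed = 42)
  expect_true(cl$informative)
  dk <- generate_degraded_frame("dark", seed = 42)
  expect_false(dk$informative)
  expect_lt(mean(dk$frame$pixels), 0.1)
  bl <- generate_degraded_frame("blur", seed = 42)
  fcl <- compute_features(cl$frame); fbl <- compute_features(bl$frame)
  expect_lt(fbl[["energy_of_laplacian"]], fcl[["energy_of_laplacian"]])
  st <- generate_degraded_frame("streak", seed = 42)
  fst <- compute_features(st$frame)
  expect_lt(fst[["energy_of_gradient"]], fcl[["energy_of_gradient"]])
  # seeded determinism
  expect_identical(generate_degraded_frame("blur", seed = 7)$frame$pixels,
                   generate_degraded_frame("blur", seed = 7)$frame$pixels)
})

test_that("direction scenarios build the stated phases, counts and transitions", {
  g <- generate_direction_signal(signal_scenario_params(600, 400))
  expect_length(g$signal$values, 2000)
  expect_true(all(g$signal$values[1:1200] == 1))
  expect_true(all(g$signal$values[1201:2000] == -1))
  expect_equal(g$truth_time, 600)
  # one oscillation adds exactly one extra insertion-to-withdrawal transition
  go <- generate_direction_signal(
    signal_scenario_params(600, 400, oscillation_spec = list(c(100, 5))))
  expect_equal(nrow(find_turning_points(go$signal)), 2)
  # seeded determinism under noise
  pn <- signal_scenario_params(300, 200, stop_prob = 0.2,
                               label_noise_prob = 0.1, seed = 8)
  expect_identical(generate_direction_signal(pn)$signal$values,
                   generate_direction_signal(pn)$signal$values)
  # oscillations too close to the phase change are rejected
  expect_error(signal_scenario_params(600, 400,
                                      oscillation_spec = list(c(590, 8))),
               "overlaps")
})

test_that("hue datasets are seeded and class-structured", {
  ds <- small_hue_dataset(3, seed = 4)
  ds2 <- small_hue_dataset(3, seed = 4)
  expect_identical(ds$images[[1]]$pixels, ds2$images[[1]]$pixels)
  expect_equal(table(ds$labels)[["insertion"]], 3)
  # stop images are near-neutral (low chroma), moving classes are saturated
  stopim <- ds$images[[which(ds$labels == "stop")[1]]]$pixels
  insim <- ds$images[[which(ds$labels == "insertion")[1]]]$pixels
  chroma <- function(px) mean(apply(px, c(1, 2), max) - apply(px, c(1, 2), min))
  expect_lt(chroma(stopim), 0.1)
  expect_gt(chroma(insim), 0.4)
})
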