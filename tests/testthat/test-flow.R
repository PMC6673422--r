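test_that("identical frames give zero flow; constant frames converge to zero", {
  set.seed(1)
  f <- generate_frame_pair(motion_scene_params("static", frame_size = c(48, 48),
                                               seed = 2))$frame1$pixels
  fl <- compute_flow(f, f)
  expect_lt(max(abs(fl$u), abs(fl$v)), 1e-6)
  flc <- compute_flow(matrix(0.5, 32, 32), matrix(0.5, 32, 32))
  expect_lt(max(abs(flc$u), abs(flc$v)), 1e-6)
})

test_that("known shifts are recovered by the mean flow", {
  # single 1 px rightward shift: mean u within 20% of 1, |mean v| small
  p <- motion_scene_params("translate", magnitude = 1, direction = c(1, 0),
                           frame_size = c(64, 64), seed = 3)
  fp <- generate_frame_pair(p)
  fl <- compute_flow(fp$frame1, fp$frame2)
  expect_lt(abs(mean(fl$u) - 1), 0.2)
  expect_lt(abs(mean(fl$v)), 0.1)
  # battery of directions and magnitudes <= 2 px: mean endpoint error < 0.3
  for (s in 1:5) for (m in c(0.5, 1, 2)) {
    pp <- motion_scene_params("translate", magnitude = m,
                              direction = c(cos(s), sin(s)),
                              frame_size = c(64, 64), seed = s)
    fpp <- generate_frame_pair(pp)
    ff <- compute_flow(fpp$frame1, fpp$frame2)
    epe <- sqrt((mean(ff$u) - mean(fpp$truth$u))^2 +
                (mean(ff$v) - mean(fpp$truth$v))^2)
    expect_lt(epe, 0.3)
  }
})

test_that("the Horn-Schunck energy is non-increasing across iterations", {
  for (s in 1:4) {
    p <- motion_scene_params(c("translate", "forward")[1 + s %% 2],
                             magnitude = 1.5, frame_size = c(48, 48),
                             seed = s, noise_sigma = 0.01)
    fp <- generate_frame_pair(p)
    e <- attr(compute_flow(fp$frame1, fp$frame2), "energy")
    expect_true(all(diff(e) <= 1e-9 * e[1]))
  }
})

test_that("flow is equivariant to 90-degree rotation and intensity scaling", {
  p <- motion_scene_params("translate", magnitude = 1, direction = c(1, 0.4),
                           frame_size = c(64, 64), seed = 3)
  fp <- generate_frame_pair(p)
  f1 <- fp$frame1$pixels; f2 <- fp$frame2$pixels
  fl <- compute_flow(f1, f2)
  # clockwise rotation maps a vector (u, v) to (-v, u)
  rotcw <- function(m) t(m[nrow(m):1, ])
  flr <- compute_flow(rotcw(f1), rotcw(f2))
  expect_lt(abs(mean(flr$u) - (-mean(fl$v))), 0.02)
  expect_lt(abs(mean(flr$v) - mean(fl$u)), 0.02)
  # scaling both frames leaves the recovered flow unchanged
  fls <- compute_flow(f1 * 5, f2 * 5)
  expect_lt(max(abs(fls$u - fl$u), abs(fls$v - fl$v)), 1e-10)
})

test_that("flow color encoding maps zero to neutral and is invertible", {
  z <- flow_to_color(flow_field(matrix(0, 8, 8), matrix(0, 8, 8)), 2)
  expect_true(all(z$pixels == 1))                 # achromatic white
  # uniform rightward flow at the scale saturates at the 0-degree hue (red)
  r <- flow_to_color(flow_field(matrix(2, 8, 8), matrix(0, 8, 8)), 2)
  expect_true(all(r$pixels[, , 1] == 1) && all(r$pixels[, , 2] == 0) &&
              all(r$pixels[, , 3] == 0))
  # round trip: decode recovers angle within 2 degrees, magnitude within one
  # 8-bit quantization step; the hue step shrinks with saturation, so the
  # angle bound applies above ~15% of the scale
  set.seed(9)
  mag <- matrix(runif(400, 0.3, 1.9), 20)
  ang <- matrix(runif(400, 0, 2 * pi), 20)
  ff <- flow_field(mag * cos(ang), mag * sin(ang))
  dec <- color_to_flow(flow_to_color(ff, 2))
  dmag <- sqrt(dec$u^2 + dec$v^2)
  expect_lt(max(abs(dmag - mag)), 2 / 255 + 1e-9)
  dang <- atan2(dec$v, dec$u)
  derr <- abs((dang - ang + pi) %% (2 * pi) - pi)
  expect_lt(max(derr * 180 / pi), 2)
})

test_that("flow_color_sequence timestamps pairs at the later frame", {
  set.seed(10)
  frames <- lapply(0:2, function(k)
    frame_image(matrix(runif(24 * 24), 24), timestamp = k * 0.5, index = k))
  seqs <- flow_color_sequence(frames, flow_params(n_iterations = 5))
  expect_length(seqs, 2)
  expect_equal(vapply(seqs, `[[`, 0, "timestamp"), c(0.5, 1.0))
})

test_that("dimension and finiteness preconditions are enforced", {
  expect_error(compute_flow(matrix(0, 4, 4), matrix(0, 5, 5)), "dimensions")
  expect_error(compute_flow(matrix(NA_real_, 4, 4), matrix(0, 4, 4)),
               "non-finite")
  expect_error(flow_field(matrix(0, 3, 3), matrix(0, 4, 4)), "identical")
  expect_error(flow_to_color(flow_field(matrix(0, 2, 2), matrix(0, 2, 2)), 0),
               "> 0")
})
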