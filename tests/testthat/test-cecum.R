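test_that("labels encode to the +1/-1/0 signal with the time base preserved", {
  s <- encode_signal(c("insertion", "stop", "withdrawal"), sample_interval = 0.5)
  expect_equal(s$values, c(1, 0, -1))
  expect_equal(s$times, c(0, 0.5, 1))
  expect_equal(encode_signal(rep("stop", 4))$values, rep(0, 4))
  expect_equal(encode_signal(c(1, -1, 0))$values, c(1, -1, 0))
  expect_error(encode_signal(character(0)), "empty")
  expect_error(encode_signal(c("insertion", "sideways")), "insertion")
  expect_error(direction_signal(c(1, 2)), "values")
})

test_that("turning points are found at insertion-to-withdrawal transitions", {
  tp <- function(v) find_turning_points(direction_signal(v, 1))
  # single clean transition: candidate at the first -1
  expect_equal(tp(c(1, 1, -1, -1))$index, 3)
  # zeros are bridged
  expect_equal(tp(c(1, 0, 0, -1))$index, 4)
  # repeated oscillation: one candidate per transition, in order
  expect_equal(tp(c(1, -1, 1, -1))$index, c(2, 4))
  # no transition
  expect_equal(nrow(tp(c(-1, -1, 0, 1, 1))), 0)
  expect_equal(nrow(tp(rep(0, 5))), 0)
  # withdrawal-to-insertion boundaries are not candidates
  expect_equal(tp(c(-1, 1, 1, 0, -1))$index, 5)
})

test_that("window areas match the stated inclusion rule and a loop oracle", {
  # all-insertion signal at 1 sample/s: closed +/-15 s window holds 31 samples
  s <- direction_signal(rep(1, 100), 1)
  expect_equal(window_area(s, 50, 30), 31)
  # antisymmetric window centered at the transition scores zero
  sa <- direction_signal(c(rep(1, 10), rep(-1, 10)), 1)
  expect_equal(window_area(sa, 11, 20), 0)     # 10 x (+1) cancel 10 x (-1)
  sa2 <- direction_signal(c(rep(1, 10), 0, rep(-1, 10)), 1)
  expect_equal(window_area(sa2, 11, 20), 0)
  # random signals against the brute-force loop
  for (s_ in 1:30) {
    sig <- random_signal(s_, n_max = 300)
    ci <- withr::with_seed(s_ + 1000, sample(length(sig$values), 1))
    t <- withr::with_seed(s_ + 2000, runif(1, 1, 60))
    expect_equal(window_area(sig, ci, t), oracle_window_area(sig, ci, t))
  }
  expect_error(window_area(s, 0, 30), "outside")
  expect_error(window_area(s, 50, 0), "> 0")
})

test_that("the locator agrees with exhaustive candidate enumeration", {
  n_checked <- 0
  for (s_ in 1:1000) {
    sig <- random_signal(s_)
    t <- c(10, 20, 30)[1 + s_ %% 3]
    est <- locate_cecum(sig, t)
    orc <- oracle_locate(sig, t)
    expect_equal(est$time, orc$time)
    if (!is.na(orc$time)) {
      expect_equal(est$score, orc$score)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 900)   # nearly all random signals have a transition
})

test_that("clean two-phase signals are recovered exactly at every window width", {
  g <- generate_direction_signal(signal_scenario_params(600, 400))
  for (t in c(10, 20, 30)) {
    est <- locate_cecum(g$signal, t)
    expect_equal(est$time, g$truth_time)
    expect_equal(est$n_candidates, 1L)
  }
})

test_that("short oscillations lose to the true phase change at t = 30", {
  p <- signal_scenario_params(600, 400, oscillation_spec = list(c(100, 5)))
  g <- generate_direction_signal(p)
  expect_equal(nrow(find_turning_points(g$signal)), 2)
  est <- locate_cecum(g$signal, 30)
  expect_equal(est$time, 600)
  expect_equal(est$n_candidates, 2L)
})

test_that("exact ties resolve to the earliest candidate", {
  # two identical symmetric transitions separated by enough slack
  v <- c(rep(1, 40), rep(-1, 40), rep(1, 40), rep(-1, 40))
  sig <- direction_signal(v, 1)
  est <- locate_cecum(sig, 10)
  areas <- est$candidates$window_area
  expect_equal(abs(areas[1]), abs(areas[2]))
  expect_equal(est$time, est$candidates$time[1])
})

test_that("stop padding beyond t/2 leaves the estimate unchanged", {
  g <- generate_direction_signal(
    signal_scenario_params(300, 200, oscillation_spec = list(c(80, 6))))
  base <- locate_cecum(g$signal, 30)$time
  pad <- rep(0, 60)                       # 30 s of stops at 0.5 s sampling
  v2 <- c(pad, g$signal$values, pad)
  sig2 <- direction_signal(v2, 0.5, start_time = -30)
  expect_equal(locate_cecum(sig2, 30)$time, base)
})

test_that("signals survive a CSV round trip in the locator's dialect", {
  g <- generate_direction_signal(signal_scenario_params(60, 40, stop_prob = 0.2,
                                                        seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(g$signal, path)
  back <- read_signal_csv(path)
  expect_equal(back$values, g$signal$values)
  expect_equal(back$times, g$signal$times)
  # label dialect
  df <- data.frame(timestamp_s = c(0, 0.5, 1),
                   label = c("insertion", "stop", "withdrawal"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_equal(read_signal_csv(p2)$values, c(1, 0, -1))
})
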