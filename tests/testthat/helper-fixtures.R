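# Shared fixture builders. CNN tests run on reduced image sizes and filter
# counts so the suite stays fast; the full-size default architecture is
# exercised in the acceptance tests.

small_cnn_cfg <- function(...) {
  base <- list(input_width = 40L, input_height = 36L,
               conv_filters = c(8L, 16L), fc_units = 32L, batch_size = 32L,
               n_search_draws = 0L, n_epochs = 8L, learning_rate = 0.01,
               seed = 11L)
  do.call(cnn_config, utils::modifyList(base, list(...)))
}

small_hue_dataset <- function(n_per_class = 40L, seed = 2L, angle_jitter = 10) {
  generate_flow_color_dataset(n_per_class = n_per_class, width = 40L,
                              height = 36L, angle_jitter = angle_jitter,
                              seed = seed)
}

# battery of noisy two-phase scenarios within the documented noise bands
# (oscillations <= 10 s, label noise <= 10%, stops <= 20%)
battery_scenario <- function(seed) {
  withr::with_seed(seed, {
    osc_t <- stats::runif(2, 50, 500)
    osc_l <- stats::runif(2, 2, 10)
  })
  signal_scenario_params(
    insertion_duration = 600, withdrawal_duration = 400,
    oscillation_spec = list(c(osc_t[1], osc_l[1]), c(osc_t[2], osc_l[2])),
    stop_prob = 0.15, label_noise_prob = 0.08, seed = seed)
}
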