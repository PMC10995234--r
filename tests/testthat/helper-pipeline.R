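# Expensive end-to-end artifacts shared across tests, computed once per
# test session.
the_cache <- new.env(parent = emptyenv())

# Full default-scale pipeline run (180-record cohort, 11 rankings,
# 68 models).
full_run <- function() {
  if (is.null(the_cache$full)) {
    the_cache$full <- run_pipeline(seed = 42)
  }
  the_cache$full
}

# Leave-one-subject-out baseline accuracy when the cough bursts are
# scaled down to the baseline noise floor, removing the class contrast.
collapsed_loso_accuracy <- function() {
  if (is.null(the_cache$collapsed)) {
    cfg <- sim_config(burst_peak_amp = sim_config()$noise_sd, seed = 43)
    co <- simulate_cohort(cfg)
    prep <- preprocess_cohort(co$manifest, co$recordings, seed = 44)
    tb <- feature_table(rbind(
      as.data.frame(extract_features(prep$train_windows)),
      as.data.frame(extract_features(prep$test_windows))))
    folds <- sort(unique(tb$subject_id))
    accs <- vapply(folds, function(s) {
      model <- fit_classifier(tb[tb$subject_id != s, ])
      held <- tb[tb$subject_id == s, ]
      mean(predict(model, held) == held$label)
    }, numeric(1))
    the_cache$collapsed <- mean(accs)
  }
  the_cache$collapsed
}
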