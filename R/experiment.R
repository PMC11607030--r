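#' End-to-end channel-shift experiment on synthetic data
#'
#' Generates the synthetic five-class dataset, balances the idle class,
#' splits recordings 80:10:10, trains the classifier on the reference
#' channel, measures the accuracy drop when the test set is convolved
#' with an attenuating adapter channel, and measures how much of that gap
#' fine-tuning on the convolved training set recovers.
#'
#' @param n_per_class recordings per class (default 40).
#' @param seed master seed for data generation, splitting and training.
#' @param profile adapter [channel_profile()] (default the silicone-tube
#'   channel, the strongest attenuator).
#' @param hp training [hyper_params()]; default RMSprop, learning rate
#'   1e-4, batch 128 (the best cell of the original grid search).
#' @param base_dir working directory for generated audio (default a
#'   session temporary directory).
#' @param specs tissue-sound class specifications.
#' @return list with `macc_clean` (reference model on unconvolved test),
#'   `macc_shifted` (reference model on convolved test), `macc_finetuned`
#'   (fine-tuned model on convolved test), `gap`, `recovery` (fraction of
#'   the gap closed), `base_model`, `finetuned_model`, reports.
#' @export
run_channel_shift_experiment <- function(n_per_class = 40, seed = 42,
                                         profile = default_channel_profile("tube"),
                                         hp = NULL,
                                         base_dir = tempfile("laparo_exp"),
                                         specs = default_tissue_specs()) {
  if (is.null(hp)) hp <- hyper_params("RMSprop", 1e-4, 128L, epochs = 30L,
                                      seed = seed %% 100000L)
  dir.create(base_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- make_dataset(n_per_class, seed = seed,
                           out_dir = file.path(base_dir, "raw"), specs = specs)
  manifest <- balance_idle(manifest, seed = seed)
  manifest <- split_manifest(manifest, seed = seed)

  ir <- synth_adapter_ir(profile, fs = 48000)
  conv_manifest <- convolve_dataset(manifest, ir,
                                    out_dir = file.path(base_dir, profile$name))

  fs_ref <- lapply(split(manifest, manifest$split), function(m)
    feature_set(patches_from_manifest(m), ir_name = "reference"))
  fs_conv <- lapply(split(conv_manifest, conv_manifest$split), function(m)
    feature_set(patches_from_manifest(m), ir_name = profile$name))

  base <- train_classifier(fs_ref$train, fs_ref$val, hp)
  rep_clean <- evaluate_model(base, fs_ref$test)
  rep_shift <- evaluate_model(base, fs_conv$test)

  ft <- fine_tune(base, fs_conv$train, fs_conv$val)
  rep_ft <- evaluate_model(ft, fs_conv$test)

  gap <- rep_clean$mAcc - rep_shift$mAcc
  list(
    macc_clean = rep_clean$mAcc,
    macc_shifted = rep_shift$mAcc,
    macc_finetuned = rep_ft$mAcc,
    gap = gap,
    recovery = if (gap > 0) (rep_ft$mAcc - rep_shift$mAcc) / gap else NA_real_,
    base_model = base, finetuned_model = ft,
    report_clean = rep_clean, report_shifted = rep_shift,
    report_finetuned = rep_ft,
    manifest = manifest
  )
}
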