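# Benchmark metrics reported by the original adapter evaluation study
# whose measurement and classification pipeline this package models. They
# serve as reference inputs for the metric arithmetic (F1 from mAP/mAR,
# cross-test-set summaries); the study's recorded dataset itself is not
# available.

#' Reported per-adapter classification results of the original study
#'
#' One row per test set: the unconvolved reference-microphone set and
#' nine adapter-convolved variants. `macc_original` is the
#' reference-trained model's accuracy on each set; the `*_finetuned`
#' columns are the metrics of the model fine-tuned on the matching
#' convolved training set (not reported for the reference row).
#'
#' @return data.frame with columns `test_set`, `macc_original`,
#'   `macc_finetuned`, `map_finetuned`, `mar_finetuned`, `f1_finetuned`.
#' @export
adapter_benchmark <- function() {
  data.frame(
    test_set = c("original (ref. mic)", "Dual channel",
                 "Luer-Lock 11 mm w/o I", "Luer-Lock 11 mm w/ I",
                 "Luer-Lock 13 mm w/o I", "Luer-Lock 13 mm w/ I",
                 "Tube 11 mm w/o I", "Tube 11 mm w/ I",
                 "Tube 13 mm w/o I", "Tube 13 mm w/ I"),
    macc_original = c(0.9657, 0.9097, 0.5939, 0.4061, 0.6941, 0.5900,
                      0.6236, 0.5682, 0.5728, 0.6282),
    macc_finetuned = c(NA, 0.8952, 0.9598, 0.9314, 0.9420, 0.9123,
                       0.8134, 0.8504, 0.9268, 0.7416),
    map_finetuned = c(NA, 0.8804, 0.9590, 0.9290, 0.9224, 0.8789,
                      0.8299, 0.9020, 0.9118, 0.7888),
    mar_finetuned = c(NA, 0.9271, 0.9494, 0.9348, 0.9207, 0.9321,
                      0.8496, 0.8936, 0.9261, 0.7594),
    f1_finetuned = c(NA, 0.9032, 0.9542, 0.9319, 0.9216, 0.9047,
                     0.8397, 0.8978, 0.9148, 0.7738),
    stringsAsFactors = FALSE
  )
}

#' Reported headline test metrics of the reference-channel model
#'
#' Overall test-set metrics of the study's best grid-search cell
#' (RMSprop, learning rate 1e-4, batch 128) on the unconvolved data.
#'
#' @return named numeric vector with `mAcc`, `mAP`, `mAR`, `f1`.
#' @export
headline_metrics <- function() {
  c(mAcc = 0.966, mAP = 0.943, mAR = 0.968, f1 = 0.955)
}
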