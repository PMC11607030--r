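#' Generate a labelled synthetic audio dataset on disk
#'
#' Draws `n_per_class` recordings per class with durations uniform over
#' each class's admissible range, writes them as float WAV files, and
#' writes a manifest CSV (`path`, `class`, `duration_s`, `seed`).
#' Fully deterministic for fixed `(n_per_class, seed, specs)`.
#'
#' @param n_per_class recordings per class (>= 2).
#' @param seed master seed; per-file seeds and durations are derived from
#'   it.
#' @param out_dir output directory (created if missing).
#' @param specs named list of [tissue_sound_spec()] objects; default the
#'   five-class set of [default_tissue_specs()].
#' @param fs sampling rate in Hz.
#' @return the manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
make_dataset <- function(n_per_class, seed, out_dir,
                         specs = default_tissue_specs(), fs = 48000) {
  stopifnot(n_per_class >= 2, length(specs) >= 1)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)

  classes <- names(specs)
  total <- n_per_class * length(classes)
  plan <- with_seed(seed, {
    file_seeds <- sample.int(.Machine$integer.max - 1L, total)
    durations <- unlist(lapply(specs, function(sp)
      stats::runif(n_per_class, sp$duration_range_s[1], sp$duration_range_s[2])))
    list(file_seeds = file_seeds, durations = durations)
  })

  manifest <- data.frame(
    path = character(total), class = character(total),
    duration_s = numeric(total), seed = integer(total),
    stringsAsFactors = FALSE
  )
  k <- 0L
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sp <- specs[[ci]]
      dur <- plan$durations[(ci - 1L) * n_per_class + i]
      sig <- synth_tissue_sound(sp, dur, seed = plan$file_seeds[k], fs = fs)
      path <- file.path(out_dir, sprintf("%s_%03d.wav", classes[ci], i))
      tryCatch(write_wav(sig, path),
               error = function(e) stop("failed writing ", path, ": ",
                                        conditionMessage(e)))
      manifest$path[k] <- path
      manifest$class[k] <- classes[ci]
      manifest$duration_s[k] <- dur
      manifest$seed[k] <- plan$file_seeds[k]
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
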