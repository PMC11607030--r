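# Dataset assembly: idle-class balancing by accumulated duration and a
# recording-level stratified 80:10:10 split, so overlapping windows from
# one recording never straddle splits.

#' Balance the idle class by accumulated duration
#'
#' Caps the total idle duration at the maximum accumulated duration among
#' the non-idle classes: idle recordings are shuffled with the given seed
#' and greedily accumulated until adding the next one would exceed the
#' cap. Non-idle rows are untouched. Idempotent.
#'
#' @param manifest data.frame with `class` and `duration_s` columns.
#' @param seed shuffle seed.
#' @param idle_class name of the idle class (default `"idle"`).
#' @return the balanced manifest (original row order preserved).
#' @export
balance_idle <- function(manifest, seed = 1, idle_class = "idle") {
  stopifnot(all(c("class", "duration_s") %in% names(manifest)))
  is_idle <- manifest$class == idle_class
  if (!any(!is_idle)) stop("manifest needs at least one non-idle class")
  if (!any(is_idle)) return(manifest)
  cap <- max(tapply(manifest$duration_s[!is_idle], manifest$class[!is_idle], sum))
  idle_idx <- which(is_idle)
  order_idle <- idle_idx[with_seed(seed, sample.int(length(idle_idx)))]
  keep <- logical(nrow(manifest))
  keep[!is_idle] <- TRUE
  acc <- 0
  for (i in order_idle) {
    if (acc + manifest$duration_s[i] <= cap) {
      keep[i] <- TRUE
      acc <- acc + manifest$duration_s[i]
    }
  }
  manifest[keep, , drop = FALSE]
}

#' Split a manifest into train / validation / test sets
#'
#' Recording-level split at the given ratios (default 80:10:10),
#' stratified by class: every recording lands in exactly one split and
#' per-class proportions are within one recording of the targets.
#'
#' @param manifest data.frame with a `class` column.
#' @param ratios length-3 positive vector summing to 1.
#' @param seed shuffle seed.
#' @param stratified split within each class (default); requires at least
#'   3 recordings per class.
#' @return the manifest with an added `split` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_manifest <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1,
                           stratified = TRUE) {
  stopifnot(length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9, "class" %in% names(manifest))
  assign_one <- function(idx) {
    n <- length(idx)
    if (n < 3L)
      stop("stratified split needs at least 3 recordings per class (got ", n, ")")
    n_val <- max(1L, round(n * ratios[2]))
    n_test <- max(1L, round(n * ratios[3]))
    n_train <- n - n_val - n_test
    if (n_train < 1L) stop("split ratios leave no training recordings")
    perm <- sample(idx)
    out <- rep("train", n)
    out[match(perm[seq_len(n_val)], idx)] <- "val"
    out[match(perm[n_val + seq_len(n_test)], idx)] <- "test"
    out
  }
  split <- character(nrow(manifest))
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(manifest$class)) {
        idx <- which(manifest$class == cl)
        split[idx] <- assign_one(idx)
      }
    } else {
      split[] <- assign_one(seq_len(nrow(manifest)))
    }
  })
  manifest$split <- split
  manifest
}
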