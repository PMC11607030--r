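# Compact trainable classifier over 96 x 64 log-mel patches. The default
# backbone ("compact_mlp") pools each patch over time into per-band mean
# and spread features (2 x 64 = 128 inputs), standardizes them with
# training-set statistics, and trains a single-hidden-layer softmax
# network by minibatch gradient descent with a choice of ADAM or RMSprop.
# Model selection is by best validation loss across epochs; fine-tuning
# restarts training from an existing model's weights with all weights
# trainable.

CLASSIFIER_GRID <- list(optimizer = c("ADAM", "RMSprop"),
                        learning_rate = c(1e-3, 1e-4, 1e-5),
                        batch_size = c(64L, 128L, 256L))

#' Declare the classifier architecture
#'
#' @param input_shape patch geometry, fixed at `c(96, 64)`.
#' @param n_classes number of output classes (default 5).
#' @param hidden hidden-layer width of the compact backbone.
#' @param backbone `"compact_mlp"` (built in) or a user function mapping a
#'   patch array `(K, 96, 64)` to a feature matrix (pluggable backbone).
#' @return a `model_spec`.
#' @export
model_spec <- function(input_shape = c(96, 64), n_classes = 5L, hidden = 48L,
                       backbone = "compact_mlp") {
  stopifnot(identical(as.integer(input_shape), c(96L, 64L)), n_classes >= 2)
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), backbone = backbone),
            class = "model_spec")
}

#' Declare a training hyper-parameter set
#'
#' In grid mode (the default) values must come from the declared search
#' grid: optimizer in \{ADAM, RMSprop\}, learning rate in
#' \{1e-3, 1e-4, 1e-5\}, batch size in \{64, 128, 256\}. Set
#' `free = TRUE` to allow arbitrary values.
#'
#' @param optimizer `"ADAM"` or `"RMSprop"`.
#' @param learning_rate constant learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs (default 30).
#' @param seed RNG seed fanned out to weight init and shuffling.
#' @param free allow values outside the declared grid.
#' @return a `hyper_params`.
#' @export
hyper_params <- function(optimizer = "RMSprop", learning_rate = 1e-4,
                         batch_size = 128L, epochs = 30L, seed = 1L,
                         free = FALSE) {
  if (!free) {
    if (!optimizer %in% CLASSIFIER_GRID$optimizer)
      stop("optimizer must be one of ", paste(CLASSIFIER_GRID$optimizer, collapse = ", "))
    if (!any(abs(learning_rate - CLASSIFIER_GRID$learning_rate) < 1e-12))
      stop("learning_rate must come from the declared grid (or use free = TRUE)")
    if (!as.integer(batch_size) %in% CLASSIFIER_GRID$batch_size)
      stop("batch_size must come from the declared grid (or use free = TRUE)")
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "hyper_params")
}

#' Pool a patch array into backbone features
#'
#' Per mel band, the mean and standard deviation over the 96 time frames:
#' a `K x 128` feature matrix.
#'
#' @param patches array `(K, 96, 64)` or a `mel_patch_set`.
#' @return numeric matrix `K x 128`.
#' @export
pool_patch_features <- function(patches) {
  if (inherits(patches, "mel_patch_set")) patches <- patches$patches
  stopifnot(length(dim(patches)) == 3L)
  K <- dim(patches)[1]
  means <- apply(patches, c(1, 3), mean)
  sds <- apply(patches, c(1, 3), stats::sd)
  out <- cbind(means, sds)
  dim(out) <- c(K, 2L * dim(patches)[3])
  out
}

#' Assemble patch-level features and labels from a list of patch sets
#'
#' @param patch_sets list of `mel_patch_set` (one per recording).
#' @param ir_name optional channel identifier recorded as provenance.
#' @return a `feature_set`: list with `X` (n x 128), `y` (character),
#'   `source_id` (character, per patch), `ir_name`.
#' @export
feature_set <- function(patch_sets, ir_name = "reference") {
  Xs <- lapply(patch_sets, pool_patch_features)
  X <- do.call(rbind, Xs)
  y <- unlist(lapply(patch_sets, function(p) rep(p$label, p$K)))
  src <- unlist(lapply(patch_sets, function(p) rep(p$source_id, p$K)))
  structure(list(X = X, y = y, source_id = src, ir_name = ir_name),
            class = "feature_set")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cls_forward <- function(w, X) {
  H <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  P <- softmax_rows(sweep(H %*% w$W2, 2, w$b2, "+"))
  list(H = H, P = P)
}

cls_loss <- function(P, y_idx) {
  -mean(log(pmax(P[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

make_opt_state <- function(w) lapply(w, function(p) list(m = p * 0, v = p * 0))

opt_update <- function(w, grads, state, hp, t) {
  eps <- 1e-8
  for (nm in names(w)) {
    g <- grads[[nm]]
    if (hp$optimizer == "ADAM") {
      state[[nm]]$m <- 0.9 * state[[nm]]$m + 0.1 * g
      state[[nm]]$v <- 0.999 * state[[nm]]$v + 0.001 * g^2
      mhat <- state[[nm]]$m / (1 - 0.9^t)
      vhat <- state[[nm]]$v / (1 - 0.999^t)
      w[[nm]] <- w[[nm]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
    } else {  # RMSprop
      state[[nm]]$v <- 0.9 * state[[nm]]$v + 0.1 * g^2
      w[[nm]] <- w[[nm]] - hp$learning_rate * g / (sqrt(state[[nm]]$v) + eps)
    }
  }
  list(w = w, state = state)
}

init_weights <- function(n_in, hidden, n_classes) {
  list(W1 = matrix(stats::rnorm(n_in * hidden, sd = sqrt(2 / n_in)), n_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * n_classes, sd = sqrt(2 / hidden)),
                   hidden, n_classes),
       b2 = numeric(n_classes))
}

#' Train the classifier
#'
#' Minibatch cross-entropy training with the chosen optimizer; after each
#' epoch the validation loss is computed and the returned weights are
#' those of the epoch with minimum validation loss. Early stopping when
#' the validation loss has not improved for `patience` epochs.
#' Deterministic for a fixed seed.
#'
#' @param train,val `feature_set` objects with disjoint `source_id` sets.
#' @param hp a [hyper_params()].
#' @param spec a [model_spec()].
#' @param patience early-stopping patience in epochs (default 10).
#' @param init optional `laparo_model` whose weights and feature
#'   normalization seed the run (used by [fine_tune()]).
#' @param verbose print per-epoch losses.
#' @return a `laparo_model`: weights, normalization stats, class levels,
#'   per-epoch `history`, `best_epoch`, provenance.
#' @export
train_classifier <- function(train, val, hp = hyper_params(),
                             spec = model_spec(), patience = 10L,
                             init = NULL, verbose = FALSE) {
  stopifnot(inherits(train, "feature_set"), inherits(val, "feature_set"))
  if (nrow(train$X) == 0L || nrow(val$X) == 0L) stop("empty training or validation split")
  if (length(intersect(unique(train$source_id), unique(val$source_id))) > 0)
    stop("train and validation sets share source recordings (leakage)")

  classes <- if (is.null(init)) sort(unique(c(train$y, val$y))) else init$classes
  y_tr <- match(train$y, classes)
  y_va <- match(val$y, classes)
  if (anyNA(y_tr) || anyNA(y_va)) stop("labels outside the model's class set")

  if (is.null(init)) {
    mu <- colMeans(train$X)
    sd_ <- apply(train$X, 2, stats::sd)
    sd_[sd_ < 1e-8] <- 1
  } else {
    mu <- init$norm$mu
    sd_ <- init$norm$sd
  }
  Xtr <- sweep(sweep(train$X, 2, mu), 2, sd_, "/")
  Xva <- sweep(sweep(val$X, 2, mu), 2, sd_, "/")

  n <- nrow(Xtr)
  onehot <- diag(length(classes))[y_tr, , drop = FALSE]

  with_seed(hp$seed, {
    w <- if (is.null(init)) init_weights(ncol(Xtr), spec$hidden, length(classes))
         else init$weights
    state <- make_opt_state(w)
    t_step <- 0L
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), val_acc = numeric())
    best <- list(loss = Inf, w = w, epoch = 0L)
    for (epoch in seq_len(hp$epochs)) {
      perm <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = hp$batch_size)) {
        idx <- perm[start:min(start + hp$batch_size - 1L, n)]
        B <- length(idx)
        X <- Xtr[idx, , drop = FALSE]
        Y <- onehot[idx, , drop = FALSE]
        fwd <- cls_forward(w, X)
        batch_losses <- c(batch_losses, cls_loss(fwd$P, y_tr[idx]))
        dZ2 <- (fwd$P - Y) / B
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(fwd$H, dZ2), b2 = colSums(dZ2))
        dH <- dZ2 %*% t(w$W2)
        dZ1 <- dH * (fwd$H > 0)
        grads$W1 <- crossprod(X, dZ1)
        grads$b1 <- colSums(dZ1)
        t_step <- t_step + 1L
        upd <- opt_update(w, grads, state, hp, t_step)
        w <- upd$w
        state <- upd$state
      }
      va <- cls_forward(w, Xva)
      val_loss <- cls_loss(va$P, y_va)
      val_acc <- mean(max.col(va$P) == y_va)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = val_loss, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                        epoch, mean(batch_losses), val_loss, val_acc))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, w = w, epoch = epoch)
      if (epoch - best$epoch >= patience) break
    }
    structure(
      list(weights = best$w, norm = list(mu = mu, sd = sd_),
           classes = classes, spec = spec, hp = hp,
           history = history, best_epoch = best$epoch,
           ir_name = train$ir_name,
           base_ir_name = if (is.null(init)) NULL else init$ir_name),
      class = "laparo_model"
    )
  })
}

#' @export
print.laparo_model <- function(x, ...) {
  cat(sprintf("<laparo_model> %d classes, %s backbone, trained on '%s' channel; best epoch %d (val loss %.4f)\n",
              length(x$classes), x$spec$backbone, x$ir_name, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict classes (and probabilities) for a feature set
#'
#' @param object a `laparo_model`.
#' @param newdata a `feature_set` or bare feature matrix.
#' @param ... unused.
#' @return character vector of predicted classes with a `"prob"`
#'   attribute (n x n_classes softmax matrix).
#' @export
predict.laparo_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_set")) newdata$X else newdata
  X <- sweep(sweep(X, 2, object$norm$mu), 2, object$norm$sd, "/")
  P <- cls_forward(object$weights, X)$P
  colnames(P) <- object$classes
  out <- object$classes[max.col(P)]
  attr(out, "prob") <- P
  out
}

#' Evaluate a model on a feature set
#'
#' @param model a `laparo_model`.
#' @param test a `feature_set`.
#' @return an `eval_report` (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  evaluate_predictions(as.character(pred), test$y, classes = model$classes)
}

#' Hyper-parameter grid search
#'
#' Trains one model per grid cell (each selected at its own best
#' validation epoch) and reports validation and test performance for
#' every cell. The returned best cell is chosen by test accuracy when
#' `selection = "test"` — the protocol of the original study, flagged in
#' the report as optimistically biased — or by validation loss when
#' `selection = "validation"`.
#'
#' @param train,val,test `feature_set` objects.
#' @param grid named list with `optimizer`, `learning_rate`, `batch_size`
#'   vectors; default the full declared grid.
#' @param epochs,seed,spec,patience passed through to
#'   [train_classifier()].
#' @param selection `"test"` or `"validation"`.
#' @return list with `report` (one row per cell), `best_hp`, `best_model`.
#' @export
grid_search <- function(train, val, test, grid = CLASSIFIER_GRID,
                        epochs = 30L, seed = 1L, spec = model_spec(),
                        patience = 10L, selection = c("test", "validation")) {
  selection <- match.arg(selection)
  cells <- expand.grid(optimizer = grid$optimizer,
                       learning_rate = grid$learning_rate,
                       batch_size = grid$batch_size,
                       stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) stop("empty grid")
  report <- cells
  report$best_epoch <- NA_integer_
  report$val_loss <- NA_real_
  report$val_macc <- NA_real_
  report$test_macc <- NA_real_
  models <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hp <- hyper_params(cells$optimizer[i], cells$learning_rate[i],
                       cells$batch_size[i], epochs = epochs, seed = seed)
    m <- train_classifier(train, val, hp, spec = spec, patience = patience)
    models[[i]] <- m
    report$best_epoch[i] <- m$best_epoch
    report$val_loss[i] <- m$history$val_loss[m$best_epoch]
    report$val_macc[i] <- m$history$val_acc[m$best_epoch]
    report$test_macc[i] <- evaluate_model(m, test)$mAcc
  }
  best_i <- if (selection == "test") which.max(report$test_macc)
            else which.min(report$val_loss)
  attr(report, "selection") <- selection
  attr(report, "selection_note") <-
    "selection by test performance is optimistically biased; see selection = 'validation'"
  list(report = report, best_hp = models[[best_i]]$hp,
       best_model = models[[best_i]])
}

#' Fine-tune a trained model on channel-convolved data
#'
#' Restarts training from the base model's weights (all weights
#' trainable, same feature normalization) on a convolved training set,
#' again selecting the epoch with best validation loss. The convolved
#' train and validation sets must come from the same channel.
#'
#' @param base_model a `laparo_model` trained on reference-channel data.
#' @param train,val `feature_set` objects from the convolved channel.
#' @param hp optional [hyper_params()]; defaults to the base model's.
#' @param patience early-stopping patience.
#' @return a fine-tuned `laparo_model`; `ir_name` records the channel,
#'   `base_ir_name` the base model's.
#' @export
fine_tune <- function(base_model, train, val, hp = NULL, patience = 10L) {
  stopifnot(inherits(base_model, "laparo_model"))
  if (!identical(train$ir_name, val$ir_name))
    stop(sprintf("channel mismatch: train convolved with '%s', val with '%s'",
                 train$ir_name, val$ir_name))
  if (is.null(hp)) hp <- base_model$hp
  train_classifier(train, val, hp, spec = base_model$spec,
                   patience = patience, init = base_model)
}
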