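#' Training configuration
#'
#' Defaults follow the study recipe: Adam (learning rate 0.001), cross
#' entropy loss, batch size 64.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param seed Base seed; the shuffle and augmentation stream of global
#'   epoch `e` is seeded deterministically from `(seed, e)`, so training is
#'   reproducible and can be resumed mid-stream via `epoch_offset` in
#'   [train_model()].
#' @param augment Optional per-image augmentation function
#'   (H x W matrix -> H x W matrix), e.g. built from [train_transform()]
#'   pieces; applied to each training image every epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L, augment = NULL) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

epoch_seed <- function(seed, global_epoch) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + global_epoch) %% 2147483629) + 1L
}

#' Train a model on a dataset
#'
#' Minibatch Adam training with cross-entropy loss. Optimizer state is
#' created fresh for each call (as in a federated round, where only model
#' parameters cross the wire); batch-norm running statistics update during
#' training and travel with the parameter vector.
#'
#' @param model A `fedceph_model`.
#' @param data A `ceph_dataset`.
#' @param cfg A [train_config()].
#' @param epoch_offset Global-epoch offset for seeding, so that successive
#'   calls (e.g. federated rounds) continue the same shuffle stream.
#' @return List with `model` (trained) and `history` (tibble of per-epoch
#'   mean loss).
#' @export
train_model <- function(model, data, cfg = train_config(), epoch_offset = 0L) {
  stopifnot(inherits(model, "fedceph_model"), inherits(data, "ceph_dataset"))
  n <- length(data$y)
  if (n == 0L) stop("empty training dataset", call. = FALSE)
  trainable <- grep("running_", names(model$params), invert = TRUE, value = TRUE)
  opt <- adam_init(trainable)
  losses <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    ge <- epoch_offset + e
    epoch_loss <- with_seed(epoch_seed(cfg$seed, ge), {
      perm <- sample.int(n)
      batch_starts <- seq.int(1L, n, by = cfg$batch_size)
      bl <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- perm[batch_starts[bi]:min(batch_starts[bi] + cfg$batch_size - 1L, n)]
        xb <- data$x[idx, , , , drop = FALSE]
        if (!is.null(cfg$augment)) {
          for (k in seq_along(idx)) xb[k, 1L, , ] <- cfg$augment(xb[k, 1L, , ])
        }
        yb <- data$y[idx]
        fwd <- model_forward(model, xb, training = TRUE)
        lo <- ce_loss(fwd$logits, yb)
        grads <- fwd$back(lo$grad)
        params <- adam_step(opt, model$params, grads, lr = cfg$lr,
                            beta1 = cfg$beta1, beta2 = cfg$beta2)
        for (nm in names(fwd$buffers)) params[[nm]] <- fwd$buffers[[nm]]
        model$params <- params
        bl[bi] <- lo$loss
      }
      mean(bl)
    })
    losses[e] <- epoch_loss
  }
  list(model = model,
       history = tibble::tibble(epoch = seq_len(cfg$epochs) + epoch_offset,
                                loss = losses))
}

#' Evaluate a model on a dataset
#'
#' Evaluation-mode forward pass in batches; scores are softmax
#' probabilities.
#'
#' @param model A `fedceph_model`.
#' @param data A `ceph_dataset`.
#' @param batch_size Evaluation batch size.
#' @return A `metrics_report` (see [compute_metrics()]).
#' @export
evaluate_model <- function(model, data, batch_size = 128L) {
  n <- length(data$y)
  scores <- matrix(0, n, model$spec$n_classes)
  for (s in seq.int(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    scores[idx, ] <- predict(model, data$x[idx, , , , drop = FALSE], type = "prob")
  }
  compute_metrics(data$y, scores)
}
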