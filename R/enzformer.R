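#' Fit a self-attention enzyme-class classifier
#'
#' Trains a transformer encoder with a CLS classification head on labelled
#' protein sequences, following the published fine-tuning recipe: flat
#' (non-hierarchical) cross-entropy over classes, Adam with geometric
#' per-epoch learning-rate decay, gradient accumulation, dropout on the
#' normalised classification embedding only, and optional inverse-frequency
#' class-balanced sampling with replacement.  Training runs from random
#' initialisation and is fully reproducible from `tconf$seed`.
#'
#' Sequences are processed one at a time and gradients averaged over the
#' effective batch (`batch_size * accumulation_steps`), which makes the
#' micro-batch/accumulation split exactly equivalent to one large batch in
#' the absence of dropout.
#'
#' @param x Character vector of training sequences.
#' @param y Class labels aligned with `x` (coerced to character).
#' @param valid Optional `list(x = sequences, y = labels)` held-out set;
#'   validation accuracy is logged per epoch.
#' @param econf An [encoder_config()].
#' @param tconf A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `enzformer`: list with elements `params`
#'   (parameter arrays), `config`, `tconf`, `classes`, and `log`, a
#'   data frame with one row per epoch (`epoch` 0-based, `lr`, `train_loss`,
#'   `train_acc`, `valid_acc`).
#' @seealso [predict.enzformer()], [forward_with_attention()],
#'   [class_weights()], [lr_schedule()]
#' @examples
#' \donttest{
#' set.seed(1)
#' syn <- gen_classified_sequences(synthetic_spec(
#'   n_sequences = 60, len_range = c(30, 40), n_classes = 2, seed = 1))
#' fit <- enzformer(syn$records$sequence, syn$labels,
#'                  econf = encoder_config(1, 2, 16, 32),
#'                  tconf = train_config(n_epochs = 1, lr0 = 1e-3, seed = 1))
#' predict(fit, syn$records$sequence[1])
#' }
#' @export
enzformer <- function(x, y, valid = NULL, econf = encoder_config(),
                      tconf = train_config(), verbose = FALSE) {
  stopifnot(inherits(econf, "encoder_config"), inherits(tconf, "train_config"),
            length(x) == length(y), length(x) > 0L)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training requires at least 2 classes")
  if (!is.null(valid)) {
    vy <- as.character(valid$y)
    missing_cls <- setdiff(unique(vy), classes)
    if (length(missing_cls))
      warning("classes present in validation but absent from training: ",
              paste(missing_cls, collapse = ", "))
  }
  set.seed(tconf$seed)
  params <- init_params(econf, length(classes))
  toks <- lapply(x, tokenize, config = econf)
  yidx <- match(y, classes)
  n <- length(x)
  w <- if (tconf$balance_sampling) class_weights(y) else NULL
  eff_batch <- tconf$batch_size * tconf$accumulation_steps

  # flat Adam state
  flat <- unlist(params, use.names = FALSE)
  m <- numeric(length(flat)); v <- numeric(length(flat)); tstep <- 0L
  eps <- 1e-8

  log <- vector("list", tconf$n_epochs)
  for (e in seq_len(tconf$n_epochs)) {
    lr <- lr_schedule(tconf$lr0, tconf$lr_decay, e - 1L)
    order <- if (tconf$balance_sampling)
      sample.int(n, n, replace = TRUE, prob = w) else sample.int(n)
    losses <- numeric(0)
    pos <- 1L
    while (pos <= n) {
      take <- order[pos:min(n, pos + eff_batch - 1L)]
      pos <- pos + eff_batch
      gacc <- NULL
      bl <- 0
      for (i in take) {
        mask <- if (tconf$dropout_cls > 0)
          (runif(econf$embed_dim) >= tconf$dropout_cls) /
            (1 - tconf$dropout_cls) else NULL
        fw <- encoder_forward(params, econf, toks[[i]], dropout_mask = mask)
        ce <- cross_entropy(fw$logits, yidx[i])
        bl <- bl + ce$loss
        bw <- encoder_backward(params, econf, fw$cache, ce$dlogits)
        gacc <- if (is.null(gacc)) bw$grad else grad_add(gacc, bw$grad)
      }
      losses <- c(losses, bl / length(take))
      gflat <- unlist(gacc, use.names = FALSE) / length(take)
      tstep <- tstep + 1L
      m <- tconf$beta1 * m + (1 - tconf$beta1) * gflat
      v <- tconf$beta2 * v + (1 - tconf$beta2) * gflat^2
      mhat <- m / (1 - tconf$beta1^tstep)
      vhat <- v / (1 - tconf$beta2^tstep)
      flat <- unlist(params, use.names = FALSE) -
        lr * mhat / (sqrt(vhat) + eps)
      params <- relist(flat, skeleton = params)
    }
    fit_now <- structure(list(params = params, config = econf,
                              classes = classes), class = "enzformer")
    train_acc <- mean(predict(fit_now, x) == y)
    valid_acc <- if (is.null(valid))
      NA_real_ else mean(predict(fit_now, valid$x) == as.character(valid$y))
    log[[e]] <- data.frame(epoch = e - 1L, lr = lr,
                           train_loss = mean(losses),
                           train_acc = train_acc, valid_acc = valid_acc)
    if (verbose)
      message(sprintf("epoch %d  lr %.3g  loss %.4f  train %.3f  valid %.3f",
                      e - 1L, lr, mean(losses), train_acc, valid_acc))
  }
  structure(list(params = params, config = econf, tconf = tconf,
                 classes = classes,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(epoch = integer(), lr = numeric(),
                              train_loss = numeric(), train_acc = numeric(),
                              valid_acc = numeric())),
            class = "enzformer")
}

#' Predict classes for protein sequences
#'
#' @param object A fitted [enzformer()] model.
#' @param newdata Character vector of sequences.
#' @param type `"class"` (default), `"prob"` for the class-probability
#'   matrix, or `"logits"`.
#' @param ... Unused.
#' @return Character vector of classes, or a numeric matrix with one row per
#'   sequence for `"prob"`/`"logits"`.
#' @export
predict.enzformer <- function(object, newdata, type = c("class", "prob",
                                                        "logits"), ...) {
  type <- match.arg(type)
  out <- t(vapply(newdata, function(s) {
    fw <- encoder_forward(object$params, object$config,
                          tokenize(s, object$config), keep_cache = FALSE)
    fw$logits
  }, numeric(length(object$classes)), USE.NAMES = FALSE))
  colnames(out) <- object$classes
  switch(type,
         logits = out,
         prob = t(apply(out, 1L, softmax_vec)),
         class = object$classes[max.col(out, ties.method = "first")])
}

#' Classifier output and attention capture for one sequence
#'
#' Runs the encoder in evaluation mode (no dropout) on a single sequence and
#' returns both the classification output and the full attention tensor of
#' shape `(L*H, T, T)`, where `T` is the token count including the
#' classification token.  Every attention row (fixed head and query indices)
#' is softmax-normalised over the key axis.
#'
#' @param model A fitted or freshly initialised `enzformer`.
#' @param sequence A residue string, or a `tokenized_seq`.
#' @return A list with `output` (elements `logits`, `probabilities`,
#'   `predicted_class`) and `capture`, an [attn_capture()] object.
#' @export
forward_with_attention <- function(model, sequence) {
  stopifnot(inherits(model, "enzformer"))
  tk <- if (inherits(sequence, "tokenized_seq")) sequence else
    tokenize(sequence, model$config)
  if (tk$T > model$config$max_len || any(tk$tokens > nrow(model$params$E)))
    stop("tokenized sequence is incompatible with the model configuration")
  fw <- encoder_forward(model$params, model$config, tk, keep_cache = FALSE)
  prob <- softmax_vec(fw$logits)
  list(output = list(logits = setNames(fw$logits, model$classes),
                     probabilities = setNames(prob, model$classes),
                     predicted_class = model$classes[which.max(fw$logits)]),
       capture = attn_capture(fw$attn, tk$special_mask,
                              residue_map = tk$residue_map))
}

#' Attention capture container
#'
#' Holds the `(L*H, T, T)` attention tensor of one sequence together with
#' the special-token mask.  Validates the row-stochasticity invariant.
#'
#' @param tensor 3-d array, first axis layer-head pairs, then query and key
#'   token axes; every row must be non-negative and sum to 1 within `1e-5`.
#' @param special_mask Logical vector of length `T`; `TRUE` marks special
#'   (non-residue) tokens.
#' @param residue_map Optional integer vector mapping token index to 1-based
#'   residue position (`NA` at special tokens).
#' @return An object of class `attn_capture`.
#' @export
attn_capture <- function(tensor, special_mask, residue_map = NULL) {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3L,
            dim(tensor)[2L] == dim(tensor)[3L],
            length(special_mask) == dim(tensor)[2L],
            is.logical(special_mask))
  if (any(tensor < 0)) stop("attention tensor has negative entries")
  rs <- apply(tensor, c(1L, 2L), sum)
  if (any(abs(rs - 1) > 1e-5))
    stop("attention rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (is.null(residue_map)) {
    residue_map <- rep(NA_integer_, length(special_mask))
    residue_map[!special_mask] <- seq_len(sum(!special_mask))
  }
  structure(list(tensor = tensor, special_mask = special_mask,
                 residue_map = residue_map),
            class = "attn_capture")
}

#' @export
print.enzformer <- function(x, ...) {
  cat("Self-attention enzyme-class classifier (enzformer)\n")
  cat(sprintf("  architecture: %d layer(s) x %d head(s), embed %d, ff %d\n",
              x$config$n_layers, x$config$n_heads, x$config$embed_dim,
              x$config$ff_dim))
  cat(sprintf("  classes (%d): %s\n", length(x$classes),
              paste(head(x$classes, 8L), collapse = ", ")))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epoch(s); final loss %.4f, train acc %.3f",
                nrow(x$log), last$train_loss, last$train_acc))
    if (!is.na(last$valid_acc))
      cat(sprintf(", valid acc %.3f", last$valid_acc))
    cat("\n")
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.enzformer <- function(object, ...) {
  npar <- length(unlist(object$params, use.names = FALSE))
  cat("enzformer model\n")
  print(object)
  cat(sprintf("  parameters: %d\n", npar))
  if (nrow(object$log)) {
    cat("  per-epoch log:\n")
    print(object$log, row.names = FALSE)
  }
  invisible(object$log)
}

#' @export
coef.enzformer <- function(object, ...) {
  list(head_weights = object$params$Wc, head_bias = object$params$bc)
}

#' Plot the training history
#'
#' @param x A fitted `enzformer` with a non-empty log.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.enzformer <- function(x, ...) {
  if (!nrow(x$log)) stop("model has no training log")
  graphics::plot(x$log$epoch, x$log$train_loss, type = "b",
                 xlab = "epoch", ylab = "mean cross-entropy",
                 main = "enzformer training loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Model state (parameter arrays, configuration, class labels and training
#' log) is stored in R's native serialisation format.
#'
#' @param model An `enzformer` object.
#' @param path File path.
#' @return `read_enzformer` returns the restored `enzformer`.
#' @export
write_enzformer <- function(model, path) {
  stopifnot(inherits(model, "enzformer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_enzformer
#' @export
read_enzformer <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "enzformer"))
  model
}
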