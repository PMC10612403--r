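# Classical interpretability baselines, producing importance_vector objects
# under the same contract as the attention-aggregation family.

#' Saliency configuration
#'
#' @param target_rule `"predicted"` (default) scores the model's predicted
#'   class; `"given"` scores `target_class`.
#' @param target_class Class label used when `target_rule = "given"`.
#' @param ig_steps Riemann-sum steps for integrated gradients (midpoint
#'   rule).
#' @param lime_samples Number of masked perturbations for the LIME
#'   surrogate.
#' @param lime_mask_rate Per-residue masking probability.
#' @param lime_kernel_width Locality-kernel width as a fraction of sequence
#'   length (exponential kernel on Hamming distance).
#' @param shuffle_reps Repetitions of the shuffled baseline.
#' @param seed RNG seed for perturbations and shuffles.
#' @return An object of class `saliency_config`.
#' @export
saliency_config <- function(target_rule = c("predicted", "given"),
                            target_class = NULL, ig_steps = 50L,
                            lime_samples = 5000L, lime_mask_rate = 0.3,
                            lime_kernel_width = 0.25, shuffle_reps = 10L,
                            seed = 0L) {
  target_rule <- match.arg(target_rule)
  stopifnot(ig_steps >= 1, lime_samples >= 10,
            lime_mask_rate > 0, lime_mask_rate < 1, shuffle_reps >= 1)
  if (target_rule == "given" && is.null(target_class))
    stop("target_rule = \"given\" requires target_class")
  structure(list(target_rule = target_rule, target_class = target_class,
                 ig_steps = as.integer(ig_steps),
                 lime_samples = as.integer(lime_samples),
                 lime_mask_rate = lime_mask_rate,
                 lime_kernel_width = lime_kernel_width,
                 shuffle_reps = as.integer(shuffle_reps),
                 seed = as.integer(seed)),
            class = "saliency_config")
}

target_index <- function(model, logits, cfg) {
  if (cfg$target_rule == "given") {
    i <- match(cfg$target_class, model$classes)
    if (is.na(i)) stop("unknown target class: ", cfg$target_class)
    i
  } else which.max(logits)
}

# gradient of the target-class logit w.r.t. the input embedding matrix X0
input_gradient <- function(model, tokens, cfg, X0_override = NULL) {
  fw <- encoder_forward(model$params, model$config, tokens,
                        X0_override = X0_override)
  ti <- target_index(model, fw$logits, cfg)
  dlogits <- numeric(length(fw$logits)); dlogits[ti] <- 1
  bw <- encoder_backward(model$params, model$config, fw$cache, dlogits)
  if (!all(is.finite(bw$dX0))) stop("non-finite gradients encountered")
  list(dX0 = bw$dX0, X0 = fw$cache$X0, logits = fw$logits, target = ti)
}

seq_or_tokens <- function(model, sequence) {
  if (inherits(sequence, "tokenized_seq")) sequence
  else tokenize(sequence, model$config)
}

#' Gradient saliency
#'
#' Per-residue score is the Euclidean norm, over embedding dimensions, of
#' the gradient of the target-class logit with respect to the input
#' embedding at that position; the classification token is stripped.
#'
#' @param model A fitted [enzformer()].
#' @param sequence Residue string or `tokenized_seq`.
#' @param cfg A [saliency_config()].
#' @param seq_id Identifier stored on the result.
#' @return An [importance_vector()].
#' @export
grad_saliency <- function(model, sequence, cfg = saliency_config(),
                          seq_id = NA_character_) {
  tk <- seq_or_tokens(model, sequence)
  g <- input_gradient(model, tk, cfg)
  sc <- sqrt(rowSums(g$dX0^2))
  importance_vector(seq_id, sc[!tk$special_mask], "Grad")
}

#' Gradient-times-input saliency
#'
#' As [grad_saliency()], but the score is the norm of the elementwise
#' product of the gradient with the input embedding.
#'
#' @inheritParams grad_saliency
#' @return An [importance_vector()].
#' @export
grad_x_input <- function(model, sequence, cfg = saliency_config(),
                         seq_id = NA_character_) {
  tk <- seq_or_tokens(model, sequence)
  g <- input_gradient(model, tk, cfg)
  sc <- sqrt(rowSums((g$dX0 * g$X0)^2))
  importance_vector(seq_id, sc[!tk$special_mask], "Grad X input")
}

#' Integrated gradients
#'
#' Midpoint Riemann-sum path integral of input gradients from an
#' information-free baseline to the input, targeting the predicted (or
#' given) class.  The baseline zeroes the token embeddings while keeping
#' the positional encodings: it carries no residue-identity information,
#' and, unlike a strictly all-zero input, it avoids the layer-norm
#' singularity at the origin (normalisation layers make the network nearly
#' scale invariant, which concentrates the path integrand in an
#' unresolvable boundary layer around an all-zero input).  The per-residue
#' score is the Euclidean norm of the attribution vector; the signed
#' attribution matrix and the completeness residual (summed signed
#' attributions minus the logit difference between input and baseline) are
#' attached as attributes for the completeness check.
#'
#' @inheritParams grad_saliency
#' @return An [importance_vector()] with attributes `attribution` (token x
#'   embedding matrix), `signed` (per-token signed sums), `logit_diff` and
#'   `completeness_error`.
#' @export
integrated_gradients <- function(model, sequence, cfg = saliency_config(),
                                 seq_id = NA_character_) {
  tk <- seq_or_tokens(model, sequence)
  fw <- encoder_forward(model$params, model$config, tk)
  ti <- target_index(model, fw$logits, cfg)
  cfg_fixed <- cfg
  cfg_fixed$target_rule <- "given"
  cfg_fixed$target_class <- model$classes[ti]
  Xin <- fw$cache$X0
  Xbase <- positional_encoding(tk$T, model$config$embed_dim)
  m <- cfg$ig_steps
  acc <- matrix(0, nrow(Xin), ncol(Xin))
  for (s in seq_len(m)) {
    alpha <- (s - 0.5) / m
    g <- input_gradient(model, tk, cfg_fixed,
                        X0_override = Xbase + alpha * (Xin - Xbase))
    acc <- acc + g$dX0
  }
  attribution <- (Xin - Xbase) * acc / m
  f1 <- fw$logits[ti]
  f0 <- encoder_forward(model$params, model$config, tk, keep_cache = FALSE,
                        X0_override = Xbase)$logits[ti]
  sc <- sqrt(rowSums(attribution^2))
  out <- importance_vector(seq_id, sc[!tk$special_mask], "Integrated grad")
  attr(out, "attribution") <- attribution
  attr(out, "signed") <- rowSums(attribution)
  attr(out, "logit_diff") <- f1 - f0
  attr(out, "completeness_error") <- sum(attribution) - (f1 - f0)
  out
}

#' Last-layer attention saliency
#'
#' Averages the final layer's attention heads and scores each residue by
#' the mean attention it receives (column mean) in the averaged map; the
#' classification token is stripped afterwards.  Equivalent to the
#' average/average aggregation computed on the final layer's sub-tensor.
#'
#' @param capture An [attn_capture()].
#' @param n_heads Heads per layer; defaults to the whole first axis (i.e. a
#'   single-layer capture).
#' @param seq_id Identifier stored on the result.
#' @return An [importance_vector()].
#' @export
attention_last_layer <- function(capture, n_heads = dim(capture$tensor)[1L],
                                 seq_id = NA_character_) {
  LH <- dim(capture$tensor)[1L]
  stopifnot(LH %% n_heads == 0L)
  last <- capture$tensor[(LH - n_heads + 1L):LH, , , drop = FALSE]
  v <- colMeans(pool_axis1(last, "average"))
  strip_special_tokens(structure(v, method = "Attn last layer"), capture,
                       seq_id = seq_id)
}

#' Attention rollout saliency
#'
#' Head-averages each layer's attention map, mixes in the residual
#' connection (`0.5 * A + 0.5 * I`, rows renormalised), multiplies the maps
#' from the first to the last layer, and reads out the classification-token
#' row of the product; the classification token is then stripped.
#'
#' @inheritParams attention_last_layer
#' @return An [importance_vector()].
#' @export
attention_rollout <- function(capture, n_heads = dim(capture$tensor)[1L],
                              seq_id = NA_character_) {
  LH <- dim(capture$tensor)[1L]
  stopifnot(LH %% n_heads == 0L)
  L <- LH %/% n_heads
  T <- dim(capture$tensor)[2L]
  cls_i <- which(capture$special_mask)
  if (length(cls_i) != 1L)
    stop("rollout readout requires exactly one classification token")
  R <- diag(T)
  for (l in seq_len(L)) {
    rows <- ((l - 1L) * n_heads + 1L):(l * n_heads)
    A <- pool_axis1(capture$tensor[rows, , , drop = FALSE], "average")
    M <- 0.5 * A + 0.5 * diag(T)
    rs <- rowSums(M)
    if (any(rs <= 0)) stop("rollout normalisation failed: zero row")
    R <- (M / rs) %*% R
  }
  strip_special_tokens(structure(R[cls_i, ], method = "Rollout"), capture,
                       seq_id = seq_id)
}

#' LIME-style surrogate saliency
#'
#' Draws masked perturbations of the sequence (each residue independently
#' replaced by the wildcard with probability `lime_mask_rate`), scores each
#' perturbation by the model probability of the target class, and fits a
#' weighted least-squares linear surrogate on the binary presence/absence
#' design with an exponential locality kernel on Hamming distance.  The
#' surrogate coefficients are the residue importances.
#'
#' @inheritParams grad_saliency
#' @return An [importance_vector()] with attribute `intercept`.
#' @export
lime_saliency <- function(model, sequence, cfg = saliency_config(),
                          seq_id = NA_character_) {
  tk <- seq_or_tokens(model, sequence)
  chars <- tk$symbols[!tk$special_mask]
  N <- length(chars)
  fw0 <- encoder_forward(model$params, model$config, tk, keep_cache = FALSE)
  ti <- target_index(model, fw0$logits, cfg)
  set.seed(cfg$seed)
  Z <- matrix(rbinom(cfg$lime_samples * N, 1L, 1 - cfg$lime_mask_rate),
              cfg$lime_samples, N)
  Z[1L, ] <- 1L  # include the unperturbed sequence
  y <- vapply(seq_len(nrow(Z)), function(i) {
    s <- chars
    s[Z[i, ] == 0L] <- TOK_WILDCARD
    fw <- encoder_forward(model$params, model$config,
                          tokenize(paste(s, collapse = ""), model$config),
                          keep_cache = FALSE)
    softmax_vec(fw$logits)[ti]
  }, numeric(1))
  dist <- N - rowSums(Z)
  w <- exp(-dist / (cfg$lime_kernel_width * N))
  X <- cbind(1, Z)
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("degenerate design: ", sum(is.na(beta)),
            " coefficient(s) set to 0")
    beta[is.na(beta)] <- 0
  }
  out <- importance_vector(seq_id, beta[-1L], "LIME")
  attr(out, "intercept") <- beta[1L]
  out
}

#' Shuffled-score baseline
#'
#' Permutes the importance scores uniformly at random within each sequence,
#' independently for each repetition.  Downstream metrics computed on the
#' repetitions are reported as mean plus or minus standard deviation.
#'
#' @param importances List of [importance_vector()]s.
#' @param cfg A [saliency_config()] (`shuffle_reps`, `seed`).
#' @return List of length `shuffle_reps`; each element is a list of
#'   importance vectors with permuted scores (method `"Random"`).
#' @export
shuffled_baseline <- function(importances, cfg = saliency_config()) {
  set.seed(cfg$seed)
  lapply(seq_len(cfg$shuffle_reps), function(r) {
    lapply(importances, function(iv) {
      importance_vector(iv$seq_id,
                        iv$scores[sample.int(length(iv$scores))], "Random")
    })
  })
}
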