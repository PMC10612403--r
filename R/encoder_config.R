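#' Encoder architecture configuration
#'
#' Describes a self-attention encoder: number of layers `L`, attention heads
#' per layer `H`, embedding width, feed-forward width and the token
#' vocabulary.  The defaults are a deliberately small configuration that
#' trains in minutes on one CPU; scaling the architecture up is a
#' configuration change, not a code change.
#'
#' @param n_layers Number of encoder layers (`L`).
#' @param n_heads Attention heads per layer (`H`); must divide `embed_dim`.
#' @param embed_dim Token embedding width.
#' @param ff_dim Hidden width of the position-wise feed-forward block.
#' @param max_len Maximum token count, classification token included.
#' @param vocab Ordered character vector of residue symbols plus special
#'   tokens; must contain the wildcard, classification and padding tokens.
#' @return An object of class `encoder_config`.
#' @examples
#' cfg <- encoder_config(n_layers = 2, n_heads = 4, embed_dim = 64)
#' @export
encoder_config <- function(n_layers = 2L, n_heads = 4L, embed_dim = 64L,
                           ff_dim = 128L, max_len = 1024L,
                           vocab = default_vocab()) {
  n_layers <- as.integer(n_layers); n_heads <- as.integer(n_heads)
  embed_dim <- as.integer(embed_dim); ff_dim <- as.integer(ff_dim)
  max_len <- as.integer(max_len)
  stopifnot(n_layers >= 1L, n_heads >= 1L, embed_dim >= 1L, ff_dim >= 1L)
  if (embed_dim %% n_heads != 0L)
    stop("embed_dim (", embed_dim, ") must be divisible by n_heads (",
         n_heads, ")")
  if (max_len < 2L) stop("max_len must be at least 2")
  needed <- c(TOK_WILDCARD, TOK_CLS, TOK_PAD)
  if (!all(needed %in% vocab))
    stop("vocab must contain the special tokens: ",
         paste(setdiff(needed, vocab), collapse = ", "))
  if (anyDuplicated(vocab)) stop("vocab contains duplicated symbols")
  structure(list(n_layers = n_layers, n_heads = n_heads,
                 embed_dim = embed_dim, ff_dim = ff_dim, max_len = max_len,
                 vocab = vocab),
            class = "encoder_config")
}

#' Fine-tuning configuration
#'
#' Optimisation hyper-parameters for [enzformer()].  The defaults mirror the
#' published fine-tuning recipe: dropout 0.2 on the classification
#' embedding, Adam with beta1 = 0.9 and beta2 = 0.999, base learning rate
#' 1e-5, geometric learning-rate decay of 0.8 per epoch, micro-batches of 2
#' sequences accumulated over 16 steps (effective batch 32), and optional
#' inverse-frequency class-balanced sampling.
#'
#' @param dropout_cls Dropout rate applied to the normalised classification
#'   embedding during training only.
#' @param batch_size Sequences per micro-batch.
#' @param accumulation_steps Micro-batches accumulated per optimiser step.
#' @param lr0 Base learning rate (epoch 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param lr_decay Multiplicative learning-rate decay per epoch; the rate at
#'   epoch `e` (counted from 0) is exactly `lr0 * lr_decay^e`.
#' @param n_epochs Number of training epochs.
#' @param balance_sampling If `TRUE`, examples are drawn with replacement
#'   with probability proportional to the inverse frequency of their class.
#' @param seed Integer seed controlling initialisation, sampling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(dropout_cls = 0.2, batch_size = 2L,
                         accumulation_steps = 16L, lr0 = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, lr_decay = 0.8,
                         n_epochs = 5L, balance_sampling = FALSE,
                         seed = 0L) {
  stopifnot(dropout_cls >= 0, dropout_cls < 1,
            lr_decay > 0, lr_decay <= 1,
            batch_size >= 1, accumulation_steps >= 1, n_epochs >= 0,
            lr0 > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1)
  structure(list(dropout_cls = dropout_cls,
                 batch_size = as.integer(batch_size),
                 accumulation_steps = as.integer(accumulation_steps),
                 lr0 = lr0, beta1 = beta1, beta2 = beta2,
                 lr_decay = lr_decay, n_epochs = as.integer(n_epochs),
                 balance_sampling = isTRUE(balance_sampling),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Geometric per-epoch decay: the learning rate used in epoch `epoch`
#' (0-based) is `lr0 * decay^epoch`.
#'
#' @param lr0 Base learning rate.
#' @param decay Per-epoch multiplicative decay.
#' @param epoch 0-based epoch index (vectorised).
#' @return Numeric vector of learning rates.
#' @export
lr_schedule <- function(lr0, decay, epoch) lr0 * decay^epoch

#' Tokenize a protein sequence
#'
#' Maps a residue string to vocabulary indices and appends the
#' classification token.  Unknown residue symbols that are plain letters map
#' to the wildcard token; any other character is an error.
#'
#' @param sequence Single residue string (one-letter amino-acid codes).
#' @param config An [encoder_config()].
#' @return A `tokenized_seq` list with elements `tokens` (integer vocabulary
#'   indices, classification token first), `symbols`, `residue_map` (token
#'   index -> 1-based residue position, `NA` for special tokens),
#'   `special_mask` (logical, `TRUE` at special-token positions) and `T`
#'   (token count = residue count + 1).
#' @examples
#' tk <- tokenize("MKV", encoder_config())
#' tk$T          # 4
#' tk$residue_map
#' @export
tokenize <- function(sequence, config) {
  stopifnot(inherits(config, "encoder_config"),
            is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop("cannot tokenize an empty sequence")
  if (n > config$max_len - 1L)
    stop("sequence of length ", n, " exceeds the model limit of ",
         config$max_len - 1L, " residues (max_len = ", config$max_len,
         " tokens including the classification token)")
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1L]])
  bad <- !grepl("^[A-Z]$", chars)
  if (any(bad))
    stop("invalid symbol \"", chars[which(bad)[1L]], "\" at position ",
         which(bad)[1L], ": sequences must use one-letter residue codes")
  chars[!chars %in% config$vocab] <- TOK_WILDCARD
  # classification token first, so it always carries the same positional
  # vector regardless of sequence length
  symbols <- c(TOK_CLS, chars)
  tokens <- match(symbols, config$vocab)
  structure(list(tokens = tokens, symbols = symbols,
                 residue_map = c(NA_integer_, seq_len(n)),
                 special_mask = c(TRUE, rep(FALSE, n)),
                 T = n + 1L),
            class = "tokenized_seq")
}

#' Inverse-frequency example weights
#'
#' Weight of an example is the inverse of the occurrence count of its class,
#' the weighting used for class-balanced sampling with replacement.
#'
#' @param labels Vector of class labels (one per example).
#' @return Numeric vector of per-example weights.
#' @examples
#' class_weights(c("A", "A", "B"))  # 0.5 0.5 1
#' @export
class_weights <- function(labels) {
  if (length(labels) == 0L) stop("empty label list")
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}
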