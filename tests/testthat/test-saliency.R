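test_that("gradient saliency matches finite differences on input embeddings", {
  fit <- tiny_model(seed = 13, L = 1, H = 2, d = 8, ff = 16)
  cfg <- saliency_config()
  tk <- tokenize("MKVLYA", fit$config)
  g <- enzattn:::input_gradient(fit, tk, cfg)
  X0 <- g$X0
  ti <- which.max(g$logits)
  f <- function(X) enzattn:::encoder_forward(
    fit$params, fit$config, tk, keep_cache = FALSE,
    X0_override = X)$logits[ti]
  set.seed(7)
  for (probe in 1:15) {
    i <- sample(nrow(X0), 1); j <- sample(ncol(X0), 1)
    e <- 1e-4
    Xp <- X0; Xp[i, j] <- Xp[i, j] + e
    Xm <- X0; Xm[i, j] <- Xm[i, j] - e
    num <- (f(Xp) - f(Xm)) / (2 * e)
    expect_lt(abs(num - g$dX0[i, j]), 1e-3 * max(abs(num), 1e-3))
  }
  iv <- grad_saliency(fit, "MKVLYA", cfg, seq_id = "s")
  expect_length(iv$scores, 6L)
  expect_equal(iv$scores,
               sqrt(rowSums(g$dX0^2))[!tk$special_mask], tolerance = 1e-12)
})

test_that("gradient-times-input is the norm of the elementwise product", {
  fit <- tiny_model(seed = 14, L = 1, H = 2, d = 8, ff = 16)
  cfg <- saliency_config()
  tk <- tokenize("ACDEF", fit$config)
  g <- enzattn:::input_gradient(fit, tk, cfg)
  iv <- grad_x_input(fit, "ACDEF", cfg)
  expect_equal(iv$scores,
               sqrt(rowSums((g$dX0 * g$X0)^2))[!tk$special_mask],
               tolerance = 1e-12)
  expect_length(iv$scores, 5L)
})

test_that("integrated gradients satisfy completeness at fine step counts", {
  # a relative completeness check needs a non-degenerate logit gap between
  # input and baseline; both fixtures have |gap| well above zero
  for (cfg in list(c(seed = 16, L = 2), c(seed = 42, L = 1))) {
    fit <- tiny_model(seed = cfg[["seed"]], L = cfg[["L"]], H = 2, d = 8,
                      ff = 16)
    out <- integrated_gradients(fit, "MKVLYACD",
                                saliency_config(ig_steps = 200))
    err <- abs(attr(out, "completeness_error"))
    expect_gt(abs(attr(out, "logit_diff")), 0.1)
    expect_lt(err, 0.01 * abs(attr(out, "logit_diff")))
    expect_length(out$scores, 8L)
    expect_true(all(is.finite(out$scores)))
  }
})

test_that("one-step integrated gradients is the midpoint gradient times the path step", {
  fit <- tiny_model(seed = 16, L = 1, H = 2, d = 8, ff = 16)
  tk <- tokenize("GHIKL", fit$config)
  out <- integrated_gradients(fit, "GHIKL", saliency_config(ig_steps = 1))
  fw <- enzattn:::encoder_forward(fit$params, fit$config, tk,
                                 keep_cache = FALSE)
  ti <- which.max(fw$logits)
  cfg1 <- saliency_config(target_rule = "given",
                          target_class = fit$classes[ti])
  pe <- enzattn:::positional_encoding(tk$T, fit$config$embed_dim)
  Emb <- fit$params$E[tk$tokens, ] * sqrt(fit$config$embed_dim)
  g <- enzattn:::input_gradient(fit, tk, cfg1, X0_override = pe + 0.5 * Emb)
  expect_equal(attr(out, "attribution"), Emb * g$dX0, tolerance = 1e-12)
})

test_that("last-layer attention equals average aggregation of the final sub-tensor", {
  fit <- tiny_model(seed = 17, L = 2, H = 4, d = 16, ff = 32)
  cap <- forward_with_attention(fit, "MKVLYACDEF")$capture
  iv <- attention_last_layer(cap, n_heads = 4)
  sub <- cap$tensor[5:8, , , drop = FALSE]
  ref <- as.numeric(aggregate_attention(sub, "AttnAgg1A1A"))
  expect_equal(iv$scores, ref[!cap$special_mask], tolerance = 1e-12)
  # single layer: coincides with the family aggregation of the full tensor
  fit1 <- tiny_model(seed = 18, L = 1, H = 2, d = 8, ff = 16)
  cap1 <- forward_with_attention(fit1, "MKVLY")$capture
  iv1 <- attention_last_layer(cap1, n_heads = 2)
  full <- as.numeric(aggregate_attention(cap1, "AttnAgg1A1A"))
  expect_equal(iv1$scores, full[!cap1$special_mask], tolerance = 1e-12)
})

test_that("rollout multiplies residual-mixed maps and stays stochastic", {
  # hand-built two-layer, one-head capture over 3 tokens (CLS first)
  A1 <- rbind(c(0.6, 0.2, 0.2), c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4))
  A2 <- rbind(c(0.2, 0.5, 0.3), c(0.4, 0.4, 0.2), c(0.1, 0.1, 0.8))
  A <- array(0, c(2, 3, 3)); A[1, , ] <- A1; A[2, , ] <- A2
  cap <- attn_capture(A, special_mask = c(TRUE, FALSE, FALSE))
  out <- attention_rollout(cap, n_heads = 1)
  M1 <- 0.5 * A1 + 0.5 * diag(3); M2 <- 0.5 * A2 + 0.5 * diag(3)
  R <- M2 %*% M1   # independent matrix-product oracle
  expect_equal(max(abs(rowSums(R) - 1)), 0, tolerance = 1e-9)
  expect_equal(out$scores, R[1, 2:3], tolerance = 1e-12)
  # identity attention: CLS row keeps all mass on itself
  I3 <- array(0, c(1, 3, 3)); I3[1, , ] <- diag(3)
  capI <- attn_capture(I3, special_mask = c(TRUE, FALSE, FALSE))
  outI <- attention_rollout(capI, n_heads = 1)
  expect_equal(outI$scores, c(0, 0))
  expect_error(attention_rollout(
    attn_capture(I3, special_mask = rep(FALSE, 3)), n_heads = 1),
    "classification token")
})

test_that("LIME coefficients solve the weighted least-squares surrogate", {
  fit <- tiny_model(seed = 19, L = 1, H = 2, d = 8, ff = 16)
  cfg <- saliency_config(lime_samples = 60, lime_mask_rate = 0.3, seed = 3)
  out <- lime_saliency(fit, "MKVLYAC", cfg, seq_id = "s")
  expect_length(out$scores, 7L)
  # normal-equations oracle on the same perturbation set
  set.seed(cfg$seed)
  N <- 7
  Z <- matrix(rbinom(cfg$lime_samples * N, 1, 1 - cfg$lime_mask_rate),
              cfg$lime_samples, N)
  Z[1, ] <- 1
  chars <- strsplit("MKVLYAC", "")[[1]]
  ti <- which.max(predict(fit, "MKVLYAC", type = "logits")[1, ])
  y <- apply(Z, 1, function(z) {
    s <- chars; s[z == 0] <- "X"
    predict(fit, paste(s, collapse = ""), type = "prob")[1, ti]
  })
  w <- exp(-(N - rowSums(Z)) / (0.25 * N))
  X <- cbind(1, Z)
  beta <- solve(crossprod(X, X * w), crossprod(X, y * w))
  expect_equal(out$scores, as.numeric(beta[-1]), tolerance = 1e-6)
})

test_that("LIME puts its top weight on planted signal residues", {
  # train a tiny model on short motif sequences, then check that the
  # surrogate's largest coefficient falls on a motif (gold) position
  syn <- gen_classified_sequences(synthetic_spec(
    n_sequences = 60, len_range = c(20, 28), n_classes = 2, motif_len = 4,
    seed = 21))
  fit <- enzformer(syn$records$sequence, syn$labels,
                   econf = encoder_config(1, 2, 16, 32),
                   tconf = train_config(n_epochs = 6, lr0 = 2e-3,
                                        lr_decay = 0.9, batch_size = 2,
                                        accumulation_steps = 1, seed = 21))
  hits <- 0L
  for (i in 1:3) {
    cfg <- saliency_config(lime_samples = 300, seed = i)
    out <- lime_saliency(fit, syn$records$sequence[i], cfg)
    hits <- hits + (which.max(out$scores) %in% syn$gold[[i]])
  }
  expect_gte(hits, 2L)
})

test_that("shuffling preserves the score multiset within each sequence", {
  ivs <- list(iv("a", c(3, 1, 2, 5)), iv("b", 7))
  reps <- shuffled_baseline(ivs, saliency_config(shuffle_reps = 5, seed = 1))
  expect_length(reps, 5L)
  for (r in reps) {
    expect_equal(sort(r[[1]]$scores), c(1, 2, 3, 5))
    expect_equal(r[[2]]$scores, 7)  # length-1 shuffle is the identity
    expect_equal(r[[1]]$method, "Random")
  }
  # repetitions are not all identical
  expect_true(any(vapply(reps, function(r)
    !identical(r[[1]]$scores, reps[[1]][[1]]$scores), logical(1))))
})
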