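# Shared fixtures and independent oracles.  Oracles are deliberately written
# as plain loops, independent of the vectorised implementation paths.

# a freshly initialised (untrained) tiny model
tiny_model <- function(seed = 1, n_classes = 3, L = 1, H = 2, d = 8,
                       ff = 16, max_len = 64) {
  x <- c("MKVLY", "ACDEF", "GHIKL", "MNPQR", "STVWY", "ADGKM")
  y <- rep(paste0("C", seq_len(n_classes)), length.out = length(x))
  enzformer(x, y, econf = encoder_config(L, H, d, ff, max_len = max_len),
            tconf = train_config(n_epochs = 0, seed = seed))
}

# triple-loop oracle for two-stage attention pooling
agg_oracle <- function(A, name) {
  sp <- agg_spec(name)
  d <- dim(A)
  pool <- function(v, f) if (f == "average") mean(v) else max(v)
  if (sp$stage1_axis == 1) {
    M <- matrix(0, d[2], d[3])
    for (q in 1:d[2]) for (k in 1:d[3]) M[q, k] <- pool(A[, q, k], sp$stage1_func)
  } else {
    M <- matrix(0, d[1], d[3])
    for (h in 1:d[1]) for (k in 1:d[3]) M[h, k] <- pool(A[h, , k], sp$stage1_func)
  }
  out <- numeric(if (sp$stage2_axis == 1) ncol(M) else nrow(M))
  if (sp$stage2_axis == 1) {
    for (j in 1:ncol(M)) out[j] <- pool(M[, j], sp$stage2_func)
  } else {
    for (i in 1:nrow(M)) out[i] <- pool(M[i, ], sp$stage2_func)
  }
  out
}

# exhaustive threshold-sweep PR oracle: O(n^2) direct comparisons
pr_oracle <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(ts))
  for (i in seq_along(ts)) {
    pos <- scores >= ts[i]
    prec[i] <- sum(labels[pos]) / sum(pos)
    rec[i] <- sum(labels[pos]) / sum(labels)
  }
  data.frame(threshold = ts, precision = prec, recall = rec)
}

# gain-curve area from PR points, written independently: clip, interpolate
# the zero crossing, trapezoid over recall gain in [0, 1]
prg_auc_oracle <- function(scores, labels) {
  prev <- mean(labels)
  pr <- pr_oracle(scores, labels)
  g <- function(x) (x - prev) / ((1 - prev) * x)
  rg <- g(pr$recall); pg <- g(pr$precision)
  ok <- is.finite(rg) & is.finite(pg)
  rg <- rg[ok]; pg <- pg[ok]
  o <- order(rg); rg <- rg[o]; pg <- pg[o]
  if (all(rg < 0)) return(0)
  if (any(rg < 0)) {
    i <- max(which(rg < 0))
    p0 <- pg[i] + (pg[i + 1] - pg[i]) * (-rg[i]) / (rg[i + 1] - rg[i])
    rg <- c(0, rg[(i + 1):length(rg)]); pg <- c(p0, pg[(i + 1):length(pg)])
  } else {
    rg <- c(0, rg); pg <- c(pg[1], pg)
  }
  pg <- pmin(pmax(pg, 0), 1)
  a <- 0
  for (i in seq_len(length(rg) - 1))
    a <- a + (rg[i + 1] - rg[i]) * (pg[i] + pg[i + 1]) / 2
  min(max(a, 0), 1)
}

# exhaustive max-F-Gain oracle: strict > sweep over unique scores plus +Inf
max_fgain_oracle <- function(scores, labels) {
  prev <- mean(labels)
  best <- 0
  for (t in c(unique(scores), Inf)) {
    pos <- scores > t
    f1 <- 2 * sum(labels[pos]) / (sum(pos) + sum(labels))
    if (f1 > best) best <- f1
  }
  if (best > 0) 100 * (best - prev) / ((1 - prev) * best) else 0
}

# exact binomial tail by direct enumeration over outcome counts
binom_tail_oracle <- function(hits, n, p) {
  s <- 0
  for (k in hits:n) s <- s + choose(n, k) * p^k * (1 - p)^(n - k)
  s
}

# simple Needleman-Wunsch (match 1, mismatch 0, gap -1) identity oracle
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  # traceback
  i <- n; j <- m; ident <- 0; alen <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      ident <- ident + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1
  }
  ident / alen
}

# importance vector shorthand for toy evaluation cases
iv <- function(id, scores) importance_vector(id, scores, "toy")
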