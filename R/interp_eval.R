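# Interpretability evaluation against catalytic-residue gold labels:
# top-k F1 curves, pooled precision-recall-gain curves and AUC, maximum
# F-Gain with per-sequence rescaling, and residue enrichment tests.

#' Per-sequence score rescaling
#'
#' @param x Numeric score vector of one sequence.
#' @param mode One of `"none"`, `"minmax"`, `"zscore"` (mean 0, sd 1),
#'   `"l1"`, `"l2"`.
#' @return Rescaled numeric vector.  Degenerate inputs (constant scores for
#'   `"minmax"`/`"zscore"`, all-zero for the norm modes) return zeros.
#' @export
rescale_scores <- function(x, mode = c("none", "minmax", "zscore", "l1",
                                       "l2")) {
  mode <- match.arg(mode)
  switch(mode,
         none = x,
         minmax = if (diff(range(x)) == 0) rep(0, length(x)) else
           (x - min(x)) / diff(range(x)),
         zscore = if (sd(x) == 0) rep(0, length(x)) else
           (x - mean(x)) / sd(x),
         l1 = if (sum(abs(x)) == 0) rep(0, length(x)) else x / sum(abs(x)),
         l2 = if (sqrt(sum(x^2)) == 0) rep(0, length(x)) else
           x / sqrt(sum(x^2)))
}

# match importance vectors to gold entries; returns the matched subset
match_gold <- function(importances, gold, on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  ids <- vapply(importances, function(iv) as.character(iv$seq_id),
                character(1))
  have <- ids %in% names(gold)
  if (any(!have)) {
    msg <- paste0("no gold annotation for sequence(s): ",
                  paste(ids[!have], collapse = ", "))
    if (on_missing == "error") stop(msg) else warning(msg, "; excluded")
  }
  for (i in which(have)) {
    g <- gold[[ids[i]]]
    n <- length(importances[[i]]$scores)
    if (length(g) && (any(g < 1) || any(g > n)))
      stop("gold positions outside [1, ", n, "] for sequence ", ids[i])
  }
  list(importances = importances[have], ids = ids[have])
}

#' Top-k F1 curve
#'
#' For each `k` from 1 to `k_max`, takes the `k` highest-scoring residues of
#' each sequence (ties broken by ascending position), computes the F1 score
#' against that sequence's gold positions, and averages over sequences.
#'
#' @param importances List of [importance_vector()]s.
#' @param gold Named list mapping sequence id to integer gold positions.
#' @param k_max Largest `k` (default 50).
#' @return Data frame with columns `k`, `f1` (mean over sequences) and
#'   `n_sequences`.
#' @export
topk_f1_curve <- function(importances, gold, k_max = 50L) {
  stopifnot(k_max >= 1)
  m <- match_gold(importances, gold)
  if (!length(m$importances)) stop("no sequence could be matched to gold")
  f1 <- matrix(0, length(m$importances), k_max)
  for (i in seq_along(m$importances)) {
    iv <- m$importances[[i]]
    g <- gold[[m$ids[i]]]
    ord <- order(-iv$scores, seq_along(iv$scores))
    hits <- cumsum(ord %in% g)
    for (k in seq_len(min(k_max, length(ord))))
      f1[i, k] <- 2 * hits[k] / (k + length(g))
    if (length(ord) < k_max && k_max > length(ord))
      f1[i, (length(ord) + 1L):k_max] <-
        2 * hits[length(ord)] / ((length(ord) + 1L):k_max + length(g))
  }
  data.frame(k = seq_len(k_max), f1 = colMeans(f1),
             n_sequences = length(m$importances))
}

gain_transform <- function(x, prev) (x - prev) / ((1 - prev) * x)

# PR points over descending-score cuts (positive = score >= cut value)
pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  n_pos <- sum(y)
  cut_at <- which(s != c(s[-1L], NA))  # last index of each tie group
  data.frame(threshold = s[cut_at],
             precision = tp[cut_at] / cut_at,
             recall = tp[cut_at] / n_pos)
}

prg_from_pr <- function(pr, prev) {
  rg <- gain_transform(pr$recall, prev)
  pg <- gain_transform(pr$precision, prev)
  keep <- is.finite(rg) & is.finite(pg)
  rg <- rg[keep]; pg <- pg[keep]
  ord <- order(rg)
  rg <- rg[ord]; pg <- pg[ord]
  # restrict to recall gain in [0, 1]; interpolate the crossing at 0
  if (all(rg < 0)) return(list(points = data.frame(recall_gain = numeric(),
                                                   precision_gain = numeric()),
                               auc = 0))
  if (any(rg < 0)) {
    i <- max(which(rg < 0))
    pg0 <- pg[i] + (pg[i + 1L] - pg[i]) * (0 - rg[i]) / (rg[i + 1L] - rg[i])
    keep_i <- (i + 1L):length(rg)
    rg <- c(0, rg[keep_i]); pg <- c(pg0, pg[keep_i])
  } else if (rg[1L] > 0) {
    rg <- c(0, rg); pg <- c(pg[1L], pg)
  }
  pg <- pmin(pmax(pg, 0), 1)
  auc <- sum(diff(rg) * (head(pg, -1L) + tail(pg, -1L)) / 2)
  list(points = data.frame(recall_gain = rg, precision_gain = pg),
       auc = min(max(auc, 0), 1))
}

#' Pooled precision-recall and precision-recall-gain curves
#'
#' Rescales scores per sequence, pools all residues of all sequences (or
#' keeps them per protein), computes the precision-recall curve over all
#' threshold placements at unique score values, and transforms it to gain
#' space: `gain(x) = (x - pi) / ((1 - pi) * x)` with `pi` the gold-label
#' prevalence.  The gain curve is restricted to non-negative recall gain,
#' precision gain is clipped to `[0, 1]`, and the AUC is the trapezoid
#' integral over recall gain in `[0, 1]`.
#'
#' @inheritParams topk_f1_curve
#' @param rescale_mode Per-sequence rescaling mode, see [rescale_scores()].
#' @param per_protein Also return one gain curve per sequence (each with its
#'   own prevalence).
#' @return An object of class `prg_curve`: list with `points` (data frame
#'   `recall_gain`, `precision_gain`), `pr` (data frame `threshold`,
#'   `precision`, `recall`), `prevalence`, `auc`, and, when requested,
#'   `per_protein` (named list of per-sequence curves).
#' @export
pooled_pr_and_prg <- function(importances, gold, rescale_mode = "none",
                              per_protein = FALSE) {
  m <- match_gold(importances, gold)
  if (!length(m$importances)) stop("no sequence could be matched to gold")
  pooled_s <- numeric(0); pooled_y <- integer(0)
  per <- if (per_protein) setNames(vector("list", length(m$importances)),
                                   m$ids)
  for (i in seq_along(m$importances)) {
    iv <- m$importances[[i]]
    s <- rescale_scores(iv$scores, rescale_mode)
    y <- as.integer(seq_along(s) %in% gold[[m$ids[i]]])
    pooled_s <- c(pooled_s, s); pooled_y <- c(pooled_y, y)
    if (per_protein) {
      prev_i <- mean(y)
      per[[i]] <- if (prev_i > 0 && prev_i < 1)
        c(prg_from_pr(pr_points(s, y), prev_i), prevalence = prev_i)
      else NULL
    }
  }
  prev <- mean(pooled_y)
  if (prev <= 0 || prev >= 1)
    stop("gold-label prevalence is ", prev,
         ": precision/recall gains are undefined")
  pr <- pr_points(pooled_s, pooled_y)
  prg <- prg_from_pr(pr, prev)
  structure(list(points = prg$points, pr = pr, prevalence = prev,
                 auc = prg$auc,
                 per_protein = if (per_protein) per),
            class = "prg_curve")
}

#' @export
print.prg_curve <- function(x, ...) {
  cat(sprintf("precision-recall-gain curve: prevalence %.4f, AUC %.4f (%d points)\n",
              x$prevalence, x$auc, nrow(x$points)))
  invisible(x)
}

#' Maximum F-Gain
#'
#' Rescales scores per sequence, pools them, and sweeps thresholds over all
#' unique pooled scores plus `+Inf`; residues scoring strictly above the
#' threshold are called positive.  The best F1 against the gold labels is
#' transformed to gain space, `(F1 - pi) / ((1 - pi) * F1)`, and reported as
#' a percentage; thresholds at which no residue is positive score 0.
#'
#' @inheritParams pooled_pr_and_prg
#' @return List with `max_fgain` (percent), `threshold`, `f1`, `prevalence`.
#' @export
max_fgain <- function(importances, gold, rescale_mode = "none") {
  m <- match_gold(importances, gold)
  if (!length(m$importances)) stop("no sequence could be matched to gold")
  pooled_s <- numeric(0); pooled_y <- integer(0)
  for (i in seq_along(m$importances)) {
    iv <- m$importances[[i]]
    s <- rescale_scores(iv$scores, rescale_mode)
    pooled_s <- c(pooled_s, s)
    pooled_y <- c(pooled_y,
                  as.integer(seq_along(s) %in% gold[[m$ids[i]]]))
  }
  n_gold <- sum(pooled_y)
  if (n_gold == 0) stop("no gold-labelled residue in the evaluation set")
  prev <- mean(pooled_y)
  thresholds <- c(sort(unique(pooled_s)), Inf)
  best <- list(f1 = 0, threshold = Inf)
  for (t in thresholds) {
    pos <- pooled_s > t
    tp <- sum(pooled_y[pos])
    f1 <- if (sum(pos) + n_gold > 0) 2 * tp / (sum(pos) + n_gold) else 0
    if (f1 > best$f1) best <- list(f1 = f1, threshold = t)
  }
  fg <- if (best$f1 > 0) 100 * gain_transform(best$f1, prev) else 0
  list(max_fgain = fg, threshold = best$threshold, f1 = best$f1,
       prevalence = prev)
}

#' Residue enrichment test
#'
#' One-sided exact binomial tail probability that at least `hits` of the
#' `top_n` highest-importance residues carry an annotation, when `annotated`
#' of the protein's `length` residues are annotated: `P(X >= hits)` with
#' `X ~ Binomial(top_n, annotated / length)`.
#'
#' @param hits Annotated residues observed among the top `top_n`.
#' @param top_n Number of top-importance residues considered.
#' @param annotated Total annotated residues in the protein.
#' @param length Protein length.
#' @return List with `p_value` (rounded to 5 decimals), `p_full` (full
#'   precision) and `expected` hits under the background rate.
#' @examples
#' enrichment_test(6, 10, 21, 271)$p_value   # 0.00003
#' enrichment_test(2, 10, 10, 907)$p_value   # 0.00516
#' @export
enrichment_test <- function(hits, top_n, annotated, length) {
  if (!(hits >= 0 && hits <= top_n && top_n <= length))
    stop("require 0 <= hits <= top_n <= length")
  if (!(annotated > 0 && annotated < length))
    stop("require 0 < annotated < length")
  p <- pbinom(hits - 1, top_n, annotated / length, lower.tail = FALSE)
  list(p_value = round(p, 5), p_full = p,
       expected = top_n * annotated / length)
}

#' Compare interpretability methods
#'
#' Computes PRG-AUC (x100) and maximum F-Gain (%) for each method against
#' the gold labels, plus a shuffled-score baseline reported as mean and
#' standard deviation over `cfg$shuffle_reps` repetitions.  Wall-clock
#' evaluation time per protein is recorded for information only.
#'
#' @param methods Named list; each element is a list of
#'   [importance_vector()]s covering every sequence in `gold`.
#' @param gold Named list of gold positions per sequence id.
#' @param cfg A [saliency_config()] (controls the shuffled baseline).
#' @param rescale_mode Per-sequence rescaling, see [rescale_scores()].
#' @return An object of class `interp_report`: list with `table` (data
#'   frame: `method`, `prg_auc`, `prg_auc_sd`, `max_fgain`, `max_fgain_sd`,
#'   `runtime_s`), `prevalence` and `rescale_mode`.
#' @export
compare_methods <- function(methods, gold, cfg = saliency_config(),
                            rescale_mode = "none") {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  for (nm in names(methods)) {
    ids <- vapply(methods[[nm]], function(iv) as.character(iv$seq_id),
                  character(1))
    miss <- setdiff(names(gold), ids)
    if (length(miss))
      stop("method ", nm, " is missing output for sequence(s): ",
           paste(miss, collapse = ", "))
  }
  eval_one <- function(ivs) {
    t0 <- proc.time()[["elapsed"]]
    prg <- pooled_pr_and_prg(ivs, gold, rescale_mode)
    fg <- max_fgain(ivs, gold, rescale_mode)
    list(prg = 100 * prg$auc, fg = fg$max_fgain, prev = prg$prevalence,
         dt = (proc.time()[["elapsed"]] - t0) / length(ivs))
  }
  rows <- lapply(names(methods), function(nm) {
    r <- eval_one(methods[[nm]])
    data.frame(method = nm, prg_auc = r$prg, prg_auc_sd = NA_real_,
               max_fgain = r$fg, max_fgain_sd = NA_real_, runtime_s = r$dt)
  })
  prev <- eval_one(methods[[1L]])$prev
  reps <- shuffled_baseline(methods[[1L]], cfg)
  rr <- vapply(reps, function(ivs) {
    r <- eval_one(ivs); c(r$prg, r$fg)
  }, numeric(2))
  rows <- c(rows, list(data.frame(
    method = "Random", prg_auc = mean(rr[1L, ]), prg_auc_sd = sd(rr[1L, ]),
    max_fgain = mean(rr[2L, ]), max_fgain_sd = sd(rr[2L, ]),
    runtime_s = NA_real_)))
  structure(list(table = do.call(rbind, rows), prevalence = prev,
                 rescale_mode = rescale_mode),
            class = "interp_report")
}

#' @export
print.interp_report <- function(x, ...) {
  cat(sprintf("Interpretability report (prevalence %.4f, rescale \"%s\")\n",
              x$prevalence, x$rescale_mode))
  cat(sprintf("%-18s %14s %16s %10s\n", "Method", "PRG-AUC (x100)",
              "Max F-Gain (%)", "Time (s)"))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    fmt <- function(v, s) if (is.na(s)) sprintf("%.2f", v) else
      sprintf("%.2f+/-%.2f", v, s)
    cat(sprintf("%-18s %14s %16s %10s\n", r$method,
                fmt(r$prg_auc, r$prg_auc_sd),
                fmt(r$max_fgain, r$max_fgain_sd),
                if (is.na(r$runtime_s)) "" else sprintf("%.3f", r$runtime_s)))
  }
  invisible(x)
}
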