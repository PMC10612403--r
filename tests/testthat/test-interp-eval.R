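test_that("top-k F1 handles perfect, partial and disjoint retrieval", {
  imp <- list(iv("a", c(0.1, 0.2, 0.3, 0.4, 0.9, 0.5, 0.6, 0.7, 0.8, 0.05)))
  # gold {5, 9}: top-2 scores are at positions 5 and 9
  gold <- list(a = c(5L, 9L))
  curve <- topk_f1_curve(imp, gold, k_max = 3)
  expect_equal(curve$f1[2], 1)                     # perfect at k = |gold|
  imp2 <- list(iv("b", c(0, 0, 1, 0, 0, 0, 0.5, 0, 0, 0)))
  expect_equal(topk_f1_curve(imp2, list(b = 3L), k_max = 2)$f1[2], 2 / 3)
  imp3 <- list(iv("c", c(1, 1, 0, 0)))
  expect_equal(topk_f1_curve(imp3, list(c = c(3L, 4L)), k_max = 2)$f1, c(0, 0))
})

test_that("top-k F1 is monotone non-increasing past the gold size for perfect rankings", {
  scores <- c(10, 9, 8, 7, 1, 1, 1, 1, 1, 1)
  imp <- list(iv("a", scores))
  gold <- list(a = 1:4)
  curve <- topk_f1_curve(imp, gold, k_max = 10)
  expect_equal(curve$f1[4], 1)
  expect_true(all(diff(curve$f1[4:10]) <= 1e-12))
})

test_that("sequences without gold are excluded with a warning", {
  imp <- list(iv("a", c(1, 2)), iv("zz", c(1, 2)))
  expect_warning(curve <- topk_f1_curve(imp, list(a = 1L), k_max = 1), "zz")
  expect_equal(curve$n_sequences[1], 1L)
})

test_that("perfect and anti-perfect rankings bracket the gain-curve AUC", {
  imp <- list(iv("a", c(0.9, 0.8, 0.1, 0.05, 0.02, 0.01)))
  gold <- list(a = c(1L, 2L))
  expect_equal(pooled_pr_and_prg(imp, gold)$auc, 1)
  rev_imp <- list(iv("a", -c(0.9, 0.8, 0.1, 0.05, 0.02, 0.01)))
  expect_equal(pooled_pr_and_prg(rev_imp, gold)$auc, 0)
})

test_that("gain-curve AUC matches the exhaustive threshold-sweep oracle", {
  # fixed worked example
  imp <- list(iv("a", c(0.9, 0.8, 0.1, 0.05)))
  gold <- list(a = c(1L, 3L))
  got <- pooled_pr_and_prg(imp, gold)$auc
  expect_equal(got, prg_auc_oracle(c(0.9, 0.8, 0.1, 0.05), c(1, 0, 1, 0)),
               tolerance = 1e-9)
  expect_equal(got, 0.25, tolerance = 1e-9)  # frozen fixture value
  # randomised cases, pooled across two sequences
  set.seed(8)
  for (i in 1:20) {
    s1 <- runif(12); s2 <- runif(9)
    g1 <- sample(12, 3); g2 <- sample(9, 2)
    imp <- list(iv("a", s1), iv("b", s2))
    gold <- list(a = g1, b = g2)
    got <- pooled_pr_and_prg(imp, gold)$auc
    want <- prg_auc_oracle(c(s1, s2),
                           c(as.integer(seq_along(s1) %in% g1),
                             as.integer(seq_along(s2) %in% g2)))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("degenerate prevalence is rejected", {
  expect_error(pooled_pr_and_prg(list(iv("a", c(1, 2))), list(a = 1:2)),
               "prevalence")
})

test_that("gain metrics are invariant under strictly increasing score transforms", {
  set.seed(12)
  s <- runif(30); g <- sample(30, 4)
  imp1 <- list(iv("a", s))
  imp2 <- list(iv("a", exp(3 * s) + 7))
  gold <- list(a = g)
  expect_equal(pooled_pr_and_prg(imp1, gold)$auc,
               pooled_pr_and_prg(imp2, gold)$auc, tolerance = 1e-12)
  expect_equal(max_fgain(imp1, gold)$max_fgain,
               max_fgain(imp2, gold)$max_fgain, tolerance = 1e-12)
})

test_that("max F-Gain spans the degenerate and perfect extremes", {
  gold <- list(a = c(2L, 5L))
  expect_equal(max_fgain(list(iv("a", rep(1, 8))), gold)$max_fgain, 0)
  sep <- c(0, 1, 0, 0, 1, 0, 0, 0)
  expect_equal(max_fgain(list(iv("a", sep)), gold)$max_fgain, 100)
  expect_error(max_fgain(list(iv("a", sep)), list(a = integer(0))), "gold")
})

test_that("max F-Gain agrees with the exhaustive-sweep oracle", {
  # 10-residue toy, 2 gold, partial separation (frozen fixture)
  s <- c(0.9, 0.7, 0.65, 0.3, 0.2, 0.15, 0.1, 0.08, 0.05, 0.01)
  gold <- list(a = c(1L, 5L))
  got <- max_fgain(list(iv("a", s)), gold)
  want <- max_fgain_oracle(s, as.integer(1:10 %in% c(1, 5)))
  expect_equal(got$max_fgain, want, tolerance = 1e-9)
  expect_equal(got$max_fgain, 87.5, tolerance = 1e-9)  # frozen fixture value
  set.seed(3)
  for (i in 1:20) {
    s <- round(runif(15), 2)  # ties on purpose
    g <- sample(15, 3)
    got <- max_fgain(list(iv("a", s)), list(a = g))$max_fgain
    expect_equal(got, max_fgain_oracle(s, as.integer(1:15 %in% g)),
                 tolerance = 1e-9)
  }
})

test_that("per-sequence rescaling modes behave as documented", {
  x <- c(1, 3, 5)
  expect_equal(rescale_scores(x, "minmax"), c(0, 0.5, 1))
  expect_equal(rescale_scores(x, "zscore"), (x - 3) / 2)
  expect_equal(sum(abs(rescale_scores(x, "l1"))), 1)
  expect_equal(sqrt(sum(rescale_scores(x, "l2")^2)), 1)
  expect_equal(rescale_scores(rep(2, 4), "minmax"), rep(0, 4))
})

test_that("always-positive classification has zero precision gain and unit recall gain", {
  prev <- 0.3
  g <- enzattn:::gain_transform
  expect_equal(g(prev, prev), 0)   # precision of always-positive = prevalence
  expect_equal(g(1, prev), 1)      # recall of always-positive = 1
})

test_that("enrichment test reproduces worked examples and the enumeration oracle", {
  expect_equal(enrichment_test(6, 10, 21, 271)$p_value, 0.00003)
  expect_equal(enrichment_test(2, 10, 10, 907)$p_value, 0.00516)
  expect_equal(enrichment_test(0, 10, 21, 271)$p_full, 1)
  expect_error(enrichment_test(11, 10, 5, 100), "hits")
  expect_error(enrichment_test(2, 10, 0, 100), "annotated")
  for (n in c(5, 9, 12)) {
    for (h in 0:n) {
      got <- enrichment_test(h, n, 7, 50)$p_full
      expect_equal(got, binom_tail_oracle(h, n, 7 / 50), tolerance = 1e-12)
    }
  }
  # strictly decreasing in hits
  p <- vapply(0:10, function(h) enrichment_test(h, 10, 21, 271)$p_full,
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("compare_methods reports identical rows for identical methods", {
  set.seed(2)
  scores <- runif(20)
  g <- sample(20, 3)
  ivs <- list(iv("a", scores))
  gold <- list(a = g)
  rep <- compare_methods(list(m1 = ivs, m2 = ivs), gold,
                         saliency_config(shuffle_reps = 3, seed = 1))
  tab <- rep$table
  expect_equal(tab$prg_auc[1], tab$prg_auc[2])
  expect_equal(tab$max_fgain[1], tab$max_fgain[2])
  expect_equal(tab$method[3], "Random")
  expect_false(is.na(tab$prg_auc_sd[3]))
})

test_that("a perfectly separating method reports 100/100", {
  ivs <- list(iv("a", c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)))
  gold <- list(a = c(1L, 2L))
  rep <- compare_methods(list(perfect = ivs), gold,
                         saliency_config(shuffle_reps = 2, seed = 4))
  expect_equal(rep$table$prg_auc[1], 100)
  expect_equal(rep$table$max_fgain[1], 100)
})

test_that("compare_methods names the missing sequence", {
  ivs <- list(iv("a", c(1, 0)))
  expect_error(compare_methods(list(m = ivs), list(a = 1L, b = 2L)), "b")
})

test_that("per-protein gain curves are emitted on request", {
  set.seed(5)
  imp <- list(iv("a", runif(10)), iv("b", runif(8)))
  gold <- list(a = c(1L, 4L), b = 2L)
  out <- pooled_pr_and_prg(imp, gold, per_protein = TRUE)
  expect_named(out$per_protein, c("a", "b"))
  expect_true(all(vapply(out$per_protein, function(p)
    p$auc >= 0 && p$auc <= 1, logical(1))))
})
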