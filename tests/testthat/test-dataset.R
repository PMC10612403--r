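test_that("level-0 labelling follows the EC/catalytic-GO rule", {
  ann <- data.frame(id = c("a", "b", "c", "d"),
                    ec = c("", "3.1.1.1", "", NA),
                    catalytic_go = c(0L, 1L, 1L, 0L))
  lab <- assign_level0_labels(ann)
  expect_equal(lab$level0, c("non-enzyme", "enzyme", "excluded",
                             "non-enzyme"))
})

test_that("pairwise identity matches an independent alignment oracle", {
  expect_equal(pairwise_identity("MKVLY", "MKVLY"), 1)
  expect_lt(pairwise_identity("AAAAA", "TTTTT"), 0.01)
  pairs <- list(c("MKVLYAD", "MKVGYAD"), c("ACDEFGHIK", "ACDEFG"),
                c("MKKVLY", "MKVLY"), c("GGGAC", "ACGGG"))
  for (p in pairs) {
    expect_equal(pairwise_identity(p[1], p[2]),
                 nw_identity_oracle(p[1], p[2]), tolerance = 1e-12,
                 label = paste(p, collapse = "/"))
  }
})

test_that("greedy clustering merges near-identical sequences and separates unrelated ones", {
  rec <- data.frame(
    id = c("A", "B", "C"),
    sequence = c("MKVLYADGKMSTV", "MKVLYADGKMSTA", "WWFFPPNNQQEER"),
    stringsAsFactors = FALSE)
  cl <- greedy_identity_cluster(rec, 0.40)
  rep_of <- setNames(cl$representative, cl$member)
  expect_equal(rep_of[["A"]], rep_of[["B"]])
  expect_false(rep_of[["C"]] == rep_of[["A"]])
  # representatives map to themselves; table covers every id
  reps <- unique(cl$representative)
  expect_true(all(rep_of[reps] == reps))
  expect_setequal(cl$member, rec$id)
  # identical sequences cluster together; disjoint ones do not
  two <- data.frame(id = c("x", "y"), sequence = c("MKVLY", "MKVLY"))
  expect_equal(length(unique(greedy_identity_cluster(two)$representative)),
               1L)
  far <- data.frame(id = c("x", "y"), sequence = c("AAAAA", "WWWWW"))
  expect_equal(length(unique(greedy_identity_cluster(far)$representative)),
               2L)
})

test_that("time split discards clusters touching the training release", {
  # 5 clusters, 2 contain training members -> 3 test representatives
  train <- data.frame(id = c("t1", "t2"),
                      sequence = c("AAAAAAAAAA", "CCCCCCCCCC"))
  new <- data.frame(
    id = c("n1", "n2", "n3", "n4", "n5"),
    sequence = c("AAAAAAAAAA", "CCCCCCCCCA", "GGGGGGGGGG", "MMMMMMMMMM",
                 "WWWWWWWWWW"))
  clusters <- data.frame(
    member = c("t1", "t2", "n1", "n2", "n3", "n4", "n5"),
    representative = c("t1", "t2", "t1", "t2", "n3", "n4", "n5"))
  split <- build_time_split(train, new, clusters)
  expect_setequal(split$test$id, c("n3", "n4", "n5"))
  expect_setequal(split$train$id, c("t1", "t2"))
  expect_setequal(split$discarded_clusters, c("t1", "t2"))
  # all clusters tainted -> empty test set with warning
  clusters2 <- clusters
  clusters2$representative <- c("t1", "t2", "t1", "t2", "t1", "t2", "t1")
  expect_warning(s2 <- build_time_split(train, new, clusters2), "empty")
  expect_equal(nrow(s2$test), 0L)
  # disjoint singleton clusters -> all new records become test
  clusters3 <- data.frame(member = c(train$id, new$id),
                          representative = c(train$id, new$id))
  s3 <- build_time_split(train, new, clusters3)
  expect_setequal(s3$test$id, new$id)
  expect_error(build_time_split(train, new, clusters[-1, ]), "cover")
})

test_that("cluster representatives for the test set are the longest members", {
  train <- data.frame(id = "t1", sequence = "AAAAAAAAAA")
  new <- data.frame(id = c("s", "l", "m"),
                    sequence = c("GGGG", "GGGGGG", "GGGGG"))
  clusters <- data.frame(member = c("t1", "s", "l", "m"),
                         representative = c("t1", "l", "l", "l"))
  split <- build_time_split(train, new, clusters)
  expect_equal(split$test$id, "l")
})

test_that("length filters honour the two presets at the boundary", {
  rec <- data.frame(id = c("a", "b"),
                    sequence = c(paste(rep("A", 40), collapse = ""),
                                 paste(rep("A", 500), collapse = "")))
  expect_equal(apply_filters(rec, ecpred_preset())$id, "b")   # 41..1024
  expect_setequal(apply_filters(rec, deepec_preset())$id, c("a", "b"))
  # idempotence
  f1 <- apply_filters(rec, ecpred_preset())
  f2 <- apply_filters(f1, ecpred_preset())
  expect_equal(f1$id, f2$id)
})

test_that("an explicit empty class list removes every EC-labelled record", {
  rec <- data.frame(id = c("a", "b"),
                    sequence = rep(paste(rep("A", 100), collapse = ""), 2),
                    ec = c("1.1.1.1", ""))
  cfg <- split_config(allowed_classes = character(0))
  out <- apply_filters(rec, cfg)
  expect_equal(out$id, "b")
})

test_that("release-pair fixtures drive the split guarantee end to end", {
  pair <- gen_release_pair(n_old = 6, n_mutated = 6, n_fresh = 6,
                           len_range = c(40, 60), mutation_rate = 0.2,
                           seed = 11)
  all_rec <- rbind(pair$old[, c("id", "sequence")],
                   pair$new[, c("id", "sequence")])
  clusters <- greedy_identity_cluster(all_rec, 0.40)
  split <- build_time_split(pair$old, pair$new, clusters)
  fresh <- pair$truth$id[pair$truth$origin == "fresh"]
  expect_setequal(split$test$id, fresh)
  # guarantee: no test record shares a cluster with any training record
  rep_of <- setNames(clusters$representative, clusters$member)
  expect_length(intersect(rep_of[split$test$id], rep_of[split$train$id]), 0)
  # and the built-in clusterer keeps identities below threshold
  for (tid in split$test$id) {
    for (rid in unique(rep_of[split$train$id])) {
      seq_t <- all_rec$sequence[all_rec$id == tid]
      seq_r <- all_rec$sequence[all_rec$id == rid]
      expect_lt(pairwise_identity(seq_t, seq_r), 0.40)
    }
  }
})

test_that("census counts planted classes and conserves totals", {
  pair <- gen_release_pair(n_old = 5, n_mutated = 3, n_fresh = 4,
                           len_range = c(30, 40), seed = 7)
  all_rec <- rbind(pair$old[, c("id", "sequence")],
                   pair$new[, c("id", "sequence")])
  clusters <- greedy_identity_cluster(all_rec, 0.40)
  split <- build_time_split(pair$old, pair$new, clusters)
  cen <- split_census(split, pair$annotations)
  class_cols <- setdiff(names(cen), c("partition", "total"))
  expect_equal(rowSums(cen[, class_cols]), cen$total,
               ignore_attr = TRUE)
  expect_equal(cen$total, c(nrow(split$train), nrow(split$test)))
  # counts match the generator's planted level-1 classes
  lvl1 <- as.integer(sub("\\..*", "", pair$annotations$ec))
  train_counts <- table(factor(lvl1[match(split$train$id,
                                          pair$annotations$id)],
                               levels = 1:7))
  expect_equal(unname(as.integer(train_counts)),
               as.integer(cen[1, class_cols][-1]))
})

test_that("cluster tables round-trip through the two-column TSV format", {
  cl <- data.frame(member = c("a", "b", "c"),
                   representative = c("a", "a", "c"))
  path <- tempfile(fileext = ".tsv")
  write_cluster_tsv(cl, path)
  back <- read_cluster_tsv(path)
  expect_equal(back[order(back$member), ], cl[order(cl$member), ],
               ignore_attr = TRUE)
  unlink(path)
})
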