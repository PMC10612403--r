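# Time-based, identity-cluster-excluded benchmark construction: labelling
# rules, a pluggable clustering step (external cluster table or built-in
# greedy aligner-based clusterer), split construction and census.

#' Split configuration
#'
#' @param identity_threshold Pairwise identity at or above which two
#'   sequences belong to the same cluster (default 0.40).
#' @param min_len,max_len Inclusive sequence-length bounds.  Presets:
#'   `ecpred_preset()` keeps 41..1024 ("more than 40, up to 1024"),
#'   `deepec_preset()` keeps 40..1000 (inclusive).
#' @param allowed_classes Optional character vector of EC labels to keep;
#'   `NULL` disables the filter (an empty vector removes every enzyme).
#' @param keep_all_training_members Keep every training-release record for
#'   training rather than one representative per cluster (default `TRUE`).
#' @return Object of class `split_config`.
#' @export
split_config <- function(identity_threshold = 0.40, min_len = 41L,
                         max_len = 1024L, allowed_classes = NULL,
                         keep_all_training_members = TRUE) {
  stopifnot(identity_threshold > 0, identity_threshold < 1,
            min_len <= max_len)
  structure(list(identity_threshold = identity_threshold,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 allowed_classes = allowed_classes,
                 keep_all_training_members = isTRUE(keep_all_training_members)),
            class = "split_config")
}

#' @rdname split_config
#' @export
ecpred_preset <- function() split_config(min_len = 41L, max_len = 1024L)

#' @rdname split_config
#' @export
deepec_preset <- function() split_config(min_len = 40L, max_len = 1000L)

#' Assign enzyme / non-enzyme / excluded level-0 labels
#'
#' A record is a non-enzyme iff it has neither an EC annotation nor a
#' catalytic-GO flag; records with a catalytic-GO flag but no EC number are
#' marked `excluded` (they are neither usable as non-enzymes nor assignable
#' to an enzyme class).
#'
#' @param annotations Data frame with columns `id`, `ec` (EC string,
#'   semicolon-joined list, or `""`/`NA` for none) and `catalytic_go`
#'   (0/1 or logical).
#' @return The input with an added `level0` column in
#'   `{enzyme, non-enzyme, excluded}`.
#' @export
assign_level0_labels <- function(annotations) {
  has_ec <- !is.na(annotations$ec) & nzchar(trimws(annotations$ec))
  go <- as.logical(annotations$catalytic_go)
  annotations$level0 <- ifelse(has_ec, "enzyme",
                               ifelse(go, "excluded", NON_ENZYME))
  annotations
}

#' Pairwise global-alignment identity
#'
#' Needleman-Wunsch global alignment with match score 1, mismatch 0 and gap
#' cost 1 per position; identity is the number of identical aligned
#' positions divided by the alignment length (gaps included).
#'
#' @param a,b Residue strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  sub <- matrix(0, 26, 26,
                dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  sum(pa == sa & pa != "-") / length(pa)
}

#' Greedy identity clustering
#'
#' Desk-scale stand-in for an external clustering tool: records are sorted
#' by descending length; each record joins the first existing cluster whose
#' representative shares at least `threshold` identity with it (see
#' [pairwise_identity()]), otherwise it founds a new cluster with itself as
#' representative.
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param threshold Identity threshold (default 0.40).
#' @return A cluster table: data frame with columns `member` and
#'   `representative` (every representative maps to itself), covering every
#'   input id.
#' @export
greedy_identity_cluster <- function(records, threshold = 0.40) {
  stopifnot(nrow(records) >= 1, !anyDuplicated(records$id))
  ord <- order(-nchar(records$sequence), records$id)
  reps <- integer(0)  # row indices of representatives
  assign <- character(nrow(records))
  names(assign) <- records$id
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(records$sequence[i],
                            records$sequence[r]) >= threshold) {
        assign[records$id[i]] <- records$id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[records$id[i]] <- records$id[i]
    }
  }
  data.frame(member = names(assign), representative = unname(assign),
             stringsAsFactors = FALSE)
}

#' Time-based cluster-excluded split
#'
#' Implements the time-based benchmark protocol: every cluster containing
#' at least one training-release record is discarded from test candidacy;
#' one representative per surviving cluster (longest sequence, ties broken
#' by lexicographic id) enters the test set.  All training-release records
#' are kept for training when `keep_all_training_members` is set; otherwise
#' one representative per training cluster is kept.  The returned object
#' records the guarantee that no test record shares a cluster with any
#' training record.
#'
#' @param train_records,new_records Data frames with columns `id`,
#'   `sequence` (training release and newly annotated records).
#' @param clusters Cluster table (`member`, `representative`) covering the
#'   union of both record sets, e.g. from [greedy_identity_cluster()] or
#'   [read_cluster_tsv()].
#' @param cfg A [split_config()].
#' @return Object of class `dataset_split`: list with `train`, `test`
#'   (data frames), `discarded_clusters`, `manifest` (data frame `id`,
#'   `partition`) and `config`.
#' @export
build_time_split <- function(train_records, new_records, clusters,
                             cfg = split_config()) {
  all_ids <- c(train_records$id, new_records$id)
  if (!all(all_ids %in% clusters$member))
    stop("cluster table does not cover all records")
  rep_of <- setNames(clusters$representative, clusters$member)
  train_clusters <- unique(rep_of[train_records$id])
  new_cl <- rep_of[new_records$id]
  tainted <- new_cl %in% train_clusters
  surviving <- unique(new_cl[!tainted])
  test_rows <- vapply(surviving, function(cl) {
    cand <- which(new_cl == cl)
    cand[order(-nchar(new_records$sequence[cand]),
               new_records$id[cand])][1L]
  }, integer(1))
  test <- new_records[test_rows, , drop = FALSE]
  train <- if (cfg$keep_all_training_members) train_records else {
    keep <- vapply(unique(rep_of[train_records$id]), function(cl) {
      cand <- which(rep_of[train_records$id] == cl)
      cand[order(-nchar(train_records$sequence[cand]),
                 train_records$id[cand])][1L]
    }, integer(1))
    train_records[keep, , drop = FALSE]
  }
  if (!nrow(test))
    warning("empty test set: every new-release cluster contains a ",
            "training record")
  manifest <- rbind(
    data.frame(id = train$id, partition = rep("train", nrow(train)),
               stringsAsFactors = FALSE),
    data.frame(id = test$id, partition = rep("test", nrow(test)),
               stringsAsFactors = FALSE))
  structure(list(train = train, test = test,
                 discarded_clusters = unique(new_cl[tainted]),
                 manifest = manifest, config = cfg,
                 cluster_of = rep_of),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "dataset_split: %d training, %d test record(s); %d new-release cluster(s) discarded\n",
    nrow(x$train), nrow(x$test), length(x$discarded_clusters)))
  invisible(x)
}

#' Length and class filters
#'
#' Removes records outside `[min_len, max_len]` and, when
#' `cfg$allowed_classes` is given (possibly empty), records whose `ec` label
#' is not in the allowed list (records without an EC label are kept by the
#' class filter).  Removal counts are attached as the `removed` attribute.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `ec`.
#' @param cfg A [split_config()].
#' @return Filtered data frame with attribute
#'   `removed = c(length = ..., class = ...)`.
#' @export
apply_filters <- function(records, cfg = split_config()) {
  len <- nchar(records$sequence)
  keep_len <- len >= cfg$min_len & len <= cfg$max_len
  removed_len <- sum(!keep_len)
  records <- records[keep_len, , drop = FALSE]
  removed_class <- 0L
  if (!is.null(cfg$allowed_classes) && !is.null(records$ec)) {
    has_ec <- !is.na(records$ec) & nzchar(records$ec)
    keep_cl <- !has_ec | records$ec %in% cfg$allowed_classes
    removed_class <- sum(!keep_cl)
    records <- records[keep_cl, , drop = FALSE]
  }
  structure(records, removed = c(length = removed_len,
                                 class = removed_class))
}

#' Per-class census of a split
#'
#' Counts records per level-1 EC class (plus non-enzyme and total) in each
#' partition, in the shape of the benchmark summary tables.
#'
#' @param split A `dataset_split` from [build_time_split()].
#' @param annotations Data frame with columns `id`, `ec` (may be `""` for
#'   none) and `catalytic_go`.
#' @return Data frame: one row per partition, columns `partition`,
#'   `non_enzyme`, one per level-1 class name, `total`.
#' @export
split_census <- function(split, annotations) {
  ann <- assign_level0_labels(annotations)
  class_names <- c("Oxidoreductases", "Transferases", "Hydrolases",
                   "Lyases", "Isomerases", "Ligases", "Translocases")
  one <- function(ids, partition) {
    a <- ann[match(ids, ann$id), , drop = FALSE]
    lvl1 <- rep(NA_integer_, nrow(a))
    enz <- !is.na(a$level0) & a$level0 == "enzyme"
    lvl1[enz] <- vapply(strsplit(a$ec[enz], "[.;]"),
                        function(p) as.integer(p[1L]), integer(1))
    row <- data.frame(partition = partition,
                      non_enzyme = sum(a$level0 == NON_ENZYME, na.rm = TRUE))
    for (k in 1:7) row[[class_names[k]]] <- sum(lvl1 == k, na.rm = TRUE)
    row$total <- length(ids)
    row
  }
  rbind(one(split$train$id, "train"), one(split$test$id, "test"))
}
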