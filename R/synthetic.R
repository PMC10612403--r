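# Seeded generators for every input the toolkit consumes: motif-determined
# sequence classes with planted "catalytic" residues, row-stochastic
# attention tensors with planted hotspots, and paired releases for testing
# the time-based split.  All generators are pure functions of their spec.

#' Synthetic-fixture specification
#'
#' Describes a corpus of motif-classed sequences: each class is defined by a
#' distinct planted k-mer motif, whose positions serve as gold
#' "catalytic-residue" labels.  When `len_range` is not given it is derived
#' from the gold-label prevalence target (`motif_len / prevalence`, +/-20%),
#' so that the default corpus reproduces the sparse ~1% prevalence regime of
#' curated catalytic-site annotations.
#'
#' Motifs are drawn from a small reserved residue alphabet
#' (`motif_alphabet`, default C/H/M/W) that never occurs in the background,
#' mirroring the compositional distinctiveness of catalytic residues
#' (histidines, cysteines and friends are strongly enriched at catalytic
#' sites); the background is uniform over the remaining residues.  This
#' keeps the planted signal crisp, so the fixtures act as sharp sanity
#' checks for training and interpretability rather than hard benchmarks.
#'
#' @param n_sequences Number of sequences.
#' @param len_range Integer length range `c(min, max)`, or `NULL` to derive
#'   it from `prevalence`.
#' @param n_classes Number of classes (distinct motifs).
#' @param motif_len Motif length in residues.
#' @param motif_alphabet Residues reserved for motifs; the background uses
#'   the remaining standard residues.
#' @param hotspot_count Hotspots per synthetic attention tensor.
#' @param hotspot_boost Mass added to hotspot columns (beta >= 0).
#' @param prevalence Target fraction of gold-labelled residues, in (0, 1).
#' @param seed RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 300L, len_range = NULL,
                           n_classes = 3L, motif_len = 5L,
                           motif_alphabet = c("C", "H", "M", "W"),
                           hotspot_count = 5L, hotspot_boost = 10,
                           prevalence = 0.012, seed = 0L) {
  stopifnot(n_sequences >= 1, n_classes >= 1, motif_len >= 1,
            prevalence > 0, prevalence < 1, hotspot_boost >= 0,
            all(motif_alphabet %in% AA_STANDARD),
            length(motif_alphabet) >= 2,
            length(motif_alphabet) < length(AA_STANDARD))
  if (is.null(len_range)) {
    center <- motif_len / prevalence
    len_range <- as.integer(round(c(0.8, 1.2) * center))
  }
  len_range <- as.integer(len_range)
  stopifnot(length(len_range) == 2L, len_range[1] <= len_range[2])
  if (motif_len >= len_range[1])
    stop("motif length (", motif_len, ") must be shorter than the minimum ",
         "sequence length (", len_range[1], ")")
  structure(list(n_sequences = as.integer(n_sequences),
                 len_range = len_range, n_classes = as.integer(n_classes),
                 motif_len = as.integer(motif_len),
                 motif_alphabet = motif_alphabet,
                 hotspot_count = as.integer(hotspot_count),
                 hotspot_boost = hotspot_boost, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_aa_string <- function(n, alphabet = AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate motif-classed sequences with planted catalytic residues
#'
#' Each class has a distinct random k-mer motif inserted at a random
#' position of an otherwise uniform-random amino-acid sequence; the motif
#' span is recorded as the gold label set of that sequence.  Deterministic
#' given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (data frame: `id`, `sequence`, `length`),
#'   `labels` (class label per record), `gold` (named list of 1-based gold
#'   positions per record) and `motifs` (named character vector, one motif
#'   per class).
#' @export
gen_classified_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  background <- setdiff(AA_STANDARD, spec$motif_alphabet)
  repeat {
    motifs <- vapply(seq_len(spec$n_classes), function(i)
      random_aa_string(spec$motif_len, spec$motif_alphabet), character(1))
    if (!anyDuplicated(motifs)) break
  }
  names(motifs) <- paste0("C", seq_len(spec$n_classes))
  n <- spec$n_sequences
  cls <- paste0("C", rep_len(seq_len(spec$n_classes), n))
  ids <- sprintf("seq%04d", seq_len(n))
  lens <- sample(spec$len_range[1]:spec$len_range[2], n, replace = TRUE)
  gold <- vector("list", n); names(gold) <- ids
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- strsplit(random_aa_string(lens[i], background), "")[[1]]
    start <- sample.int(lens[i] - spec$motif_len + 1L, 1L)
    span <- start:(start + spec$motif_len - 1L)
    s[span] <- strsplit(motifs[[cls[i]]], "")[[1]]
    seqs[i] <- paste(s, collapse = "")
    gold[[i]] <- span
  }
  list(records = data.frame(id = ids, sequence = seqs, length = lens,
                            stringsAsFactors = FALSE),
       labels = cls, gold = gold, motifs = motifs)
}

#' Generate a random attention tensor with planted hotspots
#'
#' Rows are Dirichlet(1) draws over the key axis; `beta` extra mass is added
#' to hotspot columns before renormalising, so `beta = 0` gives a pure-noise
#' tensor and large `beta` concentrates every row on the hotspots.
#'
#' @param T Token count.
#' @param L,H Layer and head counts (tensor first axis has `L * H` slices).
#' @param hotspots Integer positions in `[1, T]` (may be empty).
#' @param beta Non-negative hotspot boost.
#' @param seed RNG seed.
#' @param cls_last If `TRUE`, mark the final token as a classification token
#'   in the capture's special mask.
#' @return An [attn_capture()].
#' @export
gen_attention_tensor <- function(T, L = 2L, H = 4L, hotspots = integer(0),
                                 beta = 0, seed = 0L, cls_last = FALSE) {
  stopifnot(T >= 2, L >= 1, H >= 1, beta >= 0)
  if (length(hotspots) &&
      (any(hotspots < 1) || any(hotspots > T) || any(hotspots != round(hotspots))))
    stop("hotspot positions must be integers in [1, ", T, "]")
  set.seed(seed)
  A <- random_stochastic_tensor(L * H, T)
  if (length(hotspots) && beta > 0) {
    A[, , hotspots] <- A[, , hotspots] + beta / length(hotspots)
    s <- apply(A, c(1L, 2L), sum)
    A <- A / as.numeric(s)
  }
  mask <- rep(FALSE, T)
  if (cls_last) mask[T] <- TRUE
  attn_capture(A, mask)
}

#' Generate a paired "release" fixture for split testing
#'
#' Produces an old-release record set and a new-release set whose members
#' are either mutated copies of old records (identity well above the
#' clustering threshold, so they must be excluded from the test set
#' downstream) or fresh unrelated sequences (which must survive).  The
#' ground truth of which is which is returned for assertion, together with
#' random EC annotations for census round-trips.
#'
#' @param n_old,n_mutated,n_fresh Record counts.
#' @param len_range Sequence length range.
#' @param mutation_rate Per-position substitution probability for mutated
#'   copies (i.i.d. substitutions, no indels).
#' @param seed RNG seed.
#' @return List with `old`, `new` (data frames `id`, `sequence`,
#'   `release_tag`), `truth` (data frame `id`, `origin` in
#'   `{mutated, fresh}`, `source_id`) and `annotations` (data frame `id`,
#'   `ec`, `catalytic_go`).
#' @export
gen_release_pair <- function(n_old = 10L, n_mutated = 10L, n_fresh = 10L,
                             len_range = c(60L, 100L), mutation_rate = 0.2,
                             seed = 0L) {
  stopifnot(n_old >= 1, n_mutated <= n_old * 100, mutation_rate >= 0,
            mutation_rate <= 1)
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n_old, replace = TRUE)
  old <- data.frame(id = sprintf("old%03d", seq_len(n_old)),
                    sequence = vapply(lens, random_aa_string, character(1)),
                    release_tag = "old", stringsAsFactors = FALSE)
  src <- sample.int(n_old, n_mutated, replace = n_mutated > n_old)
  mutated <- vapply(src, function(i) {
    s <- strsplit(old$sequence[i], "")[[1]]
    hit <- runif(length(s)) < mutation_rate
    s[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  fresh <- vapply(sample(len_range[1]:len_range[2], n_fresh, replace = TRUE),
                  random_aa_string, character(1))
  new <- data.frame(
    id = c(sprintf("mut%03d", seq_len(n_mutated)),
           sprintf("new%03d", seq_len(n_fresh))),
    sequence = c(mutated, fresh), release_tag = "new",
    stringsAsFactors = FALSE)
  truth <- data.frame(
    id = new$id,
    origin = c(rep("mutated", n_mutated), rep("fresh", n_fresh)),
    source_id = c(old$id[src], rep(NA_character_, n_fresh)),
    stringsAsFactors = FALSE)
  all_ids <- c(old$id, new$id)
  annotations <- data.frame(
    id = all_ids,
    ec = paste(sample(1:6, length(all_ids), replace = TRUE),
               sample(1:9, length(all_ids), replace = TRUE),
               sample(1:9, length(all_ids), replace = TRUE),
               sample(1:99, length(all_ids), replace = TRUE), sep = "."),
    catalytic_go = 1L, stringsAsFactors = FALSE)
  list(old = old, new = new, truth = truth, annotations = annotations)
}
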