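# Readers/writers for the plain-text formats the toolkit exchanges:
# FASTA sequences, labels / annotations / gold-labels / cluster TSVs,
# importance-score TSVs and JSON-lines run logs.

#' Read and write FASTA sequence records
#'
#' @param path File path.
#' @param release_tag Optional tag stored on every record (`old`/`new`).
#' @return `read_fasta` returns a data frame with columns `id`, `sequence`
#'   and (if tagged) `release_tag`.
#' @export
read_fasta <- function(path, release_tag = NULL) {
  x <- Biostrings::readAAStringSet(path)
  out <- data.frame(id = sub("\\s.*$", "", names(x)),
                    sequence = as.character(x), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(release_tag)) out$release_tag <- release_tag
  out
}

#' @rdname read_fasta
#' @param records Data frame with columns `id` and `sequence`.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a two-column labels TSV (id, class)
#' @param path File path.
#' @return Data frame with columns `id`, `class`.
#' @export
read_labels_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, colClasses = "character")
}

#' Read an annotations TSV (id, ec, catalytic_go)
#'
#' `ec` may hold a semicolon-joined list or be empty; `catalytic_go` is 0/1.
#' @param path File path.
#' @return Data frame with columns `id`, `ec`, `catalytic_go`.
#' @export
read_annotations_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE,
                         colClasses = c("character", "character", "integer"))
  stopifnot(all(c("id", "ec", "catalytic_go") %in% names(d)))
  d$ec[is.na(d$ec)] <- ""
  d
}

#' Read catalytic-residue gold labels
#'
#' TSV with columns `id`, `position` (1-based) and `residue`.
#'
#' @param path File path.
#' @return Named list mapping sequence id to a sorted integer vector of
#'   gold positions.
#' @export
read_gold_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE)
  stopifnot(all(c("id", "position") %in% names(d)))
  lapply(split(as.integer(d$position), d$id), sort)
}

#' @rdname read_gold_tsv
#' @param gold Named list of gold positions.
#' @param records Optional data frame (`id`, `sequence`) used to fill the
#'   `residue` column.
#' @export
write_gold_tsv <- function(gold, path, records = NULL) {
  rows <- do.call(rbind, lapply(names(gold), function(id) {
    pos <- sort(gold[[id]])
    res <- if (!is.null(records)) {
      s <- records$sequence[match(id, records$id)]
      substring(s, pos, pos)
    } else rep(NA_character_, length(pos))
    data.frame(id = id, position = pos, residue = res,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write MMseqs2-style cluster tables
#'
#' Two tab-separated columns: representative, member (no header).
#'
#' @param path File path.
#' @return `read_cluster_tsv` returns a data frame with columns `member`,
#'   `representative`.
#' @export
read_cluster_tsv <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character")
  data.frame(member = d[[2L]], representative = d[[1L]],
             stringsAsFactors = FALSE)
}

#' @rdname read_cluster_tsv
#' @param clusters Data frame with columns `member`, `representative`.
#' @export
write_cluster_tsv <- function(clusters, path) {
  utils::write.table(clusters[, c("representative", "member")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write per-residue importance scores as TSV
#'
#' Columns: `id`, `position` (1-based), `residue`, `score`, `method`.
#'
#' @param importances List of [importance_vector()]s.
#' @param path File path.
#' @param records Optional data frame (`id`, `sequence`) to fill `residue`.
#' @export
write_importance_tsv <- function(importances, path, records = NULL) {
  rows <- do.call(rbind, lapply(importances, function(iv) {
    pos <- seq_along(iv$scores)
    res <- if (!is.null(records)) {
      s <- records$sequence[match(iv$seq_id, records$id)]
      substring(s, pos, pos)
    } else rep(NA_character_, length(pos))
    data.frame(id = iv$seq_id, position = pos, residue = res,
               score = iv$scores, method = iv$method,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance_tsv
#' @return `read_importance_tsv` returns a list of importance vectors.
#' @export
read_importance_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE)
  out <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$position), ]
    importance_vector(as.character(g$id[1L]), g$score,
                      as.character(g$method[1L]))
  })
  unname(out)
}

#' Append one JSON record per line to a run log
#' @param record Named list.
#' @param path Log file path.
#' @export
append_jsonl <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
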