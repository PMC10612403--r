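# EC-number data model and hierarchical evaluation: macro
# precision/recall/F1 and accuracy at levels 0-4 with level truncation.

NON_ENZYME <- "non-enzyme"

#' Parse an EC number
#'
#' Accepts dotted EC strings with dashes for unknown deeper levels
#' (`"2.7.11.1"`, `"7.-.-.-"`, `"1.2"`) or the distinguished non-enzyme
#' token (`"non-enzyme"`).  The main class must be between 1 and 7
#' (7 = translocases).
#'
#' @param text EC string or non-enzyme token.
#' @return An object of class `ec_label`: list with `components` (integer
#'   vector, `NA` for dashes), `depth` (number of leading concrete
#'   components, 0 for non-enzyme) and `non_enzyme` flag.
#' @examples
#' parse_ec("2.7.11.1")$depth  # 4
#' parse_ec("7.-.-.-")$depth   # 1
#' @export
parse_ec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (text %in% c(NON_ENZYME, "non_enzyme", "nonenzyme", "0"))
    return(structure(list(components = integer(0), depth = 0L,
                          non_enzyme = TRUE), class = "ec_label"))
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 4L || any(parts == ""))
    stop("malformed EC string: \"", text, "\"")
  comp <- suppressWarnings(as.integer(parts))
  dash <- parts == "-"
  if (any(is.na(comp) & !dash))
    stop("malformed EC string: \"", text, "\"")
  comp[dash] <- NA_integer_
  # depth = leading concrete components; a concrete field after a dash is
  # malformed ("1.-.3.4")
  depth <- if (anyNA(comp)) min(which(is.na(comp))) - 1L else length(comp)
  if (any(!is.na(comp[seq_along(comp) > depth])))
    stop("malformed EC string: \"", text,
         "\" (concrete component after a dash)")
  if (depth == 0L) stop("malformed EC string: \"", text, "\"")
  if (comp[1L] < 1L || comp[1L] > 7L)
    stop("EC class ", comp[1L], " out of range 1-7")
  if (any(comp[!is.na(comp)] < 0L))
    stop("malformed EC string: \"", text, "\"")
  structure(list(components = comp[seq_len(depth)], depth = depth,
                 non_enzyme = FALSE), class = "ec_label")
}

#' @export
format.ec_label <- function(x, ...) {
  if (x$non_enzyme) return(NON_ENZYME)
  paste(c(as.character(x$components),
          rep("-", 4L - x$depth)), collapse = ".")
}

#' @export
print.ec_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Truncate an EC label to a level
#'
#' Level 0 maps any enzyme to `"enzyme"` and the non-enzyme label to
#' `"non-enzyme"`; levels 1-4 keep the first `level` components (missing
#' deeper components stay as dashes).  The non-enzyme label is absorbing at
#' every level.
#'
#' @param label An [parse_ec()] result or an EC string.
#' @param level Integer 0-4.
#' @return Character representation of the truncated label.
#' @examples
#' truncate_level("1.2.3.4", 2)  # "1.2"
#' truncate_level("1.2.3.4", 0)  # "enzyme"
#' @export
truncate_level <- function(label, level) {
  if (is.character(label)) label <- parse_ec(label)
  stopifnot(inherits(label, "ec_label"), level >= 0, level <= 4)
  if (label$non_enzyme) return(NON_ENZYME)
  if (level == 0) return("enzyme")
  comp <- label$components[seq_len(min(level, label$depth))]
  paste(c(as.character(comp), rep("-", level - length(comp))),
        collapse = ".")
}

#' Macro metrics at one EC level
#'
#' Truncates truth and predictions to `level` and computes accuracy (exact
#' match at that level) and macro-averaged precision, recall and F1 over
#' the classes present in the truth (classes with no truth support are
#' excluded from the average; a class with zero precision and recall gets
#' F1 = 0).  With `include_nonenzyme = FALSE`, pairs whose truth is
#' non-enzyme are dropped first (the enzymes-only protocol).
#'
#' @param truth,pred Equal-length character vectors of EC strings or the
#'   non-enzyme token (level-4 predictions; coarser levels are derived by
#'   truncation).
#' @param level Integer 0-4.
#' @param include_nonenzyme Keep non-enzyme truth pairs (default `TRUE`).
#' @return List of class `level_metrics`: `level`, `macro_f1`,
#'   `macro_precision`, `macro_recall`, `accuracy`, `n_classes`, `n`.
#' @export
ec_level_metrics <- function(truth, pred, level, include_nonenzyme = TRUE) {
  stopifnot(length(truth) == length(pred))
  if (!include_nonenzyme) {
    keep <- vapply(truth, function(t) !parse_ec(t)$non_enzyme, logical(1))
    truth <- truth[keep]; pred <- pred[keep]
  }
  if (!length(truth)) stop("empty evaluation set after filtering")
  tt <- vapply(truth, truncate_level, character(1), level = level)
  pp <- vapply(pred, truncate_level, character(1), level = level)
  classes <- sort(unique(tt))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(tt == cl & pp == cl)
    fp <- sum(tt != cl & pp == cl)
    fn <- sum(tt == cl & pp != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  structure(list(level = as.integer(level),
                 macro_f1 = mean(per_class[3L, ]),
                 macro_precision = mean(per_class[1L, ]),
                 macro_recall = mean(per_class[2L, ]),
                 accuracy = mean(tt == pp),
                 n_classes = length(classes), n = length(tt)),
            class = "level_metrics")
}

#' @export
print.level_metrics <- function(x, ...) {
  cat(sprintf(
    "level %d: macro-F1 %.3f  macro-P %.3f  macro-R %.3f  acc %.3f  (%d classes, n=%d)\n",
    x$level, x$macro_f1, x$macro_precision, x$macro_recall, x$accuracy,
    x$n_classes, x$n))
  invisible(x)
}

#' Multi-level EC evaluation report
#'
#' Derives every level 0-4 by truncating the same level-4 predictions and
#' evaluates each under the selected protocol: `"all"` keeps every pair at
#' every level (no enzyme a priori); `"enzymes-only"` evaluates level 0 on
#' all pairs and levels 1-4 on pairs whose truth is an enzyme.
#'
#' @param truth,pred Character vectors of level-4 EC strings or the
#'   non-enzyme token.
#' @param protocol `"all"` or `"enzymes-only"`.
#' @return Object of class `multi_level_report`: list of five
#'   `level_metrics` plus a `table` data frame.
#' @export
multi_level_report <- function(truth, pred,
                               protocol = c("all", "enzymes-only")) {
  protocol <- match.arg(protocol)
  levels <- lapply(0:4, function(l) {
    ec_level_metrics(truth, pred, l,
                     include_nonenzyme = protocol == "all" || l == 0)
  })
  tab <- do.call(rbind, lapply(levels, function(m)
    data.frame(level = m$level, macro_f1 = m$macro_f1,
               macro_precision = m$macro_precision,
               macro_recall = m$macro_recall, accuracy = m$accuracy,
               n_classes = m$n_classes, n = m$n)))
  structure(list(levels = levels, table = tab, protocol = protocol),
            class = "multi_level_report")
}

#' @export
print.multi_level_report <- function(x, ...) {
  cat("Hierarchical EC evaluation (protocol: ", x$protocol, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
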