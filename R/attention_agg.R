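# Two-stage pooling of the (L*H, T, T) attention tensor into a per-residue
# importance vector, plus enumeration/deduplication of the variant family.
#
# Tensor orientation: axis 1 = layer-head pairs, axis 2 = attending (query)
# token, axis 3 = attended (key) token; rows are softmax-normalised over the
# key axis, so "attention received by token j" is column j.

#' Attention-aggregation variant specification
#'
#' A variant is named `AttnAgg<d1><f1><d2><f2>`: stage 1 collapses axis `d1`
#' of the tensor (1 = layer-head axis, 2 = query-token axis) with pooling
#' function `f1` (`A` = average, `M` = maximum), stage 2 collapses axis `d2`
#' of the remaining matrix with `f2`.  The family has 16 nominal members.
#'
#' @param name Variant name, e.g. `"AttnAgg1A1A"`.
#' @return An object of class `agg_spec` with fields `stage1_axis`,
#'   `stage1_func`, `stage2_axis`, `stage2_func` and `name`.
#' @examples
#' agg_spec("AttnAgg1A1A")
#' @export
agg_spec <- function(name) {
  m <- regmatches(name, regexec("^AttnAgg([12])([AM])([12])([AM])$", name))[[1]]
  if (length(m) != 5L)
    stop("malformed variant name: ", name,
         " (expected AttnAgg<1|2><A|M><1|2><A|M>)")
  fn <- c(A = "average", M = "maximum")
  structure(list(stage1_axis = as.integer(m[2]), stage1_func = fn[[m[3]]],
                 stage2_axis = as.integer(m[4]), stage2_func = fn[[m[5]]],
                 name = name),
            class = "agg_spec")
}

#' All 16 nominal variant names
#' @return Character vector of the 16 nominal `AttnAgg` names.
#' @export
agg_variant_names <- function() {
  g <- expand.grid(f2 = c("A", "M"), d2 = 1:2, f1 = c("A", "M"), d1 = 1:2,
                   stringsAsFactors = FALSE)
  sort(paste0("AttnAgg", g$d1, g$f1, g$d2, g$f2))
}

pool_axis1 <- function(A, func) {
  # collapse first axis of a 3-d array -> matrix (dim2 x dim3)
  d <- dim(A)
  if (func == "average") {
    matrix(colMeans(array(A, c(d[1L], d[2L] * d[3L]))), d[2L], d[3L])
  } else {
    M <- A[1L, , ]
    if (d[1L] > 1L) for (i in 2L:d[1L]) M <- pmax(M, A[i, , ])
    M
  }
}

pool_axis2 <- function(A, func) {
  # collapse second axis of a 3-d array -> matrix (dim1 x dim3)
  d <- dim(A)
  B <- aperm(A, c(2L, 1L, 3L))
  if (func == "average") {
    matrix(colMeans(array(B, c(d[2L], d[1L] * d[3L]))), d[1L], d[3L])
  } else {
    M <- B[1L, , ]
    if (d[2L] > 1L) for (i in 2L:d[2L]) M <- pmax(M, B[i, , ])
    M
  }
}

#' Aggregate an attention tensor into a token-level vector
#'
#' Applies the two pooling stages of `spec` to the full token-level tensor
#' (special tokens included; remove them afterwards with
#' [strip_special_tokens()]).  Variants whose surviving axis is the
#' layer-head axis (stage 1 and stage 2 both collapsing token axes) are
#' still computed but flagged degenerate: their output is not a per-token
#' vector.
#'
#' @param capture An [attn_capture()] (or a bare 3-d array).
#' @param spec An [agg_spec()] or a variant name.
#' @return Numeric vector over the surviving axis, with attributes `method`
#'   (the variant name) and `surviving_axis` (`"token"` or `"head"`).
#' @examples
#' a <- gen_attention_tensor(T = 5, L = 1, H = 2, seed = 1)
#' v <- aggregate_attention(a, "AttnAgg1A1A")
#' sum(v)  # 1: mean of column means of row-stochastic rows
#' @export
aggregate_attention <- function(capture, spec) {
  if (is.character(spec)) spec <- agg_spec(spec)
  A <- if (inherits(capture, "attn_capture")) capture$tensor else capture
  stopifnot(is.array(A), length(dim(A)) == 3L)
  M <- if (spec$stage1_axis == 1L) pool_axis1(A, spec$stage1_func)
       else pool_axis2(A, spec$stage1_func)
  v <- if (spec$stage2_axis == 1L) {
    if (spec$stage2_func == "average") colMeans(M) else apply(M, 2L, max)
  } else {
    if (spec$stage2_func == "average") rowMeans(M) else apply(M, 1L, max)
  }
  surviving <- if (spec$stage1_axis == 2L && spec$stage2_axis == 2L)
    "head" else "token"
  structure(as.numeric(v), method = spec$name, surviving_axis = surviving)
}

#' Remove special-token entries from a token-level vector
#'
#' Drops entries at special-token positions (classification token, padding)
#' and re-indexes the remainder to 1-based residue positions.
#'
#' @param raw Numeric vector indexed over the tokens of `capture`.
#' @param capture The [attn_capture()] the vector was computed from.
#' @param seq_id Identifier stored on the result.
#' @param method Method label; defaults to the `method` attribute of `raw`.
#' @return An [importance_vector()].
#' @export
strip_special_tokens <- function(raw, capture, seq_id = NA_character_,
                                 method = attr(raw, "method")) {
  mask <- capture$special_mask
  if (length(raw) != length(mask))
    stop("vector length (", length(raw), ") does not match token count (",
         length(mask), ")")
  if (all(mask)) stop("capture contains no residue tokens")
  scores <- as.numeric(raw[!mask])
  importance_vector(seq_id, scores, if (is.null(method)) "unknown" else method)
}

#' Per-residue importance vector
#'
#' @param seq_id Sequence identifier.
#' @param scores Numeric vector indexed by 1-based residue position; must be
#'   finite.
#' @param method Name of the method that produced the scores.
#' @return An object of class `importance_vector`.
#' @export
importance_vector <- function(seq_id, scores, method) {
  if (!all(is.finite(scores))) stop("importance scores must be finite")
  structure(list(seq_id = seq_id, scores = as.numeric(scores),
                 method = method),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat(sprintf("importance_vector [%s] %s: %d residues, range [%.4g, %.4g]\n",
              x$method, x$seq_id, length(x$scores), min(x$scores),
              max(x$scores)))
  invisible(x)
}

#' Enumerate and deduplicate the aggregation-variant family
#'
#' Evaluates all 16 nominal variants on seeded random row-stochastic probe
#' tensors (Dirichlet(1) rows) and merges variants into equivalence classes:
#' two variants merge when their outputs coincide within `tol` on every
#' probe, and all variants whose output is constant (zero variance) on every
#' probe collapse into a single degenerate class, since a constant vector
#' carries no ranking information.  Under this convention the 16 nominal
#' variants reduce to 13 functional classes.
#'
#' @param n_probe Number of random probe tensors (default 100).
#' @param seed RNG seed for the probes.
#' @param tol Numerical identity tolerance.
#' @return An object of class `agg_family`: list with `classes` (each a list
#'   of `members`, `representative`, `constant` flag), `n_classes`,
#'   `n_nominal`, `n_probe` and `seed`.
#' @examples
#' fam <- enumerate_variants(n_probe = 20, seed = 1)
#' fam$n_classes  # 13
#' @export
enumerate_variants <- function(n_probe = 100L, seed = 0L, tol = 1e-9) {
  n_probe <- as.integer(n_probe)
  if (n_probe < 1L) stop("n_probe must be at least 1")
  nms <- agg_variant_names()
  set.seed(seed)
  shapes <- cbind(LH = sample(3:6, n_probe, replace = TRUE),
                  T = sample(4:7, n_probe, replace = TRUE))
  outputs <- lapply(seq_len(n_probe), function(i) {
    A <- random_stochastic_tensor(shapes[i, "LH"], shapes[i, "T"])
    lapply(nms, function(nm) as.numeric(aggregate_attention(A, nm)))
  })
  is_const <- vapply(seq_along(nms), function(j)
    all(vapply(outputs, function(o) diff(range(o[[j]])) <= tol, logical(1))),
    logical(1))
  same <- function(j, k) {
    all(vapply(outputs, function(o) {
      a <- o[[j]]; b <- o[[k]]
      length(a) == length(b) && max(abs(a - b)) <= tol
    }, logical(1)))
  }
  cls <- rep(NA_integer_, length(nms))
  nextc <- 0L
  const_class <- NA_integer_
  for (j in seq_along(nms)) {
    if (is_const[j]) {
      if (is.na(const_class)) { nextc <- nextc + 1L; const_class <- nextc }
      cls[j] <- const_class
      next
    }
    for (k in seq_len(j - 1L)) {
      if (!is_const[k] && cls[k] > 0 && same(j, k)) { cls[j] <- cls[k]; break }
    }
    if (is.na(cls[j])) { nextc <- nextc + 1L; cls[j] <- nextc }
  }
  classes <- lapply(sort(unique(cls)), function(cid) {
    members <- nms[cls == cid]
    list(members = members, representative = members[1L],
         constant = cid %in% const_class)
  })
  structure(list(classes = classes, n_classes = length(classes),
                 n_nominal = length(nms), n_probe = n_probe, seed = seed),
            class = "agg_family")
}

#' @export
print.agg_family <- function(x, ...) {
  cat(sprintf(
    "AttnAgg variant family: %d nominal -> %d functional classes (%d probes, seed %d)\n",
    x$n_nominal, x$n_classes, x$n_probe, x$seed))
  for (cl in x$classes) {
    cat(sprintf("  %-12s %s%s\n", cl$representative,
                paste(cl$members, collapse = " "),
                if (cl$constant) "  [constant output]" else ""))
  }
  invisible(x)
}

# random row-stochastic tensor with Dirichlet(1) rows (normalised Exp(1))
random_stochastic_tensor <- function(LH, T) {
  A <- array(rexp(LH * T * T), c(LH, T, T))
  s <- apply(A, c(1L, 2L), sum)
  # column-major recycling of the (LH, T) row sums over the key axis
  A / as.numeric(s)
}
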