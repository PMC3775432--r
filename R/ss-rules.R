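#' Load the alpha-helix rule set
#'
#' The helix classification rules live in a declarative YAML data file so that
#' alternative readings of the (typographically ambiguous) published table can
#' be swapped in without code changes. See the bundled
#' \code{extdata/helix_rules.yaml} for the condition grammar.
#'
#' @param file Path to a rule file, or \code{NULL} for the bundled default.
#' @return An object of class \code{helix_rules}.
#' @export
load_helix_rules <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "helix_rules.yaml", package = "driftfold",
                        mustWork = TRUE)
  rules <- yaml::read_yaml(file)
  if (is.null(rules$cases)) stop("rule file has no 'cases' entry")
  for (cs in rules$cases) {
    if (!all(unlist(cs$n) %in% 1:6))
      stop("rule case n values must lie in 1..6")
  }
  class(rules) <- "helix_rules"
  rules
}

## Evaluate one atomic condition against the intervening-residue data.
.eval_condition <- function(cond, q, sum_q, prod_q, sum_h) {
  val <- switch(cond$field,
    sum_q     = sum_q,
    abs_sum_q = abs(sum_q),
    prod_q    = prod_q,
    sum_h     = sum_h,
    q         = {
      if (!is.null(cond$index)) {
        if (cond$index > length(q)) return(FALSE)
        q[[cond$index]]
      } else q
    },
    abs_q     = abs(q),
    stop("unknown rule field: ", cond$field))
  op <- cond$op
  if (op == "neq_pair") {
    idx <- unlist(cond$indices)
    if (max(idx) > length(q)) return(FALSE)
    return(q[idx[1]] != q[idx[2]])
  }
  quant <- if (is.null(cond$quantifier)) "all" else cond$quantifier
  res <- switch(op,
    gt      = val > cond$value,
    lt      = val < cond$value,
    eq      = val == cond$value,
    between = val > cond$lo & val < cond$hi,
    stop("unknown rule op: ", op))
  if (length(res) == 0L) return(FALSE)
  if (quant == "all") all(res) else any(res)
}

.make_helix_bracket <- function(seq, i, j) {
  iv <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
  structure(list(kind = "helix", start = i, end = j,
                 n_intervening = length(iv),
                 q = seq$q[iv], h = seq$h[iv],
                 sum_q = sum(seq$q[iv]),
                 prod_q = if (length(iv)) prod(seq$q[iv]) else NA_real_,
                 sum_h = sum(seq$h[iv])),
            class = "scan_bracket")
}

#' Open helix scan brackets over an annotated sequence
#'
#' Walks the sequence left to right. Each hydrophilic residue opens a bracket;
#' the bracket closes at the next hydrophilic residue provided it occurs within
#' the following six positions, and scanning resumes at the closing residue
#' (which may itself open the next bracket). A hydrophilic residue with no
#' partner within six neighbours opens no bracket and the region is left for
#' the beta pass.
#'
#' @param seq An [annotate_sequence()] result.
#' @return A list of \code{scan_bracket} objects (possibly empty). Indices are
#'   1-based and inclusive; \code{n_intervening} counts residues strictly
#'   between the bracket ends.
#' @export
open_helix_brackets <- function(seq) {
  stopifnot(inherits(seq, "annotated_seq"))
  philic <- which(seq$hydropathy == "hydrophilic")
  out <- list()
  if (length(philic) < 2L) return(out)
  i <- philic[1]
  repeat {
    nxt <- philic[philic > i]
    if (length(nxt) == 0L) break
    j <- nxt[1]
    if (j - i <= 6L) {
      out[[length(out) + 1L]] <- .make_helix_bracket(seq, i, j)
    }
    i <- j
  }
  out
}

#' Classify one helix bracket against the rule set
#'
#' Returns \code{"helix"} when any rule case matching the bracket's
#' intervening-residue count has an alternative whose conditions all hold,
#' \code{"none"} otherwise. Brackets with zero intervening residues never match
#' (the rule table starts at one).
#'
#' @param bracket A \code{scan_bracket} from [open_helix_brackets()].
#' @param rules A rule set from [load_helix_rules()].
#' @return \code{"helix"} or \code{"none"}.
#' @export
evaluate_helix_bracket <- function(bracket, rules = load_helix_rules()) {
  stopifnot(inherits(bracket, "scan_bracket"), bracket$kind == "helix")
  n <- bracket$n_intervening
  if (n < 1L) return("none")
  for (cs in rules$cases) {
    if (!(n %in% unlist(cs$n))) next
    for (alt in cs$alternatives) {
      ok <- vapply(alt$conditions, .eval_condition, logical(1),
                   q = bracket$q, sum_q = bracket$sum_q,
                   prod_q = bracket$prod_q, sum_h = bracket$sum_h)
      if (all(ok)) return("helix")
    }
  }
  "none"
}

.make_beta_bracket <- function(seq, i, h_mode) {
  idx <- i:(i + 4L)
  hidx <- if (h_mode == "literal") i:(i + 1L) else idx
  structure(list(kind = "beta", start = i, end = i + 4L,
                 sum_abs_q = sum(abs(seq$q[idx])),
                 sum_h = sum(seq$h[hidx])),
            class = "scan_bracket")
}

#' Enumerate candidate beta-sheet brackets
#'
#' Lists every 5-residue window whose residues are all currently unstructured
#' (label \code{C}), left to right, overlapping windows included. Window
#' acceptance and the skip-after-accept behaviour happen in
#' [predict_secondary()]; this operation is the raw candidate census.
#'
#' @param seq An [annotate_sequence()] result.
#' @param labels Per-residue labels from the helix pass (characters
#'   \code{H}/\code{E}/\code{C}), same length as the sequence.
#' @param h_mode \code{"bracket"} sums hydropathy over all five residues
#'   (default); \code{"literal"} over the first two only.
#' @return List of \code{scan_bracket} objects with fields \code{sum_abs_q}
#'   and \code{sum_h}.
#' @export
scan_beta_brackets <- function(seq, labels, h_mode = c("bracket", "literal")) {
  stopifnot(inherits(seq, "annotated_seq"))
  h_mode <- match.arg(h_mode)
  n <- length(seq$residues)
  if (length(labels) != n) stop("labels length must match sequence length")
  out <- list()
  if (n < 5L) return(out)
  for (i in seq_len(n - 4L)) {
    if (all(labels[i:(i + 4L)] == "C"))
      out[[length(out) + 1L]] <- .make_beta_bracket(seq, i, h_mode)
  }
  out
}

#' Classify one beta bracket
#'
#' A 5-residue window of unstructured residues is a beta sheet when both
#' strict inequalities hold: \eqn{\sum|q_i| - \sum h_i < 0.3} and
#' \eqn{\sum h_i > 0.1}. Boundary values (either sum exactly at its threshold)
#' are not sheets.
#'
#' @param bracket A \code{scan_bracket} from [scan_beta_brackets()].
#' @return \code{"sheet"} or \code{"none"}.
#' @export
evaluate_beta_bracket <- function(bracket) {
  stopifnot(inherits(bracket, "scan_bracket"), bracket$kind == "beta")
  if (bracket$sum_abs_q - bracket$sum_h < 0.3 && bracket$sum_h > 0.1)
    "sheet" else "none"
}

#' Predict secondary structure
#'
#' Two passes. Helix pass: scan brackets are opened as in
#' [open_helix_brackets()] and every bracket classified helix labels all its
#' residues (bracket ends included) \code{H}. Beta pass: the remaining
#' unstructured residues are scanned left to right in 5-residue windows; an
#' accepted window labels all five residues \code{E} and the scan resumes
#' after the window, otherwise it advances by one residue. Everything else is
#' \code{C}.
#'
#' @param seq An [annotate_sequence()] result, or a plain sequence string
#'   (annotated at \code{pH}).
#' @param rules Helix rule set, see [load_helix_rules()].
#' @param h_mode Beta-rule hydropathy summation mode, see
#'   [scan_beta_brackets()].
#' @param pH Ambient pH, used only when \code{seq} is a plain string.
#' @return An object of class \code{ss_annotation}: list with \code{labels}
#'   (character vector over H/E/C) and \code{regions} (data.frame with
#'   1-based inclusive \code{start}, \code{end}, \code{kind}).
#' @export
#' @examples
#' predict_secondary("LLLNHQLLL")$labels
predict_secondary <- function(seq, rules = load_helix_rules(),
                              h_mode = c("bracket", "literal"), pH = 7) {
  if (is.character(seq)) seq <- annotate_sequence(seq, pH = pH)
  stopifnot(inherits(seq, "annotated_seq"))
  h_mode <- match.arg(h_mode)
  n <- length(seq$residues)
  labels <- rep("C", n)

  for (b in open_helix_brackets(seq)) {
    if (evaluate_helix_bracket(b, rules) == "helix")
      labels[b$start:b$end] <- "H"
  }

  i <- 1L
  while (i <= n - 4L) {
    if (all(labels[i:(i + 4L)] == "C")) {
      b <- .make_beta_bracket(seq, i, h_mode)
      if (evaluate_beta_bracket(b) == "sheet") {
        labels[i:(i + 4L)] <- "E"
        i <- i + 5L
        next
      }
    }
    i <- i + 1L
  }

  structure(list(labels = labels, regions = labels_to_regions(labels)),
            class = "ss_annotation")
}

#' Convert a label vector to a region table
#'
#' @param labels Character vector (or single string) over \code{H}, \code{E},
#'   \code{C}.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive) and \code{kind} (\code{H} or \code{E}); maximal runs of equal
#'   non-coil labels.
#' @export
labels_to_regions <- function(labels) {
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "", fixed = TRUE)[[1]]
  if (!all(labels %in% c("H", "E", "C"))) stop("labels must be H, E or C")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "C"
  data.frame(start = starts[keep], end = ends[keep], kind = r$values[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.ss_annotation <- function(x, ...) {
  cat("ss_annotation:", length(x$labels), "residues,",
      nrow(x$regions), "region(s)\n")
  cat(" ", paste(x$labels, collapse = ""), "\n")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}
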