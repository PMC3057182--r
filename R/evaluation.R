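# Performance evaluation: Enzyme Commission-based true-positive
# definitions, ROC curves over the full score range, and per-class score
# distributions (bin width 10, each class normalized to unit area).

#' Compare two Enzyme Commission numbers
#'
#' @param ec_a,ec_b dotted E.C. strings (e.g. \code{"2.6.1.1"}).
#' @param depth compare the first 3 or all 4 components.
#' @return logical.
#' @export
ec_match <- function(ec_a, ec_b, depth = 4L) {
  stopifnot(depth %in% c(3L, 4L))
  parse <- function(x) {
    parts <- strsplit(trimws(x), ".", fixed = TRUE)[[1]]
    if (length(parts) < depth || any(!grepl("^[0-9]+$", parts[seq_len(depth)])))
      stop("malformed E.C. number: '", x, "'")
    parts
  }
  a <- parse(ec_a); b <- parse(ec_b)
  all(a[seq_len(depth)] == b[seq_len(depth)])
}

#' Truth definition for evaluation
#'
#' Declares what counts as a functionally similar site (a true positive)
#' when labelling search results: identical four-component E.C. number plus
#' an equivalent ligand (\code{ec4_and_ligand}), identical first three E.C.
#' components (\code{ec3}), or simply binding the same ligand class
#' (\code{same_ligand}).
#'
#' @param level one of \code{"ec4_and_ligand"}, \code{"ec3"},
#'   \code{"same_ligand"}.
#' @param ec_annotations named character vector: cpass_id -> E.C. number.
#' @param ligand_equivalence named character vector mapping ligand codes to
#'   equivalence classes ("very similar" ligands share a class); codes not
#'   listed are their own class.
#' @return a \code{cpass_truth} list.
#' @export
truth_definition <- function(level = c("ec4_and_ligand", "ec3",
                                       "same_ligand"),
                             ec_annotations = character(0),
                             ligand_equivalence = character(0)) {
  structure(list(level = match.arg(level),
                 ec_annotations = ec_annotations,
                 ligand_equivalence = ligand_equivalence),
            class = "cpass_truth")
}

.ligand_class <- function(code, truth) {
  cls <- truth$ligand_equivalence[toupper(code)]
  ifelse(is.na(cls), toupper(code), cls)
}

#' Label comparisons as true positives under a truth definition
#'
#' @param truth a \code{cpass_truth}.
#' @param query_ec E.C. number of the query protein.
#' @param query_ligand ligand code of the query site.
#' @param target_ids cpass_ids of the compared records.
#' @param target_ligands ligand codes of the compared records.
#' @return logical vector; \code{NA} when a needed annotation is missing.
#' @export
label_positives <- function(truth, query_ec, query_ligand, target_ids,
                            target_ligands) {
  same_lig <- .ligand_class(target_ligands, truth) ==
    .ligand_class(query_ligand, truth)
  if (truth$level == "same_ligand") return(unname(same_lig))
  ecs <- truth$ec_annotations[target_ids]
  depth <- if (truth$level == "ec3") 3L else 4L
  ecok <- vapply(seq_along(target_ids), function(k) {
    if (is.na(ecs[k])) return(NA)
    ec_match(query_ec, ecs[k], depth = depth)
  }, logical(1))
  out <- if (truth$level == "ec4_and_ligand") ecok & same_lig else ecok
  unname(out)
}

#' ROC curve and AUC
#'
#' Standard threshold sweep over all observed scores: the curve starts at
#' (0, 0), ends at (1, 1), and the area is computed by the trapezoid rule.
#'
#' @param scores numeric scores (higher = more similar).
#' @param labels logical (or 0/1) true-positive labels, same length.
#' @return list with \code{points} (data frame \code{fpr}, \code{tpr},
#'   \code{threshold}) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, 0)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Per-class score distributions
#'
#' Bins scores per class with a fixed bin width (default 10: bins
#' [0,10), [10,20), ..., with scores of 100 or more collected in a final
#' closed bin) and divides by the class total, so every class's fractions
#' sum to 1 (unit area).
#'
#' @param scores numeric scores (percent similarities).
#' @param labels class labels, same length (e.g. logical positives).
#' @param bin_width bin width (default 10).
#' @return data frame: \code{class}, \code{bin_lo}, \code{bin_hi},
#'   \code{count}, \code{fraction}.
#' @export
score_distribution <- function(scores, labels, bin_width = 10) {
  stopifnot(length(scores) == length(labels), bin_width > 0)
  n_bins <- ceiling(100 / bin_width) + 1L   # final closed bin for >= 100
  bin <- pmin(floor(scores / bin_width), n_bins - 1L)
  out <- list()
  for (cl in unique(labels)) {
    sel <- labels == cl
    tot <- sum(sel)
    cnt <- vapply(seq_len(n_bins) - 1L,
                  function(b) sum(bin[sel] == b), 0)
    out[[length(out) + 1L]] <- data.frame(
      class = cl, bin_lo = (seq_len(n_bins) - 1L) * bin_width,
      bin_hi = seq_len(n_bins) * bin_width,
      count = cnt, fraction = cnt / tot)
  }
  do.call(rbind, out)
}

#' Evaluate a result table against a truth definition
#'
#' Convenience wrapper: labels each comparison, then computes the ROC curve
#' and the bin-10 score distributions.
#'
#' @param results result table from \code{\link{run_search}} (run with
#'   \code{min_percent = 0} so negatives are retained).
#' @param truth a \code{cpass_truth}.
#' @param query_ec,query_ligand annotations of the query.
#' @param db the record database (provides target ligand codes).
#' @return list with \code{labels}, \code{roc}, \code{distribution}.
#' @export
evaluate_search <- function(results, truth, query_ec, query_ligand, db) {
  lig <- vapply(db[results$target_id], function(r) r$ligand_code, "")
  lab <- label_positives(truth, query_ec, query_ligand,
                         results$target_id, lig)
  list(labels = lab,
       roc = roc_curve(results$percent, lab),
       distribution = score_distribution(results$percent, lab))
}
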