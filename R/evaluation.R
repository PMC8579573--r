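# Evaluation: confusion counts, the five headline metrics, ROC/AUC, and
# the Friedman + Nemenyi multi-method comparison.
#
# For region prediction all counts are per residue: TP = hotspot residues
# predicted hotspot, FP = regular residues predicted hotspot, TN = regular
# predicted regular, FN = hotspot predicted regular. Hotspot residues are
# rare, so the balanced accuracy Q = (SE + SP)/2 is the headline metric.

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,predicted 0/1 (or logical) vectors of equal length.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(as.logical(truth))
  predicted <- as.integer(as.logical(predicted))
  stopifnot(length(truth) == length(predicted))
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP =", x$tp, " FP =", x$fp,
      " TN =", x$tn, " FN =", x$fn, "\n")
  invisible(x)
}

#' Per-residue confusion counts for one protein
#'
#' Truth and prediction are 1-based inclusive intervals (or masks) over a
#' protein of length `L`; residues are compared one by one.
#'
#' @param truth data.frame with `start`, `end` (the annotated hotspots), or
#'   a logical mask of length `L`.
#' @param predicted Same forms as `truth`.
#' @param L Protein length.
#' @return A `confusion_counts` object; counts sum to `L`.
#' @export
residue_confusion <- function(truth, predicted, L) {
  as_mask <- function(x) {
    if (is.logical(x) || (is.numeric(x) && !is.data.frame(x))) {
      if (length(x) != L) stop("mask length must equal L")
      as.logical(x)
    } else {
      regions_to_mask(x, L)
    }
  }
  confusion_counts(as_mask(truth), as_mask(predicted))
}

#' The five headline metrics from confusion counts
#'
#' ACC = (TP+TN)/total, SE = TP/(TP+FN), SP = TN/(TN+FP),
#' Q = (SE+SP)/2, MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any MCC denominator factor is zero the coefficient is undefined
#' and reported as 0 (the conventional choice). SE (or SP) is `NaN` when
#' no positive (negative) residues were evaluated.
#'
#' @param c A `confusion_counts` object.
#' @return List of class `metrics_report` with `acc`, `se`, `sp`, `q`,
#'   `mcc`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$tn + c$fn
  if (total == 0L) stop("empty confusion table")
  se <- if (c$tp + c$fn > 0L) c$tp / (c$tp + c$fn) else NaN
  sp <- if (c$tn + c$fp > 0L) c$tn / (c$tn + c$fp) else NaN
  denom <- prod(sqrt(c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)))
  mcc <- if (denom == 0) 0 else (c$tp * c$tn - c$fp * c$fn) / denom
  structure(list(acc = (c$tp + c$tn) / total, se = se, sp = sp,
                 q = (se + sp) / 2, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  vals <- round_half_up(unlist(x), digits)
  cat(paste(sprintf("%s = %.*f", toupper(names(vals)), digits, vals),
            collapse = "  "), "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Conventional report rounding: an exact trailing 5 rounds away from zero
#' (26/32 = 0.8125 prints as 0.813), unlike [round()]'s round-half-even.
#' Used when printing metrics to the customary three decimals; full
#' precision is always retained internally.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3).
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @method as.data.frame metrics_report
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  out <- data.frame(acc = x$acc, se = x$se, sp = x$sp, q = x$q, mcc = x$mcc)
  if (!is.null(x$auc)) out$auc <- x$auc
  out
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counting one half (the rank / Mann--Whitney definition);
#' computed via pROC.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `auc` and `points` (data.frame `fpr`, `tpr` sorted by
#'   `fpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes required for ROC")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  row.names(pts) <- NULL
  list(auc = as.numeric(r$auc), points = pts)
}

#' Pool residue-level evaluation over many proteins
#'
#' Sums per-protein residue confusion counts and computes the pooled
#' metrics; when per-residue scores are supplied, also the pooled AUC of
#' hotspot vs regular residues.
#'
#' @param truths Named list of annotation data.frames (`start`, `end`),
#'   one per protein id.
#' @param predictions Named list of `region_prediction` objects (or
#'   masks) keyed by protein id.
#' @param lengths Named integer vector of protein lengths (only needed
#'   when predictions are masks; inferred from `region_prediction`s).
#' @return List with `counts`, `metrics` and (when scores are available)
#'   `auc`.
#' @export
evaluate_regions <- function(truths, predictions, lengths = NULL) {
  ids <- names(predictions)
  missing <- setdiff(ids, names(truths))
  if (length(missing) > 0L) {
    stop("no annotation for protein id(s): ", paste(missing, collapse = ", "))
  }
  tot <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  all_scores <- numeric(); all_truth <- integer()
  for (id in ids) {
    p <- predictions[[id]]
    if (inherits(p, "region_prediction")) {
      L <- nchar(p$sequence)
      pred_mask <- p$mask
      scores <- p$residue_score
    } else {
      L <- if (!is.null(lengths)) lengths[[id]] else length(p)
      pred_mask <- as.logical(p)
      scores <- NULL
    }
    truth_mask <- regions_to_mask(truths[[id]], L)
    cc <- confusion_counts(truth_mask, pred_mask)
    for (k in names(tot)) tot[[k]] <- tot[[k]] + cc[[k]]
    if (!is.null(scores)) {
      all_scores <- c(all_scores, scores)
      all_truth <- c(all_truth, as.integer(truth_mask))
    }
  }
  counts <- structure(tot, class = "confusion_counts")
  out <- list(counts = counts, metrics = compute_metrics(counts))
  if (length(all_scores) > 0L && length(unique(all_truth)) == 2L) {
    out$auc <- roc_auc(all_scores, all_truth)$auc
  }
  out
}

# critical-difference q_alpha: studentized range quantile / sqrt(2)
nemenyi_q <- function(k, alpha) stats::qtukey(1 - alpha, nmeans = k,
                                              df = Inf) / sqrt(2)

#' Friedman test with Nemenyi post-hoc comparison
#'
#' Input is a methods x items matrix of performance ranks (smaller = better;
#' ties as mid-ranks are fine — ranks are re-ranked within each item, which
#' leaves proper mid-rank columns unchanged). The Friedman chi-square (with
#' tie correction, via [stats::friedman.test()]) asks whether the methods
#' perform identically; if rejected at `alpha`, method pairs whose mean
#' ranks differ by more than the Nemenyi critical difference
#' `CD = q_alpha * sqrt(k (k + 1) / (6 n))` are flagged significantly
#' different.
#'
#' @param ranks Numeric matrix, rows = methods (named), columns = items.
#' @param alpha Significance level (default 0.1).
#' @return List with `statistic`, `p_value`, `rejected`, `mean_ranks`
#'   (named, sorted ascending), `cd` (critical difference) and `pairs`
#'   (data.frame method_a, method_b, rank_diff, significant).
#' @export
friedman_nemenyi <- function(ranks, alpha = 0.1) {
  stopifnot(is.matrix(ranks), nrow(ranks) >= 2L, ncol(ranks) >= 2L)
  if (is.null(rownames(ranks))) {
    rownames(ranks) <- paste0("method", seq_len(nrow(ranks)))
  }
  k <- nrow(ranks); n <- ncol(ranks)
  mean_ranks <- sort(rowMeans(apply(ranks, 2L, rank)))
  if (all(apply(ranks, 2L, function(col) length(unique(col)) == 1L))) {
    # every item ranks all methods equally: nothing to test
    return(list(statistic = 0, p_value = 1, rejected = FALSE,
                mean_ranks = mean_ranks, cd = NA_real_,
                pairs = data.frame()))
  }
  ft <- stats::friedman.test(t(ranks))
  rejected <- is.finite(ft$p.value) && ft$p.value < alpha
  cd <- nemenyi_q(k, alpha) * sqrt(k * (k + 1) / (6 * n))
  pairs <- data.frame()
  if (rejected) {
    cmb <- utils::combn(names(mean_ranks), 2L)
    diffs <- abs(mean_ranks[cmb[1L, ]] - mean_ranks[cmb[2L, ]])
    pairs <- data.frame(method_a = cmb[1L, ], method_b = cmb[2L, ],
                        rank_diff = as.numeric(diffs),
                        significant = as.numeric(diffs) > cd,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       rejected = rejected, mean_ranks = mean_ranks, cd = cd, pairs = pairs)
}
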