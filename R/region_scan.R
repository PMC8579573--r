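# Hexapeptide sliding-window scan: protein -> window scores -> per-residue
# mask -> maximal regions.

WINDOW <- 6L

#' Enumerate hexapeptide windows of a protein
#'
#' @param sequence Validated sequence of length >= 6.
#' @return data.frame with `start` (1-based) and `window` (6-mer), exactly
#'   L - 5 rows in order.
#' @export
enumerate_windows <- function(sequence) {
  L <- nchar(sequence)
  if (L < WINDOW) {
    stop("protein shorter than window (L = ", L, " < ", WINDOW, ")")
  }
  starts <- seq_len(L - WINDOW + 1L)
  data.frame(start = starts,
             window = substring(sequence, starts, starts + WINDOW - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a protein for amyloidogenic regions
#'
#' Every hexapeptide window is scored by the model; a window is called
#' positive when its score reaches the decision threshold. Window calls
#' map to residues by the union rule (`aggregate = "union"`): residue r is
#' a hotspot iff at least one window covering r is positive.
#' `aggregate = "majority"` instead requires more than half of the
#' covering windows. The per-residue score is the max (or mean) of the
#' covering window scores; regions are the maximal runs of the mask.
#'
#' @param protein One-row data.frame (`id`, `sequence`) or a list with
#'   those fields; sequence must be validated and of length >= 6.
#' @param model An `amylo_model`.
#' @param threshold Decision threshold; defaults to the model's.
#' @param aggregate Window-to-residue rule: `"union"` (default) or
#'   `"majority"`.
#' @param score_rule Per-residue score: `"max"` (default) or `"mean"` over
#'   covering windows.
#' @return Object of class `region_prediction`: list with `protein_id`,
#'   `sequence`, `windows` (start, window, score, call), `mask` (logical,
#'   length L), `residue_score` (length L), `regions` (start, end,
#'   max_score).
#' @export
scan_protein <- function(protein, model, threshold = NULL,
                         aggregate = c("union", "majority"),
                         score_rule = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  score_rule <- match.arg(score_rule)
  if (is.null(threshold)) threshold <- model$config$decision_threshold
  id <- protein$id[1L]
  sequence <- protein$sequence[1L]
  win <- enumerate_windows(sequence)
  records <- data.frame(id = sprintf("%s_w%d", id, win$start),
                        sequence = win$window, stringsAsFactors = FALSE)
  pred <- predict_proba(model, records, policy = "skip")
  win$score <- pred$score
  win$call <- as.integer(win$score >= threshold)
  L <- nchar(sequence)
  n_cover <- integer(L)
  n_pos <- integer(L)
  sum_score <- numeric(L)
  max_score <- rep(-Inf, L)
  for (w in seq_len(nrow(win))) {
    if (is.na(win$score[w])) next  # unencodable window abstains
    span <- win$start[w]:(win$start[w] + WINDOW - 1L)
    n_cover[span] <- n_cover[span] + 1L
    n_pos[span] <- n_pos[span] + win$call[w]
    sum_score[span] <- sum_score[span] + win$score[w]
    max_score[span] <- pmax(max_score[span], win$score[w])
  }
  mask <- if (aggregate == "union") n_pos > 0L else n_pos > n_cover / 2
  residue_score <- if (score_rule == "max") max_score else sum_score / n_cover
  residue_score[n_cover == 0L] <- 0  # residues seen by no scorable window
  regions <- mask_to_regions(mask)
  regions$max_score <- vapply(seq_len(nrow(regions)), function(i) {
    max(residue_score[regions$start[i]:regions$end[i]])
  }, numeric(1L))
  structure(list(protein_id = id, sequence = sequence, windows = win,
                 mask = mask, residue_score = residue_score,
                 regions = regions, threshold = threshold),
            class = "region_prediction")
}

#' @export
print.region_prediction <- function(x, ...) {
  cat("<region_prediction>", x$protein_id, "(L =", nchar(x$sequence),
      "):", nrow(x$regions), "region(s),", sum(x$mask), "hotspot residue(s)\n")
  if (nrow(x$regions) > 0L) print(x$regions)
  invisible(x)
}

#' Maximal runs of TRUE in a mask, as 1-based inclusive intervals
#'
#' @param mask Logical vector.
#' @return data.frame with `start`, `end`, sorted by start.
#' @export
mask_to_regions <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Expand 1-based inclusive intervals into a residue mask
#'
#' @param regions data.frame with `start`, `end` (may be empty).
#' @param L Sequence length.
#' @return Logical vector of length `L`.
#' @export
regions_to_mask <- function(regions, L) {
  mask <- logical(L)
  if (is.null(regions) || nrow(regions) == 0L) return(mask)
  if (any(regions$start < 1L) || any(regions$end > L) ||
      any(regions$start > regions$end)) {
    stop("interval out of bounds for sequence of length ", L)
  }
  for (i in seq_len(nrow(regions))) mask[regions$start[i]:regions$end[i]] <- TRUE
  mask
}

#' Classify a whole peptide as amyloidogenic or not
#'
#' A peptide is amyloidogenic iff at least one of its hexapeptide windows
#' is called positive; the best-scoring window is returned either way.
#' Peptides shorter than six residues cannot host a hotspot and are
#' rejected.
#'
#' @inheritParams scan_protein
#' @param peptide One-row data.frame (`id`, `sequence`), length >= 6.
#' @return List with `id`, `call` (0/1), `score` (best window score) and
#'   `best_window` (start, window, score).
#' @export
classify_peptide <- function(peptide, model, threshold = NULL) {
  sp <- scan_protein(peptide, model, threshold = threshold)
  if (all(is.na(sp$windows$score))) {
    stop("no scorable window in peptide '", sp$protein_id, "'")
  }
  best <- which.max(sp$windows$score)
  list(id = sp$protein_id,
       call = as.integer(any(sp$windows$call == 1L, na.rm = TRUE)),
       score = sp$windows$score[best],
       best_window = sp$windows[best, c("start", "window", "score")])
}

#' Scan many proteins
#'
#' Convenience wrapper around [scan_protein()]; proteins shorter than six
#' residues are skipped with a warning.
#'
#' @param records data.frame with `id`, `sequence` (validated).
#' @inheritParams scan_protein
#' @return Named list of `region_prediction` objects.
#' @export
scan_proteins <- function(records, model, threshold = NULL,
                          aggregate = c("union", "majority"),
                          score_rule = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  score_rule <- match.arg(score_rule)
  out <- list()
  for (i in seq_len(nrow(records))) {
    if (nchar(records$sequence[i]) < WINDOW) {
      warning("skipping '", records$id[i], "': shorter than the ",
              WINDOW, "-residue window")
      next
    }
    out[[records$id[i]]] <- scan_protein(records[i, ], model,
                                         threshold = threshold,
                                         aggregate = aggregate,
                                         score_rule = score_rule)
  }
  out
}
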