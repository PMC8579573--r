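# Binomial-distribution feature selection over the 8000 tripeptides.
#
# For each tripeptide i and class j, the upper-tail probability
# P_ij = sum_{k = n_ij}^{N_i} C(N_i, k) q_j^k (1 - q_j)^(N_i - k)
# measures how surprising its class-j occurrence count n_ij is under a
# null where each of its N_i occurrences falls in class j independently
# with the class's token share q_j. The confidence level CL_i is the
# larger of 1 - P_i1 and 1 - P_i0; tripeptides are ranked by CL.

#' Count tripeptide occurrences per class
#'
#' Occurrences are counted over all overlapping windows of all sequences of
#' each class; the class weights q are the shares of tripeptide tokens
#' (not sequences) per class.
#'
#' @param dataset Labeled data.frame with columns `sequence`, `label`.
#' @return Object of class `tripeptide_counts`: list with integer vectors
#'   `n_pos`, `n_neg` (length 8000, named by tripeptide), totals
#'   `tokens_pos`, `tokens_neg`, and shares `q_pos`, `q_neg`.
#' @export
count_tripeptides <- function(dataset) {
  stopifnot(is.data.frame(dataset),
            all(c("sequence", "label") %in% names(dataset)))
  if (nrow(dataset) == 0L) stop("dataset is empty")
  if (length(unique(dataset$label)) < 2L) {
    stop("both classes required to compare tripeptide distributions")
  }
  count_class <- function(seqs) {
    codes <- unlist(lapply(seqs, .tripeptide_codes), use.names = FALSE)
    tabulate(codes + 1L, nbins = 8000L)
  }
  n_pos <- count_class(dataset$sequence[dataset$label == 1L])
  n_neg <- count_class(dataset$sequence[dataset$label == 0L])
  names(n_pos) <- names(n_neg) <- all_tripeptides()
  tokens_pos <- sum(n_pos); tokens_neg <- sum(n_neg)
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 tokens_pos = tokens_pos, tokens_neg = tokens_neg,
                 q_pos = tokens_pos / (tokens_pos + tokens_neg),
                 q_neg = tokens_neg / (tokens_pos + tokens_neg)),
            class = "tripeptide_counts")
}

#' Per-class tripeptide content (for contribution analysis)
#'
#' Content of tripeptide t in class j is its occurrence count divided by
#' the class's total tripeptide tokens, the quantity plotted when
#' inspecting what the top-ranked tripeptides look like per class.
#'
#' @param counts A `tripeptide_counts` object.
#' @return data.frame with `tripeptide`, `content_pos`, `content_neg`.
#' @export
tripeptide_content <- function(counts) {
  stopifnot(inherits(counts, "tripeptide_counts"))
  data.frame(tripeptide = all_tripeptides(),
             content_pos = as.numeric(counts$n_pos) / counts$tokens_pos,
             content_neg = as.numeric(counts$n_neg) / counts$tokens_neg,
             stringsAsFactors = FALSE)
}

#' Upper tail of a binomial distribution
#'
#' Returns `sum_{k = n}^{N} C(N, k) q^k (1 - q)^(N - k)`, evaluated with
#' the numerically stable upper-tail of [stats::pbinom()] rather than term
#' summation.
#'
#' @param n Lower summation bound(s), `0 <= n <= N`.
#' @param N Number of trials (vectorized with `n`).
#' @param q Success probability in (0, 1).
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @export
binomial_tail <- function(n, N, q) {
  if (any(q <= 0) || any(q >= 1)) stop("q must be strictly inside (0, 1)")
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
  stats::pbinom(n - 1, size = N, prob = q, lower.tail = FALSE)
}

#' Confidence levels for all 8000 tripeptides
#'
#' For each tripeptide, the class-specific tail probabilities are computed
#' with [binomial_tail()] at the class token shares from `counts`; the
#' confidence level is `1 - min(p_pos, p_neg)`. Tripeptides never observed
#' (N = 0) carry no evidence and get CL = 0.
#'
#' @param counts A `tripeptide_counts` object.
#' @return data.frame with one row per tripeptide: `tripeptide`, `n_pos`,
#'   `n_neg`, `n_total`, `p_pos`, `p_neg`, `cl`.
#' @export
confidence_levels <- function(counts) {
  stopifnot(inherits(counts, "tripeptide_counts"))
  N <- counts$n_pos + counts$n_neg
  p_pos <- binomial_tail(counts$n_pos, N, counts$q_pos)
  p_neg <- binomial_tail(counts$n_neg, N, counts$q_neg)
  cl <- 1 - pmin(p_pos, p_neg)
  cl[N == 0L] <- 0
  data.frame(tripeptide = all_tripeptides(),
             n_pos = as.integer(counts$n_pos),
             n_neg = as.integer(counts$n_neg),
             n_total = as.integer(N),
             p_pos = p_pos, p_neg = p_neg, cl = cl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combined feature specification (PseAAC block + selected tripeptides)
#'
#' @param tripeptides Character vector of selected tripeptides, stored in
#'   rank order, duplicate-free.
#' @param pseaac [pseaac_params()] describing the PseAAC block.
#' @return Object of class `feature_spec` with `tripeptides`, `pseaac`,
#'   `total_dim`.
#' @export
feature_spec <- function(tripeptides, pseaac = pseaac_params()) {
  tripeptides <- as.character(tripeptides)
  if (anyDuplicated(tripeptides)) stop("selected tripeptides must be unique")
  if (length(tripeptides) > 0L) tripeptide_index(tripeptides)  # validates
  structure(list(tripeptides = tripeptides, pseaac = pseaac,
                 total_dim = 20L + length(pseaac$scales) * pseaac$lambda +
                   length(tripeptides)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec>", length(x$tripeptides), "selected tripeptides +",
      20L + length(x$pseaac$scales) * x$pseaac$lambda, "PseAAC components =",
      x$total_dim, "features\n")
  invisible(x)
}

#' Rank tripeptides by confidence level and select a subset
#'
#' Sorting is by CL descending with deterministic tie-breaks: larger total
#' count first, then alphabetical tripeptide. `mode = "threshold"` keeps
#' every tripeptide with CL >= `value`; `mode = "top_k"` keeps the first
#' `value` ranks.
#'
#' @param stats data.frame from [confidence_levels()].
#' @param mode `"threshold"` or `"top_k"`.
#' @param value CL threshold in `[0, 1]`, or k in `[0, 8000]`.
#' @param pseaac [pseaac_params()] stored in the resulting spec.
#' @return A `feature_spec` whose tripeptides are in descending-CL order.
#' @export
rank_and_select <- function(stats, mode = c("threshold", "top_k"), value,
                            pseaac = pseaac_params()) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(stats),
            all(c("tripeptide", "n_total", "cl") %in% names(stats)))
  o <- order(-stats$cl, -stats$n_total, stats$tripeptide)
  ranked <- stats[o, , drop = FALSE]
  keep <- if (mode == "threshold") {
    if (value < 0 || value > 1) stop("threshold must be in [0, 1]")
    ranked$tripeptide[ranked$cl >= value]
  } else {
    value <- as.integer(value)
    if (is.na(value) || value < 0L || value > nrow(ranked)) {
      stop("top_k must be in [0, ", nrow(ranked), "]")
    }
    utils::head(ranked$tripeptide, value)
  }
  feature_spec(keep, pseaac = pseaac)
}

#' Ranked-feature report
#'
#' @param stats data.frame from [confidence_levels()].
#' @return The same table sorted by rank (CL desc, count desc,
#'   alphabetical) with a `rank` column prepended.
#' @export
ranked_report <- function(stats) {
  o <- order(-stats$cl, -stats$n_total, stats$tripeptide)
  out <- stats[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  row.names(out) <- NULL
  out
}

#' Tune the selection cutoff by cross-validated performance
#'
#' Every candidate rank k defines a feature set (top-k tripeptides + the
#' full PseAAC block); each set is scored by stratified k-fold
#' cross-validation and the candidate maximizing the chosen metric wins,
#' smaller k on ties (prefer the leaner model).
#'
#' @param candidates Integer vector of candidate ranks.
#' @param dataset Labeled data.frame (`id`, `sequence`, `label`).
#' @param stats data.frame from [confidence_levels()] on `dataset`.
#' @param config [training_config()].
#' @param pseaac [pseaac_params()].
#' @param metric Metric to maximize (default `"acc"`).
#' @return List with `best_k`, `best_spec`, and `table` (per-candidate CV
#'   metrics).
#' @export
tune_cutoff <- function(candidates, dataset, stats,
                        config = training_config(), pseaac = pseaac_params(),
                        metric = c("acc", "auc", "mcc", "q")) {
  metric <- match.arg(metric)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0L) stop("no candidate ranks given")
  if (any(candidates < 0L) || any(candidates > 8000L)) {
    stop("candidate ranks must be in [0, 8000]")
  }
  rows <- lapply(candidates, function(k) {
    spec <- rank_and_select(stats, mode = "top_k", value = k, pseaac = pseaac)
    cv <- cross_validate(dataset, spec, config)
    cbind(data.frame(k = k), as.data.frame(cv$pooled))
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab[[metric]])  # which.max takes the first = smallest k
  list(best_k = tab$k[best],
       best_spec = rank_and_select(stats, "top_k", tab$k[best], pseaac),
       table = tab)
}

#' Candidate cutoff ranks around a confidence-level boundary
#'
#' Enumerates the ranks at which CL crosses values inside
#' `[threshold - width, threshold + width]`, capped at `max_candidates`
#' evenly spaced picks — the default recipe for choosing cutoffs to feed
#' into [tune_cutoff()].
#'
#' @param stats data.frame from [confidence_levels()].
#' @param threshold Center of the CL window (default 0.85).
#' @param width Half-width of the window (default 0.05).
#' @param max_candidates Cap on the number of candidates (default 20).
#' @return Integer vector of candidate ranks (k values).
#' @export
candidate_cutoffs <- function(stats, threshold = 0.85, width = 0.05,
                              max_candidates = 20L) {
  rep_tab <- ranked_report(stats)
  in_band <- which(rep_tab$cl >= threshold - width &
                     rep_tab$cl <= threshold + width)
  ks <- if (length(in_band) == 0L) {
    # nothing in the band: fall back to the threshold crossing itself
    sum(rep_tab$cl >= threshold)
  } else {
    unique(in_band)
  }
  if (length(ks) > max_candidates) {
    ks <- unique(round(seq(min(ks), max(ks), length.out = max_candidates)))
  }
  as.integer(ks[ks > 0L])
}

#' Write / read a feature spec as a versioned text file
#'
#' The file stores the PseAAC parameters (lambda, weight, freq mode, scale
#' names with raw values) and the ordered tripeptide list, so a selection
#' made on one machine can be applied on another.
#'
#' @param spec A `feature_spec`.
#' @param path Output path.
#' @export
write_feature_spec <- function(spec, path) {
  stopifnot(inherits(spec, "feature_spec"))
  p <- spec$pseaac
  lines <- c("amyloscan_feature_spec\tv1",
             paste0("lambda\t", p$lambda),
             paste0("weight\t", format(p$weight, digits = 17)),
             paste0("freq_mode\t", p$freq_mode))
  for (s in p$scales) {
    lines <- c(lines, paste0("scale\t", s$name, "\t",
                             paste(format(s$raw, digits = 17),
                                   collapse = ",")))
  }
  lines <- c(lines, paste0("tripeptide\t", spec$tripeptides))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_spec
#' @param path Path to a file written by [write_feature_spec()].
#' @return A `feature_spec`.
#' @export
read_feature_spec <- function(path) {
  if (!file.exists(path)) stop("feature spec file not found: ", path)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) == 0L || parts[[1L]][1L] != "amyloscan_feature_spec") {
    stop("not a feature spec file: ", path)
  }
  get1 <- function(key) {
    hit <- Filter(function(p) p[1L] == key, parts)
    if (length(hit) == 0L) stop("feature spec file missing field '", key, "'")
    hit[[1L]][2L]
  }
  scales <- lapply(Filter(function(p) p[1L] == "scale", parts), function(p) {
    raw <- as.numeric(strsplit(p[3L], ",", fixed = TRUE)[[1L]])
    names(raw) <- AMINO_ACIDS
    standardize_scale(raw, name = p[2L])
  })
  names(scales) <- vapply(scales, `[[`, character(1L), "name")
  trip <- vapply(Filter(function(p) p[1L] == "tripeptide", parts),
                 `[[`, character(1L), 2L)
  feature_spec(trip,
               pseaac = pseaac_params(lambda = as.integer(get1("lambda")),
                                      weight = as.numeric(get1("weight")),
                                      scales = scales,
                                      freq_mode = get1("freq_mode")))
}
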