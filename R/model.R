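# Feature-matrix assembly and the classifier layer.
#
# The classifier sits behind a small fit/score-probability contract so
# alternatives can be registered; the default is a probability random
# forest (ranger).

#' Training configuration
#'
#' @param classifier_name Registered classifier (default `"random_forest"`).
#' @param n_trees Trees in the forest (default 500).
#' @param seed Integer seed controlling fold assignment and the learner.
#' @param decision_threshold Probability cutoff for a positive call
#'   (default 0.5).
#' @param folds Folds for cross-validation (default 10).
#' @return Object of class `training_config`.
#' @export
training_config <- function(classifier_name = "random_forest",
                            n_trees = 500L, seed = 1L,
                            decision_threshold = 0.5, folds = 10L) {
  n_trees <- as.integer(n_trees); folds <- as.integer(folds)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be >= 1")
  if (is.na(folds) || folds < 2L) stop("folds must be >= 2")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("decision_threshold must be in (0, 1)")
  }
  structure(list(classifier_name = classifier_name, n_trees = n_trees,
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold, folds = folds),
            class = "training_config")
}

# --- classifier registry ----------------------------------------------------

.classifiers <- new.env(parent = emptyenv())

#' Register a classifier behind the fit/score-probability contract
#'
#' `fit(x, y, config)` receives a numeric matrix, a 0/1 integer vector and
#' the [training_config()], and returns an opaque state;
#' `predict_proba(state, x)` returns the positive-class probability per
#' row. Registered learners are drop-in replacements for the default
#' random forest everywhere (training, cross-validation, scanning).
#'
#' @param name Classifier name.
#' @param fit,predict_proba Functions implementing the contract.
#' @export
register_classifier <- function(name, fit, predict_proba) {
  stopifnot(is.character(name), is.function(fit), is.function(predict_proba))
  assign(name, list(fit = fit, predict_proba = predict_proba),
         envir = .classifiers)
  invisible(name)
}

get_classifier <- function(name) {
  if (!exists(name, envir = .classifiers, inherits = FALSE)) {
    stop("unknown classifier '", name, "'; registered: ",
         paste(ls(.classifiers), collapse = ", "))
  }
  get(name, envir = .classifiers, inherits = FALSE)
}

.fit_random_forest <- function(x, y, config) {
  df <- as.data.frame(x)
  df$.label <- factor(y, levels = c(0L, 1L))
  ranger::ranger(dependent.variable.name = ".label", data = df,
                 num.trees = config$n_trees, probability = TRUE,
                 mtry = max(1L, floor(sqrt(ncol(x)))),
                 seed = config$seed, num.threads = 1L,
                 verbose = FALSE)
}

.predict_random_forest <- function(state, x) {
  p <- stats::predict(state, data = as.data.frame(x),
                      num.threads = 1L, verbose = FALSE)$predictions
  unname(p[, "1"])
}

register_classifier("random_forest", .fit_random_forest,
                    .predict_random_forest)

# --- feature matrix ---------------------------------------------------------

#' Build the combined feature matrix for a set of sequences
#'
#' Each row is the PseAAC vector of the sequence followed by the selected
#' tripeptide frequencies (count of the tripeptide over the L - 2 windows,
#' divided by L - 2), in spec order. Column names are stable across calls
#' with the same spec.
#'
#' @param records data.frame with `id`, `sequence` (and optionally
#'   `label`), all sequences validated.
#' @param spec A [feature_spec()].
#' @param policy On a record failing the encoder preconditions (too short,
#'   degenerate PseAAC denominator): `"error"` aborts naming the record
#'   (default), `"skip"` drops the row with a warning.
#' @return List with `x` (numeric matrix, rows named by record id), `y`
#'   (integer labels, or NULL if unlabeled) and `failed` (ids of skipped
#'   records, empty under `policy = "error"`).
#' @export
build_feature_matrix <- function(records, spec, policy = c("error", "skip")) {
  policy <- match.arg(policy)
  stopifnot(inherits(spec, "feature_spec"), is.data.frame(records))
  n_sel <- length(spec$tripeptides)
  sel_codes <- if (n_sel > 0L) tripeptide_index(spec$tripeptides) else integer()
  encode_row <- function(i) {
    seq_i <- records$sequence[i]
    pse <- encode_pseaac(seq_i, spec$pseaac)
    if (n_sel > 0L) {
      codes <- .tripeptide_codes(seq_i)
      counts <- tabulate(codes + 1L, nbins = 8000L)
      tpc <- counts[sel_codes + 1L] / length(codes)
    } else {
      tpc <- numeric()
    }
    c(pse, tpc)
  }
  rows <- vector("list", nrow(records))
  failed <- character()
  for (i in seq_len(nrow(records))) {
    rows[i] <- list(tryCatch(encode_row(i), error = function(e) {
      if (policy == "error") {
        stop("record '", records$id[i], "': ", conditionMessage(e),
             call. = FALSE)
      }
      warning("record '", records$id[i], "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    }))
    if (is.null(rows[[i]])) failed <- c(failed, records$id[i])
  }
  ok <- !vapply(rows, is.null, logical(1L))
  if (!any(ok)) stop("no encodable records")
  x <- do.call(rbind, rows[ok])
  colnames(x) <- c(names(rows[ok][[1L]])[seq_len(spec$total_dim - n_sel)],
                   if (n_sel > 0L) paste0("tpc_", spec$tripeptides))
  rownames(x) <- records$id[ok]
  list(x = x,
       y = if ("label" %in% names(records)) as.integer(records$label[ok]) else NULL,
       failed = failed)
}

# --- training / prediction --------------------------------------------------

#' Train a hexapeptide classifier
#'
#' @param dataset Labeled data.frame (`id`, `sequence`, `label`), at least
#'   two samples per class.
#' @param spec A [feature_spec()].
#' @param config A [training_config()].
#' @return Object of class `amylo_model` holding the feature spec, config
#'   and fitted classifier state.
#' @export
train_model <- function(dataset, spec, config = training_config()) {
  fm <- build_feature_matrix(dataset, spec)
  if (is.null(fm$y)) stop("dataset must be labeled")
  if (length(unique(fm$y)) < 2L) stop("training data contain a single class")
  if (min(table(fm$y)) < 2L) stop("need at least 2 samples per class")
  clf <- get_classifier(config$classifier_name)
  state <- clf$fit(fm$x, fm$y, config)
  structure(list(feature_spec = spec, config = config,
                 classifier_state = state,
                 n_train = nrow(fm$x),
                 class_counts = table(factor(fm$y, levels = c(0L, 1L)))),
            class = "amylo_model")
}

#' @export
print.amylo_model <- function(x, ...) {
  cat("<amylo_model>", x$config$classifier_name, "on",
      x$feature_spec$total_dim, "features;",
      x$n_train, "training samples (",
      x$class_counts[["1"]], "pos /", x$class_counts[["0"]], "neg )\n")
  invisible(x)
}

#' Score peptides with a trained model
#'
#' @param model An `amylo_model`.
#' @param records data.frame with `id`, `sequence` (validated).
#' @param policy `"error"` aborts on a record failing the encoder
#'   preconditions; `"skip"` continues the batch, returning `NA` score and
#'   call for the failing record.
#' @return data.frame with `id`, `score` (positive-class probability) and
#'   `call` (1 iff score >= the model's decision threshold), one row per
#'   input record in input order.
#' @export
predict_proba <- function(model, records, policy = c("error", "skip")) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "amylo_model"))
  fm <- build_feature_matrix(records, model$feature_spec, policy = policy)
  clf <- get_classifier(model$config$classifier_name)
  p <- clf$predict_proba(model$classifier_state, fm$x)
  score <- rep(NA_real_, nrow(records))
  score[match(rownames(fm$x), records$id)] <- p
  data.frame(id = records$id, score = score,
             call = as.integer(score >= model$config$decision_threshold),
             stringsAsFactors = FALSE)
}

#' Stratified fold assignment
#'
#' @param y 0/1 integer labels.
#' @param folds Number of folds.
#' @param seed Seed controlling the permutation within each class.
#' @return Integer vector of fold ids in `1..folds`; class ratios per fold
#'   match the overall ratio within one sample.
#' @export
stratified_folds <- function(y, folds, seed) {
  if (folds > min(table(y))) stop("folds exceed the smaller class size")
  out <- integer(length(y))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cls in unique(y)) {
    idx <- which(y == cls)
    out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  out
}

# temporarily set the RNG, returning a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Cross-validate a feature spec + classifier on a labeled dataset
#'
#' Folds are stratified and fixed by `config$seed`; metrics are computed
#' from the concatenated out-of-fold predictions (pooled), with per-fold
#' metrics reported alongside.
#'
#' @inheritParams train_model
#' @return List with `pooled` (metrics incl. AUC), `per_fold` data.frame,
#'   `scores` (out-of-fold scores, in dataset order) and `fold` ids.
#' @export
cross_validate <- function(dataset, spec, config = training_config()) {
  fm <- build_feature_matrix(dataset, spec)
  if (is.null(fm$y)) stop("dataset must be labeled")
  y <- fm$y
  fold <- stratified_folds(y, config$folds, config$seed)
  clf <- get_classifier(config$classifier_name)
  scores <- numeric(length(y))
  for (f in seq_len(config$folds)) {
    hold <- fold == f
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    state <- clf$fit(fm$x[!hold, , drop = FALSE], y[!hold], cfg_f)
    scores[hold] <- clf$predict_proba(state, fm$x[hold, , drop = FALSE])
  }
  thr <- config$decision_threshold
  pooled_counts <- confusion_counts(y, as.integer(scores >= thr))
  pooled <- compute_metrics(pooled_counts)
  pooled$auc <- roc_auc(scores, y)$auc
  per_fold <- do.call(rbind, lapply(seq_len(config$folds), function(f) {
    hold <- fold == f
    m <- compute_metrics(confusion_counts(y[hold],
                                          as.integer(scores[hold] >= thr)))
    cbind(data.frame(fold = f), as.data.frame(m))
  }))
  list(pooled = pooled, per_fold = per_fold, scores = scores, fold = fold)
}

#' Save / load a trained model
#'
#' The model file is a single RDS archive with a format-version field,
#' containing the feature spec, the training config and the serialized
#' classifier state.
#'
#' @param model An `amylo_model`.
#' @param path Model file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "amylo_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @return An `amylo_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version)) {
    stop("not an amyloscan model file: ", path)
  }
  obj$model
}
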