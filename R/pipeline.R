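# File-to-file pipeline steps. Each run_* function is the body of one
# `amyloscan` shell subcommand (see exec/amyloscan): it reads and writes
# the package's plain-text formats, logs the resolved configuration to
# stderr, and returns its main result invisibly.

.log <- function(...) message("[amyloscan] ", ...)

.log_config <- function(cmd, cfg) {
  .log(cmd, " (amyloscan ",
       as.character(utils::packageVersion("amyloscan")), ") config: ",
       paste(names(cfg), unname(vapply(cfg, function(v)
         paste(format(v), collapse = ","), character(1L))),
         sep = "=", collapse = " "))
}

#' Pipeline step: simulate a synthetic benchmark
#'
#' Writes a labeled hexapeptide TSV, a protein FASTA and a hotspot
#' annotation TSV under `out_prefix`.
#'
#' @param out_prefix Path prefix for the three output files
#'   (`<prefix>_hexapeptides.tsv`, `<prefix>_proteins.fasta`,
#'   `<prefix>_annotations.tsv`).
#' @param n_pos,n_neg,plant_rate,composition_bias,seed See
#'   [synthetic_config()].
#' @param n_proteins,hotspots_per_protein See
#'   [generate_annotated_proteins()].
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(out_prefix, n_pos = 200L, n_neg = 200L,
                         plant_rate = 0.8, composition_bias = 1,
                         n_proteins = 10L, hotspots_per_protein = 2L,
                         seed = 1L) {
  cfg <- synthetic_config(n_pos = n_pos, n_neg = n_neg,
                          plant_rate = plant_rate,
                          composition_bias = composition_bias, seed = seed)
  .log_config("simulate", list(n_pos = n_pos, n_neg = n_neg,
                               plant_rate = plant_rate,
                               composition_bias = composition_bias,
                               n_proteins = n_proteins,
                               hotspots_per_protein = hotspots_per_protein,
                               seed = seed))
  hex <- generate_hexapeptides(cfg)
  prot <- generate_annotated_proteins(n_proteins = n_proteins,
                                      hotspots_per_protein = hotspots_per_protein,
                                      config = cfg)
  paths <- c(hexapeptides = paste0(out_prefix, "_hexapeptides.tsv"),
             proteins = paste0(out_prefix, "_proteins.fasta"),
             annotations = paste0(out_prefix, "_annotations.tsv"))
  write_labeled_dataset(hex, paths[["hexapeptides"]])
  write_fasta(prot$proteins, paths[["proteins"]])
  utils::write.table(prot$annotations, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .log("wrote ", nrow(hex), " hexapeptides, ", nrow(prot$proteins),
       " proteins, ", nrow(prot$annotations), " annotated regions")
  invisible(paths)
}

#' Pipeline step: rank tripeptides and select features
#'
#' @param dataset_path Labeled hexapeptide TSV (`sequence`, `label`).
#' @param spec_out Output path for the feature-spec text file.
#' @param report_out Optional output path for the ranked-feature TSV.
#' @param mode,value Selection rule, see [rank_and_select()].
#' @param lambda,weight PseAAC parameters.
#' @param scales_path Optional TSV overriding the default property scales.
#' @return Invisibly, the `feature_spec`.
#' @export
run_select <- function(dataset_path, spec_out, report_out = NULL,
                       mode = "threshold", value = 0.85,
                       lambda = 2L, weight = 0.7, scales_path = NULL) {
  .log_config("select", list(dataset = dataset_path, mode = mode,
                             value = value, lambda = lambda, weight = weight))
  dataset <- read_labeled_dataset(dataset_path)
  scales <- if (is.null(scales_path)) default_property_scales() else {
    load_property_scales(scales_path)
  }
  pse <- pseaac_params(lambda = lambda, weight = weight, scales = scales)
  stats <- confidence_levels(count_tripeptides(dataset))
  spec <- rank_and_select(stats, mode = mode, value = value, pseaac = pse)
  write_feature_spec(spec, spec_out)
  if (!is.null(report_out)) {
    utils::write.table(ranked_report(stats), report_out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  .log("selected ", length(spec$tripeptides), " tripeptides (total dim ",
       spec$total_dim, ")")
  invisible(spec)
}

#' Pipeline step: train and cross-validate the classifier
#'
#' @param dataset_path Labeled hexapeptide TSV.
#' @param spec_path Feature-spec file from [run_select()].
#' @param model_out Output path for the model file.
#' @param report_out Optional output path for the CV metrics TSV.
#' @param n_trees,seed,folds,decision_threshold See [training_config()].
#' @return Invisibly, the trained `amylo_model`.
#' @export
run_train <- function(dataset_path, spec_path, model_out, report_out = NULL,
                      n_trees = 500L, seed = 1L, folds = 10L,
                      decision_threshold = 0.5) {
  .log_config("train", list(dataset = dataset_path, spec = spec_path,
                            n_trees = n_trees, seed = seed, folds = folds,
                            decision_threshold = decision_threshold))
  dataset <- read_labeled_dataset(dataset_path)
  spec <- read_feature_spec(spec_path)
  config <- training_config(n_trees = n_trees, seed = seed, folds = folds,
                            decision_threshold = decision_threshold)
  cv <- cross_validate(dataset, spec, config)
  model <- train_model(dataset, spec, config)
  model$training_summary <- cv$pooled
  save_model(model, model_out)
  if (!is.null(report_out)) {
    pooled <- cbind(data.frame(fold = "pooled"), as.data.frame(cv$pooled))
    per_fold <- cv$per_fold
    per_fold$auc <- NA_real_
    utils::write.table(rbind(pooled, per_fold), report_out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  .log(sprintf("pooled %d-fold CV: ACC %.3f SE %.3f SP %.3f Q %.3f MCC %.3f AUC %.3f",
               config$folds, cv$pooled$acc, cv$pooled$se, cv$pooled$sp,
               cv$pooled$q, cv$pooled$mcc, cv$pooled$auc))
  invisible(model)
}

#' Pipeline step: scan proteins (or classify peptides)
#'
#' In region mode writes the region TSV (and optionally a per-residue
#' TSV); with `peptide_mode = TRUE` writes per-peptide calls instead,
#' using the at-least-one-positive-window rule.
#'
#' @param fasta_path Input FASTA.
#' @param model_path Model file from [run_train()].
#' @param regions_out Output TSV (regions, or peptide calls in peptide
#'   mode).
#' @param residues_out Optional per-residue TSV output path.
#' @param threshold Optional override of the model's decision threshold.
#' @param peptide_mode Classify whole peptides instead of locating
#'   regions.
#' @param policy Validation policy for input sequences.
#' @return Invisibly, the list of predictions.
#' @export
run_scan <- function(fasta_path, model_path, regions_out,
                     residues_out = NULL, threshold = NULL,
                     peptide_mode = FALSE, policy = "skip") {
  .log_config("scan", list(fasta = fasta_path, model = model_path,
                           peptide_mode = peptide_mode, policy = policy))
  model <- load_model(model_path)
  records <- validate_records(read_fasta(fasta_path), policy = policy)
  if (peptide_mode) {
    keep <- nchar(records$sequence) >= 6L
    if (any(!keep)) {
      warning("skipping ", sum(!keep), " peptide(s) shorter than 6 residues")
    }
    calls <- lapply(which(keep), function(i) {
      classify_peptide(records[i, ], model, threshold = threshold)
    })
    out <- do.call(rbind, lapply(calls, function(cl) {
      data.frame(id = cl$id, call = cl$call, score = cl$score,
                 best_window_start = cl$best_window$start,
                 best_window = cl$best_window$window,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(out, regions_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .log("classified ", nrow(out), " peptide(s), ",
         sum(out$call), " positive")
    return(invisible(calls))
  }
  preds <- scan_proteins(records, model, threshold = threshold)
  write_regions(preds, regions_out, residue_path = residues_out)
  .log("scanned ", length(preds), " protein(s), ",
       sum(vapply(preds, function(p) nrow(p$regions), integer(1L))),
       " region(s) called")
  invisible(preds)
}

#' Pipeline step: evaluate per-residue predictions against annotations
#'
#' Consumes the per-residue TSV written by [run_scan()] and an annotation
#' TSV; reports pooled per-residue confusion counts, the five metrics and
#' the hotspot-vs-regular AUC of the residue scores.
#'
#' @param residues_path Per-residue prediction TSV.
#' @param annotations_path Hotspot annotation TSV.
#' @param report_out Optional output path for a metrics TSV.
#' @return Invisibly, the evaluation list from [evaluate_regions()].
#' @export
run_evaluate <- function(residues_path, annotations_path, report_out = NULL) {
  .log_config("evaluate", list(residues = residues_path,
                               annotations = annotations_path))
  res <- read_residue_predictions(residues_path)
  ann <- read_annotations(annotations_path)
  ids <- unique(res$protein_id)
  missing <- setdiff(ids, unique(ann$protein_id))
  if (length(missing) > 0L) {
    stop("no annotation for protein id(s): ", paste(missing, collapse = ", "))
  }
  predictions <- lapply(ids, function(id) {
    d <- res[res$protein_id == id, ]
    d <- d[order(d$position), ]
    structure(list(protein_id = id,
                   sequence = paste(d$residue, collapse = ""),
                   mask = d$call == 1L, residue_score = d$score,
                   regions = mask_to_regions(d$call == 1L)),
              class = "region_prediction")
  })
  names(predictions) <- ids
  truths <- lapply(split(ann, ann$protein_id), function(d) {
    d[, c("start", "end")]
  })
  ev <- evaluate_regions(truths, predictions)
  m <- ev$metrics
  .log(sprintf("per-residue: TP %d FP %d TN %d FN %d | ACC %.3f SE %.3f SP %.3f Q %.3f MCC %.3f%s",
               ev$counts$tp, ev$counts$fp, ev$counts$tn, ev$counts$fn,
               m$acc, m$se, m$sp, m$q, m$mcc,
               if (!is.null(ev$auc)) sprintf(" AUC %.3f", ev$auc) else ""))
  if (!is.null(report_out)) {
    tab <- data.frame(tp = ev$counts$tp, fp = ev$counts$fp,
                      tn = ev$counts$tn, fn = ev$counts$fn,
                      acc = m$acc, se = m$se, sp = m$sp, q = m$q,
                      mcc = m$mcc,
                      auc = if (!is.null(ev$auc)) ev$auc else NA_real_)
    utils::write.table(tab, report_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ev)
}
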