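# Sequence, label and annotation I/O.
#
# Peptide/protein sets are plain data.frames with columns id, sequence and
# (when labeled) label in {0, 1}; hotspot annotations are data.frames with
# protein_id, start, end (1-based inclusive). All external coordinates are
# 1-based inclusive.

#' Validate a protein sequence against the 20-letter alphabet
#'
#' Uppercases `raw` and checks every character against [AMINO_ACIDS].
#' Non-standard characters (`X`, `B`, `Z`, `U`, `*`, gaps, ...) either abort
#' with the offending position (`policy = "error"`) or reject the sequence
#' with a warning and return `NA` (`policy = "skip"`), so scanning arbitrary
#' proteins never crashes on the odd selenocysteine.
#'
#' @param raw Character scalar, the raw sequence.
#' @param policy `"error"` or `"skip"`.
#' @param id Optional record id used in messages.
#' @return The validated uppercase sequence, or `NA_character_` when the
#'   sequence is rejected under `policy = "skip"`.
#' @export
validate_sequence <- function(raw, policy = c("skip", "error"), id = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || !nzchar(raw)) {
    stop("sequence is empty", if (!is.null(id)) paste0(" (record '", id, "')"))
  }
  seq <- toupper(raw)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AMINO_ACIDS))
  if (length(bad) == 0L) {
    return(seq)
  }
  what <- sprintf("non-standard character '%s' at position %d", chars[bad[1L]], bad[1L])
  label <- if (is.null(id)) "sequence" else paste0("record '", id, "'")
  if (policy == "error") {
    stop(label, ": ", what)
  }
  warning(label, " rejected: ", what)
  NA_character_
}

#' Validate every record of a peptide set
#'
#' Applies [validate_sequence()] row-wise; under `policy = "skip"` rejected
#' records are dropped (with a warning per record).
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @inheritParams validate_sequence
#' @return The validated data.frame (possibly fewer rows).
#' @export
validate_records <- function(records, policy = c("skip", "error")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  seqs <- vapply(seq_len(nrow(records)), function(i) {
    validate_sequence(records$sequence[i], policy = policy, id = records$id[i])
  }, character(1L))
  records$sequence <- seqs
  records[!is.na(seqs), , drop = FALSE]
}

#' Read protein or peptide sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. Validation is left to [validate_records()] so
#' callers choose the policy.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA (", path, "): line ", nonblank[1L],
         " does not start with '>'")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1L), 1L)
  data.frame(id = ids,
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a labeled hexapeptide/peptide dataset
#'
#' Expects delimited text with columns `sequence` and `label` (an `id`
#' column is optional; missing ids are synthesised as `seq_<row>`). Labels
#' must be 0 (non-amyloidogenic) or 1 (amyloidogenic). Duplicate sequences
#' are kept with a warning — deduplication is the caller's choice.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param sep Field separator (default tab; `","` for CSV).
#' @param policy Validation policy, see [validate_sequence()].
#' @return data.frame with columns `id`, `sequence`, `label`.
#' @export
read_labeled_dataset <- function(path, sep = "\t", policy = c("skip", "error")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no records in dataset file: ", path)
  if (!all(c("sequence", "label") %in% names(df))) {
    stop("dataset must have columns 'sequence' and 'label' (found: ",
         paste(names(df), collapse = ", "), ")")
  }
  bad <- which(!(df$label %in% c("0", "1")))
  if (length(bad) > 0L) {
    stop("label outside {0,1} at row ", bad[1L], " (value '",
         df$label[bad[1L]], "')")
  }
  id <- if ("id" %in% names(df)) df$id else sprintf("seq_%d", seq_len(nrow(df)))
  out <- data.frame(id = id, sequence = df$sequence,
                    label = as.integer(df$label), stringsAsFactors = FALSE)
  dup <- duplicated(out$sequence)
  if (any(dup)) {
    conflicting <- any(vapply(split(out$label, out$sequence),
                              function(l) length(unique(l)) > 1L, logical(1L)))
    warning(sum(dup), " duplicate sequence(s) kept",
            if (conflicting) "; some duplicates carry conflicting labels")
  }
  out <- validate_records(out, policy = policy)
  if (nrow(out) == 0L) stop("no valid records in dataset file: ", path)
  out
}

#' Write a labeled dataset as TSV
#'
#' @param records data.frame with `id`, `sequence`, `label`.
#' @param path Output path.
#' @export
write_labeled_dataset <- function(records, path) {
  utils::write.table(records[, c("id", "sequence", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read hotspot annotations (1-based inclusive intervals)
#'
#' Expects TSV with header `protein_id`, `start`, `end`. Overlapping or
#' adjacent intervals of the same protein are merged on load (with a
#' message), so downstream per-residue truth masks are unambiguous.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with `protein_id`, `start`, `end`, sorted by protein
#'   then start, intervals disjoint within each protein.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end)) ||
      any(df$start < 1L) || any(df$start > df$end)) {
    stop("invalid interval in annotation file (need 1 <= start <= end)")
  }
  merged <- do.call(rbind, lapply(split(df, df$protein_id), function(d) {
    m <- merge_intervals(d$start, d$end)
    if (nrow(m) < nrow(d)) {
      message("merged ", nrow(d) - nrow(m), " overlapping interval(s) for ",
              d$protein_id[1L])
    }
    data.frame(protein_id = d$protein_id[1L], start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  }))
  row.names(merged) <- NULL
  merged[order(merged$protein_id, merged$start), , drop = FALSE]
}

#' Merge overlapping or adjacent 1-based inclusive intervals
#'
#' @param start,end Integer vectors of equal length.
#' @return data.frame with disjoint `start`, `end`, sorted by start.
#' @export
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Write predicted regions (and optionally per-residue calls) to TSV
#'
#' Region lines are `protein_id  start  end  max_score` with 1-based
#' inclusive coordinates, sorted by protein then start; proteins with an
#' empty mask contribute no region lines. The optional residue file has one
#' row per residue: `protein_id  position  residue  call  score`.
#'
#' @param predictions List of region predictions from [scan_protein()].
#' @param path Output path for the region TSV.
#' @param residue_path Optional output path for the per-residue TSV.
#' @export
write_regions <- function(predictions, path, residue_path = NULL) {
  if (inherits(predictions, "region_prediction")) predictions <- list(predictions)
  rows <- lapply(predictions, function(p) {
    if (nrow(p$regions) == 0L) return(NULL)
    data.frame(protein_id = p$protein_id, start = p$regions$start,
               end = p$regions$end, max_score = p$regions$max_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(protein_id = character(),
                                                start = integer(),
                                                end = integer(),
                                                max_score = numeric()))))
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(residue_path)) {
    res <- do.call(rbind, lapply(predictions, function(p) {
      chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
      data.frame(protein_id = p$protein_id,
                 position = seq_along(chars), residue = chars,
                 call = as.integer(p$mask), score = p$residue_score,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(res, residue_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-residue prediction file written by [write_regions()]
#'
#' @param path Path to the residue TSV.
#' @return data.frame with `protein_id`, `position`, `residue`, `call`,
#'   `score`.
#' @export
read_residue_predictions <- function(path) {
  if (!file.exists(path)) stop("residue prediction file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "call", "score")
  if (!all(need %in% names(df))) {
    stop("residue file must have columns ", paste(need, collapse = ", "))
  }
  df
}
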