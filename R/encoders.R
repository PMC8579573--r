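# Sequence encoders: Type 2 (series correlation) pseudo amino acid
# composition and tripeptide composition.

#' Parameters for the Type 2 PseAAC encoder
#'
#' @param lambda Correlation rank: lags 1..lambda contribute correlation
#'   factors. Default 2, which with nine scales gives the standard
#'   20 + 9*2 = 38-component vector.
#' @param weight Weight factor `w` applied to the correlation block
#'   (default 0.7).
#' @param scales Named list of `property_scale` objects
#'   (default [default_property_scales()], nine scales).
#' @param freq_mode How the composition numerators are computed:
#'   `"count"` (raw occurrence counts, the default) or `"relative"`
#'   (counts / L, so they sum to 1). With nine standardized scales,
#'   `lambda = 2` and `w = 0.7` on hexapeptides, the correlation block
#'   often outweighs a unit-sum composition block and drives the common
#'   denominator negative; raw counts keep the composition block at
#'   magnitude L and make that degeneracy rare (~1e-5 instead of ~0.3 on
#'   random hexapeptides). The encoded vector sums to 1 in either mode.
#' @return Object of class `pseaac_params`.
#' @export
pseaac_params <- function(lambda = 2L, weight = 0.7,
                          scales = default_property_scales(),
                          freq_mode = c("count", "relative")) {
  freq_mode <- match.arg(freq_mode)
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 1L) stop("lambda must be a positive integer")
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0")
  if (!is.list(scales) || length(scales) == 0L ||
      !all(vapply(scales, inherits, logical(1L), "property_scale"))) {
    stop("scales must be a non-empty list of property_scale objects")
  }
  structure(list(lambda = lambda, weight = weight, scales = scales,
                 freq_mode = freq_mode),
            class = "pseaac_params")
}

#' @export
print.pseaac_params <- function(x, ...) {
  cat("<pseaac_params> lambda =", x$lambda, " w =", x$weight,
      " scales =", length(x$scales),
      " (", paste(names(x$scales), collapse = ", "), ")\n")
  cat("  vector length:", 20L + length(x$scales) * x$lambda,
      " freq_mode:", x$freq_mode, "\n")
  invisible(x)
}

# standardized scale values as a (n_scales x 20) matrix for fast lookup
.scale_matrix <- function(params) {
  m <- do.call(rbind, lapply(params$scales, `[[`, "standardized"))
  rownames(m) <- names(params$scales)
  m
}

.seq_to_idx <- function(sequence) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], AMINO_ACIDS)
  if (anyNA(idx)) stop("sequence contains non-standard characters; validate first")
  idx
}

#' Lag-correlation factors of a sequence
#'
#' For each lag d = 1..lambda and each property scale k, the factor is the
#' mean over the L - d residue pairs of the product of standardized
#' property values: (1/(L-d)) * sum_i h_k(R_i) * h_k(R_{i+d}). Factors are
#' ordered lag-major: all scales at lag 1, then all scales at lag 2, ...
#'
#' @param sequence Validated sequence (length > lambda).
#' @param params [pseaac_params()].
#' @return Named numeric vector of length `n_scales * lambda`.
#' @export
correlation_factors <- function(sequence, params = pseaac_params()) {
  idx <- .seq_to_idx(sequence)
  L <- length(idx)
  if (L <= params$lambda) {
    stop("sequence shorter than correlation rank (L = ", L,
         ", lambda = ", params$lambda, ")")
  }
  H <- .scale_matrix(params)      # n_scales x 20
  vals <- H[, idx, drop = FALSE]  # n_scales x L
  out <- numeric(0L)
  for (d in seq_len(params$lambda)) {
    prod_d <- vals[, 1:(L - d), drop = FALSE] * vals[, (1 + d):L, drop = FALSE]
    theta_d <- rowMeans(prod_d)
    names(theta_d) <- paste0("theta_", rownames(H), "_lag", d)
    out <- c(out, theta_d)
  }
  out
}

#' Encode a sequence as a Type 2 PseAAC vector
#'
#' The vector has 20 composition components followed by
#' `n_scales * lambda` correlation components. With composition numerators
#' f_u and correlation factors theta_j, component u is
#' `f_u / D` for u <= 20 and `w * theta_{u-20} / D` otherwise, where
#' `D = sum(f) + w * sum(theta)` is the common denominator; the full vector
#' therefore sums to 1. Correlation factors of standardized properties may
#' be negative, so a near-zero denominator is a hard error rather than a
#' silent clamp.
#'
#' @inheritParams correlation_factors
#' @param eps Denominator guard (default 1e-12).
#' @return Named numeric vector of length `20 + n_scales * lambda`.
#' @export
encode_pseaac <- function(sequence, params = pseaac_params(), eps = 1e-12) {
  idx <- .seq_to_idx(sequence)
  L <- length(idx)
  counts <- tabulate(idx, nbins = 20L)
  f <- if (params$freq_mode == "relative") counts / L else as.numeric(counts)
  theta <- correlation_factors(sequence, params)
  denom <- sum(f) + params$weight * sum(theta)
  if (!is.finite(denom) || denom <= eps) {
    stop("degenerate PseAAC normalization (denominator = ",
         format(denom), ")")
  }
  out <- c(f, params$weight * theta) / denom
  names(out) <- c(paste0("f_", AMINO_ACIDS), names(theta))
  out
}

#' Tripeptide indexing: 3-mer string to integer code and back
#'
#' Bijective base-20 positional code with amino acids ordered
#' alphabetically (A = 0 ... Y = 19):
#' `index = 400*a1 + 20*a2 + a3`, so "AAA" is 0 and "YYY" is 7999.
#'
#' @param tripeptide Character vector of 3-letter strings.
#' @return Integer vector of codes in `[0, 7999]`.
#' @export
tripeptide_index <- function(tripeptide) {
  bad <- nchar(tripeptide) != 3L
  if (any(bad)) stop("tripeptide must have exactly 3 letters: '",
                     tripeptide[which(bad)[1L]], "'")
  m <- matrix(match(unlist(strsplit(toupper(tripeptide), "", fixed = TRUE)),
                    AMINO_ACIDS),
              nrow = 3L)
  if (anyNA(m)) stop("tripeptide contains an invalid amino-acid letter")
  as.integer(400L * (m[1L, ] - 1L) + 20L * (m[2L, ] - 1L) + (m[3L, ] - 1L))
}

#' @rdname tripeptide_index
#' @param index Integer vector of codes in `[0, 7999]`.
#' @export
tripeptide_from_index <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0L) || any(index > 7999L)) {
    stop("tripeptide index must be in [0, 7999]")
  }
  a1 <- index %/% 400L
  a2 <- (index %/% 20L) %% 20L
  a3 <- index %% 20L
  paste0(AMINO_ACIDS[a1 + 1L], AMINO_ACIDS[a2 + 1L], AMINO_ACIDS[a3 + 1L])
}

#' All 8000 tripeptides in index order
#' @return Character vector of length 8000 ("AAA" ... "YYY").
#' @export
all_tripeptides <- function() tripeptide_from_index(0:7999)

# PseAAC common denominator of a sequence; <= 0 marks a degenerate
# scale/sequence combination that encode_pseaac refuses
.pseaac_denominator <- function(sequence, params = pseaac_params()) {
  idx <- .seq_to_idx(sequence)
  counts <- tabulate(idx, nbins = 20L)
  f <- if (params$freq_mode == "relative") counts / length(idx) else counts
  sum(f) + params$weight * sum(correlation_factors(sequence, params))
}

# integer codes of the L-2 overlapping tripeptide windows of a sequence
.tripeptide_codes <- function(sequence) {
  idx <- .seq_to_idx(sequence)
  L <- length(idx)
  if (L < 3L) stop("sequence too short for tripeptides (L = ", L, ")")
  400L * (idx[1:(L - 2L)] - 1L) + 20L * (idx[2:(L - 1L)] - 1L) +
    (idx[3:L] - 1L)
}

#' Encode a sequence as a tripeptide-composition vector
#'
#' Component i is the count of the i-th tripeptide over the L - 2
#' overlapping windows, divided by L - 2; the 8000 components sum to 1.
#'
#' @param sequence Validated sequence of length >= 3.
#' @return Named numeric vector of length 8000 (names = tripeptides).
#' @export
encode_tpc <- function(sequence) {
  codes <- .tripeptide_codes(sequence)
  f <- tabulate(codes + 1L, nbins = 8000L) / length(codes)
  names(f) <- all_tripeptides()
  f
}
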