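# Independent reference implementations and small fixtures used across the
# suite. These deliberately mirror the defining formulas with naive loops /
# term-by-term summation, never the package's optimized code paths.

# two toy property scales over the 20 amino acids, already standardized by
# construction checks in the tests that use them
toy_scales <- function() {
  # alternate +1/-1: mean 0, population sd 1 exactly
  alt <- rep(c(1, -1), 10)
  names(alt) <- AMINO_ACIDS
  ramp <- seq(-2, 2, length.out = 20)
  names(ramp) <- AMINO_ACIDS
  list(alt = standardize_scale(alt, "alt"),
       ramp = standardize_scale(ramp, "ramp"))
}

# naive evaluation of the standardization formula
oracle_standardize <- function(raw) {
  raw <- raw[AMINO_ACIDS]
  mu <- sum(raw) / 20
  sd_pop <- sqrt(sum((raw - mu)^2) / 20)
  (raw - mu) / sd_pop
}

# naive, loop-based Type 2 PseAAC: explicit sums over residues and lags
oracle_pseaac <- function(sequence, params) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  f <- vapply(AMINO_ACIDS, function(a) sum(chars == a), numeric(1L))
  if (params$freq_mode == "relative") f <- f / L
  theta <- numeric(0L)
  for (d in seq_len(params$lambda)) {
    for (s in params$scales) {
      h <- s$standardized
      acc <- 0
      for (i in seq_len(L - d)) acc <- acc + h[[chars[i]]] * h[[chars[i + d]]]
      theta <- c(theta, acc / (L - d))
    }
  }
  denom <- sum(f) + params$weight * sum(theta)
  structure(unname(c(f, params$weight * theta) / denom), denom = denom)
}

# term-by-term binomial upper tail
oracle_binomial_tail <- function(n, N, q) {
  if (n > N) return(0)
  ks <- n:N
  sum(choose(N, ks) * q^ks * (1 - q)^(N - ks))
}

# pairwise-comparison (Mann-Whitney) AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# untied Friedman chi-square from the textbook formula
oracle_friedman <- function(ranks) {
  k <- nrow(ranks); n <- ncol(ranks)
  rbar <- rowMeans(ranks)
  12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}

# uniform random peptide over the 20-letter alphabet
random_peptide <- function(L) {
  paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = "")
}

# a rule-based classifier for controlled region-scan tests: score 0.9 when
# any selected tripeptide is present in the window, else 0.1; registered
# once at load
register_classifier("toy_rule",
                    fit = function(x, y, config) NULL,
                    predict_proba = function(state, x) {
                      tp <- grep("^tpc_", colnames(x))
                      if (length(tp) == 0L) return(rep(0.1, nrow(x)))
                      ifelse(rowSums(x[, tp, drop = FALSE]) > 0, 0.9, 0.1)
                    })

# a trained-model shell around the toy rule
toy_model <- function(tripeptides = "VIV", threshold = 0.5) {
  train <- data.frame(id = c("p1", "p2", "n1", "n2"),
                      sequence = c("AVIVAA", "CVIVCC", "AAAAAA", "CCCCCC"),
                      label = c(1L, 1L, 0L, 0L))
  cfg <- training_config(classifier_name = "toy_rule", n_trees = 1L,
                         seed = 1L, decision_threshold = threshold,
                         folds = 2L)
  train_model(train, feature_spec(tripeptides), cfg)
}

# the worked calcitonin fragment used throughout the evaluation tests
calcitonin <- list(
  sequence = "CGNLSTCMLGTYTQDFNKFHTFPQTAIGVGAP",
  truth = data.frame(start = 15L, end = 20L),
  predicted = data.frame(start = 11L, end = 23L)
)
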