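make_dataset <- function(pos, neg) {
  data.frame(id = sprintf("s%d", seq_along(c(pos, neg))),
             sequence = c(pos, neg),
             label = rep(c(1L, 0L), c(length(pos), length(neg))))
}

test_that("tripeptide counting works per class on token totals", {
  cnt <- count_tripeptides(make_dataset("AAA", "CCC"))
  expect_equal(unname(cnt$n_pos[["AAA"]]), 1L)
  expect_equal(unname(cnt$n_neg[["CCC"]]), 1L)
  expect_equal(cnt$q_pos, 0.5)
  expect_equal(cnt$q_neg, 0.5)

  # "AAAA" holds 2 overlapping AAA tokens
  cnt2 <- count_tripeptides(make_dataset("AAAA", "CCC"))
  expect_equal(unname(cnt2$n_pos[["AAA"]]), 2L)
  expect_equal(cnt2$q_pos, 2 / 3)

  expect_error(count_tripeptides(make_dataset("AAA", character())),
               "both classes")
})

test_that("token totals equal the sum of L - 2 over sequences", {
  set.seed(5)
  pos <- replicate(15, random_peptide(sample(6:12, 1)))
  neg <- replicate(20, random_peptide(sample(6:12, 1)))
  cnt <- count_tripeptides(make_dataset(pos, neg))
  expect_equal(cnt$tokens_pos + cnt$tokens_neg,
               sum(nchar(c(pos, neg)) - 2L))
})

test_that("per-class content matches direct window enumeration", {
  set.seed(9)
  pos <- replicate(10, random_peptide(6))
  neg <- replicate(10, random_peptide(6))
  content <- tripeptide_content(count_tripeptides(make_dataset(pos, neg)))
  # direct enumeration of all windows of the positive class
  windows <- unlist(lapply(pos, function(s)
    substring(s, 1:4, 3:6)))
  for (t in unique(windows)) {
    expect_equal(content$content_pos[content$tripeptide == t],
                 sum(windows == t) / length(windows))
  }
})

test_that("binomial_tail matches endpoints and direct summation", {
  expect_equal(binomial_tail(0, 10, 0.3), 1.0)
  expect_equal(binomial_tail(1, 1, 0.5), 0.5)
  expect_equal(binomial_tail(7, 10, 0.3), oracle_binomial_tail(7, 10, 0.3),
               tolerance = 1e-14)
  expect_error(binomial_tail(3, 10, 0), "inside")
  expect_error(binomial_tail(11, 10, 0.5), "<= N")
})

test_that("binomial_tail is monotone in n with the right endpoints", {
  for (q in c(0.2, 0.5, 0.8)) {
    tails <- binomial_tail(0:30, 30, q)
    expect_true(all(diff(tails) <= 1e-15))
    expect_equal(tails[1], 1)
    expect_equal(tails[31], q^30, tolerance = 1e-12)
  }
})

test_that("binomial_tail agrees with Monte-Carlo frequency", {
  set.seed(12)
  p <- binomial_tail(3, 12, 0.4)
  draws <- rbinom(1e6, 12, 0.4)
  freq <- mean(draws >= 3)
  se <- sqrt(p * (1 - p) / 1e6)
  expect_lt(abs(freq - p), 3 * se)
})

test_that("confidence levels follow the exact tail sums", {
  set.seed(21)
  pos <- replicate(10, random_peptide(6))
  neg <- replicate(10, random_peptide(6))
  cnt <- count_tripeptides(make_dataset(pos, neg))
  cl <- confidence_levels(cnt)
  # unseen tripeptides carry no evidence
  expect_true(all(cl$cl[cl$n_total == 0L] == 0))
  # observed ones equal 1 - min of the two exact sums
  seen <- which(cl$n_total > 0L)
  for (i in seen) {
    p1 <- oracle_binomial_tail(cl$n_pos[i], cl$n_total[i], cnt$q_pos)
    p0 <- oracle_binomial_tail(cl$n_neg[i], cl$n_total[i], cnt$q_neg)
    expect_equal(cl$cl[i], 1 - min(p1, p0), tolerance = 1e-12)
  }
})

test_that("a class-exclusive tripeptide with many tokens approaches CL 1", {
  d <- make_dataset(rep("VIVIVI", 30), replicate(30, strrep("N", 6)))
  cl <- confidence_levels(count_tripeptides(d))
  expect_gt(cl$cl[cl$tripeptide == "VIV"], 0.999)
})

test_that("rank_and_select honors mode, order and determinism", {
  set.seed(33)
  cfg <- synthetic_config(n_pos = 100, n_neg = 100, seed = 33)
  d <- generate_hexapeptides(cfg)
  stats <- confidence_levels(count_tripeptides(d))

  # threshold mode on all-zero CL gives the empty selection
  zero <- stats; zero$cl <- 0
  expect_length(rank_and_select(zero, "threshold", 0.85)$tripeptides, 0L)

  # top_k = 8000 keeps everything, sorted
  full <- rank_and_select(stats, "top_k", 8000)
  expect_length(full$tripeptides, 8000L)
  ranked <- ranked_report(stats)
  expect_identical(full$tripeptides, ranked$tripeptide)
  expect_true(all(diff(ranked$cl) <= 0))

  # planted discriminative tripeptides all land in the top 20 ranks
  planted <- c(cfg$planted_tripeptides_pos, cfg$planted_tripeptides_neg)
  expect_true(all(match(planted, ranked$tripeptide) <= 20))

  # byte-for-byte determinism of the selection
  spec_a <- rank_and_select(stats, "threshold", 0.85)
  spec_b <- rank_and_select(confidence_levels(count_tripeptides(d)),
                            "threshold", 0.85)
  expect_identical(spec_a$tripeptides, spec_b$tripeptides)
  expect_equal(spec_a$total_dim, 38L + length(spec_a$tripeptides))

  expect_error(rank_and_select(stats, "top_k", 8001), "top_k")
  expect_error(rank_and_select(stats, "threshold", 1.2), "threshold")
})

test_that("tune_cutoff prefers the informative feature set", {
  # anagram plants: identical residue composition between classes, so the
  # PseAAC block alone is nearly uninformative and the tripeptide block
  # is decisive by construction
  cfg <- synthetic_config(n_pos = 60, n_neg = 60,
                          planted_tripeptides_pos = "VIA",
                          planted_tripeptides_neg = "AIV",
                          plant_rate = 1, composition_bias = 0, seed = 5)
  d <- generate_hexapeptides(cfg)
  stats <- confidence_levels(count_tripeptides(d))
  config <- training_config(n_trees = 150, seed = 5, folds = 3)
  res <- tune_cutoff(c(0L, 10L), d, stats, config)
  expect_equal(res$best_k, 10L)
  expect_equal(nrow(res$table), 2L)
  expect_gt(res$table$acc[res$table$k == 10],
            res$table$acc[res$table$k == 0])

  # single candidate round-trips with its CV metrics
  one <- tune_cutoff(10L, d, stats, config)
  expect_equal(one$best_k, 10L)
  expect_equal(one$table$acc, res$table$acc[res$table$k == 10])
})

test_that("candidate_cutoffs enumerates ranks near the CL boundary", {
  set.seed(44)
  d <- generate_hexapeptides(synthetic_config(n_pos = 100, n_neg = 100,
                                              seed = 44))
  stats <- confidence_levels(count_tripeptides(d))
  ks <- candidate_cutoffs(stats, threshold = 0.85, width = 0.05)
  expect_true(length(ks) >= 1 && length(ks) <= 20)
  ranked <- ranked_report(stats)
  expect_true(all(ranked$cl[ks] >= 0.80 - 1e-9 & ranked$cl[ks] <= 0.90 + 1e-9))
})

test_that("feature specs round-trip through the text format", {
  spec <- feature_spec(c("VIV", "NGQ", "AAA"),
                       pseaac_params(lambda = 1L, weight = 0.5,
                                     scales = toy_scales()))
  f <- withr::local_tempfile(fileext = ".txt")
  write_feature_spec(spec, f)
  back <- read_feature_spec(f)
  expect_identical(back$tripeptides, spec$tripeptides)
  expect_equal(back$total_dim, spec$total_dim)
  expect_equal(back$pseaac$lambda, 1L)
  expect_equal(back$pseaac$weight, 0.5)
  expect_equal(back$pseaac$scales$alt$standardized,
               spec$pseaac$scales$alt$standardized)
  expect_error(read_feature_spec(f2 <- withr::local_tempfile(lines = "x")),
               "not a feature spec")
})
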