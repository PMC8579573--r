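test_that("residue confusion matches the calcitonin worked example", {
  L <- nchar(calcitonin$sequence)  # 32
  cc <- residue_confusion(calcitonin$truth, calcitonin$predicted, L)
  expect_equal(cc$tp, 6L)
  expect_equal(cc$fp, 7L)
  expect_equal(cc$tn, 19L)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, L)

  # predicted == truth: no errors
  exact <- residue_confusion(calcitonin$truth, calcitonin$truth, L)
  expect_equal(exact$fp + exact$fn, 0L)

  # all-negative prediction
  none <- residue_confusion(calcitonin$truth,
                            data.frame(start = integer(), end = integer()), L)
  expect_equal(unlist(none[c("tp", "fp", "tn", "fn")]),
               c(tp = 0L, fp = 0L, tn = 26L, fn = 6L))

  expect_error(residue_confusion(data.frame(start = 1L, end = 40L),
                                 calcitonin$predicted, L), "out of bounds")
})

test_that("metrics reproduce the worked example to three decimals", {
  m <- compute_metrics(residue_confusion(calcitonin$truth,
                                         calcitonin$predicted, 32L))
  expect_equal(m$acc, 25 / 32)          # 0.78125 -> 0.781
  expect_equal(round(m$acc, 3), 0.781)
  expect_equal(m$se, 1.0)
  expect_equal(round(m$sp, 3), 0.731)
  expect_equal(round(m$q, 3), 0.865)

  none <- compute_metrics(residue_confusion(
    calcitonin$truth, data.frame(start = integer(), end = integer()), 32L))
  expect_equal(round_half_up(none$acc, 3), 0.813)
  expect_equal(none$q, 0.5)

  perfect <- compute_metrics(confusion_counts(rep(c(1, 0), each = 10),
                                              rep(c(1, 0), each = 10)))
  expect_equal(unlist(perfect), c(acc = 1, se = 1, sp = 1, q = 1, mcc = 1))
})

test_that("MCC falls back to 0 on zero denominator factors", {
  all_pos_pred <- compute_metrics(confusion_counts(c(1, 0, 0), c(1, 1, 1)))
  expect_equal(all_pos_pred$mcc, 0)
  expect_error(compute_metrics(confusion_counts(logical(0), logical(0))),
               "empty")
})

test_that("Q is the mean of SE and SP on random confusion tables", {
  set.seed(23)
  for (i in 1:200) {
    truth <- rbinom(40, 1, 0.3)
    pred <- rbinom(40, 1, 0.5)
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(confusion_counts(truth, pred))
    expect_equal(m$q, (m$se + m$sp) / 2)
    # accuracy is the class-size weighted mix of SE and SP
    n1 <- sum(truth); n0 <- sum(1 - truth)
    expect_equal(m$acc, (n1 * m$se + n0 * m$sp) / (n1 + n0))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("AUC matches the pairwise-comparison statistic", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # brute-force pairwise oracle on random instances, including ties
  set.seed(29)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under monotone transforms and near 0.5 under
           independence", {
  set.seed(31)
  labels <- rbinom(1000, 1, 0.4)
  scores <- runif(1000)
  a <- roc_auc(scores, labels)$auc
  expect_lt(abs(a - 0.5), 0.05)
  expect_equal(roc_auc(qlogis(scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3, labels)$auc, a, tolerance = 1e-12)
  pts <- roc_auc(scores, labels)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(pts$tpr >= 0 & pts$tpr <= 1))
})

test_that("Friedman statistic matches the textbook formula", {
  # hand-built untied ranks: 3 methods x 5 items
  ranks <- rbind(a = c(1, 1, 2, 1, 1),
                 b = c(2, 3, 1, 2, 2),
                 c = c(3, 2, 3, 3, 3))
  res <- friedman_nemenyi(ranks, alpha = 0.1)
  expect_equal(res$statistic, oracle_friedman(ranks), tolerance = 1e-12)
  expect_true(res$rejected)
  expect_equal(names(res$mean_ranks)[1], "a")
  # the clearly separated pair is flagged, at the documented CD
  cd <- stats::qtukey(0.9, 3, Inf) / sqrt(2) * sqrt(3 * 4 / (6 * 5))
  expect_equal(res$cd, cd)
  pair_ac <- res$pairs[res$pairs$method_a == "a" & res$pairs$method_b == "c", ]
  expect_true(pair_ac$significant)
})

test_that("identical method performance yields no rejection", {
  ranks <- matrix(1.5, nrow = 4, ncol = 6,
                  dimnames = list(paste0("m", 1:4), NULL))
  res <- friedman_nemenyi(ranks)
  expect_equal(res$statistic, 0)
  expect_false(res$rejected)
  expect_equal(nrow(res$pairs), 0L)
})

test_that("the Nemenyi critical difference shrinks as 1/sqrt(n)", {
  cds <- vapply(c(5, 10, 20, 40), function(n) {
    ranks <- rbind(a = rep(1, n), b = rep(2, n), c = rep(3, n))
    friedman_nemenyi(ranks)$cd
  }, numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_equal(cds[1] / cds[3], 2, tolerance = 1e-9)
})

test_that("pooled region evaluation sums counts across proteins", {
  truths <- list(p1 = data.frame(start = 15L, end = 20L),
                 p2 = data.frame(start = 1L, end = 6L))
  mk <- function(id, L, on) {
    mask <- rep(FALSE, L); mask[on] <- TRUE
    structure(list(protein_id = id, sequence = strrep("A", L), mask = mask,
                   residue_score = as.numeric(mask),
                   regions = mask_to_regions(mask)),
              class = "region_prediction")
  }
  preds <- list(p1 = mk("p1", 32L, 11:23), p2 = mk("p2", 20L, integer(0)))
  ev <- evaluate_regions(truths, preds)
  expect_equal(ev$counts$tp, 6L)
  expect_equal(ev$counts$fp, 7L)
  expect_equal(ev$counts$fn, 6L)
  expect_equal(ev$counts$tn, 19L + 14L)
  expect_error(evaluate_regions(truths["p1"], preds), "no annotation")
})
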