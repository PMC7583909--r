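test_that("negative sampling honors the ratio and never hits positives", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  neg <- sample_negatives(fx$lncs, fx$mirs, fx$positives, beta = 1, seed = 11)
  expect_equal(nrow(neg), 100L)
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$source == "sampled"))
  key <- function(p) paste(p$lnc_id, p$mir_id)
  expect_length(intersect(key(neg), key(fx$positives)), 0L)
  expect_equal(anyDuplicated(key(neg)), 0L)

  expect_equal(nrow(sample_negatives(fx$lncs, fx$mirs, fx$positives,
                                     beta = 0.25, seed = 11)), 25L)
  # determinism
  neg2 <- sample_negatives(fx$lncs, fx$mirs, fx$positives, beta = 1, seed = 11)
  expect_identical(neg, neg2)
})

test_that("infeasible negative sampling fails before drawing", {
  lncs <- rna_records(c("l1", "l2"), rep(strrep("ACGT", 60), 2), "lncRNA")
  mirs <- rna_records(c("m1", "m2"), rep("ACGTACGTACGTACGTACGTA", 2), "miRNA")
  all_pos <- expand.grid(lnc_id = lncs$id, mir_id = mirs$id,
                         stringsAsFactors = FALSE)
  expect_error(sample_negatives(lncs, mirs, all_pos, beta = 1, seed = 1),
               "infeasible")
})

test_that("fold assignment partitions with near-equal, stratified sizes", {
  fx <- generate_fixture(fixture_spec(seed = 4))
  neg <- sample_negatives(fx$lncs, fx$mirs, fx$positives, beta = 1, seed = 2)
  pairs <- rbind(fx$positives, neg)
  fold <- kfold_split(pairs, k = 5, seed = 9)
  expect_equal(as.vector(table(fold)), rep(40L, 5))
  pos_frac <- tapply(pairs$label, fold, mean)
  expect_true(all(abs(pos_frac - 0.5) <= 1 / 40))

  # remainder rule: 101 pairs over 5 folds -> sizes 21, 20, 20, 20, 20
  fold2 <- kfold_split(pairs[1:101, ], k = 5, seed = 9)
  expect_equal(sort(as.vector(table(fold2)), decreasing = TRUE),
               c(21L, 20L, 20L, 20L, 20L))
  expect_identical(fold, kfold_split(pairs, k = 5, seed = 9))
  expect_error(kfold_split(pairs[1:3, ], k = 5), "cannot split")
})

test_that("confusion metrics match their closed forms", {
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(perfect), c(SN = 1, SP = 1, ACC = 1, F1 = 1, MCC = 1))

  sym <- confusion_metrics(1, 1, 1, 1)
  expect_equal(sym$F1, 0.5)
  expect_equal(sym$MCC, 0)

  m <- confusion_metrics(50, 10, 40, 5)
  expect_equal(m$SN, 50 / 55)
  expect_equal(m$SP, 40 / 50)
  expect_equal(m$ACC, 90 / 105)
  expect_equal(m$F1, 100 / 115)
  # MCC closed form cross-checked against the Pearson correlation of the
  # reconstructed binary prediction/truth vectors
  truth <- rep(c(1, 1, 0, 0), c(50, 5, 10, 40))
  pred <- rep(c(1, 0, 1, 0), c(50, 5, 10, 40))
  expect_equal(m$MCC, unname(cor(pred, truth)))

  und <- confusion_metrics(0, 0, 5, 0)
  expect_true(is.na(und$SN))
  expect_true(is.na(und$MCC))
  expect_equal(und$SP, 1)
})

test_that("MCC equals the Pearson correlation on random confusion tables", {
  set.seed(13)
  for (i in 1:100) {
    counts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    m <- confusion_metrics(tp, fp, tn, fn)
    truth <- rep(c(1, 1, 0, 0), c(tp, fn, fp, tn))
    pred <- rep(c(1, 0, 1, 0), c(tp, fn, fp, tn))
    r <- suppressWarnings(cor(pred, truth))
    if (is.na(r)) expect_true(is.na(m$MCC)) else expect_equal(m$MCC, unname(r))
  }
})

test_that("rank-based AUC handles separation, ties, and matches pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  # label permutation at n = 1000 stays near 1/2
  set.seed(21)
  scores <- runif(1000); labels <- sample(rep(0:1, 500))
  expect_true(abs(roc_auc(scores, labels) - 0.5) < 0.05)

  # independent implementation agreement (with ties present)
  set.seed(22)
  s2 <- round(runif(200), 2); y2 <- rbinom(200, 1, 0.4)
  expect_equal(roc_auc(s2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              direction = "<"))))

  pts <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(tail(pts$tpr, 1), 1)
})

test_that("cross-validation produces a complete, reproducible report", {
  fx <- generate_fixture(fixture_spec(n_lnc = 10, n_mir = 6, n_pos = 16,
                                      seed = 5))
  rep1 <- suppressWarnings(run_cv(
    fx$lncs, fx$mirs, fx$positives, beta = 1, k = 2, cnn = fast_cnn(epochs = 2),
    d2v_epochs = 2, encoder = fast_encoder_opts, seed = 4))
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$per_fold), 2L)
  expect_named(rep1$per_fold, c("fold", "SN", "SP", "ACC", "F1", "MCC", "AUC"))
  expect_length(rep1$mean, 6L)
  expect_length(rep1$roc, 2L)
  # fold column is a partition of all pairs
  expect_equal(nrow(rep1$pairs), 32L)
  expect_setequal(unique(rep1$pairs$fold), 0:1)
  # sampled negatives never intersect the positives
  key <- function(p) paste(p$lnc_id, p$mir_id)
  expect_length(intersect(key(rep1$pairs[rep1$pairs$source == "sampled", ]),
                          key(fx$positives)), 0L)
  # determinism of the full pipeline
  rep2 <- suppressWarnings(run_cv(
    fx$lncs, fx$mirs, fx$positives, beta = 1, k = 2, cnn = fast_cnn(epochs = 2),
    d2v_epochs = 2, encoder = fast_encoder_opts, seed = 4))
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_identical(rep1$pairs, rep2$pairs)
})
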