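# In-place Fisher-Yates (Knuth-Durstenfeld variant): walk from the end,
# swapping each element with a uniformly chosen earlier-or-equal position.
fisher_yates <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  for (i in n:2) {
    j <- sample.int(i, 1L)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

#' Sample non-interacting lncRNA-miRNA pairs
#'
#' Builds the negative class: both identifier lists are shuffled 10 times
#' with the Knuth-Durstenfeld variant of Fisher-Yates, then candidate pairs
#' are drawn by picking one id from each list uniformly at random, accepting a
#' pair only if it is neither a known positive nor an already accepted
#' negative, until `round(beta * n_positives)` negatives are collected.
#' Deterministic for a fixed seed.
#'
#' @param lncs,mirs Record data frames (only the `id` columns are used).
#' @param positives Pair data frame with columns `lnc_id`, `mir_id`.
#' @param beta Ratio of negatives to positives (default 1).
#' @param seed Integer seed.
#' @param max_draws Rejection-loop cap (default 1e7 draws).
#' @return Data frame with columns `lnc_id`, `mir_id`, `label` (0), `source`
#'   (`"sampled"`).
#' @export
sample_negatives <- function(lncs, mirs, positives, beta = 1, seed = 1L,
                             max_draws = 1e7) {
  lnc_ids <- lncs$id %||% as.character(lncs)
  mir_ids <- mirs$id %||% as.character(mirs)
  n_pos <- nrow(positives)
  n_neg <- round(beta * n_pos)
  universe <- length(lnc_ids) * length(mir_ids)
  if (n_neg > universe - n_pos)
    stop_input("infeasible beta: need %d negatives but only %d non-positive pairs exist",
               n_neg, universe - n_pos)
  if (n_neg == 0L)
    return(data.frame(lnc_id = character(), mir_id = character(),
                      label = integer(), source = character()))
  pos_key <- paste(positives$lnc_id, positives$mir_id, sep = "\r")
  with_seed(seed, {
    for (r in 1:10) lnc_ids <- fisher_yates(lnc_ids)
    for (r in 1:10) mir_ids <- fisher_yates(mir_ids)
    seen <- new.env(parent = emptyenv(), size = n_pos + n_neg)
    for (k in pos_key) assign(k, TRUE, envir = seen)
    out_l <- character(n_neg); out_m <- character(n_neg)
    got <- 0L; draws <- 0
    while (got < n_neg) {
      draws <- draws + 1
      if (draws > max_draws)
        stop_input("rejection sampling exceeded %g draws", max_draws)
      l <- lnc_ids[sample.int(length(lnc_ids), 1L)]
      m <- mir_ids[sample.int(length(mir_ids), 1L)]
      key <- paste(l, m, sep = "\r")
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        got <- got + 1L
        out_l[got] <- l; out_m[got] <- m
      }
    }
    data.frame(lnc_id = out_l, mir_id = out_m, label = 0L,
               source = "sampled", stringsAsFactors = FALSE)
  })
}

#' Stratified k-fold assignment
#'
#' Partitions pairs into `k` folds whose sizes differ by at most one, keeping
#' each fold's positive fraction within one pair of the global fraction
#' (label-stratified; set `stratify = FALSE` for a plain random split).
#' Deterministic per seed.
#'
#' @param pairs Pair data frame with a `label` column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratify Stratify by label (default TRUE).
#' @return Integer vector of fold indices in `0:(k-1)`, one per pair.
#' @export
kfold_split <- function(pairs, k = 5L, seed = 1L, stratify = TRUE) {
  n <- nrow(pairs)
  k <- as.integer(k)
  if (n < k) stop_input("cannot split %d pairs into %d folds", n, k)
  with_seed(seed, {
    fold <- integer(n)
    groups <- if (stratify) split(seq_len(n), pairs$label) else list(seq_len(n))
    offset <- 0L
    for (g in groups) {
      g <- g[sample.int(length(g))]
      fold[g] <- (offset + seq_along(g) - 1L) %% k
      offset <- (offset + length(g)) %% k
    }
    fold
  })
}

#' Confusion-table metrics
#'
#' Computes sensitivity, specificity, accuracy, F1 and the Matthews
#' correlation coefficient from confusion counts:
#' `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `ACC = (TP+TN)/total`,
#' `F1 = 2TP/(2TP+FP+FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Named list with `SN`, `SP`, `ACC`, `F1`, `MCC`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  list(SN = div(tp, tp + fn),
       SP = div(tn, tn + fp),
       ACC = div(tp + tn, tp + tn + fp + fn),
       F1 = div(2 * tp, 2 * tp + fp + fn),
       MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for tied scores: the
#' probability that a uniformly chosen positive scores above a uniformly
#' chosen negative, counting ties as 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_input("AUC needs both classes (got %d positives, %d negatives)",
               n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame of `(fpr, tpr)` points over all score thresholds.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / max(sum(labels == 0L), 1L)),
             tpr = c(0, tp[keep] / max(sum(labels == 1L), 1L)))
}

#' Cross-validated evaluation of the full pipeline
#'
#' Samples negatives once globally, assigns stratified folds, and for each
#' fold trains the entire pipeline on the remaining folds and evaluates on
#' the held-out fold. The doc2vec embedder and the similarity graphs are
#' fitted on the RNAs that occur in training-fold pairs only; held-out RNAs
#' are encoded by doc2vec inference and role-based graph-embedding lookup, so
#' no test-fold information reaches any fitted component.
#'
#' @param lncs,mirs Record data frames.
#' @param positives Positive pair data frame (`lnc_id`, `mir_id`).
#' @param features Feature categories used as tensor channels, a subset of
#'   `c("kmer", "ctd", "doc2vec", "graph")`.
#' @param beta Negative/positive ratio (default 1).
#' @param k Number of folds (default 5).
#' @param bins Histogram grid resolution (default 20).
#' @param cnn Classifier settings, a [cnn_config()].
#' @param d2v_epochs doc2vec training epochs (default 40).
#' @param encoder Optional named list of extra [fit_feature_model()]
#'   arguments (e.g. `n_walks`, `walk_len`, `r2v_epochs`) for scaling the
#'   encoders to the problem size.
#' @param seed Integer seed driving sampling, folds and training.
#' @param shuffle_labels Permute the pair labels before splitting (negative
#'   control; the planted structure is destroyed but class balance kept).
#' @param verbose Print per-fold progress.
#' @return A list of class `cv_report`: `per_fold` (metrics + AUC per fold),
#'   `mean` and `sd` across folds, `roc` (list of per-fold ROC point data
#'   frames), `pairs` (with fold assignment), and the call settings.
#' @export
run_cv <- function(lncs, mirs, positives,
                   features = c("kmer", "ctd", "doc2vec", "graph"),
                   beta = 1, k = 5L, bins = 20L, cnn = cnn_config(),
                   d2v_epochs = 40L, encoder = list(), seed = 1L,
                   shuffle_labels = FALSE, verbose = FALSE) {
  features <- match.arg(features, several.ok = TRUE)
  negatives <- sample_negatives(lncs, mirs, positives, beta = beta,
                                seed = derive_seed(seed, 21L))
  pos <- positives
  pos$label <- 1L
  pos$source <- pos$source %||% "curated"
  pairs <- rbind(pos[, c("lnc_id", "mir_id", "label", "source")],
                 negatives[, c("lnc_id", "mir_id", "label", "source")])
  if (shuffle_labels)
    pairs$label <- with_seed(derive_seed(seed, 22L), sample(pairs$label))
  pairs$fold <- kfold_split(pairs, k = k, seed = derive_seed(seed, 23L))

  per_fold <- NULL
  roc_list <- vector("list", k)
  for (f in 0:(k - 1L)) {
    train <- pairs[pairs$fold != f, ]
    test <- pairs[pairs$fold == f, ]
    fit <- fit_fold(lncs, mirs, train, features, bins, cnn, d2v_epochs,
                    encoder = encoder, seed = derive_seed(seed, 31L + f))
    pred <- predict_pairs(fit, test)
    m <- confusion_metrics(tp = sum(pred$call & test$label == 1L),
                           fp = sum(pred$call & test$label == 0L),
                           tn = sum(!pred$call & test$label == 0L),
                           fn = sum(!pred$call & test$label == 1L))
    auc <- roc_auc(pred$probability, test$label)
    roc_list[[f + 1L]] <- roc_points(pred$probability, test$label)
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, SN = m$SN, SP = m$SP, ACC = m$ACC,
                                 F1 = m$F1, MCC = m$MCC, AUC = auc))
    if (verbose)
      message(sprintf("fold %d: ACC %.3f AUC %.3f", f, m$ACC, auc))
  }
  metrics_cols <- c("SN", "SP", "ACC", "F1", "MCC", "AUC")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metrics_cols], na.rm = TRUE),
                 sd = apply(per_fold[metrics_cols], 2L, stats::sd, na.rm = TRUE),
                 roc = roc_list, pairs = pairs, features = features,
                 beta = beta, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (features: %s, beta = %g)\n",
              x$k, paste(x$features, collapse = "+"), x$beta))
  print(round(x$per_fold, 4))
  cat("mean:\n"); print(round(x$mean, 4))
  invisible(x)
}

# Fit encoders + classifier on one training set of pairs; returns everything
# needed to score new pairs over the same record universe.
fit_fold <- function(lncs, mirs, train_pairs, features, bins, cnn_cfg,
                     d2v_epochs, encoder = list(), seed) {
  train_l <- lncs[lncs$id %in% train_pairs$lnc_id, , drop = FALSE]
  train_m <- mirs[mirs$id %in% train_pairs$mir_id, , drop = FALSE]
  fm_l <- do.call(fit_feature_model, c(
    list(train_l, features = features, d2v_epochs = d2v_epochs,
         seed = derive_seed(seed, 1L)), encoder))
  fm_m <- do.call(fit_feature_model, c(
    list(train_m, features = features, d2v_epochs = d2v_epochs,
         seed = derive_seed(seed, 2L)), encoder))
  tensor_cache <- new.env(parent = emptyenv())
  get_tensor <- function(id, kind) {
    key <- paste(kind, id, sep = "\r")
    if (is.null(tensor_cache[[key]])) {
      recs <- if (kind == "lncRNA") lncs else mirs
      fm <- if (kind == "lncRNA") fm_l else fm_m
      rec <- recs[recs$id == id, , drop = FALSE]
      if (nrow(rec) == 0L) stop_input("unknown %s id %s", kind, id)
      tensor_cache[[key]] <- fuse_histogram(encode_rna(rec, fm), bins = bins,
                                            channels = features)
    }
    tensor_cache[[key]]
  }
  xl <- stack_tensors(lapply(train_pairs$lnc_id, get_tensor, kind = "lncRNA"))
  xm <- stack_tensors(lapply(train_pairs$mir_id, get_tensor, kind = "miRNA"))
  cfg <- cnn_cfg
  cfg$seed <- derive_seed(seed, 3L)
  model <- build_cnn(input_shape = dim(xl)[1:3], config = cfg)
  model <- train_cnn(model, xl, xm, train_pairs$label)
  list(model = model, get_tensor = get_tensor,
       feature_model_lnc = fm_l, feature_model_mir = fm_m, bins = bins,
       features = features)
}

# Score a pair table with a fitted fold.
predict_pairs <- function(fit, pairs) {
  xl <- stack_tensors(lapply(pairs$lnc_id, fit$get_tensor, kind = "lncRNA"))
  xm <- stack_tensors(lapply(pairs$mir_id, fit$get_tensor, kind = "miRNA"))
  predict(fit$model, xl, xm, ids = pairs[, c("lnc_id", "mir_id")])
}
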