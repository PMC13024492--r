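#' @include models.R
NULL

#' Assign train/val/test splits to labels
#'
#' With \code{stratified = TRUE} each class is partitioned separately.
#' Validation and test counts are the rounded fractions of the class (or
#' total) size; the remainder goes to training. Assignment is a pure
#' function of the labels, fractions and seed.
#'
#' @param labels vector of class labels.
#' @param fractions numeric c(train, val, test), positive, summing to 1.
#' @param stratified logical, default TRUE.
#' @param seed RNG seed.
#' @return character vector of "train"/"val"/"test" along \code{labels}.
#' @examples
#' table(assignSplits(rep(0:9, each = 100), seed = 1))
#' @export
assignSplits <- function(labels, fractions = c(0.6, 0.2, 0.2),
                         stratified = TRUE, seed = 1) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three positive numbers summing to 1")
  }
  split <- character(length(labels))
  assign_group <- function(idx) {
    n <- length(idx)
    n_val <- round(fractions[2] * n)
    n_test <- round(fractions[3] * n)
    if (n_val + n_test >= n) stop("group too small for the requested fractions")
    idx <- idx[sample.int(n)]
    out <- rep("train", n)
    out[seq_len(n_val)] <- "val"
    out[n_val + seq_len(n_test)] <- "test"
    split[idx] <<- out
    invisible(NULL)
  }
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(labels)) assign_group(which(labels == cl))
    } else {
      assign_group(seq_along(labels))
    }
  })
  split
}

#' Split a dataset into train/val/test
#'
#' @param ds an \linkS4class{AcousticDataset}.
#' @inheritParams assignSplits
#' @return the dataset with its \code{split} column filled in.
#' @export
splitDataset <- function(ds, fractions = c(0.6, 0.2, 0.2), stratified = TRUE,
                         seed = 1) {
  SummarizedExperiment::colData(ds)$split <-
    assignSplits(massLabels(ds), fractions, stratified, seed)
  validObject(ds)
  ds
}

#' Featurise a dataset for one architecture
#'
#' Produces the input tensor each classifier consumes:
#' \describe{
#'   \item{cnn}{array (N, B, 2): the raw + spectrum dual channel (batch in
#'     the middle, matching the conv engine's layout).}
#'   \item{lstm}{array (steps, 2*frame, B): the dual channel cut into
#'     consecutive frames of \code{frame} samples; each timestep carries the
#'     raw frame and the matching spectrum-channel frame.}
#'   \item{transformer}{array (n_patches, T, B): standardized raw waveform
#'     patches (single channel).}
#' }
#' Labels are returned as 1-based integers over the sorted class set.
#'
#' @param ds an \linkS4class{AcousticDataset}.
#' @param arch "cnn", "lstm" or "transformer".
#' @param subset optional: "train", "val" or "test" to featurise one split.
#' @param frame LSTM frame length (samples per timestep).
#' @param T,stride transformer patch length and hop.
#' @return list(x = array, y = integer labels, classes = sorted class set).
#' @export
featurizeDataset <- function(ds, arch = c("cnn", "lstm", "transformer"),
                             subset = NULL, frame = 48L, T = 48L,
                             stride = T) {
  arch <- match.arg(arch)
  keep <- if (is.null(subset)) seq_len(ncol(ds)) else which(splitOf(ds) == subset)
  if (length(keep) == 0L) stop("no segments in the requested subset")
  wav <- SummarizedExperiment::assay(ds, "waveform")
  fs <- samplingRate(ds)
  labels <- massLabels(ds)[keep]
  classes <- sort(unique(massLabels(ds)))
  y <- match(labels, classes)
  n <- nrow(wav)
  B <- length(keep)
  if (arch == "cnn") {
    x <- array(0, dim = c(n, B, 2L))
    for (j in seq_len(B)) x[, j, ] <- dualChannelInput(wav[, keep[j]], fs = fs)
  } else if (arch == "lstm") {
    if (n %% frame != 0L) stop("frame must divide the segment length")
    steps <- n %/% frame
    x <- array(0, dim = c(steps, 2L * frame, B))
    for (j in seq_len(B)) {
      dc <- dualChannelInput(wav[, keep[j]], fs = fs)
      x[, , j] <- cbind(t(matrix(dc[, 1], nrow = frame)),
                        t(matrix(dc[, 2], nrow = frame)))
    }
  } else {
    ps1 <- patchify(wav[, keep[1]], T = T, stride = stride)
    x <- array(0, dim = c(ps1$n_patches, T, B))
    x[, , 1] <- ps1$patches
    for (j in seq_len(B)[-1]) {
      x[, , j] <- patchify(wav[, keep[j]], T = T, stride = stride)$patches
    }
  }
  list(x = x, y = y, classes = classes)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs (0 returns the initial model).
#' @param patience early-stopping patience on validation accuracy.
#' @param seed seed for batch order, dropout and any other training
#'   randomness.
#' @return a list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learning_rate = 1e-3, batch_size = 64L,
                        max_epochs = 50L, patience = 10L, seed = 1L) {
  stopifnot(max_epochs >= 0L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "TrainConfig")
}

.accuracy_of <- function(probs, y) mean(max.col(probs, ties.method = "first") == y)

#' Train a classifier
#'
#' Minibatch Adam on the cross-entropy objective. After each epoch the
#' validation accuracy is recorded; the returned model carries the
#' parameters of the best-validation epoch and the full per-epoch history
#' (train/val loss and accuracy) in \code{model@meta$history}. Training
#' stops early when validation accuracy has not improved for
#' \code{patience} epochs. Fully seeded: identical data, model seed and
#' train config reproduce the history.
#'
#' @param model an untrained \linkS4class{ClassifierModel}.
#' @param x,y featurised training inputs and 1-based labels
#'   (\code{\link{featurizeDataset}}).
#' @param x_val,y_val optional validation split.
#' @param cfg a \code{\link{trainConfig}}.
#' @param verbose print per-epoch progress.
#' @return the trained \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(model, x, y, x_val = NULL, y_val = NULL,
                            cfg = trainConfig(), verbose = FALSE) {
  if (.batch_count(model@arch, x) == 0L || length(y) == 0L) {
    stop("empty training split")
  }
  if (cfg$max_epochs == 0L) {
    model@meta$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                     train_accuracy = numeric(),
                                     val_loss = numeric(),
                                     val_accuracy = numeric())
    return(model)
  }
  layers <- model@layers
  state <- adam_init(layers)
  n <- .batch_count(model@arch, x)
  has_val <- !is.null(x_val)
  best_metric <- -Inf
  best_layers <- layers
  hist <- vector("list", cfg$max_epochs)
  step <- 0L
  stall <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_acc <- 0; n_seen <- 0L
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- .batch_slice(model@arch, x, idx)
        mdl_tmp <- model; mdl_tmp@layers <- layers
        fw <- model_forward(mdl_tmp, xb, training = TRUE)
        layers <- fw$layers
        loss <- ce_loss(fw$out, y[idx])
        if (!is.finite(loss$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        grads <- nn_backward(layers, fw$caches, loss$grad)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, cfg$learning_rate, step)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + loss$loss * length(idx)
        ep_acc <- ep_acc + sum(max.col(loss$probs, ties.method = "first") == y[idx])
        n_seen <- n_seen + length(idx)
      }
      mdl_tmp <- model; mdl_tmp@layers <- layers
      if (has_val) {
        vp <- predictProb(mdl_tmp, x_val)
        vl <- ce_loss(log(pmax(vp, 1e-12)), y_val)$loss
        va <- .accuracy_of(vp, y_val)
      } else {
        vl <- NA_real_; va <- NA_real_
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n_seen,
                                  train_accuracy = ep_acc / n_seen,
                                  val_loss = vl, val_accuracy = va)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.4f val_acc %s", epoch,
                        ep_loss / n_seen, ep_acc / n_seen, format(va)))
      }
      metric <- if (has_val) va else ep_acc / n_seen
      if (metric > best_metric + 1e-12) {
        best_metric <- metric
        best_layers <- layers
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model@layers <- best_layers
  model@meta$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model@meta$train_config <- cfg
  model
}

#' Build a confusion matrix from labels
#'
#' @param truth,pred vectors of class labels (same label set).
#' @param class_labels ordered class set; defaults to the sorted union.
#' @return a \linkS4class{ConfusionMatrix} (rows true, columns predicted).
#' @export
confusionMatrix <- function(truth, pred,
                            class_labels = sort(unique(c(truth, pred)))) {
  counts <- table(factor(truth, levels = class_labels),
                  factor(pred, levels = class_labels))
  new("ConfusionMatrix",
      counts = matrix(as.integer(counts), nrow = length(class_labels),
                      dimnames = list(true = as.character(class_labels),
                                      predicted = as.character(class_labels))),
      class_labels = as.numeric(class_labels))
}

#' Evaluate a classifier on a test split
#'
#' Predictions are the argmax of the class-probability output; the counts
#' of the returned matrix sum to the number of test segments.
#'
#' @param model a trained \linkS4class{ClassifierModel}.
#' @param x,y featurised inputs and 1-based integer labels.
#' @param classes class label set (ug), in the order used for \code{y}.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
evaluateClassifier <- function(model, x, y, classes = seq_len(model@config@n_classes) - 1) {
  pred <- predictClass(model, x)
  confusionMatrix(classes[y], classes[pred], class_labels = classes)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is trace/total; macro-recall is the unweighted mean of
#' per-class recalls (identical to accuracy when the class counts are
#' exactly balanced); macro-F1 is the unweighted mean of per-class
#' harmonic means of precision and recall. Classes absent from the test
#' set (empty rows) are excluded from the macro averages with a warning
#' and flagged in the result.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return list with \code{accuracy}, \code{macro_recall}, \code{macro_f1},
#'   \code{per_class_recall}, \code{n}, \code{n_misclassified},
#'   \code{excluded_classes}.
#' @examples
#' cm <- confusionMatrix(rep(0:1, each = 5), c(rep(0, 5), rep(1, 4), 0))
#' classifierMetrics(cm)$accuracy
#' @export
classifierMetrics <- function(cm) {
  counts <- cm@counts
  total <- sum(counts)
  if (total <= 0) stop("confusion matrix is empty")
  tp <- diag(counts)
  row_sums <- rowSums(counts)
  col_sums <- colSums(counts)
  empty <- row_sums == 0
  if (any(empty)) {
    warning("recall undefined for class(es) with no test samples: ",
            paste(cm@class_labels[empty], collapse = ", "),
            "; excluded from macro averages")
  }
  recall <- ifelse(row_sums > 0, tp / row_sums, NA_real_)
  precision <- ifelse(col_sums > 0, tp / col_sums, 0)
  f1 <- ifelse(!is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(recall), NA_real_, 0))
  list(accuracy = sum(tp) / total,
       macro_recall = mean(recall[!empty]),
       macro_f1 = mean(f1[!empty]),
       per_class_recall = stats::setNames(recall, as.character(cm@class_labels)),
       n = total,
       n_misclassified = total - sum(tp),
       excluded_classes = cm@class_labels[empty])
}

#' Architecture sweep
#'
#' Re-trains one architecture family across a grid of its sweep axis
#' (feature blocks for the CNN, memory blocks for the LSTM, encoder depth
#' for the transformer), with \code{n_reps} seeded repetitions per value,
#' and reports mean and standard deviation of test accuracy. Failed runs
#' are recorded in the \code{n_failed} column, never silently dropped.
#'
#' @param arch "cnn", "lstm" or "transformer".
#' @param values integer vector of sweep-axis values.
#' @param feats_train,feats_val,feats_test featurised splits as returned by
#'   \code{\link{featurizeDataset}}.
#' @param cfg a \code{\link{trainConfig}}; rep r uses seed
#'   \code{cfg$seed + r - 1} for both initialisation and training.
#' @param n_reps repetitions per value.
#' @param ... extra arguments to the model builder (e.g. input channel
#'   overrides via \code{input_shape}).
#' @return data.frame(value, mean_accuracy, sd_accuracy, n_reps, n_failed).
#' @export
sweepArchitecture <- function(arch = c("cnn", "lstm", "transformer"), values,
                              feats_train, feats_val, feats_test,
                              cfg = trainConfig(), n_reps = 1L, ...) {
  arch <- match.arg(arch)
  if (length(values) == 0L) stop("values must be nonempty")
  shape <- if (arch == "cnn") dim(feats_train$x)[c(1, 3)]
           else dim(feats_train$x)[1:2]
  n_classes <- length(feats_train$classes)
  rows <- lapply(values, function(v) {
    accs <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      res <- tryCatch({
        sd_r <- cfg$seed + r - 1L
        model <- switch(arch,
          cnn = buildCNN(cnnConfig(n_blocks = v, n_classes = n_classes, ...),
                         input_shape = shape, seed = sd_r),
          lstm = buildLSTM(lstmConfig(n_units = v, n_classes = n_classes, ...),
                           input_shape = shape, seed = sd_r),
          transformer = buildTransformer(
            transformerConfig(L = v, T = shape[2], n_classes = n_classes, ...),
            input_shape = shape, seed = sd_r))
        cfg_r <- cfg; cfg_r$seed <- sd_r
        model <- trainClassifier(model, feats_train$x, feats_train$y,
                                 feats_val$x, feats_val$y, cfg_r)
        cm <- evaluateClassifier(model, feats_test$x, feats_test$y,
                                 classes = feats_train$classes)
        classifierMetrics(cm)$accuracy
      }, error = function(e) {
        warning(sprintf("sweep run failed (%s = %s, rep %d): %s", arch, v, r,
                        conditionMessage(e)))
        NA_real_
      })
      accs[r] <- res
    }
    ok <- accs[!is.na(accs)]
    data.frame(value = v,
               mean_accuracy = if (length(ok)) mean(ok) else NA_real_,
               sd_accuracy = if (length(ok) > 1) stats::sd(ok) else NA_real_,
               n_reps = n_reps, n_failed = sum(is.na(accs)))
  })
  do.call(rbind, rows)
}
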