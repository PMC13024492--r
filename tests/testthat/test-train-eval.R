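# Splitting, training loop contract, metrics, sweeps.

test_that("stratified splitting reproduces the 60/20/20 counts", {
  labels <- rep(0:9, each = 2500)
  sp <- assignSplits(labels, seed = 3)
  expect_equal(as.vector(table(sp)[c("train", "val", "test")]),
               c(15000L, 5000L, 5000L))
  # 500 per class in the test split
  expect_equal(as.vector(table(labels[sp == "test"])), rep(500L, 10))
  expect_identical(sp, assignSplits(labels, seed = 3))
  expect_false(identical(sp, assignSplits(labels, seed = 4)))
  expect_error(assignSplits(labels, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("splitDataset stamps a valid split column", {
  ds <- buildDataset(pvdfSpec(), classes = 0:4, n_per_class = 10, seed = 2)
  ds <- splitDataset(ds, seed = 2)
  expect_equal(as.vector(table(splitOf(ds))[c("train", "val", "test")]),
               c(30L, 10L, 10L))
  per_class <- table(massLabels(ds)[splitOf(ds) == "test"])
  expect_true(all(per_class == 2L))
})

test_that("featurisation produces the documented tensor shapes", {
  ds <- splitDataset(buildDataset(pvdfSpec(), classes = c(0, 5),
                                  n_per_class = 5, seed = 3), seed = 3)
  f_cnn <- featurizeDataset(ds, "cnn")
  expect_equal(dim(f_cnn$x), c(4800L, 10L, 2L))
  f_lstm <- featurizeDataset(ds, "lstm", frame = 48L)
  expect_equal(dim(f_lstm$x), c(100L, 96L, 10L))
  f_tr <- featurizeDataset(ds, "transformer", T = 48L)
  expect_equal(dim(f_tr$x), c(100L, 48L, 10L))
  expect_equal(f_cnn$classes, c(0, 5))
  expect_true(all(f_cnn$y %in% 1:2))
  f_sub <- featurizeDataset(ds, "cnn", subset = "test")
  expect_equal(dim(f_sub$x)[2], 2L)
})

test_that("max_epochs = 0 returns the initial model unchanged", {
  toy <- two_tone_toy(10L)
  x <- featurize_matrix(toy$wav, toy$fs, "lstm")
  m0 <- buildLSTM(lstmConfig(n_units = 8L, n_classes = 2L),
                  input_shape = dim(x)[1:2], seed = 1)
  m <- trainClassifier(m0, x, toy$y, cfg = trainConfig(max_epochs = 0))
  expect_identical(m@layers, m0@layers)
  expect_equal(nrow(m@meta$history), 0L)
})

test_that("a small CNN separates the two-tone toy problem", {
  toy <- two_tone_toy(75L) # 100 train / 50 val after the split below
  sp <- assignSplits(toy$y, fractions = c(2 / 3, 1 / 3 - 1e-9, 1e-9),
                     seed = 1)
  sp[sp == "test"] <- "val"
  x <- featurize_matrix(toy$wav, toy$fs, "cnn")
  tr <- which(sp == "train"); va <- which(sp == "val")
  m <- buildCNN(cnnConfig(n_blocks = 2L, kernel_size = 5L,
                          base_channels = 4L, pool_size = 4L,
                          n_classes = 2L),
                input_shape = c(4800L, 2L), seed = 1)
  m <- trainClassifier(m, x[, tr, , drop = FALSE], toy$y[tr],
                       x[, va, , drop = FALSE], toy$y[va],
                       trainConfig(max_epochs = 20, patience = 20, seed = 1))
  expect_gte(max(m@meta$history$val_accuracy), 0.99)
})

test_that("training histories are reproducible from the seeds", {
  toy <- two_tone_toy(15L)
  x <- featurize_matrix(toy$wav, toy$fs, "transformer", T = 480L)
  build <- function() {
    buildTransformer(transformerConfig(L = 1L, d_model = 16L, n_heads = 2L,
                                       ffn_dim = 16L, T = 480L,
                                       n_classes = 2L),
                     input_shape = dim(x)[1:2], seed = 2)
  }
  cfg <- trainConfig(max_epochs = 3, seed = 9)
  h1 <- trainClassifier(build(), x, toy$y, cfg = cfg)@meta$history
  h2 <- trainClassifier(build(), x, toy$y, cfg = cfg)@meta$history
  expect_identical(h1, h2)
})

test_that("evaluation fills a conserving confusion matrix", {
  # perfect predictor
  cm <- confusionMatrix(rep(0:9, each = 500), rep(0:9, each = 500))
  expect_equal(diag(cm@counts), rep(500L, 10), ignore_attr = TRUE)
  expect_equal(sum(cm@counts), 5000L)
  # constant predictor: one nonzero column
  cm2 <- confusionMatrix(rep(0:9, each = 50), rep(3, 500),
                         class_labels = 0:9)
  expect_equal(sum(colSums(cm2@counts) > 0), 1L)
  expect_equal(sum(cm2@counts), 500L)
})

test_that("metrics reproduce the balanced worked examples", {
  m1 <- classifierMetrics(balanced_cm(4845L))
  expect_equal(m1$accuracy, 0.969)
  expect_equal(m1$macro_recall, m1$accuracy, tolerance = 1e-15)
  expect_equal(m1$n_misclassified, 155L)
  m2 <- classifierMetrics(balanced_cm(4975L))
  expect_equal(m2$accuracy, 0.995)
  expect_equal(m2$n_misclassified, 25L)
  ident <- classifierMetrics(balanced_cm(5000L))
  expect_equal(ident$accuracy, 1)
  expect_equal(ident$macro_recall, 1)
  expect_equal(ident$macro_f1, 1)
})

test_that("macro-recall equals accuracy exactly on balanced matrices", {
  ptfm:::with_seed(44, {
    for (i in 1:20) {
      k <- sample(3:10, 1)
      n <- 60L
      counts <- t(sapply(seq_len(k), function(j) {
        as.integer(stats::rmultinom(1, n, runif(k, 0.05, 1)))
      }))
      cm <- new("ConfusionMatrix", counts = counts,
                class_labels = as.numeric(seq_len(k)))
      met <- classifierMetrics(cm)
      expect_equal(met$macro_recall, met$accuracy, tolerance = 1e-15)
      expect_equal(sum(cm@counts), k * n)
    }
  })
})

test_that("empty test classes are excluded from macros with a warning", {
  counts <- matrix(c(5L, 0L, 0L,
                     1L, 4L, 0L,
                     0L, 0L, 0L), 3, 3, byrow = TRUE)
  cm <- new("ConfusionMatrix", counts = counts, class_labels = c(0, 1, 2))
  expect_warning(met <- classifierMetrics(cm), "no test samples")
  expect_equal(met$excluded_classes, 2)
  expect_equal(met$macro_recall, mean(c(1, 0.8)))
  expect_true(is.na(met$per_class_recall[["2"]]))
})

test_that("architecture sweep returns one audited row per value", {
  toy <- two_tone_toy(15L)
  x <- featurize_matrix(toy$wav, toy$fs, "lstm")
  sp <- assignSplits(toy$y, seed = 2)
  mk <- function(s) list(x = x[, , sp == s, drop = FALSE],
                         y = toy$y[sp == s], classes = c(0, 1))
  tab <- sweepArchitecture("lstm", c(4L, 8L), mk("train"), mk("val"),
                           mk("test"),
                           cfg = trainConfig(max_epochs = 2, seed = 1),
                           n_reps = 2L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$value, c(4L, 8L))
  expect_true(all(tab$n_failed == 0L))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  expect_error(sweepArchitecture("lstm", integer(0), mk("train"), mk("val"),
                                 mk("test")), "nonempty")
})
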