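#' @include nn-engine.R
NULL

#' Model configurations
#'
#' Constructors for the three classifier families. Only the swept
#' architecture axis (feature blocks / memory blocks / encoder depth) is
#' essential; the remaining hyperparameters are package defaults recorded
#' in the returned object.
#'
#' @param n_blocks CNN feature-extraction blocks (conv + batchnorm + ReLU +
#'   maxpool), >= 1.
#' @param kernel_size,base_channels,max_channels,pool_size CNN layer sizing.
#' @param dropout_rate dropout before the classification head.
#' @param n_classes number of output classes.
#' @return a config object of the matching class.
#' @name modelConfigs
#' @export
cnnConfig <- function(n_blocks = 3L, kernel_size = 9L, base_channels = 16L,
                      max_channels = 128L, pool_size = 2L, head_pool = 4L,
                      dropout_rate = 0.3, n_classes = 10L) {
  new("CNNConfig", n_blocks = as.integer(n_blocks),
      kernel_size = as.integer(kernel_size),
      base_channels = as.integer(base_channels),
      max_channels = as.integer(max_channels),
      pool_size = as.integer(pool_size), head_pool = as.integer(head_pool),
      dropout_rate = dropout_rate, n_classes = as.integer(n_classes))
}

#' @rdname modelConfigs
#' @param n_units LSTM memory blocks (20--160 is the sweep range of
#'   interest).
#' @export
lstmConfig <- function(n_units = 80L, dropout_rate = 0.2, n_classes = 10L) {
  new("LSTMConfig", n_units = as.integer(n_units),
      dropout_rate = dropout_rate, n_classes = as.integer(n_classes))
}

#' @rdname modelConfigs
#' @param L encoder depth.
#' @param d_model,n_heads,ffn_dim transformer sizing; d_model must be
#'   divisible by n_heads.
#' @param T patch length consumed per token.
#' @export
transformerConfig <- function(L = 2L, d_model = 64L, n_heads = 4L,
                              ffn_dim = 128L, T = 48L, dropout_rate = 0.1,
                              n_classes = 10L) {
  new("TransformerConfig", L = as.integer(L), d_model = as.integer(d_model),
      n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
      T = as.integer(T), dropout_rate = dropout_rate,
      n_classes = as.integer(n_classes))
}

#' Build the 1-D convolutional classifier
#'
#' Layer sequence: input -> [conv -> batchnorm -> ReLU -> maxpool] x
#' n_blocks -> average pool -> dropout -> fully connected -> softmax over
#' the classes. The input length is zero-padded to a multiple of
#' \code{pool_size^n_blocks * head_pool}; a configuration where pooling
#' would collapse the signal to nothing is rejected with the offending
#' block named.
#'
#' @param cfg a \linkS4class{CNNConfig}.
#' @param input_shape integer c(length, channels) of one input, default
#'   c(4800, 2) for the raw + spectrum pairing.
#' @param seed initialisation seed; two builds with the same seed are
#'   parameter-identical.
#' @return a \linkS4class{ClassifierModel}.
#' @examples
#' m <- buildCNN(cnnConfig(n_blocks = 2L), seed = 1)
#' countParams(m)
#' @export
buildCNN <- function(cfg, input_shape = c(4800L, 2L), seed = 1) {
  validObject(cfg)
  L <- as.integer(input_shape[1]); C <- as.integer(input_shape[2])
  p <- cfg@pool_size
  if (p^cfg@n_blocks > L) {
    bad <- which(p^seq_len(cfg@n_blocks) > L)[1]
    stop(sprintf("pooling in block %d collapses the signal to zero length", bad))
  }
  unit <- p^cfg@n_blocks * cfg@head_pool
  pad_to <- as.integer(ceiling(L / unit) * unit)
  l_head <- pad_to %/% unit
  with_seed(seed, {
    layers <- list()
    c_in <- C
    for (b in seq_len(cfg@n_blocks)) {
      c_out <- min(cfg@base_channels * 2L^(b - 1L), cfg@max_channels)
      layers <- c(layers, list(layer_conv1d(c_in, c_out, cfg@kernel_size),
                               layer_batchnorm(c_out),
                               layer_relu(),
                               layer_maxpool(p)))
      c_in <- c_out
    }
    layers <- c(layers, list(layer_avgpool(cfg@head_pool),
                             layer_dropout(cfg@dropout_rate),
                             layer_flatten(),
                             layer_dense(l_head * c_in, cfg@n_classes)))
    new("ClassifierModel", arch = "cnn", config = cfg, layers = layers,
        input_shape = c(L, C),
        meta = list(seed = seed, pad_to = pad_to))
  })
}

#' Build the LSTM classifier
#'
#' Layer sequence: sequence input -> LSTM(\code{n_units}) -> dropout ->
#' fully connected -> softmax. The final hidden state feeds the head. By
#' default the sequence is the framed raw + spectrum representation
#' produced by \code{\link{featurizeDataset}}.
#'
#' @param cfg an \linkS4class{LSTMConfig}.
#' @param input_shape integer c(timesteps, features_per_step).
#' @param seed initialisation seed.
#' @return a \linkS4class{ClassifierModel}.
#' @export
buildLSTM <- function(cfg, input_shape = c(100L, 96L), seed = 1) {
  validObject(cfg)
  with_seed(seed, {
    layers <- list(layer_lstm(as.integer(input_shape[2]), cfg@n_units),
                   layer_dropout(cfg@dropout_rate),
                   layer_dense(cfg@n_units, cfg@n_classes))
    new("ClassifierModel", arch = "lstm", config = cfg, layers = layers,
        input_shape = as.integer(input_shape), meta = list(seed = seed))
  })
}

#' Build the transformer-encoder classifier
#'
#' Forward contract: each patch is linearly projected to \code{d_model}
#' (X_emb), a learnable positional encoding is added (X_pos = X_emb + PE),
#' \code{L} encoder layers of multi-head self-attention and feed-forward
#' network -- each followed by a residual connection and layer
#' normalisation -- produce the final sequence H_final, which is globally
#' average-pooled over the token dimension (H_pooled) and passed through
#' one fully connected layer and a softmax over the classes.
#'
#' @param cfg a \linkS4class{TransformerConfig}.
#' @param input_shape integer c(n_tokens, patch_length); the patch length
#'   must match \code{cfg@T}.
#' @param seed initialisation seed.
#' @return a \linkS4class{ClassifierModel}.
#' @export
buildTransformer <- function(cfg, input_shape = c(100L, cfg@T), seed = 1) {
  validObject(cfg)
  Tn <- as.integer(input_shape[1]); Tp <- as.integer(input_shape[2])
  if (Tp != cfg@T) stop("input patch length does not match cfg@T")
  with_seed(seed, {
    layers <- list(layer_patch_embed(Tp, cfg@d_model, Tn))
    for (l in seq_len(cfg@L)) {
      layers <- c(layers, list(layer_encoder(cfg@d_model, cfg@n_heads,
                                             cfg@ffn_dim, cfg@dropout_rate)))
    }
    layers <- c(layers, list(layer_token_gap(Tn),
                             layer_dense(cfg@d_model, cfg@n_classes)))
    new("ClassifierModel", arch = "transformer", config = cfg,
        layers = layers, input_shape = c(Tn, Tp), meta = list(seed = seed))
  })
}

#' @describeIn countParams total length of all trainable parameter arrays
#' @export
setMethod("countParams", "ClassifierModel", function(object) {
  sum(vapply(object@layers, function(ly) {
    sum(vapply(ly$params, length, integer(1)), 0L)
  }, integer(1)))
})

#' Layer-type sequence of a model
#'
#' Structural audit helper: the ordered vector of internal layer types,
#' e.g. counting \code{"conv1d"} entries verifies the number of feature
#' blocks actually built.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @return character vector.
#' @export
layerTypes <- function(model) {
  vapply(model@layers, function(ly) ly$type, character(1))
}

# Arch-aware forward over a full input array; pads CNN input, supplies
# token geometry to encoder layers.
model_forward <- function(model, x, training = FALSE) {
  if (model@arch == "cnn") {
    L <- dim(x)[1] # layout (L, B, C)
    pad_to <- model@meta$pad_to
    if (L < pad_to) {
      xp <- array(0, dim = c(pad_to, dim(x)[2], dim(x)[3]))
      xp[seq_len(L), , ] <- x
      x <- xp
    }
    nn_forward(model@layers, x, training)
  } else if (model@arch == "transformer") {
    nn_forward(model@layers, x, training,
               token_geom = list(Tn = dim(x)[1], B = dim(x)[3]))
  } else {
    nn_forward(model@layers, x, training)
  }
}

# batch axis: 2 for the conv layout (L, B, C), 3 elsewhere
.batch_axis <- function(arch) if (arch == "cnn") 2L else 3L

.batch_slice <- function(arch, x, idx) {
  if (arch == "cnn") x[, idx, , drop = FALSE] else x[, , idx, drop = FALSE]
}

.batch_count <- function(arch, x) dim(x)[.batch_axis(arch)]

#' @describeIn predictProb forward pass in evaluation mode; rows sum to 1
#' @param batch_size evaluation batch size.
#' @export
setMethod("predictProb", "ClassifierModel",
          function(object, x, batch_size = 256L, ...) {
  B <- .batch_count(object@arch, x)
  out <- matrix(0, B, object@config@n_classes)
  for (s in seq(1L, B, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, B)
    fw <- model_forward(object, .batch_slice(object@arch, x, idx),
                        training = FALSE)
    out[idx, ] <- softmax_probs(fw$out)
  }
  out
})

#' Hard class predictions
#'
#' Argmax of \code{\link{predictProb}}; ties break to the lowest class
#' index.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param x featurised input array.
#' @return integer vector of 1-based class indices.
#' @export
predictClass <- function(model, x) {
  max.col(predictProb(model, x), ties.method = "first")
}
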