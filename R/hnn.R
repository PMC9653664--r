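#' Rectified linear unit
#'
#' `max(0, x)`: the activation used throughout the network. Its derivative
#' is 1 for positive input, which keeps gradients from vanishing during
#' backpropagation.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with negative entries replaced by 0.
#' @export
relu <- function(x) pmax(x, 0)

#' Configuration for the hybrid neural network
#'
#' The SMILES branch embeds each character index (vocabulary 94 characters
#' plus the padding index 0, hence `vocab_size = 95`) into a dense vector
#' of size `embedding_dim = 100`, applies a 1D convolution with ReLU and
#' global max pooling; the descriptor branch is a feed-forward network
#' with ReLU hidden layers. Both branch outputs are concatenated into a
#' merge layer feeding the final fully connected output layer: sigmoid for
#' binary classification, softmax over `n_classes` for ternary
#' classification, linear for pTD50 regression.
#'
#' Only the embedding size, the ReLU activation, pooling, and the merge
#' topology are fixed by the method; the remaining hyperparameters are
#' free and exposed here with the package defaults.
#'
#' @param task "binary", "multiclass" or "regression".
#' @param embedding_dim size of the character embedding (default 100).
#' @param vocab_size embedding input cardinality, indices 0..94 (95).
#' @param max_len fixed encoded SMILES length L (default 325).
#' @param conv_filters number of 1D convolution filters (default 64).
#' @param conv_kernel convolution window width in characters (default 5).
#' @param pooling pooling type; only "global_max" is implemented.
#' @param ffnn_hidden widths of the descriptor-branch hidden layers.
#' @param merge_hidden width of the post-concatenation merge layer.
#' @param dropout dropout rate applied to hidden layers during training.
#' @param n_classes number of classes for the multiclass task (3).
#' @param epochs,batch_size,learning_rate Adam training schedule defaults.
#' @param seed integer seed governing initialization, shuffling, dropout.
#' @return list of class `hnn_config`.
#' @export
hnn_config <- function(task = c("binary", "multiclass", "regression"),
                       embedding_dim = 100L, vocab_size = 95L,
                       max_len = 325L, conv_filters = 64L, conv_kernel = 5L,
                       pooling = "global_max", ffnn_hidden = c(256L, 128L),
                       merge_hidden = 64L, dropout = 0.2, n_classes = 3L,
                       epochs = 30L, batch_size = 32L, learning_rate = 1e-3,
                       seed = 1L) {
  task <- match.arg(task)
  stopifnot(pooling == "global_max", conv_kernel >= 1L,
            conv_kernel <= max_len, dropout >= 0, dropout < 1,
            length(ffnn_hidden) >= 1L)
  if (task == "multiclass" && n_classes != 3L) {
    stop("the ternary task uses n_classes = 3")
  }
  structure(list(task = task, embedding_dim = as.integer(embedding_dim),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel), pooling = pooling,
                 ffnn_hidden = as.integer(ffnn_hidden),
                 merge_hidden = as.integer(merge_hidden), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "hnn_config")
}

.out_dim <- function(cfg) if (cfg$task == "multiclass") cfg$n_classes else 1L

#' Build an untrained hybrid neural network
#'
#' Allocates and initializes all parameters (He-scaled Gaussian weights,
#' zero biases, small-uniform embedding with the padding row fixed at
#' zero) from `cfg$seed`.
#'
#' @param cfg an [hnn_config()].
#' @param n_descriptors number of descriptor columns the model accepts.
#' @return object of class `hnn_model` with elements `params`, `cfg`,
#'   `n_descriptors`.
#' @export
build_hnn <- function(cfg, n_descriptors) {
  stopifnot(inherits(cfg, "hnn_config"), n_descriptors >= 1L)
  d <- as.integer(n_descriptors)
  set.seed(cfg$seed)
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  emb <- matrix(stats::runif(cfg$vocab_size * cfg$embedding_dim,
                             -0.05, 0.05),
                cfg$vocab_size, cfg$embedding_dim)
  emb[1, ] <- 0  # padding index 0: zero vector, never updated
  fan_conv <- cfg$conv_kernel * cfg$embedding_dim
  h1 <- cfg$ffnn_hidden[1]
  h2 <- cfg$ffnn_hidden[length(cfg$ffnn_hidden)]
  if (length(cfg$ffnn_hidden) != 2L) {
    stop("the descriptor branch currently uses exactly two hidden layers")
  }
  params <- list(
    E = emb,
    Wc = he(fan_conv, cfg$conv_filters), bc = numeric(cfg$conv_filters),
    W1 = he(d, h1), b1 = numeric(h1),
    W2 = he(h1, h2), b2 = numeric(h2),
    Wm = he(cfg$conv_filters + h2, cfg$merge_hidden),
    bm = numeric(cfg$merge_hidden),
    Wo = he(cfg$merge_hidden, .out_dim(cfg)), bo = numeric(.out_dim(cfg)))
  structure(list(params = params, cfg = cfg, n_descriptors = d),
            class = "hnn_model")
}

# add a bias row vector to every row of a matrix without extra copies
.addb <- function(m, b) m + rep(b, each = nrow(m))

.softmax <- function(s) {
  z <- exp(s - apply(s, 1, max))
  z / rowSums(z)
}

# Forward pass over a batch. idx: K x L integer matrix (0..94); desc: K x D.
# When train = TRUE, dropout masks are drawn from the current RNG stream and
# all intermediates needed by .hnn_backward are returned.
.hnn_forward <- function(params, cfg, idx, desc, train = FALSE) {
  K <- nrow(idx); L <- cfg$max_len
  if (ncol(idx) != L) stop("encoded SMILES width does not match max_len")
  if (nrow(desc) != K) stop("descriptor row count does not match SMILES count")
  ker <- cfg$conv_kernel; emb <- cfg$embedding_dim
  P <- L - ker + 1L; Fn <- cfg$conv_filters
  flat <- as.vector(t(idx)) + 1L
  Emb <- params$E[flat, , drop = FALSE]
  base <- rep((seq_len(K) - 1L) * L, each = P) + rep(seq_len(P), K)
  A <- matrix(0, K * P, ker * emb)
  for (j in 0:(ker - 1L)) {
    A[, j * emb + seq_len(emb)] <- Emb[base + j, , drop = FALSE]
  }
  Z <- .addb(A %*% params$Wc, params$bc)
  H <- pmax(Z, 0)
  tM <- t(matrix(H, nrow = P))              # (K*Fn) x P, k fastest within f
  am <- max.col(tM, ties.method = "first")  # argmax window per (k, f)
  C <- matrix(tM[cbind(seq_len(K * Fn), am)], nrow = K)
  keep <- 1 - cfg$dropout
  mask <- function(nr, nc) {
    if (train && cfg$dropout > 0) {
      matrix((stats::runif(nr * nc) < keep) / keep, nr, nc)
    } else NULL
  }
  Z1 <- .addb(desc %*% params$W1, params$b1); H1 <- pmax(Z1, 0)
  m1 <- mask(K, ncol(H1)); H1d <- if (is.null(m1)) H1 else H1 * m1
  Z2 <- .addb(H1d %*% params$W2, params$b2); H2 <- pmax(Z2, 0)
  m2 <- mask(K, ncol(H2)); H2d <- if (is.null(m2)) H2 else H2 * m2
  Mcat <- cbind(C, H2d)
  Zm <- .addb(Mcat %*% params$Wm, params$bm); Hm <- pmax(Zm, 0)
  mm <- mask(K, ncol(Hm)); Hmd <- if (is.null(mm)) Hm else Hm * mm
  S <- .addb(Hmd %*% params$Wo, params$bo)
  out <- switch(cfg$task,
                binary = 1 / (1 + exp(-S)),
                multiclass = .softmax(S),
                regression = S)
  res <- list(out = out, S = S)
  if (train) {
    res <- c(res, list(A = A, Z = Z, am = am, flat = flat, base = base,
                       H1 = H1, H1d = H1d, m1 = m1, H2 = H2, H2d = H2d,
                       m2 = m2, Mcat = Mcat, Hm = Hm, Hmd = Hmd, mm = mm,
                       desc = desc, K = K, P = P))
  }
  res
}

.hnn_loss <- function(cfg, out, y) {
  eps <- 1e-12
  switch(cfg$task,
         binary = -mean(y * log(out + eps) + (1 - y) * log(1 - out + eps)),
         multiclass = -mean(log(out[cbind(seq_len(nrow(out)), y + 1L)] + eps)),
         regression = mean((out - y)^2))
}

.hnn_backward <- function(params, cfg, fw, y) {
  K <- fw$K; P <- fw$P; Fn <- cfg$conv_filters
  emb <- cfg$embedding_dim; ker <- cfg$conv_kernel
  dS <- switch(cfg$task,
    binary = (fw$out - y) / K,
    multiclass = {
      Y <- matrix(0, K, cfg$n_classes)
      Y[cbind(seq_len(K), y + 1L)] <- 1
      (fw$out - Y) / K
    },
    regression = 2 * (fw$S - y) / K)
  g <- list()
  g$Wo <- crossprod(fw$Hmd, dS); g$bo <- colSums(dS)
  dHmd <- dS %*% t(params$Wo)
  if (!is.null(fw$mm)) dHmd <- dHmd * fw$mm
  dZm <- dHmd * (fw$Hm > 0)
  g$Wm <- crossprod(fw$Mcat, dZm); g$bm <- colSums(dZm)
  dMcat <- dZm %*% t(params$Wm)
  dC <- dMcat[, seq_len(Fn), drop = FALSE]
  dH2d <- dMcat[, Fn + seq_len(ncol(fw$H2)), drop = FALSE]
  if (!is.null(fw$m2)) dH2d <- dH2d * fw$m2
  dZ2 <- dH2d * (fw$H2 > 0)
  g$W2 <- crossprod(fw$H1d, dZ2); g$b2 <- colSums(dZ2)
  dH1d <- dZ2 %*% t(params$W2)
  if (!is.null(fw$m1)) dH1d <- dH1d * fw$m1
  dZ1 <- dH1d * (fw$H1 > 0)
  g$W1 <- crossprod(fw$desc, dZ1); g$b1 <- colSums(dZ1)
  # route pooled gradients back to each (sample, filter) argmax window
  dH <- matrix(0, K * P, Fn)
  kk <- rep(seq_len(K), Fn)
  ff <- rep(seq_len(Fn), each = K)
  dH[cbind((kk - 1L) * P + fw$am, ff)] <- as.vector(dC)
  dZc <- dH * (fw$Z > 0)
  g$Wc <- crossprod(fw$A, dZc); g$bc <- colSums(dZc)
  dA <- dZc %*% t(params$Wc)
  dEmb <- matrix(0, K * cfg$max_len, emb)
  for (j in 0:(ker - 1L)) {
    ii <- fw$base + j
    dEmb[ii, ] <- dEmb[ii, ] + dA[, j * emb + seq_len(emb), drop = FALSE]
  }
  agg <- rowsum(dEmb, group = fw$flat)
  gE <- matrix(0, cfg$vocab_size, emb)
  gE[as.integer(rownames(agg)), ] <- agg
  gE[1, ] <- 0  # padding embedding stays zero
  g$E <- gE
  g
}

#' Train the hybrid neural network
#'
#' Minibatch Adam on the task loss (binary cross-entropy, categorical
#' cross-entropy, or mean squared error). Data are reshuffled every epoch;
#' all randomness (shuffling, dropout) flows from `cfg$seed`, so the same
#' seed and data reproduce the same fit exactly.
#'
#' @param model an `hnn_model` from [build_hnn()].
#' @param encoded K x L integer matrix from [encode_batch()].
#' @param descriptors K x D numeric matrix or data.frame (standardized
#'   descriptors; see [standardize_features()]).
#' @param targets labels 0/1 (binary), 0/1/2 (multiclass), or numeric
#'   pTD50 values (regression).
#' @param epochs,batch_size,learning_rate optional overrides of the
#'   config's training schedule.
#' @param verbose print the per-epoch loss.
#' @return object of class `hnn_fit`: trained `params`, `cfg`,
#'   `n_descriptors`, and `history` (data.frame of per-epoch mean training
#'   loss).
#' @export
train_hnn <- function(model, encoded, descriptors, targets,
                      epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hnn_model"))
  cfg <- model$cfg
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else
    as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate
  desc <- as.matrix(descriptors)
  n <- nrow(encoded)
  if (nrow(desc) != n || length(targets) != n) {
    stop("encoded SMILES, descriptors and targets must have matching rows")
  }
  if (ncol(desc) != model$n_descriptors) {
    stop("descriptor count does not match the model")
  }
  y <- targets
  if (cfg$task == "binary" && !all(y %in% c(0, 1))) {
    stop("binary task requires labels in {0, 1}")
  }
  if (cfg$task == "multiclass" && !all(y %in% 0:(cfg$n_classes - 1L))) {
    stop("multiclass task requires labels in 0..", cfg$n_classes - 1L)
  }
  if (cfg$task == "regression" && !is.numeric(y)) {
    stop("regression task requires numeric targets")
  }
  params <- model$params
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
  set.seed(cfg$seed + 1L)  # training stream, distinct from init stream
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- perm[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      idx_b <- encoded[rows, , drop = FALSE]
      desc_b <- desc[rows, , drop = FALSE]
      y_b <- y[rows]
      fw <- .hnn_forward(params, cfg, idx_b, desc_b, train = TRUE)
      losses[bi] <- .hnn_loss(cfg, fw$out, y_b)
      grad <- .hnn_backward(params, cfg, fw, y_b)
      t_step <- t_step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^t_step)
        vhat <- vel[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
      params$E[1, ] <- 0
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, epochs,
                                 history[ep]))
  }
  structure(list(params = params, cfg = cfg,
                 n_descriptors = model$n_descriptors,
                 history = data.frame(epoch = seq_len(epochs),
                                      loss = history)),
            class = c("hnn_fit", "hnn_model"))
}

#' Predict with a (trained) hybrid neural network
#'
#' @param fitted an `hnn_fit` (or untrained `hnn_model`).
#' @param encoded K x L integer matrix from [encode_batch()].
#' @param descriptors K x D numeric matrix/data.frame.
#' @param type "response" (default: probability vector for binary, K x 3
#'   probability matrix for multiclass, numeric vector for regression) or
#'   "class" (0/1 at threshold 0.5 for binary; argmax with ties broken
#'   toward the lower class index for multiclass).
#' @return predictions in input row order; empty input yields empty output.
#' @export
predict_hnn <- function(fitted, encoded, descriptors,
                        type = c("response", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(fitted, "hnn_model"))
  cfg <- fitted$cfg
  desc <- as.matrix(descriptors)
  if (nrow(encoded) == 0L) {
    return(switch(cfg$task,
                  binary = numeric(0), regression = numeric(0),
                  multiclass = matrix(numeric(0), 0, cfg$n_classes)))
  }
  fw <- .hnn_forward(fitted$params, cfg, encoded, desc, train = FALSE)
  out <- fw$out
  if (type == "response") {
    return(if (cfg$task == "multiclass") out else as.vector(out))
  }
  switch(cfg$task,
         binary = as.integer(as.vector(out) >= 0.5),
         multiclass = max.col(out, ties.method = "first") - 1L,
         regression = as.vector(out))
}

#' Character embedding output of the SMILES branch
#'
#' Exposes the embedding layer: the K x L index matrix is mapped to a
#' K x L x `embedding_dim` array of dense character vectors (the tensor
#' fed to the 1D convolution).
#'
#' @param model an `hnn_model` or `hnn_fit`.
#' @param encoded K x L integer matrix.
#' @return numeric array of dimension K x L x embedding_dim.
#' @export
embedding_output <- function(model, encoded) {
  stopifnot(inherits(model, "hnn_model"))
  cfg <- model$cfg
  K <- nrow(encoded); L <- cfg$max_len
  stopifnot(ncol(encoded) == L)
  flat <- as.vector(t(encoded)) + 1L
  Emb <- model$params$E[flat, , drop = FALSE]
  arr <- array(0, dim = c(K, L, cfg$embedding_dim))
  for (k in seq_len(K)) {
    arr[k, , ] <- Emb[(k - 1L) * L + seq_len(L), ]
  }
  arr
}
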