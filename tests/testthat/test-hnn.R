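test_that("relu clamps negatives and passes positives", {
  expect_equal(relu(-3.2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(relu(c(-1, 0.5, 3)), c(0, 0.5, 3))
})

test_that("embedding output is K x L x 100 under the default configuration", {
  cfg <- hnn_config("binary")
  expect_identical(cfg$embedding_dim, 100L)
  expect_identical(cfg$max_len, 325L)
  expect_identical(cfg$vocab_size, 95L)  # 94 characters + padding index 0
  model <- build_hnn(cfg, n_descriptors = 4L)
  enc <- encode_batch(c("C=CC#N", "CCO"))
  emb <- embedding_output(model, enc)
  expect_identical(dim(emb), c(2L, 325L, 100L))
  # padding positions embed to the zero vector
  expect_true(all(emb[1, 7:325, ] == 0))
  expect_true(all(emb[2, 4:325, ] == 0))
  # identical characters share an embedding row
  expect_equal(emb[1, 1, ], emb[1, 3, ])
})

test_that("output heads respect their task ranges", {
  set.seed(8)
  enc <- encode_batch(c("C=CC#N", "c1ccccc1", "CCO"), max_len = 60)
  desc <- matrix(rnorm(9), 3)
  for (task in c("binary", "multiclass", "regression")) {
    model <- build_hnn(tiny_hnn_config(task), n_descriptors = 3L)
    out <- predict_hnn(model, enc, desc)
    if (task == "binary") {
      expect_true(all(out >= 0 & out <= 1))
      expect_length(out, 3L)
    } else if (task == "multiclass") {
      expect_identical(dim(out), c(3L, 3L))
      expect_equal(rowSums(out), rep(1, 3), tolerance = 1e-6)
      expect_true(all(out >= 0))
    } else {
      expect_true(is.numeric(out) && length(out) == 3L)
    }
  }
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- hnn_config("multiclass", embedding_dim = 4L, max_len = 12L,
                    conv_filters = 3L, conv_kernel = 3L,
                    ffnn_hidden = c(5L, 4L), merge_hidden = 4L,
                    dropout = 0, seed = 2L)
  model <- build_hnn(cfg, n_descriptors = 3L)
  enc <- encode_batch(c("C=CC#N", "CCO", "N#N"), max_len = 12)
  set.seed(3)
  desc <- matrix(rnorm(9), 3)
  y <- c(0L, 2L, 1L)
  params <- model$params
  # nudge biases off the ReLU kink at exactly zero, where the loss is not
  # differentiable and the finite-difference probe would disagree
  for (nm in c("bc", "b1", "b2", "bm", "bo")) {
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 0.1)
  }
  fw <- hnncarc:::.hnn_forward(params, cfg, enc, desc, train = TRUE)
  grad <- hnncarc:::.hnn_backward(params, cfg, fw, y)
  loss_at <- function(p) {
    f <- hnncarc:::.hnn_forward(p, cfg, enc, desc, train = FALSE)
    hnncarc:::.hnn_loss(cfg, f$out, y)
  }
  eps <- 1e-6
  set.seed(4)
  for (nm in c("E", "Wc", "bc", "W1", "W2", "Wm", "Wo", "bo")) {
    # probe a handful of random coordinates of each parameter block
    for (probe in 1:4) {
      i <- sample(length(params[[nm]]), 1)
      if (nm == "E" && (i %% nrow(params$E)) == 1) next  # frozen padding row
      p_up <- params; p_up[[nm]][i] <- p_up[[nm]][i] + eps
      p_dn <- params; p_dn[[nm]][i] <- p_dn[[nm]][i] - eps
      num <- (loss_at(p_up) - loss_at(p_dn)) / (2 * eps)
      expect_equal(grad[[nm]][i], num, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("training is deterministic, records its loss, and memorizes a toy set", {
  enc <- encode_batch(rep(c("N(=O)=O", "CCOCC"), each = 10), max_len = 60)
  desc <- matrix(rep(c(5, -5), each = 10), ncol = 1)
  y <- rep(c(1, 0), each = 10)
  cfg <- tiny_hnn_config("binary", seed = 21L)
  fit1 <- train_hnn(build_hnn(cfg, 1L), enc, desc, y, epochs = 25)
  fit2 <- train_hnn(build_hnn(cfg, 1L), enc, desc, y, epochs = 25)
  expect_identical(fit1$history, fit2$history)  # same seed, same data
  expect_identical(fit1$params, fit2$params)
  expect_identical(nrow(fit1$history), 25L)
  expect_lt(tail(fit1$history$loss, 1), head(fit1$history$loss, 1))
  acc <- mean(predict_hnn(fit1, enc, desc, type = "class") == y)
  expect_equal(acc, 1)  # memorizable set
})

test_that("target range mismatches and shape mismatches are rejected", {
  cfg <- tiny_hnn_config("binary")
  model <- build_hnn(cfg, 2L)
  enc <- encode_batch(c("CC", "CCC"), max_len = 60)
  desc <- matrix(0, 2, 2)
  expect_error(train_hnn(model, enc, desc, c(0, 2)), "\\{0, 1\\}")
  expect_error(train_hnn(model, enc, desc[1, , drop = FALSE], c(0, 1)),
               "matching rows")
  expect_error(train_hnn(model, enc, matrix(0, 2, 5), c(0, 1)),
               "descriptor count")
  expect_error(predict_hnn(model, enc[, 1:30], desc), "max_len")
})

test_that("prediction preserves order, handles empty input, and duplicates rows identically", {
  cfg <- tiny_hnn_config("regression", seed = 5L)
  model <- build_hnn(cfg, 2L)
  enc <- encode_batch(c("C=CC#N", "C=CC#N", "CCO"), max_len = 60)
  desc <- matrix(c(1, 1, 0, 2, 2, 1), ncol = 2)
  out <- predict_hnn(model, enc, desc)
  expect_identical(out[1], out[2])  # duplicated input row, identical output
  empty <- predict_hnn(model, enc[0, , drop = FALSE],
                       desc[0, , drop = FALSE])
  expect_length(empty, 0L)
})

test_that("the two branches are architecturally separable", {
  cfg <- tiny_hnn_config("binary", seed = 9L)
  model <- build_hnn(cfg, 2L)
  enc <- encode_batch(c("C=CC#N", "C=CC#N"), max_len = 60)
  # descriptor branch ablated (zeroed input): prediction is a function of
  # SMILES alone, so two different zero-descriptor rows agree
  zeros <- matrix(0, 2, 2)
  p <- predict_hnn(model, enc, zeros)
  expect_identical(p[1], p[2])
  # SMILES branch ablated (all-padding input embeds to zeros): prediction
  # is a function of descriptors alone
  pad <- matrix(0L, 2, 60)
  desc <- matrix(c(1, 1, 2, 2), 2)
  q <- predict_hnn(model, pad, desc)
  expect_identical(q[1], q[2])
  desc2 <- matrix(c(1, 3, 2, 4), 2)
  q2 <- predict_hnn(model, pad, desc2)
  expect_false(identical(q2[1], q2[2]))
})

test_that("predictions are invariant to how the padding was produced", {
  cfg <- tiny_hnn_config("binary", seed = 13L)
  model <- build_hnn(cfg, 1L)
  s <- "C=CC#N"
  e1 <- encode_batch(s, max_len = 60)
  e2 <- matrix(as.integer(encode_smiles(s, max_len = 60)), nrow = 1)
  desc <- matrix(1, 2, 1)
  expect_identical(predict_hnn(model, e1, desc[1, , drop = FALSE]),
                   predict_hnn(model, e2, desc[1, , drop = FALSE]))
})
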