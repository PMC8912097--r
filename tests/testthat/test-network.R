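# Small peptide sets shared by the network tests.
make_toy_split <- function(seed = 7, n = 40) {
  d <- generate_peptides(generator_spec(n, n, length_range = c(11, 25),
                                        seed = seed))
  split_dataset(d, 0.8, seed = seed)
}

test_that("seeded builds are identical and modes wire the right branches", {
  cfg <- acpnet_config(seed = 123, max_len = 30)
  m1 <- acpnet_build(cfg); m2 <- acpnet_build(cfg)
  expect_identical(m1$params, m2$params)

  ms <- acpnet_build(acpnet_config(mode = "MS", max_len = 30))
  expect_null(ms$params$emb)
  expect_false(is.null(ms$params$ms))
  ae <- acpnet_build(acpnet_config(mode = "AE", max_len = 30))
  expect_null(ae$params$ms)
  expect_equal(dim(ae$params$emb), c(21, 50))
  expect_equal(ae$params$emb[1, ], rep(0, 50))  # padding row zero

  # fused head input is exactly the union of branch outputs
  fused <- acpnet_build(acpnet_config(max_len = 30))
  expect_equal(nrow(fused$params$head[[1]]$W),
               2 * 64 + 32)
  expect_equal(nrow(ms$params$head[[1]]$W), 32)
  expect_equal(nrow(ae$params$head[[1]]$W), 2 * 64)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(99)
  cfg <- acpnet_config(mode = "MS+AE", max_len = 7, embed_dim = 4,
                       rnn_units = 3, dense_units = 5, head_units = 4,
                       dropout = 0, seed = 11)
  model <- acpnet_build(cfg, n_manual = 6)
  n <- 5
  idx <- matrix(sample(0:20, n * 7, replace = TRUE), n, 7)
  for (i in 1:n) {
    v <- idx[i, ]; v <- v[v > 0]; if (length(v) == 0) v <- 3L
    idx[i, ] <- c(v, rep(0L, 7 - length(v)))
  }
  inputs <- list(manual = matrix(rnorm(n * 6), n, 6), encoded = idx,
                 encoded_rev = acpnet:::reverse_encoded(idx))
  y <- c(1, 0, 1, 1, 0)
  p <- model$params
  loss_fn <- function(pp) acpnet:::bce_loss(
    y, acpnet:::model_forward(pp, cfg, inputs)$score)
  fp <- acpnet:::model_forward(p, cfg, inputs, keep_cache = TRUE)
  g <- acpnet:::model_backward(p, cfg, inputs, fp, y)
  eps <- 1e-6
  num_grad <- function(set_elem, get_elem, k) {
    p1 <- set_elem(p, k, +eps); p2 <- set_elem(p, k, -eps)
    (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
  }
  spots <- list(
    list(g = g$emb, set = function(p, k, e) { p$emb[k] <- p$emb[k] + e; p }),
    list(g = g$lf$W, set = function(p, k, e) { p$lf$W[k] <- p$lf$W[k] + e; p }),
    list(g = g$lf$U, set = function(p, k, e) { p$lf$U[k] <- p$lf$U[k] + e; p }),
    list(g = g$lb$b, set = function(p, k, e) { p$lb$b[k] <- p$lb$b[k] + e; p }),
    list(g = g$ms[[1]]$W,
         set = function(p, k, e) { p$ms[[1]]$W[k] <- p$ms[[1]]$W[k] + e; p }),
    list(g = g$head[[1]]$W,
         set = function(p, k, e) { p$head[[1]]$W[k] <- p$head[[1]]$W[k] + e; p }),
    list(g = g$out$W,
         set = function(p, k, e) { p$out$W[k] <- p$out$W[k] + e; p }))
  for (sp in spots) {
    ks <- sample(length(sp$g), min(5, length(sp$g)))
    for (k in ks)  # absolute error: many embedding grads are exactly zero
      expect_lt(abs(num_grad(sp$set, NULL, k) - sp$g[k]), 1e-6)
  }
})

test_that("the network memorizes a two-sequence dataset", {
  pos <- "KLWKKIEKLIKKLLTSIR"
  neg <- "SDEKASPDKHHRFSLSDE"
  tr <- acpnet:::new_peptide_set(paste0("p", 1:32),
                                 c(rep(pos, 16), rep(neg, 16)),
                                 c(rep(1L, 16), rep(0L, 16)))
  va <- acpnet:::new_peptide_set(c("v1", "v2"), c(pos, neg), c(1L, 0L))
  cfg <- acpnet_config(mode = "MS+AE", max_epochs = 50, patience = 50,
                       seed = 3, dropout = 0)
  m <- acpnet_train(tr, va, cfg)
  expect_gte(max(m$history$train_acc), 1.0)
})

test_that("training validates inputs and records history", {
  sp <- make_toy_split()
  one_class <- sp$train[sp$train$label == 1L, , drop = FALSE]
  expect_error(acpnet_train(one_class, sp$validation, fast_config()),
               "both classes")
  empty_val <- sp$validation[0, , drop = FALSE]
  expect_error(acpnet_train(sp$train, empty_val, fast_config()),
               "empty validation")
  m <- acpnet_train(sp$train, sp$validation, fast_config(seed = 5))
  expect_true(all(c("train_loss", "val_loss", "val_acc") %in%
                    names(m$history)))
  expect_gte(nrow(m$history), m$best_epoch)
})

test_that("training is reproducible under a fixed seed", {
  sp <- make_toy_split(seed = 17, n = 25)
  cfg <- fast_config(seed = 99)
  m1 <- acpnet_train(sp$train, sp$validation, cfg)
  m2 <- acpnet_train(sp$train, sp$validation, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, sp$validation)$score,
                   predict(m2, sp$validation)$score)
})

test_that("predictions are probabilities with a strict threshold rule", {
  sp <- make_toy_split(seed = 23, n = 30)
  m <- acpnet_train(sp$train, sp$validation, fast_config(seed = 23))
  pr <- predict(m, sp$validation)
  expect_equal(nrow(pr), nrow(sp$validation))
  expect_identical(pr$id, sp$validation$id)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_identical(pr$label, as.integer(pr$score > 0.5))
  # strict inequality: a score equal to the threshold is non-ACP
  thr <- pr$score[1]
  pr2 <- predict(m, sp$validation, threshold = thr)
  expect_equal(pr2$label[1], 0L)
  # inference is deterministic
  expect_identical(predict(m, sp$validation)$score, pr$score)
  # sequences longer than max_len are truncated with a warning
  long <- acpnet:::new_peptide_set("long", strrep("KLWKI", 20))
  expect_warning(pl <- predict(m, long), "truncated")
  expect_true(pl$score >= 0 && pl$score <= 1)
})

test_that("checkpoints round-trip bit-identically", {
  sp <- make_toy_split(seed = 29, n = 20)
  m <- acpnet_train(sp$train, sp$validation, fast_config(seed = 29))
  before <- predict(m, sp$validation)$score
  path <- tempfile(fileext = ".rds")
  acpnet_save(m, path)
  m2 <- acpnet_load(path)
  expect_identical(predict(m2, sp$validation)$score, before)
  expect_identical(m2$config$max_len, m$config$max_len)
  expect_error(acpnet_load(tempfile()), "not found")
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(acpnet_load(bad), "format version")
})

test_that("inner-layer vectors have penultimate width and are input-determined", {
  sp <- make_toy_split(seed = 31, n = 20)
  m <- acpnet_train(sp$train, sp$validation, fast_config(seed = 31))
  z <- extract_inner(m, sp$validation)
  expect_equal(dim(z), c(nrow(sp$validation),
                         tail(m$config$head_units, 1)))
  dup <- acpnet:::new_peptide_set(c("a", "b"),
                                  rep(sp$validation$seq[1], 2))
  zd <- extract_inner(m, dup)
  expect_equal(zd[1, ], zd[2, ], ignore_attr = TRUE)
  um <- acpnet_build(acpnet_config(max_len = 30))
  expect_error(extract_inner(um, sp$validation), "not trained")
})
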