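#' Model configuration
#'
#' Architecture and training hyperparameters of the hybrid classifier.
#' `mode` selects the ablation variant: `"MS"` uses only the 35 manually
#' selected features through the dense branch, `"AE"` only the learned
#' embedding through the bidirectional LSTM branch, and `"MS+AE"` (default)
#' fuses both by concatenating the branch outputs before the fully connected
#' head with a single sigmoid output.
#'
#' @param mode one of `"MS+AE"`, `"MS"`, `"AE"`.
#' @param max_len fixed encoded sequence length; `NULL` means "longest
#'   training sequence", frozen at training time.
#' @param embed_dim embedding dimension per residue; default 50.
#' @param rnn_units LSTM units per direction; default 64.
#' @param dense_units hidden widths of the manual-feature branch.
#' @param head_units hidden widths of the merged head.
#' @param dropout dropout rate on hidden dense activations during training.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss; best-epoch
#'   weights are restored.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param threshold default decision threshold (strict `>`).
#' @param normalize_manual z-score the manual features with training-set
#'   statistics (frozen into the model); without it molecular weight (~10^3)
#'   swamps the PAAC components (~10^-2).
#' @return object of class `acpnet_config`.
#' @export
acpnet_config <- function(mode = c("MS+AE", "MS", "AE"), max_len = NULL,
                          embed_dim = 50L, rnn_units = 64L,
                          dense_units = c(64L, 32L),
                          head_units = c(64L, 32L), dropout = 0.3,
                          learning_rate = 1e-3, batch_size = 32L,
                          max_epochs = 200L, patience = 20L, seed = 42L,
                          threshold = 0.5, normalize_manual = TRUE) {
  mode <- match.arg(mode)
  stopifnot(embed_dim >= 1L, rnn_units >= 1L, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L)
  structure(list(mode = mode, max_len = max_len,
                 embed_dim = as.integer(embed_dim),
                 rnn_units = as.integer(rnn_units),
                 dense_units = as.integer(dense_units),
                 head_units = as.integer(head_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 threshold = threshold, normalize_manual = normalize_manual),
            class = "acpnet_config")
}

use_ae <- function(config) config$mode %in% c("AE", "MS+AE")
use_ms <- function(config) config$mode %in% c("MS", "MS+AE")

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

lstm_init <- function(din, h) {
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1  # forget-gate bias opens the memory path early
  list(W = glorot(din, 4L * h), U = glorot(h, 4L * h), b = b)
}

#' Build an untrained model
#'
#' Initializes all weight matrices for the configured mode with seeded
#' Glorot-uniform draws; the embedding table has 21 rows, row one being the
#' padding index 0 which is held at zero and masked from the recurrent
#' branch.
#'
#' @param config an [acpnet_config()].
#' @param n_manual manual feature dimension (default 35).
#' @return object of class `acpnet_model` (untrained).
#' @export
acpnet_build <- function(config, n_manual = 35L) {
  stopifnot(inherits(config, "acpnet_config"))
  set.seed(config$seed)
  p <- list()
  h <- config$rnn_units
  if (use_ae(config)) {
    emb <- matrix(runif(21L * config$embed_dim, -0.05, 0.05), 21L,
                  config$embed_dim)
    emb[1L, ] <- 0
    p$emb <- emb
    p$lf <- lstm_init(config$embed_dim, h)
    p$lb <- lstm_init(config$embed_dim, h)
  }
  ms_out <- 0L
  if (use_ms(config)) {
    dims <- c(n_manual, config$dense_units)
    p$ms <- lapply(seq_len(length(dims) - 1L), function(l)
      list(W = glorot(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L])))
    ms_out <- dims[length(dims)]
  }
  head_in <- ms_out + if (use_ae(config)) 2L * h else 0L
  dims <- c(head_in, config$head_units)
  p$head <- lapply(seq_len(length(dims) - 1L), function(l)
    list(W = glorot(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L])))
  p$out <- list(W = glorot(dims[length(dims)], 1L), b = numeric(1L))
  structure(list(config = config, params = p, n_manual = as.integer(n_manual),
                 trained = FALSE),
            class = "acpnet_model")
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))
sigmoid <- function(x) 1 / (1 + exp(-x))

## Forward pass through one LSTM direction over a padded index matrix.
## Masked (padding) steps hold h and c unchanged, so the state at step T is
## the state at each sequence's true final residue.
lstm_forward <- function(emb, wts, idx, keep_cache = FALSE) {
  n <- nrow(idx); tmax <- ncol(idx); h_dim <- ncol(wts$U)/4L
  xall <- emb[as.vector(idx) + 1L, , drop = FALSE]      # (n*tmax) x d, t-major
  gin <- add_bias(xall %*% wts$W, wts$b)                # precomputed input part
  hs <- matrix(0, n, h_dim); cs <- matrix(0, n, h_dim)
  cache <- if (keep_cache) vector("list", tmax)
  i1 <- 1:h_dim; i2 <- (h_dim + 1L):(2L * h_dim)
  i3 <- (2L * h_dim + 1L):(3L * h_dim); i4 <- (3L * h_dim + 1L):(4L * h_dim)
  for (t in seq_len(tmax)) {
    rows <- ((t - 1L) * n + 1L):(t * n)
    g <- gin[rows, , drop = FALSE] + hs %*% wts$U
    gi <- sigmoid(g[, i1, drop = FALSE])
    gf <- sigmoid(g[, i2, drop = FALSE])
    go <- sigmoid(g[, i3, drop = FALSE])
    gc <- tanh(g[, i4, drop = FALSE])
    c_new <- gf * cs + gi * gc
    tanh_c <- tanh(c_new)
    h_new <- go * tanh_c
    m <- as.numeric(idx[, t] > 0L)
    if (keep_cache)
      cache[[t]] <- list(gi = gi, gf = gf, go = go, gc = gc, c_prev = cs,
                         h_prev = hs, tanh_c = tanh_c, m = m)
    hs <- h_new * m + hs * (1 - m)
    cs <- c_new * m + cs * (1 - m)
  }
  list(h = hs, cache = cache, xall = xall, idx = idx)
}

## Backpropagation through time for one LSTM direction; dh_final is the
## gradient arriving at the final hidden state. Returns weight grads and the
## embedding-table gradient contribution.
lstm_backward <- function(emb, wts, fwd, dh_final) {
  idx <- fwd$idx; cache <- fwd$cache
  n <- nrow(idx); tmax <- ncol(idx); h_dim <- ncol(dh_final)
  dh <- dh_final; dc <- matrix(0, n, h_dim)
  dgall <- matrix(0, n * tmax, 4L * h_dim)
  du <- matrix(0, h_dim, 4L * h_dim); db <- numeric(4L * h_dim)
  for (t in rev(seq_len(tmax))) {
    ch <- cache[[t]]; m <- ch$m
    dh_eff <- dh * m; dc_eff <- dc * m
    do_ <- dh_eff * ch$tanh_c
    dct <- dc_eff + dh_eff * ch$go * (1 - ch$tanh_c^2)
    dgi <- dct * ch$gc * ch$gi * (1 - ch$gi)
    dgf <- dct * ch$c_prev * ch$gf * (1 - ch$gf)
    dgo <- do_ * ch$go * (1 - ch$go)
    dgc <- dct * ch$gi * (1 - ch$gc^2)
    dg <- cbind(dgi, dgf, dgo, dgc)
    rows <- ((t - 1L) * n + 1L):(t * n)
    dgall[rows, ] <- dg
    du <- du + crossprod(ch$h_prev, dg)
    db <- db + colSums(dg)
    dh <- dg %*% t(wts$U) + dh * (1 - m)
    dc <- dct * ch$gf + dc * (1 - m)
  }
  dw <- crossprod(fwd$xall, dgall)
  dxall <- dgall %*% t(wts$W)
  grp <- as.vector(idx)
  demb_rows <- rowsum(dxall, group = grp)                # by residue index
  demb <- matrix(0, 21L, ncol(emb))
  present <- as.integer(rownames(demb_rows))
  keep <- present > 0L                                   # padding row stays 0
  demb[present[keep] + 1L, ] <- demb_rows[keep, , drop = FALSE]
  list(W = dw, U = du, b = db, emb = demb)
}

## Dense stack with ReLU and inverted dropout; returns output and caches.
dense_forward <- function(x, layers, dropout = 0, training = FALSE) {
  caches <- vector("list", length(layers))
  a <- x
  for (l in seq_along(layers)) {
    z <- add_bias(a %*% layers[[l]]$W, layers[[l]]$b)
    act <- pmax(z, 0)
    dmask <- NULL
    if (training && dropout > 0) {
      keep <- 1 - dropout
      dmask <- matrix((runif(length(act)) < keep) / keep, nrow(act))
      act <- act * dmask
    }
    caches[[l]] <- list(a_prev = a, z = z, dmask = dmask)
    a <- act
  }
  list(out = a, caches = caches)
}

dense_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ch <- caches[[l]]
    if (!is.null(ch$dmask)) dout <- dout * ch$dmask
    dz <- dout * (ch$z > 0)
    grads[[l]] <- list(W = crossprod(ch$a_prev, dz), b = colSums(dz))
    dout <- dz %*% t(layers[[l]]$W)
  }
  list(grads = grads, dinput = dout)
}

## Reverse each row's valid prefix so the backward LSTM direction reads the
## sequence end-to-start while padding stays trailing.
reverse_encoded <- function(idx) {
  out <- idx
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, idx[i, ] > 0L]
    out[i, seq_along(v)] <- rev(v)
  }
  out
}

## Full forward pass. inputs: list(manual, encoded, encoded_rev).
model_forward <- function(params, config, inputs, training = FALSE,
                          keep_cache = FALSE) {
  parts <- list(); fwd <- list()
  if (use_ae(config)) {
    fwd$lf <- lstm_forward(params$emb, params$lf, inputs$encoded, keep_cache)
    fwd$lb <- lstm_forward(params$emb, params$lb, inputs$encoded_rev,
                           keep_cache)
    parts$ae <- cbind(fwd$lf$h, fwd$lb$h)
  }
  if (use_ms(config)) {
    fwd$ms <- dense_forward(inputs$manual, params$ms, config$dropout,
                            training)
    parts$ms <- fwd$ms$out
  }
  merged <- do.call(cbind, unname(parts))
  fwd$head <- dense_forward(merged, params$head, config$dropout, training)
  z_out <- add_bias(fwd$head$out %*% params$out$W, params$out$b)
  score <- sigmoid(z_out)
  list(score = as.vector(score), merged = merged, fwd = fwd,
       penultimate = fwd$head$out)
}

model_backward <- function(params, config, inputs, fpass, y) {
  n <- length(y)
  dz <- matrix((fpass$score - y) / n, ncol = 1L)   # BCE + sigmoid
  grads <- list(out = list(W = crossprod(fpass$fwd$head$out, dz),
                           b = colSums(dz)))
  dhead_out <- dz %*% t(params$out$W)
  hb <- dense_backward(params$head, fpass$fwd$head$caches, dhead_out)
  grads$head <- hb$grads
  dmerged <- hb$dinput
  off <- 0L
  if (use_ae(config)) {
    h <- config$rnn_units
    dlf <- dmerged[, 1:h, drop = FALSE]
    dlb <- dmerged[, (h + 1L):(2L * h), drop = FALSE]
    gf <- lstm_backward(params$emb, params$lf, fpass$fwd$lf, dlf)
    gb <- lstm_backward(params$emb, params$lb, fpass$fwd$lb, dlb)
    grads$lf <- gf[c("W", "U", "b")]
    grads$lb <- gb[c("W", "U", "b")]
    grads$emb <- gf$emb + gb$emb
    off <- 2L * h
  }
  if (use_ms(config)) {
    dms <- dmerged[, (off + 1L):ncol(dmerged), drop = FALSE]
    mb <- dense_backward(params$ms, fpass$fwd$ms$caches, dms)
    grads$ms <- mb$grads
  }
  grads
}

## --- Adam over the nested parameter tree ------------------------------

tree_zero <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, tree_zero)
}

adam_step <- function(p, g, m, v, lr_t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.numeric(p)) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr_t * m / (sqrt(v) + eps)
    return(list(p = p, m = m, v = v))
  }
  keys <- if (is.null(names(p))) seq_along(p) else names(p)
  for (k in keys) {
    r <- adam_step(p[[k]], g[[k]], m[[k]], v[[k]], lr_t, beta1, beta2, eps)
    p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
  }
  list(p = p, m = m, v = v)
}

bce_loss <- function(y, score) {
  eps <- 1e-12
  -mean(y * log(score + eps) + (1 - y) * log(1 - score + eps))
}

prepare_inputs <- function(model, features) {
  inputs <- list()
  if (use_ms(model$config)) {
    x <- features$manual
    if (!is.null(model$preproc)) {
      x <- sweep(x, 2L, model$preproc$mean, "-")
      x <- sweep(x, 2L, model$preproc$sd, "/")
    }
    inputs$manual <- x
  }
  if (use_ae(model$config)) {
    inputs$encoded <- features$encoded
    inputs$encoded_rev <- reverse_encoded(features$encoded)
  }
  inputs
}

subset_inputs <- function(inputs, ix) {
  lapply(inputs, function(m) m[ix, , drop = FALSE])
}

#' Train the hybrid classifier
#'
#' Minimizes binary cross-entropy with Adam over minibatches; after each
#' epoch the validation loss is evaluated and early stopping with the
#' configured patience restores the best-epoch weights. Deterministic under
#' `config$seed` (single-threaded BLAS assumed; the R RNG drives
#' initialization, shuffling and dropout).
#'
#' @param train,validation labeled `peptide_set`s (both classes present in
#'   `train`; `validation` non-empty).
#' @param config an [acpnet_config()].
#' @param paac_pars,charge_pars feature parameters, frozen into the model.
#' @param verbose print per-epoch progress.
#' @return trained `acpnet_model` with `$history` (per-epoch train/validation
#'   loss and accuracy) and frozen feature preprocessing.
#' @export
acpnet_train <- function(train, validation, config = acpnet_config(),
                         paac_pars = paac_params(),
                         charge_pars = charge_params(), verbose = FALSE) {
  stopifnot(inherits(train, "peptide_set"),
            inherits(validation, "peptide_set"))
  if (nrow(validation) == 0L) stop("empty validation set")
  if (length(unique(train$label)) < 2L)
    stop("training set must contain both classes")
  max_len <- config$max_len
  if (is.null(max_len)) max_len <- max(nchar(train$seq))
  config$max_len <- as.integer(max_len)

  ftr <- featurize_dataset(train, paac_pars, charge_pars, max_len)
  fva <- featurize_dataset(validation, paac_pars, charge_pars, max_len)

  model <- acpnet_build(config, n_manual = ncol(ftr$manual))
  model$paac_pars <- paac_pars
  model$charge_pars <- charge_pars
  if (use_ms(config) && config$normalize_manual) {
    mu <- colMeans(ftr$manual)
    sdev <- apply(ftr$manual, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    model$preproc <- list(mean = mu, sd = sdev)
  }
  in_tr <- prepare_inputs(model, ftr)
  in_va <- prepare_inputs(model, fva)
  y_tr <- ftr$labels; y_va <- fva$labels

  p <- model$params
  m_state <- tree_zero(p); v_state <- tree_zero(p)
  step <- 0L
  best <- list(loss = Inf, params = p, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  n <- length(y_tr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq(1L, n, by = config$batch_size)
    for (bs in batch_starts) {
      ix <- ord[bs:min(bs + config$batch_size - 1L, n)]
      bi <- subset_inputs(in_tr, ix)
      fp <- model_forward(p, config, bi, training = TRUE, keep_cache = TRUE)
      if (!is.finite(bce_loss(y_tr[ix], fp$score)))
        stop("NaN/Inf loss at epoch ", epoch, "; aborting")
      g <- model_backward(p, config, bi, fp, y_tr[ix])
      step <- step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - 0.999^step) / (1 - 0.9^step)
      upd <- adam_step(p, g, m_state, v_state, lr_t)
      p <- upd$p; m_state <- upd$m; v_state <- upd$v
    }
    sc_tr <- model_forward(p, config, in_tr)$score
    sc_va <- model_forward(p, config, in_va)$score
    row <- data.frame(
      epoch = epoch,
      train_loss = bce_loss(y_tr, sc_tr),
      train_acc = mean((sc_tr > config$threshold) == (y_tr == 1L)),
      val_loss = bce_loss(y_va, sc_va),
      val_acc = mean((sc_va > config$threshold) == (y_va == 1L)))
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, row$train_loss, row$train_acc, row$val_loss, row$val_acc))
    if (row$val_loss < best$loss)
      best <- list(loss = row$val_loss, params = p, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model$config <- config
  model
}

#' Predict anticancer-peptide scores
#'
#' @param object trained `acpnet_model`.
#' @param newdata a `peptide_set` (or character vector of sequences).
#' @param threshold decision threshold; scores strictly greater are labeled
#'   ACP (a score of exactly the threshold is non-ACP).
#' @param ... unused.
#' @return data.frame with id, seq, score and label (1 = ACP) columns, input
#'   order preserved.
#' @export
predict.acpnet_model <- function(object, newdata,
                                 threshold = object$config$threshold, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  if (is.character(newdata))
    newdata <- new_peptide_set(paste0("seq", seq_along(newdata)), newdata)
  stopifnot(inherits(newdata, "peptide_set"))
  feats <- featurize_dataset(newdata, object$paac_pars, object$charge_pars,
                             object$config$max_len)
  inputs <- prepare_inputs(object, feats)
  score <- model_forward(object$params, object$config, inputs)$score
  data.frame(id = newdata$id, seq = newdata$seq, score = score,
             label = as.integer(score > threshold),
             stringsAsFactors = FALSE)
}

#' Extract the penultimate-layer ("media") vectors
#'
#' Activations of the layer immediately before the sigmoid output, one row
#' per peptide; these condense both branches and feed external 2-D
#' projections (UMAP/t-SNE style) for visualizing class separation.
#'
#' @param model trained `acpnet_model`.
#' @param peptides a `peptide_set`.
#' @return numeric matrix, N x penultimate-width.
#' @export
extract_inner <- function(model, peptides) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  stopifnot(inherits(peptides, "peptide_set"))
  feats <- featurize_dataset(peptides, model$paac_pars, model$charge_pars,
                             model$config$max_len)
  inputs <- prepare_inputs(model, feats)
  out <- model_forward(model$params, model$config, inputs)$penultimate
  rownames(out) <- peptides$id
  out
}

ACPNET_CHECKPOINT_VERSION <- 1L

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive holding a format version, the full
#' configuration, weights, feature parameters and frozen preprocessing
#' statistics; predictions from a reloaded model are bit-identical.
#'
#' @param model trained `acpnet_model`.
#' @param path file path.
#' @return `acpnet_save` returns `path` invisibly; `acpnet_load` the model.
#' @export
acpnet_save <- function(model, path) {
  stopifnot(inherits(model, "acpnet_model"))
  obj <- unclass(model)
  obj$format_version <- ACPNET_CHECKPOINT_VERSION
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname acpnet_save
#' @export
acpnet_load <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$format_version))
    stop("corrupted or foreign checkpoint (no format version)")
  if (obj$format_version > ACPNET_CHECKPOINT_VERSION)
    stop("checkpoint format version ", obj$format_version,
         " is newer than this package supports")
  obj$format_version <- NULL
  structure(obj, class = "acpnet_model")
}

#' @export
print.acpnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("hybrid ACP classifier (mode %s, %s)\n", cfg$mode,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  if (use_ae(cfg))
    cat(sprintf("  embedding 21x%d -> BiLSTM %d/direction\n",
                cfg$embed_dim, cfg$rnn_units))
  if (use_ms(cfg))
    cat(sprintf("  manual branch %s\n",
                paste(c(x$n_manual, cfg$dense_units), collapse = "-")))
  cat(sprintf("  head %s-1 (sigmoid), dropout %.2f\n",
              paste(cfg$head_units, collapse = "-"), cfg$dropout))
  if (isTRUE(x$trained))
    cat(sprintf("  best epoch %d, validation loss %.4f\n", x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  invisible(x)
}
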