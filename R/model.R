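#' Model architecture configuration
#'
#' @param embed_dim token embedding width (default 128; must be divisible
#'   by `n_heads`).
#' @param n_heads number of attention heads (default 4).
#' @param n_classes number of output classes (default 3).
#' @param hidden_dims hidden widths of the post-fusion MLP (default
#'   `c(256, 64)`).
#' @param dropout dropout fraction applied to MLP hidden activations during
#'   training (default 0.1).
#' @return A list of class `model_config`.
#' @export
model_config <- function(embed_dim = 128L, n_heads = 4L, n_classes = 3L,
                         hidden_dims = c(256L, 64L), dropout = 0.1) {
  embed_dim <- as.integer(embed_dim)
  n_heads <- as.integer(n_heads)
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  stopifnot(dropout >= 0, dropout < 1, n_classes >= 2L)
  structure(list(embed_dim = embed_dim, n_heads = n_heads,
                 n_classes = as.integer(n_classes),
                 hidden_dims = as.integer(hidden_dims), dropout = dropout),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the published optimum: SGD with learning rate 1e-4,
#' weight decay 1e-4 and momentum 0.9. Model selection uses the weighted F1
#' score on the validation set (first epoch attaining the maximum).
#'
#' @param lr learning rate (default 0.0001).
#' @param weight_decay L2 penalty coefficient on weight matrices
#'   (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param epochs training epochs (default 500).
#' @param batch_size minibatch size (default 128).
#' @param seed integer seed covering initialization, batch shuffling and
#'   dropout.
#' @param clip_norm global gradient-norm ceiling (default 5; keeps training
#'   finite across the learning-rate sensitivity sweep).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, momentum = 0.9,
                         epochs = 500L, batch_size = 128L, seed = 1L,
                         clip_norm = 5) {
  stopifnot(lr > 0, weight_decay >= 0, momentum >= 0, momentum < 1,
            epochs >= 1L, batch_size >= 1L, clip_norm > 0)
  structure(list(lr = lr, weight_decay = weight_decay, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), clip_norm = clip_norm),
            class = "train_config")
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Fresh parameter set; draws from the current RNG stream.
init_params <- function(mcfg, slices) {
  d <- mcfg$embed_dim
  dims <- c(length(slices) * d, mcfg$hidden_dims, mcfg$n_classes)
  list(
    W_in = lapply(slices, function(sl) xavier(length(sl), d)),
    b_in = lapply(slices, function(sl) numeric(d)),
    Wq = xavier(d, d), bq = numeric(d),
    Wk = xavier(d, d), bk = numeric(d),
    Wv = xavier(d, d), bv = numeric(d),
    Wo = xavier(d, d), bo = numeric(d),
    W_mlp = lapply(seq_len(length(dims) - 1L),
                   function(i) xavier(dims[i], dims[i + 1L])),
    b_mlp = lapply(seq_len(length(dims) - 1L),
                   function(i) numeric(dims[i + 1L]))
  )
}

#' Scaled dot-product attention (single head)
#'
#' `weights = row-softmax(Q %*% t(K) / sqrt(ncol(K)))`;
#' `output = weights %*% V`.
#'
#' @param Q,K,V conforming `tokens x d_head` matrices.
#' @return A list with elements `output` (`tokens x d_head`) and `weights`
#'   (`tokens x tokens`, rows summing to 1).
#' @export
#' @examples
#' a <- scaled_dot_product_attention(diag(2), diag(2), diag(2))
#' rowSums(a$weights)
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop("shape mismatch: need ncol(Q) == ncol(K) and nrow(K) == nrow(V)")
  }
  w <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = w %*% V, weights = w)
}

# Full forward pass over a batch. Returns probabilities plus (optionally)
# every intermediate needed by the backward pass. Dropout masks are drawn
# from the current RNG stream only when training = TRUE and dropout > 0.
attn_forward <- function(params, X, mcfg, slices, training = FALSE) {
  B <- nrow(X)
  S <- length(slices)
  d <- mcfg$embed_dim
  H <- mcfg$n_heads
  dh <- d %/% H
  scale <- 1 / sqrt(dh)

  Tok <- vector("list", S)
  for (s in seq_len(S)) {
    Tok[[s]] <- X[, slices[[s]], drop = FALSE] %*% params$W_in[[s]]
    Tok[[s]] <- sweep(Tok[[s]], 2L, params$b_in[[s]], "+")
  }
  Q <- lapply(Tok, function(t) sweep(t %*% params$Wq, 2L, params$bq, "+"))
  K <- lapply(Tok, function(t) sweep(t %*% params$Wk, 2L, params$bk, "+"))
  V <- lapply(Tok, function(t) sweep(t %*% params$Wv, 2L, params$bv, "+"))

  head_cols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  # attention weights per (source scale, head): B x S matrices over targets
  AW <- vector("list", S)
  O <- vector("list", S)   # attended tokens before the output projection
  for (s in seq_len(S)) {
    AW[[s]] <- vector("list", H)
    O[[s]] <- matrix(0, B, d)
    for (h in seq_len(H)) {
      ch <- head_cols[[h]]
      logits <- matrix(0, B, S)
      for (t in seq_len(S)) {
        logits[, t] <- rowSums(Q[[s]][, ch, drop = FALSE] *
                               K[[t]][, ch, drop = FALSE]) * scale
      }
      w <- softmax_rows(logits)
      AW[[s]][[h]] <- w
      acc <- matrix(0, B, dh)
      for (t in seq_len(S)) {
        acc <- acc + w[, t] * V[[t]][, ch, drop = FALSE]
      }
      O[[s]][, ch] <- acc
    }
  }
  A <- lapply(O, function(o) sweep(o %*% params$Wo, 2L, params$bo, "+"))
  Fus <- do.call(cbind, A)

  n_layers <- length(params$W_mlp)
  pre <- vector("list", n_layers)
  act <- vector("list", n_layers)
  mask <- vector("list", n_layers)
  cur <- Fus
  p <- mcfg$dropout
  for (l in seq_len(n_layers)) {
    pre[[l]] <- sweep(cur %*% params$W_mlp[[l]], 2L, params$b_mlp[[l]], "+")
    if (l < n_layers) {
      a <- pmax(pre[[l]], 0)
      if (training && p > 0) {
        m <- matrix(runif(length(a)) >= p, nrow(a), ncol(a)) / (1 - p)
        mask[[l]] <- m
        a <- a * m
      }
      act[[l]] <- a
      cur <- a
    }
  }
  probs <- softmax_rows(pre[[n_layers]])
  out <- list(probs = probs)
  if (training) {
    out$cache <- list(X = X, Tok = Tok, Q = Q, K = K, V = V, AW = AW, O = O,
                      A = A, Fus = Fus, pre = pre, act = act, mask = mask,
                      head_cols = head_cols, scale = scale)
  }
  out
}

# Cross-entropy loss and full parameter gradient for one batch.
attn_backward <- function(params, mcfg, slices, cache, probs, Y) {
  B <- nrow(probs)
  S <- length(slices)
  d <- mcfg$embed_dim
  H <- mcfg$n_heads
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), Y)], eps)))

  g <- list(W_in = vector("list", S), b_in = vector("list", S),
            W_mlp = vector("list", length(params$W_mlp)),
            b_mlp = vector("list", length(params$b_mlp)))

  # --- MLP ---
  dZ <- probs
  dZ[cbind(seq_len(B), Y)] <- dZ[cbind(seq_len(B), Y)] - 1
  dZ <- dZ / B
  n_layers <- length(params$W_mlp)
  dcur <- dZ
  for (l in rev(seq_len(n_layers))) {
    inp <- if (l == 1L) cache$Fus else cache$act[[l - 1L]]
    g$W_mlp[[l]] <- crossprod(inp, dcur)
    g$b_mlp[[l]] <- colSums(dcur)
    if (l > 1L) {
      da <- dcur %*% t(params$W_mlp[[l]])
      if (!is.null(cache$mask[[l - 1L]])) da <- da * cache$mask[[l - 1L]]
      dcur <- da * (cache$pre[[l - 1L]] > 0)
    } else {
      dFus <- dcur %*% t(params$W_mlp[[1L]])
    }
  }

  # --- output projection ---
  dA <- lapply(seq_len(S), function(s) dFus[, ((s - 1L) * d + 1L):(s * d),
                                             drop = FALSE])
  g$Wo <- matrix(0, d, d); g$bo <- numeric(d)
  dO <- vector("list", S)
  for (s in seq_len(S)) {
    g$Wo <- g$Wo + crossprod(cache$O[[s]], dA[[s]])
    g$bo <- g$bo + colSums(dA[[s]])
    dO[[s]] <- dA[[s]] %*% t(params$Wo)
  }

  # --- attention ---
  dQ <- lapply(seq_len(S), function(s) matrix(0, B, d))
  dK <- dQ; dV <- dQ
  for (s in seq_len(S)) {
    for (h in seq_len(H)) {
      ch <- cache$head_cols[[h]]
      dOh <- dO[[s]][, ch, drop = FALSE]
      w <- cache$AW[[s]][[h]]
      dw <- matrix(0, B, S)
      for (t in seq_len(S)) {
        dw[, t] <- rowSums(dOh * cache$V[[t]][, ch, drop = FALSE])
        dV[[t]][, ch] <- dV[[t]][, ch, drop = FALSE] + w[, t] * dOh
      }
      dlog <- w * (dw - rowSums(dw * w))  # softmax backward, row-wise
      for (t in seq_len(S)) {
        dQ[[s]][, ch] <- dQ[[s]][, ch, drop = FALSE] +
          dlog[, t] * cache$K[[t]][, ch, drop = FALSE] * cache$scale
        dK[[t]][, ch] <- dK[[t]][, ch, drop = FALSE] +
          dlog[, t] * cache$Q[[s]][, ch, drop = FALSE] * cache$scale
      }
    }
  }

  # --- Q/K/V projections back to tokens ---
  g$Wq <- matrix(0, d, d); g$Wk <- matrix(0, d, d); g$Wv <- matrix(0, d, d)
  g$bq <- numeric(d); g$bk <- numeric(d); g$bv <- numeric(d)
  for (s in seq_len(S)) {
    Tok <- cache$Tok[[s]]
    g$Wq <- g$Wq + crossprod(Tok, dQ[[s]]); g$bq <- g$bq + colSums(dQ[[s]])
    g$Wk <- g$Wk + crossprod(Tok, dK[[s]]); g$bk <- g$bk + colSums(dK[[s]])
    g$Wv <- g$Wv + crossprod(Tok, dV[[s]]); g$bv <- g$bv + colSums(dV[[s]])
    dTok <- dQ[[s]] %*% t(params$Wq) + dK[[s]] %*% t(params$Wk) +
            dV[[s]] %*% t(params$Wv)
    g$W_in[[s]] <- crossprod(cache$X[, slices[[s]], drop = FALSE], dTok)
    g$b_in[[s]] <- colSums(dTok)
  }
  list(loss = loss, grads = g)
}

# Flatten-free helpers over the nested parameter/gradient lists.
param_walk <- function(p, g, fun) {
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")) {
    p[[nm]] <- fun(p[[nm]], g[[nm]], nm)
  }
  for (nm in c("W_in", "b_in", "W_mlp", "b_mlp")) {
    for (i in seq_along(p[[nm]])) {
      p[[nm]][[i]] <- fun(p[[nm]][[i]], g[[nm]][[i]], nm)
    }
  }
  p
}

grad_sq_norm <- function(g) {
  tot <- 0
  param_walk(g, g, function(x, ...) { tot <<- tot + sum(x^2); x })
  tot
}

#' Train the multi-scale attention classifier
#'
#' Minimizes multinomial cross-entropy with SGD (momentum, weight decay on
#' weight matrices, global gradient-norm clipping). Features are
#' standardized column-wise with training-set statistics (stored in the
#' returned state). Validation accuracy, macro F1 and weighted F1 are
#' recorded each epoch; the returned parameters are the snapshot from the
#' first epoch attaining the maximum validation weighted F1. Fully
#' deterministic given `tcfg$seed` (initialization, batch order, dropout).
#'
#' @param train_fm,val_fm `feature_matrix` objects (see [featurize()]) whose
#'   `labels` attributes are fully labelled.
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param class_names optional ordered class names; defaults to sorted
#'   unique training labels.
#' @param verbose print a progress line every 25 epochs.
#' @return An `attention_classifier`: list with `params` (best snapshot),
#'   `history` (per-epoch data.frame), `best_epoch`, `scaler`, `mcfg`,
#'   `class_names`, `feature_names`, `scale_slices`.
#' @export
train_classifier <- function(train_fm, val_fm, mcfg = model_config(),
                             tcfg = train_config(), class_names = NULL,
                             verbose = FALSE) {
  y_train <- attr(train_fm, "labels")
  y_val <- attr(val_fm, "labels")
  if (anyNA(y_train) || anyNA(y_val)) stop("all records must be labelled")
  if (is.null(class_names)) class_names <- sort(unique(y_train))
  if (length(unique(y_train)) < 2L) {
    stop("training set contains a single class")
  }
  if (!nrow(val_fm)) stop("validation set is empty")
  mcfg$n_classes <- length(class_names)
  slices <- attr(train_fm, "scale_slices")
  if (is.null(slices)) slices <- list(all = seq_len(ncol(train_fm)))

  mu <- colMeans(train_fm)
  sdv <- apply(train_fm, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Xtr <- sweep(sweep(unclass(train_fm), 2L, mu), 2L, sdv, "/")
  Xva <- sweep(sweep(unclass(val_fm), 2L, mu), 2L, sdv, "/")
  Ytr <- match(y_train, class_names)

  set.seed(tcfg$seed)
  params <- init_params(mcfg, slices)
  vel <- param_walk(params, params, function(x, ...) x * 0)

  n <- nrow(Xtr)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric(), val_f1_macro = numeric(),
                        val_f1_weighted = numeric())
  best <- list(f1w = -Inf, epoch = NA_integer_, params = NULL)
  wd <- tcfg$weight_decay

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      rows <- batches[[b]]
      fw <- attn_forward(params, Xtr[rows, , drop = FALSE], mcfg, slices,
                         training = TRUE)
      bk <- attn_backward(params, mcfg, slices, fw$cache, fw$probs, Ytr[rows])
      losses[b] <- bk$loss
      if (!is.finite(bk$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             "; try a smaller learning rate")
      }
      g <- bk$grads
      # L2 weight decay on weight matrices only
      g <- param_walk(g, params, function(gx, px, nm) {
        if (startsWith(nm, "W")) gx + wd * px else gx
      })
      gn <- sqrt(grad_sq_norm(g))
      if (gn > tcfg$clip_norm) {
        sc <- tcfg$clip_norm / gn
        g <- param_walk(g, g, function(gx, ...) gx * sc)
      }
      vel <- param_walk(vel, g, function(v, gx, nm) tcfg$momentum * v + gx)
      params <- param_walk(params, vel, function(px, v, nm) px - tcfg$lr * v)
    }
    val_probs <- attn_forward(params, Xva, mcfg, slices)$probs
    val_pred <- class_names[max.col(val_probs, ties.method = "first")]
    # early epochs may leave a class unpredicted; the 0/0 -> 0 rule applies
    rep_val <- suppressWarnings(
      compute_metrics(confusion_matrix(y_val, val_pred, class_names)))
    history[epoch, ] <- list(epoch, mean(losses), rep_val$accuracy,
                             rep_val$f1_macro, rep_val$f1_weighted)
    if (rep_val$f1_weighted > best$f1w) {
      best <- list(f1w = rep_val$f1_weighted, epoch = epoch, params = params)
    }
    if (verbose && (epoch %% 25L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  loss %.4f  val F1w %.4f",
                      epoch, mean(losses), rep_val$f1_weighted))
    }
  }

  structure(list(params = best$params, history = history,
                 best_epoch = best$epoch,
                 scaler = list(mean = mu, sd = sdv),
                 mcfg = mcfg, class_names = class_names,
                 feature_names = colnames(train_fm),
                 scale_slices = slices, tcfg = tcfg),
            class = "attention_classifier")
}

#' Class probabilities from a trained classifier
#'
#' Pure function of the inputs (dropout disabled); probability rows sum
#' to 1.
#'
#' @param state an `attention_classifier` from [train_classifier()].
#' @param features a `feature_matrix` (or plain matrix) with the columns the
#'   state was trained on.
#' @return Numeric matrix of per-class probabilities (columns named by
#'   class).
#' @export
model_forward <- function(state, features) {
  stopifnot(inherits(state, "attention_classifier"))
  X <- unclass(features)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(state$feature_names)) {
    stop("feature column count (", ncol(X), ") does not match the ",
         length(state$feature_names), " columns the model was trained on (",
         "k-mer scales: ", paste(names(state$scale_slices), collapse = "+"),
         ")")
  }
  X <- sweep(sweep(X, 2L, state$scaler$mean), 2L, state$scaler$sd, "/")
  probs <- attn_forward(state$params, X, state$mcfg, state$scale_slices)$probs
  colnames(probs) <- state$class_names
  rownames(probs) <- rownames(features)
  probs
}

#' Predict class labels
#'
#' Labels are the argmax class; exact ties break to the earlier class in
#' `class_names` order.
#'
#' @param object an `attention_classifier`.
#' @param features a `feature_matrix` or plain matrix.
#' @param ... unused.
#' @return A `data.frame` with `id`, `label` and one probability column per
#'   class.
#' @export
predict.attention_classifier <- function(object, features, ...) {
  probs <- model_forward(object, features)
  label <- object$class_names[max.col(probs, ties.method = "first")]
  out <- data.frame(id = rownames(probs) %||% seq_len(nrow(probs)),
                    label = label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs, row.names = FALSE))
}

#' Evaluate a classifier on a labelled feature matrix
#'
#' @param state an `attention_classifier`.
#' @param features a `feature_matrix` with a `labels` attribute.
#' @return A [compute_metrics()] report; attribute `confusion` holds the
#'   confusion matrix.
#' @export
evaluate_classifier <- function(state, features) {
  y <- attr(features, "labels")
  if (is.null(y) || anyNA(y)) stop("features must carry complete labels")
  pred <- predict(state, features)$label
  cm <- confusion_matrix(y, pred, state$class_names)
  rep <- compute_metrics(cm)
  attr(rep, "confusion") <- cm
  rep
}

#' Scale-ablation experiment
#'
#' Trains one model per k-mer scale subset under identical configuration and
#' seed, and reports validation and test weighted F1 for each.
#'
#' @param dataset a curated, split, labelled [rna_set()].
#' @param scale_subsets list of integer vectors of k values, e.g.
#'   `list(3, c(3, 4, 5))`.
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @return A `data.frame` with columns `scales`, `val_f1_weighted`,
#'   `test_f1_weighted`, `best_epoch`.
#' @export
ablate_scales <- function(dataset, scale_subsets, mcfg = model_config(),
                          tcfg = train_config()) {
  stopifnot(length(scale_subsets) >= 1L)
  rows <- lapply(scale_subsets, function(ks) {
    spec <- kmer_spec(ks)
    fm <- featurize(dataset, "multiscale", spec = spec)
    spl <- attr(fm, "splits")
    state <- train_classifier(fm_subset(fm, spl == "train"),
                              fm_subset(fm, spl == "val"),
                              mcfg = mcfg, tcfg = tcfg,
                              class_names = class_names(dataset))
    val_rep <- evaluate_classifier(state, fm_subset(fm, spl == "val"))
    test_rep <- evaluate_classifier(state, fm_subset(fm, spl == "test"))
    data.frame(scales = paste(ks, collapse = "+"),
               val_f1_weighted = val_rep$f1_weighted,
               test_f1_weighted = test_rep$f1_weighted,
               best_epoch = state$best_epoch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
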