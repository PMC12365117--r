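# Bidirectional recurrent network for sequence-to-sequence regression of a
# gene's expression trajectory from the accessibility trajectories of its
# linked cCREs. Implemented in plain matrix code: a tanh RNN over the T time
# steps in each direction (hidden size h per direction), per-step
# concatenated states (2h) -> dense(d) -> ReLU -> dense(1), trained with
# mean per-sample MSE loss and Adam. Dense-head weights are shared across
# time steps.

#' Default predictor configuration
#'
#' @param hidden_size Hidden units per RNN direction.
#' @param dense_size Units of the dense head.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam initial learning rate.
#' @param epochs Training epochs.
#' @param split Training fraction of the train/test split.
#' @param seed Seed governing split, initialization and shuffling.
#' @return List of class `predictor_config`.
#' @export
predictor_config <- function(hidden_size = 30, dense_size = 10,
                             batch_size = 4, learning_rate = 1e-4,
                             epochs = 200, split = 0.8, seed = 1) {
  stopifnot(hidden_size > 0, dense_size > 0, batch_size > 0,
            learning_rate > 0, epochs > 0, split > 0, split < 1)
  structure(list(hidden_size = hidden_size, dense_size = dense_size,
                 batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, split = split, seed = seed),
            class = "predictor_config")
}

#' Assemble the predictor input tensor from links and fitted trajectories
#'
#' For each gene, the fitted trajectories of its linked cCREs are stacked
#' closest-first (by proximity rank), truncated at `m` slots, and
#' zero-padded to exactly `m`; the gene's own fitted trajectory is the
#' regression target.
#'
#' @param links Link table with `ccre_id`, `gene_id`, `proximity_rank`
#'   (see [build_links()]).
#' @param ccre_fitted,gene_fitted Matrices of fitted trajectories, rows
#'   named by ids, columns = the T time points.
#' @param groups Optional named character vector (gene_id -> regulatory
#'   group).
#' @param m Number of cCRE feature slots.
#' @return List of class `predictor_input`: `x` (array genes x m x T), `y`
#'   (matrix genes x T), `gene_ids`, `group`, `m`, `T`.
#' @export
build_input <- function(links, ccre_fitted, gene_fitted, groups = NULL,
                        m = 60) {
  T_ <- ncol(gene_fitted)
  if (ncol(ccre_fitted) != T_)
    stop("cCRE and gene trajectories must cover the same time points")
  gene_ids <- intersect(unique(links$gene_id), rownames(gene_fitted))
  gene_ids <- sort(gene_ids)
  n <- length(gene_ids)
  x <- array(0, dim = c(n, m, T_))
  y <- matrix(NA_real_, n, T_, dimnames = list(gene_ids, colnames(gene_fitted)))
  for (i in seq_len(n)) {
    g <- gene_ids[i]
    d <- links[links$gene_id == g & links$ccre_id %in% rownames(ccre_fitted), ,
               drop = FALSE]
    d <- d[order(d$proximity_rank), , drop = FALSE]
    keep <- utils::head(d$ccre_id, m)
    if (length(keep) > 0)
      x[i, seq_along(keep), ] <- ccre_fitted[keep, , drop = FALSE]
    y[i, ] <- gene_fitted[g, ]
  }
  grp <- if (is.null(groups)) rep(NA_character_, n) else unname(groups[gene_ids])
  structure(list(x = x, y = y, gene_ids = gene_ids, group = grp,
                 m = m, T = T_), class = "predictor_input")
}

# time-step slice of a samples x m x T array, kept as a matrix even for a
# single sample
.xslice <- function(x, t) matrix(x[, , t], dim(x)[1], dim(x)[2])

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) initialization.
.init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Initialize a bidirectional RNN model
#'
#' @param m Input features per time step.
#' @param hidden_size,dense_size Layer sizes.
#' @param seed Seed for weight initialization.
#' @return List of class `birnn_model` holding the weight matrices.
#' @export
birnn_init <- function(m, hidden_size = 30, dense_size = 10, seed = 1) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old))
  set.seed(seed)
  h <- hidden_size; d <- dense_size
  structure(list(
    Wf = .init_mat(m, h, m), Uf = .init_mat(h, h, h), bf = rep(0, h),
    Wb = .init_mat(m, h, m), Ub = .init_mat(h, h, h), bb = rep(0, h),
    W1 = .init_mat(2 * h, d, 2 * h), b1 = rep(0, d),
    W2 = .init_mat(d, 1, d), b2 = 0,
    m = m, hidden_size = h, dense_size = d
  ), class = "birnn_model")
}

#' Forward pass of the bidirectional RNN
#'
#' @param model A `birnn_model`.
#' @param x Input array, samples x m x T.
#' @param keep_cache Keep intermediate activations (needed for gradients).
#' @return List with `pred` (samples x T) and, if requested, `cache`.
#' @export
birnn_forward <- function(model, x, keep_cache = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[2] == model$m)
  n <- dim(x)[1]; T_ <- dim(x)[3]; h <- model$hidden_size
  hf <- hb <- vector("list", T_)
  prev <- matrix(0, n, h)
  for (t in seq_len(T_)) {
    hf[[t]] <- tanh(.xslice(x, t) %*% model$Wf +
                    prev %*% model$Uf +
                    matrix(model$bf, n, h, byrow = TRUE))
    prev <- hf[[t]]
  }
  nxt <- matrix(0, n, h)
  for (t in rev(seq_len(T_))) {
    hb[[t]] <- tanh(.xslice(x, t) %*% model$Wb +
                    nxt %*% model$Ub +
                    matrix(model$bb, n, h, byrow = TRUE))
    nxt <- hb[[t]]
  }
  pred <- matrix(0, n, T_)
  Z1 <- A1 <- H <- vector("list", T_)
  for (t in seq_len(T_)) {
    H[[t]] <- cbind(hf[[t]], hb[[t]])
    Z1[[t]] <- H[[t]] %*% model$W1 +
      matrix(model$b1, n, model$dense_size, byrow = TRUE)
    A1[[t]] <- pmax(Z1[[t]], 0)
    pred[, t] <- A1[[t]] %*% model$W2 + model$b2
  }
  out <- list(pred = pred)
  if (keep_cache) out$cache <- list(hf = hf, hb = hb, H = H, Z1 = Z1, A1 = A1)
  out
}

#' Per-sample MSE and batch loss
#'
#' The per-sample MSE averages squared errors over the T time points; the
#' batch loss is the mean of the per-sample MSEs.
#'
#' @param true,pred Matrices, samples x T.
#' @return List with `per_sample_mse` and `loss`.
#' @export
birnn_loss <- function(true, pred) {
  stopifnot(all(dim(true) == dim(pred)))
  per <- rowMeans((true - pred)^2)
  list(per_sample_mse = per, loss = mean(per))
}

# Analytic gradients by backpropagation through time. Returns grads in the
# same layout as the model plus the loss.
.birnn_grad <- function(model, x, y) {
  fw <- birnn_forward(model, x, keep_cache = TRUE)
  cache <- fw$cache; pred <- fw$pred
  n <- dim(x)[1]; T_ <- dim(x)[3]; h <- model$hidden_size
  loss <- mean(rowMeans((y - pred)^2))
  dpred <- 2 * (pred - y) / (n * T_)

  g <- list(Wf = 0 * model$Wf, Uf = 0 * model$Uf, bf = 0 * model$bf,
            Wb = 0 * model$Wb, Ub = 0 * model$Ub, bb = 0 * model$bb,
            W1 = 0 * model$W1, b1 = 0 * model$b1,
            W2 = 0 * model$W2, b2 = 0)
  dH <- vector("list", T_)
  for (t in seq_len(T_)) {
    dp <- dpred[, t, drop = FALSE]            # n x 1
    g$W2 <- g$W2 + t(cache$A1[[t]]) %*% dp
    g$b2 <- g$b2 + sum(dp)
    dA1 <- dp %*% t(model$W2)                 # n x d
    dZ1 <- dA1 * (cache$Z1[[t]] > 0)
    g$W1 <- g$W1 + t(cache$H[[t]]) %*% dZ1
    g$b1 <- g$b1 + colSums(dZ1)
    dH[[t]] <- dZ1 %*% t(model$W1)            # n x 2h
  }
  # forward-direction BPTT (flows t -> t-1)
  carry <- matrix(0, n, h)
  for (t in rev(seq_len(T_))) {
    dhf <- dH[[t]][, seq_len(h), drop = FALSE] + carry
    dpre <- dhf * (1 - cache$hf[[t]]^2)
    g$Wf <- g$Wf + t(.xslice(x, t)) %*% dpre
    prev <- if (t > 1) cache$hf[[t - 1]] else matrix(0, n, h)
    g$Uf <- g$Uf + t(prev) %*% dpre
    g$bf <- g$bf + colSums(dpre)
    carry <- dpre %*% t(model$Uf)
  }
  # backward-direction BPTT (flows t -> t+1)
  carry <- matrix(0, n, h)
  for (t in seq_len(T_)) {
    dhb <- dH[[t]][, h + seq_len(h), drop = FALSE] + carry
    dpre <- dhb * (1 - cache$hb[[t]]^2)
    g$Wb <- g$Wb + t(.xslice(x, t)) %*% dpre
    nxt <- if (t < T_) cache$hb[[t + 1]] else matrix(0, n, h)
    g$Ub <- g$Ub + t(nxt) %*% dpre
    g$bb <- g$bb + colSums(dpre)
    carry <- dpre %*% t(model$Ub)
  }
  list(grads = g, loss = loss)
}

.param_names <- c("Wf", "Uf", "bf", "Wb", "Ub", "bb", "W1", "b1", "W2", "b2")

#' Train a bidirectional RNN on one sample set
#'
#' Minibatch Adam on the mean per-sample-MSE loss.
#'
#' @param x Input array, samples x m x T.
#' @param y Target matrix, samples x T.
#' @param config A [predictor_config()].
#' @param verify_loss If TRUE, assert on every step that the batch loss
#'   equals the mean of the per-sample MSEs.
#' @return List with `model` (trained `birnn_model`) and `history`
#'   (loss per epoch).
#' @export
birnn_train <- function(x, y, config = predictor_config(),
                        verify_loss = FALSE) {
  stopifnot(inherits(config, "predictor_config"),
            dim(x)[1] == nrow(y), dim(x)[3] == ncol(y))
  n <- dim(x)[1]
  model <- birnn_init(dim(x)[2], config$hidden_size, config$dense_size,
                      seed = config$seed)
  mstate <- vstate <- lapply(model[.param_names], function(p) 0 * p)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0
  history <- numeric(config$epochs)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old))
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      xb <- x[idx, , , drop = FALSE]; yb <- y[idx, , drop = FALSE]
      gr <- .birnn_grad(model, xb, yb)
      if (verify_loss) {
        lf <- birnn_loss(yb, birnn_forward(model, xb)$pred)
        stopifnot(abs(lf$loss - mean(lf$per_sample_mse)) < 1e-12)
      }
      step <- step + 1
      for (nm in .param_names) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr$grads[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr$grads[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + gr$loss * length(idx)
    }
    history[epoch] <- ep_loss / n
  }
  list(model = model, history = history)
}

#' Seed-reproducible train/test split
#'
#' @param n Number of samples.
#' @param split Training fraction.
#' @param seed Seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, split = 0.8, seed = 1) {
  old <- .Random.seed_exists(); on.exit(.restore_seed(old))
  set.seed(seed)
  n_train <- round(split * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train one predictor per regulatory group
#'
#' Splits each group's samples 80:20 (per `config$split`), trains a
#' bidirectional RNN per group, and evaluates on the held-out samples.
#' Groups with fewer than `min_samples` members are skipped with a warning.
#'
#' @param input A `predictor_input` (see [build_input()]) with group labels.
#' @param config A [predictor_config()].
#' @param min_samples Minimum samples per trainable group.
#' @return Named list per group: `model`, `history`, `test_idx`,
#'   `prediction` (true/predicted matrices plus [evaluate_predictions()]
#'   metrics on the held-out split).
#' @export
train_predictor <- function(input, config = predictor_config(),
                            min_samples = 5) {
  stopifnot(inherits(input, "predictor_input"))
  out <- list()
  for (grp in unique(stats::na.omit(input$group))) {
    sel <- which(input$group == grp)
    if (length(sel) < min_samples) {
      warning("group ", grp, " has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    sp <- split_train_test(length(sel), config$split, config$seed)
    tr <- sel[sp$train]; te <- sel[sp$test]
    fit <- birnn_train(input$x[tr, , , drop = FALSE],
                       input$y[tr, , drop = FALSE], config)
    pred <- birnn_forward(fit$model, input$x[te, , , drop = FALSE])$pred
    ev <- evaluate_predictions(input$y[te, , drop = FALSE], pred)
    out[[grp]] <- list(model = fit$model, history = fit$history,
                       test_idx = te,
                       prediction = c(list(true = input$y[te, , drop = FALSE],
                                           predicted = pred), ev))
  }
  out
}

#' Evaluate predicted against true trajectories
#'
#' Cross-gene r pools all (gene, time point) pairs into one Pearson
#' correlation; cross-timepoint r is the per-gene Pearson across the T
#' points (NA, flagged, for constant trajectories); per-sample MSE averages
#' squared error over time points.
#'
#' @param true,pred Matrices, samples x T.
#' @return List with `cross_gene_r`, `cross_timepoint_r` (vector),
#'   `per_sample_mse`, `excluded` (indices with undefined per-gene r).
#' @export
evaluate_predictions <- function(true, pred) {
  stopifnot(all(dim(true) == dim(pred)))
  cross_gene_r <- stats::cor(as.vector(true), as.vector(pred))
  ctr <- vapply(seq_len(nrow(true)), function(i) {
    if (stats::sd(true[i, ]) == 0 || stats::sd(pred[i, ]) == 0) NA_real_
    else stats::cor(true[i, ], pred[i, ])
  }, numeric(1))
  list(cross_gene_r = cross_gene_r, cross_timepoint_r = ctr,
       per_sample_mse = birnn_loss(true, pred)$per_sample_mse,
       excluded = which(is.na(ctr)))
}

#' Permutation feature importance of cCRE slots over time
#'
#' For every feature slot and time point, the slot's values at that time
#' point are permuted across the test samples and the mean increase in the
#' batch loss over `n_perm` permutations is recorded. Rows follow the
#' proximity-rank ordering of the input slots. Constant (e.g. zero-padded)
#' slots get importance 0 exactly.
#'
#' @param model Trained `birnn_model`.
#' @param x Test input array, samples x m x T.
#' @param y Test target matrix.
#' @param n_perm Permutations per (slot, time point).
#' @param seed Seed for the permutations.
#' @return m x T matrix of mean loss increases.
#' @export
feature_importance <- function(model, x, y, n_perm = 20, seed = 1) {
  stopifnot(dim(x)[1] >= 2)
  m <- dim(x)[2]; T_ <- dim(x)[3]; n <- dim(x)[1]
  base <- birnn_loss(y, birnn_forward(model, x)$pred)$loss
  imp <- matrix(0, m, T_)
  old <- .Random.seed_exists(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (j in seq_len(m)) {
    for (t in seq_len(T_)) {
      v <- x[, j, t]
      if (max(v) == min(v)) next   # permuting a constant changes nothing
      acc <- 0
      for (p in seq_len(n_perm)) {
        xp <- x
        xp[, j, t] <- v[sample.int(n)]
        acc <- acc + birnn_loss(y, birnn_forward(model, xp)$pred)$loss
      }
      imp[j, t] <- acc / n_perm - base
    }
  }
  imp
}
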