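#' Training configuration for the cell-matching network
#'
#' Defaults are the method's standard hyperparameters: a 64-unit then 32-unit
#' shared embedding stack, 200 epochs of Adam at learning rate 0.001, L2
#' weight `l2_gamma = 0.01`, label smoothing `smoothing = 0.1`, dynamic class
#' weight range controlled by `weight_alpha = 9` (weights in `[1, 10]`),
#' 5000 cells sampled per species per batch, and 20 cross-species alignment
#' neighbours.
#'
#' @param hidden_dim width of the first embedding layer.
#' @param embed_dim width of the second (final) embedding layer.
#' @param epochs number of training epochs (one batch per species per epoch).
#' @param lr Adam learning rate.
#' @param l2_gamma L2 regularisation weight on all parameters.
#' @param smoothing label-smoothing mass `epsilon`, in `(0, 1)`.
#' @param weight_alpha dynamic class-weight slope `alpha`; weights live in
#'   `[1, alpha + 1]`.
#' @param batch_per_species cells sampled (with replacement) per species per
#'   batch.
#' @param k_align number of nearest cross-species neighbours in the alignment
#'   loss.
#' @param align_mode `"soft"` (differentiable softmax-weighted neighbours,
#'   the default) or `"hard"` (literal K-nearest-mean; contributes loss value
#'   but no gradient).
#' @param seed integer seed controlling initialisation and sampling.
#' @return a list of class `match_config`.
#' @export
match_config <- function(hidden_dim = 64L, embed_dim = 32L, epochs = 200L,
                         lr = 0.001, l2_gamma = 0.01, smoothing = 0.1,
                         weight_alpha = 9, batch_per_species = 5000L,
                         k_align = 20L, align_mode = c("soft", "hard"),
                         seed = 1L) {
  align_mode <- match.arg(align_mode)
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              embed_dim = as.integer(embed_dim),
              epochs = as.integer(epochs), lr = lr, l2_gamma = l2_gamma,
              smoothing = smoothing, weight_alpha = weight_alpha,
              batch_per_species = as.integer(batch_per_species),
              k_align = as.integer(k_align), align_mode = align_mode,
              seed = as.integer(seed))
  with(cfg, stopifnot(hidden_dim > 0, embed_dim > 0, epochs > 0, lr > 0,
                      l2_gamma >= 0, smoothing > 0, smoothing < 1,
                      weight_alpha > 0, batch_per_species > 0, k_align > 0))
  class(cfg) <- "match_config"
  cfg
}

#' Label smoothing
#'
#' Turns hard class indices into smoothed target distributions: the true
#' class gets `1 - epsilon`, every other class `epsilon / (T - 1)`.
#'
#' @param true_idx integer vector of 1-based true class indices.
#' @param n_types total number of classes `T` (>= 2).
#' @param epsilon smoothing mass in `[0, 1)`.
#' @return for a single index, a probability vector of length `n_types`;
#'   otherwise an `N x T` matrix with one row per index.
#' @export
smooth_labels <- function(true_idx, n_types, epsilon = 0.1) {
  if (n_types < 2L) stop("label smoothing requires >= 2 classes")
  stopifnot(all(true_idx >= 1L), all(true_idx <= n_types),
            epsilon >= 0, epsilon < 1)
  out <- matrix(epsilon / (n_types - 1L), length(true_idx), n_types)
  out[cbind(seq_along(true_idx), true_idx)] <- 1 - epsilon
  if (length(true_idx) == 1L) drop(out) else out
}

#' Class-weighted cross-entropy against smoothed targets
#'
#' `-(1/N) sum_i sum_t w_t Y_it ln h_it` with a numerical floor of 1e-12
#' inside the logarithm.
#'
#' @param probs `N x T` matrix of predicted class probabilities (rows sum
#'   to 1).
#' @param targets `N x T` matrix of (smoothed) target distributions.
#' @param w per-class weight vector of length `T`.
#' @return a single nonnegative number.
#' @export
classification_loss <- function(probs, targets, w) {
  probs <- rbind(probs); targets <- rbind(targets)
  stopifnot(ncol(probs) == ncol(targets), length(w) == ncol(probs))
  -sum(sweep(targets, 2L, w, "*") * log(pmax(probs, 1e-12))) / nrow(probs)
}

#' Dynamic class weights from per-type accuracy
#'
#' `w_t = (1 - acc_t) * alpha + 1`: a type classified perfectly gets weight 1,
#' a type never classified correctly gets `alpha + 1` (10 at the default
#' `alpha = 9`).
#'
#' @param accuracy per-type accuracies in `[0, 1]`.
#' @param alpha weight slope.
#' @return numeric vector of weights in `[1, alpha + 1]`.
#' @export
update_class_weights <- function(accuracy, alpha = 9) {
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]")
  (1 - accuracy) * alpha + 1
}

# row-stable softmax
.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# One direction of the alignment loss: cells of S predict their shared
# features from the K nearest opposite-species cells O in embedding space.
# mode "soft": neighbour weights are a softmax over -squared distance
# restricted to the K nearest (differentiable); "hard": uniform 1/K weights
# (paper-literal, zero gradient). Returns loss and, if want_grad, gradients
# w.r.t. both embedding matrices.
.align_dir <- function(emb_s, emb_o, feat_s, feat_o, k, mode, want_grad = FALSE) {
  ns <- nrow(emb_s); no <- nrow(emb_o); Fdim <- ncol(feat_s)
  if (no == 0L) stop("empty opposite batch")
  if (k > no) {
    warning(sprintf("k_align = %d exceeds opposite batch size %d; clamped", k, no))
    k <- no
  }
  d2 <- outer(rowSums(emb_s^2), rowSums(emb_o^2), "+") -
    2 * tcrossprod(emb_s, emb_o)
  S <- matrix(0, ns, no)  # neighbour weights
  for (i in seq_len(ns)) {
    nb <- order(d2[i, ], seq_len(no))[seq_len(k)]
    if (mode == "hard") {
      S[i, nb] <- 1 / k
    } else {
      u <- -d2[i, nb]
      e <- exp(u - max(u))
      S[i, nb] <- e / sum(e)
    }
  }
  pred <- S %*% feat_o
  resid <- pred - feat_s
  loss <- mean(rowMeans(resid^2))
  if (!want_grad || mode == "hard") {
    return(list(loss = loss,
                g_s = matrix(0, ns, ncol(emb_s)),
                g_o = matrix(0, no, ncol(emb_o))))
  }
  R <- resid * (2 / (ns * Fdim))             # dL/dpred
  A <- R %*% t(feat_o)                       # dL/dS (before softmax jacobian)
  abar <- rowSums(S * A)
  G <- -(S * (A - abar))                     # dL/d d2  (u = -d2)
  g_s <- 2 * (rowSums(G) * emb_s - G %*% emb_o)
  g_o <- -2 * crossprod(G, emb_s) + 2 * colSums(G) * emb_o
  list(loss = loss, g_s = g_s, g_o = g_o)
}

#' Cross-species alignment loss
#'
#' For each cell, its K nearest opposite-species cells in the current
#' embedding space predict its shared-feature vector (by their weighted
#' average feature vector); the loss is the mean, over cells, of the
#' mean-squared error of that prediction. Returned separately per species.
#'
#' @param emb_a,emb_b batch embedding matrices (cells x embed_dim).
#' @param feat_a,feat_b the same cells' shared-feature rows.
#' @param k neighbourhood size (default 20); clamped with a warning when it
#'   exceeds the opposite batch.
#' @param mode `"soft"` (softmax-weighted neighbours) or `"hard"` (uniform
#'   K-nearest mean).
#' @return named numeric vector `c(a = , b = )`.
#' @export
alignment_loss <- function(emb_a, emb_b, feat_a, feat_b, k = 20L,
                           mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(ncol(emb_a) == ncol(emb_b), ncol(feat_a) == ncol(feat_b),
            nrow(emb_a) == nrow(feat_a), nrow(emb_b) == nrow(feat_b))
  if (nrow(emb_a) == 0L || nrow(emb_b) == 0L) stop("empty batch")
  c(a = .align_dir(emb_a, emb_b, feat_a, feat_b, k, mode)$loss,
    b = .align_dir(emb_b, emb_a, feat_b, feat_a, k, mode)$loss)
}

#' Composite training loss
#'
#' Sum of the two classification losses, the two alignment losses, and
#' `gamma` times the squared L2 norm of all model parameters.
#'
#' @param cls_a,cls_b,align_a,align_b the four partial losses.
#' @param theta model parameters: numeric vector, matrix, or list of them.
#' @param gamma L2 weight.
#' @return a single number.
#' @export
total_loss <- function(cls_a, cls_b, align_a, align_b, theta, gamma = 0.01) {
  if (is.list(theta)) theta <- unlist(theta, use.names = FALSE)
  cls_a + cls_b + align_a + align_b + gamma * sum(theta^2)
}

#' Class-balanced batch sampling
#'
#' Samples cell indices with replacement, each cell weighted proportionally
#' to the inverse size of its type (`N / N_t` up to normalisation), so the
#' expected number of cells per type in a batch is equal across types.
#'
#' @param labels per-cell type labels.
#' @param batch_size number of cells to draw.
#' @return integer vector of cell indices of length `batch_size`.
#' @export
sample_batch <- function(labels, batch_size) {
  n <- length(labels)
  if (n == 0L) stop("empty dataset")
  labels <- as.character(labels)
  sizes <- table(labels)
  if (batch_size < length(sizes))
    warning("batch_size is smaller than the number of cell types")
  w <- as.numeric(n / sizes[labels])
  sample.int(n, batch_size, replace = TRUE, prob = w)
}

# ---- network internals ---------------------------------------------------

.init_params <- function(n_feat, cfg, n_types_a, n_types_b) {
  kaiming <- function(fan_in, fan_out) {
    lim <- sqrt(6 / fan_in)
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  list(W1 = kaiming(n_feat, cfg$hidden_dim), b1 = numeric(cfg$hidden_dim),
       W2 = kaiming(cfg$hidden_dim, cfg$embed_dim), b2 = numeric(cfg$embed_dim),
       Wa = kaiming(cfg$embed_dim, n_types_a), ba = numeric(n_types_a),
       Wb = kaiming(cfg$embed_dim, n_types_b), bb = numeric(n_types_b))
}

# forward through the shared two-layer ReLU embedding stack
.forward_embed <- function(p, x) {
  z1 <- sweep(x %*% p$W1, 2L, p$b1, "+")
  h1 <- pmax(z1, 0)
  z2 <- sweep(h1 %*% p$W2, 2L, p$b2, "+")
  list(z1 = z1, h1 = h1, z2 = z2, emb = pmax(z2, 0))
}

# backprop d(loss)/d(emb) through the shared stack; returns param grads
.backward_embed <- function(p, x, fwd, d_emb) {
  dz2 <- d_emb * (fwd$z2 > 0)
  dW2 <- crossprod(fwd$h1, dz2)
  db2 <- colSums(dz2)
  dh1 <- tcrossprod(dz2, p$W2)
  dz1 <- dh1 * (fwd$z1 > 0)
  dW1 <- crossprod(x, dz1)
  db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# gradient of the weighted smoothed cross-entropy w.r.t. logits
.ce_logit_grad <- function(probs, targets, w) {
  wY <- sweep(targets, 2L, w, "*")
  (probs * rowSums(wY) - wY) / nrow(probs)
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# full-batch losses + parameter gradients for one training step
.train_step_grads <- function(p, xa, xb, Ya, Yb, wa, wb, cfg) {
  fa <- .forward_embed(p, xa)
  fb <- .forward_embed(p, xb)
  pa <- .softmax(sweep(fa$emb %*% p$Wa, 2L, p$ba, "+"))
  pb <- .softmax(sweep(fb$emb %*% p$Wb, 2L, p$bb, "+"))
  cls_a <- classification_loss(pa, Ya, wa)
  cls_b <- classification_loss(pb, Yb, wb)
  al_ab <- .align_dir(fa$emb, fb$emb, xa, xb, cfg$k_align, cfg$align_mode, TRUE)
  al_ba <- .align_dir(fb$emb, fa$emb, xb, xa, cfg$k_align, cfg$align_mode, TRUE)

  dza <- .ce_logit_grad(pa, Ya, wa)
  dzb <- .ce_logit_grad(pb, Yb, wb)
  d_emb_a <- tcrossprod(dza, p$Wa) + al_ab$g_s + al_ba$g_o
  d_emb_b <- tcrossprod(dzb, p$Wb) + al_ba$g_s + al_ab$g_o
  ga <- .backward_embed(p, xa, fa, d_emb_a)
  gb <- .backward_embed(p, xb, fb, d_emb_b)
  grads <- list(
    W1 = ga$W1 + gb$W1, b1 = ga$b1 + gb$b1,
    W2 = ga$W2 + gb$W2, b2 = ga$b2 + gb$b2,
    Wa = crossprod(fa$emb, dza), ba = colSums(dza),
    Wb = crossprod(fb$emb, dzb), bb = colSums(dzb))
  for (nm in names(grads))
    grads[[nm]] <- grads[[nm]] + 2 * cfg$l2_gamma * p[[nm]]
  list(grads = grads, cls_a = cls_a, cls_b = cls_b,
       align_a = al_ab$loss, align_b = al_ba$loss,
       probs_a = pa, probs_b = pb)
}
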