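#' Fit a cross-species cell-type matching model
#'
#' Trains the shared-weight two-layer cell-embedding network with one linear
#' softmax classifier per species on the two species' shared-feature
#' matrices. Per epoch, one class-balanced batch is sampled per species
#' ([sample_batch()]), the composite loss (class-weighted label-smoothed
#' cross-entropy per species, the cross-species alignment loss per species,
#' and an L2 penalty; see [total_loss()]) is evaluated on it, and one Adam
#' step is taken. Class weights are recomputed after every epoch from that
#' epoch's per-type batch accuracy via [update_class_weights()]; a type not
#' sampled in an epoch keeps its previous weight. Training is fully
#' reproducible for a fixed `config$seed`.
#'
#' @param x_a,x_b `shared_features` objects (see [impute_shared()]) or
#'   cells x features matrices with identical column names in identical
#'   order.
#' @param labels_a,labels_b per-cell type labels for each species.
#' @param config a [match_config()].
#' @param species optional length-2 species labels (taken from
#'   `shared_features` inputs when available).
#' @return an object of class `cellmatch` with elements `params` (network
#'   weights), `config`, `feature_ids`, `types_a`, `types_b`,
#'   `class_weights`, `log` (per-epoch losses and accuracies) and `species`.
#' @seealso [predict.cellmatch()], [transfer_labels()], [match_types()]
#' @examples
#' \donttest{
#' sim <- simulate_species_pair(sim_config(n_types = 3, cells_per_type_a = 20,
#'   cells_per_type_b = 20, n_genes_shared = 40, seed = 1))
#' shared <- prepare_shared_features(sim$dataset_a, sim$dataset_b, sim$graph)
#' fit <- cellmatch(shared$a, shared$b, sim$dataset_a$cell_types,
#'   sim$dataset_b$cell_types,
#'   config = match_config(epochs = 30, batch_per_species = 120, seed = 1))
#' fit
#' }
#' @export
cellmatch <- function(x_a, x_b, labels_a, labels_b, config = match_config(),
                      species = NULL) {
  stopifnot(inherits(config, "match_config"))
  if (is.null(species))
    species <- c(if (inherits(x_a, "shared_features")) x_a$species else "A",
                 if (inherits(x_b, "shared_features")) x_b$species else "B")
  xa <- as.matrix(x_a); xb <- as.matrix(x_b)
  if (!identical(colnames(xa), colnames(xb)))
    stop("x_a and x_b must share one feature ordering")
  if (nrow(xa) != length(labels_a) || nrow(xb) != length(labels_b))
    stop("one label per cell required")
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  types_a <- sort(unique(labels_a)); types_b <- sort(unique(labels_b))
  if (length(types_a) < 2L || length(types_b) < 2L)
    stop("each species needs >= 2 cell types")
  ia_all <- match(labels_a, types_a)
  ib_all <- match(labels_b, types_b)

  set.seed(config$seed)
  p <- .init_params(ncol(xa), config, length(types_a), length(types_b))
  opt <- .adam_init(p)
  wa <- rep(1, length(types_a)); wb <- rep(1, length(types_b))
  log_rows <- vector("list", config$epochs)

  for (ep in seq_len(config$epochs)) {
    ba <- sample_batch(labels_a, config$batch_per_species)
    bb <- sample_batch(labels_b, config$batch_per_species)
    Ya <- smooth_labels(ia_all[ba], length(types_a), config$smoothing)
    Yb <- smooth_labels(ib_all[bb], length(types_b), config$smoothing)
    st <- .train_step_grads(p, xa[ba, , drop = FALSE], xb[bb, , drop = FALSE],
                            rbind(Ya), rbind(Yb), wa, wb, config)
    loss <- total_loss(st$cls_a, st$cls_b, st$align_a, st$align_b, p,
                       config$l2_gamma)
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at epoch %d (cls %.3g/%.3g align %.3g/%.3g)",
                   ep, st$cls_a, st$cls_b, st$align_a, st$align_b))
    upd <- .adam_step(p, st$grads, opt, config$lr)
    p <- upd$params; opt <- upd$state

    acc_of <- function(probs, idx, n_types) {
      pred <- max.col(probs, ties.method = "first")
      vapply(seq_len(n_types), function(t) {
        sel <- idx == t
        if (!any(sel)) NA_real_ else mean(pred[sel] == t)
      }, numeric(1L))
    }
    acc_a <- acc_of(st$probs_a, ia_all[ba], length(types_a))
    acc_b <- acc_of(st$probs_b, ib_all[bb], length(types_b))
    wa <- ifelse(is.na(acc_a), wa,
                 update_class_weights(ifelse(is.na(acc_a), 0, acc_a),
                                      config$weight_alpha))
    wb <- ifelse(is.na(acc_b), wb,
                 update_class_weights(ifelse(is.na(acc_b), 0, acc_b),
                                      config$weight_alpha))
    log_rows[[ep]] <- data.frame(
      epoch = ep, loss = loss, cls_a = st$cls_a, cls_b = st$cls_b,
      align_a = st$align_a, align_b = st$align_b,
      acc_a = mean(acc_a, na.rm = TRUE), acc_b = mean(acc_b, na.rm = TRUE))
  }

  structure(list(params = p, config = config,
                 feature_ids = colnames(xa),
                 types_a = types_a, types_b = types_b,
                 class_weights = list(a = wa, b = wb),
                 species = stats::setNames(species, c("a", "b")),
                 log = do.call(rbind, log_rows),
                 call = match.call()),
            class = "cellmatch")
}

#' Embed cells through the shared two-layer stack
#'
#' Applies the trained shared embedding layers (affine + ReLU, twice) to a
#' shared-feature matrix. The same weights are used regardless of species.
#'
#' @param model a fitted `cellmatch` object.
#' @param x `shared_features` or matrix with the training feature ordering.
#' @return cells x `embed_dim` matrix.
#' @export
embed_cells <- function(model, x) {
  stopifnot(inherits(model, "cellmatch"))
  x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_ids))
    stop("feature ordering does not match the trained model")
  .forward_embed(model$params, x)$emb
}

#' Predict from a fitted cell-matching model
#'
#' @param object a `cellmatch` fit.
#' @param newdata `shared_features` or matrix over the training features.
#' @param species which species' cells `newdata` holds (`"a"` or `"b"`).
#' @param classifier `"native"` (the species' own classifier) or `"cross"`
#'   (the opposite species' classifier, i.e. label transfer).
#' @param type `"class"` (factor of predicted types), `"prob"` (probability
#'   matrix) or `"embedding"`.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.cellmatch <- function(object, newdata, species = c("a", "b"),
                              classifier = c("native", "cross"),
                              type = c("class", "prob", "embedding"), ...) {
  species <- match.arg(species); classifier <- match.arg(classifier)
  type <- match.arg(type)
  emb <- embed_cells(object, newdata)
  if (type == "embedding") return(emb)
  use_a <- (species == "a") == (classifier == "native")
  p <- object$params
  probs <- if (use_a) .softmax(sweep(emb %*% p$Wa, 2L, p$ba, "+"))
           else .softmax(sweep(emb %*% p$Wb, 2L, p$bb, "+"))
  vocab <- if (use_a) object$types_a else object$types_b
  colnames(probs) <- vocab
  if (type == "prob") return(probs)
  idx <- max.col(probs, ties.method = "first")
  out <- factor(vocab[idx], levels = vocab)
  attr(out, "max_prob") <- probs[cbind(seq_len(nrow(probs)), idx)]
  out
}

#' @export
print.cellmatch <- function(x, ...) {
  cat("Cross-species cell-type matching model\n")
  cat(sprintf("  species: %s (%d types) vs %s (%d types)\n",
              x$species["a"], length(x$types_a),
              x$species["b"], length(x$types_b)))
  cat(sprintf("  features: %d shared; embedding: %d -> %d -> %d\n",
              length(x$feature_ids), length(x$feature_ids),
              x$config$hidden_dim, x$config$embed_dim))
  n <- nrow(x$log)
  cat(sprintf("  %d epochs; final loss %.4f (train acc %.3f / %.3f)\n",
              n, x$log$loss[n], x$log$acc_a[n], x$log$acc_b[n]))
  invisible(x)
}

#' @export
summary.cellmatch <- function(object, ...) {
  print(object)
  cat("\nFinal class weights:\n")
  cat(sprintf("  %s: %s\n", object$species["a"],
              paste(sprintf("%s=%.2f", object$types_a,
                            object$class_weights$a), collapse = " ")))
  cat(sprintf("  %s: %s\n", object$species["b"],
              paste(sprintf("%s=%.2f", object$types_b,
                            object$class_weights$b), collapse = " ")))
  invisible(object)
}

#' @export
coef.cellmatch <- function(object, ...) object$params

#' Plot training curves
#'
#' Loss components and mean per-type batch accuracy per epoch.
#'
#' @param x a `cellmatch` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cellmatch <- function(x, ...) {
  l <- x$log
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::matplot(l$epoch, cbind(l$loss, l$cls_a + l$cls_b,
                                   l$align_a + l$align_b),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "classification", "alignment"),
                   col = 1:3, lty = 1, bty = "n")
  graphics::matplot(l$epoch, cbind(l$acc_a, l$acc_b), type = "l", lty = 1,
                    xlab = "epoch", ylab = "mean per-type accuracy")
  graphics::legend("bottomright", unname(x$species), col = 1:2, lty = 1,
                   bty = "n")
  invisible(x)
}
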