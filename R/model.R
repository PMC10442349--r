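# The expression model: a backbone feature extractor with a linear main
# head predicting the K top-expressed genes and, attached to the same
# penultimate features, an auxiliary head (one fully connected layer)
# predicting the remaining genes.  The auxiliary loss, weighted by lambda,
# regularises the shared features.

#' Loss specification for the combined objective
#'
#' The overall training loss is `L = L_main + lambda * L_aux`, both heads
#' scored by the same per-head regression loss on log-transformed
#' expression.  The default per-head loss is mean squared error;
#' `"smooth_l1"` (Huber, delta = 1) is available as a robust alternative.
#'
#' @param lambda Non-negative auxiliary weight (default 40).
#' @param loss Per-head loss: `"mse"` or `"smooth_l1"`.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(lambda = 40, loss = c("mse", "smooth_l1")) {
  loss <- match.arg(loss)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    hx_validation_error("lambda must be a single non-negative number")
  }
  structure(list(lambda = as.numeric(lambda), loss = loss), class = "loss_spec")
}

# Per-head loss value and gradient w.r.t. predictions (mean reduction over
# all elements).
head_loss <- function(pred, target, loss = "mse") {
  d <- pred - target
  n <- length(d)
  if (loss == "mse") {
    list(value = mean(d * d), grad = 2 * d / n)
  } else { # smooth_l1, delta = 1
    a <- abs(d)
    v <- ifelse(a < 1, 0.5 * d * d, a - 0.5)
    list(value = mean(v), grad = pmin(pmax(d, -1), 1) / n)
  }
}

#' Combined main + auxiliary loss
#'
#' `L = L_main + lambda * L_aux`; with the auxiliary head disabled (or
#' `aux_pred = NULL`) the total equals the main loss exactly.
#'
#' @param main_pred,main_target Matrices `B x n_main` of predictions and
#'   log-expression targets.
#' @param aux_pred,aux_target Matrices `B x n_aux`, or `NULL`.
#' @param spec A [loss_spec()].
#' @return List with `total`, `main` and `aux` loss components.
#' @export
combined_loss <- function(main_pred, main_target, aux_pred = NULL,
                          aux_target = NULL, spec = loss_spec()) {
  if (!identical(dim(main_pred), dim(main_target))) {
    hx_validation_error("main prediction/target shape mismatch")
  }
  lm <- head_loss(main_pred, main_target, spec$loss)$value
  la <- 0
  if (!is.null(aux_pred)) {
    if (is.null(aux_target) || !identical(dim(aux_pred), dim(aux_target))) {
      hx_validation_error("aux prediction/target shape mismatch")
    }
    la <- head_loss(aux_pred, aux_target, spec$loss)$value
  }
  list(total = lm + spec$lambda * la, main = lm, aux = la)
}

#' Build an expression model
#'
#' Assembles a backbone feature extractor (see the supported names in the
#' details) with a linear main head mapping the penultimate features to
#' `n_main` genes and, when `aux_enabled`, a single-fully-connected-layer
#' auxiliary head for the remaining `n_aux` genes.  Weights are randomly
#' initialised (no pretraining), deterministically under `seed`.
#'
#' Supported backbones: `tiny_cnn` (small three-block convnet, the
#' desk-scale default), `resnet101`, `inception_v3`, `efficientnet_b0` ..
#' `efficientnet_b5`, `vit_b16`, `vit_b32` — compact in-package presets of
#' the respective architecture families.
#'
#' @param backbone Backbone name.
#' @param n_main,n_aux Gene counts for the two heads.
#' @param aux_enabled With `FALSE` the auxiliary head is absent from both
#'   the forward output and the loss.
#' @param patch_size Input patch side in pixels.
#' @param seed Integer seed for weight initialisation.
#' @return An `expr_model` object (untrained; see [fit_expression()]).
#' @export
build_model <- function(backbone = "tiny_cnn", n_main, n_aux = 0L,
                        aux_enabled = n_aux > 0L, patch_size = 64L, seed = 0L) {
  stopifnot(is_count(n_main), n_aux >= 0)
  if (aux_enabled && n_aux == 0L) hx_validation_error("aux_enabled requires n_aux > 0")
  with_seed(seed, {
    bb <- build_backbone(backbone, img_size = patch_size)
    main_head <- nn_dense(bb$feature_dim, n_main, init_sd = 0.01)
    aux_head <- if (aux_enabled) nn_dense(bb$feature_dim, n_aux, init_sd = 0.01) else NULL
    structure(
      list(
        backbone_name = backbone, patch_size = as.integer(patch_size),
        n_main = as.integer(n_main), n_aux = as.integer(n_aux),
        aux_enabled = aux_enabled, feature_dim = bb$feature_dim,
        net = bb$net, main_head = main_head, aux_head = aux_head,
        norm_stats = NULL, main_genes = NULL, aux_genes = NULL,
        loss_spec = NULL, history = NULL, seed = as.integer(seed)
      ),
      class = "expr_model"
    )
  })
}

# Forward pass on a standardized (H, W, C, N) batch.
model_forward <- function(model, x, train = FALSE) {
  feats <- nn_forward(model$net, x, train = train)
  out <- list(
    features = feats,
    main = nn_forward(model$main_head, feats, train = train)
  )
  if (model$aux_enabled) out$aux <- nn_forward(model$aux_head, feats, train = train)
  out
}

# Backward pass: gradients w.r.t. head outputs -> parameter gradients.
model_backward <- function(model, grad_main, grad_aux = NULL) {
  gf <- nn_backward(model$main_head, grad_main)
  if (model$aux_enabled && !is.null(grad_aux)) {
    gf <- gf + nn_backward(model$aux_head, grad_aux)
  }
  nn_backward(model$net, gf)
}

model_layers <- function(model) {
  c(
    nn_param_layers(model$net), nn_param_layers(model$main_head),
    if (model$aux_enabled) nn_param_layers(model$aux_head)
  )
}

model_state <- function(model) lapply(model_layers(model), function(l) l$params)

model_load_state <- function(model, state) {
  layers <- model_layers(model)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) layers[[i]]$params <- state[[i]]
  invisible(model)
}

model_zero_grads <- function(model) {
  for (l in model_layers(model)) l$grads <- list()
  invisible(NULL)
}

model_sgd_step <- function(model, lr, momentum, weight_decay) {
  nn_sgd_step(model$net, lr, momentum, weight_decay)
  nn_sgd_step(model$main_head, lr, momentum, weight_decay)
  if (model$aux_enabled) nn_sgd_step(model$aux_head, lr, momentum, weight_decay)
  invisible(NULL)
}

# N x 3 x s x s patches -> standardized (s, s, 3, N) batch.
prep_batch <- function(patches, norm_stats) {
  d <- dim(patches)
  x <- aperm(patches, c(3L, 4L, 2L, 1L)) # H, W, C, N
  for (c in 1:3) {
    x[, , c, ] <- (x[, , c, ] - norm_stats$mean[c]) / norm_stats$sd[c]
  }
  x
}

#' Predict expression for a batch of patches
#'
#' Evaluation-mode forward pass: deterministic (no augmentation), batched;
#' batched and un-batched calls agree to numerical precision.  Patches are
#' raw 8-bit pixel patches; the channel standardization stored on the model
#' at fit time is applied internally.
#'
#' @param object A fitted `expr_model`.
#' @param patches `N x 3 x s x s` array of patches (a `patch_set$patches`).
#' @param type `"main"` returns the main-head matrix; `"both"` a list with
#'   `main` and (if enabled) `aux`.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return `N x n_main` matrix, or a list of head matrices.
#' @export
predict.expr_model <- function(object, patches, type = c("main", "both"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  d <- dim(patches)
  if (length(d) != 4L || d[2] != 3L || d[3] != object$patch_size || d[4] != object$patch_size) {
    hx_validation_error(
      "patches must be N x 3 x ", object$patch_size, " x ", object$patch_size
    )
  }
  if (is.null(object$norm_stats)) hx_validation_error("model has no normalization stats; fit it first")
  n <- d[1]
  main <- matrix(0, n, object$n_main)
  aux <- if (object$aux_enabled && type == "both") matrix(0, n, object$n_aux)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- prep_batch(patches[idx, , , , drop = FALSE], object$norm_stats)
    out <- model_forward(object, x, train = FALSE)
    main[idx, ] <- out$main
    if (!is.null(aux)) aux[idx, ] <- out$aux
  }
  colnames(main) <- object$main_genes
  if (type == "main") {
    main
  } else {
    if (!is.null(aux)) colnames(aux) <- object$aux_genes
    list(main = main, aux = aux)
  }
}

#' @export
print.expr_model <- function(x, ...) {
  cat(sprintf(
    "<expr_model> backbone %s (%s params), %d-px patches -> %d main%s genes%s\n",
    x$backbone_name, format(nn_n_params(x$net) +
      nn_n_params(x$main_head) + if (x$aux_enabled) nn_n_params(x$aux_head) else 0,
    big.mark = ","
    ),
    x$patch_size, x$n_main,
    if (x$aux_enabled) sprintf(" + %d aux", x$n_aux) else "",
    if (is.null(x$history)) " (untrained)" else sprintf(
      " (trained %d epochs, best val loss %.4f)",
      nrow(x$history), min(x$history$val_loss)
    )
  ))
  invisible(x)
}

#' @export
summary.expr_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf(
      "  final lr %.2g; train loss %.4f -> %.4f; val loss %.4f -> %.4f (best %.4f @ epoch %d)\n",
      utils::tail(h$lr, 1), h$train_loss[1], utils::tail(h$train_loss, 1),
      h$val_loss[1], utils::tail(h$val_loss, 1),
      min(h$val_loss), which.min(h$val_loss)
    ))
  }
  if (!is.null(object$loss_spec)) {
    cat(sprintf(
      "  loss: %s, lambda = %g\n",
      object$loss_spec$loss, object$loss_spec$lambda
    ))
  }
  invisible(object)
}

#' @export
coef.expr_model <- function(object, ...) {
  out <- list(main = object$main_head$params)
  if (object$aux_enabled) out$aux <- object$aux_head$params
  out
}

#' Residuals of a fitted expression model
#'
#' @param object A fitted `expr_model`.
#' @param patches `N x 3 x s x s` patch array.
#' @param targets `N x n_main` matrix of log-expression targets.
#' @param ... Unused.
#' @return Matrix of `targets - predictions` for the main head.
#' @export
residuals.expr_model <- function(object, patches, targets, ...) {
  targets - predict(object, patches)
}

#' Plot training history of an expression model
#'
#' @param x A fitted `expr_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.expr_model <- function(x, ...) {
  if (is.null(x$history)) hx_validation_error("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss,
    type = "l", col = "steelblue", lwd = 2,
    xlab = "epoch", ylab = "combined loss",
    ylim = range(c(h$train_loss, h$val_loss)), ...
  )
  graphics::lines(h$epoch, h$val_loss, col = "firebrick", lwd = 2)
  graphics::legend("topright",
    legend = c("train", "validation"),
    col = c("steelblue", "firebrick"), lwd = 2, bty = "n"
  )
  invisible(x)
}
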