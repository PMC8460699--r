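#' Training configuration for the attention-MIL head
#'
#' Defaults are the pipeline's standard training recipe: Adam for 30 epochs with an
#' effective bag batch of 8, learning rate 1e-4 for all parameters except the
#' attention scale gamma, which uses 1e-3; cross-entropy loss; gamma starts
#' at 1 (see [mil_params()]).
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size bags per optimisation step (gradients are accumulated
#'   over single bags — bags have variable size, so there is no padding).
#' @param lr learning rate for all parameters except gamma.
#' @param lr_gamma learning rate for gamma.
#' @param beta1,beta2,eps Adam moment and stability constants.
#' @param hidden widths of the two fully connected layers.
#' @param d_attn attention query/key width.
#' @param seed seed controlling initialisation and batch order.
#' @return List of class `mil_config`.
#' @export
mil_config <- function(epochs = 30L, batch_size = 8L, lr = 1e-4,
                       lr_gamma = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, hidden = c(512L, 128L), d_attn = 16L,
                       seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0, lr_gamma > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_gamma = lr_gamma, beta1 = beta1, beta2 = beta2,
                 eps = eps, hidden = hidden, d_attn = as.integer(d_attn),
                 seed = as.integer(seed)),
            class = "mil_config")
}

bag_matrices <- function(bags) {
  if (inherits(bags, "bag_set")) bags <- bags$bags
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  lapply(bags, function(b) if (inherits(b, "feature_bag")) b$features else as.matrix(b))
}

bag_ids <- function(bags) {
  if (inherits(bags, "bag_set")) bags <- bags$bags
  if (inherits(bags, "feature_bag")) bags <- list(bags)
  vapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    if (inherits(b, "feature_bag")) b$patient_id else sprintf("bag%03d", i)
  }, "")
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, config, freeze = character()) {
  state$t <- state$t + 1L
  for (nm in setdiff(names(grads), freeze)) {
    g <- grads[[nm]]
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * g
    state$v[[nm]] <- config$beta2 * state$v[[nm]] + (1 - config$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - config$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - config$beta2^state$t)
    lr <- if (nm == "gamma") config$lr_gamma else config$lr
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + config$eps)
  }
  list(params = params, state = state)
}

#' Fit the self-attention multiple-instance classifier
#'
#' Trains the aggregation head (two fully connected layers, self-attention,
#' mean pooling, two-class output) on per-patient feature bags with
#' cross-entropy loss and Adam. Bags are processed one at a time with
#' gradients accumulated to an effective batch, so variable bag sizes need no
#' padding. When a validation set is supplied, the per-epoch validation AUC
#' is recorded and the returned parameters are those of the best validation
#' epoch (ties going to the earlier epoch); otherwise the final epoch is
#' kept.
#'
#' @param bags training bags: a `bag_set`, or a list of [feature_bag()]
#'   objects / feature matrices.
#' @param labels 0/1 bag labels (taken from the `bag_set` if omitted). Both
#'   classes must be present.
#' @param val_bags,val_labels optional validation bags and labels.
#' @param config a [mil_config()].
#' @param init optional [mil_params()] to start from (used for transfer).
#' @param freeze character vector of parameter names excluded from updates
#'   (e.g. `c("W1", "b1", "W2", "b2")` for the transfer protocol).
#' @return Object of class `mil_fit`: `params` (best epoch), `history`
#'   (data.frame epoch / train_loss / val_auc), `best_epoch`, `config`,
#'   `freeze`, `input_dim`.
#' @examples
#' bs <- generate_feature_bags(12, c(5, 10), 0.4, dim = 8, effect_size = 3, seed = 1)
#' fit <- mil_fit(bs, config = mil_config(epochs = 2, hidden = c(16, 8),
#'                                        d_attn = 4, seed = 1))
#' fit
#' @export
mil_fit <- function(bags, labels = NULL, val_bags = NULL, val_labels = NULL,
                    config = mil_config(), init = NULL, freeze = character()) {
  if (inherits(bags, "bag_set") && is.null(labels)) labels <- bags$bag_labels
  x <- bag_matrices(bags)
  labels <- as.integer(labels)
  stopifnot(length(x) == length(labels))
  if (length(unique(labels)) < 2L)
    stop_arg("training labels contain a single class; cannot train")
  if (inherits(val_bags, "bag_set") && is.null(val_labels))
    val_labels <- val_bags$bag_labels
  vx <- if (is.null(val_bags)) NULL else bag_matrices(val_bags)
  input_dim <- ncol(x[[1L]])

  params <- init %||% mil_params(input_dim, hidden = config$hidden,
                                 d_attn = config$d_attn, seed = config$seed)
  stopifnot(nrow(params$W1) == input_dim)
  opt <- adam_init(params)
  n <- length(x)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  best <- list(auc = -Inf, params = params, epoch = 0L)

  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      acc <- NULL
      in_batch <- 0L
      for (k in seq_len(n)) {
        i <- ord[k]
        fw <- mil_forward_full(x[[i]], params)
        losses[k] <- -log(max(fw$prob[labels[i] + 1L], 1e-12))
        g <- mil_backward(x[[i]], labels[i], fw, params)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        in_batch <- in_batch + 1L
        if (in_batch == config$batch_size || k == n) {
          acc <- lapply(acc, function(gr) gr / in_batch)
          st <- adam_step(params, acc, opt, config, freeze)
          params <- st$params
          opt <- st$state
          acc <- NULL
          in_batch <- 0L
        }
      }
      val_auc <- NA_real_
      if (!is.null(vx)) {
        scores <- vapply(vx, function(m) mil_forward_full(m, params)$prob[2L], 0)
        # a single-class validation set leaves the AUC undefined; record NA
        val_auc <- tryCatch(auc(scores, val_labels),
                            error = function(e) NA_real_)
        if (!is.na(val_auc) && val_auc > best$auc)
          best <- list(auc = val_auc, params = params, epoch = epoch)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_auc = val_auc))
    }
  })
  if (is.null(vx) || !is.finite(best$auc))
    best <- list(auc = NA_real_, params = params, epoch = config$epochs)
  structure(list(params = best$params, final_params = params,
                 history = history, best_epoch = best$epoch,
                 config = config, freeze = freeze, input_dim = input_dim,
                 call = match.call()),
            class = "mil_fit")
}

#' @export
print.mil_fit <- function(x, ...) {
  cat("Self-attention multiple-instance classifier\n")
  cat(sprintf("  input dim %d, hidden %s, d_attn %d, gamma = %.4f\n",
              x$input_dim, paste(x$config$hidden, collapse = "/"),
              x$config$d_attn, x$params$gamma))
  cat(sprintf("  %d epochs trained; best epoch %d", nrow(x$history), x$best_epoch))
  if (!all(is.na(x$history$val_auc)))
    cat(sprintf(" (validation AUC %.3f)", max(x$history$val_auc, na.rm = TRUE)))
  cat("\n")
  if (length(x$freeze))
    cat("  frozen parameters:", paste(x$freeze, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mil_fit <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f", h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_auc)))
    cat(sprintf("; final val AUC %.3f", h$val_auc[nrow(h)]))
  cat("\n")
  invisible(object)
}

#' @export
coef.mil_fit <- function(object, ...) object$params

#' Predict from a fitted attention-MIL model
#'
#' @param object a [mil_fit()].
#' @param bags bags to score (same forms as in [mil_fit()]).
#' @param type `"prob"` for the positive-class probability per bag,
#'   `"class"` for the 0/1 argmax label, `"attention"` for the list of
#'   attention states, or `"beta"` for the list of per-tile weight vectors
#'   (see [tile_weights()]).
#' @param ... unused.
#' @return Named vector (`prob`, `class`) or list (`attention`, `beta`).
#' @export
predict.mil_fit <- function(object, bags,
                            type = c("prob", "class", "attention", "beta"), ...) {
  type <- match.arg(type)
  x <- bag_matrices(bags)
  ids <- bag_ids(bags)
  if (type %in% c("prob", "class")) {
    p <- vapply(x, function(m) mil_forward_full(m, object$params)$prob[2L], 0)
    names(p) <- ids
    return(if (type == "prob") p else as.integer(p > 0.5))
  }
  states <- lapply(x, function(m) model_forward(m, object$params)$state)
  names(states) <- ids
  if (type == "attention") return(states)
  lapply(states, function(s) tile_weights(s, object$params$gamma)$beta)
}

#' Plot the training history of a fitted model
#'
#' Training loss per epoch, with validation AUC overlaid on a second axis
#' when present.
#'
#' @param x a [mil_fit()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mil_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss", ...)
  if (!all(is.na(h$val_auc))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_auc, type = "b", pch = 1, col = "forestgreen",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation AUC", side = 4, line = 2, col = "forestgreen")
    graphics::abline(v = x$best_epoch, lty = 3)
  }
  invisible(x)
}

#' Transfer a fitted model to a new cohort with frozen early layers
#'
#' Implements the fine-tuning protocol: the first two fully connected layers
#' keep their source-cohort parameters bit-for-bit, and only the
#' self-attention layer (`W_f`, `W_g`, `gamma`) and the final classification
#' layer are updated on the new cohort. Gene tasks are only eligible when
#' sufficiently prevalent in the new cohort: strictly more than 3% positives
#' for point-mutation tasks and strictly more than 5% for copy-number tasks;
#' an ineligible task is refused with an explanation. Zero epochs return the
#' source model parameters unchanged.
#'
#' @param object the source [mil_fit()].
#' @param bags,labels new-cohort bags and 0/1 labels.
#' @param val_bags,val_labels optional validation split of the new cohort.
#' @param config a [mil_config()] for the fine-tuning run; its `hidden` and
#'   `d_attn` are taken from the source model.
#' @param task_kind `"point"`, `"cna"` or `"other"`; gene-task prevalence
#'   eligibility is enforced for the first two.
#' @return A [mil_fit()] whose `params$W1/b1/W2/b2` equal the source
#'   model's.
#' @export
finetune <- function(object, bags, labels = NULL, val_bags = NULL,
                     val_labels = NULL, config = mil_config(),
                     task_kind = c("other", "point", "cna")) {
  stopifnot(inherits(object, "mil_fit"))
  task_kind <- match.arg(task_kind)
  if (inherits(bags, "bag_set") && is.null(labels)) labels <- bags$bag_labels
  prev <- mean(labels)
  if (task_kind == "point" && prev <= 0.03)
    stop_arg(sprintf("task refused: point-mutation prevalence %.1f%% in the new cohort is not > 3%%",
                     100 * prev))
  if (task_kind == "cna" && prev <= 0.05)
    stop_arg(sprintf("task refused: CNA prevalence %.1f%% in the new cohort is not > 5%%",
                     100 * prev))
  config$hidden <- c(ncol(object$params$W1), ncol(object$params$W2))
  config$d_attn <- ncol(object$params$Wf)
  if (config$epochs == 0L) {
    out <- object
    out$freeze <- c("W1", "b1", "W2", "b2")
    out$call <- match.call()
    return(out)
  }
  mil_fit(bags, labels, val_bags, val_labels, config = config,
          init = object$params, freeze = c("W1", "b1", "W2", "b2"))
}

#' Checksum of the frozen fully connected layers
#'
#' md5 of the serialised `W1`, `b1`, `W2`, `b2`; used to verify the transfer
#' freeze contract.
#'
#' @param params a [mil_params()] or [mil_fit()].
#' @return Character md5 string.
#' @export
frozen_layer_checksum <- function(params) {
  if (inherits(params, "mil_fit")) params <- params$params
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeBin(c(as.vector(params$W1), params$b1, as.vector(params$W2), params$b2),
           con, size = 8L, endian = "little")
  close(con)
  md5_of_file(tmp)
}

#' Save / load a fitted model checkpoint
#'
#' The parameter archive is a flat binary file of doubles plus a JSON
#' metadata file carrying shapes, the extractor id, `d_attn` and gamma, so a
#' checkpoint can be restored without R serialisation.
#'
#' @param object a [mil_fit()].
#' @param path file stem; writes `<path>.bin` and `<path>.json`.
#' @param extractor_id optional extractor identifier stored in the metadata.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(object, path, extractor_id = NA_character_) {
  stopifnot(inherits(object, "mil_fit"))
  p <- object$params
  order <- c("W1", "b1", "W2", "b2", "Wf", "Wg", "gamma", "Wo", "bo")
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(unlist(lapply(order, function(nm) as.vector(p[[nm]]))), con,
           size = 8L, endian = "little")
  close(con)
  meta <- list(input_dim = object$input_dim, hidden = object$config$hidden,
               d_attn = object$config$d_attn, gamma = p$gamma,
               extractor_id = extractor_id, best_epoch = object$best_epoch)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- meta$input_dim
  h <- meta$hidden
  da <- meta$d_attn
  shapes <- list(W1 = c(d, h[1]), b1 = h[1], W2 = c(h[1], h[2]), b2 = h[2],
                 Wf = c(h[2], da), Wg = c(h[2], da), gamma = 1,
                 Wo = c(h[2], 2), bo = 2)
  n_total <- sum(vapply(shapes, prod, 0))
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "double", n = n_total, size = 8L, endian = "little")
  close(con)
  params <- list()
  off <- 0L
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    v <- vals[(off + 1):(off + sz)]
    params[[nm]] <- if (length(shapes[[nm]]) == 2L)
      matrix(v, shapes[[nm]][1], shapes[[nm]][2]) else if (sz == 1L) v else v
    off <- off + sz
  }
  class(params) <- "mil_params"
  structure(list(params = params, final_params = params,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_auc = numeric()),
                 best_epoch = meta$best_epoch,
                 config = mil_config(hidden = h, d_attn = da),
                 freeze = character(), input_dim = d, call = NULL),
            class = "mil_fit")
}
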