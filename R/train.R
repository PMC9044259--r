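#' Training loop
#'
#' Adam optimization of the composite detection loss with a cosine-annealed
#' learning rate, optional on-the-fly augmentation and Mosaic composition,
#' per-epoch loss logging and optional validation mAP plus best-checkpoint
#' saving.
#'
#' @name training
NULL

adam_init <- function(model) {
  for (mod in nn_modules(model)) {
    mod$opt_m <- lapply(mod$params, function(p) { z <- p; z[] <- 0; z })
    mod$opt_v <- mod$opt_m
  }
  invisible(model)
}

adam_step <- function(model, lr, t, weight_decay = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (mod in nn_modules(model)) {
    for (nm in names(mod$params)) {
      g <- mod$grads[[nm]]
      if (weight_decay > 0 && !(nm %in% c("beta", "b"))) {
        g <- g + weight_decay * mod$params[[nm]]
      }
      mod$opt_m[[nm]] <- beta1 * mod$opt_m[[nm]] + (1 - beta1) * g
      mod$opt_v[[nm]] <- beta2 * mod$opt_v[[nm]] + (1 - beta2) * g * g
      mod$params[[nm]] <- mod$params[[nm]] -
        lr * (mod$opt_m[[nm]] / bc1) / (sqrt(mod$opt_v[[nm]] / bc2) + eps)
    }
  }
  invisible(model)
}

# normalize the accepted dataset forms to list(images = list of (3,H,W)
# arrays in [0,1], gt = list of box matrices)
as_training_set <- function(dataset) {
  if (!is.null(dataset$images) && !is.null(dataset$gt)) return(dataset)
  if (is.list(dataset) && length(dataset) && inherits(dataset[[1]], "scene")) {
    return(list(images = lapply(dataset, function(s) {
      aperm(s$image / 255, c(3, 1, 2))
    }), gt = lapply(dataset, function(s) s$boxes)))
  }
  stop("dataset must be a list of scenes or list(images=, gt=)")
}

# one optimization step on a prepared batch; returns the loss record
train_step <- function(model, batch_x, batch_gt, cfg, weights, lr, t) {
  targets <- assign_targets(batch_gt, model$anchors, cfg$input_size,
                            cfg$iou_threshold)
  x <- fm_from_array(batch_x)
  preds <- nn_forward(model, x, training = TRUE)
  loss <- detection_loss_fm(preds, targets, model$anchors, cfg$input_size,
                            weights, model$num_classes)
  if (!is.finite(loss$total)) {
    stop("training diverged: non-finite loss (",
         paste(names(loss$components), sprintf("%.3g", loss$components),
               collapse = ", "), ")")
  }
  nn_zero_grads(model)
  nn_backward(model, lapply(loss$dpreds, function(d) fm_like(d, d)))
  adam_step(model, lr, t, cfg$weight_decay)
  loss
}

#' Train a detector
#'
#' @param model a [detector()] whose `input_size` matches `cfg$input_size`
#' @param dataset a list of `scene` objects or `list(images=, gt=)` with
#'   images as (3, H, W) arrays in \[0, 1\]
#' @param cfg a [train_config()]
#' @param weights a [loss_weights()]
#' @param val_dataset optional held-out set; when given, validation mAP@0.5
#'   is computed each `eval_every` epochs and the best checkpoint is kept
#' @param eval_every validation cadence in epochs
#' @param checkpoint_path where to save the best (or final) checkpoint;
#'   `NULL` skips saving
#' @param verbose print a line per epoch?
#' @return list with the trained `model`, the per-epoch `history`
#'   data.frame and `best_map` (NA without validation)
#' @export
train <- function(model, dataset, cfg = train_config(),
                  weights = loss_weights(), val_dataset = NULL,
                  eval_every = 5, checkpoint_path = NULL, verbose = FALSE) {
  ds <- as_training_set(dataset)
  n <- length(ds$images)
  if (!n) stop("empty training dataset")
  scenes <- NULL
  if (is.list(dataset) && length(dataset) && inherits(dataset[[1]], "scene")) {
    scenes <- dataset
  }
  adam_init(model)
  set.seed(cfg$seed)
  history <- list()
  best_map <- NA_real_
  t <- 0
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg$epochs, cfg$learning_rate, cfg$cosine_annealing)
    idx <- sample.int(n)
    ep_loss <- c(total = 0, box = 0, objectness = 0, class = 0)
    n_steps <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1, n)]
      imgs <- list(); gts <- list()
      for (k in seq_along(take)) {
        i <- take[k]
        if (!is.null(scenes) && (cfg$augment || cfg$mosaic_prob > 0)) {
          sc <- scenes[[i]]
          if (cfg$mosaic_prob > 0 && stats::runif(1) < cfg$mosaic_prob) {
            others <- sample.int(n, 3, replace = TRUE)
            sc <- mosaic(c(list(sc), scenes[others]),
                         seed = sample.int(1e6, 1))
          }
          if (cfg$augment) {
            ops <- c(if (stats::runif(1) < 0.5) "mirror",
                     if (stats::runif(1) < 0.3) "saturation")
            if (length(ops)) sc <- augment(sc, ops, seed = sample.int(1e6, 1))
          }
          imgs[[k]] <- aperm(sc$image / 255, c(3, 1, 2))
          gts[[k]] <- sc$boxes
        } else {
          imgs[[k]] <- ds$images[[i]]
          gts[[k]] <- ds$gt[[i]]
        }
      }
      bx <- array(0, c(length(imgs), dim(imgs[[1]])))
      for (k in seq_along(imgs)) bx[k, , , ] <- imgs[[k]]
      t <- t + 1
      loss <- train_step(model, bx, gts, cfg, weights, lr, t)
      ep_loss <- ep_loss + c(loss$total, loss$components)
      n_steps <- n_steps + 1
    }
    ep_loss <- ep_loss / n_steps
    rec <- data.frame(epoch = epoch, lr = lr, loss = ep_loss[1],
                      box = ep_loss[2], objectness = ep_loss[3],
                      class = ep_loss[4], val_map = NA_real_)
    if (!is.null(val_dataset) &&
        (epoch %% eval_every == 0 || epoch == cfg$epochs)) {
      vs <- as_training_set(val_dataset)
      met <- evaluate(model, vs$images, vs$gt,
                      iou_threshold = cfg$iou_threshold)
      rec$val_map <- met$ap
      if (is.na(best_map) || met$ap >= best_map) {
        best_map <- met$ap
        if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
      }
    }
    history[[epoch]] <- rec
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.5f  loss %.4f (box %.4f obj %.4f cls %.4f)%s",
        epoch, lr, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4],
        if (!is.na(rec$val_map)) sprintf("  val mAP %.3f", rec$val_map) else ""))
    }
  }
  if (!is.null(checkpoint_path) && is.null(val_dataset)) {
    save_checkpoint(model, checkpoint_path)
  }
  list(model = model, history = do.call(rbind, history), best_map = best_map)
}
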