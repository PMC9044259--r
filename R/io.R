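#' Annotation readers and writers
#'
#' GWHD-style CSV (columns `image_id, width, height, bbox, source` with
#' bbox strings `"[x, y, w, h]"`) and YOLO txt (one
#' `class cx cy w h` line per box, coordinates normalized to the image
#' size). Boxes are converted to half-open pixel corner coordinates
#' (x1 = x, y1 = y, x2 = x + w, y2 = y + h).
#'
#' @name annotation_io
NULL

gwhd_rows <- function(image_id, boxes, width, height, source = "synthetic") {
  if (!NROW(boxes)) {
    return(data.frame(image_id = image_id, width = width, height = height,
                      bbox = "", source = source))
  }
  data.frame(
    image_id = image_id, width = width, height = height,
    bbox = apply(boxes, 1, function(b) {
      sprintf("[%s, %s, %s, %s]",
              formatC(b[1], digits = 17, format = "g"),
              formatC(b[2], digits = 17, format = "g"),
              formatC(b[3] - b[1], digits = 17, format = "g"),
              formatC(b[4] - b[2], digits = 17, format = "g"))
    }),
    source = source)
}

#' @rdname annotation_io
#' @param path CSV file path
#' @return `read_gwhd_csv()`: a named list, one entry per image, each a
#'   list with `image_id`, `width`, `height` and a `boxes` matrix
#'   (columns x1, y1, x2, y2; zero rows for images without ears)
#' @export
read_gwhd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "width", "height", "bbox")
  if (!all(need %in% names(df))) {
    stop("GWHD csv must have columns ", paste(need, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$image_id[i]
    if (is.null(out[[id]])) {
      out[[id]] <- list(image_id = id, width = df$width[i],
                        height = df$height[i],
                        boxes = matrix(numeric(0), 0, 4,
                                       dimnames = list(NULL,
                                                       c("x1", "y1",
                                                         "x2", "y2"))))
    }
    s <- trimws(df$bbox[i])
    if (identical(s, "") || is.na(s)) next
    m <- regmatches(s, regexec(
      "^\\[\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*\\]$",
      s))[[1]]
    if (length(m) != 5) stop("malformed bbox string in row ", i, ": ", s)
    v <- as.numeric(m[2:5])
    out[[id]]$boxes <- rbind(out[[id]]$boxes,
                             c(v[1], v[2], v[1] + v[3], v[2] + v[4]))
  }
  out
}

#' @rdname annotation_io
#' @param ann either the data.frame of rows to write (as produced
#'   internally) or a list as returned by `read_gwhd_csv()`
#' @export
write_gwhd_csv <- function(ann, path) {
  if (is.list(ann) && !is.data.frame(ann)) {
    ann <- do.call(rbind, lapply(ann, function(sc) {
      gwhd_rows(sc$image_id, sc$boxes, sc$width, sc$height)
    }))
  }
  utils::write.csv(ann, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname annotation_io
#' @param image_w,image_h image size in pixels
#' @return `read_yolo_labels()`: a boxes matrix (columns x1, y1, x2, y2)
#' @export
read_yolo_labels <- function(path, image_w, image_h) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  }
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(vals) != 5) stop("YOLO label lines need 5 fields: class cx cy w h")
  if (any(vals[, 2:5] < 0) || any(vals[, 2:5] > 1)) {
    stop("YOLO label coordinates must lie in [0, 1]")
  }
  cx <- vals[, 2] * image_w; cy <- vals[, 3] * image_h
  w <- vals[, 4] * image_w; h <- vals[, 5] * image_h
  cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
}

#' @rdname annotation_io
#' @param boxes matrix with columns x1, y1, x2, y2
#' @param class_id class index written in the first field
#' @export
write_yolo_labels <- function(boxes, path, image_w, image_h, class_id = 0) {
  lines <- character(0)
  if (NROW(boxes)) {
    cx <- (boxes[, 1] + boxes[, 3]) / 2 / image_w
    cy <- (boxes[, 2] + boxes[, 4]) / 2 / image_h
    w <- (boxes[, 3] - boxes[, 1]) / image_w
    h <- (boxes[, 4] - boxes[, 2]) / image_h
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", class_id, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- training configuration ----

#' Training configuration
#'
#' Defaults follow the reference training recipe: input 1024, batch size 4,
#' 100 epochs, initial learning rate 0.01 with cosine annealing down to
#' `cosine_annealing` times the initial rate, weight decay 5e-4, matching
#' IOU threshold 0.5, Adam.
#'
#' @param input_size square input side (pixels, divisible by 32)
#' @param batch_size images per gradient step
#' @param epochs training epochs
#' @param learning_rate initial Adam learning rate
#' @param weight_decay L2 weight decay coefficient
#' @param iou_threshold IOU threshold used in assignment and evaluation
#' @param cosine_annealing final/initial learning-rate ratio of the cosine
#'   schedule
#' @param optimizer only `"adam"` is implemented
#' @param seed integer seed controlling shuffling and augmentation draws
#' @param augment apply the augmentation suite (mirror/scale/rotate/
#'   saturation) on the fly?
#' @param mosaic_prob probability of composing a Mosaic batch sample
#' @return a list of class `train_config`
#' @export
train_config <- function(input_size = 1024, batch_size = 4, epochs = 100,
                         learning_rate = 0.01, weight_decay = 5e-4,
                         iou_threshold = 0.5, cosine_annealing = 0.2,
                         optimizer = "adam", seed = 1, augment = TRUE,
                         mosaic_prob = 0.5) {
  stopifnot(input_size > 0, input_size %% 32 == 0, batch_size >= 1,
            epochs >= 1, learning_rate > 0, weight_decay >= 0,
            iou_threshold > 0, iou_threshold < 1, cosine_annealing > 0,
            identical(optimizer, "adam"))
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 iou_threshold = iou_threshold,
                 cosine_annealing = cosine_annealing,
                 optimizer = optimizer, seed = as.integer(seed),
                 augment = augment, mosaic_prob = mosaic_prob),
            class = "train_config")
}

#' @rdname train_config
#' @param cfg a `train_config`
#' @param path YAML file path
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname train_config
#' @export
load_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(train_config, v)
}

#' Cosine-annealed learning rate
#'
#' Decays from `lr0` at epoch 1 to `ratio * lr0` at the final epoch along
#' a half cosine.
#'
#' @param epoch current epoch (1-based)
#' @param epochs total epochs
#' @param lr0 initial learning rate
#' @param ratio final/initial ratio
#' @return the learning rate for `epoch`
#' @export
cosine_lr <- function(epoch, epochs, lr0, ratio = 0.2) {
  lr_final <- ratio * lr0
  if (epochs <= 1) return(lr0)
  lr_final + 0.5 * (lr0 - lr_final) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

## ---- checkpointing ----

#' Save / load model checkpoints
#'
#' A checkpoint stores every parameter and normalization buffer plus the
#' constructor arguments, so a loaded model reproduces the saved model's
#' predictions bit for bit.
#'
#' @param model a [detector()]
#' @param path checkpoint file path (RDS)
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(state = nn_state(model), spec = model$spec,
               neck_widths = model$neck_widths, anchors = model$anchors,
               input_size = model$input_size,
               num_classes = model$num_classes, seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: the restored detector
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- detector(spec = ck$spec, neck_widths = ck$neck_widths,
                anchors = ck$anchors, input_size = ck$input_size,
                num_classes = ck$num_classes, seed = ck$seed)
  nn_load_state(m, ck$state)
  m
}
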