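#' Synthetic wheat-field scenes
#'
#' A generator for dense, overlapping, elongated "ear" objects on textured
#' green-brown backgrounds, emulating the geometric and statistical
#' properties of annotated wheat-field imagery (by default 20-70 ears per
#' 1024 x 1024 image) without any download. Ears are rendered as oriented,
#' banded ellipses with per-ear colour jitter; each ear's tight axis-aligned
#' bounding box is recorded as ground truth. Realism is deliberately
#' minimal: the purpose is density, overlap and scale fidelity, not
#' photorealism.
#'
#' @name synthetic_data
NULL

#' Synthetic-scene configuration
#'
#' @param image_size square image side in pixels
#' @param ear_count_range inclusive range of ears per image
#' @param ear_length_range ear major-axis length range in pixels
#' @param ear_width_range ear minor-axis width range in pixels
#' @param orientation_range ear orientation range in degrees
#' @param overlap_allowance maximum IOU a new ear's box may have with an
#'   already placed one before re-sampling its position (up to 20 tries);
#'   larger values give denser, harder scenes
#' @param background `"field"` (textured green-brown) or `"plain"` (dark,
#'   low-noise; high ear contrast)
#' @param color_jitter per-ear relative colour jitter
#' @param preset `"field"` for the default condition or `"easy"` for a
#'   small, sparse, high-contrast configuration used in training-recovery
#'   experiments
#' @return a list of class `synth_config`
#' @export
synth_config <- function(image_size = 1024, ear_count_range = c(20, 70),
                         ear_length_range = c(50, 140),
                         ear_width_range = c(18, 45),
                         orientation_range = c(-90, 90),
                         overlap_allowance = 0.4,
                         background = c("field", "plain"),
                         color_jitter = 0.15,
                         preset = NULL) {
  if (!is.null(preset) && preset == "easy") {
    return(synth_config(image_size = 256, ear_count_range = c(6, 12),
                        ear_length_range = c(36, 56),
                        ear_width_range = c(14, 22),
                        orientation_range = c(-90, 90),
                        overlap_allowance = 0.05, background = "plain",
                        color_jitter = 0.08))
  }
  background <- match.arg(background)
  stopifnot(image_size >= 64,
            length(ear_count_range) == 2,
            ear_count_range[1] <= ear_count_range[2],
            ear_length_range[1] <= ear_length_range[2],
            ear_width_range[1] <= ear_width_range[2],
            orientation_range[1] <= orientation_range[2],
            overlap_allowance >= 0)
  structure(list(image_size = as.integer(image_size),
                 ear_count_range = as.integer(ear_count_range),
                 ear_length_range = ear_length_range,
                 ear_width_range = ear_width_range,
                 orientation_range = orientation_range,
                 overlap_allowance = overlap_allowance,
                 background = background, color_jitter = color_jitter),
            class = "synth_config")
}

render_background <- function(size, kind) {
  if (kind == "plain") {
    base <- c(45, 62, 38) / 255
    img <- array(rep(base, each = size * size), c(size, size, 3))
    img + array(stats::runif(size * size * 3, -0.02, 0.02), dim(img))
  } else {
    coarse_n <- max(8, size %/% 32)
    up <- size / coarse_n
    coarse <- matrix(stats::runif(coarse_n^2), coarse_n)
    field <- kronecker(coarse, matrix(1, up, up))
    fine <- matrix(stats::runif(size^2, -0.08, 0.08), size)
    t0 <- pmin(pmax(field + fine, 0), 1)
    # blend soil brown with leaf green by the texture value
    img <- array(0, c(size, size, 3))
    img[, , 1] <- (0.32 + 0.18 * t0)
    img[, , 2] <- (0.36 + 0.22 * t0)
    img[, , 3] <- (0.16 + 0.10 * t0)
    img + array(stats::runif(size * size * 3, -0.03, 0.03), dim(img))
  }
}

#' Sample one synthetic scene
#'
#' Draws the ear count uniformly from the configured range, places oriented
#' elliptical ears (re-sampling positions that exceed the overlap
#' allowance), renders them with banded texture over the background and
#' records each ear's tight axis-aligned box. A pure function of
#' `(cfg, seed)`.
#'
#' @param cfg a [synth_config()]
#' @param seed integer seed
#' @return a list of class `scene`: `image` (H x W x 3 integer array,
#'   0-255), `boxes` (matrix with columns x1, y1, x2, y2), `seed`, and
#'   `ear_map` (integer H x W matrix of ear ids, 0 = background)
#' @export
sample_scene <- function(cfg = synth_config(), seed = 1) {
  set.seed(seed)
  size <- cfg$image_size
  img <- render_background(size, cfg$background)
  n <- sample(cfg$ear_count_range[1]:cfg$ear_count_range[2], 1)
  boxes <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  ear_map <- matrix(0L, size, size)
  placed <- 0
  for (e in seq_len(n)) {
    for (try in 1:20) {
      len <- stats::runif(1, cfg$ear_length_range[1], cfg$ear_length_range[2])
      wid <- stats::runif(1, cfg$ear_width_range[1], cfg$ear_width_range[2])
      th <- stats::runif(1, cfg$orientation_range[1],
                         cfg$orientation_range[2]) * pi / 180
      a <- len / 2; b <- wid / 2
      hw <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      hh <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
      cx <- stats::runif(1, hw, size - hw)
      cy <- stats::runif(1, hh, size - hh)
      cand <- c(cx - hw, cy - hh, cx + hw, cy + hh)
      if (placed == 0 || cfg$overlap_allowance >= 1) break
      worst <- max(iou(boxes[seq_len(placed), , drop = FALSE],
                       matrix(cand, 1)))
      if (worst <= cfg$overlap_allowance) break
    }
    boxes[e, ] <- cand
    placed <- e
    # rasterize the ellipse over its bounding box
    cols <- max(1L, floor(cand[1]) + 1L):min(size, ceiling(cand[3]))
    rws <- max(1L, floor(cand[2]) + 1L):min(size, ceiling(cand[4]))
    px <- cols - 0.5; py <- rws - 0.5
    dx <- outer(rep(1, length(rws)), px - cx)
    dy <- outer(py - cy, rep(1, length(cols)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    base <- c(0.78, 0.68, 0.33) *
      (1 + stats::runif(3, -cfg$color_jitter, cfg$color_jitter))
    band <- 0.85 + 0.2 * sin(u * (2 * pi / max(6, wid / 2)))
    grain <- matrix(stats::runif(length(u), -0.05, 0.05), nrow(u))
    idx <- which(inside, arr.ind = TRUE)
    rr <- rws[idx[, 1]]; cc <- cols[idx[, 2]]
    f <- band[inside] + grain[inside]
    for (ch in 1:3) {
      img[cbind(rr, cc, ch)] <- pmin(pmax(base[ch] * f, 0), 1)
    }
    ear_map[cbind(rr, cc)] <- e
  }
  img <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), dim(img))
  structure(list(image = img, boxes = boxes, seed = seed, ear_map = ear_map),
            class = "scene")
}

# scene image (H, W, 3; 0-255) -> model input array (1, 3, H, W) in [0, 1]
scene_input <- function(scene) {
  a <- aperm(scene$image / 255, c(3, 1, 2))
  array(a, c(1, dim(a)))
}

#' Generate and write a synthetic dataset
#'
#' Writes `n_images` PNG scenes with annotations in both GWHD-style CSV
#' (one `annotations.csv` for the whole set) and YOLO txt (one file per
#' image under `labels/`), plus a train/val split manifest.
#'
#' @param cfg a [synth_config()]
#' @param n_images number of scenes
#' @param seed integer seed; scene i uses `seed + i`
#' @param out_dir output directory (created if needed)
#' @param train_fraction fraction of images assigned to the training split
#' @return the manifest data.frame (`image_id`, `file`, `n_boxes`, `split`)
#' @export
make_dataset <- function(cfg = synth_config(), n_images, seed = 1, out_dir,
                         train_fraction = 0.8) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- list()
  ann <- list()
  n_train <- floor(n_images * train_fraction)
  for (i in seq_len(n_images)) {
    sc <- sample_scene(cfg, seed + i)
    id <- sprintf("synth_%05d", i)
    png_path <- file.path(out_dir, "images", paste0(id, ".png"))
    png::writePNG(sc$image / 255, png_path)
    write_yolo_labels(sc$boxes, file.path(out_dir, "labels",
                                          paste0(id, ".txt")),
                      cfg$image_size, cfg$image_size)
    ann[[i]] <- gwhd_rows(id, sc$boxes, cfg$image_size, cfg$image_size)
    rows[[i]] <- data.frame(image_id = id, file = png_path,
                            n_boxes = nrow(sc$boxes),
                            split = if (i <= n_train) "train" else "val")
  }
  write_gwhd_csv(do.call(rbind, ann), file.path(out_dir, "annotations.csv"))
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

## ---- augmentations ----

resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  ri <- pmin(d[1], pmax(1, ceiling(seq_len(out_h) * d[1] / out_h)))
  ci <- pmin(d[2], pmax(1, ceiling(seq_len(out_w) * d[2] / out_w)))
  img[ri, ci, , drop = FALSE]
}

clip_boxes <- function(boxes, w, h, min_area = 4) {
  if (!NROW(boxes)) return(boxes)
  b <- boxes
  b[, 1] <- pmax(0, pmin(b[, 1], w)); b[, 3] <- pmax(0, pmin(b[, 3], w))
  b[, 2] <- pmax(0, pmin(b[, 2], h)); b[, 4] <- pmax(0, pmin(b[, 4], h))
  keep <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) >= min_area
  b[keep, , drop = FALSE]
}

#' Augment a scene
#'
#' Applies the listed operations in order, remapping the boxes with each:
#' `mirror` flips horizontally (x1' = W - x2), `scale` rescales image and
#' coordinates by a factor drawn from `scale_range` (canvas size is kept;
#' shrunk images are zero-padded, grown ones cropped), `rotate` rotates
#' about the image center by an angle drawn from `rotate_range` (boxes
#' become the tight hull of their rotated corners, clipped), `saturation`
#' moves pixel colours away from or toward their grey value. Boxes whose
#' remaining area falls below 4 px^2 are dropped.
#'
#' @param scene a `scene` from [sample_scene()]
#' @param ops character vector, subset of
#'   `c("scale", "mirror", "rotate", "saturation")`
#' @param seed integer seed for the drawn factors
#' @param scale_range,rotate_range,saturation_range sampling ranges
#'   (rotation in degrees)
#' @return an augmented `scene` (without `ear_map`)
#' @export
augment <- function(scene, ops, seed = 1, scale_range = c(0.75, 1.25),
                    rotate_range = c(-15, 15),
                    saturation_range = c(0.6, 1.4)) {
  bad <- setdiff(ops, c("scale", "mirror", "rotate", "saturation"))
  if (length(bad)) stop("unknown augmentation op: ", paste(bad, collapse = ", "))
  set.seed(seed)
  img <- scene$image
  boxes <- scene$boxes
  h <- dim(img)[1]; w <- dim(img)[2]
  for (op in ops) {
    if (op == "mirror") {
      img <- img[, w:1, , drop = FALSE]
      if (NROW(boxes)) {
        nx1 <- w - boxes[, 3]; nx2 <- w - boxes[, 1]
        boxes[, 1] <- nx1; boxes[, 3] <- nx2
      }
    } else if (op == "scale") {
      f <- stats::runif(1, scale_range[1], scale_range[2])
      nh <- max(1, round(h * f)); nw <- max(1, round(w * f))
      scaled <- resize_nearest(img, nh, nw)
      canvas <- array(0L, c(h, w, 3))
      ch <- min(h, nh); cw <- min(w, nw)
      canvas[1:ch, 1:cw, ] <- scaled[1:ch, 1:cw, , drop = FALSE]
      img <- canvas
      if (NROW(boxes)) boxes <- clip_boxes(boxes * f, w, h)
    } else if (op == "rotate") {
      ang <- stats::runif(1, rotate_range[1], rotate_range[2]) * pi / 180
      if (ang != 0) {
        cxy <- c(w, h) / 2
        # inverse map each output pixel center back to the source
        oc <- matrix(rep(seq_len(w) - 0.5, each = h), h) - cxy[1]
        or <- matrix(rep(seq_len(h) - 0.5, w), h) - cxy[2]
        sx <- cos(-ang) * oc - sin(-ang) * or + cxy[1]
        sy <- sin(-ang) * oc + cos(-ang) * or + cxy[2]
        sc <- pmin(w, pmax(1, ceiling(sx)))
        sr <- pmin(h, pmax(1, ceiling(sy)))
        valid <- sx >= 0 & sx <= w & sy >= 0 & sy <= h
        out <- array(0L, dim(img))
        for (chn in 1:3) {
          plane <- img[, , chn]
          o <- plane[cbind(as.vector(sr), as.vector(sc))]
          o[!as.vector(valid)] <- 0L
          out[, , chn] <- o
        }
        img <- out
        if (NROW(boxes)) {
          nb <- t(apply(boxes, 1, function(bx) {
            cs <- rbind(c(bx[1], bx[2]), c(bx[3], bx[2]),
                        c(bx[1], bx[4]), c(bx[3], bx[4]))
            cs <- sweep(cs, 2, cxy)
            rot <- cs %*% matrix(c(cos(ang), sin(ang),
                                   -sin(ang), cos(ang)), 2)
            rot <- sweep(rot, 2, cxy, "+")
            c(min(rot[, 1]), min(rot[, 2]), max(rot[, 1]), max(rot[, 2]))
          }))
          boxes <- clip_boxes(nb, w, h)
        }
      }
    } else if (op == "saturation") {
      f <- stats::runif(1, saturation_range[1], saturation_range[2])
      g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      for (chn in 1:3) {
        img[, , chn] <- as.integer(round(pmin(pmax(
          g + (img[, , chn] - g) * f, 0), 255)))
      }
    }
  }
  structure(list(image = img, boxes = boxes, seed = seed), class = "scene")
}

#' Mosaic augmentation
#'
#' Composites four same-sized scenes into one: a random center point splits
#' the canvas into four quadrants, each filled with a random same-sized
#' crop of its source scene; boxes are offset into place and clipped to
#' their quadrant.
#'
#' @param scenes list of exactly 4 `scene` objects with equal image sizes
#' @param seed integer seed for the center point and crop offsets
#' @param center optional fixed center `c(x, y)` (used instead of sampling)
#' @return a combined `scene`
#' @export
mosaic <- function(scenes, seed = 1, center = NULL) {
  stopifnot(length(scenes) == 4)
  dims <- lapply(scenes, function(s) dim(s$image))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("mosaic requires four scenes of identical size")
  }
  set.seed(seed)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (is.null(center)) {
    center <- c(round(stats::runif(1, 0.3, 0.7) * w),
                round(stats::runif(1, 0.3, 0.7) * h))
  }
  cx <- center[1]; cy <- center[2]
  out <- array(0L, c(h, w, 3))
  boxes <- list()
  # quadrant rectangles in (x1, y1, x2, y2) pixel units
  quads <- list(c(0, 0, cx, cy), c(cx, 0, w, cy),
                c(0, cy, cx, h), c(cx, cy, w, h))
  for (q in 1:4) {
    r <- quads[[q]]
    qw <- r[3] - r[1]; qh <- r[4] - r[2]
    if (qw < 1 || qh < 1) next
    src <- scenes[[q]]
    ox <- if (w - qw > 0) sample.int(w - qw + 1, 1) - 1 else 0
    oy <- if (h - qh > 0) sample.int(h - qh + 1, 1) - 1 else 0
    out[(r[2] + 1):r[4], (r[1] + 1):r[3], ] <-
      src$image[(oy + 1):(oy + qh), (ox + 1):(ox + qw), , drop = FALSE]
    if (NROW(src$boxes)) {
      b <- src$boxes
      b[, c(1, 3)] <- b[, c(1, 3)] - ox + r[1]
      b[, c(2, 4)] <- b[, c(2, 4)] - oy + r[2]
      # clip to the quadrant
      b[, 1] <- pmax(r[1], pmin(b[, 1], r[3]))
      b[, 3] <- pmax(r[1], pmin(b[, 3], r[3]))
      b[, 2] <- pmax(r[2], pmin(b[, 2], r[4]))
      b[, 4] <- pmax(r[2], pmin(b[, 4], r[4]))
      keep <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) >= 4
      if (any(keep)) boxes[[length(boxes) + 1]] <- b[keep, , drop = FALSE]
    }
  }
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  structure(list(image = out, boxes = boxes, seed = seed), class = "scene")
}
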