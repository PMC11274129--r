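# Synthetic six-behavior dataset generator. The real footage (infrared
# video of cave-guarding giant salamanders) is private, so test fixtures
# are procedural: each behavior class is rendered as a visually distinct
# parametric silhouette on a dark, noisy, cave-like background, with
# YOLO-format labels derived from the exact pixel support of the
# silhouette. Everything is deterministic given the seed.

# run expr with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# class-conditional silhouette mask on an n x n grid centred at (cx, cy)
# with half-size r and orientation th. Pose encodes the class, mirroring
# that the behaviors are pose/position-defined.
class_mask <- function(class_id, n, cx, cy, r, th) {
  xs <- matrix(rep(seq_len(n), each = n), n) - cx   # column offsets
  ys <- matrix(rep(seq_len(n), times = n), n) - cy  # row offsets
  x <- cos(th) * xs + sin(th) * ys
  y <- -sin(th) * xs + cos(th) * ys
  switch(as.character(class_id),
    "0" = { # tail fanning: body ellipse + triangular tail fan
      body <- (x / r)^2 + (y / (0.45 * r))^2 <= 1
      fan <- x > 0.6 * r & x < 1.8 * r & abs(y) < (x - 0.6 * r) * 0.8
      body | fan
    },
    "1" = { # agitating: thick S-curve through the egg pile
      abs(y - 0.5 * r * sin(2.2 * x / r)) < 0.28 * r & abs(x) < 1.4 * r
    },
    "2" = { # shaking: cross (body straddling, swinging both axes)
      (abs(x) < 1.3 * r & abs(y) < 0.3 * r) | (abs(y) < 1.3 * r & abs(x) < 0.3 * r)
    },
    "3" = { # egg eating: open ring (mouth) holding a dot (egg)
      rr <- sqrt(x^2 + y^2)
      (rr < r & rr > 0.55 * r & !(x > 0 & abs(y) < 0.25 * r)) |
        (sqrt((x - 0.45 * r)^2 + y^2) < 0.22 * r)
    },
    "4" = { # entering caves: half-disc (head at the cave mouth)
      (x / r)^2 + (y / r)^2 <= 1 & y <= 0
    },
    "5" = { # exiting caves: thin tapered bar (tail at the cave mouth)
      abs(x) < 0.25 * r * (1 - 0.5 * abs(y) / (1.4 * r)) & abs(y) < 1.4 * r
    },
    stop("unknown class_id: ", class_id))
}

CLASS_TINT <- rbind(c(0.95, 0.85, 0.75), c(0.75, 0.95, 0.80),
                    c(0.80, 0.80, 1.00), c(1.00, 0.95, 0.70),
                    c(0.95, 0.70, 0.90), c(0.70, 1.00, 1.00))

box_blur3 <- function(ch) {
  n <- nrow(ch); m <- ncol(ch)
  p <- ch[c(1, 1:n, n), c(1, 1:m, m)]
  (p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
   p[2:(n + 1), 1:m] + p[2:(n + 1), 2:(m + 1)] + p[2:(n + 1), 3:(m + 2)] +
   p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] + p[3:(n + 2), 3:(m + 2)]) / 9
}

#' Render one synthetic behavior scene
#'
#' Draws `n_objects` class-conditional silhouettes on a low-light noisy
#' background and returns the image together with tight YOLO-normalized
#' boxes derived from the silhouette pixel support. Deterministic given
#' `seed`. Objects whose support would fall fully outside the frame are
#' resampled (bounded retries).
#'
#' @param class_id behavior class 0..5 (scalar or one per object).
#' @param img_size square image size in pixels.
#' @param n_objects number of objects.
#' @param degradation one of "none", "blur", "low_light", "shadow".
#' @param magnitude degradation strength in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `image` (img_size x img_size x 3, values in 0..1)
#'   and `labels` (data.frame class_id, cx, cy, w, h, normalized).
#' @export
render_scene <- function(class_id, img_size = 160L, n_objects = 1L,
                         degradation = c("none", "blur", "low_light", "shadow"),
                         magnitude = 0.5, seed = 0L) {
  degradation <- match.arg(degradation)
  n <- as.integer(img_size)
  cls <- rep(as.integer(class_id), length.out = n_objects)
  stopifnot(all(cls >= 0 & cls <= 5))
  with_seed(seed, {
    img <- array(0.06 + 0.04 * stats::runif(n * n), c(n, n, 3))
    # coarse rock texture: a few dim blobs
    for (b in seq_len(6)) {
      bx <- stats::runif(1, 1, n); by <- stats::runif(1, 1, n)
      br <- stats::runif(1, 0.1, 0.3) * n
      xs <- matrix(rep(seq_len(n), each = n), n) - bx
      ys <- matrix(rep(seq_len(n), times = n), n) - by
      blob <- exp(-(xs^2 + ys^2) / (2 * br^2)) * stats::runif(1, 0.02, 0.06)
      for (c in 1:3) img[, , c] <- img[, , c] + blob
    }
    labels <- NULL
    for (o in seq_len(n_objects)) {
      ok <- FALSE
      for (try in 1:25) {
        r <- stats::runif(1, 0.14, 0.20) * n
        cx <- stats::runif(1, 0.25 * n, 0.75 * n)
        cy <- stats::runif(1, 0.25 * n, 0.75 * n)
        th <- stats::runif(1, -0.5, 0.5)
        mask <- class_mask(cls[o], n, cx, cy, r, th)
        if (any(mask)) { ok <- TRUE; break }
      }
      if (!ok) stop("render_scene: could not place object after bounded retries")
      lev <- stats::runif(1, 0.55, 0.8)
      for (c in 1:3)
        img[, , c][mask] <- lev * CLASS_TINT[cls[o] + 1L, c]
      rows <- range(which(rowSums(mask) > 0))
      colsr <- range(which(colSums(mask) > 0))
      # mask is indexed [row, col]; convert pixel support to box edges
      x1 <- colsr[1] - 1; x2 <- colsr[2]; y1 <- rows[1] - 1; y2 <- rows[2]
      labels <- rbind(labels, data.frame(
        class_id = cls[o],
        cx = (x1 + x2) / 2 / n, cy = (y1 + y2) / 2 / n,
        w = (x2 - x1) / n, h = (y2 - y1) / n))
    }
    if (is.null(labels))
      labels <- data.frame(class_id = integer(0), cx = numeric(0),
                           cy = numeric(0), w = numeric(0), h = numeric(0))
    img <- switch(degradation,
      none = img,
      blur = { k <- max(1L, round(3 * magnitude))
               for (it in seq_len(k)) for (c in 1:3) img[, , c] <- box_blur3(img[, , c])
               img },
      low_light = img * (1 - 0.7 * magnitude),
      shadow = { xs <- matrix(rep(seq_len(n), each = n), n) - 0.5 * n
                 ys <- matrix(rep(seq_len(n), times = n), n) - 0.5 * n
                 sh <- 1 - magnitude * 0.6 * exp(-((xs / (0.4 * n))^2 + (ys / (0.4 * n))^2))
                 for (c in 1:3) img[, , c] <- img[, , c] * sh
                 img })
    img <- pmin(pmax(img, 0), 1)
    list(image = img, labels = labels)
  })
}

#' Read / write YOLO-format label files
#'
#' One line per object: `class cx cy w h`, centre/size normalized to the
#' image. Writing rounds to 6 decimals; write followed by read is the
#' identity at that precision. Coordinates are clamped to `[0, 1]` on
#' write.
#'
#' @param path label file path.
#' @return data.frame with class_id, cx, cy, w, h (empty for empty files).
#' @export
read_yolo_labels <- function(path) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else
    stop("label file not found: ", path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 5L || anyNA(suppressWarnings(as.numeric(tok))))
      stop("malformed YOLO label at ", path, " line ", i, ": '", lines[i], "'")
    data.frame(class_id = as.integer(tok[1]), cx = as.numeric(tok[2]),
               cy = as.numeric(tok[3]), w = as.numeric(tok[4]),
               h = as.numeric(tok[5]))
  })
  do.call(rbind, rows)
}

#' @rdname read_yolo_labels
#' @param labels data.frame with class_id, cx, cy, w, h.
#' @export
write_yolo_labels <- function(labels, path) {
  clamp <- function(v) pmin(pmax(v, 0), 1)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id,
                   clamp(labels$cx), clamp(labels$cy),
                   clamp(labels$w), clamp(labels$h))
  writeLines(lines, path)
  invisible(path)
}

#' Dataset manifest for the six-behavior preset
#'
#' Defaults mirror the published dataset: per-class image counts
#' 600/700/500/700/250/250 and a stratified 8:2 train/test split.
#'
#' @param counts per-class image counts, named by the class labels.
#' @param split train fraction (default 0.8; train takes the floor,
#'   remainder goes to test).
#' @param img_size rendered image size.
#' @param objects_per_image objects rendered per image.
#' @param seed master seed (drives the split and every scene).
#' @return a list of class `mlyolo_manifest`.
#' @export
dataset_manifest <- function(counts = c(shanwei = 600L, jiaodong = 700L,
                                        zhendong = 500L, chsihi = 700L,
                                        jindong = 250L, chudong = 250L),
                             split = 0.8, img_size = 160L,
                             objects_per_image = 1L, seed = 0L) {
  if (is.null(names(counts))) names(counts) <- BEHAVIOR_LABELS[seq_along(counts)]
  structure(list(counts = counts, split = split, img_size = as.integer(img_size),
                 objects_per_image = as.integer(objects_per_image),
                 seed = as.integer(seed)),
            class = "mlyolo_manifest")
}

#' Generate a synthetic dataset tree in YOLO layout
#'
#' Writes `images/{train,test}/*.png`, `labels/{train,test}/*.txt` and a
#' `data.yaml` manifest. The split is stratified per class: each class
#' contributes `floor(split * n)` training images, remainder to test;
#' which images land where is a seeded random permutation. Regenerating
#' with the same manifest is byte-identical.
#'
#' @param manifest a [dataset_manifest()].
#' @param out_dir destination directory (created if needed).
#' @return invisibly, a data.frame listing file, split and class.
#' @export
generate_dataset <- function(manifest, out_dir) {
  for (d in c("images/train", "images/test", "labels/train", "labels/test"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  files <- NULL
  labels_all <- names(manifest$counts)
  for (ci in seq_along(manifest$counts)) {
    lab <- labels_all[ci]
    ncls <- manifest$counts[[ci]]
    ntr <- floor(manifest$split * ncls)
    perm <- with_seed(manifest$seed * 1000L + ci, sample.int(ncls))
    split_of <- ifelse(seq_len(ncls) %in% perm[seq_len(ntr)], "train", "test")
    for (i in seq_len(ncls)) {
      sc <- render_scene(ci - 1L, img_size = manifest$img_size,
                         n_objects = manifest$objects_per_image,
                         seed = manifest$seed * 1000000L + ci * 10000L + i)
      base <- sprintf("%s_%04d", lab, i)
      png::writePNG(sc$image,
                    file.path(out_dir, "images", split_of[i], paste0(base, ".png")))
      write_yolo_labels(sc$labels,
                        file.path(out_dir, "labels", split_of[i], paste0(base, ".txt")))
      files <- rbind(files, data.frame(file = base, split = split_of[i],
                                       class_id = ci - 1L))
    }
  }
  yaml::write_yaml(list(
    path = normalizePath(out_dir),
    train = "images/train", val = "images/test",
    nc = length(manifest$counts), names = as.list(labels_all),
    img_size = manifest$img_size, seed = manifest$seed),
    file.path(out_dir, "data.yaml"))
  invisible(files)
}

#' Load a YOLO-layout dataset split into memory
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @param split "train" or "test".
#' @param max_images optional cap (first `max_images` files, sorted).
#' @return list with `images` (list of H x W x 3 arrays), `labels`
#'   (list of label data.frames) and `names` (class labels).
#' @export
load_yolo_dataset <- function(dir, split = "train", max_images = Inf) {
  man <- yaml::read_yaml(file.path(dir, "data.yaml"))
  imgs <- sort(list.files(file.path(dir, "images", split), pattern = "\\.png$"))
  if (is.finite(max_images)) imgs <- utils::head(imgs, max_images)
  images <- lapply(imgs, function(f) png::readPNG(file.path(dir, "images", split, f)))
  labels <- lapply(imgs, function(f)
    read_yolo_labels(file.path(dir, "labels", split,
                               sub("\\.png$", ".txt", f))))
  list(images = images, labels = labels, names = unlist(man$names), files = imgs)
}
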