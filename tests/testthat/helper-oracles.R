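# Shared fixtures and independent oracles used across the suite.

rand_tensor <- function(h, w, c, n = 1L) array(rnorm(h * w * c * n), c(h, w, c, n))

# plain-R depthwise 2-D convolution, "same" zero padding, dilation dil.
# kernel: kh x kw matrix applied to every channel. Independent of the
# Rcpp path (nested loops, no im2col).
dw_conv2d_ref <- function(x, kernel, dil = c(1L, 1L)) {
  d <- dim(x)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- dil[1] * (kh - 1) / 2; pw <- dil[2] * (kw - 1) / 2
  y <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- 0
      for (a in seq_len(kh)) for (b in seq_len(kw)) {
        ii <- i + dil[1] * (a - 1) - ph
        jj <- j + dil[2] * (b - 1) - pw
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          acc <- acc + kernel[a, b] * x[ii, jj, c, n]
      }
      y[i, j, c, n] <- acc
    }
  y
}

# brute-force greedy NMS oracle, O(n^2), per class
nms_ref <- function(det, iou_thr) {
  keep <- logical(nrow(det))
  for (cl in unique(det$class_id)) {
    idx <- which(det$class_id == cl)
    ord <- idx[order(-det$conf[idx], idx)]
    for (i in seq_along(ord)) {
      ok <- TRUE
      for (k in ord[seq_len(i - 1)][keep[ord[seq_len(i - 1)]]]) {
        if (box_iou(as.numeric(det[ord[i], 1:4]), as.numeric(det[k, 1:4])) > iou_thr)
          ok <- FALSE
      }
      keep[ord[i]] <- ok
    }
  }
  det[keep, , drop = FALSE]
}

# independent AP: explicit threshold sweep over every distinct confidence,
# computing (recall, precision) points and integrating the right-monotone
# envelope by rectangle sum. Matching itself follows the same greedy rule
# but is re-implemented here from scratch.
ap_ref <- function(dets, truths, cl, iou_thr) {
  n_tr <- sum(truths$class_id == cl)
  if (n_tr == 0) return(NA_real_)
  td <- dets[dets$class_id == cl, , drop = FALSE]
  if (!nrow(td)) return(0)
  td <- td[order(-td$conf, as.integer(rownames(td))), , drop = FALSE]
  flags <- logical(nrow(td))
  used <- character(0)
  for (i in seq_len(nrow(td))) {
    best <- 0; bj <- NA
    for (j in which(truths$class_id == cl & truths$image == td$image[i])) {
      key <- paste(td$image[i], j)
      if (key %in% used) next
      v <- box_iou(as.numeric(td[i, c("x1", "y1", "x2", "y2")]),
                   as.numeric(truths[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (!is.na(bj) && best >= iou_thr) {
      flags[i] <- TRUE
      used <- c(used, paste(td$image[i], bj))
    }
  }
  # threshold sweep: PR point at each rank prefix
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_tr; prec <- tp / (tp + fp)
  ap <- 0; last_r <- 0
  for (i in seq_along(rec)) {
    penv <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - last_r) * penv
    last_r <- rec[i]
  }
  ap
}

# random toy detection scene: ground truths plus jittered/false detections
random_scene <- function(n_images = 3, n_classes = 3, img = 100) {
  truths <- NULL; dets <- NULL
  for (im in seq_len(n_images)) {
    for (g in seq_len(sample(1:3, 1))) {
      cl <- sample(0:(n_classes - 1), 1)
      x1 <- runif(1, 0, img - 30); y1 <- runif(1, 0, img - 30)
      w <- runif(1, 10, 25); h <- runif(1, 10, 25)
      truths <- rbind(truths, data.frame(image = im, class_id = cl,
                                         x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h))
      if (runif(1) < 0.8) {  # a detection near this truth
        j <- runif(4, -4, 4)
        dets <- rbind(dets, data.frame(image = im, class_id = cl,
                                       x1 = x1 + j[1], y1 = y1 + j[2],
                                       x2 = x1 + w + j[3], y2 = y1 + h + j[4],
                                       conf = runif(1, 0.3, 1)))
      }
    }
    for (f in seq_len(sample(0:2, 1))) {  # false positives
      x1 <- runif(1, 0, img - 20); y1 <- runif(1, 0, img - 20)
      dets <- rbind(dets, data.frame(image = im,
                                     class_id = sample(0:(n_classes - 1), 1),
                                     x1 = x1, y1 = y1, x2 = x1 + 15, y2 = y1 + 15,
                                     conf = runif(1, 0.05, 0.6)))
    }
  }
  dets <- dets[, c("image", "x1", "y1", "x2", "y2", "conf", "class_id")]
  list(dets = dets, truths = truths)
}

# set every bare convolution inside a module tree to the identity impulse
set_all_convs_identity <- function(m) {
  walk_modules(m, function(mm, p) {
    if (mm$kind == "conv2d") conv_set_identity(mm)
  })
  invisible(m)
}

# numeric gradient of sum(module_forward(m, x, train) * proj) w.r.t.
# selected input entries, by central differences. train = TRUE so that
# normalisation layers use batch statistics, matching the analytic path.
numgrad_input_train <- function(m, x, proj, entries, eps = 1e-5) {
  vapply(entries, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (sum(module_forward(m, xp, train = TRUE) * proj) -
       sum(module_forward(m, xm, train = TRUE) * proj)) / (2 * eps)
  }, numeric(1))
}

# tiny in-memory synthetic dataset (n_per images per class)
make_tiny_dataset <- function(n_per, seed0, img_size = 96) {
  imgs <- list(); labs <- list(); k <- 0
  for (cl in 0:5) for (i in seq_len(n_per)) {
    sc <- render_scene(cl, img_size = img_size, seed = seed0 + cl * 1000 + i)
    k <- k + 1; imgs[[k]] <- sc$image; labs[[k]] <- sc$labels
  }
  list(images = imgs, labels = labs)
}

smoke_model <- function(seed = 7, input_size = 96) {
  set.seed(seed)
  build_model(variant_config("full", num_classes = 6, input_size = input_size,
                             width_multiple = 0.125))
}
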