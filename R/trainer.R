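# Desk-scale training loop: anchor-free center-prior target assignment,
# composite loss (box regression CIoU/WIoU + binary cross-entropy
# classification + distribution-focal box bins), analytic gradients into
# the raw head outputs, and plain SGD with momentum.

#' Training configuration
#'
#' Defaults follow the published training protocol (640 input, batch 16,
#' 300 epochs, SGD lr 0.01 momentum 0.937, weight decay 0.0005); smoke
#' profiles override them with tiny values.
#'
#' @param input_size square training resolution, divisible by 32.
#' @param batch_size images per step.
#' @param epochs training epochs.
#' @param lr learning rate; @param momentum SGD momentum;
#' @param weight_decay L2 penalty on convolution weights.
#' @param box_weight,cls_weight,dfl_weight loss-term weights.
#' @param seed RNG seed for shuffling (and any augmentation).
#' @param mosaic enable the simple 4-image mosaic augmentation.
#' @param close_mosaic disable mosaic for the final `close_mosaic` epochs.
#' @param eval_every evaluate held-out mAP every this many epochs (0 = only
#'   at the end).
#' @return a list of class `mlyolo_train_config`.
#' @export
train_config <- function(input_size = 640L, batch_size = 16L, epochs = 300L,
                         lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
                         box_weight = 7.5, cls_weight = 0.5, dfl_weight = 1.5,
                         seed = 0L, mosaic = FALSE, close_mosaic = 10L,
                         eval_every = 0L) {
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0, epochs >= 1, batch_size >= 1)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 box_weight = box_weight, cls_weight = cls_weight,
                 dfl_weight = dfl_weight, seed = as.integer(seed),
                 mosaic = isTRUE(mosaic), close_mosaic = as.integer(close_mosaic),
                 eval_every = as.integer(eval_every)),
            class = "mlyolo_train_config")
}

#' Assign ground-truth boxes to grid cells (center prior)
#'
#' A grid point is a positive for a box when its centre lies inside the
#' box's central region (the inner half of the box, centre +- w/4, h/4),
#' at every scale. Cells claimed by several boxes go to the smallest-area
#' box (deterministic tie-break). A box that captures no cell at any
#' scale falls back to the single nearest cell at the scale whose stride
#' best matches the box size, so every truth trains something.
#'
#' @param truths data.frame per image: class_id, x1, y1, x2, y2 (pixels).
#' @param input_hw c(H, W) of the network input.
#' @param strides the three detection strides.
#' @return list over scales of data.frames: n (image), i, j (cell), gt
#'   geometry and class.
#' @export
assign_targets <- function(truths, input_hw, strides = c(8L, 16L, 32L)) {
  if (!is.list(truths) || is.data.frame(truths)) truths <- list(truths)
  out <- lapply(strides, function(s) NULL)
  for (n in seq_along(truths)) {
    tt <- truths[[n]]
    if (is.null(tt) || nrow(tt) == 0L) next
    got <- rep(FALSE, nrow(tt))
    for (si in seq_along(strides)) {
      s <- strides[si]
      gh <- input_hw[1] %/% s; gw <- input_hw[2] %/% s
      claim <- list()  # key "i,j" -> row with area
      for (g in seq_len(nrow(tt))) {
        cx <- (tt$x1[g] + tt$x2[g]) / 2; cy <- (tt$y1[g] + tt$y2[g]) / 2
        w <- tt$x2[g] - tt$x1[g]; h <- tt$y2[g] - tt$y1[g]
        area <- w * h
        jr <- seq(max(1, ceiling((cx - w / 4) / s + 0.5)),
                  min(gw, floor((cx + w / 4) / s + 0.5)))
        ir <- seq(max(1, ceiling((cy - h / 4) / s + 0.5)),
                  min(gh, floor((cy + h / 4) / s + 0.5)))
        if (!length(jr) || !length(ir) || jr[1] > jr[length(jr)] ||
            ir[1] > ir[length(ir)]) next
        for (i in ir) for (j in jr) {
          key <- paste(i, j)
          if (is.null(claim[[key]]) || claim[[key]]$area > area) {
            claim[[key]] <- list(i = i, j = j, g = g, area = area)
            got[g] <- TRUE
          }
        }
      }
      if (length(claim)) {
        rows <- do.call(rbind, lapply(claim, function(cl)
          data.frame(n = n, i = cl$i, j = cl$j,
                     class_id = tt$class_id[cl$g],
                     x1 = tt$x1[cl$g], y1 = tt$y1[cl$g],
                     x2 = tt$x2[cl$g], y2 = tt$y2[cl$g])))
        out[[si]] <- rbind(out[[si]], rows)
      }
    }
    # fallback for truths that captured no cell anywhere
    for (g in which(!got)) {
      w <- tt$x2[g] - tt$x1[g]; h <- tt$y2[g] - tt$y1[g]
      si <- which.min(abs(log2(pmax(w, h) / (4 * strides))))
      s <- strides[si]
      gh <- input_hw[1] %/% s; gw <- input_hw[2] %/% s
      cx <- (tt$x1[g] + tt$x2[g]) / 2; cy <- (tt$y1[g] + tt$y2[g]) / 2
      j <- min(gw, max(1, round(cx / s + 0.5)))
      i <- min(gh, max(1, round(cy / s + 0.5)))
      out[[si]] <- rbind(out[[si]], data.frame(
        n = n, i = i, j = j, class_id = tt$class_id[g],
        x1 = tt$x1[g], y1 = tt$y1[g], x2 = tt$x2[g], y2 = tt$y2[g]))
    }
  }
  out
}

bce_with_logits <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))

#' One training step: composite loss and gradients
#'
#' Runs the forward pass in training mode, computes the weighted loss
#' `box_weight * L_box + cls_weight * L_cls + dfl_weight * L_dfl`
#' (box term CIoU or WIoU per the model config), backpropagates analytic
#' gradients through the whole graph, and leaves parameter gradients
#' accumulated in the modules.
#'
#' @param model an `mlyolo_model`.
#' @param x input batch, array c(H, W, 3, N), values in `[0, 1]`.
#' @param truths list (length N) of data.frames class_id, x1..y2 (pixels).
#' @param cfg a [train_config()].
#' @return loss breakdown: list(box, cls, dfl, total, n_pos).
#' @export
training_step <- function(model, x, truths, cfg = train_config()) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  raw <- model_forward(model, x, train = TRUE)
  reg_max <- model$cfg$reg_max
  nb <- 4L * reg_max
  nc <- model$cfg$num_classes
  asn <- assign_targets(truths, d[1:2], model$strides)
  npos <- sum(vapply(asn, function(a) if (is.null(a)) 0L else nrow(a), integer(1)))
  norm <- max(1L, npos)
  bins <- 0:(reg_max - 1)
  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0
  dys <- vector("list", 3L)

  for (si in 1:3) {
    r <- raw[[si]]
    rd <- dim(r)
    s <- model$strides[si]
    # classification BCE over every cell
    z <- r[, , nb + seq_len(nc), , drop = FALSE]
    y <- array(0, dim(z))
    a <- asn[[si]]
    if (!is.null(a))
      y[cbind(a$i, a$j, a$class_id + 1L, a$n)] <- 1
    loss_cls <- loss_cls + sum(bce_with_logits(z, y)) / norm
    dy <- array(0, rd)
    dy[, , nb + seq_len(nc), ] <- (sigmoid(z) - y) * (cfg$cls_weight / norm)

    if (!is.null(a)) {
      np <- nrow(a)
      logits <- matrix(0, np, nb)
      for (ch in seq_len(nb))
        logits[, ch] <- r[cbind(a$i, a$j, rep(ch, np), a$n)]
      dd <- dfl_expect(logits, reg_max)
      ax <- (a$j - 0.5) * s; ay <- (a$i - 0.5) * s
      pred <- cbind(ax - dd$dist[, 1] * s, ay - dd$dist[, 2] * s,
                    ax + dd$dist[, 3] * s, ay + dd$dist[, 4] * s)
      # degenerate (not yet separated) predictions: nudge to a tiny box
      bad <- pred[, 3] <= pred[, 1] | pred[, 4] <= pred[, 2]
      if (any(bad)) {
        pred[bad, 3] <- pmax(pred[bad, 3], pred[bad, 1] + 1e-3)
        pred[bad, 4] <- pmax(pred[bad, 4], pred[bad, 2] + 1e-3)
      }
      gt <- cbind(a$x1, a$y1, a$x2, a$y2)
      if (model$cfg$loss_box == "wiou") {
        lb <- wiou_loss(pred, gt)
        gb <- wiou_grad(pred, gt)
      } else {
        lb <- ciou_loss(pred, gt)
        gb <- ciou_grad(pred, gt)
      }
      loss_box <- loss_box + sum(lb) / norm
      gb <- gb * (cfg$box_weight / norm)
      ddist <- cbind(-s * gb[, 1], -s * gb[, 2], s * gb[, 3], s * gb[, 4])
      # distribution-focal targets: distances from the cell centre, grid units
      tdist <- cbind((ax - gt[, 1]) / s, (ay - gt[, 2]) / s,
                     (gt[, 3] - ax) / s, (gt[, 4] - ay) / s)
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-2)
      dlogits <- matrix(0, np, nb)
      for (k in 1:4) {
        cols <- (k - 1) * reg_max + seq_len(reg_max)
        p <- matrix(dd$prob[, , k], nrow = np)
        # box-loss chain through the softmax expectation
        dlogits[, cols] <- dlogits[, cols] +
          ddist[, k] * p * (matrix(bins, np, reg_max, byrow = TRUE) - dd$dist[, k])
        # distribution-focal cross-entropy to the two neighbouring bins
        tl <- floor(tdist[, k]); wr <- tdist[, k] - tl; wl <- 1 - wr
        ce <- -(wl * log(p[cbind(seq_len(np), tl + 1)] + 1e-12) +
                wr * log(p[cbind(seq_len(np), pmin(tl + 2, reg_max))] + 1e-12))
        loss_dfl <- loss_dfl + sum(ce) / (norm * 4)
        tgt <- matrix(0, np, reg_max)
        tgt[cbind(seq_len(np), tl + 1)] <- wl
        tgt[cbind(seq_len(np), pmin(tl + 2, reg_max))] <-
          tgt[cbind(seq_len(np), pmin(tl + 2, reg_max))] + wr
        dlogits[, cols] <- dlogits[, cols] +
          (p - tgt) * (cfg$dfl_weight / (norm * 4))
      }
      for (ch in seq_len(nb))
        dy[cbind(a$i, a$j, rep(ch, np), a$n)] <-
          dy[cbind(a$i, a$j, rep(ch, np), a$n)] + dlogits[, ch]
    }
    dys[[si]] <- dy
  }
  model$graph$bwd(dys)
  total <- cfg$box_weight * loss_box + cfg$cls_weight * loss_cls +
    cfg$dfl_weight * loss_dfl
  if (!is.finite(total))
    stop("non-finite loss (box=", loss_box, ", cls=", loss_cls,
         ", dfl=", loss_dfl, ")")
  out <- list(box = loss_box, cls = loss_cls, dfl = loss_dfl,
              total = total, n_pos = npos)
  attr(out, "raw_grads") <- dys
  out
}

# ---- SGD ----------------------------------------------------------------

sgd_new <- function() new.env(parent = emptyenv())

sgd_step <- function(opt, model, lr, momentum, weight_decay) {
  mods <- module_collect(model$graph)
  for (p in names(mods)) {
    mm <- mods[[p]]
    for (nm in names(mm$par)) {
      g <- mm$gr[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0 && length(dim(mm$par[[nm]])) == 4L)
        g <- g + weight_decay * mm$par[[nm]]
      key <- paste0(p, ".", nm)
      v <- opt[[key]]
      v <- if (is.null(v)) g else momentum * v + g
      opt[[key]] <- v
      mm$par[[nm]] <- mm$par[[nm]] - lr * v
    }
  }
  invisible(NULL)
}

# simple 4-image mosaic: 2x2 grid of half-resolution images
mosaic_batch <- function(images, labels) {
  stopifnot(length(images) == 4L)
  half <- function(img) {
    d <- dim(img)
    (img[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     img[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     img[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     img[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
  }
  d <- dim(images[[1]])
  out <- array(0, d)
  offs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  lab <- NULL
  for (q in 1:4) {
    h <- half(images[[q]])
    oi <- offs[[q]][1] * d[1] / 2; oj <- offs[[q]][2] * d[2] / 2
    out[oi + seq_len(d[1] / 2), oj + seq_len(d[2] / 2), ] <- h
    lq <- labels[[q]]
    if (!is.null(lq) && nrow(lq)) {
      lq$cx <- lq$cx / 2 + offs[[q]][2] / 2
      lq$cy <- lq$cy / 2 + offs[[q]][1] / 2
      lq$w <- lq$w / 2; lq$h <- lq$h / 2
      lab <- rbind(lab, lq)
    }
  }
  list(image = out, labels = lab)
}

labels_to_pixels <- function(lab, hw) {
  if (is.null(lab) || nrow(lab) == 0L)
    return(data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  xy <- cxcywh_to_xyxy(as.matrix(lab[, c("cx", "cy", "w", "h")]), hw[2], hw[1])
  data.frame(class_id = lab$class_id, x1 = xy[, 1], y1 = xy[, 2],
             x2 = xy[, 3], y2 = xy[, 4])
}

#' Evaluate a model on an in-memory dataset split
#'
#' @param model an `mlyolo_model`.
#' @param data list with `images` and `labels` (normalized YOLO format),
#'   as returned by [load_yolo_dataset()].
#' @param conf_threshold low detection cut used for PR-curve construction.
#' @param iou_nms NMS threshold.
#' @return an `mlyolo_eval` (see [evaluate_detections()]).
#' @export
evaluate_model <- function(model, data, conf_threshold = 0.01, iou_nms = 0.45) {
  dets <- NULL; tr <- NULL
  for (k in seq_along(data$images)) {
    img <- data$images[[k]]
    hw <- dim(img)[1:2]
    dd <- predict(model, img, conf_threshold = conf_threshold,
                  iou_threshold = iou_nms)
    if (nrow(dd)) dets <- rbind(dets, cbind(image = k, dd[, 1:6]))
    tt <- labels_to_pixels(data$labels[[k]], hw)
    if (nrow(tt)) tr <- rbind(tr, cbind(image = k, tt))
  }
  if (is.null(tr)) stop("evaluate_model: dataset has no ground-truth boxes")
  if (is.null(dets))
    dets <- data.frame(image = integer(0), x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0), conf = numeric(0),
                       class_id = integer(0))
  evaluate_detections(dets, tr)
}

#' Train a detector
#'
#' Plain SGD-with-momentum training of an `mlyolo_model` on an in-memory
#' dataset (see [load_yolo_dataset()]); per-epoch loss terms are logged
#' and held-out metrics computed per `cfg$eval_every`. Deterministic for
#' fixed seeds: identical seeds give identical metric history.
#'
#' @param model an `mlyolo_model` (modified in place and returned).
#' @param data list with `train` and optional `val` splits.
#' @param cfg a [train_config()].
#' @return list of class `mlyolo_fit`: model, history (data.frame), and
#'   final `eval` when a validation split was given.
#' @export
fit <- function(model, data, cfg = train_config()) {
  tr <- data$train
  if (is.null(tr$images) || !length(tr$images))
    stop("fit: empty training split")
  hw <- dim(tr$images[[1]])[1:2]
  if (any(hw %% 32L != 0L))
    stop("fit: image size ", paste(hw, collapse = "x"), " not divisible by 32")
  if (any(hw != cfg$input_size))
    stop("fit: dataset images are ", paste(hw, collapse = "x"),
         " but cfg$input_size is ", cfg$input_size)
  set.seed(cfg$seed)
  opt <- sgd_new()
  nimg <- length(tr$images)
  hist <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nimg)
    ep_loss <- c(box = 0, cls = 0, dfl = 0, total = 0)
    nb <- 0L
    use_mosaic <- cfg$mosaic && ep <= cfg$epochs - cfg$close_mosaic
    for (b0 in seq(1, nimg, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, nimg)]
      imgs <- tr$images[idx]
      labs <- tr$labels[idx]
      if (use_mosaic && length(idx) >= 4L) {
        mq <- mosaic_batch(imgs[1:4], labs[1:4])
        imgs[[1]] <- mq$image; labs[[1]] <- mq$labels
      }
      x <- array(0, c(hw[1], hw[2], 3L, length(idx)))
      for (k in seq_along(imgs)) x[, , , k] <- imgs[[k]]
      truths <- lapply(labs, labels_to_pixels, hw = hw)
      module_zero_grad(model$graph)
      lb <- training_step(model, x, truths, cfg)
      sgd_step(opt, model, cfg$lr, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + c(lb$box, lb$cls, lb$dfl, lb$total)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    row <- data.frame(epoch = ep, loss_box = ep_loss[1], loss_cls = ep_loss[2],
                      loss_dfl = ep_loss[3], loss_total = ep_loss[4],
                      map50 = NA_real_)
    if (!is.null(data$val) && cfg$eval_every > 0 && ep %% cfg$eval_every == 0)
      row$map50 <- evaluate_model(model, data$val)$map50
    hist <- rbind(hist, row)
    message(sprintf("epoch %3d  box %.4f  cls %.4f  dfl %.4f  total %.4f%s",
                    ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4],
                    if (!is.na(row$map50)) sprintf("  mAP50 %.3f", row$map50) else ""))
    utils::flush.console()
  }
  ev <- if (!is.null(data$val)) evaluate_model(model, data$val) else NULL
  rownames(hist) <- NULL
  structure(list(model = model, history = hist, eval = ev),
            class = "mlyolo_fit")
}

#' @export
print.mlyolo_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mlyolo_fit> %d epochs, final loss %.4f\n",
              nrow(h), h$loss_total[nrow(h)]))
  if (!is.null(x$eval)) print(x$eval)
  invisible(x)
}
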