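# Assembly of the baseline YOLOv8s detector and the improved ML-YOLOv8
# variant (C2f-MSConv placements, SPPF-LSKA, WIoU loss toggle), plus
# anchor-free decoding and non-maximum suppression.

# C2f sites in the layer graph that may be replaced by C2f-MSConv
# (layer numbering of the standard 22-layer backbone+neck).
C2F_SITES <- c(2L, 4L, 6L, 8L, 12L, 15L, 18L, 21L)

# Placement and LSKA setting reproducing the printed parameter budgets;
# found by calibrate_placements() against the ablation-table counts and
# frozen here (see the methods vignette).
DEFAULT_MSCONV_PLACEMENTS <- c(6L, 8L, 12L, 15L, 18L, 21L)
DEFAULT_LSKA <- c(K = 11L, d = 4L)

BEHAVIOR_LABELS <- c("shanwei", "jiaodong", "zhendong", "chsihi", "jindong", "chudong")
BEHAVIOR_NAMES <- c(shanwei = "tail fanning", jiaodong = "agitating",
                    zhendong = "shaking", chsihi = "egg eating",
                    jindong = "entering caves", chudong = "exiting caves")

make_divisible <- function(x, divisor = 8L) {
  as.integer(max(divisor, round(x / divisor) * divisor))
}

#' Detector variant configuration
#'
#' Describes one model variant: the "s"-scale baseline plus optional
#' modifications. The four ablation rows (baseline; +C2f-MSConv;
#' +SPPF-LSKA; +WIoU) are expressible via [variant_config()].
#'
#' @param num_classes number of object classes (6 behaviors by default).
#' @param input_size nominal square input size in pixels (default 640).
#' @param depth_multiple,width_multiple,max_channels scale factors; the
#'   defaults are the "s" scale (0.33 / 0.50 / 1024).
#' @param use_c2f_msconv replace C2f with C2f-MSConv at `msconv_placements`.
#' @param msconv_placements integer subset of `C2F_SITES` (layer indices).
#' @param use_sppf_lska insert LSKA into the SPPF layer.
#' @param lska_k,lska_d LSKA kernel size and dilation.
#' @param loss_box bounding-box regression loss, "ciou" or "wiou".
#' @param reg_max number of bins of the discretized box-distribution head.
#' @param class_names optional character vector of class labels.
#' @return an object of class `mlyolo_config`.
#' @export
ml_yolo_config <- function(num_classes = 6L, input_size = 640L,
                           depth_multiple = 0.33, width_multiple = 0.50,
                           max_channels = 1024L,
                           use_c2f_msconv = FALSE,
                           msconv_placements = DEFAULT_MSCONV_PLACEMENTS,
                           use_sppf_lska = FALSE,
                           lska_k = DEFAULT_LSKA[["K"]], lska_d = DEFAULT_LSKA[["d"]],
                           loss_box = c("ciou", "wiou"),
                           reg_max = 16L,
                           class_names = NULL) {
  loss_box <- match.arg(loss_box)
  if (!all(msconv_placements %in% C2F_SITES))
    stop("unknown C2f placement index: ",
         paste(setdiff(msconv_placements, C2F_SITES), collapse = ", "))
  if (is.null(class_names))
    class_names <- if (num_classes == 6L) BEHAVIOR_LABELS else
      paste0("class", seq_len(num_classes) - 1L)
  cfg <- list(num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              depth_multiple = depth_multiple, width_multiple = width_multiple,
              max_channels = as.integer(max_channels),
              use_c2f_msconv = isTRUE(use_c2f_msconv),
              msconv_placements = as.integer(sort(msconv_placements)),
              use_sppf_lska = isTRUE(use_sppf_lska),
              lska_k = as.integer(lska_k), lska_d = as.integer(lska_d),
              loss_box = loss_box, reg_max = as.integer(reg_max),
              class_names = class_names)
  class(cfg) <- "mlyolo_config"
  cfg
}

#' Ablation-variant shorthand
#'
#' @param variant one of "baseline", "msconv", "msconv+lska", "full".
#'   "full" is ML-YOLOv8: C2f-MSConv + SPPF-LSKA + WIoU. The WIoU toggle
#'   changes no weights or shapes, so "msconv+lska" and "full" share one
#'   architecture.
#' @param ... overrides passed to [ml_yolo_config()].
#' @return an `mlyolo_config`.
#' @export
variant_config <- function(variant = c("baseline", "msconv", "msconv+lska", "full"),
                           ...) {
  variant <- match.arg(variant)
  args <- switch(variant,
    baseline = list(),
    msconv = list(use_c2f_msconv = TRUE),
    `msconv+lska` = list(use_c2f_msconv = TRUE, use_sppf_lska = TRUE),
    full = list(use_c2f_msconv = TRUE, use_sppf_lska = TRUE, loss_box = "wiou"))
  do.call(ml_yolo_config, utils::modifyList(args, list(...)))
}

#' Build the detector
#'
#' Assembles the 22-layer backbone + FPN-PAN neck and the anchor-free
#' decoupled head (per-scale classification logits and a discretized
#' box-distribution branch with `reg_max` bins per side) at strides
#' 8/16/32. The parameter count is deterministic for a fixed config.
#'
#' @param cfg an [ml_yolo_config()].
#' @param init "random" (Kaiming-normal from the current RNG) or "zeros"
#'   (fast, for architecture accounting only).
#' @return an object of class `mlyolo_model`.
#' @export
build_model <- function(cfg = ml_yolo_config(), init = c("random", "zeros")) {
  init <- match.arg(init)
  old <- getOption("mlyolo.init_zeros")
  options(mlyolo.init_zeros = identical(init, "zeros"))
  on.exit(options(mlyolo.init_zeros = old))

  wch <- function(c) make_divisible(min(c, cfg$max_channels) * cfg$width_multiple)
  dep <- function(n) max(1L, as.integer(round(n * cfg$depth_multiple)))
  ms <- function(site) cfg$use_c2f_msconv && site %in% cfg$msconv_placements
  ch <- vapply(c(64, 128, 256, 512, 1024), wch, integer(1))
  c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]; c5 <- ch[5]

  nodes <- list(
    list(from = 0L,  m = conv_block(3L, c1, 3L, 2L)),                     # 1  L0 P1/2
    list(from = 1L,  m = conv_block(c1, c2, 3L, 2L)),                     # 2  L1 P2/4
    list(from = 2L,  m = c2f_block(c2, c2, dep(3), TRUE, ms(2L))),        # 3  L2
    list(from = 3L,  m = conv_block(c2, c3, 3L, 2L)),                     # 4  L3 P3/8
    list(from = 4L,  m = c2f_block(c3, c3, dep(6), TRUE, ms(4L))),        # 5  L4
    list(from = 5L,  m = conv_block(c3, c4, 3L, 2L)),                     # 6  L5 P4/16
    list(from = 6L,  m = c2f_block(c4, c4, dep(6), TRUE, ms(6L))),        # 7  L6
    list(from = 7L,  m = conv_block(c4, c5, 3L, 2L)),                     # 8  L7 P5/32
    list(from = 8L,  m = c2f_block(c5, c5, dep(3), TRUE, ms(8L))),        # 9  L8
    list(from = 9L,  m = sppf_block(c5, c5, 5L, lska = cfg$use_sppf_lska,
                                    lska_k = cfg$lska_k, lska_d = cfg$lska_d)), # 10 L9
    list(from = 10L, m = nn_upsample2()),                                 # 11 L10
    list(from = c(11L, 7L), m = nn_concat()),                             # 12 L11
    list(from = 12L, m = c2f_block(c5 + c4, c4, dep(3), FALSE, ms(12L))), # 13 L12
    list(from = 13L, m = nn_upsample2()),                                 # 14 L13
    list(from = c(14L, 5L), m = nn_concat()),                             # 15 L14
    list(from = 15L, m = c2f_block(c4 + c3, c3, dep(3), FALSE, ms(15L))), # 16 L15 P3 out
    list(from = 16L, m = conv_block(c3, c3, 3L, 2L)),                     # 17 L16
    list(from = c(17L, 13L), m = nn_concat()),                            # 18 L17
    list(from = 18L, m = c2f_block(c4 + c3, c4, dep(3), FALSE, ms(18L))), # 19 L18 P4 out
    list(from = 19L, m = conv_block(c4, c4, 3L, 2L)),                     # 20 L19
    list(from = c(20L, 10L), m = nn_concat()),                            # 21 L20
    list(from = 21L, m = c2f_block(c5 + c4, c5, dep(3), FALSE, ms(21L)))  # 22 L21 P5 out
  )

  scale_nodes <- c(16L, 19L, 22L)
  head_ch <- c(c3, c4, c5)
  nc <- cfg$num_classes
  hc2 <- max(16L, head_ch[1] %/% 4L, cfg$reg_max * 4L)
  hc3 <- max(head_ch[1], min(nc, 100L))
  out_ids <- integer(3)
  for (i in 1:3) {
    box <- nn_graph(list(
      list(from = 0L, m = conv_block(head_ch[i], hc2, 3L)),
      list(from = 1L, m = conv_block(hc2, hc2, 3L)),
      list(from = 2L, m = nn_conv2d(hc2, 4L * cfg$reg_max, 1L, bias = TRUE))
    ), label = "Head-box")
    cls <- nn_graph(list(
      list(from = 0L, m = conv_block(head_ch[i], hc3, 3L)),
      list(from = 1L, m = conv_block(hc3, hc3, 3L)),
      list(from = 2L, m = nn_conv2d(hc3, nc, 1L, bias = TRUE))
    ), label = "Head-cls")
    if (init == "random") {
      # stabilising output-layer bias init: boxes start near 1-cell
      # distances, class probabilities near 1%
      box$nodes[[3]]$m$par$b <- rep(1, 4L * cfg$reg_max)
      cls$nodes[[3]]$m$par$b <- rep(-log(99), nc)
    }
    nodes <- c(nodes, list(list(from = scale_nodes[i], m = box)))
    bid <- length(nodes)
    nodes <- c(nodes, list(list(from = scale_nodes[i], m = cls)))
    nodes <- c(nodes, list(list(from = c(bid, bid + 1L), m = nn_concat())))
    out_ids[i] <- length(nodes)
  }

  g <- nn_graph(nodes, out_ids = out_ids, label = "ML-YOLOv8")
  model <- list(graph = g, cfg = cfg, strides = c(8L, 16L, 32L),
                head_ch = head_ch, layer_nodes = seq_len(22L))
  class(model) <- "mlyolo_model"
  model
}

#' Forward pass of the detector
#'
#' @param model an `mlyolo_model`.
#' @param x image array c(H, W, 3) or batch c(H, W, 3, N), values in
#'   `[0, 1]`; H and W must be divisible by 32.
#' @param train training mode (batch statistics + caches for backward).
#' @return list of three raw prediction arrays at strides 8/16/32, each of
#'   dim c(H/s, W/s, 4 * reg_max + num_classes, N): the first 4*reg_max
#'   channels are the box-distribution logits (left, top, right, bottom
#'   blocks of reg_max bins), the rest classification logits.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial dims must be divisible by 32, got ", d[1], "x", d[2])
  model$graph$fwd(list(x), train = train)
}

# Distribution-focal decode: expected distance per side, in grid units.
# logits: matrix (cells, 4*reg_max) -> list(dist = (cells, 4), prob = array)
dfl_expect <- function(logits, reg_max) {
  cells <- nrow(logits)
  dist <- matrix(0, cells, 4)
  prob <- array(0, c(cells, reg_max, 4))
  bins <- 0:(reg_max - 1)
  for (s in 1:4) {
    z <- logits[, (s - 1) * reg_max + seq_len(reg_max), drop = FALSE]
    z <- z - apply(z, 1, max)
    p <- exp(z); p <- p / rowSums(p)
    prob[, , s] <- p
    dist[, s] <- as.vector(p %*% bins)
  }
  list(dist = dist, prob = prob)
}

# Decode one scale's raw output (N = 1) into pixel-space candidate boxes.
decode_scale <- function(raw, stride, reg_max, nc) {
  d <- dim(raw)
  h <- d[1]; w <- d[2]
  nb <- 4L * reg_max
  cells <- h * w
  box_logits <- matrix(raw[, , seq_len(nb), 1], nrow = cells)
  cls_logits <- matrix(raw[, , nb + seq_len(nc), 1], nrow = cells)
  dd <- dfl_expect(box_logits, reg_max)
  # cell (i, j) has centre ((j - 0.5) * stride, (i - 0.5) * stride)
  ii <- rep(seq_len(h), times = w)
  jj <- rep(seq_len(w), each = h)
  ax <- (jj - 0.5) * stride
  ay <- (ii - 0.5) * stride
  data.frame(
    x1 = ax - dd$dist[, 1] * stride, y1 = ay - dd$dist[, 2] * stride,
    x2 = ax + dd$dist[, 3] * stride, y2 = ay + dd$dist[, 4] * stride,
    conf = apply(sigmoid(cls_logits), 1, max),
    class_id = max.col(cls_logits, ties.method = "first") - 1L)
}

#' Greedy per-class non-maximum suppression
#'
#' @param det data.frame with columns x1, y1, x2, y2, conf, class_id.
#' @param iou_threshold suppress boxes with IoU above this versus an
#'   already-kept higher-confidence box of the same class.
#' @return the surviving rows, sorted by descending confidence; equal
#'   confidences tie-break on the lower original row index.
#' @export
nms_detections <- function(det, iou_threshold = 0.45) {
  if (nrow(det) == 0L) return(det)
  keep_all <- integer(0)
  for (cl in unique(det$class_id)) {
    idx <- which(det$class_id == cl)
    ord <- idx[order(-det$conf[idx], idx)]
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (k in kept) {
        if (box_iou(as.numeric(det[i, 1:4]), as.numeric(det[k, 1:4])) > iou_threshold) {
          ok <- FALSE; break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    keep_all <- c(keep_all, kept)
  }
  out <- det[keep_all, , drop = FALSE]
  out <- out[order(-out$conf, keep_all), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decode raw predictions and apply NMS
#'
#' @param model the `mlyolo_model` that produced the predictions.
#' @param raw list of three per-scale raw outputs from [model_forward()]
#'   (batch size 1).
#' @param conf_threshold minimum class confidence in (0, 1).
#' @param iou_threshold NMS IoU threshold in (0, 1).
#' @param image_hw c(H, W) of the input, used to clip boxes.
#' @return data.frame of detections: x1, y1, x2, y2, conf, class_id, label.
#' @export
decode_and_nms <- function(model, raw, conf_threshold = 0.25,
                           iou_threshold = 0.45, image_hw = NULL) {
  stopifnot(conf_threshold > 0, conf_threshold < 1,
            iou_threshold > 0, iou_threshold < 1)
  cfg <- model$cfg
  dets <- do.call(rbind, lapply(1:3, function(i)
    decode_scale(raw[[i]], model$strides[i], cfg$reg_max, cfg$num_classes)))
  dets <- dets[dets$conf >= conf_threshold, , drop = FALSE]
  if (is.null(image_hw))
    image_hw <- dim(raw[[1]])[1:2] * model$strides[1]
  dets$x1 <- pmin(pmax(dets$x1, 0), image_hw[2])
  dets$x2 <- pmin(pmax(dets$x2, 0), image_hw[2])
  dets$y1 <- pmin(pmax(dets$y1, 0), image_hw[1])
  dets$y2 <- pmin(pmax(dets$y2, 0), image_hw[1])
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  dets <- nms_detections(dets, iou_threshold)
  dets$label <- cfg$class_names[dets$class_id + 1L]
  dets
}

#' Detect objects in an image
#'
#' @param object an `mlyolo_model`.
#' @param image array c(H, W, 3) with values in `[0, 1]` (H, W divisible
#'   by 32), or a path to a PNG file.
#' @param conf_threshold,iou_threshold post-processing thresholds.
#' @param ... unused.
#' @return data.frame of detections (see [decode_and_nms()]).
#' @export
predict.mlyolo_model <- function(object, image, conf_threshold = 0.25,
                                 iou_threshold = 0.45, ...) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2L) image <- array(rep(image, 3), c(dim(image), 3L))
  raw <- model_forward(object, image, train = FALSE)
  decode_and_nms(object, raw, conf_threshold, iou_threshold,
                 image_hw = dim(image)[1:2])
}

#' @export
print.mlyolo_model <- function(x, ...) {
  cfg <- x$cfg
  mods <- c(if (cfg$use_c2f_msconv)
              sprintf("C2f-MSConv@{%s}", paste(cfg$msconv_placements, collapse = ",")),
            if (cfg$use_sppf_lska)
              sprintf("SPPF-LSKA(K=%d,d=%d)", cfg$lska_k, cfg$lska_d),
            if (cfg$loss_box == "wiou") "WIoU")
  cat(sprintf("<mlyolo_model> %s, %d classes\n",
              if (length(mods)) paste("ML-YOLOv8:", paste(mods, collapse = " + "))
              else "YOLOv8s baseline", cfg$num_classes))
  np <- count_parameters(x)
  cat(sprintf("  parameters: %s (%.2fM)  GFLOPs@%d: %.1f\n",
              format(np, big.mark = ","), params_millions(np),
              cfg$input_size, estimate_gflops(x, cfg$input_size)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the config and all parameter and normalisation
#' buffers; reloading reproduces the model bit-exactly.
#'
#' @param model an `mlyolo_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  state <- list()
  walk_modules(model$graph, function(mm, p) {
    entry <- list(par = mm$par)
    if (mm$kind == "batchnorm")
      entry$buffers <- list(running_mean = mm$running_mean,
                            running_var = mm$running_var)
    if (length(entry$par) || !is.null(entry$buffers)) state[[p]] <<- entry
  })
  saveRDS(list(cfg = model$cfg, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, init = "zeros")
  walk_modules(model$graph, function(mm, p) {
    entry <- ck$state[[p]]
    if (is.null(entry)) return(invisible(NULL))
    mm$par <- entry$par
    if (!is.null(entry$buffers)) {
      mm$running_mean <- entry$buffers$running_mean
      mm$running_var <- entry$buffers$running_var
    }
  })
  model
}
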