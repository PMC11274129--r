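# Bounding-box regression losses: IoU, CIoU (baseline) and Wise-IoU
# (WIoU v1), with analytic gradients. Boxes are continuous pixel-space
# rectangles in corner form c(x1, y1, x2, y2) (or n x 4 matrices); the
# corner <-> centre conversion is exact.
#
# WIoU: L = R * (1 - IoU), R = exp(rho^2 / (W^2 + H^2)) where rho is the
# distance between the two box centres and (W, H) is the size of the
# smallest box enclosing both. The enclosing size is treated as a constant
# in differentiation (gradient detachment), so the R factor pulls centres
# together without the enclosure geometry feeding back into the gradient.

BOX_EPS <- 1e-7

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop("boxes must have 4 columns (x1, y1, x2, y2)")
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop("degenerate box: require x1 < x2 and y1 < y2")
  b
}

box_geom <- function(a, b) {
  xi1 <- pmax(a[, 1], b[, 1]); yi1 <- pmax(a[, 2], b[, 2])
  xi2 <- pmin(a[, 3], b[, 3]); yi2 <- pmin(a[, 4], b[, 4])
  iw <- pmax(0, xi2 - xi1); ih <- pmax(0, yi2 - yi1)
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  union <- area_a + area_b - inter
  W <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  H <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  list(iw = iw, ih = ih, inter = inter, area_a = area_a, area_b = area_b,
       union = union, W = W, H = H,
       iou = inter / (union + BOX_EPS))
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes c(x1, y1, x2, y2) or n x 4 matrices (rowwise pairs).
#' @return IoU in `[0, 1]`; 0 for disjoint boxes; symmetric in a, b.
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- box_geom(a, b)
  unname(g$iou)
}

#' IoU loss, `1 - IoU`
#' @inheritParams box_iou
#' @return value in `[0, 1]`: 0 for identical boxes, 1 for disjoint ones.
#' @export
l_iou <- function(a, b) 1 - box_iou(a, b)

#' Wise-IoU distance factor
#'
#' `exp(((xa - xb)^2 + (ya - yb)^2) / (W^2 + H^2))` with centres
#' (xa, ya), (xb, yb) and enclosing-box size (W, H) excluded from the
#' gradient. Equals 1 exactly when the centres coincide.
#'
#' @inheritParams box_iou
#' @return factor >= 1.
#' @export
r_wiou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- box_geom(a, b)
  dcx <- (a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2
  dcy <- (a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2
  unname(exp((dcx^2 + dcy^2) / (g$W^2 + g$H^2 + BOX_EPS)))
}

#' Wise-IoU loss (v1)
#'
#' `r_wiou(a, b) * l_iou(a, b)`; zero iff the boxes coincide, and always
#' at least `l_iou` since the distance factor is >= 1. An opt-in focusing
#' variant (v3) that reweights by a detached outlier degree is available
#' via `focusing`; it is not the default.
#'
#' @inheritParams box_iou
#' @param focusing apply the v3 non-monotonic focusing factor
#'   `beta / (delta * alpha^(beta - delta))` with outlier degree
#'   `beta = l_iou / mean(l_iou)` (mean detached).
#' @param alpha,delta focusing hyper-parameters (v3 defaults 1.9, 3).
#' @return nonnegative loss value(s).
#' @export
wiou_loss <- function(a, b, focusing = FALSE, alpha = 1.9, delta = 3) {
  base <- r_wiou(a, b) * l_iou(a, b)
  if (!focusing) return(base)
  li <- l_iou(a, b)
  beta <- li / (mean(li) + BOX_EPS)
  gain <- beta / (delta * alpha^(beta - delta))
  base * gain
}

#' Complete-IoU (CIoU) loss
#'
#' The baseline regression loss: `1 - IoU + rho^2 / c^2 + alpha * v`,
#' where rho is the centre distance, c the enclosing-box diagonal, v the
#' aspect-ratio term `(4 / pi^2) * (atan(wb/hb) - atan(wa/ha))^2` and
#' `alpha = v / (1 - IoU + v)` (treated as a constant in the gradient, as
#' is standard). Zero on identical boxes; for concentric boxes of equal
#' aspect ratio it reduces to `1 - IoU`.
#'
#' @inheritParams box_iou
#' @return nonnegative loss value(s).
#' @export
ciou_loss <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- box_geom(a, b)
  dcx <- (a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2
  dcy <- (a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2
  rho2 <- dcx^2 + dcy^2
  c2 <- g$W^2 + g$H^2 + BOX_EPS
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- v / (1 - g$iou + v + BOX_EPS)
  unname(1 - g$iou + rho2 / c2 + alpha * v)
}

# ---- analytic gradients (w.r.t. the first box's corners) ----------------

# d(IoU)/d(a corners): n x 4 matrix.
iou_grad <- function(a, b) {
  g <- box_geom(a, b)
  pos <- g$inter > 0
  dI <- matrix(0, nrow(a), 4)
  dI[, 1] <- -g$ih * (a[, 1] > b[, 1]) * pos
  dI[, 3] <-  g$ih * (a[, 3] < b[, 3]) * pos
  dI[, 2] <- -g$iw * (a[, 2] > b[, 2]) * pos
  dI[, 4] <-  g$iw * (a[, 4] < b[, 4]) * pos
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  dA <- cbind(-ha, -wa, ha, wa)
  dU <- dA - dI
  u <- g$union + BOX_EPS
  (dI * u - g$inter * dU) / u^2
}

#' Gradient of the WIoU loss with respect to the predicted box
#'
#' Analytic gradient honouring the detachment contract: the enclosing-box
#' size (W, H) is a constant in differentiation. With
#' `detach_enclosure = FALSE` the (incorrect, for reference) full gradient
#' including the enclosure dependence is returned — used in tests to show
#' the two differ whenever the enclosure is box-dependent.
#'
#' @param a predicted box(es), n x 4; @param b target box(es).
#' @param detach_enclosure treat W, H as constants (the contract).
#' @return n x 4 matrix d(loss)/d(a corners).
#' @export
wiou_grad <- function(a, b, detach_enclosure = TRUE) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- box_geom(a, b)
  dcx <- (a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2
  dcy <- (a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2
  denom <- g$W^2 + g$H^2 + BOX_EPS
  R <- exp((dcx^2 + dcy^2) / denom)
  L <- 1 - g$iou
  dL <- -iou_grad(a, b)
  # d rho^2 / d corners: centre moves at rate 1/2 per corner
  drho2 <- cbind(dcx, dcy, dcx, dcy)
  dR <- R * drho2 / denom
  if (!detach_enclosure) {
    dW <- cbind(-(a[, 1] < b[, 1]), 0, (a[, 3] > b[, 3]), 0)
    dH <- cbind(0, -(a[, 2] < b[, 2]), 0, (a[, 4] > b[, 4]))
    ddenom <- 2 * g$W * dW + 2 * g$H * dH
    dR <- dR - R * (dcx^2 + dcy^2) / denom^2 * ddenom
  }
  dR * L + R * dL
}

#' Gradient of the CIoU loss with respect to the predicted box
#'
#' Analytic gradient with the standard conventions: `alpha` is treated as
#' a constant, the enclosure diagonal c^2 is NOT detached (unlike WIoU).
#'
#' @inheritParams wiou_grad
#' @return n x 4 matrix.
#' @export
ciou_grad <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  g <- box_geom(a, b)
  dcx <- (a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2
  dcy <- (a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2
  rho2 <- dcx^2 + dcy^2
  c2 <- g$W^2 + g$H^2 + BOX_EPS
  dL <- -iou_grad(a, b)
  drho2 <- cbind(dcx, dcy, dcx, dcy)
  dW <- cbind(-(a[, 1] < b[, 1]), 0, (a[, 3] > b[, 3]), 0)
  dH <- cbind(0, -(a[, 2] < b[, 2]), 0, (a[, 4] > b[, 4]))
  dc2 <- 2 * g$W * dW + 2 * g$H * dH
  dpen <- drho2 / c2 - rho2 / c2^2 * dc2
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  dlt <- atan(wb / hb) - atan(wa / ha)
  v <- (4 / pi^2) * dlt^2
  alpha <- v / (1 - g$iou + v + BOX_EPS)
  # d v / d corners through wa, ha
  dv_dwa <- (8 / pi^2) * dlt * (-ha / (wa^2 + ha^2))
  dv_dha <- (8 / pi^2) * dlt * (wa / (wa^2 + ha^2))
  dv <- cbind(-dv_dwa, -dv_dha, dv_dwa, dv_dha)
  dL + dpen + alpha * dv
}

#' Convert between corner and normalized-centre box conventions
#'
#' `xyxy_to_cxcywh` maps pixel corners to normalized centre/size given the
#' image size; `cxcywh_to_xyxy` is its exact inverse.
#'
#' @param b n x 4 matrix (or length-4 vector).
#' @param img_w,img_h image size in pixels.
#' @return n x 4 matrix in the other convention.
#' @export
xyxy_to_cxcywh <- function(b, img_w, img_h) {
  b <- as.matrix(b); if (ncol(b) != 4) b <- matrix(b, ncol = 4)
  cbind((b[, 1] + b[, 3]) / 2 / img_w, (b[, 2] + b[, 4]) / 2 / img_h,
        (b[, 3] - b[, 1]) / img_w, (b[, 4] - b[, 2]) / img_h)
}

#' @rdname xyxy_to_cxcywh
#' @export
cxcywh_to_xyxy <- function(b, img_w, img_h) {
  b <- as.matrix(b); if (ncol(b) != 4) b <- matrix(b, ncol = 4)
  cbind((b[, 1] - b[, 3] / 2) * img_w, (b[, 2] - b[, 4] / 2) * img_h,
        (b[, 1] + b[, 3] / 2) * img_w, (b[, 2] + b[, 4] / 2) * img_h)
}
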