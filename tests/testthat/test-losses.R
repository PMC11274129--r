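# IoU-family regression losses: hand-geometry examples, the enclosure
# detachment contract, and invariance properties.

test_that("iou and l_iou match hand geometry", {
  expect_equal(box_iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1, tolerance = 1e-6)
  expect_equal(box_iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 1e-6)
  expect_equal(l_iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0, tolerance = 1e-6)
  expect_equal(l_iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 1)
  expect_equal(l_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 6 / 7, tolerance = 1e-6)
  # symmetry
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               box_iou(c(1, 1, 3, 3), c(0, 0, 2, 2)))
  expect_error(box_iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")
})

test_that("wiou factor and loss match the hand-geometry examples to 1e-5", {
  # concentric boxes: distance factor exactly 1
  expect_equal(r_wiou(c(0, 0, 4, 4), c(1, 1, 3, 3)), 1, tolerance = 1e-6)
  # disjoint pair: centres (0.5,0.5)/(2.5,2.5), enclosure 3x3
  expect_equal(r_wiou(c(0, 0, 1, 1), c(2, 2, 3, 3)), exp(8 / 18), tolerance = 1e-5)
  expect_equal(r_wiou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 1.55962, tolerance = 1e-5)
  expect_equal(r_wiou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1.11751, tolerance = 1e-5)
  expect_equal(wiou_loss(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0, tolerance = 1e-6)
  expect_equal(wiou_loss(c(0, 0, 1, 1), c(2, 2, 3, 3)), 1.55962, tolerance = 1e-5)
  expect_equal(wiou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 0.95787, tolerance = 1e-5)
})

test_that("ciou: identities and agreement with an independent recomputation", {
  expect_equal(ciou_loss(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0, tolerance = 1e-7)
  # concentric same-aspect boxes: distance and aspect terms vanish
  a <- c(1, 1, 5, 5); b <- c(2, 2, 4, 4)
  expect_equal(ciou_loss(a, b), l_iou(a, b), tolerance = 1e-6)
  # textbook recomputation as an independent oracle
  ciou_ref <- function(a, b) {
    inter <- max(0, min(a[3], b[3]) - max(a[1], b[1])) *
      max(0, min(a[4], b[4]) - max(a[2], b[2]))
    un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    iou <- inter / un
    rho2 <- ((a[1] + a[3]) / 2 - (b[1] + b[3]) / 2)^2 +
      ((a[2] + a[4]) / 2 - (b[2] + b[4]) / 2)^2
    c2 <- (max(a[3], b[3]) - min(a[1], b[1]))^2 +
      (max(a[4], b[4]) - min(a[2], b[2]))^2
    v <- 4 / pi^2 * (atan((b[3] - b[1]) / (b[4] - b[2])) -
                     atan((a[3] - a[1]) / (a[4] - a[2])))^2
    1 - iou + rho2 / c2 + v / (1 - iou + v) * v
  }
  set.seed(11)
  for (i in 1:50) {
    a <- c(sort(runif(2, 0, 10)), sort(runif(2, 0, 10)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2, 0, 10)), sort(runif(2, 0, 10)))[c(1, 3, 2, 4)]
    expect_equal(ciou_loss(a, b), ciou_ref(a, b), tolerance = 1e-5)
  }
})

test_that("wiou detachment: analytic gradient matches enclosure-frozen finite differences", {
  set.seed(12)
  # independent oracle: numeric gradient of R(frozen denom) * (1 - IoU)
  wiou_frozen <- function(a, b, denom) {
    dcx <- (a[1] + a[3]) / 2 - (b[1] + b[3]) / 2
    dcy <- (a[2] + a[4]) / 2 - (b[2] + b[4]) / 2
    exp((dcx^2 + dcy^2) / denom) * l_iou(a, b)
  }
  n_dep <- 0
  for (t in 1:20) {
    a <- c(runif(1, 0, 4), runif(1, 0, 4)); a <- c(a, a + runif(2, 0.5, 3))
    b <- c(runif(1, 0, 4), runif(1, 0, 4)); b <- c(b, b + runif(2, 0.5, 3))
    W <- max(a[3], b[3]) - min(a[1], b[1]); H <- max(a[4], b[4]) - min(a[2], b[2])
    denom <- W^2 + H^2 + 1e-7
    g <- wiou_grad(matrix(a, 1), matrix(b, 1))
    gn <- numeric(4); eps <- 1e-6
    for (i in 1:4) {
      ap <- a; ap[i] <- ap[i] + eps; am <- a; am[i] <- am[i] - eps
      gn[i] <- (wiou_frozen(ap, b, denom) - wiou_frozen(am, b, denom)) / (2 * eps)
    }
    expect_equal(as.numeric(g), gn, tolerance = 1e-4)
    # the full (non-detached) gradient must differ whenever the enclosure
    # depends on the predicted box
    encl_dep <- any(a[1] < b[1], a[2] < b[2], a[3] > b[3], a[4] > b[4])
    if (encl_dep) {
      gf <- wiou_grad(matrix(a, 1), matrix(b, 1), detach_enclosure = FALSE)
      expect_gt(max(abs(gf - g)), 1e-8)
      n_dep <- n_dep + 1
    }
  }
  expect_gt(n_dep, 0)
})

test_that("loss invariances over 1000 random box pairs", {
  set.seed(13)
  n <- 1000
  a <- cbind(runif(n, 0, 5), runif(n, 0, 5))
  a <- cbind(a, a + cbind(runif(n, 0.2, 4), runif(n, 0.2, 4)))
  b <- cbind(runif(n, 0, 5), runif(n, 0, 5))
  b <- cbind(b, b + cbind(runif(n, 0.2, 4), runif(n, 0.2, 4)))
  # translation invariance
  off <- matrix(rep(c(3.2, -1.7, 3.2, -1.7), each = n), n)
  expect_equal(wiou_loss(a + off, b + off), wiou_loss(a, b), tolerance = 1e-9)
  expect_equal(ciou_loss(a + off, b + off), ciou_loss(a, b), tolerance = 1e-9)
  expect_equal(l_iou(a + off, b + off), l_iou(a, b), tolerance = 1e-9)
  # scale covariance: s > 0 leaves all four quantities unchanged
  s <- 2.7
  expect_equal(box_iou(a * s, b * s), box_iou(a, b), tolerance = 1e-6)
  expect_equal(r_wiou(a * s, b * s), r_wiou(a, b), tolerance = 1e-6)
  expect_equal(wiou_loss(a * s, b * s), wiou_loss(a, b), tolerance = 1e-6)
  # wiou >= l_iou pointwise, equality iff centres coincide
  expect_true(all(wiou_loss(a, b) >= l_iou(a, b) - 1e-12))
  cent <- cbind((a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2,
                (a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2)
  coincide <- rowSums(cent^2) < 1e-16
  strict <- wiou_loss(a, b) > l_iou(a, b) + 1e-12
  expect_true(all(strict[!coincide] | l_iou(a, b)[!coincide] == 0))
})

test_that("box convention conversion round-trips exactly", {
  set.seed(14)
  b <- cbind(runif(50, 0, 50), runif(50, 0, 50))
  b <- cbind(b, b + cbind(runif(50, 1, 30), runif(50, 1, 30)))[, c(1, 3, 2, 4)]
  cc <- xyxy_to_cxcywh(b, 128, 96)
  expect_equal(cxcywh_to_xyxy(cc, 128, 96), unname(b), tolerance = 1e-12)
})
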