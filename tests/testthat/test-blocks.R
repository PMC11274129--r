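# Building blocks: shape contracts, hand-enumerated parameter counts,
# identity constructions and gradient checks.

test_that("conv block: zero propagation, parameter count, stride arithmetic", {
  set.seed(1)
  cb <- conv_block(16, 32, 3)
  # zeros through linear + BN + SiLU(0) = 0 (batch statistics of a zero
  # batch are zero-mean, and the SiLU fixes 0)
  y <- module_forward(cb, array(0, c(8, 8, 16, 2)), train = TRUE)
  expect_equal(max(abs(y)), 0)
  # 16*32*9 weights + 2*32 batch-norm = 4672
  expect_identical(module_n_params(cb), 16 * 32 * 9 + 2 * 32)
  # stride-2 halves spatial dims: symbolic pass at 640
  s2 <- conv_block(3, 8, 3, stride = 2)
  expect_equal(s2$out_shape(list(c(640, 640, 3)))[1:2], c(320, 320))
  # channel mismatch is a configuration error naming the block
  expect_error(module_forward(cb, rand_tensor(8, 8, 4)), "16")
})

test_that("c2f: parameter enumeration, config errors, gradient reaches all bottlenecks", {
  set.seed(2)
  expect_error(c2f_block(64, 64, n = 0), "n_bottlenecks")
  blk <- c2f_block(64, 64, n = 1, shortcut = TRUE)
  # hand enumeration: cv1 Conv(64,64,1)=64*64+128; one bottleneck with two
  # 3x3 Convs(32,32)=2*(32*32*9+64); cv2 Conv(96,64,1)=96*64+128
  hand <- (64 * 64 + 128) + 2 * (32 * 32 * 9 + 64) + (96 * 64 + 128)
  expect_identical(module_n_params(blk), hand)
  x <- rand_tensor(8, 8, 64)
  y <- module_forward(blk, x, train = TRUE)
  expect_equal(dim(y)[1:3], c(8, 8, 64))
  module_backward(blk, array(1, dim(y)))
  grads_ok <- TRUE
  walk_modules(blk, function(mm, p) {
    for (g in mm$gr) if (all(g == 0)) grads_ok <<- FALSE
  })
  expect_true(grads_ok)
})

test_that("sppf: pooling cascade equivalence and shape preservation", {
  set.seed(3)
  # max of a constant is the constant
  cst <- array(3.7, c(6, 6, 4, 1))
  expect_equal(module_forward(nn_maxpool(5), cst), cst)
  # two cascaded k=5 s=1 max-pools equal one k=9 max-pool
  for (rep in 1:5) {
    x <- rand_tensor(16, 16, 1)
    p5 <- nn_maxpool(5)
    y2 <- module_forward(p5, module_forward(p5, x))
    y9 <- module_forward(nn_maxpool(9), x)
    expect_equal(y2, y9)
  }
  expect_error(sppf_block(64, 64, k = 4), "odd")
  blk <- sppf_block(64, 64)
  x <- rand_tensor(8, 8, 64)
  expect_equal(dim(module_forward(blk, x)), dim(x) * c(1, 1, 1, 1))
})

test_that("res2net oracle block follows the split-hierarchy recursion exactly", {
  set.seed(4)
  # s=2: concat(X1, K2(X2)), no cross-split addition
  blk2 <- res2net_block(8, s = 2)
  set_all_convs_identity(blk2)
  x <- rand_tensor(6, 6, 8)
  expect_equal(module_forward(blk2, x), x)
  # s=4 with identity K: Y3 = X3 + X2, Y4 = X4 + X3 + X2
  blk4 <- res2net_block(16, s = 4)
  set_all_convs_identity(blk4)
  y <- module_forward(blk4, x <- rand_tensor(5, 5, 16))
  X <- function(i) x[, , (i - 1) * 4 + 1:4, , drop = FALSE]
  Y <- function(i) y[, , (i - 1) * 4 + 1:4, , drop = FALSE]
  expect_equal(Y(1), X(1))
  expect_equal(Y(2), X(2))
  expect_equal(Y(3), X(3) + X(2))
  expect_equal(Y(4), X(4) + X(3) + X(2))
  # zero input -> zero output for bias-free convolutions
  blkr <- res2net_block(8, s = 2)
  expect_equal(max(abs(module_forward(blkr, array(0, c(4, 4, 8, 1))))), 0)
  expect_error(res2net_block(10, s = 4), "divisible")
})

test_that("msconv: branch kernels {1,3,5,7}, impulse support, parameter enumeration", {
  set.seed(5)
  expect_error(msconv_block(3, 8), "at least 4")
  blk <- msconv_block(64, 64)
  # zero in -> zero out (bias-free branches, batch-norm on a zero batch)
  expect_equal(max(abs(module_forward(blk, array(0, c(8, 8, 64, 1)), train = TRUE))), 0)
  # the four branch convolutions have kernel sizes exactly 1,3,5,7 and the
  # impulse response of each branch spans exactly k x k pixels
  ks <- c()
  walk_modules(blk, function(mm, p) {
    if (mm$kind == "conv2d" && dim(mm$par$w)[1] > 0 && mm$cin == 16 && mm$cout == 16)
      ks <<- c(ks, dim(mm$par$w)[1])
  })
  expect_identical(sort(ks), c(1L, 3L, 5L, 7L))
  for (k in c(3L, 7L)) {
    conv <- nn_conv2d(2, 2, k)
    conv$par$w[] <- 1
    imp <- array(0, c(15, 15, 2, 1)); imp[8, 8, 1, 1] <- 1
    resp <- module_forward(conv, imp)[, , 1, 1]
    expect_identical(sum(rowSums(abs(resp)) > 0), as.integer(k))
    expect_identical(sum(colSums(abs(resp)) > 0), as.integer(k))
  }
  # parameter count under the dense-branch design:
  # branches sum((c/4)^2 * k^2) + fusion Conv(64,64,1) + its BN
  hand <- sum(16^2 * c(1, 9, 25, 49)) + 64 * 64 + 2 * 64
  expect_identical(module_n_params(blk), hand)
  # uneven split: first (c %% 4) groups get the extra channel
  blk6 <- msconv_block(6, 8)
  sizes <- c()
  walk_modules(blk6, function(mm, p)
    if (mm$kind == "slice") sizes <<- c(sizes, mm$to - mm$from + 1L))
  expect_identical(sizes, c(2L, 2L, 1L, 1L))
})

test_that("c2f-msconv keeps the C2f shape contract with strictly fewer parameters", {
  set.seed(6)
  a <- c2f_block(64, 64, n = 1, shortcut = TRUE)
  b <- c2f_block(64, 64, n = 1, shortcut = TRUE, msconv = TRUE)
  x <- rand_tensor(8, 8, 64)
  expect_equal(dim(module_forward(a, x)), dim(module_forward(b, x, train = TRUE)))
  expect_lt(module_n_params(b), module_n_params(a))
  # gradient reaches all four multi-scale branches
  y <- module_forward(b, x, train = TRUE)
  module_backward(b, array(1, dim(y)))
  branch_grads <- c()
  walk_modules(b, function(mm, p) {
    if (mm$kind == "conv2d" && mm$cin == 8 && mm$cout == 8)
      branch_grads <<- c(branch_grads, max(abs(mm$gr$w)))
  })
  expect_length(branch_grads, 4L)
  expect_true(all(branch_grads > 0))
})

test_that("separable attention: 1D cascades reproduce outer-product 2D depthwise kernels", {
  set.seed(7)
  worst <- 0
  for (rep in 1:100) {
    k <- sample(c(3L, 5L), 1)
    cN <- sample(1:3, 1)
    x <- rand_tensor(9, 9, cN)
    hconv <- nn_conv2d(cN, cN, c(1L, k), groups = cN)
    vconv <- nn_conv2d(cN, cN, c(k, 1L), groups = cN)
    hv <- runif(k, -1, 1); vv <- runif(k, -1, 1)
    for (c in seq_len(cN)) {
      hconv$par$w[1, , 1, c] <- hv
      vconv$par$w[, 1, 1, c] <- vv
    }
    y1 <- module_forward(vconv, module_forward(hconv, x))
    y2 <- dw_conv2d_ref(x, outer(vv, hv))
    worst <- max(worst, max(abs(y1 - y2)))
  }
  expect_lt(worst, 1e-5)
})

test_that("lska: identity kernels gate x by itself; dilated receptive field", {
  set.seed(8)
  blk <- lska_block(8, K = 11, d = 4)
  set_all_convs_identity(blk)
  x <- rand_tensor(10, 10, 8)
  expect_equal(module_forward(blk, x), x * x)
  # dilated 1D pair spans d*(ceil(K/d)-1)+1 pixels per axis
  K <- 11L; d <- 4L; kd <- as.integer(ceiling(K / d))
  h <- nn_conv2d(1, 1, c(1L, kd), dilation = c(1L, d), groups = 1)
  v <- nn_conv2d(1, 1, c(kd, 1L), dilation = c(d, 1L), groups = 1)
  h$par$w[] <- 1; v$par$w[] <- 1
  imp <- array(0, c(21, 21, 1, 1)); imp[11, 11, 1, 1] <- 1
  resp <- module_forward(v, module_forward(h, imp))[, , 1, 1]
  span <- d * (kd - 1) + 1
  extent <- function(v) diff(range(which(v > 0))) + 1L
  expect_identical(extent(rowSums(abs(resp))), as.integer(span))
  expect_identical(extent(colSums(abs(resp))), as.integer(span))
  # even effective kernels are rejected (K/d even -> asymmetric padding)
  expect_error(lska_block(8, K = 11, d = 3), "even effective kernel")
})

test_that("sppf-lska with identity attention equals sppf with elementwise self-gating", {
  set.seed(9)
  blk <- sppf_block(16, 16, lska = TRUE)
  walk_modules(blk, function(mm, p) if (mm$kind == "conv2d") {
    if (mm$groups == mm$cin || (mm$cin == mm$cout && all(dim(mm$par$w)[1:2] == 1) &&
                                mm$has_bias)) conv_set_identity(mm)
  })
  x <- rand_tensor(8, 8, 16)
  # reference: run the sppf nodes by hand, square the concatenation
  n <- blk$nodes
  z1 <- n[[1]]$m$fwd(list(x))
  z2 <- n[[2]]$m$fwd(list(z1)); z3 <- n[[3]]$m$fwd(list(z2)); z4 <- n[[4]]$m$fwd(list(z3))
  cc <- n[[5]]$m$fwd(list(z1, z2, z3, z4))
  ref <- n[[7]]$m$fwd(list(cc * cc))
  expect_equal(module_forward(blk, x), ref)
})

test_that("all blocks preserve spatial dims at stride 1 and pass finite-difference checks", {
  set.seed(10)
  builders <- list(
    function() conv_block(8, 12, 3),
    function() c2f_block(8, 8, n = 2, shortcut = TRUE),
    function() c2f_block(8, 8, n = 1, msconv = TRUE),
    function() sppf_block(8, 8),
    function() sppf_block(8, 8, lska = TRUE, lska_k = 7, lska_d = 2),
    function() msconv_block(8, 8),
    function() lska_block(8, K = 7, d = 2),
    function() res2net_block(8, 4))
  for (mk in builders) {
    blk <- mk()
    h <- sample(5:12, 1); w <- sample(5:12, 1)
    x <- rand_tensor(h, w, 8)
    y <- module_forward(blk, x, train = TRUE)
    expect_identical(dim(y)[1:2], c(h, w))
    # finite differences vs analytic input gradient on random entries
    proj <- array(rnorm(length(y)), dim(y))
    dx <- module_backward(blk, proj)
    entries <- sample(length(x), 4)
    gn <- numgrad_input_train(blk, x, proj, entries)
    expect_lt(max(abs(gn - dx[entries])), 1e-3)
  }
})
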