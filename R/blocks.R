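# Network building blocks. Each constructor returns a module graph built
# from the primitives in nn.R, so forward/backward, parameter counting and
# FLOPs estimation come for free from the graph engine.

#' Conv + BatchNorm + SiLU block
#'
#' The standard convolution unit of the detector: a bias-free 2-D
#' convolution followed by batch normalisation and the smooth
#' sigmoid-weighted linear activation (Swish/SiLU, `x * sigmoid(x)`).
#' Stride 1 preserves the spatial dimensions ("same" padding); kernels must
#' therefore have odd effective size.
#'
#' @param cin,cout channel counts in/out.
#' @param k odd kernel size (scalar or c(kh, kw)).
#' @param stride stride.
#' @param groups channel groups for the convolution.
#' @return a module; run it with [module_forward()].
#' @export
conv_block <- function(cin, cout, k = 1L, stride = 1L, groups = 1L) {
  nn_graph(list(
    list(from = 0L, m = nn_conv2d(cin, cout, k, stride, groups = groups)),
    list(from = 1L, m = nn_batchnorm(cout)),
    list(from = 2L, m = nn_silu())
  ), label = sprintf("Conv(%d,%d,k%s,s%d)", cin, cout,
                     paste(rep(k, length.out = 1), collapse = "x"), stride))
}

#' @keywords internal
bottleneck_block <- function(c1, c2, shortcut = TRUE, msconv = FALSE) {
  cv1 <- conv_block(c1, c2, 3L)
  cv2 <- if (msconv) msconv_block(c2, c2) else conv_block(c2, c2, 3L)
  nodes <- list(list(from = 0L, m = cv1), list(from = 1L, m = cv2))
  if (shortcut && c1 == c2)
    nodes <- c(nodes, list(list(from = c(2L, 0L), m = nn_add())))
  nn_graph(nodes, label = "Bottleneck")
}

#' C2f cross-stage feature-extraction block
#'
#' Splits the features of a 1x1 convolution into two halves, chains `n`
#' bottlenecks on the second half appending every intermediate output, and
#' fuses the concatenation with a final 1x1 convolution — the main feature
#' extractor of the YOLOv8 backbone and neck.
#'
#' @param c1,c2 channel counts in/out.
#' @param n number of bottlenecks (>= 1).
#' @param shortcut use residual shortcuts inside the bottlenecks.
#' @param msconv replace the second 3x3 convolution of every bottleneck
#'   with a multi-scale convolution ([msconv_block()]), giving C2f-MSConv.
#' @return a module.
#' @export
c2f_block <- function(c1, c2, n = 1L, shortcut = FALSE, msconv = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("c2f_block: n_bottlenecks must be >= 1")
  ch <- as.integer(c2 %/% 2L)
  nodes <- list(
    list(from = 0L, m = conv_block(c1, 2L * ch, 1L)),
    list(from = 1L, m = nn_slice(1L, ch)),
    list(from = 1L, m = nn_slice(ch + 1L, 2L * ch))
  )
  prev <- 3L
  for (b in seq_len(n)) {
    nodes <- c(nodes, list(list(from = prev,
                                m = bottleneck_block(ch, ch, shortcut, msconv))))
    prev <- length(nodes)
  }
  nodes <- c(nodes, list(list(from = c(2L, 3L, 3L + seq_len(n)), m = nn_concat())))
  nodes <- c(nodes, list(list(from = length(nodes),
                              m = conv_block((2L + n) * ch, c2, 1L))))
  nn_graph(nodes, label = sprintf("%s(%d,%d,n=%d)",
                                  if (msconv) "C2f-MSConv" else "C2f", c1, c2, n))
}

#' Spatial pyramid pooling fast (SPPF)
#'
#' Three cascaded stride-1 max-pools (kernel `k`) whose outputs are
#' concatenated with the pre-pool branch and fused by a 1x1 convolution;
#' cascading equal kernels emulates pooling at receptive fields k, 2k-1,
#' 3k-2 at low cost.
#'
#' @param c1,c2 channel counts in/out.
#' @param k odd pooling kernel (default 5).
#' @param lska insert large separable kernel attention after the
#'   concatenation, before the fusion convolution (SPPF-LSKA).
#' @param lska_k,lska_d LSKA kernel size and dilation (see [lska_block()]).
#' @return a module.
#' @export
sppf_block <- function(c1, c2, k = 5L, lska = FALSE, lska_k = 11L, lska_d = 4L) {
  if (k %% 2L == 0L) stop("sppf_block: pool kernel must be odd")
  ch <- as.integer(c1 %/% 2L)
  nodes <- list(
    list(from = 0L, m = conv_block(c1, ch, 1L)),
    list(from = 1L, m = nn_maxpool(k)),
    list(from = 2L, m = nn_maxpool(k)),
    list(from = 3L, m = nn_maxpool(k)),
    list(from = c(1L, 2L, 3L, 4L), m = nn_concat())
  )
  if (lska)
    nodes <- c(nodes, list(list(from = 5L, m = lska_block(4L * ch, lska_k, lska_d))))
  nodes <- c(nodes, list(list(from = length(nodes),
                              m = conv_block(4L * ch, c2, 1L))))
  nn_graph(nodes, label = sprintf("%s(%d,%d)",
                                  if (lska) "SPPF-LSKA" else "SPPF", c1, c2))
}

#' Multi-scale convolution (MSConv)
#'
#' Divides the input channels into four groups and convolves them with
#' 1x1, 3x3, 5x5 and 7x7 kernels respectively (dense within each group),
#' capturing detail and context at four receptive fields; a 1x1
#' Conv-BN-SiLU then fuses the multi-scale features. When the channel
#' count is not divisible by four, the first `channels %% 4` groups take
#' one extra channel.
#'
#' @param cin input channels (>= 4).
#' @param cout output channels of the fusion convolution.
#' @return a module.
#' @export
msconv_block <- function(cin, cout) {
  cin <- as.integer(cin)
  if (cin < 4L) stop("msconv_block: needs at least 4 input channels")
  base <- cin %/% 4L
  sizes <- rep(base, 4L) + as.integer(seq_len(4L) <= cin %% 4L)
  kernels <- c(1L, 3L, 5L, 7L)
  nodes <- list()
  at <- 0L
  for (g in 1:4) {
    nodes <- c(nodes, list(list(from = 0L, m = nn_slice(at + 1L, at + sizes[g]))))
    nodes <- c(nodes, list(list(from = length(nodes),
                                m = nn_conv2d(sizes[g], sizes[g], kernels[g]))))
    at <- at + sizes[g]
  }
  nodes <- c(nodes, list(list(from = c(2L, 4L, 6L, 8L), m = nn_concat())))
  nodes <- c(nodes, list(list(from = length(nodes), m = conv_block(cin, cout, 1L))))
  nn_graph(nodes, label = sprintf("MSConv(%d,%d)", cin, cout))
}

#' Large separable kernel attention (LSKA)
#'
#' Approximates a large K x K depthwise attention kernel by a cascade of
#' separable depthwise convolutions: 1x(2d-1) and (2d-1)x1 depthwise, then
#' 1x ceil(K/d) and ceil(K/d)x1 depthwise with dilation d, then a 1x1
#' pointwise channel-mixing convolution. The result gates the input
#' elementwise (attention * x). Channel count is unchanged. `ceil(K/d)`
#' must be odd so that "same" padding stays symmetric.
#'
#' @param c channels.
#' @param K nominal large kernel size.
#' @param d dilation of the long-range pair.
#' @return a module.
#' @export
lska_block <- function(c, K = 11L, d = 4L) {
  K <- as.integer(K); d <- as.integer(d)
  if (d < 1L || K < d) stop("lska_block: need K >= d >= 1")
  k0 <- 2L * d - 1L
  kd <- as.integer(ceiling(K / d))
  nodes <- list(
    list(from = 0L, m = nn_conv2d(c, c, c(1L, k0), groups = c, bias = TRUE)),
    list(from = 1L, m = nn_conv2d(c, c, c(k0, 1L), groups = c, bias = TRUE)),
    list(from = 2L, m = nn_conv2d(c, c, c(1L, kd), dilation = c(1L, d),
                                  groups = c, bias = TRUE)),
    list(from = 3L, m = nn_conv2d(c, c, c(kd, 1L), dilation = c(d, 1L),
                                  groups = c, bias = TRUE)),
    list(from = 4L, m = nn_conv2d(c, c, 1L, bias = TRUE)),
    list(from = c(5L, 0L), m = nn_mul())
  )
  nn_graph(nodes, label = sprintf("LSKA(%d,K=%d,d=%d)", c, K, d))
}

#' Hierarchical residual (Res2Net-style) reference block
#'
#' Splits channels into `s` equal groups and applies Y1 = X1,
#' Y2 = K2(X2), Yi = Ki(Xi + Y(i-1)) for 2 < i <= s, concatenating the Yi.
#' The Ki are bias-free dense 3x3 convolutions within each split. This
#' block is a test oracle for the hierarchy that motivates MSConv; it is
#' not part of the shipped detector.
#'
#' @param c channels, divisible by `s`.
#' @param s number of splits (>= 2).
#' @return a module.
#' @export
res2net_block <- function(c, s = 4L) {
  c <- as.integer(c); s <- as.integer(s)
  if (s < 2L) stop("res2net_block: s must be >= 2")
  if (c %% s != 0L) stop("res2net_block: channels (", c, ") not divisible by s (", s, ")")
  cs <- c %/% s
  nodes <- list()
  for (i in seq_len(s))
    nodes <- c(nodes, list(list(from = 0L, m = nn_slice((i - 1L) * cs + 1L, i * cs))))
  y_ids <- integer(s)
  y_ids[1] <- 1L
  nodes <- c(nodes, list(list(from = 2L, m = nn_conv2d(cs, cs, 3L))))
  y_ids[2] <- length(nodes)
  if (s > 2L) for (i in 3:s) {
    nodes <- c(nodes, list(list(from = c(i, y_ids[i - 1L]), m = nn_add())))
    nodes <- c(nodes, list(list(from = length(nodes), m = nn_conv2d(cs, cs, 3L))))
    y_ids[i] <- length(nodes)
  }
  nodes <- c(nodes, list(list(from = y_ids, m = nn_concat())))
  nn_graph(nodes, label = sprintf("Res2Net(%d,s=%d)", c, s))
}

#' Set a bare convolution's kernel to a centred impulse (identity)
#'
#' Utility for constructing identity-initialised blocks in oracles and
#' tests: after this, the convolution maps each channel to itself
#' unchanged (requires cin == cout for dense, or depthwise layout).
#'
#' @param conv a `nn_conv2d` module.
#' @return the module, invisibly.
#' @export
conv_set_identity <- function(conv) {
  d <- dim(conv$par$w)
  w <- array(0, d)
  ci <- (d[1] + 1L) %/% 2L
  cj <- (d[2] + 1L) %/% 2L
  if (d[3] == 1L) {
    w[ci, cj, 1L, ] <- 1
  } else {
    for (o in seq_len(d[4])) w[ci, cj, o, o] <- 1
  }
  conv$par$w <- w
  if (conv$has_bias) conv$par$b <- numeric(d[4])
  invisible(conv)
}
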