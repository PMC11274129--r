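# Minimal reverse-mode layer engine on dense arrays, layout c(H, W, C, N).
# Every module is an environment with:
#   $kind      character tag
#   $fwd(xs, train)  list-of-tensors -> tensor (caches what backward needs)
#   $bwd(dy)         output gradient -> list of input gradients
#   $par, $gr  named lists of parameter arrays and their gradients
#   $out_shape(shapes), $flops(shapes)  symbolic passes on c(H, W, C) shapes
# Composite blocks and the full detector are graphs of these primitives, so
# backward, parameter counting and FLOPs accounting are all generic.

sigmoid <- function(x) 1 / (1 + exp(-x))

new_module <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- list()
  e$gr <- list()
  e$trainable <- TRUE
  class(e) <- c(paste0("mlyolo_", kind), "mlyolo_module")
  e
}

same_pad <- function(k, d = 1L) {
  if ((d * (k - 1L)) %% 2L != 0L)
    stop("even effective kernel (k=", k, ", d=", d, "): symmetric padding impossible")
  as.integer(d * (k - 1L) / 2L)
}

#' Bare 2-D convolution module
#'
#' Grouped, dilated, optionally rectangular-kernel convolution. Weights are
#' Kaiming-normal initialised from the current RNG stream. Padding defaults
#' to "same" (stride 1 preserves the spatial dims), which requires odd
#' effective kernels.
#'
#' @param cin,cout input/output channel counts.
#' @param k kernel size, scalar or c(kh, kw).
#' @param stride stride, scalar or c(sh, sw).
#' @param dilation dilation, scalar or c(dh, dw).
#' @param groups number of channel groups; must divide both cin and cout.
#' @param bias include an additive bias term.
#' @param pad explicit padding c(ph, pw); default "same".
#' @return a module environment.
#' @keywords internal
nn_conv2d <- function(cin, cout, k = 1L, stride = 1L, dilation = 1L,
                      groups = 1L, bias = FALSE, pad = NULL) {
  k <- rep(as.integer(k), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  dilation <- rep(as.integer(dilation), length.out = 2L)
  groups <- as.integer(groups)
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("conv2d: groups=", groups, " must divide channels (", cin, "->", cout, ")")
  if (is.null(pad)) pad <- c(same_pad(k[1], dilation[1]), same_pad(k[2], dilation[2]))
  pad <- rep(as.integer(pad), length.out = 2L)
  m <- new_module("conv2d")
  m$cin <- as.integer(cin); m$cout <- as.integer(cout)
  m$k <- k; m$stride <- stride; m$dilation <- dilation
  m$groups <- groups; m$padv <- pad; m$has_bias <- isTRUE(bias)
  cg <- cin %/% groups
  fan_in <- k[1] * k[2] * cg
  nw <- k[1] * k[2] * cg * cout
  m$par$w <- if (isTRUE(getOption("mlyolo.init_zeros"))) array(0, c(k[1], k[2], cg, cout))
             else array(stats::rnorm(nw, sd = sqrt(2 / fan_in)), c(k[1], k[2], cg, cout))
  if (m$has_bias) m$par$b <- numeric(cout)
  m$fwd <- function(xs, train = FALSE) {
    x <- xs[[1]]
    if (dim(x)[3] != m$cin)
      stop("conv2d: expected ", m$cin, " input channels, got ", dim(x)[3])
    if (train) m$x <- x
    .conv2d_fw(x, m$par$w, if (m$has_bias) m$par$b else NULL,
               m$stride[1], m$stride[2], m$padv[1], m$padv[2],
               m$dilation[1], m$dilation[2], m$groups)
  }
  m$bwd <- function(dy) {
    g <- .conv2d_bw(m$x, m$par$w, dy, m$has_bias,
                    m$stride[1], m$stride[2], m$padv[1], m$padv[2],
                    m$dilation[1], m$dilation[2], m$groups)
    m$gr$w <- if (is.null(m$gr$w)) g$dw else m$gr$w + g$dw
    if (m$has_bias) m$gr$b <- if (is.null(m$gr$b)) g$db else m$gr$b + g$db
    list(g$dx)
  }
  m$out_shape <- function(shapes) {
    s <- shapes[[1]]
    ho <- (s[1] + 2 * m$padv[1] - m$dilation[1] * (m$k[1] - 1) - 1) %/% m$stride[1] + 1
    wo <- (s[2] + 2 * m$padv[2] - m$dilation[2] * (m$k[2] - 1) - 1) %/% m$stride[2] + 1
    c(ho, wo, m$cout)
  }
  m$flops <- function(shapes) {
    o <- m$out_shape(shapes)
    2 * m$k[1] * m$k[2] * (m$cin / m$groups) * m$cout * o[1] * o[2]
  }
  m
}

#' @keywords internal
nn_batchnorm <- function(c, eps = 1e-3, momentum = 0.03) {
  m <- new_module("batchnorm")
  m$c <- as.integer(c); m$eps <- eps; m$momentum <- momentum
  m$par$gamma <- rep(1, c)
  m$par$beta <- rep(0, c)
  m$running_mean <- rep(0, c)
  m$running_var <- rep(1, c)
  to_mat <- function(x) {
    d <- dim(x)
    matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  }
  from_mat <- function(xm, d) aperm(array(xm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  m$fwd <- function(xs, train = FALSE) {
    x <- xs[[1]]
    d <- dim(x)
    xm <- to_mat(x)
    if (train) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      va <- colMeans(xc * xc)
      m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
      m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * va
      istd <- 1 / sqrt(va + m$eps)
      xhat <- sweep(xc, 2, istd, `*`)
      m$xhat <- xhat; m$istd <- istd; m$d <- d
      ym <- sweep(sweep(xhat, 2, m$par$gamma, `*`), 2, m$par$beta, `+`)
    } else {
      istd <- 1 / sqrt(m$running_var + m$eps)
      ym <- sweep(sweep(sweep(xm, 2, m$running_mean), 2, istd * m$par$gamma, `*`),
                  2, m$par$beta, `+`)
    }
    from_mat(ym, d)
  }
  m$bwd <- function(dy) {
    d <- m$d
    dym <- to_mat(dy)
    nm <- nrow(dym)
    dgamma <- colSums(dym * m$xhat)
    dbeta <- colSums(dym)
    m$gr$gamma <- if (is.null(m$gr$gamma)) dgamma else m$gr$gamma + dgamma
    m$gr$beta <- if (is.null(m$gr$beta)) dbeta else m$gr$beta + dbeta
    dxhat <- sweep(dym, 2, m$par$gamma, `*`)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(m$xhat, 2, colMeans(dxhat * m$xhat), `*`)
    dxm <- sweep(t1 - t2, 2, m$istd, `*`)
    list(from_mat(dxm, d))
  }
  m$out_shape <- function(shapes) shapes[[1]]
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_silu <- function() {
  m <- new_module("silu")
  m$fwd <- function(xs, train = FALSE) {
    x <- xs[[1]]
    if (train) m$x <- x
    x * sigmoid(x)
  }
  m$bwd <- function(dy) {
    s <- sigmoid(m$x)
    list(dy * (s * (1 + m$x * (1 - s))))
  }
  m$out_shape <- function(shapes) shapes[[1]]
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_maxpool <- function(k = 5L, stride = 1L, pad = NULL) {
  m <- new_module("maxpool")
  m$k <- as.integer(k); m$stride <- as.integer(stride)
  m$padv <- if (is.null(pad)) m$k %/% 2L else as.integer(pad)
  m$fwd <- function(xs, train = FALSE) {
    r <- .maxpool_fw(xs[[1]], m$k, m$stride, m$padv)
    if (train) { m$idx <- r$idx; m$in_dim <- dim(xs[[1]]) }
    r$y
  }
  m$bwd <- function(dy) list(.maxpool_bw(dy, m$idx, m$in_dim))
  m$out_shape <- function(shapes) {
    s <- shapes[[1]]
    c((s[1] + 2 * m$padv - m$k) %/% m$stride + 1,
      (s[2] + 2 * m$padv - m$k) %/% m$stride + 1, s[3])
  }
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_upsample2 <- function() {
  m <- new_module("upsample2")
  m$fwd <- function(xs, train = FALSE) {
    x <- xs[[1]]
    d <- dim(x)
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  }
  m$bwd <- function(dy) {
    d <- dim(dy)
    i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
    j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
    list(dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
         dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE])
  }
  m$out_shape <- function(shapes) {
    s <- shapes[[1]]; c(2 * s[1], 2 * s[2], s[3])
  }
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_concat <- function() {
  m <- new_module("concat")
  m$fwd <- function(xs, train = FALSE) {
    m$splits <- vapply(xs, function(x) dim(x)[3], integer(1))
    d <- dim(xs[[1]])
    y <- array(0, c(d[1], d[2], sum(m$splits), d[4]))
    at <- 0L
    for (x in xs) {
      cc <- dim(x)[3]
      y[, , at + seq_len(cc), ] <- x
      at <- at + cc
    }
    y
  }
  m$bwd <- function(dy) {
    out <- vector("list", length(m$splits))
    at <- 0L
    for (i in seq_along(m$splits)) {
      out[[i]] <- dy[, , at + seq_len(m$splits[i]), , drop = FALSE]
      at <- at + m$splits[i]
    }
    out
  }
  m$out_shape <- function(shapes) {
    s <- shapes[[1]]
    c(s[1], s[2], sum(vapply(shapes, function(z) z[3], numeric(1))))
  }
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_slice <- function(from, to) {
  m <- new_module("slice")
  m$from <- as.integer(from); m$to <- as.integer(to)
  m$fwd <- function(xs, train = FALSE) {
    if (train) m$cin <- dim(xs[[1]])[3]
    xs[[1]][, , m$from:m$to, , drop = FALSE]
  }
  m$bwd <- function(dy) {
    d <- dim(dy)
    dx <- array(0, c(d[1], d[2], m$cin, d[4]))
    dx[, , m$from:m$to, ] <- dy
    list(dx)
  }
  m$out_shape <- function(shapes) {
    s <- shapes[[1]]; c(s[1], s[2], m$to - m$from + 1L)
  }
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_add <- function() {
  m <- new_module("add")
  m$fwd <- function(xs, train = FALSE) {
    m$n_in <- length(xs)
    Reduce(`+`, xs)
  }
  m$bwd <- function(dy) rep(list(dy), m$n_in)
  m$out_shape <- function(shapes) shapes[[1]]
  m$flops <- function(shapes) 0
  m
}

#' @keywords internal
nn_mul <- function() {
  m <- new_module("mul")
  m$fwd <- function(xs, train = FALSE) {
    if (train) { m$a <- xs[[1]]; m$b <- xs[[2]] }
    xs[[1]] * xs[[2]]
  }
  m$bwd <- function(dy) list(dy * m$b, dy * m$a)
  m$out_shape <- function(shapes) shapes[[1]]
  m$flops <- function(shapes) 0
  m
}

#' Directed-graph container of modules
#'
#' `nodes` is a list of `list(from = <integer vector>, m = <module>)` where
#' index 0 denotes the graph input and positive indices earlier nodes.
#' `out_ids` selects the node(s) whose outputs the graph returns. Backward
#' accumulates gradients across fan-out automatically.
#'
#' @keywords internal
nn_graph <- function(nodes, out_ids = length(nodes), label = NULL) {
  m <- new_module("graph")
  m$nodes <- nodes
  m$out_ids <- as.integer(out_ids)
  m$label <- label
  m$fwd <- function(xs, train = FALSE) {
    x <- xs[[1]]
    outs <- vector("list", length(m$nodes))
    for (i in seq_along(m$nodes)) {
      nd <- m$nodes[[i]]
      ins <- lapply(nd$from, function(f) if (f == 0L) x else outs[[f]])
      outs[[i]] <- nd$m$fwd(ins, train = train)
    }
    m$outs_dim <- lapply(outs, dim)
    if (length(m$out_ids) == 1L) outs[[m$out_ids]] else outs[m$out_ids]
  }
  m$bwd <- function(dy) {
    if (length(m$out_ids) == 1L) dy <- list(dy)
    gbuf <- vector("list", length(m$nodes))
    gin <- NULL
    for (j in seq_along(m$out_ids)) {
      id <- m$out_ids[j]
      gbuf[[id]] <- if (is.null(gbuf[[id]])) dy[[j]] else gbuf[[id]] + dy[[j]]
    }
    for (i in rev(seq_along(m$nodes))) {
      if (is.null(gbuf[[i]])) next
      nd <- m$nodes[[i]]
      dxs <- nd$m$bwd(gbuf[[i]])
      gbuf[[i]] <- NULL
      for (j in seq_along(nd$from)) {
        f <- nd$from[j]
        if (f == 0L) gin <- if (is.null(gin)) dxs[[j]] else gin + dxs[[j]]
        else gbuf[[f]] <- if (is.null(gbuf[[f]])) dxs[[j]] else gbuf[[f]] + dxs[[j]]
      }
    }
    list(gin)
  }
  m$shapes_pass <- function(in_shape) {
    shp <- vector("list", length(m$nodes))
    for (i in seq_along(m$nodes)) {
      nd <- m$nodes[[i]]
      ins <- lapply(nd$from, function(f) if (f == 0L) in_shape else shp[[f]])
      shp[[i]] <- nd$m$out_shape(ins)
    }
    shp
  }
  m$out_shape <- function(shapes) {
    shp <- m$shapes_pass(shapes[[1]])
    if (length(m$out_ids) == 1L) shp[[m$out_ids]] else shp[m$out_ids]
  }
  m$flops <- function(shapes) {
    shp <- m$shapes_pass(shapes[[1]])
    tot <- 0
    for (i in seq_along(m$nodes)) {
      nd <- m$nodes[[i]]
      ins <- lapply(nd$from, function(f) if (f == 0L) shapes[[1]] else shp[[f]])
      tot <- tot + nd$m$flops(ins)
    }
    tot
  }
  m
}

#' Run a module forward
#'
#' @param m a module (block or full graph).
#' @param x input array of dim c(H, W, C) or c(H, W, C, N).
#' @param train keep caches for a subsequent backward pass and use batch
#'   statistics in normalisation layers.
#' @return output array (4-D), or a list of arrays for multi-output graphs.
#' @export
module_forward <- function(m, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  m$fwd(list(x), train = train)
}

#' Run a module backward
#'
#' Propagates an output gradient through a module previously run with
#' `module_forward(..., train = TRUE)`; parameter gradients accumulate into
#' the modules, and the input gradient is returned.
#'
#' @param m a module.
#' @param dy gradient with respect to the module output (same shape).
#' @return gradient with respect to the module input.
#' @export
module_backward <- function(m, dy) m$bwd(dy)[[1]]

#' Apply a function to every primitive module in a tree
#' @keywords internal
walk_modules <- function(m, fn, path = "") {
  if (m$kind == "graph") {
    for (i in seq_along(m$nodes))
      walk_modules(m$nodes[[i]]$m, fn, paste0(path, "/", i))
  } else {
    fn(m, path)
  }
  invisible(NULL)
}

#' Count trainable parameters of a module
#' @param m a module.
#' @return integer-valued count of trainable scalar parameters.
#' @export
module_n_params <- function(m) {
  tot <- 0
  walk_modules(m, function(mm, p) {
    if (isTRUE(mm$trainable))
      tot <<- tot + sum(vapply(mm$par, length, numeric(1)))
  })
  tot
}

#' Zero accumulated parameter gradients
#' @keywords internal
module_zero_grad <- function(m) {
  walk_modules(m, function(mm, p) mm$gr <- list())
  invisible(NULL)
}

#' Collect references to all parameterised modules (for the optimizer)
#' @keywords internal
module_collect <- function(m) {
  out <- list()
  walk_modules(m, function(mm, p) {
    if (length(mm$par)) out[[p]] <<- mm
  })
  out
}
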