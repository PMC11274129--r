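# Trainer: target assignment rules, loss-term structure, gradient flow
# through a full step, and training determinism.

test_that("center-prior assignment: centred box, empty image, nested tie-break", {
  # one large centred box: the centre cell is positive at every scale
  tt <- data.frame(class_id = 0L, x1 = 8, y1 = 8, x2 = 88, y2 = 88)
  asn <- assign_targets(list(tt), c(96, 96))
  for (si in 1:3) {
    a <- asn[[si]]
    expect_false(is.null(a))
    s <- c(8, 16, 32)[si]
    ctr <- 48 / s + 0.5
    expect_true(any(abs(a$i - ctr) <= 0.5 & abs(a$j - ctr) <= 0.5))
  }
  # empty image: no positives anywhere
  asn0 <- assign_targets(list(tt[0, ]), c(96, 96))
  expect_true(all(vapply(asn0, is.null, logical(1))))
  # nested boxes: shared cells go to the smaller box
  big <- data.frame(class_id = 0L, x1 = 8, y1 = 8, x2 = 88, y2 = 88)
  small <- data.frame(class_id = 1L, x1 = 32, y1 = 32, x2 = 64, y2 = 64)
  asn2 <- assign_targets(list(rbind(big, small)), c(96, 96))
  a8 <- asn2[[1]]
  ctr_cell <- a8[abs(a8$i - 6.5) <= 0.5 & abs(a8$j - 6.5) <= 0.5, ]
  expect_true(all(ctr_cell$class_id == 1L))
})

test_that("training step: finite losses, weight linearity, loss-switch locality", {
  set.seed(61)
  m <- smoke_model(seed = 61)
  dat <- make_tiny_dataset(1, 500)
  x <- array(0, c(96, 96, 3, 2))
  x[, , , 1] <- dat$images[[1]]; x[, , , 2] <- dat$images[[2]]
  truths <- lapply(dat$labels[1:2], mlyolo:::labels_to_pixels, hw = c(96, 96))
  cfg <- train_config(input_size = 96, batch_size = 2, epochs = 1, seed = 61)
  module_zero_grad(m$graph)
  lb <- training_step(m, x, truths, cfg)
  expect_true(all(is.finite(unlist(lb[c("box", "cls", "dfl", "total")]))))
  expect_gt(lb$n_pos, 0)
  expect_equal(lb$total,
               cfg$box_weight * lb$box + cfg$cls_weight * lb$cls +
                 cfg$dfl_weight * lb$dfl)
  # doubling the box weight doubles its weighted contribution only
  cfg2 <- cfg; cfg2$box_weight <- 2 * cfg$box_weight
  module_zero_grad(m$graph)
  lb2 <- training_step(m, x, truths, cfg2)
  expect_equal(lb2$box, lb$box, tolerance = 1e-12)
  expect_equal(lb2$total - lb$total, cfg$box_weight * lb$box, tolerance = 1e-9)
  # empty image: classification-only loss, box and dfl terms zero
  module_zero_grad(m$graph)
  lb0 <- training_step(m, x[, , , 1, drop = FALSE],
                       list(truths[[1]][0, ]), cfg)
  expect_equal(lb0$box, 0); expect_equal(lb0$dfl, 0)
  expect_gt(lb0$cls, 0)
})

test_that("a full training step backpropagates correct gradients (finite differences)", {
  set.seed(62)
  m <- build_model(variant_config("full", num_classes = 6, input_size = 64,
                                  width_multiple = 0.125))
  sc <- render_scene(1, img_size = 64, seed = 4242)
  x <- array(sc$image, c(64, 64, 3, 1))
  truths <- list(mlyolo:::labels_to_pixels(sc$labels, c(64, 64)))
  cfg <- train_config(input_size = 64, batch_size = 1, epochs = 1, seed = 62)
  module_zero_grad(m$graph)
  lb <- training_step(m, x, truths, cfg)
  mods <- mlyolo:::module_collect(m$graph)
  eps <- 1e-4
  # probe a few parameters spread over the network, including an MSConv
  # branch and an LSKA kernel
  probe <- list()
  for (p in names(mods)) {
    mm <- mods[[p]]
    if (is.null(mm$gr$w)) next
    if (mm$kind == "conv2d") probe[[p]] <- mm
  }
  sel <- probe[round(seq(1, length(probe), length.out = 5))]
  for (mm in sel) {
    # gradients accumulate across steps, so re-zero before reading
    module_zero_grad(m$graph)
    training_step(m, x, truths, cfg)
    i <- which.max(abs(mm$gr$w))
    g_analytic <- mm$gr$w[i]
    w0 <- mm$par$w[i]
    mm$par$w[i] <- w0 + eps
    lp <- training_step(m, x, truths, cfg)$total
    mm$par$w[i] <- w0 - eps
    lm <- training_step(m, x, truths, cfg)$total
    mm$par$w[i] <- w0
    g_num <- (lp - lm) / (2 * eps)
    # end-to-end through ~60 layers: finite differences accumulate
    # truncation error, so this check is looser than the per-block ones
    expect_equal(g_analytic, g_num, tolerance = 1e-2)
  }
})

test_that("all four ablation variants run a training step without error", {
  set.seed(63)
  sc <- render_scene(3, img_size = 64, seed = 777)
  x <- array(sc$image, c(64, 64, 3, 1))
  truths <- list(mlyolo:::labels_to_pixels(sc$labels, c(64, 64)))
  cfg <- train_config(input_size = 64, batch_size = 1, epochs = 1)
  for (v in c("baseline", "msconv", "msconv+lska", "full")) {
    m <- build_model(variant_config(v, num_classes = 6, input_size = 64,
                                    width_multiple = 0.125))
    module_zero_grad(m$graph)
    lb <- training_step(m, x, truths, cfg)
    expect_true(is.finite(lb$total))
  }
})

test_that("identical seeds give identical histories; checkpoint resume is deterministic", {
  dat <- make_tiny_dataset(1, 9000, img_size = 64)
  cfg <- train_config(input_size = 64, batch_size = 3, epochs = 2, seed = 5)
  run <- function() {
    m <- build_model(variant_config("full", num_classes = 6, input_size = 64,
                                    width_multiple = 0.125))
    suppressMessages(fit(m, list(train = dat), cfg))
  }
  set.seed(99); h1 <- run()$history
  set.seed(99); h2 <- run()$history
  expect_identical(h1, h2)
  # resuming from a checkpoint reproduces the next epoch's losses bit-exactly
  set.seed(99)
  m <- build_model(variant_config("full", num_classes = 6, input_size = 64,
                                  width_multiple = 0.125))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  r1 <- suppressMessages(fit(load_checkpoint(ck), list(train = dat), cfg))
  r2 <- suppressMessages(fit(load_checkpoint(ck), list(train = dat), cfg))
  expect_identical(r1$history, r2$history)
  unlink(ck)
})

test_that("config validation fails before training begins", {
  dat <- make_tiny_dataset(1, 9500, img_size = 64)
  m <- build_model(variant_config("full", num_classes = 6, input_size = 96,
                                  width_multiple = 0.125), init = "zeros")
  expect_error(fit(m, list(train = dat), train_config(input_size = 96)),
               "input_size")
  expect_error(fit(m, list(train = list(images = list(), labels = list())),
                   train_config()), "empty training split")
  expect_error(train_config(lr = -1))
})
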