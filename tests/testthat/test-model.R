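# Architecture family: padding rule, shape inference, parameter counts,
# initialization, and engine correctness (conv paths, gradients,
# determinism, equivariance).

test_that("alignment padding follows (k - k_min) / 2 per axis", {
  ks <- list(kernel_spec(3, 3, 6), kernel_spec(5, 3, 6),
             kernel_spec(7, 3, 6))
  pad <- compute_padding(ks)
  expect_equal(pad[, "temporal"], c(0L, 1L, 2L))
  expect_equal(pad[, "frequency"], c(0L, 0L, 0L))
  expect_equal(pad[, "spatial"], c(0L, 0L, 0L))
  # single branch gets zero padding
  expect_equal(as.integer(compute_padding(list(kernel_spec(5, 5)))),
               c(0L, 0L, 0L))
  # {3, 9} -> {0, 3}, and the aligned output length checks out
  pad2 <- compute_padding(list(kernel_spec(3, 1), kernel_spec(9, 1)))
  expect_equal(pad2[, "temporal"], c(0L, 3L))
  L <- 20
  out <- c(L + 2 * 0 - 3 + 1, L + 2 * 3 - 9 + 1)
  expect_equal(out[1], out[2])
  # parity mismatch is an error
  expect_error(compute_padding(list(kernel_spec(3, 1), kernel_spec(4, 1))),
               "parity")
})

test_that("shape inference rejects infeasible stacks with a module name", {
  expect_error(
    network_spec("2d", list(
      module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 8, 8),
                  reduce = FALSE),
      module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 8, 8),
                  reduce = FALSE),
      module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 8, 8),
                  reduce = FALSE)), input_dim = c(1, 1, 40, 40)),
    "pooling exhausts")
  expect_error(network_spec("2d", list()), "3-5")
})

test_that("closed-form parameter count matches the built network", {
  for (nm in c("1d_simple", "2d_ms_length", "3d_ms_length")) {
    spec <- table1_specs(width = 1 / 12)[[nm]]
    net <- build_network(spec, seed = 2)
    expect_equal(erpauth:::count_network_parameters(net),
                 count_parameters(spec), info = nm)
  }
  # adding a branch strictly increases the count
  g2 <- grid_spec(2, 3, width = 1 / 12)
  g3 <- grid_spec(3, 3, width = 1 / 12)
  expect_gt(count_parameters(g3), count_parameters(g2))
})

test_that("kaiming-uniform init respects its bound and variance", {
  spec <- fixture_spec_small()
  net1 <- build_network(spec, seed = 11)
  net2 <- build_network(spec, seed = 11)
  expect_identical(net1$params, net2$params)
  net3 <- build_network(spec, seed = 12)
  expect_false(identical(net1$params, net3$params))
  # per-branch bound: |w| <= sqrt(6 / fan_in) on the nonzero block
  w <- net1$params$m2_branch_w  # union 5x5, branch 1 kernel 3x3, cin = 2
  fan_in_b1 <- 2 * 3 * 3
  b1 <- w[1:2, , , 2:4, 2:4]
  expect_lte(max(abs(b1)), sqrt(6 / fan_in_b1))
  # large-fan-in empirical variance ~ 2 / fan_in within 10%
  big <- with_seed_test(99, erpauth:::kaiming_uniform(c(8, 2000)))
  expect_lt(abs(stats::var(as.numeric(big)) - 2 / 2000) / (2 / 2000), 0.1)
})

test_that("float im2col and double offset conv paths agree", {
  set.seed(3)
  x <- array(rnorm(2 * 6 * 12 * 10 * 2), c(2, 6, 12, 10, 2))
  w <- array(rnorm(4 * 2 * 3 * 3 * 3), c(4, 2, 3, 3, 3))
  pad <- c(1L, 1L, 0L)
  y1 <- erpauth:::conv3d_fwd_cpp(x, dim(x), w, dim(w), pad, 1L)
  y2 <- erpauth:::conv3d_fwd_cpp(x, dim(x), w, dim(w), pad, 2L)
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-5)
  r <- array(rnorm(length(y1)), dim(y1))
  b1 <- erpauth:::conv3d_bwd_cpp(x, dim(x), w, dim(w), r, pad, TRUE, 1L)
  b2 <- erpauth:::conv3d_bwd_cpp(x, dim(x), w, dim(w), r, pad, TRUE, 2L)
  expect_lt(max(abs(b1$dw - b2$dw)) / max(abs(b2$dw)), 1e-5)
  expect_lt(max(abs(b1$dx - b2$dx)) / max(abs(b2$dx)), 1e-5)
})

test_that("conv gradients match finite differences (double path)", {
  set.seed(4)
  x <- array(rnorm(1 * 4 * 8 * 8 * 2), c(1, 4, 8, 8, 2))
  w <- array(rnorm(3 * 1 * 2 * 3 * 3), c(3, 1, 2, 3, 3))
  pad <- c(0L, 1L, 1L)
  y <- erpauth:::conv3d_fwd_cpp(x, dim(x), w, dim(w), pad, 2L)
  r <- array(rnorm(length(y)), dim(y))
  bw <- erpauth:::conv3d_bwd_cpp(x, dim(x), w, dim(w), r, pad, TRUE, 2L)
  fd <- function(arr, idx, eps) {
    a <- arr; a[matrix(idx, 1)] <- a[matrix(idx, 1)] + eps; a
  }
  loss <- function(xx, ww) {
    sum(r * erpauth:::conv3d_fwd_cpp(xx, dim(xx), ww, dim(ww), pad, 2L))
  }
  for (rep in 1:5) {
    iw <- sapply(dim(w), function(k) sample(k, 1))
    gn <- (loss(x, fd(w, iw, 1e-6)) - loss(x, fd(w, iw, -1e-6))) / 2e-6
    expect_equal(bw$dw[matrix(iw, 1)], gn, tolerance = 1e-6)
    ix <- sapply(dim(x), function(k) sample(k, 1))
    gn <- (loss(fd(x, ix, 1e-6), w) - loss(fd(x, ix, -1e-6), w)) / 2e-6
    expect_equal(bw$dx[matrix(ix, 1)], gn, tolerance = 1e-6)
  }
})

test_that("whole-network gradients match scalar finite differences", {
  set.seed(5)
  spec <- network_spec("2d", list(
    module_spec(list(kernel_spec(3, 3), kernel_spec(5, 5)), 2,
                pool = c(1, 2, 2)),
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 2, 2)),
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 2, 2))),
    dropout = 0, input_dim = c(1, 1, 30, 30))
  net <- build_network(spec, 6)
  x <- array(rnorm(30 * 30 * 4), c(1, 1, 30, 30, 4))
  y <- c(0L, 1L, 1L, 0L)
  fw <- erpauth:::forward_network(net, x, training = TRUE)
  bw <- erpauth:::backward_network(net, fw, y)
  lossf <- function(n2) {
    f <- erpauth:::forward_network(n2, x, training = TRUE)
    -mean(log(pmax(f$probs[cbind(y + 1L, seq_along(y))], 1e-12)))
  }
  masks <- list()
  for (pm in net$plan) {
    if (!is.null(pm$mask)) masks[[paste0(pm$branch_name, "_w")]] <- pm$mask
  }
  rels <- c()
  for (nm in names(net$params)) {
    pv <- net$params[[nm]]
    for (rep in 1:2) {
      ii <- sample(length(pv), 1)
      if (!is.null(masks[[nm]]) && masks[[nm]][ii] == 0) next
      ga <- bw$grads[[nm]][ii]
      if (abs(ga) < 0.03) next  # below float-path FD noise floor
      eps <- 3e-4
      n2 <- net
      n2$params[[nm]][ii] <- pv[ii] + eps
      lp <- lossf(n2)
      n2$params[[nm]][ii] <- pv[ii] - eps
      lm <- lossf(n2)
      gn <- (lp - lm) / (2 * eps)
      rels <- c(rels, abs(gn - ga) / (abs(gn) + abs(ga)))
    }
  }
  # agreement in aggregate; individual probes carry float-FD noise and
  # occasional pool-switch kinks
  expect_gt(length(rels), 5)
  expect_lt(stats::median(rels), 0.05)
  expect_lt(mean(rels), 0.15)
  # masked entries always carry zero gradient
  expect_true(all(bw$grads[["m1_branch_w"]][masks[["m1_branch_w"]] == 0]
                  == 0))
})

test_that("softmax output is a probability over two classes", {
  spec <- fixture_spec_small()
  net <- build_network(spec, 3)
  x <- array(rnorm(1 * 1 * 94 * 60 * 3), c(1, 1, 94, 60, 3))
  probs <- erpauth:::predict_network(net, x)
  expect_equal(colSums(probs), rep(1, 3), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("time translation translates pre-head features equally", {
  # no pooling, no padding -> conv stack is translation-equivariant
  spec <- network_spec("2d", list(
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 1, 1),
                reduce = FALSE),
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 1, 1),
                reduce = FALSE),
    module_spec(list(kernel_spec(3, 3)), 2, pool = c(1, 1, 1),
                reduce = FALSE)), dropout = 0, input_dim = c(1, 1, 40, 20))
  net <- build_network(spec, 8)
  set.seed(9)
  base <- array(0, c(1, 1, 40, 20, 1))
  patch <- array(rnorm(10 * 20), c(10, 20))
  base[1, 1, 11:20, , 1] <- patch
  shifted <- array(0, c(1, 1, 40, 20, 1))
  shifted[1, 1, 16:25, , 1] <- patch
  f1 <- erpauth:::forward_network(net, base)
  f2 <- erpauth:::forward_network(net, shifted)
  a1 <- f1$caches[[3]]$branch$act
  a2 <- f2$caches[[3]]$branch$act
  # interior region: feature maps shifted by 5 pixels along time
  expect_equal(a2[, , 16:20, , 1], a1[, , 11:15, , 1], tolerance = 1e-6)
})

test_that("all ten reference architectures pass shape inference", {
  specs <- table1_specs()
  expect_length(specs, 10)
  flat <- vapply(specs, function(s) s$shapes$flatten, 0)
  expect_equal(unname(flat[c("2d_ms_width", "3d_ms_length")]),
               c(4 * 2 * 216, 1 * 4 * 2 * 216))
  expect_true(all(vapply(specs, count_parameters, 0L) > 0))
})
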