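# Declarative network specifications for the single- and multi-scale
# convolution family. A kernel is (spatial, temporal, frequency) pixels;
# modules are 1x1 reduction + parallel branches + batch-norm + leaky-ReLU
# + channel concatenation + max-pool; networks stack 3-5 modules ahead of
# a dropout/linear/softmax head.

#' Declare a convolution kernel
#'
#' @param temporal,frequency kernel size in time/frequency pixels.
#' @param spatial kernel size along the channel (spatial) axis; fixed at 6
#'   for 3D kernels in the reference family, 1 otherwise.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(temporal, frequency = 1, spatial = 1) {
  k <- c(spatial = spatial, temporal = temporal, frequency = frequency)
  if (any(k < 1)) stop("kernel sizes must be >= 1", call. = FALSE)
  structure(as.list(k), class = "kernel_spec")
}

#' @export
format.kernel_spec <- function(x, ...) {
  sprintf("%d x %d x %d", x$spatial, x$temporal, x$frequency)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("kernel (spatial x temporal x frequency):", format(x), "\n")
  invisible(x)
}

as_kdim <- function(kernel, form) {
  switch(form,
    "3d" = c(kernel$spatial, kernel$temporal, kernel$frequency),
    "2d" = {
      if (kernel$spatial != 1) {
        stop("2d kernels must have spatial size 1", call. = FALSE)
      }
      c(1L, kernel$temporal, kernel$frequency)
    },
    "1d" = {
      if (kernel$frequency != 1) {
        stop("1d kernels must have frequency size 1", call. = FALSE)
      }
      c(kernel$spatial, kernel$temporal, 1L)
    })
}

#' Alignment-preserving paddings for a set of branch kernels
#'
#' Per axis, each branch is padded by `(k - k_min) / 2`, where `k_min` is
#' the smallest kernel on that axis in the module; all branch outputs then
#' share the same spatial dimensions (`L - k_min + 1`). An odd size
#' difference (parity mismatch) cannot be equalized and raises an error.
#'
#' @param kernels list of [kernel_spec()].
#' @return Integer matrix `branches x 3` of per-axis paddings
#'   (spatial, temporal, frequency).
#' @export
compute_padding <- function(kernels) {
  ks <- t(vapply(kernels, function(k) {
    c(k$spatial, k$temporal, k$frequency)
  }, numeric(3)))
  kmin <- apply(ks, 2, min)
  diffs <- sweep(ks, 2, kmin)
  if (any(diffs %% 2 != 0)) {
    stop("kernel parity mismatch: branch sizes must differ by even ",
         "amounts for output alignment", call. = FALSE)
  }
  pad <- diffs / 2
  dimnames(pad) <- list(NULL, c("spatial", "temporal", "frequency"))
  storage.mode(pad) <- "integer"
  pad
}

#' Declare one multi-scale convolution module
#'
#' @param kernels list of [kernel_spec()], one per branch (1-6 branches).
#' @param out_channels feature channels per branch.
#' @param pool max-pool window `c(spatial, temporal, frequency)`
#'   (1 = no pooling on that axis).
#' @param reduce if `TRUE`, a 1x1 input convolution with `out_channels`
#'   outputs precedes the branches (the multi-scale variants); single-scale
#'   serial variants omit it.
#' @param padding optional explicit `branches x 3` padding matrix;
#'   defaults to [compute_padding()].
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(kernels, out_channels, pool = c(1, 2, 2),
                        reduce = TRUE, padding = NULL) {
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  if (length(kernels) < 1) stop("need at least one branch", call. = FALSE)
  if (any(pool < 1)) stop("pool sizes must be >= 1", call. = FALSE)
  if (is.null(padding)) padding <- compute_padding(kernels)
  structure(list(kernels = kernels, out_channels = as.integer(out_channels),
                 pool = as.integer(pool), reduce = isTRUE(reduce),
                 padding = padding),
            class = "module_spec")
}

#' Declare a network of the authentication family
#'
#' A network is 3-5 stacked modules over a 1D/2D/3D input form, followed
#' by the head: dropout(`dropout`) - linear(flatten -> `hidden`) -
#' leaky-ReLU - dropout - linear(`hidden` -> 2) - softmax. Shape inference
#' runs at declaration time and an infeasible stack (a pooled-away axis)
#' raises an error naming the offending module.
#'
#' @param input_form `"1d"`, `"2d"` or `"3d"`.
#' @param modules list of [module_spec()] (depth 3-5).
#' @param hidden hidden width of the first linear layer (default 32).
#' @param dropout dropout probability in the head (default 0.4).
#' @param leaky_slope negative slope of the leaky-ReLU (default 0.01).
#' @param input_dim input volume `(channels, depth, height, width)`;
#'   defaults to the canonical tensor (1, 16, 94, 60) arranged for the
#'   form.
#' @return An object of class `network_spec` with inferred `shapes`.
#' @export
network_spec <- function(input_form = c("3d", "2d", "1d"), modules,
                         hidden = 32, dropout = 0.4, leaky_slope = 0.01,
                         input_dim = NULL) {
  input_form <- match.arg(input_form)
  if (length(modules) < 3 || length(modules) > 5) {
    stop("module depth must be within 3-5", call. = FALSE)
  }
  nb <- vapply(modules, function(m) length(m$kernels), 0L)
  if (any(nb < 1 | nb > 6)) {
    stop("branch count must be within 1-6", call. = FALSE)
  }
  if (is.null(input_dim)) {
    input_dim <- switch(input_form,
      "3d" = c(1L, 16L, 94L, 60L),
      "2d" = c(1L, 1L, 94L, 60L),
      "1d" = c(1L, 16L, 94L, 1L))
  }
  spec <- structure(list(input_form = input_form, modules = modules,
                         hidden = as.integer(hidden), dropout = dropout,
                         leaky_slope = leaky_slope,
                         input_dim = as.integer(input_dim)),
                    class = "network_spec")
  spec$shapes <- infer_network_shapes(spec)
  spec
}

# Shape inference: walks the module stack and returns per-module conv and
# pool output dims plus the flatten size. Errors name the offending module.
infer_network_shapes <- function(spec) {
  dims <- spec$input_dim[2:4]
  ch <- spec$input_dim[1]
  out <- vector("list", length(spec$modules))
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    mod_name <- paste0("module ", letters[mi])
    branch_dims <- NULL
    for (bi in seq_along(m$kernels)) {
      kd <- as_kdim(m$kernels[[bi]], spec$input_form)
      pad <- m$padding[bi, ]
      od <- dims + 2 * pad - kd + 1
      if (any(od < 1)) {
        stop(sprintf(
          "%s branch %d: kernel (%s) exceeds its input volume (%s)",
          mod_name, bi, paste(kd, collapse = "x"),
          paste(dims, collapse = "x")), call. = FALSE)
      }
      if (is.null(branch_dims)) {
        branch_dims <- od
      } else if (!all(branch_dims == od)) {
        stop(mod_name, ": branch output dims are not aligned", call. = FALSE)
      }
    }
    pooled <- branch_dims %/% m$pool
    if (any(pooled < 1)) {
      stop(mod_name, ": pooling exhausts an axis (conv output ",
           paste(branch_dims, collapse = "x"), ", pool ",
           paste(m$pool, collapse = "x"), ")", call. = FALSE)
    }
    ch <- length(m$kernels) * m$out_channels
    out[[mi]] <- list(conv = branch_dims, pool = pooled, channels = ch)
    dims <- pooled
  }
  list(modules = out, flatten = ch * prod(dims))
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %s input (%s), %d modules\n", x$input_form,
              paste(x$input_dim, collapse = " x "), length(x$modules)))
  for (mi in seq_along(x$modules)) {
    m <- x$modules[[mi]]
    sh <- x$shapes$modules[[mi]]
    cat(sprintf("  module %s: %d branch(es) [%s] x%d%s, pool %s -> %s x %s\n",
                letters[mi], length(m$kernels),
                paste(vapply(m$kernels, format, ""), collapse = "; "),
                m$out_channels, if (m$reduce) " (+1x1 reduce)" else "",
                paste(m$pool, collapse = "x"), sh$channels,
                paste(sh$pool, collapse = "x")))
  }
  cat(sprintf("  head: flatten %d -> dropout %.1f -> %d -> 2 (softmax)\n",
              x$shapes$flatten, x$dropout, x$hidden))
  cat(sprintf("  parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Trainable parameter count of a network specification
#'
#' Closed-form count: convolutions carry `out * in * prod(kernel)` weights
#' (no conv bias; each conv is followed by batch-norm, which contributes a
#' gain and a shift per channel), linear layers carry weights plus bias.
#'
#' @param spec a [network_spec()].
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- spec$input_dim[1]
  total <- 0
  for (m in spec$modules) {
    cin <- ch
    if (m$reduce) {
      total <- total + m$out_channels * cin + 2 * m$out_channels
      cin <- m$out_channels
    }
    for (k in m$kernels) {
      kd <- as_kdim(k, spec$input_form)
      total <- total + m$out_channels * cin * prod(kd) + 2 * m$out_channels
    }
    ch <- length(m$kernels) * m$out_channels
  }
  flat <- spec$shapes$flatten
  total <- total + (flat * spec$hidden + spec$hidden) +
    (spec$hidden * 2 + 2)
  as.integer(total)
}

# widths helper: reference widths 24 (module a) / 72 (b..) scaled for
# desk-size experiments
family_widths <- function(depth, width = 1) {
  w <- c(24, rep(72, depth - 1))
  pmax(1L, as.integer(round(w * width)))
}

#' The ten reference architectures
#'
#' Builds the shipped network family: three single-scale serial networks
#' (1D/2D/3D) and seven multi-scale variants (long / wide / equal kernel
#' strategies in 1D/2D/3D; the 1D form admits only the long strategy).
#' Multi-scale modules use three branches, widths 24/72/72, pools
#' 2-2-5 on the varying axes; single-scale variants have one branch, no
#' 1x1 reduction, and their published per-module kernels.
#'
#' @param width width multiplier applied to all channel counts (1 = the
#'   reference widths; smaller values give desk-scale networks for
#'   experimentation).
#' @return Named list of [network_spec()] objects.
#' @export
table1_specs <- function(width = 1) {
  w <- family_widths(3, width)
  ms3 <- function(form, kernels, pools) {
    network_spec(form, lapply(1:3, function(mi) {
      module_spec(kernels, w[mi], pools[[mi]], reduce = TRUE)
    }))
  }
  k3 <- function(t, f) kernel_spec(t, f, spatial = 6)
  k2 <- function(t, f) kernel_spec(t, f, spatial = 1)
  k1 <- function(t) kernel_spec(t, 1, spatial = 1)
  pool3 <- list(c(1, 2, 2), c(1, 2, 2), c(1, 5, 5))
  pool1 <- list(c(1, 2, 1), c(1, 2, 1), c(1, 5, 1))

  specs <- list(
    "1d_simple" = network_spec("1d", lapply(1:3, function(mi) {
      module_spec(list(k1(7)), w[mi],
                  if (mi < 3) c(1, 2, 1) else c(1, 6, 1), reduce = FALSE)
    })),
    "2d_simple" = network_spec("2d", {
      ks <- list(k2(9, 7), k2(12, 8), k2(6, 4))
      pools <- list(c(1, 2, 2), c(1, 4, 4), c(1, 2, 2))
      lapply(1:3, function(mi) {
        module_spec(list(ks[[mi]]), w[mi], pools[[mi]], reduce = FALSE)
      })
    }),
    "3d_simple" = network_spec("3d", {
      ks <- list(kernel_spec(9, 7, spatial = 5),
                 kernel_spec(12, 8, spatial = 7),
                 kernel_spec(6, 4, spatial = 6))
      pools <- list(c(1, 2, 2), c(1, 4, 4), c(1, 1, 1))
      lapply(1:3, function(mi) {
        module_spec(list(ks[[mi]]), w[mi], pools[[mi]], reduce = FALSE)
      })
    }),
    "1d_ms_length" = network_spec("1d", lapply(1:3, function(mi) {
      module_spec(list(k1(7), k1(5), k1(3)), w[mi], pool1[[mi]],
                  reduce = TRUE)
    })),
    "2d_ms_width" = ms3("2d", list(k2(3, 7), k2(3, 5), k2(3, 3)), pool3),
    "2d_ms_equal" = ms3("2d", list(k2(7, 7), k2(5, 5), k2(3, 3)), pool3),
    "2d_ms_length" = ms3("2d", list(k2(7, 3), k2(5, 3), k2(3, 3)), pool3),
    "3d_ms_width" = ms3("3d", list(k3(3, 7), k3(3, 5), k3(3, 3)), pool3),
    "3d_ms_equal" = ms3("3d", list(k3(7, 7), k3(5, 5), k3(3, 3)), pool3),
    "3d_ms_length" = ms3("3d", list(k3(7, 3), k3(5, 3), k3(3, 3)), pool3))
  specs
}

#' Single-scale serial network for a kernel sweep
#'
#' Three serial modules sharing one time x frequency kernel (3D kernels
#' use the fixed spatial depth 6, which walks the 16-channel axis down
#' 16 -> 11 -> 6 -> 1). The first two modules pool 2 x 2 in
#' time/frequency and the last pools 5 x 5 (clamped to the remaining
#' axis), mirroring the 2-2-5 schedule of the reference family.
#'
#' @param temporal,frequency kernel size in pixels.
#' @param form input form (`"3d"` or `"2d"`).
#' @param width width multiplier (see [table1_specs()]).
#' @return A [network_spec()].
#' @export
single_scale_spec <- function(temporal, frequency, form = "3d", width = 1) {
  w <- family_widths(3, width)
  dims <- switch(form, "3d" = c(16, 94, 60), "2d" = c(1, 94, 60))
  modules <- vector("list", 3)
  for (mi in 1:3) {
    kd <- c(if (form == "3d") 6 else 1, temporal, frequency)
    conv <- dims - kd + 1
    if (any(conv < 1)) {
      stop("kernel too large for a 3-module serial stack", call. = FALSE)
    }
    pool <- if (mi < 3) pmin(c(1, 2, 2), conv) else pmin(c(1, 5, 5), conv)
    modules[[mi]] <- module_spec(
      list(kernel_spec(temporal, frequency, spatial = kd[1])),
      w[mi], pool, reduce = FALSE)
    dims <- conv %/% pool
  }
  network_spec(form, modules)
}

#' Multi-branch, multi-layer network for the breadth/depth grid
#'
#' Long-strategy branch kernels (temporal sizes 3, 5, 7, ... with
#' frequency size 3), centered ("same") padding on the time/frequency
#' axes so depth is controlled by the 2 x 2 pooling alone. The spatial
#' axis uses depth-6 kernels for the first three modules (16 -> 11 -> 6
#' -> 1) and size-1 kernels after that.
#'
#' @param branches number of parallel branches (2-6).
#' @param layers module depth (3-5).
#' @param width width multiplier.
#' @param form input form (`"3d"` or `"2d"`).
#' @return A [network_spec()].
#' @export
grid_spec <- function(branches, layers, width = 1, form = "3d") {
  stopifnot(branches >= 1, branches <= 6, layers >= 3, layers <= 5)
  w <- family_widths(layers, width)
  tsizes <- seq(3, by = 2, length.out = branches)
  modules <- lapply(seq_len(layers), function(mi) {
    sp <- if (form == "3d" && mi <= 3) 6 else 1
    kernels <- lapply(tsizes, function(t) kernel_spec(t, 3, spatial = sp))
    pad <- cbind(spatial = 0L, temporal = as.integer((tsizes - 1) / 2),
                 frequency = 1L)
    module_spec(kernels, w[mi], pool = c(1, 2, 2), reduce = TRUE,
                padding = pad)
  })
  network_spec(form, modules)
}
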