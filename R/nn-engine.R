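# Network engine: builds an executable network from a network_spec and
# implements forward, backward, Adam updates and batch-norm statistics.
# Activation arrays are (channels, depth, height, width, batch); the
# GEMM-heavy convolution and pooling primitives live in src/conv_ops.cpp.
#
# Execution schedule: a module's parallel branches are run as ONE
# convolution at the union kernel size with structured-sparse weights.
# Under the alignment padding rule every branch kernel embeds centered in
# the union kernel, so the fused convolution followed by per-channel
# batch-norm is exactly the parallel-branch computation with the branch
# outputs already concatenated along the channel axis (channel block b =
# branch b). Masked weight entries are frozen at zero by zeroing their
# gradients before the optimizer step.

BN_EPS <- 1e-5

#' Build an executable network from a specification
#'
#' Allocates all trainable tensors and initializes convolution and linear
#' weights with the kaiming-uniform rule (uniform on +/- sqrt(6 / fan_in),
#' with each branch's fan-in computed from its own kernel size), biases at
#' zero, batch-norm gains at one. Branch alignment (equal output dims
#' before concatenation) is asserted at build time via shape inference.
#' Deterministic given `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the initialization.
#' @return An object of class `eeg_network`.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  infer_network_shapes(spec)  # asserts branch alignment and feasibility
  params <- list()
  bn <- list()
  plan <- vector("list", length(spec$modules))
  ch <- spec$input_dim[1]
  with_seed(seed, {
    for (mi in seq_along(spec$modules)) {
      m <- spec$modules[[mi]]
      cin <- ch
      pm <- list(reduce = m$reduce, pool = m$pool)
      if (m$reduce) {
        nm <- sprintf("m%d_reduce", mi)
        params[[paste0(nm, "_w")]] <-
          kaiming_uniform(c(m$out_channels, cin, 1, 1, 1))
        params[[paste0(nm, "_g")]] <- rep(1, m$out_channels)
        params[[paste0(nm, "_b")]] <- rep(0, m$out_channels)
        bn[[nm]] <- list(mean = rep(0, m$out_channels),
                         var = rep(1, m$out_channels))
        cin <- m$out_channels
        pm$reduce_name <- nm
      }
      kdims <- lapply(m$kernels, as_kdim, spec$input_form)
      union_k <- apply(do.call(rbind, kdims), 2, max)
      nb <- length(m$kernels)
      oc <- m$out_channels
      nm <- sprintf("m%d_branch", mi)
      w <- array(0, dim = c(nb * oc, cin, union_k))
      mask <- NULL
      for (bi in seq_len(nb)) {
        kd <- kdims[[bi]]
        shift <- (union_k - kd) / 2
        stopifnot(all(shift == floor(shift)))
        blk <- kaiming_uniform(c(oc, cin, kd))
        rows <- (bi - 1) * oc + seq_len(oc)
        w[rows, , shift[1] + seq_len(kd[1]), shift[2] + seq_len(kd[2]),
          shift[3] + seq_len(kd[3])] <- blk
      }
      if (nb > 1 || any(union_k != kdims[[1]])) {
        mask <- array(0, dim = dim(w))
        for (bi in seq_len(nb)) {
          kd <- kdims[[bi]]
          shift <- (union_k - kd) / 2
          rows <- (bi - 1) * oc + seq_len(oc)
          mask[rows, , shift[1] + seq_len(kd[1]),
               shift[2] + seq_len(kd[2]), shift[3] + seq_len(kd[3])] <- 1
        }
      }
      params[[paste0(nm, "_w")]] <- w
      params[[paste0(nm, "_g")]] <- rep(1, nb * oc)
      params[[paste0(nm, "_b")]] <- rep(0, nb * oc)
      bn[[nm]] <- list(mean = rep(0, nb * oc), var = rep(1, nb * oc))
      # union padding keeps the fused output at the aligned branch dims
      pm$branch_name <- nm
      pm$pad <- as.integer(apply(m$padding, 2, max))
      pm$mask <- mask
      pm$nb <- nb
      pm$oc <- oc
      plan[[mi]] <- pm
      ch <- nb * oc
    }
    flat <- spec$shapes$flatten
    params[["head_w1"]] <- matrix(kaiming_uniform(c(spec$hidden, flat)),
                                  spec$hidden, flat)
    params[["head_b1"]] <- rep(0, spec$hidden)
    params[["head_w2"]] <- matrix(kaiming_uniform(c(2, spec$hidden)),
                                  2, spec$hidden)
    params[["head_b2"]] <- rep(0, 2)
  })
  structure(list(spec = spec, plan = plan, params = params, bn = bn,
                 init_seed = seed),
            class = "eeg_network")
}

# kaiming-uniform draw for a weight of the given dim vector; fan_in is the
# product of all non-leading dims.
kaiming_uniform <- function(dims) {
  dims <- as.integer(unlist(dims))
  fan_in <- prod(dims[-1])
  bound <- sqrt(6 / fan_in)
  w <- runif(prod(dims), -bound, bound)
  if (length(dims) > 1) dim(w) <- dims
  w
}

conv_f <- function(x, w, pad) {
  conv3d_fwd_cpp(x, dim(x), w, dim(w), as.integer(pad))
}

# Fused batch-norm + leaky-ReLU forward. Returns the activation plus the
# caches backward needs (normalized input, inverse std).
bnleaky_forward <- function(x, g, b, state, training, slope,
                            acc = NULL, name = NULL) {
  C <- dim(x)[1]
  if (training) {
    st <- bn_stats_cpp(x, C)
    mu <- st$mean
    v <- st$var
    if (!is.null(acc)) {
      m <- length(x) / C
      acc$sum[[name]] <- (acc$sum[[name]] %||% 0) + mu * m
      acc$sumsq[[name]] <- (acc$sumsq[[name]] %||% 0) + (v + mu^2) * m
      acc$n[[name]] <- (acc$n[[name]] %||% 0) + m
    }
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  r <- bnleaky_fwd_cpp(x, C, g, b, mu, invstd, slope,
                       want_cache = training)
  list(y = r$y, xhat = r$xhat, invstd = invstd)
}

leaky_f <- function(x, slope) {
  x * ((x > 0) + slope * (x <= 0))
}

# derivative factor recovered from the *output* sign (slope > 0 preserves
# sign, so no extra mask needs caching)
leaky_b <- function(dy, y, slope) {
  dy * ((y > 0) + slope * (y <= 0))
}

# --- forward ---------------------------------------------------------------

forward_network <- function(net, x, training = FALSE, acc = NULL) {
  spec <- net$spec
  p <- net$params
  caches <- vector("list", length(net$plan))
  for (mi in seq_along(net$plan)) {
    pm <- net$plan[[mi]]
    cache <- list()
    if (pm$reduce) {
      nm <- pm$reduce_name
      cache$x_in <- x
      conv <- conv_f(x, p[[paste0(nm, "_w")]], c(0, 0, 0))
      bnr <- bnleaky_forward(conv, p[[paste0(nm, "_g")]],
                             p[[paste0(nm, "_b")]], net$bn[[nm]],
                             training, spec$leaky_slope, acc, nm)
      x <- bnr$y
      cache$reduce <- list(xhat = bnr$xhat, invstd = bnr$invstd,
                           act = bnr$y, in_dim = dim(conv))
    } else {
      cache$x_in <- x
    }
    nm <- pm$branch_name
    cache$branch_in <- x
    conv <- conv_f(x, p[[paste0(nm, "_w")]], pm$pad)
    bnb <- bnleaky_forward(conv, p[[paste0(nm, "_g")]],
                           p[[paste0(nm, "_b")]], net$bn[[nm]],
                           training, spec$leaky_slope, acc, nm)
    cache$branch <- list(xhat = bnb$xhat, invstd = bnb$invstd,
                         act = bnb$y, out_dim = dim(conv))
    pl <- maxpool3d_fwd_cpp(bnb$y, dim(conv), pm$pool)
    cache$pool_idx <- pl$idx
    cache$concat_dim <- dim(conv)
    x <- pl$y
    caches[[mi]] <- cache
  }
  n <- dim(x)[5]
  flat <- matrix(x, ncol = n)
  hc <- list(flat = flat)
  h <- flat
  if (training && spec$dropout > 0) {
    hc$mask1 <- matrix((runif(length(h)) >= spec$dropout) /
                         (1 - spec$dropout), nrow(h), n)
    h <- h * hc$mask1
  }
  z1 <- p$head_w1 %*% h + p$head_b1
  a1 <- leaky_f(z1, spec$leaky_slope)
  hc$h_dropped <- h
  hc$a1 <- a1
  h2 <- a1
  if (training && spec$dropout > 0) {
    hc$mask2 <- matrix((runif(length(h2)) >= spec$dropout) /
                         (1 - spec$dropout), nrow(h2), n)
    h2 <- h2 * hc$mask2
  }
  hc$h2 <- h2
  z2 <- p$head_w2 %*% h2 + p$head_b2
  zs <- sweep(z2, 2, apply(z2, 2, max))
  ez <- exp(zs)
  probs <- sweep(ez, 2, colSums(ez), "/")
  list(probs = probs, caches = caches, head = hc, out_dim = dim(x))
}

# --- backward --------------------------------------------------------------

# fw: result of forward_network(training = TRUE); y01: 0/1 labels.
# Returns gradients for every parameter plus the mean cross-entropy loss.
backward_network <- function(net, fw, y01) {
  spec <- net$spec
  p <- net$params
  n <- length(y01)
  probs <- fw$probs
  idx <- cbind(y01 + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  grads <- list()
  dz2 <- probs
  dz2[idx] <- dz2[idx] - 1
  dz2 <- dz2 / n
  hc <- fw$head
  grads$head_w2 <- dz2 %*% t(hc$h2)
  grads$head_b2 <- rowSums(dz2)
  da1 <- t(p$head_w2) %*% dz2
  if (!is.null(hc$mask2)) da1 <- da1 * hc$mask2
  dz1 <- leaky_b(da1, hc$a1, spec$leaky_slope)
  grads$head_w1 <- dz1 %*% t(hc$h_dropped)
  grads$head_b1 <- rowSums(dz1)
  dflat <- t(p$head_w1) %*% dz1
  if (!is.null(hc$mask1)) dflat <- dflat * hc$mask1
  dx <- dflat
  dim(dx) <- fw$out_dim
  for (mi in rev(seq_along(net$plan))) {
    pm <- net$plan[[mi]]
    cache <- fw$caches[[mi]]
    dact <- maxpool3d_bwd_cpp(dx, cache$pool_idx, cache$concat_dim)
    nm <- pm$branch_name
    bc <- cache$branch
    bb <- bnleaky_bwd_cpp(dact, bc$act, bc$xhat, bc$out_dim[1],
                          p[[paste0(nm, "_g")]], bc$invstd,
                          spec$leaky_slope, TRUE)
    grads[[paste0(nm, "_g")]] <- bb$dgamma
    grads[[paste0(nm, "_b")]] <- bb$dbeta
    need_dx <- mi > 1 || pm$reduce
    cv <- conv3d_bwd_cpp(cache$branch_in, dim(cache$branch_in),
                         p[[paste0(nm, "_w")]],
                         dim(p[[paste0(nm, "_w")]]),
                         bb$dx, pm$pad, need_dx)
    grads[[paste0(nm, "_w")]] <- if (is.null(pm$mask)) cv$dw else
      cv$dw * pm$mask
    if (pm$reduce) {
      rnm <- pm$reduce_name
      rc <- cache$reduce
      d_in <- cv$dx
      dim(d_in) <- rc$in_dim
      bb <- bnleaky_bwd_cpp(d_in, rc$act, rc$xhat, rc$in_dim[1],
                            p[[paste0(rnm, "_g")]], rc$invstd,
                            spec$leaky_slope, TRUE)
      grads[[paste0(rnm, "_g")]] <- bb$dgamma
      grads[[paste0(rnm, "_b")]] <- bb$dbeta
      cv <- conv3d_bwd_cpp(cache$x_in, dim(cache$x_in),
                           p[[paste0(rnm, "_w")]],
                           dim(p[[paste0(rnm, "_w")]]),
                           bb$dx, c(0L, 0L, 0L), mi > 1)
      grads[[paste0(rnm, "_w")]] <- cv$dw
    }
    if (mi > 1) dx <- cv$dx
  }
  list(grads = grads, loss = loss)
}

# --- optimization ----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training control parameters
#'
#' Defaults follow the reference protocol: learning rate 5e-4, 5 epochs,
#' batch size 50, Adam.
#'
#' @param learning_rate Adam step size.
#' @param epochs passes over the training set.
#' @param batch_size mini-batch size (capped at the sample count).
#' @param seed seed controlling shuffling, dropout and initialization.
#' @param balanced if `TRUE`, mini-batches are drawn with equal class
#'   proportions (sampling the minority class with replacement), which
#'   counters the ~1:4.5 self/non-self imbalance of the paradigm.
#' @param optimizer `"adam"` or `"sgd"`.
#' @return A list of class `train_control`.
#' @export
train_control <- function(learning_rate = 5e-4, epochs = 5, batch_size = 50,
                          seed = 1, balanced = FALSE,
                          optimizer = c("adam", "sgd")) {
  stopifnot(learning_rate >= 0, epochs > 0, batch_size > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), balanced = isTRUE(balanced),
                 optimizer = match.arg(optimizer)),
            class = "train_control")
}

slice_batch <- function(x, idx) {
  d <- dim(x)
  out <- x[, , , , idx, drop = FALSE]
  dim(out) <- c(d[1:4], length(idx))
  out
}

# Train a built network in place; returns list(net, trace).
train_network <- function(net, x, y01, control) {
  n <- dim(x)[5]
  stopifnot(length(y01) == n)
  bs <- min(control$batch_size, n)
  trace <- numeric(0)
  pos <- which(y01 == 1)
  neg <- which(y01 == 0)
  opt <- adam_init(net$params)
  with_seed(derive_seed(control$seed, 17L), {
    for (ep in seq_len(control$epochs)) {
      batches <- if (control$balanced && length(pos) && length(neg)) {
        nb <- max(1L, ceiling(n / bs))
        lapply(seq_len(nb), function(i) {
          c(sample(pos, ceiling(bs / 2), replace = TRUE),
            sample(neg, floor(bs / 2), replace = length(neg) < bs / 2))
        })
      } else {
        ord <- sample.int(n)
        split(ord, ceiling(seq_along(ord) / bs))
      }
      for (b in batches) {
        fw <- forward_network(net, slice_batch(x, b), training = TRUE)
        bw <- backward_network(net, fw, y01[b])
        if (!is.finite(bw$loss)) {
          stop(sprintf(
            "non-finite loss at iteration %d (lr = %g); aborting",
            length(trace) + 1L, control$learning_rate), call. = FALSE)
        }
        trace <- c(trace, bw$loss)
        if (control$learning_rate > 0) {
          if (control$optimizer == "adam") {
            st <- adam_step(net$params, bw$grads, opt,
                            control$learning_rate)
            net$params <- st$params
            opt <- st$state
          } else {
            for (nm in names(bw$grads)) {
              net$params[[nm]] <- net$params[[nm]] -
                control$learning_rate * bw$grads[[nm]]
            }
          }
        }
      }
    }
  })
  net <- finalize_bn(net, x, bs)
  list(net = net, trace = trace)
}

# Replace batch-norm running statistics with population statistics
# aggregated over the training set (chunked to bound memory).
finalize_bn <- function(net, x, batch_size) {
  n <- dim(x)[5]
  acc <- new.env()
  acc$sum <- list(); acc$sumsq <- list(); acc$n <- list()
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    forward_network(net, slice_batch(x, b), training = TRUE, acc = acc)
  }
  for (nm in names(net$bn)) {
    if (is.null(acc$n[[nm]])) next
    mu <- acc$sum[[nm]] / acc$n[[nm]]
    net$bn[[nm]] <- list(mean = mu,
                         var = pmax(acc$sumsq[[nm]] / acc$n[[nm]] - mu^2, 0))
  }
  net
}

# Evaluation-mode class-probability prediction, chunked over the batch.
predict_network <- function(net, x, chunk = 64L) {
  n <- dim(x)[5]
  probs <- matrix(0, 2, n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    probs[, b] <- forward_network(net, slice_batch(x, b),
                                  training = FALSE)$probs
  }
  probs
}

# Branch activation tap used by feature heat maps: returns the
# post-BN/leaky activation of one branch in one module (eval mode);
# channel block `branch` of the fused module output.
network_activations <- function(net, x, module, branch) {
  stopifnot(module >= 1, module <= length(net$plan))
  pm <- net$plan[[module]]
  stopifnot(branch >= 1, branch <= pm$nb)
  fw <- forward_network(net, x, training = FALSE)
  act <- fw$caches[[module]]$branch$act
  d <- dim(act)
  rows <- (branch - 1) * pm$oc + seq_len(pm$oc)
  out <- act[rows, , , , , drop = FALSE]
  dim(out) <- c(pm$oc, d[2:5])
  out
}

# Introspective count of trainable scalars in a built network: masked
# (structurally zero) fused-conv entries are excluded.
count_network_parameters <- function(net) {
  total <- 0
  masked <- character(0)
  for (pm in net$plan) {
    if (!is.null(pm$mask)) {
      nm <- paste0(pm$branch_name, "_w")
      total <- total + sum(pm$mask)
      masked <- c(masked, nm)
    }
  }
  for (nm in names(net$params)) {
    if (!(nm %in% masked)) total <- total + length(net$params[[nm]])
  }
  as.integer(total)
}
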