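## Reverse-mode automatic differentiation on a linear tape.
##
## Nodes are environments holding a value (an R array), an accumulated
## gradient, and a backward closure distributing the gradient to parent
## nodes. The tape is created per forward pass; operations record
## themselves in creation order, which is a valid topological order, so
## the backward sweep simply walks the tape in reverse. Constants are
## not recorded and receive no gradient.

td_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

td_record <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node$id <- n
  node
}

#' @noRd
td_node <- function(tape, value, parents = list(), back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  nd$rec <- FALSE
  class(nd) <- "td_node"
  rec <- any(vapply(parents, function(p) isTRUE(p$rec), logical(1)))
  if (rec && !is.null(back)) {
    nd$rec <- TRUE
    td_record(tape, nd)
  }
  nd
}

## A leaf with respect to which gradients are requested (a parameter).
td_leaf <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- list()
  nd$back <- NULL
  nd$rec <- TRUE
  class(nd) <- "td_node"
  td_record(tape, nd)
}

## A constant: carried along but never recorded, never differentiated.
td_const <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- list()
  nd$back <- NULL
  nd$rec <- FALSE
  class(nd) <- "td_node"
  nd
}

td_acc <- function(node, g) {
  if (!isTRUE(node$rec)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

## Backward sweep from a scalar node.
td_backward <- function(tape, node) {
  stopifnot(length(node$value) == 1L)
  node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
  invisible(NULL)
}

## ---------------------------------------------------------------------
## Elementwise operations

td_add <- function(tape, a, b) {
  td_node(tape, a$value + b$value, list(a, b), function(g) {
    td_acc(a, g); td_acc(b, g)
  })
}

td_sub <- function(tape, a, b) {
  td_node(tape, a$value - b$value, list(a, b), function(g) {
    td_acc(a, g); td_acc(b, -g)
  })
}

td_mul <- function(tape, a, b) {
  td_node(tape, a$value * b$value, list(a, b), function(g) {
    td_acc(a, g * b$value); td_acc(b, g * a$value)
  })
}

td_div <- function(tape, a, b) {
  td_node(tape, a$value / b$value, list(a, b), function(g) {
    td_acc(a, g / b$value)
    td_acc(b, -g * a$value / (b$value * b$value))
  })
}

td_smul <- function(tape, a, s) {
  td_node(tape, a$value * s, list(a), function(g) td_acc(a, g * s))
}

td_sadd <- function(tape, a, s) {
  td_node(tape, a$value + s, list(a), function(g) td_acc(a, g))
}

td_neg <- function(tape, a) td_smul(tape, a, -1)

td_exp <- function(tape, a) {
  v <- exp(a$value)
  td_node(tape, v, list(a), function(g) td_acc(a, g * v))
}

td_abs <- function(tape, a) {
  s <- sign(a$value)
  td_node(tape, abs(a$value), list(a), function(g) td_acc(a, g * s))
}

td_square <- function(tape, a) {
  td_node(tape, a$value^2, list(a), function(g) td_acc(a, 2 * g * a$value))
}

td_sqrt <- function(tape, a) {
  v <- sqrt(a$value)
  td_node(tape, v, list(a), function(g) td_acc(a, g / (2 * v)))
}

td_relu <- function(tape, a) {
  m <- a$value > 0
  td_node(tape, a$value * m, list(a), function(g) td_acc(a, g * m))
}

td_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  td_node(tape, v, list(a), function(g) td_acc(a, g * v * (1 - v)))
}

td_tanh <- function(tape, a) {
  v <- tanh(a$value)
  td_node(tape, v, list(a), function(g) td_acc(a, g * (1 - v * v)))
}

## max(x, m) with constant floor m
td_clamp_min <- function(tape, a, m) {
  keep <- a$value > m
  td_node(tape, pmax(a$value, m), list(a), function(g) td_acc(a, g * keep))
}

## ---------------------------------------------------------------------
## Reductions and broadcasts

td_mean <- function(tape, a) {
  n <- length(a$value)
  td_node(tape, mean(a$value), list(a), function(g) {
    td_acc(a, array(g / n, dim = dim(a$value) %||% length(a$value)))
  })
}

td_sum <- function(tape, a) {
  td_node(tape, sum(a$value), list(a), function(g) {
    td_acc(a, array(g, dim = dim(a$value) %||% length(a$value)))
  })
}

## mean over the channel (4th) axis of [X,Y,Z,C] -> [X,Y,Z]
td_chan_mean <- function(tape, a) {
  d <- dim(a$value)
  C <- d[4]
  v <- array(rowMeans(matrix(a$value, ncol = C)), dim = d[1:3])
  td_node(tape, v, list(a), function(g) {
    td_acc(a, array(rep(as.vector(g) / C, C), dim = d))
  })
}

## max over the channel axis of [X,Y,Z,C] -> [X,Y,Z]; subgradient to the
## first attaining channel.
td_chan_max <- function(tape, a) {
  d <- dim(a$value)
  C <- d[4]
  m <- matrix(a$value, ncol = C)
  am <- max.col(m, ties.method = "first")
  nvox <- nrow(m)
  v <- array(m[cbind(seq_len(nvox), am)], dim = d[1:3])
  td_node(tape, v, list(a), function(g) {
    gm <- matrix(0, nvox, C)
    gm[cbind(seq_len(nvox), am)] <- as.vector(g)
    td_acc(a, array(gm, dim = d))
  })
}

## x[X,Y,Z,C] / v[X,Y,Z], broadcast over channels
td_div_bc <- function(tape, a, v) {
  d <- dim(a$value)
  C <- d[4]
  vv <- as.vector(v$value)
  val <- array(as.vector(a$value) / rep(vv, C), dim = d)
  td_node(tape, val, list(a, v), function(g) {
    td_acc(a, array(as.vector(g) / rep(vv, C), dim = d))
    if (isTRUE(v$rec)) {
      gv <- -rowSums(matrix(as.vector(g) * as.vector(val) / rep(vv, C),
                            ncol = C))
      td_acc(v, array(gv, dim = d[1:3]))
    }
  })
}

## ---------------------------------------------------------------------
## Structural operations

## ensure a 4th (channel) axis
td_as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

td_concat_c <- function(tape, xs) {
  origDims <- lapply(xs, function(x) dim(x$value))
  vals <- lapply(xs, function(x) td_as4d(x$value))
  dims <- lapply(vals, dim)
  d0 <- dims[[1]][1:3]
  cs <- vapply(dims, function(d) d[4], integer(1))
  v <- array(unlist(vals, use.names = FALSE), dim = c(d0, sum(cs)))
  offs <- cumsum(c(0L, cs))
  td_node(tape, v, xs, function(g) {
    for (i in seq_along(xs)) {
      gi <- g[, , , (offs[i] + 1L):offs[i + 1L], drop = FALSE]
      dim(gi) <- origDims[[i]]
      td_acc(xs[[i]], gi)
    }
  })
}

## extract the slice x == i (1-based) from [X,Y,Z] -> [Y,Z] or from
## [X,Y,Z,C] -> [Y,Z,C]
td_slice_x <- function(tape, a, i) {
  d <- dim(a$value)
  if (length(d) == 4L) {
    v <- array(a$value[i, , , ], dim = d[2:4])
    td_node(tape, v, list(a), function(g) {
      ga <- array(0, dim = d)
      ga[i, , , ] <- g
      td_acc(a, ga)
    })
  } else {
    v <- array(a$value[i, , ], dim = d[2:3])
    td_node(tape, v, list(a), function(g) {
      ga <- array(0, dim = d)
      ga[i, , ] <- g
      td_acc(a, ga)
    })
  }
}

td_reshape <- function(tape, a, dims) {
  d0 <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  td_node(tape, v, list(a), function(g) {
    dim(g) <- d0
    td_acc(a, g)
  })
}

td_transpose <- function(tape, a) {
  td_node(tape, t(a$value), list(a), function(g) td_acc(a, t(g)))
}

## zero-pad a [X,Y,Z] volume by k voxels on each side
td_pad3 <- function(tape, a, k) {
  d <- dim(a$value)
  v <- array(0, dim = d + 2L * k)
  ix <- (k + 1L):(k + d[1]); iy <- (k + 1L):(k + d[2])
  iz <- (k + 1L):(k + d[3])
  v[ix, iy, iz] <- a$value
  td_node(tape, v, list(a), function(g) {
    td_acc(a, array(g[ix, iy, iz], dim = d))
  })
}

## crop a [X,Y,Z] or [X,Y,Z,C] array by k voxels on each spatial side
td_crop3 <- function(tape, a, k) {
  d <- dim(a$value)
  ix <- (k + 1L):(d[1] - k); iy <- (k + 1L):(d[2] - k)
  iz <- (k + 1L):(d[3] - k)
  if (length(d) == 4L) {
    v <- a$value[ix, iy, iz, , drop = FALSE]
    td_node(tape, v, list(a), function(g) {
      ga <- array(0, dim = d)
      ga[ix, iy, iz, ] <- g
      td_acc(a, ga)
    })
  } else {
    v <- a$value[ix, iy, iz, drop = FALSE]
    td_node(tape, v, list(a), function(g) {
      ga <- array(0, dim = d)
      ga[ix, iy, iz] <- g
      td_acc(a, ga)
    })
  }
}

## subset of a vector node (indices fixed)
td_slice_vec <- function(tape, a, idx) {
  td_node(tape, a$value[idx], list(a), function(g) {
    ga <- numeric(length(a$value))
    ga[idx] <- g
    td_acc(a, ga)
  })
}

td_index <- function(tape, a, i) td_slice_vec(tape, a, i)

td_concat_vec <- function(tape, xs) {
  lens <- vapply(xs, function(x) length(x$value), integer(1))
  offs <- cumsum(c(0L, lens))
  td_node(tape, unlist(lapply(xs, function(x) as.vector(x$value)),
                       use.names = FALSE),
          xs, function(g) {
    for (i in seq_along(xs)) {
      td_acc(xs[[i]], g[(offs[i] + 1L):offs[i + 1L]])
    }
  })
}

## ---------------------------------------------------------------------
## Linear algebra

## dense layer: W [out,in], x vector, b vector
td_dense <- function(tape, x, W, b) {
  v <- as.vector(W$value %*% x$value) + b$value
  td_node(tape, v, list(x, W, b), function(g) {
    td_acc(x, as.vector(crossprod(W$value, g)))
    td_acc(W, g %o% as.vector(x$value))
    td_acc(b, g)
  })
}

## plain matrix product of small matrices
td_matmul <- function(tape, a, b) {
  td_node(tape, a$value %*% b$value, list(a, b), function(g) {
    td_acc(a, g %*% t(b$value))
    td_acc(b, crossprod(a$value, g))
  })
}

## global mean over spatial axes of [X,Y,Z,C] -> vector length C
td_gap <- function(tape, a) {
  d <- dim(a$value)
  C <- d[4]
  nvox <- prod(d[1:3])
  v <- colMeans(matrix(a$value, ncol = C))
  td_node(tape, v, list(a), function(g) {
    td_acc(a, array(rep(g / nvox, each = nvox), dim = d))
  })
}

## ---------------------------------------------------------------------
## Neural-network kernels

td_conv3d <- function(tape, x, w, b, stride = c(1L, 1L, 1L)) {
  xv <- td_as4d(x$value)
  d <- dim(xv)
  wd <- dim(w$value)
  k <- wd[1]
  cin <- wd[4]; cout <- wd[5]
  ## cache the im2row matrix for the backward pass on stride-1 convs
  ## that will be differentiated (forward-only passes skip it)
  keepK <- all(stride == 1L) &&
    (isTRUE(x$rec) || isTRUE(w$rec) || isTRUE(b$rec))
  r <- cpp_conv3d(xv, w$value, b$value, d[1:3], cin, cout, k,
                  as.integer(stride), as.integer(keepK))
  v <- r$out
  Kc <- r$K
  td_node(tape, v, list(x, w, b), function(g) {
    bk <- cpp_conv3d_backward(xv, w$value, g, d[1:3], cin, cout, k,
                              as.integer(stride),
                              as.integer(isTRUE(x$rec)), Kc)
    if (isTRUE(x$rec)) {
      gx <- bk$gx
      if (is.null(dim(x$value)) || length(dim(x$value)) == 3L)
        dim(gx) <- d[1:3]
      td_acc(x, gx)
    }
    td_acc(w, bk$gw)
    td_acc(b, as.vector(bk$gb))
  })
}

td_boxfilter3 <- function(tape, a) {
  d <- dim(a$value)
  v <- cpp_boxfilter3(a$value, d)
  td_node(tape, v, list(a), function(g) {
    td_acc(a, cpp_boxfilter3(g, d))
  })
}

td_shift3d <- function(tape, a, s) {
  d <- dim(a$value)
  s <- as.integer(s)
  v <- cpp_shift3d(a$value, d, s)
  td_node(tape, v, list(a), function(g) {
    td_acc(a, cpp_shift3d(g, d, -s))
  })
}

td_upsample_nn <- function(tape, a, f) {
  d <- dim(td_as4d(a$value))
  f <- as.integer(f)
  v <- cpp_upsample_nn(td_as4d(a$value), d, f)
  td_node(tape, v, list(a), function(g) {
    ga <- cpp_upsample_nn_backward(g, dim(v), f)
    if (length(dim(a$value)) == 3L) dim(ga) <- dim(a$value)
    td_acc(a, ga)
  })
}

## Instance normalisation over spatial axes, per channel, with trainable
## gain g and bias b (vectors of length C).
td_instnorm <- function(tape, x, gain, bias, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[4]
  nvox <- prod(d[1:3])
  xm <- matrix(x$value, ncol = C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  v <- array(sweep(xhat, 2, gain$value, `*`) +
               rep(bias$value, each = nvox), dim = d)
  td_node(tape, v, list(x, gain, bias), function(g) {
    gm <- matrix(g, ncol = C)
    td_acc(gain, colSums(gm * xhat))
    td_acc(bias, colSums(gm))
    gh <- sweep(gm, 2, gain$value, `*`)
    ## standard instance/batch-norm input gradient
    t1 <- gh
    t2 <- matrix(rep(colMeans(gh), each = nvox), ncol = C)
    t3 <- xhat * matrix(rep(colMeans(gh * xhat), each = nvox), ncol = C)
    gx <- sweep(t1 - t2 - t3, 2, istd, `*`)
    td_acc(x, array(gx, dim = d))
  })
}

## ---------------------------------------------------------------------
## Rotations and differentiable rigid warping

## Elementary right-handed rotation about axis 1, 2 or 3 (3x3), from a
## scalar node; cyclic axis pairs as in rotAxis().
td_rot3 <- function(tape, angle, axis) {
  th <- angle$value
  c_ <- cos(th); s_ <- sin(th)
  ij <- switch(axis, c(2L, 3L), c(3L, 1L), c(1L, 2L))
  R <- diag(3)
  dR <- matrix(0, 3, 3)
  i <- ij[1]; j <- ij[2]
  R[i, i] <- c_;  R[i, j] <- -s_
  R[j, i] <- s_;  R[j, j] <- c_
  dR[i, i] <- -s_; dR[i, j] <- -c_
  dR[j, i] <- c_;  dR[j, j] <- -s_
  td_node(tape, R, list(angle), function(g) {
    td_acc(angle, sum(g * dR))
  })
}

## pack rotation (3x3) and translation (length-3) into a 3x4 affine
td_affine_pack <- function(tape, R, t) {
  v <- cbind(R$value, as.vector(t$value))
  td_node(tape, v, list(R, t), function(g) {
    td_acc(R, g[, 1:3, drop = FALSE])
    td_acc(t, as.vector(g[, 4]))
  })
}

## Differentiable rigid resampling of a constant volume by a node-valued
## 3x4 voxel-space sampling map (gradient flows into the map only).
td_warp <- function(tape, vol, A) {
  v <- if (inherits(vol, "td_node")) vol$value else vol
  d <- dim(v)
  out <- cpp_warp_affine(v, A$value, d, d, 0L)
  td_node(tape, out, list(A), function(g) {
    td_acc(A, cpp_warp_affine_backward(v, A$value, g, d))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------
## Adam optimiser over a flat named list of parameter arrays

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
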