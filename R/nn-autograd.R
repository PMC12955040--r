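# Minimal reverse-mode tape for the reconstruction network.
#
# Feature maps are arrays in (H, W, C) layout; nodes are environments holding
# a value, an accumulated gradient, parent links and a backward closure.
# Convolutions run as im2col matrix products through BLAS.

tg_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- FALSE
  class(e) <- "tg_node"
  e
}

#' Trainable tensor parameter
#' @param value Numeric array.
#' @return A `tg_node` marked as a parameter.
#' @keywords internal
tg_param <- function(value) {
  n <- tg_node(value)
  n$is_param <- TRUE
  n
}

tg_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# reverse-topological traversal from the loss node
tg_backward <- function(loss) {
  order <- list()
  visit <- function(n) {
    if (isTRUE(n$.seen)) return()
    n$.seen <- TRUE
    for (p in n$parents) visit(p)
    order[[length(order) + 1L]] <<- n
  }
  visit(loss)
  for (n in order) {
    n$.seen <- NULL
    n$grad <- NULL
  }
  loss$grad <- 1
  for (n in rev(order)) {
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n)
  }
  invisible(loss)
}

# ---- convolution -----------------------------------------------------------

# im2col for 'same' k x k convolution of an (H, W, C) array; returns
# (H*W, C*k*k) with offset-major, channel-minor column order. The gather is a
# single vectorised subscript with indices cached per shape.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, cc, k) {
  key <- paste(h, w, cc, k, sep = "_")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  y <- rep.int(seq_len(h), w)
  x <- rep(seq_len(w), each = h)
  base <- y + hp * (x - 1L)                       # position of (y, x, c = 1)
  j <- seq_len(cc * k * k) - 1L
  o <- j %/% cc
  cj <- j %% cc
  dy <- o %% k; dx <- o %/% k
  off <- dy + hp * dx + hp * wp * cj
  inner <- as.vector(outer(p + seq_len(h), hp * (p + seq_len(w) - 1L), "+"))
  inner <- rep.int(inner, cc) + rep(hp * wp * (seq_len(cc) - 1L), each = h * w)
  out <- list(src = rep.int(base, length(j)) + rep(off, each = h * w),
              inner = inner, hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

tg_im2col <- function(x, k) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cc <- d[3]
  if (k == 1L) {
    dim(x) <- c(h * w, cc)
    return(x)
  }
  ix <- im2col_indices(h, w, cc, k)
  xp <- numeric(ix$hp * ix$wp * cc)
  xp[ix$inner] <- x
  cols <- xp[ix$src]
  dim(cols) <- c(h * w, cc * k * k)
  cols
}

# 'same' convolution; w$value is (C_in*k*k, C_out), b$value length C_out.
# The input gradient is computed as a convolution of the output gradient with
# the spatially flipped, channel-transposed kernel (exact adjoint of the
# zero-padded 'same' convolution), which keeps backward as a gather + GEMM.
tg_conv2d <- function(x, w, b, k = 3L) {
  d <- dim(x$value)
  cc_in <- d[3]
  cols <- tg_im2col(x$value, k)
  y <- cols %*% w$value
  cc_out <- ncol(w$value)
  y <- y + rep(b$value, each = d[1] * d[2])
  dim(y) <- c(d[1], d[2], cc_out)
  out <- tg_node(y, parents = list(x, w, b))
  out$.cols <- cols
  out$backward <- function(node) {
    dy <- node$grad
    dim(dy) <- c(d[1] * d[2], cc_out)
    tg_accum(w, crossprod(node$.cols, dy))
    tg_accum(b, colSums(dy))
    wq <- array(w$value, dim = c(cc_in, k * k, cc_out))
    wf <- matrix(aperm(wq[, (k * k):1, , drop = FALSE], c(3, 2, 1)),
                 cc_out * k * k, cc_in)
    dim(dy) <- c(d[1], d[2], cc_out)
    dx <- tg_im2col(dy, k) %*% wf
    dim(dx) <- c(d[1], d[2], cc_in)
    tg_accum(x, dx)
  }
  out
}

tg_relu <- function(x) {
  y <- x$value
  y[y < 0] <- 0
  out <- tg_node(y, parents = list(x))
  out$backward <- function(node) {
    g <- node$grad
    g[x$value < 0] <- 0
    tg_accum(x, g)
  }
  out
}

tg_add <- function(a, b) {
  out <- tg_node(a$value + b$value, parents = list(a, b))
  out$backward <- function(node) {
    tg_accum(a, node$grad)
    tg_accum(b, node$grad)
  }
  out
}

tg_scale <- function(x, s) {
  out <- tg_node(x$value * s, parents = list(x))
  out$backward <- function(node) tg_accum(x, node$grad * s)
  out
}

tg_cat <- function(a, b) {
  ca <- dim(a$value)[3]
  out <- tg_node(array(c(a$value, b$value),
                       dim = dim(a$value) + c(0, 0, dim(b$value)[3])),
                 parents = list(a, b))
  out$backward <- function(node) {
    tg_accum(a, node$grad[, , seq_len(ca), drop = FALSE])
    tg_accum(b, node$grad[, , -seq_len(ca), drop = FALSE])
  }
  out
}

# 2x2 mean pooling (H, W must be even)
tg_pool2 <- function(x) {
  d <- dim(x$value)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  y <- (x$value[io, jo, , drop = FALSE] + x$value[io + 1, jo, , drop = FALSE] +
        x$value[io, jo + 1, , drop = FALSE] +
        x$value[io + 1, jo + 1, , drop = FALSE]) / 4
  out <- tg_node(y, parents = list(x))
  out$backward <- function(node) {
    g <- node$grad / 4
    dx <- array(0, dim = d)
    dx[io, jo, ] <- g; dx[io + 1, jo, ] <- g
    dx[io, jo + 1, ] <- g; dx[io + 1, jo + 1, ] <- g
    tg_accum(x, dx)
  }
  out
}

# 2x nearest-neighbour upsampling
tg_up2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2); ci <- rep(seq_len(d[2]), each = 2)
  out <- tg_node(x$value[ri, ci, , drop = FALSE], parents = list(x))
  out$backward <- function(node) {
    g <- node$grad
    io <- seq(1, 2 * d[1], 2); jo <- seq(1, 2 * d[2], 2)
    tg_accum(x, g[io, jo, , drop = FALSE] + g[io + 1, jo, , drop = FALSE] +
                g[io, jo + 1, , drop = FALSE] + g[io + 1, jo + 1, , drop = FALSE])
  }
  out
}

# linear interpolation matrix mapping n_in samples onto n_out (align-corners;
# the identity when n_out == n_in)
tg_interp_matrix <- function(n_in, n_out) {
  m <- matrix(0, n_out, n_in)
  if (n_in == 1) { m[, 1] <- 1; return(m) }
  pos <- if (n_out == 1) (n_in - 1) / 2 else
    (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  t <- pos - i0
  for (r in seq_len(n_out)) {
    m[r, i0[r] + 1] <- 1 - t[r]
    m[r, i0[r] + 2] <- m[r, i0[r] + 2] + t[r]
  }
  m
}

# bilinear resize of (H, W, C) to (h_out, w_out)
tg_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$value)
  ry <- tg_interp_matrix(d[1], h_out)
  rx <- tg_interp_matrix(d[2], w_out)
  resize <- function(v, my, mx) {
    dd <- dim(v)
    v1 <- my %*% matrix(v, dd[1], dd[2] * dd[3])       # rows
    dim(v1) <- c(nrow(my), dd[2], dd[3])
    v2 <- aperm(v1, c(2, 1, 3))
    v2 <- mx %*% matrix(v2, dd[2], nrow(my) * dd[3])   # cols
    dim(v2) <- c(nrow(mx), nrow(my), dd[3])
    aperm(v2, c(2, 1, 3))
  }
  out <- tg_node(resize(x$value, ry, rx), parents = list(x))
  out$backward <- function(node) tg_accum(x, resize(node$grad, t(ry), t(rx)))
  out
}

tg_mse <- function(x, target) {
  diffv <- x$value - target
  out <- tg_node(mean(diffv^2), parents = list(x))
  out$backward <- function(node)
    tg_accum(x, node$grad * 2 * diffv / length(diffv))
  out
}

tg_sum_scalars <- function(nodes) {
  out <- tg_node(sum(vapply(nodes, function(n) n$value, numeric(1))),
                 parents = nodes)
  out$backward <- function(node)
    for (p in nodes) tg_accum(p, node$grad)
  out
}

# ---- parameters and optimiser ---------------------------------------------

# He-style initialisation for a (fan_in, fan_out) conv weight matrix
tg_init_conv <- function(c_in, c_out, k, scale = 1) {
  fan_in <- c_in * k * k
  w <- matrix(stats::rnorm(fan_in * c_out, 0, scale * sqrt(2 / fan_in)),
              fan_in, c_out)
  list(w = tg_param(w), b = tg_param(numeric(c_out)))
}

adam_state_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim_or_len(p$value))),
       v = lapply(params, function(p) array(0, dim = dim_or_len(p$value))),
       t = 0)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

adam_step <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  state
}
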