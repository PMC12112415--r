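# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Every network in the package (frame generator/critic, plugin, video critic)
# records its forward pass as a sequence of nodes on a tape; tp_backward()
# replays the tape in reverse and accumulates gradients with respect to both
# parameters (named) and any leaf inputs. Batches are stored as base-R arrays
# in (batch, height, width, channel) order so that `matrix(x, B*H*W, C)` is a
# zero-copy-in-spirit reshape and convolutions reduce to one BLAS matmul per
# kernel offset.

tape_new <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$n <- 0L
  env
}

tp_push <- function(tp, node) {
  tp$n <- tp$n + 1L
  node$id <- tp$n
  tp$nodes[[tp$n]] <- node
  tp$n
}

tp_value <- function(tp, id) tp$nodes[[id]]$val

# Leaf input. `track` marks it as a differentiation root for input gradients.
tp_input <- function(tp, x, track = FALSE) {
  tp_push(tp, list(kind = "input", val = x, track = track))
}

# ---- dense / convolution ----------------------------------------------------

# y = x %*% (W*scale) + b ; pnames = c(W_name, b_name) or NULL when frozen
tp_linear <- function(tp, id, W, b, pnames = NULL, scale = 1) {
  x <- tp_value(tp, id)
  y <- x %*% (W * scale)
  y <- sweep(y, 2L, b, "+")
  tp_push(tp, list(kind = "linear", in1 = id, W = W, b = b, scale = scale,
                   pnames = pnames, val = y))
}

# Valid convolution with optional symmetric zero padding, computed in
# compiled code (src/conv.cpp: im2col + BLAS matrix product).
# x: (B,H,W,Cin); W: (kh,kw,Cin,Cout); stride, pad: length-2 integer.
conv2d_fw <- function(x, W, b, stride, pad, scale = 1) {
  cpp_conv2d_fw(x, if (scale == 1) W else W * scale, as.double(b),
                as.integer(stride), as.integer(pad))
}

tp_conv <- function(tp, id, W, b, stride = c(1L, 1L), pad = c(0L, 0L),
                    pnames = NULL, scale = 1) {
  x <- tp_value(tp, id)
  y <- tryCatch(conv2d_fw(x, W, b, stride, pad, scale),
                error = function(e) stop_input(conditionMessage(e)))
  tp_push(tp, list(kind = "conv", in1 = id, W = W, b = b, stride = stride,
                   pad = pad, pnames = pnames, scale = scale, val = y))
}

conv2d_bw <- function(x, W, stride, pad, dy, scale = 1, want_dx = TRUE,
                      want_dw = TRUE) {
  res <- cpp_conv2d_bw(x, if (scale == 1) W else W * scale,
                       as.integer(stride), as.integer(pad), dy,
                       isTRUE(want_dx), isTRUE(want_dw))
  list(dx = res$dx,
       dW = if (want_dw && scale != 1) res$dW * scale else res$dW,
       db = res$db)
}

# ---- elementwise / shape ops ------------------------------------------------

tp_lrelu <- function(tp, id, slope = 0.2) {
  x <- tp_value(tp, id)
  dmask <- 1 - (1 - slope) * (x < 0)   # 1 where x >= 0, slope where x < 0
  tp_push(tp, list(kind = "lrelu", in1 = id, slope = slope, dmask = dmask,
                   val = x * dmask))
}

tp_relu <- function(tp, id) tp_lrelu(tp, id, slope = 0)

tp_tanh <- function(tp, id) {
  tp_push(tp, list(kind = "tanh", in1 = id, val = tanh(tp_value(tp, id))))
}

tp_sigmoid <- function(tp, id) {
  x <- tp_value(tp, id)
  tp_push(tp, list(kind = "sigmoid", in1 = id, val = 1 / (1 + exp(-x))))
}

tp_reshape <- function(tp, id, dims) {
  x <- tp_value(tp, id)
  olddim <- dim(x) %||% length(x)
  dim(x) <- dims
  tp_push(tp, list(kind = "reshape", in1 = id, olddim = olddim, val = x))
}

# blend y = (1-alpha)*a + alpha*b (progressive-growth fade-in)
tp_blend <- function(tp, id_a, id_b, alpha) {
  a <- tp_value(tp, id_a); b <- tp_value(tp, id_b)
  tp_push(tp, list(kind = "blend", in1 = id_a, in2 = id_b, alpha = alpha,
                   val = (1 - alpha) * a + alpha * b))
}

# append constant (non-differentiated) columns to a matrix
tp_concat_const <- function(tp, id, const) {
  x <- tp_value(tp, id)
  tp_push(tp, list(kind = "concat_const", in1 = id, ncol_x = ncol(x),
                   val = cbind(x, const)))
}

# nearest-neighbour 2x upsampling on (B,H,W,C)
tp_up2 <- function(tp, id) {
  x <- tp_value(tp, id)
  d <- dim(x)
  y <- x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
         drop = FALSE]
  tp_push(tp, list(kind = "up2", in1 = id, val = y))
}

# 2x2 average-pool downsampling on (B,H,W,C)
tp_down2 <- function(tp, id) {
  x <- tp_value(tp, id)
  d <- dim(x)
  o1 <- seq(1L, d[2], by = 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[3], by = 2L); e2 <- o2 + 1L
  y <- (x[, o1, o2, , drop = FALSE] + x[, e1, o2, , drop = FALSE] +
        x[, o1, e2, , drop = FALSE] + x[, e1, e2, , drop = FALSE]) / 4
  tp_push(tp, list(kind = "down2", in1 = id, val = y))
}

# per-pixel feature-vector normalisation (ProGAN pixelnorm) over channels
tp_pixelnorm <- function(tp, id, eps = 1e-8) {
  x <- tp_value(tp, id)
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  r <- 1 / sqrt(rowMeans(xm * xm) + eps)
  y <- xm * r
  dim(y) <- d
  tp_push(tp, list(kind = "pixelnorm", in1 = id, r = r, val = y))
}

# row-wise L2 normalisation onto the unit hypersphere, with an epsilon guard
# so the all-zero row stays finite
tp_l2norm_rows <- function(tp, id, eps = 1e-8) {
  x <- tp_value(tp, id)
  rn <- sqrt(rowSums(x * x))
  m <- pmax(rn, eps)
  tp_push(tp, list(kind = "l2norm", in1 = id, m = m, guarded = rn < eps,
                   val = x / m))
}

# minibatch standard-deviation channel (ProGAN critic staple): appends one
# channel holding the mean over features of the per-feature batch std dev
tp_mbstd <- function(tp, id, eps = 1e-8) {
  x <- tp_value(tp, id)
  d <- dim(x)
  B <- d[1]
  mu <- colMeans(matrix(x, B, prod(d[2:4])))
  ctr <- x - array(rep(mu, each = B), d)
  v <- colMeans(matrix(ctr * ctr, B, prod(d[2:4])))
  sd <- sqrt(v + eps)
  s <- mean(sd)
  y <- array(0, c(B, d[2], d[3], d[4] + 1L))
  y[, , , seq_len(d[4])] <- x
  y[, , , d[4] + 1L] <- s
  tp_push(tp, list(kind = "mbstd", in1 = id, ctr = ctr, sd = sd, val = y))
}

# ---- backward pass ----------------------------------------------------------

acc_grad <- function(store, key, val) {
  cur <- store[[key]]
  store[[key]] <- if (is.null(cur)) val else cur + val
  store
}

# Backpropagate `dout` from node `out_id`. Returns:
#   $params — named list of parameter gradients (only for nodes with pnames)
#   $inputs — list keyed by leaf node id (as character) for tracked inputs
tp_backward <- function(tp, out_id, dout) {
  grads <- vector("list", tp$n)
  g_out <- dout
  vd <- dim(tp$nodes[[out_id]]$val)
  if (!is.null(vd) && is.null(dim(g_out))) dim(g_out) <- vd
  grads[[out_id]] <- g_out
  pgrads <- list()
  igrads <- list()
  for (id in seq(out_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    switch(nd$kind,
      input = {
        if (isTRUE(nd$track)) igrads[[as.character(id)]] <- g
      },
      linear = {
        x <- tp_value(tp, nd$in1)
        pin <- tp$nodes[[nd$in1]]
        want_dx <- !(pin$kind == "input" && !isTRUE(pin$track))
        if (want_dx) {
          grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + g %*% t(nd$W * nd$scale)
        }
        if (!is.null(nd$pnames)) {
          pgrads <- acc_grad(pgrads, nd$pnames[1], nd$scale * crossprod(x, g))
          pgrads <- acc_grad(pgrads, nd$pnames[2], colSums(g))
        }
      },
      conv = {
        x <- tp_value(tp, nd$in1)
        pin <- tp$nodes[[nd$in1]]
        want_dx <- !(pin$kind == "input" && !isTRUE(pin$track))
        bw <- conv2d_bw(x, nd$W, nd$stride, nd$pad, g, nd$scale,
                        want_dx = want_dx, want_dw = !is.null(nd$pnames))
        if (want_dx) grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + bw$dx
        if (!is.null(nd$pnames)) {
          pgrads <- acc_grad(pgrads, nd$pnames[1], bw$dW)
          pgrads <- acc_grad(pgrads, nd$pnames[2], bw$db)
        }
      },
      lrelu = {
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + g * nd$dmask
      },
      tanh = {
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + g * (1 - nd$val^2)
      },
      sigmoid = {
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + g * nd$val * (1 - nd$val)
      },
      reshape = {
        dim(g) <- nd$olddim
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + g
      },
      blend = {
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + (1 - nd$alpha) * g
        grads[[nd$in2]] <- (grads[[nd$in2]] %||% 0) + nd$alpha * g
      },
      concat_const = {
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) +
          g[, seq_len(nd$ncol_x), drop = FALSE]
      },
      up2 = {
        d <- dim(g)
        o1 <- seq(1L, d[2], by = 2L); o2 <- seq(1L, d[3], by = 2L)
        dx <- g[, o1, o2, , drop = FALSE] + g[, o1 + 1L, o2, , drop = FALSE] +
              g[, o1, o2 + 1L, , drop = FALSE] + g[, o1 + 1L, o2 + 1L, , drop = FALSE]
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + dx
      },
      down2 = {
        x <- tp_value(tp, nd$in1)
        d <- dim(x)
        dx <- array(0, d)
        o1 <- seq(1L, d[2], by = 2L); o2 <- seq(1L, d[3], by = 2L)
        q <- g / 4
        dx[, o1, o2, ] <- q
        dx[, o1 + 1L, o2, ] <- q
        dx[, o1, o2 + 1L, ] <- q
        dx[, o1 + 1L, o2 + 1L, ] <- q
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + dx
      },
      pixelnorm = {
        x <- tp_value(tp, nd$in1)
        d <- dim(x)
        C <- d[4]
        xm <- x; dim(xm) <- c(prod(d[1:3]), C)
        gm <- g; dim(gm) <- c(prod(d[1:3]), C)
        r <- nd$r
        dot <- rowSums(xm * gm)
        dx <- gm * r - xm * (r^3 * dot / C)
        dim(dx) <- d
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + dx
      },
      l2norm = {
        x <- tp_value(tp, nd$in1)
        m <- nd$m
        dot <- rowSums(x * g)
        dx <- g / m - x * ifelse(nd$guarded, 0, dot / m^3)
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + dx
      },
      mbstd = {
        x <- tp_value(tp, nd$in1)
        d <- dim(x)
        B <- d[1]; K <- prod(d[2:4])
        dx <- g[, , , seq_len(d[4]), drop = FALSE]
        ds <- sum(g[, , , d[4] + 1L])
        # s = mean_k sd_k, sd_k = sqrt(var_k + eps); d sd_k / d x_bk = ctr/(B*sd)
        ctrm <- nd$ctr; dim(ctrm) <- c(B, K)
        dsd <- sweep(ctrm, 2L, B * nd$sd, "/") * (ds / K)
        dim(dsd) <- d
        grads[[nd$in1]] <- (grads[[nd$in1]] %||% 0) + dx + dsd
      },
      stop("unknown tape node kind: ", nd$kind)
    )
    grads[[id]] <- NULL  # free as we go
  }
  list(params = pgrads, inputs = igrads)
}
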