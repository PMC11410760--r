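# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are (H, W, C, N) arrays, dense matrices are (D, N); every
# tensor is an environment holding its value, its accumulated gradient and a
# closure that maps the output gradient to parent gradients. A forward pass
# records nodes on a tape; ad_backward() sweeps it in reverse. Parameters
# live off-tape and persist across steps.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$k <- 0L

new_tensor <- function(val, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$val <- val
  t$grad <- NULL
  t$parents <- list()
  t$backfn <- NULL
  t$requires_grad <- requires_grad
  class(t) <- "ad_tensor"
  t
}

ad_param <- function(val) new_tensor(val, requires_grad = TRUE)

ad_const <- function(val) new_tensor(val, requires_grad = FALSE)

as_tensor <- function(x) if (inherits(x, "ad_tensor")) x else ad_const(x)

ad_reset_tape <- function() {
  .ad$tape <- vector("list", 64L)
  .ad$k <- 0L
  invisible(NULL)
}

ad_record <- function(node) {
  k <- .ad$k + 1L
  if (k > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[k]] <- node
  .ad$k <- k
  node
}

# Create an op node. backfn(g) must return a list of gradients aligned with
# `parents`; NULL entries skip accumulation.
ad_op <- function(val, parents, backfn) {
  node <- new_tensor(val)
  node$parents <- parents
  node$backfn <- backfn
  ad_record(node)
}

ad_accumulate <- function(t, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- 1.0
  for (i in seq_len(.ad$k)) {
    node <- .ad$tape[[.ad$k - i + 1L]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (inherits(p, "ad_tensor")) ad_accumulate(p, gs[[j]])
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive ops -------------------------------------------------------

op_conv2d <- function(x, w, b, pad = 1L) {
  x <- as_tensor(x)
  H <- dim(x$val)[1L]; W <- dim(x$val)[2L]
  # constant leaves (e.g. the input batch) need no input gradient
  need_gx <- x$requires_grad || !is.null(x$backfn)
  fw <- cpp_conv2d_fw(x$val, w$val, b$val, as.integer(pad), TRUE)
  y <- fw$y
  ad_op(y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bw <- cpp_conv2d_bw(fw$cols, w$val, g, as.integer(pad), H, W, need_gx)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_upconv2 <- function(x, w, b) {
  x <- as_tensor(x)
  y <- cpp_upconv2_fw(x$val, w$val, b$val)
  ad_op(y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bw <- cpp_upconv2_bw(x$val, w$val, g)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_maxpool2 <- function(x) {
  x <- as_tensor(x)
  fw <- cpp_maxpool2_fw(x$val)
  H <- dim(x$val)[1L]; W <- dim(x$val)[2L]
  ad_op(fw$y, list(x), function(g) {
    dim(g) <- dim(fw$y)
    list(cpp_maxpool2_bw(fw$idx, g, H, W))
  })
}

op_relu <- function(x) {
  x <- as_tensor(x)
  mask <- x$val > 0
  ad_op(x$val * mask, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  x <- as_tensor(x)
  s <- 1 / (1 + exp(-x$val))
  ad_op(s, list(x), function(g) list(g * s * (1 - s)))
}

op_pad_reflect <- function(x, p) {
  x <- as_tensor(x)
  H <- dim(x$val)[1L]; W <- dim(x$val)[2L]
  y <- cpp_pad_reflect_fw(x$val, as.integer(p))
  ad_op(y, list(x), function(g) {
    dim(g) <- dim(y)
    list(cpp_pad_reflect_bw(g, as.integer(p), H, W))
  })
}

# rank-1 factorization of a separable kernel (NULL when not separable)
separate_kernel <- function(kernel) {
  s <- svd(kernel)
  kcol <- s$u[, 1L] * s$d[1L]
  krow <- s$v[, 1L]
  if (max(abs(outer(kcol, krow) - kernel)) < 1e-12) list(kcol, krow) else NULL
}

# depth-wise 'valid' correlation with a fixed kernel; separable kernels
# (e.g. the Gaussian SSIM window) take the two-pass fast path
dwconv_valid <- function(xval, kernel) {
  sep <- separate_kernel(kernel)
  if (is.null(sep)) cpp_dwconv_fw(xval, kernel)
  else cpp_dwconv_sep_fw(xval, sep[[1L]], sep[[2L]])
}

# depth-wise correlation with a fixed (non-learnable) kernel, 'valid'
op_dwconv_fixed <- function(x, kernel) {
  x <- as_tensor(x)
  H <- dim(x$val)[1L]; W <- dim(x$val)[2L]
  sep <- separate_kernel(kernel)
  y <- if (is.null(sep)) cpp_dwconv_fw(x$val, kernel)
       else cpp_dwconv_sep_fw(x$val, sep[[1L]], sep[[2L]])
  ad_op(y, list(x), function(g) {
    dim(g) <- dim(y)
    gx <- if (is.null(sep)) cpp_dwconv_bw(kernel, g, H, W)
          else cpp_dwconv_sep_bw(sep[[1L]], sep[[2L]], g, H, W)
    list(gx)
  })
}

op_concat_c <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  Ca <- da[3L]; Cb <- db[3L]; N <- da[4L]
  out <- array(0, c(da[1L], da[2L], Ca + Cb, N))
  out[, , seq_len(Ca), ] <- a$val
  out[, , Ca + seq_len(Cb), ] <- b$val
  ad_op(out, list(a, b), function(g) {
    dim(g) <- dim(out)
    list(array(g[, , seq_len(Ca), , drop = FALSE], da),
         array(g[, , Ca + seq_len(Cb), , drop = FALSE], db))
  })
}

# global average pooling: (H,W,C,N) -> (C,N)
op_gap <- function(x) {
  x <- as_tensor(x)
  d <- dim(x$val)
  HW <- d[1L] * d[2L]
  m <- matrix(x$val, nrow = HW)
  y <- matrix(colSums(m) / HW, nrow = d[3L], ncol = d[4L])
  ad_op(y, list(x), function(g) {
    gx <- array(rep(as.numeric(g), each = HW) / HW, d)
    list(gx)
  })
}

# dense layer on (D,N) inputs: y = W x + b, W is (K,D), b length K
op_dense <- function(x, w, b) {
  x <- as_tensor(x)
  y <- w$val %*% x$val + b$val
  ad_op(y, list(x, w, b), function(g) {
    g <- matrix(g, nrow = nrow(y))
    list(crossprod(w$val, g), tcrossprod(g, x$val), rowSums(g))
  })
}

op_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  ad_op(a$val + b$val, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  ad_op(a$val - b$val, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  ad_op(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

op_div <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  ad_op(a$val / b$val, list(a, b),
        function(g) list(g / b$val, -g * a$val / (b$val^2)))
}

op_sadd <- function(x, s) {
  x <- as_tensor(x)
  ad_op(x$val + s, list(x), function(g) list(g))
}

op_smul <- function(x, s) {
  x <- as_tensor(x)
  ad_op(x$val * s, list(x), function(g) list(g * s))
}

op_mean <- function(x) {
  x <- as_tensor(x)
  n <- length(x$val)
  ad_op(mean(x$val), list(x), function(g) {
    gx <- array(g / n, dim = if (is.null(dim(x$val))) NULL else dim(x$val))
    if (is.null(dim(x$val))) gx <- rep(g / n, n)
    list(gx)
  })
}

# scale every element by a scalar parameter (the fuzziness gamma)
op_scale_by_param <- function(x, gamma) {
  x <- as_tensor(x)
  ad_op(x$val * as.numeric(gamma$val), list(x, gamma),
        function(g) list(g * as.numeric(gamma$val), sum(g * x$val)))
}

# multiply each column n of x (K,N) by s[n]; s is a (1,N) or length-N tensor
op_colscale <- function(x, s) {
  x <- as_tensor(x); s <- as_tensor(s)
  sv <- as.numeric(s$val)
  y <- sweep(x$val, 2L, sv, `*`)
  ad_op(y, list(x, s), function(g) {
    g <- matrix(g, nrow = nrow(x$val))
    gs <- colSums(g * x$val)
    dim(gs) <- dim(s$val)
    list(sweep(g, 2L, sv, `*`), gs)
  })
}

# slice one row of a matrix tensor, keeping grad flow
op_row <- function(x, i) {
  x <- as_tensor(x)
  ad_op(x$val[i, , drop = TRUE], list(x), function(g) {
    gx <- array(0, dim(x$val))
    gx[i, ] <- g
    list(gx)
  })
}

# stack matrix tensors by rows: list of (k_i, N) -> (sum k_i, N)
op_concat_rows <- function(tensors) {
  tensors <- lapply(tensors, as_tensor)
  vals <- lapply(tensors, function(t) t$val)
  rows <- vapply(vals, nrow, integer(1))
  out <- do.call(rbind, vals)
  offs <- cumsum(c(0L, rows))
  ad_op(out, tensors, function(g) {
    g <- matrix(g, nrow = nrow(out))
    lapply(seq_along(tensors), function(i)
      g[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
  })
}

# column-wise softmax of (K,N) logits (forward value only used in predict)
op_softmax <- function(x) {
  x <- as_tensor(x)
  z <- sweep(x$val, 2L, apply(x$val, 2L, max), `-`)
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), `/`)
  ad_op(p, list(x), function(g) {
    g <- matrix(g, nrow = nrow(p))
    dot <- colSums(g * p)
    list(p * sweep(g, 2L, dot, `-`))
  })
}

# fused softmax + cross-entropy over (K,N) logits and 1-based class labels
op_softmax_xent <- function(logits, classes) {
  logits <- as_tensor(logits)
  z <- sweep(logits$val, 2L, apply(logits$val, 2L, max), `-`)
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), `/`)
  n <- ncol(p)
  pick <- p[cbind(classes, seq_len(n))]
  loss <- -mean(log(pmax(pick, 1e-12)))
  node <- ad_op(loss, list(logits), function(g) {
    gl <- p
    gl[cbind(classes, seq_len(n))] <- gl[cbind(classes, seq_len(n))] - 1
    list(gl * (g / n))
  })
  attr(node, "probs") <- p
  node
}
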