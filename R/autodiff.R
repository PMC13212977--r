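# Minimal reverse-mode automatic differentiation over dense/sparse matrices.
# A tape records each operation; ad_backward() walks it in reverse, pushing
# gradients from a scalar loss into every parameter node. This is the engine
# under the graph neural network; it is validated against finite-difference
# gradients in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

is_ad <- function(x) is.environment(x)
ad_val <- function(x) if (is_ad(x)) x$val else x

acc_grad <- function(nd, g) {
  if (is.null(nd)) return(invisible())
  if (!is.matrix(g)) g <- as.matrix(g)
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible()
}

# wrap a plain matrix as a leaf node (parameter or input we differentiate to)
ad_leaf <- function(tape, val) ad_node(tape, val)

ad_backward <- function(tape, loss) {
  stopifnot(length(ad_val(loss)) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible()
}

ad_matmul <- function(tape, x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  v <- xv %*% yv
  if (!is.matrix(v)) v <- as.matrix(v)
  ad_node(tape, v, list(x = x, y = y), function(nd) {
    g <- nd$grad
    if (is_ad(nd$parents$x))
      acc_grad(nd$parents$x, tcrossprod(g, ad_val(nd$parents$y)))
    if (is_ad(nd$parents$y))
      acc_grad(nd$parents$y, crossprod(ad_val(nd$parents$x), g))
  })
}

# x (n x c) plus either a same-shape term or a 1 x c bias row (broadcast)
ad_add <- function(tape, x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  bias <- is.matrix(yv) && nrow(yv) == 1L && nrow(xv) > 1L
  val <- if (bias) sweep(xv, 2, as.numeric(yv), "+") else xv + yv
  ad_node(tape, val, list(x = x, y = y, bias = bias), function(nd) {
    g <- nd$grad
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, g)
    if (is_ad(nd$parents$y))
      acc_grad(nd$parents$y,
               if (nd$parents$bias) matrix(colSums(g), 1) else g)
  })
}

ad_scale <- function(tape, x, k) {
  ad_node(tape, ad_val(x) * k, list(x = x, k = k), function(nd) {
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, nd$grad * nd$parents$k)
  })
}

ad_mul <- function(tape, x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(tape, xv * yv, list(x = x, y = y), function(nd) {
    g <- nd$grad
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, g * ad_val(nd$parents$y))
    if (is_ad(nd$parents$y)) acc_grad(nd$parents$y, g * ad_val(nd$parents$x))
  })
}

ad_div <- function(tape, x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(tape, xv / yv, list(x = x, y = y), function(nd) {
    g <- nd$grad
    xv <- ad_val(nd$parents$x); yv <- ad_val(nd$parents$y)
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, g / yv)
    if (is_ad(nd$parents$y)) acc_grad(nd$parents$y, -g * xv / yv^2)
  })
}

ad_relu <- function(tape, x) {
  xv <- ad_val(x)
  ad_node(tape, pmax(xv, 0), list(x = x, mask = xv > 0), function(nd) {
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, nd$grad * nd$parents$mask)
  })
}

ad_elu <- function(tape, x, alpha = 1) {
  xv <- ad_val(x)
  neg <- xv <= 0
  val <- xv
  val[neg] <- alpha * (exp(xv[neg]) - 1)
  ad_node(tape, val, list(x = x, neg = neg, alpha = alpha, val = val),
          function(nd) {
    p <- nd$parents
    if (!is_ad(p$x)) return()
    d <- matrix(1, nrow(p$val), ncol(p$val))
    d[p$neg] <- p$val[p$neg] + p$alpha
    acc_grad(p$x, nd$grad * d)
  })
}

ad_leaky_relu <- function(tape, x, slope = 0.2) {
  xv <- ad_val(x)
  neg <- xv <= 0
  val <- xv
  val[neg] <- slope * xv[neg]
  ad_node(tape, val, list(x = x, neg = neg, slope = slope), function(nd) {
    p <- nd$parents
    if (!is_ad(p$x)) return()
    g <- nd$grad
    g[p$neg] <- g[p$neg] * p$slope
    acc_grad(p$x, g)
  })
}

ad_exp <- function(tape, x) {
  val <- exp(ad_val(x))
  ad_node(tape, val, list(x = x, val = val), function(nd) {
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, nd$grad * nd$parents$val)
  })
}

# gather rows by index (with repetition); scatter-add on the way back
ad_gather <- function(tape, x, idx) {
  ad_node(tape, ad_val(x)[idx, , drop = FALSE], list(x = x, idx = idx),
          function(nd) {
    if (!is_ad(nd$parents$x)) return()
    g <- nd$grad
    agg <- rowsum(g, group = nd$parents$idx)
    full <- matrix(0, nrow(ad_val(nd$parents$x)), ncol(g))
    full[as.integer(rownames(agg)), ] <- agg
    acc_grad(nd$parents$x, full)
  })
}

# sum rows within segments 1..n_seg (e.g. attention denominators per node)
ad_seg_sum <- function(tape, x, seg, n_seg) {
  v <- rowsum(ad_val(x), group = factor(seg, levels = seq_len(n_seg)))
  v[is.na(v)] <- 0
  ad_node(tape, v, list(x = x, seg = seg), function(nd) {
    if (is_ad(nd$parents$x))
      acc_grad(nd$parents$x, nd$grad[nd$parents$seg, , drop = FALSE])
  })
}

ad_concat_cols <- function(tape, xs) {
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  ad_node(tape, do.call(cbind, vals), list(xs = xs, widths = widths),
          function(nd) {
    g <- nd$grad
    off <- 0L
    for (i in seq_along(nd$parents$xs)) {
      w <- nd$parents$widths[i]
      if (is_ad(nd$parents$xs[[i]]))
        acc_grad(nd$parents$xs[[i]], g[, off + seq_len(w), drop = FALSE])
      off <- off + w
    }
  })
}

# column-wise max over row groups (global max pooling per graph)
ad_group_max <- function(tape, x, groups, n_groups) {
  xv <- ad_val(x)
  nc <- ncol(xv)
  val <- matrix(-Inf, n_groups, nc)
  argrow <- matrix(NA_integer_, n_groups, nc)
  rows_by_group <- split(seq_len(nrow(xv)), groups)
  for (gname in names(rows_by_group)) {
    g <- as.integer(gname)
    rows <- rows_by_group[[gname]]
    xm <- xv[rows, , drop = FALSE]
    amax <- max.col(t(xm), ties.method = "first")
    val[g, ] <- xm[cbind(amax, seq_len(nc))]
    argrow[g, ] <- rows[amax]
  }
  ad_node(tape, val, list(x = x, argrow = argrow), function(nd) {
    if (!is_ad(nd$parents$x)) return()
    g <- nd$grad
    ar <- nd$parents$argrow
    full <- matrix(0, nrow(ad_val(nd$parents$x)), ncol(g))
    for (j in seq_len(ncol(g))) {
      idx <- ar[, j]
      ok <- !is.na(idx)
      full[cbind(idx[ok], j)] <- full[cbind(idx[ok], j)] + g[ok, j]
    }
    acc_grad(nd$parents$x, full)
  })
}

# (S*P) x C node matrix (sample-major rows) -> S x (P*C) flattened per-sample
ad_flatten_nodes <- function(tape, x, S, P) {
  xv <- ad_val(x)
  C <- ncol(xv)
  a <- array(as.vector(xv), c(P, S, C))  # rows are sample-major: p fastest
  val <- matrix(aperm(a, c(2, 1, 3)), S, P * C)
  ad_node(tape, val, list(x = x, S = S, P = P, C = C), function(nd) {
    p <- nd$parents
    if (!is_ad(p$x)) return()
    b <- array(as.vector(nd$grad), c(p$S, p$P, p$C))
    acc_grad(p$x, matrix(aperm(b, c(2, 1, 3)), p$S * p$P, p$C))
  })
}

ad_mean <- function(tape, x) {
  xv <- ad_val(x)
  ad_node(tape, matrix(mean(xv), 1, 1), list(x = x, n = length(xv),
                                             dims = dim(xv)),
          function(nd) {
    p <- nd$parents
    if (is_ad(p$x))
      acc_grad(p$x, matrix(as.numeric(nd$grad) / p$n, p$dims[1], p$dims[2]))
  })
}

ad_mean_rows <- function(tape, x) {
  xv <- ad_val(x)
  ad_node(tape, matrix(colMeans(xv), 1), list(x = x, n = nrow(xv)),
          function(nd) {
    p <- nd$parents
    if (is_ad(p$x))
      acc_grad(p$x, matrix(rep(as.numeric(nd$grad) / p$n, each = p$n),
                           p$n, ncol(ad_val(p$x))))
  })
}

# scale each row of x (n x c) by the matching entry of s (n x 1)
ad_col_scale <- function(tape, x, s) {
  xv <- ad_val(x); sv <- as.numeric(ad_val(s))
  ad_node(tape, xv * sv, list(x = x, s = s), function(nd) {
    g <- nd$grad
    xv <- ad_val(nd$parents$x); sv <- as.numeric(ad_val(nd$parents$s))
    if (is_ad(nd$parents$x)) acc_grad(nd$parents$x, g * sv)
    if (is_ad(nd$parents$s)) acc_grad(nd$parents$s, matrix(rowSums(g * xv)))
  })
}

# per-head dot products: x is E x (H*F) in F-sized blocks, a_list holds H
# parameter vectors (F x 1); output column h = x[, block_h] %*% a_h
ad_headwise_dot <- function(tape, x, a_list) {
  xv <- ad_val(x)
  H <- length(a_list)
  F <- ncol(xv) %/% H
  val <- matrix(0, nrow(xv), H)
  for (h in seq_len(H))
    val[, h] <- xv[, (h - 1L) * F + seq_len(F), drop = FALSE] %*%
      ad_val(a_list[[h]])
  ad_node(tape, val, list(x = x, a_list = a_list, F = F), function(nd) {
    p <- nd$parents
    g <- nd$grad
    H <- length(p$a_list)
    xv <- ad_val(p$x)
    if (is_ad(p$x)) {
      gx <- matrix(0, nrow(xv), ncol(xv))
      for (h in seq_len(H)) {
        cols <- (h - 1L) * p$F + seq_len(p$F)
        gx[, cols] <- tcrossprod(g[, h], as.numeric(ad_val(p$a_list[[h]])))
      }
      acc_grad(p$x, gx)
    }
    for (h in seq_len(H)) {
      if (!is_ad(p$a_list[[h]])) next
      cols <- (h - 1L) * p$F + seq_len(p$F)
      acc_grad(p$a_list[[h]],
               matrix(crossprod(xv[, cols, drop = FALSE], g[, h])))
    }
  })
}

# scale F-sized column blocks of x (E x H*F) by the matching column of
# s (E x H): block h of the output is x[, block_h] * s[, h]
ad_rep_col_scale <- function(tape, x, s, F) {
  xv <- ad_val(x); sv <- ad_val(s)
  H <- ncol(sv)
  rep_idx <- rep(seq_len(H), each = F)
  val <- xv * sv[, rep_idx, drop = FALSE]
  ad_node(tape, val, list(x = x, s = s, rep_idx = rep_idx, F = F),
          function(nd) {
    p <- nd$parents
    g <- nd$grad
    xv <- ad_val(p$x); sv <- ad_val(p$s)
    if (is_ad(p$x)) acc_grad(p$x, g * sv[, p$rep_idx, drop = FALSE])
    if (is_ad(p$s)) {
      H <- ncol(sv)
      gs <- matrix(0, nrow(sv), H)
      for (h in seq_len(H)) {
        cols <- (h - 1L) * p$F + seq_len(p$F)
        gs[, h] <- rowSums(g[, cols, drop = FALSE] *
                             xv[, cols, drop = FALSE])
      }
      acc_grad(p$s, gs)
    }
  })
}
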