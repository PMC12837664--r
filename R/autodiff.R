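## Reverse-mode automatic differentiation on plain R arrays.
##
## Every operator accepts either a plain numeric array/matrix (treated as a
## constant) or an `ad_node`. When at least one input is a node the operator
## returns a new node carrying the forward value and a vector-Jacobian
## product (vjp) closure; otherwise it returns the plain value, so the same
## code path serves both inference and training. Gradients are propagated by
## `ad_backward()` in reverse topological order. All backward rules used by
## the network (including the hand-derived selective-scan and bilinear
## sampling kernels defined elsewhere) are verified against central finite
## differences in the test suite.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

ad_next_id <- function() {
  .ad_state$counter <- .ad_state$counter + 1L
  .ad_state$counter
}

#' Create an autodiff node
#'
#' @param value numeric array carried by the node.
#' @param parents list of parent `ad_node`s this node depends on.
#' @param vjp function taking the incoming gradient and returning a list of
#'   gradients aligned with `parents`.
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), vjp = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$vjp <- vjp
  n$grad <- NULL
  n$id <- ad_next_id()
  class(n) <- "ad_node"
  n
}

#' Create a trainable parameter (leaf node)
#' @param value initial numeric array.
#' @export
ad_param <- function(value) ad_node(value)

#' Test for an autodiff node
#' @param x object.
#' @export
is_node <- function(x) inherits(x, "ad_node")

#' Extract the numeric value of a node or pass a plain array through
#' @param x node or numeric array.
#' @export
ad_val <- function(x) if (is_node(x)) x$value else x

#' @export
print.ad_node <- function(x, ...) {
  cat("<ad_node id=", x$id, " dim=", paste(dim(x$value) %||% length(x$value),
      collapse = "x"), ">\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Wrap a forward value + full-length vjp into a node, keeping only the
## node-typed inputs as parents. `vjp_all(g)` must return one slot per input.
ad_apply <- function(inputs, value, vjp_all) {
  isn <- vapply(inputs, is_node, logical(1))
  if (!any(isn)) return(value)
  ad_node(value, parents = inputs[isn], vjp = function(g) vjp_all(g)[isn])
}

.acc <- function(cur, g) if (is.null(cur)) g else cur + g

#' Backpropagate gradients from a scalar loss node
#'
#' Fills the `$grad` field of every node reachable from `root`.
#' @param root scalar `ad_node`.
#' @export
ad_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1L)
  ## iterative depth-first post-order (one parent explored at a time, exactly
  ## mirroring the recursive traversal); reversing the order guarantees every
  ## consumer is processed before the node it consumes
  order <- vector("list", 256L); no <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, pi = 0L)); ns <- 1L
  assign(as.character(root$id), TRUE, envir = seen)
  while (ns > 0L) {
    fr <- stack[[ns]]
    np <- length(fr$node$parents)
    advanced <- FALSE
    while (fr$pi < np) {
      fr$pi <- fr$pi + 1L
      p <- fr$node$parents[[fr$pi]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        stack[[ns]] <- fr
        ns <- ns + 1L
        stack[[ns]] <- list(node = p, pi = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- fr$node
      stack[[ns]] <- NULL
      ns <- ns - 1L
    }
  }
  root$grad <- 1
  for (i in seq(no, 1L)) {
    nd <- order[[i]]
    if (is.null(nd$vjp) || is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) nd$parents[[j]]$grad <- .acc(nd$parents[[j]]$grad, gs[[j]])
    }
  }
  invisible(root)
}

#' Zero the gradients of a list of parameters
#' @param params list (possibly nested) of `ad_node`s.
#' @export
ad_zero_grad <- function(params) {
  for (p in ad_flatten_params(params)) p$grad <- NULL
  invisible(params)
}

#' Flatten a nested list of parameters to a flat list of nodes
#' @param params nested list.
#' @export
ad_flatten_params <- function(params) {
  out <- list()
  rec <- function(x) {
    if (is_node(x)) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (e in x) rec(e)
  }
  rec(params)
  out
}

## ---- elementwise arithmetic ------------------------------------------------

.sum_to_shape <- function(g, v) {
  if (length(v) == 1L) sum(g) else g
}

#' Elementwise sum of two arrays (or array + scalar)
#' @param a,b operands (node or numeric).
#' @export
ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), av + bv,
           function(g) list(.sum_to_shape(g, av), .sum_to_shape(g, bv)))
}

#' Elementwise difference
#' @inheritParams ad_add
#' @export
ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), av - bv,
           function(g) list(.sum_to_shape(g, av), .sum_to_shape(-g, bv)))
}

#' Elementwise product (supports scalar operands)
#' @inheritParams ad_add
#' @export
ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), av * bv,
           function(g) list(.sum_to_shape(g * bv, av), .sum_to_shape(g * av, bv)))
}

#' Elementwise quotient
#' @inheritParams ad_add
#' @export
ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), av / bv,
           function(g) list(.sum_to_shape(g / bv, av),
                            .sum_to_shape(-g * av / (bv * bv), bv)))
}

#' Negation
#' @param a operand.
#' @export
ad_neg <- function(a) ad_apply(list(a), -ad_val(a), function(g) list(-g))

## ---- matrix ops ------------------------------------------------------------

#' Matrix product
#' @param a,b matrices (node or numeric).
#' @export
ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), av %*% bv,
           function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

#' Add a row vector (bias) to every row of a matrix
#' @param a n x m matrix; @param b length-m vector.
#' @export
ad_add_rowvec <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_apply(list(a, b), sweep(av, 2L, bv, "+"),
           function(g) list(g, colSums(g)))
}

## ---- shape ops -------------------------------------------------------------

#' Reshape without reordering data
#' @param x operand; @param dims new dim vector.
#' @export
ad_reshape <- function(x, dims) {
  xv <- ad_val(x)
  old <- dim(xv) %||% length(xv)
  v <- xv; dim(v) <- dims
  ad_apply(list(x), v, function(g) { dim(g) <- old; list(g) })
}

#' Permute array dimensions
#' @param x operand; @param perm permutation of seq_along(dim(x)).
#' @export
ad_aperm <- function(x, perm) {
  xv <- ad_val(x)
  inv <- order(perm)
  ad_apply(list(x), aperm(xv, perm), function(g) list(aperm(g, inv)))
}

## ---- reductions ------------------------------------------------------------

#' Sum of all elements
#' @param x operand.
#' @export
ad_sum <- function(x) {
  xv <- ad_val(x)
  ad_apply(list(x), sum(xv),
           function(g) list(array(g, dim = dim(xv) %||% length(xv))))
}

#' Mean of all elements
#' @param x operand.
#' @export
ad_mean <- function(x) {
  xv <- ad_val(x); n <- length(xv)
  ad_apply(list(x), mean(xv),
           function(g) list(array(g / n, dim = dim(xv) %||% length(xv))))
}

#' Column sums of a matrix
#' @param x matrix operand.
#' @export
ad_colsums <- function(x) {
  xv <- ad_val(x)
  ad_apply(list(x), colSums(xv),
           function(g) list(matrix(g, nrow = nrow(xv), ncol = ncol(xv), byrow = TRUE)))
}

#' Row sums of a matrix
#' @param x matrix operand.
#' @export
ad_rowsums <- function(x) {
  xv <- ad_val(x)
  ad_apply(list(x), rowSums(xv),
           function(g) list(matrix(g, nrow = nrow(xv), ncol = ncol(xv))))
}

#' Pick a single element (scalar output)
#' @param x vector operand; @param i index.
#' @export
ad_pick <- function(x, i) {
  xv <- ad_val(x)
  ad_apply(list(x), xv[[i]], function(g) {
    z <- array(0, dim = dim(xv) %||% length(xv)); z[i] <- g; list(z)
  })
}

#' Row-wise maximum of a matrix
#'
#' Gradient flows to the first arg-max entry of each row.
#' @param x matrix operand.
#' @export
ad_rowmax <- function(x) {
  xv <- ad_val(x)
  idx <- max.col(xv, ties.method = "first")
  ad_apply(list(x), xv[cbind(seq_len(nrow(xv)), idx)], function(g) {
    z <- matrix(0, nrow(xv), ncol(xv))
    z[cbind(seq_len(nrow(xv)), idx)] <- g
    list(z)
  })
}

## ---- nonlinearities ---------------------------------------------------------

.unary <- function(x, f, df) {
  xv <- ad_val(x); v <- f(xv)
  ad_apply(list(x), v, function(g) list(g * df(xv, v)))
}

#' @rdname ad_nonlin
#' @param x operand.
#' @export
ad_exp <- function(x) .unary(x, exp, function(xv, v) v)

#' Elementwise nonlinearities with autodiff support
#' @name ad_nonlin
#' @rdname ad_nonlin
#' @export
ad_log <- function(x) .unary(x, log, function(xv, v) 1 / xv)

#' @rdname ad_nonlin
#' @export
ad_sigmoid <- function(x) .unary(x, function(z) 1 / (1 + exp(-z)),
                                 function(xv, v) v * (1 - v))

#' @rdname ad_nonlin
#' @export
ad_tanh <- function(x) .unary(x, tanh, function(xv, v) 1 - v * v)

#' @rdname ad_nonlin
#' @export
ad_relu <- function(x) .unary(x, function(z) pmax(z, 0),
                              function(xv, v) (xv > 0) + 0)

#' @rdname ad_nonlin
#' @export
ad_softplus <- function(x) .unary(x, function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
                                  function(xv, v) 1 / (1 + exp(-xv)))

#' @rdname ad_nonlin
#' @export
ad_silu <- function(x) .unary(x, function(z) z / (1 + exp(-z)),
                              function(xv, v) {
                                s <- 1 / (1 + exp(-xv)); s * (1 + xv * (1 - s))
                              })

#' @rdname ad_nonlin
#' @export
ad_sqrt <- function(x) .unary(x, sqrt, function(xv, v) 0.5 / v)

## ---- softmax family ---------------------------------------------------------

.softmax_rows_val <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

#' Row-wise softmax
#' @param x matrix of logits (node or numeric).
#' @export
ad_softmax_rows <- function(x) {
  xv <- ad_val(x)
  p <- .softmax_rows_val(xv)
  ad_apply(list(x), p, function(g) list(p * (g - rowSums(g * p))))
}

#' Softmax of a vector
#' @param x vector operand.
#' @export
ad_softmax_vec <- function(x) {
  xv <- ad_val(x)
  e <- exp(xv - max(xv)); p <- e / sum(e)
  ad_apply(list(x), p, function(g) list(p * (g - sum(g * p))))
}

#' Mean cross-entropy from logits (numerically stable)
#'
#' @param logits n x K matrix; @param y integer labels in 1..K.
#' @return scalar mean of logsumexp(row) - logit[i, y_i].
#' @export
ad_ce_logits <- function(logits, y) {
  lv <- ad_val(logits)
  n <- nrow(lv)
  m <- apply(lv, 1L, max)
  lse <- m + log(rowSums(exp(lv - m)))
  v <- mean(lse - lv[cbind(seq_len(n), y)])
  ad_apply(list(logits), v, function(g) {
    p <- .softmax_rows_val(lv)
    p[cbind(seq_len(n), y)] <- p[cbind(seq_len(n), y)] - 1
    list(g * p / n)
  })
}

#' Column-wise smooth maximum via log-sum-exp
#'
#' out_k = (1/alpha) * log(sum_l exp(alpha * x[l, k])).
#' @param x L x K matrix; @param alpha temperature (> 0, constant).
#' @export
ad_smoothmax_cols <- function(x, alpha) {
  xv <- ad_val(x)
  m <- apply(xv, 2L, max)
  e <- exp(alpha * sweep(xv, 2L, m, "-"))
  out <- m + log(colSums(e)) / alpha
  ad_apply(list(x), out, function(g) {
    w <- sweep(e, 2L, colSums(e), "/")          # d out_k / d x[l,k]
    list(sweep(w, 2L, g, "*"))
  })
}

#' Row-wise L2 normalisation with an epsilon guard
#'
#' Rows with norm below `eps` are divided by `eps` (their direction gradient
#' is then the plain scaled gradient).
#' @param x matrix; @param eps guard.
#' @export
ad_row_normalize <- function(x, eps = 1e-8) {
  xv <- ad_val(x)
  n <- sqrt(rowSums(xv * xv))
  d <- pmax(n, eps)
  y <- xv / d
  ad_apply(list(x), y, function(g) {
    free <- (n > eps) + 0
    list(g / d - xv * (free * rowSums(xv * g) / d^3))
  })
}

## ---- broadcast helpers over feature grids ----------------------------------
## Feature grids are stored as arrays of dim (P, C, L): P = h*w spatial
## positions, C channels, L segments.

#' Global average pooling over the spatial dimension of a (P, C, L) grid
#' @param x feature grid.
#' @return L x C matrix (node if input is a node).
#' @export
ad_gap <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv); P <- d[1]; C <- d[2]; L <- d[3]
  v <- t(matrix(colMeans(matrix(xv, P, C * L)), C, L))   # L x C
  ad_apply(list(x), v, function(g) {
    gt <- t(g)                                           # C x L
    list(array(rep(as.vector(gt), each = P) / P, dim = d))
  })
}

#' Add a per-(segment, channel) vector to a (P, C, L) grid, broadcast over P
#' @param x grid; @param tok L x C matrix.
#' @export
ad_add_chan <- function(x, tok) {
  xv <- ad_val(x); tv <- ad_val(tok)
  d <- dim(xv); P <- d[1]
  b <- array(rep(as.vector(t(tv)), each = P), dim = d)
  ad_apply(list(x, tok), xv + b, function(g) {
    list(g, t(matrix(colSums(matrix(g, P, d[2] * d[3])), d[2], d[3])))
  })
}

#' Multiply a (P, C, L) grid by a per-(segment, channel) gate, broadcast over P
#' @param x grid; @param gate L x C matrix.
#' @export
ad_mul_chan <- function(x, gate) {
  xv <- ad_val(x); gv <- ad_val(gate)
  d <- dim(xv); P <- d[1]
  b <- array(rep(as.vector(t(gv)), each = P), dim = d)
  ad_apply(list(x, gate), xv * b, function(g) {
    list(g * b,
         t(matrix(colSums(matrix(g * xv, P, d[2] * d[3])), d[2], d[3])))
  })
}

#' Layer normalisation across channels of a (P, C, L) grid
#'
#' Normalises the C values at each (position, segment) site, then applies a
#' learnable per-channel affine transform.
#' @param x grid; @param gamma,beta length-C parameters; @param eps variance guard.
#' @export
ad_layernorm_chan <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x); gav <- as.numeric(ad_val(gamma)); bev <- as.numeric(ad_val(beta))
  d <- dim(xv); P <- d[1]; C <- d[2]; L <- d[3]
  xm <- matrix(aperm(xv, c(2, 1, 3)), C, P * L)     # C x (P*L)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, "-")
  va <- colMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- sweep(xc, 2L, sd, "/")
  ym <- xhat * gav + bev
  y <- aperm(array(ym, dim = c(C, P, L)), c(2, 1, 3))
  ad_apply(list(x, gamma, beta), y, function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3)), C, P * L)
    dxhat <- gm * gav
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dxm <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"), 2L, sd, "/")
    gx <- aperm(array(dxm, dim = c(C, P, L)), c(2, 1, 3))
    list(gx, rowSums(gm * xhat), rowSums(gm))
  })
}

## ---- optimiser ---------------------------------------------------------------

#' Create an Adam optimiser state for a parameter list
#' @param params nested list of `ad_node`s.
#' @param lr learning rate; @param beta1,beta2 moment decays; @param eps guard.
#' @export
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flat <- ad_flatten_params(params)
  st <- new.env(parent = emptyenv())
  st$flat <- flat
  st$m <- lapply(flat, function(p) p$value * 0)   # zero moments, same shape
  st$v <- lapply(flat, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

#' Apply one Adam update in place (skips parameters with no gradient)
#' @param st state from [adam_new()].
#' @export
adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$flat)) {
    p <- st$flat[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + st$eps)
  }
  invisible(st)
}

#' Central finite-difference gradient of a scalar function
#'
#' Test utility: independent oracle for every analytic backward rule.
#' @param f function of one numeric array returning a scalar.
#' @param x evaluation point; @param eps step.
#' @export
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
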