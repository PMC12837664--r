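## Selective state-space sequence core.
##
## The scan is the diagonal-state selective SSM recurrence with
## zero-order-hold style discretisation and input-dependent step size and
## input/output projections:
##
##   delta_t = softplus(u_t W_dt + b_dt)            (per-channel step size)
##   B_t     = u_t W_B,   C_t = u_t W_C             (input-dependent projections)
##   Abar_t  = exp(delta_t (x) A),  A = -exp(A_log) (stable: A < 0)
##   h_t     = Abar_t * h_{t-1} + (delta_t * u_t) (x) B_t
##   y_t     = <h_t, C_t> + D * u_t
##
## Implemented as an explicit per-step recurrence (linear in N) with a
## hand-derived backpropagation-through-time rule, registered as a single
## autodiff node. The backward rule is checked against finite differences
## and the forward against an independently coded naive loop in the tests.

#' Initialise parameters of one selective-scan SSM
#'
#' @param d_model token width handled by the scan.
#' @param state_dim hidden state size per channel.
#' @return list of numeric parameter arrays (`A_log`, `W_dt`, `b_dt`,
#'   `W_B`, `W_C`, `D`).
#' @export
ssm_params <- function(d_model, state_dim = 16) {
  stopifnot(d_model >= 1, state_dim >= 1)
  dt <- stats::runif(d_model, 0.01, 0.1)
  list(
    A_log = matrix(log(seq_len(state_dim)), d_model, state_dim, byrow = TRUE),
    W_dt  = .rmat(d_model, d_model, 1 / sqrt(d_model)) * 0.1,
    b_dt  = log(expm1(dt)),                       # inverse softplus of dt
    W_B   = .rmat(d_model, state_dim, 1 / sqrt(d_model)),
    W_C   = .rmat(d_model, state_dim, 1 / sqrt(d_model)),
    D     = rep(1, d_model)
  )
}

#' Batched selective scan over a (N, B, d_model) token array
#'
#' Core autodiff operation; `u` may be an `ad_node`. Parameters may be nodes
#' (training) or plain arrays (inference/oracle checks). Internally the
#' per-step state is kept as a (B*Dm) x S matrix (batch index fastest) so
#' every recurrence step is a handful of flat vectorised operations.
#' @param u array of dim (N, B, d_model).
#' @param p parameter list as from [ssm_params()] (entries node or numeric).
#' @return array (or node) of dim (N, B, d_model).
#' @keywords internal
ad_selective_scan <- function(u, p) {
  uv <- ad_val(u)
  d <- dim(uv); N <- d[1]; B <- d[2]; Dm <- d[3]
  A_log <- ad_val(p$A_log); W_dt <- ad_val(p$W_dt); b_dt <- ad_val(p$b_dt)
  W_B <- ad_val(p$W_B); W_C <- ad_val(p$W_C); Dvec <- ad_val(p$D)
  S <- ncol(A_log)

  Um <- matrix(uv, N * B, Dm)
  Z <- sweep(Um %*% W_dt, 2L, as.numeric(b_dt), "+")
  delta <- ifelse(Z > 30, Z, log1p(exp(pmin(Z, 30))))
  Bm <- Um %*% W_B
  Cm <- Um %*% W_C
  A <- -exp(A_log)

  fw <- scan_fwd_cpp(delta, Um, Bm, Cm, A, as.numeric(Dvec), N, B)
  yv <- array(fw$Y, c(N, B, Dm))

  inputs <- list(u, p$A_log, p$W_dt, p$b_dt, p$W_B, p$W_C, p$D)
  ad_apply(inputs, yv, function(g) {
    gY <- matrix(g, N * B, Dm)
    bw <- scan_bwd_cpp(gY, delta, Um, Bm, Cm, A, as.numeric(Dvec), fw$H, N, B)
    gZ <- bw$gdelta / (1 + exp(-Z))
    gUm <- bw$gU + gZ %*% t(W_dt) + bw$gBm %*% t(W_B) + bw$gCm %*% t(W_C)
    list(array(gUm, c(N, B, Dm)),         # u
         bw$gA * A,                       # A_log (dA/dA_log = -exp(A_log) = A)
         crossprod(Um, gZ),               # W_dt
         colSums(gZ),                     # b_dt
         crossprod(Um, bw$gBm),           # W_B
         crossprod(Um, bw$gCm),           # W_C
         bw$gD)                           # D
  })
}

#' Reverse an array along its first dimension
#' @param x array operand (node or numeric).
#' @export
ad_flip1 <- function(x) {
  xv <- ad_val(x)
  n <- dim(xv)[1]
  idx <- seq(n, 1L)
  flip <- function(a) {
    d <- dim(a)
    m <- matrix(a, n, length(a) / n)[idx, , drop = FALSE]
    array(m, d)
  }
  ad_apply(list(x), flip(xv), function(g) list(flip(g)))
}

#' Selective state-space scan over a token sequence
#'
#' Causal in the requested direction: in forward mode output t depends only
#' on tokens 1..t; in backward mode only on tokens t..N.
#'
#' @param tokens N x d_model matrix (one row per sequence element), or an
#'   (N, B, d_model) array for batched sequences.
#' @param params list from [ssm_params()].
#' @param direction "forward" (index 1 -> N) or "backward" (N -> 1).
#' @return object of the same shape as `tokens`.
#' @export
selective_scan <- function(tokens, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  tv <- ad_val(tokens)
  two_d <- length(dim(tv)) == 2L || is.null(dim(tv))
  if (two_d) {
    if (is.null(dim(tv))) stop("tokens must be a matrix or 3-d array")
    if (nrow(tv) < 1L) stop("empty sequence")
    tokens <- ad_reshape(tokens, c(nrow(tv), 1L, ncol(tv)))
  } else if (dim(tv)[1] < 1L) stop("empty sequence")
  x <- if (direction == "backward") ad_flip1(tokens) else tokens
  y <- ad_selective_scan(x, params)
  if (direction == "backward") y <- ad_flip1(y)
  if (two_d) y <- ad_reshape(y, c(nrow(tv), ncol(tv)))
  y
}

#' Initialise a Mamba block
#'
#' @param d_token width of the incoming tokens (preserved by the block).
#' @param d_model internal scan width; @param state_dim SSM state size.
#' @export
mamba_block_init <- function(d_token, d_model, state_dim = 16) {
  list(
    ln_g = rep(1, d_token), ln_b = numeric(d_token),
    W_x = glorot_init(d_token, d_model), b_x = numeric(d_model),
    W_z = glorot_init(d_token, d_model), b_z = numeric(d_model),
    ssm = ssm_params(d_model, state_dim),
    W_out = glorot_init(d_model, d_token)
  )
}

#' Residual gated Mamba block
#'
#' LayerNorm -> parallel input/gate projections -> selective scan on the
#' input path -> SiLU-gated merge -> down projection -> residual add.
#' Shape preserving for any sequence length.
#'
#' @param tokens N x d_token matrix or (N, B, d_token) array.
#' @param params list from [mamba_block_init()].
#' @param direction scan direction, see [selective_scan()].
#' @export
mamba_block <- function(tokens, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  tv <- ad_val(tokens)
  two_d <- length(dim(tv)) == 2L
  if (two_d) {
    if (nrow(tv) < 1L) stop("empty sequence")
    N <- nrow(tv); B <- 1L; D <- ncol(tv)
  } else {
    d <- dim(tv); N <- d[1]; B <- d[2]; D <- d[3]
    if (N < 1L) stop("empty sequence")
  }
  t2 <- ad_reshape(tokens, c(N * B, D))
  ln <- ad_layernorm_rows(t2, params$ln_g, params$ln_b)
  x <- linear(ln, params$W_x, params$b_x)
  z <- linear(ln, params$W_z, params$b_z)
  dm <- length(ad_val(params$b_x))
  x3 <- ad_reshape(x, c(N, B, dm))
  if (direction == "backward") x3 <- ad_flip1(x3)
  y3 <- ad_selective_scan(x3, params$ssm)
  if (direction == "backward") y3 <- ad_flip1(y3)
  y <- ad_mul(ad_reshape(y3, c(N * B, dm)), ad_silu(z))
  out <- ad_add(t2, ad_matmul(y, params$W_out))
  ad_reshape(out, if (two_d) c(N, D) else c(N, B, D))
}
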