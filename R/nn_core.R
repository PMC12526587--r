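# Dense-matrix neural-network primitives with hand-written backward passes.
# All parameters live in nested lists of plain matrices/vectors; forward
# functions return caches that the matching backward functions consume.
# Conventions: leaf names starting "W"/"pos" are Xavier-initialized weights,
# "b*" are zero biases, "g*" are LayerNorm gains (ones).

# Glorot/Xavier uniform draw: var = 2 / (fan_in + fan_out).
xavier_mat <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -a, a), nrow, ncol)
}

add_bias <- function(M, b) .add_bias_cpp(M, b)

relu <- function(x) .relu_cpp(x)

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- LayerNorm (per-row) ------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  list(out = add_bias(Xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE), b),
       Xhat = Xhat, inv = inv, g = g)
}

layernorm_bwd <- function(cache, dout) {
  d <- ncol(dout)
  dXhat <- dout * matrix(cache$g, nrow(dout), d, byrow = TRUE)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * cache$Xhat)
  dX <- (dXhat - m1 - cache$Xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dout * cache$Xhat), db = colSums(dout))
}

# --- patch / conv index helpers ----------------------------------------

# Sliding-window index matrix: rows = window positions, cols = offsets.
window_index <- function(input_len, width, stride = 1L) {
  n_pos <- (input_len - width) %/% stride + 1L
  outer((seq_len(n_pos) - 1L) * stride, seq_len(width), `+`)
}

# Gather windows from a batch matrix X (B x L) into sample-major blocks:
# rows ((b-1)*P + p), columns = window offsets. Uses one cached linear index
# per (B, L, width, stride) so the gather is a single subscript operation.
.window_cache <- new.env(parent = emptyenv())

gather_windows <- function(X, idx) {
  P <- nrow(idx); k <- ncol(idx); B <- nrow(X)
  stride <- if (P > 1L) idx[2, 1] - idx[1, 1] else 1L
  key <- sprintf("%d_%d_%d_%d_%d", B, ncol(X), k, P, stride)
  I <- .window_cache[[key]]
  if (is.null(I) || length(I) != P * B * k) {
    # linear index of X[b, idx[p, j]] at output row (b-1)*P + p, col j
    b_of <- rep(seq_len(B), each = P)
    p_of <- rep(seq_len(P), B)
    I <- matrix(0L, P * B, k)
    for (j in seq_len(k))
      I[, j] <- b_of + (idx[p_of, j] - 1L) * B
    .window_cache[[key]] <- I
  }
  out <- X[as.vector(I)]
  dim(out) <- c(P * B, k)
  out
}

# --- RMSprop ------------------------------------------------------------

# Elementwise walk over two (or three) parallel nested lists.
map_params <- function(a, b, fn) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- map_params(a[[nm]], b[[nm]], fn)
    out
  } else fn(a, b)
}

zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0

add_params <- function(a, b) map_params(a, b, `+`)
scale_params <- function(a, s) if (is.list(a)) lapply(a, scale_params, s = s) else a * s

rmsprop_state <- function(params) list(v = zero_like(params))

rmsprop_update <- function(params, grads, state, lr, rho = 0.99, eps = 1e-8) {
  state$v <- map_params(state$v, grads, function(v, g) rho * v + (1 - rho) * g^2)
  params <- {
    rec <- function(p, v, g) {
      if (is.list(p)) {
        for (i in seq_along(p)) p[[i]] <- rec(p[[i]], v[[i]], g[[i]])
        p
      } else p - lr * g / (sqrt(v) + eps)
    }
    rec(params, state$v, grads)
  }
  list(params = params, state = state)
}

# Flatten a nested parameter list to one numeric vector (testing aid).
flatten_params <- function(p) {
  if (is.list(p)) unlist(lapply(p, flatten_params), use.names = FALSE)
  else as.numeric(p)
}

# Rebuild a nested parameter list from a flat vector (testing aid).
unflatten_params <- function(template, vec) {
  i <- 0L
  rec <- function(p) {
    if (is.list(p)) return(lapply(p, rec))
    n <- length(p)
    out <- p
    out[] <- vec[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  rec(template)
}
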