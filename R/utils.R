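# Internal numeric helpers shared across the layer implementations.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x)

check_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  invisible(x)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

row_max <- function(x) {
  # max over each row without apply(); max.col is C-level
  x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
}

# x + b broadcast over rows / columnwise scale, avoiding sweep()'s aperm
add_rows <- function(x, b) x + matrix(b, nrow(x), ncol(x), byrow = TRUE)
mul_rows <- function(x, b) x * matrix(b, nrow(x), ncol(x), byrow = TRUE)

#' @noRd
#' Row-wise softmax over the entries where `mask` is TRUE; masked-out entries
#' are exactly zero. Every row must contain at least one TRUE.
masked_softmax <- function(scores, mask) {
  z <- scores
  z[!mask] <- -Inf
  m <- row_max(z)
  if (any(!is.finite(m))) stopf("masked softmax: a row has an empty mask")
  e <- exp(z - m)
  e[!mask] <- 0
  e / rowSums(e)
}

# Backward of row-wise softmax: given probabilities p and upstream dp,
# returns gradient w.r.t. the pre-softmax scores. Valid for masked softmax
# too, because p is 0 outside the mask.
softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) {
  pos <- x > 0
  pos + exp(pmin(x, 0)) * !pos
}

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope) {
  pos <- x > 0
  pos + slope * !pos
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Cross-entropy of a logit vector against a 0/1 label; returns loss and the
# gradient w.r.t. the logits (softmax - one-hot).
cross_entropy <- function(logits, label) {
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1, got %s", label)
  p <- exp(logits - logsumexp(logits))
  loss <- logsumexp(logits) - logits[label + 1L]
  g <- p
  g[label + 1L] <- g[label + 1L] - 1
  list(loss = loss, grad = g)
}

# Glorot-uniform initialisation; draws from the active RNG stream.
glorot <- function(fan_in, fan_out, shape = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(shape), -lim, lim), shape[1], shape[2])
}

# Deterministic integer mixing for derived seeds; stays below 2^31 - 1.
mix_seed <- function(...) {
  xs <- as.numeric(c(...))
  h <- 104729
  for (x in xs) {
    h <- (h * 69069 + abs(x) * 2654435 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Flatten a nested parameter list to a numeric vector and back. The rebuild
# walks the skeleton once (relist() re-unlists the skeleton at every level,
# which is far too slow for large parameter trees).
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flesh, skeleton) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- flesh[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- rec(skeleton)
  if (pos != length(flesh)) {
    stopf("flat vector length %d does not match skeleton size %d",
          length(flesh), pos)
  }
  out
}

# Elementwise sum of two identically-shaped nested lists (gradient
# accumulation across samples in a batch).
add_params <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(add_params, a, b, SIMPLIFY = FALSE))
  a + b
}

scale_params <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_params, s = s))
  a * s
}

zero_like <- function(a) {
  if (is.list(a)) return(lapply(a, zero_like))
  a * 0
}
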