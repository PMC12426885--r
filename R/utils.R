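# Internal numeric helpers shared across modules.

# DFT sample frequencies in cycles per unit, matching the usual fftfreq layout
# (DC first, then positive, then negative frequencies).
fftfreq <- function(n, d = 1) {
  c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / (n * d)
}

# Forward-difference gradient with Neumann (zero) boundary on the last
# sample of each axis.  Accepts a matrix or a 3D array; returns a list of
# per-axis difference arrays of the same shape.  All dTV-related code and the
# gradient-direction analysis share this one discretisation.
grad_forward <- function(u) {
  d <- dim(u)
  if (length(d) == 2L) d <- c(d, 1L)
  u <- array(u, d)
  gx <- array(0, d); gy <- array(0, d)
  gx[-d[1], , ] <- u[-1, , , drop = FALSE] - u[-d[1], , , drop = FALSE]
  gy[, -d[2], ] <- u[, -1, , drop = FALSE] - u[, -d[2], , drop = FALSE]
  g <- list(x = gx, y = gy)
  if (d[3] > 1L) {
    gz <- array(0, d)
    gz[, , -d[3]] <- u[, , -1, drop = FALSE] - u[, , -d[3], drop = FALSE]
    g$z <- gz
  }
  g
}

# Negative adjoint of grad_forward: div such that <grad u, g> = -<u, div g>.
div_backward <- function(g) {
  d <- dim(g$x)
  out <- array(0, d)
  # x axis: adjoint of forward difference with Neumann end
  dx <- array(0, d)
  dx[1, , ] <- g$x[1, , , drop = FALSE]
  if (d[1] > 2L) dx[2:(d[1] - 1), , ] <-
      g$x[2:(d[1] - 1), , , drop = FALSE] - g$x[1:(d[1] - 2), , , drop = FALSE]
  dx[d[1], , ] <- -g$x[d[1] - 1, , , drop = FALSE]
  dy <- array(0, d)
  dy[, 1, ] <- g$y[, 1, , drop = FALSE]
  if (d[2] > 2L) dy[, 2:(d[2] - 1), ] <-
      g$y[, 2:(d[2] - 1), , drop = FALSE] - g$y[, 1:(d[2] - 2), , drop = FALSE]
  dy[, d[2], ] <- -g$y[, d[2] - 1, , drop = FALSE]
  out <- dx + dy
  if (!is.null(g$z) && d[3] > 1L) {
    dz <- array(0, d)
    dz[, , 1] <- g$z[, , 1, drop = FALSE]
    if (d[3] > 2L) dz[, , 2:(d[3] - 1)] <-
        g$z[, , 2:(d[3] - 1), drop = FALSE] - g$z[, , 1:(d[3] - 2), drop = FALSE]
    dz[, , d[3]] <- -g$z[, , d[3] - 1, drop = FALSE]
    out <- out + dz
  }
  out
}

grad_magnitude <- function(g) {
  m <- g$x^2 + g$y^2
  if (!is.null(g$z)) m <- m + g$z^2
  sqrt(m)
}

# Separable Gaussian convolution with reflective (half-sample) boundary and a
# global flux renormalisation so the image total is conserved exactly.
gauss_blur <- function(img, sigma) {
  stopifnot(all(sigma >= 0))
  img <- as.matrix(img)
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  total <- sum(img)
  out <- img
  for (ax in 1:2) {
    s <- sigma[ax]
    if (s <= 0 || dim(out)[ax] == 1L) next
    hw <- max(1L, ceiling(5 * s))
    k <- exp(-(seq(-hw, hw))^2 / (2 * s^2))
    k <- k / sum(k)
    if (ax == 2L) out <- t(out)
    n <- nrow(out)
    pad_top <- out[pmin(hw:1, n), , drop = FALSE]
    pad_bot <- out[pmax(n - (1:hw) + 1, 1), , drop = FALSE]
    ext <- rbind(pad_top, out, pad_bot)
    res <- matrix(0, n, ncol(out))
    for (m in seq_along(k)) res <- res + k[m] * ext[(m - 1) + seq_len(n), , drop = FALSE]
    out <- if (ax == 2L) t(res) else res
  }
  if (total != 0 && sum(out) != 0) out <- out * (total / sum(out))
  out
}

# Run code with a locally seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, code) withr::with_seed(seed, code)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation without the cor() NA machinery, for internal use.
pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ac <- a - mean(a); bc <- b - mean(b)
  den <- sqrt(sum(ac^2) * sum(bc^2))
  if (den == 0) stop("degenerate (constant) input to correlation")
  sum(ac * bc) / den
}
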