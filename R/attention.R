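# Channel and spatial attention. ECA reweights channels through a 1-D
# convolution over the globally pooled channel vector, its width chosen
# adaptively from the channel count; SAM reweights spatial positions from
# concatenated channelwise mean/max maps.

#' Adaptive ECA kernel size
#'
#' The 1-D cross-channel convolution width is the nearest odd integer to
#' `log2(C)/gamma + b/gamma`, with ties broken downward. With the default
#' `gamma = 2, b = 1` the four backbone stages (96, 192, 384, 768 channels)
#' receive kernel sizes 3, 5, 5 and 5.
#'
#' @param C number of channels (>= 2).
#' @param gamma,b mapping coefficients (defaults 2 and 1).
#' @return an odd integer >= 1.
#' @examples
#' eca_kernel_size(96)   # 3
#' eca_kernel_size(768)  # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1 || !is.finite(C) || C < 2) {
    stop("C must be a single channel count >= 2")
  }
  t <- log2(C) / gamma + b / gamma
  lower <- 2 * floor((t - 1) / 2) + 1
  upper <- lower + 2
  k <- if ((t - lower) <= (upper - t)) lower else upper
  as.integer(max(1, k))
}

#' Apply efficient channel attention to a feature map
#'
#' Global average pooling over each channel gives a length-C vector; a 1-D
#' convolution of width `k` (zero padded, no bias) followed by a sigmoid gives
#' per-channel weights in (0, 1), which scale the input channels.
#'
#' @param X feature array dim c(H, W, C).
#' @param weight numeric vector of length `k` (odd), the 1-D kernel.
#' @return list with `output` (same shape as `X`) and `weights` (length C).
#' @export
eca_apply <- function(X, weight) {
  k <- length(weight)
  if (k %% 2 == 0) stop("ECA kernel size must be odd")
  d <- dim(X)
  C <- d[3]
  if (k > C) stop("kernel size exceeds channel count")
  z <- colMeans(matrix(X, prod(d[1:2]), C))
  s <- conv1d_same(z, weight)
  a <- sigmoid(s)
  out <- array(sweep(matrix(X, prod(d[1:2]), C), 2, a, "*"), d)
  list(output = out, weights = a)
}

# 1-D correlation with zero padding, output length == input length
conv1d_same <- function(z, w) {
  k <- length(w)
  h <- (k - 1) / 2
  zp <- c(numeric(h), z, numeric(h))
  n <- length(z)
  s <- numeric(n)
  for (j in seq_len(k)) s <- s + w[j] * zp[j:(j + n - 1)]
  s
}

#' ECA layer (trainable)
#' @param C channel count; kernel size derived via [eca_kernel_size()].
#' @keywords internal
layer_eca <- function(C, gamma = 2, b = 1) {
  k <- eca_kernel_size(C, gamma, b)
  m <- fs_module("eca", params = list(
    weight = fs_parameter(numeric(k) + 1 / k, decay = FALSE)))
  m$k <- k
  m$forward <- function(x) {
    d <- dim(x)
    npos <- prod(d[1:2])
    xm <- matrix(x, npos, d[3])
    z <- colMeans(xm)
    s <- conv1d_same(z, m$params$weight$value)
    a <- sigmoid(s)
    m$cache <- list(xm = xm, z = z, a = a, d = d)
    array(sweep(xm, 2, a, "*"), d)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    npos <- prod(cc$d[1:2])
    dym <- matrix(dy, npos, cc$d[3])
    da <- colSums(dym * cc$xm)
    ds <- da * cc$a * (1 - cc$a)
    k <- m$k
    h <- (k - 1) / 2
    n <- cc$d[3]
    zp <- c(numeric(h), cc$z, numeric(h))
    dw <- numeric(k)
    for (j in seq_len(k)) dw[j] <- sum(ds * zp[j:(j + n - 1)])
    m$params$weight$grad <- m$params$weight$grad + dw
    # transpose of zero-padded correlation: dz_m = sum_j w_j * ds_{m - (j - h - 1)}
    dz <- numeric(n)
    for (j in seq_len(k)) {
      shift <- j - h - 1
      src <- seq_len(n) - shift
      ok <- src >= 1 & src <= n
      dz[ok] <- dz[ok] + m$params$weight$value[j] * ds[src[ok]]
    }
    dx <- sweep(dym, 2, cc$a, "*")
    dx <- dx + matrix(rep(dz / npos, each = npos), npos, n)
    array(dx, cc$d)
  }
  m
}

#' Spatial attention weights
#'
#' Channelwise mean and max maps are concatenated to a 2-channel map and
#' passed through a single `k x k` convolution (no bias) and a sigmoid,
#' yielding one weight in (0, 1) per spatial position.
#'
#' @param X feature array dim c(H, W, C).
#' @param kernel numeric array dim c(k, k, 2), the convolution kernel
#'   (channel 1 acts on the mean map, channel 2 on the max map).
#' @return an H x W matrix of weights in (0, 1).
#' @export
sam_weights <- function(X, kernel) {
  k <- dim(kernel)[1]
  if (k %% 2 == 0) stop("SAM kernel size must be odd")
  d <- dim(X)
  xm <- matrix(X, prod(d[1:2]), d[3])
  avg <- array(rowMeans(xm), d[1:2])
  mx <- array(apply(xm, 1, max), d[1:2])
  stacked <- array(c(avg, mx), c(d[1], d[2], 2))
  conv <- layer_conv2d(2L, 1L, k, pad = (k - 1) %/% 2, bias = FALSE)
  conv$params$weight$value[] <- kernel
  s <- conv$forward(stacked)
  matrix(sigmoid(s), d[1], d[2])
}

#' SAM layer (trainable)
#' @param kernel_size 3 or 7 (default 7).
#' @keywords internal
layer_sam <- function(kernel_size = 7L) {
  if (kernel_size %% 2 == 0) stop("SAM kernel size must be odd")
  conv <- layer_conv2d(2L, 1L, kernel_size, pad = (kernel_size - 1L) %/% 2L,
                       bias = FALSE, init = "he")
  conv$params$weight$decay <- FALSE
  m <- fs_module("sam", submodules = list(conv = conv))
  m$forward <- function(x) {
    d <- dim(x)
    npos <- prod(d[1:2])
    xm <- matrix(x, npos, d[3])
    avg <- rowMeans(xm)
    amax <- max.col(xm, ties.method = "first")
    mx <- xm[cbind(seq_len(npos), amax)]
    stacked <- array(c(avg, mx), c(d[1], d[2], 2))
    s <- conv$forward(stacked)
    w <- sigmoid(as.vector(s))
    m$cache <- list(xm = xm, w = w, amax = amax, d = d)
    array(xm * w, d)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d <- cc$d
    npos <- prod(d[1:2])
    dym <- matrix(dy, npos, d[3])
    dw <- rowSums(dym * cc$xm)
    ds <- dw * cc$w * (1 - cc$w)
    dstacked <- conv$backward(array(ds, c(d[1], d[2], 1)))
    davg <- as.vector(dstacked[, , 1])
    dmx <- as.vector(dstacked[, , 2])
    dx <- dym * cc$w + davg / d[3]
    ij <- cbind(seq_len(npos), cc$amax)
    dx[ij] <- dx[ij] + dmx
    array(dx, d)
  }
  m
}
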