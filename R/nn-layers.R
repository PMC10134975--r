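# Individual layers. Convolutions use cached im2col index matrices and BLAS
# matrix products; backward passes scatter-add through the same indices.

.fs_idx_cache <- new.env(parent = emptyenv())

# im2col linear-index matrix for an (Hp, Wp, C) padded array:
# rows = output positions (row index fastest), cols = (dy, dx, ch) taps.
im2col_index <- function(Hp, Wp, C, k, stride) {
  key <- paste(Hp, Wp, C, k, stride, sep = "_")
  idx <- .fs_idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- rep(seq_len(Ho) - 1L, times = Wo) * stride
  ox <- rep(seq_len(Wo) - 1L, each = Ho) * stride
  base <- oy + ox * Hp
  dy <- rep(seq_len(k) - 1L, times = k * C)
  dx <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  ch <- rep(seq_len(C) - 1L, each = k * k)
  off <- dy + dx * Hp + ch * Hp * Wp
  idx <- outer(base, off, "+") + 1L
  attr(idx, "out_hw") <- c(Ho, Wo)
  .fs_idx_cache[[key]] <- idx
  idx
}

pad_hw <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[(p + 1):(p + H), (p + 1):(p + W), , drop = FALSE]
}

#' 2-D convolution layer
#'
#' @param in_ch,out_ch channel counts.
#' @param k odd or even kernel side.
#' @param stride,pad stride and zero padding.
#' @param bias include a bias term.
#' @param depthwise if TRUE, grouped convolution with groups = in_ch
#'   (requires out_ch == in_ch).
#' @param init one of "trunc_normal", "he", "zero", or a numeric sd for plain
#'   normal initialization.
#' @return an `fs_module`.
#' @keywords internal
layer_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE,
                         depthwise = FALSE, init = "trunc_normal") {
  if (depthwise && out_ch != in_ch) stop("depthwise requires out_ch == in_ch")
  wdim <- if (depthwise) c(k, k, in_ch) else c(k, k, in_ch, out_ch)
  fan_in <- if (depthwise) k * k else k * k * in_ch
  w0 <- switch(as.character(init),
    trunc_normal = init_trunc_normal(wdim),
    he = init_he(wdim, fan_in),
    zero = array(0, wdim),
    array(stats::rnorm(prod(wdim), 0, as.numeric(init)), wdim))
  params <- list(weight = fs_parameter(w0))
  if (bias) params$bias <- fs_parameter(numeric(out_ch), decay = FALSE)
  m <- fs_module("conv2d", params = params)
  m$k <- k; m$stride <- stride; m$pad <- pad
  m$in_ch <- in_ch; m$out_ch <- out_ch; m$depthwise <- depthwise

  if (!depthwise) {
    m$forward <- function(x) {
      H <- dim(x)[1]; W <- dim(x)[2]
      xp <- pad_hw(x, pad)
      idx <- im2col_index(dim(xp)[1], dim(xp)[2], in_ch, k, stride)
      hw <- attr(idx, "out_hw")
      xcol <- xp[idx]
      dim(xcol) <- dim(idx)
      wmat <- matrix(m$params$weight$value, k * k * in_ch, out_ch)
      y <- xcol %*% wmat
      if (bias) y <- sweep(y, 2, m$params$bias$value, "+")
      m$cache <- list(xcol = xcol, idx = idx, hw = hw, H = H, W = W,
                      dp = dim(xp))
      array(y, c(hw[1], hw[2], out_ch))
    }
    m$backward <- function(dy) {
      cc <- m$cache
      dym <- matrix(dy, prod(cc$hw), out_ch)
      wmat <- matrix(m$params$weight$value, k * k * in_ch, out_ch)
      m$params$weight$grad <- m$params$weight$grad +
        array(crossprod(cc$xcol, dym), dim(m$params$weight$grad))
      if (bias) m$params$bias$grad <- m$params$bias$grad + colSums(dym)
      dxcol <- tcrossprod(dym, wmat)
      # col2im: per spatial tap, target indices are unique across positions,
      # so plain indexed addition is safe (and fast)
      Hp <- cc$dp[1]; Wp <- cc$dp[2]
      dxpm <- matrix(0, Hp * Wp, in_ch)
      kk <- k * k
      spat <- cc$idx[, seq_len(kk), drop = FALSE]  # channel-0 tap indices
      chcols <- (seq_len(in_ch) - 1L) * kk
      for (j in seq_len(kk)) {
        rows <- spat[, j]
        dxpm[rows, ] <- dxpm[rows, ] + dxcol[, j + chcols, drop = FALSE]
      }
      dxp <- array(dxpm, cc$dp)
      unpad_hw(dxp, pad, cc$H, cc$W)
    }
  } else {
    m$forward <- function(x) {
      H <- dim(x)[1]; W <- dim(x)[2]
      xp <- pad_hw(x, pad)
      Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
      idx <- im2col_index(Hp, Wp, 1L, k, stride)
      hw <- attr(idx, "out_hw")
      xpm <- matrix(xp, Hp * Wp, in_ch)
      w <- matrix(m$params$weight$value, k * k, in_ch)
      y <- matrix(0, prod(hw), in_ch)
      for (j in seq_len(k * k)) {
        y <- y + xpm[idx[, j], , drop = FALSE] *
          rep(w[j, ], each = prod(hw))
      }
      if (bias) y <- sweep(y, 2, m$params$bias$value, "+")
      m$cache <- list(xpm = xpm, idx = idx, hw = hw, H = H, W = W,
                      Hp = Hp, Wp = Wp)
      array(y, c(hw[1], hw[2], in_ch))
    }
    m$backward <- function(dy) {
      cc <- m$cache
      npos <- prod(cc$hw)
      dym <- matrix(dy, npos, in_ch)
      w <- matrix(m$params$weight$value, k * k, in_ch)
      dw <- matrix(0, k * k, in_ch)
      dxpm <- matrix(0, cc$Hp * cc$Wp, in_ch)
      for (j in seq_len(k * k)) {
        rows <- cc$idx[, j]
        dw[j, ] <- colSums(cc$xpm[rows, , drop = FALSE] * dym)
        dxpm[rows, ] <- dxpm[rows, ] + dym * rep(w[j, ], each = npos)
      }
      m$params$weight$grad <- m$params$weight$grad +
        array(dw, dim(m$params$weight$grad))
      if (bias) m$params$bias$grad <- m$params$bias$grad + colSums(dym)
      dxp <- array(dxpm, c(cc$Hp, cc$Wp, in_ch))
      unpad_hw(dxp, pad, cc$H, cc$W)
    }
  }
  m
}

#' Fully connected layer on a flat vector
#' @keywords internal
layer_linear <- function(in_dim, out_dim, bias = TRUE, init = "he") {
  w0 <- switch(as.character(init),
    he = init_he(c(in_dim, out_dim), in_dim),
    trunc_normal = init_trunc_normal(c(in_dim, out_dim)),
    zero = array(0, c(in_dim, out_dim)),
    array(stats::rnorm(in_dim * out_dim, 0, as.numeric(init)),
          c(in_dim, out_dim)))
  params <- list(weight = fs_parameter(w0))
  if (bias) params$bias <- fs_parameter(numeric(out_dim), decay = FALSE)
  m <- fs_module("linear", params = params)
  m$forward <- function(x) {
    xv <- as.vector(x)
    m$cache <- xv
    y <- drop(xv %*% m$params$weight$value)
    if (bias) y <- y + m$params$bias$value
    y
  }
  m$backward <- function(dy) {
    dy <- as.vector(dy)
    m$params$weight$grad <- m$params$weight$grad + outer(m$cache, dy)
    if (bias) m$params$bias$grad <- m$params$bias$grad + dy
    drop(m$params$weight$value %*% dy)
  }
  m
}

#' Layer normalization over the channel axis at every spatial position
#' @keywords internal
layer_norm_channels <- function(C, eps = 1e-6) {
  m <- fs_module("layernorm", params = list(
    gamma = fs_parameter(rep(1, C), decay = FALSE),
    beta = fs_parameter(numeric(C), decay = FALSE)))
  m$forward <- function(x) {
    d <- dim(x)
    xm <- matrix(x, prod(d[1:2]), d[3])
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    m$cache <- list(xhat = xhat, inv = inv, d = d)
    y <- sweep(xhat, 2, m$params$gamma$value, "*")
    y <- sweep(y, 2, m$params$beta$value, "+")
    array(y, d)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dym <- matrix(dy, prod(cc$d[1:2]), cc$d[3])
    m$params$gamma$grad <- m$params$gamma$grad + colSums(dym * cc$xhat)
    m$params$beta$grad <- m$params$beta$grad + colSums(dym)
    dxhat <- sweep(dym, 2, m$params$gamma$value, "*")
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * cc$xhat)
    dx <- cc$inv * (dxhat - t1 - cc$xhat * t2)
    array(dx, cc$d)
  }
  m
}

#' Per-channel learnable scale (layer scale)
#' @keywords internal
layer_scale <- function(C, init_value = 1e-6) {
  m <- fs_module("scale", params = list(
    gamma = fs_parameter(rep(init_value, C), decay = FALSE)))
  m$forward <- function(x) {
    m$cache <- x
    d <- dim(x)
    array(sweep(matrix(x, prod(d[1:2]), d[3]), 2, m$params$gamma$value, "*"), d)
  }
  m$backward <- function(dy) {
    d <- dim(dy)
    dym <- matrix(dy, prod(d[1:2]), d[3])
    xm <- matrix(m$cache, prod(d[1:2]), d[3])
    m$params$gamma$grad <- m$params$gamma$grad + colSums(dym * xm)
    array(sweep(dym, 2, m$params$gamma$value, "*"), d)
  }
  m
}

#' GELU activation (exact, erf form)
#' @keywords internal
layer_gelu <- function() {
  m <- fs_module("gelu")
  m$forward <- function(x) {
    m$cache <- x
    x * stats::pnorm(x)
  }
  m$backward <- function(dy) {
    x <- m$cache
    dy * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  m
}

#' ReLU activation
#' @keywords internal
layer_relu <- function() {
  m <- fs_module("relu")
  m$forward <- function(x) {
    m$cache <- x > 0
    x * m$cache
  }
  m$backward <- function(dy) dy * m$cache
  m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Nearest-neighbour 2x upsampling
#' @keywords internal
layer_upsample2x <- function() {
  m <- fs_module("upsample2x")
  m$forward <- function(x) {
    d <- dim(x)
    ri <- rep(seq_len(d[1]), each = 2)
    ci <- rep(seq_len(d[2]), each = 2)
    m$cache <- d
    x[ri, ci, , drop = FALSE]
  }
  m$backward <- function(dy) {
    d <- m$cache
    dd <- dim(dy)
    # sum each 2x2 block
    g <- dy[seq(1, dd[1], 2), , , drop = FALSE] +
         dy[seq(2, dd[1], 2), , , drop = FALSE]
    g[, seq(1, dd[2], 2), , drop = FALSE] +
      g[, seq(2, dd[2], 2), , drop = FALSE]
  }
  m
}

#' Stride-2 subsampling (used to derive the coarsest pyramid level)
#' @keywords internal
layer_subsample2x <- function() {
  m <- fs_module("subsample2x")
  m$forward <- function(x) {
    m$cache <- dim(x)
    x[seq(1, dim(x)[1], 2), seq(1, dim(x)[2], 2), , drop = FALSE]
  }
  m$backward <- function(dy) {
    d <- m$cache
    dx <- array(0, d)
    dx[seq(1, d[1], 2), seq(1, d[2], 2), ] <- dy
    dx
  }
  m
}
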