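# ConvNeXt-style backbone with efficient channel attention appended to each
# stage, a standard FPN neck, and exact parameter accounting.
#
# Stage layout (tiny variant of the ConvNeXt family): 4x4/4 conv stem with a
# channel layer norm, four stages of depths (3,3,9,3) at widths
# (96,192,384,768); each block is 7x7 depthwise conv -> LN -> 1x1 expand
# (4x) -> GELU -> 1x1 project -> per-channel scale, with a residual. Between
# stages: LN + 2x2/2 conv downsampling. With ECA enabled, one ECA module
# reweights each stage's output after its final block (adding
# 3 + 5 + 5 + 5 = 18 scalars over the four stages).

#' Backbone configuration
#'
#' @param depths,widths per-stage block counts and channel widths (length 4,
#'   widths strictly increasing).
#' @param eca_enabled append an ECA module to each stage output.
#' @param eca_gamma,eca_b adaptive kernel-size coefficients.
#' @param layer_scale_init initial per-channel scale (1e-6).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(depths = c(3L, 3L, 9L, 3L),
                            widths = c(96L, 192L, 384L, 768L),
                            eca_enabled = TRUE, eca_gamma = 2, eca_b = 1,
                            layer_scale_init = 1e-6) {
  stopifnot(length(depths) == 4, length(widths) == 4,
            all(diff(widths) > 0))
  structure(list(depths = as.integer(depths), widths = as.integer(widths),
                 eca_enabled = eca_enabled, eca_gamma = eca_gamma,
                 eca_b = eca_b, layer_scale_init = layer_scale_init),
            class = "backbone_config")
}

#' Reduced backbone configuration for CPU-scale runs
#' @inheritParams backbone_config
#' @export
tiny_backbone_config <- function(eca_enabled = TRUE) {
  backbone_config(depths = c(1L, 1L, 2L, 1L), widths = c(32L, 64L, 128L, 256L),
                  eca_enabled = eca_enabled)
}

build_convnext_block <- function(C, ls_init = 1e-6) {
  sub <- list(
    dw = layer_conv2d(C, C, 7L, pad = 3L, depthwise = TRUE),
    norm = layer_norm_channels(C),
    pw1 = layer_conv2d(C, 4L * C, 1L),
    act = layer_gelu(),
    pw2 = layer_conv2d(4L * C, C, 1L),
    scale = layer_scale(C, ls_init))
  m <- fs_module("convnext_block", submodules = sub)
  m$forward <- function(x) {
    y <- x
    for (l in m$submodules) y <- l$forward(y)
    x + y
  }
  m$backward <- function(dy) {
    g <- dy
    for (l in rev(m$submodules)) g <- l$backward(g)
    g + dy
  }
  m
}

#' Build the backbone module
#'
#' @param config a [backbone_config()].
#' @return an `fs_module` whose `$forward(image)` returns the list of four
#'   stage features (strides 4, 8, 16, 32) and whose `$backward(grads)`
#'   accepts the matching gradient list.
#' @export
build_backbone <- function(config) {
  w <- config$widths
  sub <- list(
    stem = layer_conv2d(3L, w[1], 4L, stride = 4L),
    stem_norm = layer_norm_channels(w[1]))
  for (s in 1:4) {
    if (s > 1) {
      sub[[paste0("down", s)]] <- nn_sequential(list(
        norm = layer_norm_channels(w[s - 1]),
        conv = layer_conv2d(w[s - 1], w[s], 2L, stride = 2L)))
    }
    blocks <- lapply(seq_len(config$depths[s]), function(b) {
      build_convnext_block(w[s], config$layer_scale_init)
    })
    names(blocks) <- sprintf("b%d", seq_along(blocks))
    sub[[paste0("stage", s)]] <- nn_sequential(blocks)
    if (config$eca_enabled) {
      sub[[paste0("eca", s)]] <- layer_eca(w[s], config$eca_gamma, config$eca_b)
    }
  }
  m <- fs_module("backbone", submodules = sub)
  m$config <- config
  m$forward <- function(image) {
    x <- m$submodules$stem_norm$forward(m$submodules$stem$forward(image))
    feats <- vector("list", 4)
    for (s in 1:4) {
      if (s > 1) x <- m$submodules[[paste0("down", s)]]$forward(x)
      x <- m$submodules[[paste0("stage", s)]]$forward(x)
      if (config$eca_enabled) {
        x <- m$submodules[[paste0("eca", s)]]$forward(x)
      }
      feats[[s]] <- x
    }
    feats
  }
  m$backward <- function(dfeats) {
    g <- NULL
    for (s in 4:1) {
      gs <- dfeats[[s]]
      if (!is.null(g)) gs <- gs + g
      if (config$eca_enabled) {
        gs <- m$submodules[[paste0("eca", s)]]$backward(gs)
      }
      gs <- m$submodules[[paste0("stage", s)]]$backward(gs)
      g <- if (s > 1) m$submodules[[paste0("down", s)]]$backward(gs) else gs
    }
    m$submodules$stem$backward(m$submodules$stem_norm$backward(g))
  }
  m
}

#' Forward pass through the backbone
#'
#' Pads the image on the right/bottom to a multiple of 32 if needed (the
#' original size is recorded in the `orig_size` attribute of the result).
#'
#' @param backbone module from [build_backbone()].
#' @param image H x W x 3 array (normalized).
#' @return list of four stage feature arrays at strides 4, 8, 16, 32.
#' @export
backbone_forward <- function(backbone, image) {
  d <- dim(image)
  H32 <- 32 * ceiling(d[1] / 32); W32 <- 32 * ceiling(d[2] / 32)
  if (H32 != d[1] || W32 != d[2]) {
    padded <- array(0, c(H32, W32, 3))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- image
    image <- padded
  }
  feats <- backbone$forward(image)
  attr(feats, "orig_size") <- d[1:2]
  feats
}

# --- parameter accounting ----------------------------------------------------

#' Closed-form backbone parameter count
#'
#' Sums every trainable scalar in the backbone (stem, blocks, downsamplers,
#' ECA kernels; no classification head, no FPN). Matches
#' [module_n_parameters()] on the instantiated module exactly.
#'
#' @param config a [backbone_config()].
#' @return count of trainable scalars.
#' @export
count_backbone_parameters <- function(config) {
  w <- config$widths
  block <- function(C) {
    (49 * C + C) +            # depthwise 7x7 + bias
      2 * C +                 # layer norm
      (C * 4 * C + 4 * C) +   # 1x1 expand
      (4 * C * C + C) +       # 1x1 project
      C                       # layer scale
  }
  total <- (3 * 16 * w[1] + w[1]) + 2 * w[1]   # stem conv + stem norm
  for (s in 1:4) {
    if (s > 1) {
      total <- total + 2 * w[s - 1] +                  # downsample norm
        (w[s - 1] * 4 * w[s] + w[s])                   # 2x2 conv + bias
    }
    total <- total + config$depths[s] * block(w[s])
    if (config$eca_enabled) {
      total <- total + eca_kernel_size(w[s], config$eca_gamma, config$eca_b)
    }
  }
  total
}

# --- FPN ---------------------------------------------------------------------

#' Build the feature pyramid network
#'
#' Lateral 1x1 projections to `out_channels`, top-down nearest-neighbour
#' upsampling with addition, 3x3 output smoothing, and a stride-2 subsampled
#' P6 on top of P5. Levels P2..P6 sit at strides 4, 8, 16, 32, 64.
#'
#' @param in_channels the four backbone stage widths.
#' @param out_channels pyramid width (256 in the full model).
#' @return an `fs_module`: `$forward(stage_feats)` -> named list P2..P6;
#'   `$backward(dlevels)` -> gradient list for the stage features.
#' @export
build_fpn <- function(in_channels, out_channels = 256L) {
  sub <- list()
  for (i in 1:4) {
    sub[[paste0("lateral", i)]] <- layer_conv2d(in_channels[i], out_channels, 1L)
    sub[[paste0("out", i)]] <- layer_conv2d(out_channels, out_channels, 3L,
                                            pad = 1L)
  }
  sub$up3 <- layer_upsample2x(); sub$up2 <- layer_upsample2x()
  sub$up1 <- layer_upsample2x()
  sub$pool6 <- layer_subsample2x()
  m <- fs_module("fpn", submodules = sub)
  m$out_channels <- out_channels
  m$forward <- function(feats) {
    lat <- lapply(1:4, function(i) {
      m$submodules[[paste0("lateral", i)]]$forward(feats[[i]])
    })
    tops <- vector("list", 4)
    tops[[4]] <- lat[[4]]
    for (i in 3:1) {
      tops[[i]] <- lat[[i]] +
        m$submodules[[paste0("up", i)]]$forward(tops[[i + 1]])
    }
    out <- lapply(1:4, function(i) {
      m$submodules[[paste0("out", i)]]$forward(tops[[i]])
    })
    p6 <- m$submodules$pool6$forward(out[[4]])
    stats::setNames(c(out, list(p6)), c("P2", "P3", "P4", "P5", "P6"))
  }
  m$backward <- function(dlevels) {
    d_out <- list(dlevels$P2, dlevels$P3, dlevels$P4,
                  dlevels$P5 + m$submodules$pool6$backward(dlevels$P6))
    d_top <- lapply(1:4, function(i) {
      m$submodules[[paste0("out", i)]]$backward(d_out[[i]])
    })
    for (i in 1:3) {
      d_top[[i + 1]] <- d_top[[i + 1]] +
        m$submodules[[paste0("up", i)]]$backward(d_top[[i]])
    }
    lapply(1:4, function(i) {
      m$submodules[[paste0("lateral", i)]]$backward(d_top[[i]])
    })
  }
  m
}

#' Pyramid strides for levels P2..P6
#' @return named integer vector.
#' @export
fpn_strides <- function() c(P2 = 4L, P3 = 8L, P4 = 16L, P5 = 32L, P6 = 64L)
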