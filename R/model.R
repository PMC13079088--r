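#' Specification of the compact keypoint detector
#'
#' A small three-branch high-resolution convolutional network: a stride-2
#' stem keeps a half-resolution feature stream alive end-to-end while two
#' coarser branches (1/4 and 1/8 resolution, doubling channel width) supply
#' context, fused back into the high-resolution stream by 1x1 convolutions
#' and nearest-neighbour upsampling. The head emits a sigmoid heatmap at
#' half the input resolution (`downsample = 2`). Keeping the coarsest
#' pyramid levels pruned bounds the receptive field, which is measured at
#' construction by a gradient-impulse probe and must stay within
#' `receptive_field_bound` input pixels.
#'
#' @param channels Width of the high-resolution branch (coarser branches use
#'   2x and 4x this width).
#' @param receptive_field_bound Maximum allowed effective receptive field
#'   (input px).
#' @param parameter_budget Maximum allowed number of trainable parameters.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(channels = 6L, receptive_field_bound = 96L,
                       parameter_budget = 20000L) {
  stopifnot(channels >= 2, receptive_field_bound >= 8)
  structure(list(channels = as.integer(channels),
                 branches = 3L,
                 downsample = 2L,
                 receptive_field_bound = as.integer(receptive_field_bound),
                 parameter_budget = as.integer(parameter_budget)),
            class = "model_spec")
}

# Layer table for the fixed 3-branch topology. pad keeps "same" geometry.
model_layers <- function(spec) {
  C <- spec$channels
  list(
    stem = list(k = 3L, stride = 2L, dil = 1L, cin = 1L,     cout = C),
    b1   = list(k = 3L, stride = 1L, dil = 1L, cin = C,      cout = C),
    d2   = list(k = 3L, stride = 2L, dil = 1L, cin = C,      cout = 2L * C),
    b2   = list(k = 3L, stride = 1L, dil = 1L, cin = 2L * C, cout = 2L * C),
    d3   = list(k = 3L, stride = 2L, dil = 1L, cin = 2L * C, cout = 4L * C),
    b3   = list(k = 3L, stride = 1L, dil = 1L, cin = 4L * C, cout = 4L * C),
    f2   = list(k = 1L, stride = 1L, dil = 1L, cin = 2L * C, cout = C),
    f3   = list(k = 1L, stride = 1L, dil = 1L, cin = 4L * C, cout = C),
    h1   = list(k = 3L, stride = 1L, dil = 1L, cin = C,      cout = C),
    h2   = list(k = 1L, stride = 1L, dil = 1L, cin = C,      cout = 1L))
}

layer_pad <- function(l) as.integer((l$k - 1L) * l$dil / 2L)

#' Build (initialize) a keypoint detector
#'
#' Seeded He-normal initialization; the same seed always yields the same
#' weights. The effective receptive field is measured numerically at
#' construction and the constructor errors if it exceeds the spec bound, or
#' if the parameter count exceeds the budget.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `keypoint_model`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- model_layers(spec)
  weights <- with_seed(as.integer(seed), {
    lapply(layers, function(l) {
      fan_in <- l$k * l$k * l$cin
      list(w = matrix(stats::rnorm(l$cout * fan_in, 0, sqrt(2 / fan_in)),
                      l$cout, fan_in),
           b = rep(0, l$cout))
    })
  })
  # bias the logit head towards "no cell" so blank frames start near 0
  weights$h2$b <- rep(-3, layers$h2$cout)
  model <- structure(list(spec = spec, layers = layers, weights = weights,
                          seed = as.integer(seed)),
                     class = "keypoint_model")
  np <- n_parameters(model)
  if (np > spec$parameter_budget)
    stop(sprintf("parameter count %d exceeds budget %d", np,
                 spec$parameter_budget))
  rf <- measure_receptive_field(model)
  if (rf > spec$receptive_field_bound)
    stop(sprintf("measured receptive field %d px exceeds bound %d px", rf,
                 spec$receptive_field_bound))
  model$receptive_field_px <- rf
  model
}

#' @export
print.keypoint_model <- function(x, ...) {
  cat(sprintf(paste0(
    "keypoint_model: 3-branch high-resolution net, C = %d, %d parameters,\n",
    "  output stride %d, measured receptive field %s px (bound %d)\n"),
    x$spec$channels, n_parameters(x), x$spec$downsample,
    if (is.null(x$receptive_field_px)) "?" else x$receptive_field_px,
    x$spec$receptive_field_bound))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `keypoint_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, function(wb) length(wb$w) + length(wb$b), 0))
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

conv_l <- function(model, name, x) {
  l <- model$layers[[name]]
  wb <- model$weights[[name]]
  conv2d_fwd(x, wb$w, wb$b, l$k, l$stride, layer_pad(l), l$dil)
}

relu <- function(x) { x[x < 0] <- 0; x }

#' Run the detector on one frame
#'
#' @param model A `keypoint_model`.
#' @param x Numeric matrix (normalized frame); both dimensions must be
#'   divisible by 8.
#' @param cache Keep intermediate activations (needed for backprop)?
#' @return Heatmap matrix (`H/2 x W/2`, values in `[0, 1]`); with
#'   `cache = TRUE`, a list `list(p, cache)`.
#' @export
model_forward <- function(model, x, cache = FALSE) {
  stopifnot(inherits(model, "keypoint_model"))
  if (is.matrix(x)) {
    if (nrow(x) %% 8L != 0L || ncol(x) %% 8L != 0L)
      stop("frame dimensions must be divisible by 8")
  }
  x0 <- as_cube(x)
  s   <- relu(conv_l(model, "stem", x0))
  a   <- relu(conv_l(model, "b1", s))
  d2o <- relu(conv_l(model, "d2", a))
  b2o <- relu(conv_l(model, "b2", d2o))
  d3o <- relu(conv_l(model, "d3", b2o))
  b3o <- relu(conv_l(model, "b3", d3o))
  c2  <- conv_l(model, "f2", b2o)
  c3  <- conv_l(model, "f3", b3o)
  ff  <- relu(a + upsample_nn_fwd(c2, 2L) + upsample_nn_fwd(c3, 4L))
  hh  <- relu(conv_l(model, "h1", ff))
  z   <- conv_l(model, "h2", hh)
  p   <- 1 / (1 + exp(-z[, , 1]))
  if (!cache) return(p)
  list(p = p, cache = list(x0 = x0, s = s, a = a, d2o = d2o, b2o = b2o,
                           d3o = d3o, b3o = b3o, ff = ff, hh = hh, z = z))
}

bwd_l <- function(model, name, x, gy) {
  l <- model$layers[[name]]
  conv2d_bwd(x, model$weights[[name]]$w, gy, l$k, l$stride, layer_pad(l),
             l$dil)
}

relu_bwd <- function(g, act) g * (act > 0)

# Backpropagate d(loss)/d(logits) through the network.
# Returns per-layer weight/bias gradients plus the input gradient.
model_backward <- function(model, cache, gz) {
  gz3 <- array(gz, dim = c(dim(gz), 1L))
  g_h2 <- bwd_l(model, "h2", cache$hh, gz3)
  ghh <- relu_bwd(g_h2$gx, cache$hh)
  g_h1 <- bwd_l(model, "h1", cache$ff, ghh)
  gff <- relu_bwd(g_h1$gx, cache$ff)
  ga <- gff
  gc2 <- upsample_nn_bwd(gff, 2L)
  gc3 <- upsample_nn_bwd(gff, 4L)
  g_f2 <- bwd_l(model, "f2", cache$b2o, gc2)
  g_f3 <- bwd_l(model, "f3", cache$b3o, gc3)
  gb3o <- relu_bwd(g_f3$gx, cache$b3o)
  g_b3 <- bwd_l(model, "b3", cache$d3o, gb3o)
  gd3o <- relu_bwd(g_b3$gx, cache$d3o)
  g_d3 <- bwd_l(model, "d3", cache$b2o, gd3o)
  gb2o <- relu_bwd(g_f2$gx + g_d3$gx, cache$b2o)
  g_b2 <- bwd_l(model, "b2", cache$d2o, gb2o)
  gd2o <- relu_bwd(g_b2$gx, cache$d2o)
  g_d2 <- bwd_l(model, "d2", cache$a, gd2o)
  ga <- relu_bwd(ga + g_d2$gx, cache$a)
  g_b1 <- bwd_l(model, "b1", cache$s, ga)
  gs <- relu_bwd(g_b1$gx, cache$s)
  g_stem <- bwd_l(model, "stem", cache$x0, gs)
  list(grads = list(stem = g_stem, b1 = g_b1, d2 = g_d2, b2 = g_b2,
                    d3 = g_d3, b3 = g_b3, f2 = g_f2, f3 = g_f3,
                    h1 = g_h1, h2 = g_h2),
       gx = g_stem$gx)
}

#' Measure the effective receptive field
#'
#' Gradient-impulse probe: back-propagates a unit impulse placed at the
#' centre of the output heatmap through the network (for a few random
#' inputs) and measures the spatial extent of nonzero input gradient. This
#' is the effective receptive field actually seen by the output unit.
#'
#' @param model A `keypoint_model`.
#' @param shape Probe grid `c(height, width)`, divisible by 8.
#' @param n_probes Number of random-input probes; the max extent is reported.
#' @return Receptive-field side length in input pixels.
#' @export
measure_receptive_field <- function(model, shape = c(104L, 104L),
                                    n_probes = 2L) {
  h <- shape[1]; w <- shape[2]
  ext <- 0L
  for (i in seq_len(n_probes)) {
    x <- with_seed(1000L + i, matrix(stats::rnorm(h * w), h, w))
    fw <- model_forward(model, x, cache = TRUE)
    gz <- matrix(0, nrow(fw$p), ncol(fw$p))
    cy <- ceiling(nrow(gz) / 2); cx <- ceiling(ncol(gz) / 2)
    gz[cy, cx] <- 1
    gx <- model_backward(model, fw$cache, gz)$gx[, , 1]
    nz <- which(abs(gx) > 1e-12, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    # impulse at output (cy,cx) maps to input pixel (2cy-1, 2cx-1) region
    span <- max(max(nz[, 1]) - min(nz[, 1]), max(nz[, 2]) - min(nz[, 2])) + 1L
    ext <- max(ext, span)
  }
  as.integer(ext)
}

#' Bilinear upsampling of a heatmap
#'
#' Used to lift the half-resolution output heatmap back to input resolution
#' for peak localization.
#'
#' @param m Numeric matrix.
#' @param f Integer upsampling factor.
#' @return Matrix `f*nrow x f*ncol`.
#' @export
upsample_bilinear <- function(m, f = 2L) {
  h <- nrow(m); w <- ncol(m)
  # output pixel centres mapped into input coordinates (align-corners false)
  yo <- ((seq_len(h * f) - 0.5) / f) - 0.5
  xo <- ((seq_len(w * f) - 0.5) / f) - 0.5
  y0 <- pmin(pmax(floor(yo), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xo), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(yo - y0, 0), 1); wx <- pmin(pmax(xo - x0, 0), 1)
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  WY <- matrix(wy, length(yo), length(xo))
  WX <- matrix(wx, length(yo), length(xo), byrow = TRUE)
  m00 * (1 - WY) * (1 - WX) + m01 * (1 - WY) * WX +
    m10 * WY * (1 - WX) + m11 * WY * WX
}
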