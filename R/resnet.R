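# 50-layer residual scalogram encoder. The standard bottleneck layout
# (stages of 3/4/6/3 blocks, widths 64/128/256/512 with expansion 4) is
# instantiated with seeded He-normal weights and used as a fixed feature
# extractor: the global pooling of the final 7 x 7 x 2048 map gives the
# 2048-dimensional branch feature. Normalisation layers at their identity
# initialisation are omitted from the forward pass (they would be no-ops).

RESNET_STAGES <- list(c(blocks = 3L, width = 64L), c(blocks = 4L, width = 128L),
                      c(blocks = 6L, width = 256L), c(blocks = 3L, width = 512L))

he_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(w = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), nrow = fan_in),
       b = numeric(cout), kh = kh, kw = kw)
}

#' Instantiate 50-layer residual network weights
#'
#' `random-fixed` mode draws He-normal weights under the given seed; with a
#' fixed seed the extractor is a deterministic, training-free image
#' embedding (the network is never trained here, matching its use as a
#' frozen feature extractor). Weight sets are cached per seed within the
#' session.
#'
#' @param weights_mode `"random-fixed"` (default). `"pretrained"` requires
#'   externally supplied weights via `weights_file` (an RDS file with the
#'   same structure as this function's value); no download is performed.
#' @param seed Integer seed for `random-fixed` initialisation.
#' @param weights_file Path to a weights RDS file for `"pretrained"`.
#' @return Weight list of class `resnet50_weights`.
#' @export
resnet50_weights <- function(weights_mode = c("random-fixed", "pretrained"),
                             seed = 42L, weights_file = NULL) {
  weights_mode <- match.arg(weights_mode)
  if (weights_mode == "pretrained") {
    if (is.null(weights_file) || !file.exists(weights_file %||% ""))
      stopf("pretrained mode needs `weights_file` (no weights are bundled)")
    w <- readRDS(weights_file)
    stopifnot(inherits(w, "resnet50_weights"))
    return(w)
  }
  key <- as.character(seed)
  if (!is.null(.resnet_cache[[key]])) return(.resnet_cache[[key]])
  w <- with_local_seed(seed, {
    stem <- he_conv(7L, 7L, 3L, 64L)
    cin <- 64L
    stages <- lapply(seq_along(RESNET_STAGES), function(si) {
      st <- RESNET_STAGES[[si]]
      width <- st[["width"]]; cout <- 4L * width
      lapply(seq_len(st[["blocks"]]), function(bi) {
        stride <- if (bi == 1L && si > 1L) 2L else 1L
        blk <- list(
          conv1 = he_conv(1L, 1L, cin, width),
          conv2 = he_conv(3L, 3L, width, width),
          conv3 = he_conv(1L, 1L, width, cout),
          stride = stride,
          proj = if (bi == 1L) he_conv(1L, 1L, cin, cout) else NULL)
        cin <<- cout
        blk
      })
    })
    structure(list(stem = stem, stages = stages, seed = seed),
              class = "resnet50_weights")
  })
  .resnet_cache[[key]] <- w
  w
}

.resnet_cache <- new.env(parent = emptyenv())

relu_cube <- function(x) { x[x < 0] <- 0; x }

bottleneck_forward <- function(x, blk) {
  s <- blk$stride
  out <- relu_cube(conv2d_forward(x, blk$conv1$w, blk$conv1$b, 1L, 1L, 1L, 0L))
  out <- relu_cube(conv2d_forward(out, blk$conv2$w, blk$conv2$b, 3L, 3L, s, 1L))
  out <- conv2d_forward(out, blk$conv3$w, blk$conv3$b, 1L, 1L, 1L, 0L)
  shortcut <- if (!is.null(blk$proj))
    conv2d_forward(x, blk$proj$w, blk$proj$b, 1L, 1L, s, 0L)
  else x
  relu_cube(out + shortcut)
}

#' Convolutional features of a scalogram image
#'
#' Runs a 224 x 224 x 3 image through the 50-layer residual network and
#' returns the spatially pooled output of the last convolutional stage: a
#' 2048-vector, deterministic for fixed weights.
#'
#' @param image 224 x 224 x 3 array with values in `[0, 255]` (from
#'   [render_scalogram_image()]).
#' @param weights A [resnet50_weights()] object, or `NULL` to use the
#'   default seeded `random-fixed` weights.
#' @return Numeric feature vector of length 2048.
#' @export
cnn_scalogram_features <- function(image, weights = NULL) {
  if (!is.array(image) || length(dim(image)) != 3L ||
      !all(dim(image) == c(224L, 224L, 3L)))
    stopf("`image` must be a 224 x 224 x 3 array (got %s)",
          paste(dim(image), collapse = " x "))
  weights <- weights %||% resnet50_weights()
  x <- array(image / 255 - 0.5, dim = dim(image))
  x <- relu_cube(conv2d_forward(x, weights$stem$w, weights$stem$b, 7L, 7L, 2L, 3L))
  x <- maxpool2d(x, 3L, 2L, 1L)
  for (stage in weights$stages)
    for (blk in stage)
      x <- bottleneck_forward(x, blk)
  apply(x, 3L, mean)
}
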