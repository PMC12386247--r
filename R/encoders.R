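# Modality-specific encoders: two shallow convolutional branches (RGB and
# thermal) producing C x H x W feature maps, and an affine environmental
# encoder producing a width-64 embedding. "Shallow" is realized as three
# conv3x3 -> RMSNorm -> SiLU blocks with stride-2 downsampling in the first
# two, followed by adaptive average pooling to the declared spatial size, so
# the output shape is fixed regardless of input resolution.

#' Feature map container
#'
#' Tokens are spatial positions in R's column-major order; semantically the
#' tensor is channels-first `C x H x W` as declared by `layout`.
#' @param x `(H*W) x C` matrix or `ag` node.
#' @param H,W Spatial extent.
#' @param modality One of `"rgb"`, `"thermal"`, `"fused"`.
#' @return A `pf_fmap` list with fields `x`, `H`, `W`, `C`, `modality`,
#'   `layout`.
#' @export
feature_map <- function(x, H, W, modality = c("rgb", "thermal", "fused")) {
  modality <- match.arg(modality)
  v <- ag_val(x)
  stopifnot(nrow(v) == H * W, all(is.finite(v)), H > 0, W > 0, ncol(v) > 0)
  structure(list(x = x, H = H, W = W, C = ncol(v), modality = modality,
                 layout = "C x H x W (stored as (H*W) x C tokens, column-major spatial)"),
            class = "pf_fmap")
}

#' Construct a shallow convolutional image encoder
#'
#' @param cin Input channels (3 for RGB, 1 for thermal).
#' @param channels Output channel count `C`.
#' @param spatial Output spatial side `H = W`.
#' @param depth Number of conv blocks (the first two downsample by 2).
#' @return An encoder module.
#' @export
image_encoder_new <- function(cin, channels = 64L, spatial = 64L, depth = 3L) {
  widths <- unique(round(seq(max(4, channels / 4), channels,
                             length.out = depth)))
  widths <- c(widths, rep(channels, depth - length(widths)))[seq_len(depth)]
  widths[depth] <- channels
  blocks <- vector("list", depth)
  prev <- cin
  for (i in seq_len(depth)) {
    blocks[[i]] <- list(
      conv = conv_new(prev, widths[i], 3L, stride = if (i <= 2L) 2L else 1L),
      gain = ag_param(rep(1, widths[i])))
    prev <- widths[i]
  }
  structure(list(blocks = blocks, cin = cin, channels = channels,
                 spatial = spatial),
            class = "pf_image_encoder")
}

# image array (H x W x C or H x W) -> (H*W) x C token matrix
image_to_tokens <- function(img) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  matrix(img, nrow = prod(dim(img)[1:2]), ncol = dim(img)[3])
}

#' Encode an image into a fixed-shape feature map
#'
#' @param enc An [image_encoder_new()] module.
#' @param img `H x W x C` (RGB) or `H x W` (thermal) array in `[0, 1]`, with
#'   spatial side at least 64 px at the published scale (any size the conv
#'   stack can downsample works).
#' @param modality Tag for the resulting [feature_map()].
#' @return A `pf_fmap` with `C = channels`, `H = W = spatial`.
#' @export
encode_image <- function(enc, img, modality = "rgb") {
  d <- dim(img)
  cin <- if (length(d) == 3L) d[3] else 1L
  if (cin != enc$cin) {
    stop(sprintf("encoder expects %d input channel(s), got %d", enc$cin, cin))
  }
  x <- image_to_tokens(img)
  H <- d[1]; W <- d[2]
  for (bl in enc$blocks) {
    r <- conv_apply(bl$conv, x, H, W)
    x <- ag_silu(rmsnorm_apply(r$x, bl$gain))
    H <- r$H; W <- r$W
  }
  if (H != enc$spatial || W != enc$spatial) {
    P <- adaptive_pool_matrix(H, W, enc$spatial, enc$spatial)
    x <- ag_matmul(P, x)
    H <- W <- enc$spatial
  }
  feature_map(x, H, W, modality)
}

#' Construct the affine environmental encoder
#'
#' Projects the 3-vector (temperature, humidity, light; all min-max
#' normalized) into a `width`-dimensional embedding. The map is affine:
#' `encode(0)` is the bias vector.
#' @param width Embedding width (64 in the published model).
#' @return An encoder module.
#' @export
env_encoder_new <- function(width = 64L) {
  structure(list(lin = linear_new(3L, width), width = width),
            class = "pf_env_encoder")
}

#' Encode environment vectors
#'
#' @param enc An [env_encoder_new()] module.
#' @param x A length-3 vector or a `T x 3` matrix of normalized environment
#'   readings (a 1 Hz history, oldest first).
#' @return A `T x width` embedding node (one row for a single vector).
#' @export
encode_env <- function(enc, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3L, all(is.finite(x)))
  linear_apply(enc$lin, x)
}
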