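#' Convolutional layer geometry
#'
#' Describes a single 2-D convolutional layer by its kernel size, stride,
#' zero padding and kernel count. The default matches the first
#' convolutional layer of AlexNet (11 x 11 kernels, stride 4, padding 2,
#' 64 kernels), which for a 640 x 360 input frame yields an
#' 89 x 159 x 64 activation volume.
#'
#' @param kernel kernel size in pixels (square kernels).
#' @param stride stride in pixels.
#' @param padding zero padding in pixels per border.
#' @param n_kernels number of kernels (output channels).
#' @export
conv_layer_spec <- function(kernel = 11L, stride = 4L, padding = 2L,
                            n_kernels = 64L) {
  stopifnot_scalar_count(kernel, "kernel", min = 1L)
  stopifnot_scalar_count(stride, "stride", min = 1L)
  stopifnot_scalar_count(padding, "padding", min = 0L)
  stopifnot_scalar_count(n_kernels, "n_kernels", min = 1L)
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = as.integer(padding), n_kernels = as.integer(n_kernels)),
            class = "conv_layer_spec")
}

#' Output shape of a convolutional layer
#'
#' Standard convolution arithmetic:
#' `out = floor((in + 2 * padding - kernel) / stride) + 1` per spatial axis.
#'
#' @param input_h,input_w input height and width in pixels.
#' @param spec a [conv_layer_spec()].
#' @return Integer vector `c(out_h, out_w, n_kernels)`.
#' @export
#'
#' @examples
#' conv_output_shape(360, 640, conv_layer_spec())  # 89 159 64
conv_output_shape <- function(input_h, input_w, spec = conv_layer_spec()) {
  stopifnot(inherits(spec, "conv_layer_spec"))
  out <- function(n) {
    o <- floor((n + 2 * spec$padding - spec$kernel) / spec$stride) + 1
    if (o < 1) stop("input too small for kernel/stride/padding", call. = FALSE)
    as.integer(o)
  }
  c(out(input_h), out(input_w), spec$n_kernels)
}

#' Extract first-layer convolutional features from an image
#'
#' Applies a single 2-D convolutional layer (cross-correlation, as in deep
#' learning frameworks) with the given weights to one image and returns the
#' flattened activation volume. The operation is linear in the image for
#' fixed weights; an optional rectification (`relu`, the default, matching
#' post-activation features) can be disabled with `activation = "linear"`.
#' Weights are accepted as supplied (e.g. exported from any pretrained
#' network); no weights ship with the package.
#'
#' @param image numeric matrix `[h, w]` (single channel) or array
#'   `[h, w, c]`.
#' @param spec a [conv_layer_spec()].
#' @param weights array `[kernel, kernel, in_channels, n_kernels]`.
#' @param bias numeric vector of length `n_kernels` (default zeros).
#' @param activation `"relu"` or `"linear"`.
#' @return Numeric array `[out_h, out_w, n_kernels]` with attribute
#'   `activation`.
#' @export
extract_conv_features <- function(image, spec, weights, bias = NULL,
                                  activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot(length(dim(image)) == 3L, length(dim(weights)) == 4L)
  if (dim(weights)[1] != spec$kernel || dim(weights)[2] != spec$kernel ||
      dim(weights)[3] != dim(image)[3] || dim(weights)[4] != spec$n_kernels) {
    stop("weights shape must be [kernel, kernel, in_channels, n_kernels]",
         call. = FALSE)
  }
  bias <- bias %||% rep(0, spec$n_kernels)
  stopifnot(length(bias) == spec$n_kernels)

  shape <- conv_output_shape(dim(image)[1], dim(image)[2], spec)
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  k <- spec$kernel; s <- spec$stride; p <- spec$padding
  padded <- array(0, c(h + 2 * p, w + 2 * p, nc))
  padded[p + seq_len(h), p + seq_len(w), ] <- image

  # im2col: rows = output positions (column-major over [out_h, out_w], so
  # the result reshapes directly into the activation array), cols = kernel
  # entries (row, col, channel)
  out_h <- shape[1]; out_w <- shape[2]
  top <- (seq_len(out_h) - 1L) * s
  left <- (seq_len(out_w) - 1L) * s
  patch <- matrix(0, out_h * out_w, k * k * nc)
  col <- 0L
  for (ch in seq_len(nc)) {
    for (kc in seq_len(k)) {
      for (kr in seq_len(k)) {
        col <- col + 1L
        block <- padded[top + kr, left + kc, ch, drop = FALSE]
        patch[, col] <- as.numeric(block)
      }
    }
  }
  wmat <- matrix(weights, k * k * nc, spec$n_kernels)
  act <- patch %*% wmat
  act <- sweep(act, 2L, bias, "+")
  if (activation == "relu") act <- pmax(act, 0)
  out <- array(act, c(out_h, out_w, spec$n_kernels))
  attr(out, "activation") <- activation
  out
}

#' Per-frame motion energy from dense optical flow
#'
#' Motion energy for frame *f* is the sum over pixels of the flow-vector
#' magnitude `sqrt(u^2 + v^2)` at that frame (componentwise sums can cancel
#' opposing motion, magnitudes cannot). One scalar per frame.
#'
#' @param flow_fields list with one element per frame; each element either a
#'   numeric array `[h, w, 2]` of (u, v) components or a complex matrix
#'   `u + i v`.
#' @return Numeric vector of length `length(flow_fields)`.
#' @export
#'
#' @examples
#' f <- array(1 / sqrt(2), c(10, 10, 2))  # unit-magnitude flow everywhere
#' motion_energy_vector(list(f))  # 100
motion_energy_vector <- function(flow_fields) {
  if (length(flow_fields) < 1L) stop("need at least one frame", call. = FALSE)
  vapply(flow_fields, function(f) {
    if (is.complex(f)) {
      if (length(f) == 0L) stop("empty frame", call. = FALSE)
      sum(Mod(f))
    } else {
      stopifnot(length(dim(f)) == 3L, dim(f)[3] == 2L)
      if (prod(dim(f)[1:2]) == 0L) stop("empty frame", call. = FALSE)
      sum(sqrt(f[, , 1]^2 + f[, , 2]^2))
    }
  }, numeric(1))
}
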