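#' Normalize integer pixel intensities to the unit interval
#'
#' Fixed-scale normalization: raw values are divided by the dtype maximum
#' (`2^bit_depth - 1`), never min-max scaled per image, so that genuine
#' brightness differences between frames — the diagnostic fluorescein signal —
#' survive preprocessing. Normalizing an already-normalized frame (values in
#' `[0, 1]`, `bit_depth = NULL`) is the identity.
#'
#' @param raw_frame Numeric matrix of raw intensities.
#' @param bit_depth 8 or 16, or `NULL` for frames already in `[0, 1]`.
#' @return Numeric matrix in `[0, 1]`.
#' @examples
#' normalize_intensity(matrix(0:255, 16, 16), bit_depth = 8)[16, 16]
#' @export
normalize_intensity <- function(raw_frame, bit_depth = 8) {
  assert_that(is.matrix(raw_frame) && is.numeric(raw_frame),
              "raw_frame must be a numeric matrix")
  if (is.null(bit_depth)) {
    assert_that(min(raw_frame) >= 0 && max(raw_frame) <= 1,
                "frame is not already normalized to [0, 1]")
    return(raw_frame)
  }
  assert_that(bit_depth %in% c(8, 16), "bit_depth must be 8 or 16")
  top <- 2^bit_depth - 1
  assert_that(min(raw_frame) >= 0 && max(raw_frame) <= top,
              sprintf("raw values must lie in [0, %d]", top))
  raw_frame / top
}

#' Resize a frame with bilinear interpolation
#'
#' Square frames are resized directly to `target x target`; non-square frames
#' are first resized preserving aspect ratio (longest side = `target`) and
#' then padded symmetrically to a square at the frame's median intensity,
#' which approximates the local background level. Bilinear interpolation
#' (half-pixel centers, no corner alignment) maps constant input to constant
#' output and never leaves the input intensity range beyond interpolation
#' tolerance.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param target Output side length in pixels (>= 1).
#' @return `target x target` numeric matrix.
#' @export
resize_frame <- function(frame, target) {
  assert_that(is.matrix(frame) && is.numeric(frame),
              "frame must be a numeric matrix")
  assert_that(is_count(target, min = 1), "target must be a positive integer")
  h <- nrow(frame); w <- ncol(frame)
  if (h == w) {
    return(bilinear_resize(frame, target, target))
  }
  if (h > w) {
    new_w <- max(1L, round(w * target / h))
    resized <- bilinear_resize(frame, target, new_w)
  } else {
    new_h <- max(1L, round(h * target / w))
    resized <- bilinear_resize(frame, new_h, target)
  }
  pad_square(resized, target, fill = stats::median(frame))
}

bilinear_resize <- function(frame, out_h, out_w) {
  if (nrow(frame) == out_h && ncol(frame) == out_w) return(frame)
  out <- EBImage::resize(frame, w = out_h, h = out_w, filter = "bilinear")
  m <- EBImage::imageData(out)
  dim(m) <- c(out_h, out_w)
  m
}

pad_square <- function(m, target, fill) {
  out <- matrix(fill, target, target)
  r0 <- (target - nrow(m)) %/% 2
  c0 <- (target - ncol(m)) %/% 2
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

#' Assemble a sequence into a model-input batch
#'
#' Stacks the (normalized, resized) frames of a sequence into a
#' `T x C x H x W` array, replicating the grayscale intensities across `C`
#' channels so single-channel CLE frames satisfy the 3-channel input contract
#' of ImageNet-pretrained backbones. Frame order is preserved; taking the
#' channel mean inverts the replication exactly.
#'
#' @param sequence A `cle_sequence` (or plain list of matrices).
#' @param channels Number of channels to replicate into (default 1).
#' @return Numeric array of dimension `c(T, channels, H, W)`.
#' @export
to_model_input <- function(sequence, channels = 1L) {
  frames <- if (inherits(sequence, "cle_sequence")) sequence$frames else sequence
  assert_that(length(frames) >= 1, "empty sequence")
  assert_that(is_count(channels, min = 1), "channels must be >= 1")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- array(NA_real_, dim = c(length(frames), channels, h, w))
  for (t in seq_along(frames)) {
    assert_that(all(dim(frames[[t]]) == c(h, w)),
                "all frames must share dimensions")
    for (c in seq_len(channels)) out[t, c, , ] <- frames[[t]]
  }
  out
}

#' Preprocess a CLE sequence for a backbone
#'
#' Convenience composition of [normalize_intensity()] (skipped for frames
#' already in `[0, 1]`), [resize_frame()] to the backbone input size, and
#' [to_model_input()].
#'
#' @param sequence A `cle_sequence`.
#' @param input_size Backbone input side length in pixels.
#' @param channels Channels to replicate into.
#' @param bit_depth Bit depth of raw integer frames, or `NULL` when frames
#'   are already normalized.
#' @return A `T x C x input_size x input_size` array.
#' @export
preprocess_sequence <- function(sequence, input_size = 32L, channels = 1L,
                                bit_depth = NULL) {
  frames <- if (inherits(sequence, "cle_sequence")) sequence$frames else sequence
  frames <- lapply(frames, function(fr) {
    fr <- normalize_intensity(fr, bit_depth = bit_depth)
    resize_frame(fr, input_size)
  })
  to_model_input(frames, channels = channels)
}
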