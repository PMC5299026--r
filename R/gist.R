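# Gabor-energy spatial-envelope ("gist") features of grayscale video frames:
# a bank of zero-mean Gabor kernels spanning orientations x octave-spaced
# scales, applied in the frequency domain with wraparound, with filter
# energies pooled over a coarse spatial grid and averaged over the frames of
# each second.

#' Build a Gabor filter bank
#'
#' `orientations x scales` zero-mean cosine-phase Gabor kernels. Orientations
#' are spaced `pi/orientations`; spatial frequencies halve per scale (one
#' octave), starting at `f0` cycles/pixel; the Gaussian envelope width tracks
#' the wavelength (`sigma = 0.56 / f`, about one octave of bandwidth). Each
#' kernel is mean-subtracted so that responses are invariant to constant
#' luminance.
#'
#' @param orientations number of orientations (default 8).
#' @param scales number of scales (default 4).
#' @param size kernel side length in pixels (default 32).
#' @param f0 frequency of the finest scale in cycles/pixel (default 0.25).
#' @return object of class `gabor_bank`: list with `filters` (list of
#'   `size x size` kernels), `orientations`, `scales`, `info` (data.frame of
#'   per-filter parameters).
#' @export
build_gabor_bank <- function(orientations = 8, scales = 4, size = 32, f0 = 0.25) {
  assert_that(orientations >= 1 && scales >= 1, "orientation and scale counts must be positive")
  half <- (size - 1) / 2
  xs <- seq_len(size) - 1 - half
  gx <- matrix(xs, size, size, byrow = TRUE)
  gy <- matrix(xs, size, size)
  filters <- list()
  info <- NULL
  for (s in seq_len(scales)) {
    f <- f0 / 2^(s - 1)
    sigma <- 0.56 / f
    for (o in seq_len(orientations)) {
      theta <- (o - 1) * pi / orientations
      xr <- gx * cos(theta) + gy * sin(theta)
      yr <- -gx * sin(theta) + gy * cos(theta)
      g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * f * xr)
      g <- g - mean(g)
      filters[[length(filters) + 1L]] <- g
      info <- rbind(info, data.frame(scale = s, orientation = o,
                                     frequency = f, theta = theta, sigma = sigma))
    }
  }
  structure(list(filters = filters, orientations = orientations,
                 scales = scales, size = size, info = info),
            class = "gabor_bank")
}

# Circular (wraparound) 2-D convolution via FFT; kernel centered.
filter_frame_fft <- function(frame, kernel) {
  n <- nrow(frame)
  k <- matrix(0, n, n)
  ks <- nrow(kernel)
  k[seq_len(ks), seq_len(ks)] <- kernel
  # center the kernel at (1,1) so the response is not spatially shifted
  shift <- floor((ks - 1) / 2)
  k <- k[c((shift + 1):n, seq_len(shift)), c((shift + 1):n, seq_len(shift))]
  Re(stats::fft(stats::fft(frame) * Conj(stats::fft(k)), inverse = TRUE)) / n^2
}

#' Gist features of one second of video
#'
#' Each frame is filtered with every kernel of the bank (frequency domain,
#' wraparound); the filter energy (mean squared response) is pooled in each
#' cell of a `grid x grid` partition of the frame; energies are averaged over
#' frames and concatenated as regions-within-filter. With the default
#' 8-orientation x 4-scale bank and a 4 x 4 grid this yields a
#' 512-dimensional vector.
#'
#' @param frames a `n_frames x H x W` array, a list of matrices, or a single
#'   matrix; frames must be square with side divisible by `grid`.
#' @param bank a [build_gabor_bank()].
#' @param grid pooling grid per side (default 4).
#' @return numeric vector of length `grid^2 * length(bank$filters)`.
#' @export
gist_features <- function(frames, bank = build_gabor_bank(), grid = 4) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  assert_that(length(frames) >= 1, "need at least one frame")
  n <- nrow(frames[[1]])
  assert_that(n == ncol(frames[[1]]), "frames must be square")
  assert_that(n %% grid == 0, "frame size must be divisible by the pooling grid")
  cell <- n %/% grid
  region_of <- rep(rep(seq_len(grid), each = cell), times = n) +
    grid * rep(rep(seq_len(grid) - 1, each = cell), each = n)
  # region_of indexes column-major pixels into grid^2 cells
  acc <- numeric(grid^2 * length(bank$filters))
  for (fr in frames) {
    col <- 0L
    feats <- numeric(length(acc))
    for (k in seq_along(bank$filters)) {
      resp2 <- filter_frame_fft(fr, bank$filters[[k]])^2
      e <- vapply(split(as.vector(resp2), region_of), mean, 0)
      feats[(col + 1):(col + grid^2)] <- e
      col <- col + grid^2
    }
    acc <- acc + feats
  }
  acc / length(frames)
}

#' Gist feature sequence for a movie
#'
#' Splits a frame stack into consecutive 1 s groups of `fps` frames and
#' returns one gist vector per second.
#'
#' @param movie `n_frames x H x W` array.
#' @param fps frames per second (default 15).
#' @inheritParams gist_features
#' @return matrix `floor(n_frames/fps) x (grid^2 * n_filters)`.
#' @export
gist_feature_sequence <- function(movie, fps = 15, bank = build_gabor_bank(), grid = 4) {
  n_sec <- nrow_array(movie) %/% fps
  assert_that(n_sec >= 1, "movie shorter than one second")
  out <- NULL
  for (s in seq_len(n_sec)) {
    idx <- ((s - 1) * fps + 1):(s * fps)
    out <- rbind(out, gist_features(movie[idx, , , drop = FALSE], bank, grid))
  }
  out
}

nrow_array <- function(a) dim(a)[1]
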