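# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

#' Robust background noise scale of an image
#'
#' Median-absolute-deviation estimate of the standard deviation of the
#' background, taken from the pixels of an image (or of its border frame),
#' assuming the background dominates those pixels.
#'
#' @param img numeric matrix.
#' @param border if > 0, use only a frame of this many pixels around the
#'   image edge (where signal is least likely).
#' @return estimated background sigma (counts).
#' @keywords internal
robust_background_sigma <- function(img, border = 0L) {
  v <- if (border > 0L) {
    nr <- nrow(img); nc <- ncol(img)
    b <- min(border, floor(min(nr, nc) / 2))
    idx <- rbind(
      cbind(rep(seq_len(b), each = nc), rep(seq_len(nc), b)),
      cbind(rep(nr - seq_len(b) + 1L, each = nc), rep(seq_len(nc), b)),
      cbind(rep(seq_len(nr), b), rep(seq_len(b), each = nr)),
      cbind(rep(seq_len(nr), b), rep(nc - seq_len(b) + 1L, each = nr))
    )
    img[unique(idx)]
  } else as.vector(img)
  stats::mad(v, constant = 1.4826)
}

# Separable Gaussian blur with replicate padding; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                 m[rep(n, rad), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# Local maxima of a matrix (8-connected); ties on plateaus resolved to the
# lexicographically smallest (row, col). Returns a matrix [row, col, value].
local_maxima <- function(img, threshold = -Inf) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) return(cbind(row = integer(), col = integer(), value = numeric()))
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ge <- matrix(TRUE, nr, nc)   # strictly greater than earlier neighbours,
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    # lexicographic tie-break: must strictly exceed neighbours that come
    # earlier in (row, col) order, and be >= the rest
    if (dr < 0L || (dr == 0L && dc < 0L)) ge <- ge & (img > nb)
    else ge <- ge & (img >= nb)
  }
  keep <- which(ge & img > threshold, arr.ind = TRUE)
  cbind(row = keep[, 1L], col = keep[, 2L],
        value = img[keep])
}

# Connected components of an undirected edge list over n nodes.
edge_components <- function(n, edges) {
  if (n == 0L) return(integer())
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::components(g)$membership
}
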