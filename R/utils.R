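#' @keywords internal
"_PACKAGE"

#' @importFrom stats rgamma rnorm var kmeans quantile
#' @importFrom utils packageVersion
NULL

## Internal numeric/image helpers shared across modules. All images are plain
## numeric matrices (row = image row, 0-based pixel coordinates at integer
## centers); intensity images live in [0,1], log-domain fields are unrestricted.

stop_octedema <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "octedema_error")))
}

assert_gray <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_octedema(name, " must be a numeric matrix", class = "octedema_type_error")
  if (!all(is.finite(x)))
    stop_octedema(name, " contains non-finite values", class = "octedema_type_error")
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_octedema(what, " have mismatched shapes: ",
                  paste(dim(a), collapse = "x"), " vs ",
                  paste(dim(b), collapse = "x"),
                  class = "octedema_shape_error")
  invisible(NULL)
}

## Half-sample symmetric reflection of an out-of-range index into 1..n
## (pattern ... c b a | a b c | c b a ... with period 2n).
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

## Half-sample symmetric (reflect) padding by `ry` rows / `rx` cols each
## side; radii may exceed the image size (the reflection repeats).
pad_reflect <- function(x, ry, rx = ry) {
  h <- nrow(x); w <- ncol(x)
  rows <- reflect_index(seq.int(1L - ry, h + ry), h)
  cols <- reflect_index(seq.int(1L - rx, w + rx), w)
  x[rows, cols, drop = FALSE]
}

## 2-D convolution with reflect padding at the borders. The FFT backend is
## wrap-around, so we pad by the kernel radius first and crop afterwards;
## the wrapped contamination never reaches the retained region. Kernels used
## in this package are centrosymmetric, so correlation == convolution.
conv2_reflect <- function(x, kernel) {
  ry <- (nrow(kernel) - 1L) %/% 2L
  rx <- (ncol(kernel) - 1L) %/% 2L
  xp <- pad_reflect(x, ry, rx)
  out <- EBImage::filter2(xp, kernel, boundary = "circular")
  out[(ry + 1L):(ry + nrow(x)), (rx + 1L):(rx + ncol(x)), drop = FALSE]
}

## Central-difference gradient magnitude with replicate boundaries.
grad_mag <- function(x) {
  h <- nrow(x); w <- ncol(x)
  gx <- (x[, c(2:w, w), drop = FALSE] - x[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (x[c(2:h, h), , drop = FALSE] - x[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  sqrt(gx^2 + gy^2)
}

## Forward differences with replicate (Neumann) boundaries: last row/col zero.
fdiff_h <- function(x) {
  w <- ncol(x)
  cbind(x[, 2:w, drop = FALSE] - x[, 1:(w - 1), drop = FALSE], 0)
}

fdiff_v <- function(x) {
  h <- nrow(x)
  rbind(x[2:h, , drop = FALSE] - x[1:(h - 1), , drop = FALSE], 0)
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

fill_holes <- function(mask) {
  EBImage::fillHull(mask * 1L) > 0
}
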