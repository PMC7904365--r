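# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

# per-pixel accumulation of the two region means
oracle_region_means <- function(image, phi) {
  s1 <- n1 <- s2 <- n2 <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (phi[i, j] > 0) { s1 <- s1 + image[i, j]; n1 <- n1 + 1 }
    else               { s2 <- s2 + image[i, j]; n2 <- n2 + 1 }
  }
  c(s1 / n1, s2 / n2)
}

oracle_mean_var <- function(image, mask) {
  v <- c()
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j]) v <- c(v, image[i, j])
  c(mean = sum(v) / length(v),
    var = sum((v - sum(v) / length(v))^2) / (length(v) - 1))
}

oracle_cnr <- function(image, rois, background) {
  b <- oracle_mean_var(image, background)
  vals <- sapply(rois, function(r) {
    m <- oracle_mean_var(image, r)
    (m["mean"] - b["mean"]) / sqrt(m["var"] + b["var"])
  })
  sum(vals) / length(vals)
}

oracle_enl <- function(image, rois) {
  vals <- sapply(rois, function(r) {
    m <- oracle_mean_var(image, r)
    m["mean"]^2 / m["var"]
  })
  sum(vals) / length(vals)
}

# set-operation confusion counts
oracle_confusion <- function(pred, truth) {
  idx <- seq_along(pred)
  P <- idx[as.logical(pred)]; T <- idx[as.logical(truth)]
  list(tp = length(intersect(P, T)),
       fp = length(setdiff(P, T)),
       fn = length(setdiff(T, P)),
       tn = length(setdiff(idx, union(P, T))))
}

# dense direct assembly and solve of the structure-transfer system
oracle_structure_transfer <- function(image, vh, vv, lam) {
  h <- nrow(image); w <- ncol(image); n <- h * w
  idx <- function(i, j) (j - 1) * h + i
  Dx <- matrix(0, n, n); Dy <- matrix(0, n, n)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (j < w) { Dx[idx(i, j), idx(i, j)] <- -1; Dx[idx(i, j), idx(i, j + 1)] <- 1 }
    if (i < h) { Dy[idx(i, j), idx(i, j)] <- -1; Dy[idx(i, j), idx(i + 1, j)] <- 1 }
  }
  A <- lam * diag(n) + t(Dx) %*% Dx + t(Dy) %*% Dy
  rhs <- lam * as.vector(image) + t(Dx) %*% as.vector(vh) + t(Dy) %*% as.vector(vv)
  matrix(solve(A, rhs), h, w)
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small fast phantom for module-level tests
small_spec <- function(seed = 0L, ...) {
  phantom_spec(height = 64L, width = 96L, band_top = 18L, band_bottom = 50L,
               band_offset = 2, edema = list(c(34, 48, 7, 14)), seed = seed, ...)
}
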