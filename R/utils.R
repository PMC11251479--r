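# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All randomness in the package flows from one root seed; each stage or
#' replicate draws its own substream seed so stages can be re-run in
#' isolation without perturbing one another.
#'
#' @param root_seed integer root seed.
#' @param label character label naming the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, label) {
  stopifnot(length(root_seed) == 1L, is.finite(root_seed))
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(root_seed)) * 48271 + h) %% 2147483647)
}

# Mean-center the columns of a T x V matrix.
center_cols <- function(x) sweep(x, 2L, colMeans(x), "-")

# Scale columns to unit L2 norm after centering; zero-variance columns are
# returned as all-zero and reported in the "zero_var" attribute.
unit_cols <- function(x) {
  xc <- center_cols(x)
  nrm <- sqrt(colSums(xc^2))
  zv <- nrm <= 0 | !is.finite(nrm)
  nrm[zv] <- 1
  out <- sweep(xc, 2L, nrm, "/")
  out[, zv] <- 0
  attr(out, "zero_var") <- zv
  out
}

# Flatten a T x V column-correlation against a single reference series.
cor_with_reference <- function(x, ref) {
  xc <- center_cols(x)
  rc <- ref - mean(ref)
  denom <- sqrt(colSums(xc^2)) * sqrt(sum(rc^2))
  r <- as.numeric(crossprod(xc, rc)) / denom
  r[!is.finite(r)] <- NA_real_
  r
}

# 4D array (x, y, z, t) -> T x V matrix restricted to `mask` voxels.
bold_matrix <- function(data4d, mask = NULL) {
  d <- dim(data4d)
  stopifnot(length(d) == 4L)
  v <- prod(d[1:3])
  m <- matrix(data4d, nrow = v, ncol = d[4])
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  t(m)
}

# Write a T x V matrix back into a 4D array at `mask` voxels.
matrix_to_bold <- function(mat, dim3, mask = NULL, fill = 0) {
  tt <- nrow(mat)
  out <- array(fill, dim = c(dim3, tt))
  v <- prod(dim3)
  flat <- matrix(fill, nrow = v, ncol = tt)
  if (is.null(mask)) flat[] <- t(mat) else flat[as.logical(mask), ] <- t(mat)
  out[] <- flat
  out
}

# Linear voxel indices of a logical 3D mask.
mask_indices <- function(mask) which(as.logical(mask))

stop_psd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_psd <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
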