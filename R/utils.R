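# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# All package randomness funnels through this so a single seed reproduces a run.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

clamp_hu <- function(x, lo = -1024, hi = 3071) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Row-normalized 1D Gaussian convolution matrix (kernel truncated at 4 sd).
# Renormalization at the edges keeps constants exactly invariant.
gauss_band_matrix <- function(n, sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok]
  }
  K / rowSums(K)
}

# Separable Gaussian smoothing of a 3D array; sigma_vox is per-axis, in voxels.
smooth_array3d <- function(a, sigma_vox) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    K <- gauss_band_matrix(dm[1], sigma_vox[ax])
    m <- array(K %*% matrix(m, nrow = dm[1]), dim = dm)
    a <- aperm(m, order(perm))
  }
  a
}

# Small non-cryptographic hash for provenance stamps in reports.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                                     null = "null", force = TRUE))
  bytes <- utf8ToInt(s)
  h <- Reduce(function(acc, b) (acc * 31 + b) %% 2147483647, bytes, accumulate = FALSE, 0)
  sprintf("%08x", as.integer(h))
}

# Voxel-centre coordinates (mm) relative to the grid centre, as three long
# vectors aligned with R's column-major linearization of the array.
grid_coords <- function(grid_shape, spacing) {
  ax <- lapply(1:3, function(i)
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * spacing[i])
  list(
    x = rep(ax[[1]], times = grid_shape[2] * grid_shape[3]),
    y = rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
    z = rep(ax[[3]], each = grid_shape[1] * grid_shape[2]),
    axis = ax
  )
}
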