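# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators are reproducible without leaking global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# index vector implementing y[i] = x[i + s] on a periodic axis of length n
shift_idx <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L

# circular shift: y(r) = x(r + s), s = integer 3-vector
circshift3 <- function(x, s) {
  d <- dim(x)
  x[shift_idx(d[1], s[1]), shift_idx(d[2], s[2]), shift_idx(d[3], s[3]),
    drop = FALSE]
}

# move DC from corner (index 1,1,1) to the central voxel floor(N/2)+1
fftshift3 <- function(x) {
  d <- dim(x)
  h <- floor(d / 2)
  x[shift_idx(d[1], -h[1]), shift_idx(d[2], -h[2]), shift_idx(d[3], -h[3]),
    drop = FALSE]
}

# inverse of fftshift3 (differs from it for odd N)
ifftshift3 <- function(x) {
  d <- dim(x)
  h <- floor(d / 2)
  x[shift_idx(d[1], h[1]), shift_idx(d[2], h[2]), shift_idx(d[3], h[3]),
    drop = FALSE]
}

.ardecon_cache <- new.env(parent = emptyenv())

# Precomputed DC-centered Fourier geometry for an N^3 grid: integer voxel
# offsets from the DC voxel, radii, unit direction vectors and shell indices
# (shell width 1 Fourier voxel, centers at integer radii).  Cached per N.
fourier_geometry <- function(n) {
  key <- paste0("geom", n)
  g <- .ardecon_cache[[key]]
  if (!is.null(g)) return(g)
  c0 <- floor(n / 2) + 1L
  o <- as.numeric(seq_len(n) - c0)
  off <- cbind(x = rep(o, times = n * n),
               y = rep(rep(o, each = n), times = n),
               z = rep(o, each = n * n))
  r <- sqrt(rowSums(off^2))
  khat <- off / pmax(r, .Machine$double.eps)
  khat[r == 0, ] <- 0
  g <- list(n = n, center = c0, offsets = off, r = r, khat = khat,
            shell = as.integer(round(r)), nyq = as.integer(floor(n / 2)))
  .ardecon_cache[[key]] <- g
  g
}
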