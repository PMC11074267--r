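# Map standardization: resampling to a uniform voxel size and percentile
# normalization of density values into [0, 1].

# Vectorized trilinear sampling of `arr` at per-axis zero-based positions
# ux, uy, uz (the sample set is the Cartesian product). Positions outside
# [0, n-1] on any axis evaluate to `fill`.
.trilinear_sample <- function(arr, ux, uy, uz, fill = 0) {
  d <- dim(arr)
  nx <- length(ux); ny <- length(uy); nz <- length(uz)
  axis_parts <- function(u, n) {
    i0 <- floor(u)
    f <- u - i0
    # clamp so corner lookups stay in range; out-of-support handled by mask
    i0c <- pmin(pmax(i0, 0), n - 1)
    i1c <- pmin(i0c + 1, n - 1)
    list(i0 = i0c + 1, i1 = i1c + 1, f = f,
         inside = u >= 0 & u <= n - 1)
  }
  px <- axis_parts(ux, d[1]); py <- axis_parts(uy, d[2]); pz <- axis_parts(uz, d[3])
  out <- array(0, dim = c(nx, ny, nz))
  FX <- array(px$f, dim = c(nx, ny, nz))
  FY <- array(rep(py$f, each = nx), dim = c(nx, ny, nz))
  FZ <- array(rep(pz$f, each = nx * ny), dim = c(nx, ny, nz))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- if (cx == 0) px$i0 else px$i1
    iy <- if (cy == 0) py$i0 else py$i1
    iz <- if (cz == 0) pz$i0 else pz$i1
    w <- (if (cx == 0) 1 - FX else FX) *
         (if (cy == 0) 1 - FY else FY) *
         (if (cz == 0) 1 - FZ else FZ)
    idx <- cbind(rep(ix, times = ny * nz),
                 rep(rep(iy, each = nx), times = nz),
                 rep(iz, each = nx * ny))
    out <- out + w * array(arr[idx], dim = c(nx, ny, nz))
  }
  inside <- outer(outer(px$inside, py$inside, "&"), pz$inside, "&")
  out[!inside] <- fill
  out
}

# Nearest-neighbor sampling with the same geometry; used for label masks
# where interpolation would invent classes.
.nearest_sample <- function(arr, ux, uy, uz, fill = 0) {
  d <- dim(arr)
  nx <- length(ux); ny <- length(uy); nz <- length(uz)
  rx <- floor(ux + 0.5); ry <- floor(uy + 0.5); rz <- floor(uz + 0.5)
  inx <- rx >= 0 & rx <= d[1] - 1
  iny <- ry >= 0 & ry <= d[2] - 1
  inz <- rz >= 0 & rz <= d[3] - 1
  rx <- pmin(pmax(rx, 0), d[1] - 1) + 1
  ry <- pmin(pmax(ry, 0), d[2] - 1) + 1
  rz <- pmin(pmax(rz, 0), d[3] - 1) + 1
  idx <- cbind(rep(rx, times = ny * nz),
               rep(rep(ry, each = nx), times = nz),
               rep(rz, each = nx * ny))
  out <- array(arr[idx], dim = c(nx, ny, nz))
  inside <- outer(outer(inx, iny, "&"), inz, "&")
  out[!inside] <- fill
  out
}

#' Resample a density grid to a uniform voxel size
#'
#' Resamples by trilinear interpolation onto a grid with `target_voxel`
#' Angstrom spacing on every axis, keeping the input origin. The output
#' covers the full input bounding box: the dimension per axis is
#' `ceiling(extent / target_voxel)` where `extent = dim * voxel`, and
#' sample points beyond the input support take the value 0. Trilinear
#' interpolation reproduces constant and affine fields exactly.
#'
#' @param grid a [density_grid].
#' @param target_voxel target voxel edge in Angstrom (default 1.0, the
#'   standard training-grid spacing).
#' @param method `"trilinear"` for densities or `"nearest"` for integer
#'   masks.
#' @return a resampled [density_grid].
#' @export
resample_grid <- function(grid, target_voxel = 1.0,
                          method = c("trilinear", "nearest")) {
  stopifnot(inherits(grid, "density_grid"))
  method <- match.arg(method)
  if (!is.finite(target_voxel) || target_voxel <= 0) {
    stop("`target_voxel` must be > 0")
  }
  d <- dim(grid$data)
  extent <- d * grid$voxel
  nd <- pmax(ceiling(extent / target_voxel), 1)
  # positions of output voxel centers in input index units, per axis
  u <- lapply(1:3, function(a) {
    (seq_len(nd[a]) - 1) * target_voxel / grid$voxel[a]
  })
  sampler <- if (method == "trilinear") .trilinear_sample else .nearest_sample
  out <- sampler(grid$data, u[[1]], u[[2]], u[[3]], fill = 0)
  density_grid(out, voxel = target_voxel, origin = grid$origin,
               mode = grid$mode, labels = grid$labels)
}

#' Percentile-normalize density values into [0, 1]
#'
#' Divides every voxel by the 95th percentile of the strictly positive
#' density values (linear interpolation between order statistics), then
#' clips to `[0, 1]`: values below 0 become 0 and values above 1 become 1.
#' This makes density scales comparable across maps produced under
#' different experimental conditions and software.
#'
#' @param grid a [density_grid] containing at least one strictly positive
#'   value.
#' @param percentile percentile of the positive values used as the scale
#'   (default 95).
#' @return a [density_grid] with all values in `[0, 1]`.
#' @export
normalize_grid <- function(grid, percentile = 95) {
  stopifnot(inherits(grid, "density_grid"))
  pos <- grid$data[grid$data > 0]
  if (length(pos) == 0) {
    stop("degenerate map: no strictly positive density values to normalize by")
  }
  p <- stats::quantile(pos, percentile / 100, names = FALSE, type = 7)
  out <- pmin(pmax(grid$data / p, 0), 1)
  density_grid(array(out, dim = dim(grid$data)), voxel = grid$voxel,
               origin = grid$origin, mode = grid$mode, labels = grid$labels)
}
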