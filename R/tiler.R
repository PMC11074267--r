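# Overlapping sub-grid tiling and central-core stitching.
#
# A volume is cut into tile_size^3 cubes whose central cores
# (edge tile_size - 2*overlap) partition the volume exactly once; the
# overlap voxels give a predictor spatial context so voxels near sub-grid
# faces are not predicted from a cut-off neighborhood.

#' Divide a volume into overlapping cubic tiles
#'
#' With stride `s = tile_size - 2 * overlap`, the tile at axis position
#' `m` (zero-based) covers parent voxels
#' `[m*s - overlap, m*s - overlap + tile_size)`; voxels outside the
#' volume are zero-padded. There are `ceiling(dim / s)` tiles per axis
#' and the central cores cover every parent voxel exactly once. Defaults
#' (32 with overlap 6) give 20-voxel cores.
#'
#' @param volume a [density_grid], `label_mask`, or bare 3D array.
#' @param tile_size cube edge in voxels (default 32).
#' @param overlap context voxels on each face (default 6);
#'   `tile_size > 2 * overlap` is required.
#' @return object of class `tile_set`: list with `tiles` (each a list of
#'   `data`, `offset`), `full_shape`, `tile_size`, `overlap`.
#' @export
divide_grid <- function(volume, tile_size = 32L, overlap = 6L) {
  arr <- if (is.array(volume)) volume else volume$data
  if (length(dim(arr)) != 3 || any(dim(arr) < 1)) stop("volume must be a non-empty 3D array")
  tile_size <- as.integer(tile_size); overlap <- as.integer(overlap)
  if (tile_size <= 2L * overlap) {
    stop("tile_size must exceed 2 * overlap (stride would be <= 0)")
  }
  d <- dim(arr)
  stride <- tile_size - 2L * overlap
  ntiles <- ceiling(d / stride)
  tiles <- vector("list", prod(ntiles))
  t <- 0L
  for (mz in seq_len(ntiles[3]) - 1L) {
    for (my in seq_len(ntiles[2]) - 1L) {
      for (mx in seq_len(ntiles[1]) - 1L) {
        off <- c(mx, my, mz) * stride - overlap
        block <- array(0, dim = rep(tile_size, 3))
        lo <- pmax(off, 0L)                       # parent range, 0-based
        hi <- pmin(off + tile_size, d) - 1L
        if (all(lo <= hi)) {
          block[(lo[1] - off[1] + 1):(hi[1] - off[1] + 1),
                (lo[2] - off[2] + 1):(hi[2] - off[2] + 1),
                (lo[3] - off[3] + 1):(hi[3] - off[3] + 1)] <-
            arr[(lo[1] + 1):(hi[1] + 1),
                (lo[2] + 1):(hi[2] + 1),
                (lo[3] + 1):(hi[3] + 1)]
        }
        t <- t + 1L
        tiles[[t]] <- list(data = block, offset = off)
      }
    }
  }
  out <- list(tiles = tiles, full_shape = d, tile_size = tile_size,
              overlap = overlap)
  class(out) <- "tile_set"
  out
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf(
    "tile_set: %d tiles of %d^3 (overlap %d, core %d^3) covering %s\n",
    length(x$tiles), x$tile_size, x$overlap, x$tile_size - 2 * x$overlap,
    paste(x$full_shape, collapse = " x ")))
  invisible(x)
}

#' Stitch tiles back into a full volume
#'
#' Each output voxel takes its value from the unique tile whose central
#' core contains it; core cells beyond the volume boundary are dropped.
#' `stitch_grid(divide_grid(V))` reproduces `V` for every shape.
#'
#' @param tiles a `tile_set`, or a plain list of `list(data, offset)`
#'   tiles (then `full_shape`, `tile_size`, `overlap` must be given).
#' @param full_shape integer triple, the parent volume shape.
#' @inheritParams divide_grid
#' @return a 3D array of shape `full_shape`.
#' @export
stitch_grid <- function(tiles, full_shape = NULL, tile_size = 32L,
                        overlap = 6L) {
  if (inherits(tiles, "tile_set")) {
    full_shape <- tiles$full_shape
    tile_size <- tiles$tile_size
    overlap <- tiles$overlap
    tiles <- tiles$tiles
  }
  if (is.null(full_shape)) stop("`full_shape` required for a bare tile list")
  stride <- tile_size - 2L * overlap
  out <- array(NA_real_, dim = full_shape)
  for (tl in tiles) {
    off <- tl$offset
    if (any(off %% stride != -overlap %% stride)) {
      stop("tile offset not aligned to the stride grid")
    }
    core_lo <- off + overlap                     # parent 0-based
    core_hi <- pmin(core_lo + stride, full_shape) - 1L
    if (any(core_lo > core_hi)) next
    out[(core_lo[1] + 1):(core_hi[1] + 1),
        (core_lo[2] + 1):(core_hi[2] + 1),
        (core_lo[3] + 1):(core_hi[3] + 1)] <-
      tl$data[(overlap + 1):(overlap + 1 + core_hi[1] - core_lo[1]),
              (overlap + 1):(overlap + 1 + core_hi[2] - core_lo[2]),
              (overlap + 1):(overlap + 1 + core_hi[3] - core_lo[3])]
  }
  if (anyNA(out)) {
    stop("incomplete tile cover: some core voxels received no value")
  }
  out
}

#' Write a tile set to disk
#'
#' Serializes the blocks as one container file plus a JSON manifest
#' recording offsets and geometry, mirroring the one-entity-per-map
#' convention of the training pipeline.
#'
#' @param tileset a `tile_set`.
#' @param dir output directory (created if needed).
#' @param name basename for the container/manifest pair.
#' @return paths of the two files written, invisibly.
#' @export
write_tiles <- function(tileset, dir, name = "tiles") {
  stopifnot(inherits(tileset, "tile_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  container <- file.path(dir, paste0(name, ".rds"))
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  saveRDS(tileset, container)
  meta <- list(
    container = basename(container),
    n_tiles = length(tileset$tiles),
    tile_size = tileset$tile_size,
    overlap = tileset$overlap,
    full_shape = tileset$full_shape,
    offsets = do.call(rbind, lapply(tileset$tiles, `[[`, "offset"))
  )
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE)
  invisible(c(container = container, manifest = manifest))
}

#' Read a tile set written by [write_tiles()]
#'
#' @param container path to the `.rds` container.
#' @return a `tile_set`.
#' @export
read_tiles <- function(container) {
  ts <- readRDS(container)
  if (!inherits(ts, "tile_set")) stop("not a tile_set container")
  ts
}
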