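# MRC2014 I/O and the density-grid data model.
#
# Internal array convention: grid$data is an R array dim = c(nx, ny, nz),
# indexed [ix, iy, iz] (1-based) with x fastest -- the on-disk MRC order
# when mapc,mapr,maps = 1,2,3. The zero-based spatial index along axis a of
# a point at coordinate v is (v - origin[a]) / voxel[a]; see
# coord_to_index() for the two index-assignment conventions.

.MRC_MODES <- c(`0` = 1L, `1` = 2L, `2` = 4L, `4` = 8L, `6` = 2L, `12` = 2L)

#' Construct a density grid
#'
#' A `density_grid` is a 3D scalar field with voxel sizes and an origin in
#' Angstrom. The array is indexed `[ix, iy, iz]` so that the voxel with
#' zero-based index `(m_x, m_y, m_z)` is centered at
#' `origin + m * voxel` per axis.
#'
#' @param data numeric 3D array.
#' @param voxel numeric length-3 voxel size in Angstrom per (x, y, z) axis;
#'   a scalar is recycled.
#' @param origin numeric length-3 offset in Angstrom of voxel (0, 0, 0).
#' @param mode MRC storage mode code (2 = 32-bit real, the mode this
#'   package writes).
#' @param labels character vector of free-text header labels (at most 10,
#'   each truncated to 80 bytes on write).
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(data, voxel = 1, origin = c(0, 0, 0), mode = 2L,
                         labels = character()) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array")
  }
  if (any(dim(data) < 1)) stop("all grid dimensions must be >= 1")
  voxel <- rep_len(as.numeric(voxel), 3)
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    stop("all voxel sizes must be finite and > 0")
  }
  origin <- rep_len(as.numeric(origin), 3)
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(
    list(data = data, voxel = voxel, origin = origin,
         mode = as.integer(mode), labels = as.character(labels)),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "density_grid: %d x %d x %d voxels, voxel %s A, origin (%s) A, mode %d\n",
    d[1], d[2], d[3], paste(format(x$voxel, digits = 4), collapse = " x "),
    paste(format(x$origin, digits = 4), collapse = ", "), x$mode))
  r <- range(x$data)
  cat(sprintf("  values in [%g, %g], mean %g\n", r[1], r[2], mean(x$data)))
  invisible(x)
}

#' @export
dim.density_grid <- function(x) dim(x$data)

# Read and decode the fixed 1024-byte header. Returns raw fields plus the
# byte order inferred from the machine stamp.
.mrc_read_header <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 1024) stop("not an MRC file: header shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  machst <- hdr[213:216]
  endian <- if (as.integer(machst[1]) == 0x11) "big" else "little"
  int_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "integer",
                                1, 4, endian = endian)
  flt_at <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "double",
                                1, 4, endian = endian)
  ints <- vapply(1:10, int_at, integer(1))
  labels_raw <- hdr[225:1024]
  labels <- vapply(0:9, function(i) {
    b <- labels_raw[(80 * i + 1):(80 * i + 80)]
    b <- b[b != as.raw(0)]
    trimws(rawToChar(b), which = "right")
  }, character(1))
  list(
    nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
    nstart = ints[5:7], m = ints[8:10],
    cella = vapply(11:13, flt_at, numeric(1)),
    mapc = int_at(17), mapr = int_at(18), maps = int_at(19),
    dmin = flt_at(20), dmax = flt_at(21), dmean = flt_at(22),
    ispg = int_at(23), nsymbt = int_at(24),
    exttyp = trimws(rawToChar(hdr[105:108][hdr[105:108] != as.raw(0)])),
    nversion = int_at(28),
    origin = vapply(50:52, flt_at, numeric(1)),
    map_id = rawToChar(hdr[209:212][hdr[209:212] != as.raw(0)]),
    machst = machst,
    rms = flt_at(55), nlabl = int_at(56), labels = labels,
    endian = endian
  )
}

.mrc_read_data <- function(path, h) {
  nvox <- as.numeric(h$nx) * h$ny * h$nz
  size <- .MRC_MODES[as.character(h$mode)]
  if (is.na(size)) stop("unsupported MRC mode for data reading: ", h$mode)
  if (h$mode %in% c(4L, 12L)) {
    stop("MRC mode ", h$mode, " (complex / half float) data is not supported")
  }
  expected <- 1024 + h$nsymbt + nvox * size
  if (file.size(path) < expected) {
    stop(sprintf("MRC data section truncated: file has %d bytes, header implies %.0f",
                 file.size(path), expected))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 1024 + h$nsymbt)
  what <- if (h$mode == 2L) "double" else "integer"
  signed <- h$mode != 6L
  vals <- readBin(con, what, n = nvox, size = size, signed = signed,
                  endian = h$endian)
  array(as.numeric(vals), dim = c(h$nx, h$ny, h$nz))
}

#' Read an MRC2014 density volume
#'
#' Reads a volume and resolves the header's axis permutation
#' (`mapc`/`mapr`/`maps`) so the returned array is always stored x-fastest
#' with dimensions `(nx, ny, nz)` along the spatial (x, y, z) axes. When
#' the origin header fields are all zero but the `nstart` offsets are not,
#' the origin falls back to `nstart * voxel` (both dialects occur in
#' deposited maps).
#'
#' @param path path to an MRC file.
#' @return a [density_grid].
#' @seealso [write_mrc()], [validate_mrc()]
#' @export
read_mrc <- function(path) {
  h <- tryCatch(.mrc_read_header(path), error = function(e) {
    stop("unreadable MRC header in '", path, "': ", conditionMessage(e))
  })
  if (!grepl("^MAP", h$map_id)) {
    stop("not an MRC2014 file: MAP id string missing in '", path, "'")
  }
  axes <- c(h$mapc, h$mapr, h$maps)
  if (!setequal(axes, 1:3)) stop("invalid axis mapping in MRC header")
  arr <- .mrc_read_data(path, h)
  # arr dims are (columns, rows, sections) = spatial axes (mapc, mapr, maps)
  if (!all(axes == 1:3)) arr <- aperm(arr, match(1:3, axes))
  if (any(h$m <= 0) || any(h$cella <= 0)) {
    stop("non-positive sampling or cell dimensions in MRC header")
  }
  voxel <- h$cella / h$m
  origin <- h$origin
  if (all(origin == 0) && any(h$nstart != 0)) {
    nstart_xyz <- h$nstart[match(1:3, axes)]
    origin <- nstart_xyz * voxel
  }
  labels <- h$labels[seq_len(max(0, min(h$nlabl, 10)))]
  density_grid(arr, voxel = voxel, origin = origin, mode = h$mode,
               labels = labels[nzchar(labels)])
}

.pad_raw <- function(x, n) {
  r <- charToRaw(x)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, rep(as.raw(0x20), n - length(r)))
}

#' Write a density grid as MRC2014
#'
#' Writes mode 2 (32-bit real) with the identity axis mapping 1,2,3,
#' header statistics recomputed from the data, machine stamp for
#' little-endian IEEE floats and `nversion` 20141. Files written here pass
#' every [validate_mrc()] check. Integer label masks are stored exactly
#' (all label values are far below 2^24).
#'
#' @param grid a [density_grid] (or a `label_mask`, which is converted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  if (inherits(grid, "label_mask")) grid <- as_density_grid(grid)
  stopifnot(inherits(grid, "density_grid"))
  if (any(!is.finite(grid$data))) {
    stop("grid data contains non-finite values; refusing to write")
  }
  d <- dim(grid$data)
  vals <- as.numeric(grid$data)
  # Stats are computed on the float32 values actually stored so the header
  # matches the file contents exactly.
  stored <- readBin(writeBin(vals, raw(), size = 4, endian = "little"),
                    "double", length(vals), size = 4, endian = "little")
  dmin <- min(stored); dmax <- max(stored); dmean <- mean(stored)
  rms <- sqrt(mean((stored - dmean)^2))
  labels <- utils::head(grid$labels[nzchar(grid$labels)], 10)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                  # nx ny nz
  wi(2L)                                 # mode
  wi(c(0L, 0L, 0L))                      # nstart
  wi(d)                                  # mx my mz
  wf(d * grid$voxel)                     # cella
  wf(c(90, 90, 90))                      # cellb
  wi(1:3)                                # mapc mapr maps
  wf(c(dmin, dmax, dmean))
  wi(1L)                                 # ispg: volume
  wi(0L)                                 # nsymbt
  wi(c(0L, 0L))                          # extra words 25-26
  writeBin(rep(as.raw(0), 4), con)       # exttyp (no extended header)
  wi(20141L)                             # nversion
  writeBin(rep(as.raw(0), 4 * 21), con)  # extra words 29-49
  wf(grid$origin)                        # origin x y z
  writeBin(c(charToRaw("MAP"), as.raw(0x20)), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(rms)
  wi(length(labels))
  for (i in seq_len(10)) {
    writeBin(.pad_raw(if (i <= length(labels)) labels[i] else "", 80), con)
  }
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

.mrc_check_names <- c(
  "id_string", "machine_stamp", "mode", "dimensions", "axis_mapping",
  "volume_stack", "labels", "version", "extended_header", "statistics",
  "file_size"
)

#' Validate an MRC2014 file
#'
#' Runs the standard battery of MRC2014 header checks and reports each
#' outcome; the file is never modified. Checks: the `MAP` id string; a
#' recognized machine stamp (`44 44 00 00`, `44 41 00 00` or
#' `11 11 00 00`); a supported mode (0, 1, 2, 4, 6, 12); positive
#' `nx/ny/nz`, `mx/my/mz` and cell dimensions; `mapc/mapr/maps` a
#' permutation of 1,2,3; `nz` divisible by `mz` for volume stacks
#' (spacegroups 401--630); label count consistent with the labels in use;
#' `nversion` 20140 or 20141; `exttyp` set when an extended header is
#' present; header statistics matching the data (or flagged undetermined);
#' and on-disk file size matching the header.
#'
#' @param path path to the file to check.
#' @return a `mrc_validation_report`: a data frame with columns `check`,
#'   `pass`, `detail`, and an `overall` attribute that is `TRUE` iff every
#'   check passes.
#' @export
validate_mrc <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "'")
  h <- .mrc_read_header(path)
  res <- stats::setNames(rep(NA, length(.mrc_check_names)), .mrc_check_names)
  det <- stats::setNames(rep("", length(.mrc_check_names)), .mrc_check_names)

  res["id_string"] <- grepl("^MAP", h$map_id)
  if (!res["id_string"]) det["id_string"] <- sprintf("map field is '%s'", h$map_id)

  stamp <- as.integer(h$machst[1:2])
  res["machine_stamp"] <- identical(stamp, c(0x44L, 0x44L)) ||
    identical(stamp, c(0x44L, 0x41L)) || identical(stamp, c(0x11L, 0x11L))
  if (!res["machine_stamp"]) {
    det["machine_stamp"] <- paste("bytes", paste(sprintf("0x%02x", stamp), collapse = " "))
  }

  res["mode"] <- h$mode %in% c(0L, 1L, 2L, 4L, 6L, 12L)
  if (!res["mode"]) det["mode"] <- sprintf("mode %d unsupported", h$mode)

  dims <- c(h$nx, h$ny, h$nz, h$m, h$cella)
  res["dimensions"] <- all(is.finite(dims)) && all(dims > 0)
  if (!res["dimensions"]) det["dimensions"] <- "non-positive map or cell dimension"

  res["axis_mapping"] <- setequal(c(h$mapc, h$mapr, h$maps), 1:3)
  if (!res["axis_mapping"]) {
    det["axis_mapping"] <- sprintf("mapc/mapr/maps = %d/%d/%d", h$mapc, h$mapr, h$maps)
  }

  if (h$ispg >= 401 && h$ispg <= 630) {
    res["volume_stack"] <- h$m[3] > 0 && (h$nz %% h$m[3] == 0)
    if (!res["volume_stack"]) det["volume_stack"] <- "nz not divisible by mz"
  } else {
    res["volume_stack"] <- TRUE
    det["volume_stack"] <- "not a volume stack"
  }

  in_use <- which(nzchar(h$labels))
  res["labels"] <- h$nlabl >= 0 && h$nlabl <= 10 &&
    length(in_use) == h$nlabl &&
    (length(in_use) == 0 || max(in_use) == length(in_use))
  if (!res["labels"]) {
    det["labels"] <- sprintf("nlabl = %d, labels in use = %d", h$nlabl, length(in_use))
  }

  res["version"] <- h$nversion %in% c(20140L, 20141L)
  if (!res["version"]) det["version"] <- sprintf("nversion = %d", h$nversion)

  if (h$nsymbt > 0) {
    res["extended_header"] <- nzchar(h$exttyp)
    if (!res["extended_header"]) det["extended_header"] <- "exttyp unset"
  } else {
    res["extended_header"] <- TRUE
    det["extended_header"] <- "no extended header"
  }

  undetermined <- (h$dmax < h$dmin) || (h$dmean < min(h$dmin, h$dmax))
  if (undetermined) {
    res["statistics"] <- TRUE
    det["statistics"] <- "flagged undetermined"
  } else if (!h$mode %in% c(0L, 1L, 2L, 6L)) {
    res["statistics"] <- TRUE
    det["statistics"] <- "not recomputed for this mode"
  } else {
    ok <- tryCatch({
      vals <- .mrc_read_data(path, h)
      tol <- max(1e-4 * (max(vals) - min(vals)), 1e-6)
      m <- mean(vals)
      good <- abs(h$dmin - min(vals)) <= tol && abs(h$dmax - max(vals)) <= tol &&
        abs(h$dmean - m) <= tol
      if (h$rms >= 0) {
        good <- good && abs(h$rms - sqrt(mean((vals - m)^2))) <= tol
      }
      good
    }, error = function(e) FALSE)
    res["statistics"] <- ok
    if (!ok) det["statistics"] <- "recorded statistics disagree with data"
  }

  size <- .MRC_MODES[as.character(h$mode)]
  if (is.na(size)) {
    res["file_size"] <- FALSE
    det["file_size"] <- "unknown mode; expected size undefined"
  } else {
    expected <- 1024 + h$nsymbt + as.numeric(h$nx) * h$ny * h$nz * size
    res["file_size"] <- file.size(path) == expected
    if (!res["file_size"]) {
      det["file_size"] <- sprintf("on disk %d, expected %.0f", file.size(path), expected)
    }
  }

  report <- data.frame(check = .mrc_check_names, pass = as.logical(res),
                       detail = unname(det), stringsAsFactors = FALSE)
  structure(report, overall = all(report$pass),
            class = c("mrc_validation_report", "data.frame"))
}

#' @export
print.mrc_validation_report <- function(x, ...) {
  status <- ifelse(x$pass, "ok", "FAIL")
  note <- ifelse(nzchar(x$detail), paste0("  (", x$detail, ")"), "")
  cat(sprintf("%-16s %-4s%s\n", x$check, status, note), sep = "")
  cat(if (attr(x, "overall")) "overall: pass\n" else "overall: FAIL\n")
  invisible(x)
}

#' @rdname validate_mrc
#' @param report a `mrc_validation_report`.
#' @return `mrc_overall_pass()` returns the overall flag as a logical scalar.
#' @export
mrc_overall_pass <- function(report) isTRUE(attr(report, "overall"))
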