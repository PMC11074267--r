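# Atomic-structure parsing and voxel labeling.
#
# A backbone_structure is a data frame with one row per residue carrying
# chain id, residue number (+ insertion code), the integer amino code
# (1-20 alphabetical by three-letter code, 0 = non-standard), secondary
# structure code (1 coil, 2 helix, 3 strand, 0 unassigned) and the Ca/N/C
# coordinates in Angstrom (NA where the atom is missing). Per-chain
# sequences are attached as an attribute.

.new_backbone_structure <- function(df, sequences = NULL) {
  if (is.null(sequences)) {
    sequences <- vapply(split(df, df$chain_id), function(ch) {
      paste(amino_one_letter(ch$amino_code), collapse = "")
    }, character(1))
  }
  structure(df, sequences = sequences,
            class = c("backbone_structure", "data.frame"))
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("backbone_structure: %d residues in %d chain(s) [%s]\n",
              nrow(x), length(unique(x$chain_id)),
              paste(unique(x$chain_id), collapse = ", ")))
  NextMethod()
}

#' Chain sequences of a backbone structure
#'
#' @param structure a `backbone_structure`.
#' @return named character vector of one-letter sequences, one per chain.
#' @export
chain_sequences <- function(structure) attr(structure, "sequences")

# Residues covered by HELIX / SHEET header records, parsed from the raw
# fixed-column lines (columns per the PDB format v3.3).
.parse_ss_records <- function(lines) {
  span <- function(rec, chain_col, start_col, end_chain_col, end_col) {
    recs <- lines[startsWith(lines, rec)]
    if (length(recs) == 0) return(NULL)
    data.frame(
      chain = trimws(substr(recs, chain_col, chain_col)),
      start = suppressWarnings(as.integer(substr(recs, start_col, start_col + 3))),
      end   = suppressWarnings(as.integer(substr(recs, end_col, end_col + 3))),
      stringsAsFactors = FALSE
    )
  }
  list(helix = span("HELIX", 20, 22, 32, 34),
       sheet = span("SHEET", 22, 23, 33, 34))
}

.ss_code_for <- function(chain, resno, spans) {
  code <- rep(1L, length(resno))  # coil wherever backbone exists
  mark <- function(tab, value) {
    if (is.null(tab)) return()
    for (r in seq_len(nrow(tab))) {
      if (is.na(tab$start[r]) || is.na(tab$end[r])) next
      hit <- chain == tab$chain[r] & resno >= tab$start[r] & resno <= tab$end[r]
      code[hit] <<- value
    }
  }
  mark(spans$helix, 2L)
  mark(spans$sheet, 3L)
  code
}

#' Parse a PDB file into an ordered backbone residue table
#'
#' Extracts one row per residue that carries any of the C-alpha, amide N
#' or carbonyl C backbone atoms. Amino types use the fixed alphabetical
#' 1--20 coding ([amino_codes()]); non-standard residues (e.g. MSE) get
#' code 0. Secondary structure is taken from HELIX/SHEET header records
#' (helix = 2, strand = 3, otherwise coil = 1); an external per-residue
#' table can override it via `ss_table`. Only the first alternate-location
#' conformer is kept; insertion codes are preserved in residue identity.
#'
#' @param pdb_path path to a PDB file.
#' @param ss_table optional data frame with columns `chain_id`,
#'   `residue_number`, `ss_code` overriding the header-derived secondary
#'   structure.
#' @return a `backbone_structure` data frame (see Details) with per-chain
#'   sequences in `attr(, "sequences")`.
#' @export
parse_structure <- function(pdb_path, ss_table = NULL) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  at <- at[at$elety %in% c("CA", "N", "C"), , drop = FALSE]
  # drop monoatomic ions that reuse backbone atom names (e.g. calcium)
  at <- at[!(at$resid %in% c("HOH", "WAT", "CA", "NA", "CL", "ZN", "MG")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no backbone ATOM records found")
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  # first conformer per (residue, atom)
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert)
  first <- !duplicated(rkey)
  res <- data.frame(
    chain_id = at$chain[first],
    residue_number = at$resno[first],
    insert = at$insert[first],
    resid = at$resid[first],
    stringsAsFactors = FALSE
  )
  res$amino_code <- {
    idx <- match(res$resid, .AA3)
    idx[is.na(idx)] <- 0L
    as.integer(idx)
  }
  take <- function(elety, col) {
    m <- match(paste(res$chain_id, res$residue_number, res$insert, elety),
               paste(at$chain, at$resno, at$insert, at$elety))
    at[[col]][m]
  }
  for (a in c("ca", "n", "c")) {
    ele <- toupper(if (a == "ca") "CA" else a)
    res[[paste0(a, "_x")]] <- take(ele, "x")
    res[[paste0(a, "_y")]] <- take(ele, "y")
    res[[paste0(a, "_z")]] <- take(ele, "z")
  }

  lines <- readLines(pdb_path, warn = FALSE)
  spans <- .parse_ss_records(lines)
  res$ss_code <- .ss_code_for(res$chain_id, res$residue_number, spans)
  if (!is.null(ss_table)) {
    m <- match(paste(res$chain_id, res$residue_number),
               paste(ss_table$chain_id, ss_table$residue_number))
    res$ss_code[!is.na(m)] <- as.integer(ss_table$ss_code[m[!is.na(m)]])
  }
  rownames(res) <- NULL
  .new_backbone_structure(res)
}

#' Convert atomic coordinates to voxel indices
#'
#' Maps a coordinate in Angstrom to the zero-based grid index triple
#' `(i, j, k)` where `i` indexes the z axis, `j` the y axis and `k` the x
#' axis. Two conventions are provided:
#' \describe{
#'   \item{`nearest`}{(default) rounds `(coord - origin) / voxel` to the
#'     nearest integer, ties toward +Inf. Reconstructed voxel centers then
#'     deviate by at most half a voxel per axis.}
#'   \item{`eq1`}{the literal floor-then-ceiling index formula
#'     `i = ceil(floor(z - origin_z) / voxel_z)` (and likewise for j, k),
#'     kept for compatibility; its round-trip error can approach a full
#'     voxel at 1 Angstrom spacing.}
#' }
#'
#' @param xyz numeric matrix (n x 3) or length-3 vector of coordinates in
#'   Angstrom, columns (x, y, z).
#' @param origin length-3 origin in Angstrom.
#' @param voxel length-3 (or scalar) voxel size in Angstrom, all > 0.
#' @param mode `"nearest"` or `"eq1"`.
#' @return integer matrix (n x 3) with columns `i`, `j`, `k` (zero-based;
#'   i from z, j from y, k from x).
#' @seealso [index_to_coord()] for the inverse mapping.
#' @export
coord_to_index <- function(xyz, origin = c(0, 0, 0), voxel = c(1, 1, 1),
                           mode = c("nearest", "eq1")) {
  mode <- match.arg(mode)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = FALSE)
  voxel <- rep_len(as.numeric(voxel), 3)
  if (any(voxel <= 0)) stop("voxel components must be > 0")
  origin <- rep_len(as.numeric(origin), 3)
  off <- sweep(xyz, 2, origin)
  idx_xyz <- switch(mode,
    nearest = floor(sweep(off, 2, voxel, "/") + 0.5),
    eq1 = ceiling(sweep(floor(off), 2, voxel, "/"))
  )
  out <- cbind(i = idx_xyz[, 3], j = idx_xyz[, 2], k = idx_xyz[, 1])
  storage.mode(out) <- "integer"
  out
}

#' Convert voxel indices back to approximate coordinates
#'
#' The inverse of [coord_to_index()] up to voxel quantization:
#' `x = k * voxel_x + origin_x`, `y = j * voxel_y + origin_y`,
#' `z = i * voxel_z + origin_z` — i.e. the center of the indexed voxel.
#'
#' @param ijk integer matrix (n x 3) or length-3 vector, columns
#'   `(i, j, k)` zero-based with i indexing z, j indexing y, k indexing x.
#' @inheritParams coord_to_index
#' @return numeric matrix (n x 3) with columns `x`, `y`, `z` in Angstrom.
#' @export
index_to_coord <- function(ijk, origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3, byrow = FALSE)
  voxel <- rep_len(as.numeric(voxel), 3)
  if (any(voxel <= 0)) stop("voxel components must be > 0")
  origin <- rep_len(as.numeric(origin), 3)
  cbind(x = ijk[, 3] * voxel[1] + origin[1],
        y = ijk[, 2] * voxel[2] + origin[2],
        z = ijk[, 1] * voxel[3] + origin[3])
}

.new_label_mask <- function(data, scheme, voxel, origin) {
  structure(list(data = data, scheme = scheme, voxel = voxel, origin = origin),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_mask (%s): %d x %d x %d voxels, %d labeled\n",
              x$scheme, d[1], d[2], d[3], sum(x$data != 0)))
  invisible(x)
}

#' Convert a label mask to a density grid
#'
#' Used when writing masks to MRC (integer labels stored exactly as 32-bit
#' reals).
#'
#' @param mask a `label_mask`.
#' @return a [density_grid] with the mask geometry and a scheme label.
#' @export
as_density_grid <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  density_grid(mask$data + 0, voxel = mask$voxel, origin = mask$origin,
               mode = 2L, labels = paste0("cryoforge label mask: ", mask$scheme))
}

#' Build the four voxel label masks from a backbone structure
#'
#' On the geometry of `grid`, produces:
#' \describe{
#'   \item{atom}{backbone atoms: C-alpha voxel = 1, N voxel = 2,
#'     carbonyl C voxel = 3}
#'   \item{ca}{C-alpha voxels = 1}
#'   \item{amino}{C-alpha voxel = amino code 1--20 (0 elsewhere/unknown)}
#'   \item{ss}{C-alpha voxel = secondary-structure code 1--3}
#' }
#' Atoms falling outside the grid are counted and skipped. Voxel
#' collisions resolve by priority C-alpha > N > C (first writer wins
#' within equal priority) so C-alpha-derived labels are never destroyed.
#'
#' @param structure a `backbone_structure`.
#' @param grid a [density_grid] (or anything with `dim`, `voxel`,
#'   `origin`) defining the mask geometry.
#' @param mode index-assignment convention, see [coord_to_index()].
#' @return list with elements `atom`, `ca`, `amino`, `ss` (each a
#'   `label_mask`) and `n_out_of_bounds`.
#' @export
make_masks <- function(structure, grid, mode = c("nearest", "eq1")) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "backbone_structure"))
  if (nrow(structure) == 0) stop("empty structure")
  d <- dim(grid$data)
  blank <- function() array(0L, dim = d)
  atom <- blank(); ca <- blank(); amino <- blank(); ss <- blank()
  skipped <- 0L

  place <- function(xyz_cols) {
    xyz <- as.matrix(structure[, xyz_cols])
    keep <- stats::complete.cases(xyz)
    ijk <- coord_to_index(xyz[keep, , drop = FALSE], grid$origin, grid$voxel,
                          mode = mode)
    # array subscripts [x, y, z] are (k, j, i) + 1
    sub <- cbind(ijk[, "k"], ijk[, "j"], ijk[, "i"]) + 1L
    inb <- sub[, 1] >= 1 & sub[, 1] <= d[1] &
           sub[, 2] >= 1 & sub[, 2] <= d[2] &
           sub[, 3] >= 1 & sub[, 3] <= d[3]
    skipped <<- skipped + sum(!inb)
    list(sub = sub[inb, , drop = FALSE], rows = which(keep)[inb])
  }

  pca <- place(c("ca_x", "ca_y", "ca_z"))
  pn  <- place(c("n_x", "n_y", "n_z"))
  pc  <- place(c("c_x", "c_y", "c_z"))

  # lowest priority first; C-alpha written last so it always wins
  write_first <- function(mask, sub, values, overwrite_ok) {
    # first writer wins within one atom class
    dup <- duplicated(sub)
    sub <- sub[!dup, , drop = FALSE]; values <- values[!dup]
    occupied <- mask[sub] != 0
    take <- if (overwrite_ok) rep(TRUE, nrow(sub)) else !occupied
    mask[sub[take, , drop = FALSE]] <- values[take]
    mask
  }
  atom <- write_first(atom, pc$sub, rep(3L, nrow(pc$sub)), overwrite_ok = FALSE)
  atom <- write_first(atom, pn$sub, rep(2L, nrow(pn$sub)), overwrite_ok = TRUE)
  atom <- write_first(atom, pca$sub, rep(1L, nrow(pca$sub)), overwrite_ok = TRUE)

  ca    <- write_first(ca, pca$sub, rep(1L, nrow(pca$sub)), overwrite_ok = TRUE)
  amino <- write_first(amino, pca$sub, structure$amino_code[pca$rows],
                       overwrite_ok = TRUE)
  ss    <- write_first(ss, pca$sub, structure$ss_code[pca$rows],
                       overwrite_ok = TRUE)

  list(
    atom = .new_label_mask(atom, "atom", grid$voxel, grid$origin),
    ca = .new_label_mask(ca, "ca", grid$voxel, grid$origin),
    amino = .new_label_mask(amino, "amino", grid$voxel, grid$origin),
    ss = .new_label_mask(ss, "ss", grid$voxel, grid$origin),
    n_out_of_bounds = skipped
  )
}

#' Verify a C-alpha mask by coordinate round trip
#'
#' Converts every labeled C-alpha voxel back to coordinates (voxel
#' centers, [index_to_coord()]) and matches them one-to-one against the
#' true C-alpha coordinates, nearest pair first. Reports how many voxels
#' land exactly on a true C-alpha position and the maximum per-axis
#' deviation in Angstrom over all matches.
#'
#' @param ca_mask the `ca` scheme `label_mask` produced by [make_masks()].
#' @param structure the `backbone_structure` the mask was built from.
#' @param tol absolute tolerance for an "exact" match per axis (default
#'   1e-6 A, i.e. the coordinate sits on the voxel center).
#' @return list of class `label_verification` with `n_ca_total`,
#'   `n_exact`, `fraction_exact`, `max_axis_deviation`.
#' @export
verify_labels <- function(ca_mask, structure, tol = 1e-6) {
  stopifnot(inherits(ca_mask, "label_mask"), ca_mask$scheme == "ca")
  sub <- which(ca_mask$data != 0, arr.ind = TRUE)
  if (nrow(sub) == 0) stop("empty C-alpha mask")
  ijk <- cbind(i = sub[, 3] - 1L, j = sub[, 2] - 1L, k = sub[, 1] - 1L)
  rec <- index_to_coord(ijk, ca_mask$origin, ca_mask$voxel)
  truth <- as.matrix(structure[, c("ca_x", "ca_y", "ca_z")])
  truth <- truth[stats::complete.cases(truth), , drop = FALSE]

  # greedy nearest-pair one-to-one matching
  d2 <- outer(rowSums(rec^2), rowSums(truth^2), "+") - 2 * rec %*% t(truth)
  n_exact <- 0L
  max_dev <- 0
  n_pairs <- min(nrow(rec), nrow(truth))
  for (p in seq_len(n_pairs)) {
    best <- arrayInd(which.min(d2), dim(d2))
    dev <- abs(rec[best[1], ] - truth[best[2], ])
    max_dev <- max(max_dev, dev)
    if (all(dev <= tol)) n_exact <- n_exact + 1L
    d2[best[1], ] <- Inf
    d2[, best[2]] <- Inf
  }
  out <- list(n_ca_total = nrow(rec), n_exact = n_exact,
              fraction_exact = n_exact / nrow(rec),
              max_axis_deviation = max_dev)
  class(out) <- "label_verification"
  out
}

#' @export
print.label_verification <- function(x, ...) {
  cat(sprintf(
    "label verification: %d/%d C-alpha voxels exact (%.1f%%), max per-axis deviation %.3f A\n",
    x$n_exact, x$n_ca_total, 100 * x$fraction_exact, x$max_axis_deviation))
  invisible(x)
}

#' Write per-chain sequences as FASTA
#'
#' @param structure a `backbone_structure`.
#' @param path output FASTA path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(structure, path, width = 60) {
  seqs <- chain_sequences(structure)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in '", path, "'")
  grp <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- vapply(strsplit(names, "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  stats::setNames(toupper(seqs), names)
}
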