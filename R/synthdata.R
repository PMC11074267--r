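# Synthetic backbones, density volumes and oracle probability volumes.
#
# These generators stand in for experimental map/model pairs so every
# pipeline stage can be exercised end to end. They emulate the geometric
# essentials -- consecutive C-alpha spacing near 3.8 A, atom-centered
# density blobs plus noise, probability volumes concentrated at true
# voxels -- not the full complexity of experimental maps.

#' Specification for a synthetic fixture
#'
#' @param n_residues number of residues (>= 2; default 30).
#' @param motif named fractions for `helix`, `strand`, `coil` segments
#'   (must sum to 1; default pure helix, the most regular and most
#'   testable geometry).
#' @param voxel voxel size in Angstrom (default 1, the standardized
#'   training grid).
#' @param blob_sigma Gaussian blob width in Angstrom (default 1.0: blobs
#'   resolvable but overlapping, like intermediate-resolution maps).
#' @param noise_sigma additive Gaussian noise SD in density units
#'   (default 0.05).
#' @param fidelity oracle prediction fidelity in `[0, 1]`: probability
#'   mass the true class receives at each voxel (default 1).
#' @param seed integer seed controlling all randomness.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_residues = 30L, motif = c(helix = 1, strand = 0, coil = 0),
                       voxel = 1, blob_sigma = 1.0, noise_sigma = 0.05,
                       fidelity = 1.0, seed = 1L) {
  if (n_residues < 2) stop("`n_residues` must be >= 2")
  motif <- motif[c("helix", "strand", "coil")]
  motif[is.na(motif)] <- 0
  names(motif) <- c("helix", "strand", "coil")
  if (abs(sum(motif) - 1) > 1e-9) stop("motif fractions must sum to 1")
  if (fidelity < 0 || fidelity > 1) stop("`fidelity` must be in [0, 1]")
  out <- list(n_residues = as.integer(n_residues), motif = motif,
              voxel = voxel, blob_sigma = blob_sigma,
              noise_sigma = noise_sigma, fidelity = fidelity,
              seed = as.integer(seed))
  class(out) <- "synth_spec"
  out
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Unit vector uniform on the sphere.
.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Rotation matrix taking the z axis onto unit vector u.
.rot_to <- function(u) {
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3)) else return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A per residue,
# 100 degree twist -- consecutive spacing ~3.83 A.
.helix_segment <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), (seq_len(n) - 1) * 1.5)
}

# Extended strand as a flat zigzag with 3.8 A consecutive spacing.
.strand_segment <- function(n) {
  along <- (seq_len(n) - 1) * 3.3
  zig <- ifelse(seq_len(n) %% 2 == 0, 0.94, -0.94)
  cbind(along, zig, rep(0, n))  # |step| = sqrt(3.3^2 + 1.88^2) ~= 3.80
}

# Self-avoiding random walk with 3.8 A steps and limited turn angle.
.coil_segment <- function(n, start_dir = NULL) {
  pts <- matrix(0, n, 3)
  dir <- if (is.null(start_dir)) .rand_unit() else start_dir
  for (r in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in 1:50) {
      perturb <- dir + 0.6 * stats::rnorm(3)
      perturb <- perturb / sqrt(sum(perturb^2))
      cand <- pts[r - 1, ] + 3.8 * perturb
      prev <- pts[seq_len(max(1, r - 2)), , drop = FALSE]
      if (r == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= 3.0) {
        pts[r, ] <- cand; dir <- perturb; placed <- TRUE; break
      }
    }
    if (!placed) stop("coil generation failed self-avoidance after bounded retries")
  }
  pts
}

#' Generate a synthetic backbone structure
#'
#' Builds a single-chain C-alpha trace with consecutive spacing within
#' 3.8 +/- 0.05 A: ideal-helix parameterization for helix spans, a flat
#' zigzag for strands, a self-avoiding random walk for coil. Segments are
#' joined end to end with random orientations and a 3.8 A junction step,
#' retrying (bounded) until the whole chain is self-avoiding. Amide N and
#' carbonyl C atoms are placed on the C-alpha--C-alpha segments; amino
#' types are drawn from the background distribution.
#'
#' @param spec a [synth_spec()].
#' @param background amino frequencies for sequence drawing.
#' @return a `backbone_structure` (single chain `A`) with per-chain
#'   sequence attached.
#' @export
make_backbone <- function(spec, background = background_frequencies()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_residues
  .with_seed(spec$seed, {
    # segment plan: contiguous runs per motif, at least 4 residues each
    counts <- round(n * spec$motif)
    counts["helix"] <- n - sum(counts[c("strand", "coil")])
    plan <- rep(names(counts), times = pmax(counts, 0))[seq_len(n)]
    runs <- rle(plan)

    for (attempt in 1:25) {
      pts <- NULL
      ok <- TRUE
      for (rr in seq_along(runs$lengths)) {
        nseg <- runs$lengths[rr]
        seg <- switch(runs$values[rr],
                      helix = .helix_segment(nseg),
                      strand = .strand_segment(nseg),
                      coil = tryCatch(.coil_segment(nseg),
                                      error = function(e) NULL))
        if (is.null(seg)) { ok <- FALSE; break }
        seg <- seg %*% t(.rot_to(.rand_unit()))
        if (is.null(pts)) {
          pts <- seg
        } else {
          step <- 3.8 * .rand_unit()
          seg <- sweep(seg, 2, seg[1, ]) # segment starts at origin
          seg <- sweep(seg, 2, pts[nrow(pts), ] + step, "+")
          pts <- rbind(pts, seg)
        }
      }
      if (!ok || nrow(pts) != n) next
      # global self-avoidance: non-adjacent pairs at least 3.0 A apart
      d <- as.matrix(stats::dist(pts))
      diag(d) <- Inf
      adj <- abs(row(d) - col(d)) == 1
      if (min(d[!adj]) >= 3.0) break
      if (attempt == 25) stop("backbone generation failed self-avoidance after bounded retries")
    }

    # N on the incoming segment, C on the outgoing (approximate bond geometry)
    nxyz <- pts; cxyz <- pts
    dirs <- rbind(pts[2, ] - pts[1, ], diff(pts))
    for (r in seq_len(n)) {
      incoming <- if (r == 1) dirs[1, ] else pts[r, ] - pts[r - 1, ]
      outgoing <- if (r == n) pts[n, ] - pts[n - 1, ] else pts[r + 1, ] - pts[r, ]
      nxyz[r, ] <- pts[r, ] - 0.38 * incoming
      cxyz[r, ] <- pts[r, ] + 0.40 * outgoing
    }

    aa <- sample(20, n, replace = TRUE, prob = background)
    ss <- c(coil = 1L, helix = 2L, strand = 3L)[plan]
    df <- data.frame(
      chain_id = "A", residue_number = seq_len(n), insert = "",
      resid = amino_three_letter(aa), amino_code = as.integer(aa),
      ca_x = pts[, 1], ca_y = pts[, 2], ca_z = pts[, 3],
      n_x = nxyz[, 1], n_y = nxyz[, 2], n_z = nxyz[, 3],
      c_x = cxyz[, 1], c_y = cxyz[, 2], c_z = cxyz[, 3],
      ss_code = unname(ss), stringsAsFactors = FALSE
    )
    .new_backbone_structure(df)
  })
}

#' Simulate a density map for a structure
#'
#' Density is a sum of isotropic Gaussian blobs centered on every
#' backbone atom (C-alpha, N, C), sampled on a grid with at least 5 A
#' margin around the structure, plus zero-mean Gaussian noise.
#'
#' @param structure a `backbone_structure`.
#' @param spec a [synth_spec()] (uses `voxel`, `blob_sigma`,
#'   `noise_sigma`, `seed`).
#' @param amplitude peak height of each blob (default 1).
#' @return a [density_grid].
#' @export
simulate_map <- function(structure, spec, amplitude = 1) {
  stopifnot(inherits(structure, "backbone_structure"))
  atoms <- rbind(
    as.matrix(structure[, c("ca_x", "ca_y", "ca_z")]),
    as.matrix(structure[, c("n_x", "n_y", "n_z")]),
    as.matrix(structure[, c("c_x", "c_y", "c_z")])
  )
  atoms <- atoms[stats::complete.cases(atoms), , drop = FALSE]
  if (nrow(atoms) == 0) stop("structure has no atoms")
  margin <- 5
  origin <- unname(floor(apply(atoms, 2, min) - margin))
  extent <- unname(ceiling(apply(atoms, 2, max) + margin)) - origin
  d <- pmax(ceiling(extent / spec$voxel) + 1, 1)
  arr <- array(0, dim = d)
  s2 <- 2 * spec$blob_sigma^2
  reach <- ceiling(3 * spec$blob_sigma / spec$voxel)
  ax <- origin[1] + (seq_len(d[1]) - 1) * spec$voxel
  ay <- origin[2] + (seq_len(d[2]) - 1) * spec$voxel
  az <- origin[3] + (seq_len(d[3]) - 1) * spec$voxel
  for (a in seq_len(nrow(atoms))) {
    ctr <- atoms[a, ]
    ix <- which(abs(ax - ctr[1]) <= reach * spec$voxel)
    iy <- which(abs(ay - ctr[2]) <= reach * spec$voxel)
    iz <- which(abs(az - ctr[3]) <= reach * spec$voxel)
    gx <- exp(-(ax[ix] - ctr[1])^2 / s2)
    gy <- exp(-(ay[iy] - ctr[2])^2 / s2)
    gz <- exp(-(az[iz] - ctr[3])^2 / s2)
    arr[ix, iy, iz] <- arr[ix, iy, iz] +
      amplitude * (gx %o% gy %o% gz)
  }
  if (spec$noise_sigma > 0) {
    noise <- .with_seed(spec$seed + 1L,
                        array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d))
    arr <- arr + noise
  }
  density_grid(arr, voxel = spec$voxel, origin = origin,
               labels = "cryoforge synthetic map")
}

#' Oracle per-voxel probability volumes from label masks
#'
#' Emulates a per-voxel classifier of tunable quality: at every voxel the
#' true class receives probability `fidelity` and the remaining mass is
#' spread uniformly over the other classes. At `fidelity = 1` the argmax
#' reproduces the masks exactly. The construction is deterministic.
#'
#' @param masks the list produced by [make_masks()] (uses `ca`, `atom`,
#'   `amino`).
#' @param fidelity probability assigned to the true class, in `[0, 1]`.
#' @param seed accepted for interface stability (reserved for optional
#'   prediction jitter); the default construction is deterministic.
#' @return list with `ca_prob` (3D array, probability the voxel holds a
#'   C-alpha), `atom_prob` (4D, 4 classes: background, C-alpha, N, C) and
#'   `amino_prob` (4D, 21 classes: background + 20 amino types), plus the
#'   grid `voxel` and `origin`.
#' @export
simulate_predictions <- function(masks, fidelity = 1.0, seed = 1L) {
  if (fidelity < 0 || fidelity > 1) stop("`fidelity` must be in [0, 1]")
  ca <- masks$ca$data
  atom <- masks$atom$data
  amino <- masks$amino$data
  d <- dim(ca)

  # binary C-alpha volume: truth voxel -> fidelity, background -> 1 - fidelity
  ca_prob <- array(ifelse(ca != 0, fidelity, 1 - fidelity), dim = d)

  class_stack <- function(labels, n_classes) {
    out <- array((1 - fidelity) / (n_classes - 1), dim = c(d, n_classes))
    for (cc in seq_len(n_classes)) {
      idx <- which(labels == (cc - 1L))
      if (length(idx) == 0) next
      out[idx + (cc - 1L) * prod(d)] <- fidelity
    }
    out
  }
  list(
    ca_prob = ca_prob,
    atom_prob = class_stack(atom, 4L),
    amino_prob = class_stack(amino, 21L),
    voxel = masks$ca$voxel,
    origin = masks$ca$origin
  )
}

#' Write a complete synthetic fixture to a directory
#'
#' Generates backbone, map, masks and oracle probability volumes and
#' writes them in their standard formats (MRC, PDB, FASTA). Every MRC
#' file written passes [validate_mrc()].
#'
#' @param spec a [synth_spec()].
#' @param dir output directory.
#' @return invisible list with the in-memory objects and file paths.
#' @export
write_synth_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bb <- make_backbone(spec)
  map <- simulate_map(bb, spec)
  norm <- normalize_grid(map)
  masks <- make_masks(bb, norm)
  probs <- simulate_predictions(masks, fidelity = spec$fidelity,
                                seed = spec$seed)
  paths <- list(
    map = file.path(dir, "emd_normalized_map.mrc"),
    model = file.path(dir, "model.pdb"),
    fasta = file.path(dir, "seq.fasta"),
    atom_mask = file.path(dir, "atom_emd_normalized_map.mrc"),
    ca_mask = file.path(dir, "atom_ca_emd_normalized_map.mrc"),
    amino_mask = file.path(dir, "amino_emd_normalized_map.mrc"),
    ss_mask = file.path(dir, "sec_struc_emd_normalized_map.mrc"),
    ca_prob = file.path(dir, "ca_prob.mrc")
  )
  write_mrc(norm, paths$map)
  .write_structure_pdb(bb, paths$model)
  write_chain_fasta(bb, paths$fasta)
  write_mrc(masks$atom, paths$atom_mask)
  write_mrc(masks$ca, paths$ca_mask)
  write_mrc(masks$amino, paths$amino_mask)
  write_mrc(masks$ss, paths$ss_mask)
  write_mrc(density_grid(probs$ca_prob, voxel = probs$voxel,
                         origin = probs$origin), paths$ca_prob)
  invisible(list(spec = spec, backbone = bb, map = norm, masks = masks,
                 predictions = probs, paths = paths))
}

# Full-backbone PDB writer (CA, N, C records) for synthetic structures.
.write_structure_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   synthetic backbone (cryoforge)", con)
  serial <- 0L
  fmt <- function(name, res3, chain, resno, xyz, ele) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res3, chain, resno, xyz[1], xyz[2], xyz[3], ele)
  }
  for (r in seq_len(nrow(structure))) {
    row <- structure[r, ]
    res3 <- amino_three_letter(row$amino_code)
    if (!is.na(row$n_x)) {
      writeLines(fmt(" N", res3, row$chain_id, row$residue_number,
                     c(row$n_x, row$n_y, row$n_z), "N"), con)
    }
    if (!is.na(row$ca_x)) {
      writeLines(fmt(" CA", res3, row$chain_id, row$residue_number,
                     c(row$ca_x, row$ca_y, row$ca_z), "C"), con)
    }
    if (!is.na(row$c_x)) {
      writeLines(fmt(" C", res3, row$chain_id, row$residue_number,
                     c(row$c_x, row$c_y, row$c_z), "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
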