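# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

random_grid <- function(dims = c(12, 10, 8), voxel = 1, origin = c(0, 0, 0),
                        seed = 1) {
  set.seed(seed)
  density_grid(array(stats::rnorm(prod(dims)), dim = dims),
               voxel = voxel, origin = origin)
}

# Fixed-column PDB ATOM/HETATM line (v3.3 layout).
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          ele = "C", record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resn, chain, resno, x, y, z, ele)
}

# HELIX / SHEET span header line with only the fields the parser reads.
pdb_span_line <- function(rec, chain, from, to) {
  s <- strrep(" ", 80)
  substr(s, 1, nchar(rec)) <- rec
  if (rec == "HELIX") {
    substr(s, 20, 20) <- chain
    substr(s, 22, 25) <- sprintf("%4d", from)
    substr(s, 32, 32) <- chain
    substr(s, 34, 37) <- sprintf("%4d", to)
  } else {
    substr(s, 22, 22) <- chain
    substr(s, 23, 26) <- sprintf("%4d", from)
    substr(s, 33, 33) <- chain
    substr(s, 34, 37) <- sprintf("%4d", to)
  }
  s
}

write_test_pdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# A three-residue ALA/GLY/VAL chain with full backbone, on integer coords.
tiny_pdb <- function() {
  write_test_pdb(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 1, 1, 1, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 2, 2),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 3, 2, 2),
    pdb_atom_line(4, "N",  "GLY", "A", 2, 4, 3, 2, "N"),
    pdb_atom_line(5, "CA", "GLY", "A", 2, 5, 4, 3),
    pdb_atom_line(6, "C",  "GLY", "A", 2, 6, 4, 3),
    pdb_atom_line(7, "N",  "VAL", "A", 3, 7, 5, 4, "N"),
    pdb_atom_line(8, "CA", "VAL", "A", 3, 8, 6, 5),
    pdb_atom_line(9, "C",  "VAL", "A", 3, 9, 6, 5)
  ))
}

# Candidate set built directly (the shape extract_candidates produces).
make_candidates <- function(xyz, amino_probs, p_ca = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(p_ca)) p_ca <- rep(1, nrow(xyz))
  out <- list(xyz = xyz,
              ijk = cbind(i = round(xyz[, 3]), j = round(xyz[, 2]),
                          k = round(xyz[, 1])),
              p_ca = p_ca, amino_probs = amino_probs)
  class(out) <- "ca_candidates"
  out
}

random_candidates <- function(n, seed, box = 6) {
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
  ap <- matrix(stats::runif(20 * n) + 0.02, ncol = 20)
  ap <- ap / rowSums(ap)
  make_candidates(xyz, ap)
}
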