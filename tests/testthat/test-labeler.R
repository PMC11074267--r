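test_that("a minimal PDB parses into residues with the alphabetical amino coding", {
  bb <- parse_structure(tiny_pdb())
  expect_equal(nrow(bb), 3)
  expect_equal(bb$amino_code, c(1L, 8L, 20L))   # ALA, GLY, VAL
  expect_equal(bb$ca_x, c(2, 5, 8))
  expect_equal(bb$n_y, c(1, 3, 5))
  expect_equal(bb$c_z, c(2, 3, 5))
  expect_equal(chain_sequences(bb), c(A = "AGV"))
})

test_that("non-standard residues get amino code 0 and empty structures error", {
  tf <- write_test_pdb(c(
    pdb_atom_line(1, "CA", "MSE", "A", 1, 1, 1, 1, "SE", record = "HETATM"),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 4, 1, 1)
  ))
  bb <- parse_structure(tf)
  expect_equal(bb$amino_code, c(0L, 1L))

  empty <- write_test_pdb(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, "O",
                                        record = "HETATM"))
  expect_error(parse_structure(empty), "empty structure")
})

test_that("HELIX and SHEET header spans set the secondary-structure codes", {
  tf <- write_test_pdb(c(
    pdb_span_line("HELIX", "A", 1, 1),
    pdb_span_line("SHEET", "A", 3, 3),
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 1, 1),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 4, 1, 1),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 8, 1, 1)
  ))
  bb <- parse_structure(tf)
  expect_equal(bb$ss_code, c(2L, 1L, 3L))  # helix, coil, strand
})

test_that("coordinate-to-index conversion matches the printed formulas", {
  # floor/ceiling formula evaluated by hand
  expect_equal(coord_to_index(c(2.3, 5.7, 8.1), mode = "eq1")[1, ],
               c(i = 8L, j = 5L, k = 2L))
  expect_equal(coord_to_index(c(10, 20, 30), origin = c(10, 20, 30),
                              voxel = c(0.7, 1.3, 2))[1, ],
               c(i = 0L, j = 0L, k = 0L))
  expect_equal(coord_to_index(c(2.6, 0, 0), mode = "nearest")[1, "k"],
               c(k = 3L))
  # half-voxel ties round toward +Inf
  expect_equal(coord_to_index(c(2.5, 0, 0), mode = "nearest")[1, "k"],
               c(k = 3L))
  expect_error(coord_to_index(c(0, 0, 0), voxel = c(0, 1, 1)), "voxel")
})

test_that("index-to-coordinate conversion inverts grid-aligned points", {
  expect_equal(index_to_coord(c(8, 5, 2))[1, ], c(x = 2, y = 5, z = 8))
  expect_equal(index_to_coord(c(0, 0, 0), origin = c(10, 20, 30))[1, ],
               c(x = 10, y = 20, z = 30))
  set.seed(20)
  origin <- c(-3, 2, 7)
  p <- matrix(sample(0:40, 30, replace = TRUE), ncol = 3) + origin[col(matrix(0, 10, 3))]
  ijk <- coord_to_index(p, origin = origin)
  expect_equal(unname(index_to_coord(ijk, origin = origin)), unname(p))
})

test_that("at unit voxels the printed formula reduces to a floor, property-checked", {
  set.seed(21)
  xyz <- matrix(stats::runif(3000, -20, 20), ncol = 3)
  ijk <- coord_to_index(xyz, origin = c(-20, -20, -20), voxel = 1, mode = "eq1")
  brute <- ceiling(floor(xyz - (-20)) / 1)  # the formula, evaluated directly
  expect_equal(unname(ijk[, c("k", "j", "i")]), unname(brute))
  expect_equal(unname(ijk[, c("k", "j", "i")]), floor(xyz + 20))
})

test_that("make_masks produces the four schemes with the documented codes", {
  bb <- parse_structure(tiny_pdb())
  grid <- density_grid(array(0, dim = c(12, 12, 12)))
  masks <- make_masks(bb, grid)
  expect_equal(sort(unique(as.integer(masks$atom$data))), c(0L, 1L, 2L, 3L))
  expect_equal(sum(masks$atom$data == 1), 3)  # three C-alpha voxels
  expect_equal(sum(masks$ca$data), 3)
  # GLY C-alpha at (5, 4, 3) -> amino voxel value 8
  expect_equal(masks$amino$data[6, 5, 4], 8L)
  expect_equal(sort(unique(masks$amino$data[masks$amino$data > 0])),
               c(1L, 8L, 20L))
  # amino and ss masks are nonzero exactly where the ca mask is
  expect_equal(masks$amino$data != 0, masks$ca$data != 0)
  expect_equal(masks$ss$data != 0, masks$ca$data != 0)
  expect_equal(masks$n_out_of_bounds, 0)
})

test_that("atoms outside the grid are counted and skipped", {
  bb <- parse_structure(tiny_pdb())
  small <- density_grid(array(0, dim = c(2, 2, 2)), origin = c(100, 100, 100))
  masks <- make_masks(bb, small)
  expect_equal(sum(masks$atom$data), 0)
  expect_equal(masks$n_out_of_bounds, 9)  # 3 residues x 3 atoms
})

test_that("C-alpha labels survive collisions with N and C atoms", {
  # all three atoms of a residue in the same voxel: C-alpha label wins
  tf <- write_test_pdb(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 2.1, 2.1, 2.1, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2.2, 2.2, 2.2),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 1.9, 1.9, 1.9)
  ))
  bb <- parse_structure(tf)
  masks <- make_masks(bb, density_grid(array(0, dim = c(6, 6, 6))))
  expect_equal(sum(masks$atom$data != 0), 1)
  expect_equal(masks$atom$data[3, 3, 3], 1L)
})

test_that("label verification reports exact matches and bounded deviations", {
  bb <- parse_structure(tiny_pdb())  # integer coordinates = voxel centers
  grid <- density_grid(array(0, dim = c(12, 12, 12)))
  masks <- make_masks(bb, grid)
  v <- verify_labels(masks$ca, bb)
  expect_equal(v$fraction_exact, 1)
  expect_equal(v$max_axis_deviation, 0)
  expect_equal(v$n_ca_total, 3)

  # fractional coordinates at 1 A voxels
  set.seed(22)
  n <- 40
  xyz <- matrix(stats::runif(3 * n, 2, 28), ncol = 3)
  df <- data.frame(
    chain_id = "A", residue_number = seq_len(n), insert = "", resid = "ALA",
    amino_code = 1L, ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
    n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
    c_x = NA_real_, c_y = NA_real_, c_z = NA_real_, ss_code = 1L
  )
  bb2 <- structure(df, sequences = c(A = strrep("A", n)),
                   class = c("backbone_structure", "data.frame"))
  grid2 <- density_grid(array(0, dim = c(31, 31, 31)))
  near <- verify_labels(make_masks(bb2, grid2, mode = "nearest")$ca, bb2)
  expect_lte(near$max_axis_deviation, 0.5)
  eq1 <- verify_labels(make_masks(bb2, grid2, mode = "eq1")$ca, bb2)
  expect_lt(eq1$max_axis_deviation, 1.0)
})

test_that("chain sequences round-trip through FASTA", {
  bb <- parse_structure(tiny_pdb())
  tf <- tempfile(fileext = ".fasta")
  write_chain_fasta(bb, tf)
  expect_equal(read_fasta(tf), c(A = "AGV"))
})
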