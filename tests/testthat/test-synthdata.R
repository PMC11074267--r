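test_that("helical backbones keep consecutive C-alpha spacing in 3.8 +/- 0.05 A", {
  bb <- make_backbone(synth_spec(n_residues = 20, seed = 1))
  ca <- as.matrix(bb[, c("ca_x", "ca_y", "ca_z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(d >= 3.75 & d <= 3.85))
  expect_equal(bb$ss_code, rep(2L, 20))
})

test_that("mixed-motif backbones respect spacing and self-avoidance", {
  for (seed in 1:3) {
    bb <- make_backbone(synth_spec(
      n_residues = 40, motif = c(helix = 0.5, strand = 0.25, coil = 0.25),
      seed = seed))
    ca <- as.matrix(bb[, c("ca_x", "ca_y", "ca_z")])
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(d >= 3.75 & d <= 3.85))
    dm <- as.matrix(stats::dist(ca))
    diag(dm) <- Inf
    nonadj <- abs(row(dm) - col(dm)) > 1
    expect_gte(min(dm[nonadj]), 3.0)
    expect_setequal(unique(bb$ss_code), c(2L, 3L, 1L))
  }
})

test_that("the minimal two-residue backbone and seed determinism hold", {
  bb <- make_backbone(synth_spec(n_residues = 2, seed = 9))
  expect_equal(nrow(bb), 2)
  ca <- as.matrix(bb[, c("ca_x", "ca_y", "ca_z")])
  expect_equal(sqrt(sum(diff(ca)^2)), 3.8297, tolerance = 1e-3)

  a <- make_backbone(synth_spec(n_residues = 15, seed = 4))
  b <- make_backbone(synth_spec(n_residues = 15, seed = 4))
  expect_identical(a, b)
  expect_error(synth_spec(n_residues = 1), "n_residues")
})

test_that("simulated maps peak at atom centers and scale linearly", {
  spec <- synth_spec(n_residues = 10, noise_sigma = 0, seed = 2)
  bb <- make_backbone(spec)
  map <- simulate_map(bb, spec)
  peak <- which(map$data == max(map$data), arr.ind = TRUE)[1, ]
  peak_xyz <- map$origin + (peak - 1) * map$voxel
  atoms <- rbind(as.matrix(bb[, c("ca_x", "ca_y", "ca_z")]),
                 as.matrix(bb[, c("n_x", "n_y", "n_z")]),
                 as.matrix(bb[, c("c_x", "c_y", "c_z")]))
  nearest <- min(sqrt(rowSums(sweep(atoms, 2, peak_xyz)^2)))
  expect_lte(nearest, sqrt(3) * max(map$voxel))  # within one voxel

  doubled <- simulate_map(bb, spec, amplitude = 2)
  expect_equal(doubled$data, 2 * map$data, tolerance = 1e-12)

  # composition with normalization stays in [0, 1]
  noisy <- simulate_map(bb, synth_spec(n_residues = 10, seed = 2))
  n <- normalize_grid(noisy)
  expect_gte(min(n$data), 0)
  expect_lte(max(n$data), 1)
})

test_that("oracle predictions at fidelity 1 reproduce the masks exactly", {
  spec <- synth_spec(n_residues = 12, seed = 5)
  bb <- make_backbone(spec)
  map <- normalize_grid(simulate_map(bb, spec))
  masks <- make_masks(bb, map)
  probs <- simulate_predictions(masks, fidelity = 1.0)
  expect_equal(probs$ca_prob >= 0.5, masks$ca$data == 1L)
  am_argmax <- apply(probs$amino_prob, 1:3, which.max) - 1L
  expect_equal(array(as.integer(am_argmax), dim = dim(masks$amino$data)),
               masks$amino$data)
  at_argmax <- apply(probs$atom_prob, 1:3, which.max) - 1L
  expect_equal(array(as.integer(at_argmax), dim = dim(masks$atom$data)),
               masks$atom$data)
  expect_error(simulate_predictions(masks, fidelity = 1.5), "fidelity")
})

test_that("end-to-end tracing at fidelity 1 recovers the true C-alpha voxel set", {
  spec <- synth_spec(n_residues = 30, fidelity = 1.0, seed = 6)
  bb <- make_backbone(spec)
  map <- normalize_grid(simulate_map(bb, spec))
  masks <- make_masks(bb, map)
  probs <- simulate_predictions(masks, fidelity = 1.0)
  cand <- extract_candidates(probs$ca_prob, probs$amino_prob,
                             voxel = probs$voxel, origin = probs$origin,
                             threshold = 0.5)
  chains <- viterbi_align(build_hmm(cand), chain_sequences(bb))
  traced <- chains[[1]]$xyz
  true_centers <- index_to_coord(
    coord_to_index(as.matrix(bb[, c("ca_x", "ca_y", "ca_z")]),
                   origin = map$origin, voxel = map$voxel),
    origin = map$origin, voxel = map$voxel)
  expect_equal(traced[order(traced[, 1], traced[, 2], traced[, 3]), ],
               true_centers[order(true_centers[, 1], true_centers[, 2],
                                  true_centers[, 3]), ],
               ignore_attr = TRUE)
})

test_that("degrading fidelity does not raise the true path's expected score", {
  score_true_path <- function(fidelity, seed) {
    spec <- synth_spec(n_residues = 15, fidelity = fidelity, seed = seed)
    bb <- make_backbone(spec)
    ca <- round(as.matrix(bb[, c("ca_x", "ca_y", "ca_z")]))
    ap <- matrix((1 - fidelity) / 19, nrow = 15, ncol = 20)
    ap[cbind(1:15, bb$amino_code)] <- fidelity
    tables <- oracle_score_tables(make_candidates(ca, ap))
    oracle_path_score(tables, bb$amino_code, seq_len(15))
  }
  seeds <- 1:6
  hi <- mean(vapply(seeds, function(s) score_true_path(0.95, s), numeric(1)))
  lo <- mean(vapply(seeds, function(s) score_true_path(0.6, s), numeric(1)))
  expect_gte(hi, lo)
})

test_that("synthetic fixtures round-trip through their file formats", {
  spec <- synth_spec(n_residues = 10, seed = 7)
  td <- tempfile()
  fix <- write_synth_fixture(spec, td)
  # MRC round trip
  back <- read_mrc(fix$paths$map)
  expect_equal(back$data, fix$map$data, tolerance = 1e-6)
  # every MRC written passes validation
  for (f in unlist(fix$paths)[grepl("\\.mrc$", unlist(fix$paths))]) {
    expect_true(mrc_overall_pass(validate_mrc(f)))
  }
  # PDB round trip of the backbone
  reread <- parse_structure(fix$paths$model)
  expect_equal(nrow(reread), 10)
  expect_equal(reread$amino_code, fix$backbone$amino_code)
  expect_equal(reread$ca_x, fix$backbone$ca_x, tolerance = 1e-3)
  # FASTA matches the generated sequence
  expect_equal(unname(read_fasta(fix$paths$fasta)),
               unname(chain_sequences(fix$backbone)))
})
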