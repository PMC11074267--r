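# HMM-guided alignment of protein sequences to candidate C-alpha voxels.
#
# Hidden states are candidate C-alpha voxels taken from a per-voxel
# probability volume. Emissions over the 20 amino-acid types are the
# normalized geometric mean of the predicted per-voxel amino probabilities
# and background frequencies; transitions follow a Gaussian over the
# Euclidean inter-candidate distance centered at the consecutive C-alpha
# spacing. Decoding is a beam search over injective paths: no state may be
# used twice, within or across chains.

#' Extract C-alpha candidate states from probability volumes
#'
#' Keeps every voxel whose C-alpha probability reaches `threshold`,
#' converts its index to Angstrom coordinates (voxel centers) and attaches
#' the per-voxel amino-acid distribution renormalized over the 20 residue
#' classes (mass on the background/unknown class is discarded).
#'
#' @param ca_prob 3D array (or [density_grid]) of per-voxel C-alpha
#'   probabilities.
#' @param amino_prob 4D array `[x, y, z, class]` with 21 classes (class 1
#'   = background/unknown, classes 2..21 = amino codes 1..20) or exactly
#'   20 amino classes.
#' @param voxel,origin grid geometry in Angstrom.
#' @param threshold inclusion threshold in (0, 1) (default 0.5).
#' @return object of class `ca_candidates`: list with `xyz` (n x 3),
#'   `ijk` (n x 3, zero-based, columns i/j/k indexing z/y/x), `p_ca`
#'   (length n), `amino_probs` (n x 20, rows summing to 1).
#' @export
extract_candidates <- function(ca_prob, amino_prob, voxel = c(1, 1, 1),
                               origin = c(0, 0, 0), threshold = 0.5) {
  if (inherits(ca_prob, "density_grid")) {
    voxel <- ca_prob$voxel; origin <- ca_prob$origin; ca_prob <- ca_prob$data
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1")
  }
  da <- dim(amino_prob)
  if (length(da) != 4 || !all(dim(ca_prob) == da[1:3])) {
    stop("`amino_prob` must be [x, y, z, class] matching `ca_prob` in shape")
  }
  sub <- which(ca_prob >= threshold, arr.ind = TRUE)
  if (nrow(sub) == 0) stop("no candidate voxel reaches the threshold")
  ijk <- cbind(i = sub[, 3] - 1L, j = sub[, 2] - 1L, k = sub[, 1] - 1L)
  xyz <- index_to_coord(ijk, origin, voxel)
  nclass <- da[4]
  cls <- if (nclass == 21) 2:21 else if (nclass == 20) 1:20 else
    stop("`amino_prob` must carry 20 or 21 classes")
  ap <- vapply(cls, function(cc) {
    amino_prob[cbind(sub, cc)]
  }, numeric(nrow(sub)))
  ap <- matrix(ap, nrow = nrow(sub))
  rs <- rowSums(ap)
  if (any(rs <= 0)) stop("candidate with zero amino-probability mass")
  ap <- ap / rs
  out <- list(xyz = xyz, ijk = ijk, p_ca = ca_prob[sub], amino_probs = ap)
  class(out) <- "ca_candidates"
  out
}

#' @export
print.ca_candidates <- function(x, ...) {
  cat(sprintf("ca_candidates: %d candidate voxels, p_ca in [%.3f, %.3f]\n",
              nrow(x$xyz), min(x$p_ca), max(x$p_ca)))
  invisible(x)
}

#' Emission distribution of one candidate state
#'
#' The emission probability of amino type `aa` is the normalized geometric
#' mean `sqrt(p(aa) * bg(aa)) / sum_aa' sqrt(p(aa') * bg(aa'))` of the
#' predicted amino probability and its background frequency.
#'
#' @param amino_probs nonnegative 20-vector of predicted amino
#'   probabilities (rows of a candidate set also work via `apply`).
#' @param background 20-vector of background frequencies summing to 1.
#' @return 20-vector summing to 1.
#' @export
emission_probs <- function(amino_probs, background = background_frequencies()) {
  if (length(amino_probs) != 20 || any(amino_probs < 0)) {
    stop("`amino_probs` must be 20 nonnegative values")
  }
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-6) {
    stop("`background` must be 20 frequencies summing to 1")
  }
  g <- sqrt(amino_probs * background)
  s <- sum(g)
  if (s <= 0) stop("degenerate emission: geometric mean vanishes for every type")
  g / s
}

#' Gaussian transition weight over inter-candidate distance
#'
#' The unnormalized weight of stepping between two candidate C-alpha
#' states at Euclidean distance `x` is the Gaussian density with mean
#' `mu` (3.8047 A, the consecutive C-alpha spacing) and standard
#' deviation `sigma * lambda_scale` (0.036 x 10 = 0.36 A). Per-state
#' outgoing weights over the neighbor set are normalized to probabilities
#' when the model is built.
#'
#' @param distance nonnegative distance(s) in Angstrom.
#' @param mu Gaussian mean in Angstrom.
#' @param sigma base standard deviation in Angstrom.
#' @param lambda_scale dimensionless scaling factor applied to `sigma`.
#' @return nonnegative weight(s).
#' @export
transition_weight <- function(distance, mu = 3.8047, sigma = 0.036,
                              lambda_scale = 10) {
  if (any(distance < 0)) stop("`distance` must be nonnegative")
  stats::dnorm(distance, mean = mu, sd = sigma * lambda_scale)
}

#' Build an HMM over C-alpha candidates
#'
#' Precomputes per-state emission vectors and the sparse transition
#' structure: each state's neighbors are the candidates within
#' `cutoff` Angstrom (default [2, 6], where the 0.36 A transition
#' Gaussian retains all non-negligible mass), with Gaussian weights
#' normalized to outgoing probabilities.
#'
#' @param candidates a `ca_candidates` object.
#' @param mu,sigma,lambda_scale transition Gaussian parameters, see
#'   [transition_weight()].
#' @param background background amino frequencies
#'   ([background_frequencies()]).
#' @param cutoff length-2 neighbor distance window in Angstrom.
#' @return object of class `hmm_model`.
#' @export
build_hmm <- function(candidates, mu = 3.8047, sigma = 0.036,
                      lambda_scale = 10,
                      background = background_frequencies(),
                      cutoff = c(2, 6)) {
  stopifnot(inherits(candidates, "ca_candidates"))
  n <- nrow(candidates$xyz)
  emissions <- t(apply(candidates$amino_probs, 1, emission_probs,
                       background = background))
  emissions <- matrix(emissions, nrow = n)
  xyz <- candidates$xyz
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d <- sqrt(pmax(d2, 0))
  neighbors <- vector("list", n)
  trans_log <- vector("list", n)
  for (s in seq_len(n)) {
    nb <- which(d[s, ] >= cutoff[1] & d[s, ] <= cutoff[2])
    nb <- nb[nb != s]
    neighbors[[s]] <- nb
    if (length(nb) > 0) {
      w <- transition_weight(d[s, nb], mu, sigma, lambda_scale)
      if (sum(w) <= 0) {
        # numerically dead neighborhood: fall back to uniform over neighbors
        trans_log[[s]] <- rep(-log(length(nb)), length(nb))
      } else {
        trans_log[[s]] <- log(w / sum(w))
      }
    } else {
      trans_log[[s]] <- numeric(0)
    }
  }
  out <- list(candidates = candidates, emissions = emissions,
              log_emissions = log(emissions), neighbors = neighbors,
              trans_log = trans_log, mu = mu, sigma = sigma,
              lambda_scale = lambda_scale, background = background,
              cutoff = cutoff)
  class(out) <- "hmm_model"
  out
}

#' @export
print.hmm_model <- function(x, ...) {
  nn <- lengths(x$neighbors)
  cat(sprintf(
    "hmm_model: %d states, mu %.4f A, effective sd %.3f A, neighbors/state %.1f (window [%g, %g] A)\n",
    nrow(x$emissions), x$mu, x$sigma * x$lambda_scale, mean(nn),
    x$cutoff[1], x$cutoff[2]))
  invisible(x)
}

#' Initial state distribution for a chain
#'
#' Every state may start a chain; the probability of state `s` starting is
#' its emission of the chain's first amino type, normalized over all
#' (available) states.
#'
#' @param model an `hmm_model`.
#' @param first_aa amino code 1--20 of the first residue.
#' @param available optional integer vector of state indices still free.
#' @return numeric vector over `available` (or all states) summing to 1.
#' @export
initial_probs <- function(model, first_aa, available = NULL) {
  stopifnot(inherits(model, "hmm_model"))
  if (is.null(available)) available <- seq_len(nrow(model$emissions))
  if (length(available) == 0) stop("no states available")
  e <- model$emissions[available, first_aa]
  s <- sum(e)
  if (s <= 0) stop("degenerate start: no available state emits this amino type")
  e / s
}

#' Align protein sequences to candidate states (injective beam Viterbi)
#'
#' Decodes, per chain, the highest-scoring injective state path realizing
#' the sequence: score = log initial + sum of log transition + sum of log
#' emission, all in log domain. A state used once is never reused, within
#' a chain or by later chains. Chains are processed longest first; each
#' chain consumes its states from the global pool. Exact decoding under
#' the no-reuse constraint is combinatorial, so a beam over partial
#' injective paths is used; with a beam at least the number of injective
#' paths the search is exhaustive. Equal scores break toward the
#' lexicographically smaller state path.
#'
#' @param model an `hmm_model`.
#' @param sequences named list/vector of chain sequences (one-letter
#'   strings or integer amino-code vectors).
#' @param beam_width maximum number of partial paths retained per step
#'   (default 32).
#' @return list of `traced_chain` objects (in input order), each with
#'   `chain_id`, `sequence`, `states` (1-based candidate indices,
#'   injective), `xyz`, `score` (log domain).
#' @export
viterbi_align <- function(model, sequences, beam_width = 32L) {
  stopifnot(inherits(model, "hmm_model"))
  if (length(sequences) == 0) stop("no sequences supplied")
  seqs <- lapply(sequences, function(s) {
    if (is.character(s)) {
      amino_from_one_letter(strsplit(s, "")[[1]])
    } else as.integer(s)
  })
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- LETTERS[seq_along(seqs)]
  }
  if (any(lengths(seqs) == 0)) stop("empty sequence supplied")
  if (any(vapply(seqs, function(s) any(s < 1 | s > 20), logical(1)))) {
    stop("sequences must contain only the 20 standard amino types")
  }
  n_states <- nrow(model$emissions)
  if (sum(lengths(seqs)) > n_states) {
    stop(sprintf(
      "infeasible alignment: %d residues requested but only %d candidate states",
      sum(lengths(seqs)), n_states))
  }
  order_idx <- order(-lengths(seqs))
  available <- rep(TRUE, n_states)
  results <- vector("list", length(seqs))
  for (ci in order_idx) {
    aa <- seqs[[ci]]
    if (sum(available) < length(aa)) {
      stop("infeasible alignment: sequence longer than remaining free states")
    }
    path <- .beam_decode(model, aa, which(available), beam_width)
    available[path$states] <- FALSE
    tc <- list(chain_id = names(seqs)[ci],
               sequence = paste(amino_one_letter(aa), collapse = ""),
               states = path$states,
               xyz = model$candidates$xyz[path$states, , drop = FALSE],
               score = path$score)
    class(tc) <- "traced_chain"
    results[[ci]] <- tc
  }
  results
}

# Beam search over injective partial paths for one chain.
.beam_decode <- function(model, aa, avail, beam_width) {
  avail_set <- logical(nrow(model$emissions))
  avail_set[avail] <- TRUE
  pi0 <- initial_probs(model, aa[1], avail)
  keep <- pi0 > 0
  beam <- list(paths = lapply(avail[keep], function(s) s),
               scores = log(pi0[keep]) + model$log_emissions[avail[keep], aa[1]])
  beam <- .beam_prune(beam, beam_width)
  for (t in seq_along(aa)[-1]) {
    new_paths <- list(); new_scores <- numeric(0)
    for (b in seq_along(beam$paths)) {
      p <- beam$paths[[b]]
      last <- p[length(p)]
      nb <- model$neighbors[[last]]
      lw <- model$trans_log[[last]]
      ok <- avail_set[nb] & !(nb %in% p)
      if (!any(ok)) next
      cand <- nb[ok]
      sc <- beam$scores[b] + lw[ok] + model$log_emissions[cand, aa[t]]
      fin <- is.finite(sc)
      if (!any(fin)) next
      new_paths <- c(new_paths, lapply(cand[fin], function(s) c(p, s)))
      new_scores <- c(new_scores, sc[fin])
    }
    if (length(new_paths) == 0) {
      stop(sprintf(
        "beam exhausted at residue %d: no injective continuation within the neighbor window", t))
    }
    beam <- .beam_prune(list(paths = new_paths, scores = new_scores), beam_width)
  }
  best <- .beam_best(beam)
  list(states = beam$paths[[best]], score = beam$scores[best])
}

# Keep the top beam_width paths; ties broken toward lexicographically
# smaller state paths so decoding is deterministic.
.beam_prune <- function(beam, beam_width) {
  if (length(beam$paths) <= beam_width) return(beam)
  key <- vapply(beam$paths, function(p) paste(sprintf("%08d", p), collapse = ","),
                character(1))
  ord <- order(-beam$scores, key)
  keep <- ord[seq_len(beam_width)]
  list(paths = beam$paths[keep], scores = beam$scores[keep])
}

.beam_best <- function(beam) {
  top <- which(beam$scores == max(beam$scores))
  if (length(top) == 1) return(top)
  key <- vapply(beam$paths[top], function(p) paste(sprintf("%08d", p), collapse = ","),
                character(1))
  top[order(key)[1]]
}

#' @export
print.traced_chain <- function(x, ...) {
  cat(sprintf("traced_chain %s: %d residues, log score %.2f\n",
              x$chain_id, length(x$states), x$score))
  invisible(x)
}

#' Write traced chains as a C-alpha-only PDB file
#'
#' One `ATOM` record per traced residue (atom name `CA`), residue names
#' from the standard amino coding, chain ids preserved, `TER` after each
#' chain. The output parses back through [parse_structure()].
#'
#' @param chains list of `traced_chain` objects (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   traced C-alpha backbone (cryoforge)", con)
  serial <- 0L
  for (tc in chains) {
    stopifnot(inherits(tc, "traced_chain"))
    aa <- amino_from_one_letter(strsplit(tc$sequence, "")[[1]])
    res3 <- amino_three_letter(aa)
    for (r in seq_along(aa)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3[r], substr(tc$chain_id, 1, 1), r,
        tc$xyz[r, 1], tc$xyz[r, 2], tc$xyz[r, 3]), con)
    }
    if (length(aa) > 0) {
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %3s %1s%4d",
                         serial, res3[length(aa)], substr(tc$chain_id, 1, 1),
                         length(aa)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
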