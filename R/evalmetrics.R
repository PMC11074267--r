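# Voxel-level and chain-level evaluation, dataset statistics and splits.

#' Voxel-wise precision, recall and F1 for C-alpha predictions
#'
#' A voxel is predicted positive iff its probability reaches `threshold`.
#' F1 is the balanced summary appropriate here because C-alpha voxels are
#' a tiny fraction of a map. Vanishing denominators yield 0 by convention.
#'
#' @param predicted_prob numeric 3D array (or [density_grid]) of
#'   probabilities.
#' @param truth a `label_mask` (ca scheme) or 0/1 array of the same shape.
#' @param threshold decision threshold in `[0, 1]`.
#' @return named numeric: `precision`, `recall`, `f1`, plus counts `tp`,
#'   `fp`, `fn`.
#' @export
voxel_f1 <- function(predicted_prob, truth, threshold = 0.5) {
  if (inherits(predicted_prob, "density_grid")) predicted_prob <- predicted_prob$data
  if (inherits(truth, "label_mask")) truth <- truth$data
  if (!all(dim(predicted_prob) == dim(truth))) {
    stop("prediction and truth shapes differ")
  }
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  pred <- predicted_prob >= threshold
  tru <- truth != 0
  tp <- sum(pred & tru); fp <- sum(pred & !tru); fn <- sum(!pred & tru)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn)
}

.ca_matrix <- function(x) {
  if (inherits(x, "traced_chain")) {
    xyz <- x$xyz
    aa <- amino_from_one_letter(strsplit(x$sequence, "")[[1]])
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "traced_chain"))) {
    xyz <- do.call(rbind, lapply(x, `[[`, "xyz"))
    aa <- unlist(lapply(x, function(tc)
      amino_from_one_letter(strsplit(tc$sequence, "")[[1]])))
  } else if (inherits(x, "backbone_structure")) {
    keep <- stats::complete.cases(x[, c("ca_x", "ca_y", "ca_z")])
    xyz <- as.matrix(x[keep, c("ca_x", "ca_y", "ca_z")])
    aa <- x$amino_code[keep]
  } else {
    stop("expected a backbone_structure or traced_chain(s)")
  }
  list(xyz = xyz, aa = as.integer(aa))
}

#' Compare a traced backbone against a reference structure
#'
#' Matches model C-alpha atoms to reference C-alpha atoms one-to-one,
#' globally nearest pair first, accepting only pairs within `match_cutoff`
#' Angstrom. Reports the RMSD over matched pairs, the matching percentage
#' (share of reference residues matched) and the sequence identity
#' (share of matched pairs with identical amino type).
#'
#' @param model traced chain(s) or a `backbone_structure`.
#' @param reference a `backbone_structure` (or traced chains) with at
#'   least one C-alpha.
#' @param match_cutoff maximum pairing distance in Angstrom (default 3.0,
#'   the conventional chain-comparison cutoff).
#' @return object of class `chain_comparison`: list with `rmsd`,
#'   `matching_pct`, `seq_id_pct`, `n_reference`, `n_model`, `n_matched`.
#' @export
chain_compare <- function(model, reference, match_cutoff = 3.0) {
  m <- .ca_matrix(model)
  r <- .ca_matrix(reference)
  if (nrow(m$xyz) == 0 || nrow(r$xyz) == 0) stop("empty structure")
  d2 <- outer(rowSums(m$xyz^2), rowSums(r$xyz^2), "+") - 2 * m$xyz %*% t(r$xyz)
  d2 <- pmax(d2, 0)
  cut2 <- match_cutoff^2
  matched_d2 <- numeric(0)
  matched_id <- logical(0)
  repeat {
    best <- which.min(d2)
    if (length(best) == 0 || d2[best] > cut2) break
    bi <- arrayInd(best, dim(d2))
    matched_d2 <- c(matched_d2, d2[best])
    matched_id <- c(matched_id, m$aa[bi[1]] == r$aa[bi[2]])
    d2[bi[1], ] <- Inf
    d2[, bi[2]] <- Inf
    if (all(!is.finite(d2))) break
  }
  n_matched <- length(matched_d2)
  out <- list(
    rmsd = if (n_matched > 0) sqrt(mean(matched_d2)) else NA_real_,
    matching_pct = 100 * n_matched / nrow(r$xyz),
    seq_id_pct = if (n_matched > 0) 100 * mean(matched_id) else 0,
    n_reference = nrow(r$xyz), n_model = nrow(m$xyz), n_matched = n_matched
  )
  class(out) <- "chain_comparison"
  out
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat(sprintf(
    "chain comparison: %d/%d reference residues matched (%.1f%%), RMSD %.2f A, sequence ID %.1f%%\n",
    x$n_matched, x$n_reference, x$matching_pct,
    if (is.na(x$rmsd)) NaN else x$rmsd, x$seq_id_pct))
  invisible(x)
}

#' Column means over per-structure evaluation records
#'
#' Arithmetic mean of every numeric column; the standard summary row for
#' a benchmark table of per-structure resolution, residue counts, RMSD,
#' matching and sequence-identity percentages.
#'
#' @param records data frame with at least one row.
#' @return named numeric vector of per-column means (numeric columns
#'   only).
#' @export
summarize_reports <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a data frame with at least one row")
  }
  num <- vapply(records, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to summarize")
  colMeans(records[, num, drop = FALSE])
}

# round half away from zero (commonly expected for reported percentages;
# base round() is half-to-even)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Resolution-bin counts and percentages of a map set
#'
#' Bins map resolutions into [1, 2), [2, 3) and [3, 4] Angstrom and
#' reports counts and percentages (half-up, 2 decimals).
#'
#' @param metadata data frame with columns `id` and `resolution`
#'   (Angstrom, within `[1, 4]`).
#' @return data frame with columns `bin`, `count`, `pct`.
#' @export
dataset_stats <- function(metadata) {
  res <- metadata$resolution
  if (any(res < 1 | res > 4)) stop("resolutions must lie within [1, 4] Angstrom")
  counts <- c(
    sum(res >= 1 & res < 2),
    sum(res >= 2 & res < 3),
    sum(res >= 3 & res <= 4)
  )
  data.frame(
    bin = c("1.0-2.0", "2.0-3.0", "3.0-4.0"),
    count = counts,
    pct = .round_half_up(100 * counts / length(res), 2)
  )
}

#' Split map ids into training and validation sets
#'
#' Shuffles deterministically under `seed` and assigns the first
#' `floor(train_fraction * n)` ids to training, the rest to validation.
#' With `stratify`, the split is performed within each resolution bin
#' ([1,2), [2,3), [3,4]) so both sets share the resolution distribution.
#'
#' @param ids vector of map ids.
#' @param train_fraction fraction in (0, 1] assigned to training
#'   (default 0.9).
#' @param seed integer RNG seed; identical seeds give identical splits.
#' @param stratify optional numeric vector of per-id resolutions to
#'   stratify by.
#' @return object of class `split_spec`: list with `train`, `validation`,
#'   `train_fraction`, `seed`.
#' @export
split_dataset <- function(ids, train_fraction = 0.9, seed = 1L,
                          stratify = NULL) {
  if (train_fraction <= 0 || train_fraction > 1) {
    stop("`train_fraction` must be in (0, 1]")
  }
  do_split <- function(v, s) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(s)
    perm <- sample(length(v))
    ntr <- floor(train_fraction * length(v))
    list(train = v[perm[seq_len(ntr)]],
         validation = v[perm[-seq_len(ntr)]])
  }
  if (is.null(stratify)) {
    parts <- do_split(ids, seed)
  } else {
    if (length(stratify) != length(ids)) stop("`stratify` must match `ids`")
    bin <- cut(stratify, breaks = c(1, 2, 3, 4.000001), right = FALSE,
               include.lowest = TRUE)
    tr <- list(); va <- list()
    for (b in levels(bin)) {
      sel <- ids[which(bin == b)]
      if (length(sel) == 0) next
      p <- do_split(sel, seed + match(b, levels(bin)))
      tr[[b]] <- p$train; va[[b]] <- p$validation
    }
    parts <- list(train = unlist(tr, use.names = FALSE),
                  validation = unlist(va, use.names = FALSE))
  }
  out <- list(train = parts$train, validation = parts$validation,
              train_fraction = train_fraction, seed = seed)
  class(out) <- "split_spec"
  out
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: %d train / %d validation (fraction %.2f, seed %d)\n",
              length(x$train), length(x$validation), x$train_fraction, x$seed))
  invisible(x)
}
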