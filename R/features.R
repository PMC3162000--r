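# The eight regression features of an annotated (or register-assumed)
# segment, and their per-position factorization used to assemble MRF
# singleton potentials:
#   1  sum of log dimer per-heptad residue probabilities
#   2  sum of log trimer per-heptad residue probabilities
#   3  sum of log background (heptad-free) residue probabilities
#   4  dimer pairwise-correlation statistic, distances 1..7 pooled
#   5  trimer pairwise-correlation statistic
#   6  background pairwise-correlation statistic (heptad-free)
#   7  Eisenberg hydrophobicity summed over a-position residues
#   8  Eisenberg hydrophobicity summed over d-position residues
# The correlation statistic at distance k is the log of the joint
# probability of the residue pair (i-k, i) over the product of its
# single-residue marginals, summed over all pairs inside the segment.

#' @keywords internal
FEATURE_NAMES <- c("lp_dimer", "lp_trimer", "lp_bg",
                   "corr_dimer", "corr_trimer", "corr_bg",
                   "hyd_a", "hyd_d")

# Precompute X-augmented log tables (index 21 = column-average for X).
#' @keywords internal
augment_tables <- function(tables) {
  single <- array(0, dim = c(2, 7, 21))
  for (c_ in 1:2) single[c_, , ] <- augment_single(tables$single[c_, , ])
  pair <- array(0, dim = c(2, 7, 7, 21, 21))
  for (c_ in 1:2) for (k in 1:7) for (h in 1:7) {
    pair[c_, k, h, , ] <- augment_pair_slice(tables$pair[c_, k, h, , ])
  }
  pair_bg <- array(0, dim = c(7, 21, 21))
  for (k in 1:7) pair_bg[k, , ] <- augment_pair_slice(tables$pair_bg[k, , ])
  list(log_single = log(single),
       log_single_bg = log(augment_bg(tables$single_bg)),
       log_pair = log(pair),
       log_pair_bg = log(pair_bg))
}

#' Compute the eight regression features of an annotated segment
#'
#' @param residues Character vector of residues (one-letter codes).
#' @param register Character vector of heptad letters, same length,
#'   cyclically continuous.
#' @param tables A `coil_freq_tables` object.
#' @param scale Hydrophobicity scale, as from [hydropathy_scale()].
#' @return Named numeric vector of the 8 features.
#' @export
compute_features <- function(residues, register, tables,
                             scale = hydropathy_scale()) {
  stopifnot(length(residues) == length(register), length(residues) > 0)
  validate_register(paste(register, collapse = ""))
  aug <- augment_tables(tables)
  compute_features_aug(residues, register, aug, scale)
}

# Internal variant taking pre-augmented tables (to amortize augmentation
# over many segments).
#' @keywords internal
compute_features_aug <- function(residues, register, aug, scale) {
  aa <- aa_index_aug(residues)
  h <- heptad_index(register)
  L <- length(aa)

  f <- stats::setNames(numeric(8), FEATURE_NAMES)
  f["lp_dimer"] <- sum(aug$log_single[cbind(1L, h, aa)])
  f["lp_trimer"] <- sum(aug$log_single[cbind(2L, h, aa)])
  f["lp_bg"] <- sum(aug$log_single_bg[aa])

  for (k in 1:7) {
    if (L <= k) break
    i <- (k + 1L):L
    up <- aa[i - k]
    dn <- aa[i]
    hd <- h[i]
    hu <- h[i - k]
    for (c_ in 1:2) {
      lq <- aug$log_pair[cbind(c_, k, hd, up, dn)]
      lm <- aug$log_single[cbind(c_, hu, up)] + aug$log_single[cbind(c_, hd, dn)]
      f[3L + c_] <- f[3L + c_] + sum(lq - lm)
    }
    f["corr_bg"] <- f["corr_bg"] +
      sum(aug$log_pair_bg[cbind(k, up, dn)] -
            aug$log_single_bg[up] - aug$log_single_bg[dn])
  }

  hyd <- scale[residues]
  f["hyd_a"] <- sum(hyd[register == "a"])
  f["hyd_d"] <- sum(hyd[register == "d"])
  f
}

#' Per-position feature contribution under a hidden state
#'
#' Returns the position-`i` summands of the 8 features when position `i`
#' is in the given coil state.  The distance-k correlation terms are
#' included only when the state's location label guarantees that the
#' residue k positions upstream lies inside the same coil: `k < p` for
#' locations `p` in 1..7, and all distances 1..7 for locations 8 and 9.
#' Summed along the forced state path of a full coil this reproduces
#' [compute_features()] exactly (the factorization the MRF potentials
#' rely on).
#'
#' @param i Position (1-based) within `residues`.
#' @param state State label of a coil state (e.g. `"D.c4"`).
#' @param residues Character vector, full sequence.
#' @param tables A `coil_freq_tables` object.
#' @param scale Hydrophobicity scale.
#' @param space A `coil_state_space` (defaults to a fresh one).
#' @return Named numeric vector of the 8 per-position summands.
#' @export
per_position_contribution <- function(i, state, residues, tables,
                                      scale = hydropathy_scale(),
                                      space = build_state_space()) {
  s <- state_index(space, state)
  if (space$states$oligomer[s] == "NONCOIL") {
    stop("the non-coil state carries no features (reference class)",
         call. = FALSE)
  }
  h <- heptad_index(space$states$heptad[s])
  p <- space$states$location[s]
  gate <- min(p - 1L, 7L)
  aug <- augment_tables(tables)
  aa <- aa_index_aug(residues)

  f <- stats::setNames(numeric(8), FEATURE_NAMES)
  f["lp_dimer"] <- aug$log_single[1L, h, aa[i]]
  f["lp_trimer"] <- aug$log_single[2L, h, aa[i]]
  f["lp_bg"] <- aug$log_single_bg[aa[i]]
  if (gate > 0L) {
    for (k in seq_len(gate)) {
      # location > k guarantees an in-coil predecessor, hence i > k
      stopifnot(i - k >= 1L)
      up <- aa[i - k]
      hu <- ((h - 1L - k) %% 7L) + 1L
      for (c_ in 1:2) {
        f[3L + c_] <- f[3L + c_] +
          aug$log_pair[c_, k, h, up, aa[i]] -
          aug$log_single[c_, hu, up] - aug$log_single[c_, h, aa[i]]
      }
      f["corr_bg"] <- f["corr_bg"] +
        aug$log_pair_bg[k, up, aa[i]] -
        aug$log_single_bg[up] - aug$log_single_bg[aa[i]]
    }
  }
  if (space$states$heptad[s] == "a") f["hyd_a"] <- scale[residues[i]]
  if (space$states$heptad[s] == "d") f["hyd_d"] <- scale[residues[i]]
  f
}
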