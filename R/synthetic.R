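# Synthetic register-annotated coiled-coil families and negative
# sequences, for training and evaluating every stage without external
# databases.  Dimer and trimer classes are separated through their a/d
# core compositions (dimer Leu-heavy, trimer beta-branched Ile/Val-heavy,
# echoing the known core-packing preference); this is a device to make
# the classes learnable, not a biological claim.  Families are small
# multiplicative perturbations of the class composition, emulating
# family-level composition drift.

# Approximate natural amino-acid background frequencies.
#' @keywords internal
BACKGROUND_FREQS <- c(
  A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
  G = 0.074, H = 0.022, I = 0.051, K = 0.057, L = 0.091,
  M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
  S = 0.071, T = 0.058, V = 0.065, W = 0.013, Y = 0.032
)

# Fix some residue probabilities and spread the remaining mass over the
# others proportionally to a base composition.
#' @keywords internal
mix_composition <- function(base, fixed) {
  out <- stats::setNames(numeric(20), AMINO_ACIDS)
  out[names(fixed)] <- fixed
  rest <- setdiff(AMINO_ACIDS, names(fixed))
  out[rest] <- base[rest] / sum(base[rest]) * (1 - sum(fixed))
  out
}

#' @keywords internal
default_coil_compositions <- function() {
  bg <- BACKGROUND_FREQS
  # solvent-exposed b/c/f positions: mildly polar helix formers; e/g
  # positions carry the inter-helix salt-bridge charge signature shared
  # by both classes (phase information without class information)
  surface <- mix_composition(bg, c(E = 0.12, K = 0.10, Q = 0.09, R = 0.07,
                                   A = 0.10, L = 0.08, P = 0.001))
  edge <- mix_composition(bg, c(E = 0.22, K = 0.18, Q = 0.10, R = 0.08,
                                A = 0.08, L = 0.05, P = 0.001))
  comp <- function(a_core, d_core) {
    m <- matrix(0, 7, 20, dimnames = list(HEPTADS, AMINO_ACIDS))
    for (h in c("b", "c", "f")) m[h, ] <- surface
    for (h in c("e", "g")) m[h, ] <- edge
    m["a", ] <- mix_composition(bg, a_core)
    m["d", ] <- mix_composition(bg, d_core)
    m
  }
  # dimer cores follow the classic parallel-dimer profile: Leu-dominated
  # a with the Asn marker, Leu-dominated d; trimer cores are
  # beta-branched (Ile-heavy a, Val-heavy d).  The a/d asymmetry within
  # each class and the e/g charge signature pin the register phase.
  list(
    DIMER = comp(c(L = 0.45, N = 0.14, I = 0.04, V = 0.05, A = 0.06,
                   K = 0.05, M = 0.03, P = 0.001),
                 c(L = 0.60, A = 0.08, I = 0.04, V = 0.03, M = 0.06,
                   P = 0.001)),
    TRIMER = comp(c(I = 0.48, V = 0.18, L = 0.05, T = 0.06, M = 0.04,
                    N = 0.02, P = 0.001),
                  c(V = 0.32, I = 0.24, L = 0.08, T = 0.08, Q = 0.04,
                    P = 0.001)),
    background = bg
  )
}

#' Specification of a synthetic coiled-coil dataset
#'
#' Defines the generating conditions: number of families per class,
#' sequences per family, coil and flank length ranges, negative-sequence
#' count and length range, the per-class per-heptad residue
#' compositions, family-level composition jitter, optional pairwise
#' coupling, and the seed.
#'
#' @param n_families Families per coil class (default 6).
#' @param seqs_per_family Sequences per family (default 15).
#' @param coil_len Inclusive coil-length range, minimum 9 (default
#'   `c(21, 49)`).
#' @param flank_len Inclusive flank-length range on each side (default
#'   `c(5, 25)`).
#' @param n_negatives Number of negative sequences (default 150).
#' @param neg_len Inclusive negative-length range (default `c(60, 200)`).
#' @param family_jitter Standard deviation of the multiplicative
#'   log-normal perturbation applied per family (default 0.15).
#' @param compositions List with `DIMER`, `TRIMER` (7 x 20 per-heptad
#'   composition matrices) and `background` (length-20 vector).
#' @param coupling_k Optional distance (1..7) at which to couple coil
#'   residue pairs; see [plant_correlations()].
#' @param coupling_strength Coupling probability in `[0, 1]`; 0 means
#'   independent positions.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the spec.
#' @return Object of class `coil_synth_spec`.
#' @export
synthetic_spec <- function(n_families = 6L, seqs_per_family = 15L,
                           coil_len = c(21L, 49L), flank_len = c(5L, 25L),
                           n_negatives = 150L, neg_len = c(60L, 200L),
                           family_jitter = 0.15,
                           compositions = default_coil_compositions(),
                           coupling_k = integer(0), coupling_strength = 0,
                           seed = 42L) {
  coil_len <- as.integer(coil_len)
  flank_len <- as.integer(flank_len)
  neg_len <- as.integer(neg_len)
  stopifnot(n_families >= 1, seqs_per_family >= 1,
            length(coil_len) == 2, coil_len[1] >= 9,
            coil_len[2] >= coil_len[1],
            length(flank_len) == 2, flank_len[2] >= flank_len[1],
            flank_len[1] >= 0,
            n_negatives >= 1, neg_len[2] >= neg_len[1], neg_len[1] >= 1,
            family_jitter >= 0, coupling_strength >= 0,
            coupling_strength <= 1)
  for (cls in COIL_CLASSES) {
    m <- compositions[[cls]]
    stopifnot(all(dim(m) == c(7, 20)), all(m >= 0),
              all(abs(rowSums(m) - 1) < 1e-8))
  }
  stopifnot(abs(sum(compositions$background) - 1) < 1e-8)
  structure(list(n_families = n_families, seqs_per_family = seqs_per_family,
                 coil_len = coil_len, flank_len = flank_len,
                 n_negatives = n_negatives, neg_len = neg_len,
                 family_jitter = family_jitter, compositions = compositions,
                 coupling_k = coupling_k,
                 coupling_strength = coupling_strength, seed = seed),
            class = "coil_synth_spec")
}

#' Plant pairwise correlations into a synthetic spec
#'
#' Couples coil residue pairs at distance `k`: when generating a coil
#' residue whose distance-`k` upstream neighbour lies inside the same
#' coil, the residue copies that neighbour with probability `strength`
#' and is otherwise drawn from the per-heptad composition.  Strength 0
#' recovers independent positions; increasing strength increases the
#' mutual information of the distance-`k` joint.
#'
#' @param spec A `coil_synth_spec`.
#' @param k Coupling distance in 1..7.
#' @param strength Coupling probability in `[0, 1]`.
#' @return The modified spec.
#' @export
plant_correlations <- function(spec, k, strength) {
  if (!(length(k) == 1L && k %in% 1:7)) {
    stop("coupling distance k must be a single integer in 1..7",
         call. = FALSE)
  }
  stopifnot(strength >= 0, strength <= 1)
  spec$coupling_k <- as.integer(k)
  spec$coupling_strength <- strength
  spec
}

#' @keywords internal
draw_coil_residues <- function(register, comp, coupling_k,
                               coupling_strength) {
  L <- length(register)
  if (length(coupling_k) == 0L || coupling_strength == 0) {
    res <- character(L)
    for (h in unique(register)) {
      idx <- which(register == h)
      res[idx] <- sample(AMINO_ACIDS, length(idx), replace = TRUE,
                         prob = comp[h, ])
    }
    return(res)
  }
  res <- character(L)
  for (j in seq_len(L)) {
    if (j > coupling_k && stats::runif(1) < coupling_strength) {
      res[j] <- res[j - coupling_k]
    } else {
      res[j] <- sample(AMINO_ACIDS, 1, prob = comp[register[j], ])
    }
  }
  res
}

#' @keywords internal
draw_background_residues <- function(n, bg) {
  sample(AMINO_ACIDS, n, replace = TRUE, prob = bg)
}

#' Generate a synthetic dataset from a spec
#'
#' Deterministic given the spec (including its seed).  Every record
#' carries one coil with a continuous register starting at a random
#' heptad, embedded in background-composition flanks; families are
#' log-normal perturbations of the class composition; negatives are
#' background-composition sequences.
#'
#' @param spec A `coil_synth_spec`.
#' @return List with `families` (named list of `nps_record` lists) and
#'   `negatives` (named character vector).
#' @export
sample_dataset <- function(spec) {
  stopifnot(inherits(spec, "coil_synth_spec"))
  set.seed(spec$seed)
  rint <- function(rng) {
    if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  }
  families <- list()
  for (cls in COIL_CLASSES) {
    base <- spec$compositions[[cls]]
    for (j in seq_len(spec$n_families)) {
      fam_name <- sprintf("%s_fam%02d", tolower(cls), j)
      comp <- base
      if (spec$family_jitter > 0) {
        for (h in HEPTADS) {
          w <- base[h, ] * exp(stats::rnorm(20, 0, spec$family_jitter))
          comp[h, ] <- w / sum(w)
        }
      }
      recs <- list()
      for (s in seq_len(spec$seqs_per_family)) {
        L <- rint(spec$coil_len)
        left <- rint(spec$flank_len)
        right <- rint(spec$flank_len)
        start_h <- sample(HEPTADS, 1L)
        register <- heptad_shift(start_h, seq_len(L) - 1L)
        coil <- draw_coil_residues(register, comp, spec$coupling_k,
                                   spec$coupling_strength)
        seqres <- c(draw_background_residues(left, spec$compositions$background),
                    coil,
                    draw_background_residues(right, spec$compositions$background))
        recs[[s]] <- new_nps_record(
          name = sprintf("%s_seq%02d", fam_name, s),
          descriptors = c("synthetic", "parallel", "homo", tolower(cls)),
          sequence = paste(seqres, collapse = ""),
          annotations = list(list(start = left, end = left + L,
                                  register = paste(register, collapse = ""))),
          oligomer = cls, family = fam_name)
      }
      families[[fam_name]] <- recs
    }
  }
  negatives <- vapply(seq_len(spec$n_negatives), function(i) {
    paste(draw_background_residues(rint(spec$neg_len),
                                   spec$compositions$background),
          collapse = "")
  }, "")
  names(negatives) <- sprintf("neg%03d", seq_len(spec$n_negatives))
  list(families = families, negatives = negatives)
}

#' Write a synthetic dataset to disk in the standard formats
#'
#' One 4-line family file per family plus a FASTA of negatives, so
#' synthetic data flows through the same readers as real data.
#'
#' @param dataset List from [sample_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fam in names(dataset$families)) {
    write_nps_family_file(dataset$families[[fam]],
                          file.path(dir, paste0(fam, ".txt")))
  }
  write_fasta(dataset$negatives, file.path(dir, "negatives.fasta"))
  invisible(dir)
}

#' Read a dataset directory written by [write_synthetic_dataset()]
#'
#' @param dir Directory containing `*.txt` family files and
#'   `negatives.fasta`.
#' @return List with `families` and `negatives`.
#' @export
read_dataset_dir <- function(dir) {
  fam_files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  families <- lapply(fam_files, parse_nps_family_file)
  names(families) <- sub("\\.txt$", "", basename(fam_files))
  list(families = families,
       negatives = read_fasta(file.path(dir, "negatives.fasta")))
}
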