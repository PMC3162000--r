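# MRF potentials and exact posterior decoding.
#
# The joint over hidden states y and residues x factorizes into singleton
# potentials psi1 (learned: exp of the regression score of the state's
# per-position feature contribution) and transition indicators psi2 (the
# 0/1 transition matrix of the state space).  Per-residue posteriors are
# exact marginals computed by forward-backward in log space; a
# brute-force path-enumeration oracle verifies them on short sequences.

#' Build the singleton log-potentials for a sequence
#'
#' For a dimer state the log-potential at position i is the dot product
#' of the dimer coefficients with the per-position feature contribution
#' of that state (see [per_position_contribution()]); trimer states use
#' the trimer coefficients; the class constant (after offset) is added
#' exactly at location-1 states, so every coil path picks it up once.
#' The non-coil state is the reference with log-potential 0.
#'
#' @param residues Character vector (or single string) of residues.
#' @param model A `coil_mrf_model`.
#' @param tables A `coil_freq_tables` object.
#' @param scale Hydrophobicity scale.
#' @param space A `coil_state_space`.
#' @return Object of class `coil_potentials`: list with `log_psi1`
#'   (n x 127 matrix) and `space`.
#' @export
build_potentials <- function(residues, model, tables,
                             scale = hydropathy_scale(),
                             space = build_state_space()) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  n <- length(residues)
  stopifnot(n >= 1L)
  aug <- augment_tables(tables)
  aa <- aa_index_aug(residues)
  hyd <- unname(scale[residues])

  M1 <- aug$log_single[1, , ]           # 7 x 21, dimer
  M2 <- aug$log_single[2, , ]
  lsd <- M1[, aa, drop = FALSE]         # 7 x n
  lst <- M2[, aa, drop = FALSE]
  lbg <- aug$log_single_bg[aa]          # n

  # Correlation summands C[k, h, i] for the downstream residue at i in
  # heptad h with an in-coil predecessor at distance k.  Entries with
  # i <= k are left at 0: the location gating (k < p <= i) makes any
  # state needing them unreachable, so they never touch a posterior.
  Cd <- array(0, dim = c(7, 7, n))
  Ct <- array(0, dim = c(7, 7, n))
  Cbg <- matrix(0, 8, n)                # row g+1 = cumulative over k <= g
  cbg_k <- matrix(0, 7, n)
  for (k in 1:7) {
    if (n <= k) break
    i <- (k + 1L):n
    up <- aa[i - k]
    dn <- aa[i]
    Sbg <- aug$log_pair_bg[k, , ]
    cbg_k[k, i] <- Sbg[cbind(up, dn)] -
      aug$log_single_bg[up] - aug$log_single_bg[dn]
    for (h in 1:7) {
      hu <- ((h - 1L - k) %% 7L) + 1L
      S1 <- aug$log_pair[1, k, h, , ]
      S2 <- aug$log_pair[2, k, h, , ]
      Cd[k, h, i] <- S1[cbind(up, dn)] - M1[hu, up] - M1[h, dn]
      Ct[k, h, i] <- S2[cbind(up, dn)] - M2[hu, up] - M2[h, dn]
    }
  }
  # cumulative over distance: gate index g+1 holds sum over k <= g
  cumd <- array(0, dim = c(8, 7, n))
  cumt <- array(0, dim = c(8, 7, n))
  for (h in 1:7) {
    cumd[2:8, h, ] <- apply(Cd[, h, , drop = FALSE], 3, cumsum)
    cumt[2:8, h, ] <- apply(Ct[, h, , drop = FALSE], 3, cumsum)
  }
  Cbg[2:8, ] <- apply(cbg_k, 2, cumsum)

  # 63 coil states per class, heptad-major: state (h, p) at row (h-1)*9+p
  hs <- rep(1:7, each = 9)
  ps <- rep(1:9, times = 7)
  gi <- pmin(ps, 8L)                    # gate index = min(p-1, 7) + 1
  cum_rows <- gi + 8L * (hs - 1L)
  dim(cumd) <- c(8 * 7, n)
  dim(cumt) <- c(8 * 7, n)

  F1 <- lsd[hs, , drop = FALSE]
  F2 <- lst[hs, , drop = FALSE]
  F3 <- matrix(lbg, 63, n, byrow = TRUE)
  F4 <- cumd[cum_rows, , drop = FALSE]
  F5 <- cumt[cum_rows, , drop = FALSE]
  F6 <- Cbg[gi, , drop = FALSE]
  F7 <- outer(as.numeric(hs == 1L), hyd)
  F8 <- outer(as.numeric(hs == 4L), hyd)

  score <- function(cf, const) {
    cf[1] * F1 + cf[2] * F2 + cf[3] * F3 + cf[4] * F4 +
      cf[5] * F5 + cf[6] * F6 + cf[7] * F7 + cf[8] * F8 +
      const * (ps == 1L)
  }
  log_psi1 <- matrix(0, n, 127)
  log_psi1[, 2:64] <- t(score(unname(model$alpha), model$c_dimer))
  log_psi1[, 65:127] <- t(score(unname(model$beta), model$c_trimer))
  colnames(log_psi1) <- space$states$label
  structure(list(log_psi1 = log_psi1, space = space),
            class = "coil_potentials")
}

#' Exact per-residue state posteriors by forward-backward
#'
#' Log-space forward and backward recursions over the 127-state chain
#' with the initial/final state restrictions of the state space; returns
#' the marginal posterior of every state at every position and the log
#' normalizer (computed from both passes as a numerical self-check).
#'
#' @param potentials A `coil_potentials` object.
#' @return Object of class `coil_posterior`: `gamma` (n x 127 matrix of
#'   posteriors), `logZ`, `logZ_backward`.
#' @export
forward_backward <- function(potentials) {
  lp <- potentials$log_psi1
  space <- potentials$space
  n <- nrow(lp)
  ns <- ncol(lp)
  Tm <- space$transition

  la <- matrix(-Inf, n, ns)
  la[1, space$initial] <- lp[1, space$initial]
  if (n > 1) {
    for (i in 2:n) {
      prev <- la[i - 1, ]
      m <- max(prev)
      s <- as.vector(exp(prev - m) %*% Tm)
      la[i, ] <- lp[i, ] + log(s) + m
    }
  }
  lb <- matrix(-Inf, n, ns)
  lb[n, space$final] <- 0
  if (n > 1) {
    for (i in (n - 1):1) {
      nxt <- lp[i + 1, ] + lb[i + 1, ]
      m <- max(nxt)
      lb[i, ] <- log(as.vector(Tm %*% exp(nxt - m))) + m
    }
  }
  logZ <- logsumexp(la[n, space$final])
  logZb <- logsumexp(lp[1, space$initial] + lb[1, space$initial])
  gamma <- exp(la + lb - logZ)
  colnames(gamma) <- space$states$label
  structure(list(gamma = gamma, logZ = logZ, logZ_backward = logZb),
            class = "coil_posterior")
}

#' Brute-force posterior oracle by explicit path summation
#'
#' Enumerates every valid state path for the sequence length (guarded to
#' 14), scores each path as the sum of its singleton log-potentials, and
#' accumulates normalized path weights into per-position state
#' posteriors.  Independent of the forward-backward recursions; used to
#' verify them.
#'
#' @param potentials A `coil_potentials` object for a sequence of at
#'   most 14 residues.
#' @return A `coil_posterior` object.
#' @export
brute_force_posterior <- function(potentials) {
  lp <- potentials$log_psi1
  space <- potentials$space
  n <- nrow(lp)
  paths <- enumerate_valid_paths(space, n)
  scores <- vapply(seq_len(nrow(paths)), function(j) {
    sum(lp[cbind(seq_len(n), paths[j, ])])
  }, 0)
  logZ <- logsumexp(scores)
  wts <- exp(scores - logZ)
  gamma <- matrix(0, n, ncol(lp))
  for (j in seq_len(nrow(paths))) {
    gamma[cbind(seq_len(n), paths[j, ])] <-
      gamma[cbind(seq_len(n), paths[j, ])] + wts[j]
  }
  colnames(gamma) <- space$states$label
  structure(list(gamma = gamma, logZ = logZ, logZ_backward = logZ),
            class = "coil_posterior")
}

#' Collapse state posteriors to per-residue oligomer probabilities
#'
#' Sums the posterior over the 63 states of each coil class per residue.
#' The displayed register is the heptad of the arg-max coil state when
#' the total coil probability exceeds 0.5, otherwise `-`.
#'
#' @param posterior A `coil_posterior` object.
#' @param residues Character vector of residues (for the output table).
#' @param space A `coil_state_space`.
#' @return Data frame of prediction rows: `position`, `residue`,
#'   `best_register`, `p_dimer`, `p_trimer`, `p_coil`.
#' @export
posterior_oligomer_probs <- function(posterior, residues,
                                     space = build_state_space()) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  g <- posterior$gamma
  dimer_cols <- which(space$states$oligomer == "DIMER")
  trimer_cols <- which(space$states$oligomer == "TRIMER")
  coil_cols <- c(dimer_cols, trimer_cols)
  p_dimer <- rowSums(g[, dimer_cols, drop = FALSE])
  p_trimer <- rowSums(g[, trimer_cols, drop = FALSE])
  p_coil <- p_dimer + p_trimer
  best <- apply(g[, coil_cols, drop = FALSE], 1, which.max)
  reg <- ifelse(p_coil > 0.5, space$states$heptad[coil_cols[best]], "-")
  data.frame(position = seq_len(nrow(g)), residue = residues,
             best_register = reg, p_dimer = p_dimer, p_trimer = p_trimer,
             p_coil = p_coil, stringsAsFactors = FALSE)
}
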