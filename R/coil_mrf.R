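# The user-facing model: fit once from annotated families plus negative
# sequences, then predict per-residue coil/oligomer posteriors for new
# sequences.

#' Fit a coiled-coil MRF predictor
#'
#' End-to-end training: tallies smoothed single and pairwise frequency
#' tables from the annotated records and negatives, draws one
#' register-randomized window per negative sequence, computes the 8
#' features of every example, fits the class-weighted multinomial
#' regression (non-coil reference class), and subtracts the coil-bias
#' offset from the class constants.
#'
#' @param records List of annotated `nps_record` objects (or a named
#'   list of per-family record lists, which is flattened).
#' @param negatives Named character vector of negative (non-coil)
#'   residue strings.
#' @param pseudocount Additive smoothing constant for all tables.
#' @param offset Coil-bias offset subtracted from both class constants
#'   (default 20).
#' @param class_totals Per-class training weight totals (defaults:
#'   dimer 1, trimer 1, non-coil 1000).
#' @param ridge L2 penalty on the 16 feature coefficients.
#' @param tol,max_iter Convergence controls for the regression.
#' @param seed Optional integer seed for the negative-window draws,
#'   recorded in the fit.
#' @return Object of class `coil_mrf` with components `model`
#'   (regression fit), `tables`, `space`, `training` (the example
#'   table), and the call.
#' @seealso [predict.coil_mrf()], [leave_family_out()]
#' @export
#' @examples
#' dataset <- sample_dataset(synthetic_spec(n_families = 2,
#'                                          seqs_per_family = 3,
#'                                          n_negatives = 12, seed = 7))
#' fit <- coil_mrf(dataset$families, dataset$negatives, seed = 7)
#' print(fit)
#' pred <- predict(fit, dataset$negatives[1])
#' head(pred[[1]])
coil_mrf <- function(records, negatives, pseudocount = 1, offset = 20,
                     class_totals = c(dimer = 1, trimer = 1, noncoil = 1000),
                     ridge = 1e-3, tol = 1e-6, max_iter = 200L,
                     seed = NULL) {
  if (length(records) > 0 && !inherits(records[[1]], "nps_record")) {
    records <- do.call(c, unname(records))
  }
  tables <- coil_freq_tables(records, negatives, pseudocount)
  scale <- hydropathy_scale()
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(negatives))) {
    names(negatives) <- sprintf("neg%03d", seq_along(negatives))
  }
  windows <- lapply(names(negatives), function(id) {
    sample_negative_window(negatives[[id]], id = id)
  })
  segs <- segments_by_class(records)
  examples <- assemble_training_set(segs$DIMER, segs$TRIMER, windows,
                                    tables, scale, class_totals)
  fit <- fit_multinomial(examples, ridge = ridge, tol = tol,
                         max_iter = max_iter)
  fit <- apply_offset(fit, offset)
  structure(list(model = fit, tables = tables, space = build_state_space(),
                 scale = scale, training = examples,
                 class_totals = class_totals, seed = seed,
                 call = match.call()),
            class = "coil_mrf")
}

#' @export
print.coil_mrf <- function(x, ...) {
  cat("Coiled-coil MRF predictor\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  tab <- table(x$training$label)
  cat(sprintf("Training examples: %d dimer coils, %d trimer coils, %d negative windows\n",
              tab[["DIMER"]], tab[["TRIMER"]], tab[["NONCOIL"]]))
  cat(sprintf("Regression converged in %d iterations (offset %g applied)\n",
              x$model$iterations, x$model$offset))
  invisible(x)
}

#' @export
coef.coil_mrf <- function(object, ...) {
  m <- object$model
  c(stats::setNames(c(m$c_dimer, m$alpha),
                    paste0("dimer.", c("constant", FEATURE_NAMES))),
    stats::setNames(c(m$c_trimer, m$beta),
                    paste0("trimer.", c("constant", FEATURE_NAMES))))
}

#' @export
logLik.coil_mrf <- function(object, ...) {
  structure(object$model$loglik, df = 18L, class = "logLik")
}

#' @export
summary.coil_mrf <- function(object, ...) {
  m <- object$model
  structure(list(
    coefficients = rbind(dimer = c(constant = m$c_dimer, m$alpha),
                         trimer = c(constant = m$c_trimer, m$beta)),
    n_examples = table(object$training$label),
    weight_totals = tapply(object$training$weight, object$training$label, sum),
    offset = m$offset, loglik = m$loglik, iterations = m$iterations,
    pseudocount = object$tables$pseudocount
  ), class = "summary.coil_mrf")
}

#' @export
print.summary.coil_mrf <- function(x, ...) {
  cat("Coiled-coil MRF predictor\n\n")
  cat("Regression coefficients (non-coil is the reference class):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nOffset applied to constants: %g\n", x$offset))
  cat(sprintf("Weighted log-likelihood: %.4f (%d Newton iterations)\n",
              x$loglik, x$iterations))
  cat("\nTraining class totals (example count / weight sum):\n")
  for (g in names(x$n_examples)) {
    cat(sprintf("  %-8s %4d / %g\n", g, x$n_examples[[g]],
                x$weight_totals[[g]]))
  }
  invisible(x)
}

#' Per-residue posterior predictions for new sequences
#'
#' Runs exact forward-backward posterior decoding for each sequence and
#' collapses the 127 state posteriors to per-residue dimer, trimer and
#' total coil probabilities.
#'
#' @param object A fitted `coil_mrf`.
#' @param sequences Character vector of residue strings (named or not),
#'   or a single string.
#' @param ... Unused.
#' @return Named list of prediction data frames (one per sequence) with
#'   columns `position`, `residue`, `best_register`, `p_dimer`,
#'   `p_trimer`, `p_coil`.
#' @export
predict.coil_mrf <- function(object, sequences, ...) {
  sequences <- normalize_residues(sequences)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  out <- lapply(sequences, function(s) {
    pot <- build_potentials(s, object$model, object$tables, object$scale,
                            object$space)
    posterior_oligomer_probs(forward_backward(pot), s, object$space)
  })
  out
}

#' Plot the posterior coil profile of a sequence
#'
#' @param x A fitted `coil_mrf`.
#' @param sequence A residue string.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coil_mrf <- function(x, sequence, main = "coiled-coil posterior", ...) {
  rows <- predict(x, sequence)[[1]]
  graphics::plot(rows$position, rows$p_coil, type = "l", ylim = c(0, 1),
                 xlab = "residue position", ylab = "posterior probability",
                 main = main, ...)
  graphics::lines(rows$position, rows$p_dimer, lty = 2)
  graphics::lines(rows$position, rows$p_trimer, lty = 3)
  graphics::legend("topright", legend = c("coil", "dimer", "trimer"),
                   lty = 1:3, bty = "n")
  invisible(rows)
}

#' Simulate annotated records from a fitted predictor
#'
#' Draws synthetic records whose coil residues follow the fitted
#' per-heptad single-residue tables and whose flanks follow the fitted
#' background table.  A generative check of the single-site part of the
#' model (pairwise correlations are not simulated).
#'
#' @param object A fitted `coil_mrf`.
#' @param nsim Number of records.
#' @param seed Optional seed.
#' @param oligomer Class to simulate from, `"DIMER"` or `"TRIMER"`
#'   (recycled over `nsim`).
#' @param coil_len,flank_len Length ranges.
#' @param ... Unused.
#' @return List of `nps_record` objects.
#' @export
simulate.coil_mrf <- function(object, nsim = 1, seed = NULL,
                              oligomer = c("DIMER", "TRIMER"),
                              coil_len = c(21L, 49L),
                              flank_len = c(5L, 25L), ...) {
  if (!is.null(seed)) set.seed(seed)
  oligomer <- rep_len(match.arg(oligomer, several.ok = TRUE), nsim)
  bg <- object$tables$single_bg
  lapply(seq_len(nsim), function(i) {
    cls <- oligomer[i]
    L <- sample(coil_len[1]:coil_len[2], 1L)
    left <- sample(flank_len[1]:flank_len[2], 1L)
    right <- sample(flank_len[1]:flank_len[2], 1L)
    register <- heptad_shift(sample(HEPTADS, 1L), seq_len(L) - 1L)
    coil <- vapply(register, function(h) {
      sample(AMINO_ACIDS, 1L, prob = object$tables$single[cls, h, ])
    }, "")
    seqres <- c(sample(AMINO_ACIDS, left, replace = TRUE, prob = bg), coil,
                sample(AMINO_ACIDS, right, replace = TRUE, prob = bg))
    new_nps_record(name = sprintf("sim%03d", i),
                   descriptors = c("synthetic", "parallel", "homo",
                                   tolower(cls)),
                   sequence = paste(seqres, collapse = ""),
                   annotations = list(list(start = left, end = left + L,
                                           register = paste(register,
                                                            collapse = ""))),
                   oligomer = cls, family = "simulated")
  })
}
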