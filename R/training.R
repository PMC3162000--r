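# Training-set assembly and the class-weighted multinomial logistic
# regression whose coefficients parameterize the MRF potentials.
#
# Positive examples are annotated dimer/trimer coil segments.  Negative
# examples are windows of non-coil sequences given a random assumed
# register: a window length is drawn uniformly on 0..249 (redrawn below
# 9), the window is the first L residues (the whole sequence if
# shorter), and the register starts at a uniformly drawn heptad and
# continues without skips.  Per-class example weights are normalized so
# the dimer and trimer classes each total 1 and the non-coil class
# totals 1000, encoding the strong prior that non-coil residues dominate
# natural sequences.

#' @keywords internal
rwindow_length <- function(n, max_window = 250L) {
  sample.int(max_window, n, replace = TRUE) - 1L
}

#' Sample a register-randomized negative window
#'
#' Draws a window length uniformly on `0..(max_window-1)` (lengths below
#' 9 are redrawn: they cannot host a valid coil path), takes the first
#' `L` residues of the sequence (all of it if shorter), and assigns a
#' continuous register starting at a uniformly drawn heptad.  Uses the
#' current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param sequence Residue string of at least 9 residues.
#' @param max_window Exclusive upper bound on the drawn length
#'   (default 250).
#' @param id Provenance label.
#' @return List with `residues`, `register` (character vectors) and
#'   `provenance`.
#' @export
sample_negative_window <- function(sequence, max_window = 250L, id = "neg") {
  n <- nchar(sequence)
  if (n < 9L) {
    stop("negative sequence shorter than 9 residues: ", id, call. = FALSE)
  }
  repeat {
    L <- rwindow_length(1L, max_window)
    if (L >= 9L) break
  }
  len <- min(L, n)
  start <- sample(HEPTADS, 1L)
  list(residues = strsplit(substr(sequence, 1L, len), "")[[1]],
       register = heptad_shift(start, seq_len(len) - 1L),
       provenance = id)
}

#' Assemble the weighted regression training set
#'
#' Computes the 8 features for every dimer coil, trimer coil and
#' negative window, and attaches per-class weights `total / count` with
#' class totals 1 (dimer), 1 (trimer) and 1000 (non-coil).
#'
#' @param dimer_segments,trimer_segments Lists of segments (fields
#'   `residues`, `register`, `provenance`), e.g. the annotated coils of
#'   parsed records.
#' @param negative_windows List of windows from
#'   [sample_negative_window()].
#' @param tables A `coil_freq_tables` object.
#' @param scale Hydrophobicity scale.
#' @param class_totals Named totals for `dimer`, `trimer`, `noncoil`.
#' @return Data frame with the 8 feature columns, `label`, `weight` and
#'   `provenance`.
#' @export
assemble_training_set <- function(dimer_segments, trimer_segments,
                                  negative_windows, tables,
                                  scale = hydropathy_scale(),
                                  class_totals = c(dimer = 1, trimer = 1,
                                                   noncoil = 1000)) {
  groups <- list(DIMER = dimer_segments, TRIMER = trimer_segments,
                 NONCOIL = negative_windows)
  totals <- c(DIMER = unname(class_totals[["dimer"]]),
              TRIMER = unname(class_totals[["trimer"]]),
              NONCOIL = unname(class_totals[["noncoil"]]))
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0) {
      stop("no training examples for class ", g, call. = FALSE)
    }
  }
  aug <- augment_tables(tables)
  rows <- list()
  for (g in names(groups)) {
    w <- totals[[g]] / length(groups[[g]])
    for (seg in groups[[g]]) {
      f <- compute_features_aug(seg$residues, seg$register, aug, scale)
      rows[[length(rows) + 1L]] <- c(
        as.list(f),
        list(label = g, weight = w,
             provenance = if (is.null(seg$provenance)) "" else seg$provenance))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# -- weighted multinomial logistic regression --------------------------------

#' Fit the class-weighted multinomial logistic regression
#'
#' Maximizes the weight-scaled multinomial log-likelihood over the three
#' classes with the non-coil class as reference (its linear score fixed
#' at 0), by Newton's method with step-halving (so the penalized
#' log-likelihood is non-decreasing across iterations).  A small L2
#' ridge on the 16 feature coefficients (never on the two constants)
#' guards against perfect separation.
#'
#' @param examples Training-set data frame from
#'   [assemble_training_set()].
#' @param ridge L2 penalty on feature coefficients (default 1e-3).
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `coil_mrf_model`: coefficient vectors `alpha`
#'   (dimer) and `beta` (trimer), raw constants `c_dimer`, `c_trimer`,
#'   `offset` (0 until [apply_offset()] is called), and convergence
#'   diagnostics (`loglik`, `loglik_trace`, `iterations`,
#'   `gradient_norm`, `converged`).
#' @export
fit_multinomial <- function(examples, ridge = 1e-3, tol = 1e-6,
                            max_iter = 200L) {
  stopifnot(all(FEATURE_NAMES %in% names(examples)))
  y <- match(examples$label, OLIGOMER_CLASSES)  # 1 NC, 2 D, 3 T
  if (anyNA(y) || length(unique(y)) < 3) {
    stop("training set must contain all three classes", call. = FALSE)
  }
  X <- cbind(1, as.matrix(examples[, FEATURE_NAMES]))
  if (!all(is.finite(X))) stop("non-finite feature value(s)", call. = FALSE)
  w <- examples$weight
  stopifnot(all(w > 0))
  n <- nrow(X)
  p <- ncol(X)                      # 9: intercept + 8 features
  pen_mask <- c(0, rep(1, p - 1L))  # ridge never touches the constants
  theta <- numeric(2L * p)          # (c_dimer, alpha) then (c_trimer, beta)

  obj <- function(theta) {
    S <- cbind(0, X %*% theta[1:p], X %*% theta[(p + 1L):(2L * p)])
    m <- pmax(S[, 1], S[, 2], S[, 3])
    lse <- m + log(exp(S[, 1] - m) + exp(S[, 2] - m) + exp(S[, 3] - m))
    ll <- sum(w * (S[cbind(seq_len(n), y)] - lse))
    P <- exp(S - lse)
    list(ll = ll - 0.5 * ridge * sum((pen_mask * theta[1:p])^2) -
           0.5 * ridge * sum((pen_mask * theta[(p + 1L):(2L * p)])^2),
         P = P)
  }

  cur <- obj(theta)
  trace <- cur$ll
  converged <- FALSE
  gnorm <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- cur$P
    gd <- crossprod(X, w * ((y == 2) - P[, 2])) - ridge * pen_mask * theta[1:p]
    gt <- crossprod(X, w * ((y == 3) - P[, 3])) -
      ridge * pen_mask * theta[(p + 1L):(2L * p)]
    g <- c(gd, gt)
    gnorm <- max(abs(g))
    if (gnorm < tol) {
      converged <- TRUE
      break
    }
    wdd <- w * P[, 2] * (1 - P[, 2])
    wtt <- w * P[, 3] * (1 - P[, 3])
    wdt <- w * P[, 2] * P[, 3]
    H <- rbind(
      cbind(crossprod(X, X * wdd) + diag(ridge * pen_mask, p),
            -crossprod(X, X * wdt)),
      cbind(-crossprod(X, X * wdt),
            crossprod(X, X * wtt) + diag(ridge * pen_mask, p)))
    step <- tryCatch(solve(H, g),
                     error = function(e) solve(H + diag(1e-10, 2L * p), g))
    lambda <- 1
    repeat {
      cand <- obj(theta + lambda * as.vector(step))
      if (cand$ll >= cur$ll || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    theta <- theta + lambda * as.vector(step)
    cur <- cand
    trace <- c(trace, cur$ll)
  }
  if (!converged) {
    stop(sprintf(paste0("multinomial regression did not converge in %d ",
                        "iterations (gradient infinity norm %.3g)"),
                 max_iter, gnorm), call. = FALSE)
  }
  structure(list(
    alpha = stats::setNames(theta[2:p], FEATURE_NAMES),
    beta = stats::setNames(theta[(p + 2L):(2L * p)], FEATURE_NAMES),
    c_dimer = theta[1],
    c_trimer = theta[p + 1L],
    offset = 0,
    ridge = ridge,
    loglik = cur$ll,
    loglik_trace = trace,
    iterations = iter,
    gradient_norm = gnorm,
    converged = converged
  ), class = "coil_mrf_model")
}

#' Subtract the coil-bias offset from the class constants
#'
#' Summing over state paths gives many coil paths but only one non-coil
#' path per residue, biasing raw posteriors towards coils; subtracting a
#' constant from both class constants compensates.  The default of 20 is
#' the conventional operating point.
#'
#' @param model A `coil_mrf_model`.
#' @param offset Amount subtracted from both constants (default 20).
#' @return The model with `c_dimer` and `c_trimer` reduced by `offset`
#'   and the cumulative amount recorded in `model$offset`.
#' @export
apply_offset <- function(model, offset = 20) {
  model$c_dimer <- model$c_dimer - offset
  model$c_trimer <- model$c_trimer - offset
  model$offset <- model$offset + offset
  model
}

#' @export
print.coil_mrf_model <- function(x, ...) {
  cat("Weighted multinomial regression (3 classes, non-coil reference)\n")
  cat("  converged in", x$iterations, "iterations; weighted log-likelihood",
      format(x$loglik, digits = 6), "\n")
  cat("  offset applied to constants:", x$offset, "\n")
  m <- rbind(dimer = c(constant = x$c_dimer, x$alpha),
             trimer = c(constant = x$c_trimer, x$beta))
  print(round(m, 4))
  invisible(x)
}

# -- model serialization -----------------------------------------------------

#' Write a fitted regression model to a versioned JSON file
#'
#' @param model A `coil_mrf_model`.
#' @param path Output path.
#' @param extra Optional named list of provenance fields (training seed,
#'   pseudocount, table reference) stored alongside the coefficients.
#' @export
write_model <- function(model, path, extra = list()) {
  payload <- c(list(
    format = "coilmrf-model", version = "1",
    alpha = as.list(model$alpha), beta = as.list(model$beta),
    c_dimer = model$c_dimer, c_trimer = model$c_trimer,
    offset = model$offset, ridge = model$ridge,
    loglik = model$loglik
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Input path.
#' @return A `coil_mrf_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "coilmrf-model")) {
    stop("not a coilmrf model file: ", path, call. = FALSE)
  }
  structure(list(
    alpha = stats::setNames(unlist(p$alpha), FEATURE_NAMES),
    beta = stats::setNames(unlist(p$beta), FEATURE_NAMES),
    c_dimer = p$c_dimer, c_trimer = p$c_trimer,
    offset = p$offset, ridge = p$ridge, loglik = p$loglik,
    converged = TRUE
  ), class = "coil_mrf_model")
}
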