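# Sequence-level evaluation: the dimer/trimer ratio statistic, coil
# detection rules, ROC sweeps, and the nested leave-family-out
# cross-validation protocol.

#' Dimer/trimer ratio statistic over an annotated coil
#'
#' For each residue of the interval with nonzero coil posterior, the
#' dimer ratio is `p_dimer / (p_dimer + p_trimer)`; the dimer score of
#' the coil is the sum of these ratios, the trimer score the sum of the
#' complementary ratios, and the statistic their ratio (`Inf` when the
#' trimer score is 0).
#'
#' @param rows Prediction data frame (see [posterior_oligomer_probs()]).
#' @param interval Optional 0-based half-open `c(start, end)` residue
#'   interval; defaults to all rows.
#' @return Object of class `coil_seq_score`: list with `dimer_score`,
#'   `trimer_score`, `statistic`, `n_residues`.
#' @export
dimer_trimer_statistic <- function(rows, interval = NULL) {
  if (!is.null(interval)) {
    rows <- rows[rows$position > interval[1] & rows$position <= interval[2], ,
                 drop = FALSE]
  }
  rows <- rows[rows$p_coil > 0, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("undefined statistic: no residue in the interval has nonzero ",
         "coil posterior", call. = FALSE)
  }
  ratio <- rows$p_dimer / (rows$p_dimer + rows$p_trimer)
  ds <- sum(ratio)
  ts <- sum(1 - ratio)
  structure(list(dimer_score = ds, trimer_score = ts,
                 statistic = if (ts == 0) Inf else ds / ts,
                 n_residues = nrow(rows)),
            class = "coil_seq_score")
}

#' @export
print.coil_seq_score <- function(x, ...) {
  cat(sprintf("dimer score %.3f / trimer score %.3f over %d residues: statistic %s\n",
              x$dimer_score, x$trimer_score, x$n_residues,
              format(x$statistic, digits = 4)))
  invisible(x)
}

#' Classify a sequence as dimer or trimer from its ratio statistic
#'
#' Dimer when the statistic exceeds the threshold, trimer when below;
#' a tie is called dimer (configurable convention).
#'
#' @param score A `coil_seq_score` (or a bare statistic value).
#' @param threshold Decision threshold (default 1).
#' @param tie One of `"DIMER"`/`"TRIMER"`: the call at exact equality.
#' @return `"DIMER"` or `"TRIMER"`.
#' @export
classify_sequence <- function(score, threshold = 1, tie = "DIMER") {
  s <- if (inherits(score, "coil_seq_score")) score$statistic else score
  if (s > threshold) "DIMER" else if (s < threshold) "TRIMER" else
    match.arg(tie, c("DIMER", "TRIMER"))
}

#' Per-residue coil detection calls
#'
#' @param rows Prediction data frame.
#' @param cutoff Coil-probability cutoff; a residue is called when
#'   `p_coil` strictly exceeds it.
#' @return Logical vector of calls.
#' @export
detect_residues <- function(rows, cutoff = 0.5) {
  rows$p_coil > cutoff
}

#' Sequence-level coil detection verdict
#'
#' With an annotation (positive-sequence test): detected iff every
#' residue of the annotated coil exceeds the cutoff.  Without one
#' (negative-sequence test): detected iff some 28-residue window has
#' every residue above the cutoff; sequences shorter than 28 residues
#' can therefore never be (falsely) detected.
#'
#' @param rows Prediction data frame.
#' @param cutoff Coil-probability cutoff.
#' @param annotation Optional 0-based half-open `c(start, end)` coil
#'   interval marking a known coil.
#' @return `TRUE` iff a coil is detected under the applicable rule.
#' @export
detect_sequence <- function(rows, cutoff = 0.5, annotation = NULL) {
  calls <- detect_residues(rows, cutoff)
  if (!is.null(annotation)) {
    idx <- (annotation[1] + 1L):annotation[2]
    return(all(calls[idx]))
  }
  n <- length(calls)
  if (n < 28L) return(FALSE)
  r <- rle(calls)
  any(r$values & r$lengths >= 28L)
}

#' ROC curve from positive and negative score distributions
#'
#' Sweeps thresholds over the sorted unique scores plus infinities; a
#' case is called positive when its score strictly exceeds the
#' threshold.
#'
#' @param positive,negative Numeric score vectors (higher = more
#'   positive-like).
#' @return Data frame of `threshold`, `tpr`, `fpr`, sorted by
#'   descending threshold (so tpr and fpr are non-decreasing).
#' @export
roc_curve <- function(positive, negative) {
  stopifnot(length(positive) > 0, length(negative) > 0)
  thr <- sort(unique(c(positive, negative, -Inf, Inf)), decreasing = TRUE)
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(positive > t), 0),
    fpr = vapply(thr, function(t) mean(negative > t), 0)
  )
}

#' Area under an ROC curve (trapezoidal)
#'
#' @param roc Data frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]
  tpr <- roc$tpr[o]
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' Merge small families into a single miscellaneous family
#'
#' Families with four sequences or fewer are pooled into one
#' `miscellaneous` family before leave-family-out testing, so that
#' trivially small folds do not arise.
#'
#' @param families Named list; each element a list of records.
#' @param min_size Smallest family size kept separate (default 5).
#' @return Regrouped named list.
#' @export
group_small_families <- function(families, min_size = 5L) {
  sizes <- vapply(families, length, 0L)
  small <- sizes < min_size
  if (!any(small)) return(families)
  out <- families[!small]
  out$miscellaneous <- do.call(c, unname(families[small]))
  out
}

# Coil segments of all records of some families, split by class.
#' @keywords internal
segments_by_class <- function(records) {
  segs <- do.call(c, lapply(records, record_segments))
  list(DIMER = Filter(function(s) s$oligomer == "DIMER", segs),
       TRIMER = Filter(function(s) s$oligomer == "TRIMER", segs))
}

#' Nested leave-family-out cross-validation
#'
#' For each held-out family F: the regression features of every training
#' family G are computed from frequency tables tallied over the training
#' families other than G (the nested n-2 scheme, so the regression sees
#' features of the same "unseen family" kind it will meet at test time);
#' negative-window features and the inference tables for predicting F
#' use all n-1 training families.  The held-out family contributes to no
#' table and no regression in its own fold; the per-fold input
#' fingerprints recorded in the result allow an explicit leakage audit.
#'
#' @param families Named list of record lists (after
#'   [group_small_families()]; at least 3 families).
#' @param negatives Named character vector of negative sequences.
#' @param pseudocount,offset,ridge,class_totals Passed to the tallying
#'   and regression stages.
#' @param threshold Dimer/trimer decision threshold.
#' @param cutoff Detection cutoff for per-residue calls.
#' @param seed Integer seed for negative-window sampling.
#' @return Object of class `coil_mrf_cv`: per-sequence results,
#'   per-family confusion table, pooled detection scores, and per-fold
#'   provenance (`fold_inputs`).
#' @export
leave_family_out <- function(families, negatives, pseudocount = 1,
                             offset = 20, ridge = 1e-3,
                             class_totals = c(dimer = 1, trimer = 1,
                                              noncoil = 1000),
                             threshold = 1, cutoff = 0.5, seed = 1L) {
  if (length(families) < 3L) {
    stop("the nested scheme needs at least 3 families after grouping",
         call. = FALSE)
  }
  space <- build_state_space()
  scale <- hydropathy_scale()
  results <- list()
  fold_inputs <- list()
  for (fam in names(families)) {
    train_fams <- setdiff(names(families), fam)
    train_records <- do.call(c, unname(families[train_fams]))

    # regression features for family G from tables over the other n-2
    pos_segments <- list(DIMER = list(), TRIMER = list())
    nested_table_records <- list()
    for (g in train_fams) {
      recs_g <- do.call(c, unname(families[setdiff(train_fams, g)]))
      nested_table_records[[g]] <-
        vapply(recs_g, function(r) paste0(r$family, "/", r$name), "")
      tab_g <- coil_freq_tables(recs_g, negatives, pseudocount)
      aug_g <- augment_tables(tab_g)
      for (rec in families[[g]]) {
        for (seg in record_segments(rec)) {
          f <- compute_features_aug(seg$residues, seg$register, aug_g, scale)
          pos_segments[[seg$oligomer]] <-
            c(pos_segments[[seg$oligomer]],
              list(list(features = f, provenance = seg$provenance)))
        }
      }
    }

    tab_full <- coil_freq_tables(train_records, negatives, pseudocount)
    aug_full <- augment_tables(tab_full)
    set.seed(seed)
    neg_examples <- lapply(names(negatives), function(id) {
      win <- sample_negative_window(negatives[[id]], id = id)
      list(features = compute_features_aug(win$residues, win$register,
                                           aug_full, scale),
           provenance = id)
    })

    examples <- assemble_precomputed(pos_segments$DIMER, pos_segments$TRIMER,
                                     neg_examples, class_totals)
    fit <- apply_offset(fit_multinomial(examples, ridge = ridge), offset)

    fold_inputs[[fam]] <- list(
      table_families = train_fams,
      table_records = vapply(train_records,
                             function(r) paste0(r$family, "/", r$name), ""),
      nested_table_records = nested_table_records,
      regression_provenance = examples$provenance)

    for (rec in families[[fam]]) {
      pot <- build_potentials(rec$sequence, fit, tab_full, scale, space)
      rows <- posterior_oligomer_probs(forward_backward(pot),
                                       rec$sequence, space)
      for (a in rec$annotations) {
        stat <- tryCatch(
          dimer_trimer_statistic(rows, c(a$start, a$end)),
          error = function(e) NULL)
        results[[length(results) + 1L]] <- data.frame(
          family = fam, name = rec$name, truth = rec$oligomer,
          statistic = if (is.null(stat)) NA_real_ else stat$statistic,
          predicted = if (is.null(stat)) NA_character_ else
            classify_sequence(stat, threshold),
          coil_detected = detect_sequence(rows, cutoff, c(a$start, a$end)),
          mean_p_coil = mean(rows$p_coil[(a$start + 1L):a$end]),
          stringsAsFactors = FALSE)
      }
      attr(results[[length(results)]], "p_coil") <- rows$p_coil
      attr(results[[length(results)]], "coil_mask") <- {
        m <- rep(FALSE, nrow(rows))
        for (a in rec$annotations) m[(a$start + 1L):a$end] <- TRUE
        m
      }
    }
  }
  res <- do.call(rbind, lapply(results, function(r) r))
  pos_scores <- unlist(lapply(results, function(r) {
    p <- attr(r, "p_coil")
    if (is.null(p)) return(NULL)
    p[attr(r, "coil_mask")]
  }))
  confusion <- table(family = res$family, truth = res$truth,
                     predicted = factor(res$predicted,
                                        levels = c("DIMER", "TRIMER")))
  structure(list(results = res, confusion = confusion,
                 accuracy = mean(res$predicted == res$truth, na.rm = TRUE),
                 positive_residue_scores = pos_scores,
                 fold_inputs = fold_inputs,
                 threshold = threshold, cutoff = cutoff),
            class = "coil_mrf_cv")
}

# Assemble a training-set data frame from precomputed feature lists.
#' @keywords internal
assemble_precomputed <- function(dimers, trimers, negs, class_totals) {
  groups <- list(DIMER = dimers, TRIMER = trimers, NONCOIL = negs)
  totals <- c(DIMER = unname(class_totals[["dimer"]]),
              TRIMER = unname(class_totals[["trimer"]]),
              NONCOIL = unname(class_totals[["noncoil"]]))
  rows <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0) {
      stop("no training examples for class ", g, call. = FALSE)
    }
    w <- totals[[g]] / length(groups[[g]])
    for (e in groups[[g]]) {
      rows[[length(rows) + 1L]] <- c(as.list(e$features),
                                     list(label = g, weight = w,
                                          provenance = e$provenance))
    }
  }
  do.call(rbind,
          lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' @export
print.coil_mrf_cv <- function(x, ...) {
  cat("Leave-family-out cross-validation over",
      length(x$fold_inputs), "families\n")
  cat(sprintf("  sequence-level dimer/trimer accuracy: %.1f%% (%d coils)\n",
              100 * x$accuracy, nrow(x$results)))
  cat(sprintf("  coil detected (cutoff %.2f) in %d/%d annotated coils\n",
              x$cutoff, sum(x$results$coil_detected), nrow(x$results)))
  invisible(x)
}
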