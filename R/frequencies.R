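# Smoothed residue frequency tables tallied from annotated coils and
# negative (non-coil) sequences:
#   - per-class (dimer/trimer) per-heptad single-residue probabilities,
#   - per-class distance-1..7 pairwise joint probabilities, indexed by
#     the heptad of the downstream residue (the upstream heptad is
#     implied by the distance modulo 7 in a contiguous coil),
#   - heptad-free background single and pair tables from negatives.
# Additive smoothing keeps every entry strictly positive so the log-space
# potentials downstream stay finite.

#' @keywords internal
FREQ_TABLE_VERSION <- "1"

#' @keywords internal
empty_single_counts <- function() {
  array(0, dim = c(2, 7, 20),
        dimnames = list(class = COIL_CLASSES, heptad = HEPTADS,
                        residue = AMINO_ACIDS))
}

#' @keywords internal
empty_pair_counts <- function() {
  array(0, dim = c(2, 7, 7, 20, 20),
        dimnames = list(class = COIL_CLASSES, k = 1:7, heptad = HEPTADS,
                        up = AMINO_ACIDS, down = AMINO_ACIDS))
}

# Raw (unsmoothed) per-heptad single counts over annotated coil residues.
# X residues are skipped; they receive column-average probabilities at
# lookup instead of contributing counts.
#' @keywords internal
count_single <- function(records) {
  counts <- empty_single_counts()
  for (rec in records) {
    cls <- match(rec$oligomer, COIL_CLASSES)
    if (is.na(cls)) next
    for (seg in record_segments(rec)) {
      aa <- aa_index(seg$residues)
      h <- heptad_index(seg$register)
      ok <- !is.na(aa)
      if (!any(ok)) next
      li <- cls + 2L * ((h[ok] - 1L) + 7L * (aa[ok] - 1L))
      counts <- counts + array(tabulate(li, nbins = length(counts)),
                               dim = dim(counts), dimnames = dimnames(counts))
    }
  }
  counts
}

#' @keywords internal
count_pairs <- function(records) {
  counts <- empty_pair_counts()
  acc <- numeric(length(counts))
  for (rec in records) {
    cls <- match(rec$oligomer, COIL_CLASSES)
    if (is.na(cls)) next
    for (seg in record_segments(rec)) {
      aa <- aa_index(seg$residues)
      h <- heptad_index(seg$register)
      L <- length(aa)
      for (k in 1:7) {
        if (L <= k) next
        i <- (k + 1L):L
        up <- aa[i - k]
        down <- aa[i]
        hd <- h[i]
        ok <- !is.na(up) & !is.na(down)
        if (!any(ok)) next
        li <- cls + 2L * ((k - 1L) + 7L * ((hd[ok] - 1L) +
              7L * ((up[ok] - 1L) + 20L * (down[ok] - 1L))))
        acc <- acc + tabulate(li, nbins = length(acc))
      }
    }
  }
  counts + array(acc, dim = dim(counts), dimnames = dimnames(counts))
}

#' @keywords internal
smooth_normalize <- function(counts, pseudocount, margin) {
  sm <- counts + pseudocount
  sweep(sm, margin, apply(sm, margin, sum), "/")
}

#' Tally per-heptad single-residue probability tables
#'
#' Accumulates residue counts over the annotated coil residues of dimer
#' and trimer records, applies additive smoothing, and normalizes each
#' (class, heptad) column to a probability distribution.
#'
#' @param records List of `nps_record` objects with `DIMER`/`TRIMER`
#'   oligomer labels.
#' @param pseudocount Additive smoothing constant per cell (default 1).
#' @return 2 x 7 x 20 probability array (class x heptad x residue).
#' @export
tally_single <- function(records, pseudocount = 1) {
  counts <- count_single(records)
  for (cls in COIL_CLASSES) {
    if (sum(counts[cls, , ]) == 0) {
      stop("no annotated residues for class ", cls, call. = FALSE)
    }
  }
  smooth_normalize(counts, pseudocount, c(1, 2))
}

#' Tally distance-1..7 pairwise joint probability tables
#'
#' For every annotated coil and every distance k in 1..7, each ordered
#' residue pair (i-k, i) lying entirely inside the same coil contributes
#' one count, indexed by the heptad of the downstream residue.  Pairs
#' never straddle two disjoint coils.
#'
#' When `marginals` (a smoothed single-residue table, as from
#' [tally_single()]) is supplied, each slice is smoothed with a
#' Dirichlet prior centered on the product of the slice's marginals,
#' with total prior mass `400 * pseudocount` (the mass plain additive
#' smoothing would add).  Centering on independence leaves the
#' downstream log joint-over-marginals correlation statistic shrunk
#' toward zero where data are sparse instead of biased toward the
#' uniform joint.  Without `marginals`, plain additive smoothing is
#' used.
#'
#' @inheritParams tally_single
#' @param marginals Optional 2 x 7 x 20 smoothed single-residue table
#'   used as the independence center of the smoothing prior.
#' @return 2 x 7 x 7 x 20 x 20 probability array
#'   (class x distance x heptad x upstream x downstream); each
#'   (class, distance, heptad) slice sums to 1.
#' @export
tally_pairs <- function(records, pseudocount = 1, marginals = NULL) {
  counts <- count_pairs(records)
  for (cls in COIL_CLASSES) {
    if (sum(counts[cls, , , , ]) == 0) {
      stop("no annotated residue pairs for class ", cls, call. = FALSE)
    }
  }
  if (is.null(marginals)) {
    return(smooth_normalize(counts, pseudocount, c(1, 2, 3)))
  }
  out <- counts
  mass <- 400 * pseudocount
  for (c_ in 1:2) {
    for (k in 1:7) {
      for (h in 1:7) {
        hu <- ((h - 1L - k) %% 7L) + 1L
        center <- outer(marginals[c_, hu, ], marginals[c_, h, ])
        sl <- counts[c_, k, h, , ] + mass * center
        out[c_, k, h, , ] <- sl / sum(sl)
      }
    }
  }
  out
}

#' Tally heptad-free background tables from negative sequences
#'
#' @param negatives Character vector of residue strings (non-coil
#'   sequences).
#' @param pseudocount Additive smoothing constant per cell (default 1).
#' @param center_on_marginals If `TRUE`, smooth the pair table with a
#'   prior centered on the product of the background marginals (see
#'   [tally_pairs()]) instead of plain additive smoothing.
#' @return List with `single` (length-20 probability vector) and `pair`
#'   (7 x 20 x 20 array; each distance slice sums to 1).
#' @export
tally_background <- function(negatives, pseudocount = 1,
                             center_on_marginals = FALSE) {
  if (length(negatives) == 0) {
    stop("no negative sequences supplied", call. = FALSE)
  }
  single <- stats::setNames(numeric(20), AMINO_ACIDS)
  pair <- array(0, dim = c(7, 20, 20),
                dimnames = list(k = 1:7, up = AMINO_ACIDS, down = AMINO_ACIDS))
  pacc <- numeric(length(pair))
  for (s in negatives) {
    aa <- aa_index(strsplit(s, "")[[1]])
    tab <- tabulate(aa[!is.na(aa)], nbins = 20)
    single <- single + tab
    L <- length(aa)
    for (k in 1:7) {
      if (L <= k) next
      i <- (k + 1L):L
      up <- aa[i - k]
      down <- aa[i]
      ok <- !is.na(up) & !is.na(down)
      if (!any(ok)) next
      li <- k + 7L * ((up[ok] - 1L) + 20L * (down[ok] - 1L))
      pacc <- pacc + tabulate(li, nbins = length(pacc))
    }
  }
  pair <- pair + array(pacc, dim = dim(pair), dimnames = dimnames(pair))
  single <- single + pseudocount
  single <- single / sum(single)
  if (center_on_marginals) {
    mass <- 400 * pseudocount
    center <- outer(single, single)
    for (k in 1:7) {
      sl <- pair[k, , ] + mass * center
      pair[k, , ] <- sl / sum(sl)
    }
  } else {
    pair <- smooth_normalize(pair, pseudocount, 1)
  }
  list(single = single, pair = pair)
}

#' Build the full frequency-table set
#'
#' Combines [tally_single()], [tally_pairs()] and [tally_background()]
#' into the single object consumed by feature computation and inference.
#'
#' @param records List of annotated `nps_record` objects.
#' @param negatives Character vector of negative residue strings.
#' @param pseudocount Additive smoothing constant per cell (default 1).
#' @return Object of class `coil_freq_tables` with components `single`,
#'   `pair`, `single_bg`, `pair_bg`, `pseudocount`, `version`.
#' @export
coil_freq_tables <- function(records, negatives, pseudocount = 1) {
  bg <- tally_background(negatives, pseudocount, center_on_marginals = TRUE)
  single <- tally_single(records, pseudocount)
  structure(list(
    single = single,
    pair = tally_pairs(records, pseudocount, marginals = single),
    single_bg = bg$single,
    pair_bg = bg$pair,
    pseudocount = pseudocount,
    version = FREQ_TABLE_VERSION
  ), class = "coil_freq_tables")
}

#' @export
print.coil_freq_tables <- function(x, ...) {
  cat("Coiled-coil frequency tables (version ", x$version,
      ", pseudocount ", x$pseudocount, ")\n", sep = "")
  cat("  single: 2 classes x 7 heptads x 20 residues\n")
  cat("  pair:   2 classes x 7 distances x 7 heptads x 20 x 20\n")
  invisible(x)
}

# -- X-aware lookup helpers --------------------------------------------------

# Augment a heptad x residue matrix with a 21st column holding the row
# mean, so index 21 (the X code) looks up the column-average probability.
#' @keywords internal
augment_single <- function(m) {
  cbind(m, rowMeans(m))
}

#' @keywords internal
augment_bg <- function(v) {
  c(v, mean(v))
}

# Augment a 20 x 20 joint slice to 21 x 21 with marginal means for X.
#' @keywords internal
augment_pair_slice <- function(s) {
  out <- matrix(0, 21, 21)
  out[1:20, 1:20] <- s
  out[21, 1:20] <- colMeans(s)
  out[1:20, 21] <- rowMeans(s)
  out[21, 21] <- mean(s)
  out
}

# Residue indices with X mapped to the augmented slot 21.
#' @keywords internal
aa_index_aug <- function(residues) {
  i <- aa_index(residues)
  i[is.na(i)] <- 21L
  i
}

# -- serialization -----------------------------------------------------------

#' Write frequency tables to a versioned JSON file
#'
#' @param tables A `coil_freq_tables` object.
#' @param path Output path.
#' @export
write_freq_tables <- function(tables, path) {
  payload <- list(
    format = "coilmrf-freq-tables",
    version = tables$version,
    pseudocount = tables$pseudocount,
    single = list(dim = dim(tables$single), data = as.vector(tables$single)),
    pair = list(dim = dim(tables$pair), data = as.vector(tables$pair)),
    single_bg = as.list(tables$single_bg),
    pair_bg = list(dim = dim(tables$pair_bg), data = as.vector(tables$pair_bg))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read frequency tables written by [write_freq_tables()]
#'
#' @param path Input path.
#' @return A `coil_freq_tables` object.
#' @export
read_freq_tables <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "coilmrf-freq-tables")) {
    stop("not a coilmrf frequency-table file: ", path, call. = FALSE)
  }
  single <- array(p$single$data, dim = p$single$dim,
                  dimnames = dimnames(empty_single_counts()))
  pair <- array(p$pair$data, dim = p$pair$dim,
                dimnames = dimnames(empty_pair_counts()))
  pair_bg <- array(p$pair_bg$data, dim = p$pair_bg$dim,
                   dimnames = list(k = 1:7, up = AMINO_ACIDS,
                                   down = AMINO_ACIDS))
  structure(list(
    single = single, pair = pair,
    single_bg = stats::setNames(unlist(p$single_bg), AMINO_ACIDS),
    pair_bg = pair_bg,
    pseudocount = p$pseudocount, version = p$version
  ), class = "coil_freq_tables")
}
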