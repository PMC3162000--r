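# Hidden-state space of the chain MRF.
#
# One non-coil state plus, for each coil class (dimer, trimer), 63 states
# indexed by heptad letter a-g and location 1-9.  Locations 1-7 are the
# first seven residues of a coil, 8 is any middle residue, 9 is the last;
# the location labels enforce the minimum coil length of 9 and gate which
# pairwise-correlation distances lie inside the coil.

#' Build the hidden-state space
#'
#' Constructs the 127-state space of the chain MRF: one non-coil state,
#' then 63 dimer and 63 trimer states ordered heptad-major
#' (`a1 ... a9, b1, ..., g9`).  The transition indicator allows, for coil
#' states of a fixed class: heptad advancing cyclically by one while the
#' location goes `1,2,...,7,8` (possibly repeating 8) and ends at 9; a coil
#' may start (from non-coil) at any heptad but only at location 1, and may
#' only return to non-coil from location 9.  Consecutive coils are
#' therefore separated by at least one non-coil residue, and every coil
#' spans at least 9 residues.  Sequences must start in non-coil or a
#' location-1 state and end in non-coil or a location-9 state, so
#' truncated coils at sequence edges are not representable.
#'
#' @return An object of class `coil_state_space` with components
#'   `states` (data frame of `label`, `oligomer`, `heptad`, `location`),
#'   `transition` (127 x 127 0/1 matrix), `initial` and `final`
#'   (logical masks), and index helpers used internally.
#' @export
#' @examples
#' sp <- build_state_space()
#' nrow(sp$states)              # 127
#' sum(sp$states$oligomer == "DIMER")  # 63
build_state_space <- function() {
  labels <- "NC"
  olig <- "NONCOIL"
  hept <- NA_character_
  loc <- NA_integer_
  for (cls in COIL_CLASSES) {
    tag <- if (cls == "DIMER") "D" else "T"
    for (h in HEPTADS) {
      for (p in 1:9) {
        labels <- c(labels, paste0(tag, ".", h, p))
        olig <- c(olig, cls)
        hept <- c(hept, h)
        loc <- c(loc, p)
      }
    }
  }
  states <- data.frame(label = labels, oligomer = olig, heptad = hept,
                       location = loc, stringsAsFactors = FALSE)
  n <- nrow(states)
  stopifnot(n == 127L)

  trans <- matrix(0, n, n, dimnames = list(labels, labels))
  nc <- 1L
  trans[nc, nc] <- 1
  for (s in 2:n) {
    h <- states$heptad[s]
    p <- states$location[s]
    cls <- states$oligomer[s]
    if (p == 1L) trans[nc, s] <- 1
    if (p == 9L) trans[s, nc] <- 1
    nh <- heptad_shift(h, 1L)
    succ_loc <- if (p <= 7L) p + 1L else if (p == 8L) c(8L, 9L) else integer(0)
    for (q in succ_loc) {
      t_idx <- which(states$oligomer == cls & states$heptad == nh &
                       states$location == q)
      trans[s, t_idx] <- 1
    }
  }

  structure(list(
    states = states,
    transition = trans,
    initial = states$oligomer == "NONCOIL" | states$location %in% 1L,
    final = states$oligomer == "NONCOIL" | states$location %in% 9L
  ), class = "coil_state_space")
}

#' @export
print.coil_state_space <- function(x, ...) {
  cat("Coiled-coil MRF state space:", nrow(x$states), "states",
      "(1 non-coil + 63 dimer + 63 trimer),",
      sum(x$transition), "allowed transitions\n")
  invisible(x)
}

#' @keywords internal
state_index <- function(space, label) {
  i <- match(label, space$states$label)
  if (anyNA(i)) {
    stop("unknown state label(s): ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Test whether a state transition is allowed
#'
#' @param space A `coil_state_space`.
#' @param from,to State labels (e.g. `"NC"`, `"D.a1"`, `"T.g9"`).
#' @return `TRUE` iff the transition indicator is 1.
#' @export
#' @examples
#' sp <- build_state_space()
#' is_valid_transition(sp, "D.a1", "D.b2")  # TRUE
#' is_valid_transition(sp, "D.c4", "T.d5")  # FALSE: class cannot switch
is_valid_transition <- function(space, from, to) {
  space$transition[state_index(space, from), state_index(space, to)] == 1
}

#' Enumerate all valid state paths of a given length
#'
#' Exhaustive depth-first enumeration over the transition graph,
#' respecting the initial- and final-state restrictions.  Used as a
#' brute-force oracle for the forward-backward recursions; guarded to
#' short lengths because the path count grows with sequence length.
#'
#' @param space A `coil_state_space`.
#' @param length Path length (number of residues), at most 14.
#' @return Integer matrix, one row per valid path, entries are state
#'   indices into `space$states`.
#' @export
#' @examples
#' sp <- build_state_space()
#' nrow(enumerate_valid_paths(sp, 1))  # 1: the all-non-coil path
enumerate_valid_paths <- function(space, length) {
  if (length < 1L || length > 14L) {
    stop("path enumeration supports lengths 1..14 (got ", length, ")",
         call. = FALSE)
  }
  succ <- apply(space$transition, 1L, function(r) which(r == 1), simplify = FALSE)
  final <- which(space$final)
  paths <- list()
  walk <- function(prefix) {
    d <- length(prefix)
    if (d == length) {
      if (prefix[d] %in% final) paths[[length(paths) + 1L]] <<- prefix
      return(invisible())
    }
    for (s in succ[[prefix[d]]]) walk(c(prefix, s))
  }
  for (s in which(space$initial)) walk(s)
  do.call(rbind, paths)
}

# Lengths of contiguous coil runs (non-NC stretches) in a path of indices.
#' @keywords internal
coil_run_lengths <- function(space, path) {
  r <- rle(space$states$oligomer[path] != "NONCOIL")
  r$lengths[r$values]
}

# The forced state path of an annotated coil of length L (>= 9) in a given
# class, starting at a given register letter: locations 1..7, 8 repeated,
# then 9; heptads advance cyclically.
#' @keywords internal
forced_coil_path <- function(space, class, start_heptad, len) {
  stopifnot(len >= 9L)
  locs <- c(1:7, rep(8L, len - 7L))[seq_len(len)]
  locs[len] <- 9L
  hepts <- heptad_shift(start_heptad, seq_len(len) - 1L)
  tag <- if (class == "DIMER") "D" else "T"
  state_index(space, paste0(tag, ".", hepts, locs))
}
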