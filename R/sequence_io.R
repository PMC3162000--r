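# Sequence and annotation I/O: FASTA, the 4-line annotated family record
# format, and the per-residue prediction table.

# -- residue normalization ---------------------------------------------------

#' Normalize a residue string to the canonical alphabet
#'
#' Uppercases and maps ambiguity/non-standard codes (`B`, `Z`, `J`, `U`,
#' `O`, `*`) to `X`.  Any remaining character outside the 20 standard
#' residues plus `X` is an error.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of normalized residue strings.
#' @export
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr("BZJUO", "XXXXX", x)
  x <- gsub("*", "X", x, fixed = TRUE)
  bad <- setdiff(unique(unlist(strsplit(x, ""))), c(AMINO_ACIDS, "X"))
  if (length(bad) > 0) {
    stop("illegal residue character(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  x
}

# -- FASTA -------------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a named
#' character vector of normalized residue strings.  Sequence ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are sequence ids.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    withCallingHandlers(
      Biostrings::readAAStringSet(path),
      # Biostrings silently drops invalid codes; treat them as an error
      warning = function(w) {
        if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
          stop("illegal residue character(s) in ", path, call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(as.character(set)))) {
    stop("empty sequence(s) in ", path, call. = FALSE)
  }
  seqs <- normalize_residues(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- register validation -----------------------------------------------------

#' Validate heptad-register continuity
#'
#' A register string is continuous when its letters advance cyclically
#' `a -> b -> ... -> g -> a` with no skips.
#'
#' @param register A string over `a`-`g`.
#' @return `TRUE` invisibly; stops on a discontinuity.
#' @export
validate_register <- function(register) {
  h <- strsplit(register, "")[[1]]
  idx <- heptad_index(h)
  if (anyNA(idx)) {
    stop("register contains non-heptad character(s): ",
         paste(unique(h[is.na(idx)]), collapse = " "), call. = FALSE)
  }
  if (length(idx) > 1) {
    step <- diff(idx) %% 7L
    if (any(step != 1L)) {
      at <- which(step != 1L)[1]
      stop("register discontinuity at offset ", at, ": ",
           h[at], " -> ", h[at + 1L], call. = FALSE)
    }
  }
  invisible(TRUE)
}

# -- 4-line annotated family records -----------------------------------------

# Controlled vocabulary for the structural descriptor line; configurable
# because the format prints only one example descriptor.
#' @export
default_descriptor_vocabulary <- function() {
  c("long", "short", "parallel", "antiparallel", "homo", "hetero",
    "dimer", "trimer", "tetramer", "pc2", "socket", "new", "synthetic")
}

#' @keywords internal
oligomer_from_descriptors <- function(tokens) {
  hit <- intersect(c("dimer", "trimer", "tetramer"), tokens)
  if (length(hit) != 1) {
    stop("descriptor line must contain exactly one of dimer/trimer/tetramer",
         call. = FALSE)
  }
  toupper(hit)
}

# Extract coil annotations by aligning the register line to the sequence
# line.  Register positions are letters a-g; anything else (spaces, '-',
# '.') is unannotated.  Supports multiple disjoint coils per record.
#' @keywords internal
annotations_from_register_line <- function(sequence, register_line) {
  n <- nchar(sequence)
  reg <- strsplit(register_line, "")[[1]]
  if (length(reg) > n) {
    stop("register line longer than sequence (", length(reg), " > ", n, ")",
         call. = FALSE)
  }
  reg <- c(reg, rep(" ", n - length(reg)))
  is_reg <- reg %in% HEPTADS
  if (any(!is_reg & !reg %in% c(" ", "-", "."))) {
    stop("register line contains illegal character(s): ",
         paste(unique(reg[!is_reg & !reg %in% c(" ", "-", ".")]),
               collapse = " "), call. = FALSE)
  }
  out <- list()
  r <- rle(is_reg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    register <- paste(reg[starts[j]:ends[j]], collapse = "")
    validate_register(register)
    # 0-based half-open interval
    out[[length(out) + 1L]] <- list(start = starts[j] - 1L, end = ends[j],
                                    register = register)
  }
  out
}

#' @keywords internal
new_nps_record <- function(name, descriptors, sequence, annotations,
                           oligomer, family) {
  structure(list(name = name, descriptors = descriptors, sequence = sequence,
                 annotations = annotations, oligomer = oligomer,
                 family = family),
            class = "nps_record")
}

#' @export
print.nps_record <- function(x, ...) {
  cat("<", x$oligomer, " record '", x$name, "' (family ", x$family, "): ",
      nchar(x$sequence), " aa, ", length(x$annotations), " coil(s)>\n",
      sep = "")
  invisible(x)
}

#' Parse a 4-line annotated coiled-coil family file
#'
#' Each record spans four lines: a name line, a structural descriptor
#' line drawn from a controlled vocabulary (e.g. `long parallel homo
#' dimer`), the amino-acid sequence, and a heptad-register line aligned
#' under the sequence (letters `a`-`g` over annotated coil residues,
#' blanks elsewhere).  Register continuity is validated; the
#' oligomerization state is parsed from the descriptor line.
#'
#' @param path Path to a family file.
#' @param family_name Family label attached to every record; defaults to
#'   the file name without extension.
#' @param strict If `TRUE` (default) malformed records are errors; if
#'   `FALSE` they are skipped with a warning.
#' @param vocabulary Allowed descriptor tokens.
#' @return List of `nps_record` objects.
#' @export
parse_nps_family_file <- function(path, family_name = NULL, strict = TRUE,
                                  vocabulary = default_descriptor_vocabulary()) {
  if (is.null(family_name)) {
    family_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    stop("family file '", path, "' has ", length(lines),
         " lines; expected a multiple of 4", call. = FALSE)
  }
  records <- list()
  for (i in seq(1, length(lines), by = 4)) {
    rec <- tryCatch({
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][1]
      tokens <- strsplit(trimws(tolower(lines[i + 1])), "\\s+")[[1]]
      unknown <- setdiff(tokens, vocabulary)
      if (length(unknown) > 0) {
        stop("unknown descriptor token(s): ",
             paste(unknown, collapse = " "), call. = FALSE)
      }
      sequence <- normalize_residues(trimws(lines[i + 2]))
      anns <- annotations_from_register_line(sequence, lines[i + 3])
      new_nps_record(name, tokens, sequence, anns,
                     oligomer_from_descriptors(tokens), family_name)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) {
        stop("record ", (i - 1) %/% 4 + 1, " of '", path, "': ",
             conditionMessage(rec), call. = FALSE)
      }
      warning("skipping record ", (i - 1) %/% 4 + 1, " of '", path, "': ",
              conditionMessage(rec), call. = FALSE)
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write records to a 4-line annotated family file
#'
#' @param records List of `nps_record` objects.
#' @param path Output path.
#' @export
write_nps_family_file <- function(records, path) {
  lines <- character(0)
  for (rec in records) {
    reg <- rep(" ", nchar(rec$sequence))
    for (a in rec$annotations) {
      reg[(a$start + 1L):a$end] <- strsplit(a$register, "")[[1]]
    }
    lines <- c(lines,
               rec$name,
               paste(rec$descriptors, collapse = " "),
               rec$sequence,
               sub("\\s+$", "", paste(reg, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}

# Annotated coil segments (residues + register) of a record, as lists
# with fields residues, register (character vectors) and provenance.
#' @keywords internal
record_segments <- function(rec) {
  lapply(rec$annotations, function(a) {
    list(residues = strsplit(substr(rec$sequence, a$start + 1L, a$end), "")[[1]],
         register = strsplit(a$register, "")[[1]],
         oligomer = rec$oligomer,
         provenance = paste0(rec$family, "/", rec$name))
  })
}

# -- prediction tables -------------------------------------------------------

#' Write a per-residue prediction table
#'
#' Tab-separated columns `position`, `residue`, `best_register`,
#' `p_dimer`, `p_trimer`, `p_coil`, probabilities printed with six
#' decimal places.  Positions are 1-based in the printed output.
#'
#' @param rows Data frame of prediction rows (as returned by
#'   [predict.coil_mrf()]).
#' @param path Output path or connection.
#' @export
write_predictions <- function(rows, path) {
  stopifnot(nrow(rows) > 0)
  lines <- c(paste(c("position", "residue", "best_register",
                     "p_dimer", "p_trimer", "p_coil"), collapse = "\t"),
             sprintf("%d\t%s\t%s\t%.6f\t%.6f\t%.6f",
                     rows$position, rows$residue, rows$best_register,
                     rows$p_dimer, rows$p_trimer, rows$p_coil))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-residue prediction table written by [write_predictions()]
#'
#' @param path Input path.
#' @return Data frame of prediction rows.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "numeric", "numeric", "numeric"))
}
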