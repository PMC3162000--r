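# Shared fixtures, built in code.  Expensive objects are memoized per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but non-degenerate synthetic dataset (3 families per class).
small_dataset <- function() {
  memo("small_dataset", function() {
    sample_dataset(synthetic_spec(n_families = 3, seqs_per_family = 6,
                                  n_negatives = 40, seed = 101))
  })
}

# Frequency tables tallied from the small dataset.
small_tables <- function() {
  memo("small_tables", function() {
    ds <- small_dataset()
    coil_freq_tables(do.call(c, unname(ds$families)), ds$negatives, 1)
  })
}

# Uniform tables: every single probability 1/20, every joint 1/400, so
# log-probability features are L*log(1/20) and correlation features
# vanish identically.
uniform_tables <- function() {
  aa <- coilmrf:::AMINO_ACIDS
  single <- array(1 / 20, dim = c(2, 7, 20),
                  dimnames = list(class = c("DIMER", "TRIMER"),
                                  heptad = letters[1:7], residue = aa))
  pair <- array(1 / 400, dim = c(2, 7, 7, 20, 20))
  pair_bg <- array(1 / 400, dim = c(7, 20, 20))
  structure(list(single = single, pair = pair,
                 single_bg = stats::setNames(rep(1 / 20, 20), aa),
                 pair_bg = pair_bg, pseudocount = 0, version = "1"),
            class = "coil_freq_tables")
}

# A random small regression model (coefficients drawn from the current
# RNG state).
random_model <- function(sd = 0.5) {
  fn <- coilmrf:::FEATURE_NAMES
  structure(list(alpha = stats::setNames(stats::rnorm(8, 0, sd), fn),
                 beta = stats::setNames(stats::rnorm(8, 0, sd), fn),
                 c_dimer = stats::rnorm(1, 1, 2),
                 c_trimer = stats::rnorm(1, 1, 2),
                 offset = 0),
            class = "coil_mrf_model")
}

# A single annotated record built by hand.
make_record <- function(sequence, reg_start, reg_len, start_heptad = "a",
                        oligomer = "DIMER", name = "rec1", family = "fam1") {
  register <- paste(coilmrf:::heptad_shift(start_heptad,
                                           seq_len(reg_len) - 1L),
                    collapse = "")
  coilmrf:::new_nps_record(
    name = name,
    descriptors = c("synthetic", "parallel", "homo", tolower(oligomer)),
    sequence = sequence,
    annotations = list(list(start = reg_start, end = reg_start + reg_len,
                            register = register)),
    oligomer = oligomer, family = family)
}

random_coil_segment <- function(len, start_heptad = sample(letters[1:7], 1)) {
  list(residues = sample(coilmrf:::AMINO_ACIDS, len, replace = TRUE),
       register = coilmrf:::heptad_shift(start_heptad, seq_len(len) - 1L))
}
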