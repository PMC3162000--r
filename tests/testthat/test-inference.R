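test_that("posteriors normalize and partition into the three classes", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(41)
  for (t in 1:5) {
    n <- sample(c(3, 15, 60), 1)
    s <- paste(sample(coilmrf:::AMINO_ACIDS, n, TRUE), collapse = "")
    pot <- build_potentials(s, random_model(), tab, space = sp)
    fb <- forward_backward(pot)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
    rows <- posterior_oligomer_probs(fb, s, sp)
    p_nc <- fb$gamma[, 1]
    expect_lt(max(abs(rows$p_dimer + rows$p_trimer + p_nc - 1)), 1e-9)
    expect_equal(rows$p_coil, rows$p_dimer + rows$p_trimer)
  }
})

test_that("sequences shorter than 9 residues have zero coil posterior", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(42)
  m <- random_model()
  m$c_dimer <- 50  # even absurdly coil-favoring potentials cannot help
  for (n in 1:8) {
    s <- paste(sample(coilmrf:::AMINO_ACIDS, n, TRUE), collapse = "")
    rows <- posterior_oligomer_probs(
      forward_backward(build_potentials(s, m, tab, space = sp)), s, sp)
    expect_equal(max(rows$p_coil), 0)
  }
})

test_that("forward-backward equals the brute-force path-sum oracle", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(43)
  for (t in 1:50) {
    n <- sample(1:12, 1)
    s <- paste(sample(c(coilmrf:::AMINO_ACIDS, "X"), n, TRUE), collapse = "")
    pot <- build_potentials(s, random_model(), tab, space = sp)
    fb <- forward_backward(pot)
    bf <- brute_force_posterior(pot)
    expect_lt(max(abs(fb$gamma - bf$gamma)), 1e-9)
    expect_lt(abs(fb$logZ - bf$logZ), 1e-9)
  }
})

test_that("forward and backward passes agree on the normalizer", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(44)
  for (n in c(1, 9, 40, 150)) {
    s <- paste(sample(coilmrf:::AMINO_ACIDS, n, TRUE), collapse = "")
    fb <- forward_backward(build_potentials(s, random_model(), tab,
                                            space = sp))
    expect_lt(abs(fb$logZ - fb$logZ_backward), 1e-9)
  }
})

test_that("posteriors are gauge-invariant under per-position potential shifts", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(45)
  s <- paste(sample(coilmrf:::AMINO_ACIDS, 25, TRUE), collapse = "")
  pot <- build_potentials(s, random_model(), tab, space = sp)
  fb <- forward_backward(pot)
  shifted <- pot
  shifted$log_psi1[10, ] <- shifted$log_psi1[10, ] + 3.7
  fb2 <- forward_backward(shifted)
  expect_lt(max(abs(fb2$gamma - fb$gamma)), 1e-9)
  expect_equal(fb2$logZ, fb$logZ + 3.7, tolerance = 1e-9)
})

test_that("raising the dimer constant never lowers any dimer posterior", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(46)
  s <- paste(sample(coilmrf:::AMINO_ACIDS, 30, TRUE), collapse = "")
  m <- random_model()
  prev <- NULL
  for (cd in c(-5, 0, 5, 10)) {
    m$c_dimer <- cd
    rows <- posterior_oligomer_probs(
      forward_backward(build_potentials(s, m, tab, space = sp)), s, sp)
    if (!is.null(prev)) expect_true(all(rows$p_dimer >= prev - 1e-12))
    prev <- rows$p_dimer
  }
})

test_that("potentials at a position depend only on residues i-7..i", {
  tab <- small_tables()
  sp <- build_state_space()
  set.seed(47)
  res <- sample(coilmrf:::AMINO_ACIDS, 30, TRUE)
  m <- random_model()
  p1 <- build_potentials(res, m, tab, space = sp)
  res2 <- res
  res2[20:30] <- sample(coilmrf:::AMINO_ACIDS, 11, TRUE)
  p2 <- build_potentials(res2, m, tab, space = sp)
  expect_equal(p2$log_psi1[1:19, ], p1$log_psi1[1:19, ])
})

test_that("potentials apply the class constant exactly once per coil", {
  # constants only: each coil path scores (length-independent) c per coil
  tab <- small_tables()
  sp <- build_state_space()
  fn <- coilmrf:::FEATURE_NAMES
  m <- structure(list(alpha = stats::setNames(numeric(8), fn),
                      beta = stats::setNames(numeric(8), fn),
                      c_dimer = 2.5, c_trimer = -1.25, offset = 0),
                 class = "coil_mrf_model")
  s <- paste(rep("A", 12), collapse = "")
  pot <- build_potentials(s, m, tab, space = sp)
  paths <- enumerate_valid_paths(sp, 12)
  for (j in seq_len(nrow(paths))) {
    path <- paths[j, ]
    score <- sum(pot$log_psi1[cbind(1:12, path)])
    olig <- sp$states$oligomer[path]
    n_coils_d <- sum(olig == "DIMER" & sp$states$location[path] == 1L)
    n_coils_t <- sum(olig == "TRIMER" & sp$states$location[path] == 1L)
    expect_equal(score, 2.5 * n_coils_d - 1.25 * n_coils_t, tolerance = 1e-12)
  }
})

test_that("zero potentials reduce posteriors to path counting", {
  tab <- small_tables()
  sp <- build_state_space()
  fn <- coilmrf:::FEATURE_NAMES
  m <- structure(list(alpha = stats::setNames(numeric(8), fn),
                      beta = stats::setNames(numeric(8), fn),
                      c_dimer = 0, c_trimer = 0, offset = 0),
                 class = "coil_mrf_model")
  s <- paste(rep("L", 10), collapse = "")
  pot <- build_potentials(s, m, tab, space = sp)
  expect_true(all(pot$log_psi1 == 0))
  fb <- forward_backward(pot)
  paths <- enumerate_valid_paths(sp, 10)
  # uniform path weights: posterior = fraction of paths through the state
  frac_coil <- mean(sp$states$oligomer[paths[, 5]] != "NONCOIL")
  rows <- posterior_oligomer_probs(fb, s, sp)
  expect_equal(rows$p_coil[5], frac_coil, tolerance = 1e-9)
})

test_that("the arg-max register recovers the generating register", {
  # strong-dimer fixture: exact class compositions (no family jitter)
  # and long coils, so the register phase is identifiable
  ds <- sample_dataset(synthetic_spec(n_families = 2, seqs_per_family = 30,
                                      coil_len = c(35, 42),
                                      n_negatives = 60,
                                      family_jitter = 0, seed = 17))
  fit <- coil_mrf(ds$families, ds$negatives, seed = 3)
  hits <- 0L
  total <- 0L
  for (rec in ds$families[["dimer_fam01"]][1:10]) {
    rows <- predict(fit, stats::setNames(rec$sequence, rec$name))[[1]]
    a <- rec$annotations[[1]]
    idx <- (a$start + 1L):a$end
    true_reg <- strsplit(a$register, "")[[1]]
    called <- rows$best_register[idx]
    scored <- called != "-"
    hits <- hits + sum(called[scored] == true_reg[scored])
    total <- total + sum(scored)
  }
  expect_gt(total, 50)
  expect_gte(hits / total, 0.95)
})
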