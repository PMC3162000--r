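test_that("negative window lengths are uniform on 0..249", {
  set.seed(5)
  draws <- coilmrf:::rwindow_length(10000)
  expect_true(all(draws >= 0 & draws <= 249))
  expect_true(all(0:249 %in% draws))
  p <- stats::chisq.test(tabulate(draws + 1L, nbins = 250))$p.value
  expect_gt(p, 0.01)
})

test_that("negative windows truncate to the sequence and carry a continuous register", {
  set.seed(6)
  seq30 <- paste(sample(coilmrf:::AMINO_ACIDS, 30, TRUE), collapse = "")
  lens <- integer(200)
  for (i in 1:200) {
    w <- sample_negative_window(seq30)
    lens[i] <- length(w$residues)
    expect_identical(w$residues,
                     strsplit(substr(seq30, 1, lens[i]), "")[[1]])
    expect_true(validate_register(paste(w$register, collapse = "")))
    expect_gte(lens[i], 9L)
  }
  # drawn lengths above 30 collapse to the whole sequence
  expect_true(any(lens == 30L))
  expect_true(all(lens <= 30L))
  expect_error(sample_negative_window("MKQL"), "shorter than 9")
})

test_that("class weights are total/count with totals 1, 1, 1000", {
  tab <- uniform_tables()
  seg <- function(n) replicate(n, random_coil_segment(12), simplify = FALSE)
  set.seed(8)
  ex <- assemble_training_set(seg(4), seg(2), seg(10), tab)
  w <- tapply(ex$weight, ex$label, unique)
  expect_equal(unname(w[["DIMER"]]), 0.25)
  expect_equal(unname(w[["TRIMER"]]), 0.5)
  expect_equal(unname(w[["NONCOIL"]]), 100)
  sums <- tapply(ex$weight, ex$label, sum)
  expect_identical(unname(sums[["DIMER"]]), 1)
  expect_identical(unname(sums[["TRIMER"]]), 1)
  expect_identical(unname(sums[["NONCOIL"]]), 1000)
  expect_error(assemble_training_set(seg(2), list(), seg(3), tab),
               "TRIMER")
})

intercept_only_examples <- function() {
  f <- matrix(0, 16, 8, dimnames = list(NULL, coilmrf:::FEATURE_NAMES))
  ex <- as.data.frame(f)
  ex$label <- rep(c("DIMER", "TRIMER", "NONCOIL"), c(4, 4, 8))
  ex$weight <- c(rep(1 / 4, 8), rep(1000 / 8, 8))
  ex$provenance <- ""
  ex
}

test_that("intercept-only fit recovers the weighted class priors", {
  fit <- fit_multinomial(intercept_only_examples())
  probs <- exp(c(0, fit$c_dimer, fit$c_trimer))
  probs <- probs / sum(probs)
  expect_equal(probs[2], 1 / 1002, tolerance = 1e-6)
  expect_equal(probs[3], 1 / 1002, tolerance = 1e-6)
  expect_equal(probs[1], 1000 / 1002, tolerance = 1e-6)
  # 16 feature coefficients plus 2 constants
  expect_length(c(fit$alpha, fit$beta), 16L)
  expect_length(c(fit$c_dimer, fit$c_trimer), 2L)
})

noisy_examples <- function(n_per_class = 40, sep = 1.5, noise = 2) {
  set.seed(13)
  f <- matrix(rnorm(3 * n_per_class * 8, 0, noise), ncol = 8,
              dimnames = list(NULL, coilmrf:::FEATURE_NAMES))
  lab <- rep(c("DIMER", "TRIMER", "NONCOIL"), each = n_per_class)
  f[lab == "DIMER", 1] <- f[lab == "DIMER", 1] + sep
  f[lab == "TRIMER", 2] <- f[lab == "TRIMER", 2] + sep
  ex <- as.data.frame(f)
  ex$label <- lab
  ex$weight <- ifelse(lab == "NONCOIL", 1000 / n_per_class, 1 / n_per_class)
  ex$provenance <- ""
  ex
}

test_that("penalized log-likelihood is non-decreasing over Newton iterations", {
  fit <- fit_multinomial(noisy_examples())
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
})

test_that("fit is invariant to weight rescaling and example duplication", {
  ex <- noisy_examples()
  fit <- fit_multinomial(ex, ridge = 0)
  # common rescaling of all weights leaves the MLE unchanged
  ex2 <- ex
  ex2$weight <- ex$weight * 7.3
  fit2 <- fit_multinomial(ex2, ridge = 0)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-4)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-4)
  expect_equal(fit2$c_dimer, fit$c_dimer, tolerance = 1e-4)
  # splitting one example into two half-weight copies changes nothing
  ex3 <- rbind(ex, ex[1, ])
  ex3$weight[c(1, nrow(ex3))] <- ex$weight[1] / 2
  fit3 <- fit_multinomial(ex3, ridge = 0)
  expect_equal(fit3$alpha, fit$alpha, tolerance = 1e-5)
  expect_equal(fit3$c_trimer, fit$c_trimer, tolerance = 1e-5)
})

test_that("separable features are fit to training-set consistency", {
  ex <- noisy_examples(sep = 30, noise = 0.5)
  fit <- fit_multinomial(ex)
  X <- as.matrix(ex[, coilmrf:::FEATURE_NAMES])
  S <- cbind(NONCOIL = 0,
             DIMER = drop(X %*% fit$alpha) + fit$c_dimer,
             TRIMER = drop(X %*% fit$beta) + fit$c_trimer)
  # within each class, its own score exceeds the competing coil class
  expect_true(all(S[ex$label == "DIMER", "DIMER"] >
                    S[ex$label == "DIMER", "TRIMER"]))
  expect_true(all(S[ex$label == "TRIMER", "TRIMER"] >
                    S[ex$label == "TRIMER", "DIMER"]))
})

test_that("fitted probabilities agree with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  ex <- noisy_examples()
  fit <- fit_multinomial(ex, ridge = 0, tol = 1e-8)
  X <- as.matrix(ex[, coilmrf:::FEATURE_NAMES])
  S <- cbind(0, drop(X %*% fit$alpha) + fit$c_dimer,
             drop(X %*% fit$beta) + fit$c_trimer)
  P <- exp(S - apply(S, 1, coilmrf:::logsumexp))
  dat <- ex
  dat$label <- factor(dat$label, levels = c("NONCOIL", "DIMER", "TRIMER"))
  ref <- nnet::multinom(label ~ lp_dimer + lp_trimer + lp_bg + corr_dimer +
                          corr_trimer + corr_bg + hyd_a + hyd_d,
                        data = dat, weights = dat$weight, trace = FALSE,
                        maxit = 500, reltol = 1e-14)
  Pref <- stats::fitted(ref)
  expect_lt(max(abs(P - Pref[, c("NONCOIL", "DIMER", "TRIMER")])), 1e-3)
})

test_that("the offset shifts both constants and only the constants", {
  fit <- fit_multinomial(intercept_only_examples())
  fit$c_dimer <- 5
  fit$c_trimer <- 3
  off <- apply_offset(fit, 20)
  expect_equal(off$c_dimer, -15)
  expect_equal(off$c_trimer, -17)
  expect_equal(off$alpha, fit$alpha)
  expect_equal(off$offset, 20)
  expect_equal(apply_offset(fit, 0)$c_dimer, 5)
})

test_that("increasing the offset never raises any coil posterior", {
  # on sequences shorter than 19 residues at most one coil segment fits
  # (9 + separator + 9 will not), so every path carries the constant 0
  # or 1 times and per-residue monotonicity in the offset is exact
  ds <- small_dataset()
  fit0 <- coil_mrf(ds$families, ds$negatives, offset = 0, seed = 3)
  set.seed(61)
  for (t in 1:3) {
    seqres <- paste(sample(coilmrf:::AMINO_ACIDS, 16, TRUE), collapse = "")
    prev <- NULL
    for (off in c(0, 5, 10, 20, 30)) {
      m <- apply_offset(fit0$model, off)
      pot <- build_potentials(seqres, m, fit0$tables, fit0$scale, fit0$space)
      rows <- posterior_oligomer_probs(forward_backward(pot), seqres,
                                       fit0$space)
      if (!is.null(prev)) {
        expect_true(all(rows$p_coil <= prev + 1e-12))
      }
      prev <- rows$p_coil
    }
  }
})

test_that("models serialize losslessly", {
  fit <- fit_multinomial(noisy_examples())
  fit <- apply_offset(fit, 20)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f, extra = list(seed = 3L))
  back <- read_model(f)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$c_dimer, fit$c_dimer)
  expect_equal(back$offset, fit$offset)
})
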