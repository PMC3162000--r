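ratio_rows <- function(ratios, p_coil = 0.9) {
  data.frame(position = seq_along(ratios),
             residue = "A", best_register = "-",
             p_dimer = ratios * p_coil, p_trimer = (1 - ratios) * p_coil,
             p_coil = p_coil, stringsAsFactors = FALSE)
}

test_that("the dimer/trimer statistic sums per-residue ratios", {
  s <- dimer_trimer_statistic(ratio_rows(c(0.8, 0.6, 0.7)))
  expect_equal(s$dimer_score, 2.1)
  expect_equal(s$trimer_score, 0.9)
  expect_equal(s$statistic, 2.1 / 0.9)

  all_d <- dimer_trimer_statistic(ratio_rows(rep(1, 10)))
  expect_equal(all_d$dimer_score, 10)
  expect_equal(all_d$trimer_score, 0)
  expect_equal(all_d$statistic, Inf)
  expect_equal(classify_sequence(all_d, threshold = 1e12), "DIMER")

  even <- dimer_trimer_statistic(ratio_rows(rep(0.5, 6)))
  expect_equal(even$statistic, 1)

  zero <- ratio_rows(c(0.5, 0.5))
  zero$p_dimer <- zero$p_trimer <- zero$p_coil <- 0
  expect_error(dimer_trimer_statistic(zero), "undefined")
})

test_that("sequence classification follows the threshold with dimer ties", {
  expect_equal(classify_sequence(2.333, 1), "DIMER")
  expect_equal(classify_sequence(0.2, 1), "TRIMER")
  expect_equal(classify_sequence(1.0, 1), "DIMER")
  expect_equal(classify_sequence(1.0, 1, tie = "TRIMER"), "TRIMER")
  # threshold-monotone: raising the threshold never flips trimer to dimer
  stats_ <- c(0.2, 0.9, 1.4, 3)
  prev <- NULL
  for (thr in c(0.5, 1, 2, 5)) {
    calls <- vapply(stats_, classify_sequence, "", threshold = thr)
    if (!is.null(prev)) {
      expect_false(any(prev == "TRIMER" & calls == "DIMER"))
    }
    prev <- calls
  }
})

test_that("residue detection uses a strict cutoff and is monotone", {
  rows <- ratio_rows(rep(0.5, 5), p_coil = 1)
  rows$p_coil <- c(0.9, 0.5, 0.51, 0.1, 0.6)
  expect_equal(detect_residues(rows, 0.5), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  prev <- Inf
  for (cut in seq(0, 1, 0.1)) {
    n <- sum(detect_residues(rows, cut))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("sequence detection applies the 28-residue window rule", {
  mk <- function(p) {
    data.frame(position = seq_along(p), residue = "A", best_register = "-",
               p_dimer = p / 2, p_trimer = p / 2, p_coil = p,
               stringsAsFactors = FALSE)
  }
  # negative with a 27-residue above-cutoff run: not detected
  p <- rep(0.1, 40); p[3:29] <- 0.9
  expect_false(detect_sequence(mk(p), 0.5))
  # a 28-residue run is a false positive
  p[3:30] <- 0.9
  expect_true(detect_sequence(mk(p), 0.5))
  # sequences shorter than 28 can never be detected as negatives
  expect_false(detect_sequence(mk(rep(0.99, 27)), 0.5))
  # positives: one sub-cutoff residue inside the coil is a miss
  p <- rep(0.9, 40); p[20] <- 0.4
  expect_false(detect_sequence(mk(p), 0.5, annotation = c(10, 30)))
  expect_true(detect_sequence(mk(p), 0.5, annotation = c(25, 35)))
})

test_that("ROC sweep has the standard endpoints and permutation behaviour", {
  roc <- roc_curve(c(5, 6, 7), c(1, 2, 3))
  expect_true(any(roc$tpr == 1 & roc$fpr == 0))
  expect_equal(roc$tpr[roc$threshold == -Inf], 1)
  expect_equal(roc$fpr[roc$threshold == -Inf], 1)
  expect_equal(roc_auc(roc), 1)
  set.seed(19)
  a <- rnorm(500)
  b <- rnorm(500)
  expect_lt(abs(roc_auc(roc_curve(a, b)) - 0.5), 0.05)
})

test_that("trapezoidal AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  pos <- rnorm(80, 1)
  neg <- rnorm(120)
  ours <- roc_auc(roc_curve(pos, neg))
  ref <- suppressMessages(
    as.numeric(pROC::auc(c(rep(1, 80), rep(0, 120)), c(pos, neg))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("families of four or fewer sequences merge into miscellaneous", {
  fam <- function(n) replicate(n, list(name = "r"), simplify = FALSE)
  fams <- list(big = fam(5), small = fam(4), tiny = fam(1))
  out <- group_small_families(fams)
  expect_named(out, c("big", "miscellaneous"))
  expect_length(out$miscellaneous, 5)
  all_small <- group_small_families(list(a = fam(2), b = fam(3)))
  expect_named(all_small, "miscellaneous")
  expect_length(all_small$miscellaneous, 5)
  expect_named(group_small_families(fams["big"]), "big")
})

test_that("cross-validation folds never see the held-out family", {
  ds <- small_dataset()
  cv <- leave_family_out(ds$families, ds$negatives, seed = 2)
  expect_length(cv$fold_inputs, 6)
  for (fam in names(cv$fold_inputs)) {
    fi <- cv$fold_inputs[[fam]]
    expect_false(fam %in% fi$table_families)
    expect_false(any(startsWith(fi$table_records, paste0(fam, "/"))))
    expect_false(any(startsWith(fi$regression_provenance, paste0(fam, "/"))))
    for (g in names(fi$nested_table_records)) {
      recs <- fi$nested_table_records[[g]]
      expect_false(any(startsWith(recs, paste0(fam, "/"))))
      # the nested tables for family G also exclude G itself
      expect_false(any(startsWith(recs, paste0(g, "/"))))
    }
  }
  # confusion rows account for every annotated coil of every family
  per_fam <- table(cv$results$family)
  for (fam in names(ds$families)) {
    expect_equal(unname(per_fam[[fam]]), length(ds$families[[fam]]))
  }
})

test_that("three families give the degenerate n-2 = 1 nested scheme", {
  ds <- small_dataset()
  # mixed-class families so every fold still trains on both coil classes
  mix <- function(name, d, t) {
    recs <- c(ds$families[[d]], ds$families[[t]])
    lapply(recs, function(r) { r$family <- name; r })
  }
  fams3 <- list(famA = mix("famA", "dimer_fam01", "trimer_fam01"),
                famB = mix("famB", "dimer_fam02", "trimer_fam02"),
                famC = mix("famC", "dimer_fam03", "trimer_fam03"))
  cv <- leave_family_out(fams3, ds$negatives, seed = 2)
  fi <- cv$fold_inputs[["famA"]]
  for (g in names(fi$nested_table_records)) {
    other <- setdiff(names(fams3), c("famA", g))
    expect_length(other, 1)  # n-2 = 1: exactly one family feeds the tables
    expect_true(all(startsWith(fi$nested_table_records[[g]],
                               paste0(other, "/"))))
  }
  expect_error(leave_family_out(fams3[1:2], ds$negatives), "at least 3")
})
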