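test_that("Mann-Whitney handles separation, ties and branch selection", {
  # most extreme of the C(6,3) = 20 labelings, two-sided
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$branch, "exact")

  # identical constant groups carry no separation
  res <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p_value, 1.0)

  # ties push the auto branch to the corrected normal approximation
  res <- mann_whitney(c(1, 2, 2, 4), c(2, 3, 5, 6))
  expect_equal(res$branch, "normal")
  # forcing exact with ties enumerates labelings directly
  forced <- mann_whitney(c(1, 2, 2, 4), c(2, 3, 5, 6), mode = "exact")
  expect_equal(forced$branch, "exact_ties")
  expect_equal(forced$p_value, oracle_mw_p(c(1, 2, 2, 4), c(2, 3, 5, 6)))

  # large samples switch to the normal branch under auto
  res <- mann_whitney(rnorm(20), rnorm(20))
  expect_equal(res$branch, "normal")

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact p-values agree with permutation enumeration at small n", {
  set.seed(71)
  for (i in 1:40) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- round(rnorm(n1, 0, 10), 3)
    y <- round(rnorm(n2, 1, 10), 3)
    if (anyDuplicated(c(x, y))) next
    res <- mann_whitney(x, y)
    expect_equal(res$branch, "exact")
    expect_equal(res$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact p-values live on the k / C(n, n1) lattice at 13 vs 8", {
  set.seed(73)
  denom <- choose(21, 13)
  for (i in 1:10) {
    x <- rnorm(13)
    y <- rnorm(8)
    res <- mann_whitney(x, y)
    expect_equal(res$branch, "exact")
    k <- res$p_value * denom
    expect_lt(abs(k - round(k)), 1e-6)
  }
})

test_that("fold changes and sentinels follow the group means", {
  expect_equal(fold_change(c(4, 4), c(2, 2)), 2)
  expect_equal(fold_change(c(3, 3), c(3, 3)), 1)
  expect_identical(fold_change(c(1, 2), c(0, 0)), Inf)   # only in cases
  expect_identical(fold_change(c(0, 0), c(1, 2)), 0)     # only in controls
  expect_true(is.nan(fold_change(c(0, 0), c(0, 0))))
})

test_that("the discovery criteria mirror the shortlist rules", {
  # printed shortlist rows: apolipoprotein B-100 (68 peptides, 2.47,
  # p = 3.26e-2) qualifies; a 1.8-fold protein does not
  expect_true(meets_de_criteria(68L, 2.47, 3.26e-2))
  expect_false(meets_de_criteria(5L, 1.8, 0.001))
  expect_false(meets_de_criteria(1L, 3.0, 0.001))   # single peptide
  expect_false(meets_de_criteria(3L, 2.5, 0.06))    # p too large
  expect_true(meets_de_criteria(2L, 0.44, 7.58e-4)) # down-regulation
  expect_true(meets_de_criteria(2L, Inf, 0.01))     # only-in-cases sentinel

  # verification: same trend at two-fold
  expect_true(meets_verification(2.37, 2.50))   # up stays up
  expect_false(meets_verification(2.37, 1.5))   # fold fails
  expect_true(meets_verification(0.33, 0.37))   # down stays down
  expect_false(meets_verification(0.33, 2.5))   # trend flips
  expect_true(meets_verification(0.01, 0))      # only-in-controls, down
})

test_that("de_filter flags equal a brute-force three-predicate scan", {
  set.seed(79)
  n_prot <- 30L
  groups <- rep(c("case", "control"), c(13, 8))
  mat <- matrix(rlnorm(n_prot * 21, 10, 1), n_prot, 21,
                dimnames = list(sprintf("P%05d", 1:n_prot),
                                sprintf("s%d", 1:21)))
  mat[1:5, groups == "case"] <- mat[1:5, groups == "case"] * 4
  mat[6, ] <- 0
  mat[6, groups == "case"] <- rlnorm(13, 10, 1)
  pc <- setNames(sample(1:4, n_prot, TRUE), rownames(mat))
  design <- data.frame(sample_id = colnames(mat), group = groups,
                       set = "discovery", is_reference = FALSE)
  prot <- list(matrix = mat, peptide_count = pc, design = design,
               set = "discovery")
  de <- de_filter(prot)
  for (i in seq_len(n_prot)) {
    r <- fold_change(mat[i, groups == "case"], mat[i, groups == "control"])
    p <- suppressWarnings(wilcox.test(mat[i, groups == "case"],
                                      mat[i, groups == "control"],
                                      exact = TRUE))$p.value
    want <- pc[i] >= 2 && p <= 0.05 &&
      (is.infinite(r) || r == 0 || r >= 2 || r <= 0.5)
    expect_equal(de$is_de_discovery[de$accession == rownames(mat)[i]],
                 unname(want))
  }

  # flag count is monotone in fold and alpha
  n_de <- function(fold, alpha) sum(de_filter(prot, fold = fold,
                                              alpha = alpha)$is_de_discovery)
  expect_gte(n_de(1.5, 0.05), n_de(2, 0.05))
  expect_gte(n_de(2, 0.05), n_de(2, 0.01))
  expect_gte(n_de(2, 0.05), n_de(3, 0.05))
})

test_that("verification requires presence, trend and fold in the test set", {
  disc <- data.frame(
    accession = c("P00001", "P00002", "P00003", "P00004"),
    peptides_discovery = c(3L, 2L, 2L, 2L),
    ratio_discovery = c(2.37, 0.33, 4.0, 3.0),
    p_discovery = c(0.001, 0.02, 0.01, 0.01),
    branch_discovery = "exact",
    p_adjust_discovery = NA_real_,
    is_de_discovery = TRUE,
    stringsAsFactors = FALSE
  )
  groups <- rep(c("case", "control"), c(6, 5))
  mat <- rbind(
    P00001 = c(rep(25, 6), rep(10, 5)),   # up 2.5x: verified
    P00002 = c(rep(3.7, 6), rep(10, 5)),  # down 0.37x: verified
    P00003 = c(rep(15, 6), rep(10, 5))    # up 1.5x: fold fails
    # P00004 absent from the test matrix: not verified
  )
  colnames(mat) <- sprintf("t%d", 1:11)
  prot_test <- list(
    matrix = mat,
    peptide_count = setNames(c(2L, 3L, 2L), rownames(mat)),
    design = data.frame(sample_id = colnames(mat), group = groups,
                        set = "test", is_reference = FALSE),
    set = "test")
  out <- verify_in_test(disc, prot_test)
  expect_equal(out$is_verified_test, c(TRUE, TRUE, FALSE, FALSE))
  # complete separation at 6 vs 5 is significant in the test set
  expect_equal(out$is_significant_test, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("Spearman correlation on logs matches hand-ranked values", {
  x <- 1:10
  expect_equal(spearman_log(x, 2 * x)$rho, 1)
  expect_equal(spearman_log(x, rev(x))$rho, -1)

  # hand computation: d^2 = (1,1,4,1,1), rho = 1 - 6*8/(5*24) = 0.6
  res <- spearman_log(c(1, 2, 3, 4, 5), c(5, 6, 4, 8, 7))
  expect_equal(res$rho, 0.6)
  expect_equal(res$n_pairs, 5L)

  # non-positive pairs are dropped and counted
  res <- spearman_log(c(1, 2, 3, 0, 5), c(5, 6, 4, 8, -1))
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$n_dropped, 2L)
  expect_error(spearman_log(c(1, 2, 0), c(1, 2, 3)), "fewer than 3")
})
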