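# build a peptide_table directly, bypassing clustering
make_ptab <- function(area, status, groups, set = "discovery",
                      accession = NULL, sequence = NULL) {
  n <- nrow(area)
  design <- data.frame(
    sample_id = colnames(area),
    group = groups,
    set = set,
    is_reference = FALSE,
    stringsAsFactors = FALSE
  )
  structure(
    list(area = area, status = status, design = design,
         sequence = if (is.null(sequence)) sprintf("PEP%02d", seq_len(n))
                    else sequence,
         accession = if (is.null(accession)) sprintf("P%05d", seq_len(n))
                     else accession,
         set = set),
    class = "peptide_table")
}

test_that("the 2/3 split honors labels, balance and the seed", {
  design <- data.frame(
    sample_id = sprintf("s%02d", 1:32),
    group = rep(c("case", "control"), c(19, 13)),
    is_reference = FALSE,
    stringsAsFactors = FALSE
  )
  split1 <- split_sets(design, seed = 7L)
  disc <- split1[split1$set == "discovery", ]
  expect_equal(sum(disc$group == "case"), 13L)
  expect_true(sum(disc$group == "control") %in% c(8L, 9L))
  expect_identical(split_sets(design, seed = 7L), split1)

  # pre-labeled designs pass through unchanged
  labeled <- split1
  expect_identical(split_sets(labeled, seed = 99L), labeled)

  tiny <- design[c(1, 2, 20, 21), ]
  expect_error(split_sets(tiny), "too small")
})

test_that("imputation applies the group-mean and zero rules cell by cell", {
  area <- rbind(c(10, 20, 0, 5), c(0, 0, 7, 0))
  status <- rbind(c("detected", "detected", "no_area", "detected"),
                  c("absent", "no_area", "detected", "absent"))
  dimnames(area) <- dimnames(status) <-
    list(NULL, sprintf("s%d", 1:4))
  rownames(area) <- rownames(status) <- c("PEPA", "PEPB")
  groups <- c("case", "case", "control", "control")
  ptab <- make_ptab(area, status, groups)
  out <- impute_missing(ptab)
  # identified-but-no-area in controls: mean of observed control areas = 5
  expect_equal(out$area["PEPA", "s3"], 5)
  # identified-but-no-area in cases with no observed case area: falls to 0
  expect_equal(out$area["PEPB", "s2"], 0)
  # not-identified cells are zero
  expect_equal(out$area["PEPB", "s1"], 0)
  # observed cells never change
  expect_equal(out$area["PEPA", c("s1", "s2", "s4")], c(s1 = 10, s2 = 20, s4 = 5))

  # group areas [10, 20] with one identified-no-area cell -> 15
  area2 <- rbind(c(10, 20, 0))
  status2 <- rbind(c("detected", "detected", "no_area"))
  dimnames(area2) <- dimnames(status2) <- list("PEPC", sprintf("s%d", 1:3))
  out2 <- impute_missing(make_ptab(area2, status2, rep("case", 3)))
  expect_equal(out2$area["PEPC", "s3"], 15)

  # random tables match a cell-by-cell application of the rules
  set.seed(47)
  for (rep_i in 1:10) {
    n <- 8L
    m <- 9L
    groups <- sample(c("case", "control"), m, TRUE, prob = c(0.6, 0.4))
    status <- matrix(sample(c("detected", "no_area", "absent"), n * m, TRUE),
                     n, m, dimnames = list(sprintf("p%d", 1:n),
                                           sprintf("s%d", 1:m)))
    area <- matrix(round(runif(n * m, 1, 100)), n, m,
                   dimnames = dimnames(status))
    area[status != "detected"] <- 0
    out <- impute_missing(make_ptab(area, status, groups))
    for (i in 1:n) for (j in 1:m) {
      expected <- if (status[i, j] == "detected") {
        area[i, j]
      } else if (status[i, j] == "absent") {
        0
      } else {
        obs <- status[i, ] == "detected" & groups == groups[j]
        if (any(obs)) mean(area[i, obs]) else 0
      }
      expect_equal(out$area[i, j], expected)
    }
  }
})

test_that("the detection filter keeps >= 50% in at least one group", {
  # 7/13 cases (0.538) detected, 2/8 controls -> kept
  groups <- rep(c("case", "control"), c(13, 8))
  status <- matrix("absent", 2, 21,
                   dimnames = list(c("kept", "dropped"), sprintf("s%d", 1:21)))
  status["kept", c(1:7, 14:15)] <- "detected"
  # 6/13 (0.462) and 3/8 (0.375): both below 0.5 -> dropped
  status["dropped", c(1:6, 14:16)] <- "detected"
  area <- matrix(1, 2, 21, dimnames = dimnames(status))
  ptab <- make_ptab(area, status, groups)
  out <- detection_filter(ptab, 0.5, apply = TRUE)
  expect_equal(rownames(out$area), "kept")

  # apply = FALSE (test set) is the identity
  expect_identical(detection_filter(ptab, 0.5, apply = FALSE), ptab)

  # monotone: raising the threshold never adds peptides
  set.seed(53)
  status <- matrix(sample(c("detected", "absent"), 40 * 21, TRUE), 40, 21,
                   dimnames = list(sprintf("p%d", 1:40), sprintf("s%d", 1:21)))
  area <- matrix(1, 40, 21, dimnames = dimnames(status))
  ptab <- make_ptab(area, status, groups)
  kept_rows <- lapply(c(0.3, 0.5, 0.7), function(f) {
    rownames(detection_filter(ptab, f, apply = TRUE)$area)
  })
  expect_true(all(kept_rows[[2]] %in% kept_rows[[1]]))
  expect_true(all(kept_rows[[3]] %in% kept_rows[[2]]))
})

test_that("ppm normalization makes every sample sum to one million", {
  area <- matrix(c(2e6, 3e6, 5e6), 3, 1,
                 dimnames = list(sprintf("p%d", 1:3), "s1"))
  expect_equal(as.vector(ppm_normalize(area)), c(2e5, 3e5, 5e5))

  # single-peptide sample maps to 1e6
  one <- matrix(123.4, 1, 1, dimnames = list("p1", "s1"))
  expect_equal(as.vector(ppm_normalize(one)), 1e6)

  set.seed(59)
  for (i in 1:10) {
    m <- matrix(rlnorm(60, 10, 2), 12, 5,
                dimnames = list(sprintf("p%d", 1:12), sprintf("s%d", 1:5)))
    norm <- ppm_normalize(m)
    expect_lt(max(abs(colSums(norm) - 1e6)) / 1e6, 1e-6)
  }

  bad <- matrix(c(1, 0, 2, 0), 2, 2,
                dimnames = list(NULL, c("ok", "empty")))
  bad[, 2] <- 0
  expect_error(ppm_normalize(bad), "empty")
})

test_that("protein abundance sums peptides and counts sequences", {
  area <- matrix(c(100, 200, 50), 3, 1,
                 dimnames = list(sprintf("CL%d", 1:3), "s1"))
  status <- matrix("detected", 3, 1, dimnames = dimnames(area))
  ptab <- make_ptab(area, status, "case",
                    accession = c("P00001", "P00001", "P00002"),
                    sequence = c("AAA", "BBB", "CCC"))
  prot <- protein_abundance(ptab)
  expect_equal(prot$matrix["P00001", "s1"], 300)
  expect_equal(prot$matrix["P00002", "s1"], 50)
  expect_equal(unname(prot$peptide_count[c("P00001", "P00002")]), c(2L, 1L))
})

test_that("per-sample protein totals conserve the one-million budget", {
  study <- generate_study(synth_config(n_proteins = 20L, seed = 61L))
  res <- run_pipeline(study$peptides, study$design, quiet = TRUE)
  for (set_res in list(res$discovery, res$test)) {
    expect_lt(max(abs(colSums(set_res$protein$matrix) - 1e6)) / 1e6, 1e-6)
  }
})

test_that("zero-noise protein matrices rank-match the ground truth", {
  study <- generate_study(synth_config_zero_noise(n_proteins = 15L,
                                                  seed = 67L))
  res <- run_pipeline(study$peptides, study$design, quiet = TRUE)
  pm <- res$discovery$protein$matrix
  tm <- study$truth$protein_abundance[rownames(pm), colnames(pm)]
  rhos <- vapply(seq_len(ncol(pm)), function(j) {
    cor(pm[, j], tm[, j], method = "spearman")
  }, numeric(1))
  expect_equal(rhos, rep(1, ncol(pm)))
})
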