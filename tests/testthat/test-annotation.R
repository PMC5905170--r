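test_that("representative sequence follows mode, Xcorr, then lexicon", {
  expect_equal(representative_sequence(c("A", "A", "B"), c(1, 1, 9)), "A")
  # frequency tie: the sequence attaining the highest Xcorr wins
  expect_equal(representative_sequence(c("A", "B"), c(2.0, 3.5)), "B")
  # exact tie on frequency and Xcorr: lexicographically smallest
  expect_equal(representative_sequence(c("B", "A"), c(2.0, 2.0)), "A")

  # 200 random clusters match a brute-force frequency/Xcorr scan
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    seqs <- sample(LETTERS[1:4], n, TRUE)
    xc <- round(runif(n, 1, 5), 1)
    got <- representative_sequence(seqs, xc)
    freq <- table(seqs)
    cand <- names(freq)[freq == max(freq)]
    bx <- vapply(cand, function(sq) max(xc[seqs == sq]), numeric(1))
    want <- sort(cand[bx == max(bx)])[1]
    expect_identical(got, want)
  }
})

# helper: build an annotated-in-progress cluster set from explicit groups
cluster_set_from_groups <- function(groups) {
  rec_list <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    n <- length(g$proteins)
    make_records(n,
                 measured_mass = g$mass * (1 + seq_len(n) * 1e-7),
                 theoretical_mass = g$mass,
                 rt = rep(100, n),
                 sequence = rep(g$sequence, n),
                 xcorr = rep(3, n),
                 proteins = g$proteins)
  })
  rec <- do.call(rbind, rec_list)
  rec$sample_id <- sprintf("s%d", seq_len(nrow(rec)))
  cs <- build_clusters(list(all = rec))
  filter_min_members(cs, 2L)
}

test_that("shared peptides resolve to the study-wide most frequent protein", {
  # P00001 backs 3 clusters, P00002 backs 1; the shared peptide goes to P00001
  groups <- c(
    lapply(1:3, function(i) list(mass = 1000 + 10 * i, sequence = sprintf("UNIQ%d", i),
                                 proteins = rep("P00001", 2))),
    list(list(mass = 2000, sequence = "ONLY2", proteins = rep("P00002", 2))),
    list(list(mass = 3000, sequence = "SHARED",
              proteins = rep("P00001;P00002", 2)))
  )
  cs <- cluster_set_from_groups(groups)
  cs <- assign_representative_sequences(cs)
  cs <- assign_protein(cs)
  shared <- cs$clusters$accession[cs$clusters$representative_sequence == "SHARED"]
  expect_equal(shared, "P00001")

  # the assignment is a function of the whole cluster list: adding more
  # P00002-backed clusters flips the shared peptide's protein
  groups2 <- c(groups, lapply(1:3, function(i) {
    list(mass = 4000 + 10 * i, sequence = sprintf("EXTRA%d", i),
         proteins = rep("P00002", 2))
  }))
  cs2 <- assign_protein(assign_representative_sequences(
    cluster_set_from_groups(groups2)))
  shared2 <- cs2$clusters$accession[cs2$clusters$representative_sequence == "SHARED"]
  expect_equal(shared2, "P00002")

  # single-candidate sequences keep their accession
  expect_true(all(cs$clusters$accession[
    cs$clusters$representative_sequence == "ONLY2"] == "P00002"))
})

test_that("annotation fills names and warns on absent accessions", {
  groups <- list(
    list(mass = 1000, sequence = "AAA", proteins = rep("P12345", 2)),
    list(mass = 2000, sequence = "BBB", proteins = rep("P99999", 2))
  )
  cs <- assign_representative_sequences(cluster_set_from_groups(groups))
  expect_warning(cs <- assign_protein(cs, annotation = toy_annotation()),
                 "P99999")
  cl <- cs$clusters
  expect_equal(cl$protein_name[cl$accession == "P12345"], "Toy protein A")
  expect_equal(cl$protein_name[cl$accession == "P99999"], "")
})

test_that("mass-accuracy filtering is strict and cascades", {
  # deviation of exactly 5.0 ppm is removed (strict '<'), 0 ppm is kept
  boundary <- 800 * (1 + 5e-6)
  stopifnot((boundary - 800) / 800 >= 5e-6)  # lands on/above the bound
  rec <- make_records(4L,
                      measured_mass = c(800, 800 * (1 + 1e-9), boundary,
                                        800 * (1 + 4.9e-6)),
                      theoretical_mass = rep(800, 4),
                      rt = rep(100, 4),
                      sequence = rep("AAA", 4))
  rec$sample_id <- sprintf("s%d", 1:4)
  cs <- filter_min_members(build_clusters(list(all = rec)), 2L)
  expect_equal(cs$clusters$member_count, 4L)
  filtered <- filter_mass_accuracy(cs, max_ppm = 5)
  expect_equal(filtered$clusters$member_count, 3L)
  dev <- abs(filtered$records$measured_mass -
               filtered$records$theoretical_mass) /
    filtered$records$theoretical_mass
  expect_true(all(dev[!is.na(filtered$assignment)] < 5e-6))

  # random deviations match a brute-force scan with cascade drop
  set.seed(37)
  study <- generate_study(synth_config(n_proteins = 15L, mass_error_sd = 4,
                                       seed = 41L))
  cs <- filter_min_members(build_clusters(study$peptides), 2L)
  filtered <- filter_mass_accuracy(cs, max_ppm = 5)
  recs <- cs$records
  dev_ok <- abs(recs$measured_mass - recs$theoretical_mass) /
    recs$theoretical_mass < 5e-6
  expected_sizes <- vapply(seq_len(nrow(cs$clusters)), function(k) {
    sum(cs$assignment == k & dev_ok, na.rm = TRUE)
  }, integer(1))
  expect_equal(sort(filtered$clusters$member_count),
               sort(expected_sizes[expected_sizes >= 2L]))
})

test_that("the full annotation pass keeps invariants assertable", {
  study <- generate_study(synth_config(n_proteins = 15L, seed = 43L))
  cal <- calibrate_study(study$peptides, study$design)
  cs <- filter_min_members(build_clusters(cal$peptides), 2L)
  cs <- annotate_clusters(cs)
  check_cluster_invariants(cs)
  recs <- cs$records
  members <- split(seq_along(cs$assignment), cs$assignment)
  for (k in seq_len(nrow(cs$clusters))) {
    idx <- members[[as.character(k)]]
    # representative sequence is modal among final members
    freq <- table(recs$sequence[idx])
    expect_true(freq[cs$clusters$representative_sequence[k]] == max(freq))
  }
})
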