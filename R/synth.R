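# Run the RNG under a fixed seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration of a synthetic multi-run study
#'
#' Defines the statistical structure of a simulated label-free plasma study:
#' a shared set of true peptide features (protein, tryptic-like sequence,
#' theoretical mass, true retention time), per-sample monotone retention-time
#' drift, ppm-scale mass error, log-normal peak areas with a multiplicative
#' group effect on designated proteins, identification-level dropout,
#' area-level missingness, and run-unique spurious singleton features.
#'
#' Defaults mirror the study design the pipeline targets: 13 cases + 8
#' controls in the discovery set and 6 cases + 5 controls in the test set
#' (32 runs), a long-gradient retention-time range, and 2 ppm mass error
#' (the event-detector precision of a modern Orbitrap workflow). The default
#' 50 proteins with 2-6 peptides each and 8 spiked proteins at |log2 effect|
#' 1.5 keep a full simulated study small enough for routine testing while
#' exercising every pipeline rule.
#'
#' @param n_cases_discovery,n_controls_discovery,n_cases_test,n_controls_test
#'   group sizes per set.
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (length 2) of peptides drawn per
#'   protein.
#' @param n_de_proteins number of proteins given a true group effect
#'   (default: 8, capped at `n_proteins`; ignored when `true_de_proteins`
#'   is given).
#' @param de_log2_effect absolute log2 effect size of spiked proteins; signs
#'   alternate up/down.
#' @param true_de_proteins optional data frame (`accession`, `log2_effect`)
#'   overriding the automatic spike-in choice.
#' @param rt_range numeric length 2, observable retention-time range
#'   (minutes).
#' @param drift_slope_range per-sample affine drift slope range.
#' @param drift_intercept_range per-sample affine drift intercept range
#'   (minutes).
#' @param drift_amplitude amplitude (minutes) of the smooth sinusoidal drift
#'   perturbation; clamped so every sample's drift stays strictly monotone.
#' @param rt_jitter_sd per-observation retention-time jitter sd (minutes),
#'   applied before drift.
#' @param mass_error_sd ppm standard deviation of the measured-mass error.
#' @param area_lognormal_params `c(meanlog, sdlog)` of base peptide areas.
#' @param area_noise_sd per-observation multiplicative log-normal area noise
#'   (sdlog).
#' @param identification_dropout_rate probability a true feature is not
#'   identified in a given run.
#' @param area_missing_rate probability an identified record has no
#'   retrievable area (empty `area` field).
#' @param decoy_singleton_rate expected run-unique spurious features per run,
#'   as a fraction of the true feature count.
#' @param shared_peptide_rate probability a peptide is annotated with a
#'   second (shared) candidate protein.
#' @param seed integer seed; the same configuration and seed always yield an
#'   identical study.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cases_discovery = 13L, n_controls_discovery = 8L,
                         n_cases_test = 6L, n_controls_test = 5L,
                         n_proteins = 50L,
                         peptides_per_protein = c(2L, 6L),
                         n_de_proteins = NULL,
                         de_log2_effect = 1.5,
                         true_de_proteins = NULL,
                         rt_range = c(30, 450),
                         drift_slope_range = c(0.97, 1.03),
                         drift_intercept_range = c(-2, 2),
                         drift_amplitude = 1.0,
                         rt_jitter_sd = 0.1,
                         mass_error_sd = 2,
                         area_lognormal_params = c(16, 1.2),
                         area_noise_sd = 0.3,
                         identification_dropout_rate = 0.1,
                         area_missing_rate = 0.02,
                         decoy_singleton_rate = 0.05,
                         shared_peptide_rate = 0.05,
                         seed = 1L) {
  if (is.null(n_de_proteins)) {
    n_de_proteins <- min(8L, as.integer(n_proteins))
  }
  cfg <- list(
    n_cases_discovery = as.integer(n_cases_discovery),
    n_controls_discovery = as.integer(n_controls_discovery),
    n_cases_test = as.integer(n_cases_test),
    n_controls_test = as.integer(n_controls_test),
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_de_proteins = as.integer(n_de_proteins),
    de_log2_effect = de_log2_effect,
    true_de_proteins = true_de_proteins,
    rt_range = rt_range,
    drift_slope_range = drift_slope_range,
    drift_intercept_range = drift_intercept_range,
    drift_amplitude = drift_amplitude,
    rt_jitter_sd = rt_jitter_sd,
    mass_error_sd = mass_error_sd,
    area_lognormal_params = area_lognormal_params,
    area_noise_sd = area_noise_sd,
    identification_dropout_rate = identification_dropout_rate,
    area_missing_rate = area_missing_rate,
    decoy_singleton_rate = decoy_singleton_rate,
    shared_peptide_rate = shared_peptide_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  rates <- c(cfg$identification_dropout_rate, cfg$area_missing_rate,
             cfg$decoy_singleton_rate, cfg$shared_peptide_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$n_cases_discovery, cfg$n_controls_discovery,
            cfg$n_cases_test, cfg$n_controls_test) < 1L)) {
    stop("every group/set cell needs at least one sample", call. = FALSE)
  }
  if (cfg$rt_range[1] <= 0 || diff(cfg$rt_range) <= 0) {
    stop("rt_range must be positive and increasing", call. = FALSE)
  }
  if (cfg$n_proteins < 1L || cfg$peptides_per_protein[1] < 1L ||
      cfg$peptides_per_protein[2] < cfg$peptides_per_protein[1]) {
    stop("invalid protein/peptide counts", call. = FALSE)
  }
  if (cfg$n_de_proteins > cfg$n_proteins) {
    stop("n_de_proteins cannot exceed n_proteins", call. = FALSE)
  }
  if (!is.finite(cfg$de_log2_effect)) {
    stop("de_log2_effect must be finite", call. = FALSE)
  }
  invisible(cfg)
}

#' Apply a monotone retention-time drift
#'
#' A drift specification is affine plus a smooth sinusoidal perturbation:
#' `f(rt) = b + a * rt + amp * sin(2 * pi * freq * (rt - r0) / span + phase)`.
#' The specification is rejected unless `f` is strictly increasing over
#' `rt_range` (checked through its derivative bound), which keeps the drift
#' numerically invertible — the property the calibration stage relies on.
#'
#' @param rt retention times (minutes).
#' @param spec list with elements `a`, `b`, `amp`, `freq`, `phase`,
#'   `rt_range`. `drift_identity()` builds the identity spec.
#' @return drifted retention times.
#' @export
apply_drift <- function(rt, spec) {
  check_drift_monotone(spec)
  span <- diff(spec$rt_range)
  spec$b + spec$a * rt +
    spec$amp * sin(2 * pi * spec$freq * (rt - spec$rt_range[1]) / span +
                     spec$phase)
}

check_drift_monotone <- function(spec) {
  span <- diff(spec$rt_range)
  min_deriv <- spec$a - abs(spec$amp) * 2 * pi * spec$freq / span
  if (min_deriv <= 0) {
    stop("drift specification is not monotone over rt_range", call. = FALSE)
  }
  invisible(spec)
}

#' @rdname apply_drift
#' @param rt_range observable retention-time range of the spec.
#' @export
drift_identity <- function(rt_range = c(30, 450)) {
  list(a = 1, b = 0, amp = 0, freq = 1, phase = 0, rt_range = rt_range)
}

# Invert a drift spec numerically (monotone root finding).
invert_drift <- function(rt_obs, spec) {
  span <- diff(spec$rt_range)
  lo <- spec$rt_range[1] - 0.5 * span
  hi <- spec$rt_range[2] + 0.5 * span
  vapply(rt_obs, function(y) {
    stats::uniroot(function(x) apply_drift(x, spec) - y, c(lo, hi),
                   tol = 1e-9)$root
  }, numeric(1))
}

# Draw a random per-sample monotone drift spec.
random_drift_spec <- function(cfg) {
  span <- diff(cfg$rt_range)
  a <- stats::runif(1, cfg$drift_slope_range[1], cfg$drift_slope_range[2])
  freq <- stats::runif(1, 0.5, 2)
  # clamp the amplitude so the derivative bound stays strictly positive
  amp_max <- 0.8 * a * span / (2 * pi * freq)
  amp <- min(cfg$drift_amplitude, amp_max) * stats::runif(1, 0.5, 1)
  list(
    a = a,
    b = stats::runif(1, cfg$drift_intercept_range[1],
                     cfg$drift_intercept_range[2]),
    amp = amp, freq = freq, phase = stats::runif(1, 0, 2 * pi),
    rt_range = cfg$rt_range
  )
}

# Theoretical masses pairwise separated by > 25 ppm so distinct true features
# never share a clustering mass window.
draw_separated_masses <- function(n, lo = 600, hi = 5000, min_ppm = 25) {
  masses <- numeric(0)
  tries <- 0L
  while (length(masses) < n) {
    m <- stats::runif(1, lo, hi)
    if (length(masses) == 0L ||
        min(abs(masses - m) / m) > min_ppm * 1e-6) {
      masses <- c(masses, m)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) stop("mass space exhausted", call. = FALSE)
  }
  masses
}

random_sequences <- function(n, len_range = c(8L, 20L)) {
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    new <- vapply(seq_len(need), function(i) {
      len <- sample(len_range[1]:len_range[2], 1L)
      paste(sample(AMINO_ACIDS, len, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs
}

#' Generate a synthetic multi-run study with known ground truth
#'
#' Simulates per-sample peptide exports plus the study design and a ground
#' truth that records, for every generated non-decoy record, the true feature
#' it came from, the true protein abundance matrix, and the true
#' differential-abundance label per protein. Every downstream pipeline stage
#' can therefore be scored without any external data.
#'
#' Each true feature appears in a run with probability
#' `1 - identification_dropout_rate`; its retention time is the true rt plus
#' jitter passed through the run's monotone drift; its measured mass is the
#' theoretical mass times `1 + e` with `e ~ N(0, mass_error_sd ppm)`; its
#' area is log-normal with the protein's group effect applied
#' multiplicatively in cases. A fraction of identified records lose their
#' area (empty field), and each run gains run-unique spurious singleton
#' features that the minimum-member filter must remove.
#'
#' @param config a [synth_config()].
#' @return list with elements:
#' \describe{
#'   \item{peptides}{named list of per-sample peptide-record data frames,
#'     each carrying a hidden `feature_id` column (`NA` for decoys) used only
#'     for scoring.}
#'   \item{design}{study design; the first discovery control is the
#'     reference.}
#'   \item{truth}{list with `features` (feature_id, accession, sequence,
#'     theoretical_mass, rt_true, proteins), `protein_abundance` (true mean
#'     peak-area matrix, protein x sample), `de_labels` (accession,
#'     log2_effect, is_de), and `drift` (per-sample drift specs).}
#' }
#' @export
generate_study <- function(config = synth_config()) {
  validate_synth_config(config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  design <- make_design(cfg)
  n_samples <- nrow(design)
  accessions <- sprintf("P%05d", seq_len(cfg$n_proteins))

  if (is.null(cfg$true_de_proteins)) {
    de_idx <- seq_len(cfg$n_de_proteins)
    de <- data.frame(
      accession = accessions[de_idx],
      log2_effect = cfg$de_log2_effect *
        rep_len(c(1, -1), length(de_idx)),
      stringsAsFactors = FALSE
    )
  } else {
    de <- cfg$true_de_proteins
  }
  log2_effect <- stats::setNames(rep(0, cfg$n_proteins), accessions)
  log2_effect[de$accession] <- de$log2_effect

  n_pep <- sample(cfg$peptides_per_protein[1]:cfg$peptides_per_protein[2],
                  cfg$n_proteins, replace = TRUE)
  n_feat <- sum(n_pep)
  feat_protein <- rep(accessions, n_pep)
  feat_mass <- draw_separated_masses(n_feat)
  feat_rt <- stats::runif(n_feat, cfg$rt_range[1], cfg$rt_range[2])
  feat_seq <- random_sequences(n_feat)
  feat_base <- stats::rlnorm(n_feat, cfg$area_lognormal_params[1],
                             cfg$area_lognormal_params[2])
  shared <- stats::runif(n_feat) < cfg$shared_peptide_rate
  feat_proteins <- feat_protein
  if (any(shared)) {
    other <- vapply(feat_protein[shared], function(p) {
      sample(setdiff(accessions, p), 1L)
    }, character(1))
    feat_proteins[shared] <- paste(feat_protein[shared], other, sep = ";")
  }
  features <- data.frame(
    feature_id = sprintf("F%05d", seq_len(n_feat)),
    accession = feat_protein,
    sequence = feat_seq,
    theoretical_mass = feat_mass,
    rt_true = feat_rt,
    proteins = feat_proteins,
    stringsAsFactors = FALSE
  )

  is_case <- design$group == "case"
  # true mean area per feature and sample (group effect, no noise)
  eff <- 2^(log2_effect[feat_protein])
  true_area <- outer(feat_base, rep(1, n_samples))
  true_area[, is_case] <- true_area[, is_case] * eff

  drift <- lapply(seq_len(n_samples), function(i) random_drift_spec(cfg))
  names(drift) <- design$sample_id

  n_decoy <- round(cfg$decoy_singleton_rate * n_feat)
  peptides <- vector("list", n_samples)
  names(peptides) <- design$sample_id
  for (s in seq_len(n_samples)) {
    present <- stats::runif(n_feat) >= cfg$identification_dropout_rate
    idx <- which(present)
    n_s <- length(idx)
    rt_in <- feat_rt[idx] +
      stats::rnorm(n_s, 0, cfg$rt_jitter_sd)
    rt_in <- pmin(pmax(rt_in, cfg$rt_range[1]), cfg$rt_range[2])
    rt_obs <- apply_drift(rt_in, drift[[s]])
    mass_obs <- feat_mass[idx] *
      (1 + stats::rnorm(n_s, 0, cfg$mass_error_sd * 1e-6))
    area <- true_area[idx, s] *
      stats::rlnorm(n_s, 0, cfg$area_noise_sd)
    area[stats::runif(n_s) < cfg$area_missing_rate] <- NA_real_
    rec <- data.frame(
      sample_id = design$sample_id[s],
      sequence = feat_seq[idx],
      measured_mass = mass_obs,
      theoretical_mass = feat_mass[idx],
      rt = pmax(rt_obs, 1e-6),
      area = area,
      xcorr = stats::runif(n_s, 1, 6),
      confidence = sample(CONFIDENCE_LEVELS, n_s, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)),
      rank = sample(1:2, n_s, replace = TRUE, prob = c(0.9, 0.1)),
      proteins = feat_proteins[idx],
      stringsAsFactors = FALSE
    )
    rec$feature_id <- features$feature_id[idx]
    if (n_decoy > 0L) {
      dmass <- draw_separated_masses(n_decoy)
      dec <- data.frame(
        sample_id = design$sample_id[s],
        sequence = random_sequences(n_decoy),
        measured_mass = dmass,
        theoretical_mass = dmass,
        rt = stats::runif(n_decoy, cfg$rt_range[1], cfg$rt_range[2]),
        area = stats::rlnorm(n_decoy, cfg$area_lognormal_params[1],
                             cfg$area_lognormal_params[2]),
        xcorr = stats::runif(n_decoy, 0.5, 3),
        confidence = sample(CONFIDENCE_LEVELS, n_decoy, replace = TRUE,
                            prob = c(0.2, 0.3, 0.5)),
        rank = sample(1:6, n_decoy, replace = TRUE),
        proteins = sample(accessions, n_decoy, replace = TRUE),
        stringsAsFactors = FALSE
      )
      dec$feature_id <- NA_character_
      rec <- rbind(rec, dec)
    }
    # shuffle row order: downstream stages must not rely on generation order
    rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
    rownames(rec) <- NULL
    peptides[[s]] <- rec
  }

  protein_truth <- rowsum(true_area, feat_protein)
  colnames(protein_truth) <- design$sample_id

  list(
    peptides = peptides,
    design = design,
    truth = list(
      features = features,
      protein_abundance = protein_truth,
      de_labels = data.frame(
        accession = accessions,
        log2_effect = unname(log2_effect),
        is_de = unname(log2_effect != 0),
        stringsAsFactors = FALSE
      ),
      drift = drift
    )
  )
}

make_design <- function(cfg) {
  groups <- c(rep("case", cfg$n_cases_discovery),
              rep("control", cfg$n_controls_discovery),
              rep("case", cfg$n_cases_test),
              rep("control", cfg$n_controls_test))
  sets <- c(rep("discovery", cfg$n_cases_discovery + cfg$n_controls_discovery),
            rep("test", cfg$n_cases_test + cfg$n_controls_test))
  n <- length(groups)
  design <- data.frame(
    sample_id = sprintf("sample_%02d", seq_len(n)),
    group = groups,
    set = sets,
    is_reference = FALSE,
    stringsAsFactors = FALSE
  )
  # reference: first discovery control (the role the calibration anchors on)
  ref <- which(design$set == "discovery" & design$group == "control")[1L]
  design$is_reference[ref] <- TRUE
  validate_study_design(design)
  design
}

#' Write a generated study to disk
#'
#' Materializes a [generate_study()] result as per-sample TSV exports, a
#' manifest, and ground-truth tables, mirroring what a multi-run export
#' directory looks like in practice. The hidden `feature_id` column is
#' written to a separate truth file, not into the exports.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  truth_map <- list()
  for (sid in names(study$peptides)) {
    rec <- study$peptides[[sid]]
    p <- file.path(dir, paste0(sid, ".tsv"))
    write_peptide_export(rec[, PEPTIDE_COLUMNS], p)
    truth_map[[sid]] <- data.frame(
      sample_id = sid, row_index = seq_len(nrow(rec)),
      feature_id = rec$feature_id, stringsAsFactors = FALSE
    )
    paths[sid] <- basename(p)
  }
  manifest <- cbind(
    data.frame(sample_id = study$design$sample_id,
               path = unname(paths[study$design$sample_id]),
               stringsAsFactors = FALSE),
    study$design[, c("group", "set", "is_reference")]
  )
  mpath <- file.path(dir, "manifest.tsv")
  tsv_write(manifest, mpath)
  tsv_write(do.call(rbind, truth_map), file.path(dir, "truth_records.tsv"))
  tsv_write(study$truth$features, file.path(dir, "truth_features.tsv"))
  tsv_write(study$truth$de_labels, file.path(dir, "truth_de_labels.tsv"))
  write_abundance_matrix(study$truth$protein_abundance,
                         file.path(dir, "truth_protein_abundance.tsv"),
                         id_name = "accession")
  invisible(mpath)
}

#' Zero-noise configuration helper
#'
#' Convenience wrapper producing a study with no mass error, no rt jitter or
#' drift, no dropout and no decoys — under which the full pipeline must
#' recover the ground truth exactly.
#'
#' @param ... overrides passed on to [synth_config()].
#' @export
synth_config_zero_noise <- function(...) {
  synth_config(
    drift_slope_range = c(1, 1), drift_intercept_range = c(0, 0),
    drift_amplitude = 0, rt_jitter_sd = 0, mass_error_sd = 0,
    area_noise_sd = 0, identification_dropout_rate = 0,
    area_missing_rate = 0, decoy_singleton_rate = 0,
    shared_peptide_rate = 0, ...
  )
}
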