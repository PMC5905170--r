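#' Two-sided Mann-Whitney test
#'
#' Wraps the rank-sum test with an explicit branch rule: the exact null
#' distribution is used when `mode = "exact"`, or under `mode = "auto"`
#' when there are no ties and the combined sample size is at most 30;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The branch taken is reported. Forcing `mode =
#' "exact"` in the presence of ties enumerates all group labelings directly
#' (feasible for small samples only).
#'
#' @param values_cases,values_controls numeric vectors, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `p_value`, `statistic` (the Mann-Whitney U of the
#'   cases) and `branch` (`"exact"`, `"normal"` or `"exact_ties"`).
#' @export
mann_whitney <- function(values_cases, values_controls,
                         mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(values_cases)
  y <- as.numeric(values_controls)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    # no separation at all: every labeling is equally extreme
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                branch = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  n <- length(x) + length(y)
  u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (mode == "exact" && ties) {
    return(list(p_value = exact_permutation_p(x, y), statistic = u,
                branch = "exact_ties"))
  }
  exact <- mode == "exact" || (mode == "auto" && !ties && n <= 30L)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(p_value = unname(res$p.value), statistic = unname(u),
       branch = if (exact) "exact" else "normal")
}

# Full enumeration of all group labelings (exact even with ties).
exact_permutation_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  if (choose(n, n1) > 2e6) {
    stop("exact enumeration infeasible for this sample size", call. = FALSE)
  }
  rk <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(rk[seq_len(n1)]) - mu)
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(rk[combos], nrow = n1))
  mean(abs(sums - mu) >= obs - 1e-12)
}

#' Case/control fold change
#'
#' Ratio of group means of non-negative abundances. A zero control mean
#' with a positive case mean yields `Inf` (detected only in cases); the
#' reverse yields `0` (only in controls); two zero means yield `NaN`
#' (undefined). [fold_label()] renders these sentinels as text.
#'
#' @param values_cases,values_controls non-negative numeric vectors.
#' @return the ratio (possibly `Inf`, `0` or `NaN`).
#' @export
fold_change <- function(values_cases, values_controls) {
  mc <- mean(values_cases)
  mk <- mean(values_controls)
  if (mk == 0 && mc == 0) return(NaN)
  if (mk == 0) return(Inf)
  mc / mk
}

#' @rdname fold_change
#' @param ratio numeric ratios to label / labels to parse.
#' @export
fold_label <- function(ratio) {
  out <- format_double(ratio)
  out[is.infinite(ratio) & ratio > 0] <- "only_in_cases"
  out[!is.na(ratio) & ratio == 0] <- "only_in_controls"
  out[is.nan(ratio)] <- "undefined"
  out
}

#' @rdname fold_change
#' @export
fold_unlabel <- function(ratio) {
  out <- suppressWarnings(as.numeric(ratio))
  out[!is.na(ratio) & ratio == "only_in_cases"] <- Inf
  out[!is.na(ratio) & ratio == "only_in_controls"] <- 0
  out[!is.na(ratio) & ratio == "undefined"] <- NaN
  out
}

# does `ratio` show at least `fold`-fold change (either direction)?
# Inf and 0 sentinels satisfy the criterion in their direction.
meets_fold <- function(ratio, fold) {
  !is.na(ratio) & !is.nan(ratio) & (ratio >= fold | ratio <= 1 / fold)
}

#' Differential-abundance and verification criteria
#'
#' The row-level predicates of the discovery/test analysis, applicable to
#' any table of peptide counts, case/control ratios and p-values (vectors
#' recycle). `meets_de_criteria` is the discovery rule: at least
#' `min_peptides` peptides, p-value at most `alpha`, and at least a
#' `fold`-fold change in either direction (`Inf`/`0` sentinels qualify in
#' their direction). `meets_verification` is the test-set rule: same
#' expression trend as in discovery with at least a `fold`-fold change in
#' that direction.
#'
#' @param peptide_count integer vector of per-protein peptide counts.
#' @param ratio,ratio_discovery,ratio_test case/control mean ratios.
#' @param p_value Mann-Whitney p-values.
#' @param min_peptides,alpha,fold thresholds (defaults 2, 0.05, 2).
#' @return logical vector.
#' @export
meets_de_criteria <- function(peptide_count, ratio, p_value,
                              min_peptides = 2L, alpha = 0.05, fold = 2) {
  peptide_count >= min_peptides & !is.na(p_value) & p_value <= alpha &
    meets_fold(ratio, fold)
}

#' @rdname meets_de_criteria
#' @export
meets_verification <- function(ratio_discovery, ratio_test, fold = 2) {
  up <- !is.na(ratio_discovery) & ratio_discovery > 1
  ifelse(up,
         !is.na(ratio_test) & ratio_test >= fold,
         !is.na(ratio_test) & !is.nan(ratio_test) & ratio_test <= 1 / fold)
}

#' Discovery-set differential-abundance filter
#'
#' Flags a protein as differentially abundant in the discovery set when it
#' is quantified from at least `min_peptides` peptides, its two-sided
#' Mann-Whitney p-value is at most `alpha`, and its case/control ratio
#' changes at least `fold`-fold in either direction (the only-in-cases /
#' only-in-controls sentinels satisfy the fold criterion in their
#' direction).
#'
#' @param protein protein-level result from [protein_abundance()] or
#'   [quantify_set()] (`$protein`), for the discovery set.
#' @param min_peptides minimum peptide count (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @param fold fold-change threshold (default 2).
#' @param mode Mann-Whitney branch mode (see [mann_whitney()]).
#' @return data frame with one row per protein: `accession`,
#'   `peptides_discovery`, `ratio_discovery`, `p_discovery`,
#'   `branch_discovery`, `p_adjust_discovery` (Benjamini-Hochberg, reported
#'   for information only) and `is_de_discovery`.
#' @export
de_filter <- function(protein, min_peptides = 2L, alpha = 0.05, fold = 2,
                      mode = "auto") {
  mat <- protein$matrix
  des <- protein$design
  case_cols <- des$sample_id[des$group == "case"]
  ctrl_cols <- des$sample_id[des$group == "control"]
  n <- nrow(mat)
  ratio <- numeric(n)
  pval <- numeric(n)
  branch <- character(n)
  for (i in seq_len(n)) {
    xc <- mat[i, case_cols]
    xk <- mat[i, ctrl_cols]
    ratio[i] <- fold_change(xc, xk)
    mw <- mann_whitney(xc, xk, mode = mode)
    pval[i] <- mw$p_value
    branch[i] <- mw$branch
  }
  out <- data.frame(
    accession = rownames(mat),
    peptides_discovery = as.integer(protein$peptide_count[rownames(mat)]),
    ratio_discovery = ratio,
    p_discovery = pval,
    branch_discovery = branch,
    p_adjust_discovery = stats::p.adjust(pval, method = "BH"),
    stringsAsFactors = FALSE
  )
  out$is_de_discovery <- meets_de_criteria(
    out$peptides_discovery, out$ratio_discovery, out$p_discovery,
    min_peptides = min_peptides, alpha = alpha, fold = fold)
  rownames(out) <- NULL
  out
}

#' Test-set verification of discovery findings
#'
#' A discovery-flagged protein is verified when the test set shows the same
#' expression trend (up in cases stays up, down stays down) with at least a
#' `fold`-fold change in that direction; it is additionally significant in
#' the test set when its test Mann-Whitney p-value is at most `alpha`.
#' Proteins absent from the test matrix are not verified.
#'
#' @param de discovery table from [de_filter()].
#' @param protein_test protein-level result for the test set.
#' @param fold fold-change threshold (default 2).
#' @param alpha test-set p-value threshold (default 0.05).
#' @param mode Mann-Whitney branch mode.
#' @return `de` with test-set columns (`peptides_test`, `ratio_test`,
#'   `p_test`, `branch_test`) and flags `is_verified_test`,
#'   `is_significant_test`.
#' @export
verify_in_test <- function(de, protein_test, fold = 2, alpha = 0.05,
                           mode = "auto") {
  mat <- protein_test$matrix
  des <- protein_test$design
  case_cols <- des$sample_id[des$group == "case"]
  ctrl_cols <- des$sample_id[des$group == "control"]
  idx <- match(de$accession, rownames(mat))
  n <- nrow(de)
  ratio <- rep(NA_real_, n)
  pval <- rep(NA_real_, n)
  branch <- rep(NA_character_, n)
  for (i in which(!is.na(idx))) {
    xc <- mat[idx[i], case_cols]
    xk <- mat[idx[i], ctrl_cols]
    ratio[i] <- fold_change(xc, xk)
    mw <- mann_whitney(xc, xk, mode = mode)
    pval[i] <- mw$p_value
    branch[i] <- mw$branch
  }
  de$peptides_test <- as.integer(protein_test$peptide_count[de$accession])
  de$ratio_test <- ratio
  de$p_test <- pval
  de$branch_test <- branch
  same_trend <- meets_verification(de$ratio_discovery, ratio, fold = fold)
  de$is_verified_test <- de$is_de_discovery & !is.na(idx) & same_trend
  de$is_significant_test <- de$is_verified_test & !is.na(pval) &
    pval <= alpha
  de
}

#' Spearman correlation on log-transformed values
#'
#' Concordance analysis between two positive-valued quantities (e.g.
#' pipeline protein abundances versus catalogued plasma concentrations).
#' Pairs with a non-positive member are dropped and counted; the Spearman
#' rank correlation and its two-sided p-value are computed on the
#' log10-transformed surviving pairs (the coefficient itself is invariant
#' under the strictly increasing transform, which is retained for fidelity
#' of the reported scale).
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p_value`, `n_pairs`, `n_dropped` and
#'   `transform = "log10"`.
#' @export
spearman_log <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_dropped <- sum(!ok)
  x <- log10(x[ok])
  y <- log10(y[ok])
  if (length(x) < 3L) {
    stop("fewer than 3 positive pairs for correlation", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(x), n_dropped = n_dropped, transform = "log10")
}
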