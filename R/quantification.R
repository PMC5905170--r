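#' Split samples into discovery and test sets
#'
#' If the design already carries `set` labels they are honored unchanged.
#' Otherwise a seeded random split assigns two thirds of each group
#' (round-half-up) to the discovery set and the remainder to the test set,
#' preserving case/control balance group-wise.
#'
#' @param design study design.
#' @param seed integer seed for the random split.
#' @return the design with `set` filled in.
#' @export
split_sets <- function(design, seed = 1L) {
  if (all(c("set") %in% names(design)) &&
      all(design$set %in% c("discovery", "test"))) {
    return(design)
  }
  design$set <- NA_character_
  for (g in unique(design$group)) {
    idx <- which(design$group == g)
    if (length(idx) < 3L) {
      stop("design error: group '", g, "' too small to split (",
           length(idx), " samples)", call. = FALSE)
    }
    n_disc <- floor(2 * length(idx) / 3 + 0.5)
    picked <- with_seed(seed + match(g, sort(unique(design$group))),
                        sample(idx, n_disc))
    design$set[idx] <- "test"
    design$set[picked] <- "discovery"
  }
  design
}

#' Build the per-set peptide quantification table
#'
#' For one sample set, assembles the cluster-by-sample peak-area table
#' together with each cell's detection state: `detected` (cluster member
#' identified with an area; multiple members in the same run are summed),
#' `no_area` (identified but no area retrievable) or `absent` (not
#' identified in that run).
#'
#' @param cluster_set an annotated `cluster_set`.
#' @param design study design.
#' @param set `"discovery"` or `"test"`.
#' @return object of class `peptide_table`: list with `area` (matrix,
#'   clusters x samples), `status` (character matrix, same shape), `design`
#'   (rows of the chosen set), `sequence` and `accession` (per cluster row).
#' @export
build_peptide_table <- function(cluster_set, design,
                                set = c("discovery", "test")) {
  set <- match.arg(set)
  cl <- cluster_set$clusters
  if (is.null(cl$accession)) {
    stop("cluster set must be annotated first", call. = FALSE)
  }
  des <- design[design$set == set, , drop = FALSE]
  recs <- cluster_set$records
  n_cl <- nrow(cl)
  n_s <- nrow(des)
  area <- matrix(0, n_cl, n_s,
                 dimnames = list(cl$cluster_id, des$sample_id))
  status <- matrix("absent", n_cl, n_s,
                   dimnames = dimnames(area))
  assigned <- which(!is.na(cluster_set$assignment) &
                      recs$sample_id %in% des$sample_id)
  for (i in assigned) {
    k <- cluster_set$assignment[i]
    s <- match(recs$sample_id[i], des$sample_id)
    a <- recs$area[i]
    if (is.na(a)) {
      if (status[k, s] == "absent") status[k, s] <- "no_area"
    } else {
      area[k, s] <- area[k, s] + a
      status[k, s] <- "detected"
    }
  }
  structure(
    list(area = area, status = status, design = des,
         sequence = cl$representative_sequence, accession = cl$accession,
         set = set),
    class = "peptide_table"
  )
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("peptide_table (%s): %d peptides x %d samples\n",
              x$set, nrow(x$area), ncol(x$area)))
  invisible(x)
}

#' Detection filter
#'
#' Keeps peptides identified (detected or identified-without-area) in at
#' least `min_fraction` of the samples of cases or of controls. Applied to
#' the discovery set only; with `apply = FALSE` (test set) the table is
#' returned unchanged.
#'
#' @param ptab a `peptide_table`.
#' @param min_fraction detection fraction threshold (default 0.5).
#' @param apply whether to apply the filter.
#' @return the filtered `peptide_table`.
#' @export
detection_filter <- function(ptab, min_fraction = 0.5, apply = TRUE) {
  if (!apply) return(ptab)
  identified <- ptab$status != "absent"
  keep_rows <- rep(FALSE, nrow(ptab$area))
  for (g in c("case", "control")) {
    cols <- ptab$design$group == g
    if (!any(cols)) next
    frac <- rowMeans(identified[, cols, drop = FALSE])
    keep_rows <- keep_rows | frac >= min_fraction
  }
  subset_peptide_table(ptab, keep_rows)
}

subset_peptide_table <- function(ptab, keep) {
  ptab$area <- ptab$area[keep, , drop = FALSE]
  ptab$status <- ptab$status[keep, , drop = FALSE]
  ptab$sequence <- ptab$sequence[keep]
  ptab$accession <- ptab$accession[keep]
  ptab
}

#' Impute missing peptide areas
#'
#' Cells identified without a retrievable area are replaced by the mean of
#' the peptide's observed areas within the sample's group (case/control,
#' same set); if the group has no observed area for that peptide the cell
#' falls back to zero. Cells where the peptide was not identified at all are
#' set to zero. Observed cells are never altered.
#'
#' @param ptab a `peptide_table`.
#' @return the `peptide_table` with a complete `area` matrix; the `status`
#'   matrix is retained for reference.
#' @export
impute_missing <- function(ptab) {
  for (g in c("case", "control")) {
    cols <- which(ptab$design$group == g)
    if (length(cols) == 0L) next
    obs <- ptab$status[, cols, drop = FALSE] == "detected"
    a <- ptab$area[, cols, drop = FALSE]
    n_obs <- rowSums(obs)
    means <- ifelse(n_obs > 0, rowSums(a * obs) / pmax(n_obs, 1L), 0)
    for (j in seq_along(cols)) {
      fill <- ptab$status[, cols[j]] == "no_area"
      ptab$area[fill, cols[j]] <- means[fill]
    }
  }
  ptab$area[ptab$status == "absent"] <- 0
  ptab
}

#' Parts-per-million normalization
#'
#' Scales each sample column so the included peptide areas sum to one
#' million: `normalized = area / column total * 1e6`.
#'
#' @param x a `peptide_table` (its `area` matrix is normalized in place) or
#'   a numeric matrix with samples in columns.
#' @return the same type, normalized.
#' @export
ppm_normalize <- function(x) {
  mat <- if (inherits(x, "peptide_table")) x$area else x
  totals <- colSums(mat)
  zero <- totals <= 0
  if (any(zero)) {
    stop("normalization error: zero total area in sample(s) ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  mat <- sweep(mat, 2L, totals, "/") * 1e6
  if (inherits(x, "peptide_table")) {
    x$area <- mat
    x
  } else {
    mat
  }
}

#' Protein abundance by peptide summation
#'
#' Sums the normalized areas of each protein's peptides per sample. The
#' per-protein peptide count is the number of distinct representative
#' sequences contributing to the protein in this set (post-filter).
#'
#' @param ptab a normalized `peptide_table`.
#' @return list with `matrix` (proteins x samples, rows sorted by
#'   accession), `peptide_count` (named integer vector) and `design`.
#' @export
protein_abundance <- function(ptab) {
  mat <- rowsum(ptab$area, group = ptab$accession)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  pc <- vapply(split(ptab$sequence, ptab$accession),
               function(s) length(unique(s)), integer(1))
  pc <- pc[rownames(mat)]
  list(matrix = mat, peptide_count = pc, design = ptab$design,
       set = ptab$set)
}

#' Quantify one sample set
#'
#' Runs the quantification chain for one set: table assembly, detection
#' filter (discovery only), group-mean/zero imputation, ppm normalization
#' and protein summation.
#'
#' @param cluster_set annotated `cluster_set`.
#' @param design study design.
#' @param set `"discovery"` or `"test"`.
#' @param min_fraction detection-filter threshold (default 0.5).
#' @param apply_filter whether the detection filter applies; defaults to
#'   TRUE for the discovery set and FALSE for the test set.
#' @return list with `peptide` (normalized `peptide_table`) and `protein`
#'   (see [protein_abundance()]).
#' @export
quantify_set <- function(cluster_set, design, set = c("discovery", "test"),
                         min_fraction = 0.5,
                         apply_filter = (set == "discovery")) {
  set <- match.arg(set)
  apply_filter <- isTRUE(apply_filter)
  ptab <- build_peptide_table(cluster_set, design, set)
  ptab <- detection_filter(ptab, min_fraction = min_fraction,
                           apply = apply_filter)
  ptab <- impute_missing(ptab)
  ptab <- ppm_normalize(ptab)
  list(peptide = ptab, protein = protein_abundance(ptab))
}
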