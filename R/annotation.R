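#' Representative sequence of a cluster
#'
#' Chooses the sequence with the highest frequency among a cluster's member
#' records. Frequency ties are broken by the highest Xcorr attained by any
#' member carrying the sequence; an exact further tie goes to the
#' lexicographically smallest sequence.
#'
#' @param sequences character vector of member sequences.
#' @param xcorr numeric vector of member Xcorr scores (same length).
#' @return the representative sequence.
#' @export
representative_sequence <- function(sequences, xcorr) {
  stopifnot(length(sequences) > 0L, length(sequences) == length(xcorr))
  freq <- table(sequences)
  cand <- names(freq)[freq == max(freq)]
  if (length(cand) > 1L) {
    best_x <- vapply(cand, function(sq) max(xcorr[sequences == sq]),
                     numeric(1))
    cand <- cand[best_x == max(best_x)]
    cand <- sort(cand)
  }
  cand[1L]
}

#' Assign representative sequences to every cluster
#'
#' Applies [representative_sequence()] to each cluster of a `cluster_set`
#' and records the union of the member records' candidate accessions.
#'
#' @param cluster_set a `cluster_set` (after the minimum-member filter).
#' @return the `cluster_set` with `representative_sequence` and `candidates`
#'   (semicolon-joined accession union, sorted) columns on `$clusters`.
#' @export
assign_representative_sequences <- function(cluster_set) {
  recs <- cluster_set$records
  members <- cluster_members(cluster_set)
  seqs <- character(length(members))
  cands <- character(length(members))
  for (k in seq_along(members)) {
    idx <- members[[k]]
    seqs[k] <- representative_sequence(recs$sequence[idx], recs$xcorr[idx])
    accs <- sort(unique(unlist(
      strsplit(recs$proteins[idx], ";", fixed = TRUE))))
    cands[k] <- paste(accs, collapse = ";")
  }
  cluster_set$clusters$representative_sequence <- seqs
  cluster_set$clusters$candidates <- cands
  cluster_set
}

#' Mass-accuracy filter
#'
#' Removes member records whose measured mass deviates from the theoretical
#' mass of their sequence by `max_ppm` ppm or more (strict: only deviations
#' < `max_ppm` ppm are retained). Clusters left with fewer than
#' `min_members` members are dropped and their ids renumbered.
#'
#' @param cluster_set a `cluster_set`.
#' @param max_ppm maximum allowed ppm deviation, exclusive (default 5).
#' @param min_members minimum cluster size after filtering (default 2).
#' @return the filtered `cluster_set`.
#' @export
filter_mass_accuracy <- function(cluster_set, max_ppm = 5, min_members = 2L) {
  recs <- cluster_set$records
  dev <- abs(recs$measured_mass - recs$theoretical_mass) /
    recs$theoretical_mass
  offend <- dev >= max_ppm * 1e-6
  cluster_set$assignment[offend] <- NA_integer_
  counts <- tabulate(cluster_set$assignment[!is.na(cluster_set$assignment)],
                     nbins = nrow(cluster_set$clusters))
  cluster_set$clusters$member_count <- as.integer(counts)
  filter_min_members(cluster_set, min_members)
}

#' Assign one protein per cluster
#'
#' Clusters whose representative sequence carries a single candidate
#' accession get that accession. For shared peptides (multiple candidates),
#' the accession represented with the highest frequency across the whole
#' cluster list is chosen — by default counting the clusters whose candidate
#' sets include the accession (`count_by = "cluster"`); `count_by =
#' "record"` counts member records instead. Remaining ties go to the
#' lexicographically smallest accession. Protein name and gene symbol are
#' filled from the annotation table where available (blank otherwise, with
#' one warning listing unannotated accessions).
#'
#' @param cluster_set a `cluster_set` with representative sequences and
#'   candidate accessions assigned.
#' @param annotation optional annotation table (`accession`, `protein_name`,
#'   `gene_symbol`).
#' @param count_by frequency unit for shared-peptide resolution.
#' @return the `cluster_set` with `accession`, `protein_name` and
#'   `gene_symbol` columns on `$clusters`.
#' @export
assign_protein <- function(cluster_set, annotation = NULL,
                           count_by = c("cluster", "record")) {
  count_by <- match.arg(count_by)
  cl <- cluster_set$clusters
  if (is.null(cl$candidates)) {
    stop("run assign_representative_sequences() first", call. = FALSE)
  }
  cand_list <- strsplit(cl$candidates, ";", fixed = TRUE)
  if (count_by == "cluster") {
    freq <- table(unlist(lapply(cand_list, unique)))
  } else {
    counts <- cluster_set$clusters$member_count
    freq <- table(unlist(mapply(
      function(cands, n) rep(cands, each = n), cand_list, counts,
      SIMPLIFY = FALSE)))
  }
  accession <- vapply(cand_list, function(cands) {
    if (length(cands) == 1L) return(cands)
    f <- as.vector(freq[cands])
    best <- cands[f == max(f)]
    sort(best)[1L]
  }, character(1))
  cl$accession <- accession
  if (!is.null(annotation)) {
    idx <- match(accession, annotation$accession)
    cl$protein_name <- ifelse(is.na(idx), "", annotation$protein_name[idx])
    cl$gene_symbol <- ifelse(is.na(idx), "", annotation$gene_symbol[idx])
    miss <- unique(accession[is.na(idx)])
    if (length(miss) > 0L) {
      warning("accession(s) absent from annotation table: ",
              paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
  } else {
    cl$protein_name <- ""
    cl$gene_symbol <- ""
  }
  cluster_set$clusters <- cl
  cluster_set
}

#' Annotate a cluster set end to end
#'
#' Convenience driver applying, in order: representative-sequence
#' assignment, the strict < `max_ppm` ppm theoretical-mass accuracy filter
#' (with its cascade drop of clusters below `min_members`), and protein
#' assignment by the study-wide frequency rule.
#'
#' @param cluster_set a `cluster_set` after [filter_min_members()].
#' @param annotation optional annotation table.
#' @param max_ppm mass-accuracy bound in ppm (default 5, strict).
#' @param min_members minimum cluster size (default 2).
#' @param count_by frequency unit for shared-peptide protein assignment.
#' @return annotated `cluster_set`.
#' @export
annotate_clusters <- function(cluster_set, annotation = NULL, max_ppm = 5,
                              min_members = 2L,
                              count_by = c("cluster", "record")) {
  cs <- assign_representative_sequences(cluster_set)
  cs <- filter_mass_accuracy(cs, max_ppm = max_ppm,
                             min_members = min_members)
  # representative sequences survive the member filter; recompute candidates
  # on the surviving members, then resolve proteins study-wide
  cs <- assign_representative_sequences(cs)
  assign_protein(cs, annotation = annotation, count_by = count_by)
}
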