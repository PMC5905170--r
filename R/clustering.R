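# indices of sorted `mass` falling in [lo, hi]
mass_slice <- function(lo, hi, mass) {
  i1 <- findInterval(lo, mass, left.open = TRUE) + 1L
  i2 <- findInterval(hi, mass)
  if (i2 < i1) integer(0) else i1:i2
}

#' Combine per-sample peptide lists into one feature table
#'
#' Stacks the calibrated per-sample records into a single table, adding a
#' `row_index` column (position within the sample's list) so each record can
#' be traced back to its export.
#'
#' @param peptides named list of per-sample peptide-record data frames.
#' @return single data frame with `row_index` after `sample_id`.
#' @export
combine_records <- function(peptides) {
  if (is.data.frame(peptides)) {
    if (!"row_index" %in% names(peptides)) {
      stop("a combined record table needs a row_index column", call. = FALSE)
    }
    return(peptides)
  }
  if (length(peptides) == 0L) {
    out <- empty_peptide_records()
    out$row_index <- integer(0)
    return(out)
  }
  out <- do.call(rbind, lapply(peptides, function(df) {
    df$row_index <- seq_len(nrow(df))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Cluster (mass, rt) features across all runs
#'
#' Groups the calibrated features of every run into cross-run clusters by a
#' deterministic mode-seeking procedure on the two-dimensional (mass, rt)
#' plane. A cluster's window is +/- `mass_window_ppm` ppm in mass and +/-
#' `rt_window_frac` of the center's retention time.
#'
#' The procedure: points are sorted by mass then rt; a candidate center is
#' seeded at every point and iteratively moved to the mean of the points
#' inside its window until the largest window-normalized movement falls
#' below `tol` or `max_iter` is reached. Converged centers closer than half
#' a window in both dimensions are merged (the center capturing more points
#' wins; ties go to the lower mass, then lower rt). Each point is then
#' assigned to the admissible center with the smallest window-normalized
#' Euclidean distance, centers are recomputed once from their assigned
#' members, and members that fall outside the recomputed center's window are
#' re-assigned to the nearest admissible center or left unassigned. Every
#' retained member therefore satisfies the window invariant against the
#' final center.
#'
#' @param records named list of calibrated per-sample peptide-record data
#'   frames, or a combined table from [combine_records()].
#' @param mass_window_ppm half-width of the mass window in ppm (default 5).
#' @param rt_window_frac half-width of the rt window as a fraction of the
#'   center's rt (default 0.05).
#' @param max_iter maximum mode-seeking iterations (default 50).
#' @param tol convergence tolerance in window-normalized units.
#' @return an object of class `cluster_set`: list with `records` (combined
#'   table), `clusters` (cluster_id, center_mass, center_rt, member_count;
#'   sorted by center mass then rt), `assignment` (per-record index into
#'   `clusters`, NA if unassigned) and the window parameters.
#' @export
build_clusters <- function(records, mass_window_ppm = 5,
                           rt_window_frac = 0.05, max_iter = 50L,
                           tol = 1e-6) {
  stopifnot(mass_window_ppm > 0, rt_window_frac > 0, max_iter >= 1L)
  recs <- combine_records(records)
  n <- nrow(recs)
  if (n == 0L) {
    return(new_cluster_set(recs, empty_clusters(), integer(0),
                           mass_window_ppm, rt_window_frac))
  }
  eps <- mass_window_ppm * 1e-6

  ord <- order(recs$measured_mass, recs$rt)
  m <- recs$measured_mass[ord]
  r <- recs$rt[ord]

  # --- mode seeking: one candidate center per point -----------------------
  cm <- m
  cr <- r
  active <- seq_along(cm)
  for (it in seq_len(max_iter)) {
    lo <- cm[active] * (1 - eps)
    hi <- cm[active] * (1 + eps)
    i1 <- findInterval(lo, m, left.open = TRUE) + 1L
    i2 <- findInterval(hi, m)
    moved <- logical(length(active))
    for (j in seq_along(active)) {
      k <- active[j]
      if (i2[j] < i1[j]) next
      idx <- i1[j]:i2[j]
      idx <- idx[abs(r[idx] - cr[k]) <= rt_window_frac * cr[k]]
      if (length(idx) == 0L) next
      nm <- mean(m[idx])
      nr <- mean(r[idx])
      delta <- max(abs(nm - cm[k]) / (eps * cm[k]),
                   abs(nr - cr[k]) / (rt_window_frac * cr[k]))
      if (delta >= tol) {
        cm[k] <- nm
        cr[k] <- nr
        moved[j] <- TRUE
      }
    }
    active <- active[moved]
    if (length(active) == 0L) break
  }

  # --- merge near-duplicate centers ---------------------------------------
  dup <- duplicated(cbind(cm, cr))
  cm <- cm[!dup]
  cr <- cr[!dup]
  counts <- integer(length(cm))
  for (k in seq_along(cm)) {
    idx <- mass_slice(cm[k] * (1 - eps), cm[k] * (1 + eps), m)
    counts[k] <- sum(abs(r[idx] - cr[k]) <= rt_window_frac * cr[k])
  }
  keep_order <- order(-counts, cm, cr)
  cm <- cm[keep_order]; cr <- cr[keep_order]; counts <- counts[keep_order]
  absorbed <- logical(length(cm))
  for (k in seq_along(cm)) {
    if (absorbed[k]) next
    cand <- which(!absorbed)
    cand <- cand[cand != k]
    if (length(cand) == 0L) break
    close_m <- abs(cm[cand] - cm[k]) <= 0.5 * eps * cm[k]
    close_r <- abs(cr[cand] - cr[k]) <= 0.5 * rt_window_frac * cr[k]
    absorbed[cand[close_m & close_r]] <- TRUE
  }
  cm <- cm[!absorbed]
  cr <- cr[!absorbed]

  # --- assignment to nearest admissible center ----------------------------
  c_ord <- order(cm, cr)
  cm <- cm[c_ord]; cr <- cr[c_ord]
  assignment_sorted <- assign_points(m, r, cm, cr, eps, rt_window_frac)

  # --- recompute centers once, then enforce window containment ------------
  used <- sort(unique(assignment_sorted[!is.na(assignment_sorted)]))
  ncm <- vapply(used, function(k) mean(m[which(assignment_sorted == k)]),
                numeric(1))
  ncr <- vapply(used, function(k) mean(r[which(assignment_sorted == k)]),
                numeric(1))
  remap <- match(assignment_sorted, used)
  # keep center arrays sorted by mass (assign_points relies on it)
  n_ord <- order(ncm, ncr)
  ncm <- ncm[n_ord]; ncr <- ncr[n_ord]
  remap <- match(remap, n_ord)
  viol <- !is.na(remap) &
    (abs(m - ncm[remap]) > eps * ncm[remap] |
       abs(r - ncr[remap]) > rt_window_frac * ncr[remap])
  if (any(viol)) {
    re <- assign_points(m[viol], r[viol], ncm, ncr, eps, rt_window_frac)
    remap[viol] <- re
  }

  final <- sort(unique(remap[!is.na(remap)]))
  fcm <- ncm[final]
  fcr <- ncr[final]
  assignment_final <- match(remap, final)

  # back to the original record order
  assignment <- integer(n)
  assignment[ord] <- assignment_final
  member_count <- tabulate(assignment, nbins = length(fcm))

  clusters <- data.frame(
    cluster_id = sprintf("CL%05d", seq_along(fcm)),
    center_mass = fcm,
    center_rt = fcr,
    member_count = member_count,
    stringsAsFactors = FALSE
  )
  new_cluster_set(recs, clusters, assignment, mass_window_ppm,
                  rt_window_frac)
}

# nearest admissible center per point; NA when no center's window admits it.
# Ties on normalized distance go to the lower-mass, then lower-rt center.
assign_points <- function(pm, pr, cm, cr, eps, frac) {
  out <- rep(NA_integer_, length(pm))
  if (length(cm) == 0L) return(out)
  # candidate centers have cm within ~eps of the point's mass
  lo <- findInterval(pm * (1 - 2 * eps), cm, left.open = TRUE) + 1L
  hi <- findInterval(pm * (1 + 2 * eps), cm)
  for (i in seq_along(pm)) {
    if (hi[i] < lo[i]) next
    ks <- lo[i]:hi[i]
    adm <- abs(pm[i] - cm[ks]) <= eps * cm[ks] &
      abs(pr[i] - cr[ks]) <= frac * cr[ks]
    ks <- ks[adm]
    if (length(ks) == 0L) next
    d <- sqrt(((pm[i] - cm[ks]) / (eps * cm[ks]))^2 +
                ((pr[i] - cr[ks]) / (frac * cr[ks]))^2)
    best <- ks[d == min(d)]
    # centers are sorted by (mass, rt): the first tied index is the tie-break
    out[i] <- best[1L]
  }
  out
}

new_cluster_set <- function(records, clusters, assignment,
                            mass_window_ppm, rt_window_frac) {
  structure(
    list(records = records, clusters = clusters, assignment = assignment,
         mass_window_ppm = mass_window_ppm, rt_window_frac = rt_window_frac),
    class = "cluster_set"
  )
}

empty_clusters <- function() {
  data.frame(cluster_id = character(), center_mass = double(),
             center_rt = double(), member_count = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "cluster_set: %d records, %d clusters (+/- %g ppm, +/- %g%% rt)\n",
    nrow(x$records), nrow(x$clusters), x$mass_window_ppm,
    100 * x$rt_window_frac))
  invisible(x)
}

#' Keep only clusters with a minimum number of members
#'
#' Clusters observed in fewer than `min_members` records carry no cross-run
#' information and are dropped from the cluster list; surviving clusters are
#' renumbered sequentially (sorted by center mass then rt).
#'
#' @param cluster_set a `cluster_set` from [build_clusters()].
#' @param min_members minimum member count (default 2).
#' @return the filtered `cluster_set`.
#' @export
filter_min_members <- function(cluster_set, min_members = 2L) {
  keep <- which(cluster_set$clusters$member_count >= min_members)
  clusters <- cluster_set$clusters[keep, , drop = FALSE]
  clusters$cluster_id <- sprintf("CL%05d", seq_along(keep))
  rownames(clusters) <- NULL
  assignment <- match(cluster_set$assignment, keep)
  new_cluster_set(cluster_set$records, clusters, assignment,
                  cluster_set$mass_window_ppm, cluster_set$rt_window_frac)
}

#' Materialize a cluster set as the cluster-list table
#'
#' @param cluster_set a `cluster_set`.
#' @return data frame with one row per cluster: `cluster_id`, `center_mass`,
#'   `center_rt`, `member_count` and a semicolon-joined `members` column of
#'   `sample_id:row_index` pairs, plus any annotation columns present.
#' @export
as_cluster_list <- function(cluster_set) {
  recs <- cluster_set$records
  members <- vapply(seq_len(nrow(cluster_set$clusters)), function(k) {
    idx <- which(cluster_set$assignment == k)
    idx <- idx[order(recs$sample_id[idx], recs$row_index[idx])]
    paste(recs$sample_id[idx], recs$row_index[idx], sep = ":",
          collapse = ";")
  }, character(1))
  out <- cluster_set$clusters
  out$members <- members
  out
}

# member record indices (rows of cluster_set$records) per cluster
cluster_members <- function(cluster_set) {
  split(seq_along(cluster_set$assignment),
        factor(cluster_set$assignment,
               levels = seq_len(nrow(cluster_set$clusters))))
}

#' Check the window-containment invariant of a cluster set
#'
#' Asserts that every assigned record lies within its cluster's mass and rt
#' window — re-checked against the final centers.
#'
#' @param cluster_set a `cluster_set`.
#' @return TRUE invisibly; errors on the first violation.
#' @export
check_cluster_invariants <- function(cluster_set) {
  recs <- cluster_set$records
  a <- cluster_set$assignment
  ok <- is.na(a) |
    (abs(recs$measured_mass - cluster_set$clusters$center_mass[a]) <=
       cluster_set$mass_window_ppm * 1e-6 *
       cluster_set$clusters$center_mass[a] &
       abs(recs$rt - cluster_set$clusters$center_rt[a]) <=
       cluster_set$rt_window_frac * cluster_set$clusters$center_rt[a])
  if (!all(ok, na.rm = TRUE)) {
    stop("window-containment invariant violated for record(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ","), call. = FALSE)
  }
  counts <- tabulate(a[!is.na(a)], nbins = nrow(cluster_set$clusters))
  if (!identical(as.integer(counts),
                 as.integer(cluster_set$clusters$member_count))) {
    stop("member_count inconsistent with assignment", call. = FALSE)
  }
  invisible(TRUE)
}
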