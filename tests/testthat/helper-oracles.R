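# --- independent reference implementations used as oracles -----------------

# Naive mode-seeking clustering, written with plain per-point loops and no
# search structures: seed a center at every point, move each center to the
# mean of the points in its window until converged, merge centers closer
# than half a window (more points wins; ties lower mass then rt), assign
# each point to the nearest admissible center (window-normalized distance,
# ties to the first center in (mass, rt) order), recompute centers once,
# re-home members that fall outside the recomputed window.
# Returns the partition as a list of sorted original point indices.
oracle_clusters <- function(mass, rt, ppm = 5, frac = 0.05,
                            max_iter = 50L, tol = 1e-6) {
  n <- length(mass)
  if (n == 0L) return(list())
  eps <- ppm * 1e-6
  ord <- order(mass, rt)
  m <- mass[ord]
  r <- rt[ord]
  cm <- m
  cr <- r
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (k in seq_len(n)) {
      inw <- abs(m - cm[k]) <= eps * cm[k] & abs(r - cr[k]) <= frac * cr[k]
      if (!any(inw)) next
      nm <- mean(m[inw])
      nr <- mean(r[inw])
      delta <- max(abs(nm - cm[k]) / (eps * cm[k]),
                   abs(nr - cr[k]) / (frac * cr[k]))
      if (delta >= tol) {
        cm[k] <- nm
        cr[k] <- nr
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  dup <- duplicated(cbind(cm, cr))
  cm <- cm[!dup]; cr <- cr[!dup]
  counts <- integer(length(cm))
  for (k in seq_along(cm)) {
    counts[k] <- sum(abs(m - cm[k]) <= eps * cm[k] &
                       abs(r - cr[k]) <= frac * cr[k])
  }
  o <- order(-counts, cm, cr)
  cm <- cm[o]; cr <- cr[o]
  absorbed <- rep(FALSE, length(cm))
  for (k in seq_along(cm)) {
    if (absorbed[k]) next
    for (j in seq_along(cm)) {
      if (j == k || absorbed[j]) next
      if (abs(cm[j] - cm[k]) <= 0.5 * eps * cm[k] &&
          abs(cr[j] - cr[k]) <= 0.5 * frac * cr[k]) {
        absorbed[j] <- TRUE
      }
    }
  }
  cm <- cm[!absorbed]; cr <- cr[!absorbed]
  o <- order(cm, cr)
  cm <- cm[o]; cr <- cr[o]
  nearest <- function(pm, pr, cms, crs) {
    best <- NA_integer_
    bestd <- Inf
    for (k in seq_along(cms)) {
      if (abs(pm - cms[k]) <= eps * cms[k] &&
          abs(pr - crs[k]) <= frac * crs[k]) {
        d <- sqrt(((pm - cms[k]) / (eps * cms[k]))^2 +
                    ((pr - crs[k]) / (frac * crs[k]))^2)
        if (d < bestd) {
          bestd <- d
          best <- k
        }
      }
    }
    best
  }
  assign1 <- vapply(seq_len(n), function(i) nearest(m[i], r[i], cm, cr),
                    integer(1))
  used <- sort(unique(assign1[!is.na(assign1)]))
  ncm <- vapply(used, function(k) mean(m[assign1 == k & !is.na(assign1)]),
                numeric(1))
  ncr <- vapply(used, function(k) mean(r[assign1 == k & !is.na(assign1)]),
                numeric(1))
  o <- order(ncm, ncr)
  ncm <- ncm[o]; ncr <- ncr[o]
  remap <- match(match(assign1, used), o)
  for (i in seq_len(n)) {
    k <- remap[i]
    if (!is.na(k) &&
        (abs(m[i] - ncm[k]) > eps * ncm[k] ||
           abs(r[i] - ncr[k]) > frac * ncr[k])) {
      remap[i] <- nearest(m[i], r[i], ncm, ncr)
    }
  }
  groups <- split(ord[!is.na(remap)], remap[!is.na(remap)])
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# extract the package's partition in the same shape
package_partition <- function(cluster_set) {
  a <- cluster_set$assignment
  groups <- split(which(!is.na(a)), a[!is.na(a)])
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating every labeling.
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  rk <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(rk[seq_len(n1)]) - mu)
  combos <- combn(n, n1)
  extreme <- 0L
  for (j in seq_len(ncol(combos))) {
    if (abs(sum(rk[combos[, j]]) - mu) >= obs - 1e-12) {
      extreme <- extreme + 1L
    }
  }
  extreme / ncol(combos)
}
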