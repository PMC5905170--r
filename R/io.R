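# Canonical column set of the peptide-export dialect. Tab-separated, UTF-8,
# one header row; `area` may be empty (identified but no area retrieved),
# `proteins` is a semicolon-joined, ordered list of UniProt accessions.
PEPTIDE_COLUMNS <- c(
  "sample_id", "sequence", "measured_mass", "theoretical_mass",
  "rt", "area", "xcorr", "confidence", "rank", "proteins"
)

CONFIDENCE_LEVELS <- c("high", "medium", "low")

# UniProt accession syntax (both 6- and 10-character forms).
UNIPROT_REGEX <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

is_uniprot_accession <- function(x) grepl(UNIPROT_REGEX, x)

# Print a double so that it survives a text round trip bit-exactly.
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

tsv_write <- function(df, path) {
  is_dbl <- vapply(df, is.double, logical(1))
  for (j in which(is_dbl)) df[[j]] <- format_double(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

tsv_read <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
}

#' Validate a peptide-record table
#'
#' Checks the invariants of the peptide-export dialect: positive masses and
#' retention times, non-negative areas (NA = identified but no area),
#' confidence in `high`/`medium`/`low`, rank >= 1, and non-empty UniProt
#' accession lists.
#'
#' @param records data frame of peptide records.
#' @return `records`, invisibly; errors describe the first violation.
#' @keywords internal
validate_peptide_records <- function(records) {
  missing_cols <- setdiff(PEPTIDE_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("peptide table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("invalid peptide record(s) at row %s: %s",
                   paste(utils::head(which(cond), 5L), collapse = ","), what),
           call. = FALSE)
    }
  }
  bad(!is.finite(records$measured_mass) | records$measured_mass <= 0,
      "measured_mass must be > 0")
  bad(!is.finite(records$theoretical_mass) | records$theoretical_mass <= 0,
      "theoretical_mass must be > 0")
  bad(!is.finite(records$rt) | records$rt <= 0, "rt must be > 0")
  bad(!is.na(records$area) & records$area < 0, "area must be non-negative")
  bad(!records$confidence %in% CONFIDENCE_LEVELS,
      "confidence must be one of high/medium/low")
  bad(is.na(records$rank) | records$rank < 1L, "rank must be >= 1")
  bad(is.na(records$proteins) | records$proteins == "",
      "proteins must be non-empty")
  accs <- unique(unlist(strsplit(records$proteins, ";", fixed = TRUE)))
  if (!all(is_uniprot_accession(accs))) {
    stop("invalid UniProt accession(s): ",
         paste(utils::head(accs[!is_uniprot_accession(accs)], 5L),
               collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Read a per-sample peptide export
#'
#' Reads one tab-separated peptide-level identification/quantification export
#' (one row per identified peptide feature). An empty `area` field maps to
#' `NA` (identified but no area retrieved by the search software), which the
#' quantification stage treats differently from a zero.
#'
#' @param path path to a TSV file with columns `sample_id`, `sequence`,
#'   `measured_mass`, `theoretical_mass`, `rt`, `area`, `xcorr`,
#'   `confidence`, `rank`, `proteins` (semicolon-joined accessions).
#' @param sample_id optional sample identifier overriding the file's
#'   `sample_id` column.
#' @return data frame of peptide records in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' recs <- data.frame(
#'   sample_id = "s1", sequence = "ELVISLIVESK",
#'   measured_mass = 1213.696, theoretical_mass = 1213.6979,
#'   rt = 101.5, area = 2.4e7, xcorr = 3.1,
#'   confidence = "high", rank = 1L, proteins = "P01023"
#' )
#' write_peptide_export(recs, f)
#' read_peptide_export(f)
read_peptide_export <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tsv_read(path)
  missing_cols <- setdiff(PEPTIDE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' is missing mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty peptide export: ", path, call. = FALSE)
    return(empty_peptide_records())
  }
  num <- function(col, allow_empty = FALSE) {
    x <- raw[[col]]
    val <- suppressWarnings(as.numeric(x))
    bad <- is.na(val) & !(allow_empty & x == "")
    if (any(bad)) {
      stop(sprintf("'%s': non-numeric %s at line %d", path, col,
                   which(bad)[1L] + 1L), call. = FALSE)
    }
    val
  }
  records <- data.frame(
    sample_id = if (is.null(sample_id)) raw$sample_id else sample_id,
    sequence = raw$sequence,
    measured_mass = num("measured_mass"),
    theoretical_mass = num("theoretical_mass"),
    rt = num("rt"),
    area = num("area", allow_empty = TRUE),
    xcorr = num("xcorr"),
    confidence = raw$confidence,
    rank = as.integer(num("rank")),
    proteins = raw$proteins,
    stringsAsFactors = FALSE
  )
  validate_peptide_records(records)
  records
}

empty_peptide_records <- function() {
  data.frame(
    sample_id = character(), sequence = character(),
    measured_mass = double(), theoretical_mass = double(),
    rt = double(), area = double(), xcorr = double(),
    confidence = character(), rank = integer(), proteins = character(),
    stringsAsFactors = FALSE
  )
}

#' Write a peptide export
#'
#' Inverse of [read_peptide_export()]; `NA` areas are written as empty
#' fields and doubles are printed with enough digits to round-trip exactly.
#'
#' @param records peptide-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_export <- function(records, path) {
  validate_peptide_records(records)
  tsv_write(records[, PEPTIDE_COLUMNS], path)
  invisible(path)
}

#' Filter peptide records by rank and identification confidence
#'
#' Applies the post-search export filters: peptide rank up to `max_rank` and
#' identification confidence within `allowed_confidence` (all three FDR
#' confidence strata are admitted by default). Relative record order is
#' preserved.
#'
#' @param records peptide-record data frame.
#' @param max_rank maximum peptide rank retained (default 5).
#' @param allowed_confidence character vector of admitted confidence levels.
#' @return the filtered data frame.
#' @export
filter_peptide_records <- function(records, max_rank = 5L,
                                   allowed_confidence = CONFIDENCE_LEVELS) {
  stopifnot(max_rank >= 1L, length(allowed_confidence) > 0L)
  keep <- records$rank <= max_rank & records$confidence %in% allowed_confidence
  records[keep, , drop = FALSE]
}

#' Read or validate a study design
#'
#' The study design assigns each sample to a group (`case`/`control`) and a
#' set (`discovery`/`test`) and flags exactly one discovery sample as the
#' retention-time calibration reference.
#'
#' @param path TSV with columns `sample_id`, `group`, `set`, `is_reference`.
#' @return data frame with one row per sample.
#' @export
read_study_design <- function(path) {
  raw <- tsv_read(path)
  design <- data.frame(
    sample_id = raw$sample_id,
    group = raw$group,
    set = raw$set,
    is_reference = raw$is_reference %in% c("TRUE", "true", "1"),
    stringsAsFactors = FALSE
  )
  validate_study_design(design)
  design
}

#' @rdname read_study_design
#' @param design study-design data frame to validate.
#' @export
validate_study_design <- function(design) {
  stopifnot(all(c("sample_id", "group", "set", "is_reference") %in%
                  names(design)))
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in study design", call. = FALSE)
  }
  if (!all(design$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(design$set %in% c("discovery", "test"))) {
    stop("set must be 'discovery' or 'test'", call. = FALSE)
  }
  n_ref <- sum(design$is_reference)
  if (n_ref != 1L) {
    stop("exactly one sample must be flagged is_reference (found ",
         n_ref, ")", call. = FALSE)
  }
  if (design$set[design$is_reference] != "discovery") {
    stop("the reference sample must belong to the discovery set",
         call. = FALSE)
  }
  invisible(design)
}

#' @rdname read_study_design
#' @export
write_study_design <- function(design, path) {
  validate_study_design(design)
  tsv_write(design, path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Maps UniProt accessions to protein names and gene symbols used to label
#' the cluster list and the differential-abundance table.
#'
#' @param path TSV with columns `accession`, `protein_name`, `gene_symbol`.
#' @return data frame with unique accessions.
#' @export
read_annotation_table <- function(path) {
  raw <- tsv_read(path)
  stopifnot(all(c("accession", "protein_name", "gene_symbol") %in% names(raw)))
  if (anyDuplicated(raw$accession)) {
    stop("duplicate accession in annotation table", call. = FALSE)
  }
  raw[, c("accession", "protein_name", "gene_symbol")]
}

#' Read a reported-concentration table
#'
#' External plasma-concentration catalogue (e.g. spectral-counting entries of
#' the Plasma Proteome Database) used for concordance analysis against the
#' pipeline's relative abundances.
#'
#' @param path TSV with columns `accession`, `concentration` (positive,
#'   arbitrary units).
#' @return data frame with columns `accession`, `concentration`.
#' @export
read_concentration_table <- function(path) {
  raw <- tsv_read(path)
  stopifnot(all(c("accession", "concentration") %in% names(raw)))
  out <- data.frame(
    accession = raw$accession,
    concentration = as.numeric(raw$concentration),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$concentration) | out$concentration <= 0)) {
    stop("all concentrations must be positive", call. = FALSE)
  }
  out
}

#' Read a sample manifest
#'
#' A manifest lists one peptide export per sample together with the study
#' design columns, and is the on-disk entry point of [run_pipeline()].
#'
#' @param path TSV with columns `sample_id`, `path`, `group`, `set`,
#'   `is_reference`. Relative `path`s are resolved against the manifest's
#'   directory.
#' @return list with elements `design` (study design) and `paths` (named
#'   character vector, sample_id -> export path).
#' @export
read_manifest <- function(path) {
  raw <- tsv_read(path)
  stopifnot(all(c("sample_id", "path", "group", "set", "is_reference") %in%
                  names(raw)))
  design <- data.frame(
    sample_id = raw$sample_id,
    group = raw$group,
    set = raw$set,
    is_reference = raw$is_reference %in% c("TRUE", "true", "1"),
    stringsAsFactors = FALSE
  )
  validate_study_design(design)
  paths <- raw$path
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  names(paths) <- raw$sample_id
  list(design = design, paths = paths)
}

#' Write and read the cluster list
#'
#' The cluster list is the study-wide table of harmonized cross-run features:
#' one row per retained cluster with its (mass, rt) center, member count and
#' members, plus — once annotated — the representative sequence and assigned
#' protein. Rows are sorted by `cluster_id`; members are encoded
#' `sample_id:row_index` and semicolon-joined.
#'
#' @param clusters cluster-list data frame (see [build_clusters()]).
#' @param path output path.
#' @return `path` invisibly; `read_cluster_list` returns the data frame.
#' @export
write_cluster_list <- function(clusters, path) {
  df <- clusters[order(clusters$cluster_id), , drop = FALSE]
  rownames(df) <- NULL
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_cluster_list
#' @export
read_cluster_list <- function(path) {
  raw <- tsv_read(path)
  for (col in c("center_mass", "center_rt")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  if ("member_count" %in% names(raw)) {
    raw$member_count <- as.integer(raw$member_count)
  }
  raw
}

#' Write and read an abundance matrix
#'
#' Peptide- or protein-level abundances, entities in rows and samples in
#' columns. The first column holds the entity identifier; a protein-level
#' matrix carries a `peptide_count` column after it. Rows are sorted by
#' entity identifier for a deterministic file.
#'
#' @param mat numeric matrix with entity rownames and sample colnames.
#' @param path output path.
#' @param id_name name of the identifier column (e.g. `accession`).
#' @param peptide_count optional named integer vector (protein level).
#' @return `path` invisibly; the reader returns a list with elements `matrix`
#'   and (if present) `peptide_count`.
#' @export
write_abundance_matrix <- function(mat, path, id_name = "entity_id",
                                   peptide_count = NULL) {
  rn <- rownames(mat)
  if (is.null(rn)) rn <- character(nrow(mat))
  ord <- order(rn)
  mat <- mat[ord, , drop = FALSE]
  rn <- rn[ord]
  df <- data.frame(id = rn, stringsAsFactors = FALSE)
  names(df) <- id_name
  if (!is.null(peptide_count)) {
    df$peptide_count <- as.integer(peptide_count[rn])
  }
  df <- cbind(df, as.data.frame(mat, optional = TRUE))
  rownames(df) <- NULL
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  raw <- tsv_read(path)
  id <- raw[[1L]]
  pc <- NULL
  start <- 2L
  if (names(raw)[2L] == "peptide_count") {
    pc <- as.integer(raw[[2L]])
    names(pc) <- id
    start <- 3L
  }
  if (ncol(raw) >= start) {
    mat <- as.matrix(raw[, start:ncol(raw), drop = FALSE])
    storage.mode(mat) <- "double"
  } else {
    mat <- matrix(numeric(), nrow = nrow(raw), ncol = 0L)
  }
  rownames(mat) <- id
  list(matrix = mat, peptide_count = pc)
}

#' Write and read the differential-abundance table
#'
#' One row per protein with set-wise peptide counts, case/control ratios and
#' Mann-Whitney p-values, plus the discovery/verification flags. Ratios of
#' `Inf` (detected only in cases) and `0` with zero case mean (only in
#' controls) are written as the labels `only_in_cases` / `only_in_controls`.
#' Rows are sorted by accession.
#'
#' @param de differential-abundance data frame (see [de_filter()]).
#' @param path output path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_de_table <- function(de, path) {
  df <- de[order(de$accession), , drop = FALSE]
  for (col in intersect(c("ratio_discovery", "ratio_test"), names(df))) {
    df[[col]] <- fold_label(df[[col]])
  }
  rownames(df) <- NULL
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  raw <- tsv_read(path)
  for (col in intersect(c("ratio_discovery", "ratio_test"), names(raw))) {
    raw[[col]] <- fold_unlabel(raw[[col]])
  }
  num_cols <- intersect(
    c("p_discovery", "p_test", "p_adjust_discovery"), names(raw))
  for (col in num_cols) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  int_cols <- intersect(c("peptides_discovery", "peptides_test"), names(raw))
  for (col in int_cols) raw[[col]] <- suppressWarnings(as.integer(raw[[col]]))
  for (col in intersect(c("is_de_discovery", "is_verified_test",
                          "is_significant_test"), names(raw))) {
    raw[[col]] <- raw[[col]] == "TRUE"
  }
  raw
}
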