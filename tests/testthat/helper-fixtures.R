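# Build a valid peptide-record data frame from defaults, overriding fields.
make_records <- function(n = 3L, ...) {
  out <- data.frame(
    sample_id = rep("s1", n),
    sequence = sprintf("PEPTIDEK%02d", seq_len(n)),
    measured_mass = 1000 + seq_len(n),
    theoretical_mass = 1000 + seq_len(n),
    rt = 100 + seq_len(n),
    area = 1e6 * seq_len(n),
    xcorr = rep(3, n),
    confidence = rep("high", n),
    rank = rep(1L, n),
    proteins = rep("P12345", n),
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

# Random valid records for predicate-scan oracles.
random_records <- function(n, seed) {
  set.seed(seed)
  make_records(
    n,
    sequence = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE),
                                  collapse = "")),
    measured_mass = runif(n, 600, 5000),
    theoretical_mass = runif(n, 600, 5000),
    rt = runif(n, 10, 400),
    area = ifelse(runif(n) < 0.1, NA_real_, rlnorm(n, 15, 1)),
    xcorr = runif(n, 0, 6),
    confidence = sample(c("high", "medium", "low"), n, TRUE),
    rank = sample(1:8, n, TRUE)
  )
}

# A tiny annotated study used by io/annotation tests.
toy_annotation <- function() {
  data.frame(
    accession = c("P12345", "Q67890", "P01023"),
    protein_name = c("Toy protein A", "Toy protein B",
                     "Alpha-2-macroglobulin"),
    gene_symbol = c("TOYA", "TOYB", "A2M"),
    stringsAsFactors = FALSE
  )
}

shortlist_path <- function() {
  system.file("extdata", "verified_shortlist.tsv",
              package = "plasmaquant", mustWork = TRUE)
}

read_shortlist <- function() {
  df <- read.delim(shortlist_path(), stringsAsFactors = FALSE)
  df$ratio_discovery <- plasmaquant::fold_unlabel(df$ratio_discovery)
  df$ratio_test <- plasmaquant::fold_unlabel(df$ratio_test)
  df
}
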