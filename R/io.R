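# Reader/writer for the SGoF p-value file format: a header line with the
# number of tests, then one `identifier p-value` pair per line.

#' Read a p-value file in the SGoF program format
#'
#' The file starts with an integer giving the total number of tests, followed
#' by that many lines each holding an identifier (number or string) and a
#' p-value, separated by whitespace. The list need not be sorted; input order
#' is preserved. Empty lines and lines starting with `#` are skipped and not
#' counted.
#'
#' @param path Path to the input file.
#' @param lenient If `TRUE`, rows with more than two fields are accepted and
#'   only the first two are used; the default strict mode rejects them.
#' @return A [pvalue_set()].
#' @export
read_pvalue_file <- function(path, lenient = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (!length(lines)) stop(sprintf("'%s' is empty", path), call. = FALSE)
  declared <- suppressWarnings(as.integer(lines[1]))
  if (is.na(declared) || declared < 0) {
    stop(sprintf("line %d: expected a non-negative integer test count, got '%s'",
                 lineno[1], lines[1]), call. = FALSE)
  }
  rows <- lines[-1]
  if (length(rows) != declared) {
    stop(sprintf("header declares %d tests but the file has %d data rows",
                 declared, length(rows)), call. = FALSE)
  }
  ids <- character(declared)
  pv <- numeric(declared)
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], "\\s+")[[1]]
    ln <- lineno[i + 1L]
    if (length(fields) < 2 || (!lenient && length(fields) != 2)) {
      stop(sprintf("line %d: expected 2 whitespace-separated fields, found %d%s",
                   ln, length(fields),
                   if (length(fields) > 2) " (use lenient mode to ignore extras)" else ""),
           call. = FALSE)
    }
    p <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(p)) {
      stop(sprintf("line %d: cannot parse p-value '%s'", ln, fields[2]),
           call. = FALSE)
    }
    if (p < 0 || p > 1) {
      stop(sprintf("line %d: p-value %s outside [0, 1]", ln, fields[2]),
           call. = FALSE)
    }
    ids[i] <- fields[1]
    pv[i] <- p
  }
  pvalue_set(pv, ids = ids)
}

#' Write a p-value set in the SGoF program format
#'
#' P-values are serialized with 15 significant digits so a read/write
#' round-trip is lossless at double precision.
#'
#' @param pset A [pvalue_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pvalue_file <- function(pset, path) {
  pset <- .as_pvalue_set(pset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(pset$S),
               sprintf("%s %.15g", pset$ids, pset$pvalues)), con)
  invisible(path)
}

#' Write a synthetic mixture fixture file
#'
#' Generates one trial of mixture p-values with [generate_pvalues()] under
#' the given seed and writes it in the SGoF input format, plus a sidecar
#' `<path>.truth.tsv` with the ground-truth labels (columns `id`, `truth`).
#'
#' @param path Output file path for the p-value file.
#' @param S Number of tests.
#' @param effect_proportion Fraction of genuine effects.
#' @param w Standardized effect size.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(path, S, effect_proportion, w, seed) {
  set.seed(seed)
  pset <- generate_pvalues(S, effect_proportion, w)
  write_pvalue_file(pset, path)
  truth_path <- paste0(path, ".truth.tsv")
  utils::write.table(
    data.frame(id = pset$ids, truth = pset$truth),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
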