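#' Read a taxon-by-sample count table
#'
#' Reads a tab-separated count table whose first column holds taxon
#' identifiers and whose header row holds sample identifiers. The contract is
#' strict: counts must be non-negative integers, identifiers unique, and every
#' row must have the same number of fields.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `taxon_id` column followed by one integer column
#'   per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon_id\tS1\tS2", "t1\t3\t0", "t2\t1\t5"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("count table must have a header and at least one taxon row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    abort(sprintf("ragged row at line %d: expected %d fields, found %d",
                  ragged[1], width, lengths(fields)[ragged[1]]))
  }
  header <- fields[[1]]
  sample_ids <- header[-1]
  body <- fields[-1]
  taxon_ids <- vapply(body, `[[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(sample_ids)))
  )
  m <- if (is.null(dim(vals))) matrix(vals, nrow = 1) else t(vals)
  if (any(is.na(m))) abort("count table contains non-numeric cells")
  colnames(m) <- sample_ids
  rownames(m) <- taxon_ids
  ct <- matrix_to_ct(m)
  validate_count_table(ct)
  ct[-1] <- lapply(ct[-1], as.integer)
  ct
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; the round trip is lossless for integer
#' counts.
#'
#' @param ct Count tibble (`taxon_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  validate_count_table(ct)
  readr::write_tsv(ct, path)
  invisible(path)
}

#' Read sample metadata
#'
#' One row per sample with at least a `sample_id` column; remaining columns
#' (treatment, cultivar, growth_stage, field_block, ...) are kept as character.
#'
#' @param path Path to a TSV file with a header.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"sample_id" %in% names(md)) abort("metadata must have a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) {
    abort(sprintf("duplicate sample identifier(s) in metadata: %s",
                  paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", ")))
  }
  md
}

#' Read a long phenotype table
#'
#' Expects columns `sample_id`, `phenotype`, `value` with one finite value per
#' (sample, phenotype) pair; missing cells are rejected.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `phenotype`, `value`.
#' @export
read_phenotype_table <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    phenotype = readr::col_character(),
    value = readr::col_double()
  ), progress = FALSE)
  validate_phenotype_table(ph)
  ph
}

validate_phenotype_table <- function(ph) {
  need <- c("sample_id", "phenotype", "value")
  if (!all(need %in% names(ph))) {
    abort("phenotype table needs columns sample_id, phenotype, value")
  }
  if (any(!is.finite(ph$value))) abort("phenotype values must be finite (no missing cells)")
  key <- paste(ph$sample_id, ph$phenotype, sep = "\r")
  if (anyDuplicated(key)) abort("duplicate (sample, phenotype) pair in phenotype table")
  invisible(ph)
}

#' Align count, metadata and phenotype tables on shared samples
#'
#' Restricts all tables to the intersection of their sample identifiers and
#' puts every table in the canonical (lexicographic) sample order, so that
#' downstream matrices are deterministic regardless of input ordering. Dropped
#' samples are reported with a message.
#'
#' @param ct Count tibble.
#' @param md Sample metadata tibble.
#' @param ph Optional long phenotype tibble.
#' @return A list with elements `counts`, `metadata` and (when supplied)
#'   `phenotypes`, plus `dropped`, the identifiers removed from any table.
#' @export
align_tables <- function(ct, md, ph = NULL) {
  validate_count_table(ct, integer_counts = FALSE)
  ids <- list(counts = ct_samples(ct), metadata = md$sample_id)
  if (!is.null(ph)) ids$phenotypes <- unique(ph$sample_id)
  shared <- sort(Reduce(intersect, ids))
  if (length(shared) == 0) abort("no shared sample identifiers across tables")
  dropped <- sort(setdiff(unique(unlist(ids)), shared))
  if (length(dropped)) {
    inform(sprintf("align_tables: dropping %d sample(s) absent from some table: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- list(
    counts = ct[c("taxon_id", shared)],
    metadata = md[match(shared, md$sample_id), ],
    dropped = dropped
  )
  if (!is.null(ph)) {
    out$phenotypes <- ph %>%
      filter(.data$sample_id %in% shared) %>%
      arrange(.data$sample_id, .data$phenotype)
  }
  out[c("counts", "metadata", if (!is.null(ph)) "phenotypes", "dropped")]
}
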