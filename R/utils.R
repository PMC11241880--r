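# Internal helpers shared across modules.

# Convert a count/abundance tibble (taxon_id + one column per sample) to a
# numeric matrix with taxa as rows, columns in the tibble's column order.
ct_matrix <- function(ct) {
  stopifnot(is.data.frame(ct), "taxon_id" %in% names(ct))
  m <- as.matrix(ct[setdiff(names(ct), "taxon_id")])
  mode(m) <- "double"
  rownames(m) <- ct$taxon_id
  m
}

ct_samples <- function(ct) setdiff(names(ct), "taxon_id")

matrix_to_ct <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(taxon_id = rownames(m)), out)
}

# Validate the count-table contract: unique ids, finite non-negative entries,
# integer counts when `integer_counts` is TRUE.
validate_count_table <- function(ct, integer_counts = TRUE, call_name = "count table") {
  if (!is.data.frame(ct) || !"taxon_id" %in% names(ct)) {
    abort(sprintf("%s must be a data frame with a 'taxon_id' column", call_name))
  }
  if (anyDuplicated(ct$taxon_id)) {
    dup <- unique(ct$taxon_id[duplicated(ct$taxon_id)])
    abort(sprintf("duplicate taxon identifier(s): %s", paste(dup, collapse = ", ")))
  }
  smp <- ct_samples(ct)
  if (anyDuplicated(smp)) {
    dup <- unique(smp[duplicated(smp)])
    abort(sprintf("duplicate sample identifier(s): %s", paste(dup, collapse = ", ")))
  }
  m <- ct_matrix(ct)
  if (any(!is.finite(m))) abort(sprintf("%s contains non-finite values", call_name))
  if (any(m < 0)) abort(sprintf("%s contains negative values", call_name))
  if (integer_counts && any(m != floor(m))) {
    abort(sprintf("%s contains non-integer counts", call_name))
  }
  invisible(ct)
}

# Seeded evaluation that never clobbers the caller's RNG state.
with_seed <- function(seed, code) withr::with_seed(seed, code)

# Canonical pair ordering: i < j lexicographically.
order_pair <- function(a, b) {
  swap <- a > b
  tibble(i = ifelse(swap, b, a), j = ifelse(swap, a, b))
}
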