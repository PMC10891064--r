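#' @importFrom rlang .data := %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# A "sample table" is the package-wide tabular convention: a tibble whose
# first column is `sample_id` and whose remaining columns are features,
# one row per sample. These helpers move between that shape and a plain
# numeric matrix with sample_id rownames.
as_sample_matrix <- function(tbl, id_col = "sample_id") {
  if (!id_col %in% names(tbl)) {
    cli::cli_abort("Column {.field {id_col}} is required but missing.")
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) {
    cli::cli_abort("All feature columns must be numeric.")
  }
  rownames(m) <- as.character(tbl[[id_col]])
  m
}

as_sample_tbl <- function(m, id_col = "sample_id") {
  tibble::as_tibble(m, rownames = id_col)
}

feature_ids <- function(tbl, id_col = "sample_id") {
  setdiff(names(tbl), id_col)
}

check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    cli::cli_abort("Duplicate {what}: {.val {utils::head(dup, 5)}}.")
  }
  invisible(x)
}

# seeds: never clobber the caller's RNG state
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

treatment_levels <- function() c("Control", "-N", "-P", "-K")
compartment_levels <- function() c("bulk", "rhizosphere", "endosphere")

check_metadata <- function(metadata, call = rlang::caller_env()) {
  required <- c("sample_id", "treatment", "compartment", "stage_day",
                "replicate_id", "sample_mass_g")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    cli::cli_abort("Metadata is missing column{?s} {.field {missing}}.",
                   call = call)
  }
  bad_trt <- setdiff(unique(metadata$treatment), treatment_levels())
  if (length(bad_trt) > 0) {
    cli::cli_abort(
      "Unknown treatment label: {.val {bad_trt}} (allowed: Control, -N, -P, -K).",
      call = call)
  }
  bad_cmp <- setdiff(unique(metadata$compartment), compartment_levels())
  if (length(bad_cmp) > 0) {
    cli::cli_abort(
      "Unknown compartment label: {.val {bad_cmp}} (allowed: bulk, rhizosphere, endosphere).",
      call = call)
  }
  if (any(metadata$sample_mass_g <= 0)) {
    cli::cli_abort("{.field sample_mass_g} must be > 0 for every sample.",
                   call = call)
  }
  if (any(metadata$stage_day < 0)) {
    cli::cli_abort("{.field stage_day} must be >= 0.", call = call)
  }
  check_unique(metadata$sample_id, "sample IDs")
  key <- paste(metadata$treatment, metadata$compartment,
               metadata$stage_day, metadata$replicate_id)
  check_unique(key, "(treatment, compartment, stage_day, replicate_id) keys")
  invisible(metadata)
}

check_sequences <- function(seqs, what = "sequence", call = rlang::caller_env()) {
  if (length(seqs) == 0) {
    cli::cli_abort("No {what}s supplied.", call = call)
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    cli::cli_abort("Empty {what} at position{?s} {empty}.", call = call)
  }
  bad <- grepl("[^ACGTN]", toupper(seqs))
  if (any(bad)) {
    cli::cli_abort(
      "{what} {which(bad)[1]} contains characters outside A/C/G/T/N.",
      call = call)
  }
  invisible(toupper(seqs))
}
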