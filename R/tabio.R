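# Readers and writers for the tabular and sequence formats the pipeline
# touches. On disk, feature tables follow the community convention of
# features as rows and samples as columns (QIIME-style); in memory every
# function in the package works with samples as rows. The transpose
# happens here and only here.

#' Read a feature count table
#'
#' Reads a tab-separated feature table with features as rows and samples as
#' columns (first column = feature ID), validates it, and returns it in the
#' package's internal orientation: one row per sample, one column per
#' feature, first column `sample_id`. Lines starting with `#` are treated
#' as comments.
#'
#' @param path Path to a TSV file.
#' @param spike_ids Character vector of feature IDs that are spike-in
#'   standards rather than biological features. Stored on the result as the
#'   `"spike_ids"` attribute (see [spike_ids()]).
#' @return A tibble of non-negative integer counts, samples in rows.
#' @export
read_feature_table <- function(path, spike_ids = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (ncol(raw) < 2) {
    cli::cli_abort("Feature table must have a feature-ID column and at least one sample column.")
  }
  fids <- as.character(raw[[1]])
  check_unique(fids, "feature IDs")
  check_unique(names(raw)[-1], "sample IDs")
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    cli::cli_abort("Sample column {.val {names(raw)[-1][bad]}} is not numeric.")
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cli::cli_abort(paste0(
      "Counts must be non-negative integers; offending cell: feature ",
      "{.val {fids[bad[1, 1]]}}, sample {.val {colnames(m)[bad[1, 2]]}} ",
      "(value {m[bad[1, , drop = FALSE]]})."))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- fids
  out <- as_sample_tbl(t(m))
  spike_ids <- as.character(spike_ids %||% character(0))
  unknown <- setdiff(spike_ids, fids)
  if (length(unknown) > 0) {
    cli::cli_abort("spike_ids not present in the table: {.val {unknown}}.")
  }
  attr(out, "spike_ids") <- spike_ids
  out
}

#' @rdname read_feature_table
#' @param table A sample-by-feature count tibble.
#' @export
spike_ids <- function(table) {
  as.character(attr(table, "spike_ids") %||% character(0))
}

#' Write a feature count table
#'
#' Writes in the on-disk orientation (features as rows) with a leading
#' comment line recording the package version, so the file round-trips
#' through [read_feature_table()].
#'
#' @inheritParams spike_ids
#' @param path Output TSV path.
#' @export
write_feature_table <- function(table, path) {
  m <- t(as_sample_matrix(table))
  out <- tibble::as_tibble(m, rownames = "feature_id")
  write_with_header(out, path)
  invisible(path)
}

write_with_header <- function(tbl, path) {
  ver <- as.character(utils::packageVersion("rhizoqmp"))
  readr::write_lines(paste0("# rhizoqmp v", ver), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `treatment` (Control/-N/-P/-K),
#' `compartment` (bulk/rhizosphere/endosphere), `stage_day` (days post
#' germination), `replicate_id` and `sample_mass_g` (fresh mass in grams).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_metadata(md)
  md
}

#' Write sample metadata
#' @param metadata A metadata tibble (see [read_metadata()]).
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  check_metadata(metadata)
  write_with_header(metadata, path)
  invisible(path)
}

#' Read a spike-in design table
#'
#' A spike design lists the synthetic standards mixed into every sample
#' before PCR: columns `spike_id` and `copies_added` (16S copies of that
#' spike added per sample).
#'
#' @param path Path to a TSV file.
#' @export
read_spike_design <- function(path) {
  sd <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_spike_design(sd)
  sd
}

check_spike_design <- function(spikes, call = rlang::caller_env()) {
  missing <- setdiff(c("spike_id", "copies_added"), names(spikes))
  if (length(missing) > 0) {
    cli::cli_abort("Spike design is missing column{?s} {.field {missing}}.",
                   call = call)
  }
  if (any(spikes$copies_added <= 0)) {
    cli::cli_abort("{.field copies_added} must be > 0 for every spike.",
                   call = call)
  }
  check_unique(spikes$spike_id, "spike IDs")
  invisible(spikes)
}

#' @rdname read_spike_design
#' @param spikes A spike design tibble.
#' @export
write_spike_design <- function(spikes, path) {
  check_spike_design(spikes)
  write_with_header(spikes, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Columns `feature_id` plus the ranks `kingdom`, `phylum`, `class`,
#' `order`, `family`, `genus`. Missing ranks are encoded as empty strings
#' and treated as unassigned.
#'
#' @param path Path to a TSV file.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("feature_id", "kingdom", "phylum", "class", "order",
                "family", "genus")
  missing <- setdiff(required, names(tax))
  if (length(missing) > 0) {
    cli::cli_abort("Taxonomy is missing column{?s} {.field {missing}}.")
  }
  check_unique(tax$feature_id, "feature IDs")
  dplyr::mutate(tax, dplyr::across(-"feature_id", ~ tidyr::replace_na(.x, "")))
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_with_header(taxonomy, path)
  invisible(path)
}

#' Read a FASTA file of nucleotide sequences
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (header up to first whitespace ->
#'   uppercased sequence). Sequences must be non-empty and drawn from
#'   A/C/G/T/N.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  check_sequences(seqs)
  check_unique(names(seqs), "sequence names")
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  check_sequences(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes a GraphML file plus an edge-list TSV (columns `from`, `to`,
#' `rho`, `q`) and a node-attribute TSV (module, degree, Zi, Pi, role).
#'
#' @param net A `co_network` object (see [build_network()]).
#' @param dir Output directory, created if needed.
#' @param name Basename for the three files.
#' @export
write_network <- function(net, dir, name = "network") {
  stopifnot(inherits(net, "co_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  roles <- node_roles(net)
  g <- net$graph
  idx <- match(igraph::V(g)$name, roles$node)
  for (a in c("module", "degree", "Zi", "Pi", "role")) {
    g <- igraph::set_vertex_attr(g, a, value = roles[[a]][idx])
  }
  igraph::write_graph(g, file.path(dir, paste0(name, ".graphml")),
                      format = "graphml")
  write_with_header(net$edges, file.path(dir, paste0(name, "_edges.tsv")))
  write_with_header(roles, file.path(dir, paste0(name, "_nodes.tsv")))
  invisible(dir)
}
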