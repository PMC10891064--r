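# From raw counts to quantitative (QMP) and relative (RMP) profiles.
# QMP converts reads to 16S copies per gram of fresh sample via the
# spike-in ratio; RMP is the conventional proportional profile after
# rarefaction.

#' Apply the taxonomic feature filters
#'
#' Removes non-bacterial features (kingdom other than Bacteria, which
#' covers chloroplast/host reads and unassigned kingdoms) from all
#' samples, and zeroes Bradyrhizobiaceae-affiliated features in root
#' endosphere samples only — the abundant nodule symbiont would otherwise
#' distort endosphere diversity estimates. Rhizosphere and bulk samples
#' keep their Bradyrhizobiaceae counts. Spike features are never touched.
#'
#' @param table Counts tibble (samples x features) with spike IDs in its
#'   `"spike_ids"` attribute.
#' @param taxonomy Taxonomy tibble covering every biological feature.
#' @param metadata Sample metadata (for compartment labels).
#' @return The filtered counts tibble; features left with zero counts in
#'   every sample are dropped.
#' @export
filter_features <- function(table, taxonomy, metadata) {
  check_metadata(metadata)
  sp <- spike_ids(table)
  bio <- setdiff(feature_ids(table), sp)
  missing <- setdiff(bio, taxonomy$feature_id)
  if (length(missing) > 0) {
    cli::cli_abort("Taxonomy does not cover feature{?s} {.val {utils::head(missing, 5)}}.")
  }
  tax <- taxonomy[match(bio, taxonomy$feature_id), ]
  bacterial <- tax$kingdom == "Bacteria"
  keep <- bio[bacterial]
  m <- as_sample_matrix(table[c("sample_id", keep, sp)])

  brady <- intersect(keep, tax$feature_id[tax$family == "Bradyrhizobiaceae"])
  endo <- metadata$sample_id[metadata$compartment == "endosphere"]
  endo <- intersect(endo, rownames(m))
  if (length(brady) > 0 && length(endo) > 0) {
    m[endo, brady] <- 0L
  }
  # drop biological features that are now all-zero
  dead <- keep[colSums(m[, keep, drop = FALSE]) == 0]
  m <- m[, setdiff(colnames(m), dead), drop = FALSE]
  out <- as_sample_tbl(m)
  attr(out, "spike_ids") <- sp
  out
}

#' Spike-calibrated absolute abundance (QMP)
#'
#' Converts read counts to 16S copies per gram of fresh sample. For
#' sample *j* with taxon reads `c_ij`, summed spike reads `s_j`, summed
#' spike copies added `S` and mass `m_j`:
#' `A_ij = c_ij * (S / s_j) / m_j`.
#' The spike ratio pools all spikes (robust to single-spike dropout);
#' per-spike recovery ratios are reported as diagnostics and a warning is
#' raised when their coefficient of variation exceeds `cv_warn`.
#'
#' @param table Counts tibble including spike features (in the
#'   `"spike_ids"` attribute or listed in `spikes`).
#' @param spikes Spike design tibble (`spike_id`, `copies_added`).
#' @param metadata Sample metadata carrying `sample_mass_g`.
#' @param cv_warn Warn when the per-spike copies/reads ratio CV within a
#'   sample exceeds this value.
#' @return A tibble of absolute abundances (samples x biological
#'   features, copies per gram) with attributes `size_factors` (tibble of
#'   per-sample factors) and `spike_diagnostics` (see
#'   [spike_diagnostics()]). Samples with zero spike reads are excluded
#'   with a warning.
#' @export
absolute_abundance <- function(table, spikes, metadata, cv_warn = 0.5) {
  check_spike_design(spikes)
  check_metadata(metadata)
  sp <- union(spike_ids(table), spikes$spike_id)
  missing <- setdiff(spikes$spike_id, feature_ids(table))
  if (length(missing) > 0) {
    cli::cli_abort("Spike feature{?s} {.val {missing}} absent from the table.")
  }
  m <- as_sample_matrix(table)
  bio <- setdiff(colnames(m), sp)
  smat <- m[, spikes$spike_id, drop = FALSE]
  s_tot <- rowSums(smat)
  S_tot <- sum(spikes$copies_added)
  mass <- metadata$sample_mass_g[match(rownames(m), metadata$sample_id)]
  if (anyNA(mass)) {
    bad <- rownames(m)[is.na(mass)]
    cli::cli_abort("No metadata for sample{?s} {.val {bad}}.")
  }

  ok <- s_tot > 0
  if (any(!ok)) {
    cli::cli_warn("Excluding sample(s) with zero spike reads: {.val {rownames(m)[!ok]}}.")
  }
  factor <- S_tot / s_tot[ok]
  A <- m[ok, bio, drop = FALSE] * factor / mass[ok]

  diag <- tibble::as_tibble(smat[ok, , drop = FALSE], rownames = "sample_id")
  diag <- tidyr::pivot_longer(diag, -"sample_id", names_to = "spike_id",
                              values_to = "reads")
  diag <- dplyr::left_join(diag, spikes, by = "spike_id")
  diag <- dplyr::mutate(diag,
                        copies_per_read = ifelse(.data$reads > 0,
                                                 .data$copies_added / .data$reads,
                                                 NA_real_))
  cv <- dplyr::summarise(
    dplyr::group_by(diag, .data$sample_id),
    cv = stats::sd(.data$copies_per_read, na.rm = TRUE) /
      mean(.data$copies_per_read, na.rm = TRUE), .groups = "drop")
  high <- cv$sample_id[!is.na(cv$cv) & cv$cv > cv_warn]
  if (length(high) > 0) {
    cli::cli_warn("Per-spike recovery CV above {cv_warn} in {length(high)} sample(s).")
  }

  out <- as_sample_tbl(A)
  attr(out, "size_factors") <- tibble::tibble(
    sample_id = rownames(m)[ok], spike_reads = unname(s_tot[ok]),
    spike_copies = S_tot, size_factor = unname(factor),
    sample_mass_g = mass[ok])
  attr(out, "spike_diagnostics") <- dplyr::left_join(diag, cv, by = "sample_id")
  out
}

#' @rdname absolute_abundance
#' @param profile Result of [absolute_abundance()].
#' @export
spike_diagnostics <- function(profile) {
  attr(profile, "spike_diagnostics")
}

#' @rdname absolute_abundance
#' @export
size_factors <- function(profile) {
  attr(profile, "size_factors")
}

#' Rarefy counts to a fixed depth
#'
#' Subsamples each sample's biological reads without replacement to
#' exactly `depth` reads (a single draw per sample). Samples with fewer
#' biological reads than `depth` are dropped and reported. Spike features
#' are removed before rarefaction — rarefied tables feed relative
#' profiling only.
#'
#' @param table Counts tibble.
#' @param depth Target depth (default 1030 reads per sample).
#' @param seed Integer seed for the subsampling draw.
#' @return Rarefied counts tibble whose row sums all equal `depth`.
#' @export
rarefy <- function(table, depth = 1030, seed = NULL) {
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    cli::cli_abort("{.field depth} must be a positive integer.")
  }
  bio <- setdiff(feature_ids(table), spike_ids(table))
  m <- as_sample_matrix(table[c("sample_id", bio)])
  totals <- rowSums(m)
  keep <- totals >= depth
  if (any(!keep)) {
    cli::cli_warn("Dropping sample(s) below depth {depth}: {.val {rownames(m)[!keep]}}.")
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) cli::cli_abort("No sample reaches depth {depth}.")
  with_seed_if(seed, {
    # rrarefy warns whenever the smallest nonzero count exceeds 1, which
    # is routine for filtered tables; silence that specific message
    r <- withCallingHandlers(
      vegan::rrarefy(m, depth),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  storage.mode(r) <- "integer"
  as_sample_tbl(r)
}

#' Relative abundance (RMP denominator)
#'
#' Divides each sample's biological counts by its total, so rows sum to 1.
#'
#' @param table Counts tibble.
#' @return Tibble of proportions over biological features.
#' @export
relative_abundance <- function(table) {
  bio <- setdiff(feature_ids(table), spike_ids(table))
  m <- as_sample_matrix(table[c("sample_id", bio)])
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    bad <- rownames(m)[totals <= 0]
    cli::cli_abort("All-zero sample{?s}: {.val {bad}}.")
  }
  as_sample_tbl(m / totals)
}
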