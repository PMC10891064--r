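# From ecological clusters to synthetic communities: cumulative module
# loads per sample, module-level treatment tests (Kruskal-Wallis + Dunn
# vs the Control), matching network ASVs to cultured isolates by 16S
# identity, and the composition rules (best strain per ASV, one strain
# per genus, excluded families removed).

#' Cumulative module abundance per sample
#'
#' Sums member-feature absolute abundances per sample for every module.
#'
#' @param quant Absolute-abundance tibble.
#' @param modules Tibble (`feature_id`, `module`) as returned by
#'   [module_membership()]; features absent from the profile trigger an
#'   error if a module loses all its members.
#' @param metadata Sample metadata (joined onto the result).
#' @return Long tibble (`sample_id`, `treatment`, `compartment`,
#'   `stage_day`, `module`, `abundance`).
#' @export
module_abundance <- function(quant, modules, metadata) {
  check_metadata(metadata)
  m <- as_sample_matrix(quant)
  out <- purrr::map_dfr(split(modules$feature_id, modules$module),
    .id = "module", function(feats) {
      present <- intersect(feats, colnames(m))
      if (length(present) == 0) {
        cli::cli_abort("No member of a module is present in the profile.")
      }
      tibble::tibble(sample_id = rownames(m),
                     abundance = unname(rowSums(m[, present, drop = FALSE])))
    })
  dplyr::inner_join(
    out,
    dplyr::select(metadata, "sample_id", "treatment", "compartment", "stage_day"),
    by = "sample_id") |>
    dplyr::select("sample_id", "treatment", "compartment", "stage_day",
                  "module", "abundance")
}

#' Per-(treatment, stage) mean module abundance
#'
#' @param mod_abund Result of [module_abundance()].
#' @return Tibble (`module`, `treatment`, `stage_day`, `mean_abundance`).
#' @export
module_stage_means <- function(mod_abund) {
  dplyr::summarise(
    dplyr::group_by(mod_abund, .data$module, .data$treatment, .data$stage_day),
    mean_abundance = mean(.data$abundance), .groups = "drop")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's z-tests of each group against `reference` (or all pairs when
#' `reference` is `NULL`), with BH-FDR adjustment across the comparisons.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, each >= 2
#'   values).
#' @param reference Reference group for the pairwise comparisons.
#' @return List with `H`, `df`, `p_overall` and `comparisons` (tibble
#'   `group_a`, `group_b`, `z`, `p`, `q`).
#' @export
kruskal_dunn <- function(values, groups, reference = NULL) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) cli::cli_abort("Need >= 2 groups.")
  if (any(sizes < 2)) {
    cli::cli_abort("Every group needs >= 2 values; offending: {.val {names(sizes)[sizes < 2]}}.")
  }
  if (!is.null(reference) && !reference %in% names(sizes)) {
    cli::cli_abort("Reference group {.val {reference}} not found.")
  }
  n <- length(values)
  r <- rank(values)
  if (stats::sd(values) == 0) {
    kw <- list(H = 0, df = length(sizes) - 1, p_overall = 1)
  } else {
    ties <- table(r)
    tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    rbar <- tapply(r, groups, mean)
    h <- (12 / (n * (n + 1))) * sum(sizes * (rbar[names(sizes)] - (n + 1) / 2)^2)
    h <- h / tie_corr
    kw <- list(H = unname(h), df = length(sizes) - 1,
               p_overall = stats::pchisq(h, length(sizes) - 1,
                                         lower.tail = FALSE))
  }
  pairs <- if (is.null(reference)) {
    utils::combn(names(sizes), 2, simplify = FALSE)
  } else {
    lapply(setdiff(names(sizes), reference), function(g) c(g, reference))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  comp <- purrr::map_dfr(pairs, function(pr) {
    se2 <- (n * (n + 1) / 12 - tie_term) *
      (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]])
    z <- if (se2 <= 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / sqrt(se2)
    tibble::tibble(group_a = pr[1], group_b = pr[2], z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  comp$q <- bh_fdr(comp$p)
  c(kw, list(comparisons = comp))
}

#' Module enrichment calls per treatment
#'
#' A module counts as enriched in a treatment when Dunn's comparison of
#' its per-(treatment, stage) mean abundances against the control is
#' significant after FDR (`q < alpha`) and the stage-mean ratio exceeds
#' 1; depleted likewise with ratio < 1.
#'
#' @param mod_abund Result of [module_abundance()].
#' @param control Reference treatment.
#' @param alpha Significance threshold on the adjusted Dunn p.
#' @return Tibble (`module`, `treatment`, `ratio`, `z`, `p`, `q`,
#'   `status`).
#' @export
module_enrichment <- function(mod_abund, control = "Control", alpha = 0.05) {
  means <- module_stage_means(mod_abund)
  purrr::map_dfr(split(means, means$module), .id = "module", function(df) {
    kd <- kruskal_dunn(df$mean_abundance, df$treatment, reference = control)
    ctrl_mean <- mean(df$mean_abundance[df$treatment == control])
    comp <- dplyr::filter(kd$comparisons, .data$group_b == control)
    dplyr::transmute(
      comp, treatment = .data$group_a,
      ratio = vapply(.data$group_a, function(t) {
        mean(df$mean_abundance[df$treatment == t]) / ctrl_mean
      }, numeric(1)),
      z = .data$z, p = .data$p, q = .data$q,
      status = dplyr::case_when(
        .data$q < alpha & ratio > 1 ~ "enriched",
        .data$q < alpha & ratio < 1 ~ "depleted",
        TRUE ~ "ns"))
  })
}

#' Percent identity between two nucleotide sequences
#'
#' Semi-global (end-gap-free) pairwise alignment with match +2, mismatch
#' -1, affine gaps (open 2, extend 0.5, subtracted), via
#' `Biostrings::pairwiseAlignment(type = "overlap")`. Identity is the
#' share of exactly matching columns among aligned columns, terminal gaps
#' excluded, in percent.
#'
#' @param seq_a,seq_b Nucleotide strings over A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 2, mismatch = -1,
                              gap_open = 2, gap_ext = 0.5) {
  seq_a <- check_sequences(seq_a)
  seq_b <- check_sequences(seq_b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  if (length(a) == 0) return(0)
  100 * sum(a == b & a != "-") / length(a)
}

#' Match network ASVs to cultured isolates
#'
#' Computes pairwise identities of every ASV against every isolate and
#' keeps, per ASV, the best-identity strain when it exceeds
#' `min_identity` (strictly). Ties are broken by lexicographic strain ID.
#'
#' @param asv_seqs Named character vector of ASV sequences.
#' @param isolates Tibble with `strain_id`, `sequence` and optionally
#'   `genus`.
#' @param min_identity Identity threshold in percent (strict).
#' @return Tibble (`feature_id`, `strain_id`, `identity`, `matched`);
#'   unmatched ASVs keep their best candidate with `matched = FALSE`.
#' @export
match_isolates <- function(asv_seqs, isolates, min_identity = 95) {
  check_sequences(asv_seqs, "ASV sequence")
  stopifnot(all(c("strain_id", "sequence") %in% names(isolates)))
  purrr::map_dfr(names(asv_seqs), function(asv) {
    ident <- vapply(isolates$sequence, function(s) {
      pairwise_identity(asv_seqs[[asv]], s)
    }, numeric(1), USE.NAMES = FALSE)
    ord <- order(-ident, isolates$strain_id)
    best <- ord[1]
    tibble::tibble(feature_id = asv, strain_id = isolates$strain_id[best],
                   identity = ident[best],
                   matched = ident[best] > min_identity)
  })
}

#' Design a synthetic community from a module
#'
#' Applies the composition rules: members come from the matched ASVs of
#' one module; strains whose ASV is affiliated with an excluded family
#' (default Bradyrhizobiaceae, to avoid nodulation effects) are removed;
#' one strain is kept per genus (the highest-identity one, ties by strain
#' ID); optionally the plan is capped at `max_members` by descending
#' identity.
#'
#' @param module_features Character vector of the module's feature IDs.
#' @param matches Result of [match_isolates()].
#' @param taxonomy Taxonomy tibble (genus/family of each feature).
#' @param isolates Isolate tibble (used for fallback genus labels).
#' @param exclude_families Families removed from the plan.
#' @param max_members Optional cap on plan size.
#' @param name Plan name.
#' @param source_module Label recorded as the plan's source module.
#' @return A `syncom_plan`: list with `name`, `source_module`, `members`
#'   (tibble `strain_id`, `genus`, `matched_asv`, `identity`),
#'   `exclusions` (tibble of removed candidates with reasons).
#' @export
design_syncom <- function(module_features, matches, taxonomy, isolates = NULL,
                          exclude_families = "Bradyrhizobiaceae",
                          max_members = NULL, name = "SynCom",
                          source_module = NA_character_) {
  cand <- dplyr::filter(matches, .data$feature_id %in% module_features,
                        .data$matched)
  empty_members <- tibble::tibble(strain_id = character(0),
                                  genus = character(0),
                                  matched_asv = character(0),
                                  identity = numeric(0))
  if (nrow(cand) == 0) {
    cli::cli_warn("No matched isolate for this module; returning an empty plan.")
    return(new_syncom_plan(name, source_module, empty_members,
                           dplyr::mutate(empty_members, reason = character(0))))
  }
  tax <- dplyr::select(taxonomy, "feature_id", "family", tax_genus = "genus")
  cand <- dplyr::left_join(cand, tax, by = "feature_id")
  if (!is.null(isolates) && "genus" %in% names(isolates)) {
    cand <- dplyr::left_join(
      cand, dplyr::select(isolates, "strain_id", iso_genus = "genus"),
      by = "strain_id")
  } else {
    cand$iso_genus <- NA_character_
  }
  cand <- dplyr::mutate(cand, genus = dplyr::coalesce(
    dplyr::na_if(.data$tax_genus, ""), .data$iso_genus))

  excl <- dplyr::filter(cand, .data$family %in% exclude_families)
  excl$reason <- if (nrow(excl)) paste("excluded family:", excl$family) else character(0)
  cand <- dplyr::filter(cand, !.data$family %in% exclude_families)

  # one strain per genus: highest identity, ties by strain_id
  cand <- dplyr::arrange(cand, .data$genus, dplyr::desc(.data$identity),
                         .data$strain_id)
  dedup <- dplyr::distinct(cand, .data$genus, .keep_all = TRUE)
  dropped <- dplyr::anti_join(cand, dedup, by = c("strain_id", "feature_id"))
  if (nrow(dropped) > 0) dropped$reason <- "duplicate genus"
  exclusions <- dplyr::bind_rows(excl, dropped)

  members <- dplyr::arrange(dedup, dplyr::desc(.data$identity), .data$strain_id)
  if (!is.null(max_members) && nrow(members) > max_members) {
    over <- members[-seq_len(max_members), ]
    over$reason <- "over max_members"
    exclusions <- dplyr::bind_rows(exclusions, over)
    members <- members[seq_len(max_members), ]
  }
  if (nrow(members) == 0) {
    cli::cli_warn("All candidates excluded; returning an empty plan.")
  }
  new_syncom_plan(
    name, source_module,
    dplyr::select(members, "strain_id", "genus", matched_asv = "feature_id",
                  "identity"),
    dplyr::select(exclusions, "strain_id", "genus",
                  matched_asv = "feature_id", "identity", "reason"))
}

new_syncom_plan <- function(name, source_module, members, exclusions) {
  structure(list(name = name, source_module = source_module,
                 members = members, exclusions = exclusions),
            class = "syncom_plan")
}

#' @export
print.syncom_plan <- function(x, ...) {
  cat(sprintf("SynCom plan '%s' (%d member%s, source: %s)\n", x$name,
              nrow(x$members), if (nrow(x$members) == 1) "" else "s",
              x$source_module))
  if (nrow(x$members) > 0) {
    for (i in seq_len(nrow(x$members))) {
      cat(sprintf("  %s (%s) <- %s at %.1f%% identity\n",
                  x$members$strain_id[i], x$members$genus[i],
                  x$members$matched_asv[i], x$members$identity[i]))
    }
  }
  invisible(x)
}

#' @method tidy syncom_plan
#' @export
tidy.syncom_plan <- function(x, ...) x$members

#' @method glance syncom_plan
#' @export
glance.syncom_plan <- function(x, ...) {
  tibble::tibble(name = x$name, source_module = x$source_module,
                 n_members = nrow(x$members),
                 n_excluded = nrow(x$exclusions),
                 min_identity = if (nrow(x$members)) min(x$members$identity) else NA_real_)
}
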