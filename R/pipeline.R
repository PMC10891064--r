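# End-to-end orchestration: counts -> QMP -> core set -> network ->
# modules -> enrichment -> SynCom plan. Each step is an exported function;
# this wrapper just chains them with the pipeline's defaults.

#' Run the full QMP-to-SynCom pipeline
#'
#' Chains taxonomic filtering, spike calibration, core-feature selection
#' (on the unrarefied relative profile), co-occurrence network
#' construction with module detection, module-level enrichment testing
#' against the control, and SynCom design from the most enriched module of
#' `target_treatment`.
#'
#' @param counts Counts tibble including spike features.
#' @param metadata Sample metadata.
#' @param taxonomy Taxonomy tibble.
#' @param spikes Spike design tibble.
#' @param asv_seqs Named ASV sequences (for isolate matching).
#' @param isolates Isolate tibble (`strain_id`, `sequence`, optional
#'   `genus`).
#' @param target_treatment Treatment whose enriched module seeds the
#'   SynCom.
#' @param control Reference treatment.
#' @param core_threshold Relative-abundance threshold for core features.
#' @param rho_cut,alpha Network edge thresholds.
#' @param min_identity Isolate matching threshold (percent).
#' @param exclude_families Families excluded from SynCom plans.
#' @param seed Seed for module detection.
#' @return List with `qmp`, `core`, `network`, `roles`, `module_abundance`,
#'   `enrichment`, `selected_module`, `matches` and `plan`.
#' @export
run_qmp_pipeline <- function(counts, metadata, taxonomy, spikes,
                             asv_seqs = NULL, isolates = NULL,
                             target_treatment = "-N", control = "Control",
                             core_threshold = 0.001, rho_cut = 0.8,
                             alpha = 0.05, min_identity = 95,
                             exclude_families = "Bradyrhizobiaceae",
                             seed = 1) {
  filtered <- filter_features(counts, taxonomy, metadata)
  qmp <- absolute_abundance(filtered, spikes, metadata)
  rel <- relative_abundance(filtered)
  core <- core_features(rel, threshold = core_threshold)

  net <- build_network(spearman_edges(qmp, core), rho_cut = rho_cut,
                       alpha = alpha)
  net <- detect_modules(net, seed = seed)
  roles <- node_roles(net)

  mods <- module_membership(net)
  # only multi-member modules are ecological clusters worth testing
  big <- names(which(table(mods$module) >= 3))
  mod_abund <- module_abundance(qmp, dplyr::filter(mods, .data$module %in% big),
                                metadata)
  enr <- module_enrichment(mod_abund, control = control)

  hits <- dplyr::filter(enr, .data$treatment == target_treatment,
                        .data$status == "enriched")
  selected <- if (nrow(hits) > 0) {
    hits$module[which.max(hits$ratio)]
  } else {
    NA_character_
  }

  matches <- NULL
  plan <- NULL
  if (!is.na(selected) && !is.null(asv_seqs) && !is.null(isolates)) {
    feats <- mods$feature_id[mods$module == selected]
    matches <- match_isolates(asv_seqs[intersect(names(asv_seqs), feats)],
                              isolates, min_identity = min_identity)
    plan <- design_syncom(feats, matches, taxonomy, isolates,
                          exclude_families = exclude_families,
                          name = paste0("SynCom_", target_treatment),
                          source_module = selected)
  }
  list(qmp = qmp, core = core, network = net, roles = roles,
       module_abundance = mod_abund, enrichment = enr,
       selected_module = selected, matches = matches, plan = plan)
}
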