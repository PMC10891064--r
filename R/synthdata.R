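# Synthetic multi-treatment time-series communities with known absolute
# abundances. The generator plants (i) phylum-level logistic growth of the
# total load over plant development, with a late-blooming Bacteroidetes
# group, (ii) co-varying ASV modules driven by shared lognormal latent
# factors, (iii) treatment-specific multiplicative effects on whole
# modules, and (iv) multinomial sequencing with spike-in standards — so
# that every downstream stage (QMP calibration, turnover, differential
# load, networks, SynCom design) can be checked against ground truth.

#' Simulation configuration
#'
#' Defines the study design and generative parameters for
#' [simulate_dynamics()] and [simulate_sequencing()]. Defaults emulate a
#' field time series: four fertilization treatments (Control, -N, -P, -K),
#' eight sampling stages from day 1 to day 72 post germination, six
#' replicates per treatment and stage, and a planted three-fold enrichment
#' of module 2 under -N.
#'
#' @param treatments Treatment labels (subset of Control/-N/-P/-K).
#' @param stage_days Strictly increasing sampling days post germination.
#' @param n_replicates Replicates per treatment x stage (>= 1).
#' @param n_asvs Total number of biological ASVs (module members,
#'   background, and `n_contaminants` non-bacterial features).
#' @param n_modules Number of planted co-varying modules.
#' @param module_size ASVs per planted module.
#' @param module_effects Named list: treatment -> named numeric vector of
#'   per-module multiplicative effects on absolute abundance (module names
#'   `"module1"`, `"module2"`, ...). Multipliers must be > 0.
#' @param growth_params Tibble of per-phylum logistic growth parameters
#'   with columns `group`, `capacity` (16S copies per gram at saturation),
#'   `rate` (d^-1), `midpoint` (d), `baseline` (fraction of capacity
#'   present at early stages) and `weight` (probability an ASV belongs to
#'   the group). See [default_growth_params()].
#' @param module_sigma Lognormal sigma of the shared per-module latent
#'   factor; at the default (0.5, with `dispersion` 0.15) within-module
#'   Spearman correlations are ~0.9, comfortably above the 0.8 edge
#'   threshold.
#' @param dispersion Lognormal sigma of feature-specific replicate noise;
#'   total replicate variability combines this with the shared module
#'   factor (log-sd ~0.52, i.e. ~55% CV for module members).
#' @param depth Sequencing reads per sample (>= 1000).
#' @param spike_fraction Expected fraction of reads drawn from spike-in
#'   standards.
#' @param n_spikes Number of distinct spike sequences in the mix.
#' @param n_contaminants Number of planted non-bacterial (chloroplast)
#'   features, used to exercise the taxonomic filter.
#' @param compartment Compartment label for all samples.
#' @param sample_mass_g Nominal fresh sample mass (g).
#' @param seq_length Length of generated ASV sequences (nt); the default
#'   matches the scale of a 16S V5-V7 amplicon.
#' @param seed Integer seed; the same configuration always yields the same
#'   simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(treatments = c("Control", "-N", "-P", "-K"),
                       stage_days = c(1, 4, 7, 14, 28, 42, 60, 72),
                       n_replicates = 6,
                       n_asvs = 300,
                       n_modules = 3,
                       module_size = 25,
                       module_effects = list(`-N` = c(module2 = 3)),
                       growth_params = default_growth_params(),
                       module_sigma = 0.5,
                       dispersion = 0.15,
                       depth = 10000,
                       spike_fraction = 0.05,
                       n_spikes = 12,
                       n_contaminants = 3,
                       compartment = "rhizosphere",
                       sample_mass_g = 0.25,
                       seq_length = 393,
                       seed = 1) {
  cfg <- list(treatments = treatments, stage_days = stage_days,
              n_replicates = n_replicates, n_asvs = n_asvs,
              n_modules = n_modules, module_size = module_size,
              module_effects = module_effects, growth_params = growth_params,
              module_sigma = module_sigma, dispersion = dispersion,
              depth = depth, spike_fraction = spike_fraction,
              n_spikes = n_spikes, n_contaminants = n_contaminants,
              compartment = compartment, sample_mass_g = sample_mass_g,
              seq_length = seq_length, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) cli::cli_abort("Invalid {.field {field}}: {msg}.")
  }
  chk(length(cfg$treatments) >= 1 &&
        all(cfg$treatments %in% treatment_levels()),
      "treatments", "must be a non-empty subset of Control/-N/-P/-K")
  chk(length(cfg$stage_days) >= 1 && !is.unsorted(cfg$stage_days, strictly = TRUE),
      "stage_days", "must be strictly increasing")
  chk(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(cfg$n_asvs >= cfg$n_modules * cfg$module_size + cfg$n_contaminants,
      "n_asvs", "must accommodate all module members and contaminants")
  chk(cfg$n_modules >= 1, "n_modules", "must be >= 1")
  chk(cfg$depth >= 1000, "depth", "must be >= 1000")
  chk(cfg$spike_fraction > 0 && cfg$spike_fraction < 1,
      "spike_fraction", "must be in (0, 1)")
  chk(cfg$dispersion >= 0, "dispersion", "must be >= 0")
  bad_eff <- names(cfg$module_effects)[
    !names(cfg$module_effects) %in% cfg$treatments]
  chk(length(bad_eff) == 0, "module_effects",
      paste("unknown treatment(s):", paste(bad_eff, collapse = ", ")))
  if (length(cfg$module_effects) > 0) {
    chk(all(unlist(cfg$module_effects) > 0), "module_effects",
        "all multipliers must be > 0")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_growth_params <- function() {
  # Carrying capacities sum to ~2.6e10 copies g^-1 and baselines to ~5e9,
  # the scale of rhizosphere loads from early stages to day 72; the
  # Bacteroidetes group blooms late (midpoint day 55).
  tibble::tribble(
    ~group,            ~capacity, ~rate, ~midpoint, ~baseline, ~weight,
    "Proteobacteria",     1.0e10,  0.08,        30,      0.25,    0.35,
    "Actinobacteria",     6.0e9,   0.06,        25,      0.30,    0.25,
    "Bacteroidetes",      8.0e9,   0.15,        55,      0.05,    0.20,
    "Acidobacteria",      2.5e9,   0.05,        20,      0.30,    0.15,
    "Firmicutes",         1.0e9,   0.07,        35,      0.20,    0.05
  )
}

logistic_load <- function(day, capacity, rate, midpoint, baseline) {
  capacity * (baseline + (1 - baseline) / (1 + exp(-rate * (day - midpoint))))
}

module_label <- function(i) paste0("module", i)

#' Simulate community dynamics with planted ground truth
#'
#' Draws per-sample true absolute abundances as
#' `logistic(group, day) * ASV weight * module latent factor *
#' treatment module multiplier * lognormal replicate noise`,
#' together with sample metadata and a taxonomy table.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list with elements `abundance` (tibble, samples x
#'   ASVs, 16S copies per gram), `metadata`, `taxonomy`, `modules` (tibble
#'   `feature_id`, `module`; non-members are `"background"`),
#'   `module_effects`, `differential_features` (ASVs with a planted
#'   treatment effect) and `config`.
#' @export
simulate_dynamics <- function(config) {
  validate_sim_config(config)
  with_seed_if(config$seed, simulate_dynamics_impl(config))
}

simulate_dynamics_impl <- function(cfg) {
  n <- cfg$n_asvs
  ids <- sprintf("ASV%04d", seq_len(n))

  n_mod_members <- cfg$n_modules * cfg$module_size
  module <- rep("background", n)
  module[seq_len(n_mod_members)] <-
    rep(module_label(seq_len(cfg$n_modules)), each = cfg$module_size)
  # contaminants live in the background tail
  contaminant <- rep(FALSE, n)
  if (cfg$n_contaminants > 0) {
    contaminant[(n - cfg$n_contaminants + 1):n] <- TRUE
  }

  gp <- cfg$growth_params
  group <- sample(gp$group, n, replace = TRUE, prob = gp$weight)
  base_weight <- exp(stats::rnorm(n, 0, 1.2))
  # normalize weights within group so group curves keep their scale
  for (g in gp$group) {
    sel <- group == g
    if (any(sel)) base_weight[sel] <- base_weight[sel] / sum(base_weight[sel])
  }
  # contaminants: small plant-derived signal
  base_weight[contaminant] <- base_weight[contaminant] * 0.5

  taxonomy <- simulate_taxonomy(ids, group, module, contaminant)

  design <- tidyr::expand_grid(
    treatment = cfg$treatments,
    stage_day = cfg$stage_days,
    replicate_id = paste0("r", seq_len(cfg$n_replicates)))
  design <- dplyr::mutate(
    design,
    sample_id = sprintf("%s_d%02d_%s", gsub("^-", "minus", .data$treatment),
                        .data$stage_day, .data$replicate_id),
    compartment = cfg$compartment,
    sample_mass_g = cfg$sample_mass_g *
      exp(stats::rnorm(dplyr::n(), 0, 0.05)))
  metadata <- dplyr::select(design, "sample_id", "treatment", "compartment",
                            "stage_day", "replicate_id", "sample_mass_g")

  n_samp <- nrow(metadata)
  gidx <- match(group, gp$group)
  # samples x asvs deterministic backbone
  load <- matrix(0, n_samp, n)
  for (k in seq_len(nrow(gp))) {
    sel <- gidx == k
    if (!any(sel)) next
    curve <- logistic_load(metadata$stage_day, gp$capacity[k], gp$rate[k],
                           gp$midpoint[k], gp$baseline[k])
    load[, sel] <- outer(curve, base_weight[sel])
  }

  # shared lognormal latent factor per (sample, module)
  mod_names <- module_label(seq_len(cfg$n_modules))
  latent <- matrix(exp(stats::rnorm(n_samp * cfg$n_modules, 0, cfg$module_sigma)),
                   n_samp, cfg$n_modules, dimnames = list(NULL, mod_names))
  mfac <- matrix(1, n_samp, n)
  for (m in seq_len(cfg$n_modules)) {
    mfac[, module == mod_names[m]] <- latent[, m]
  }

  # treatment -> module multiplicative effects
  efac <- matrix(1, n_samp, n)
  for (trt in names(cfg$module_effects)) {
    rows <- metadata$treatment == trt
    eff <- cfg$module_effects[[trt]]
    for (m in names(eff)) {
      efac[rows, module == m] <- eff[[m]]
    }
  }

  noise <- matrix(exp(stats::rnorm(n_samp * n, 0, cfg$dispersion)), n_samp, n)
  abundance <- load * mfac * efac * noise
  colnames(abundance) <- ids

  diff_modules <- unique(unlist(lapply(cfg$module_effects, function(e) {
    names(e)[e != 1]
  })))
  structure(list(
    abundance = dplyr::bind_cols(
      tibble::tibble(sample_id = metadata$sample_id),
      tibble::as_tibble(abundance)),
    metadata = metadata,
    taxonomy = taxonomy,
    modules = tibble::tibble(feature_id = ids, module = module),
    module_effects = cfg$module_effects,
    differential_features = ids[module %in% diff_modules],
    config = cfg), class = "sim_truth")
}

# Taxonomy with a late-blooming phylum structure, a planted
# Bradyrhizobiaceae member inside module 2 (to exercise exclusion rules),
# and chloroplast contaminants.
simulate_taxonomy <- function(ids, group, module, contaminant) {
  genus_pool <- c("Rhodococcus", "Lysobacter", "Terrabacter", "Arthrobacter",
                  "Phyllobacterium", "Bosea", "Aeromicrobium", "Brevundimonas",
                  "Sediminibacterium", "Mycobacterium", "Herbaspirillum",
                  "Sphingomonas", sprintf("Genus%02d", 1:48))
  n <- length(ids)
  tax <- tibble::tibble(
    feature_id = ids,
    kingdom = "Bacteria",
    phylum = group,
    class = paste0(group, "ia"),
    order = paste0(group, "ales"),
    family = sprintf("Family%02d", 1 + (seq_len(n) %% 30)),
    genus = genus_pool[1 + (seq_len(n) %% length(genus_pool))])
  # module members get distinct genera drawn from the head of the pool so
  # SynCom deduplication is meaningful but not degenerate
  for (m in unique(module[module != "background"])) {
    sel <- which(module == m)
    tax$genus[sel] <- genus_pool[seq_along(sel)]
    tax$family[sel] <- sprintf("%s_fam%02d", m, 1 + (seq_along(sel) %% 8))
  }
  # one Bradyrhizobiaceae representative inside module 2, if it exists
  m2 <- which(module == "module2")
  if (length(m2) > 0) {
    tax$family[m2[1]] <- "Bradyrhizobiaceae"
    tax$genus[m2[1]] <- "Bradyrhizobium"
    tax$order[m2[1]] <- "Rhizobiales"
  }
  tax$kingdom[contaminant] <- "Viridiplantae"
  tax$phylum[contaminant] <- "Streptophyta"
  tax$class[contaminant] <- "Chloroplast"
  tax$order[contaminant] <- "Chloroplast"
  tax$family[contaminant] <- ""
  tax$genus[contaminant] <- ""
  tax
}

#' Build a spike-in design matched to a simulation
#'
#' Chooses total spike copies so that the expected spike read share equals
#' `config$spike_fraction` at the median community size, and spreads the
#' total over `n_spikes` standards at two-fold concentration steps
#' (spike mixes combine different concentrations of each standard).
#'
#' @param truth A `sim_truth` from [simulate_dynamics()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return A spike design tibble (`spike_id`, `copies_added`).
#' @export
default_spike_design <- function(truth, config = truth$config) {
  m <- as_sample_matrix(truth$abundance)
  community <- rowSums(m) * truth$metadata$sample_mass_g
  total <- config$spike_fraction / (1 - config$spike_fraction) *
    stats::median(community)
  w <- 2^(seq_len(config$n_spikes) - 1)
  tibble::tibble(
    spike_id = sprintf("SPIKE%02d", seq_len(config$n_spikes)),
    copies_added = total * w / sum(w))
}

#' Simulate amplicon sequencing with spike-ins
#'
#' Per sample, `config$depth` reads are drawn from a multinomial whose
#' probabilities are proportional to `true copies per gram x sample mass`
#' for ASVs and to `copies_added` for spikes.
#'
#' @inheritParams default_spike_design
#' @param spikes A spike design tibble; defaults to
#'   [default_spike_design()].
#' @return A counts tibble (samples x features, ASVs then spikes) whose
#'   row sums all equal `config$depth`, with the spike IDs recorded in the
#'   `"spike_ids"` attribute.
#' @export
simulate_sequencing <- function(truth, spikes = default_spike_design(truth, config),
                                config = truth$config) {
  validate_sim_config(config)
  check_spike_design(spikes)
  if (any(spikes$copies_added <= 0)) {
    cli::cli_abort("Spike copies must be > 0 for every sample.")
  }
  m <- as_sample_matrix(truth$abundance)
  mass <- truth$metadata$sample_mass_g[
    match(rownames(m), truth$metadata$sample_id)]
  with_seed_if(config$seed + 1L, {
    counts <- matrix(0L, nrow(m), ncol(m) + nrow(spikes))
    for (j in seq_len(nrow(m))) {
      p <- c(m[j, ] * mass[j], spikes$copies_added)
      if (sum(p) <= 0) {
        cli::cli_abort("Sample {.val {rownames(m)[j]}} has zero total copies.")
      }
      counts[j, ] <- as.integer(stats::rmultinom(1, config$depth, p))
    }
    colnames(counts) <- c(colnames(m), spikes$spike_id)
    rownames(counts) <- rownames(m)
    out <- as_sample_tbl(counts)
    attr(out, "spike_ids") <- spikes$spike_id
    out
  })
}

#' Generate random ASV reference sequences
#'
#' Sequences are i.i.d. uniform over A/C/G/T; isolate matching uses
#' identity only, so no phylogenetic signal is modeled.
#'
#' @param ids Feature IDs to name the sequences.
#' @param length Sequence length in nt.
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
simulate_asv_sequences <- function(ids, length = 393, seed = 1) {
  with_seed_if(seed, {
    seqs <- vapply(ids, function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    seqs
  })
}

#' Simulate cultured isolates from ASV sequences
#'
#' Each isolate is its source ASV sequence with point substitutions applied
#' independently at rate `(100 - target_identity) / 100`; substituted
#' positions always change to a different base, and the realized identity
#' is recorded.
#'
#' @param asv_seqs Named character vector of source sequences.
#' @param identities Tibble with columns `strain_id`, `source_feature`,
#'   `target_identity` (percent, in \[80, 100\]) and optionally `genus`.
#' @param seed Integer seed.
#' @return Tibble (`strain_id`, `source_feature`, `genus`, `sequence`,
#'   `target_identity`, `realized_identity`).
#' @export
simulate_isolates <- function(asv_seqs, identities, seed = 1) {
  check_sequences(asv_seqs, "ASV sequence")
  req <- c("strain_id", "source_feature", "target_identity")
  missing <- setdiff(req, names(identities))
  if (length(missing) > 0) {
    cli::cli_abort("identities is missing column{?s} {.field {missing}}.")
  }
  if (any(identities$target_identity < 80 | identities$target_identity > 100)) {
    cli::cli_abort("{.field target_identity} must lie in [80, 100].")
  }
  unknown <- setdiff(identities$source_feature, names(asv_seqs))
  if (length(unknown) > 0) {
    cli::cli_abort("No sequence for source feature{?s} {.val {unknown}}.")
  }
  if (!"genus" %in% names(identities)) identities$genus <- NA_character_
  with_seed_if(seed, {
    out <- purrr::pmap(identities, function(strain_id, source_feature,
                                            target_identity, genus, ...) {
      src <- strsplit(asv_seqs[[source_feature]], "")[[1]]
      rate <- (100 - target_identity) / 100
      hit <- stats::runif(length(src)) < rate
      mut <- src
      if (any(hit)) {
        mut[hit] <- vapply(src[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      tibble::tibble(
        strain_id = strain_id, source_feature = source_feature,
        genus = genus, sequence = paste(mut, collapse = ""),
        target_identity = target_identity,
        realized_identity = 100 * (1 - sum(hit) / length(src)))
    })
    dplyr::bind_rows(out)
  })
}

#' Run the full generator
#'
#' Convenience wrapper: dynamics, spike design, sequencing and ASV
#' sequences from one configuration.
#'
#' @param config A [sim_config()].
#' @return A list with `truth`, `metadata`, `taxonomy`, `spikes`, `counts`
#'   and `asv_seqs`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  truth <- simulate_dynamics(config)
  spikes <- default_spike_design(truth, config)
  counts <- simulate_sequencing(truth, spikes, config)
  asv_seqs <- simulate_asv_sequences(truth$modules$feature_id,
                                     length = config$seq_length,
                                     seed = config$seed + 2L)
  list(truth = truth, metadata = truth$metadata, taxonomy = truth$taxonomy,
       spikes = spikes, counts = counts, asv_seqs = asv_seqs)
}

#' Write a simulation to disk
#'
#' Emits the feature table, metadata, spike design, taxonomy, ground-truth
#' abundances (all TSV) and the ASV FASTA into `dir`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory, created if needed.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(sim$counts, file.path(dir, "feature_table.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_spike_design(sim$spikes, file.path(dir, "spike_design.tsv"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_feature_table(sim$truth$abundance, file.path(dir, "true_abundance.tsv"))
  write_fasta(sim$asv_seqs, file.path(dir, "asv_sequences.fasta"))
  invisible(dir)
}

#' Simulate profiles with a planted linear Bray-Curtis drift
#'
#' Builds abundance profiles in which community composition shifts
#' linearly between two feature blocks at `rate` per day, so that before
#' noise the Bray-Curtis dissimilarity between two samples equals
#' `rate * delta-day` exactly. Used to validate turnover regressions
#' against a known slope.
#'
#' @param rate Planted turnover rate (d^-1).
#' @param stage_days Sampling days.
#' @param n_replicates Replicates per day.
#' @param n_features Number of features (split into two blocks).
#' @param total Total load per sample (copies per gram).
#' @param noise_sd Lognormal sd of per-feature replicate noise (profiles
#'   are renormalized to `total` afterwards). Kept mild by default: the
#'   absolute value inside Bray-Curtis turns heavy feature noise into a
#'   downward-biased (attenuated) slope.
#' @param treatment,compartment Metadata labels for the generated samples.
#' @param seed Integer seed.
#' @return List with `profile` (samples x features tibble) and `metadata`.
#' @export
simulate_drift_profiles <- function(rate = 0.004,
                                    stage_days = c(1, 4, 7, 14, 28, 42, 60, 72),
                                    n_replicates = 6, n_features = 40,
                                    total = 1e9, noise_sd = 0.01,
                                    treatment = "Control",
                                    compartment = "rhizosphere", seed = 1) {
  if (rate < 0) cli::cli_abort("{.field rate} must be >= 0.")
  half <- n_features %/% 2
  a_share <- function(d) 0.65 - rate * d
  if (any(a_share(stage_days) <= 0 | a_share(stage_days) >= 1)) {
    cli::cli_abort("rate x max(stage_days) too large for a valid composition.")
  }
  with_seed_if(seed, {
    md <- tidyr::expand_grid(stage_day = stage_days,
                             replicate_id = paste0("r", seq_len(n_replicates)))
    md <- dplyr::mutate(
      md,
      sample_id = sprintf("drift_d%02d_%s", .data$stage_day, .data$replicate_id),
      treatment = treatment, compartment = compartment, sample_mass_g = 0.25)
    wA <- rep(1 / half, half)
    wB <- rep(1 / (n_features - half), n_features - half)
    prof <- t(vapply(md$stage_day, function(d) {
      base <- total * c(a_share(d) * wA, (1 - a_share(d)) * wB)
      noisy <- base * exp(stats::rnorm(n_features, 0, noise_sd))
      noisy * total / sum(noisy)
    }, numeric(n_features)))
    colnames(prof) <- sprintf("F%03d", seq_len(n_features))
    rownames(prof) <- md$sample_id
    list(profile = as_sample_tbl(prof),
         metadata = dplyr::select(md, "sample_id", "treatment", "compartment",
                                  "stage_day", "replicate_id", "sample_mass_g"))
  })
}

#' Simulate a treatment that diverges linearly from its control
#'
#' Control samples keep a fixed composition. In treatment samples, every
#' feature in the first block is inflated and every feature in the second
#' block deflated by `2 * rate * day * u`, with `u` a mean-one lognormal
#' noise per feature and sample — so the planted shift never changes
#' sign and the expected Bray-Curtis distance of a treatment sample to a
#' same-day control sample is `rate * day` at every stage.
#'
#' @inheritParams simulate_drift_profiles
#' @param rate Planted divergence rate (d^-1).
#' @param noise_sd Lognormal sd of the per-feature shift noise.
#' @param treatment Label of the diverging treatment.
#' @param control Label of the reference treatment.
#' @return List with `profile` and `metadata` covering both treatments.
#' @export
simulate_divergence_profiles <- function(rate = 0.002,
                                         stage_days = c(1, 4, 7, 14, 28, 42, 60, 72),
                                         n_replicates = 6, n_features = 40,
                                         total = 1e9, noise_sd = 0.3,
                                         treatment = "-P", control = "Control",
                                         compartment = "rhizosphere", seed = 1) {
  half <- n_features %/% 2
  if (rate < 0) cli::cli_abort("{.field rate} must be >= 0.")
  if (2 * rate * max(stage_days) >= 1) {
    cli::cli_abort("rate x max(stage_days) too large for a valid composition.")
  }
  with_seed_if(seed, {
    md <- tidyr::expand_grid(treatment = c(control, treatment),
                             stage_day = stage_days,
                             replicate_id = paste0("r", seq_len(n_replicates)))
    md <- dplyr::mutate(
      md,
      sample_id = sprintf("%s_d%02d_%s", gsub("^-", "minus", .data$treatment),
                          .data$stage_day, .data$replicate_id),
      compartment = compartment, sample_mass_g = 0.25)
    w <- c(rep(0.5 / half, half), rep(0.5 / (n_features - half),
                                      n_features - half))
    sign_block <- c(rep(1, half), rep(-1, n_features - half))
    mu <- -noise_sd^2 / 2  # lognormal mean one
    prof <- t(vapply(seq_len(nrow(md)), function(i) {
      if (md$treatment[i] == control) return(total * w)
      g <- 2 * rate * md$stage_day[i]
      u <- exp(stats::rnorm(n_features, mu, noise_sd))
      total * w * pmax(1 + sign_block * g * u, 0)
    }, numeric(n_features)))
    colnames(prof) <- sprintf("F%03d", seq_len(n_features))
    rownames(prof) <- md$sample_id
    list(profile = as_sample_tbl(prof),
         metadata = dplyr::select(md, "sample_id", "treatment", "compartment",
                                  "stage_day", "replicate_id", "sample_mass_g"))
  })
}
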