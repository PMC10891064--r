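# Core-taxon selection and the differential-load procedure: average
# absolute abundance per (treatment, stage), paired Wilcoxon across the
# stage means between a fertilization treatment and the Control, and a
# fold-change gate. Raw Wilcoxon p-values are used for the call (this
# test is exempt from the FDR correction applied elsewhere in the
# pipeline).

#' Core features
#'
#' Features whose relative abundance strictly exceeds `threshold`
#' (default 0.1%) in at least one sample.
#'
#' @param rel Relative-abundance tibble (rows sum to 1).
#' @param threshold Strict lower bound on the per-sample proportion.
#' @return Character vector of core feature IDs.
#' @export
core_features <- function(rel, threshold = 0.001) {
  m <- as_sample_matrix(rel)
  colnames(m)[apply(m, 2, max) > threshold]
}

#' Mean abundance per treatment and stage
#'
#' Arithmetic mean over replicates for every (treatment, stage_day,
#' feature) cell. Errors if any treatment is missing one of the stages
#' observed in the design.
#'
#' @param quant Abundance tibble (samples x features).
#' @param metadata Sample metadata.
#' @return Long tibble (`treatment`, `stage_day`, `feature_id`,
#'   `mean_abundance`, `n_replicates`).
#' @export
stage_average <- function(quant, metadata) {
  md <- dplyr::select(metadata, "sample_id", "treatment", "stage_day")
  long <- tidyr::pivot_longer(quant, -"sample_id", names_to = "feature_id",
                              values_to = "abundance")
  long <- dplyr::inner_join(long, md, by = "sample_id")
  if (nrow(long) == 0) cli::cli_abort("No sample overlap between profile and metadata.")
  present <- dplyr::distinct(long, .data$treatment, .data$stage_day)
  full <- tidyr::expand_grid(treatment = unique(present$treatment),
                             stage_day = unique(present$stage_day))
  missing <- dplyr::anti_join(full, present, by = c("treatment", "stage_day"))
  if (nrow(missing) > 0) {
    lab <- paste0(missing$treatment, "/d", missing$stage_day)
    cli::cli_abort("Missing (treatment, stage) cell{?s}: {.val {lab}}.")
  }
  dplyr::summarise(
    dplyr::group_by(long, .data$treatment, .data$stage_day, .data$feature_id),
    mean_abundance = mean(.data$abundance),
    n_replicates = dplyr::n(), .groups = "drop")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped before ranking; ties receive average ranks. For `n <= 12`
#' retained pairs the p-value is exact, from full enumeration of the
#' `2^n` sign assignments of the observed ranks; for larger `n` a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return List with `statistic` (the positive-rank sum W+), `p_value`,
#'   `n_used` (pairs retained after dropping zeros) and `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) cli::cli_abort("x and y must have equal length.")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    cli::cli_warn("All paired differences are zero; p = 1.")
    return(list(statistic = 0, p_value = 1, n_used = 0, method = "degenerate"))
  }
  if (n < 3) {
    cli::cli_abort("Need >= 3 nonzero paired differences (got {n}).")
  }
  r <- rank(abs(nz))
  w_pos <- sum(r[nz > 0])
  if (n <= 12) {
    # exact: distribution of W+ over all 2^n sign vectors of these ranks
    w_all <- signed_rank_sums(r)
    p_le <- mean(w_all <= w_pos + 1e-9)
    p_ge <- mean(w_all >= w_pos - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w_pos, p_value = p, n_used = n, method = method)
}

# All 2^n positive-rank sums for rank vector r (n <= ~16).
signed_rank_sums <- function(r) {
  n <- length(r)
  combos <- 0:(2^n - 1)
  w <- numeric(length(combos))
  for (i in seq_len(n)) {
    w <- w + r[i] * (bitwAnd(combos, bitwShiftL(1L, i - 1L)) > 0)
  }
  w
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; values are validated to lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    cli::cli_abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-load features between a treatment and the control
#'
#' Implements the stage-averaged differential rule: for each feature,
#' abundances are averaged per (treatment, stage); a paired two-sided
#' Wilcoxon test compares the treatment's stage means with the control's;
#' the fold change is the ratio of the grand means of the stage means
#' (zeros replaced by half the smallest nonzero stage mean in the
#' comparison, keeping the ratio finite and symmetric). A feature is
#' `increased` when `p < alpha` and `FC > fc_threshold`, `decreased` when
#' `p < alpha` and `FC < 1 / fc_threshold`, otherwise `ns`. Raw p-values
#' are used (no FDR on this test).
#'
#' @param quant Absolute-abundance tibble.
#' @param metadata Sample metadata.
#' @param treatment Treatment label to compare against `control`.
#' @param control Reference treatment.
#' @param alpha Significance threshold on the raw Wilcoxon p.
#' @param fc_threshold Fold-change gate (strict inequalities).
#' @return Tibble with one row per feature: `feature_id`, `fold_change`,
#'   `p_value`, `direction`, and a nested `stage_means` tibble of the
#'   paired per-stage means.
#' @export
diff_features <- function(quant, metadata, treatment, control = "Control",
                          alpha = 0.05, fc_threshold = 1.5) {
  check_metadata(metadata)
  md <- dplyr::filter(metadata, .data$treatment %in% c(!!treatment, !!control))
  if (dplyr::n_distinct(md$treatment) < 2) {
    cli::cli_abort("Both {.val {treatment}} and {.val {control}} must be present.")
  }
  quant_sub <- dplyr::filter(quant, .data$sample_id %in% md$sample_id)
  means <- stage_average(quant_sub, md)
  wide <- tidyr::pivot_wider(means, id_cols = c("feature_id", "stage_day"),
                             names_from = "treatment",
                             values_from = "mean_abundance")
  wide <- dplyr::arrange(wide, .data$feature_id, .data$stage_day)

  res <- dplyr::group_by(wide, .data$feature_id)
  res <- dplyr::group_map(res, function(df, key) {
    xt <- df[[treatment]]
    xc <- df[[control]]
    test <- tryCatch(suppressWarnings(paired_wilcoxon(xt, xc)),
                     error = function(e) list(p_value = NA_real_))
    tibble::tibble(
      feature_id = key$feature_id,
      fold_change = fold_change(xt, xc),
      p_value = test$p_value,
      stage_means = list(tibble::tibble(stage_day = df$stage_day,
                                        treatment_mean = xt,
                                        control_mean = xc)))
  })
  res <- dplyr::bind_rows(res)
  dplyr::mutate(res, direction = dplyr::case_when(
    is.na(.data$p_value) ~ "ns",
    .data$p_value < alpha & .data$fold_change > fc_threshold ~ "increased",
    .data$p_value < alpha & .data$fold_change < 1 / fc_threshold ~ "decreased",
    TRUE ~ "ns"))
}

# Ratio of grand means of the stage means, with zero-handling: zeros on
# either side are replaced by half the smallest nonzero stage mean in the
# comparison, so FC(a, b) * FC(b, a) = 1.
fold_change <- function(x, y) {
  vals <- c(x, y)
  nonzero <- vals[vals > 0]
  if (length(nonzero) == 0) return(1)
  pseudo <- min(nonzero) / 2
  mean(pmax(x, pseudo)) / mean(pmax(y, pseudo))
}
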