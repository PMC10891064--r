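# Alpha/beta diversity, ordination, PERMANOVA and the two turnover
# regressions. QMP profiles enter Bray-Curtis untransformed (copies per
# gram) so that load differences contribute to dissimilarity; RMP
# profiles enter as proportions.

#' Shannon diversity per sample
#'
#' `H = -sum(p * log(p))` over features with `p > 0`, natural log by
#' default.
#'
#' @param profile Abundance tibble (samples x features), any scale.
#' @param base Logarithm base (`exp(1)` for nats).
#' @return Tibble (`sample_id`, `shannon`).
#' @export
shannon <- function(profile, base = exp(1)) {
  m <- as_sample_matrix(profile)
  if (any(m < 0)) cli::cli_abort("Abundances must be non-negative.")
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    cli::cli_abort("All-zero sample{?s}: {.val {rownames(m)[totals <= 0]}}.")
  }
  tibble::tibble(sample_id = rownames(m),
                 shannon = as.numeric(vegan::diversity(m, index = "shannon",
                                                       base = base)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`. On QMP profiles this is
#' sensitive to total load; on relative profiles it reduces to the
#' classical compositional form.
#'
#' @param profile Abundance tibble (samples x features).
#' @return A `dist` object with sample IDs as labels.
#' @export
bray_curtis <- function(profile) {
  m <- as_sample_matrix(profile)
  if (any(m < 0)) cli::cli_abort("Abundances must be non-negative.")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    cli::cli_abort("Bray-Curtis undefined for all-zero sample{?s} {.val {rownames(m)[zero]}}.")
  }
  vegan::vegdist(m, method = "bray")
}

dist_to_pairs <- function(D) {
  m <- as.matrix(D)
  ids <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                 distance = m[idx])
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers `-D^2 / 2` and eigen-decomposes it; axis variance is
#' expressed relative to the sum of positive eigenvalues. Negative
#' eigenvalues are reported, not corrected.
#'
#' @param D A `dist` or symmetric matrix of dissimilarities.
#' @param n_axes Number of axes to return.
#' @return A `pcoa_res` list: `coordinates` (tibble `sample_id`, `Axis1`,
#'   ...), `eigenvalues`, `pct_variance`.
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  k <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < n_axes) {
    cli::cli_warn("Only {ncol(pts)} axes available (requested {n_axes}).")
  }
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  pos <- fit$eig[fit$eig > 0]
  structure(list(
    coordinates = tibble::as_tibble(pts, rownames = "sample_id"),
    eigenvalues = fit$eig,
    pct_variance = 100 * fit$eig[seq_len(ncol(pts))] / sum(pos)),
    class = "pcoa_res")
}

#' @export
print.pcoa_res <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates) - 1, "axes\n")
  cat("  % variance:", paste(sprintf("%.1f", x$pct_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @method tidy pcoa_res
#' @export
tidy.pcoa_res <- function(x, ...) x$coordinates

#' @method glance pcoa_res
#' @export
glance.pcoa_res <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_axes = ncol(x$coordinates) - 1,
                 pct_variance_axis1 = x$pct_variance[1],
                 n_negative_eig = sum(x$eigenvalues < 0))
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a dissimilarity matrix. Sums of squares are
#' computed from squared pairwise distances
#' (`SS_total = sum(d^2) / n`, `SS_within` from within-group pairs);
#' `R2 = SS_among / SS_total`; the p-value is
#' `(1 + #[F_perm >= F_obs]) / (n_perm + 1)` under free permutation of
#' sample labels.
#'
#' @param D A `dist` or symmetric dissimilarity matrix.
#' @param labels Group label per sample (in `D`'s label order).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return A `permanova_fit` with `pseudo_F`, `r_squared`, `p_value`,
#'   degrees of freedom and `n_perm`.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = NULL) {
  m <- as.matrix(stats::as.dist(D))
  n <- nrow(m)
  labels <- as.character(labels)
  if (length(labels) != n) {
    cli::cli_abort("{.field labels} must have one entry per sample ({n}).")
  }
  sizes <- table(labels)
  if (length(sizes) < 2) cli::cli_abort("Need at least two groups.")
  if (any(sizes < 2)) {
    cli::cli_abort("Every group needs >= 2 samples; offending: {.val {names(sizes)[sizes < 2]}}.")
  }
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  a <- length(sizes)

  ss_within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      sel <- lab == g
      s <- s + sum(d2[sel, sel][upper.tri(d2[sel, sel])]) / sum(sel)
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ssa <- ss_total - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(labels)
  r2 <- (ss_total - ss_within(labels)) / ss_total
  with_seed_if(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) f_stat(sample(labels)),
                     numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  structure(list(pseudo_F = f_obs, r_squared = r2, p_value = p,
                 df_among = a - 1, df_within = n - a, n_perm = n_perm,
                 n_samples = n),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(term = c("among", "within"),
                 df = c(x$df_among, x$df_within),
                 pseudo_F = c(x$pseudo_F, NA),
                 r_squared = c(x$r_squared, 1 - x$r_squared),
                 p_value = c(x$p_value, NA))
}

#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, r_squared = x$r_squared,
                 p_value = x$p_value, n_samples = x$n_samples,
                 n_perm = x$n_perm)
}

new_turnover_fit <- function(fit, pairs, mode, treatment, control = NA,
                             n_boot = 199, boot_seed = 1) {
  sm <- summary(fit)
  # constant response: slope 0 by convention, no fit quality to report
  r2 <- if (is.nan(sm$r.squared)) 0 else sm$r.squared
  slope <- unname(stats::coef(fit)[2])
  se <- boot_slope_se(pairs, mode, n_boot = n_boot, seed = boot_seed)
  p <- if (is.na(se)) NA_real_
       else if (se == 0) as.numeric(slope != 0) * 0
       else 2 * stats::pnorm(-abs(slope / se))
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_value = p,
    slope_se = se,
    n_pairs = nrow(pairs),
    pairs = pairs, mode = mode, treatment = treatment, control = control),
    class = "turnover_fit")
}

# Sample-level bootstrap SE for the turnover slope. Pairwise distances
# sharing a sample are correlated, so the naive pair-level OLS standard
# error is far too small; resampling whole samples (independently for the
# two sides of a divergence fit) and refitting with multiplicity weights
# gives an honest uncertainty for the slope.
boot_slope_se <- function(pairs, mode, n_boot = 199, seed = 1) {
  if (n_boot < 2) return(NA_real_)
  ids_a <- unique(pairs$sample_a)
  ids_b <- unique(pairs$sample_b)
  one_pool <- mode == "decay"
  if (one_pool) ids_a <- ids_b <- union(ids_a, ids_b)
  ia <- match(pairs$sample_a, ids_a)
  ib <- match(pairs$sample_b, ids_b)
  withr::with_seed(seed, {
    sl <- vapply(seq_len(n_boot), function(b) {
      cnt_a <- tabulate(sample.int(length(ids_a), replace = TRUE),
                        nbins = length(ids_a))
      cnt_b <- if (one_pool) cnt_a else
        tabulate(sample.int(length(ids_b), replace = TRUE),
                 nbins = length(ids_b))
      w <- cnt_a[ia] * cnt_b[ib]
      keep <- w > 0
      if (sum(keep) < 3 || length(unique(pairs$delta_day[keep])) < 2) {
        return(NA_real_)
      }
      unname(stats::coef(stats::lm(distance ~ delta_day, data = pairs,
                                   weights = w))[2])
    }, numeric(1))
  })
  stats::sd(sl, na.rm = TRUE)
}

select_stratum <- function(metadata, treatment, compartment, D_ids,
                           call = rlang::caller_env()) {
  md <- dplyr::filter(metadata, .data$treatment == !!treatment,
                      .data$sample_id %in% D_ids)
  if (!is.null(compartment)) {
    md <- dplyr::filter(md, .data$compartment == !!compartment)
  } else if (dplyr::n_distinct(md$compartment) > 1) {
    cli::cli_abort(
      "Samples span several compartments; pass {.arg compartment} to fit within one stratum.",
      call = call)
  }
  md
}

#' Temporal turnover (time-decay) regression
#'
#' Regresses Bray-Curtis dissimilarity on temporal distance
#' (difference in sampling day, delta-d) over all within-treatment sample
#' pairs with delta-d > 0, by ordinary least squares. The slope is the
#' community turnover rate in d^-1.
#'
#' @param D Dissimilarity `dist`/matrix whose labels are sample IDs.
#' @param metadata Sample metadata.
#' @param treatment Treatment to fit.
#' @param compartment Compartment stratum; required when the selected
#'   samples span more than one compartment.
#' @param n_boot Bootstrap replicates for the slope standard error.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `turnover_fit`; see [tidy.turnover_fit()].
#' @export
time_decay_fit <- function(D, metadata, treatment, compartment = NULL,
                           n_boot = 199, boot_seed = 1) {
  check_metadata(metadata)
  m <- as.matrix(stats::as.dist(D))
  md <- select_stratum(metadata, treatment, compartment, rownames(m))
  if (dplyr::n_distinct(md$stage_day) < 2) {
    cli::cli_abort("Need >= 2 distinct stage days within treatment {.val {treatment}}.")
  }
  sel <- match(md$sample_id, rownames(m))
  sub <- m[sel, sel, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  pairs <- tibble::tibble(
    sample_a = md$sample_id[idx[, 1]], sample_b = md$sample_id[idx[, 2]],
    delta_day = abs(md$stage_day[idx[, 1]] - md$stage_day[idx[, 2]]),
    distance = sub[idx])
  pairs <- dplyr::filter(pairs, .data$delta_day > 0)
  if (nrow(pairs) < 3) {
    cli::cli_abort("Fewer than 3 sample pairs with delta-d > 0.")
  }
  fit <- stats::lm(distance ~ delta_day, data = pairs)
  new_turnover_fit(fit, pairs, "decay", treatment,
                   n_boot = n_boot, boot_seed = boot_seed)
}

#' Divergence-from-control regression
#'
#' Regresses the Bray-Curtis distance between each treatment sample and
#' each same-stage control sample on the sampling day, quantifying how
#' fast a treatment's community diverges from the control over plant
#' development.
#'
#' @inheritParams time_decay_fit
#' @param control Reference treatment.
#' @return A `turnover_fit` (mode `"divergence"`).
#' @export
divergence_fit <- function(D, metadata, treatment, control = "Control",
                           compartment = NULL, n_boot = 199,
                           boot_seed = 1) {
  check_metadata(metadata)
  m <- as.matrix(stats::as.dist(D))
  md_t <- select_stratum(metadata, treatment, compartment, rownames(m))
  md_c <- select_stratum(metadata, control, compartment, rownames(m))
  shared <- intersect(unique(md_t$stage_day), unique(md_c$stage_day))
  if (length(shared) == 0) {
    cli::cli_abort("No shared stage days between {.val {treatment}} and {.val {control}}.")
  }
  if (length(shared) < 2) {
    cli::cli_abort("Only one shared stage day; the regression needs >= 2.")
  }
  pairs <- purrr::map_dfr(shared, function(d) {
    ta <- md_t$sample_id[md_t$stage_day == d]
    cb <- md_c$sample_id[md_c$stage_day == d]
    grid <- tidyr::expand_grid(sample_a = ta, sample_b = cb)
    dplyr::mutate(grid, stage_day = d,
                  distance = m[cbind(.data$sample_a, .data$sample_b)])
  })
  if (nrow(pairs) < 3) cli::cli_abort("Fewer than 3 cross-treatment pairs.")
  fit <- stats::lm(distance ~ stage_day, data = pairs)
  new_turnover_fit(
    fit, dplyr::rename(pairs, delta_day = "stage_day"),
    "divergence", treatment, control, n_boot = n_boot, boot_seed = boot_seed)
}

#' @export
print.turnover_fit <- function(x, ...) {
  lab <- if (x$mode == "decay") {
    sprintf("time-decay (%s)", x$treatment)
  } else {
    sprintf("divergence (%s vs %s)", x$treatment, x$control)
  }
  cat(sprintf("Turnover %s: slope = %.5f d^-1, R2 = %.3f, p = %.3g, %d pairs\n",
              lab, x$slope, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

#' Tidiers for turnover fits
#'
#' `tidy()` returns the regression terms; `glance()` a one-row model
#' summary with the turnover slope (d^-1), its bootstrap standard error
#' and normal-theory 95% confidence bounds built on it.
#'
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @method tidy turnover_fit
#' @export
tidy.turnover_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "delta_day"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.turnover_fit
#' @method glance turnover_fit
#' @export
glance.turnover_fit <- function(x, ...) {
  half <- stats::qnorm(0.975) * x$slope_se
  tibble::tibble(mode = x$mode, treatment = x$treatment,
                 slope = x$slope, slope_se = x$slope_se,
                 conf_low = x$slope - half, conf_high = x$slope + half,
                 intercept = x$intercept, r_squared = x$r_squared,
                 p_value = x$p_value, n_pairs = x$n_pairs)
}

#' QMP/RMP stage-trend disagreement
#'
#' For each feature, fits the per-(treatment, stage) mean abundance
#' against stage day on both the quantitative and the relative scale and
#' compares the signs of the two slopes. Reports the share of features
#' whose temporal trend flips sign between scales — the bias incurred by
#' interpreting relative data as load.
#'
#' @param quant Absolute-abundance tibble ([absolute_abundance()]).
#' @param rel Relative-abundance tibble ([relative_abundance()]).
#' @param metadata Sample metadata.
#' @return A list with `per_feature` (tibble `feature_id`, `treatment`,
#'   `slope_qmp`, `slope_rmp`, `disagree`) and `share_disagreeing`.
#' @export
scale_trend_disagreement <- function(quant, rel, metadata) {
  shared <- intersect(feature_ids(quant), feature_ids(rel))
  slopes <- function(profile, scale_name) {
    means <- stage_average(profile[c("sample_id", shared)], metadata)
    out <- dplyr::summarise(
      dplyr::group_by(means, .data$feature_id, .data$treatment),
      slope = {
        if (dplyr::n_distinct(.data$stage_day) < 2 ||
            stats::sd(.data$mean_abundance) == 0) 0
        else unname(stats::coef(stats::lm(mean_abundance ~ stage_day))[2])
      },
      .groups = "drop")
    dplyr::rename(out, !!paste0("slope_", scale_name) := "slope")
  }
  per <- dplyr::inner_join(slopes(quant, "qmp"), slopes(rel, "rmp"),
                           by = c("feature_id", "treatment"))
  per <- dplyr::mutate(per, disagree = sign(.data$slope_qmp) != sign(.data$slope_rmp))
  list(per_feature = per,
       share_disagreeing = mean(per$disagree))
}
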