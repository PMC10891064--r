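test_that("Shannon index matches closed forms", {
  prof <- tbl_counts(matrix(c(0.5, 0.5, 0,
                              1, 0, 0,
                              0.5, 0.25, 0.25), nrow = 3, byrow = TRUE,
                            dimnames = list(NULL, c("a", "b", "c"))))
  h <- shannon(prof)$shannon
  expect_equal(h, c(log(2), 0, 1.5 * log(2)), tolerance = 1e-12)
  zero <- tbl_counts(matrix(c(1, 0), nrow = 2, dimnames = list(NULL, "a")))
  expect_error(shannon(zero), "S2")
})

test_that("Bray-Curtis matches its definition", {
  prof <- tbl_counts(matrix(c(6, 2,
                              2, 2,
                              5, 0,
                              0, 5,
                              6, 2), nrow = 5, byrow = TRUE,
                            dimnames = list(NULL, c("x", "y"))))
  D <- as.matrix(bray_curtis(prof))
  expect_equal(D["S1", "S2"], 4 / 12, tolerance = 1e-12)
  expect_equal(D["S3", "S4"], 1)      # disjoint supports
  expect_equal(D["S1", "S5"], 0)      # identical samples
  expect_true(all(abs(D - t(D)) < 1e-15))
  prof0 <- tbl_counts(matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE,
                             dimnames = list(NULL, c("x", "y"))))
  expect_error(bray_curtis(prof0), "S2")
})

test_that("PCoA reproduces simple and Euclidean geometries", {
  # two samples at distance d -> +/- d/2 on axis 1
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  res <- suppressWarnings(pcoa(D2, n_axes = 1))
  expect_equal(sort(res$coordinates$Axis1), c(-0.4, 0.4), tolerance = 1e-9)

  # Euclidean-embeddable distances are reproduced by the full embedding
  withr::with_seed(8, pts <- matrix(rnorm(7 * 3), 7, 3))
  rownames(pts) <- paste0("S", 1:7)
  D <- dist(pts)
  expect_warning(res <- pcoa(D, n_axes = 6), "available")  # rank < request
  emb <- as.matrix(res$coordinates[-1])
  expect_equal(as.matrix(dist(emb)), as.matrix(D), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(res$pct_variance) < 1e-9))  # ordered axes

  # duplicated sample lands on identical coordinates
  pts2 <- rbind(pts, S8 = pts[1, ])
  res2 <- pcoa(dist(pts2), n_axes = 3)
  co <- res2$coordinates
  expect_equal(unlist(co[co$sample_id == "S8", -1]),
               unlist(co[co$sample_id == "S1", -1]), tolerance = 1e-9)
})

test_that("PERMANOVA separates perfectly split groups and matches adonis2", {
  # all within-group distances zero -> R2 = 1
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  rownames(m) <- colnames(m) <- paste0("S", 1:4)
  fit <- permanova(m, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # cross-check R2 and pseudo-F against vegan::adonis2 on random data
  withr::with_seed(14, x <- matrix(abs(rnorm(18 * 5)), 18, 5))
  rownames(x) <- paste0("S", 1:18)
  grp <- rep(c("a", "b", "c"), each = 6)
  D <- vegan::vegdist(x, method = "bray")
  fit <- permanova(D, grp, n_perm = 199, seed = 2)
  ad <- vegan::adonis2(D ~ grp, permutations = 199)
  expect_equal(fit$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(fit$pseudo_F, ad$F[1], tolerance = 1e-10)

  # duplicating every sample (with its label) leaves R2 unchanged
  m2 <- as.matrix(D)
  dup <- rbind(cbind(m2, m2), cbind(m2, m2))
  ids <- c(paste0("S", 1:18), paste0("T", 1:18))
  rownames(dup) <- colnames(dup) <- ids
  diag(dup) <- 0
  fit_dup <- permanova(dup, c(grp, grp), n_perm = 99, seed = 3)
  expect_equal(fit_dup$r_squared, fit$r_squared, tolerance = 1e-10)

  expect_error(permanova(m, c("g1", "g1", "g1", "g2")), "2 samples")
})

test_that("time-decay regression recovers exact and noisy linear trends", {
  drift <- simulate_drift_profiles(rate = 0.001, n_replicates = 1,
                                   noise_sd = 0, seed = 2)
  D <- bray_curtis(drift$profile)
  fit <- time_decay_fit(D, drift$metadata, "Control")
  expect_equal(fit$slope, 0.001, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # OLS agrees with the normal-equations oracle on noisy data
  noisy <- simulate_drift_profiles(rate = 0.003, n_replicates = 3,
                                   noise_sd = 0.05, seed = 5)
  fitn <- time_decay_fit(bray_curtis(noisy$profile), noisy$metadata, "Control")
  oracle <- ols_oracle(fitn$pairs$delta_day, fitn$pairs$distance)
  expect_equal(fitn$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fitn$intercept, unname(oracle["intercept"]), tolerance = 1e-12)

  # constant distances give slope zero
  flat <- simulate_drift_profiles(rate = 0, n_replicates = 2, noise_sd = 0,
                                  seed = 6)
  fit0 <- time_decay_fit(bray_curtis(flat$profile), flat$metadata, "Control")
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
})

test_that("divergence regression tracks a planted linear drift from control", {
  div <- simulate_divergence_profiles(rate = 0.002, n_replicates = 4,
                                      seed = 7)
  D <- bray_curtis(div$profile)
  fit <- divergence_fit(D, div$metadata, "-P")
  ci <- glance(fit)
  expect_gt(fit$slope, 0)
  expect_true(ci$conf_low <= 0.002 && 0.002 <= ci$conf_high)

  # treatment identical to control -> all distances ~ noise-free zero
  same <- simulate_divergence_profiles(rate = 0, n_replicates = 2,
                                       noise_sd = 0, seed = 8)
  fit0 <- divergence_fit(bray_curtis(same$profile), same$metadata, "-P")
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_true(all(fit0$pairs$distance < 1e-12))

  # a single shared stage cannot support the regression
  one <- simulate_divergence_profiles(rate = 0.001, stage_days = 28,
                                      n_replicates = 3, seed = 9)
  expect_error(divergence_fit(bray_curtis(one$profile), one$metadata, "-P"),
               "shared stage")
})

test_that("QMP and RMP stage trends can disagree and the share is reported", {
  # one feature rises in load while all loads rise; its share falls
  days <- c(1, 4, 7, 14, 28, 42, 60, 72)
  md <- toy_metadata(paste0("S", seq_along(days)), stage_day = days)
  total <- 1000 * (1 + 0.1 * days)
  quant <- tbl_counts(cbind(slowgrow = 100 + 0.5 * days,
                            fastgrow = total - (100 + 0.5 * days)),
                      md$sample_id)
  rel <- relative_abundance(quant)
  out <- scale_trend_disagreement(quant, rel, md)
  per <- out$per_feature
  expect_true(per$disagree[per$feature_id == "slowgrow"])
  expect_false(per$disagree[per$feature_id == "fastgrow"])
  expect_equal(out$share_disagreeing, 0.5)
})
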