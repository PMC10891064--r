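test_that("module abundance sums members and conserves the sample total", {
  m <- matrix(c(10, 20, 5,
                1, 2, 3), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("A1", "A2", "B1")))
  quant <- tbl_counts(m, c("S1", "S2"))
  md <- toy_metadata(c("S1", "S2"))
  modules <- tibble::tibble(feature_id = c("A1", "A2", "B1"),
                            module = c("module1", "module1", "background"))
  ma <- module_abundance(quant, modules, md)
  expect_equal(ma$abundance[ma$module == "module1" & ma$sample_id == "S1"], 30)
  totals <- tapply(ma$abundance, ma$sample_id, sum)
  expect_equal(unname(totals[c("S1", "S2")]), rowSums(m),
               ignore_attr = TRUE)

  orphan <- tibble::tibble(feature_id = "ZZ", module = "module9")
  expect_error(module_abundance(quant, orphan, md), "module")
})

test_that("a planted 3x module effect appears in the module stage-mean ratio", {
  cfg <- sim_config(treatments = c("Control", "-N"), n_replicates = 8,
                    n_asvs = 60, module_size = 10, n_modules = 2,
                    module_effects = list(`-N` = c(module2 = 3)), seed = 27)
  truth <- simulate_dynamics(cfg)
  ma <- module_abundance(truth$abundance, truth$modules, truth$metadata)
  means <- module_stage_means(ma)
  m2 <- means[means$module == "module2", ]
  ratio <- mean(m2$mean_abundance[m2$treatment == "-N"]) /
    mean(m2$mean_abundance[m2$treatment == "Control"])
  expect_lt(abs(ratio - 3) / 3, 0.25)  # simulation CI at these sizes

  enr <- module_enrichment(ma)
  expect_equal(enr$status[enr$module == "module2" & enr$treatment == "-N"],
               "enriched")
  expect_equal(enr$status[enr$module == "module1" & enr$treatment == "-N"],
               "ns")
})

test_that("Kruskal-Wallis H matches the rank formula and handles ties", {
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  values <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  kd <- kruskal_dunn(values, groups)
  expect_equal(kd$H, kw_oracle(values, groups), tolerance = 1e-12)
  ref <- stats::kruskal.test(values, factor(groups))
  expect_equal(kd$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kd$p_overall, ref$p.value, tolerance = 1e-12)

  # identical groups: H = 0, p = 1
  kd0 <- kruskal_dunn(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kd0$H, 0)
  expect_equal(kd0$p_overall, 1)

  # tie-corrected H still matches kruskal.test
  withr::with_seed(6, vt <- sample(1:4, 15, replace = TRUE))
  gt <- rep(c("a", "b", "c"), each = 5)
  expect_equal(kruskal_dunn(vt, gt)$H,
               unname(stats::kruskal.test(vt, factor(gt))$statistic),
               tolerance = 1e-12)

  # reference comparisons cover every non-reference group
  kdr <- kruskal_dunn(values, groups, reference = "g1")
  expect_setequal(kdr$comparisons$group_a, c("g2", "g3"))
  expect_true(all(kdr$comparisons$group_b == "g1"))
})

test_that("pairwise identity matches trivial cases and the DP oracle", {
  s <- strrep("ACGT", 25)
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity("AAAA", "AAAA"), 100)

  one_sub <- paste0(substr(s, 1, 49), "T", substr(s, 51, 100))
  expect_equal(pairwise_identity(s, one_sub), 99)

  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"),
               align_dp_oracle("ACGTACGT", "ACGTACGT")$identity)
  # gapped toy pair: deletion of 3 nt inside an otherwise exact match
  a <- "ACGTACGTACGTACGTACGT"
  b <- paste0(substr(a, 1, 8), substr(a, 12, 20))  # drop 3 nt
  oracle <- align_dp_oracle(a, b)
  expect_equal(pairwise_identity(a, b), oracle$identity, tolerance = 1e-9)

  expect_equal(pairwise_identity("AACGT", "CA"), pairwise_identity("CA", "AACGT"))
  expect_error(pairwise_identity("ACGU", "ACGT"), "A/C/G/T/N")
})

test_that("isolate matching keeps the best strain above the strict 95% line", {
  withr::with_seed(51, {
    asv <- simulate_asv_sequences(c("ASVx", "ASVy"), length = 400, seed = 61)
  })
  iso_spec <- tibble::tibble(
    strain_id = c("stA", "stB", "stC"),
    source_feature = c("ASVx", "ASVx", "ASVy"),
    target_identity = c(96, 98, 92))
  isolates <- simulate_isolates(asv, iso_spec, seed = 62)
  matches <- match_isolates(asv, isolates, min_identity = 95)

  mx <- matches[matches$feature_id == "ASVx", ]
  expect_true(mx$matched)
  expect_equal(mx$strain_id, "stB")      # 98% beats 96%
  expect_gt(mx$identity, 95)

  my <- matches[matches$feature_id == "ASVy", ]
  expect_false(my$matched)               # ~92% < 95

  # exact ties break lexicographically by strain id
  tie_iso <- tibble::tibble(strain_id = c("zz", "aa"),
                            sequence = c(asv[["ASVx"]], asv[["ASVx"]]))
  tie <- match_isolates(asv["ASVx"], tie_iso)
  expect_equal(tie$strain_id, "aa")
})

test_that("SynCom design applies one-per-genus and family exclusion rules", {
  tax <- tibble::tibble(
    feature_id = paste0("ASV", 1:5),
    kingdom = "Bacteria", phylum = "p", class = "c", order = "o",
    family = c("F1", "F2", "Bradyrhizobiaceae", "F3", "F4"),
    genus = c("Rhodococcus", "Lysobacter", "Bradyrhizobium", "Bosea", "Bosea"))
  matches <- tibble::tibble(
    feature_id = paste0("ASV", 1:5),
    strain_id = paste0("st", 1:5),
    identity = c(97, 98, 99, 96, 98.5),
    matched = TRUE)
  plan <- design_syncom(paste0("ASV", 1:5), matches, tax, name = "test")
  expect_s3_class(plan, "syncom_plan")
  # Bradyrhizobiaceae excluded; Bosea deduplicated to the 98.5% strain
  expect_setequal(plan$members$strain_id, c("st1", "st2", "st5"))
  expect_false("st3" %in% plan$members$strain_id)
  expect_true(all(plan$members$identity > 95))
  expect_equal(anyDuplicated(plan$members$genus), 0)
  expect_true("st3" %in% plan$exclusions$strain_id)

  # seven distinct genera, no exclusions -> all seven retained
  tax7 <- tibble::tibble(
    feature_id = paste0("A", 1:7), kingdom = "Bacteria", phylum = "p",
    class = "c", order = "o", family = paste0("F", 1:7),
    genus = c("Rhodococcus", "Lysobacter", "Terrabacter", "Arthrobacter",
              "Phyllobacterium", "Bosea", "Aeromicrobium"))
  m7 <- tibble::tibble(feature_id = paste0("A", 1:7),
                       strain_id = paste0("s", 1:7),
                       identity = 96 + (1:7) / 10, matched = TRUE)
  plan7 <- design_syncom(paste0("A", 1:7), m7, tax7)
  expect_equal(nrow(plan7$members), 7)

  # membership does not depend on isolate input order
  plan7b <- design_syncom(paste0("A", 1:7), m7[sample(7), ], tax7)
  expect_setequal(plan7$members$strain_id, plan7b$members$strain_id)

  # cap by identity
  plan5 <- design_syncom(paste0("A", 1:7), m7, tax7, max_members = 5)
  expect_equal(nrow(plan5$members), 5)
  expect_true(all(plan5$members$identity >= sort(m7$identity, decreasing = TRUE)[5]))

  expect_warning(empty <- design_syncom("A1", m7[0, ], tax7), "empty plan")
  expect_equal(nrow(empty$members), 0)
})
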