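test_that("Spearman edges match rank-then-Pearson and cor.test", {
  withr::with_seed(3, {
    x <- rnorm(20)
    m <- cbind(up = sort(x), alsoup = sort(rnorm(20)), down = rev(sort(rnorm(20))),
               tied = sample(rep(1:5, 4)), noise = rnorm(20))
  })
  cors <- spearman_edges(tbl_counts(m))
  expect_equal(cors$rho["up", "alsoup"], 1)
  expect_equal(cors$rho["up", "down"], -1)
  expect_equal(cors$rho["tied", "noise"],
               spearman_oracle(m[, "tied"], m[, "noise"]), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(m[, "tied"], m[, "noise"],
                                         method = "spearman"))
  expect_equal(cors$rho["tied", "noise"], unname(ct$estimate),
               tolerance = 1e-12)
  # t-approximation p agrees with cor.test on tie-free columns
  ct2 <- stats::cor.test(m[, "noise"], m[, "alsoup"], method = "spearman")
  p_t <- cors$p["noise", "alsoup"]
  expect_equal(p_t, ct2$p.value, tolerance = 0.05)

  # constant feature yields no testable pair
  m2 <- cbind(m, flat = rep(1, 20))
  cors2 <- spearman_edges(tbl_counts(m2))
  expect_true(all(is.na(cors2$rho["flat", ])))
})

test_that("edges require both the |rho| > 0.8 and adjusted p < 0.05 gates", {
  nodes <- c("a", "b", "c", "d")
  rho <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  p <- matrix(1, 4, 4, dimnames = list(nodes, nodes))
  set_pair <- function(i, j, r, pv) {
    rho[i, j] <<- rho[j, i] <<- r
    p[i, j] <<- p[j, i] <<- pv
  }
  set_pair("a", "b", 0.85, 1e-4)   # passes both gates
  set_pair("a", "c", 0.75, 1e-6)   # |rho| too small despite tiny p
  set_pair("b", "c", -0.9, 0.2)    # p too large despite strong rho
  set_pair("c", "d", -0.85, 1e-4)  # negative edge passes
  diag(rho) <- diag(p) <- NA
  net <- build_network(list(rho = rho, p = p), rho_cut = 0.8, alpha = 0.05)
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("a b", "c d"))
  expect_equal(net$metrics$n_nodes, 4)
  expect_equal(net$metrics$average_degree, 2 * 2 / 4)
})

test_that("FDR uses the whole pair family before thresholding", {
  # many mediocre p-values push an individually significant pair over 0.05
  nodes <- sprintf("n%02d", 1:20)
  k <- length(nodes)
  withr::with_seed(4, {
    p <- matrix(runif(k * k, 0.2, 1), k, k, dimnames = list(nodes, nodes))
  })
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  rho <- matrix(0.95, k, k, dimnames = list(nodes, nodes))
  p["n01", "n02"] <- p["n02", "n01"] <- 0.01
  diag(p) <- diag(rho) <- NA
  with_fdr <- build_network(list(rho = rho, p = p), fdr = TRUE)
  without <- build_network(list(rho = rho, p = p), fdr = FALSE)
  expect_equal(nrow(with_fdr$edges), 0)   # q = 0.01 * 190 >> 0.05
  expect_equal(nrow(without$edges), 1)
})

test_that("modules recover disconnected cliques and Q matches the closed form", {
  clique_edges <- function(members) {
    pr <- t(utils::combn(members, 2))
    tibble::tibble(from = pr[, 1], to = pr[, 2], rho = 0.9, q = 0.01)
  }
  g1 <- paste0("a", 1:5)
  g2 <- paste0("b", 1:5)
  edges <- dplyr::bind_rows(clique_edges(g1), clique_edges(g2))
  net <- manual_network(c(g1, g2), edges)
  net <- detect_modules(net, seed = 1)
  mods <- module_membership(net)
  expect_equal(dplyr::n_distinct(mods$module), 2)
  expect_equal(dplyr::n_distinct(mods$module[mods$feature_id %in% g1]), 1)
  expect_equal(dplyr::n_distinct(mods$module[mods$feature_id %in% g2]), 1)

  memb <- stats::setNames(mods$module, mods$feature_id)
  expect_equal(net$metrics$modularity_Q, modularity_oracle(edges, memb),
               tolerance = 1e-12)
  # detected partition beats all-singletons (whose Q is negative here)
  singletons <- stats::setNames(paste0("m", seq_along(memb)), names(memb))
  expect_gt(net$metrics$modularity_Q, modularity_oracle(edges, singletons))

  empty <- manual_network(c("x", "y"), tibble::tibble(from = character(0),
                                                      to = character(0),
                                                      rho = numeric(0),
                                                      q = numeric(0)))
  expect_error(detect_modules(empty), "no edges")
})

test_that("node roles follow the Zi/Pi definitions", {
  # hub with all 4 edges inside its module: Pi = 0
  # bridge with edges split 2/2 across modules: Pi = 0.5
  edges <- tibble::tibble(
    from = c("h", "h", "h", "h", "s1", "s1", "bridge", "bridge", "bridge", "bridge"),
    to = c("m1", "m2", "m3", "m4", "m1", "m2", "m1", "m2", "o1", "o2"),
    rho = 0.9, q = 0.01)
  module <- c(h = "A", m1 = "A", m2 = "A", m3 = "A", m4 = "A", s1 = "A",
              bridge = "B", o1 = "B", o2 = "B", iso = "B")
  net <- manual_network(names(module), edges, module)
  roles <- node_roles(net)
  get <- function(n, col) roles[[col]][roles$node == n]
  expect_equal(get("h", "Pi"), 0)
  expect_equal(get("bridge", "Pi"), 1 - (0.25 + 0.25))
  expect_equal(get("iso", "Zi"), 0)
  expect_equal(get("iso", "Pi"), 0)
  expect_equal(get("iso", "role"), "peripheral")

  # all-equal within-degrees -> Zi = 0 by the sd = 0 convention
  sq <- tibble::tibble(from = c("p1", "p2", "p3", "p4"),
                       to = c("p2", "p3", "p4", "p1"), rho = 0.9, q = 0.01)
  ring <- manual_network(paste0("p", 1:4), sq,
                         c(p1 = "A", p2 = "A", p3 = "A", p4 = "A"))
  expect_true(all(node_roles(ring)$Zi == 0))

  # brute-force oracle agreement on random graphs with random partitions
  withr::with_seed(44, {
    for (i in 1:10) {
      gr <- random_graph_with_modules(n = 18, p = 0.2, k = 3)
      net <- manual_network(gr$nodes, gr$edges, gr$module)
      roles <- node_roles(net)
      oracle <- zi_pi_oracle(gr$edges, gr$module)
      expect_equal(roles$Zi, oracle$Zi[match(roles$node, oracle$node)],
                   tolerance = 1e-12)
      expect_equal(roles$Pi, oracle$Pi[match(roles$node, oracle$node)],
                   tolerance = 1e-12)
    }
  })
})

test_that("role thresholds classify hubs and connectors", {
  # module hub: many within-module edges concentrated on one node
  center <- "hub"
  leaves <- paste0("l", 1:14)
  star <- tibble::tibble(from = center, to = leaves, rho = 0.9, q = 0.01)
  extra <- tibble::tibble(from = "l1", to = "l2", rho = 0.9, q = 0.01)
  module <- stats::setNames(rep("A", 15), c(center, leaves))
  net <- manual_network(c(center, leaves), dplyr::bind_rows(star, extra),
                        module)
  rr <- node_roles(net)
  expect_equal(rr$role[rr$node == "hub"], "module_hub")
  expect_gt(rr$Zi[rr$node == "hub"], 2.5)

  # connector: degree split across three modules
  edges <- tibble::tibble(from = c("c", "c", "c", "a1", "b1"),
                          to = c("a1", "b1", "d1", "a2", "b2"),
                          rho = 0.9, q = 0.01)
  module <- c(c = "C", a1 = "A", a2 = "A", b1 = "B", b2 = "B", d1 = "D")
  net2 <- manual_network(names(module), edges, module)
  rr2 <- node_roles(net2)
  expect_equal(rr2$Pi[rr2$node == "c"], 1 - 3 * (1 / 3)^2)
  expect_equal(rr2$role[rr2$node == "c"], "connector")
})

test_that("robustness behaves on complete, edgeless and path graphs", {
  k10 <- igraph::make_full_graph(10)
  r <- robustness(k10, removal_fraction = 0.5, reps = 30, seed = 1)
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)

  empty10 <- igraph::make_empty_graph(10, directed = FALSE)
  r0 <- robustness(empty10, removal_fraction = 0.5, reps = 30, seed = 1)
  expect_equal(r0$mean, 0.2)  # LCC is a single node among 5 survivors

  p10 <- igraph::make_ring(10, circular = FALSE)
  rp <- robustness(p10, removal_fraction = 0.5, reps = 3000, seed = 2)
  exact <- robustness_exhaustive(p10, 0.5)
  se <- rp$sd / sqrt(rp$reps)
  expect_lt(abs(rp$mean - exact), 3 * se + 1e-9)

  expect_error(robustness(p10, removal_fraction = 1.2), "removal_fraction")
})

test_that("robustness decreases with heavier removal on sparse graphs", {
  withr::with_seed(10, g <- igraph::sample_gnp(40, 0.06))
  means <- vapply(c(0.2, 0.5, 0.8), function(f) {
    robustness(g, removal_fraction = f, reps = 300, seed = 5)$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0.05))  # non-increasing up to MC noise
})

test_that("stage networks gain edges as planted correlations strengthen", {
  # correlation strength rises across stage groups: the latent factor's
  # weight grows from weak to dominant
  withr::with_seed(33, {
    md <- toy_metadata(sprintf("S%02d", 1:36),
                       stage_day = rep(c(1, 28, 60), each = 12))
    sigmas <- c(`1` = 1.5, `28` = 0.5, `60` = 0.1)  # noise shrinks late
    feats <- sprintf("F%02d", 1:8)
    prof <- t(vapply(seq_len(36), function(i) {
      latent <- exp(rnorm(1, 0, 1))
      s <- sigmas[[as.character(md$stage_day[i])]]
      1e6 * latent * exp(rnorm(8, 0, s))
    }, numeric(8)))
    colnames(prof) <- feats
  })
  quant <- tbl_counts(prof, md$sample_id)
  nets <- build_stage_networks(quant, md, "Control", feats,
                               stage_groups = list(early = 1, mid = 28,
                                                   late = 60))
  deg <- nets$average_degree[match(c("early", "mid", "late"),
                                   nets$stage_group)]
  expect_true(all(diff(deg) >= 0))
  expect_equal(nets$stage_group[4], "pooled")
})
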