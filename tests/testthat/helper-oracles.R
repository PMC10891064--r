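# Independent oracles: deliberately naive implementations (loops,
# enumeration, closed forms) against which the package's vectorized /
# library-backed routines are checked.

# counts tibble from a plain matrix
tbl_counts <- function(m, sample_ids = NULL, spike = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  rownames(m) <- sample_ids
  out <- tibble::as_tibble(m, rownames = "sample_id")
  attr(out, "spike_ids") <- spike
  out
}

toy_metadata <- function(sample_ids, treatment = "Control",
                         compartment = "rhizosphere", stage_day = 1,
                         mass = 0.5) {
  n <- length(sample_ids)
  tibble::tibble(sample_id = sample_ids,
                 treatment = rep_len(treatment, n),
                 compartment = rep_len(compartment, n),
                 stage_day = rep_len(stage_day, n),
                 replicate_id = paste0("r", seq_len(n)),
                 sample_mass_g = rep_len(mass, n))
}

# OLS slope/intercept via normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# exact two-sided signed-rank p by brute-force sign enumeration
# (expand.grid construction, independent of the package's bit-mask sums)
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# BH step-up by explicit sorting
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Spearman rho by rank-then-Pearson
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Kruskal-Wallis H by the rank formula, tie-free data only
kw_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  ns <- table(groups)
  (12 / (n * (n + 1))) * sum(ns * (rb[names(ns)] - (n + 1) / 2)^2)
}

# Zi and Pi by explicit per-node loops over the edge list
zi_pi_oracle <- function(edges, module) {
  nodes <- names(module)
  nbrs <- lapply(nodes, function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  names(nbrs) <- nodes
  k_within <- vapply(nodes, function(v) {
    sum(module[nbrs[[v]]] == module[[v]])
  }, numeric(1))
  zi <- vapply(nodes, function(v) {
    if (length(nbrs[[v]]) == 0) return(0)  # isolated-node convention
    members <- nodes[module == module[[v]]]
    mu <- mean(k_within[members])
    sdv <- stats::sd(k_within[members])
    if (length(members) < 2 || is.na(sdv) || sdv == 0) 0
    else (k_within[[v]] - mu) / sdv
  }, numeric(1))
  pi <- vapply(nodes, function(v) {
    k <- length(nbrs[[v]])
    if (k == 0) return(0)
    shares <- table(module[nbrs[[v]]]) / k
    1 - sum(shares^2)
  }, numeric(1))
  tibble::tibble(node = nodes, Zi = unname(zi), Pi = unname(pi))
}

# Newman-Girvan modularity by the per-community closed form
modularity_oracle <- function(edges, module) {
  m <- nrow(edges)
  deg <- table(c(edges$from, edges$to))
  q <- 0
  for (cm in unique(module)) {
    members <- names(module)[module == cm]
    e_in <- sum(edges$from %in% members & edges$to %in% members)
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + e_in / m - (d_c / (2 * m))^2
  }
  q
}

# exhaustive LCC-fraction robustness over all removal subsets
robustness_exhaustive <- function(g, f) {
  n <- igraph::vcount(g)
  k <- floor(f * n)
  sets <- utils::combn(n, k, simplify = FALSE)
  mean(vapply(sets, function(doomed) {
    sub <- igraph::delete_vertices(g, doomed)
    max(igraph::components(sub)$csize) / igraph::vcount(sub)
  }, numeric(1)))
}

# random undirected graph as an edge tibble plus a random module partition
random_graph_with_modules <- function(n = 20, p = 0.15, k = 3) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          rho = 0.9, q = 0.01)
  module <- stats::setNames(
    paste0("module", sample.int(k, n, replace = TRUE)), nodes)
  list(nodes = nodes, edges = edges, module = module)
}

# wrap an edge tibble as a co_network with a fixed module assignment
manual_network <- function(nodes, edges, module = NULL) {
  net <- build_network(edges_to_cors(nodes, edges), rho_cut = 0.8,
                       alpha = 0.05, fdr = FALSE)
  if (!is.null(module)) {
    net$nodes$module <- unname(module[net$nodes$node])
  }
  net
}

# synthesize rho/p matrices that reproduce a desired edge list exactly
edges_to_cors <- function(nodes, edges) {
  k <- length(nodes)
  rho <- matrix(0, k, k, dimnames = list(nodes, nodes))
  p <- matrix(1, k, k, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    rho[a, b] <- rho[b, a] <- edges$rho[i]
    p[a, b] <- p[b, a] <- 1e-12
  }
  diag(rho) <- NA
  diag(p) <- NA
  list(rho = rho, p = p, n = 50)
}

# planted-partition graph: k blocks of size b, within prob p_in,
# between prob p_out
planted_partition <- function(k = 3, b = 30, p_in = 0.5, p_out = 0.01) {
  n <- k * b
  nodes <- sprintf("n%03d", seq_len(n))
  block <- rep(seq_len(k), each = b)
  pairs <- t(utils::combn(n, 2))
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          rho = 0.9, q = 0.001)
  list(nodes = nodes, edges = edges,
       truth = stats::setNames(paste0("module", block), nodes))
}

# semi-global (free end gaps) affine-gap alignment by full Gotoh DP with
# traceback; scores: match, mismatch, gap of length L costs open + L * ext
align_dp_oracle <- function(a, b, match = 2, mismatch = -1,
                            gap_open = 2, gap_ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # gap in B (consume A)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in A (consume B)
  M[1, 1] <- 0
  # free end gaps: any prefix of either sequence can be skipped for free
  M[, 1] <- 0
  M[1, ] <- 0
  ptr <- array("", c(n + 1, m + 1, 3))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- max(prev) + s
      ptr[i + 1, j + 1, 1] <- c("M", "X", "Y")[which.max(prev)]
      x_opt <- c(M[i, j + 1] - gap_open - gap_ext, X[i, j + 1] - gap_ext)
      X[i + 1, j + 1] <- max(x_opt)
      ptr[i + 1, j + 1, 2] <- c("M", "X")[which.max(x_opt)]
      y_opt <- c(M[i + 1, j] - gap_open - gap_ext, Y[i + 1, j] - gap_ext)
      Y[i + 1, j + 1] <- max(y_opt)
      ptr[i + 1, j + 1, 3] <- c("M", "Y")[which.max(y_opt)]
    }
  }
  # best score on the last row or column (free terminal gaps)
  best <- NEG; bi <- bj <- 1; bs <- "M"
  for (i in seq_len(n + 1)) {
    for (st in 1:3) {
      val <- list(M, X, Y)[[st]][i, m + 1]
      if (val > best) { best <- val; bi <- i; bj <- m + 1; bs <- c("M", "X", "Y")[st] }
    }
  }
  for (j in seq_len(m + 1)) {
    for (st in 1:3) {
      val <- list(M, X, Y)[[st]][n + 1, j]
      if (val > best) { best <- val; bi <- n + 1; bj <- j; bs <- c("M", "X", "Y")[st] }
    }
  }
  # traceback to count matches and aligned columns
  i <- bi; j <- bj; st <- bs
  matches <- 0; cols <- 0
  while (i > 1 && j > 1) {
    if (st == "M") {
      nxt <- ptr[i, j, 1]
      matches <- matches + (A[i - 1] == B[j - 1])
      cols <- cols + 1
      i <- i - 1; j <- j - 1; st <- nxt
    } else if (st == "X") {
      nxt <- ptr[i, j, 2]
      cols <- cols + 1
      i <- i - 1; st <- nxt
    } else {
      nxt <- ptr[i, j, 3]
      cols <- cols + 1
      j <- j - 1; st <- nxt
    }
  }
  list(score = best, matches = matches, columns = cols,
       identity = 100 * matches / cols)
}
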