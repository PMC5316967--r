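test_that("seed-gene correlation profile recovers planted co-expression", {
  sim <- simulate_multicancer(
    simulation_config(n_cancers = 1, n_tumour = 300, n_normal = 0,
                      n_genes = 40, n_program_genes = 20, rng_seed = 111))
  b <- sim$bundles[[1]]
  prof <- seedgene_correlation_profile(b, "SFRP2")
  expect_equal(prof$r[prof$gene == "SFRP2"], 1)
  expect_gt(prof$r[prof$gene == "PRG001"], 0.5)
  expect_lt(abs(prof$r[prof$gene == "BGD001"]), 0.3)
  expect_error(seedgene_correlation_profile(b, "NOPE"), "NOPE")

  # a constant gene gets an undefined entry
  b$expression["BGD002", ] <- 3
  prof2 <- seedgene_correlation_profile(b, "SFRP2")
  expect_true(is.na(prof2$r[prof2$gene == "BGD002"]))
})

test_that("consensus rule evaluates fractions inclusively and r strictly", {
  pa <- list(fake_profile("C1", "SA", c("G1", "G2", "G3"), c(0.6, 0, 0.5)),
             fake_profile("C2", "SA", c("G1", "G2", "G3"), c(0.4, 0, 0.5)))
  pb <- list(fake_profile("C1", "SB", c("G1", "G2", "G3"), c(0.7, 0, 0.5)),
             fake_profile("C2", "SB", c("G1", "G2", "G3"), c(0.55, 0, 0.5)))
  got <- consensus_gene_set(pa, pb)
  expect_identical(got, "G1")   # 1/2 >= 50% for A and 2/2 for B
  # all-zero correlations and exactly-0.5 correlations are excluded
  expect_false("G2" %in% got)
  expect_false("G3" %in% got)
  expect_error(consensus_gene_set(list(), pb), "non-empty")
})

test_that("undefined correlations never pass the consensus rule", {
  pa <- list(fake_profile("C1", "SA", "G1", NA_real_),
             fake_profile("C2", "SA", "G1", 0.9))
  pb <- list(fake_profile("C1", "SB", "G1", 0.9),
             fake_profile("C2", "SB", "G1", 0.9))
  expect_identical(consensus_gene_set(pa, pb), "G1")  # 1/2 still passes
  pa2 <- list(fake_profile("C1", "SA", "G1", NA_real_),
              fake_profile("C2", "SA", "G1", NA_real_))
  expect_length(consensus_gene_set(pa2, pb), 0L)
})

test_that("consensus set equals the brute-force oracle on random fixtures", {
  set.seed(121)
  genes <- sprintf("G%02d", 1:50)
  for (i in 1:8) {
    pa <- lapply(1:6, function(k)
      fake_profile(paste0("A", k), "SA", genes, runif(50, -0.2, 0.9)))
    pb <- lapply(1:6, function(k)
      fake_profile(paste0("B", k), "SB", genes, runif(50, -0.2, 0.9)))
    expect_identical(consensus_gene_set(pa, pb), consensus_oracle(pa, pb))
  }
})

test_that("consensus is order-invariant and threshold-monotone", {
  set.seed(131)
  genes <- sprintf("G%02d", 1:30)
  pa <- lapply(1:4, function(k)
    fake_profile(paste0("A", k), "SA", genes, runif(30, 0, 0.9)))
  pb <- lapply(1:4, function(k)
    fake_profile(paste0("B", k), "SB", genes, runif(30, 0, 0.9)))
  base <- consensus_gene_set(pa, pb)
  shuffled <- lapply(rev(pa), function(p) p[sample(nrow(p)), ])
  for (i in seq_along(shuffled)) {
    attr(shuffled[[i]], "seed_gene") <- "SA"
    attr(shuffled[[i]], "cancer_code") <- paste0("A", i)
  }
  expect_identical(consensus_gene_set(shuffled, pb), base)
  expect_true(all(consensus_gene_set(pa, pb, r_threshold = 0.7) %in% base))
  expect_true(all(consensus_gene_set(pa, pb, frac_threshold = 0.75) %in% base))
})

test_that("network edges follow the strict threshold and match the oracle", {
  sim <- simulate_multicancer(
    simulation_config(n_cancers = 1, n_tumour = 300, n_normal = 0,
                      n_genes = 25, n_program_genes = 20, rng_seed = 141))
  b <- sim$bundles[[1]]
  members <- setdiff(sim$truth$program_genes, c("SFRP2", "SFRP4"))
  net <- build_network(b, members, c("SFRP2", "SFRP4"), edge_threshold = 0.8)
  expect_true(all(net$edges$weight > 0.8))
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  expect_true(all(net$nodes$is_seed == (net$nodes$gene %in% c("SFRP2", "SFRP4"))))

  # all-pairs brute-force oracle over the node panel
  tum <- samples_of(b, "primary")
  le <- log2_plus_one(b$expression[net$nodes$gene, tum])
  oracle_edges <- character()
  for (i in seq_len(nrow(le))) for (j in seq_len(nrow(le))) {
    if (i >= j) next
    r <- pearson_oracle(le[i, ], le[j, ])
    if (r > 0.8) {
      pair <- sort(c(rownames(le)[i], rownames(le)[j]))
      oracle_edges <- c(oracle_edges, paste(pair, collapse = "|"))
    }
  }
  got_edges <- paste(net$edges$gene_a, net$edges$gene_b, sep = "|")
  expect_setequal(got_edges, oracle_edges)

  # strictness: setting the threshold to an attained weight drops that edge
  w <- net$edges$weight[1]
  net_eq <- build_network(b, members, c("SFRP2", "SFRP4"), edge_threshold = w)
  expect_false(paste(net$edges$gene_a[1], net$edges$gene_b[1]) %in%
                 paste(net_eq$edges$gene_a, net_eq$edges$gene_b))
  # raising the threshold never adds edges
  expect_lte(nrow(net_eq$edges), nrow(net$edges))

  # absent genes stay as edgeless nodes
  net_miss <- build_network(b, c(members, "GHOST"), c("SFRP2", "SFRP4"))
  expect_true("GHOST" %in% net_miss$nodes$gene)
  expect_identical(net_miss$missing_genes, "GHOST")
  expect_false("GHOST" %in% c(net_miss$edges$gene_a, net_miss$edges$gene_b))
})

test_that("pairwise correlation matrices are symmetric and averageable", {
  sim <- simulate_multicancer(
    simulation_config(n_cancers = 4, n_tumour = 150, n_normal = 0,
                      n_genes = 30, n_program_genes = 10, rng_seed = 151))
  genes <- c("SFRP2", "SFRP4", "BGD001")
  mats <- lapply(sim$bundles, pairwise_correlation_matrix, genes = genes)
  for (m in mats) {
    expect_equal(unname(diag(m)), rep(1, 3))
    expect_equal(m, t(m), tolerance = 1e-12)
  }
  avg <- average_correlation_matrices(mats)
  expect_gt(avg$mean["SFRP2", "SFRP4"], 0.5)
  expect_equal(unname(avg$n["SFRP2", "SFRP4"]), 4L)
  expect_equal(avg$mean["SFRP2", "SFRP4"],
               mean(sapply(mats, function(m) m["SFRP2", "SFRP4"])))
  # averaging two scalar matrices: {0.6, 0.8} -> 0.7
  m1 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(average_correlation_matrices(list(m1, m2))$mean["a", "b"], 0.7)
})

test_that("network export writes SIF, GraphML and tables", {
  sim <- simulate_multicancer(small_config())
  b <- sim$bundles[[1]]
  members <- setdiff(sim$truth$program_genes, c("SFRP2", "SFRP4"))[1:5]
  net <- build_network(b, members, c("SFRP2", "SFRP4"), edge_threshold = 0.5)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, prefix)
  expect_true(all(file.exists(paths)))
  expect_length(readLines(paths[["sif"]]), nrow(net$edges))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  edges <- read.delim(paths[["edges"]])
  expect_equal(edges$weight, net$edges$weight)
})
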