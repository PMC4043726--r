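test_that("haplotype collapsing pools identical alleles with deterministic ids", {
  # 4 identical alleles -> 1 haplotype of multiplicity 4
  m <- mk_marker(rep("ACGT", 4),
                 c("1_F_1_a", "1_F_1_b", "2_M_1_a", "2_M_1_b"))
  h <- collapse_haplotypes(recode_alignment(m))
  expect_length(h$haplotypes, 1L)
  expect_equal(h$haplotypes[[1]]$multiplicity, 4L)

  # {s1, s1, s2} with d(s1, s2) = 1 -> multiplicities (2, 1)
  m2 <- mk_marker(c("ACGT", "ACGT", "ACGA"),
                  c("1_F_1_a", "1_F_1_b", "2_M_1_a"))
  h2 <- collapse_haplotypes(recode_alignment(m2))
  expect_equal(vapply(h2$haplotypes, `[[`, 1L, "multiplicity"), c(2L, 1L))
  expect_equal(h2$dist["H_1", "H_2"], 1L)

  # homozygote record counts twice
  m3 <- mk_marker(c("ACGT", "ACGA"), c("1_F_1_ab", "2_M_1_ab"))
  h3 <- collapse_haplotypes(recode_alignment(m3))
  expect_equal(sum(vapply(h3$haplotypes, `[[`, 1L, "multiplicity")), 4L)

  # ids assigned by decreasing multiplicity, ties broken by sequence
  m4 <- mk_marker(c("TTTT", "AAAA"), c("1_F_1_ab", "2_M_1_ab"))
  h4 <- collapse_haplotypes(recode_alignment(m4))
  expect_equal(h4$haplotypes[[1]]$key, "AAAA")
})

test_that("multiplicities sum to twice the complete individuals; incomplete opt-in", {
  m <- mk_marker(c("ACGT", "ACGA", "GGGG", "CCCC"),
                 c("1_F_1_a", "1_F_1_b", "2_M_1_ab", "3_M_2_a")) # 3_M_2: missing
  g <- pair_alleles(m, toy_regions())
  r <- recode_alignment(m)
  h <- collapse_haplotypes(r, g)
  expect_equal(sum(vapply(h$haplotypes, `[[`, 1L, "multiplicity")),
               2L * sum(!g$missing_allele))
  h_all <- collapse_haplotypes(r, g, include_incomplete = TRUE)
  expect_equal(sum(vapply(h_all$haplotypes, `[[`, 1L, "multiplicity")),
               2L * sum(!g$missing_allele) + 1L)
  # carriers pick up regions from the genotype table
  expect_true(all(unlist(lapply(h$haplotypes,
                                function(x) x$carriers$region)) %in%
                    c("SE_refugia", "Pannonian", "NW_Europe")))
})

test_that("connection limit follows the no-superimposition recursion", {
  # near-certain confidence trusts only single-step connections
  expect_equal(connection_limit(411, 1 - 1e-12), 1L)
  # direct evaluation of the cumulative probability agrees with the limit
  for (m in c(50L, 411L, 992L)) {
    lim <- connection_limit(m, 0.95)
    expect_gte(parsimony_probability(lim, m), 0.95)
    if (lim < m) expect_lt(parsimony_probability(lim + 1L, m), 0.95)
  }
  # non-decreasing in sequence length at fixed confidence
  lims <- vapply(c(50L, 200L, 411L, 504L, 992L, 2000L),
                 connection_limit, 1L, confidence = 0.95)
  expect_true(all(diff(lims) >= 0))

  # Monte-Carlo oracle of the underlying model: probability that j
  # mutations scattered uniformly over m sites hit j distinct sites
  set.seed(11)
  m <- 60L
  for (j in c(2L, 4L, 6L)) {
    hits <- replicate(20000, {
      length(unique(sample.int(m, j, replace = TRUE))) == j
    })
    p_hat <- mean(hits)
    se <- sqrt(p_hat * (1 - p_hat) / 20000)
    expect_lt(abs(p_hat - parsimony_probability(j, m)), 4 * se + 1e-6)
  }
})

test_that("network construction matches the brute-force MSN oracle", {
  # two haplotypes at d = 1: one edge
  m <- mk_marker(c("ACGT", "ACGA"), c("1_F_1_ab", "2_M_1_ab"))
  net <- build_network(collapse_haplotypes(recode_alignment(m)), limit = 5L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 1L)

  # chain A-B-C: the redundant A-C edge at a higher level is excluded
  m2 <- mk_marker(c("AAAA", "AAAT", "AATT"),
                  c("1_F_1_ab", "2_M_1_ab", "3_F_2_ab"))
  h2 <- collapse_haplotypes(recode_alignment(m2))
  net2 <- build_network(h2, limit = 5L)
  expect_equal(nrow(net2$edges), 2L)
  expect_true(all(net2$edges$steps == 1L))

  # pairs beyond the limit never connect
  m3 <- mk_marker(c("AAAAAA", "TTTTAA"), c("1_F_1_ab", "2_M_1_ab"))
  net3 <- build_network(collapse_haplotypes(recode_alignment(m3)), limit = 3L)
  expect_equal(nrow(net3$edges), 0L)
  expect_equal(max(net3$components), 2L)

  # random suite vs oracle
  set.seed(7)
  for (rep in 1:60) {
    k <- sample(2:6, 1)
    L <- sample(4:9, 1)
    seqs <- unique(replicate(k, paste(sample(c("A", "T"), L, TRUE),
                                      collapse = "")))
    labs <- paste0(seq_along(seqs), "_F_1_ab")
    h <- collapse_haplotypes(recode_alignment(aligned_marker(seqs, labs, "r")))
    lim <- sample(1:4, 1)
    net <- build_network(h, lim)
    ids <- rownames(h$dist)
    got <- net$edges
    want <- oracle_msn_edges(h$dist, lim)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want_keys <- sort(paste(ids[want[, 1]], ids[want[, 2]], want[, 3]))
      got_keys <- sort(paste(got$from, got$to, got$steps))
      expect_equal(got_keys, want_keys)
    }
    # invariants: weights within limit; within-component reachability
    expect_true(all(net$edges$steps <= lim))
    for (cmp in unique(net$components)) {
      members <- names(net$components)[net$components == cmp]
      if (length(members) < 2) next
      g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                         vertices = names(net$components))
      sub <- igraph::induced_subgraph(g, members)
      expect_true(igraph::is_connected(sub))
    }
  }
})

test_that("network export round-trips edges and carries node attributes", {
  sim <- simulate_marker(fast_params(5))
  g <- pair_alleles(sim$marker, sim$regions)
  rec <- recode_alignment(sim$marker,
                          repeats = list(sim$annotations$repeat_ann))
  haps <- collapse_haplotypes(rec, g)
  net <- build_network(haps, connection_limit(rec$schema$n_snp + 1L))

  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(sort(paste(back$from, back$to, back$steps)),
               sort(paste(net$edges$from, net$edges$to, net$edges$steps)))

  gml <- tempfile(fileext = ".gml")
  export_network(net, gml, "gml")
  gr <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::gorder(gr), length(net$components))
  expect_true("multiplicity" %in% igraph::vertex_attr_names(gr))
  expect_true(all(stats::na.omit(unique(igraph::V(gr)$region)) %in%
                    c("SE_refugia", "Pannonian", "NW_Europe")))
  expect_error(export_network(net, tsv, "dot"), "arg")

  # inferred intermediate nodes on multi-step edges, off by default
  expect_null(net$inferred)
  net_i <- build_network(haps, connection_limit(rec$schema$n_snp + 1L),
                         infer_intermediates = TRUE)
  if (any(net_i$edges$steps > 1)) {
    expect_equal(nrow(net_i$inferred), sum(net_i$edges$steps - 1L))
  }
})
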