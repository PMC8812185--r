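make_hits <- function(at_rank, dt_rank, chromA = "chrA", chromD = "chrD") {
  n <- length(at_rank)
  list(genes_at = data.table(id = paste0("a", seq_len(n)), chrom = chromA,
                             start = at_rank * 10000L),
       genes_dt = data.table(id = paste0("d", seq_len(n)), chrom = chromD,
                             start = dt_rank * 10000L),
       similarity = data.table(query = paste0("a", seq_len(n)),
                               subject = paste0("d", seq_len(n)),
                               score = 1000, evalue = 1e-100))
}

test_that("a perfectly collinear run forms one block; short runs none", {
  fx <- make_hits(1:10, 1:10)
  got <- find_syntenic_blocks(fx$genes_at, fx$genes_dt, fx$similarity)
  expect_equal(nrow(got$blocks), 1L)
  expect_equal(got$blocks$n_genes, 10L)
  expect_equal(got$blocks$orientation, "+")
  # four collinear genes: below the five-gene minimum
  fx4 <- make_hits(1:4, 1:4)
  got4 <- find_syntenic_blocks(fx4$genes_at, fx4$genes_dt, fx4$similarity)
  expect_equal(nrow(got4$blocks), 0L)
})

test_that("an inversion splits chains as the exhaustive oracle dictates", {
  # ranks 4..10 inverted on the Dt side: the 7-gene reversed segment
  # outscores any forward chain bridging through its last element
  dt_rank <- c(1:3, 10:4, 11:12)
  fx <- make_hits(1:12, dt_rank)
  got <- find_syntenic_blocks(fx$genes_at, fx$genes_dt, fx$similarity,
                              max_gap = 12)
  best <- chain_oracle(1:12, dt_rank, max_gap = 12)
  expect_equal(max(got$blocks$n_genes), best)
  expect_equal(sort(got$blocks$n_genes), c(5L, 7L))
  expect_setequal(got$blocks$orientation, c("+", "-"))
})

test_that("greedy chaining matches the oracle on random small instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1)
    dt_rank <- sample(n)
    fx <- make_hits(seq_len(n), dt_rank)
    got <- find_syntenic_blocks(fx$genes_at, fx$genes_dt, fx$similarity,
                                min_genes = 2, max_gap = n)
    best <- chain_oracle(seq_len(n), dt_rank, max_gap = n)
    if (nrow(got$blocks))
      expect_equal(max(got$blocks$n_genes), best)
    else expect_lt(best, 2)
  }
})

test_that("reciprocal best hits are kept only inside blocks", {
  fx <- make_hits(1:6, 1:6)
  sim <- rbind(fx$similarity,
               data.table(query = paste0("d", 1:6),
                          subject = paste0("a", 1:6),
                          score = 1000, evalue = 1e-100))
  blocks <- find_syntenic_blocks(fx$genes_at, fx$genes_dt, sim)
  pairs <- reciprocal_best_pairs(sim, blocks$hits)
  expect_equal(nrow(pairs), 6L)
  expect_equal(anyDuplicated(pairs$at_gene), 0L)
  expect_equal(anyDuplicated(pairs$dt_gene), 0L)
  # mutual best outside any block -> rejected
  pairs2 <- reciprocal_best_pairs(sim, blocks$hits[0])
  expect_equal(nrow(pairs2), 0L)
  # one-directional best -> rejected
  sim_onedir <- copy(sim)
  sim_onedir[query == "d3", subject := "a4"]
  p3 <- reciprocal_best_pairs(sim_onedir, blocks$hits)
  expect_false("a3" %in% p3$at_gene)
})

test_that("planted homoeolog pairs are recovered with no false pairs", {
  for (sd in 1:3) {
    sim <- simulate_genome(tiny_config(seed = sd))
    at <- sim$genome$genes[chrom == "chrA01"]
    dt <- sim$genome$genes[chrom == "chrD01"]
    blocks <- find_syntenic_blocks(at, dt, sim$truth$similarity)
    pairs <- reciprocal_best_pairs(sim$truth$similarity, blocks$hits)
    rec <- recovery_pairs(pairs, sim$truth$homoeologs)
    expect_gte(rec$recovered, 0.98)
    expect_equal(rec$false, 0L)
  }
})

test_that("expressed means FPKM above one in every replicate", {
  ex <- data.table(gene = "g1", stage = "0DPA", rep = 1:3,
                   fpkm = c(1.5, 1.2, 3.0))
  expect_true(expressed_flags(ex)$expressed)
  ex2 <- copy(ex)[2, fpkm := 0.9]
  expect_false(expressed_flags(ex2)$expressed)
})

test_that("the DE stand-in recovers planted fold changes and stays calibrated", {
  hits <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 100
    mu <- exp(rnorm(n, 3, 0.5))
    de <- seq_len(n) <= 20
    mu2 <- mu * ifelse(de, 8, 1)
    ex <- rbind(
      data.table(gene = rep(paste0("g", 1:n), 3), stage = "0DPA",
                 rep = rep(1:3, each = n),
                 fpkm = rnbinom(3 * n, mu = rep(mu, 3), size = 200)),
      data.table(gene = rep(paste0("g", 1:n), 3), stage = "5DPA",
                 rep = rep(1:3, each = n),
                 fpkm = rnbinom(3 * n, mu = rep(mu2, 3), size = 200)))
    got <- de_standin(ex, "0DPA", "5DPA")
    c(mean(got[gene %in% paste0("g", 1:20), de]),
      mean(got[gene %in% paste0("g", 21:n), de]))
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.95)          # planted 8x changes found
  expect_lte(mean(hits[2, ]), 0.01 + 3 * sqrt(0.01 / 800))  # null rate
})

test_that("bias thresholds are inclusive exactly as printed", {
  mk_ex <- function(at, dt) rbind(
    data.table(gene = "a1", stage = "0DPA", rep = 1:3, fpkm = at),
    data.table(gene = "d1", stage = "0DPA", rep = 1:3, fpkm = dt))
  pairs <- data.table(pair_id = "p1", at_gene = "a1", dt_gene = "d1")
  # ratio exactly 2 with zero variance: FC >= 2 holds inclusively
  got <- bias_calls(mk_ex(rep(20.01, 3), rep(10, 3)), pairs, "0DPA")
  expect_equal(got$bias, "At")
  expect_equal(got$ratio, 2, tolerance = 1e-6)
  # ratio below 2 -> none even when highly significant
  got2 <- bias_calls(mk_ex(rep(18, 3), rep(10, 3)), pairs, "0DPA")
  expect_equal(got2$bias, "none")
  # both silent -> none, flagged
  got3 <- bias_calls(mk_ex(rep(0.4, 3), rep(0.1, 3)), pairs, "0DPA")
  expect_equal(got3$bias, "none")
  expect_true(got3$both_silent)
})

test_that("bias trajectories distinguish conserved from dynamic", {
  mk <- function(b) data.table(pair_id = "p1", bias = b)
  expect_equal(bias_trajectory(lapply(rep("At", 4), mk))$trajectory,
               "conserved_At")
  expect_equal(bias_trajectory(lapply(c("At", "At", "none", "none"),
                                      mk))$trajectory, "dynamic")
  expect_equal(bias_trajectory(lapply(rep("none", 4), mk))$trajectory,
               "none")
})

test_that("planted subgenome bias is recovered through the full call chain", {
  cfg <- tiny_config(seed = 12)
  sim <- simulate_genome(cfg)
  ex <- simulate_expression(sim$genome, sim$truth, cfg)
  got <- bias_calls(ex, sim$truth$homoeologs, "0DPA")
  truth0 <- sim$truth$bias[stage == "0DPA"]
  m <- merge(got, truth0, by = "pair_id")
  planted <- m[bias.y != "none"]
  expect_gte(mean(planted$bias.x == planted$bias.y), 0.9)
  nulls <- m[bias.y == "none"]
  expect_lte(mean(nulls$bias.x != "none"), 0.05)
})

test_that("pair change categories cover all nine DE-state combinations", {
  states <- c("up", "down", "none")
  grid <- CJ(at = states, dt = states)
  got <- pair_change_category(grid$at, grid$dt)
  expect_equal(as.integer(table(got)[c("common", "opposite", "single", "none")]),
               c(2L, 2L, 4L, 1L))
  expect_equal(pair_change_category("up", "none"), "single")
  expect_equal(pair_change_category("up", "up"), "common")
  expect_equal(pair_change_category("up", "down"), "opposite")
})

nets_fixture <- function(at_edges, dt_edges) {
  # four pairs; gene g<p>A on chrA, g<p>D on chrD at distinct bins
  pairs <- data.table(pair_id = paste0("p", 1:4),
                      at_gene = paste0("g", 1:4, "A"),
                      dt_gene = paste0("g", 1:4, "D"))
  genes <- rbind(
    data.table(id = paste0("g", 1:4, "A"), chrom = "chrA",
               start = (1:4) * 50000L + 1000L),
    data.table(id = paste0("g", 1:4, "D"), chrom = "chrD",
               start = (1:4) * 50000L + 1000L))
  genes[, `:=`(end = start + 2000L, strand = "+")]
  mk <- function(edges, chrom) {
    if (!nrow(edges)) return(data.table(chrom1 = character(),
                                        start1 = integer(),
                                        chrom2 = character(),
                                        start2 = integer(),
                                        count = integer(), fdr = numeric()))
    data.table(chrom1 = chrom, start1 = edges$i * 50000L,
               chrom2 = chrom, start2 = edges$j * 50000L,
               count = 20L, fdr = 1e-4)
  }
  list(pairs = pairs, genes = genes,
       at = mk(at_edges, "chrA"), dt = mk(dt_edges, "chrD"))
}

test_that("network divergence equals the hand-count on toy graphs", {
  fx <- nets_fixture(data.table(i = 1L, j = 2L),
                     data.table(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L)))
  net_at <- build_hg_network(fx$at, fx$pairs, fx$genes, "At")
  net_dt <- build_hg_network(fx$dt, fx$pairs, fx$genes, "Dt")
  div <- network_divergence(net_at, net_dt)
  expect_equal(div$dt_vs_at, 2 / 3)           # p2-p3 and p3-p4 are Dt-only
  expect_equal(div$at_vs_dt, 0)
  expect_equal(nrow(div$shared_edges), 1L)
  # identical edge sets -> zero divergence
  fx2 <- nets_fixture(data.table(i = 1L, j = 2L), data.table(i = 1L, j = 2L))
  d2 <- network_divergence(build_hg_network(fx2$at, fx2$pairs, fx2$genes, "At"),
                           build_hg_network(fx2$dt, fx2$pairs, fx2$genes, "Dt"))
  expect_equal(d2$dt_vs_at, 0)
  # disjoint edge sets -> full divergence
  fx3 <- nets_fixture(data.table(i = 1L, j = 2L), data.table(i = 3L, j = 4L))
  d3 <- network_divergence(build_hg_network(fx3$at, fx3$pairs, fx3$genes, "At"),
                           build_hg_network(fx3$dt, fx3$pairs, fx3$genes, "Dt"))
  expect_equal(d3$dt_vs_at, 1)
  expect_true(d3$dt_vs_at >= 0 && d3$dt_vs_at <= 1)
})

test_that("loops touching unpaired genes are excluded and counted", {
  fx <- nets_fixture(data.table(i = 1L, j = 2L), data.table()[0])
  # a loop to a bin with no paired gene
  stray <- data.table(chrom1 = "chrA", start1 = 50000L, chrom2 = "chrA",
                      start2 = 900000L, count = 20L, fdr = 1e-4)
  net <- build_hg_network(rbind(fx$at, stray), fx$pairs, fx$genes, "At")
  expect_equal(net$n_excluded_loops, 1L)
  expect_equal(nrow(net$edges), 1L)
})
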