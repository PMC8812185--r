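test_that("loop filter applies strict FDR and count thresholds", {
  lp <- data.table(chrom1 = "c1", start1 = c(0L, 0L),
                   chrom2 = "c1", start2 = c(50000L, 60000L),
                   count = c(11L, 10L), fdr = c(0.004, 1e-4))
  kept <- filter_loops(lp)
  expect_equal(kept$start2, 50000L)      # 11 > 10 and 0.004 < 0.005
  # output is always a subset of the input
  expect_true(all(paste(kept$start1, kept$start2) %in%
                    paste(lp$start1, lp$start2)))
  expect_error(filter_loops(lp[, .(chrom1, start1)]), "count")
})

test_that("the binomial caller finds nothing on a uniform matrix", {
  m <- matrix(5, 80, 80)
  bm <- dense_to_bm(m, resolution = 5e3, stage = "0DPA")
  calls <- call_loops_standin(bm, max_gap = 70)
  expect_equal(nrow(calls[fdr < 0.005]), 0L)
  expect_error(call_loops_standin(dense_to_bm(matrix(0, 4, 4), 5e3)),
               "empty")
})

test_that("the caller is calibrated on decay-only matrices", {
  excess <- vapply(1:10, function(sd) {
    cfg <- sim_config(seed = sd, chrom_plan = data.table(
      name = "chrA01", length = 4e6, subgenome = "At"),
      genes_per_pair = 40, trans_pairs = 0)
    sim <- simulate_genome(cfg)
    m5 <- simulate_hic(sim$genome, sim$truth, "0DPA", cfg,
                       decay_only = TRUE)
    nrow(call_loops_standin(m5)[fdr < 0.005])
  }, numeric(1))
  expect_true(all(excess <= 1))          # at most one spurious call per run
})

test_that("planted loops are recovered at FDR < 0.005", {
  cfg <- tiny_config(seed = 4)
  sim <- simulate_genome(cfg)
  m5 <- simulate_hic(sim$genome, sim$truth, "0DPA", cfg)
  calls <- call_loops_standin(m5, stage = "0DPA")
  rec <- recovery_loops(calls, sim$truth$loops, "0DPA")
  expect_gte(rec$recovered, 0.8)
  expect_lte(rec$false_rate, 0.05)
})

test_that("anchor classes cover the gene-presence truth table", {
  genes <- data.table(id = "g1", chrom = "c1", start = 1000L, end = 3000L,
                      strand = "+")
  mk <- function(s1, s2) data.table(chrom1 = "c1", start1 = s1,
                                    chrom2 = "c1", start2 = s2,
                                    count = 20L, fdr = 1e-4)
  # gene bin is [0, 5000); bins at 50000/60000 are gene-free
  tt <- rbind(mk(0L, 50000L),       # G-N
              mk(50000L, 60000L),   # N-N
              mk(0L, 0L))           # G-G (degenerate same-bin)
  got <- classify_anchor_loops(tt, genes)
  expect_equal(got$anchor_class, c("G-N", "N-N", "G-G"))
  # exhaustive over {0,1} x {0,1} gene presence
  g2 <- rbind(genes, data.table(id = "g2", chrom = "c1", start = 61000L,
                                end = 63000L, strand = "+"))
  combos <- rbind(mk(0L, 60000L),    # gene x gene
                  mk(0L, 50000L),    # gene x none
                  mk(50000L, 60000L),# none x gene
                  mk(50000L, 55000L))# none x none
  got2 <- classify_anchor_loops(combos, g2)
  expect_equal(got2$anchor_class, c("G-G", "G-N", "G-N", "N-N"))
})

test_that("classification does not alter counts or significance", {
  cfg <- tiny_config(seed = 4)
  sim <- simulate_genome(cfg)
  lp <- data.table(chrom1 = "chrA01", start1 = c(0L, 40000L),
                   chrom2 = "chrA01", start2 = c(200000L, 400000L),
                   count = c(15L, 12L), fdr = c(1e-4, 1e-3))
  tax <- classify_anchor_loops(lp, sim$genome$genes)
  expect_equal(filter_loops(tax)[, .(start1, start2, count, fdr)],
               filter_loops(lp)[, .(start1, start2, count, fdr)])
})

test_that("per-gene loop degree counts touching loops by class", {
  genes <- data.table(id = c("g1", "g2"), chrom = "c1",
                      start = c(1000L, 51000L), end = c(3000L, 53000L),
                      strand = "+")
  lp <- data.table(chrom1 = "c1", start1 = c(0L, 0L),
                   chrom2 = "c1", start2 = c(50000L, 100000L),
                   count = 20L, fdr = 1e-4)
  tax <- classify_anchor_loops(lp, genes)
  deg <- gene_loop_degree(tax, genes)
  expect_equal(deg[id == "g1", .(n_gg, n_gn)],
               data.table(n_gg = 1L, n_gn = 1L))
  expect_equal(deg[id == "g2", .(n_gg, n_gn)],
               data.table(n_gg = 1L, n_gn = 0L))
})

hg_fixture <- function() {
  pairs <- data.table(pair_id = "p1", at_gene = "a1", dt_gene = "d1")
  genes <- data.table(id = c("a1", "d1"), chrom = c("chrA", "chrD"),
                      start = c(1000L, 1000L), end = c(3000L, 3000L),
                      strand = "+")
  ngm <- data.table(at_chrom = "chrA", at_start = 50000L, at_end = 55000L,
                    dt_chrom = "chrD", dt_start = 80000L, dt_end = 85000L)
  lp <- data.table(chrom1 = "chrA", start1 = 0L, chrom2 = "chrA",
                   start2 = 50000L, count = 20L, fdr = 1e-4)
  list(pairs = pairs, genes = genes, ngm = ngm, lp = lp)
}

test_that("HG-HN subtypes follow homology and mark identity", {
  fx <- hg_fixture()
  tax <- classify_anchor_loops(fx$lp, fx$genes)
  # same active mark on both homologous regions -> homo_same
  pk_same <- data.table(stage = "0DPA", mark = "H3K27ac",
                        chrom = c("chrA", "chrD"),
                        start = c(51000L, 81000L), end = c(52000L, 82000L))
  got <- classify_homoeolog_loops(tax, fx$pairs, fx$genes, fx$ngm,
                                  pk_same, stage = "0DPA")
  expect_equal(got$homoeolog_class, "HG-HN")
  expect_equal(got$hn_subtype, "homo_same")
  # counterpart carries only the repressive mark -> homo_different
  pk_diff <- data.table(stage = "0DPA", mark = c("H3K27ac", "H3K9me2"),
                        chrom = c("chrA", "chrD"),
                        start = c(51000L, 81000L), end = c(52000L, 82000L))
  got2 <- classify_homoeolog_loops(tax, fx$pairs, fx$genes, fx$ngm,
                                   pk_diff, stage = "0DPA")
  expect_equal(got2$hn_subtype, "homo_different")
  # anchor absent from the homology map -> non_homo
  ngm_far <- copy(fx$ngm)[, `:=`(at_start = 900000L, at_end = 905000L)]
  got3 <- classify_homoeolog_loops(tax, fx$pairs, fx$genes, ngm_far,
                                   pk_same, stage = "0DPA")
  expect_equal(got3$hn_subtype, "non_homo")
  # no map at all -> n/a with warning
  expect_warning(got4 <- classify_homoeolog_loops(tax, fx$pairs, fx$genes,
                                                  NULL, pk_same,
                                                  stage = "0DPA"),
                 "homology map")
  expect_equal(got4$hn_subtype, "n/a")
})

test_that("HG-HG requires homoeolog genes at both anchors", {
  fx <- hg_fixture()
  genes <- rbind(fx$genes,
                 data.table(id = "a2", chrom = "chrA", start = 101000L,
                            end = 103000L, strand = "+"))
  pairs2 <- rbind(fx$pairs,
                  data.table(pair_id = "p2", at_gene = "a2",
                             dt_gene = "none"))
  lp <- data.table(chrom1 = "chrA", start1 = 0L, chrom2 = "chrA",
                   start2 = 100000L, count = 20L, fdr = 1e-4)
  tax <- classify_anchor_loops(lp, genes)
  got <- suppressWarnings(classify_homoeolog_loops(tax, pairs2, genes))
  expect_equal(got$homoeolog_class, "HG-HG")
})

test_that("gene-density normalisation uses a strict 20-gene threshold", {
  chroms <- data.table(name = "c1", length = 2e6)
  # first 500-kb window: 21 genes (rich); second: exactly 20 (poor)
  genes <- data.table(
    id = paste0("g", 1:41), chrom = "c1",
    start = c(seq(1000, 490000, length.out = 21),
              seq(501000, 990000, length.out = 20)))
  genes[, end := start + 1000L]
  lp <- data.table(chrom1 = "c1", start1 = seq(0L, 45000L, by = 5000L),
                   chrom2 = "c1", start2 = seq(100000L, 145000L, by = 5000L),
                   count = 20L, fdr = 1e-4, stage = "0DPA")
  got <- loop_density_normalizations(lp, genes, chroms)
  an <- got$anchor_norm
  expect_equal(an[class == "gene_rich", prop], 1.0)
  expect_equal(an[class == "gene_poor", n_anchors], 0L)
  # doubling loop counts leaves the positional density unchanged
  lp2 <- rbind(lp, copy(lp)[, `:=`(start1 = start1 + 5000L,
                                   start2 = start2 + 5000L)])
  lp2[, stage := "5DPA"]
  both <- loop_density_normalizations(rbind(lp, lp2), genes, chroms)
  pd <- dcast(both$positional_density, chrom + pos ~ stage,
              value.var = "density", fill = 0)
  expect_equal(pd[["0DPA"]], pd[["5DPA"]], tolerance = 1e-12)
})

test_that("boundary-relative profiles localise anchors inside TADs", {
  tads <- data.table(chrom = "c1", start = 0L, end = 100000L,
                     tad_id = "t1")
  central <- data.table(chrom1 = "c1", start1 = 45000L, chrom2 = "c1",
                        start2 = 45000L, count = 1L, fdr = 0.1)
  got <- boundary_relative_profile(central, tads, n_meta_bins = 10)
  expect_equal(got$profile[density > 0, rel_mid], 0.45)
  # uniform anchors -> roughly flat
  set.seed(2)
  unif <- data.table(chrom1 = "c1",
                     start1 = sample(seq(0L, 95000L, 5000L), 400, TRUE),
                     chrom2 = "c1",
                     start2 = sample(seq(0L, 95000L, 5000L), 400, TRUE),
                     count = 1L, fdr = 0.1)
  gu <- boundary_relative_profile(unif, tads, n_meta_bins = 5)
  expect_lt(diff(range(gu$profile$density)), 0.15)
  # anchors planted at the boundaries -> bimodal mass at the ends
  bd <- data.table(chrom1 = "c1", start1 = rep(0L, 50), chrom2 = "c1",
                   start2 = rep(95000L, 50), count = 1L, fdr = 0.1)
  gb <- boundary_relative_profile(bd, tads, n_meta_bins = 10)
  expect_equal(sum(gb$profile[c(1, 10), density]), 1.0)
  # anchors outside any TAD are counted separately
  out <- data.table(chrom1 = "c1", start1 = 200000L, chrom2 = "c1",
                    start2 = 250000L, count = 1L, fdr = 0.1)
  expect_equal(boundary_relative_profile(out, tads)$n_outside, 2L)
})

test_that("mark-context transitions count active/inactive switches", {
  lp <- data.table(chrom1 = "c1", start1 = 0L, chrom2 = "c1",
                   start2 = 50000L, count = 20L, fdr = 1e-4)
  genes <- data.table(id = "g1", chrom = "c1", start = 1000L, end = 3000L,
                      strand = "+")
  tax <- classify_anchor_loops(lp, genes)
  pk <- data.table(stage = c("0DPA", "5DPA"),
                   mark = c("H3K27ac", "H3K9me2"), chrom = "c1",
                   start = 51000L, end = 52000L)
  got <- mark_context_dynamics(tax, pk, stages = c("0DPA", "5DPA"))
  expect_equal(got$transitions$active_to_inactive, 1L)
  expect_equal(got$transitions$inactive_to_active, 0L)
  # unchanged marks -> no transitions
  pk2 <- data.table(stage = c("0DPA", "5DPA"), mark = "H3K27ac",
                    chrom = "c1", start = 51000L, end = 52000L)
  got2 <- mark_context_dynamics(tax, pk2, stages = c("0DPA", "5DPA"))
  expect_equal(got2$transitions$active_to_inactive, 0L)
  expect_equal(got2$transitions$unchanged, 1L)
})

test_that("the planted loss-of-active-marks trend is recovered", {
  cfg <- tiny_config(seed = 10)
  sim <- simulate_genome(cfg)
  pk <- sim$genome$peaks
  n_act <- pk[mark != "H3K9me2", .N, by = stage][order(stage)]
  expect_gt(pk[mark != "H3K9me2" & stage == "0DPA", .N],
            pk[mark != "H3K9me2" & stage == "20DPA", .N])
  expect_lt(pk[mark == "H3K9me2" & stage == "0DPA", .N],
            pk[mark == "H3K9me2" & stage == "20DPA", .N])
})
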