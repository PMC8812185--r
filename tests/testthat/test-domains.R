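test_that("insulation is zero everywhere defined on a uniform matrix", {
  m <- matrix(4, 40, 40)
  bm <- dense_to_bm(m, resolution = 2e4)
  trk <- insulation_score(bm, window = 5)
  expect_true(all(is.na(trk$score[c(1:5, 36:40)])))
  expect_true(all(abs(trk$score[6:35]) < 1e-12))
  expect_error(insulation_score(bm, window = 25), "window")
})

test_that("two perfect blocks give a unique insulation minimum at the junction", {
  n <- 40
  m <- matrix(1, n, n)
  m[1:20, 1:20] <- 10
  m[21:40, 21:40] <- 10
  bm <- dense_to_bm(m, resolution = 2e4)
  trk <- insulation_score(bm, window = 8)
  def <- which(!is.na(trk$score))
  # the two bins flanking the junction have identical all-cross-block
  # squares; the minimum must sit on one of them and nowhere else
  expect_true(def[which.min(trk$score[def])] %in% c(20L, 21L))
  expect_true(all(trk$score[def][!def %in% c(20L, 21L)] >
                    min(trk$score[def])))
  # brute-force square sums confirm the whole track
  brute <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= 8 || i > n - 8) next
    brute[i] <- mean(m[(i - 8):(i - 1), (i + 1):(i + 8)])
  }
  expect_equal(trk$score, log2(brute / mean(brute, na.rm = TRUE)))
})

test_that("insulation equals the brute-force double loop on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    m <- matrix(rpois(n * n, 5), n, n); m <- m + t(m)
    bm <- dense_to_bm(m, resolution = 2e4)
    w <- 6
    trk <- insulation_score(bm, window = w)
    brute <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i <= w || i > n - w) next
      brute[i] <- mean(m[(i - w):(i - 1), (i + 1):(i + w)])
    }
    expect_equal(trk$score, log2(brute / mean(brute, na.rm = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("uniform matrices produce no internal boundary", {
  m <- matrix(4, 60, 60)
  bm <- dense_to_bm(m, resolution = 2e4)
  trk <- insulation_score(bm, window = 6)
  expect_warning(tads <- call_tads(trk), "no boundary")
  expect_equal(nrow(tads), 1L)
  expect_equal(tads$n_bins, 60L)
})

test_that("the deeper of two nearby minima wins", {
  n <- 40
  sc <- rep(0, n)
  sc[18] <- -0.5
  sc[20] <- -0.9                     # deeper, within delta_window = 3
  trk <- data.table(chrom = "chr1", start = (seq_len(n) - 1L) * 20000L,
                    score = sc)
  setattr(trk, "window", 5L)
  tads <- call_tads(trk, delta_window = 3, min_depth = 0.2)
  expect_true(380000L %in% tads$start)             # boundary at bin 20
  expect_false(340000L %in% tads$start)            # shallower rival loses
})

test_that("planted TAD boundaries are recovered within one bin", {
  rec <- vapply(1:3, function(sd) {
    cfg <- tiny_config(seed = sd)
    sim <- simulate_genome(cfg)
    m20 <- ice_balance(aggregate_matrix(
      simulate_hic(sim$genome, sim$truth, "0DPA", cfg), 2e4))
    tads <- call_tads(insulation_multi(m20), stage = "0DPA")
    recovery_boundaries(tads, sim$truth$tads, "0DPA")
  }, numeric(1))
  expect_gte(mean(rec), 0.9)      # across seeds at the miniature scale
  expect_true(all(rec >= 0.85))
})

test_that("TAD tiling covers chromosomes without overlap", {
  cfg <- tiny_config(seed = 14)
  sim <- simulate_genome(cfg)
  m20 <- ice_balance(aggregate_matrix(
    simulate_hic(sim$genome, sim$truth, "0DPA", cfg), 2e4))
  tads <- call_tads(insulation_score(m20), stage = "0DPA")
  for (cn in unique(tads$chrom)) {
    tc <- tads[chrom == cn][order(start)]
    expect_equal(tc$start[1], 0)
    expect_equal(tc$start[-1], tc$end[-nrow(tc)])   # contiguous, no overlap
    expect_true(all(tc$n_bins >= 3))
  }
})

test_that("boundary conservation uses an inclusive 40-kb tolerance", {
  t1 <- data.table(chrom = "chr1", start = c(0L, 300000L),
                   end = c(300000L, 600000L))
  expect_true(all(conserved_boundaries(t1, t1)$conserved))
  shift40 <- data.table(chrom = "chr1", start = c(0L, 340000L),
                        end = c(340000L, 600000L))
  cb <- conserved_boundaries(t1, shift40)
  expect_true(cb[pos == 300000L, conserved])        # exactly 40 kb away
  shift60 <- data.table(chrom = "chr1", start = c(0L, 360000L),
                        end = c(360000L, 600000L))
  cb2 <- conserved_boundaries(t1, shift60)
  expect_false(cb2[pos == 300000L, conserved])      # 60 kb: beyond
})

test_that("conservation classes count stage pairs symmetrically", {
  base <- data.table(chrom = "chr1",
                     start = c(0L, 200000L, 400000L),
                     end = c(200000L, 400000L, 600000L))
  same <- tad_conservation(list(base, copy(base), copy(base), copy(base)))
  expect_true(all(same$class == "thoroughly_conserved"))
  # symmetry of the pairwise relation
  other <- data.table(chrom = "chr1", start = c(0L, 240000L),
                      end = c(240000L, 600000L))
  f12 <- polytopo:::.tad_conserved_with(base, other, 4e4)
  f21 <- polytopo:::.tad_conserved_with(other, base, 4e4)
  expect_equal(sum(f12) > 0, sum(f21) > 0)
})

test_that("features are assigned to boundary or interior by midpoint", {
  tads <- data.table(chrom = "chr1", start = c(0L, 200000L),
                     end = c(200000L, 400000L),
                     tad_id = c("t1", "t2"))
  feats <- data.table(id = c("gj", "gc", "go"), chrom = "chr1",
                      start = c(199000L, 100000L, 500000L),
                      end = c(201000L, 102000L, 502000L))
  got <- boundary_interior_assignment(tads, feats)
  expect_equal(got$position, c("boundary", "interior", "outside"))
})

test_that("boundary-boosted gene expression is recovered by a rank test", {
  # full gene complement: the 2x boost over a log-normal baseline needs a
  # few hundred genes per group for a decisive rank test
  cfg <- sim_config(seed = 17)
  sim <- simulate_genome(cfg)
  ex <- simulate_expression(sim$genome, sim$truth, cfg)
  t1 <- sim$truth$tads[stage == "0DPA"]
  t1[, tad_id := paste0("t", .I)]
  lab <- boundary_interior_assignment(t1, sim$genome$genes)
  e0 <- ex[stage == "0DPA", .(fpkm = mean(fpkm)), by = gene]
  m <- merge(lab[, .(id, position)], e0, by.x = "id", by.y = "gene")
  bdry <- m[position == "boundary", fpkm]
  intr <- m[position == "interior", fpkm]
  expect_lt(wilcox.test(bdry, intr, alternative = "greater")$p.value, 0.01)
})

test_that("homoeologous vs partitioned TAD classification follows gene sets", {
  pairs <- data.table(pair_id = c("p1", "p2"),
                      at_gene = c("a1", "a2"), dt_gene = c("d1", "d2"))
  genes <- data.table(id = c("a1", "a2", "d1", "d2"),
                      chrom = c("chrA", "chrA", "chrD", "chrD"),
                      start = c(10000L, 30000L, 10000L, 30000L),
                      end = c(12000L, 32000L, 12000L, 32000L))
  at <- data.table(chrom = "chrA", start = 0L, end = 60000L, tad_id = "At1")
  dt_same <- data.table(chrom = "chrD", start = 0L, end = 60000L,
                        tad_id = "Dt1")
  got <- classify_tad_homology(at, dt_same, pairs, genes)
  expect_equal(got$class, "homoeologous")
  # partners split across two Dt TADs -> partitioned
  dt_split <- data.table(chrom = "chrD", start = c(0L, 20000L),
                         end = c(20000L, 60000L), tad_id = c("Dt1", "Dt2"))
  got2 <- classify_tad_homology(at, dt_split, pairs, genes)
  expect_true(all(got2$class == "partitioned"))
  expect_equal(nrow(got2), 2L)
  # no homoeologous genes -> unclassified
  empty <- classify_tad_homology(
    data.table(chrom = "chrA", start = 100000L, end = 120000L,
               tad_id = "At2"), dt_same, pairs, genes)
  expect_equal(nrow(empty), 0L)
})

test_that("swapping subgenome arguments transposes the homoeologous pairing", {
  pairs <- data.table(pair_id = c("p1", "p2"),
                      at_gene = c("a1", "a2"), dt_gene = c("d1", "d2"))
  rev_pairs <- data.table(pair_id = c("p1", "p2"),
                          at_gene = c("d1", "d2"), dt_gene = c("a1", "a2"))
  genes <- data.table(id = c("a1", "a2", "d1", "d2"),
                      chrom = c("chrA", "chrA", "chrD", "chrD"),
                      start = c(10000L, 30000L, 10000L, 30000L),
                      end = c(12000L, 32000L, 12000L, 32000L))
  at <- data.table(chrom = "chrA", start = 0L, end = 60000L, tad_id = "At1")
  dt <- data.table(chrom = "chrD", start = 0L, end = 60000L, tad_id = "Dt1")
  fwd <- classify_tad_homology(at, dt, pairs, genes)
  bwd <- classify_tad_homology(dt, at, rev_pairs, genes)
  expect_equal(fwd$class, bwd$class)
  expect_equal(fwd$at_tad, bwd$dt_tad)
})

test_that("positional-shift bias handles degenerate and planted tables", {
  # perfectly coupled 2x2 (10, 0, 0, 10) -> infinite odds ratio
  pp <- data.table(pair_id = paste0("p", 1:20),
                   at_position = c(rep("boundary", 10), rep("interior", 10)),
                   dt_position = rep("interior", 20))
  bc <- data.table(pair_id = paste0("p", 1:20),
                   bias = c(rep("At", 10), rep("none", 10)))
  res <- positional_shift_bias(pp, bc, n_perm = 50)
  expect_equal(res$odds_ratio, Inf)
  # planted coupling -> enrichment
  set.seed(3)
  n <- 200
  shifted <- rep(c(TRUE, FALSE), each = n / 2)
  bias <- ifelse(shifted, sample(c("At", "none"), n / 2, TRUE, c(0.7, 0.3)),
                 sample(c("At", "none"), n / 2, TRUE, c(0.2, 0.8)))
  pp2 <- data.table(pair_id = paste0("q", 1:n),
                    at_position = ifelse(shifted, "boundary", "interior"),
                    dt_position = "interior")
  bc2 <- data.table(pair_id = paste0("q", 1:n), bias = bias)
  res2 <- positional_shift_bias(pp2, bc2, n_perm = 200)
  expect_gt(res2$odds_ratio, 1)
  expect_lt(res2$p_perm, 0.05)
  # independent planting -> Fisher CI covers 1 in most seeds
  cover <- vapply(1:10, function(sd) {
    set.seed(sd)
    b3 <- sample(c("At", "none"), n, TRUE)
    res3 <- positional_shift_bias(pp2,
      data.table(pair_id = paste0("q", 1:n), bias = b3), n_perm = 10)
    ci <- fisher.test(res3$table)$conf.int
    ci[1] <= 1 && ci[2] >= 1
  }, logical(1))
  expect_gte(sum(cover), 8)
})
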