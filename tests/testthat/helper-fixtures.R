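library(data.table)

# small two-chromosome genome used across module tests
tiny_chrom_plan <- function() {
  data.table(name = c("chrA01", "chrD01"), length = c(6e6, 4e6),
             subgenome = c("At", "Dt"))
}

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, chrom_plan = tiny_chrom_plan(),
             genes_per_pair = 120, n_loops_per_chrom = 30,
             n_hg_loops = 25, n_cliques_per_chrom = 2, ...)
}

# dense symmetric matrix -> binned_matrix on one chromosome
dense_to_bm <- function(m, resolution = 1e4, chrom = "chr1",
                        stage = NA_character_) {
  n <- nrow(m)
  bins <- make_bins(data.table(name = chrom, length = n * resolution),
                    resolution)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  binned_matrix(idx[, 1], idx[, 2], m[idx], bins, resolution, stage = stage)
}

# brute-force reference for symmetric iterative correction on a dense matrix
ice_oracle <- function(m, iters = 2000) {
  b <- rep(1, nrow(m))
  for (it in seq_len(iters)) {
    mb <- sweep(sweep(m, 1, b, "/"), 2, b, "/")
    s <- rowSums(mb)
    if (sd(s) / mean(s) < 1e-12) break
    b <- b * sqrt(s / mean(s))
  }
  list(weights = 1 / b, balanced = sweep(sweep(m, 1, b, "/"), 2, b, "/"))
}

# exhaustive per-node maximum clique size by subset search
max_clique_oracle <- function(adj) {
  n <- nrow(adj)
  k <- rep(0L, n)
  for (sz in n:1) {
    if (all(k >= sz)) break
    combs <- utils::combn(n, sz)
    for (cc in seq_len(ncol(combs))) {
      v <- combs[, cc]
      if (length(v) == 1L) next
      sub <- adj[v, v, drop = FALSE]
      if (all(sub[upper.tri(sub)])) k[v] <- pmax(k[v], sz)
    }
  }
  k
}

# exhaustive longest collinear chain over hits (both orientations, gap cap)
chain_oracle <- function(at_rank, dt_rank, max_gap) {
  n <- length(at_rank)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) <= best) next
    o <- order(at_rank[sel])
    a <- at_rank[sel][o]; d <- dt_rank[sel][o]
    if (any(diff(a) <= 0) || any(diff(a) > max_gap)) next
    dd <- diff(d)
    ok_f <- all(dd > 0) && all(dd <= max_gap)
    ok_r <- all(dd < 0) && all(-dd <= max_gap)
    if (ok_f || ok_r) best <- length(sel)
  }
  best
}
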