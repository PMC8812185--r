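# Synthetic two-subgenome, four-stage dataset with planted structures at
# every level (compartments, TADs, loops, cliques, homoeologs, marks,
# expression), so that every analysis stage has a recoverable ground truth.

#' Simulation configuration
#'
#' Defaults describe a scaled-down allotetraploid: two At chromosomes of
#' 20 Mb and two Dt chromosomes of 12 Mb (At larger and TE-richer than Dt),
#' observed across four developmental stages.
#'
#' @param seed integer seed; mandatory for every stochastic call.
#' @param chrom_plan chromosome table (`name`, `length`, `subgenome`).
#' @param genes_per_pair ancestral genes per At/Dt chromosome pair.
#' @param homoeolog_fraction fraction of ancestral genes retained in both
#'   subgenomes (the rest become single-copy).
#' @param n_inversions collinearity-breaking inversions per chromosome pair.
#' @param inversion_span genes per inversion (range).
#' @param te_per_mb_at,te_per_mb_dt TE densities; the default 2:1 ratio makes
#'   At TE-richer.
#' @param alpha power-law distance-decay exponent of contact frequency.
#' @param lambda0 expected counts for an adjacent 5-kb cis bin pair
#'   (sequencing-depth knob).
#' @param compartment_contrast ratio of same-label to cross-label contact
#'   intensity.
#' @param tad_enrichment intra-TAD contact multiplier.
#' @param dt_compaction short-range (<= 1 Mb) contact multiplier applied to
#'   Dt chromosomes (planted compactness difference).
#' @param loop_strength extra expected counts at a planted loop anchor pair.
#' @param clique_loop_strength extra expected counts at each clique-supporting
#'   loop.
#' @param n_loops_per_chrom generic planted loops per chromosome per stage.
#' @param n_hg_loops homoeolog-gene loops planted per chromosome pair per
#'   stage (anchors at homoeolog gene bins).
#' @param hg_mirror fraction of homoeolog-gene loops mirrored in the other
#'   subgenome (drives network divergence away from 1).
#' @param n_cliques_per_chrom planted TAD cliques per chromosome per stage.
#' @param clique_size_range TADs per planted clique.
#' @param comp_block_bins mean compartment block length (40-kb bins).
#' @param comp_switch_frac fraction of 40-kb bins switching label at each
#'   stage transition (planted in runs of >= 2 bins).
#' @param tad_size_range TAD sizes in 20-kb bins.
#' @param tad_keep_prob probability a base boundary persists in a given stage.
#' @param trans_pairs sampled inter-chromosomal contact pairs per stage.
#' @param expr_dispersion negative-binomial dispersion (1/size) of FPKM
#'   draws; 0 gives the noise-free limit.
#' @param bias_effect planted expression ratio for subgenome-biased pairs.
#' @param bias_fraction fraction of homoeolog pairs with planted bias.
#' @param de_fraction fraction of genes with a planted stage fold change.
#' @param de_effect planted between-stage fold change.
#' @param silent_fraction fraction of unpaired genes planted silent
#'   (FPKM < 1; homoeolog-pair members are never silenced so that planted
#'   bias ratios stay interpretable).
#' @param n_peaks_per_chrom ChIP peaks per chromosome per mark at stage one.
#' @param peak_compartment_bias probability a peak of an active mark lands in
#'   an A bin (and a repressive mark in a B bin).
#' @param n_nongene_regions homologous non-gene regions per chromosome pair.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_plan = NULL,
                       genes_per_pair = 260,
                       homoeolog_fraction = 0.9,
                       n_inversions = 2,
                       inversion_span = c(8, 14),
                       te_per_mb_at = 80,
                       te_per_mb_dt = 40,
                       alpha = 1.0,
                       lambda0 = 20,
                       compartment_contrast = 1.5,
                       tad_enrichment = 2.0,
                       dt_compaction = 1.3,
                       loop_strength = 30,
                       clique_loop_strength = 15,
                       n_loops_per_chrom = 60,
                       n_hg_loops = 40,
                       hg_mirror = 0.25,
                       n_cliques_per_chrom = 2,
                       clique_size_range = c(3, 5),
                       comp_block_bins = 12,
                       comp_switch_frac = 0.05,
                       tad_size_range = c(5, 15),
                       tad_keep_prob = 0.88,
                       trans_pairs = 20000,
                       expr_dispersion = 0.05,
                       bias_effect = 4,
                       bias_fraction = 0.3,
                       de_fraction = 0.15,
                       de_effect = 8,
                       silent_fraction = 0.05,
                       n_peaks_per_chrom = 150,
                       peak_compartment_bias = 0.8,
                       n_nongene_regions = 80) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(chrom_plan)) {
    chrom_plan <- data.table(
      name = c("chrA01", "chrA02", "chrD01", "chrD02"),
      length = c(20e6, 20e6, 12e6, 12e6),
      subgenome = c("At", "At", "Dt", "Dt"))
  }
  cfg <- as.list(environment())
  frac <- c("homoeolog_fraction", "comp_switch_frac", "tad_keep_prob",
            "bias_fraction", "de_fraction", "silent_fraction",
            "peak_compartment_bias")
  for (f in frac)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$expr_dispersion < 0) stop("expr_dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed per simulation component, kept below 2^31
.sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1000003 + tag) %% 2147483629)
}

.stage_index <- function(stage) {
  i <- match(stage, .STAGES)
  if (is.na(i)) stop("unknown stage '", stage, "'; expected one of ",
                     paste(.STAGES, collapse = ", "))
  i
}

## ---------------------------------------------------------------------------
## Genome + truth

# alternating A/B blocks; returns per-40kb-bin label vector
.plant_compartments <- function(n_bins, mean_block) {
  lab <- character(0)
  cur <- sample(c("A", "B"), 1L)
  while (length(lab) < n_bins) {
    len <- max(5L, rpois(1L, mean_block))
    lab <- c(lab, rep(cur, len))
    cur <- if (cur == "A") "B" else "A"
  }
  lab[seq_len(n_bins)]
}

# flip runs of 2-4 bins until ~frac of bins switched relative to prev
.switch_compartments <- function(lab, frac) {
  n <- length(lab)
  target <- round(frac * n)
  flipped <- 0L
  lab2 <- lab
  guard <- 0L
  while (flipped < target && guard < 10L * n) {
    guard <- guard + 1L
    len <- sample(2:4, 1L)
    len <- min(len, target - flipped)           # do not overshoot the rate
    if (len < 2L) break
    s <- sample.int(n - len + 1L, 1L)
    idx <- s:(s + len - 1L)
    if (length(unique(lab2[idx])) > 1L) next    # keep flips label-coherent
    if (any(lab2[idx] != lab[idx])) next
    lab2[idx] <- if (lab2[idx][1L] == "A") "B" else "A"
    flipped <- flipped + len
  }
  lab2
}

# boundaries (interior 20-kb bin indices) -> TAD interval table
.boundaries_to_tads <- function(bounds, n_bins, min_bins = 3L) {
  bounds <- sort(unique(bounds))
  bounds <- bounds[bounds > min_bins & bounds <= n_bins - min_bins]
  # enforce minimum TAD size by dropping the later of two close boundaries
  keep <- logical(length(bounds))
  last <- 0L
  for (k in seq_along(bounds)) {
    if (bounds[k] - last >= min_bins) { keep[k] <- TRUE; last <- bounds[k] }
  }
  bounds <- bounds[keep]
  starts <- c(0L, bounds)
  ends <- c(bounds, n_bins)
  data.table(start_bin = starts, end_bin = ends)
}

#' Simulate a two-subgenome genome with planted multi-level truth
#'
#' Builds the chromosome set, collinear gene orders with local inversions and
#' gene loss, TEs at an At-biased density, stage-resolved compartment labels,
#' TAD tilings, planted loops and TAD cliques, homoeolog pairs with planted
#' expression-bias trajectories, a non-gene region-correspondence map, and
#' compartment-coupled ChIP peaks.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a [genome_model()]) and `truth` (a
#'   list of planted-structure tables; see Details).
#' @details `truth` holds: `compartments` (chrom, start, stage, label at
#'   40 kb), `tads` (chrom, stage, start, end in bp at 20 kb), `loops`
#'   (planted anchor pairs per stage), `cliques` (clique_id, stage, chrom,
#'   member TAD intervals), `homoeologs` (pair_id, at_gene, dt_gene, and the
#'   planted bias direction per stage), `nongene_homology` (region
#'   correspondence between subgenomes), `te_density` (per chromosome), and
#'   `similarity` (an all-vs-all-style score table with planted best hits).
#' @export
simulate_genome <- function(config) {
  set.seed(.sub_seed(config$seed, 1L))
  cp <- as.data.table(config$chrom_plan)
  at_chroms <- cp[subgenome == "At", name]
  dt_chroms <- cp[subgenome == "Dt", name]
  n_chrom_pairs <- min(length(at_chroms), length(dt_chroms))

  ## --- compartments per stage (40 kb); planted first because gene
  ## placement is A-biased (A = gene-dense by construction)
  comp <- list()
  for (cn in cp$name) {
    n40 <- as.integer(cp[name == cn, length] %/% 4e4)
    lab <- .plant_compartments(n40, config$comp_block_bins)
    labs <- list(lab)
    for (s in 2:4) labs[[s]] <- .switch_compartments(labs[[s - 1L]],
                                                     config$comp_switch_frac)
    for (s in 1:4)
      comp[[length(comp) + 1L]] <- data.table(
        chrom = cn, start = (seq_len(n40) - 1L) * 40000L,
        stage = .STAGES[s], label = labs[[s]])
  }
  comp <- rbindlist(comp)
  lab1 <- function(cn) comp[chrom == cn & stage == .STAGES[1L]][
    order(start), label]

  ## --- genes: collinear ancestral orders with loss + inversions
  genes <- list(); pairs <- list(); sim <- list()
  gene_len <- 3000L
  for (k in seq_len(n_chrom_pairs)) {
    n <- config$genes_per_pair
    at_len <- cp[name == at_chroms[k], length]
    dt_len <- cp[name == dt_chroms[k], length]
    if (n * (gene_len + 2000L) > min(at_len, dt_len))
      stop("chromosome too short for requested gene count")
    present <- runif(n) < config$homoeolog_fraction
    only <- sample(c("At", "Dt"), n, replace = TRUE)
    in_at <- present | only == "At"
    in_dt <- present | only == "Dt"
    # Dt order: collinear except planted inversions
    dt_order <- seq_len(n)
    span <- config$inversion_span
    inv_at <- rep(FALSE, n)
    for (v in seq_len(config$n_inversions)) {
      len <- sample(span[1]:span[2], 1L)
      s <- sample.int(n - len, 1L)
      dt_order[s:(s + len - 1L)] <- rev(dt_order[s:(s + len - 1L)])
      inv_at[s:(s + len - 1L)] <- TRUE
    }
    place <- function(m, chrom_name, gene_bias = 3) {
      # gene density coupled to the A compartment (stage-one labels)
      labs <- lab1(chrom_name)
      b <- sample.int(length(labs), m, replace = TRUE,
                      prob = ifelse(labs == "A", gene_bias, 1))
      sort(as.integer((b - 1L) * 40000L +
                        sample.int(40000L - gene_len, m, replace = TRUE)))
    }
    at_ids <- paste0("G", k, "A", sprintf("%04d", seq_len(n)))
    dt_ids <- paste0("G", k, "D", sprintf("%04d", seq_len(n)))
    at_pos <- integer(n); at_pos[in_at] <- place(sum(in_at), at_chroms[k])
    genes[[length(genes) + 1L]] <- data.table(
      id = at_ids[in_at], chrom = at_chroms[k], start = at_pos[in_at],
      end = at_pos[in_at] + gene_len,
      strand = sample(c("+", "-"), sum(in_at), replace = TRUE))
    dt_present_in_order <- dt_order[in_dt[dt_order]]
    dt_pos_sorted <- place(length(dt_present_in_order), dt_chroms[k])
    dt_pos <- integer(n); dt_pos[dt_present_in_order] <- dt_pos_sorted
    genes[[length(genes) + 1L]] <- data.table(
      id = dt_ids[dt_present_in_order], chrom = dt_chroms[k],
      start = dt_pos[dt_present_in_order],
      end = dt_pos[dt_present_in_order] + gene_len,
      strand = sample(c("+", "-"), length(dt_present_in_order), replace = TRUE))
    both <- which(in_at & in_dt)
    pairs[[k]] <- data.table(pair_id = paste0("P", k, "_", sprintf("%04d", both)),
                             at_gene = at_ids[both], dt_gene = dt_ids[both])
    # similarity table: true pairs get top scores both ways; noise hits lower
    true_hits <- data.table(query = c(at_ids[both], dt_ids[both]),
                            subject = c(dt_ids[both], at_ids[both]),
                            score = round(runif(2L * length(both), 800, 1200), 1),
                            evalue = 10^-runif(2L * length(both), 50, 180))
    n_noise <- length(both) * 2L
    noise <- data.table(
      query = sample(c(at_ids[in_at], dt_ids[in_dt]), n_noise, replace = TRUE),
      subject = sample(c(dt_ids[in_dt], at_ids[in_at]), n_noise, replace = TRUE),
      score = round(runif(n_noise, 50, 400), 1),
      evalue = 10^-runif(n_noise, 5, 30))
    noise <- noise[substr(query, 3, 3) != substr(subject, 3, 3)]
    sim[[k]] <- rbind(true_hits, noise)
  }
  ## chromosomes without a partner still carry (single-copy) genes
  unpaired <- c(at_chroms[-seq_len(n_chrom_pairs)],
                dt_chroms[-seq_len(n_chrom_pairs)])
  for (cn in unpaired) {
    m <- config$genes_per_pair
    labs <- lab1(cn)
    b <- sample.int(length(labs), m, replace = TRUE,
                    prob = ifelse(labs == "A", 3, 1))
    pos <- sort(as.integer((b - 1L) * 40000L +
                             sample.int(40000L - gene_len, m,
                                        replace = TRUE)))
    genes[[length(genes) + 1L]] <- data.table(
      id = paste0("G", cn, "S", sprintf("%04d", seq_len(m))), chrom = cn,
      start = pos, end = pos + gene_len,
      strand = sample(c("+", "-"), m, replace = TRUE))
  }
  genes <- rbindlist(genes)
  empty_pairs <- data.table(pair_id = character(), at_gene = character(),
                            dt_gene = character())
  pairs <- if (length(pairs)) rbindlist(pairs) else empty_pairs
  similarity <- if (length(sim))
    unique(rbindlist(sim), by = c("query", "subject"))
  else data.table(query = character(), subject = character(),
                  score = numeric(), evalue = numeric())

  ## --- TEs (At density > Dt when the ratio is > 1)
  tes <- cp[, {
    dens <- if (subgenome == "At") config$te_per_mb_at else config$te_per_mb_dt
    m <- rpois(1L, dens * length / 1e6)
    st <- sort(sample.int(length - 10000L, m))
    .(id = paste0("TE_", name, "_", seq_len(m)), chrom = name, start = st,
      end = st + sample(1000:8000, m, replace = TRUE),
      family = sample(c("Gypsy", "Copia", "CACTA"), m, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1)))
  }, by = .(name, subgenome)][, .(id, chrom, start, end, family)]
  te_density <- tes[, .N, by = chrom][
    cp[, .(chrom = name, length, subgenome)], on = "chrom"][
      , .(chrom, subgenome, te_per_mb = fifelse(is.na(N), 0, N) / (length / 1e6))]

  ## --- TADs per stage (20 kb): base boundaries, per-stage dropout
  tads <- list()
  for (cn in cp$name) {
    n20 <- as.integer(cp[name == cn, length] %/% 2e4)
    sizes <- sample(config$tad_size_range[1]:config$tad_size_range[2],
                    ceiling(n20 / config$tad_size_range[1]), replace = TRUE)
    base <- cumsum(sizes); base <- base[base < n20 - 3L]
    for (s in 1:4) {
      bset <- if (s == 1L) base else base[runif(length(base)) < config$tad_keep_prob]
      tt <- .boundaries_to_tads(bset, n20)
      tads[[length(tads) + 1L]] <- data.table(
        chrom = cn, stage = .STAGES[s],
        start = tt$start_bin * 20000L, end = tt$end_bin * 20000L)
    }
  }
  tads <- rbindlist(tads)
  tads[, tad_id := paste0(chrom, ":", stage, ":", .I)]

  ## --- planted loops (intra-TAD) and cliques per stage
  loops <- list(); cliques <- list()
  gpos <- setNames((genes$start + genes$end) %/% 2L, genes$id)
  gchrom <- setNames(genes$chrom, genes$id)
  for (s in 1:4) {
    ## homoeolog-gene loops, a fraction mirrored across subgenomes
    for (k in seq_len(n_chrom_pairs)) {
      pk <- pairs[gchrom[at_gene] == at_chroms[k]]
      if (nrow(pk) < 4L || config$n_hg_loops == 0) next
      for (q in seq_len(config$n_hg_loops)) {
        ij <- sample.int(nrow(pk), 2L)
        a1 <- (gpos[pk$at_gene[ij[1L]]] %/% 5e3) * 5000L
        a2 <- (gpos[pk$at_gene[ij[2L]]] %/% 5e3) * 5000L
        dd <- abs(a2 - a1) %/% 5e3
        if (dd < 3L || dd > 380L) next
        loops[[length(loops) + 1L]] <- data.table(
          chrom = at_chroms[k], start1 = min(a1, a2), start2 = max(a1, a2),
          stage = .STAGES[s], strength = config$loop_strength, kind = "hg")
        if (runif(1L) < config$hg_mirror) {
          d1 <- (gpos[pk$dt_gene[ij[1L]]] %/% 5e3) * 5000L
          d2 <- (gpos[pk$dt_gene[ij[2L]]] %/% 5e3) * 5000L
          ddd <- abs(d2 - d1) %/% 5e3
          if (ddd >= 3L && ddd <= 380L)
            loops[[length(loops) + 1L]] <- data.table(
              chrom = dt_chroms[k], start1 = min(d1, d2),
              start2 = max(d1, d2), stage = .STAGES[s],
              strength = config$loop_strength, kind = "hg")
        }
      }
      ## Dt-specific homoeolog-gene loops (independent wiring, so the two
      ## subgenome networks diverge except for the mirrored fraction)
      for (q in seq_len(config$n_hg_loops)) {
        ij <- sample.int(nrow(pk), 2L)
        d1 <- (gpos[pk$dt_gene[ij[1L]]] %/% 5e3) * 5000L
        d2 <- (gpos[pk$dt_gene[ij[2L]]] %/% 5e3) * 5000L
        dd <- abs(d2 - d1) %/% 5e3
        if (dd < 3L || dd > 380L) next
        loops[[length(loops) + 1L]] <- data.table(
          chrom = dt_chroms[k], start1 = min(d1, d2), start2 = max(d1, d2),
          stage = .STAGES[s], strength = config$loop_strength, kind = "hg")
      }
    }
    for (cn in cp$name) {
      tt <- tads[chrom == cn & stage == .STAGES[s]]
      big <- tt[(end - start) >= 8e4]
      pick <- big[sample.int(.N, min(config$n_loops_per_chrom, .N),
                             replace = TRUE)]
      a1 <- integer(nrow(pick)); a2 <- integer(nrow(pick))
      for (r in seq_len(nrow(pick))) {
        nb <- (pick$end[r] - pick$start[r]) %/% 5e3
        p2 <- sort(sample.int(nb, 2L))
        while (p2[2L] - p2[1L] < 3L) p2 <- sort(sample.int(nb, 2L))
        a1[r] <- pick$start[r] + (p2[1L] - 1L) * 5e3
        a2[r] <- pick$start[r] + (p2[2L] - 1L) * 5e3
      }
      loops[[length(loops) + 1L]] <- data.table(
        chrom = cn, start1 = a1, start2 = a2, stage = .STAGES[s],
        strength = config$loop_strength, kind = "loop")
      ## cliques: disjoint sets of non-adjacent TADs (a shared boundary
      ## flooded by inter-TAD loops would erode its insulation minimum);
      ## members stay >= 200 kb from chromosome ends, where the insulation
      ## score is undefined and no caller could see them
      chrom_len <- cp[name == cn, length]
      eligible <- which(tt$start >= 2e5 & tt$end <= chrom_len - 2e5)
      avail <- eligible
      for (q in seq_len(config$n_cliques_per_chrom)) {
        sz <- sample(config$clique_size_range[1]:config$clique_size_range[2], 1L)
        span_needed <- 2L * sz + 1L
        cand <- avail[avail <= max(eligible) - span_needed]
        if (!length(cand)) break
        anchor <- sample(cand, 1L)
        members <- anchor + 2L * (seq_len(sz) - 1L)    # every other TAD
        if (!all(members %in% avail)) next
        avail <- setdiff(avail, c(members, members + 1L, members - 1L))
        mem <- tt[members]
        cliques[[length(cliques) + 1L]] <- data.table(
          clique_id = paste0(cn, ":", .STAGES[s], ":c", q), chrom = cn,
          stage = .STAGES[s], start = mem$start, end = mem$end)
        cmb <- utils::combn(seq_len(nrow(mem)), 2L)
        inner <- function(tad, m) {
          # anchor bins in the inner part of the TAD, away from boundaries
          nb <- (tad$end - tad$start) %/% 5e3
          lo <- max(2L, ceiling(nb * 0.2)); hi <- min(nb - 1L, floor(nb * 0.8))
          tad$start + (sample(lo:hi, m, replace = TRUE) - 1L) * 5e3
        }
        for (cc in seq_len(ncol(cmb))) {
          ta <- mem[cmb[1L, cc]]; tb <- mem[cmb[2L, cc]]
          b1 <- (ta$end - ta$start) %/% 2e4; b2 <- (tb$end - tb$start) %/% 2e4
          L <- ceiling(0.15 * b1 * b2) + 3L
          loops[[length(loops) + 1L]] <- data.table(
            chrom = cn, start1 = inner(ta, L), start2 = inner(tb, L),
            stage = .STAGES[s], strength = config$clique_loop_strength,
            kind = "clique")
        }
      }
    }
  }
  loops <- unique(rbindlist(loops), by = c("chrom", "start1", "start2", "stage"))
  cliques <- rbindlist(cliques)

  ## --- homoeolog bias truth
  nb <- round(config$bias_fraction * nrow(pairs))
  bias_dir <- rep("none", nrow(pairs))
  if (nb > 0) {
    biased <- sample.int(nrow(pairs), nb)
    bias_dir[biased] <- sample(c("At", "Dt"), nb, replace = TRUE)
  }
  conserved <- runif(nrow(pairs)) < 0.6
  bias_truth <- list()
  for (s in 1:4) {
    d <- bias_dir
    dyn <- !conserved & d != "none" & runif(nrow(pairs)) < 0.4
    d[dyn] <- "none"
    bias_truth[[s]] <- data.table(pair_id = pairs$pair_id, stage = .STAGES[s],
                                  bias = d)
  }
  bias_truth <- rbindlist(bias_truth)

  ## --- non-gene homology map (position-scaled correspondence)
  ng <- list()
  for (k in seq_len(n_chrom_pairs)) {
    at_len <- cp[name == at_chroms[k], length]
    dt_len <- cp[name == dt_chroms[k], length]
    fr <- sort(runif(config$n_nongene_regions, 0.02, 0.97))
    a_st <- as.integer((fr * at_len) %/% 5e3) * 5000L
    d_st <- as.integer((fr * dt_len) %/% 5e3) * 5000L
    ng[[k]] <- data.table(at_chrom = at_chroms[k], at_start = a_st,
                          at_end = a_st + 5000L, dt_chrom = dt_chroms[k],
                          dt_start = d_st, dt_end = d_st + 5000L)
  }
  nongene <- rbindlist(ng)

  ## --- ChIP peaks coupled to compartments; active marks wane with stage
  peaks <- list()
  for (s in 1:4) {
    for (cn in cp$name) {
      lab <- comp[chrom == cn & stage == .STAGES[s]]
      for (mk in .MARKS) {
        active <- mk %in% c("H3K27ac", "H3K4me3")
        n_pk <- round(config$n_peaks_per_chrom *
                        (if (active) 1 - 0.08 * (s - 1L) else 0.7 + 0.1 * (s - 1L)))
        want <- if (active) "A" else "B"
        in_want <- runif(n_pk) < config$peak_compartment_bias
        pool_w <- lab[label == want, start]; pool_o <- lab[label != want, start]
        bin_start <- integer(n_pk)
        bin_start[in_want] <- sample(pool_w, sum(in_want), replace = TRUE)
        bin_start[!in_want] <- sample(pool_o, sum(!in_want), replace = TRUE)
        off <- sample.int(37000L, n_pk, replace = TRUE)
        peaks[[length(peaks) + 1L]] <- data.table(
          stage = .STAGES[s], mark = mk, chrom = cn,
          start = bin_start + off,
          end = bin_start + off + sample(800:3000, n_pk, replace = TRUE))
      }
    }
  }
  peaks <- rbindlist(peaks)

  ## --- TE expression: boundary TEs boosted (stage-1 TAD boundaries)
  te_mid <- tes[, .(id, chrom, mid = (start + end) %/% 2)]
  b1 <- tads[stage == .STAGES[1L],
             .(chrom, pos = c(start, end)), by = tad_id][
               , .(chrom, pos)]
  te_expr <- list()
  for (s in 1:4) {
    base <- rnbinom(nrow(tes), mu = 5, size = 5)
    near_b <- mapply(function(ch, m) {
      p <- b1[chrom == ch, pos]
      any(m >= p - 2e4 & m < p + 4e4)
    }, te_mid$chrom, te_mid$mid)
    lvl <- base * ifelse(near_b, 3, 1)
    te_expr[[s]] <- data.table(id = tes$id, stage = .STAGES[s],
                               level = as.numeric(lvl))
  }
  te_expr <- rbindlist(te_expr)

  genome <- genome_model(cp[, .(name, length, subgenome)], genes, tes,
                         te_expr, peaks)
  truth <- list(compartments = comp, tads = tads, loops = loops,
                cliques = cliques, homoeologs = pairs,
                bias = bias_truth, nongene_homology = nongene,
                te_density = te_density, similarity = similarity)
  list(genome = genome, truth = truth)
}

## ---------------------------------------------------------------------------
## Hi-C simulation

#' Simulate a Hi-C contact matrix for one stage
#'
#' Expected intensity for a cis bin pair at gap d is
#' `lambda0 * d^-alpha * comp(i,j) * tad(i,j)` with multiplicative
#' checkerboard (same-/cross-compartment), intra-TAD enrichment and a
#' short-range Dt compaction factor; planted loop and clique anchor pairs
#' receive additional expected counts. Counts are Poisson draws; a small set
#' of uniform trans contacts is added. Coarser matrices should be obtained
#' with [aggregate_matrix()] so that total counts are conserved exactly.
#'
#' @param genome a [genome_model()].
#' @param truth truth list from [simulate_genome()].
#' @param stage stage label (one of 0DPA, 5DPA, 10DPA, 20DPA).
#' @param config the [sim_config()].
#' @param decay_only if TRUE, suppress every planted enrichment (pure
#'   power-law background; used for null calibration).
#' @return a `binned_matrix` at 5 kb covering the whole genome.
#' @export
simulate_hic <- function(genome, truth, stage, config, decay_only = FALSE) {
  si <- .stage_index(stage)
  if (!stage %in% truth$compartments$stage)
    stop("stage '", stage, "' absent from truth")
  set.seed(.sub_seed(config$seed, 100L + si))
  stg <- stage
  res <- 5e3
  bins <- make_bins(genome$chromosomes, res)
  trip <- list()
  for (cn in genome$chromosomes$name) {
    cb <- bins[chrom == cn]
    n <- nrow(cb)
    off <- cb$bin[1L] - 1L
    sub <- genome$chromosomes[name == cn, subgenome]
    lab40 <- truth$compartments[chrom == cn & stage == stg][order(start), label]
    lab5 <- lab40[pmin(length(lab40), (cb$start %/% 4e4) + 1L)]
    tt <- truth$tads[chrom == cn & stage == stg]
    tad_of <- rep(NA_integer_, n)
    for (r in seq_len(nrow(tt))) {
      lo <- (tt$start[r] %/% res) + 1L
      hi <- min(n, tt$end[r] %/% res)
      tad_of[lo:hi] <- r
    }
    csqrt <- sqrt(config$compartment_contrast)
    max_d <- n - 1L
    li <- vector("list", max_d + 1L)
    # diagonal (self-ligation) retained
    d0 <- rpois(n, 2 * config$lambda0)
    nz <- which(d0 > 0)
    li[[1L]] <- data.table(i = nz + off, j = nz + off, x = d0[nz])
    for (d in seq_len(max_d)) {
      lam <- config$lambda0 * d^(-config$alpha)
      if (lam < 1e-4 && d > 400L) {
        # far tail: expected counts negligible; draw in one thinned block
        m <- n - d
        tot <- rpois(1L, lam * m)
        if (tot > 0L) {
          ii <- sample.int(m, tot, replace = TRUE)
          cnt <- tabulate(ii, m); nz <- which(cnt > 0L)
          li[[d + 1L]] <- data.table(i = nz + off, j = nz + d + off,
                                     x = cnt[nz])
        }
        next
      }
      iv <- seq_len(n - d)
      lamv <- rep(lam, n - d)
      if (!decay_only) {
        same <- lab5[iv] == lab5[iv + d]
        lamv <- lamv * ifelse(same, csqrt, 1 / csqrt)
        st <- !is.na(tad_of[iv]) & !is.na(tad_of[iv + d]) &
          tad_of[iv] == tad_of[iv + d]
        lamv[st] <- lamv[st] * config$tad_enrichment
        if (sub == "Dt" && d <= 200L) lamv <- lamv * config$dt_compaction
      }
      x <- rpois(n - d, lamv)
      nz <- which(x > 0L)
      if (length(nz))
        li[[d + 1L]] <- data.table(i = nz + off, j = nz + d + off, x = x[nz])
    }
    trip[[cn]] <- rbindlist(li)
    ## planted loops
    if (!decay_only) {
      pl <- truth$loops[chrom == cn & stage == stg]
      if (nrow(pl)) {
        x <- rpois(nrow(pl), pl$strength)
        trip[[paste0(cn, "_loops")]] <- data.table(
          i = (pl$start1 %/% res) + 1L + off,
          j = (pl$start2 %/% res) + 1L + off, x = x)[x > 0]
      }
    }
  }
  ## trans background
  if (config$trans_pairs > 0) {
    nb <- nrow(bins)
    ij <- cbind(sample.int(nb, config$trans_pairs, replace = TRUE),
                sample.int(nb, config$trans_pairs, replace = TRUE))
    cis <- bins$chrom[ij[, 1L]] == bins$chrom[ij[, 2L]]
    ij <- ij[!cis, , drop = FALSE]
    trip[["trans"]] <- data.table(i = pmin(ij[, 1L], ij[, 2L]),
                                  j = pmax(ij[, 1L], ij[, 2L]), x = 1)
  }
  tr <- rbindlist(trip)[, .(x = sum(x)), by = .(i, j)]
  binned_matrix(tr$i, tr$j, tr$x, bins, res, stage = stage)
}

## ---------------------------------------------------------------------------
## Expression simulation

#' Simulate a replicated FPKM expression table
#'
#' Per-gene baselines are log-normal; planted effects multiply them:
#' subgenome bias on homoeolog pairs (At or Dt member raised by
#' `bias_effect` at stages where the truth marks the pair biased), stage
#' fold changes on a `de_fraction` subset, silence on a `silent_fraction`
#' subset, a 2x boost for genes at stage-one TAD boundaries, and a clique-
#' size-dependent attenuation `2^-(k/5)` for genes inside planted clique
#' TADs. Values are negative-binomial draws around the planted mean
#' (deterministic when `expr_dispersion = 0`), three replicates per stage.
#'
#' @param genome a [genome_model()].
#' @param truth truth list from [simulate_genome()].
#' @param config the [sim_config()].
#' @return long data.table: `gene`, `stage`, `rep`, `fpkm`, plus a
#'   `planted` attribute table with per-gene planted means.
#' @export
simulate_expression <- function(genome, truth, config) {
  set.seed(.sub_seed(config$seed, 200L))
  g <- copy(genome$genes)
  ng <- nrow(g)
  base <- exp(rnorm(ng, 3, 1))
  silent <- runif(ng) < config$silent_fraction
  pr <- truth$homoeologs
  ai <- match(pr$at_gene, g$id); di <- match(pr$dt_gene, g$id)
  ok <- !is.na(ai) & !is.na(di)
  ai <- ai[ok]; di <- di[ok]
  ## homoeologs share their ancestral baseline, so planted bias ratios
  ## are not confounded by per-member draws; silence is planted only on
  ## unpaired genes (the bias truth speaks about expressed pairs)
  base[di] <- base[ai]
  silent[c(ai, di)] <- FALSE
  base[silent] <- 0.1
  ## shared (pair-coherent) structural modifiers -------------------------
  shared <- matrix(1, ng, 4L, dimnames = list(g$id, .STAGES))
  ## stage DE: fold change applied from a random stage onward
  de <- runif(ng) < config$de_fraction
  de_from <- sample(2:4, ng, replace = TRUE)
  de_up <- sample(c(TRUE, FALSE), ng, replace = TRUE)
  for (i in which(de)) {
    f <- if (de_up[i]) config$de_effect else 1 / config$de_effect
    shared[i, de_from[i]:4L] <- shared[i, de_from[i]:4L] * f
  }
  ## TAD-boundary boost (stage-one boundaries; boundary region = boundary
  ## bin plus a one-bin halo, matching the assignment rule downstream)
  gmid <- (g$start + g$end) %/% 2
  t1 <- truth$tads[stage == .STAGES[1L]]
  bpos <- t1[, .(pos = c(start, end)), by = chrom]
  at_boundary <- vapply(seq_len(ng), function(i) {
    p <- bpos[chrom == g$chrom[i], pos]
    any(gmid[i] >= p - 2e4 & gmid[i] < p + 4e4)
  }, logical(1L))
  shared[at_boundary, ] <- shared[at_boundary, ] * 2
  ## clique attenuation per stage
  for (s in .STAGES) {
    cl <- truth$cliques[stage == s]
    if (!nrow(cl)) next
    ksz <- cl[, .(k = .N), by = clique_id]
    cl <- merge(cl, ksz, by = "clique_id")
    for (r in seq_len(nrow(cl))) {
      in_cl <- g$chrom == cl$chrom[r] & gmid >= cl$start[r] & gmid < cl$end[r]
      shared[in_cl, s] <- shared[in_cl, s] * 2^(-cl$k[r] / 5)
    }
  }
  ## the Dt member inherits the At member's structural modifiers: the
  ## pair-level ratio must reflect only the planted bias
  shared[di, ] <- shared[ai, , drop = FALSE]
  ## subgenome bias: raise the favoured member -------------------------
  bias_m <- matrix(1, ng, 4L, dimnames = list(g$id, .STAGES))
  bt <- merge(truth$bias, truth$homoeologs, by = "pair_id")
  for (s in .STAGES) {
    b <- bt[stage == s & bias != "none"]
    up_at <- b[bias == "At", at_gene]; up_dt <- b[bias == "Dt", dt_gene]
    bias_m[match(intersect(up_at, g$id), g$id), s] <- config$bias_effect
    bias_m[match(intersect(up_dt, g$id), g$id), s] <- config$bias_effect
  }
  mult <- shared * bias_m
  ## silent genes take no modifiers at all (a silent locus has nothing to
  ## bias or boost)
  mult[silent, ] <- 1
  out <- CJ(gene = g$id, stage = .STAGES, rep = 1:3, sorted = FALSE)
  mu <- base[match(out$gene, g$id)] * mult[cbind(match(out$gene, g$id),
                                                 match(out$stage, .STAGES))]
  ## FPKM = NB pseudo-counts at depth 10 per FPKM unit, so values are
  ## continuous on a 0.1 grid and a silent mean of 0.1 stays below 1
  depth <- 10
  fpkm <- if (config$expr_dispersion == 0) mu else
    rnbinom(length(mu), mu = mu * depth,
            size = 1 / config$expr_dispersion) / depth
  out[, fpkm := as.numeric(fpkm)]
  planted <- data.table(gene = g$id, base = base, silent = silent,
                        at_boundary = at_boundary)
  setattr(out, "planted", planted)
  out[]
}

## ---------------------------------------------------------------------------
## Dataset writer: emit everything in the standard on-disk formats

#' Write a simulated dataset in standard formats
#'
#' Emits the genome annotation (GFF3), TEs and peaks (BED), per-stage 5-kb
#' matrices (bins + COO TSV), planted loops (BEDPE), expression (TSV),
#' similarity and truth tables (TSV), so that the analysis pipeline runs
#' identically on synthetic and real data.
#'
#' @param sim list from [simulate_genome()].
#' @param matrices named list of `binned_matrix` per stage (optional).
#' @param expression table from [simulate_expression()] (optional).
#' @param outdir output directory (created).
#' @return `outdir` invisibly.
#' @export
write_dataset <- function(sim, matrices = NULL, expression = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  g <- sim$genome
  write_annotation(g$genes, file.path(outdir, "genes.gff3"), "GFF3")
  write_annotation(g$tes[, .(id, chrom, start, end, strand = "*")],
                   file.path(outdir, "tes.bed"), "BED")
  fwrite(g$peaks, file.path(outdir, "peaks.tsv"), sep = "\t")
  fwrite(g$chromosomes, file.path(outdir, "chromosomes.tsv"), sep = "\t")
  for (nm in names(sim$truth))
    fwrite(sim$truth[[nm]], file.path(outdir, "truth", paste0(nm, ".tsv")),
           sep = "\t")
  if (!is.null(expression))
    fwrite(expression, file.path(outdir, "expression.tsv"), sep = "\t")
  if (!is.null(matrices)) {
    for (s in names(matrices)) {
      write_matrix(matrices[[s]],
                   file.path(outdir, paste0("matrix_", s, "_bins.tsv")),
                   file.path(outdir, paste0("matrix_", s, "_coo.tsv")))
    }
  }
  invisible(outdir)
}
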