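# End-to-end orchestration on synthetic data, plus truth-vs-called
# recovery metrics used to validate every analysis level.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis thresholds. The
#' threshold defaults are the printed constants of the underlying study
#' design: loop filter FDR < 0.005 and count > 10; clique-loop filter
#' count > 5 and FDR < 0.1; S > 0.09; bias FC >= 2 and FDR <= 0.05; DE
#' |log2FC| > 1 and FDR < 0.01; 40-kb boundary tolerance; >= 2-bin
#' switches; 2-Mb short/long split; > 20 genes per 500 kb for gene-rich.
#'
#' @param seed master seed (drives every stochastic step).
#' @param sim a [sim_config()]; defaults to `sim_config(seed)`.
#' @param thresholds named list of analysis constants (overrides merged
#'   onto the defaults).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, sim = NULL, thresholds = list()) {
  defaults <- list(loop_fdr = 0.005, loop_count = 10L,
                   clique_fdr = 0.1, clique_count = 5L,
                   s_threshold = 0.09, k_min = 3L,
                   bias_fc = 2, bias_fdr = 0.05,
                   de_lfc = 1, de_fdr = 0.01,
                   boundary_tol = 4e4, switch_min_bins = 2L,
                   short_long = 2e6, gene_rich_min = 20L,
                   insulation_window = 10L, tad_min_depth = 0.1)
  defaults[names(thresholds)] <- thresholds
  structure(list(seed = seed,
                 sim = if (is.null(sim)) sim_config(seed) else sim,
                 thresholds = defaults),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the genome and four-stage Hi-C + expression data, then runs
#' every analysis level (balancing, decay, compactness, compartments and
#' trajectories, TADs and conservation/homology, loop calling and
#' taxonomy, cliques and dynamics, homoeolog pairing, bias and networks)
#' and computes truth-vs-called recovery metrics.
#'
#' @param config a [pipeline_config()].
#' @param stages stage labels to process (default all four).
#' @param verbose print progress.
#' @return a nested list: `genome`, `truth`, per-stage results, cross-stage
#'   classifications, `recovery`, and a flat `summary` of headline numbers.
#' @export
run_pipeline <- function(config, stages = .STAGES, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  th <- config$thresholds
  say("simulating genome + truth")
  sim <- simulate_genome(config$sim)
  genome <- sim$genome; truth <- sim$truth
  expr <- simulate_expression(genome, truth, config$sim)

  per_stage <- list()
  tracks <- list(); tad_sets <- list(); loop_calls <- list()
  assignments <- list()
  for (s in stages) {
    say("stage ", s, ": simulating Hi-C")
    m5 <- simulate_hic(genome, truth, s, config$sim)
    m20 <- ice_balance(aggregate_matrix(m5, 2e4))
    m40 <- ice_balance(aggregate_matrix(m5, 4e4))
    say("stage ", s, ": compartments / TADs / loops")
    trk <- call_compartments(m40, genome$genes, stage = s)
    ins <- insulation_multi(m20)
    tads <- call_tads(ins, min_depth = th$tad_min_depth, stage = s)
    calls <- call_loops_standin(m5, stage = s)
    sig <- filter_loops(calls, th$loop_fdr, th$loop_count)
    cl_loops <- filter_clique_loops(calls, th$clique_count, th$clique_fdr)
    cg <- build_clique_graph(tads, cl_loops, threshold = th$s_threshold)
    tracks[[s]] <- trk; tad_sets[[s]] <- tads; loop_calls[[s]] <- calls
    assignments[[s]] <- cg$assignment
    per_stage[[s]] <- list(matrix5 = m5, matrix20 = m20, matrix40 = m40,
                           compartments = trk, insulation = ins,
                           tads = tads, loop_calls = calls,
                           significant_loops = sig, clique_graph = cg)
  }

  out <- list(genome = genome, truth = truth, expression = expr,
              stages = per_stage)

  if (length(stages) == 4L) {
    say("cross-stage classifications")
    traj <- compartment_trajectories(tracks)
    switches <- lapply(1:3, function(k)
      pairwise_switch_regions(tracks[[k]], tracks[[k + 1L]],
                              min_bins = th$switch_min_bins))
    cons <- tad_conservation(tad_sets, tol = th$boundary_tol)
    dyn <- lapply(1:3, function(k)
      clique_dynamics(assignments[[k]], assignments[[k + 1L]]))
    out$trajectories <- traj
    out$switch_regions <- switches
    out$tad_conservation <- cons
    out$clique_dynamics <- dyn
  }

  say("homoeology")
  at_chroms <- genome$chromosomes[subgenome == "At", name]
  genes_at <- genome$genes[chrom %in% at_chroms]
  genes_dt <- genome$genes[!chrom %in% at_chroms]
  blocks <- find_syntenic_blocks(genes_at, genes_dt, truth$similarity)
  pairs <- reciprocal_best_pairs(truth$similarity, blocks$hits)
  bias <- lapply(stages, function(s) bias_calls(expr, pairs, s,
                                                th$bias_fc, th$bias_fdr))
  names(bias) <- stages
  out$homoeology <- list(blocks = blocks, pairs = pairs, bias = bias)
  if (length(stages) == 4L)
    out$homoeology$bias_trajectory <- bias_trajectory(bias)

  say("loop taxonomy + networks (first stage)")
  s1 <- stages[[1L]]
  sig1 <- per_stage[[s1]]$significant_loops
  tax <- classify_anchor_loops(sig1, genome$genes)
  tax <- classify_homoeolog_loops(tax, pairs, genome$genes,
                                  truth$nongene_homology, genome$peaks,
                                  stage = s1)
  hg <- tax[homoeolog_class == "HG-HG"]
  net_at <- build_hg_network(hg[chrom1 %in% at_chroms], pairs,
                             genome$genes, "At")
  net_dt <- build_hg_network(hg[!chrom1 %in% at_chroms], pairs,
                             genome$genes, "Dt")
  out$loop_taxonomy <- tax
  out$networks <- list(at = net_at, dt = net_dt,
                       divergence = network_divergence(net_at, net_dt))

  say("recovery metrics")
  attr(out, "sim_config") <- config$sim
  out$recovery <- pipeline_recovery(out, stages)
  out$summary <- pipeline_summary(out, stages)
  out
}

## ---------------------------------------------------------------------------
## Truth-vs-called recovery metrics

#' Compartment-label agreement with planted truth
#' @param track called compartment track (one stage).
#' @param truth_comp planted compartment table.
#' @param stage stage label.
#' @return fraction of unmasked bins whose label matches the truth.
#' @export
recovery_compartments <- function(track, truth_comp, stage) {
  stg <- stage
  tr <- merge(as.data.table(track)[label %in% c("A", "B")],
              as.data.table(truth_comp)[stage == stg,
                                        .(chrom, start, planted = label)],
              by = c("chrom", "start"))
  mean(tr$label == tr$planted)
}

#' Planted-boundary recovery
#' @param tads_called called TAD table.
#' @param truth_tads planted TAD table.
#' @param stage stage label.
#' @param tol_bp matching tolerance (default one 20-kb bin).
#' @return fraction of planted internal boundaries with a called boundary
#'   within `tol_bp`.
#' @export
recovery_boundaries <- function(tads_called, truth_tads, stage,
                                tol_bp = 2e4) {
  stg <- stage
  tt <- as.data.table(truth_tads)[stage == stg]
  # internal boundaries only (chromosome ends are trivially present)
  pb <- tt[, {
    p <- sort(unique(c(start, end)))
    .(pos = p[-c(1L, length(p))])
  }, by = chrom]
  cb <- tad_boundaries(tads_called)
  hit <- vapply(seq_len(nrow(pb)), function(r) {
    p <- cb[chrom == pb$chrom[r], pos]
    length(p) > 0 && min(abs(p - pb$pos[r])) <= tol_bp
  }, logical(1L))
  mean(hit)
}

#' Planted-loop recovery and false-anchor rate
#'
#' @param calls loop-caller output for one stage.
#' @param truth_loops planted loop table.
#' @param stage stage label.
#' @param fdr_max significance cut applied to the calls.
#' @param kind which planted kinds to count (default generic loops).
#' @return list `recovered` (fraction of planted loops significant at the
#'   cut, exact anchor match), `false_rate` (fraction of significant calls
#'   farther than one bin from any planted anchor pair), `n_calls`.
#' @export
recovery_loops <- function(calls, truth_loops, stage, fdr_max = 0.005,
                           kind = "loop") {
  stg <- stage; kd <- kind
  pl <- as.data.table(truth_loops)[stage == stg & kind %in% kd]
  sig <- as.data.table(calls)[fdr < fdr_max]
  key_sig <- paste(sig$chrom1, sig$start1, sig$start2)
  recovered <- mean(paste(pl$chrom, pl$start1, pl$start2) %in% key_sig)
  all_pl <- as.data.table(truth_loops)[stage == stg]
  near <- rep(FALSE, nrow(sig))
  for (cn in unique(sig$chrom1)) {
    pc <- all_pl[chrom == cn]
    sel <- which(sig$chrom1 == cn)
    if (!nrow(pc)) next
    near[sel] <- vapply(sel, function(r)
      any(abs(pc$start1 - sig$start1[r]) <= 5e3 &
            abs(pc$start2 - sig$start2[r]) <= 5e3), logical(1L))
  }
  list(recovered = recovered,
       false_rate = if (nrow(sig)) mean(!near) else 0,
       n_calls = nrow(sig))
}

#' Planted-clique member-set recovery
#'
#' A planted clique is recovered when its members map injectively (by
#' planted-TAD midpoint containment) onto distinct called TADs that all
#' belong to one called maximal clique.
#'
#' @param clique_graph output of [build_clique_graph()].
#' @param tads_called called TAD table.
#' @param truth_cliques planted clique table.
#' @param stage stage label.
#' @return fraction of planted cliques recovered.
#' @export
recovery_cliques <- function(clique_graph, tads_called, truth_cliques,
                             stage) {
  stg <- stage
  tc <- as.data.table(truth_cliques)[stage == stg]
  if (!nrow(tc)) return(NA_real_)
  td <- as.data.table(tads_called)
  got <- vapply(unique(tc$clique_id), function(cid) {
    mem <- tc[clique_id == cid]
    mid <- (mem$start + mem$end) %/% 2
    ids <- vapply(seq_len(nrow(mem)), function(r) {
      cand <- td[chrom == mem$chrom[r] & start <= mid[r] & end > mid[r]]
      if (nrow(cand)) cand$tad_id[1L] else NA_character_
    }, character(1L))
    if (anyNA(ids) || anyDuplicated(ids)) return(FALSE)
    any(vapply(clique_graph$cliques, function(cl)
      all(ids %in% cl), logical(1L)))
  }, logical(1L))
  mean(got)
}

#' Homoeolog-pair recovery against planted truth
#' @param pairs_called output of [reciprocal_best_pairs()].
#' @param truth_pairs planted pair table.
#' @return list `recovered` (fraction of planted pairs called), `false`
#'   (number of called pairs not planted).
#' @export
recovery_pairs <- function(pairs_called, truth_pairs) {
  pc <- paste(pairs_called$at_gene, pairs_called$dt_gene)
  tp <- paste(truth_pairs$at_gene, truth_pairs$dt_gene)
  list(recovered = mean(tp %in% pc), false = sum(!pc %in% tp))
}

# all recovery metrics for a finished pipeline run
pipeline_recovery <- function(out, stages) {
  s1 <- stages[[1L]]
  # decay exponent measured on a decay-only background (same seed machinery)
  m_null <- simulate_hic(out$genome, out$truth, s1, attr(out, "sim_config"),
                         decay_only = TRUE)
  curve <- contact_probability(aggregate_matrix(m_null, 1e4),
                               balanced = FALSE)
  rec <- list(
    compartment_agreement = mean(vapply(stages, function(s)
      recovery_compartments(out$stages[[s]]$compartments,
                            out$truth$compartments, s), numeric(1L))),
    boundary_recovery = mean(vapply(stages, function(s)
      recovery_boundaries(out$stages[[s]]$tads, out$truth$tads, s),
      numeric(1L))),
    loop_recovery = recovery_loops(out$stages[[s1]]$loop_calls,
                                   out$truth$loops, s1),
    clique_recovery = mean(vapply(stages, function(s)
      recovery_cliques(out$stages[[s]]$clique_graph, out$stages[[s]]$tads,
                       out$truth$cliques, s), numeric(1L))),
    pair_recovery = recovery_pairs(out$homoeology$pairs,
                                   out$truth$homoeologs),
    decay_exponent = fit_decay_exponent(curve))
  rec
}

# headline numbers of a run, flat and machine-readable
pipeline_summary <- function(out, stages) {
  s1 <- stages[[1L]]
  smry <- list(
    n_genes = nrow(out$genome$genes),
    n_pairs_called = nrow(out$homoeology$pairs),
    n_tads_stage1 = nrow(out$stages[[s1]]$tads),
    n_significant_loops_stage1 = nrow(out$stages[[s1]]$significant_loops),
    n_clique_tads_stage1 =
      sum(out$stages[[s1]]$clique_graph$assignment$is_clique))
  if (!is.null(out$trajectories)) {
    tc <- table(out$trajectories$category)
    smry$stable_fraction <-
      unname((sum(tc[c("stable_A", "stable_B")], na.rm = TRUE)) /
               sum(tc))
  }
  if (!is.null(out$networks))
    smry$network_divergence_dt_vs_at <- out$networks$divergence$dt_vs_at
  smry
}
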