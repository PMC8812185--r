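# Homoeolog pairing (collinear blocks + reciprocal best hits), expression
# classifications (expressed / DE / subgenome bias / change categories),
# and homoeologous-gene interaction networks with divergence.

## ---------------------------------------------------------------------------
## Synteny and pairing

# longest collinear chain (DP) over hits sorted by at_rank; dt_rank must be
# strictly monotone in `direction` with gaps <= max_gap in both coordinates
.longest_chain <- function(at_rank, dt_rank, direction, max_gap) {
  n <- length(at_rank)
  ord <- order(at_rank, dt_rank * direction)
  a <- at_rank[ord]; d <- dt_rank[ord]
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a[j] >= a[i]) next
      if (a[i] - a[j] > max_gap) next
      step <- direction * (d[i] - d[j])
      if (step <= 0 || step > max_gap) next
      if (best[j] + 1L > best[i]) { best[i] <- best[j] + 1L; prev[i] <- j }
    }
  }
  top <- which.max(best)
  chain <- integer(0)
  while (!is.na(top)) { chain <- c(top, chain); top <- prev[top] }
  ord[chain]
}

#' Find syntenic blocks between the subgenomes
#'
#' Gene ranks per chromosome are chained by longest-collinear-chain dynamic
#' programming (both orientations, gap cap in both coordinates); chains are
#' extracted greedily until none reaches `min_genes` anchors. A block needs
#' at least five syntenic genes by default.
#'
#' @param genes_at,genes_dt gene tables (`id`, `chrom`, `start`) of the two
#'   subgenomes.
#' @param similarity similarity table (`query`, `subject`, `score`,
#'   `evalue`).
#' @param min_genes minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors.
#' @return list `blocks` (`block_id`, `at_chrom`, `dt_chrom`,
#'   `orientation`, `n_genes`) and `hits` (`at_gene`, `dt_gene`,
#'   `block_id`).
#' @export
find_syntenic_blocks <- function(genes_at, genes_dt, similarity,
                                 min_genes = 5L, max_gap = 25L) {
  ga <- as.data.table(genes_at); gd <- as.data.table(genes_dt)
  ga <- ga[order(chrom, start)][, rank := seq_len(.N), by = chrom]
  gd <- gd[order(chrom, start)][, rank := seq_len(.N), by = chrom]
  sim <- as.data.table(similarity)
  h1 <- sim[query %in% ga$id & subject %in% gd$id,
            .(at_gene = query, dt_gene = subject)]
  h2 <- sim[query %in% gd$id & subject %in% ga$id,
            .(at_gene = subject, dt_gene = query)]
  hits <- unique(rbind(h1, h2))
  hits <- merge(hits, ga[, .(at_gene = id, at_chrom = chrom, at_rank = rank)],
                by = "at_gene")
  hits <- merge(hits, gd[, .(dt_gene = id, dt_chrom = chrom, dt_rank = rank)],
                by = "dt_gene")
  blocks <- list(); assigned <- list()
  bid <- 0L
  for (key in unique(paste(hits$at_chrom, hits$dt_chrom))) {
    sub <- hits[paste(at_chrom, dt_chrom) == key]
    repeat {
      if (nrow(sub) < min_genes) break
      cf <- .longest_chain(sub$at_rank, sub$dt_rank, +1L, max_gap)
      cr <- .longest_chain(sub$at_rank, sub$dt_rank, -1L, max_gap)
      use <- if (length(cf) >= length(cr)) list(cf, "+") else list(cr, "-")
      if (length(use[[1L]]) < min_genes) break
      bid <- bid + 1L
      sel <- sub[use[[1L]]]
      blocks[[bid]] <- data.table(block_id = bid,
                                  at_chrom = sel$at_chrom[1L],
                                  dt_chrom = sel$dt_chrom[1L],
                                  orientation = use[[2L]],
                                  n_genes = nrow(sel))
      assigned[[bid]] <- sel[, .(at_gene, dt_gene, block_id = bid)]
      sub <- sub[-use[[1L]]]
    }
  }
  if (!bid)
    return(list(blocks = data.table(block_id = integer(),
                                    at_chrom = character(),
                                    dt_chrom = character(),
                                    orientation = character(),
                                    n_genes = integer()),
                hits = data.table(at_gene = character(),
                                  dt_gene = character(),
                                  block_id = integer())))
  list(blocks = rbindlist(blocks), hits = rbindlist(assigned))
}

#' Reciprocal-best-hit homoeolog pairs within syntenic blocks
#'
#' A pair (a, d) is kept iff d is a's best-scoring hit, a is d's best hit,
#' and the (a, d) hit lies inside a syntenic block. Score ties break by
#' lower e-value, then lexicographic subject id. Output is one-to-one.
#'
#' @param similarity similarity table (`query`, `subject`, `score`,
#'   `evalue`).
#' @param block_hits `hits` table from [find_syntenic_blocks()].
#' @return data.table `pair_id`, `at_gene`, `dt_gene`, `block_id`.
#' @export
reciprocal_best_pairs <- function(similarity, block_hits) {
  sim <- as.data.table(similarity)
  setorder(sim, query, -score, evalue, subject)
  best <- sim[, .SD[1L], by = query][, .(query, best = subject)]
  bmap <- setNames(best$best, best$query)
  bh <- as.data.table(block_hits)
  keep <- bh[!is.na(bmap[at_gene]) & !is.na(bmap[dt_gene]) &
               bmap[at_gene] == dt_gene & bmap[dt_gene] == at_gene]
  keep <- unique(keep, by = c("at_gene", "dt_gene"))
  # enforce one-to-one (a gene can appear in at most one pair)
  keep <- keep[!duplicated(at_gene) & !duplicated(dt_gene)]
  keep[, pair_id := paste0("pair", seq_len(.N))]
  keep[, .(pair_id, at_gene, dt_gene, block_id)]
}

## ---------------------------------------------------------------------------
## Expression classifications

#' Expressed-gene flags
#'
#' A gene is expressed at a stage iff FPKM > 1 in all replicates.
#'
#' @param expression long table `gene`, `stage`, `rep`, `fpkm`.
#' @return data.table `gene`, `stage`, `expressed`.
#' @export
expressed_flags <- function(expression) {
  ex <- as.data.table(expression)
  ex[, .(expressed = all(fpkm > 1)), by = .(gene, stage)]
}

# two-sided pooled-variance t test on log2(x + eps) with a
# degenerate-variance shortcut; pooled rather than Welch because the
# design is balanced with three replicates a side, where estimating
# separate variances costs most of the degrees of freedom
.safe_log_t <- function(x, y, eps = 0.01) {
  lx <- log2(x + eps); ly <- log2(y + eps)
  if (sd(lx) == 0 && sd(ly) == 0)
    return(list(p = if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0,
                degenerate = TRUE))
  p <- tryCatch(t.test(lx, ly, var.equal = TRUE)$p.value,
                error = function(e) 1)
  list(p = p, degenerate = FALSE)
}

#' Differential-expression stand-in between two stages
#'
#' A replicate-level two-sided test on log2(FPKM + 0.01) with
#' Benjamini-Hochberg correction; a gene is DE iff |log2 fold change| > 1
#' and FDR < 0.01 (strict, as for a count-based caller whose external
#' tables can be ingested instead). Zero-variance genes use an
#' exact-equality shortcut and are flagged.
#'
#' @param expression long FPKM table.
#' @param s1,s2 stage labels to compare.
#' @param lfc_min,fdr_max thresholds (strict).
#' @return data.table `gene`, `lfc` (s2 vs s1), `p`, `fdr`, `de`,
#'   `direction` (`up`/`down`/`none`), `degenerate`.
#' @export
de_standin <- function(expression, s1, s2, lfc_min = 1, fdr_max = 0.01) {
  ex <- as.data.table(expression)
  e1 <- ex[stage == s1]; e2 <- ex[stage == s2]
  genes <- intersect(unique(e1$gene), unique(e2$gene))
  res <- rbindlist(lapply(genes, function(g) {
    x <- e1[gene == g, fpkm]; y <- e2[gene == g, fpkm]
    tt <- .safe_log_t(x, y)
    data.table(gene = g,
               lfc = mean(log2(y + 0.01)) - mean(log2(x + 0.01)),
               p = tt$p, degenerate = tt$degenerate)
  }))
  res[, fdr := p.adjust(p, "BH")]
  res[, de := abs(lfc) > lfc_min & fdr < fdr_max]
  res[, direction := fifelse(!de, "none", fifelse(lfc > 0, "up", "down"))]
  res[]
}

#' Subgenome expression-bias calls for homoeolog pairs
#'
#' At one stage, a pair is At-biased iff the At/Dt mean-FPKM ratio is at
#' least `fc_min` and the replicate-level test FDR is at most `fdr_max`
#' (both inclusive); Dt bias is symmetric. A pseudo-count of 0.01 guards
#' the ratio. Pairs with both members silent (all FPKM < 1 on both sides)
#' are `none` and flagged.
#'
#' @param expression long FPKM table.
#' @param pairs homoeolog pairs.
#' @param stage stage label.
#' @param fc_min,fdr_max inclusive thresholds.
#' @return data.table `pair_id`, `ratio` (At/Dt), `p`, `fdr`, `bias`
#'   (`At`/`Dt`/`none`), `both_silent`.
#' @export
bias_calls <- function(expression, pairs, stage, fc_min = 2, fdr_max = 0.05) {
  ex <- as.data.table(expression)
  stg <- stage
  es <- ex[stage == stg]
  pr <- as.data.table(pairs)
  res <- rbindlist(lapply(seq_len(nrow(pr)), function(r) {
    x <- es[gene == pr$at_gene[r], fpkm]
    y <- es[gene == pr$dt_gene[r], fpkm]
    if (!length(x) || !length(y))
      return(data.table(pair_id = pr$pair_id[r], ratio = NA_real_, p = 1,
                        both_silent = FALSE))
    tt <- .safe_log_t(x, y)
    data.table(pair_id = pr$pair_id[r],
               ratio = (mean(x) + 0.01) / (mean(y) + 0.01), p = tt$p,
               both_silent = all(x < 1) && all(y < 1))
  }))
  res[, fdr := p.adjust(p, "BH")]
  res[, bias := fifelse(both_silent | is.na(ratio), "none",
               fifelse(ratio >= fc_min & fdr <= fdr_max, "At",
               fifelse(ratio <= 1 / fc_min & fdr <= fdr_max, "Dt", "none")))]
  res[]
}

#' Four-stage bias trajectory per pair
#'
#' `conserved_At` iff At-biased at all four stages, `conserved_Dt`
#' symmetric, `dynamic` iff biased at >= 1 stage but not all, `none`
#' otherwise.
#'
#' @param bias_list list of four [bias_calls()] tables in stage order.
#' @return data.table `pair_id`, `trajectory`.
#' @export
bias_trajectory <- function(bias_list) {
  stopifnot(length(bias_list) == 4L)
  b <- rbindlist(lapply(seq_along(bias_list), function(s)
    as.data.table(bias_list[[s]])[, .(pair_id, bias, s = s)]))
  b[, .(trajectory = {
    v <- bias[order(s)]
    if (all(v == "At")) "conserved_At"
    else if (all(v == "Dt")) "conserved_Dt"
    else if (any(v != "none")) "dynamic"
    else "none"
  }), by = pair_id]
}

#' Change category of a homoeolog pair between two stages
#'
#' `single` iff exactly one member is DE; `common` iff both are DE in the
#' same direction; `opposite` iff both are DE in opposite directions;
#' `none` otherwise.
#'
#' @param dir_at,dir_dt DE directions (`up`/`down`/`none`) of the At and
#'   Dt members (vectorised).
#' @return character vector of categories.
#' @export
pair_change_category <- function(dir_at, dir_dt) {
  stopifnot(all(dir_at %in% c("up", "down", "none")),
            all(dir_dt %in% c("up", "down", "none")))
  a <- dir_at != "none"; d <- dir_dt != "none"
  fifelse(a & d & dir_at == dir_dt, "common",
          fifelse(a & d, "opposite",
                  fifelse(xor(a, d), "single", "none")))
}

## ---------------------------------------------------------------------------
## Homoeologous-gene networks

#' Build a homoeologous-gene interaction network for one subgenome
#'
#' Nodes are homoeolog pair ids; an edge joins two pair ids when an HG-HG
#' loop within the subgenome connects anchors containing the respective
#' member genes. Loops touching genes without a pair are excluded and
#' counted.
#'
#' @param loops_hg loop table classed `HG-HG` (one stage, one subgenome's
#'   chromosomes).
#' @param pairs homoeolog pairs.
#' @param genes gene intervals with `id`.
#' @param subgenome `"At"` or `"Dt"` (selects the member gene column).
#' @param resolution anchor bin size.
#' @return list `edges` (`p1`, `p2`), `graph` (igraph), `degree` (per pair
#'   id), `n_excluded_loops`.
#' @export
build_hg_network <- function(loops_hg, pairs, genes, subgenome,
                             resolution = 5e3) {
  pr <- as.data.table(pairs)
  genes <- as.data.table(genes)
  r <- as.integer(resolution)
  gene_col <- if (subgenome == "At") "at_gene" else "dt_gene"
  pg <- merge(genes[, .(id, chrom, bstart = midpoint_bin_start(.SD, r))],
              pr[, .(pair_id, id = get(gene_col))], by = "id")
  lp <- as.data.table(loops_hg)
  a1 <- merge(lp[, .(li = seq_len(.N), chrom = chrom1, bstart = start1)],
              pg[, .(chrom, bstart, pair_id)], by = c("chrom", "bstart"),
              allow.cartesian = TRUE)
  a2 <- merge(lp[, .(li = seq_len(.N), chrom = chrom2, bstart = start2)],
              pg[, .(chrom, bstart, pair_id)], by = c("chrom", "bstart"),
              allow.cartesian = TRUE)
  ee <- merge(a1[, .(li, p1 = pair_id)], a2[, .(li, p2 = pair_id)],
              by = "li", allow.cartesian = TRUE)
  excluded <- sum(!seq_len(nrow(lp)) %in% ee$li)
  ee <- ee[p1 != p2]
  ee[, `:=`(a = pmin(p1, p2), b = pmax(p1, p2))]
  edges <- unique(ee[, .(p1 = a, p2 = b)])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = pr$pair_id))
  list(edges = edges[], graph = g,
       degree = data.table(pair_id = pr$pair_id,
                           degree = as.integer(igraph::degree(g))),
       n_excluded_loops = excluded)
}

#' Network divergence between subgenomes
#'
#' Fraction of one network's edges (in pair-id space) absent from the
#' other; shared edges are the "homoeologous loops".
#'
#' @param net_at,net_dt outputs of [build_hg_network()].
#' @return list `dt_vs_at`, `at_vs_dt` (divergence fractions in [0, 1]),
#'   `shared_edges`.
#' @export
network_divergence <- function(net_at, net_dt) {
  ea <- net_at$edges[, paste(p1, p2)]
  ed <- net_dt$edges[, paste(p1, p2)]
  list(dt_vs_at = if (length(ed)) mean(!ed %in% ea) else NA_real_,
       at_vs_dt = if (length(ea)) mean(!ea %in% ed) else NA_real_,
       shared_edges = net_at$edges[paste(p1, p2) %in% ed])
}
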