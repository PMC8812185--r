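# TAD-clique detection: loop filtering, the size-normalised interaction
# strength S between TAD pairs, maximal-clique enumeration, compartment
# context, and between-stage clique dynamics.

#' Filter loops for clique detection
#'
#' Keeps loops with contact count strictly greater than 5 and FDR strictly
#' below 0.1 (a more permissive filter than the loop-level one, because
#' cliques are a larger-scale structure supported by many loops).
#'
#' @param loops loop table with `count` and `fdr`.
#' @param min_count,max_fdr thresholds (strict inequalities).
#' @return filtered loop table.
#' @export
filter_clique_loops <- function(loops, min_count = 5L, max_fdr = 0.1) {
  dt <- as.data.table(loops)
  if (!all(c("count", "fdr") %in% names(dt)))
    stop("loops must carry 'count' and 'fdr'")
  dt[count > min_count & fdr < max_fdr]
}

#' Interaction strength between two TAD-like structures
#'
#' `density` (default): S = L / (B1 * B2), the loop count normalised by the
#' product of the two structures' bin counts, so that S does not grow with
#' structure size and a high S means intense linkage. `as_printed` computes
#' the reciprocal form S = (B1 * B2) / L (undefined at L = 0).
#'
#' @param B1,B2 bin counts of the two TADs (>= 3).
#' @param L number of qualifying loops linking them.
#' @param formula `"density"` or `"as_printed"`.
#' @return numeric S (vectorised).
#' @export
interaction_strength <- function(B1, B2, L,
                                 formula = c("density", "as_printed")) {
  formula <- match.arg(formula)
  if (any(B1 < 3 | B2 < 3)) stop("TAD bin counts must be >= 3")
  if (any(L < 0)) stop("L must be >= 0")
  if (formula == "density") L / (B1 * B2)
  else ifelse(L > 0, (B1 * B2) / L, NA_real_)
}

#' Assign loops to TAD pairs
#'
#' A loop links two TADs when its anchors fall inside two distinct TADs on
#' the same chromosome (anchor midpoint containment; an anchor in a
#' boundary bin shared by two TADs goes to the TAD containing the larger
#' share of the anchor, ties to the upstream TAD). Loops with an anchor
#' outside every TAD, or with both anchors in one TAD, are dropped here.
#'
#' @param loops cis loop table (`chrom1`, `start1`, `start2`).
#' @param tads TAD table with `tad_id`.
#' @param resolution anchor bin size (default 5 kb).
#' @return data.table `tad_i`, `tad_j`, `L` (loop count per TAD pair).
#' @export
assign_loops_to_tads <- function(loops, tads, resolution = 5e3) {
  lp <- as.data.table(loops)
  td <- as.data.table(tads)
  setorder(td, chrom, start)
  r <- as.integer(resolution)
  locate <- function(chr, pos) {
    # midpoint of the anchor bin; larger-share rule reduces to midpoint
    # containment for anchors split by a TAD edge (tie -> upstream TAD)
    mid <- pos + r / 2
    idx <- rep(NA_character_, length(pos))
    for (cn in unique(chr)) {
      sel <- chr == cn
      tc <- td[chrom == cn]
      if (!nrow(tc)) next
      w <- findInterval(mid[sel], tc$start, left.open = TRUE)
      ok <- w >= 1L & mid[sel] <= tc$end[pmax(w, 1L)]
      idx[sel][ok] <- tc$tad_id[w[ok]]
    }
    idx
  }
  lp[, `:=`(t1 = locate(chrom1, start1), t2 = locate(chrom2, start2))]
  lp <- lp[!is.na(t1) & !is.na(t2) & t1 != t2]
  lp[, `:=`(ti = pmin(t1, t2), tj = pmax(t1, t2))]
  lp[, .(L = .N), by = .(tad_i = ti, tad_j = tj)]
}

#' Build the TAD interaction graph and enumerate cliques
#'
#' Edges are TAD pairs whose interaction strength exceeds `threshold`
#' (S > 0.09 by default). Maximal cliques are enumerated with a
#' Bron-Kerbosch-class algorithm; each TAD's k is the size of the largest
#' maximal clique containing it, and clique status requires k >= 3.
#'
#' @param tads TAD table (`tad_id`, `n_bins`, `chrom`, `start`, `end`).
#' @param loops clique-filtered loop table (see [filter_clique_loops()]).
#' @param threshold S threshold (strict).
#' @param formula strength formula, see [interaction_strength()].
#' @param resolution loop anchor resolution.
#' @return list with `edges` (tad_i, tad_j, B1, B2, L, S), `assignment`
#'   (tad_id, k, is_clique, size_class), `cliques` (list of member-id
#'   vectors of maximal cliques with >= 3 members), `coverage_bp` (genome
#'   span covered by clique TADs).
#' @export
build_clique_graph <- function(tads, loops, threshold = 0.09,
                               formula = c("density", "as_printed"),
                               resolution = 5e3) {
  formula <- match.arg(formula)
  td <- as.data.table(tads)
  pairs <- assign_loops_to_tads(loops, td, resolution)
  bmap <- setNames(td$n_bins, td$tad_id)
  if (nrow(pairs)) {
    pairs[, `:=`(B1 = bmap[tad_i], B2 = bmap[tad_j])]
    pairs[, S := interaction_strength(B1, B2, L, formula)]
    edges <- pairs[!is.na(S) & S > threshold]
  } else {
    edges <- data.table(tad_i = character(), tad_j = character(),
                        L = integer(), B1 = numeric(), B2 = numeric(),
                        S = numeric())
  }
  g <- igraph::graph_from_data_frame(edges[, .(tad_i, tad_j)],
                                     directed = FALSE,
                                     vertices = data.frame(name = td$tad_id))
  mc <- igraph::max_cliques(g, min = 3L)
  k <- setNames(rep(0L, nrow(td)), td$tad_id)
  cl_list <- lapply(mc, function(v) igraph::V(g)$name[v])
  for (cl in cl_list) k[cl] <- pmax(k[cl], length(cl))
  # TADs in an edge but no >=3 clique have k = 2
  in_edge <- unique(c(edges$tad_i, edges$tad_j))
  k[in_edge] <- pmax(k[in_edge], 2L)
  assignment <- data.table(tad_id = td$tad_id, k = as.integer(k))
  assignment[, is_clique := k >= 3L]
  assignment[, size_class := fifelse(k < 3L, "non_clique",
                                     fifelse(k <= 5L, "k3_5", "k_gt5"))]
  cov_bp <- td[tad_id %in% assignment[is_clique == TRUE, tad_id],
               sum(end - start)]
  list(edges = edges[], assignment = assignment[], cliques = cl_list,
       coverage_bp = cov_bp,
       coverage_fraction = cov_bp / td[, sum(end - start)])
}

#' Compartment context of clique TADs
#'
#' Majority compartment label of the 40-kb bins constituting each TAD:
#' `active` (A) or `inactive` (B).
#'
#' @param tads TAD table.
#' @param track compartment track at 40 kb.
#' @return `tads` with a `context` column.
#' @export
clique_compartment_context <- function(tads, track) {
  td <- as.data.table(tads)
  trk <- as.data.table(track)
  td[, context := vapply(seq_len(.N), function(r) {
    lb <- trk[chrom == td$chrom[r] & start >= td$start[r] &
                start < td$end[r], label]
    lb <- lb[lb %in% c("A", "B")]
    if (!length(lb)) return(NA_character_)
    if (mean(lb == "A") >= 0.5) "active" else "inactive"
  }, character(1L))]
  td[]
}

#' Between-stage clique dynamics
#'
#' Per TAD (matched across the two stages by `tad_id`):
#' loss = clique to non-clique; formation = non-clique to clique;
#' expansion = (3 <= k <= 5) to (k > 5); reduction = (k > 5) to
#' (3 <= k <= 5); stable = unchanged size class; other cases `other`
#' (both-stage non-cliques are `stable`).
#'
#' @param assign1,assign2 `assignment` tables from [build_clique_graph()]
#'   for two stages; only shared `tad_id`s are compared (the number
#'   excluded is reported as an attribute).
#' @return data.table `tad_id`, `k1`, `k2`, `category`, plus a transition
#'   count table in the `transitions` attribute.
#' @export
clique_dynamics <- function(assign1, assign2) {
  a1 <- as.data.table(assign1); a2 <- as.data.table(assign2)
  m <- merge(a1[, .(tad_id, k1 = k, c1 = size_class)],
             a2[, .(tad_id, k2 = k, c2 = size_class)], by = "tad_id")
  m[, category := fifelse(c1 != "non_clique" & c2 == "non_clique", "loss",
                  fifelse(c1 == "non_clique" & c2 != "non_clique", "formation",
                  fifelse(c1 == "k3_5" & c2 == "k_gt5", "expansion",
                  fifelse(c1 == "k_gt5" & c2 == "k3_5", "reduction",
                  fifelse(c1 == c2, "stable", "other")))))]
  setattr(m, "n_excluded",
          length(union(a1$tad_id, a2$tad_id)) - nrow(m))
  setattr(m, "transitions", m[, .N, by = .(from = c1, to = c2)])
  m[]
}

#' Clique-size vs expression coupling
#'
#' Genes are grouped by the size class of their containing TAD; reports
#' per-class mean/median expression and a rank correlation (Spearman) of
#' expression with k across genes in clique TADs and non-cliques.
#'
#' @param assignment `assignment` table from [build_clique_graph()].
#' @param tads TAD table (for gene containment).
#' @param genes gene intervals with `id`.
#' @param expression long FPKM table (`gene`, `fpkm`); pre-filter to one
#'   stage for stage-resolved coupling.
#' @return list `by_class` (summary per size class), `rho`, `p` (Spearman
#'   test of fpkm vs k).
#' @export
clique_expression_coupling <- function(assignment, tads, genes, expression) {
  td <- as.data.table(tads)
  g <- as.data.table(genes)
  ex <- as.data.table(expression)[, .(fpkm = mean(fpkm)), by = gene]
  gmid <- g[, .(id, chrom, mid = (start + end) %/% 2)]
  gmid[, tad_id := {
    out <- rep(NA_character_, .N)
    for (cn in unique(chrom)) {
      tc <- td[chrom == cn][order(start)]
      if (!nrow(tc)) next
      sel <- chrom == cn
      w <- findInterval(mid[sel], tc$start)
      ok <- w >= 1L & mid[sel] < tc$end[pmax(w, 1L)]
      out[sel][ok] <- tc$tad_id[w[ok]]
    }
    out
  }]
  dt <- merge(gmid[!is.na(tad_id)], as.data.table(assignment), by = "tad_id")
  dt <- merge(dt, ex, by.x = "id", by.y = "gene")
  by_class <- dt[, .(n_genes = .N, mean_fpkm = mean(fpkm),
                     median_fpkm = median(fpkm)), by = size_class]
  ct <- suppressWarnings(cor.test(dt$k, dt$fpkm, method = "spearman"))
  list(by_class = by_class[], rho = unname(ct$estimate), p = ct$p.value,
       genes = dt[])
}
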