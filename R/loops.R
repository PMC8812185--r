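# Chromatin-loop module: significance filtering, a distance-stratified
# binomial loop caller, anchor taxonomies (gene / non-gene, homoeolog
# classes), density normalisations, and boundary-relative profiles.

#' Filter significant loops
#'
#' Keeps loops with FDR strictly below 0.005 and contact count strictly
#' greater than 10.
#'
#' @param loops loop table with `count` and `fdr`.
#' @param max_fdr,min_count thresholds (strict inequalities).
#' @return filtered loop table (a subset of the input).
#' @export
filter_loops <- function(loops, max_fdr = 0.005, min_count = 10L) {
  dt <- as.data.table(loops)
  if (!all(c("count", "fdr") %in% names(dt)))
    stop("loops must carry 'count' and 'fdr'")
  dt[fdr < max_fdr & count > min_count]
}

#' Distance-stratified binomial loop caller
#'
#' For each chromosome, the expected count at gap d is the mean observed
#' count over all bin pairs at that gap; a pair's p-value is the binomial
#' upper tail of its observed count given N trials (the chromosome's total
#' cis counts in the tested gap range) and success probability
#' expected(d)/N. FDR is Benjamini-Hochberg over all tested pairs,
#' including zero-count pairs (which have p = 1 and are counted in the
#' correction denominator).
#'
#' @param bm raw-count `binned_matrix` at 5 kb.
#' @param min_gap minimum gap in bins (default 2: diagonal and adjacent
#'   bins excluded as self-ligation artefacts).
#' @param max_gap maximum gap in bins (default 600 = 3 Mb, wide enough to
#'   cover loops linking distal members of multi-megabase TAD cliques).
#' @param stage stage label attached to the calls.
#' @return loop table (`chrom1`, `start1`, `chrom2`, `start2`, `count`,
#'   `p`, `fdr`, `stage`) for all tested pairs with count > 0.
#' @export
call_loops_standin <- function(bm, min_gap = 2L, max_gap = 600L,
                               stage = bm$stage) {
  if (bm_total(bm) == 0) stop("empty matrix")
  res <- bm$resolution
  tr <- bm_triplets(bm)
  tr[, `:=`(c1 = bm$bins$chrom[i], c2 = bm$bins$chrom[j])]
  tr <- tr[c1 == c2]
  tr[, gap := j - i]
  out <- list()
  for (cn in unique(bm$bins$chrom)) {
    tc <- tr[c1 == cn & gap >= min_gap & gap <= max_gap]
    nbin <- bm$bins[chrom == cn, .N]
    if (!nrow(tc)) next
    gaps <- min_gap:min(max_gap, nbin - 1L)
    npair <- pmax(0L, nbin - gaps)
    obs <- tc[, .(total = sum(x), nz = .N), by = gap]
    gtab <- data.table(gap = gaps, npair = npair)
    gtab <- merge(gtab, obs, by = "gap", all.x = TRUE)
    gtab[is.na(total), `:=`(total = 0, nz = 0L)]
    gtab[, expected := total / npair]
    N <- sum(gtab$total)
    m_tested <- sum(gtab$npair)
    tc <- merge(tc, gtab[, .(gap, expected)], by = "gap")
    tc[, p := pbinom(x - 1, size = N, prob = expected / N,
                     lower.tail = FALSE)]
    # BH over all tested pairs: zero-count pairs carry p = 1
    setorder(tc, p)
    # BH step-up from the largest p downward, m = all tested pairs
    tc[, fdr := rev(cummin(rev(pmin(1, p * m_tested / seq_len(.N)))))]
    out[[cn]] <- tc[, .(chrom1 = cn, start1 = bm$bins$start[i],
                        chrom2 = cn, start2 = bm$bins$start[j],
                        count = as.integer(x), p, fdr)]
  }
  calls <- rbindlist(out)
  stg <- stage
  calls[, stage := stg]
  setorder(calls, chrom1, start1, start2)
  calls[]
}

#' Gene / non-gene anchor taxonomy
#'
#' An anchor contains a gene iff at least one gene midpoint falls in its
#' 5-kb bin. Loops are classed G-G (both anchors genic), G-N (exactly
#' one), N-N (neither).
#'
#' @param loops loop table.
#' @param genes gene intervals with `id`.
#' @param resolution anchor bin size.
#' @param overlap_rule `"midpoint"` (default) or `"any"` (>= 1 bp overlap).
#' @return `loops` with logical `genic1`, `genic2` and `anchor_class`.
#' @export
classify_anchor_loops <- function(loops, genes, resolution = 5e3,
                                  overlap_rule = c("midpoint", "any")) {
  overlap_rule <- match.arg(overlap_rule)
  lp <- copy(as.data.table(loops))
  genes <- as.data.table(genes)
  r <- as.integer(resolution)
  if (overlap_rule == "midpoint") {
    gb <- unique(genes[, .(chrom, bstart = midpoint_bin_start(.SD, r))])
  } else {
    gb <- unique(genes[, .(bstart = seq((start %/% r) * r,
                                        ((end - 1L) %/% r) * r, by = r)),
                       by = .(chrom, id)][, .(chrom, bstart)])
  }
  key <- paste(gb$chrom, gb$bstart)
  lp[, genic1 := paste(chrom1, start1) %in% key]
  lp[, genic2 := paste(chrom2, start2) %in% key]
  lp[, anchor_class := fifelse(genic1 & genic2, "G-G",
                               fifelse(genic1 | genic2, "G-N", "N-N"))]
  lp[]
}

#' Per-gene loop degree by class
#'
#' Counts, for each gene, the G-G and G-N loops with an anchor in the
#' gene's bin.
#'
#' @param taxonomy output of [classify_anchor_loops()].
#' @param genes gene intervals with `id`.
#' @param resolution anchor bin size.
#' @return data.table `id`, `n_gg`, `n_gn`.
#' @export
gene_loop_degree <- function(taxonomy, genes, resolution = 5e3) {
  genes <- as.data.table(genes)
  r <- as.integer(resolution)
  gb <- genes[, .(id, chrom, bstart = midpoint_bin_start(.SD, r))]
  tx <- as.data.table(taxonomy)
  anch <- rbind(tx[, .(chrom = chrom1, bstart = start1, anchor_class)],
                tx[, .(chrom = chrom2, bstart = start2, anchor_class)])
  m <- merge(gb, anch, by = c("chrom", "bstart"), allow.cartesian = TRUE)
  deg <- m[, .(n_gg = sum(anchor_class == "G-G"),
               n_gn = sum(anchor_class == "G-N")), by = id]
  out <- merge(gb[, .(id)], deg, by = "id", all.x = TRUE)
  out[is.na(n_gg), n_gg := 0L]; out[is.na(n_gn), n_gn := 0L]
  out[]
}

# mark presence vector of a set of 5-kb regions at one stage
.mark_vector <- function(regions, peaks, stage_label) {
  pk <- as.data.table(peaks)
  if (!is.null(stage_label) && !is.na(stage_label))
    pk <- pk[stage == stage_label]
  pk[, mid := (start + end) %/% 2]
  sapply(.MARKS, function(mk) {
    pm <- pk[mark == mk]
    vapply(seq_len(nrow(regions)), function(r)
      nrow(pm[chrom == regions$chrom[r] & mid >= regions$start[r] &
                mid < regions$end[r]]) > 0, logical(1L))
  })
}

#' Homoeolog-aware loop taxonomy
#'
#' HG-HG: both anchors contain a member of a homoeolog pair. HG-HN: one
#' anchor does and the other contains no gene at all. HG-HN subtypes
#' compare the non-gene anchor with the other subgenome through the
#' region-correspondence map: `homo_same` when a homologous region exists
#' and carries the identical mark presence/absence vector at that stage,
#' `homo_different` when the vectors differ, `non_homo` when the anchor has
#' no homologous counterpart.
#'
#' @param taxonomy output of [classify_anchor_loops()].
#' @param pairs homoeolog pairs (`at_gene`, `dt_gene`).
#' @param genes gene intervals with `id`.
#' @param nongene_map region correspondence (`at_chrom`, `at_start`,
#'   `at_end`, `dt_chrom`, `dt_start`, `dt_end`) or NULL.
#' @param peaks peak table (`stage`, `mark`, `chrom`, `start`, `end`).
#' @param stage stage used for the mark vectors.
#' @param resolution anchor bin size.
#' @return `taxonomy` with `homoeolog_class` (`HG-HG`/`HG-HN`/`none`) and
#'   `hn_subtype` (`homo_same`/`homo_different`/`non_homo`/`n/a`).
#' @export
classify_homoeolog_loops <- function(taxonomy, pairs, genes,
                                     nongene_map = NULL, peaks = NULL,
                                     stage = NA_character_,
                                     resolution = 5e3) {
  lp <- copy(as.data.table(taxonomy))
  pairs <- as.data.table(pairs)
  genes <- as.data.table(genes)
  r <- as.integer(resolution)
  hg_genes <- genes[id %in% c(pairs$at_gene, pairs$dt_gene)]
  hb <- unique(hg_genes[, .(chrom, bstart = midpoint_bin_start(.SD, r))])
  hkey <- paste(hb$chrom, hb$bstart)
  lp[, hg1 := paste(chrom1, start1) %in% hkey]
  lp[, hg2 := paste(chrom2, start2) %in% hkey]
  lp[, homoeolog_class := fifelse(hg1 & hg2, "HG-HG",
    fifelse((hg1 & !genic2) | (hg2 & !genic1), "HG-HN", "none"))]
  lp[, hn_subtype := "n/a"]
  hn <- which(lp$homoeolog_class == "HG-HN")
  if (length(hn)) {
    if (is.null(nongene_map)) {
      warning("no non-gene homology map: HG-HN subtypes set to n/a")
    } else {
      ngm <- as.data.table(nongene_map)
      for (ii in hn) {
        ng_chrom <- if (lp$hg1[ii]) lp$chrom2[ii] else lp$chrom1[ii]
        ng_start <- if (lp$hg1[ii]) lp$start2[ii] else lp$start1[ii]
        hit <- ngm[(at_chrom == ng_chrom & at_start < ng_start + r &
                      at_end > ng_start) |
                     (dt_chrom == ng_chrom & dt_start < ng_start + r &
                        dt_end > ng_start)]
        if (!nrow(hit)) { lp$hn_subtype[ii] <- "non_homo"; next }
        hit <- hit[1L]
        if (hit$at_chrom == ng_chrom && hit$at_start < ng_start + r &&
              hit$at_end > ng_start) {
          self <- data.table(chrom = ng_chrom, start = ng_start,
                             end = ng_start + r)
          other <- data.table(chrom = hit$dt_chrom, start = hit$dt_start,
                              end = hit$dt_end)
        } else {
          self <- data.table(chrom = ng_chrom, start = ng_start,
                             end = ng_start + r)
          other <- data.table(chrom = hit$at_chrom, start = hit$at_start,
                              end = hit$at_end)
        }
        v1 <- .mark_vector(self, peaks, stage)
        v2 <- .mark_vector(other, peaks, stage)
        lp$hn_subtype[ii] <- if (identical(as.logical(v1), as.logical(v2)))
          "homo_same" else "homo_different"
      }
    }
  }
  lp[]
}

#' Gene-density-normalised loop summaries
#'
#' Windows of `window` bp are gene-rich when they contain strictly more
#' than `rich_min` gene midpoints, else gene-poor. Reports (1) the
#' proportion of loop anchors per density class divided by the class's
#' total genomic length, and (2) per-chromosome positional loop densities
#' divided by the stage's total loop count, so that stages with identical
#' spatial patterns but different loop totals give identical curves.
#'
#' @param loops loop table.
#' @param genes gene intervals.
#' @param chromosomes chromosome table (`name`, `length`).
#' @param window density window in bp (default 500 kb).
#' @param rich_min gene-count threshold (strict >).
#' @param density_bin positional density bin in bp (default 1 Mb).
#' @return list `anchor_norm` (per class: anchors, length, normalised
#'   proportion) and `positional_density`.
#' @export
loop_density_normalizations <- function(loops, genes, chromosomes,
                                        window = 5e5, rich_min = 20L,
                                        density_bin = 1e6) {
  lp <- as.data.table(loops)
  genes <- as.data.table(genes)
  cp <- as.data.table(chromosomes)
  wins <- cp[, .(wstart = seq(0L, by = as.integer(window),
                              length.out = ceiling(length / window))),
             by = .(chrom = name)]
  gmid <- genes[, .(chrom, w = ((start + end) %/% 2 %/% window) * window)]
  cnt <- gmid[, .(n_genes = .N), by = .(chrom, wstart = as.integer(w))]
  wins <- merge(wins, cnt, by = c("chrom", "wstart"), all.x = TRUE)
  wins[is.na(n_genes), n_genes := 0L]
  wins[, class := fifelse(n_genes > rich_min, "gene_rich", "gene_poor")]
  anch <- rbind(lp[, .(chrom = chrom1, pos = start1)],
                lp[, .(chrom = chrom2, pos = start2)])
  anch[, wstart := as.integer((pos %/% window) * window)]
  anch <- merge(anch, wins[, .(chrom, wstart, class)],
                by = c("chrom", "wstart"), all.x = TRUE)
  an <- anch[!is.na(class), .(n_anchors = .N), by = class]
  len <- wins[, .(length_bp = .N * window), by = class]
  an <- merge(len, an, by = "class", all.x = TRUE)
  an[is.na(n_anchors), n_anchors := 0L]
  an[, prop := n_anchors / sum(n_anchors)]
  an[, norm_prop := prop / length_bp]
  pd <- lp[, .(chrom = chrom1,
               pos = ((start1 + start2) %/% 2 %/% density_bin) * density_bin,
               stage)]
  pd <- pd[, .(n = .N), by = .(stage, chrom, pos)]
  pd[, density := n / sum(n), by = stage]
  list(anchor_norm = an[], positional_density = pd[order(stage, chrom, pos)])
}

#' Boundary-relative anchor meta-profile
#'
#' Each anchor inside a TAD is mapped to its relative position (0 = left
#' boundary, 1 = right boundary) and histogrammed over `n_meta_bins`
#' (loop-count normalised). Anchors outside every TAD are counted
#' separately.
#'
#' @param loops loop table.
#' @param tads TAD table.
#' @param n_meta_bins histogram resolution.
#' @param resolution anchor bin size.
#' @return list `profile` (`meta_bin`, `rel_mid`, `density`), `n_outside`.
#' @export
boundary_relative_profile <- function(loops, tads, n_meta_bins = 20L,
                                      resolution = 5e3) {
  lp <- as.data.table(loops)
  td <- as.data.table(tads)
  r <- as.integer(resolution)
  anch <- rbind(lp[, .(chrom = chrom1, pos = start1 + r / 2)],
                lp[, .(chrom = chrom2, pos = start2 + r / 2)])
  rel <- rep(NA_real_, nrow(anch))
  for (cn in unique(anch$chrom)) {
    tc <- td[chrom == cn][order(start)]
    if (!nrow(tc)) next
    sel <- which(anch$chrom == cn)
    w <- findInterval(anch$pos[sel], tc$start)
    ok <- w >= 1L & anch$pos[sel] < tc$end[pmax(w, 1L)]
    rel[sel[ok]] <- (anch$pos[sel][ok] - tc$start[w[ok]]) /
      (tc$end[w[ok]] - tc$start[w[ok]])
  }
  inside <- rel[!is.na(rel)]
  mb <- pmin(n_meta_bins, floor(inside * n_meta_bins) + 1L)
  prof <- data.table(meta_bin = seq_len(n_meta_bins))
  cnt <- tabulate(mb, n_meta_bins)
  prof[, rel_mid := (meta_bin - 0.5) / n_meta_bins]
  prof[, density := if (length(inside)) cnt / length(inside) else 0]
  list(profile = prof[], n_outside = sum(is.na(rel)))
}

#' Histone-mark context dynamics of non-gene anchors
#'
#' For every non-gene anchor bin, the presence/absence vector over the
#' three marks is computed per stage (peak midpoint in bin). An anchor is
#' in the `active` state when it carries H3K27ac or H3K4me3, `inactive`
#' when it carries only H3K9me2, `unmarked` otherwise. Transitions between
#' adjacent stages are counted.
#'
#' @param taxonomy output of [classify_anchor_loops()] (any one stage's
#'   loop set; anchors with `genic = FALSE` are used).
#' @param peaks peak table covering all stages.
#' @param stages stage labels in order.
#' @param resolution anchor bin size.
#' @return list `states` (anchor x stage state matrix as a long table) and
#'   `transitions` (per adjacent stage pair: active_to_inactive,
#'   inactive_to_active, unchanged).
#' @export
mark_context_dynamics <- function(taxonomy, peaks, stages = .STAGES,
                                  resolution = 5e3) {
  tx <- as.data.table(taxonomy)
  r <- as.integer(resolution)
  ng <- unique(rbind(tx[genic1 == FALSE, .(chrom = chrom1, start = start1)],
                     tx[genic2 == FALSE, .(chrom = chrom2, start = start2)]))
  if (!nrow(ng))
    return(list(states = data.table(), transitions = data.table()))
  ng[, end := start + r]
  state_by_stage <- lapply(stages, function(s) {
    mv <- .mark_vector(ng, peaks, s)
    mv <- matrix(mv, nrow = nrow(ng))
    act <- mv[, 1L] | mv[, 2L]
    ina <- mv[, 3L] & !act
    fifelse(act, "active", fifelse(ina, "inactive", "unmarked"))
  })
  states <- rbindlist(lapply(seq_along(stages), function(k)
    data.table(chrom = ng$chrom, start = ng$start, stage = stages[k],
               state = state_by_stage[[k]])))
  trans <- rbindlist(lapply(seq_len(length(stages) - 1L), function(k) {
    s1 <- state_by_stage[[k]]; s2 <- state_by_stage[[k + 1L]]
    data.table(from_stage = stages[k], to_stage = stages[k + 1L],
               active_to_inactive = sum(s1 == "active" & s2 == "inactive"),
               inactive_to_active = sum(s1 == "inactive" & s2 == "active"),
               unchanged = sum(s1 == s2))
  }))
  list(states = states, transitions = trans)
}
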