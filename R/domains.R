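# Insulation-score TAD-like structure calling at 20 kb, cross-stage
# boundary conservation, boundary/interior feature assignment, and
# inter-subgenome homoeologous/partitioned classification.

#' Insulation score track
#'
#' For bin i, the mean balanced contact count in the w x w square straddling
#' the bin ((i-w..i-1) x (i+1..i+w)), expressed as log2 against the
#' chromosome mean of that quantity. Lower scores mean stronger insulation.
#' Bins closer than w to a chromosome end are undefined (NA).
#'
#' @param bm balanced `binned_matrix` at 20 kb.
#' @param window square size in bins (default 10 = 200 kb).
#' @return data.table `chrom`, `start`, `score`, with `window` attribute.
#' @export
insulation_score <- function(bm, window = 10L) {
  res <- bm$resolution
  out <- list()
  for (cn in unique(bm$bins$chrom)) {
    blk <- bm_chrom_dense(bm, cn, balanced = TRUE)
    n <- nrow(blk$mat)
    if (window > n / 2) stop("window larger than half of chromosome ", cn)
    m <- blk$mat
    nas <- is.na(m)
    m[nas] <- 0
    # summed-area tables for values and defined-cell counts
    sat <- apply(apply(m, 2L, cumsum), 1L, cumsum)      # sat[j, i] after t
    cntm <- apply(apply(!nas, 2L, cumsum), 1L, cumsum)
    rect <- function(S, r1, r2, c1, c2) {
      # S is transposed summed-area table: S[col, row]
      S[c2, r2] - (if (r1 > 1L) S[c2, r1 - 1L] else 0) -
        (if (c1 > 1L) S[c1 - 1L, r2] else 0) +
        (if (r1 > 1L && c1 > 1L) S[c1 - 1L, r1 - 1L] else 0)
    }
    sq <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i <= window || i > n - window) next
      v <- rect(sat, i - window, i - 1L, i + 1L, i + window)
      k <- rect(cntm, i - window, i - 1L, i + 1L, i + window)
      sq[i] <- if (k > 0) v / k else NA_real_
    }
    mu <- mean(sq, na.rm = TRUE)
    score <- log2(sq / mu)
    score[!is.finite(score)] <- NA_real_
    out[[cn]] <- data.table(chrom = cn, start = blk$bins$start, score = score)
  }
  trk <- rbindlist(out)
  setattr(trk, "window", as.integer(window))
  trk[]
}

#' Multi-scale insulation track
#'
#' Mean of per-window insulation scores over several square sizes, the
#' multi-scale strategy of insulation-based TAD callers: small windows see
#' boundaries between short domains, large windows suppress point noise.
#' Bins undefined at the largest window are undefined in the combination.
#'
#' @param bm balanced `binned_matrix` at 20 kb.
#' @param windows square sizes in bins.
#' @return data.table `chrom`, `start`, `score` with a `window` attribute
#'   set to the largest window.
#' @export
insulation_multi <- function(bm, windows = c(4L, 6L, 8L, 10L)) {
  trks <- lapply(windows, function(w) insulation_score(bm, window = w))
  comb <- copy(trks[[1L]])
  comb[, score := rowMeans(do.call(cbind,
                                   lapply(trks, function(t) t$score)),
                           na.rm = FALSE)]
  setattr(comb, "window", as.integer(max(windows)))
  comb[]
}

# non-maximum suppression: deeper minimum wins within delta_window
.pick_boundaries <- function(score, delta_window, min_depth, window) {
  n <- length(score)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(score[i])) next
    lo <- max(1L, i - delta_window); hi <- min(n, i + delta_window)
    nb <- score[lo:hi]
    if (score[i] > min(nb, na.rm = TRUE)) next
    l1 <- max(1L, i - window); h1 <- min(n, i + window)
    left <- suppressWarnings(max(score[l1:(i - 1L)], na.rm = TRUE))
    right <- suppressWarnings(max(score[(i + 1L):h1], na.rm = TRUE))
    if (!is.finite(left) || !is.finite(right)) next
    if (min(left, right) - score[i] < min_depth) next
    cand <- c(cand, i)
  }
  cand <- cand[order(score[cand])]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || min(abs(keep - i)) > delta_window)
      keep <- c(keep, i)
  sort(keep)
}

#' Call TAD-like structures from an insulation track
#'
#' Boundaries are local insulation minima passing a prominence threshold
#' (`min_depth`, log2 units); when two candidates fall within
#' `delta_window` bins the deeper one wins. TADs are the intervals between
#' consecutive boundaries; a minimum size of 3 bins is enforced by merging.
#' If no boundary is found the whole chromosome is returned as a single
#' structure with a warning.
#'
#' @param track output of [insulation_score()].
#' @param delta_window minimum boundary separation in bins.
#' @param min_depth prominence threshold (log2 units).
#' @param resolution bin size in bp (default 20 kb).
#' @param stage stage label attached to the result.
#' @return data.table `chrom`, `stage`, `start`, `end`, `n_bins`, `tad_id`.
#' @export
call_tads <- function(track, delta_window = 3L, min_depth = 0.1,
                      resolution = 2e4, stage = NA_character_) {
  trk <- as.data.table(track)
  window <- attr(track, "window")
  if (is.null(window)) window <- 10L
  res <- as.integer(resolution)
  out <- list()
  for (cn in unique(trk$chrom)) {
    sc <- trk[chrom == cn][order(start)]
    n <- nrow(sc)
    b <- .pick_boundaries(sc$score, delta_window, min_depth, window)
    if (!length(b))
      warning("call_tads: no boundary on ", cn,
              "; whole chromosome returned as one structure")
    tt <- .boundaries_to_tads(b - 1L, n)     # boundary bin starts a TAD
    out[[cn]] <- data.table(chrom = cn, stage = stage,
                            start = sc$start[1L] + tt$start_bin * res,
                            end = sc$start[1L] + tt$end_bin * res)
  }
  tads <- rbindlist(out)
  tads[, n_bins := (end - start) %/% res]
  tads[, tad_id := paste0(chrom, ":", start, "-", end)]
  tads[]
}

#' Boundary positions of a TAD set
#' @param tads TAD table (`chrom`, `start`, `end`).
#' @return data.table `chrom`, `pos` of unique boundary coordinates.
#' @export
tad_boundaries <- function(tads) {
  t <- as.data.table(tads)
  unique(rbind(t[, .(chrom, pos = start)], t[, .(chrom, pos = end)]))
}

#' Conserved-boundary flags between two stages
#'
#' A boundary is conserved iff a boundary of the other stage lies within
#' `tol` bp (inclusive; default two 20-kb bins = 40 kb).
#'
#' @param tads_s1,tads_s2 TAD tables for the two stages.
#' @param tol tolerance in bp.
#' @return `tads_s1` boundaries with a logical `conserved` column.
#' @export
conserved_boundaries <- function(tads_s1, tads_s2, tol = 4e4) {
  b1 <- tad_boundaries(tads_s1); b2 <- tad_boundaries(tads_s2)
  b1[, conserved := vapply(seq_len(.N), function(r) {
    p <- b2[chrom == b1$chrom[r], pos]
    length(p) > 0 && min(abs(p - b1$pos[r])) <= tol
  }, logical(1L))]
  b1[]
}

# TAD conserved between two stages iff both its boundaries are conserved
.tad_conserved_with <- function(tads, other, tol) {
  bo <- tad_boundaries(other)
  vapply(seq_len(nrow(tads)), function(r) {
    p <- bo[chrom == tads$chrom[r], pos]
    length(p) > 0 && min(abs(p - tads$start[r])) <= tol &&
      min(abs(p - tads$end[r])) <= tol
  }, logical(1L))
}

#' Cross-stage TAD conservation classes
#'
#' A TAD is conserved with another stage iff both of its boundaries have a
#' counterpart within `tol` in that stage. Counting the other three stages:
#' conserved with all three = `thoroughly_conserved`; with one or two =
#' `relatively_conserved`; with none = `stage_specific`.
#'
#' @param tad_sets list of four TAD tables in stage order.
#' @param tol boundary tolerance in bp (default 40 kb, inclusive).
#' @return rbind of the four inputs with `n_conserved_with` and `class`.
#' @export
tad_conservation <- function(tad_sets, tol = 4e4) {
  stopifnot(length(tad_sets) == 4L)
  out <- list()
  for (s in 1:4) {
    tt <- as.data.table(tad_sets[[s]])
    ncons <- rowSums(vapply(setdiff(1:4, s), function(o)
      .tad_conserved_with(tt, tad_sets[[o]], tol), logical(nrow(tt))))
    tt[, n_conserved_with := ncons]
    tt[, class := fifelse(ncons == 3L, "thoroughly_conserved",
                          fifelse(ncons >= 1L, "relatively_conserved",
                                  "stage_specific"))]
    out[[s]] <- tt
  }
  rbindlist(out)
}

#' Boundary/interior assignment of features
#'
#' A feature is a boundary feature if its midpoint falls within a boundary
#' bin plus/minus `halo` bins; otherwise interior (features outside every
#' TAD are labelled `outside`).
#'
#' @param tads TAD table.
#' @param features intervals (`chrom`, `start`, `end`).
#' @param halo halo in bins on each side of a boundary bin.
#' @param resolution bin size in bp.
#' @return `features` with a `position` column.
#' @export
boundary_interior_assignment <- function(tads, features, halo = 1L,
                                         resolution = 2e4) {
  ft <- as.data.table(features)
  bd <- tad_boundaries(tads)
  td <- as.data.table(tads)
  r <- as.integer(resolution)
  mid <- (as.numeric(ft$start) + as.numeric(ft$end)) %/% 2
  ft[, position := vapply(seq_len(.N), function(i) {
    p <- bd[chrom == ft$chrom[i], pos]
    if (length(p) && any(mid[i] >= p - halo * r & mid[i] < p + (halo + 1L) * r))
      return("boundary")
    inside <- td[chrom == ft$chrom[i] & start <= mid[i] & end > mid[i]]
    if (nrow(inside)) "interior" else "outside"
  }, character(1L))]
  ft[]
}

#' Homoeologous vs partitioned TAD classification across subgenomes
#'
#' For each At TAD, collect the homoeolog-pair ids of contained genes (gene
#' midpoint inside the TAD); find the Dt TADs containing any partner gene.
#' The (At, Dt) pair is `homoeologous` iff one Dt TAD's pair-id set equals
#' the At TAD's set exactly and non-emptily; otherwise every involved
#' combination is `partitioned`. TADs without homoeologous genes are not
#' classified.
#'
#' @param tads_at,tads_dt TAD tables for the two subgenomes (one stage).
#' @param pairs homoeolog pairs (`pair_id`, `at_gene`, `dt_gene`).
#' @param genes gene intervals with `id`.
#' @return data.table `at_tad`, `dt_tad`, `class`, `pair_ids`
#'   (comma-separated ids on the At side).
#' @export
classify_tad_homology <- function(tads_at, tads_dt, pairs, genes) {
  pairs <- as.data.table(pairs); genes <- as.data.table(genes)
  gmid <- genes[, .(id, chrom, mid = (start + end) %/% 2)]
  content <- function(tads, gene_col) {
    td <- as.data.table(tads)
    pg <- merge(gmid, pairs[, .(pair_id, id = get(gene_col))], by = "id")
    lapply(seq_len(nrow(td)), function(r)
      sort(pg[chrom == td$chrom[r] & mid >= td$start[r] & mid < td$end[r],
              pair_id]))
  }
  at_sets <- content(tads_at, "at_gene")
  dt_sets <- content(tads_dt, "dt_gene")
  at_id <- as.data.table(tads_at)$tad_id
  dt_id <- as.data.table(tads_dt)$tad_id
  if (is.null(at_id)) at_id <- paste0("At_", seq_along(at_sets))
  if (is.null(dt_id)) dt_id <- paste0("Dt_", seq_along(dt_sets))
  out <- list()
  for (a in seq_along(at_sets)) {
    P <- at_sets[[a]]
    if (!length(P)) next
    touching <- which(vapply(dt_sets, function(q) length(intersect(q, P)) > 0,
                             logical(1L)))
    if (!length(touching)) next
    exact <- touching[vapply(touching, function(d)
      identical(dt_sets[[d]], P), logical(1L))]
    if (length(exact)) {
      out[[length(out) + 1L]] <- data.table(
        at_tad = at_id[a], dt_tad = dt_id[exact[1L]], class = "homoeologous",
        pair_ids = paste(P, collapse = ","))
    } else {
      out[[length(out) + 1L]] <- data.table(
        at_tad = at_id[a], dt_tad = dt_id[touching], class = "partitioned",
        pair_ids = paste(P, collapse = ","))
    }
  }
  if (!length(out))
    return(data.table(at_tad = character(), dt_tad = character(),
                      class = character(), pair_ids = character()))
  rbindlist(out)
}

#' Positional-shift x expression-bias contingency analysis
#'
#' Tests whether homoeolog pairs whose members change positional class
#' between subgenomes (boundary on one side, interior on the other) are
#' enriched for expression bias. Returns the 2x2 table, odds ratio
#' (reported as `Inf` for degenerate tables with an empty off-diagonal),
#' the chi-squared statistic, and a permutation p-value obtained by
#' shuffling bias labels.
#'
#' @param pair_positions data.table `pair_id`, `at_position`, `dt_position`
#'   (from [boundary_interior_assignment()] applied per subgenome).
#' @param bias_calls data.table `pair_id`, `bias` (`At`/`Dt`/`none`).
#' @param n_perm permutation count.
#' @return list `table`, `odds_ratio`, `chisq`, `p_perm`,
#'   `continuity_corrected`.
#' @export
positional_shift_bias <- function(pair_positions, bias_calls, n_perm = 200L) {
  dt <- merge(as.data.table(pair_positions), as.data.table(bias_calls),
              by = "pair_id")
  dt <- dt[at_position %in% c("boundary", "interior") &
             dt_position %in% c("boundary", "interior")]
  shifted <- dt$at_position != dt$dt_position
  biased <- dt$bias %in% c("At", "Dt")
  tab <- table(factor(shifted, c(TRUE, FALSE)), factor(biased, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  corrected <- FALSE
  if (b == 0 && cc == 0 && a > 0 && d > 0) {
    or <- Inf
  } else if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    corrected <- TRUE
  } else {
    or <- (a * d) / (b * cc)
  }
  stat <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  perm <- replicate(n_perm, {
    bp <- sample(biased)
    tp <- table(factor(shifted, c(TRUE, FALSE)), factor(bp, c(TRUE, FALSE)))
    suppressWarnings(chisq.test(tp, correct = FALSE)$statistic)
  })
  list(table = tab, odds_ratio = unname(or), chisq = unname(stat),
       p_perm = mean(perm >= stat, na.rm = TRUE),
       continuity_corrected = corrected)
}
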