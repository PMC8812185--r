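# A/B compartment calling at 40 kb, pairwise switch regions, four-stage
# trajectory classification, and gene/peak/expression overlays.

#' Call A/B compartments from a balanced 40-kb matrix
#'
#' Per chromosome: distance-normalise the balanced cis block
#' (observed/expected by gap), take the Pearson correlation matrix, and use
#' its leading eigenvector as PC1. The sign is oriented per chromosome so
#' that the positive side has the higher mean gene density; bins with
#' PC1 > 0 are A, < 0 are B (exactly 0 is assigned B). Masked bins
#' propagate; chromosomes with fewer than 10 unmasked bins are masked
#' entirely with a warning.
#'
#' @param bm balanced `binned_matrix` at 40 kb.
#' @param genes gene intervals (`chrom`, `start`, `end`) used for
#'   orientation.
#' @param stage stage label attached to the track.
#' @return data.table `chrom`, `start`, `pc1`, `label` (A/B/masked),
#'   `stage`.
#' @export
call_compartments <- function(bm, genes, stage = bm$stage) {
  res <- bm$resolution
  genes <- as.data.table(genes)
  gd <- genes[, .(chrom, gstart = midpoint_bin_start(.SD, res))]
  gd <- gd[, .(n_genes = .N), by = .(chrom, start = gstart)]
  out <- list()
  w <- bm_weights(bm)
  for (cn in unique(bm$bins$chrom)) {
    blk <- bm_chrom_dense(bm, cn, balanced = TRUE)
    n <- nrow(blk$mat)
    wc <- w[blk$bins$bin]
    ok <- !is.na(wc) & Matrix::rowSums(is.na(blk$mat)) < n
    m <- blk$mat
    m[is.na(m)] <- 0
    ok <- ok & rowSums(m) > 0
    pc1 <- rep(NA_real_, n)
    if (sum(ok) < 10L) {
      warning("call_compartments: chromosome ", cn,
              " has < 10 unmasked bins; masked entirely")
    } else {
      sub <- m[ok, ok, drop = FALSE]
      ns <- nrow(sub)
      idx <- which(ok)
      # observed/expected by gap
      gap <- abs(outer(idx, idx, "-"))
      expd <- vapply(0:(n - 1L), function(d) {
        v <- sub[gap == d]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1L))
      oe <- sub / matrix(expd[gap + 1L], ns, ns)
      oe[!is.finite(oe)] <- 0
      cm <- suppressWarnings(cor(oe))
      cm[!is.finite(cm)] <- 0
      ev <- eigen(cm, symmetric = TRUE)
      v1 <- ev$vectors[, 1L]
      # orient: positive side = higher gene density
      dens <- merge(blk$bins[ok], gd[chrom == cn], by = c("chrom", "start"),
                    all.x = TRUE)
      dens[is.na(n_genes), n_genes := 0L]
      dens <- dens[order(bin), n_genes]
      mp <- mean(dens[v1 > 0]); mn <- mean(dens[v1 < 0])
      if (!is.na(mp) && !is.na(mn) && mp < mn) v1 <- -v1
      pc1[ok] <- v1
    }
    out[[cn]] <- data.table(chrom = cn, start = blk$bins$start, pc1 = pc1)
  }
  trk <- rbindlist(out)
  trk[, label := fifelse(is.na(pc1), "masked", fifelse(pc1 > 0, "A", "B"))]
  stg <- stage
  trk[, stage := stg]
  trk[]
}

#' Switch regions between two compartment tracks
#'
#' Maximal runs of at least `min_bins` consecutive bins whose label changes
#' A->B (direction `AtoB`) or B->A (`BtoA`) between the two stages; single
#' switched bins are never emitted.
#'
#' @param track1,track2 compartment tracks on the same bin grid.
#' @param min_bins minimum run length (default 2).
#' @param genes optional gene intervals; contained gene ids are attached.
#' @param resolution bin size in bp (default 40 kb).
#' @return data.table `chrom`, `start`, `end`, `direction`, `n_bins`,
#'   optionally `gene_ids`.
#' @export
pairwise_switch_regions <- function(track1, track2, min_bins = 2L,
                                    genes = NULL, resolution = 4e4) {
  t1 <- as.data.table(track1); t2 <- as.data.table(track2)
  if (!identical(t1[, .(chrom, start)], t2[, .(chrom, start)]))
    stop("tracks are on different bin grids")
  dt <- data.table(chrom = t1$chrom, start = t1$start, l1 = t1$label,
                   l2 = t2$label)
  dt[, dir := fifelse(l1 == "A" & l2 == "B", "AtoB",
                      fifelse(l1 == "B" & l2 == "A", "BtoA", NA_character_))]
  dt[, run := rleid(chrom, dir)]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_bins = integer())
  if (!any(!is.na(dt$dir))) return(empty)
  reg <- dt[!is.na(dir), .(chrom = chrom[1L], start = min(start),
                           end = max(start) + as.integer(resolution),
                           direction = dir[1L], n_bins = .N), by = run]
  reg <- reg[n_bins >= min_bins][, run := NULL]
  if (!nrow(reg)) return(empty)
  if (!is.null(genes) && nrow(reg)) {
    genes <- as.data.table(genes)
    gmid <- genes[, .(id, chrom, mid = (start + end) %/% 2)]
    reg[, gene_ids := vapply(seq_len(.N), function(r) {
      paste(gmid[chrom == reg$chrom[r] & mid >= reg$start[r] &
                   mid < reg$end[r], id], collapse = ",")
    }, character(1L))]
  }
  reg[]
}

#' Classify a four-stage compartment trajectory
#'
#' Categories over the four-letter A/B string (stages in developmental
#' order): all A = `stable_A`; all B = `stable_B`; starts A, ends B = `AB`;
#' starts B, ends A = `BA`; starts and ends A with at least one B = `ABA`;
#' starts and ends B with at least one A = `BAB`.
#'
#' @param s character vector of 4-letter strings over {A, B}.
#' @return character vector of categories.
#' @export
classify_trajectory <- function(s) {
  if (any(nchar(s) != 4L | grepl("[^AB]", s)))
    stop("trajectories must be 4-letter strings over {A, B}")
  first <- substr(s, 1L, 1L); last <- substr(s, 4L, 4L)
  out <- character(length(s))
  out[s == "AAAA"] <- "stable_A"
  out[s == "BBBB"] <- "stable_B"
  out[first == "A" & last == "B"] <- "AB"
  out[first == "B" & last == "A"] <- "BA"
  out[out == "" & first == "A" & last == "A"] <- "ABA"
  out[out == "" & first == "B" & last == "B"] <- "BAB"
  out
}

#' Four-stage compartment trajectories per bin
#'
#' Bins masked at any stage are excluded (their number is reported in the
#' `n_excluded` attribute).
#'
#' @param tracks list of four compartment tracks in stage order.
#' @return data.table `chrom`, `start`, `trajectory`, `category`.
#' @export
compartment_trajectories <- function(tracks) {
  stopifnot(length(tracks) == 4L)
  lab <- lapply(tracks, function(t) as.data.table(t)$label)
  grid <- as.data.table(tracks[[1L]])[, .(chrom, start)]
  ok <- Reduce(`&`, lapply(lab, function(l) l %in% c("A", "B")))
  dt <- grid[ok]
  dt[, trajectory := do.call(paste0, lapply(lab, `[`, ok))]
  dt[, category := classify_trajectory(trajectory)]
  setattr(dt, "n_excluded", sum(!ok))
  dt[]
}

#' Overlay genes, peaks and expression on a compartment track
#'
#' A bin is "marked" by a modification if any peak midpoint of that mark
#' (at the track's stage) falls inside it; with `overlap_rule = "any"`, one
#' bp of overlap suffices.
#'
#' @param track compartment track.
#' @param genes gene intervals (optional).
#' @param peaks peak table `stage`, `mark`, `chrom`, `start`, `end`
#'   (optional).
#' @param expression long FPKM table (optional; averaged per gene at the
#'   track's stage).
#' @param resolution bin size (default 40 kb).
#' @param overlap_rule `"midpoint"` (default) or `"any"`.
#' @return list with `genes_by_label`, `mean_expression`, `marked_fraction`.
#' @export
overlay_compartments <- function(track, genes = NULL, peaks = NULL,
                                 expression = NULL, resolution = 4e4,
                                 overlap_rule = c("midpoint", "any")) {
  overlap_rule <- match.arg(overlap_rule)
  trk <- as.data.table(track)
  r <- as.integer(resolution)
  out <- list()
  gene_bin <- NULL
  if (!is.null(genes) && nrow(genes)) {
    genes <- as.data.table(genes)
    gene_bin <- genes[, .(id, chrom, start = midpoint_bin_start(.SD, r))]
    gb <- merge(gene_bin, trk, by = c("chrom", "start"))
    out$genes_by_label <- split(gb$id, gb$label)
    if (!is.null(expression)) {
      ex <- as.data.table(expression)
      if (!is.na(trk$stage[1L])) ex <- ex[stage == trk$stage[1L]]
      gm <- ex[, .(fpkm = mean(fpkm)), by = gene]
      gb2 <- merge(gb, gm, by.x = "id", by.y = "gene")
      out$mean_expression <- gb2[, .(mean_fpkm = mean(fpkm)), by = label]
    }
  }
  if (!is.null(peaks) && nrow(peaks)) {
    pk <- as.data.table(peaks)
    if (!is.na(trk$stage[1L]) && "stage" %in% names(pk))
      pk <- pk[stage == trk$stage[1L]]
    mf <- list()
    for (mk in unique(pk$mark)) {
      pm <- pk[mark == mk]
      if (overlap_rule == "midpoint") {
        pb <- unique(pm[, .(chrom, start = midpoint_bin_start(.SD, r))])
      } else {
        pb <- unique(pm[, .(chrom,
                            start = unlist(Map(function(s, e)
                              seq((s %/% r) * r, ((e - 1L) %/% r) * r, by = r),
                              start, end))),
                        by = seq_len(nrow(pm))][, .(chrom, start)])
      }
      pb[, marked := TRUE]
      mm <- merge(trk, pb, by = c("chrom", "start"), all.x = TRUE)
      mf[[mk]] <- mm[label %in% c("A", "B"),
                     .(fraction = mean(!is.na(marked))), by = label][
                       , mark := mk]
    }
    out$marked_fraction <- rbindlist(mf)[, .(mark, label, fraction)]
  }
  out
}
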