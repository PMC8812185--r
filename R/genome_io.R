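# Core data model: genome, binned contact matrices, interval sets, loop sets.
# All internal coordinates are 0-based half-open; GFF is converted on I/O.

#' @import data.table
#' @importFrom Matrix sparseMatrix rowSums Diagonal t
#' @importFrom stats rpois rnbinom rnorm runif setNames p.adjust pbinom
#'   prcomp cor t.test wilcox.test chisq.test cor.test fisher.test
#'   quantile median sd lm coef
#' @importFrom utils head tail
NULL

.MARKS <- c("H3K27ac", "H3K4me3", "H3K9me2")
.STAGES <- c("0DPA", "5DPA", "10DPA", "20DPA")
.RESOLUTIONS <- c(5e3, 1e4, 2e4, 4e4, 2e5)

## ---------------------------------------------------------------------------
## GenomeModel

#' Construct a genome model
#'
#' Bundles the chromosome table (with At/Dt subgenome labels), gene and
#' transposable-element intervals, and per-stage ChIP peak sets into a single
#' validated object. All coordinates are 0-based half-open.
#'
#' @param chromosomes data.table/data.frame with columns `name`, `length`
#'   (bp), `subgenome` (one of `"At"`, `"Dt"`).
#' @param genes intervals with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param tes transposable-element intervals with columns `id`, `chrom`,
#'   `start`, `end`, `family`; may be empty.
#' @param te_expression optional long table `id`, `stage`, `level` with
#'   per-stage TE expression in arbitrary units.
#' @param peaks optional peak intervals with columns `stage`, `mark`,
#'   `chrom`, `start`, `end`; `mark` restricted to H3K27ac, H3K4me3, H3K9me2.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes = NULL, tes = NULL,
                         te_expression = NULL, peaks = NULL) {
  chromosomes <- as.data.table(chromosomes)
  stopifnot(all(c("name", "length", "subgenome") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (!all(chromosomes$subgenome %in% c("At", "Dt")))
    stop("subgenome labels must be 'At' or 'Dt'")
  empty_iv <- data.table(id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character())
  genes <- if (is.null(genes)) copy(empty_iv) else as.data.table(genes)
  tes <- if (is.null(tes)) {
    data.table(id = character(), chrom = character(), start = integer(),
               end = integer(), family = character())
  } else as.data.table(tes)
  peaks <- if (is.null(peaks)) {
    data.table(stage = character(), mark = character(), chrom = character(),
               start = integer(), end = integer())
  } else as.data.table(peaks)
  te_expression <- if (is.null(te_expression)) {
    data.table(id = character(), stage = character(), level = numeric())
  } else as.data.table(te_expression)
  gm <- structure(list(chromosomes = chromosomes, genes = genes, tes = tes,
                       te_expression = te_expression, peaks = peaks),
                  class = "genome_model")
  validate_genome_model(gm)
  gm
}

#' Validate a genome model
#'
#' Checks coordinate bounds, id uniqueness, and the histone-mark vocabulary.
#' @param gm a `genome_model`.
#' @return `gm` invisibly; errors on violation.
#' @export
validate_genome_model <- function(gm) {
  lens <- setNames(gm$chromosomes$length, gm$chromosomes$name)
  chk <- function(dt, what) {
    if (nrow(dt) == 0L) return(invisible())
    if (!all(dt$chrom %in% names(lens)))
      stop(what, ": unknown chromosome")
    bad <- dt$start < 0L | dt$end > lens[dt$chrom] | dt$start >= dt$end
    if (any(bad))
      stop(what, ": interval outside [0, chrom length) or end <= start (first: row ",
           which(bad)[1L], ")")
  }
  chk(gm$genes, "genes")
  chk(gm$tes, "tes")
  chk(gm$peaks, "peaks")
  if (anyDuplicated(gm$genes$id)) stop("gene ids must be unique")
  if (nrow(gm$peaks) && !all(gm$peaks$mark %in% .MARKS))
    stop("peak marks must be one of: ", paste(.MARKS, collapse = ", "))
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes (",
      sum(x$chromosomes$subgenome == "At"), "At /",
      sum(x$chromosomes$subgenome == "Dt"), "Dt ),",
      nrow(x$genes), "genes,", nrow(x$tes), "TEs,",
      nrow(x$peaks), "peaks\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## BinnedMatrix

#' Bin table for a genome at a fixed resolution
#'
#' @param chromosomes chromosome table (`name`, `length`).
#' @param resolution bin size in bp.
#' @return data.table with `chrom`, `start` (0-based), and 1-based `bin`
#'   index in genome order.
#' @export
make_bins <- function(chromosomes, resolution) {
  chromosomes <- as.data.table(chromosomes)
  bins <- chromosomes[, .(start = seq(0L, by = as.integer(resolution),
                                      length.out = ceiling(length / resolution))),
                      by = .(chrom = name)]
  bins[, bin := seq_len(.N)]
  bins[]
}

#' Construct a binned Hi-C contact matrix
#'
#' Stores symmetric contact counts sparsely (upper triangle only, i <= j).
#'
#' @param i,j 1-based bin indices (any order; folded to upper triangle).
#' @param x non-negative counts.
#' @param bins bin table from [make_bins()].
#' @param resolution bin size in bp.
#' @param stage optional stage label.
#' @param weights optional per-bin positive balancing factors (NA = masked).
#' @return Object of class `binned_matrix`.
#' @export
binned_matrix <- function(i, j, x, bins, resolution, stage = NA_character_,
                          weights = NULL) {
  n <- nrow(bins)
  if (length(i) && (max(i, j) > n || min(i, j) < 1L))
    stop("COO index out of range (bins: ", n, ")")
  if (any(x < 0)) stop("counts must be non-negative")
  ii <- pmin(i, j); jj <- pmax(i, j)
  mat <- sparseMatrix(i = ii, j = jj, x = as.double(x), dims = c(n, n),
                      symmetric = TRUE)
  structure(list(mat = mat, bins = as.data.table(bins),
                 resolution = as.integer(resolution), stage = stage,
                 weights = weights),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("binned_matrix: ", nrow(x$bins), " bins @ ", x$resolution / 1e3,
      " kb, total count ", bm_total(x),
      if (!is.null(x$weights)) ", balanced" else "",
      if (!is.na(x$stage)) paste0(", stage ", x$stage) else "", "\n", sep = "")
  invisible(x)
}

#' Upper-triangle triplets of a binned matrix
#'
#' @param bm a `binned_matrix`.
#' @param balanced apply balancing weights (masked bins dropped).
#' @return data.table `i`, `j`, `x` with i <= j.
#' @export
bm_triplets <- function(bm, balanced = FALSE) {
  tm <- as(as(bm$mat, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j
  out <- data.table(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, x = tm@x[keep])
  if (balanced) {
    w <- bm_weights(bm)
    out <- out[!is.na(w[i]) & !is.na(w[j])]
    out[, x := x * w[i] * w[j]]
  }
  out[x != 0]
}

bm_weights <- function(bm) {
  if (is.null(bm$weights)) rep(1, nrow(bm$bins)) else bm$weights
}

#' Total contact count (diagonal counted once)
#' @param bm a `binned_matrix`.
#' @return numeric scalar.
#' @export
bm_total <- function(bm) sum(bm_triplets(bm)$x)

#' Query a contact count
#' @param bm a `binned_matrix`.
#' @param i,j 1-based bin indices.
#' @return the symmetric count at (i, j).
#' @export
bm_count <- function(bm, i, j) as.numeric(bm$mat[i, j])

#' Dense cis block for one chromosome
#'
#' @param bm a `binned_matrix`.
#' @param chrom chromosome name.
#' @param balanced apply weights; masked bins become NA rows/columns.
#' @return list with `mat` (dense symmetric), `bins` (subset of the bin
#'   table), `offset` (first genome-wide bin index minus one).
#' @export
bm_chrom_dense <- function(bm, chrom, balanced = FALSE) {
  idx <- bm$bins[chrom, on = "chrom", bin]
  m <- as.matrix(bm$mat[idx, idx, drop = FALSE])
  if (balanced) {
    w <- bm_weights(bm)[idx]
    m <- m * outer(w, w)
    m[is.na(outer(w, w))] <- NA_real_
  }
  list(mat = m, bins = bm$bins[chrom, on = "chrom"], offset = idx[1L] - 1L)
}

#' Aggregate a matrix to a coarser resolution
#'
#' Coarser matrices are exact sums of the finer one: total counts are
#' conserved.
#'
#' @param bm a `binned_matrix`.
#' @param resolution target resolution, an integer multiple of
#'   `bm$resolution`.
#' @return a `binned_matrix` at the target resolution.
#' @export
aggregate_matrix <- function(bm, resolution) {
  if (resolution %% bm$resolution != 0)
    stop("target resolution must be a multiple of ", bm$resolution)
  if (resolution == bm$resolution) return(bm)
  chroms <- unique(bm$bins[, .(name = chrom)])
  chroms <- merge(chroms,
                  bm$bins[, .(length = max(start) + bm$resolution), by = chrom],
                  by.x = "name", by.y = "chrom", sort = FALSE)
  new_bins <- make_bins(chroms, resolution)
  map <- bm$bins[, .(chrom, start = (start %/% as.integer(resolution)) *
                       as.integer(resolution), old = bin)]
  map <- new_bins[map, on = c("chrom", "start")]
  newidx <- map[order(old), bin]
  tr <- bm_triplets(bm)
  tr[, `:=`(ni = pmin(newidx[i], newidx[j]), nj = pmax(newidx[i], newidx[j]))]
  agg <- tr[, .(x = sum(x)), by = .(ni, nj)]
  binned_matrix(agg$ni, agg$nj, agg$x, new_bins, resolution, stage = bm$stage)
}

## ---------------------------------------------------------------------------
## Annotation I/O

.read_lines_tab <- function(path) {
  ln <- readLines(path)
  keep <- !startsWith(ln, "#") & nzchar(ln)
  list(fields = strsplit(ln[keep], "\t", fixed = TRUE), lineno = which(keep))
}

#' Read gene/TE/peak annotation from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention; BED is native. For GFF3 only rows whose feature type
#' is in `keep_types` are returned; others are skipped and their count
#' reported via a message.
#'
#' @param path file path.
#' @param format `"GFF3"` or `"BED"`.
#' @param keep_types GFF3 feature types to retain.
#' @return data.table with `id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("GFF3", "BED"),
                            keep_types = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  p <- .read_lines_tab(path)
  if (format == "GFF3") {
    nf <- lengths(p$fields)
    if (any(nf < 9L))
      stop("malformed GFF3 line ", p$lineno[which(nf < 9L)[1L]],
           ": expected 9 tab-separated fields")
    f <- p$fields
    type <- vapply(f, `[`, "", 3L)
    sel <- type %in% keep_types
    if (sum(!sel)) message("read_annotation: skipped ", sum(!sel),
                           " rows of other feature types")
    f <- f[sel]; lineno <- p$lineno[sel]
    start1 <- suppressWarnings(as.integer(vapply(f, `[`, "", 4L)))
    end1 <- suppressWarnings(as.integer(vapply(f, `[`, "", 5L)))
    if (anyNA(start1) || anyNA(end1))
      stop("malformed GFF3 line ",
           lineno[which(is.na(start1) | is.na(end1))[1L]],
           ": non-numeric coordinates")
    if (any(end1 < start1))
      stop("malformed GFF3 line ", lineno[which(end1 < start1)[1L]],
           ": end < start")
    attr9 <- vapply(f, `[`, "", 9L)
    id <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
    dt <- data.table(id = id, chrom = vapply(f, `[`, "", 1L),
                     start = start1 - 1L, end = end1,
                     strand = vapply(f, `[`, "", 7L))
  } else {
    nf <- lengths(p$fields)
    if (any(nf < 3L))
      stop("malformed BED line ", p$lineno[which(nf < 3L)[1L]],
           ": expected >= 3 fields")
    f <- p$fields
    start0 <- suppressWarnings(as.integer(vapply(f, `[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(f, `[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0))
      stop("malformed BED line ",
           p$lineno[which(is.na(start0) | is.na(end0))[1L]],
           ": non-numeric coordinates")
    if (any(end0 < start0))
      stop("malformed BED line ", p$lineno[which(end0 < start0)[1L]],
           ": end < start")
    dt <- data.table(
      id = vapply(f, function(z) if (length(z) >= 4L) z[4L] else NA_character_, ""),
      chrom = vapply(f, `[`, "", 1L), start = start0, end = end0,
      strand = vapply(f, function(z) if (length(z) >= 6L) z[6L] else "*", ""))
    dt[is.na(id), id := paste0("iv", .I)]
  }
  setorder(dt, chrom, start)
  dt[]
}

#' Write intervals as GFF3 or BED
#' @param dt intervals (`id`, `chrom`, `start`, `end`, `strand`).
#' @param path output path.
#' @param format `"GFF3"` or `"BED"`.
#' @param type GFF3 feature type to emit.
#' @export
write_annotation <- function(dt, path, format = c("GFF3", "BED"),
                             type = "gene") {
  format <- match.arg(format)
  dt <- as.data.table(dt)
  if (format == "GFF3") {
    out <- dt[, .(chrom, src = ".", type = type, start = start + 1L, end,
                  score = ".", strand = ifelse(is.na(strand), ".", strand),
                  phase = ".", attr = paste0("ID=", id))]
  } else {
    out <- dt[, .(chrom, start, end, id,
                  score = 0L, strand = ifelse(is.na(strand), ".", strand))]
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Matrix I/O (bin table + upper-triangle COO triples)

#' Read a sparse contact matrix (bins TSV + COO TSV)
#'
#' The bin table has columns chrom, start, end, bin (1-based); the COO file
#' has columns i, j, count with i <= j (upper triangle; the diagonal stored
#' once).
#'
#' @param path_bins bin-table path.
#' @param path_coo COO triples path.
#' @param stage optional stage label.
#' @return a `binned_matrix`.
#' @export
read_matrix <- function(path_bins, path_coo, stage = NA_character_) {
  bins <- fread(path_bins, header = FALSE,
                col.names = c("chrom", "start", "end", "bin"))
  step <- bins[, diff(start), by = chrom]$V1
  if (length(step) && length(unique(step)) > 1L)
    stop("non-constant bin step in ", path_bins)
  resolution <- bins[1L, end - start]
  coo <- fread(path_coo, header = FALSE, col.names = c("i", "j", "x"))
  binned_matrix(coo$i, coo$j, coo$x, bins[, .(chrom, start, bin)],
                resolution, stage = stage)
}

#' Write a sparse contact matrix (bins TSV + COO TSV)
#' @param bm a `binned_matrix`.
#' @param path_bins,path_coo output paths.
#' @export
write_matrix <- function(bm, path_bins, path_coo) {
  fwrite(bm$bins[, .(chrom, start, end = start + bm$resolution, bin)],
         path_bins, sep = "\t", col.names = FALSE)
  tr <- bm_triplets(bm)
  setorder(tr, i, j)
  fwrite(tr, path_coo, sep = "\t", col.names = FALSE)
  invisible(path_coo)
}

#' Write a per-bin track as bedgraph
#' @param bins bin table (`chrom`, `start`).
#' @param value numeric per-bin values (NA rows skipped).
#' @param resolution bin size in bp.
#' @param path output path.
#' @export
write_bedgraph <- function(bins, value, resolution, path) {
  dt <- data.table(chrom = bins$chrom, start = bins$start,
                   end = bins$start + as.integer(resolution), value = value)
  fwrite(dt[!is.na(value)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Loop I/O (BEDPE + contact_count, fdr in columns 8-9)

#' Construct a loop set
#'
#' Cis loops between two anchors on the declared resolution grid; anchors
#' are snapped to the grid and ordered so anchor1 < anchor2 in genome order.
#'
#' @param chrom1,start1,chrom2,start2 anchor coordinates (bin starts, bp).
#' @param count integer contact counts.
#' @param fdr false-discovery-rate values in [0, 1].
#' @param p raw p-values (optional).
#' @param stage optional stage label(s).
#' @param resolution anchor bin size (default 5 kb).
#' @return data.table of class loop set with snapped, ordered anchors.
#' @export
loop_set <- function(chrom1, start1, chrom2, start2, count, fdr,
                     p = NA_real_, stage = NA_character_, resolution = 5e3) {
  dt <- data.table(chrom1 = chrom1, start1 = as.integer(start1),
                   chrom2 = chrom2, start2 = as.integer(start2),
                   count = as.integer(count), p = p, fdr = fdr,
                   stage = stage)
  r <- as.integer(resolution)
  dt[, `:=`(start1 = (start1 %/% r) * r, start2 = (start2 %/% r) * r)]
  swap <- dt$chrom1 == dt$chrom2 & dt$start2 < dt$start1
  if (any(swap)) {
    tmp <- dt$start1[swap]
    dt[swap, start1 := start2]; dt[swap, start2 := tmp]
  }
  if (any(!is.na(dt$fdr) & (dt$fdr < 0 | dt$fdr > 1)))
    stop("fdr must lie in [0, 1]")
  if (any(dt$count < 0)) stop("contact counts must be non-negative")
  dt[]
}

#' Read loops from BEDPE (+ contact_count, fdr columns)
#'
#' Columns 1-6 are standard BEDPE anchors; by this package's convention
#' column 8 carries the contact count and column 9 the FDR (column 7 is the
#' loop name, column 10 an optional raw p-value, column 11 an optional stage
#' label).
#'
#' @param path BEDPE path.
#' @param resolution anchor resolution in bp.
#' @return loop set data.table.
#' @export
read_loops <- function(path, resolution = 5e3) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 9L) stop("BEDPE must have >= 9 columns (count, fdr)")
  w1 <- dt[[3L]] - dt[[2L]]; w2 <- dt[[6L]] - dt[[5L]]
  if (any(w1 != w2))
    stop("anchors on different resolutions at row ", which(w1 != w2)[1L])
  loop_set(dt[[1L]], dt[[2L]], dt[[4L]], dt[[5L]],
           count = dt[[8L]], fdr = dt[[9L]],
           p = if (ncol(dt) >= 10L) dt[[10L]] else NA_real_,
           stage = if (ncol(dt) >= 11L) dt[[11L]] else NA_character_,
           resolution = resolution)
}

#' Write loops as BEDPE (+ contact_count, fdr columns)
#' @param loops loop set.
#' @param path output path.
#' @param resolution anchor resolution in bp.
#' @export
write_loops <- function(loops, path, resolution = 5e3) {
  r <- as.integer(resolution)
  out <- as.data.table(loops)[, .(
    chrom1, start1, end1 = start1 + r, chrom2, start2, end2 = start2 + r,
    name = paste0("loop", seq_len(.N)), count, fdr,
    p = if ("p" %in% names(loops)) p else NA_real_,
    stage = if ("stage" %in% names(loops)) stage else NA_character_)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Interval -> bin assignment (by midpoint)

#' Assign intervals to bins by midpoint
#' @param dt intervals (`chrom`, `start`, `end`).
#' @param resolution bin size in bp.
#' @return integer vector of 0-based bin start coordinates.
#' @export
midpoint_bin_start <- function(dt, resolution) {
  mid <- (as.numeric(dt$start) + as.numeric(dt$end)) %/% 2
  as.integer((mid %/% resolution) * resolution)
}
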