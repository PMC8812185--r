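# Matrix-level statistics: ICE balancing, distance-decay contact
# probability, chromatin compactness, and interaction-range summaries.

#' ICE balancing of a contact matrix
#'
#' Iterative correction: per-bin bias factors are updated until the
#' coefficient of variation of the corrected row sums over unmasked bins
#' drops below `tol`. Bins in the lowest `filter_low` coverage quantile (and
#' all zero-coverage bins) are masked and excluded. The returned matrix
#' carries `weights` such that the balanced count for pair (i, j) is
#' `x * w[i] * w[j]`; masked bins have `NA` weights. Support is preserved
#' (zeros stay zero) and the result is invariant to a global scaling of the
#' input up to a global factor.
#'
#' @param bm a `binned_matrix` with raw counts.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the row-sum coefficient of variation.
#' @param filter_low fraction of lowest-coverage bins to mask.
#' @return `bm` with `weights` filled in.
#' @export
ice_balance <- function(bm, max_iter = 1000L, tol = 1e-5, filter_low = 0.02) {
  M <- bm$mat
  n <- nrow(M)
  cov0 <- Matrix::rowSums(M)
  if (all(cov0 == 0)) stop("all-zero matrix cannot be balanced")
  thr <- quantile(cov0[cov0 > 0], filter_low)
  mask <- cov0 == 0 | cov0 < thr
  b <- rep(1, n)
  conv <- FALSE
  cv <- NA_real_
  for (it in seq_len(max_iter)) {
    binv <- ifelse(mask, 0, 1 / b)
    # row sums of D M D in one sparse mat-vec: s = binv * (M %*% binv)
    s <- binv * as.vector(M %*% binv)
    su <- s[!mask]
    cv <- sd(su) / mean(su)
    if (is.na(cv)) break
    if (cv < tol) { conv <- TRUE; break }
    # square-root update: the stable fixed-point iteration for symmetric
    # scaling (the bias enters the row sum through both indices)
    upd <- sqrt(s / mean(su))
    upd[mask | upd == 0] <- 1
    b <- b * upd
  }
  if (!conv && it == max_iter)
    warning("ice_balance: not converged in ", max_iter,
            " iterations (cv = ", signif(cv, 3), "); returning best iterate")
  w <- 1 / b
  w[mask] <- NA_real_
  bm$weights <- as.numeric(w)
  bm
}

#' Distance-decay contact-probability curve
#'
#' Per genomic gap d, strength = log10(mean observed contacts per bin pair
#' at gap d / mean contacts per observable cis bin pair over the whole
#' distance range). A uniform matrix therefore gives 0 at every gap.
#'
#' @param bm cis contact matrix (10-kb resolution in the standard pipeline).
#' @param d_min,d_max distance range in bp (defaults 10 kb and 100 Mb).
#' @param balanced use balancing weights when present.
#' @param per_chromosome if TRUE normalise by the per-chromosome mean
#'   instead of the genome-wide mean.
#' @return data.table `distance` (bp), `strength` (log10 ratio), `n_pairs`.
#' @export
contact_probability <- function(bm, d_min = 1e4, d_max = 1e8,
                                balanced = !is.null(bm$weights),
                                per_chromosome = FALSE) {
  if (d_min >= d_max) stop("d_min must be < d_max")
  res <- bm$resolution
  tr <- bm_triplets(bm, balanced = balanced)
  tr[, `:=`(c1 = bm$bins$chrom[i], c2 = bm$bins$chrom[j])]
  tr <- tr[c1 == c2]
  tr[, d := (j - i) * res]
  tr <- tr[d >= d_min & d <= d_max]
  # observable pairs per gap
  nb <- bm$bins[, .N, by = chrom]
  gaps <- seq(max(res, d_min - d_min %% res + ifelse(d_min %% res, res, 0)),
              d_max, by = res)
  gaps <- gaps[gaps >= d_min]
  np <- data.table(distance = gaps)
  np[, n_pairs := Reduce(`+`, lapply(nb$N, function(m)
    pmax(0, m - distance / res)))]
  obs <- tr[, .(total = sum(x)), by = .(distance = d)]
  cur <- merge(np[n_pairs > 0], obs, by = "distance", all.x = TRUE)
  cur[is.na(total), total := 0]
  avg <- sum(cur$total) / sum(cur$n_pairs)
  if (per_chromosome) {
    # per-chromosome variant: average the per-chromosome curves
    pc <- tr[, .(total = sum(x)), by = .(c1, distance = d)]
    pc <- merge(pc, nb, by.x = "c1", by.y = "chrom")
    pc[, n_pairs := pmax(0, N - distance / res)]
    pc[, avg_c := sum(total) / sum(n_pairs), by = c1]
    pc[, strength := log10((total / n_pairs) / avg_c)]
    cur <- pc[, .(strength = mean(strength), n_pairs = sum(n_pairs),
                  total = sum(total)), by = distance][order(distance)]
    return(cur[, .(distance, strength, n_pairs)])
  }
  cur[, strength := log10((total / n_pairs) / avg)]
  cur[order(distance), .(distance, strength, n_pairs)]
}

#' Fit the decay exponent from a contact-probability curve
#'
#' Linear regression of strength on log10(distance); the slope estimates
#' -alpha of a power-law decay.
#'
#' @param curve output of [contact_probability()].
#' @param d_range distance range (bp) used in the fit.
#' @return slope of the regression (numeric).
#' @export
fit_decay_exponent <- function(curve, d_range = c(2e4, 2e6)) {
  cc <- curve[distance >= d_range[1] & distance <= d_range[2] &
                is.finite(strength)]
  unname(coef(lm(strength ~ log10(distance), data = cc))[2L])
}

#' Chromatin compactness track
#'
#' Per bin, the total number of contacts between the bin and every bin
#' within `window` of it on the same chromosome (self contacts counted
#' once). Chromosome-end bins use the truncated window and are flagged.
#'
#' @param bm cis matrix (10-kb resolution in the standard pipeline).
#' @param window flank size in bp (default 1 Mb).
#' @param balanced use balancing weights when present.
#' @param normalize divide by the matrix total (stage-comparable units).
#' @return data.table `chrom`, `start`, `compactness`, `truncated`.
#' @export
compactness <- function(bm, window = 1e6, balanced = !is.null(bm$weights),
                        normalize = FALSE) {
  res <- bm$resolution
  if (window < res) stop("window must be >= resolution")
  wb <- as.integer(window %/% res)
  tr <- bm_triplets(bm, balanced = balanced)
  tr[, `:=`(c1 = bm$bins$chrom[i], c2 = bm$bins$chrom[j])]
  tr <- tr[c1 == c2 & (j - i) <= wb]
  acc <- rbind(tr[, .(bin = i, x)], tr[i != j, .(bin = j, x)])
  val <- acc[, .(compactness = sum(x)), by = bin]
  out <- copy(bm$bins)
  out <- merge(out, val, by = "bin", all.x = TRUE)
  out[is.na(compactness), compactness := 0]
  out[, pos_in_chrom := seq_len(.N), by = chrom]
  out[, n_in_chrom := .N, by = chrom]
  out[, truncated := pos_in_chrom <= wb | pos_in_chrom > n_in_chrom - wb]
  if (normalize) out[, compactness := compactness / sum(bm_triplets(bm,
                                                                    balanced = balanced)$x)]
  out[order(bin), .(chrom, start, compactness, truncated)]
}

#' Short-range / long-range / trans contact summary
#'
#' Cis contacts with gap <= 2 Mb (inclusive) are short-range, > 2 Mb
#' long-range; the three classes sum to the matrix total.
#'
#' @param bm a `binned_matrix`.
#' @param boundary short/long split in bp (default 2 Mb, inclusive on the
#'   short side).
#' @return named numeric vector `cis_short`, `cis_long`, `trans`.
#' @export
range_summary <- function(bm, boundary = 2e6) {
  tr <- bm_triplets(bm)
  tr[, `:=`(c1 = bm$bins$chrom[i], c2 = bm$bins$chrom[j])]
  tr[, d := (j - i) * bm$resolution]
  c(cis_short = sum(tr[c1 == c2 & d <= boundary, x]),
    cis_long = sum(tr[c1 == c2 & d > boundary, x]),
    trans = sum(tr[c1 != c2, x]))
}
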