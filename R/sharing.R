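#' Length bins for IBD segments
#'
#' Builds a ladder of half-open length bins `[lower, upper)` in cM from a
#' vector of breakpoints. The default ladder is the 1-2, 2-3, 3-4, 4-5,
#' 5-6 cM classification used throughout the sharing analyses.
#'
#' @param breaks Increasing numeric vector of bin edges (cM).
#' @return A `length_bins` data frame with columns `lower`, `upper`,
#'   `label`.
#' @export
length_bins <- function(breaks = 1:6) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    stop("bin breaks must be strictly increasing with at least 2 values")
  }
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1])
  out$label <- sprintf("%g-%g", out$lower, out$upper)
  class(out) <- c("length_bins", "data.frame")
  out
}

#' Assign IBD segments to length bins
#'
#' Each segment is assigned to the unique bin with
#' `lower <= length_cM < upper`. Segments outside the ladder are dropped
#' with a message.
#'
#' @param segments An `ibd_segments` table.
#' @param bins A `length_bins` ladder (non-overlapping, sorted).
#' @return The segment table with an added `bin` column (bin label,
#'   factor ordered by the ladder), out-of-range rows removed.
#' @export
bin_segments <- function(segments, bins = length_bins()) {
  if (any(bins$lower[-1] < bins$upper[-nrow(bins)])) {
    stop("bins overlap or are unsorted")
  }
  edges <- c(bins$lower, bins$upper[nrow(bins)])
  if (any(abs(bins$upper[-nrow(bins)] - bins$lower[-1]) > 1e-12)) {
    # non-contiguous ladders: place each segment by explicit interval test
    idx <- rep(NA_integer_, nrow(segments))
    for (b in seq_len(nrow(bins))) {
      hit <- segments$length_cM >= bins$lower[b] &
        segments$length_cM < bins$upper[b]
      idx[hit] <- b
    }
  } else {
    idx <- findInterval(segments$length_cM, edges,
                        rightmost.closed = FALSE, left.open = FALSE)
    idx[idx < 1 | idx > nrow(bins)] <- NA_integer_
  }
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    message(dropped, " segment(s) outside the bin ladder dropped")
  }
  out <- segments[!is.na(idx), , drop = FALSE]
  out$bin <- factor(bins$label[idx[!is.na(idx)]], levels = bins$label)
  out
}

#' Length-binned IBD sharing matrix
#'
#' The core sharing statistic: for populations i and j and length bin b,
#' the total cM of bin-b segments shared between them divided by the number
#' of individual pairs — `n_i * n_j` across populations, `n_i (n_i - 1)/2`
#' within a population — giving the average sharing per pair in cM.
#'
#' @param segments An `ibd_segments` table.
#' @param pops A `pop_table`; every segment population must appear in it.
#' @param bins A `length_bins` ladder.
#' @param sample_sizes Named integer vector: number of genotyped
#'   individuals per population (names = population ids). Required because
#'   individuals without segments are invisible in the segment table.
#' @return A `sharing_matrix`: numeric array `[pop, pop, bin]`, symmetric
#'   in the first two dimensions, with attributes `sample_sizes` and
#'   `bins`. Within-population entries are `NA` when `n < 2`.
#' @export
sharing_matrix <- function(segments, pops, bins = length_bins(),
                           sample_sizes) {
  ids <- pops$population_id
  if (is.null(names(sample_sizes)) || !all(ids %in% names(sample_sizes))) {
    stop("sample_sizes must be named and cover every population")
  }
  n <- sample_sizes[ids]
  bad <- setdiff(unique(c(segments$population_a, segments$population_b)), ids)
  if (length(bad) > 0) {
    stop("segment population(s) not in pop table: ", paste(bad, collapse = ", "))
  }
  binned <- bin_segments(segments, bins)
  S <- array(0, dim = c(length(ids), length(ids), nrow(bins)),
             dimnames = list(ids, ids, bins$label))
  if (nrow(binned) > 0) {
    pa <- pmin(binned$population_a, binned$population_b)
    pb <- pmax(binned$population_a, binned$population_b)
    key <- paste(pa, pb, binned$bin, sep = "\r")
    tot <- rowsum(binned$length_cM, key)
    parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
    for (k in seq_along(parts)) {
      i <- parts[[k]][1]; j <- parts[[k]][2]; b <- parts[[k]][3]
      if (i == j) {
        if (n[i] < 2) {
          stop(sprintf("population '%s' has n < 2 but within-population segments", i))
        }
        denom <- n[i] * (n[i] - 1) / 2
      } else {
        denom <- n[i] * n[j]
      }
      S[i, j, b] <- S[i, j, b] + tot[k, 1] / denom
      if (i != j) S[j, i, b] <- S[i, j, b]
    }
  }
  for (i in seq_along(ids)) {
    if (n[i] < 2) S[i, i, ] <- NA_real_
  }
  structure(S, sample_sizes = n, bins = bins,
            class = c("sharing_matrix", class(S)))
}

#' @export
print.sharing_matrix <- function(x, ...) {
  d <- dim(x)
  cat("sharing_matrix:", d[1], "populations x", d[3], "length bins\n")
  cat("bins:", paste(dimnames(x)[[3]], collapse = ", "), "cM\n")
  cat("mean off-diagonal sharing per bin (cM/pair):\n")
  for (b in seq_len(d[3])) {
    m <- x[, , b]
    v <- m[upper.tri(m)]
    cat(sprintf("  %s: %.4g\n", dimnames(x)[[3]][b], mean(v, na.rm = TRUE)))
  }
  invisible(x)
}

# Pool a sharing matrix over bins -> plain pop x pop matrix.
pool_bins <- function(S, bins = NULL) {
  if (is.matrix(S)) return(S)
  labels <- dimnames(S)[[3]]
  use <- if (is.null(bins)) labels else {
    if (is.numeric(bins)) labels[bins] else intersect(labels, bins)
  }
  if (length(use) == 0) stop("no matching bins")
  apply(S[, , use, drop = FALSE], c(1, 2), sum)
}

#' IBD sharing distance
#'
#' Converts sharing statistics into a distance: `-ln(S)`, optionally after
#' pooling over length bins. Pairs with zero sharing are masked (`NA`)
#' rather than floored, with a message; by default the matrix is then
#' standardized by its own maximum finite entry so that the largest
#' distance is exactly 1.
#'
#' @param S A `sharing_matrix`, or a plain pop x pop matrix of (pooled)
#'   sharing values.
#' @param bins Bins to pool over before transforming: `NULL` (all bins), a
#'   vector of bin labels, or bin indices. Ignored for plain matrices.
#' @param standardize Divide by the maximum finite entry (default `TRUE`).
#' @return A symmetric matrix of IBD sharing distances (`NA` where masked).
#' @export
sharing_distance_transform <- function(S, bins = NULL, standardize = TRUE) {
  P <- pool_bins(S, bins)
  zero <- which(P == 0)
  if (length(zero) > 0) {
    message(length(zero), " zero-sharing entr(ies) masked")
  }
  P[P == 0] <- NA_real_
  if (all(is.na(P))) stop("all sharing entries are zero: nothing to correlate")
  D <- -log(P)
  if (standardize) D <- D / max(abs(D), na.rm = TRUE)
  D
}

#' Correlation between IBD sharing distance and geographic distance
#'
#' Pearson correlation over the upper-triangle off-diagonal population
#' pairs of the two distance matrices, after standardizing each matrix by
#' its own maximum (so the test is on the shape of the decay, not its
#' scale). Pairs masked (`NA`) in either matrix are removed pairwise. The
#' 95\% CI uses the Fisher z transform and the two-sided p-value the usual
#' t statistic; both treat pairs as independent, which matrix entries are
#' not, so they are nominal.
#'
#' @param ibd_dist Matrix of IBD sharing distances (e.g. from
#'   [sharing_distance_transform()]).
#' @param geo_dist Matrix of geographic distances (km), same populations
#'   in the same order.
#' @param standardize Divide each matrix by its own maximum before
#'   correlating (default `TRUE`; idempotent).
#' @return List with `r`, `ci` (length 2), `p_value`, `n_pairs`.
#' @export
decay_correlation <- function(ibd_dist, geo_dist, standardize = TRUE) {
  if (!all(dim(ibd_dist) == dim(geo_dist))) {
    stop("distance matrices must have matching dimensions")
  }
  if (standardize) {
    ibd_dist <- ibd_dist / max(abs(ibd_dist), na.rm = TRUE)
    geo_dist <- geo_dist / max(abs(geo_dist), na.rm = TRUE)
  }
  ut <- upper.tri(ibd_dist)
  x <- ibd_dist[ut]
  y <- geo_dist[ut]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 unmasked population pairs")
  r <- stats::cor(x, y)
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- 0
  }
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ci <- c(r, r)
  }
  list(r = r, ci = ci, p_value = p, n_pairs = n)
}
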