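# Per-SNP allele-1 frequency and observed chromosome count for a set of
# individuals (rows of the dosage matrix).
pop_freqs <- function(dosage, rows) {
  d <- dosage[rows, , drop = FALSE]
  obs <- colSums(!is.na(d))
  list(freq = colSums(d, na.rm = TRUE) / (2 * obs), n_chrom = 2 * obs)
}

# Weighted block jackknife for a mean over SNPs split into blocks.
# x: per-SNP values; block: integer block id per SNP.
# Returns list(est, se, n_blocks). Standard moving-block-free weighted
# jackknife with unequal block sizes (pseudo-value form).
block_jackknife_mean <- function(x, block) {
  n <- length(x)
  tot <- sum(x)
  bsum <- rowsum(x, block)
  bn <- as.vector(rowsum(rep(1, n), block))
  m <- nrow(bsum)
  if (m < 2) stop("fewer than 2 jackknife blocks with data")
  est <- tot / n
  theta_mj <- (tot - bsum[, 1]) / (n - bn)   # delete-one-block means
  h <- n / bn
  theta_J <- m * est - sum((1 - bn / n) * theta_mj)
  tau <- h * est - (h - 1) * theta_mj
  var_J <- mean((tau - theta_J)^2 / (h - 1))
  list(est = est, se = sqrt(var_J), n_blocks = m)
}

# Assign SNPs (with cM positions) to contiguous blocks of block_cM per
# chromosome; returns integer block ids.
genomic_blocks <- function(chromosome, pos_cM, block_cM = 5.0) {
  id <- rep(NA_integer_, length(pos_cM))
  offset <- 0L
  for (chr in unique(chromosome)) {
    sel <- which(chromosome == chr)
    cm <- pos_cM[sel]
    b <- floor((cm - min(cm)) / block_cM)
    id[sel] <- offset + as.integer(factor(b))
    offset <- max(id[sel])
  }
  id
}

#' Three-population (f3) admixture test
#'
#' Computes the f3 statistic of a target population against two candidate
#' sources. With sample allele frequencies a, b (sources), c (target) and
#' c's observed chromosome count n_c at a SNP, the per-SNP summand is
#' `(c - a)(c - b) - c(1 - c)/(n_c - 1)`; the second term removes the
#' bias of the squared sampling error in c. f3 is the average over SNPs;
#' its standard error comes from a weighted block jackknife over
#' contiguous cM windows, and Z = f3/SE. A significantly negative f3
#' indicates that the target is admixed between groups related to the two
#' sources.
#'
#' @param geno A `geno_dataset` with cM positions attached.
#' @param target,s1,s2 Population ids (each with >= 2 individuals).
#' @param block_cM Jackknife block length in cM (default 5).
#' @return An `f3_result` (one-row data frame): `target_id`, `source1_id`,
#'   `source2_id`, `f3`, `SE`, `Z`, `n_snps`, `n_blocks`.
#' @export
f3_statistic <- function(geno, target, s1, s2, block_cM = 5.0) {
  for (p in c(target, s1, s2)) {
    if (sum(geno$samples$population_id == p) < 2) {
      stop(sprintf("population '%s' absent or has fewer than 2 individuals", p))
    }
  }
  rows <- function(p) which(geno$samples$population_id == p)
  fa <- pop_freqs(geno$dosage, rows(s1))
  fb <- pop_freqs(geno$dosage, rows(s2))
  fc <- pop_freqs(geno$dosage, rows(target))
  keep <- fa$n_chrom >= 2 & fb$n_chrom >= 2 & fc$n_chrom >= 2 &
    !is.na(geno$snps$pos_cM)
  # monomorphic across all three populations carries no information
  mono <- (fa$freq == fb$freq) & (fb$freq == fc$freq) &
    (fc$freq == 0 | fc$freq == 1)
  keep <- keep & !(mono %in% TRUE)
  if (sum(keep, na.rm = TRUE) == 0) stop("no usable SNPs for f3")
  a <- fa$freq[keep]; b <- fb$freq[keep]; cc <- fc$freq[keep]
  nc <- fc$n_chrom[keep]
  summand <- (cc - a) * (cc - b) - cc * (1 - cc) / (nc - 1)
  block <- genomic_blocks(geno$snps$chromosome[keep],
                          geno$snps$pos_cM[keep], block_cM)
  jk <- block_jackknife_mean(summand, block)
  out <- data.frame(target_id = target, source1_id = s1, source2_id = s2,
                    f3 = jk$est, SE = jk$se, Z = jk$est / jk$se,
                    n_snps = length(summand), n_blocks = jk$n_blocks,
                    stringsAsFactors = FALSE)
  class(out) <- c("f3_result", "data.frame")
  out
}

#' Enumerate all f3 trios
#'
#' All ordered targets combined with unordered source pairs, all three
#' populations distinct: `N (N - 1)(N - 2) / 2` trios.
#'
#' @param pops Character vector of >= 3 distinct population ids.
#' @return Data frame with columns `target`, `s1`, `s2`.
#' @export
enumerate_trios <- function(pops) {
  pops <- as.character(pops)
  if (anyDuplicated(pops)) stop("duplicate population id in list")
  n <- length(pops)
  if (n < 3) stop("need at least 3 populations")
  out <- list()
  pairs <- utils::combn(pops, 2)
  for (t in pops) {
    keep <- pairs[1, ] != t & pairs[2, ] != t
    out[[t]] <- data.frame(target = t, s1 = pairs[1, keep],
                           s2 = pairs[2, keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni-corrected one-tailed Z threshold
#'
#' Divides the nominal level by the number of tests and converts the
#' corrected level to a one-tailed standard-normal quantile: f3 results
#' with Z below this (negative) cut remain significant after correction.
#'
#' @param alpha Nominal level (default 0.05).
#' @param n_tests Number of tests performed.
#' @return List with `alpha_nominal`, `n_tests`, `alpha_corrected`,
#'   `z_critical`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  ac <- alpha / n_tests
  list(alpha_nominal = alpha, n_tests = n_tests, alpha_corrected = ac,
       z_critical = stats::qnorm(ac))
}
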