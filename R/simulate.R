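#' Draw single-path IBD segment lengths
#'
#' Lengths of IBD tracts surviving a fixed chain of `2g` meioses are
#' exponential with mean `100/(2g)` cM. Draws can be truncated below a
#' detection threshold `min_cM`; truncation uses the memoryless property
#' of the exponential, which is exactly the rejection-truncated law.
#'
#' @param g Generations since the common ancestor (>= 1).
#' @param n Number of draws.
#' @param min_cM Lower truncation threshold in cM (default 0).
#' @param seed Optional integer seed (draws are deterministic given it).
#' @return Numeric vector of `n` lengths in cM.
#' @export
draw_ibd_segment_lengths <- function(g, n, min_cM = 0, seed = NULL) {
  if (g < 1) stop("g must be >= 1")
  stopifnot(n >= 1, min_cM >= 0)
  rate <- 2 * g / 100
  with_seed(seed, min_cM + stats::rexp(n, rate = rate))
}

#' Configuration for the IBD-sharing network generator
#'
#' @param populations A `pop_table` (coordinates drive the distance decay;
#'   neighbor sets, if present, are carried through for the scan).
#' @param sample_sizes Named integer vector of individuals per population.
#' @param beta Baseline expected total sharing per individual pair at
#'   distance 0, in cM, one value per length bin (recycled if scalar).
#' @param lambda_km Exponential decay scale of sharing with geodesic
#'   distance, in km.
#' @param gene_flow Data frame with columns `source`, `recipient`, `delta`
#'   (excess cM per pair per bin; recycled over bins) describing injected
#'   directional gene-flow edges; `NULL` for none.
#' @param bins Length-bin ladder (default 1-6 cM).
#' @param g_seg Generations parameterizing segment-length draws (segment
#'   lengths are exponential with mean `100/(2 g_seg)` cM, conditioned to
#'   the bin; default 20).
#' @param chrom_cM Nominal chromosome length used to place segments
#'   (default 280 cM).
#' @param seed Integer seed; output is fully determined by it.
#' @return A `sharing_sim_config` list.
#' @export
sharing_sim_config <- function(populations, sample_sizes, beta = 0.5,
                               lambda_km = 1500, gene_flow = NULL,
                               bins = length_bins(), g_seg = 20,
                               chrom_cM = 280, seed = 1L) {
  nb <- nrow(bins)
  beta <- rep_len(as.numeric(beta), nb)
  stopifnot(all(beta >= 0), lambda_km > 0, g_seg >= 1)
  ids <- populations$population_id
  if (!all(ids %in% names(sample_sizes))) {
    stop("sample_sizes must cover every population")
  }
  if (!is.null(gene_flow)) {
    stopifnot(all(c("source", "recipient", "delta") %in% names(gene_flow)))
    stopifnot(all(gene_flow$source %in% ids), all(gene_flow$recipient %in% ids))
    stopifnot(all(gene_flow$delta >= 0))
  }
  structure(list(populations = populations,
                 sample_sizes = sample_sizes[ids], beta = beta,
                 lambda_km = lambda_km, gene_flow = gene_flow, bins = bins,
                 g_seg = g_seg, chrom_cM = chrom_cM, seed = as.integer(seed)),
            class = "sharing_sim_config")
}

#' Simulate an IBD-sharing network
#'
#' Generates a pairwise IBD-segment table whose population-level structure
#' follows isolation by distance: the expected total sharing per
#' individual pair in bin b between populations i and j is
#' `beta_b * exp(-d_ij / lambda)` plus, on configured gene-flow edges,
#' an injected excess `delta_b`. Segment counts per individual pair are
#' Poisson; segment lengths are exponential (mean `100/(2 g_seg)` cM)
#' conditioned to the bin, so realized per-bin totals match the
#' expectation on average. The expectation actually used for every
#' population pair and bin is returned as a ground-truth table.
#'
#' @param config A `sharing_sim_config`.
#' @return List with `segments` (an `ibd_segments` table), `truth` (data
#'   frame pop_a, pop_b, bin, expected_cM, gene_flow flag), `sample_map`
#'   (named vector), `sample_sizes`, `populations`, and `bins`.
#' @export
simulate_sharing_network <- function(config) {
  pops <- config$populations
  ids <- pops$population_id
  n <- config$sample_sizes
  bins <- config$bins
  d <- geodesic_matrix(pops)
  edge <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  delta <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (!is.null(config$gene_flow)) {
    for (k in seq_len(nrow(config$gene_flow))) {
      s <- config$gene_flow$source[k]; r <- config$gene_flow$recipient[k]
      edge[s, r] <- edge[r, s] <- TRUE
      delta[s, r] <- delta[r, s] <- config$gene_flow$delta[k]
    }
  }
  inds <- lapply(ids, function(p) sprintf("%s_%02d", p, seq_len(n[p])))
  names(inds) <- ids
  sample_map <- stats::setNames(rep(ids, n[ids]), unlist(inds))
  rate_seg <- 2 * config$g_seg / 100
  mean_bin <- vapply(seq_len(nrow(bins)), function(b) {
    mean_trunc_exp(rate_seg, bins$lower[b], bins$upper[b])
  }, numeric(1))

  truth <- list(); segs <- list()
  with_seed(config$seed, {
    for (i in seq_along(ids)) {
      for (j in i:length(ids)) {
        pi <- ids[i]; pj <- ids[j]
        n_pairs <- if (i == j) n[pi] * (n[pi] - 1) / 2 else n[pi] * n[pj]
        if (n_pairs == 0) next
        for (b in seq_len(nrow(bins))) {
          mu <- config$beta[b] * exp(-d[pi, pj] / config$lambda_km) +
            (if (edge[pi, pj]) delta[pi, pj] else 0)
          truth[[length(truth) + 1]] <- data.frame(
            pop_a = pi, pop_b = pj, bin = bins$label[b], expected_cM = mu,
            gene_flow = edge[pi, pj], stringsAsFactors = FALSE)
          if (mu <= 0) next
          n_seg <- stats::rpois(1, n_pairs * mu / mean_bin[b])
          if (n_seg == 0) next
          len <- rtrunc_exp(n_seg, rate_seg, bins$lower[b], bins$upper[b])
          if (i == j) {
            ia <- sample(inds[[pi]], n_seg, replace = TRUE)
            ib <- sample(inds[[pi]], n_seg, replace = TRUE)
            while (any(same <- ia == ib)) {
              ib[same] <- sample(inds[[pi]], sum(same), replace = TRUE)
            }
          } else {
            ia <- sample(inds[[pi]], n_seg, replace = TRUE)
            ib <- sample(inds[[pj]], n_seg, replace = TRUE)
          }
          start <- stats::runif(n_seg, 0, pmax(config$chrom_cM - len, 0))
          segs[[length(segs) + 1]] <- data.frame(
            sample_a = ia, sample_b = ib, population_a = pi,
            population_b = pj, chromosome = "1", start_cM = start,
            end_cM = start + len, stringsAsFactors = FALSE)
        }
      }
    }
  })
  seg_df <- if (length(segs) > 0) do.call(rbind, segs) else
    data.frame(sample_a = character(0), sample_b = character(0),
               population_a = character(0), population_b = character(0),
               chromosome = character(0), start_cM = numeric(0),
               end_cM = numeric(0), stringsAsFactors = FALSE)
  segments <- ibd_segments(seg_df$sample_a, seg_df$sample_b,
                           seg_df$population_a, seg_df$population_b,
                           seg_df$chromosome, seg_df$start_cM, seg_df$end_cM)
  list(segments = segments, truth = do.call(rbind, truth),
       sample_map = sample_map, sample_sizes = n, populations = pops,
       bins = bins)
}

#' Configuration for the admixed-haplotype forward simulator
#'
#' @param alpha Admixture proportion from source 1, in `[0, 1]`.
#' @param g Generations since the single admixture pulse (>= 1).
#' @param n_haplotypes Even number of admixed haplotypes to output (>= 4).
#' @param chromosome_lengths Chromosome lengths in Morgans (default 15
#'   chromosomes of 2 M: 30 M total).
#' @param n_snps SNPs per chromosome (recycled; default 1500).
#' @param F Balding-Nichols drift parameter separating the two source
#'   populations, in (0, 1) (default 0.2).
#' @param N Diploid population size during propagation (default 500).
#' @param n_ref Diploid individuals genotyped per source panel
#'   (default 25).
#' @param seed Integer seed.
#' @return An `admixture_sim_config` list.
#' @export
admixture_sim_config <- function(alpha = 0.5, g = 20, n_haplotypes = 100,
                                 chromosome_lengths = rep(2, 15),
                                 n_snps = 1500, F = 0.2, N = 500,
                                 n_ref = 25, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, g >= 1, sum(chromosome_lengths) > 0,
            F > 0, F < 1, N >= 2)
  if (n_haplotypes < 4) stop("n_haplotypes must be >= 4")
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")
  structure(list(alpha = alpha, g = as.integer(g),
                 n_haplotypes = as.integer(n_haplotypes),
                 chromosome_lengths = as.numeric(chromosome_lengths),
                 n_snps = rep_len(as.integer(n_snps),
                                  length(chromosome_lengths)),
                 F = F, N = as.integer(N), n_ref = as.integer(n_ref),
                 seed = as.integer(seed)),
            class = "admixture_sim_config")
}

#' Simulate admixed diploid genotypes with known ancestry tracts
#'
#' One-pulse admixture: founder haplotypes in a population of `N` diploids
#' are assigned whole-genome ancestry 1 with probability `alpha`, then the
#' population is propagated `g` generations under random mating with
#' recombination as a Poisson process of rate 1 per Morgan per meiosis.
#' Source allele frequencies are drawn per SNP from a Balding-Nichols
#' divergence model with parameter `F` around a shared ancestral frequency
#' Uniform(0.05, 0.95); alleles on sampled admixed haplotypes are copied
#' from the frequency of their local ancestry, and pure source panels are
#' genotyped from the source frequencies. True ancestry tracts of the
#' sampled haplotypes are recorded.
#'
#' @param config An `admixture_sim_config`.
#' @return List with `genotypes` (a `geno_dataset` containing populations
#'   `SRC1`, `SRC2`, `ADM`), `tracts` (an `ancestry_tracts` data frame
#'   with attribute `chromosome_lengths`), `freqs` (list `p1`, `p2`,
#'   `ancestral`), and `config`.
#' @export
simulate_admixed_haplotypes <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    n_hap_pop <- 2L * cfg$N
    founder_anc <- ifelse(stats::runif(n_hap_pop) < cfg$alpha, 1L, 2L)
    tr <- forward_tracts_cpp(cfg$N, cfg$g, cfg$chromosome_lengths,
                             founder_anc, cfg$n_haplotypes)
    tracts <- as.data.frame(tr, stringsAsFactors = FALSE)
    class(tracts) <- c("ancestry_tracts", "data.frame")
    attr(tracts, "chromosome_lengths") <- cfg$chromosome_lengths

    # SNP map: evenly spaced within each chromosome
    snps <- do.call(rbind, lapply(seq_along(cfg$chromosome_lengths), function(c) {
      m <- cfg$n_snps[c]
      pos_M <- seq_len(m) / (m + 1) * cfg$chromosome_lengths[c]
      data.frame(id = sprintf("snp%d_%d", c, seq_len(m)),
                 chromosome = as.character(c), pos_bp = round(pos_M * 1e8),
                 pos_cM = pos_M * 100, stringsAsFactors = FALSE)
    }))
    n_snp <- nrow(snps)
    anc_p <- stats::runif(n_snp, 0.05, 0.95)
    shp <- (1 - cfg$F) / cfg$F
    p1 <- stats::rbeta(n_snp, anc_p * shp, (1 - anc_p) * shp)
    p2 <- stats::rbeta(n_snp, anc_p * shp, (1 - anc_p) * shp)

    # local ancestry of each sampled haplotype at each SNP
    n_hap <- cfg$n_haplotypes
    hap_alleles <- matrix(0L, nrow = n_hap, ncol = n_snp)
    pos_M_all <- snps$pos_cM / 100
    snp_by_chr <- split(seq_len(n_snp), snps$chromosome)
    tract_idx <- split(seq_len(nrow(tracts)),
                       list(hap = tracts$haplotype, chr = tracts$chromosome))
    for (h in seq_len(n_hap)) {
      anc_at <- integer(n_snp)
      for (c in seq_along(cfg$chromosome_lengths)) {
        sel_snp <- snp_by_chr[[as.character(c)]]
        ti <- tract_idx[[paste(h, c, sep = ".")]]
        ends <- tracts$end_M[ti]
        idx <- findInterval(pos_M_all[sel_snp], ends, left.open = FALSE) + 1L
        idx[idx > length(ti)] <- length(ti)
        anc_at[sel_snp] <- tracts$ancestry[ti][idx]
      }
      p_loc <- ifelse(anc_at == 1L, p1, p2)
      hap_alleles[h, ] <- stats::rbinom(n_snp, 1L, p_loc)
    }
    adm_dosage <- hap_alleles[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap_alleles[seq(2, n_hap, by = 2), , drop = FALSE]

    ref1 <- matrix(stats::rbinom(cfg$n_ref * n_snp, 2L, rep(p1, each = cfg$n_ref)),
                   nrow = cfg$n_ref)
    ref2 <- matrix(stats::rbinom(cfg$n_ref * n_snp, 2L, rep(p2, each = cfg$n_ref)),
                   nrow = cfg$n_ref)
    dosage <- rbind(ref1, ref2, adm_dosage)
    samples <- data.frame(
      sample_id = c(sprintf("SRC1_%02d", seq_len(cfg$n_ref)),
                    sprintf("SRC2_%02d", seq_len(cfg$n_ref)),
                    sprintf("ADM_%02d", seq_len(n_hap / 2))),
      population_id = c(rep("SRC1", cfg$n_ref), rep("SRC2", cfg$n_ref),
                        rep("ADM", n_hap / 2)),
      stringsAsFactors = FALSE)
    geno <- geno_dataset(dosage, snps, samples)
    list(genotypes = geno, tracts = tracts,
         freqs = list(p1 = p1, p2 = p2, ancestral = anc_p), config = cfg)
  })
}

#' Simulate a source/source/target allele-frequency trio
#'
#' Two source populations diverge from a shared ancestral frequency under
#' the Balding-Nichols model with parameter `F`; the target's frequency is
#' the mixture `alpha * p1 + (1 - alpha) * p2` (optionally with extra
#' post-admixture Balding-Nichols drift `drift_F`). Genotypes are
#' Binomial(2, p) per individual. SNPs are spread over 20 nominal
#' chromosomes with uniform cM spacing so that block-jackknife f3 applies
#' directly.
#'
#' @param alpha Admixture proportion in (0, 1), exclusive.
#' @param F Source divergence parameter in (0, 1).
#' @param n_snps Number of SNPs.
#' @param n_per_pop Diploid individuals per population.
#' @param seed Integer seed.
#' @param drift_F Post-admixture drift applied to the target frequency
#'   (default 0 = none).
#' @param n_chrom Number of nominal chromosomes (default 20).
#' @return A `geno_dataset` with populations `SRC1`, `SRC2`, `TGT`.
#' @export
simulate_frequency_trio <- function(alpha, F = 0.2, n_snps = 5000,
                                    n_per_pop = 25, seed = 1L,
                                    drift_F = 0, n_chrom = 20) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be strictly inside (0, 1)")
  stopifnot(F > 0, F < 1, n_per_pop >= 2)
  with_seed(seed, {
    if (n_snps == 0) {
      snps <- data.frame(id = character(0), chromosome = character(0),
                         pos_bp = numeric(0), pos_cM = numeric(0),
                         stringsAsFactors = FALSE)
      samples <- data.frame(
        sample_id = c(sprintf("SRC1_%02d", seq_len(n_per_pop)),
                      sprintf("SRC2_%02d", seq_len(n_per_pop)),
                      sprintf("TGT_%02d", seq_len(n_per_pop))),
        population_id = rep(c("SRC1", "SRC2", "TGT"), each = n_per_pop),
        stringsAsFactors = FALSE)
      return(geno_dataset(matrix(0, 3 * n_per_pop, 0), snps, samples))
    }
    anc_p <- stats::runif(n_snps, 0.05, 0.95)
    shp <- (1 - F) / F
    p1 <- stats::rbeta(n_snps, anc_p * shp, (1 - anc_p) * shp)
    p2 <- stats::rbeta(n_snps, anc_p * shp, (1 - anc_p) * shp)
    p3 <- alpha * p1 + (1 - alpha) * p2
    if (drift_F > 0) {
      shp3 <- (1 - drift_F) / drift_F
      p3 <- stats::rbeta(n_snps, p3 * shp3, (1 - p3) * shp3)
    }
    chrom <- rep_len(seq_len(n_chrom), n_snps)
    chrom <- sort(chrom)
    pos <- unlist(lapply(seq_len(n_chrom), function(c) {
      m <- sum(chrom == c)
      seq_len(m) / (m + 1) * 100
    }))
    snps <- data.frame(id = sprintf("snp%d", seq_len(n_snps)),
                       chromosome = as.character(chrom), pos_bp = round(pos * 1e6),
                       pos_cM = pos, stringsAsFactors = FALSE)
    gmat <- function(p, tag) {
      m <- matrix(stats::rbinom(n_per_pop * n_snps, 2L, rep(p, each = n_per_pop)),
                  nrow = n_per_pop)
      rownames(m) <- sprintf("%s_%02d", tag, seq_len(n_per_pop))
      m
    }
    dosage <- rbind(gmat(p1, "SRC1"), gmat(p2, "SRC2"), gmat(p3, "TGT"))
    samples <- data.frame(sample_id = rownames(dosage),
                          population_id = rep(c("SRC1", "SRC2", "TGT"),
                                              each = n_per_pop),
                          stringsAsFactors = FALSE)
    geno_dataset(dosage, snps, samples)
  })
}
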