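# Per-individual totals of bin-b sharing with a source population.
# Returns a named vector over `individuals`, zeros included.
individual_source_totals <- function(binned, individuals, source_inds, bin_label) {
  seg <- binned[binned$bin == bin_label, , drop = FALSE]
  in_a <- seg$sample_a %in% individuals & seg$sample_b %in% source_inds
  in_b <- seg$sample_b %in% individuals & seg$sample_a %in% source_inds
  tot <- stats::setNames(numeric(length(individuals)), individuals)
  if (any(in_a)) {
    t1 <- rowsum(seg$length_cM[in_a], seg$sample_a[in_a])
    tot[rownames(t1)] <- tot[rownames(t1)] + t1[, 1]
  }
  if (any(in_b)) {
    t2 <- rowsum(seg$length_cM[in_b], seg$sample_b[in_b])
    tot[rownames(t2)] <- tot[rownames(t2)] + t2[, 1]
  }
  tot
}

#' Permutation test for excess IBD sharing with a source population
#'
#' Tests whether the average per-pair sharing (in one length bin) between
#' a focal population and a candidate source exceeds what populations of
#' the same size drawn from the focal's pooled geographic neighbors show.
#' All neighbor individuals are pooled; each permutation draws, without
#' replacement, a pseudo-population of the focal's sample size and
#' recomputes the same statistic against the source. The p-value is the
#' fraction of permuted statistics greater than or equal to the observed
#' one (ties count), with no +1 correction; the minimum resolvable value
#' `1/n_perm` is reported alongside.
#'
#' @param segments An `ibd_segments` table (segment detection is fixed;
#'   only individuals are resampled).
#' @param sample_map Named vector (or two-column data frame) mapping
#'   individual id to population id; defines population membership,
#'   including individuals with no segments.
#' @param focal Focal population id.
#' @param source Candidate source population id (not in the pool).
#' @param neighbor_pool Character vector of neighbor population ids to
#'   pool (focal and source excluded).
#' @param bin Bin label to test, or a `length_bins` row index.
#' @param bins The bin ladder (default ladder).
#' @param n_perm Number of permutations (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed.
#' @param perm_draws Optional precomputed permutation index matrix
#'   (`n_perm` x focal size, indices into the pooled individuals), used by
#'   [permtest_suite()] to share draws across sources within one focal.
#' @return A one-row data frame of class `perm_result`: `focal_id`,
#'   `source_id`, `bin`, `observed`, `n_perm`, `n_geq`, `p_value`,
#'   `min_p`, `seed`.
#' @export
excess_sharing_pvalue <- function(segments, sample_map, focal, source,
                                  neighbor_pool, bin = 1L,
                                  bins = length_bins(), n_perm = 10000L,
                                  seed = NULL, perm_draws = NULL) {
  map <- as_sample_map(sample_map)
  if (focal %in% neighbor_pool) stop("focal population must not be in the pool")
  if (source %in% neighbor_pool) stop("source population must not be in the pool")
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is very coarse")
  bin_label <- if (is.numeric(bin)) bins$label[bin] else as.character(bin)
  binned <- bin_segments(segments, bins)
  focal_inds <- names(map)[map == focal]
  source_inds <- names(map)[map == source]
  pool_inds <- names(map)[map %in% neighbor_pool]
  n_f <- length(focal_inds)
  n_s <- length(source_inds)
  if (n_f == 0 || n_s == 0) stop("focal or source population has no individuals")
  if (length(pool_inds) < n_f) {
    stop("pooled neighbor pool smaller than the focal sample size")
  }
  t_focal <- individual_source_totals(binned, focal_inds, source_inds, bin_label)
  observed <- sum(t_focal) / (n_f * n_s)
  t_pool <- individual_source_totals(binned, pool_inds, source_inds, bin_label)
  if (is.null(perm_draws)) {
    perm_draws <- with_seed(seed, {
      t(replicate(n_perm, sample.int(length(pool_inds), n_f)))
    })
  }
  perm_tot <- matrix(t_pool[as.vector(perm_draws)], nrow = nrow(perm_draws))
  perm_stat <- rowSums(perm_tot) / (n_f * n_s)
  n_geq <- sum(perm_stat >= observed)
  out <- data.frame(focal_id = focal, source_id = source, bin = bin_label,
                    observed = observed, n_perm = nrow(perm_draws),
                    n_geq = n_geq, p_value = n_geq / nrow(perm_draws),
                    min_p = 1 / nrow(perm_draws),
                    seed = if (is.null(seed)) NA_integer_ else seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("perm_result", "data.frame")
  out
}

#' Permutation-test suite over multiple focal/source targets
#'
#' Runs [excess_sharing_pvalue()] for every (focal, source, bin)
#' combination in `targets`, reusing the same permutation draws across
#' sources and bins within one focal so that the per-focal count of
#' significant sources is internally consistent. A failing single test is
#' recorded as `NA` with a message and does not abort the suite.
#'
#' @param segments An `ibd_segments` table.
#' @param sample_map Individual-to-population mapping.
#' @param targets List of lists, each with elements `focal` (id),
#'   `sources` (character vector), `neighbor_pool` (character vector) and
#'   optionally `bins` (labels; default first ladder bin).
#' @param bins Bin ladder.
#' @param n_perm Permutations per test.
#' @param seed Master seed; per-focal seeds are derived from it.
#' @param p_threshold Significance level for the per-focal source count
#'   (default 0.01).
#' @return List with `results` (a `perm_result` data frame) and `summary`
#'   (per focal: number of sources with `p_value <= p_threshold`).
#' @export
permtest_suite <- function(segments, sample_map, targets,
                           bins = length_bins(), n_perm = 10000L,
                           seed = 1L, p_threshold = 0.01) {
  if (length(targets) == 0) {
    empty <- data.frame(focal_id = character(0), source_id = character(0),
                        bin = character(0), observed = numeric(0),
                        n_perm = integer(0), n_geq = integer(0),
                        p_value = numeric(0), min_p = numeric(0),
                        seed = integer(0), stringsAsFactors = FALSE)
    return(list(results = empty,
                summary = data.frame(focal_id = character(0),
                                     n_significant = integer(0))))
  }
  map <- as_sample_map(sample_map)
  seeds <- derive_seeds(seed, length(targets))
  rows <- list()
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    tg_bins <- tg$bins %||% bins$label[1]
    focal_inds <- names(map)[map == tg$focal]
    pool_inds <- names(map)[map %in% tg$neighbor_pool]
    draws <- with_seed(seeds[k], {
      t(replicate(n_perm, sample.int(length(pool_inds), length(focal_inds))))
    })
    for (src in tg$sources) {
      for (b in tg_bins) {
        res <- tryCatch(
          excess_sharing_pvalue(segments, map, tg$focal, src,
                                tg$neighbor_pool, bin = b, bins = bins,
                                n_perm = n_perm, seed = seeds[k],
                                perm_draws = draws),
          error = function(e) {
            message(sprintf("test (%s vs %s, bin %s) failed: %s",
                            tg$focal, src, b, conditionMessage(e)))
            data.frame(focal_id = tg$focal, source_id = src, bin = b,
                       observed = NA_real_, n_perm = n_perm,
                       n_geq = NA_integer_, p_value = NA_real_,
                       min_p = 1 / n_perm, seed = seeds[k],
                       stringsAsFactors = FALSE)
          })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  class(results) <- c("perm_result", "data.frame")
  counts <- tapply(results$p_value <= p_threshold, results$focal_id,
                   sum, na.rm = TRUE)
  summary <- data.frame(focal_id = names(counts),
                        n_significant = as.integer(counts),
                        stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}
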