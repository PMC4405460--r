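#' Expected single-path IBD tract length
#'
#' An IBD tract surviving a fixed chain of `2g` meioses has expected
#' length `100/(2g)` cM.
#'
#' @param g Generations (>= 1).
#' @return Expected tract length in cM.
#' @export
expected_tract_length_cM <- function(g) {
  if (any(g < 1)) stop("g must be >= 1")
  100 / (2 * g)
}

#' Convert calendar years to generations
#'
#' @param years Elapsed years (>= 0).
#' @param gen_time Generation time in years (default 30).
#' @return Number of generations (not rounded).
#' @export
years_to_generations <- function(years, gen_time = 30) {
  stopifnot(all(years >= 0), gen_time > 0)
  years / gen_time
}

#' Convert generations since admixture to a calendar year
#'
#' Anchored at 2000 CE with a 30-year generation time:
#' `year = 2000 - 30 g`. Negative values are years BCE, reported with a
#' negative sign.
#'
#' @param g Generations (>= 0).
#' @param anchor_year Present-day anchor (default 2000).
#' @param gen_time Generation time in years (default 30).
#' @return Calendar year (CE; negative = BCE).
#' @export
generations_to_calendar <- function(g, anchor_year = 2000, gen_time = 30) {
  stopifnot(all(g >= 0))
  anchor_year - gen_time * g
}

#' Weighted-LD decay curve for admixture dating
#'
#' For each SNP the weight is the reference allele-frequency difference
#' `w_s = p_ref1(s) - p_ref2(s)`. For every within-chromosome SNP pair at
#' genetic distance between `d_min_cM` and `d_max_cM`, the product
#' `D_st * w_s * w_t` is accumulated into the distance bin of the pair,
#' where `D_st` is the sample covariance of the admixed population's
#' dosages at the two SNPs (pairwise-complete). Under one-pulse admixture
#' the bin average decays as `exp(-g d)` with d in Morgans, which
#' [fit_ld_decay()] exploits to date the event.
#'
#' @param geno A `geno_dataset` with cM positions.
#' @param admixed,ref1,ref2 Population ids (ref1 != ref2).
#' @param bin_width_cM Distance bin width (default 0.25 cM).
#' @param d_min_cM Minimum pair distance (default 0.5 cM; excludes
#'   short-range background LD).
#' @param d_max_cM Maximum pair distance (default 30 cM).
#' @return An `ld_curve`: data frame with `mid_cM`, `wld`, `n_pairs`
#'   (bins with no pairs removed), plus attributes `bin_sums`,
#'   `bin_counts` (bin x chromosome matrices enabling the chromosome
#'   jackknife) and `mids`.
#' @export
weighted_ld_curve <- function(geno, admixed, ref1, ref2,
                              bin_width_cM = 0.25, d_min_cM = 0.5,
                              d_max_cM = 30) {
  if (identical(ref1, ref2)) stop("ref1 and ref2 must differ")
  for (p in c(admixed, ref1, ref2)) {
    if (!p %in% geno$samples$population_id) stop("population absent: ", p)
  }
  rows <- function(p) which(geno$samples$population_id == p)
  w_all <- pop_freqs(geno$dosage, rows(ref1))$freq -
    pop_freqs(geno$dosage, rows(ref2))$freq
  X <- geno$dosage[rows(admixed), , drop = FALSE]
  usable <- !is.na(geno$snps$pos_cM) & !is.na(w_all)
  chroms <- unique(geno$snps$chromosome[usable])
  edges <- seq(d_min_cM, d_max_cM + bin_width_cM, by = bin_width_cM)
  n_bin <- length(edges) - 1
  bin_sums <- matrix(0, n_bin, length(chroms), dimnames = list(NULL, chroms))
  bin_counts <- matrix(0, n_bin, length(chroms), dimnames = list(NULL, chroms))
  for (chr in chroms) {
    sel <- which(usable & geno$snps$chromosome == chr)
    if (length(sel) < 2) next
    pos <- geno$snps$pos_cM[sel]
    w <- w_all[sel]
    Xs <- X[, sel, drop = FALSE]
    if (anyNA(Xs)) {
      C <- stats::cov(Xs, use = "pairwise.complete.obs")
    } else {
      Xc <- sweep(Xs, 2, colMeans(Xs))
      C <- crossprod(Xc) / (nrow(Xs) - 1)
    }
    WC <- C * tcrossprod(w)
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dd)
    dv <- dd[ut]
    vv <- WC[ut]
    keep <- dv >= d_min_cM & dv <= d_max_cM & !is.na(vv)
    if (!any(keep)) next
    b <- findInterval(dv[keep], edges, rightmost.closed = TRUE)
    v <- vv[keep]
    sums <- numeric(n_bin)
    agg <- rowsum(v, b)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    bin_sums[, chr] <- bin_sums[, chr] + sums
    bin_counts[, chr] <- bin_counts[, chr] + tabulate(b, nbins = n_bin)
  }
  counts <- rowSums(bin_counts)
  if (all(counts == 0)) stop("no SNP pairs retained in the distance window")
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  keep_bin <- counts > 0
  out <- data.frame(mid_cM = mids[keep_bin],
                    wld = rowSums(bin_sums)[keep_bin] / counts[keep_bin],
                    n_pairs = counts[keep_bin])
  structure(out, bin_sums = bin_sums, bin_counts = bin_counts, mids = mids,
            class = c("ld_curve", "data.frame"))
}

# Fit y = A exp(-g d) + c (d in Morgans) to a binned curve.
# Returns c(A, g, c) or NULL on failure.
fit_exp_decay <- function(d_M, y) {
  ok <- is.finite(y)
  d_M <- d_M[ok]; y <- y[ok]
  if (length(y) < 8) stop("fewer than 8 retained bins")
  c0 <- min(y)
  eps <- max(diff(range(y)) * 1e-3, 1e-12)
  ylog <- log(y - c0 + eps)
  lf <- stats::lm(ylog ~ d_M)
  g0 <- max(-unname(stats::coef(lf)[2]), 1)
  A0 <- max(exp(unname(stats::coef(lf)[1])), eps)
  starts <- list(c(A = A0, g = g0, c = c0),
                 c(A = max(y) - c0, g = 10, c = c0),
                 c(A = max(y) - c0, g = 50, c = c0))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-g * d_M) + c,
                        start = as.list(st),
                        lower = c(A = 1e-12, g = 1e-6, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) return(stats::coef(fit))
  }
  NULL
}

#' Date admixture from a weighted-LD decay curve
#'
#' Least-squares fit of `y(d) = A exp(-g d) + c` with d in Morgans and
#' constraints `A > 0`, `g > 0`, initialized from a log-linear regression.
#' `g` is the point estimate of generations since the admixture pulse; the
#' affine term `c` absorbs background covariance and is reported but never
#' interpreted. The 95\% CI is a delete-one-chromosome jackknife over the
#' per-chromosome bin contributions stored in the curve.
#'
#' @param curve An `ld_curve` from [weighted_ld_curve()] (>= 8 bins).
#' @param anchor_year,gen_time Calendar conversion parameters passed to
#'   [generations_to_calendar()].
#' @return A `date_estimate`: list with `g_hat`, `ci` (length 2),
#'   `method = "weighted_ld"`, `A`, `c`, `calendar_year`, `n_bins`.
#' @export
fit_ld_decay <- function(curve, anchor_year = 2000, gen_time = 30) {
  d_M <- curve$mid_cM / 100
  if (diff(range(curve$wld, na.rm = TRUE)) <=
      1e-12 * max(1, abs(max(curve$wld, na.rm = TRUE)))) {
    stop("no admixture LD detected (flat curve)")
  }
  cf <- fit_exp_decay(d_M, curve$wld)
  if (is.null(cf)) stop("exponential decay fit did not converge")
  if (cf["A"] <= 2e-12) stop("no admixture LD detected (amplitude at zero)")
  g_hat <- unname(cf["g"])
  # chromosome jackknife on the stored per-chromosome contributions
  bs <- attr(curve, "bin_sums"); bc <- attr(curve, "bin_counts")
  mids <- attr(curve, "mids")
  g_jk <- c()
  if (!is.null(bs) && ncol(bs) >= 2) {
    for (chr in colnames(bs)) {
      s <- rowSums(bs) - bs[, chr]
      n <- rowSums(bc) - bc[, chr]
      kb <- n > 0
      cfj <- tryCatch(fit_exp_decay(mids[kb] / 100, s[kb] / n[kb]),
                      error = function(e) NULL)
      if (!is.null(cfj)) g_jk <- c(g_jk, unname(cfj["g"]))
    }
  }
  if (length(g_jk) >= 2) {
    m <- length(g_jk)
    se <- sqrt((m - 1) / m * sum((g_jk - mean(g_jk))^2))
    ci <- g_hat + c(-1, 1) * stats::qnorm(0.975) * se
    ci[1] <- max(ci[1], 0)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(g_hat = g_hat, ci = ci, method = "weighted_ld",
                 A = unname(cf["A"]), c = unname(cf["c"]),
                 calendar_year = generations_to_calendar(g_hat, anchor_year,
                                                         gen_time),
                 n_bins = nrow(curve)),
            class = "date_estimate")
}

#' @export
print.date_estimate <- function(x, ...) {
  cat(sprintf("admixture date (%s): g = %.2f generations", x$method, x$g_hat))
  if (all(is.finite(x$ci))) cat(sprintf(" [%.2f, %.2f]", x$ci[1], x$ci[2]))
  cat("\n")
  yr <- x$calendar_year
  cat(sprintf("calendar year: %s %s\n", format(round(abs(yr))),
              if (yr >= 0) "CE" else "BCE"))
  if (!is.null(x$A)) cat(sprintf("fit: A = %.4g, c = %.4g\n", x$A, x$c))
  invisible(x)
}

#' Date admixture from ancestry- or IBD-tract lengths
#'
#' Ancestry mode: ancestry tracts of one source in a one-pulse admixed
#' genome have mean length `1/(g q)` Morgans, where `q` is the proportion
#' of the *other* ancestry (the per-Morgan rate of switching out); the
#' estimate inverts the interior-tract mean length. Tracts touching a
#' chromosome end are length-censored and excluded. Single-path IBD mode:
#' inverts the `1/(2g)` Morgan expectation of single-path IBD tract
#' lengths. CIs are percentile bootstrap over tracts.
#'
#' @param tracts An `ancestry_tracts` data frame (ancestry mode), or a
#'   plain numeric vector of tract lengths in cM (`ibd_single_path`
#'   mode).
#' @param ancestry Which ancestry's tracts to use (1 or 2; default 1).
#' @param alpha Admixture proportion of ancestry 1 (required for ancestry
#'   mode, strictly inside (0, 1)).
#' @param mode `"ancestry"` or `"ibd_single_path"`.
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param seed Optional seed for the bootstrap.
#' @param anchor_year,gen_time Calendar conversion parameters.
#' @return A `date_estimate` with `method = "tracts"`, plus `mean_length_M`
#'   and `n_tracts`.
#' @export
date_from_tract_lengths <- function(tracts, ancestry = 1L, alpha = NULL,
                                    mode = c("ancestry", "ibd_single_path"),
                                    n_boot = 200L, seed = NULL,
                                    anchor_year = 2000, gen_time = 30) {
  mode <- match.arg(mode)
  if (mode == "ancestry") {
    if (!inherits(tracts, "ancestry_tracts")) {
      stop("ancestry mode needs an ancestry_tracts table")
    }
    if (is.null(alpha) || alpha <= 0 || alpha >= 1) {
      stop("ancestry mode needs alpha strictly inside (0, 1)")
    }
    chrom_len <- attr(tracts, "chromosome_lengths")
    if (is.null(chrom_len)) stop("tracts lack chromosome_lengths attribute")
    L <- chrom_len[as.integer(tracts$chromosome)]
    interior <- tracts$start_M > 0 & tracts$end_M < L
    sel <- interior & tracts$ancestry == ancestry
    if (sum(tracts$ancestry == ancestry) > 0 && !any(sel)) {
      stop("all tracts of the chosen ancestry are chromosome-end censored")
    }
    lengths_M <- tracts$end_M[sel] - tracts$start_M[sel]
    q <- if (ancestry == 1L) 1 - alpha else alpha
    estimator <- function(l) 1 / (mean(l) * q)
  } else {
    lengths_M <- if (is.numeric(tracts)) tracts / 100 else
      (tracts$end_M - tracts$start_M)
    estimator <- function(l) 1 / (2 * mean(l))
  }
  if (length(lengths_M) < 30) stop("need at least 30 tracts")
  g_hat <- estimator(lengths_M)
  if (n_boot >= 2) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        estimator(sample(lengths_M, replace = TRUE))
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(g_hat = g_hat, ci = ci, method = "tracts",
                 A = NULL, c = NULL,
                 calendar_year = generations_to_calendar(g_hat, anchor_year,
                                                         gen_time),
                 mean_length_M = mean(lengths_M),
                 n_tracts = length(lengths_M)),
            class = "date_estimate")
}

#' Admixture proportion from projection coordinates
#'
#' Given mean coordinates of the two parental populations (`x1`, `x2`)
#' and the admixed population (`x3`) on one projection axis (e.g. a
#' principal component separating the parents), the proportion of
#' ancestry contributed by the first parent is
#' `alpha = (x2 - x3)/(x2 - x1)`. Values outside `[0, 1]` (admixed mean
#' outside the parental span) are returned with a warning.
#'
#' @param x1,x2 Mean coordinates of parental populations 1 and 2
#'   (`x1 != x2`).
#' @param x3 Mean coordinate of the admixed population.
#' @return Estimated admixture proportion alpha.
#' @export
projection_admixture_proportion <- function(x1, x2, x3) {
  if (x1 == x2) stop("degenerate projection axis: x1 == x2")
  alpha <- (x2 - x3) / (x2 - x1)
  if (alpha < 0 || alpha > 1) {
    warning("admixed mean lies outside the parental span: alpha outside [0, 1]")
  }
  alpha
}

#' RMSE/bias benchmark of the dating estimators
#'
#' For each true admixture age in `scenarios`, simulates `reps`
#' independent admixed datasets (seeds derived from `seed`), applies the
#' chosen estimator, and summarizes accuracy as
#' `RMSE = sqrt(mean((g_hat - g)^2))` and
#' `bias = (sum(g_hat) - sum(g)) / n`, per scenario and overall.
#' Estimator failures are recorded as missing and excluded with a logged
#' count.
#'
#' @param scenarios Integer vector of true generations since admixture
#'   (default the 5-60 grid).
#' @param reps Replicates per scenario (>= 2).
#' @param estimator `"tracts"`, `"weighted_ld"`, or a function
#'   `f(sim, g_true)` returning a numeric estimate (stubs for harness
#'   checks).
#' @param sim_config An `admixture_sim_config` template; its `g` and
#'   `seed` are overridden per run.
#' @param seed Master seed.
#' @return An `ld_benchmark`: list with `per_scenario` (data frame
#'   g_true, n_ok, rmse, bias), `overall` (rmse, bias), `estimates`
#'   (long data frame), `n_failed`.
#' @export
benchmark_rmse_bias <- function(scenarios = c(5, 10, 20, 30, 40, 50, 60),
                                reps = 10L, estimator = "tracts",
                                sim_config = admixture_sim_config(),
                                seed = 1L) {
  stopifnot(reps >= 2)
  est_fun <- if (is.function(estimator)) {
    estimator
  } else if (identical(estimator, "tracts")) {
    function(sim, g_true) {
      date_from_tract_lengths(sim$tracts, ancestry = 1L,
                              alpha = sim$config$alpha, n_boot = 0L)$g_hat
    }
  } else if (identical(estimator, "weighted_ld")) {
    function(sim, g_true) {
      curve <- weighted_ld_curve(sim$genotypes, "ADM", "SRC1", "SRC2")
      fit_ld_decay(curve)$g_hat
    }
  } else stop("unknown estimator")
  seeds <- matrix(derive_seeds(seed, length(scenarios) * reps),
                  nrow = length(scenarios))
  rows <- list()
  for (i in seq_along(scenarios)) {
    for (r in seq_len(reps)) {
      g_true <- scenarios[i]
      sim <- NULL
      if (!is.function(estimator)) {
        cfg <- sim_config
        cfg$g <- as.integer(g_true)
        cfg$seed <- seeds[i, r]
        sim <- simulate_admixed_haplotypes(cfg)
      }
      g_hat <- tryCatch(est_fun(sim, g_true), error = function(e) {
        message(sprintf("estimator failed (g = %d, rep %d): %s",
                        g_true, r, conditionMessage(e)))
        NA_real_
      })
      rows[[length(rows) + 1]] <- data.frame(g_true = g_true, rep = r,
                                             g_hat = g_hat)
    }
  }
  est <- do.call(rbind, rows)
  n_failed <- sum(is.na(est$g_hat))
  ok <- est[!is.na(est$g_hat), , drop = FALSE]
  per_scenario <- do.call(rbind, lapply(scenarios, function(g) {
    e <- ok[ok$g_true == g, , drop = FALSE]
    if (nrow(e) == 0) {
      return(data.frame(g_true = g, n_ok = 0L, rmse = NA_real_,
                        bias = NA_real_))
    }
    data.frame(g_true = g, n_ok = nrow(e),
               rmse = sqrt(mean((e$g_hat - e$g_true)^2)),
               bias = (sum(e$g_hat) - sum(e$g_true)) / nrow(e))
  }))
  overall <- data.frame(
    rmse = sqrt(mean((ok$g_hat - ok$g_true)^2)),
    bias = (sum(ok$g_hat) - sum(ok$g_true)) / nrow(ok))
  structure(list(per_scenario = per_scenario, overall = overall,
                 estimates = est, n_failed = n_failed,
                 estimator = if (is.function(estimator)) "custom" else estimator),
            class = "ld_benchmark")
}

#' @export
print.ld_benchmark <- function(x, ...) {
  cat("dating benchmark (", x$estimator, " estimator)\n", sep = "")
  print(x$per_scenario, row.names = FALSE)
  cat(sprintf("overall: RMSE = %.3g, bias = %.3g", x$overall$rmse,
              x$overall$bias))
  if (x$n_failed > 0) cat(sprintf("  (%d failed run(s) excluded)", x$n_failed))
  cat("\n")
  invisible(x)
}
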