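#' Configuration for the subtraction-accumulation scan
#'
#' @param focal_ids Character vector of focal population ids (the
#'   populations suspected of carrying an immigrant signal).
#' @param neighbor_sets Named list, one entry per focal id, of that focal's
#'   geographic-neighbor population ids. A focal id appearing in another
#'   focal's neighbor set is removed with a warning (it would subtract the
#'   signal from itself).
#' @param reference_ids Populations the sharing vectors are taken against
#'   (default: all populations in the sharing matrix that are not focal).
#' @param bin Length-bin label (or index) to scan; default the first bin.
#' @param q Sample quantile above which an accumulated value is flagged
#'   (default 0.90).
#' @param n_null_replicates Number of random-neighbor null replicates used
#'   by [null_scan_replicates()] (default 10).
#' @param seed Integer seed for the null replicates.
#' @param neighbor_method `"pooled"` (pool neighbor individuals into one
#'   super-population; default) or `"average"` (mean of the neighbor
#'   populations' sharing values).
#' @param allow_focal_in_references Internal switch used by the null
#'   replicates, where a pseudo-focal can legitimately sit in the
#'   reference list.
#' @return A `scan_config` list.
#' @export
scan_config <- function(focal_ids, neighbor_sets, reference_ids = NULL,
                        bin = 1L, q = 0.90, n_null_replicates = 10L,
                        seed = NULL, neighbor_method = c("pooled", "average"),
                        allow_focal_in_references = FALSE) {
  neighbor_method <- match.arg(neighbor_method)
  focal_ids <- as.character(focal_ids)
  if (!all(focal_ids %in% names(neighbor_sets))) {
    stop("every focal id needs an entry in neighbor_sets")
  }
  neighbor_sets <- neighbor_sets[focal_ids]
  for (f in focal_ids) {
    nb <- neighbor_sets[[f]]
    inside <- intersect(nb, focal_ids)
    if (length(inside) > 0) {
      warning(sprintf("focal id(s) %s removed from neighbor set of '%s'",
                      paste(inside, collapse = ", "), f))
      nb <- setdiff(nb, focal_ids)
    }
    if (length(nb) == 0) stop(sprintf("neighbor set of '%s' is empty", f))
    neighbor_sets[[f]] <- nb
  }
  if (!is.null(reference_ids) && !allow_focal_in_references) {
    overlap <- intersect(reference_ids, focal_ids)
    if (length(overlap) > 0) {
      stop("focal and reference sets overlap: ", paste(overlap, collapse = ", "))
    }
  }
  structure(list(focal_ids = focal_ids, neighbor_sets = neighbor_sets,
                 reference_ids = reference_ids, bin = bin, q = q,
                 n_null_replicates = as.integer(n_null_replicates),
                 seed = seed, neighbor_method = neighbor_method,
                 allow_focal_in_references = allow_focal_in_references),
            class = "scan_config")
}

#' Ordered sharing vector of a population or pooled set
#'
#' For a single population, the row of the sharing matrix over the
#' references. For a set (a focal population's geographic neighbors), the
#' pooled statistic: neighbor individuals are merged into one
#' super-population and the per-pair average sharing with each reference
#' is recomputed from the population-level totals (within-reference pairs
#' counted once when the reference itself belongs to the set). The
#' `"average"` method instead averages the member populations' sharing
#' values.
#'
#' @param S A `sharing_matrix`.
#' @param group A population id, or a character vector of ids to pool.
#' @param references Character vector of reference ids; the result is
#'   ordered exactly as given.
#' @param bin Bin label or index.
#' @param method `"pooled"` or `"average"`.
#' @return Named numeric vector of sharing values (cM per pair), one per
#'   reference.
#' @export
sharing_vector <- function(S, group, references, bin = 1L,
                           method = c("pooled", "average")) {
  method <- match.arg(method)
  if (length(references) == 0) stop("references must be non-empty")
  M <- pool_bins(S, bin)
  n <- attr(S, "sample_sizes")
  ids <- rownames(M)
  stopifnot(all(group %in% ids), all(references %in% ids))
  if (length(group) == 1) {
    out <- M[group, references]
  } else if (method == "average") {
    out <- colMeans(M[group, references, drop = FALSE])
  } else {
    ng <- n[group]
    out <- vapply(references, function(r) {
      if (r %in% group) {
        others <- setdiff(group, r)
        tot <- sum(M[others, r] * n[others] * n[r])
        npair <- sum(n[others]) * n[r]
        if (n[r] >= 2) {
          tot <- tot + M[r, r] * n[r] * (n[r] - 1) / 2
          npair <- npair + n[r] * (n[r] - 1) / 2
        }
        tot / npair
      } else {
        sum(M[group, r] * ng) / sum(ng)
      }
    }, numeric(1))
  }
  names(out) <- references
  out
}

#' Flag accumulated values above a sample quantile
#'
#' The threshold is the type-7 (linear interpolation) sample quantile of
#' the accumulated values; flagging uses strict inequality, so ties with
#' the threshold do not flag.
#'
#' @param values Named numeric vector of accumulated sharing differences.
#' @param q Quantile level (default 0.90).
#' @return List with `threshold` and `flagged` (character vector of names).
#' @export
flag_quantile <- function(values, q = 0.90) {
  if (length(values) < 5) stop("need at least 5 values for a quantile flag")
  threshold <- unname(stats::quantile(values, probs = q, type = 7))
  list(threshold = threshold, flagged = names(values)[values > threshold])
}

#' Subtraction-accumulation scan
#'
#' For each focal population f the ordered sharing vector against the
#' references is computed, the corresponding vector of f's pooled
#' geographic neighbors is subtracted element-wise, and the difference
#' vectors are summed element-wise across all focal populations. A
#' reference whose accumulated value exceeds the `q` sample quantile of
#' all accumulated values is flagged as showing a correlated excess of
#' sharing with the focal group.
#'
#' @param S A `sharing_matrix`.
#' @param config A `scan_config`.
#' @return An `ibd_scan` object: list with `accumulated` (named vector),
#'   `threshold`, `flagged`, `diffs` (focal x reference matrix of
#'   per-focal differences) and `config`.
#' @export
subtract_accumulate <- function(S, config) {
  ids <- rownames(pool_bins(S, config$bin))
  refs <- config$reference_ids %||% setdiff(ids, config$focal_ids)
  if (length(refs) < 5) stop("reference list shorter than 5")
  diffs <- matrix(0, nrow = length(config$focal_ids), ncol = length(refs),
                  dimnames = list(config$focal_ids, refs))
  for (f in config$focal_ids) {
    vf <- sharing_vector(S, f, refs, config$bin, config$neighbor_method)
    vn <- sharing_vector(S, config$neighbor_sets[[f]], refs, config$bin,
                         config$neighbor_method)
    diffs[f, ] <- vf - vn
  }
  accumulated <- colSums(diffs)
  fl <- flag_quantile(accumulated, config$q)
  structure(list(accumulated = accumulated, threshold = fl$threshold,
                 flagged = fl$flagged, diffs = diffs, config = config),
            class = "ibd_scan")
}

#' @export
print.ibd_scan <- function(x, ...) {
  cat("subtraction-accumulation scan:", nrow(x$diffs), "focal populations,",
      ncol(x$diffs), "references\n")
  cat(sprintf("threshold (q = %.2f): %.4g cM\n", x$config$q, x$threshold))
  if (length(x$flagged) > 0) {
    top <- sort(x$accumulated[x$flagged], decreasing = TRUE)
    cat("flagged references:\n")
    for (i in seq_along(top)) {
      cat(sprintf("  %s  A = %.4g cM\n", names(top)[i], top[i]))
    }
  } else {
    cat("no reference flagged\n")
  }
  invisible(x)
}

#' Random-neighbor null replicates of the scan
#'
#' Re-runs the subtraction-accumulation scan after replacing each focal
#' population with one population drawn at random from its own
#' geographic-neighbor set (the drawn population's new neighbor set is the
#' remainder of the set). Because the pseudo-focals are, by construction,
#' ordinary members of their neighborhoods, flags in these replicates show
#' what the scan produces when no systematic focal-specific signal exists.
#'
#' @param S A `sharing_matrix`.
#' @param config A `scan_config`; `n_null_replicates` and `seed` control
#'   the replicates. Neighbor sets of size 1 cannot be split; those focals
#'   are skipped with a warning.
#' @return List of `ibd_scan` objects, one per replicate.
#' @export
null_scan_replicates <- function(S, config) {
  n_rep <- config$n_null_replicates
  if (n_rep == 0) return(list())
  seeds <- derive_seeds(config$seed %||% 1L, n_rep)
  splittable <- vapply(config$neighbor_sets, function(nb) length(nb) >= 2,
                       logical(1))
  if (any(!splittable)) {
    warning("focal(s) skipped in null replicates (neighbor set of size 1): ",
            paste(config$focal_ids[!splittable], collapse = ", "))
  }
  focals <- config$focal_ids[splittable]
  if (length(focals) == 0) stop("no focal population has a splittable neighbor set")
  lapply(seq_len(n_rep), function(k) {
    with_seed(seeds[k], {
      pseudo <- character(length(focals))
      sets <- vector("list", length(focals))
      for (i in seq_along(focals)) {
        nb <- config$neighbor_sets[[focals[i]]]
        pick <- sample(nb, 1L)
        pseudo[i] <- pick
        sets[[i]] <- setdiff(nb, pick)
      }
      names(sets) <- pseudo
      if (anyDuplicated(pseudo)) {
        # two focals drew the same neighbor: keep ids unique by redrawing
        # within the replicate where possible
        for (i in which(duplicated(pseudo))) {
          nb <- setdiff(config$neighbor_sets[[focals[i]]], pseudo)
          if (length(nb) > 0) {
            pseudo[i] <- sample(nb, 1L)
            sets[[i]] <- setdiff(config$neighbor_sets[[focals[i]]], pseudo[i])
          }
        }
        names(sets) <- pseudo
        keep <- !duplicated(pseudo)
        pseudo <- pseudo[keep]
        sets <- sets[keep]
      }
      # a pseudo-focal may sit in another pseudo-focal's set: remove, and
      # drop focals left with nothing to subtract
      sets <- lapply(sets, setdiff, y = pseudo)
      keep <- lengths(sets) > 0
      pseudo <- pseudo[keep]
      sets <- sets[keep]
      cfg <- scan_config(pseudo, sets,
                         reference_ids = config$reference_ids,
                         bin = config$bin, q = config$q,
                         n_null_replicates = 0L,
                         neighbor_method = config$neighbor_method,
                         allow_focal_in_references = TRUE)
      subtract_accumulate(S, cfg)
    })
  })
}
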