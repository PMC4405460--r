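# Build a sharing_matrix-like object directly from a pop x pop matrix so
# scan arithmetic can be hand-checked.
as_sharing <- function(M, n) {
  S <- array(M, dim = c(nrow(M), ncol(M), 1),
             dimnames = list(rownames(M), colnames(M), "1-2"))
  structure(S, sample_sizes = n, bins = length_bins(1:2),
            class = c("sharing_matrix", class(S)))
}

test_that("sharing vector projects rows and respects reference order", {
  ids <- c("A", "B", "X", "Y", "Z")
  M <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  n <- stats::setNames(rep(10L, 5), ids)
  S <- as_sharing(M, n)
  v <- sharing_vector(S, "A", c("X", "Y", "Z"))
  expect_equal(v, M["A", c("X", "Y", "Z")])
  # singleton set equals the single population's vector
  expect_equal(sharing_vector(S, c("B"), c("X", "Y")),
               sharing_vector(S, "B", c("X", "Y")))
  # permuted reference order permutes the vector identically
  expect_equal(sharing_vector(S, "A", c("Z", "X", "Y")),
               v[c("Z", "X", "Y")])
  expect_error(sharing_vector(S, "A", character(0)), "non-empty")
})

test_that("pooled neighbor vector is the sample-size-weighted pair average", {
  ids <- c("N1", "N2", "R")
  M <- matrix(0, 3, 3, dimnames = list(ids, ids))
  M["N1", "R"] <- M["R", "N1"] <- 2
  M["N2", "R"] <- M["R", "N2"] <- 4
  n <- c(N1 = 10L, N2 = 30L, R = 5L)
  S <- as_sharing(M, n)
  # pooled: (2*10*5 + 4*30*5) / (40*5) = 700/200 = 3.5
  expect_equal(unname(sharing_vector(S, c("N1", "N2"), "R")), 3.5)
  # average variant: (2 + 4)/2 = 3
  expect_equal(unname(sharing_vector(S, c("N1", "N2"), "R",
                                     method = "average")), 3)
})

test_that("type-7 quantile flagging uses strict inequality", {
  v <- stats::setNames(as.numeric(0:9), letters[1:10])
  fl <- flag_quantile(v, 0.90)
  expect_equal(fl$threshold, 8.1)
  expect_equal(fl$flagged, "j")
  # all equal: nothing exceeds the threshold
  expect_equal(flag_quantile(stats::setNames(rep(2, 6), letters[1:6]))$flagged,
               character(0))
  # q = 1: the max cannot exceed itself
  expect_equal(flag_quantile(v, 1.0)$flagged, character(0))
  expect_error(flag_quantile(v[1:4]), "at least 5")
})

test_that("subtract-accumulate matches hand-computed differences", {
  ids <- c("F1", "F2", "F3", "n1", "n2", "n3",
           "R1", "R2", "R3", "R4", "R5")
  set.seed(21)
  M <- matrix(runif(121, 0.1, 1), 11, 11, dimnames = list(ids, ids))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  n <- stats::setNames(rep(10L, 11), ids)
  S <- as_sharing(M, n)
  refs <- c("R1", "R2", "R3", "R4", "R5")
  nbs <- list(F1 = "n1", F2 = "n2", F3 = "n3")
  cfg <- scan_config(c("F1", "F2", "F3"), nbs, reference_ids = refs)
  res <- subtract_accumulate(S, cfg)
  manual <- (M["F1", refs] - M["n1", refs]) +
    (M["F2", refs] - M["n2", refs]) + (M["F3", refs] - M["n3", refs])
  expect_equal(res$accumulated, manual)
  # invariant: row sums of the diffs matrix reproduce the accumulation
  expect_equal(colSums(res$diffs), res$accumulated)
  # flags agree with flag_quantile
  expect_equal(res$flagged, flag_quantile(manual, 0.9)$flagged)
})

test_that("adding a constant to all sharing values leaves A unchanged", {
  ids <- c("F1", "F2", "n1", "n2", "R1", "R2", "R3", "R4", "R5")
  set.seed(31)
  M <- matrix(runif(81, 0.1, 1), 9, 9, dimnames = list(ids, ids))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  n <- stats::setNames(rep(10L, 9), ids)
  cfg <- scan_config(c("F1", "F2"), list(F1 = "n1", F2 = "n2"),
                     reference_ids = c("R1", "R2", "R3", "R4", "R5"))
  a1 <- subtract_accumulate(as_sharing(M, n), cfg)$accumulated
  a2 <- subtract_accumulate(as_sharing(M + 5, n), cfg)$accumulated
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("scan config validates focal/reference overlap and neighbor sets", {
  expect_error(scan_config("F", list(F = character(0))), "empty")
  expect_error(scan_config("F", list(F = "N"), reference_ids = c("F", "R")),
               "overlap")
  expect_warning(scan_config(c("F1", "F2"), list(F1 = c("F2", "N"),
                                                 F2 = "N2")),
                 "removed")
})

test_that("injected source is flagged with A close to n_focal * delta", {
  sim <- make_injected_network(delta = 2, n_per_pop = 25L, seed = 101)
  S <- sharing_matrix(sim$segments, sim$pops, length_bins(1:2),
                      sim$sample_sizes)
  cfg <- scan_config(sim$focal, sim$neighbor_sets, seed = 7,
                     n_null_replicates = 10L)
  res <- subtract_accumulate(S, cfg)
  expect_true("SRC" %in% res$flagged)
  expect_equal(unname(res$accumulated["SRC"]), 12 * 2, tolerance = 0.15)
  # null replicates: the pseudo-focals carry no injected signal, so SRC
  # drops back into the pack
  nulls <- null_scan_replicates(S, cfg)
  expect_length(nulls, 10)
  expect_lt(mean(vapply(nulls, function(r) "SRC" %in% r$flagged,
                        logical(1))), 0.3 + 1e-9)
})

test_that("null replicates are deterministic given the seed and empty at 0", {
  sim <- make_injected_network(delta = 0, n_per_pop = 8L, seed = 55,
                               pops = make_scan_world(4, 6, seed = 3))
  S <- suppressMessages(sharing_matrix(sim$segments, sim$pops,
                                       length_bins(1:2), sim$sample_sizes))
  cfg <- scan_config(sim$focal, sim$neighbor_sets, seed = 42,
                     n_null_replicates = 5L)
  n1 <- null_scan_replicates(S, cfg)
  n2 <- null_scan_replicates(S, cfg)
  expect_equal(lapply(n1, `[[`, "accumulated"),
               lapply(n2, `[[`, "accumulated"))
  cfg0 <- scan_config(sim$focal, sim$neighbor_sets, seed = 42,
                      n_null_replicates = 0L)
  expect_equal(null_scan_replicates(S, cfg0), list())
})

test_that("exchangeable focals yield near-centered accumulated values", {
  # focals and neighbors generated identically: A_ref should be centered
  # at 0 for every reference across null replicates
  sim <- make_injected_network(delta = 0, n_per_pop = 15L, seed = 77)
  S <- sharing_matrix(sim$segments, sim$pops, length_bins(1:2),
                      sim$sample_sizes)
  cfg <- scan_config(sim$focal, sim$neighbor_sets, seed = 9,
                     n_null_replicates = 50L)
  nulls <- null_scan_replicates(S, cfg)
  A <- do.call(rbind, lapply(nulls, `[[`, "accumulated"))
  ref_mean <- colMeans(A)
  ref_se <- apply(A, 2, stats::sd) / sqrt(nrow(A))
  expect_gt(mean(abs(ref_mean) <= 2 * ref_se + 1e-12), 0.8)
  # and no reference is flagged in more than 30% of replicates
  flag_freq <- colMeans(do.call(rbind, lapply(nulls, function(r) {
    stats::setNames(names(r$accumulated) %in% r$flagged,
                    names(r$accumulated))
  })))
  expect_lt(max(flag_freq), 0.30 + 1e-9)
})
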