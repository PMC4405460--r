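# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A small world for scan tests: n_focal focal populations each with its own
# trio of nearby neighbors, n_extra scattered references, and one source
# population SRC in the east.
make_scan_world <- function(n_focal = 12, n_extra = 15, seed = 1) {
  set.seed(seed)
  ids <- c(); lat <- c(); lon <- c(); grp <- c(); nbs <- list()
  for (i in seq_len(n_focal)) {
    f <- sprintf("F%02d", i)
    base_lat <- runif(1, 35, 55); base_lon <- runif(1, 0, 90)
    nb <- sprintf("N%02d_%d", i, 1:3)
    ids <- c(ids, f, nb)
    lat <- c(lat, base_lat + runif(4, -1, 1))
    lon <- c(lon, base_lon + runif(4, -1, 1))
    grp <- c(grp, "focal", rep("neighbor", 3))
    nbs[[f]] <- nb
  }
  ex <- sprintf("R%02d", seq_len(n_extra))
  ids <- c(ids, ex, "SRC")
  lat <- c(lat, runif(n_extra, 30, 60), 50)
  lon <- c(lon, runif(n_extra, 0, 100), 100)
  grp <- c(grp, rep("reference", n_extra), "source")
  ns <- rep(list(character(0)), length(ids)); names(ns) <- ids
  for (f in names(nbs)) ns[[f]] <- nbs[[f]]
  pop_table(ids, lat, lon, group = grp, neighbor_set = unname(ns[ids]))
}

# Simulated sharing network with an injected SRC -> focal excess.
make_injected_network <- function(delta = 2, n_per_pop = 25L, seed = 11,
                                  pops = make_scan_world()) {
  n <- stats::setNames(rep(n_per_pop, nrow(pops)), pops$population_id)
  foc <- pops$population_id[pops$group == "focal"]
  gf <- if (delta > 0) data.frame(source = "SRC", recipient = foc,
                                  delta = delta) else NULL
  cfg <- sharing_sim_config(pops, n, beta = 0.5, lambda_km = 1500,
                            gene_flow = gf, bins = length_bins(1:2),
                            seed = seed)
  sim <- simulate_sharing_network(cfg)
  sim$pops <- pops
  sim$focal <- foc
  sim$neighbor_sets <- stats::setNames(pops$neighbor_set,
                                       pops$population_id)[foc]
  sim
}

# Tiny deterministic segment table for hand-checked statistics.
make_hand_segments <- function() {
  ibd_segments(
    sample_a = c("a1", "a1", "a2", "b1", "a1"),
    sample_b = c("b1", "b2", "b3", "b2", "a2"),
    population_a = c("A", "A", "A", "B", "A"),
    population_b = c("B", "B", "B", "B", "A"),
    chromosome = "1",
    start_cM = c(10, 20, 30, 40, 50),
    end_cM = c(11.5, 21.2, 34.5, 41.9, 51.1))
}

# Exchangeable-null permutation world: focal + 6 identical neighbor
# populations + source, all at the same coordinates.
make_null_perm_world <- function() {
  nb <- sprintf("N%d", 1:6)
  pops <- pop_table(c("FOC", nb, "SRC"), latitude = rep(50, 8),
                    longitude = rep(40, 8),
                    neighbor_set = c(list(nb), rep(list(character(0)), 7)))
  n <- stats::setNames(c(10L, rep(80L, 6), 10L), pops$population_id)
  list(pops = pops, n = n, neighbors = nb)
}

run_null_perm_pvalue <- function(seed, world = make_null_perm_world(),
                                 n_perm = 1000L) {
  cfg <- sharing_sim_config(world$pops, world$n, beta = 0.35,
                            lambda_km = 1500, bins = length_bins(1:2),
                            seed = seed)
  sim <- simulate_sharing_network(cfg)
  excess_sharing_pvalue(sim$segments, sim$sample_map, "FOC", "SRC",
                        world$neighbors, bin = 1L, bins = length_bins(1:2),
                        n_perm = n_perm, seed = seed + 1L)$p_value
}

# Independent loop-based f3 + weighted block jackknife oracle, computed
# directly from a dosage matrix. Used to cross-check f3_statistic.
f3_oracle <- function(dosage, pop_of, target, s1, s2, chromosome, pos_cM,
                      block_cM = 5) {
  freq <- function(p, j) {
    x <- dosage[pop_of == p, j]
    x <- x[!is.na(x)]
    list(f = sum(x) / (2 * length(x)), n = 2 * length(x))
  }
  n_snp <- ncol(dosage)
  summand <- numeric(n_snp)
  use <- logical(n_snp)
  for (j in seq_len(n_snp)) {
    a <- freq(s1, j); b <- freq(s2, j); cc <- freq(target, j)
    if (a$n < 2 || b$n < 2 || cc$n < 2 || is.na(pos_cM[j])) next
    if (a$f == b$f && b$f == cc$f && (cc$f == 0 || cc$f == 1)) next
    use[j] <- TRUE
    summand[j] <- (cc$f - a$f) * (cc$f - b$f) -
      cc$f * (1 - cc$f) / (cc$n - 1)
  }
  s <- summand[use]
  chr <- chromosome[use]; cm <- pos_cM[use]
  # block labels: contiguous block_cM windows per chromosome
  lab <- character(length(s))
  for (ch in unique(chr)) {
    i <- chr == ch
    lab[i] <- paste(ch, floor((cm[i] - min(cm[i])) / block_cM))
  }
  blocks <- unique(lab)
  m <- length(blocks)
  n <- length(s)
  est <- mean(s)
  theta_mj <- numeric(m); bn <- numeric(m)
  for (k in seq_len(m)) {
    out <- lab == blocks[k]
    theta_mj[k] <- mean(s[!out])
    bn[k] <- sum(out)
  }
  h <- n / bn
  theta_J <- m * est - sum((1 - bn / n) * theta_mj)
  tau <- h * est - (h - 1) * theta_mj
  se <- sqrt(mean((tau - theta_J)^2 / (h - 1)))
  list(f3 = est, se = se, n_blocks = m, n_snps = n)
}
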