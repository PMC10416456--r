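## Shared fixtures, built in code. The small simulated study is cached per
## session so several test files can reuse it.

STG <- m6a_stages()

## Three hand-made genes on two chromosomes (0-based half-open).
tiny_annotation <- function() {
  tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~tx_start, ~tx_end, ~cds_start, ~cds_end,
    "geneA", "chr1", "+", 0L, 1000L, 50L, 500L,
    "geneB", "chr1", "+", 2000L, 5000L, 2500L, 4000L,
    "geneC", "chr2", "-", 100L, 3100L, 1100L, 2100L)
}

## stage_counts from plain matrices (equal libsizes unless given).
tiny_counts <- function(ip, input, lib_ip = NULL, lib_input = NULL) {
  ids <- rownames(ip) %||% paste0("p", seq_len(nrow(ip)))
  as_keyed <- function(m) {
    tb <- tibble::as_tibble(m, .name_repair = "minimal")
    names(tb) <- STG
    tb$peak_id <- ids
    tb[, c("peak_id", STG)]
  }
  eq <- stats::setNames(rep(1e6, 4), STG)
  stage_counts(as_keyed(ip), as_keyed(input),
               ip_libsize = lib_ip %||% eq, input_libsize = lib_input %||% eq)
}

`%||%` <- rlang::`%||%`

## A small but complete simulated study, shared across test files.
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_study(
      sim_config(n_genes = 300, n_peaks = 450, n_targets = 20, seed = 101))
  }
  .sim_cache$sim
}
## The default-scale study (2000 genes, 60 targets per regulator, seed 7),
## used by the acceptance checks.
shared_default_sim <- function() {
  if (is.null(.sim_cache$default_sim)) {
    .sim_cache$default_sim <- simulate_study(sim_config(seed = 7))
  }
  .sim_cache$default_sim
}
shared_default_profile <- function() {
  if (is.null(.sim_cache$default_profile)) {
    sim <- shared_default_sim()
    .sim_cache$default_profile <-
      suppressMessages(m6a_profile(sim$counts, sim$peaks))
  }
  .sim_cache$default_profile
}

shared_profile <- function() {
  if (is.null(.sim_cache$profile)) {
    sim <- shared_sim()
    .sim_cache$profile <- suppressMessages(m6a_profile(sim$counts, sim$peaks))
  }
  .sim_cache$profile
}

## ---- independent oracles -------------------------------------------------

## Exhaustive hypergeometric upper tail: enumerate all subsets of the
## universe of size |A| and count how often the overlap with B reaches k.
hyper_tail_enum <- function(n_universe, n_a, n_b, k) {
  u <- seq_len(n_universe)
  b <- seq_len(n_b)
  subsets <- utils::combn(u, n_a)
  ov <- apply(subsets, 2, function(s) length(intersect(s, b)))
  mean(ov >= k)
}

## Exact two-sided Mann-Whitney p by enumeration of all group assignments,
## using the same two-sided convention as the implementation under test.
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(s) sum(rk[s]) - n1 * (n1 + 1) / 2)
  p <- if (u_obs > n1 * n2 / 2) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p, 1)
}

## Sliding-window DRACH count (overlapping), independent of Biostrings.
drach_count_enum <- function(seq) {
  if (nchar(seq) < 5) return(0L)
  n <- 0L
  for (i in seq_len(nchar(seq) - 4L)) {
    w <- substr(seq, i, i + 4L)
    if (grepl("^[AGT][AG]AC[ACT]$", w)) n <- n + 1L
  }
  n
}

## Adjusted Rand index (for cluster recovery) via mclust.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
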