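## Per-peak m6A dynamics: differential transitions, modified calls, origin
## stages, change-count classes, dynamic genes, k-means trajectory clusters,
## expression dispersion scores, and the hypergeometric overlap test.

## Pearson chi-square without continuity correction on 2x2 tables given as
## columns a,b,c,d = [[a,b],[c,d]] (vectorized).
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

min_expected_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  pmin((a + b) * (a + c), (a + b) * (b + d),
       (c + d) * (a + c), (c + d) * (b + d)) / n
}

#' Differential m6A peaks between consecutive stages
#'
#' For each retained peak and each consecutive transition, computes the
#' symmetric fold change of the normalized m6A level (max/min, direction
#' free) and a Pearson chi-square p-value (no continuity correction) on the
#' 2x2 coverage table `[[ip1, input1], [ip2, input2]]`. Counts enter the
#' table normalized to a common sequencing depth (each of the four
#' libraries scaled to the smallest one involved), so stage-specific
#' library-size ratios cannot masquerade as, or mask, a change in the
#' IP:input proportion; scaling down only ever makes the test
#' conservative. A transition is differential when both the fold change
#' exceeds `fc_threshold` and `p < alpha`. Tables with a minimum expected
#' cell below 1 are flagged `low_count` and tested by Fisher's exact
#' enumeration instead. A Benjamini-Hochberg adjusted column is emitted for
#' reference but is not used by the differential call.
#'
#' @param counts A filtered [stage_counts()] object.
#' @param fc_threshold Fold-change threshold (default 1.2, strict `>`).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per peak and transition: `peak_id`,
#'   `transition`, `fold_change`, `p`, `padj`, `low_count`, `differential`.
#' @export
differential_peaks <- function(counts, fc_threshold = 1.2, alpha = 0.05) {
  lv <- stage_matrix(peak_levels(counts), "peak_id")
  ip <- stage_matrix(counts$ip, "peak_id")
  input <- stage_matrix(counts$input, "peak_id")
  ip_lib <- as.numeric(counts$ip_libsize[STAGES])
  in_lib <- as.numeric(counts$input_libsize[STAGES])
  out <- purrr::map_dfr(1:3, function(t) {
    s1 <- STAGES[t]; s2 <- STAGES[t + 1]
    r1 <- lv[, s1]; r2 <- lv[, s2]
    fc <- sym_fc(r2 / r1)
    ## depth-normalize the four cells to the smallest involved library
    u <- min(ip_lib[t], ip_lib[t + 1], in_lib[t], in_lib[t + 1])
    a <- ip[, s1] * (u / ip_lib[t]); b <- input[, s1] * (u / in_lib[t])
    c <- ip[, s2] * (u / ip_lib[t + 1]); d <- input[, s2] * (u / in_lib[t + 1])
    cs <- chisq_2x2(a, b, c, d)
    low <- min_expected_2x2(a, b, c, d) < 1
    p <- cs$p
    for (i in which(low)) {
      p[i] <- fisher.test(matrix(round(c(a[i], b[i], c[i], d[i])), 2,
                                 byrow = TRUE))$p.value
    }
    tibble(peak_id = rownames(lv), transition = TRANSITIONS[t],
           fold_change = unname(fc), p = unname(p), low_count = unname(low))
  })
  out %>%
    group_by(.data$transition) %>%
    mutate(padj = p.adjust(.data$p, method = "BH")) %>%
    ungroup() %>%
    mutate(differential = .data$fold_change > fc_threshold & .data$p < alpha) %>%
    select("peak_id", "transition", "fold_change", "p", "padj",
           "low_count", "differential")
}

#' Call per-stage modified status
#'
#' A peak (or gene) is modified at a stage when its m6A level strictly
#' exceeds `threshold`.
#'
#' @param levels Keyed level tibble (first column id, then stages).
#' @param threshold Modified threshold on the IP/input ratio (default 1.5).
#' @return Tibble of logical flags with the same shape.
#' @export
call_modified <- function(levels, threshold = 1.5) {
  key <- names(levels)[1]
  m <- stage_matrix(levels, key)
  out <- as_tibble(m > threshold)
  out[[key]] <- rownames(m)
  out[, c(key, STAGES)]
}

#' Origin stage of each peak
#'
#' The earliest stage at which the peak is modified, or `"never"`.
#'
#' @param modified Tibble of per-stage logical flags (from
#'   [call_modified()]).
#' @return Tibble with the id column and `origin`.
#' @export
peak_origin <- function(modified) {
  key <- names(modified)[1]
  m <- as.matrix(modified[, STAGES])
  first <- apply(m, 1, function(x) if (any(x)) which(x)[1] else 5L)
  tibble(!!key := modified[[key]], origin = c(STAGES, "never")[first])
}

#' Change-count classes over the three transitions
#'
#' Counts, per peak, how many of the three consecutive transitions were
#' called differential, and summarizes the fractions of peaks changing
#' zero, one, two or three times.
#'
#' @param differential Output of [differential_peaks()] (or any tibble with
#'   `peak_id`, `transition`, `differential`).
#' @return List with `peaks` (tibble `peak_id`, `change_count`) and
#'   `summary` (tibble `change_count`, `n`, `fraction`; fractions sum to 1).
#' @export
change_classes <- function(differential) {
  pk <- differential %>%
    group_by(.data$peak_id) %>%
    summarise(change_count = sum(.data$differential), .groups = "drop")
  summ <- tibble(change_count = 0:3) %>%
    left_join(pk %>% dplyr::count(.data$change_count), by = "change_count") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = .data$n / sum(.data$n))
  list(peaks = pk, summary = summ)
}

#' Dynamic m6A genes
#'
#' Genes whose pooled m6A level shows a symmetric fold change above
#' `fc_threshold` in at least one consecutive transition.
#'
#' @param gene_level Gene-by-stage level tibble.
#' @param fc_threshold Fold-change threshold (default 1.2, strict `>`).
#' @return Character vector of dynamic gene ids.
#' @export
dynamic_genes <- function(gene_level, fc_threshold = 1.2) {
  m <- stage_matrix(gene_level, "gene_id")
  fc <- sym_fc(transition_ratios(m))
  rownames(m)[apply(fc > fc_threshold, 1, any)]
}

#' Cluster m6A trajectories by k-means
#'
#' Rows are z-scored across the stages and clustered with k-means++
#' initialization and `n_restarts` restarts under a fixed seed. Rows with
#' zero variance cannot be z-scored; they are flagged and assigned to the
#' cluster whose centroid of unscaled member profiles is nearest.
#'
#' @param peak_level Peak-by-stage level tibble.
#' @param k Number of clusters (default 8).
#' @param seed Integer seed making the clustering reproducible.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return List with `clusters` (tibble `peak_id`, `cluster`, `flagged`),
#'   `centers` (z-score space) and `tot_withinss`.
#' @export
cluster_profiles <- function(peak_level, k = 8, seed = 1, n_restarts = 10) {
  m <- stage_matrix(peak_level, "peak_id")
  if (nrow(m) < k) abort("need at least k peaks to form k clusters")
  rs <- apply(m, 1, sd)
  const <- rs == 0
  z <- t(scale(t(m[!const, , drop = FALSE])))
  if (sum(!const) < k) abort("fewer non-constant profiles than clusters")

  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- if (k == 1) {
        z[sample.int(nrow(z), 1), , drop = FALSE]
      } else {
        kmeanspp_init(z, k)
      }
      km <- suppressWarnings(kmeans(z, centers = centers, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })

  cluster <- integer(nrow(m))
  cluster[!const] <- fit$cluster
  if (any(const)) {
    ## centroids of unscaled member profiles
    cent_raw <- rowsum(m[!const, , drop = FALSE], fit$cluster)
    cent_raw <- cent_raw / as.numeric(table(fit$cluster)[rownames(cent_raw)])
    for (i in which(const)) {
      d <- rowSums(sweep(cent_raw, 2, m[i, ])^2)
      cluster[i] <- as.integer(rownames(cent_raw)[which.min(d)])
    }
  }
  list(clusters = tibble(peak_id = rownames(m), cluster = cluster,
                         flagged = const),
       centers = fit$centers, tot_withinss = fit$tot.withinss)
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE] + matrix(rnorm(k * ncol(x), 0, 1e-9), k)
}

#' Expression dispersion scores
#'
#' The dispersion score of a gene is the sample standard deviation
#' (denominator n-1) of `log2(expression + 1)` across the four stages.
#'
#' @param expression Gene-by-stage expression tibble.
#' @return Tibble with `gene_id` and `dispersion`, sorted decreasing.
#' @export
dispersion_scores <- function(expression) {
  m <- log2(stage_matrix(expression, "gene_id") + 1)
  tibble(gene_id = rownames(m), dispersion = unname(apply(m, 1, sd))) %>%
    arrange(desc(.data$dispersion))
}

#' One-tailed hypergeometric overlap test
#'
#' Tests whether the overlap of two gene sets drawn from a common universe
#' is larger than expected: `p = P(X >= overlap)` with
#' `X ~ Hypergeometric(|U|, |A|, |B|)`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of the background gene universe.
#' @return List with `overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("empty universe")
  a <- intersect(unique(set_a), universe)
  b <- intersect(unique(set_b), universe)
  ov <- length(intersect(a, b))
  p <- phyper(ov - 1, length(a), length(universe) - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = ov, n_a = length(a), n_b = length(b),
       n_universe = length(universe), p = p)
}

#' Per-peak dynamics summary
#'
#' Convenience wrapper combining [differential_peaks()], [call_modified()],
#' [peak_origin()] and [change_classes()] on a quantification profile.
#'
#' @param profile An [m6a_profile()] object.
#' @param fc_threshold,alpha,mod_threshold Thresholds, see the individual
#'   functions.
#' @param fc_only If `TRUE`, a transition is called on fold change alone,
#'   without the chi-square condition (the noiseless classification rule).
#' @return A `peak_dynamics` object: list with `transitions`, `peaks`
#'   (per-peak `change_count`, `origin`), `summary` (class fractions) and
#'   `origin_summary`.
#' @export
peak_dynamics <- function(profile, fc_threshold = 1.2, alpha = 0.05,
                          mod_threshold = 1.5, fc_only = FALSE) {
  diff <- differential_peaks(profile$counts, fc_threshold = fc_threshold,
                             alpha = alpha)
  if (fc_only) diff$differential <- diff$fold_change > fc_threshold
  cls <- change_classes(diff)
  mod <- call_modified(profile$peak_level, threshold = mod_threshold)
  org <- peak_origin(mod)
  peaks <- cls$peaks %>% left_join(org, by = "peak_id")
  org_summary <- peaks %>%
    dplyr::count(.data$origin) %>%
    mutate(fraction = .data$n / sum(.data$n))
  structure(list(transitions = diff, peaks = peaks, summary = cls$summary,
                 origin_summary = org_summary,
                 params = list(fc_threshold = fc_threshold, alpha = alpha,
                               mod_threshold = mod_threshold, fc_only = fc_only)),
            class = "peak_dynamics")
}

#' Noiseless dynamics labels from a trajectory table
#'
#' Applies the fold-change classification rule directly to (noise-free)
#' level trajectories: change counts from symmetric fold changes and origin
#' stages from the modified threshold. Used for planted-truth comparisons.
#'
#' @param levels Keyed level tibble (peak or gene by stage).
#' @param fc_threshold,mod_threshold Classification thresholds.
#' @return Tibble with the id column, `change_count` and `origin`.
#' @export
dynamics_from_levels <- function(levels, fc_threshold = 1.2,
                                 mod_threshold = 1.5) {
  key <- names(levels)[1]
  m <- stage_matrix(levels, key)
  fc <- sym_fc(transition_ratios(m))
  mod <- m > mod_threshold
  first <- apply(mod, 1, function(x) if (any(x)) which(x)[1] else 5L)
  tibble(!!key := rownames(m),
         change_count = rowSums(fc > fc_threshold),
         origin = c(STAGES, "never")[first])
}

#' @export
print.peak_dynamics <- function(x, ...) {
  cat("<peak_dynamics> ", nrow(x$peaks), " peaks\n", sep = "")
  fr <- x$summary
  cat("change classes: ",
      paste0(fr$change_count, "x=", sprintf("%.1f%%", 100 * fr$fraction),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}
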