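## Integration of gene-level chromatin accessibility (and TF binding) with
## m6A: group comparisons, the five-category co-dynamics classification,
## PCC-binned change analysis, and stage overlaps.

#' Wilcoxon rank-sum test wrapper
#'
#' Two-sided Mann-Whitney test: exact when the smaller group has at most 20
#' observations and the data are tie-free, normal approximation with tie
#' correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U of `x`), `p` and `exact` (logical).
#' @export
rank_sum_test <- function(x, y) {
  use_exact <- min(length(x), length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Accessibility of target genes versus random and all genes
#'
#' Per stage, compares the accessibility of the target genes against all
#' genes and against a size-matched random control (sampled without
#' replacement under a fixed seed), with two-sided rank-sum tests.
#'
#' @param accessibility Gene-by-stage accessibility tibble.
#' @param targets Character vector of target gene ids (subset of the
#'   accessibility rows).
#' @param seed Seed for the random control.
#' @return Tibble with per-stage medians of the three groups and p-values
#'   `p_vs_all`, `p_vs_random`; the control gene set is attached as
#'   attribute `random_genes`. Empty (with a warning) when fewer than 3
#'   targets are available.
#' @export
compare_target_accessibility <- function(accessibility, targets, seed = 1) {
  acc <- stage_matrix(accessibility, "gene_id")
  targets <- intersect(targets, rownames(acc))
  if (length(targets) < 3) {
    warn("fewer than 3 target genes with accessibility; comparison skipped")
    return(tibble(stage = character(0), median_target = double(0),
                  median_random = double(0), median_all = double(0),
                  p_vs_all = double(0), p_vs_random = double(0)))
  }
  random_genes <- withr::with_seed(
    seed, sample_safe(rownames(acc), length(targets)))
  out <- purrr::map_dfr(STAGES, function(s) {
    tv <- acc[targets, s]; rv <- acc[random_genes, s]; av <- acc[, s]
    tibble(stage = s,
           median_target = median(tv), median_random = median(rv),
           median_all = median(av),
           p_vs_all = rank_sum_test(tv, av)$p,
           p_vs_random = rank_sum_test(tv, rv)$p)
  })
  attr(out, "random_genes") <- random_genes
  out
}

#' Split genes into accessibility groups
#'
#' Per stage, ranks genes by accessibility and splits them into the top
#' `frac` (`high10`), bottom `frac` (`low10`) and the remainder (`mid`),
#' with floor-sized extreme groups and deterministic tie-breaking by
#' `gene_id`.
#'
#' @param accessibility Gene-by-stage accessibility tibble.
#' @param frac Fraction in each extreme group (default 0.1).
#' @return Tibble with `gene_id`, `stage`, `group`.
#' @export
accessibility_groups <- function(accessibility, frac = 0.1) {
  acc <- stage_matrix(accessibility, "gene_id")
  k <- floor(frac * nrow(acc))
  purrr::map_dfr(STAGES, function(s) {
    ord <- order(-acc[, s], rownames(acc))
    grp <- rep("mid", nrow(acc))
    grp[ord[seq_len(k)]] <- "high10"
    grp[ord[seq(nrow(acc) - k + 1, nrow(acc))]] <- "low10"
    tibble(gene_id = rownames(acc), stage = s, group = grp)
  })
}

#' m6A levels across accessibility groups
#'
#' Per stage, reports the median m6A level of the low/mid/high accessibility
#' groups and pairwise two-sided rank-sum p-values between them.
#'
#' @param accessibility Gene-by-stage accessibility tibble.
#' @param gene_level Gene-by-stage m6A level tibble (common genes used).
#' @param frac Extreme group fraction, see [accessibility_groups()].
#' @return List with `medians` (stage x group) and `tests` (pairwise
#'   p-values per stage).
#' @export
m6a_by_accessibility_group <- function(accessibility, gene_level, frac = 0.1) {
  common <- intersect(accessibility$gene_id, gene_level$gene_id)
  if (length(common) < 10) abort("too few genes shared by the two matrices")
  acc <- accessibility[match(common, accessibility$gene_id), ]
  gl <- stage_matrix(gene_level[match(common, gene_level$gene_id), ], "gene_id")
  groups <- accessibility_groups(acc, frac = frac)
  medians <- groups %>%
    mutate(m6a = gl[cbind(.data$gene_id, .data$stage)]) %>%
    group_by(.data$stage, .data$group) %>%
    summarise(n = dplyr::n(), median_m6a = median(.data$m6a), .groups = "drop")
  pairs <- list(c("low10", "mid"), c("mid", "high10"), c("low10", "high10"))
  tests <- purrr::map_dfr(STAGES, function(s) {
    g <- groups %>% filter(.data$stage == s)
    purrr::map_dfr(pairs, function(pr) {
      x <- gl[g$gene_id[g$group == pr[1]], s]
      y <- gl[g$gene_id[g$group == pr[2]], s]
      tibble(stage = s, group1 = pr[1], group2 = pr[2],
             p = rank_sum_test(x, y)$p)
    })
  })
  list(medians = medians, tests = tests, groups = groups)
}

#' Accessibility of modified versus unmodified genes
#'
#' Per stage, rank-sum comparison of accessibility between genes with and
#' without the m6A modification call.
#'
#' @param modified Tibble of per-stage logical modified flags (from
#'   [call_modified()] on gene levels), keyed by `gene_id`.
#' @param accessibility Gene-by-stage accessibility tibble.
#' @return Tibble with per-stage group medians and `p`.
#' @export
accessibility_by_modification <- function(modified, accessibility) {
  common <- intersect(modified$gene_id, accessibility$gene_id)
  acc <- stage_matrix(accessibility[match(common, accessibility$gene_id), ],
                      "gene_id")
  mod <- as.matrix(modified[match(common, modified$gene_id), STAGES])
  purrr::map_dfr(STAGES, function(s) {
    m <- mod[, s]
    if (all(m) || all(!m)) {
      abort(paste0("stage ", s, ": one modification group is empty"))
    }
    tibble(stage = s,
           median_modified = median(acc[m, s]),
           median_unmodified = median(acc[!m, s]),
           p = rank_sum_test(acc[m, s], acc[!m, s])$p)
  })
}

#' Five-category m6A/accessibility co-dynamics classification
#'
#' A signal "changes" when any consecutive symmetric fold change exceeds
#' `fc_threshold`. Whole-trajectory categories: (1) neither signal changes;
#' (2) only accessibility; (3) only m6A; both change and the Pearson
#' correlation of the two 3-length change-ratio vectors is negative (4,
#' discordant) or positive (5, concordant); a zero or undefined correlation
#' falls into 4 with a flag. Per-transition window labels apply the same
#' scheme to each single transition (4/5 decided by the direction signs).
#'
#' @param gene_level Gene-by-stage m6A level tibble.
#' @param accessibility Gene-by-stage accessibility tibble.
#' @param fc_threshold Change threshold on the symmetric fold change
#'   (default 1.2).
#' @return An `m6a_codynamics` object: list with `genes` (tibble `gene_id`,
#'   `category`, `flagged`), `windows` (tibble `gene_id`, `window`,
#'   `category`) and `summary` (category counts; a partition of the genes).
#' @export
co_dynamics <- function(gene_level, accessibility, fc_threshold = 1.2) {
  common <- intersect(gene_level$gene_id, accessibility$gene_id)
  gm <- stage_matrix(gene_level[match(common, gene_level$gene_id), ], "gene_id")
  am <- stage_matrix(accessibility[match(common, accessibility$gene_id), ],
                     "gene_id")
  rg <- transition_ratios(gm)
  ra <- transition_ratios(am)
  chg_g <- sym_fc(rg) > fc_threshold
  chg_a <- sym_fc(ra) > fc_threshold

  any_g <- apply(chg_g, 1, any)
  any_a <- apply(chg_a, 1, any)
  cat <- integer(length(common))
  flag <- logical(length(common))
  cat[!any_g & !any_a] <- 1L
  cat[!any_g & any_a] <- 2L
  cat[any_g & !any_a] <- 3L
  both <- which(any_g & any_a)
  for (i in both) {
    r <- pcc(rg[i, ], ra[i, ])
    if (is.na(r) || r == 0) {
      cat[i] <- 4L; flag[i] <- TRUE
    } else {
      cat[i] <- if (r > 0) 5L else 4L
    }
  }

  windows <- purrr::map_dfr(1:3, function(t) {
    wcat <- dplyr::case_when(
      !chg_g[, t] & !chg_a[, t] ~ 1L,
      !chg_g[, t] & chg_a[, t] ~ 2L,
      chg_g[, t] & !chg_a[, t] ~ 3L,
      (rg[, t] > 1) == (ra[, t] > 1) ~ 5L,
      TRUE ~ 4L)
    tibble(gene_id = common, window = TRANSITIONS[t], category = wcat)
  })

  summary <- tibble(category = 1:5) %>%
    left_join(tibble(category = cat) %>% dplyr::count(.data$category),
              by = "category") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L), fraction = .data$n / length(common))

  structure(list(genes = tibble(gene_id = common, category = cat, flagged = flag),
                 windows = windows, summary = summary),
            class = "m6a_codynamics")
}

#' @export
print.m6a_codynamics <- function(x, ...) {
  cat("<m6a_codynamics> ", nrow(x$genes), " genes\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' m6A change magnitude along the accessibility-correlation rank
#'
#' Genes are ranked by the Pearson correlation of their m6A level with
#' their accessibility over the four stages; the top and bottom 5% are
#' dropped and the remainder is split into 18 consecutive 5% bins (sizes
#' differing by at most one). Per bin and transition, the mean absolute
#' (symmetric) m6A fold change is reported.
#'
#' @param gene_level Gene-by-stage m6A level tibble.
#' @param accessibility Gene-by-stage accessibility tibble.
#' @param n_bins Number of bins after tail dropping (default 18).
#' @param drop_frac Tail fraction dropped at each end (default 0.05).
#' @return List with `bins` (tibble `bin`, `n`, `mean_pcc`, one row per bin
#'   and transition with `mean_abs_fc`) and `gene_pcc`.
#' @export
pcc_bins <- function(gene_level, accessibility, n_bins = 18, drop_frac = 0.05) {
  common <- intersect(gene_level$gene_id, accessibility$gene_id)
  gm <- stage_matrix(gene_level[match(common, gene_level$gene_id), ], "gene_id")
  am <- stage_matrix(accessibility[match(common, accessibility$gene_id), ],
                     "gene_id")
  r <- vapply(seq_along(common), function(i) pcc(gm[i, ], am[i, ]), double(1))
  keep <- !is.na(r)
  ids <- common[keep]; r <- r[keep]; gm <- gm[keep, , drop = FALSE]
  ord <- order(-r, ids)
  k <- floor(drop_frac * length(ord))
  mid <- ord[seq(k + 1, length(ord) - k)]
  n_mid <- length(mid)
  sizes <- rep(n_mid %/% n_bins, n_bins)
  extra <- n_mid %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin <- rep(seq_len(n_bins), sizes)

  fc <- sym_fc(transition_ratios(gm))
  per_bin <- purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- mid[bin == b]
    purrr::map_dfr(1:3, function(t) {
      tibble(bin = b, n = length(idx), mean_pcc = mean(r[idx]),
             transition = TRANSITIONS[t], mean_abs_fc = mean(fc[idx, t]))
    })
  })
  list(bins = per_bin,
       gene_pcc = tibble(gene_id = ids, r = r),
       dropped = 2 * k)
}

#' Category overlaps across transition windows
#'
#' For each co-dynamics category, the sizes of all window-set intersections
#' and the genes assigned to the category consistently in every window.
#'
#' @param windows Window label tibble from [co_dynamics()] (`gene_id`,
#'   `window`, `category`).
#' @return List with `counts` (tibble `category`, `windows`, `n`) and
#'   `consistent` (tibble `gene_id`, `category`).
#' @export
category_overlap <- function(windows) {
  wins <- unique(windows$window)
  cats <- sort(unique(windows$category))
  counts <- purrr::map_dfr(cats, function(cc) {
    sets <- lapply(wins, function(w) {
      windows$gene_id[windows$window == w & windows$category == cc]
    })
    names(sets) <- wins
    combos <- unlist(lapply(seq_along(wins), function(m) {
      utils::combn(wins, m, simplify = FALSE)
    }), recursive = FALSE)
    purrr::map_dfr(combos, function(cb) {
      tibble(category = cc, windows = paste(cb, collapse = "&"),
             n = length(Reduce(intersect, sets[cb])))
    })
  })
  consistent <- windows %>%
    group_by(.data$gene_id) %>%
    summarise(consistent = dplyr::n_distinct(.data$category) == 1,
              category = .data$category[1], .groups = "drop") %>%
    filter(.data$consistent) %>%
    select("gene_id", "category")
  list(counts = counts, consistent = consistent)
}

#' Compare empirical CDFs of m6A levels between gene groups
#'
#' @param values Tibble with `group`, `value` (at least 2 groups).
#' @return List with `curves` (per-group sorted values and cumulative
#'   fractions) and `tests` (pairwise two-sided rank-sum p-values).
#' @export
ecdf_compare <- function(values) {
  groups <- unique(values$group)
  if (length(groups) < 2) abort("need at least two groups")
  curves <- values %>%
    group_by(.data$group) %>%
    arrange(.data$value, .by_group = TRUE) %>%
    mutate(cum_fraction = row_number() / dplyr::n()) %>%
    ungroup()
  combos <- utils::combn(groups, 2, simplify = FALSE)
  tests <- purrr::map_dfr(combos, function(cb) {
    x <- values$value[values$group == cb[1]]
    y <- values$value[values$group == cb[2]]
    tibble(group1 = cb[1], group2 = cb[2], p = rank_sum_test(x, y)$p)
  })
  list(curves = curves, tests = tests)
}

#' m6A level groups (low / medium / high)
#'
#' Genes with a level below `low` are `low`, above `high` are `high`, and
#' `medium` otherwise.
#'
#' @param levels Numeric vector of m6A levels.
#' @param low,high Group thresholds (defaults 1.5 and 4).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
m6a_level_groups <- function(levels, low = 1.5, high = 4) {
  factor(dplyr::case_when(levels < low ~ "low",
                          levels > high ~ "high",
                          TRUE ~ "medium"),
         levels = c("low", "medium", "high"))
}

#' TF binding strength across m6A level groups
#'
#' Per transcription factor and stage, compares binding scores between the
#' low/medium/high m6A groups with pairwise rank-sum tests. Pairs with an
#' empty group are skipped with a warning.
#'
#' @param tf_binding Long tibble with `gene_id`, `tf`, `stage`, `score`.
#' @param gene_level Gene-by-stage m6A level tibble.
#' @param low,high m6A group thresholds, see [m6a_level_groups()].
#' @return List with `medians` and `tests` tibbles.
#' @export
tf_binding_by_m6a_group <- function(tf_binding, gene_level, low = 1.5, high = 4) {
  gl <- stage_matrix(gene_level, "gene_id")
  tb <- tf_binding %>%
    filter(.data$gene_id %in% rownames(gl), .data$stage %in% STAGES) %>%
    mutate(m6a_group = m6a_level_groups(gl[cbind(.data$gene_id, .data$stage)],
                                        low = low, high = high))
  medians <- tb %>%
    group_by(.data$tf, .data$stage, .data$m6a_group) %>%
    summarise(n = dplyr::n(), median_score = median(.data$score), .groups = "drop")
  pairs <- list(c("low", "medium"), c("medium", "high"), c("low", "high"))
  tests <- purrr::map_dfr(unique(tb$tf), function(tf1) {
    purrr::map_dfr(unique(tb$stage[tb$tf == tf1]), function(s) {
      sub <- tb %>% filter(.data$tf == tf1, .data$stage == s)
      purrr::map_dfr(pairs, function(pr) {
        x <- sub$score[sub$m6a_group == pr[1]]
        y <- sub$score[sub$m6a_group == pr[2]]
        if (length(x) == 0 || length(y) == 0) {
          warn(paste0("empty m6A group for ", tf1, " at ", s,
                      " (", pr[1], " vs ", pr[2], "); pair skipped"))
          return(tibble(tf = character(0)))
        }
        tibble(tf = tf1, stage = s, group1 = pr[1], group2 = pr[2],
               p = rank_sum_test(x, y)$p)
      })
    })
  })
  list(medians = medians, tests = tests)
}
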