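## Writer/eraser target discovery: correlate regulator expression with
## transcriptome-wide m6A and expression over the four stages, classify
## the correlation extremes, and intersect them into candidate target sets.

#' Pearson correlation over the four stage points
#'
#' Standard Pearson r; returns `NA` when either vector has zero variance
#' (such genes are labelled unclassified downstream and excluded from
#' ranking).
#'
#' @param x,y Numeric vectors of equal length (the four stage values).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pcc <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Correlate every gene with a regulator trajectory
#'
#' @param mat Gene-by-stage tibble (m6A levels or expression).
#' @param trajectory Numeric vector of the regulator's four stage values.
#' @return Tibble with `gene_id` and `r`.
#' @export
gene_stage_cor <- function(mat, trajectory) {
  m <- stage_matrix(mat, names(mat)[1])
  tr <- as.numeric(trajectory)
  if (sd(tr) == 0) abort("regulator trajectory has zero variance")
  ctr <- tr - mean(tr)
  rs <- unname(apply(m, 1, sd))
  num <- as.numeric((m - rowMeans(m)) %*% ctr)
  r <- num / (3 * rs * sd(tr))
  r[rs == 0] <- NA_real_
  tibble(gene_id = rownames(m), r = r)
}

#' Classify correlation extremes
#'
#' Ranks genes by r: the top `floor(extreme_frac * n)` are `pos_cor`, the
#' bottom as many are `neg_cor` (ties broken by lexicographic `gene_id` for
#' determinism; the extreme classes take precedence over the not-correlated
#' band). Of the remainder, genes with `|r| < not_cor_band` are `not_cor`;
#' genes with undefined r, and the rest, are `unclassified`.
#'
#' @param cors Tibble with `gene_id` and `r` (from [gene_stage_cor()]).
#' @param extreme_frac Fraction classified into each extreme (default 0.05).
#' @param not_cor_band Half-width of the not-correlated band (default 0.1).
#' @return Tibble with `gene_id`, `r`, `class`.
#' @export
classify_correlations <- function(cors, extreme_frac = 0.05, not_cor_band = 0.1) {
  def <- cors %>% filter(!is.na(.data$r))
  if (nrow(def) < 40) abort("need at least 40 genes with defined correlations")
  if (all(def$r == def$r[1])) {
    inform("classify_correlations: all correlations identical; extremes set by tie-break")
  }
  k <- floor(extreme_frac * nrow(def))
  pos <- def %>% arrange(desc(.data$r), .data$gene_id) %>% slice(seq_len(k))
  neg <- def %>% filter(!.data$gene_id %in% pos$gene_id) %>%
    arrange(.data$r, .data$gene_id) %>% slice(seq_len(k))
  cors %>%
    mutate(class = case_when(
      .data$gene_id %in% pos$gene_id ~ "pos_cor",
      .data$gene_id %in% neg$gene_id ~ "neg_cor",
      is.na(.data$r) ~ "unclassified",
      abs(.data$r) < not_cor_band ~ "not_cor",
      TRUE ~ "unclassified"))
}

#' Identify candidate target genes of a writer or eraser
#'
#' Writer targets are the genes whose m6A level correlates most positively
#' with the regulator's expression while their own expression correlates
#' most negatively (the intersection of the two extreme classes); eraser
#' targets have both signs reversed. Significance of the intersection comes
#' from the one-tailed hypergeometric [overlap_test()] over the genes with
#' defined correlations for both signals.
#'
#' @param role `"writer"` or `"eraser"` (readers are not targeted).
#' @param m6a_classes,expr_classes Outputs of [classify_correlations()] for
#'   the gene m6A levels and gene expression against the same regulator.
#' @return An `m6a_targets` object: list with `targets` (character vector),
#'   `overlap` test result, and the two class tables.
#' @export
identify_targets <- function(role, m6a_classes, expr_classes) {
  if (!role %in% c("writer", "eraser")) {
    abort("targets are defined for writers and erasers only")
  }
  m6a_side <- if (role == "writer") "pos_cor" else "neg_cor"
  expr_side <- if (role == "writer") "neg_cor" else "pos_cor"
  set_m <- m6a_classes$gene_id[m6a_classes$class == m6a_side]
  set_e <- expr_classes$gene_id[expr_classes$class == expr_side]
  universe <- intersect(m6a_classes$gene_id[!is.na(m6a_classes$r)],
                        expr_classes$gene_id[!is.na(expr_classes$r)])
  ov <- overlap_test(set_m, set_e, universe)
  structure(list(targets = sort(intersect(set_m, set_e)), overlap = ov,
                 role = role, m6a_classes = m6a_classes,
                 expr_classes = expr_classes),
            class = "m6a_targets")
}

#' @export
print.m6a_targets <- function(x, ...) {
  cat("<m6a_targets> ", length(x$targets), " candidate ", x$role,
      " targets (hypergeometric p = ", format(x$overlap$p, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Target discovery for every targeted regulator
#'
#' Runs [gene_stage_cor()], [classify_correlations()] and
#' [identify_targets()] for each writer/eraser in the panel against the
#' gene m6A levels and expression.
#'
#' @param gene_level Gene-by-stage m6A level tibble.
#' @param expression Gene-by-stage expression tibble.
#' @param regulators Regulator panel tibble (see [regulator_templates()]);
#'   only writers and erasers are targeted.
#' @param which Regulator names to analyze (default METTL14, RBM15, ALKBH5).
#' @inheritParams classify_correlations
#' @return Named list of `m6a_targets` objects.
#' @export
regulator_target_analysis <- function(gene_level, expression,
                                      regulators = regulator_templates(),
                                      which = c("METTL14", "RBM15", "ALKBH5"),
                                      extreme_frac = 0.05, not_cor_band = 0.1) {
  ## correlate against genes other than the regulator itself
  out <- list()
  for (reg in which) {
    row <- regulators[regulators$name == reg, ]
    if (nrow(row) == 0) abort(paste0("unknown regulator: ", reg))
    traj <- as.numeric(row[, STAGES])
    gl <- gene_level[gene_level$gene_id != reg, ]
    ex <- expression[expression$gene_id != reg, ]
    common <- intersect(gl$gene_id, ex$gene_id)
    cors_m <- gene_stage_cor(gl[match(common, gl$gene_id), ], traj)
    cors_e <- gene_stage_cor(ex[match(common, ex$gene_id), ], traj)
    out[[reg]] <- identify_targets(
      row$role,
      classify_correlations(cors_m, extreme_frac, not_cor_band),
      classify_correlations(cors_e, extreme_frac, not_cor_band))
  }
  out
}

#' Reader association of target genes
#'
#' Pearson correlation of each target gene's expression with each reader's
#' expression; the strongest reader per gene is reported.
#'
#' @param target_expression Gene-by-stage expression tibble of the target
#'   genes.
#' @param readers Regulator panel rows with `role == "reader"`.
#' @return Tibble with `gene_id`, `reader`, `r` and `top` (logical: the
#'   argmax-r reader of that gene).
#' @export
reader_association <- function(target_expression, readers) {
  readers <- readers %>% filter(.data$role == "reader")
  if (nrow(readers) == 0) abort("no readers in the panel")
  res <- purrr::map_dfr(seq_len(nrow(readers)), function(i) {
    gene_stage_cor(target_expression, as.numeric(readers[i, STAGES])) %>%
      mutate(reader = readers$name[i])
  })
  res %>%
    group_by(.data$gene_id) %>%
    mutate(top = !is.na(.data$r) & .data$r == max(.data$r, na.rm = TRUE)) %>%
    ungroup() %>%
    select("gene_id", "reader", "r", "top")
}

#' Relative stage-to-stage change of a regulator's own m6A and expression
#'
#' For each transition, the ratio of the later to the earlier stage value,
#' for both the regulator's m6A level and its expression.
#'
#' @param gene_level Gene-by-stage m6A level tibble (must contain the
#'   regulator gene).
#' @param expression Gene-by-stage expression tibble.
#' @param regulator Gene id of the regulator.
#' @return Tibble with `transition`, `m6a_change`, `expr_change`.
#' @export
regulator_change <- function(gene_level, expression, regulator) {
  gl <- gene_level %>% filter(.data$gene_id == regulator)
  ex <- expression %>% filter(.data$gene_id == regulator)
  if (nrow(gl) == 0) {
    abort(paste0("regulator ", regulator, " has no retained m6A peaks"))
  }
  if (nrow(ex) == 0) abort(paste0("regulator ", regulator, " not in expression"))
  rm6 <- as.numeric(transition_ratios(stage_matrix(gl, "gene_id")))
  rex <- as.numeric(transition_ratios(stage_matrix(ex, "gene_id")))
  tibble(transition = TRANSITIONS, m6a_change = rm6, expr_change = rex)
}
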