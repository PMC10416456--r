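## broom-style tidiers for the package's result objects.

#' Tidy an m6A quantification profile
#'
#' @param x An [m6a_profile()] object.
#' @param ... Unused.
#' @return Long tibble with `peak_id`, `gene_id`, `region`, `stage`,
#'   `level`.
#' @method tidy m6a_profile
#' @export
tidy.m6a_profile <- function(x, ...) {
  x$peak_level %>%
    tidyr::pivot_longer(dplyr::all_of(STAGES), names_to = "stage",
                        values_to = "level") %>%
    left_join(x$peaks %>% select("peak_id", "gene_id", "region"),
              by = "peak_id") %>%
    mutate(stage = factor(.data$stage, levels = STAGES)) %>%
    select("peak_id", "gene_id", "region", "stage", "level")
}

#' @rdname tidy.m6a_profile
#' @method glance m6a_profile
#' @export
glance.m6a_profile <- function(x, ...) {
  sl <- setNames(x$sample_level$level, x$sample_level$stage)
  tibble(n_peaks = nrow(x$peak_level), n_genes = nrow(x$gene_level),
         n_removed = x$n_removed,
         level_D0 = sl[["D0"]], level_D2 = sl[["D2"]],
         level_D5 = sl[["D5"]], level_D15 = sl[["D15"]])
}

#' Tidy a peak dynamics classification
#'
#' @param x A [peak_dynamics()] object.
#' @param ... Unused.
#' @return Per-peak tibble with `change_count` and `origin`.
#' @method tidy peak_dynamics
#' @export
tidy.peak_dynamics <- function(x, ...) x$peaks

#' @rdname tidy.peak_dynamics
#' @method glance peak_dynamics
#' @export
glance.peak_dynamics <- function(x, ...) {
  fr <- setNames(x$summary$fraction, paste0("frac_change_", x$summary$change_count))
  org <- x$origin_summary
  tibble(n_peaks = nrow(x$peaks),
         frac_unchanged = fr[["frac_change_0"]],
         frac_change_1 = fr[["frac_change_1"]],
         frac_change_2 = fr[["frac_change_2"]],
         frac_change_3 = fr[["frac_change_3"]],
         frac_origin_D0 = sum(org$fraction[org$origin == "D0"]))
}

#' Tidy a target discovery result
#'
#' @param x An [identify_targets()] result.
#' @param ... Unused.
#' @return Tibble of target genes with their correlation values.
#' @method tidy m6a_targets
#' @export
tidy.m6a_targets <- function(x, ...) {
  tibble(gene_id = x$targets) %>%
    left_join(x$m6a_classes %>% rename(r_m6a = "r") %>%
                select("gene_id", "r_m6a"), by = "gene_id") %>%
    left_join(x$expr_classes %>% rename(r_expr = "r") %>%
                select("gene_id", "r_expr"), by = "gene_id")
}

#' @rdname tidy.m6a_targets
#' @method glance m6a_targets
#' @export
glance.m6a_targets <- function(x, ...) {
  tibble(role = x$role, n_targets = length(x$targets),
         overlap = x$overlap$overlap, n_universe = x$overlap$n_universe,
         p = x$overlap$p)
}

#' Tidy a co-dynamics classification
#'
#' @param x An [co_dynamics()] result.
#' @param ... Unused.
#' @return Per-gene tibble of whole-trajectory categories.
#' @method tidy m6a_codynamics
#' @export
tidy.m6a_codynamics <- function(x, ...) x$genes

#' @rdname tidy.m6a_codynamics
#' @method glance m6a_codynamics
#' @export
glance.m6a_codynamics <- function(x, ...) {
  fr <- setNames(x$summary$fraction, paste0("frac_cat", x$summary$category))
  dplyr::bind_cols(tibble(n_genes = nrow(x$genes)), as_tibble(as.list(fr)))
}
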