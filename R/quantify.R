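## From raw IP/input counts to m6A levels at peak, gene, region and sample
## resolution, plus the metagene density and DRACH motif scan.

#' Filter peaks by minimum input coverage
#'
#' Retains exactly the peaks whose input count is at least `min_input` in
#' every stage; the number removed is attached as attribute `n_removed` and
#' reported via a message.
#'
#' @param counts A [stage_counts()] object of raw counts.
#' @param min_input Minimum input count per stage (default 5, i.e. peaks
#'   with input reads less than 5 in any sample are dropped).
#' @return A filtered [stage_counts()] object.
#' @export
filter_peaks <- function(counts, min_input = 5) {
  m <- stage_matrix(counts$input, "peak_id")
  keep <- rowSums(m >= min_input) == length(STAGES)
  if (!any(keep)) {
    abort("all peaks removed by the input filter; increase sequencing depth")
  }
  out <- stage_counts(counts$ip[keep, ], counts$input[keep, ],
                      counts$ip_libsize, counts$input_libsize)
  attr(out, "n_removed") <- sum(!keep)
  inform(paste0("filter_peaks: removed ", sum(!keep), " of ", length(keep),
                " peaks (input < ", min_input, " in some stage)"))
  out
}

#' Normalize counts to counts per million
#'
#' Divides each column by its whole-library size and scales to 1e6,
#' separately for the IP and input libraries.
#'
#' @param counts A [stage_counts()] object.
#' @return List with `ip_cpm` and `input_cpm` tibbles.
#' @export
cpm_normalize <- function(counts) {
  if (any(counts$ip_libsize <= 0) || any(counts$input_libsize <= 0)) {
    abort("library sizes must be positive")
  }
  norm1 <- function(tb, lib) {
    m <- stage_matrix(tb, "peak_id")
    m <- sweep(m, 2, as.numeric(lib[STAGES]), "/") * 1e6
    matrix_tibble(m, "peak_id")
  }
  list(ip_cpm = norm1(counts$ip, counts$ip_libsize),
       input_cpm = norm1(counts$input, counts$input_libsize))
}

#' Per-peak m6A levels
#'
#' The m6A level of a peak at a stage is the ratio of its CPM-normalized IP
#' coverage to its CPM-normalized input coverage.
#'
#' @param counts A filtered [stage_counts()] object (every input count
#'   positive).
#' @return Peak-by-stage tibble of levels.
#' @export
peak_levels <- function(counts) {
  cpm <- cpm_normalize(counts)
  ipm <- stage_matrix(cpm$ip_cpm, "peak_id")
  inm <- stage_matrix(cpm$input_cpm, "peak_id")
  if (any(inm == 0)) {
    abort("zero input coverage encountered; run filter_peaks() first")
  }
  matrix_tibble(ipm / inm, "peak_id")
}

#' Full m6A quantification profile
#'
#' Filters, normalizes and aggregates counts into m6A levels at the four
#' resolutions the analysis uses. Gene, region and sample levels are pooled
#' ratios, `sum(IP cpm) / sum(input cpm)` over the member peaks, so deeper
#' peaks weigh more and a single-peak gene equals its peak. Genes with no
#' retained peak are absent from the gene table.
#'
#' @param counts Raw [stage_counts()].
#' @param peaks Annotated peak tibble (see [annotate_peaks()]).
#' @param min_input Input filter threshold, see [filter_peaks()].
#' @return An `m6a_profile` object: list with `peak_level`, `gene_level`,
#'   `region_level`, `sample_level` tibbles, the retained `peaks`, the
#'   filtered `counts`, and `n_removed`.
#' @export
m6a_profile <- function(counts, peaks, min_input = 5) {
  fc <- filter_peaks(counts, min_input = min_input)
  cpm <- cpm_normalize(fc)
  ipm <- stage_matrix(cpm$ip_cpm, "peak_id")
  inm <- stage_matrix(cpm$input_cpm, "peak_id")
  pk <- peaks[match(rownames(ipm), peaks$peak_id), ]
  if (anyNA(pk$peak_id)) abort("counts contain peaks absent from the peak table")

  pooled <- function(group) {
    keys <- sort(unique(group[!is.na(group)]))
    ip_s <- rowsum(ipm[!is.na(group), , drop = FALSE], group[!is.na(group)])
    in_s <- rowsum(inm[!is.na(group), , drop = FALSE], group[!is.na(group)])
    m <- ip_s[keys, , drop = FALSE] / in_s[keys, , drop = FALSE]
    m
  }
  gene_m <- pooled(pk$gene_id)
  region_m <- pooled(pk$region)
  sample_lv <- colSums(ipm) / colSums(inm)

  structure(list(
    peak_level = matrix_tibble(ipm / inm, "peak_id"),
    gene_level = matrix_tibble(gene_m, "gene_id"),
    region_level = matrix_tibble(region_m, "region"),
    sample_level = tibble(stage = STAGES, level = as.numeric(sample_lv[STAGES])),
    peaks = pk, counts = fc, n_removed = attr(fc, "n_removed")),
    class = "m6a_profile")
}

#' @export
print.m6a_profile <- function(x, ...) {
  cat("<m6a_profile> ", nrow(x$peak_level), " peaks / ", nrow(x$gene_level),
      " genes (", x$n_removed, " peaks removed by input filter)\n", sep = "")
  cat("sample m6A levels: ",
      paste(x$sample_level$stage, round(x$sample_level$level, 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count modified and expressed genes per stage
#'
#' A gene is called m6A-modified at a stage when its pooled m6A level
#' strictly exceeds `threshold`; expressed when its expression passes
#' `min_expr` at that stage.
#'
#' @param gene_level Gene-by-stage m6A level tibble.
#' @param expression Gene-by-stage expression tibble.
#' @param threshold Modified-call threshold on the IP/input ratio
#'   (default 1.5).
#' @param min_expr Low-expression filter threshold (default 1).
#' @return Tibble with per-stage counts of modified and expressed genes and
#'   the modified fraction among expressed genes.
#' @export
count_m6a_genes <- function(gene_level, expression, threshold = 1.5,
                            min_expr = 1) {
  gl <- stage_matrix(gene_level, "gene_id")
  ex <- stage_matrix(expression, "gene_id")
  tibble(stage = STAGES,
         n_modified = colSums(gl > threshold)[STAGES],
         n_expressed = colSums(ex > min_expr)[STAGES]) %>%
    mutate(modified_fraction = .data$n_modified / .data$n_expressed)
}

#' Metagene density of peak midpoints
#'
#' Maps each assigned peak midpoint to a normalized transcript coordinate:
#' 5'UTR to `[0, 1)`, CDS to `[1, 2)`, 3'UTR to `[2, 3)` by fractional
#' position within the region (strand aware), then histograms the
#' coordinates. Genes lacking a UTR contribute to the CDS segment only.
#'
#' @param peaks Annotated peak tibble.
#' @param annotation Gene annotation tibble.
#' @param n_bins Number of histogram bins over `[0, 3)` (default 90).
#' @return Tibble with `coord` (bin midpoints) and `density`, area-normalized
#'   to 1.
#' @export
metagene_density <- function(peaks, annotation, n_bins = 90) {
  pk <- peaks %>% filter(!is.na(.data$gene_id))
  ann <- annotation[match(pk$gene_id, annotation$gene_id), ]
  mid <- floor((pk$start + pk$end) / 2)
  coord <- metagene_coord(mid, ann)
  coord <- coord[!is.na(coord)]
  breaks <- seq(0, 3, length.out = n_bins + 1)
  h <- graphics::hist(coord, breaks = breaks, plot = FALSE)
  tibble(coord = h$mids, density = h$density)
}

## Normalized transcript coordinate in [0, 3) of genomic positions `mid`
## inside the genes `ann` (row-matched), strand aware.
metagene_coord <- function(mid, ann) {
  minus <- ann$strand == "-"
  len5 <- ifelse(minus, ann$tx_end - ann$cds_end, ann$cds_start - ann$tx_start)
  lenc <- ann$cds_end - ann$cds_start
  len3 <- ifelse(minus, ann$cds_start - ann$tx_start, ann$tx_end - ann$cds_end)
  ## position from the 5' end of the transcript
  in_cds <- mid >= ann$cds_start & mid < ann$cds_end
  off_cds <- ifelse(minus, ann$cds_end - mid, mid - ann$cds_start)
  before_cds <- ifelse(minus, mid >= ann$cds_end, mid < ann$cds_start)
  off5 <- ifelse(minus, ann$tx_end - mid, mid - ann$tx_start)
  off3 <- ifelse(minus, ann$cds_start - mid, mid - ann$cds_end)
  coord <- dplyr::case_when(
    in_cds & lenc > 0 ~ 1 + off_cds / lenc,
    before_cds & len5 > 0 ~ off5 / len5,
    !in_cds & !before_cds & len3 > 0 ~ 2 + off3 / len3,
    TRUE ~ NA_real_)
  pmin(coord, 3 - 1e-9)
}

#' Scan peak sequences for the DRACH motif
#'
#' Counts occurrences (including overlapping ones) of the m6A consensus
#' `[AGT][AG]AC[ACT]` on the given strand of each sequence.
#'
#' @param sequences Named character vector or tibble with `peak_id` and
#'   `sequence` columns. Only A, C, G, T, N characters are allowed.
#' @return Tibble with `peak_id`, `n_drach`; the fraction of peaks with at
#'   least one match is attached as attribute `frac_with_motif`.
#' @export
scan_drach <- function(sequences) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$peak_id)
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    abort("sequences contain characters other than A, C, G, T, N")
  }
  ss <- Biostrings::DNAStringSet(sequences)
  cnt <- Biostrings::vcountPattern("DRACH", ss, fixed = FALSE)
  out <- tibble(peak_id = names(sequences) %||% as.character(seq_along(sequences)),
                n_drach = cnt)
  attr(out, "frac_with_motif") <- mean(cnt >= 1)
  out
}
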