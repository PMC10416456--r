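## Reading and writing the plain-text formats the pipeline touches:
## BED6 peak catalogs, GTF/TSV gene annotation, keyed stage matrices,
## and the TSV result bundle. Coordinates are 0-based half-open
## throughout (BED convention); GTF is converted on read/write.

#' Read a gene annotation
#'
#' `read_gene_annotation()` imports a GTF file (gene and CDS features) and
#' reduces it to one row per gene with transcript and CDS bounds;
#' `read_annotation_table()` reads the equivalent simplified TSV with columns
#' `gene_id, chrom, strand, tx_start, tx_end, cds_start, cds_end`. Both
#' return 0-based half-open coordinates.
#'
#' @param path Path to a GTF file or annotation TSV.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) abort("GTF lacks gene_id attributes")
  genes <- df %>%
    filter(.data$type == "gene") %>%
    mutate(start = .data$start - 1L) %>% # GTF 1-based closed -> 0-based half-open
    select(gene_id = "gene_id", chrom = "seqnames", strand = "strand",
           tx_start = "start", tx_end = "end")
  cds <- df %>%
    filter(.data$type == "CDS") %>%
    group_by(.data$gene_id) %>%
    summarise(cds_start = min(.data$start) - 1L, cds_end = max(.data$end),
              .groups = "drop")
  out <- genes %>%
    left_join(cds, by = "gene_id") %>%
    mutate(chrom = as.character(.data$chrom), strand = as.character(.data$strand),
           cds_start = ifelse(is.na(.data$cds_start), .data$tx_start, .data$cds_start),
           cds_end = ifelse(is.na(.data$cds_end), .data$tx_end, .data$cds_end))
  validate_annotation(out)
}

#' @rdname read_gene_annotation
#' @export
read_annotation_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    abort(paste0("annotation table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_annotation(tb[, need])
}

validate_annotation <- function(tb) {
  bad <- with(tb, !(tx_start <= cds_start & cds_start < cds_end & cds_end <= tx_end))
  if (any(bad)) {
    abort(paste0("invalid CDS bounds for gene(s): ",
                 paste(head(tb$gene_id[bad], 5), collapse = ", ")))
  }
  if (anyDuplicated(tb$gene_id)) abort("duplicated gene_id in annotation")
  as_tibble(tb)
}

#' Read a BED6 peak catalog and assign peaks to genes
#'
#' Parses a BED file (at least 3 columns; name, score and strand optional),
#' validates coordinates, and annotates each peak by the gene whose
#' transcript interval contains the peak midpoint. Ties between overlapping
#' genes are broken by the longest peak/gene overlap, then lexicographic
#' `gene_id`. The transcript-region label is derived from the midpoint
#' position relative to the CDS bounds; a midpoint within `stop_window` nt
#' of the stop codon is labelled `stop_proximal`.
#'
#' @param path Path to a BED file.
#' @param annotation Gene annotation tibble from [read_gene_annotation()].
#' @param stop_window Half-width (nt) of the stop-proximal window (default 50).
#' @return A peak tibble: `peak_id`, `chrom`, `start`, `end`, `strand`,
#'   `gene_id` (NA when unassigned), `region`.
#' @export
read_peak_bed <- function(path, annotation, stop_window = 50) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) abort("empty BED file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3)) {
    abort(paste0("BED line ", which(ncol < 3)[1], " has fewer than 3 columns"))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    abort(paste0("malformed coordinates (start >= end or non-integer) at BED line ",
                 which(bad)[1]))
  }
  name <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                   character(1)), NA_character_)
  name[is.na(name) | name == "." | name == ""] <-
    paste0("peak_", which(is.na(name) | name == "." | name == ""))
  if (anyDuplicated(name)) abort("duplicated peak names in BED file")
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                     character(1)), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  peaks <- tibble(peak_id = name, chrom = chrom, start = start, end = end,
                  strand = strand)
  annotate_peaks(peaks, annotation, stop_window = stop_window)
}

#' Assign peaks to genes and transcript regions
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @inheritParams read_peak_bed
#' @return The peak tibble with `gene_id` and `region` columns
#'   (`5UTR`, `CDS`, `3UTR`, `stop_proximal` or `other`).
#' @export
annotate_peaks <- function(peaks, annotation, stop_window = 50) {
  peaks <- as_tibble(peaks)
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  mid <- floor((peaks$start + peaks$end) / 2)

  gene_id <- rep(NA_character_, nrow(peaks))
  region <- rep("other", nrow(peaks))
  ann <- annotation
  by_chrom <- split(seq_len(nrow(ann)), ann$chrom)
  for (i in seq_len(nrow(peaks))) {
    cand <- by_chrom[[peaks$chrom[i]]]
    if (is.null(cand)) next
    hit <- cand[ann$tx_start[cand] <= mid[i] & mid[i] < ann$tx_end[cand]]
    if (length(hit) == 0) next
    if (length(hit) > 1) {
      ov <- pmin(peaks$end[i], ann$tx_end[hit]) - pmax(peaks$start[i], ann$tx_start[hit])
      hit <- hit[order(-ov, ann$gene_id[hit])][1]
    }
    gene_id[i] <- ann$gene_id[hit]
    region[i] <- region_label(mid[i], ann[hit, ], stop_window)
  }
  peaks$gene_id <- gene_id
  peaks$region <- region
  peaks
}

## Region label for a midpoint inside a gene, strand aware. The stop codon
## boundary is cds_end on "+" and cds_start on "-".
region_label <- function(mid, gene, stop_window) {
  stop_pos <- if (gene$strand == "-") gene$cds_start else gene$cds_end
  if (abs(mid - stop_pos) <= stop_window) return("stop_proximal")
  if (mid >= gene$cds_start && mid < gene$cds_end) return("CDS")
  upstream <- mid < gene$cds_start
  if (gene$strand == "-") upstream <- !upstream
  if (upstream) "5UTR" else "3UTR"
}

#' Paired IP/input stage counts
#'
#' Container for the raw peak-by-stage count matrices of the IP and input
#' libraries plus whole-library sizes. Row keys of both matrices must match.
#'
#' @param ip,input Tibbles with a `peak_id` column and one integer column per
#'   stage (`D0`, `D2`, `D5`, `D15`).
#' @param ip_libsize,input_libsize Named positive numeric vectors of
#'   whole-library read totals per stage.
#' @return An object of class `stage_counts`.
#' @export
stage_counts <- function(ip, input, ip_libsize, input_libsize) {
  ip <- as_tibble(ip); input <- as_tibble(input)
  if (!identical(ip$peak_id, input$peak_id)) {
    abort("IP and input count matrices have different peak keys")
  }
  for (m in list(ip, input)) {
    v <- as.matrix(m[, STAGES])
    if (any(v < 0) || any(!is.finite(v))) abort("counts must be finite and non-negative")
  }
  for (ls in list(ip_libsize, input_libsize)) {
    if (!all(STAGES %in% names(ls))) abort("library sizes must be named by stage")
    if (any(ls[STAGES] <= 0)) abort("library sizes must be positive")
  }
  structure(list(ip = ip, input = input,
                 ip_libsize = ip_libsize[STAGES],
                 input_libsize = input_libsize[STAGES]),
            class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat("<stage_counts> ", nrow(x$ip), " peaks x ", length(STAGES),
      " stages (IP + input)\n", sep = "")
  invisible(x)
}

#' Read a keyed numeric stage matrix from TSV
#'
#' First column holds row keys, header names the samples. Duplicate keys,
#' missing values and non-numeric cells are rejected with the offending
#' row/column named.
#'
#' @param path Path to a TSV file.
#' @param key Name for the key column in the returned tibble.
#' @return Tibble with the key column followed by numeric sample columns.
#' @export
read_stage_matrix <- function(path, key = "id") {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("empty or missing matrix file: ", path))
  }
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(tb) == 0 || ncol(tb) < 2) abort(paste0("matrix file has no data: ", path))
  keys <- tb[[1]]
  if (anyDuplicated(keys)) {
    abort(paste0("duplicated row key '", keys[duplicated(keys)][1], "' in ", path))
  }
  vals <- tb[, -1]
  for (cn in names(vals)) {
    x <- suppressWarnings(as.numeric(vals[[cn]]))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      abort(paste0("non-numeric or missing value at row '", keys[bad[1]],
                   "', column '", cn, "' in ", path))
    }
    vals[[cn]] <- x
  }
  out <- bind_cols_keyed(keys, vals, key)
  out
}

bind_cols_keyed <- function(keys, vals, key) {
  out <- as_tibble(vals)
  out[[key]] <- keys
  out[, c(key, setdiff(names(out), key))]
}

#' Write a set of result tables as TSV
#'
#' One TSV per named table, columns in their existing order, floating point
#' values rendered at 6 significant digits so repeated runs are
#' byte-identical.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_result_tables <- function(tables, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- as_tibble(tables[[nm]])
    for (cn in names(tb)) {
      if (is.double(tb[[cn]])) {
        tb[[cn]] <- formatC(tb[[cn]], digits = 6, format = "g")
      }
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
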