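test_that("the input filter keeps exactly peaks with >= 5 reads in every stage", {
  ip <- matrix(10, 2, 4)
  input <- rbind(c(5, 5, 5, 5), c(5, 5, 5, 4))
  rownames(ip) <- rownames(input) <- c("keep", "drop")
  counts <- tiny_counts(ip, input)
  out <- suppressMessages(filter_peaks(counts))
  expect_equal(out$input$peak_id, "keep")
  expect_equal(attr(out, "n_removed"), 1)
  ## min_input = 0 is the identity
  out0 <- suppressMessages(filter_peaks(counts, min_input = 0))
  expect_equal(nrow(out0$input), 2)
  ## everything removed is an error
  expect_error(suppressMessages(filter_peaks(counts, min_input = 100)), "depth")
})

test_that("CPM normalization scales by library size only", {
  ip <- matrix(10, 1, 4); input <- matrix(10, 1, 4)
  counts <- tiny_counts(ip, input)
  cpm <- cpm_normalize(counts)
  expect_equal(as.numeric(cpm$ip_cpm[1, STG]), rep(10, 4))
  ## doubling one library halves that column only
  lib2 <- setNames(c(2e6, 1e6, 1e6, 1e6), STG)
  cpm2 <- cpm_normalize(tiny_counts(ip, input, lib_ip = lib2))
  expect_equal(as.numeric(cpm2$ip_cpm[1, STG]), c(5, 10, 10, 10))
  expect_equal(as.numeric(cpm2$input_cpm[1, STG]), rep(10, 4))
  expect_error(cpm_normalize(tiny_counts(ip, input,
                                         lib_ip = setNames(rep(0, 4), STG))),
               "positive")
})

test_that("peak m6A levels are CPM ratios", {
  ip <- matrix(c(30, 30, 30, 30), 1); input <- matrix(10, 1, 4)
  counts <- tiny_counts(ip, input)
  expect_equal(as.numeric(peak_levels(counts)[1, STG]), rep(3, 4))
  ## IP = input gives level 1
  expect_equal(as.numeric(peak_levels(tiny_counts(input, input))[1, STG]),
               rep(1, 4))
  ## unequal library sizes: raw IP 60 over 2e6 vs raw input 10 over 1e6
  counts3 <- tiny_counts(matrix(60, 1, 4), matrix(10, 1, 4),
                         lib_ip = setNames(rep(2e6, 4), STG))
  expect_equal(as.numeric(peak_levels(counts3)[1, STG]), rep(3, 4))
})

test_that("gene levels pool IP and input coverage across the gene's peaks", {
  ann <- tiny_annotation()
  peaks <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                          chrom = "chr1",
                          start = c(100L, 200L, 2600L),
                          end = c(150L, 250L, 2700L), strand = "+")
  peaks <- annotate_peaks(peaks, ann)  # p1,p2 -> geneA; p3 -> geneB
  ip <- rbind(rep(30, 4), rep(10, 4), rep(20, 4))
  input <- rbind(rep(10, 4), rep(10, 4), rep(10, 4))
  rownames(ip) <- rownames(input) <- peaks$peak_id
  pr <- suppressMessages(m6a_profile(tiny_counts(ip, input), peaks,
                                     min_input = 5))
  gl <- pr$gene_level
  expect_equal(as.numeric(gl[gl$gene_id == "geneA", STG]), rep(2, 4))
  ## a single-peak gene equals its peak
  expect_equal(as.numeric(gl[gl$gene_id == "geneB", STG]), rep(2, 4))
  expect_equal(as.numeric(pr$sample_level$level), rep(2, 4))
})

test_that("pooled gene levels are bounded by their peaks' levels", {
  sim <- shared_sim()
  pr <- shared_profile()
  pl <- as.matrix(pr$peak_level[, STG])
  gl <- as.matrix(pr$gene_level[, STG])
  rownames(gl) <- pr$gene_level$gene_id
  by_gene <- split(seq_len(nrow(pl)), pr$peaks$gene_id)
  for (g in names(by_gene)[1:50]) {
    mins <- apply(pl[by_gene[[g]], , drop = FALSE], 2, min)
    maxs <- apply(pl[by_gene[[g]], , drop = FALSE], 2, max)
    expect_true(all(gl[g, ] >= mins - 1e-12 & gl[g, ] <= maxs + 1e-12))
  }
})

test_that("levels are invariant under rescaling the IP libraries", {
  sim <- shared_sim()
  c1 <- sim$counts
  c2 <- stage_counts(c1$ip, c1$input, ip_libsize = 3 * c1$ip_libsize,
                     input_libsize = c1$input_libsize)
  l1 <- peak_levels(suppressMessages(filter_peaks(c1)))
  l2 <- peak_levels(suppressMessages(filter_peaks(c2)))
  expect_equal(as.matrix(l2[, STG]), as.matrix(l1[, STG]) / 3)
  ## rescaling BOTH libraries by the same factor changes nothing
  c3 <- stage_counts(c1$ip, c1$input, ip_libsize = 3 * c1$ip_libsize,
                     input_libsize = 3 * c1$input_libsize)
  l3 <- peak_levels(suppressMessages(filter_peaks(c3)))
  expect_equal(l3, l1)
})

test_that("modified gene counting uses a strict threshold", {
  gl <- tibble::tibble(gene_id = c("g1", "g2"))
  ex <- tibble::tibble(gene_id = c("g1", "g2"))
  for (s in STG) { gl[[s]] <- c(1.6, 1.4); ex[[s]] <- c(10, 10) }
  out <- count_m6a_genes(gl, ex)
  expect_equal(out$n_modified, rep(1L, 4), ignore_attr = TRUE)
  expect_equal(out$n_expressed, rep(2L, 4), ignore_attr = TRUE)
  out_inf <- count_m6a_genes(gl, ex, threshold = Inf)
  expect_equal(out_inf$n_modified, rep(0L, 4), ignore_attr = TRUE)
})

test_that("metagene coordinates map region boundaries correctly", {
  ann <- tiny_annotation()
  ## geneA '+': tx 0-1000, CDS 50-500
  mk <- function(mid) tibble::tibble(peak_id = paste0("p", mid), chrom = "chr1",
                                     start = mid - 1L, end = mid + 1L,
                                     strand = "+", gene_id = "geneA",
                                     region = "CDS")
  dens <- function(mid) {
    pk <- mk(mid)
    a <- ann[ann$gene_id == "geneA", ]
    m6adyn:::metagene_coord(mid, a)
  }
  expect_equal(dens(50L), 1.0)    # CDS start
  expect_equal(dens(275L), 1.5)   # CDS midpoint
  expect_equal(dens(25L), 0.5)    # middle of the 5'UTR
  expect_equal(dens(750L), 2.5)   # middle of the 3'UTR
})

test_that("uniform midpoints give a flat metagene density in each segment", {
  ann <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                        tx_start = 0L, tx_end = 3000L,
                        cds_start = 1000L, cds_end = 2000L)
  mids <- withr::with_seed(7, sample.int(2998, 2500) )
  peaks <- tibble::tibble(peak_id = paste0("p", seq_along(mids)),
                          chrom = "chr1", start = mids - 1L, end = mids + 1L,
                          strand = "+", gene_id = "g", region = "CDS")
  dens <- metagene_density(peaks, ann, n_bins = 90)
  ## area normalized to 1
  expect_equal(sum(dens$density) * (3 / 90), 1, tolerance = 1e-9)
  ## flat within each segment (chi-square goodness of fit)
  counts <- round(dens$density * length(mids) * (3 / 90))
  for (seg in 0:2) {
    idx <- dens$coord > seg & dens$coord < seg + 1
    p <- stats::chisq.test(counts[idx])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("DRACH scanning counts overlapping motifs on the given strand", {
  out <- scan_drach(c(a = "GGACT", b = "CCCCC", c = "GGACAGGACT"))
  expect_equal(out$n_drach, c(1L, 0L, 2L))
  expect_equal(attr(out, "frac_with_motif"), 2 / 3)
  expect_error(scan_drach(c(x = "GGACU")), "characters")
  ## agreement with an exhaustive sliding-window scan on random sequences
  seqs <- withr::with_seed(5, vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- paste0("s", 1:40)
  expect_equal(scan_drach(seqs)$n_drach,
               vapply(seqs, drach_count_enum, integer(1), USE.NAMES = FALSE))
})
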