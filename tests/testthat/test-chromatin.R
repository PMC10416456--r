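test_that("the rank-sum wrapper matches exact enumeration for small samples", {
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    out <- rank_sum_test(x, y)
    expect_true(out$exact)
    expect_equal(out$p, mw_enum_p(x, y), tolerance = 1e-12)
  }
  ## ties force the corrected normal approximation
  out_t <- rank_sum_test(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_false(out_t$exact)
  expect_equal(out_t$p,
               suppressWarnings(stats::wilcox.test(c(1, 2, 2, 3), c(2, 3, 3, 4),
                                                   exact = FALSE,
                                                   correct = TRUE))$p.value)
})

test_that("target accessibility comparison uses a reproducible random control", {
  sim <- shared_sim()
  targets <- sim$truth$targets$gene_id
  out1 <- compare_target_accessibility(sim$accessibility, targets, seed = 3)
  out2 <- compare_target_accessibility(sim$accessibility, targets, seed = 3)
  expect_identical(attr(out1, "random_genes"), attr(out2, "random_genes"))
  expect_equal(nrow(out1), 4)
  ## targets identical to the whole gene set: medians coincide and the
  ## rank-sum test is far from significant
  all_g <- sim$accessibility$gene_id
  out_all <- compare_target_accessibility(sim$accessibility, all_g, seed = 3)
  expect_equal(out_all$median_target, out_all$median_all)
  expect_true(all(out_all$p_vs_all > 0.9))
  expect_warning(compare_target_accessibility(sim$accessibility, all_g[1:2]),
                 "fewer than 3")
})

test_that("planted accessibility shifts of target genes are detected", {
  set.seed(17)
  hits <- 0
  for (s in 1:10) {
    n <- 400
    acc <- tibble::tibble(gene_id = sprintf("g%03d", 1:n))
    targets <- acc$gene_id[1:50]
    for (st in STG) {
      v <- rlnorm(n, log(10), 0.5)
      v[1:50] <- v[1:50] * 2  # +2-fold accessibility for targets
      acc[[st]] <- v
    }
    out <- compare_target_accessibility(acc, targets, seed = s)
    if (all(out$p_vs_all < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("accessibility groups split 10/80/10 deterministically", {
  set.seed(4)
  acc <- tibble::tibble(gene_id = sprintf("g%03d", 1:100))
  for (st in STG) acc[[st]] <- runif(100)
  g <- accessibility_groups(acc)
  tab <- table(g$group[g$stage == "D0"])
  expect_equal(as.integer(tab[c("low10", "mid", "high10")]), c(10, 80, 10))
  ## highest values are high10
  d0 <- g[g$stage == "D0", ]
  expect_true(all(acc$D0[match(d0$gene_id[d0$group == "high10"], acc$gene_id)] >
                    max(acc$D0[match(d0$gene_id[d0$group == "low10"],
                                     acc$gene_id)])))
})

test_that("planted negative accessibility-m6A coupling shows in group medians", {
  set.seed(9)
  n <- 500
  acc <- tibble::tibble(gene_id = sprintf("g%03d", 1:n))
  gl <- tibble::tibble(gene_id = acc$gene_id)
  for (st in STG) {
    a <- rlnorm(n, log(10), 0.8)
    acc[[st]] <- a
    gl[[st]] <- 4 / sqrt(a / 10) * rlnorm(n, 0, 0.1)  # high access -> low m6A
  }
  res <- m6a_by_accessibility_group(acc, gl)
  med <- res$medians
  for (st in STG) {
    lo <- med$median_m6a[med$stage == st & med$group == "low10"]
    hi <- med$median_m6a[med$stage == st & med$group == "high10"]
    expect_gt(lo, hi)
  }
  p_lh <- res$tests$p[res$tests$group1 == "low10" & res$tests$group2 == "high10"]
  expect_true(all(p_lh < 0.05))
})

test_that("modified/unmodified accessibility comparison handles degenerate input", {
  set.seed(5)
  n <- 100
  acc <- tibble::tibble(gene_id = sprintf("g%03d", 1:n))
  mod <- tibble::tibble(gene_id = acc$gene_id)
  for (st in STG) { acc[[st]] <- rlnorm(n); mod[[st]] <- rep(c(TRUE, FALSE), n / 2) }
  out <- accessibility_by_modification(mod, acc)
  expect_equal(nrow(out), 4)
  expect_true(all(out$p > 1e-4))  # identical distributions
  mod_all <- mod; for (st in STG) mod_all[[st]] <- TRUE
  expect_error(accessibility_by_modification(mod_all, acc), "empty")
})

test_that("co-dynamics categories partition the genes by their definitions", {
  gl <- tibble::tibble(gene_id = c("none", "acc_only", "m6a_only", "disc", "conc"),
                       D0 = c(2, 2, 1, 2, 2), D2 = c(2, 2, 2, 3, 3),
                       D5 = c(2, 2, 2, 2, 2), D15 = c(2, 2, 2, 3, 3))
  acc <- tibble::tibble(gene_id = gl$gene_id,
                        D0 = c(5, 5, 5, 6, 2), D2 = c(5, 8, 5, 4, 3),
                        D5 = c(5, 8, 5, 6, 2), D15 = c(5, 8, 5, 4, 3))
  out <- co_dynamics(gl, acc)
  expect_equal(out$genes$category, c(1L, 2L, 3L, 4L, 5L))
  expect_equal(sum(out$summary$n), 5)
  expect_false(any(out$genes$flagged))
  ## per-window labels: gene "disc" at D0-D2 has both changed, opposite signs
  w <- out$windows
  expect_equal(w$category[w$gene_id == "disc" & w$window == "D0-D2"], 4L)
  expect_equal(w$category[w$gene_id == "conc" & w$window == "D0-D2"], 5L)
  expect_equal(w$category[w$gene_id == "none" & w$window == "D0-D2"], 1L)
})

test_that("co-dynamics recovery matches the planted categories", {
  sim <- shared_sim()
  pr <- shared_profile()
  cod <- co_dynamics(pr$gene_level, sim$accessibility,
                     fc_threshold = sim$config$fc_threshold)
  merged <- dplyr::inner_join(cod$genes, sim$truth$gene, by = "gene_id")
  expect_gt(mean(merged$category.x == merged$category.y), 0.9)
  ## partition: every gene gets exactly one category
  expect_equal(sum(cod$summary$n), nrow(cod$genes))
  expect_true(all(cod$genes$category %in% 1:5))
})

test_that("pcc_bins drops the 5% tails and forms 18 near-equal bins", {
  set.seed(6)
  n <- 2000
  gl <- tibble::tibble(gene_id = sprintf("g%04d", 1:n))
  acc <- tibble::tibble(gene_id = gl$gene_id)
  for (st in STG) { gl[[st]] <- rlnorm(n, 1, 0.3); acc[[st]] <- rlnorm(n, 2, 0.3) }
  out <- pcc_bins(gl, acc)
  expect_equal(out$dropped, 200)
  sizes <- unique(out$bins[, c("bin", "n")])$n
  expect_equal(length(sizes), 18)
  expect_equal(sum(sizes), 1800)
  expect_lte(max(sizes) - min(sizes), 1)
  ## m6A changes independent of the PCC: no trend across bins
  b <- out$bins[out$bins$transition == "D0-D2", ]
  fit <- stats::lm(mean_abs_fc ~ bin, data = b)
  ci <- stats::confint(fit)["bin", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("category overlaps count window intersections and consistent genes", {
  w <- tibble::tibble(
    gene_id = rep(c("a", "b", "c"), each = 3),
    window = rep(m6a_transitions(), 3),
    category = c(3L, 3L, 3L, 3L, 1L, 3L, 1L, 1L, 1L))
  out <- category_overlap(w)
  triple <- out$counts[out$counts$category == 3 &
                         out$counts$windows == "D0-D2&D2-D5&D5-D15", ]
  expect_equal(triple$n, 1)  # only gene a has category 3 in all windows
  expect_equal(out$consistent$gene_id, c("a", "c"))
  ## identical labels across windows: consistent set equals the category set
  w2 <- w; w2$category <- rep(c(2L, 5L, 4L), each = 3)
  out2 <- category_overlap(w2)
  expect_equal(nrow(out2$consistent), 3)
})

test_that("ECDF comparison separates shifted groups", {
  set.seed(8)
  vals <- tibble::tibble(group = rep(c("a", "b"), each = 200),
                         value = c(rnorm(200), rnorm(200) + 1))
  out <- ecdf_compare(vals)
  expect_lt(out$tests$p, 0.05)
  same <- tibble::tibble(group = rep(c("a", "b"), each = 200),
                         value = rep(rnorm(200), 2))
  expect_gt(ecdf_compare(same)$tests$p, 0.9)
  ## single-member group: a one-step curve
  single <- tibble::tibble(group = c("a", "b", "b"), value = c(2, 1, 3))
  crv <- ecdf_compare(single)$curves
  expect_equal(crv$cum_fraction[crv$group == "a"], 1)
  expect_error(ecdf_compare(vals[vals$group == "a", ]), "two groups")
})

test_that("m6A level groups use the 1.5 and 4 thresholds", {
  g <- m6a_level_groups(c(1.0, 1.5, 2, 4, 4.5))
  expect_equal(as.character(g), c("low", "medium", "medium", "medium", "high"))
})

test_that("TF binding coupled to m6A groups is detected; empty groups skipped", {
  sim <- shared_sim()
  pr <- shared_profile()
  res <- suppressWarnings(tf_binding_by_m6a_group(sim$tf_binding,
                                                  pr$gene_level))
  ## POU5F1 at D0 is planted proportional to m6A: some group contrast at D0
  ## must be significant (the "high" group can be empty at D0)
  p_coupled <- res$tests$p[res$tests$tf == "POU5F1" & res$tests$stage == "D0"]
  expect_true(length(p_coupled) >= 1)
  expect_lt(min(p_coupled), 0.05)
  ## NANOG is uncoupled: median ordering is not monotone in general; just
  ## check the table covers both stages
  expect_true(all(c("D0", "D15") %in% res$medians$stage))
  ## a level table with no high genes leads to skipped pairs, with warnings
  gl_low <- pr$gene_level
  for (st in STG) gl_low[[st]] <- pmin(gl_low[[st]], 3)
  w <- testthat::capture_warnings(tf_binding_by_m6a_group(sim$tf_binding, gl_low))
  expect_true(any(grepl("skipped", w)))
})
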