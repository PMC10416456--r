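test_that("the 2x2 chi-square matches the hand computation and stats::chisq.test", {
  ## [[100,100],[200,100]]: chi-square = 500*(100*100-100*200)^2 /
  ## (200*300*300*200) = 125/9
  cs <- m6adyn:::chisq_2x2(100, 100, 200, 100)
  expect_equal(cs$stat, 125 / 9, tolerance = 1e-12)
  expect_equal(cs$stat, 13.89, tolerance = 1e-3)
  ref <- stats::chisq.test(matrix(c(100, 100, 200, 100), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(cs$stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cs$p, unname(ref$p.value), tolerance = 1e-10)
  ## identical columns: statistic 0, p 1
  cs0 <- m6adyn:::chisq_2x2(50, 70, 50, 70)
  expect_equal(cs0$stat, 0)
  expect_equal(cs0$p, 1)
})

test_that("differential calls need both the fold change and the chi-square", {
  ip <- rbind(c(100, 200, 200, 200), c(100, 100, 100, 100))
  input <- rbind(c(100, 100, 100, 100), c(100, 100, 100, 100))
  rownames(ip) <- rownames(input) <- c("chg", "flat")
  out <- differential_peaks(tiny_counts(ip, input))
  d02 <- out[out$peak_id == "chg" & out$transition == "D0-D2", ]
  expect_equal(d02$fold_change, 2)
  expect_true(d02$differential)
  flat <- out[out$peak_id == "flat", ]
  expect_equal(flat$fold_change, rep(1, 3))
  expect_false(any(flat$differential))
  ## symmetric in stage order: the reverse change has the same fold change/p
  d515 <- out[out$peak_id == "chg" & out$transition == "D5-D15", ]
  expect_equal(d515$fold_change, 1)
  ip_rev <- rbind(c(200, 100, 100, 100))
  rownames(ip_rev) <- "rev"
  out_rev <- differential_peaks(tiny_counts(ip_rev, input[1, , drop = FALSE]))
  r02 <- out_rev[out_rev$transition == "D0-D2", ]
  expect_equal(r02$fold_change, d02$fold_change)
  expect_equal(r02$p, d02$p, tolerance = 1e-12)
})

test_that("tables with tiny expected cells fall back to the exact test", {
  ip <- matrix(c(1, 0, 1, 2), 1)
  input <- matrix(c(8, 9, 9, 8), 1)
  rownames(ip) <- rownames(input) <- "low"
  out <- differential_peaks(tiny_counts(ip, input), fc_threshold = 1.2)
  expect_true(any(out$low_count))
  lc <- out[out$low_count, ][1, ]
  s <- match(strsplit(lc$transition, "-")[[1]], STG)
  ref <- stats::fisher.test(matrix(c(ip[1, s[1]], input[1, s[1]],
                                     ip[1, s[2]], input[1, s[2]]),
                                   2, byrow = TRUE))
  expect_equal(lc$p, ref$p.value, tolerance = 1e-12)
})

test_that("modified calls, origins and change classes follow their definitions", {
  lv <- tibble::tibble(peak_id = c("a", "b", "c", "d"),
                       D0 = c(1.6, 1.5, 1.2, 1.0), D2 = c(1.6, 1.6, 1.8, 1.2),
                       D5 = c(1.6, 1.4, 1.8, 1.3), D15 = c(1.6, 1.2, 1.2, 1.1))
  mod <- call_modified(lv)
  expect_equal(as.logical(mod[mod$peak_id == "a", STG]), rep(TRUE, 4))
  ## 1.5 is NOT modified (strict >)
  expect_equal(as.logical(mod[mod$peak_id == "b", STG]),
               c(FALSE, TRUE, FALSE, FALSE))
  org <- peak_origin(mod)
  expect_equal(org$origin, c("D0", "D2", "D2", "never"))

  diff <- tibble::tibble(
    peak_id = rep(c("a", "b"), each = 3),
    transition = rep(m6a_transitions(), 2),
    differential = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  cls <- change_classes(diff)
  expect_equal(cls$peaks$change_count[cls$peaks$peak_id == "a"], 2)
  expect_equal(cls$peaks$change_count[cls$peaks$peak_id == "b"], 0)
  expect_equal(sum(cls$summary$fraction), 1)
})

test_that("dynamic genes are those with any transition fold change > 1.2", {
  gl <- tibble::tibble(gene_id = c("up", "flat"),
                       D0 = c(2, 3), D2 = c(2.5, 3), D5 = c(2.5, 3),
                       D15 = c(2.5, 3))
  expect_equal(dynamic_genes(gl), "up")  # 2.5/2 = 1.25 > 1.2
  gl2 <- gl; gl2$D2 <- c(2.3, 3)         # 1.15 never exceeds 1.2
  gl2$D5 <- c(2.3, 3); gl2$D15 <- c(2.3, 3)
  expect_equal(dynamic_genes(gl2), character(0))
})

test_that("null counts yield a differential fraction below alpha", {
  cfg <- sim_config(n_genes = 800, n_peaks = 2000, n_targets = 0,
                    frac_unchanged = 1, frac_change_once = 0,
                    frac_change_twice = 0, frac_change_thrice = 0,
                    category_fracs = c(0.5, 0.5, 0, 0, 0),
                    stasis_jitter = 1, seed = 21)
  sim <- simulate_study(cfg)
  pr <- suppressMessages(m6a_profile(sim$counts, sim$peaks))
  diff <- differential_peaks(pr$counts)
  frac <- mean(diff$differential)
  expect_lte(frac, 0.05)
})

test_that("k-means recovers well-separated planted profile groups", {
  n <- 60
  grp <- rep(1:2, each = n)
  base <- withr::with_seed(3, {
    up <- t(replicate(n, c(1, 2, 3, 4) + rnorm(4, 0, 0.05)))
    down <- t(replicate(n, c(4, 3, 2, 1) + rnorm(4, 0, 0.05)))
    rbind(up, down)
  })
  lv <- tibble::as_tibble(base, .name_repair = "minimal")
  names(lv) <- STG
  lv$peak_id <- paste0("p", seq_len(2 * n))
  lv <- lv[, c("peak_id", STG)]
  cl <- cluster_profiles(lv, k = 2, seed = 5)
  expect_equal(ari(cl$clusters$cluster, grp), 1)
  ## determinism and k = 1
  cl2 <- cluster_profiles(lv, k = 2, seed = 5)
  expect_identical(cl$clusters, cl2$clusters)
  expect_equal(unique(cluster_profiles(lv, k = 1, seed = 5)$clusters$cluster), 1L)
  ## constant profiles are flagged and still assigned
  lv$D0[1] <- lv$D2[1] <- lv$D5[1] <- lv$D15[1] <- 2
  cl3 <- cluster_profiles(lv, k = 2, seed = 5)
  expect_true(cl3$clusters$flagged[1])
  expect_true(cl3$clusters$cluster[1] %in% 1:2)
})

test_that("dispersion scores are the sample SD of log2 expression", {
  ## log2(x+1) = 1,2,3,4  =>  sd = sqrt(5/3)
  ex <- tibble::tibble(gene_id = c("v", "const"),
                       D0 = c(1, 7), D2 = c(3, 7), D5 = c(7, 7), D15 = c(15, 7))
  out <- dispersion_scores(ex)
  expect_equal(out$dispersion[out$gene_id == "v"], sqrt(5 / 3),
               tolerance = 1e-12)
  expect_equal(round(out$dispersion[out$gene_id == "v"], 4), 1.291)
  expect_equal(out$dispersion[out$gene_id == "const"], 0)
})

test_that("the hypergeometric overlap test matches exhaustive enumeration", {
  u <- paste0("g", 1:20)
  a <- u[1:5]; b <- u[c(1, 2, 3, 8, 9)]
  out <- overlap_test(a, b, u)
  expect_equal(out$overlap, 3)
  expect_equal(out$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(out$p, hyper_tail_enum(20, 5, 5, 3), tolerance = 1e-10)
  expect_equal(round(out$p, 4), 0.0726)
  ## A = B: the tail is the single maximal-overlap term
  out_eq <- overlap_test(a, a, u)
  expect_equal(out_eq$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(out_eq$p, stats::dhyper(5, 5, 15, 5), tolerance = 1e-12)
  expect_equal(out_eq$p, hyper_tail_enum(20, 5, 5, 5), tolerance = 1e-10)
  ## disjoint sets: upper tail at overlap 0 is 1
  out_dis <- overlap_test(u[1:5], u[6:10], u)
  expect_equal(out_dis$p, 1)
  expect_error(overlap_test(a, b, character(0)), "empty universe")
})

test_that("change classes partition the peaks and recovery matches truth", {
  sim <- shared_sim()
  pr <- shared_profile()
  dyn <- peak_dynamics(pr, fc_threshold = sim$config$fc_threshold,
                       mod_threshold = sim$config$mod_threshold)
  expect_equal(sum(dyn$summary$fraction), 1)
  expect_equal(sum(dyn$summary$n), nrow(dyn$peaks))
  m <- dplyr::inner_join(sim$truth$peak, dyn$peaks, by = "peak_id",
                         suffix = c(".t", ".r"))
  expect_gt(mean(m$change_count.t == m$change_count.r), 0.9)
  expect_gt(mean(m$origin.t == m$origin.r), 0.97)
  ## noiseless levels recover the labels exactly
  noiseless <- dynamics_from_levels(sim$truth$mu_peak)
  expect_equal(noiseless$change_count, sim$truth$peak$change_count)
})
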