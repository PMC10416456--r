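## Synthetic four-stage MeRIP-seq study generator. Plants per-peak
## methylation trajectories realizing prescribed change-count classes and
## origin stages at the pipeline's own thresholds, regulator-coupled target
## genes with exact Pearson correlations, and accessibility trajectories
## matching the five co-dynamics categories, then draws negative-binomial
## IP/input counts on top. Everything is deterministic given the seed.

## Trajectory bands. Peaks sit in LOW (< modified threshold 1.5, with
## margin) before their origin stage and in HIGH (> 1.5, with margin) from
## it onward, so noisy level estimates at realistic depth do not flip
## modified calls.
BAND_LOW <- c(0.6, 1.3)
BAND_HIGH <- c(1.7, 6.0)

#' Simulation configuration
#'
#' Collects every knob of the synthetic study. Defaults plant the headline
#' structure of the cardiomyocyte differentiation time course: 14% of peaks
#' with a constant m6A level, 9% changing in all three transitions, 90% of
#' peaks already modified at D0, and 60 target genes per regulator coupled
#' at Pearson r = 0.9.
#'
#' @param n_genes,n_peaks Study size; every gene receives at least one peak,
#'   so `n_peaks >= n_genes` is required.
#' @param frac_unmodified Fraction of peaks never exceeding the modified
#'   threshold at any stage.
#' @param frac_origin_D0 Fraction of peaks already modified at D0.
#' @param frac_unchanged,frac_change_once,frac_change_twice,frac_change_thrice
#'   Change-count class fractions (number of the three consecutive
#'   transitions with symmetric fold change > `fc_threshold`); the three
#'   change fractions must sum to `1 - frac_unchanged`.
#' @param n_targets Planted target genes per targeted regulator
#'   (METTL14, RBM15, ALKBH5).
#' @param r_plant Coupling strength in `[0, 1]`: the exact Pearson
#'   correlation between a target gene's trajectories and its regulator's
#'   expression (0 = uncoupled null).
#' @param depth_mean Expected input read count per peak (sequencing depth).
#' @param dispersion Negative-binomial overdispersion: counts with mean `m`
#'   are drawn with size `dispersion * m`, i.e. variance
#'   `m * (1 + 1/dispersion)`, so estimates tighten as depth grows.
#' @param category_fracs Length-5 fractions of the m6A-by-accessibility
#'   co-dynamics categories; must sum to 1, and the first two (the
#'   m6A-unchanged categories) must sum to `frac_unchanged`.
#' @param fc_threshold,mod_threshold The fold-change and modified-call
#'   thresholds the trajectories are planted against.
#' @param stasis_jitter Maximum symmetric fold change of a non-changing
#'   transition (1 = exactly constant trajectories, for null simulations).
#' @param access_noise_sd Log-normal noise SD on accessibility values.
#' @param seed Integer seed; fully determines the study.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000, n_peaks = 3000,
                       frac_unmodified = 0.05, frac_origin_D0 = 0.90,
                       frac_unchanged = 0.14, frac_change_once = 0.47,
                       frac_change_twice = 0.30, frac_change_thrice = 0.09,
                       n_targets = 60, r_plant = 0.9,
                       depth_mean = 1e4, dispersion = 10,
                       category_fracs = c(0.07, 0.07, 0.30, 0.28, 0.28),
                       fc_threshold = 1.2, mod_threshold = 1.5,
                       stasis_jitter = 1.08, access_noise_sd = 0.02,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_peaks = n_peaks,
              frac_unmodified = frac_unmodified, frac_origin_D0 = frac_origin_D0,
              frac_unchanged = frac_unchanged, frac_change_once = frac_change_once,
              frac_change_twice = frac_change_twice,
              frac_change_thrice = frac_change_thrice,
              n_targets = n_targets, r_plant = r_plant,
              depth_mean = depth_mean, dispersion = dispersion,
              category_fracs = category_fracs,
              fc_threshold = fc_threshold, mod_threshold = mod_threshold,
              stasis_jitter = stasis_jitter, access_noise_sd = access_noise_sd,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_unmodified, cfg$frac_origin_D0, cfg$frac_unchanged,
          cfg$frac_change_once, cfg$frac_change_twice, cfg$frac_change_thrice,
          cfg$category_fracs)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  chg <- cfg$frac_change_once + cfg$frac_change_twice + cfg$frac_change_thrice
  if (abs(chg - (1 - cfg$frac_unchanged)) > 1e-8) {
    abort("change-class fractions must sum to 1 - frac_unchanged")
  }
  if (length(cfg$category_fracs) != 5 || abs(sum(cfg$category_fracs) - 1) > 1e-8) {
    abort("category_fracs must be 5 fractions summing to 1")
  }
  if (abs(sum(cfg$category_fracs[1:2]) - cfg$frac_unchanged) > 1e-6) {
    abort(paste0("infeasible config: category_fracs[1]+category_fracs[2] must ",
                 "equal frac_unchanged (categories 1-2 are the m6A-unchanged genes)"))
  }
  if (cfg$frac_origin_D0 > 1 - cfg$frac_unmodified + 1e-12) {
    abort("infeasible config: frac_origin_D0 exceeds the modified fraction")
  }
  if (cfg$r_plant < 0 || cfg$r_plant > 1) abort("r_plant must lie in [0, 1]")
  if (cfg$n_peaks < cfg$n_genes) abort("n_peaks must be >= n_genes")
  if (cfg$n_targets > cfg$n_genes / 10) abort("n_targets must be <= n_genes/10")
  if (cfg$depth_mean <= 0 || cfg$dispersion <= 0) {
    abort("depth_mean and dispersion must be positive")
  }
  if (cfg$stasis_jitter < 1) abort("stasis_jitter must be >= 1")
  cfg
}

#' Built-in m6A regulator panel
#'
#' Writer, eraser and reader genes with fixed smooth four-stage expression
#' templates. METTL14, RBM15 (writers) and ALKBH5 (eraser) carry the
#' high-dispersion trajectories that drive target planting; the remaining
#' regulators are comparatively flat.
#'
#' @return Tibble with `name`, `role` and one column per stage.
#' @export
regulator_templates <- function() {
  tb <- tibble(
    name = c("METTL3", "METTL14", "RBM15", "FTO", "ALKBH5",
             "YTHDF1", "YTHDF2", "YTHDF3", "YTHDC1", "YTHDC2", "IGF2BP2"),
    role = c("writer", "writer", "writer", "eraser", "eraser",
             rep("reader", 6)))
  expr <- rbind(
    c(55, 50, 48, 52),   # METTL3
    c(40, 95, 60, 20),   # METTL14: peaks at mesoderm
    c(85, 30, 20, 60),   # RBM15: dips mid-course
    c(35, 33, 36, 34),   # FTO
    c(20, 30, 85, 55),   # ALKBH5: peaks at cardiac progenitor
    c(60, 62, 58, 61), c(45, 40, 50, 47), c(30, 32, 31, 29),
    c(70, 66, 72, 69), c(25, 27, 24, 26), c(90, 80, 85, 88))
  colnames(expr) <- STAGES
  dplyr::bind_cols(tb, as_tibble(expr))
}

## The regulators whose targets are planted / searched for.
TARGETED_REGULATORS <- c(METTL14 = "writer", RBM15 = "writer", ALKBH5 = "eraser")

## ---- trajectory machinery ------------------------------------------------

## Sample a change pattern (logical over the 3 transitions) of given size,
## forced to contain the transition entering the origin stage when the
## origin is D2/D5/D15.
sample_pattern <- function(class_count, forced) {
  pat <- rep(FALSE, 3)
  pool <- 1:3
  if (!is.na(forced)) {
    pat[forced] <- TRUE
    pool <- setdiff(pool, forced)
    class_count <- class_count - 1
  }
  if (class_count > 0) pat[sample_safe(pool, class_count)] <- TRUE
  pat
}

## sample() that treats a length-1 x as a set, not 1:x.
sample_safe <- function(x, size) x[sample.int(length(x), size)]

## Build n methylation trajectories over the 4 stages. `pattern` is n x 3
## logical (which transitions change), `origin` in 1..4 = first modified
## stage, 5 = never modified. Band membership follows the origin; a change
## moves by a factor in [1.38, band max] and a non-change by at most
## `jitter`, keeping safe margins around the 1.2 and 1.5 thresholds.
build_mu <- function(pattern, origin, jitter = 1.08) {
  n <- nrow(pattern)
  mu <- matrix(NA_real_, n, 4, dimnames = list(NULL, STAGES))
  mu[, 1] <- ifelse(origin == 1, runif(n, 1.8, 3.5), runif(n, 0.7, 1.2))
  for (t in 1:3) {
    cur <- mu[, t]
    entering <- origin == (t + 1)
    in_high <- origin <= t
    lo <- ifelse(in_high, BAND_HIGH[1], BAND_LOW[1])
    hi <- ifelse(in_high, BAND_HIGH[2], BAND_LOW[2])
    fmax <- ifelse(in_high, 1.9, 1.75)
    nxt <- numeric(n)
    ei <- which(entering)
    if (length(ei) > 0) {
      nxt[ei] <- runif(length(ei), pmax(BAND_HIGH[1], 1.38 * cur[ei]), 2.8)
    }
    si <- which(!entering)
    if (length(si) > 0) {
      chg <- pattern[si, t]
      up_cap <- hi[si] / cur[si]
      dn_cap <- cur[si] / lo[si]
      fmin <- ifelse(chg, 1.38, 1)
      fcap <- ifelse(chg, fmax[si], jitter)
      up_ok <- up_cap >= fmin
      dn_ok <- dn_cap >= fmin
      both <- up_ok & dn_ok
      go_up <- up_ok
      go_up[both] <- runif(sum(both)) < 0.5
      cap <- ifelse(go_up, up_cap, dn_cap)
      f <- runif(length(si), fmin, pmax(fmin, pmin(fcap, cap)))
      nxt[si] <- ifelse(go_up, cur[si] * f, cur[si] / f)
    }
    mu[, t + 1] <- nxt
  }
  mu
}

## Exact-correlation direction: a standardized 4-vector whose sample Pearson
## correlation with `z` is exactly r (noise component orthogonalized).
## The free noise component is resampled until the direction's correlation
## with every vector in `avoid` stays at or below `max_cross`, so a target
## planted for one regulator does not leak into another regulator's
## correlation extremes.
exact_cor_direction <- function(z, r, avoid = NULL, max_cross = 0.8) {
  z <- as.numeric(scale(z))
  for (try in 1:200) {
    e <- rnorm(4)
    e <- e - mean(e)
    e <- e - sum(e * z) / sum(z * z) * z
    if (sqrt(sum(e^2)) < 1e-8) next
    e <- e / sd(e)
    d <- r * z + sqrt(1 - r^2) * e
    ok <- TRUE
    if (!is.null(avoid) && ncol(avoid) > 0) {
      ok <- all(abs(suppressWarnings(cor(d, avoid))) <= max_cross, na.rm = TRUE)
    }
    if (ok) return(d)
  }
  d
}

## ---- planting operations -------------------------------------------------

#' Plant regulator-coupled target genes
#'
#' Overwrites the methylation and expression trajectories of `n_targets`
#' genes per targeted regulator (METTL14, RBM15: writers; ALKBH5: eraser) so
#' that the sample Pearson correlation over the four stages between the
#' gene's m6A level and the regulator's expression is exactly `+r_plant`
#' (writers) or `-r_plant` (eraser), and the gene's expression correlates
#' with the opposite sign. Target m6A levels stay above the modified
#' threshold at every stage.
#'
#' @param config A [sim_config()].
#' @param expression Gene-by-stage expression tibble (`gene_id` + stages).
#' @param mu Gene-by-stage true m6A level tibble.
#' @param regulators Regulator panel, see [regulator_templates()].
#' @param target_genes Optional character vector of candidate genes to draw
#'   targets from (defaults to all genes not named like a regulator).
#' @return List with modified `expression` and `mu` tibbles, the `regulators`
#'   panel, and `targets`: a tibble of `gene_id`, `regulator`, `role`.
#' @export
plant_regulator_targets <- function(config, expression, mu,
                                    regulators = regulator_templates(),
                                    target_genes = NULL) {
  r <- config$r_plant
  if (r < 0 || r > 1) abort("r_plant must lie in [0, 1]")
  genes <- expression$gene_id
  pool <- target_genes %||% setdiff(genes, regulators$name)
  need <- config$n_targets * length(TARGETED_REGULATORS)
  if (config$n_targets > length(genes) / 10) abort("n_targets must be <= n_genes/10")
  if (need > length(pool)) abort("not enough genes to host the planted targets")

  expr_m <- stage_matrix(expression, "gene_id")
  mu_m <- stage_matrix(mu, "gene_id")
  chosen <- if (need > 0) sample_safe(pool, need) else character(0)
  targets <- tibble(gene_id = character(0), regulator = character(0),
                    role = character(0))
  for (k in seq_along(TARGETED_REGULATORS)) {
    reg <- names(TARGETED_REGULATORS)[k]
    role <- TARGETED_REGULATORS[[k]]
    if (config$n_targets == 0) next
    tg <- chosen[((k - 1) * config$n_targets + 1):(k * config$n_targets)]
    z <- as.numeric(regulators[regulators$name == reg, STAGES])
    others <- setdiff(names(TARGETED_REGULATORS), reg)
    avoid <- vapply(others, function(o) {
      as.numeric(regulators[regulators$name == o, STAGES])
    }, double(4))
    s_m <- if (role == "writer") 1 else -1
    for (g in tg) {
      d_m <- exact_cor_direction(z, r, avoid = avoid) * s_m
      d_e <- exact_cor_direction(z, r, avoid = avoid) * (-s_m)
      mu_m[g, ] <- 2.9 + 0.7 * d_m
      expr_m[g, ] <- rlnorm(1, log(60), 0.4) * (1 + 0.3 * d_e)
    }
    targets <- bind_rows(targets, tibble(gene_id = tg, regulator = reg, role = role))
  }
  list(expression = matrix_tibble(expr_m, "gene_id"),
       mu = matrix_tibble(mu_m, "gene_id"),
       regulators = regulators, targets = targets)
}

#' Plant gene-level accessibility trajectories
#'
#' Assigns each gene one of the five m6A-by-accessibility co-dynamics
#' categories, conditional on whether its m6A level changes (any consecutive
#' symmetric fold change above `fc_threshold` in the noiseless trajectory),
#' and constructs an accessibility trajectory realizing that category:
#' constant (1, 3), independently changing (2), change ratios reciprocal to
#' the m6A change ratios (4, discordant) or equal to them (5, concordant).
#'
#' @inheritParams plant_regulator_targets
#' @param mu Gene-by-stage true m6A level tibble.
#' @return List with `accessibility` (gene-by-stage tibble) and `categories`
#'   (tibble of `gene_id`, `category`).
#' @export
plant_accessibility <- function(config, mu) {
  mu_m <- stage_matrix(mu, "gene_id")
  n <- nrow(mu_m)
  ratios <- transition_ratios(mu_m)
  changed <- apply(sym_fc(ratios) > config$fc_threshold, 1, any)

  cf <- config$category_fracs
  category <- integer(n)
  iu <- which(!changed); ic <- which(changed)
  if (length(iu) > 0) {
    p <- cf[1:2]; p <- if (sum(p) > 0) p / sum(p) else c(0.5, 0.5)
    category[iu] <- sample(1:2, length(iu), replace = TRUE, prob = p)
  }
  if (length(ic) > 0) {
    p <- cf[3:5]; p <- if (sum(p) > 0) p / sum(p) else rep(1 / 3, 3)
    category[ic] <- sample(3:5, length(ic), replace = TRUE, prob = p)
  }

  a_ratio <- matrix(exp(runif(n * 3, -log(1.06), log(1.06))), n, 3)
  for (i in which(category == 2)) {
    nc <- sample.int(3, 1)
    tr <- sample_safe(1:3, nc)
    f <- runif(nc, 1.35, 1.7)^(sample(c(-1, 1), nc, replace = TRUE))
    a_ratio[i, tr] <- f
  }
  i4 <- category == 4
  a_ratio[i4, ] <- 1 / ratios[i4, ]
  i5 <- category == 5
  a_ratio[i5, ] <- ratios[i5, ]

  a0 <- rlnorm(n, log(10), 0.6)
  acc <- cbind(a0, a0 * t(apply(a_ratio, 1, cumprod)))
  acc <- acc * matrix(exp(rnorm(n * 4, 0, config$access_noise_sd)), n, 4)
  colnames(acc) <- STAGES
  rownames(acc) <- rownames(mu_m)
  list(accessibility = matrix_tibble(acc, "gene_id"),
       categories = tibble(gene_id = rownames(mu_m), category = category))
}

#' Draw negative-binomial IP/input counts for given methylation levels
#'
#' Counts are drawn with mean `depth_mean * weight * mu * sizefactor` (IP)
#' and `depth_mean * weight * sizefactor` (input) and negative-binomial size
#' `dispersion * mean`. Library sizes are proportional to the per-stage
#' sizefactors, so CPM-normalized IP/input ratios recover `mu` in
#' expectation.
#'
#' @param mu Peak-by-stage tibble of true m6A levels (`peak_id` + stages).
#' @param depth_mean Expected input count per peak.
#' @param dispersion Overdispersion parameter, see [sim_config()].
#' @param weights Optional peak-by-stage matrix of abundance weights
#'   (expression-proportional; default 1).
#' @param sf_ip,sf_input Optional named per-stage sizefactors (default drawn
#'   log-uniform in `[0.5, 2]`).
#' @return A [stage_counts()] object; the expected input counts are attached
#'   as attribute `input_mean`.
#' @export
simulate_counts <- function(mu, depth_mean = 1e4, dispersion = 10,
                            weights = NULL, sf_ip = NULL, sf_input = NULL) {
  mu_m <- stage_matrix(mu, "peak_id")
  n <- nrow(mu_m)
  if (is.null(weights)) weights <- matrix(1, n, 4)
  sf_ip <- sf_ip %||% setNames(exp(runif(4, log(0.5), log(2))), STAGES)
  sf_input <- sf_input %||% setNames(exp(runif(4, log(0.5), log(2))), STAGES)

  m_in <- depth_mean * weights * matrix(sf_input[STAGES], n, 4, byrow = TRUE)
  m_ip <- depth_mean * weights * mu_m * matrix(sf_ip[STAGES], n, 4, byrow = TRUE)
  draw <- function(m) {
    cnt <- matrix(rnbinom(length(m), mu = m, size = dispersion * m), nrow(m), 4,
                  dimnames = list(rownames(mu_m), STAGES))
    cnt
  }
  ip <- draw(m_ip); input <- draw(m_in)
  lib <- 20 * depth_mean * n
  out <- stage_counts(matrix_tibble(ip, "peak_id"), matrix_tibble(input, "peak_id"),
                      ip_libsize = round(lib * sf_ip),
                      input_libsize = round(lib * sf_input))
  attr(out, "input_mean") <- m_in
  attr(out, "ip_mean") <- m_ip
  out
}

## ---- full study ----------------------------------------------------------

#' Simulate a complete four-stage study with planted truth
#'
#' Generates a toy genome and peak catalog, per-peak methylation
#' trajectories realizing the configured change-class/origin structure,
#' regulator-coupled target genes, co-dynamics-labelled accessibility, TF
#' binding scores, peak sequences, and negative-binomial IP/input counts.
#' All ground-truth labels are re-derived from the noiseless trajectories by
#' the pipeline's own rules, so planted truth and pipeline semantics agree
#' exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `m6a_simulation`: a list with `peaks`,
#'   `annotation`, `counts` ([stage_counts()]), `expression`,
#'   `accessibility`, `tf_binding`, `regulators`, `sequences`, `truth`
#'   (peak/gene labels, targets, true trajectories) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  regs <- regulator_templates()
  n_g <- cfg$n_genes
  if (n_g < nrow(regs) + 3 * cfg$n_targets) {
    abort("n_genes too small for the regulator panel and planted targets")
  }
  gene_id <- c(regs$name, sprintf("gene_%04d", seq_len(n_g - nrow(regs))))

  annotation <- toy_annotation(gene_id)
  peaks0 <- toy_peaks(cfg$n_peaks, annotation)

  ## per-gene change class and origin
  class_g <- sample(0:3, n_g, replace = TRUE,
                    prob = c(cfg$frac_unchanged, cfg$frac_change_once,
                             cfg$frac_change_twice, cfg$frac_change_thrice))
  p_late <- (1 - cfg$frac_origin_D0 - cfg$frac_unmodified) / 3
  origin_g <- sample(1:5, n_g, replace = TRUE,
                     prob = c(cfg$frac_origin_D0, rep(p_late, 3), cfg$frac_unmodified))
  ## a class-0 peak cannot cross into the HIGH band mid-course
  origin_g[class_g == 0 & origin_g %in% 2:4] <- 1L

  pattern <- matrix(FALSE, n_g, 3)
  for (i in seq_len(n_g)) {
    forced <- if (origin_g[i] %in% 2:4) origin_g[i] - 1L else NA_integer_
    pattern[i, ] <- sample_pattern(class_g[i], forced)
  }

  mu_g <- build_mu(pattern, origin_g, jitter = cfg$stasis_jitter)
  rownames(mu_g) <- gene_id

  ## background expression
  e0 <- rlnorm(n_g, log(50), 0.8)
  efac <- matrix(exp(runif(n_g * 3, log(0.75), log(1.33))), n_g, 3)
  expr_g <- cbind(e0, e0 * t(apply(efac, 1, cumprod)))
  colnames(expr_g) <- STAGES
  rownames(expr_g) <- gene_id

  ## regulator genes carry their templates and mildly varying m6A
  ri <- match(regs$name, gene_id)
  expr_g[ri, ] <- as.matrix(regs[, STAGES])
  mu_g[ri, 1] <- runif(length(ri), 1.9, 2.6)
  for (t in 1:3) mu_g[ri, t + 1] <- mu_g[ri, t] * runif(length(ri), 0.97, 1.03)

  ## choose targets, then decorrelate the remaining background from the
  ## targeted regulators so planted couplings are identifiable from 4 points
  pool <- setdiff(gene_id, regs$name)
  n_need <- 3 * cfg$n_targets
  target_ids <- if (n_need > 0) sample_safe(pool, n_need) else character(0)
  bg <- setdiff(pool, target_ids)
  regz <- t(as.matrix(regs[match(names(TARGETED_REGULATORS), regs$name), STAGES]))

  bi <- match(bg, gene_id)
  for (round in 1:100) {
    viol_mu <- apply(abs(suppressWarnings(cor(t(mu_g[bi, , drop = FALSE]), regz))) > 0.8,
                     1, any)
    viol_ex <- apply(abs(suppressWarnings(cor(t(expr_g[bi, , drop = FALSE]), regz))) > 0.8,
                     1, any)
    viol_mu[is.na(viol_mu)] <- FALSE; viol_ex[is.na(viol_ex)] <- FALSE
    if (!any(viol_mu) && !any(viol_ex)) break
    vm <- bi[viol_mu]
    if (length(vm) > 0) {
      newpat <- matrix(FALSE, length(vm), 3)
      for (j in seq_along(vm)) {
        forced <- if (origin_g[vm[j]] %in% 2:4) origin_g[vm[j]] - 1L else NA_integer_
        newpat[j, ] <- sample_pattern(class_g[vm[j]], forced)
      }
      pattern[vm, ] <- newpat
      mu_g[vm, ] <- build_mu(newpat, origin_g[vm], jitter = cfg$stasis_jitter)
    }
    ve <- bi[viol_ex]
    if (length(ve) > 0) {
      f <- matrix(exp(runif(length(ve) * 3, log(0.75), log(1.33))), length(ve), 3)
      expr_g[ve, ] <- cbind(e0[ve], e0[ve] * t(apply(f, 1, cumprod)))
    }
  }

  planted <- plant_regulator_targets(
    cfg, matrix_tibble(expr_g, "gene_id"), matrix_tibble(mu_g, "gene_id"),
    regulators = regs, target_genes = target_ids)
  expr_g <- stage_matrix(planted$expression, "gene_id")
  mu_g <- stage_matrix(planted$mu, "gene_id")

  acc <- plant_accessibility(cfg, planted$mu)

  ## peak-level truth: peaks inherit their gene's trajectory
  gi <- match(peaks0$gene_id, gene_id)
  mu_p <- mu_g[gi, , drop = FALSE]
  rownames(mu_p) <- peaks0$peak_id

  ## derived labels from the noiseless trajectories (pipeline's own rules)
  truth_peak <- derive_truth(mu_p, cfg) %>%
    mutate(gene_id = peaks0$gene_id, .after = "peak_id")
  truth_gene <- derive_truth(mu_g, cfg) %>%
    rename(gene_id = "peak_id") %>%
    left_join(acc$categories, by = "gene_id")

  ## counts: input abundance proportional to expression
  w <- expr_g[gi, , drop = FALSE]
  w <- sweep(w, 2, colMeans(expr_g), "/")
  counts <- simulate_counts(matrix_tibble(mu_p, "peak_id"),
                            depth_mean = cfg$depth_mean,
                            dispersion = cfg$dispersion, weights = w)

  tfb <- toy_tf_binding(mu_g)
  seqs <- toy_sequences(peaks0)

  structure(list(
    config = cfg,
    peaks = peaks0,
    annotation = annotation,
    counts = counts,
    expression = matrix_tibble(expr_g, "gene_id"),
    accessibility = acc$accessibility,
    tf_binding = tfb,
    regulators = regs,
    sequences = seqs,
    truth = list(mu_peak = matrix_tibble(mu_p, "peak_id"),
                 mu_gene = matrix_tibble(mu_g, "gene_id"),
                 peak = truth_peak, gene = truth_gene,
                 targets = planted$targets,
                 input_mean = attr(counts, "input_mean"))),
    class = "m6a_simulation")
}

## Labels implied by a noiseless trajectory matrix under the pipeline rules.
derive_truth <- function(mu, cfg) {
  fc <- sym_fc(transition_ratios(mu))
  chg <- fc > cfg$fc_threshold
  modified <- mu > cfg$mod_threshold
  first_mod <- apply(modified, 1, function(x) if (any(x)) which(x)[1] else 5L)
  tibble(peak_id = rownames(mu),
         change_count = rowSums(chg),
         origin = c(STAGES, "never")[first_mod],
         m6a_changed = rowSums(chg) > 0)
}

#' @export
print.m6a_simulation <- function(x, ...) {
  cat("<m6a_simulation> ", nrow(x$peaks), " peaks / ", nrow(x$expression),
      " genes, depth_mean = ", x$config$depth_mean,
      ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

## ---- toy genome, sequences, TF binding -----------------------------------

toy_annotation <- function(gene_id) {
  n <- length(gene_id)
  chrom <- paste0("chr", (seq_len(n) - 1) %/% 50 + 1)
  tx_len <- sample(2000:6000, n, replace = TRUE)
  gap <- sample(500:2000, n, replace = TRUE)
  tx_start <- integer(n)
  cursor <- list()
  for (i in seq_len(n)) {
    cur <- cursor[[chrom[i]]] %||% 0L
    tx_start[i] <- cur + gap[i]
    cursor[[chrom[i]]] <- tx_start[i] + tx_len[i]
  }
  utr5 <- pmax(100L, as.integer(round(0.1 * tx_len)))
  utr3 <- pmax(100L, as.integer(round(0.3 * tx_len)))
  tibble(gene_id = gene_id, chrom = chrom,
         strand = sample(c("+", "-"), n, replace = TRUE),
         tx_start = tx_start, tx_end = tx_start + tx_len,
         cds_start = tx_start + utr5, cds_end = tx_start + tx_len - utr3)
}

toy_peaks <- function(n_peaks, annotation) {
  n_g <- nrow(annotation)
  gene_of <- c(seq_len(n_g), sample.int(n_g, n_peaks - n_g, replace = TRUE))
  gene_of <- sort(gene_of)
  width <- sample(100:200, n_peaks, replace = TRUE)
  ann <- annotation[gene_of, ]
  stop_pos <- ifelse(ann$strand == "-", ann$cds_start, ann$cds_end)
  near_stop <- runif(n_peaks) < 0.6
  mid <- ifelse(near_stop,
                stop_pos + sample(-120:120, n_peaks, replace = TRUE),
                ann$cds_start +
                  floor(runif(n_peaks) * (ann$tx_end - ann$cds_start)))
  start <- pmax(ann$tx_start, as.integer(mid - width %/% 2))
  end <- pmin(ann$tx_end, start + width)
  start <- pmin(start, end - 50L)
  peaks <- tibble(peak_id = sprintf("peak_%05d", seq_len(n_peaks)),
                  chrom = ann$chrom, start = start, end = end, strand = ann$strand)
  annotate_peaks(peaks, annotation)
}

toy_sequences <- function(peaks) {
  n <- nrow(peaks)
  width <- peaks$end - peaks$start
  seqs <- vapply(width, function(w) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  has_motif <- runif(n) < 0.85
  for (i in which(has_motif)) {
    pos <- sample.int(width[i] - 5L, 1)
    substr(seqs[i], pos, pos + 4L) <- "GGACT"
  }
  setNames(seqs, peaks$peak_id)
}

toy_tf_binding <- function(mu_g) {
  genes <- rownames(mu_g)
  n <- length(genes)
  specs <- list(list(tf = "NANOG", stage = "D0", coupled = FALSE),
                list(tf = "NANOG", stage = "D15", coupled = FALSE),
                list(tf = "POU5F1", stage = "D0", coupled = TRUE),
                list(tf = "POU5F1", stage = "D15", coupled = FALSE),
                list(tf = "GATA4", stage = "D0", coupled = FALSE),
                list(tf = "GATA4", stage = "D15", coupled = TRUE))
  purrr::map_dfr(specs, function(s) {
    score <- rlnorm(n, log(20), 0.5)
    if (s$coupled) score <- score * exp(0.5 * as.numeric(scale(log(mu_g[, s$stage]))))
    tibble(gene_id = genes, tf = s$tf, stage = s$stage, score = score)
  })
}

#' Write a simulated study to disk
#'
#' Emits the same plain-text files the reading functions accept: a BED6 peak
#' catalog, GTF and TSV annotation, IP/input count and library-size TSVs,
#' expression/accessibility/TF-binding/regulator tables, peak sequences, and
#' `truth_`-prefixed ground-truth tables.
#'
#' @param sim An [simulate_study()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$peaks
  readr::write_tsv(tibble(p$chrom, p$start, p$end, p$peak_id, 0L, p$strand),
                   file.path(dir, "peaks.bed"), col_names = FALSE, progress = FALSE)
  write_toy_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(sim$counts$ip, file.path(dir, "counts_ip.tsv"), progress = FALSE)
  readr::write_tsv(sim$counts$input, file.path(dir, "counts_input.tsv"), progress = FALSE)
  readr::write_tsv(tibble(stage = STAGES,
                          ip_libsize = as.numeric(sim$counts$ip_libsize),
                          input_libsize = as.numeric(sim$counts$input_libsize)),
                   file.path(dir, "libsizes.tsv"), progress = FALSE)
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(sim$accessibility, file.path(dir, "accessibility.tsv"), progress = FALSE)
  readr::write_tsv(sim$tf_binding, file.path(dir, "tf_binding.tsv"), progress = FALSE)
  readr::write_tsv(sim$regulators, file.path(dir, "regulators.tsv"), progress = FALSE)
  readr::write_tsv(tibble(peak_id = names(sim$sequences), sequence = sim$sequences),
                   file.path(dir, "peak_sequences.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$peak, file.path(dir, "truth_peaks.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$gene, file.path(dir, "truth_genes.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$targets, file.path(dir, "truth_targets.tsv"), progress = FALSE)
  invisible(dir)
}

write_toy_gtf <- function(ann, path) {
  gene_lines <- sprintf(
    '%s\tm6adyn\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    ann$chrom, ann$tx_start + 1L, ann$tx_end, ann$strand, ann$gene_id)
  cds_lines <- sprintf(
    '%s\tm6adyn\tCDS\t%d\t%d\t.\t%s\t0\tgene_id "%s";',
    ann$chrom, ann$cds_start + 1L, ann$cds_end, ann$strand, ann$gene_id)
  writeLines(c(gene_lines, cds_lines), path)
}
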