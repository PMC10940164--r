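series5 <- c("WT", "DKO", "TKO", "QKO", "PKO")

centred_from_matrix <- function(m, design, ids = sprintf("Y%03d", seq_len(nrow(m)))) {
  colnames(m) <- design$sample_id
  dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(m))
}

test_that("the indicator matrix is the cumulative-deletion staircase", {
  des <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    genotype = series5
  )
  ad <- build_design(des, series5)
  expect_equal(unname(ad$X),
               rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0),
                     c(1, 1, 1, 0), c(1, 1, 1, 1)))
  expect_equal(colnames(ad$X),
               c("WT->DKO", "DKO->TKO", "TKO->QKO", "QKO->PKO"))

  des3 <- plex_design(sim_config(n_proteins = 1, n_er = 0, receptors = NULL,
                                 replicates = 3, seed = 1))
  ad3 <- build_design(des3, series5)
  expect_equal(dim(ad3$X), c(15L, 4L))
  expect_equal(unname(colSums(ad3$X)), c(12, 9, 6, 3))
})

test_that("designs missing a mutant genotype are rejected as rank-deficient", {
  wt_only <- tibble::tibble(sample_id = paste0("s", 1:4),
                            genotype = rep("WT", 4))
  expect_error(build_design(wt_only, series5), "rank-deficient")
  expect_error(
    build_design(tibble::tibble(sample_id = "s1", genotype = "XKO"), series5),
    "outside the series"
  )
})

test_that("noise-free staircase means invert to the exact coefficients", {
  cfg <- sim_config(n_proteins = 1, n_er = 0, receptors = NULL,
                    replicates = 3, seed = 1)
  des <- plex_design(cfg)
  g <- match(des$genotype, series5)
  y_means <- c(0, 1, 1, 1, 1)      # genotype-level values
  cen <- centred_from_matrix(matrix(y_means[g], nrow = 1), des)
  fit <- fit_allelic(cen, des)
  expect_equal(unname(fit$beta[1, ]), c(1, 0, 0, 0))
  expect_equal(fit$flag[1], "zero_residual")
  # all-zero y: zero coefficients, degenerate p reported as 1
  cen0 <- centred_from_matrix(matrix(0, nrow = 1, ncol = 15), des)
  fit0 <- fit_allelic(cen0, des)
  expect_equal(unname(fit0$beta[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(fit0$p[1, ]), rep(1, 4))
  expect_equal(fit0$flag[1], "zero_residual")
})

test_that("solver coefficients equal the closed form on unbalanced designs", {
  set.seed(71)
  max_dev <- 0
  for (i in 1:300) {
    reps <- c(sample(1:4, 1), sample(1:4, 4, replace = TRUE))
    des <- tibble::tibble(
      genotype = rep(series5, times = reps),
      sample_id = paste0(rep(series5, times = reps), "_",
                         unlist(lapply(reps, seq_len)))
    )
    y <- rnorm(sum(reps))
    y <- y - mean(y[des$genotype == "WT"])   # reference-centred
    cen <- centred_from_matrix(matrix(y, nrow = 1), des)
    oracle <- allelicER:::beta_closed_form(y, des$genotype, series5)
    for (ic in c("nuisance", "none")) {
      fit <- suppressWarnings(fit_allelic(cen, des, intercept = ic))
      max_dev <- max(max_dev, max(abs(fit$beta[1, ] - oracle)))
    }
  }
  expect_lt(max_dev, 1e-10)
})

test_that("both inference modes agree with their lm() counterparts", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  ad <- build_design(s$design, series5)
  fit_nuis <- fit_allelic(s$centred, s$design)
  fit_pin <- fit_allelic(s$centred, s$design, intercept = "none")
  for (i in c(1, 7, 50)) {
    y <- unlist(s$centred[i, ad$sample_id])
    # pinned reference: no-intercept lm on centred values
    sm_pin <- summary(lm(y ~ ad$X - 1))
    expect_equal(unname(fit_pin$beta[i, ]),
                 unname(sm_pin$coefficients[, 1]), tolerance = 1e-10)
    expect_equal(unname(fit_pin$se[i, ]),
                 unname(sm_pin$coefficients[, 2]), tolerance = 1e-10)
    expect_equal(unname(fit_pin$p[i, ]),
                 unname(sm_pin$coefficients[, 4]), tolerance = 1e-10)
    # nuisance intercept: same coefficients, reference uncertainty kept
    sm_nuis <- summary(lm(y ~ ad$X))
    expect_equal(unname(fit_nuis$beta[i, ]),
                 unname(sm_nuis$coefficients[-1, 1]), tolerance = 1e-10)
    expect_equal(unname(fit_nuis$se[i, ]),
                 unname(sm_nuis$coefficients[-1, 2]), tolerance = 1e-10)
    expect_equal(unname(fit_nuis$p[i, ]),
                 unname(sm_nuis$coefficients[-1, 4]), tolerance = 1e-10)
    # the two modes share every point estimate on centred data
    expect_equal(fit_nuis$beta[i, ], fit_pin$beta[i, ], tolerance = 1e-10)
  }
  expect_equal(glance(fit_nuis)$df_residual, 15 - 5)
  expect_equal(glance(fit_pin)$df_residual, 15 - 4)
})

test_that("beta3 is the mean change from triple to quadruple knockout", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  qko <- s$design$sample_id[s$design$genotype == "QKO"]
  tko <- s$design$sample_id[s$design$genotype == "TKO"]
  diff_means <- rowMeans(as.matrix(s$centred[, qko])) -
    rowMeans(as.matrix(s$centred[, tko]))
  expect_equal(unname(fit$beta[, "TKO->QKO"]), unname(diff_means),
               tolerance = 1e-10)
})

test_that("adding a constant to all mutant samples shifts only beta1", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  shifted <- s$centred
  mut <- s$design$sample_id[s$design$genotype != "WT"]
  for (col in mut) shifted[[col]] <- shifted[[col]] + 0.7
  fit2 <- fit_allelic(shifted, s$design)
  expect_equal(fit2$beta[, 1], fit$beta[, 1] + 0.7, tolerance = 1e-10)
  expect_equal(fit2$beta[, 2:4], fit$beta[, 2:4], tolerance = 1e-10)
})

test_that("noise-free synthetic data is recovered exactly through the fit", {
  cfg <- sim_config(n_proteins = 200, n_er = 40, noise_sigma = 0, seed = 13)
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  truth_beta <- as.matrix(s$truth[match(fit$protein_id, s$truth$protein_id),
                                  paste0("beta", 1:4)])
  expect_lt(max(abs(fit$beta - truth_beta)), 1e-10)
})

test_that("a deleted receptor shows its step effect and nothing afterwards", {
  cfg <- sim_config(n_proteins = 300, n_er = 60, noise_sigma = 0, seed = 17)
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  i <- match("FAM134A", fit$protein_id)
  expect_equal(unname(fit$beta[i, ]), c(-2.5, 0, 0, 0), tolerance = 1e-10)
  # subsequent steps: coefficient zero, reported non-significant
  expect_equal(unname(fit$p[i, 2:4]), rep(1, 3))
})

test_that("extra genotypes in the plex are dropped before fitting", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  extra <- tibble::tibble(channel = "ch99", sample_id = "ATG12KO_1",
                          genotype = "ATG12KO", replicate = 1L,
                          condition = "base")
  des2 <- dplyr::bind_rows(s$design, extra)
  cen2 <- s$centred
  cen2$ATG12KO_1 <- rnorm(nrow(cen2))
  expect_message(fit <- fit_allelic(cen2, des2), "dropped")
  ref <- fit_allelic(s$centred, s$design)
  expect_equal(fit$beta, ref$beta)
  expect_error(fit_allelic(cen2, des2, extra_genotypes = "error"),
               "outside the series")
})

test_that("per-step BH and significance flow into the tidy view", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$protein_id) * 4L)
  for (j in seq_len(4)) {
    expect_equal(unname(fit$p_adjusted[, j]), bh_oracle(fit$p[, j]))
  }
  expect_true(all(td$p.adjusted >= td$p.value, na.rm = TRUE))
})

test_that("nuisance-intercept inference is calibrated where pinning is not", {
  # under the global null, step-1 p-values: pinned reference understates
  # Var(beta1) two-fold, nuisance intercept propagates it correctly
  p1_pin <- c()
  p1_nuis <- c()
  for (s in 1:3) {
    cfg <- sim_config_null(n_proteins = 1000, n_er = 0, seed = 900 + s)
    sdat <- sim_centred(cfg)
    p1_pin <- c(p1_pin,
                fit_allelic(sdat$centred, sdat$design,
                            intercept = "none")$p[, 1])
    p1_nuis <- c(p1_nuis, fit_allelic(sdat$centred, sdat$design)$p[, 1])
  }
  band <- 3 * sqrt(0.05 * 0.95 / length(p1_nuis))
  expect_lt(abs(mean(p1_nuis < 0.05) - 0.05), band)
  expect_gt(mean(p1_pin < 0.05), 0.09)  # anti-conservative by ~2x variance
})

test_that("group summaries average coefficients and conserve counts", {
  cfg <- small_config()
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  ann <- parse_annotations(sim_annotations(s$truth, seed = 1))
  sm <- summarize_beta(fit, ann, group = "er_class")
  expect_equal(sum(sm$n[sm$step == "WT->DKO"]), length(fit$protein_id))
  # two-protein toy group: mean of 0.1 and 0.3 is 0.2
  toy_ann <- tibble::tibble(protein_id = c("A", "B"), er_class = "ER-lumen")
  des <- s$design
  m <- matrix(0, nrow = 2, ncol = nrow(des))
  g <- match(des$genotype, series5)
  m[1, ] <- c(0, 0.1, 0.1, 0.1, 0.1)[g]
  m[2, ] <- c(0, 0.3, 0.3, 0.3, 0.3)[g]
  toy_fit <- fit_allelic(centred_from_matrix(m, des, ids = c("A", "B")), des)
  toy_sm <- summarize_beta(toy_fit, toy_ann)
  expect_equal(toy_sm$mean_beta[toy_sm$step == "WT->DKO"], 0.2)
  expect_equal(toy_sm$n[toy_sm$step == "WT->DKO"], 2L)
})

test_that("group mean recovery tracks the simulated ER signature", {
  cfg <- sim_config(n_proteins = 800, n_er = 200, seed = 23)
  s <- sim_centred(cfg)
  fit <- fit_allelic(s$centred, s$design)
  er_ids <- s$truth$protein_id[s$truth$er_class != "none"]
  ann <- tibble::tibble(protein_id = er_ids, group = "ER")
  sm <- summarize_beta(fit, ann, group = "group")
  est <- sm$mean_beta[sm$group == "ER" & sm$step == "WT->DKO"]
  truth_mean <- mean(s$truth$beta1[s$truth$er_class != "none"])
  se <- sd(fit$beta[fit$protein_id %in% er_ids, 1]) / sqrt(length(er_ids))
  expect_lt(abs(est - truth_mean), 4 * se)
})

test_that("ranking partitions, breaks ties by accession and stars significance", {
  set.seed(3)
  vals <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:30),
    log2fc = seq(3, -3, length.out = 30),
    p_adjusted = rep(c(0.01, 0.5), 15)
  )
  rk <- rank_top(vals, n_top = 25, n_bottom = 5)
  expect_equal(nrow(rk), 30L)
  expect_setequal(rk$protein_id, vals$protein_id)
  expect_true(all(rk$value[rk$direction == "top"] >=
                  max(rk$value[rk$direction == "bottom"])))
  expect_true(all(grepl("\\*$", rk$label[rk$p_adjusted < 0.05])))
  # tie on the value: accession order decides
  tie <- tibble::tibble(protein_id = c("B", "A"), log2fc = c(1, 1))
  rk2 <- rank_top(tie, n_top = 1, n_bottom = 1)
  expect_equal(rk2$protein_id[rk2$direction == "top"], "A")
})

test_that("constructed strong step-4 effects all reach the step-4 top 25", {
  cfg <- sim_config(n_proteins = 400, n_er = 0, receptors = NULL,
                    effect_sparsity = 0.1, effect_scale = 0.3, seed = 29)
  truth <- generate_truth(cfg)
  idx <- sample(nrow(truth), 10)
  truth$beta4[idx] <- 3 + runif(10)
  pq <- simulate_protein_matrix(truth, cfg)
  des <- plex_design(cfg)
  fit <- fit_allelic(center_log2(pq, des), des)
  rk <- rank_top(fit, step = "QKO->PKO", n_top = 25, n_bottom = 5)
  expect_true(all(truth$protein_id[idx] %in%
                  rk$protein_id[rk$direction == "top"]))
})
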