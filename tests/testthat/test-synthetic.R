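test_that("reference panel construction: marker geometry and determinism", {
  p <- make_reference_panel(K = 2, markers_per_type = 1, n_background = 5,
                            seed = 1)
  mk <- which(attr(p, "is_marker"))
  expect_length(mk, 2)
  # a single direct-polarity marker separates its own column by >= 0.6
  expect_gte(abs(p[mk[1], 1] - p[mk[1], 2]), 0.6)
  # background rows identical across cell types
  bg <- unclass(p)[!attr(p, "is_marker"), ]
  expect_equal(bg[, 1], bg[, 2])

  expect_identical(make_reference_panel(K = 3, markers_per_type = 4,
                                        n_background = 7, seed = 9),
                   make_reference_panel(K = 3, markers_per_type = 4,
                                        n_background = 7, seed = 9))
  expect_error(make_reference_panel(K = 1), "K must be")

  p12 <- make_reference_panel(K = 12, markers_per_type = 50,
                              n_background = 10, seed = 2)
  expect_equal(sum(attr(p12, "is_marker")), 600)
  expect_equal(colnames(p12), blood_cell_types())
})

test_that("noise-free cohort is an exact mixture of the panel", {
  panel <- tiny_panel()
  cfg <- sim_config(n_samples = 8, cell_types = colnames(panel),
                    markers_per_type = 10, n_background = 40,
                    dirichlet_weights = setNames(rep(1, 4), colnames(panel)),
                    noise_sd = 0, batch_sd = 0)
  co <- simulate_cohort(cfg, panel, "c1", seed = 3)
  W <- unclass(co$truth$fractions)
  expect_equal(unname(unclass(co$beta)),
               unname(unclass(panel) %*% t(W)), tolerance = 1e-12)
  expect_equal(rowSums(W), setNames(rep(1, 8), rownames(W)))
  expect_identical(simulate_cohort(cfg, panel, "c1", seed = 3)$beta, co$beta)
})

test_that("planted DMCs shift only the target cell type's contribution", {
  panel <- tiny_panel(n_background = 10)
  dmc <- data.frame(cpg_id = "bg_00001", target = "CT1",
                    covariate = "condition", slope = 0.3)
  cfg <- sim_config(n_samples = 40, cell_types = colnames(panel),
                    markers_per_type = 10, n_background = 10,
                    dirichlet_weights = setNames(rep(1, 4), colnames(panel)),
                    dmc_spec = dmc, noise_sd = 0, batch_sd = 0)
  co <- simulate_cohort(cfg, panel, "c1", seed = 4)
  W <- unclass(co$truth$fractions)
  base <- unclass(panel) %*% t(W)
  delta <- unclass(co$beta)["bg_00001", ] - base["bg_00001", ]
  cases <- co$samples$condition == 1
  expect_equal(unname(delta[cases]), unname(0.3 * W[cases, "CT1"]),
               tolerance = 1e-12)
  expect_equal(unname(delta[!cases]), rep(0, sum(!cases)))
  # unknown DMC CpG is rejected
  cfg2 <- cfg; cfg2$dmc_spec$cpg_id <- "nope"
  expect_error(simulate_cohort(cfg2, panel, "c1", seed = 4), "not in panel")
})

test_that("acute regime raises the neutrophil fraction in cases", {
  panel <- blood_panel(markers_per_type = 2, n_background = 5)
  cfg <- sim_config(n_samples = 400, regime = "acute",
                    markers_per_type = 2, n_background = 5,
                    noise_sd = 0, batch_sd = 0)
  hits <- vapply(1:100, function(s) {
    co <- simulate_cohort(cfg, panel, "c", seed = s)
    W <- unclass(co$truth$fractions)
    w <- wilcox.test(W[co$samples$condition == 1, "Neu"],
                     W[co$samples$condition == 0, "Neu"],
                     alternative = "greater")
    w$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("with no regime the neutrophil fraction is independent of condition", {
  panel <- blood_panel(markers_per_type = 2, n_background = 5)
  cfg <- sim_config(n_samples = 200, regime = "none",
                    markers_per_type = 2, n_background = 5,
                    noise_sd = 0, batch_sd = 0)
  covers <- vapply(1:100, function(s) {
    co <- simulate_cohort(cfg, panel, "c", seed = s)
    f <- lm(unclass(co$truth$fractions)[, "Neu"] ~ co$samples$condition)
    ci <- confint(f)[2, ]
    ci[1] < 0 && ci[2] > 0
  }, logical(1))
  expect_gte(mean(covers), 0.90)
})

test_that("inflammaging tilt is monotone in gamma", {
  panel <- blood_panel(markers_per_type = 2, n_background = 5)
  gap <- vapply(c(0, 0.02, 0.05), function(g) {
    cfg <- sim_config(n_samples = 600, regime = "inflammaging",
                      inflammaging_gamma = g, markers_per_type = 2,
                      n_background = 5, noise_sd = 0, batch_sd = 0)
    co <- simulate_cohort(cfg, panel, "c", seed = 7)
    W <- unclass(co$truth$fractions)
    mean(W[, "CD4Tmem"] - W[, "CD4Tnv"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("multi-cohort simulation: independent batches, labels, seeds", {
  panel <- tiny_panel(n_background = 20)
  cfg <- sim_config(n_samples = 30, cell_types = colnames(panel),
                    markers_per_type = 10, n_background = 20,
                    dirichlet_weights = setNames(rep(1, 4), colnames(panel)))
  mc <- simulate_multi_cohort(cfg, panel, paste0("c", 1:5), seeds = 1:5)
  expect_length(mc$cohorts, 5)
  expect_equal(nrow(mc$samples), 150)
  expect_setequal(unique(mc$samples$cohort), paste0("c", 1:5))
  batches <- sapply(mc$cohorts, function(co) co$truth$batch)
  expect_equal(nrow(unique(t(batches))), 5)  # 5 distinct offset vectors
  fr1 <- unclass(mc$cohorts$c1$truth$fractions)
  fr2 <- unclass(mc$cohorts$c2$truth$fractions)
  expect_false(isTRUE(all.equal(unname(fr1), unname(fr2))))
  expect_error(simulate_multi_cohort(cfg, panel, c("a", "a"), seeds = 1:2),
               "duplicate cohort_id")

  # with batch_sd = 0, cohort means of background CpGs agree within noise
  cfg0 <- sim_config(n_samples = 200, cell_types = colnames(panel),
                     markers_per_type = 10, n_background = 20,
                     dirichlet_weights = setNames(rep(1, 4), colnames(panel)),
                     batch_sd = 0)
  mc0 <- simulate_multi_cohort(cfg0, panel, c("a", "b"), seeds = c(1, 2))
  bg <- rownames(panel)[!attr(panel, "is_marker")]
  m1 <- rowMeans(unclass(mc0$cohorts$a$beta)[bg, ])
  m2 <- rowMeans(unclass(mc0$cohorts$b$beta)[bg, ])
  expect_lt(max(abs(m1 - m2)), 0.02)
})

test_that("synthetic clock and signature track the intended cell types", {
  panel <- blood_panel(markers_per_type = 20, n_background = 10)
  ck <- synth_clock(panel, n_cpgs = 15, seed = 1)
  expect_true(all(ck$entries$coefficient > 0))
  expect_true(all(grepl("^mk_Neu_", ck$entries$cpg_id)))
  sig <- synth_signature(panel)
  expect_true(all(sig$entries$sign %in% c(-1, 1)))
  types <- sub("^mk_([A-Za-z0-9]+)_.*$", "\\1", sig$entries$cpg_id)
  expect_setequal(unique(types),
                  c("Bmem", "CD4Tmem", "CD8Tmem", "NK",
                    "Bnv", "CD4Tnv", "CD8Tnv"))
  expect_error(synth_clock(panel, n_cpgs = 100), "only")
})
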