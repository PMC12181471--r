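make_clock <- function() {
  clock_definition(data.frame(cpg_id = c("cg1", "cg2"),
                              coefficient = c(20, 30),
                              rectify = c(FALSE, TRUE)), intercept = 10)
}

test_that("rectification flips flagged rows and is an involution", {
  bm <- tiny_beta(matrix(c(0.8, 0.2, 0.3, 0.6, 0.1, 0.9), 3, 2),
                  cpgs = c("cg1", "cg2", "cg3"))
  ck <- make_clock()
  r <- rectify_betas(bm, ck)
  expect_equal(unclass(r)["cg2", ], 1 - unclass(bm)["cg2", ])
  expect_equal(unclass(r)["cg1", ], unclass(bm)["cg1", ])    # flag off
  expect_equal(unclass(rectify_betas(r, ck)), unclass(bm))   # involution
  ck0 <- clock_definition(data.frame(cpg_id = c("cg1", "cg2"),
                                     coefficient = c(20, 30),
                                     rectify = c(FALSE, FALSE)), intercept = 10)
  expect_equal(unclass(rectify_betas(bm, ck0)), unclass(bm)) # identity
})

test_that("apply_clock reproduces the hand-computed linear predictor", {
  # intercept 10; cg1 coef 20 flag off beta .5; cg2 coef 30 flag on beta .8
  bm <- tiny_beta(matrix(c(0.5, 0.8, 0.5, 0.8), 2, 2),
                  cpgs = c("cg1", "cg2"))
  expect_equal(unname(apply_clock(bm, make_clock())), c(26, 26))
  # all betas zero, no flags: the intercept comes back
  bm0 <- tiny_beta(matrix(0, 2, 2), cpgs = c("cg1", "cg2"))
  ck0 <- clock_definition(data.frame(cpg_id = c("cg1", "cg2"),
                                     coefficient = c(20, 30),
                                     rectify = c(FALSE, FALSE)), intercept = 10)
  expect_equal(unname(apply_clock(bm0, ck0)), c(10, 10))
  # doubling coefficients doubles the age above the intercept
  ck2 <- clock_definition(data.frame(cpg_id = c("cg1", "cg2"),
                                     coefficient = c(40, 60),
                                     rectify = c(FALSE, TRUE)), intercept = 10)
  expect_equal(apply_clock(bm, ck2) - 10, 2 * (apply_clock(bm, make_clock()) - 10))
  ckX <- clock_definition(data.frame(cpg_id = c("cg1", "cgX"),
                                     coefficient = c(20, 30),
                                     rectify = c(FALSE, TRUE)), intercept = 10)
  expect_error(apply_clock(tiny_beta(), ckX, policy = "strict"),
               "missing CpG")
  ckZ <- clock_definition(data.frame(cpg_id = "cgZ", coefficient = 1,
                                     rectify = FALSE), intercept = 10)
  expect_error(apply_clock(tiny_beta(), ckZ), "none of the clock")
})

test_that("EAA residuals: zero for affine maps, OLS oracle on 3 points", {
  age <- c(20, 30, 40)
  expect_equal(unname(compute_eaa(age, age)), rep(0, 3))
  expect_equal(unname(compute_eaa(2 * age + 5, age)), rep(0, 3))
  dnam <- c(22, 28, 40)
  b <- ols_oracle(dnam, age)
  expect_equal(unname(compute_eaa(dnam, age)),
               unname(dnam - b[1] - b[2] * age))
  expect_error(compute_eaa(c(1, 2, 3), c(5, 5, 5)), "age variance zero")
  expect_error(compute_eaa(c(1, 2), c(1, 2)), "at least 3")
})

test_that("EAA properties: mean zero, uncorrelated with age, shift-invariant", {
  set.seed(8)
  age <- runif(50, 20, 80)
  dnam <- 0.9 * age + rnorm(50, 0, 3)
  e <- compute_eaa(dnam, age)
  expect_lt(abs(mean(e)), 1e-10)
  expect_lt(abs(cor(e, age)), 1e-10)
  expect_equal(compute_eaa(dnam + 7, age), e)
  # NA ages propagate as NA residuals without shifting the fit
  age2 <- age; age2[3] <- NA
  e2 <- compute_eaa(dnam, age2)
  expect_true(is.na(e2[3]))
  expect_lt(abs(mean(e2, na.rm = TRUE)), 1e-10)
})

test_that("z-scoring: documented 2-sample example, zero-variance handling", {
  bm <- tiny_beta(matrix(c(0.2, 0.3, 0.4, 0.3), 2, 2),
                  cpgs = c("cgA", "cgConst"))
  z <- zscore_by_cpg(bm)
  expect_equal(unname(z["cgA", ]), c(-sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(attr(z, "dropped"), "cgConst")
  expect_false("cgConst" %in% rownames(z))
  set.seed(1)
  big <- beta_matrix(matrix(runif(200), 20, 10,
                            dimnames = list(paste0("cg", 1:20),
                                            paste0("s", 1:10))))
  zb <- zscore_by_cpg(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-10)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 1e-10)
  expect_error(zscore_by_cpg(tiny_beta(matrix(0.2, 2, 1),
                                       cpgs = c("a", "b"),
                                       samples = "s1")), "at least 2")
})

test_that("inflammation score: perfect, inverted and derived correlations", {
  z <- matrix(c(1, 0, -1, -1, 0, 1, 2, 0, -2), 3, 3,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2", "s3")))
  sig <- signature_definition(data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                                         sign = c(1, 1, -1)))
  sc <- infl_score(z, sig)
  expect_equal(unname(sc["s1"]), sqrt(3) / 2, tolerance = 1e-12)
  # z proportional to the sign vector scores exactly 1; the negation -1
  z2 <- matrix(c(2, 2, -2, -1, -1, 1), 3, 2,
               dimnames = list(c("cg1", "cg2", "cg3"), c("a", "b")))
  sc2 <- infl_score(z2, sig)
  expect_equal(as.numeric(sc2), c(1, -1))
  expect_equal(attr(sc2, "coverage"), 1)
  # fewer than 3 overlapping CpGs is an error; zero-variance sample is NA
  sig2 <- signature_definition(data.frame(cpg_id = c("cg1", "x", "y"),
                                          sign = c(1, -1, 1)))
  expect_error(infl_score(z, sig2), "fewer than 3")
  z3 <- z; z3[, 2] <- 0
  expect_warning(sc3 <- infl_score(z3, sig), "zero-variance")
  expect_true(is.na(sc3["s2"]))
})

test_that("inflammation score is invariant to per-CpG affine rescaling", {
  set.seed(2)
  v <- matrix(runif(80, 0.2, 0.8), 8, 10,
              dimnames = list(paste0("cg", 1:8), paste0("s", 1:10)))
  sig <- signature_definition(data.frame(cpg_id = paste0("cg", 1:8),
                                         sign = rep(c(1, -1), 4)))
  s1 <- infl_score(zscore_by_cpg(beta_matrix(v)), sig)
  v2 <- 0.3 + 0.4 * v  # per-CpG affine map (same for all, absorbed by z)
  s2 <- infl_score(zscore_by_cpg(beta_matrix(v2)), sig)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("composition-tracking clock and signature reproduce the expected
           association patterns on synthetic cohorts", {
  panel <- blood_panel(markers_per_type = 10, n_background = 30)
  # acute regime: EAA of a neutrophil-tracking clock rises with Neu fraction
  cfg_a <- sim_config(n_samples = 150, regime = "acute",
                      markers_per_type = 10, n_background = 30)
  ck <- synth_clock(panel, n_cpgs = 10, seed = 1)
  for (s in 1:3) {
    co <- simulate_cohort(cfg_a, panel, "c", seed = s)
    eaa <- compute_eaa(apply_clock(co$beta, ck), co$samples$age)
    W <- unclass(co$truth$fractions)
    expect_gt(cor(eaa, W[, "Neu"]), 0.5)
    expect_lt(cor(eaa, lymphocyte_fraction(co$truth$fractions)), -0.5)
  }
  # inflammaging regime: signature score rises with memory, falls with naive
  cfg_i <- sim_config(n_samples = 150, regime = "inflammaging",
                      markers_per_type = 10, n_background = 30)
  sig <- synth_signature(panel)
  for (s in 1:3) {
    co <- simulate_cohort(cfg_i, panel, "c", seed = s)
    sc <- infl_score(zscore_by_cpg(co$beta), sig)
    W <- unclass(co$truth$fractions)
    expect_gt(cor(sc, W[, "CD4Tmem"]), 0.2)
    expect_lt(cor(sc, W[, "CD4Tnv"]), -0.2)
  }
})

test_that("score_table assembles per-cohort scores with zero-mean EAA", {
  panel <- blood_panel(markers_per_type = 5, n_background = 20)
  cfg <- sim_config(n_samples = 40, regime = "acute", markers_per_type = 5,
                    n_background = 20)
  mc <- simulate_multi_cohort(cfg, panel, c("a", "b"), seeds = c(1, 2))
  st <- score_table(mc$cohorts, clock = synth_clock(panel, n_cpgs = 5, seed = 3),
                    sig = synth_signature(panel))
  expect_equal(nrow(st), 80)
  for (id in c("a", "b"))
    expect_lt(abs(mean(st$eaa[st$cohort == id])), 1e-8)
  expect_true(all(abs(st$infl_score) <= 1))
})
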