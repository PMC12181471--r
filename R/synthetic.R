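# Multi-cohort simulator. Bulk methylomes are generated as convex mixtures of
# cell-type reference profiles with Dirichlet-distributed fractions; regimes
# tilt the Dirichlet concentrations (acute inflammation: neutrophils up in
# cases; inflammaging: memory/NK up and naive down with age); optional
# cell-type-specific DMCs perturb the reference profile itself; cohorts add
# a shared per-CpG batch offset; measurement noise is Gaussian with the
# observed beta clipped to [0.001, 0.999].

.default_dirichlet_weights <- function() {
  c(Neu = 55, Mono = 8, Eos = 3, Baso = 1, NK = 5, Bnv = 3, Bmem = 2,
    CD4Tnv = 7, CD4Tmem = 6, CD8Tnv = 4, CD8Tmem = 4, Treg = 2)
}

#' Simulation configuration
#'
#' Collects every knob of the cohort simulator with blood-realistic defaults:
#' a blood-like Dirichlet composition prior (neutrophil-dominated, total
#' concentration 30, giving the sample-to-sample composition variability seen
#' in adult whole-blood cohorts), adult age range 20-80 years, measurement
#' noise SD 0.02 on the beta scale and cohort batch offset SD 0.01.
#'
#' @param n_samples Number of samples.
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param cell_types Cell-type labels (default the 12 blood types).
#' @param markers_per_type Marker CpGs per cell type in the matching panel.
#' @param n_background Non-discriminative background CpGs.
#' @param dirichlet_weights Named non-negative weights, one per cell type;
#'   normalized and scaled by `concentration` to give the Dirichlet alphas.
#' @param concentration Total Dirichlet concentration c0.
#' @param regime `"none"`, `"acute"` (neutrophilia in cases) or
#'   `"inflammaging"` (memory/NK up, naive down with age).
#' @param acute_neu_factor Multiplier on the neutrophil alpha in cases under
#'   the acute regime.
#' @param inflammaging_gamma Per-year log-tilt of memory/NK (up) and naive
#'   (down) alphas under the inflammaging regime.
#' @param dmc_spec Optional data frame of planted DMCs with columns
#'   `cpg_id`, `target` (a cell type or `"global"`), `covariate` (`"age"` or
#'   `"condition"`) and `slope` (delta beta per year or per case).
#' @param noise_sd Measurement noise SD on the beta scale.
#' @param batch_sd SD of the per-CpG additive cohort batch offset.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_samples,
                       age_range = c(20, 80),
                       cell_types = blood_cell_types(),
                       markers_per_type = 50,
                       n_background = 2000,
                       dirichlet_weights = .default_dirichlet_weights(),
                       concentration = 30,
                       regime = c("none", "acute", "inflammaging"),
                       acute_neu_factor = 1.6,
                       inflammaging_gamma = 0.02,
                       dmc_spec = NULL,
                       noise_sd = 0.02,
                       batch_sd = 0.01) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 2, length(age_range) == 2, age_range[1] < age_range[2],
            noise_sd >= 0, batch_sd >= 0, concentration > 0,
            acute_neu_factor > 0, markers_per_type >= 1, n_background >= 0)
  cell_types <- as.character(cell_types)
  dirichlet_weights <- dirichlet_weights[cell_types]
  if (any(is.na(dirichlet_weights)) || any(dirichlet_weights <= 0))
    stop("dirichlet_weights must name every cell type with a positive weight")
  if (!is.null(dmc_spec)) {
    dmc_spec <- as.data.frame(dmc_spec, stringsAsFactors = FALSE)
    need <- c("cpg_id", "target", "covariate", "slope")
    if (length(setdiff(need, names(dmc_spec))))
      stop("dmc_spec needs columns: ", paste(need, collapse = ", "))
    if (any(!dmc_spec$covariate %in% c("age", "condition")))
      stop("dmc_spec covariate must be 'age' or 'condition'")
    if (any(!dmc_spec$target %in% c(cell_types, "global")))
      stop("dmc_spec target must be a cell type or 'global'")
  }
  structure(list(
    n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
    cell_types = cell_types, markers_per_type = as.integer(markers_per_type),
    n_background = as.integer(n_background),
    dirichlet_alpha = dirichlet_weights / sum(dirichlet_weights) * concentration,
    regime = regime, acute_neu_factor = acute_neu_factor,
    inflammaging_gamma = inflammaging_gamma, dmc_spec = dmc_spec,
    noise_sd = noise_sd, batch_sd = batch_sd), class = "sim_config")
}

#' Generate a synthetic cell-type reference panel
#'
#' For each cell type, `markers_per_type` marker CpGs discriminate that type
#' from all others: direct-polarity markers are hypomethylated in the type
#' (beta ~ U(0.05, 0.15)) and hypermethylated elsewhere (U(0.75, 0.95));
#' half the markers have reversed polarity. `n_background` additional CpGs
#' carry a common beta ~ U(0.1, 0.9) in every cell type and so carry no
#' composition signal. Rows are flagged via the panel's `is_marker`
#' attribute; `marker_type` records which cell type each marker belongs to.
#'
#' @param K Number of cell types (>= 2).
#' @param markers_per_type Markers per cell type.
#' @param n_background Background CpGs shared by all cell types.
#' @param cell_types Optional labels; defaults to the blood 12 when K = 12,
#'   otherwise `CT1..CTK`.
#' @param seed Optional integer seed.
#' @return A [reference_panel()] with `is_marker` and `marker_type`
#'   attributes.
#' @export
make_reference_panel <- function(K = 12, markers_per_type = 50,
                                 n_background = 2000, cell_types = NULL,
                                 seed = NULL) {
  if (K < 2) stop("K must be >= 2")
  stopifnot(markers_per_type >= 1, n_background >= 0)
  if (is.null(cell_types))
    cell_types <- if (K == 12) blood_cell_types() else paste0("CT", seq_len(K))
  stopifnot(length(cell_types) == K)
  if (!is.null(seed)) set.seed(seed)
  n_mark <- K * markers_per_type
  vals <- matrix(NA_real_, n_mark + n_background, K,
                 dimnames = list(NULL, cell_types))
  ids <- character(n_mark + n_background)
  mtype <- rep(NA_character_, n_mark + n_background)
  n_rev <- markers_per_type %/% 2  # half reversed polarity
  row <- 0L
  for (k in seq_len(K)) {
    for (i in seq_len(markers_per_type)) {
      row <- row + 1L
      reversed <- i > markers_per_type - n_rev
      own <- if (reversed) runif(1, 0.75, 0.95) else runif(1, 0.05, 0.15)
      oth <- if (reversed) runif(K - 1, 0.05, 0.15) else runif(K - 1, 0.75, 0.95)
      vals[row, ] <- replace(rep(NA_real_, K), seq_len(K)[-k], oth)
      vals[row, k] <- own
      ids[row] <- sprintf("mk_%s_%03d", cell_types[k], i)
      mtype[row] <- cell_types[k]
    }
  }
  if (n_background > 0) {
    bg <- runif(n_background, 0.1, 0.9)
    vals[n_mark + seq_len(n_background), ] <- matrix(bg, n_background, K)
    ids[n_mark + seq_len(n_background)] <- sprintf("bg_%05d", seq_len(n_background))
  }
  rownames(vals) <- ids
  panel <- reference_panel(vals, is_marker = !is.na(mtype))
  attr(panel, "marker_type") <- mtype
  panel
}

.marker_types <- function(panel) {
  mt <- attr(panel, "marker_type")
  if (!is.null(mt)) return(mt)
  # infer: a marker of type k is far from the mean of the other columns
  v <- unclass(panel)
  K <- ncol(v)
  mt <- rep(NA_character_, nrow(v))
  for (k in seq_len(K)) {
    gap <- abs(v[, k] - rowMeans(v[, -k, drop = FALSE]))
    mt[gap > 0.3] <- colnames(v)[k]
  }
  mt
}

# Per-sample Dirichlet alphas after the regime tilt.
.regime_alphas <- function(cfg, age, condition) {
  n <- length(age)
  A <- matrix(cfg$dirichlet_alpha, n, length(cfg$cell_types), byrow = TRUE,
              dimnames = list(NULL, cfg$cell_types))
  if (cfg$regime == "acute") {
    A[, "Neu"] <- A[, "Neu"] * ifelse(condition == 1, cfg$acute_neu_factor, 1)
  } else if (cfg$regime == "inflammaging") {
    up <- intersect(c("Bmem", "CD4Tmem", "CD8Tmem", "NK"), cfg$cell_types)
    dn <- intersect(c("Bnv", "CD4Tnv", "CD8Tnv"), cfg$cell_types)
    A[, up] <- A[, up] * exp(cfg$inflammaging_gamma * age)
    A[, dn] <- A[, dn] * exp(-cfg$inflammaging_gamma * age)
  }
  A
}

#' Simulate one whole-blood methylation cohort
#'
#' Draws per-sample cell fractions from the (regime-tilted) Dirichlet prior,
#' mixes the reference profiles accordingly, plants the configured DMC
#' effects into the target cell type's profile before mixing, adds the
#' cohort batch offset and measurement noise, and clips observed betas to
#' `[0.001, 0.999]`. All randomness flows from `seed` through one generator
#' in a fixed draw order (ages, sexes, batch offsets, fractions, noise), so
#' equal seeds give identical cohorts.
#'
#' Ground truth returned alongside the data: the true fraction matrix, a
#' per-sample inflammation burden (log of the realized memory:naive CD4
#' alpha ratio under inflammaging, log of the realized neutrophil:lymphocyte
#' alpha ratio otherwise — a simulator construct for monotonicity checks),
#' the planted DMC table and the batch offset vector.
#'
#' @param cfg A [sim_config()].
#' @param panel A [reference_panel()] whose cell types match `cfg`.
#' @param cohort_id Cohort label (string).
#' @param seed Optional integer seed.
#' @return List with elements `beta` ([beta_matrix()]), `samples`
#'   ([sample_sheet()]) and `truth` (list: `fractions`, `burden`, `dmc`,
#'   `batch`).
#' @export
simulate_cohort <- function(cfg, panel, cohort_id = "cohort1", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "reference_panel"))
  if (!identical(sort(colnames(panel)), sort(cfg$cell_types)))
    stop("panel cell types do not match the configuration")
  P <- unclass(panel)[, cfg$cell_types, drop = FALSE]
  if (!is.null(cfg$dmc_spec) && any(!cfg$dmc_spec$cpg_id %in% rownames(P)))
    stop("dmc_spec cpg_id not in panel: ",
         paste(setdiff(cfg$dmc_spec$cpg_id, rownames(P)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  K <- length(cfg$cell_types)
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- rbinom(n, 1, 0.5)
  condition <- as.numeric(seq_len(n) > n / 2)  # balanced, deterministic
  batch <- if (cfg$batch_sd > 0) rnorm(nrow(P), 0, cfg$batch_sd) else
    numeric(nrow(P))
  names(batch) <- rownames(P)
  A <- .regime_alphas(cfg, age, condition)
  G <- matrix(rgamma(n * K, shape = A), n, K)  # Dirichlet via gammas
  W <- G / rowSums(G)
  dimnames(W) <- list(sprintf("%s_S%04d", cohort_id, seq_len(n)),
                      cfg$cell_types)
  X <- P %*% t(W)   # CpG x sample mixture
  if (!is.null(cfg$dmc_spec)) {
    for (r in seq_len(nrow(cfg$dmc_spec))) {
      d <- cfg$dmc_spec[r, ]
      z <- if (d$covariate == "age") age else condition
      j <- d$cpg_id
      ks <- if (d$target == "global") cfg$cell_types else d$target
      for (k in ks) {
        shifted <- pmin(1, pmax(0, P[j, k] + d$slope * z))
        X[j, ] <- X[j, ] - P[j, k] * W[, k] + shifted * W[, k]
      }
    }
  }
  X <- X + batch
  if (cfg$noise_sd > 0)
    X <- X + matrix(rnorm(length(X), 0, cfg$noise_sd), nrow(X), ncol(X))
  X <- pmin(pmax(X, 0.001), 0.999)
  colnames(X) <- rownames(W)
  bm <- beta_matrix(X)
  ss <- sample_sheet(data.frame(
    sample_id = rownames(W), age = age, sex = sex, condition = condition,
    cohort = cohort_id, stringsAsFactors = FALSE))
  lymph <- intersect(lymphocyte_types(), cfg$cell_types)
  burden <- if (cfg$regime == "inflammaging" &&
                all(c("CD4Tmem", "CD4Tnv") %in% cfg$cell_types)) {
    log(A[, "CD4Tmem"] / A[, "CD4Tnv"])
  } else if ("Neu" %in% cfg$cell_types && length(lymph)) {
    log(A[, "Neu"] / rowSums(A[, lymph, drop = FALSE]))
  } else {
    rep(NA_real_, n)  # burden undefined for non-blood cell-type sets
  }
  names(burden) <- rownames(W)
  truth <- list(fractions = fraction_matrix(W), burden = burden,
                dmc = cfg$dmc_spec, batch = batch)
  list(beta = bm, samples = ss, truth = truth)
}

#' Simulate several independent cohorts
#'
#' Each cohort gets its own configuration, seed and batch offset vector;
#' sample and cohort ids are kept globally unique and the concatenated
#' sample sheet carries the cohort label.
#'
#' @param cfgs List of [sim_config()] (a single config is recycled when
#'   `cohort_ids` is longer).
#' @param panel A shared [reference_panel()].
#' @param cohort_ids Unique cohort labels, one per cohort.
#' @param seeds Integer seeds, one per cohort.
#' @return List with `cohorts` (named list of [simulate_cohort()] outputs)
#'   and `samples` (the concatenated [sample_sheet()]).
#' @export
simulate_multi_cohort <- function(cfgs, panel, cohort_ids, seeds) {
  if (inherits(cfgs, "sim_config")) cfgs <- list(cfgs)
  if (length(cfgs) == 1) cfgs <- rep(cfgs, length(cohort_ids))
  stopifnot(length(cfgs) >= 1,
            length(cohort_ids) == length(cfgs),
            length(seeds) == length(cfgs))
  .check_unique(as.character(cohort_ids), "cohort_id")
  cohorts <- Map(function(cfg, id, sd) simulate_cohort(cfg, panel, id, sd),
                 cfgs, cohort_ids, seeds)
  names(cohorts) <- cohort_ids
  samples <- do.call(rbind, lapply(cohorts, function(co)
    as.data.frame(co$samples)))
  rownames(samples) <- NULL
  list(cohorts = cohorts, samples = sample_sheet(samples))
}

#' Build a mock composition-tracking rectified clock from a panel
#'
#' Constructs an all-positive linear clock whose CpGs are the marker CpGs of
#' one cell type, with rectification flags set so that the (rectified) beta
#' at every clock CpG increases with that cell type's fraction. Such a clock
#' deliberately tracks composition — it is the test instrument for showing
#' that a rectified "inflammation clock" can be driven entirely by a
#' neutrophil-to-lymphocyte shift.
#'
#' @param panel A [reference_panel()] from [make_reference_panel()].
#' @param cell_type Tracked cell type (default `"Neu"`).
#' @param n_cpgs Number of clock CpGs (default 47, the size of published
#'   rectified inflammation clocks).
#' @param coef_range Range of the positive coefficients (years per beta
#'   unit).
#' @param intercept Clock intercept in years.
#' @param seed Optional integer seed.
#' @return A [clock_definition()] with all coefficients positive.
#' @export
synth_clock <- function(panel, cell_type = "Neu", n_cpgs = 47,
                        coef_range = c(0.8, 1.2), intercept = 20,
                        seed = NULL) {
  stopifnot(cell_type %in% colnames(panel))
  mt <- .marker_types(panel)
  own <- which(!is.na(mt) & mt == cell_type)
  if (length(own) < n_cpgs)
    stop("panel has only ", length(own), " markers for ", cell_type)
  if (!is.null(seed)) set.seed(seed)
  own <- own[seq_len(n_cpgs)]
  v <- unclass(panel)
  low_in_own <- v[own, cell_type] < rowMeans(v[own, -match(cell_type, colnames(v)),
                                               drop = FALSE])
  clock_definition(data.frame(
    cpg_id = rownames(v)[own],
    coefficient = runif(n_cpgs, coef_range[1], coef_range[2]),
    rectify = low_in_own, stringsAsFactors = FALSE),
    intercept = intercept, all_positive = TRUE)
}

#' Build a mock signed inflammation signature from a panel
#'
#' Assigns each marker CpG of the "up" cell types (by default the memory
#' lymphocyte subsets and NK cells, the compartments that expand under
#' chronic low-grade inflammation) a sign such that a sample's z-scored
#' profile correlates positively with the sign vector when those fractions
#' are high, and the opposite sign to markers of the "down" (naive) types.
#'
#' @param panel A [reference_panel()].
#' @param up_types Cell types whose fractions the score should track
#'   positively.
#' @param down_types Cell types tracked negatively.
#' @return A [signature_definition()].
#' @export
synth_signature <- function(panel,
                            up_types = c("Bmem", "CD4Tmem", "CD8Tmem", "NK"),
                            down_types = c("Bnv", "CD4Tnv", "CD8Tnv")) {
  mt <- .marker_types(panel)
  v <- unclass(panel)
  rows <- which(!is.na(mt) & mt %in% c(up_types, down_types))
  if (!length(rows)) stop("panel has no markers for the requested cell types")
  sign_of <- function(j) {
    t <- mt[j]
    low_in_own <- v[j, t] < mean(v[j, -match(t, colnames(v))])
    # beta at a low-in-own marker decreases as that fraction grows
    s <- if (low_in_own) -1 else 1
    if (t %in% down_types) s <- -s
    s
  }
  signature_definition(data.frame(
    cpg_id = rownames(v)[rows],
    sign = vapply(rows, sign_of, numeric(1)), stringsAsFactors = FALSE))
}
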