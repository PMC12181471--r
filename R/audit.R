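# Full-pipeline orchestration: simulate (optional) -> deconvolve -> clock +
# inflammation score -> EWAS -> per-cohort associations -> meta-analysis ->
# coefficient concordance, with a checksummed artifact manifest. All
# randomness flows from one top-level seed, so equal seeds give identical
# manifests.

#' Build a run configuration for the full audit
#'
#' Returns the default configuration as a nested list; any element can be
#' overridden through `...` (partial lists are merged). The same structure
#' can be stored as a YAML file and loaded with [yaml::read_yaml()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Top-level integer seed.
#' @param ... Named overrides merged into the defaults, e.g.
#'   `simulate = list(n_cohorts = 3)`.
#' @return A nested configuration list.
#' @export
audit_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(
      enabled = TRUE, n_cohorts = 2, n_samples = 120, regime = "acute",
      markers_per_type = 50, n_background = 400, noise_sd = 0.02,
      batch_sd = 0.01),
    inputs = list(beta = NULL, samples = NULL, panel = NULL,
                  clock = NULL, signature = NULL),
    deconv = list(method = "rpc", maxit = 500),
    ewas = list(alpha = 0.05, adjust = TRUE),
    concordance = list(alpha_mix = 0.5, lambda = 0.01))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

#' Run the full cell-type-heterogeneity audit
#'
#' Executes the whole pipeline described in the package overview and writes
#' every artifact (fractions, score table, EWAS table, per-cohort and pooled
#' association tables, forest-plot data, concordance summary) as plain CSV/
#' TSV/JSON under `config$out_dir`, ending with a `manifest.json` listing
#' every file with its MD5 checksum and per-stage wall-clock timings. A
#' stage failure aborts with an error naming the stage; files already
#' written by the failed stage are kept with a `.partial` suffix.
#'
#' @param config A configuration list from [audit_config()] or the path to
#'   an equivalent YAML file.
#' @return Invisibly, the manifest as a list.
#' @export
run_full_audit <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # validate referenced inputs before any computation
  for (f in unlist(cfg$inputs)) {
    if (!is.null(f) && !file.exists(f)) {
      what <- names(which(vapply(cfg$inputs, identical, logical(1), f)))[1]
      stop(if (identical(what, "panel")) "reference panel not found: "
           else paste0(what, " file not found: "), f)
    }
  }
  state <- new.env(parent = emptyenv())
  state$files <- character()
  state$timings <- list()
  out <- function(name) file.path(cfg$out_dir, name)
  track <- function(path) { state$files <- c(state$files, path); path }
  stage <- function(name, code) {
    before <- state$files
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      new <- setdiff(state$files, before)
      for (f in new) if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    state$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  set.seed(cfg$seed)

  dat <- stage("simulate", {
    if (!is.null(cfg$inputs$beta)) {
      bm <- read_beta_matrix(cfg$inputs$beta)
      ss <- read_sample_sheet(cfg$inputs$samples)
      panel <- read_reference_panel(cfg$inputs$panel)
      cohorts <- lapply(split(ss$sample_id, ss$cohort), function(ids)
        list(beta = beta_matrix(unclass(bm)[, ids, drop = FALSE]),
             samples = sample_sheet(as.data.frame(ss)[match(ids, ss$sample_id), ])))
      list(panel = panel, cohorts = cohorts, samples = ss)
    } else {
      sm <- cfg$simulate
      panel <- make_reference_panel(
        K = 12, markers_per_type = sm$markers_per_type,
        n_background = sm$n_background, seed = cfg$seed)
      sc <- sim_config(n_samples = sm$n_samples, regime = sm$regime,
                       markers_per_type = sm$markers_per_type,
                       n_background = sm$n_background,
                       noise_sd = sm$noise_sd, batch_sd = sm$batch_sd)
      ids <- sprintf("cohort%02d", seq_len(sm$n_cohorts))
      mc <- simulate_multi_cohort(sc, panel, ids, seeds = cfg$seed + seq_along(ids))
      write_reference_panel(panel, track(out("panel.csv")))
      write_sample_sheet(mc$samples, track(out("samples.csv")))
      for (id in ids)
        write_beta_matrix(mc$cohorts[[id]]$beta,
                          track(out(sprintf("beta_%s.csv", id))))
      list(panel = panel, cohorts = mc$cohorts, samples = mc$samples)
    }
  })

  clock <- stage("clock_definition", {
    if (!is.null(cfg$inputs$clock)) read_clock_definition(cfg$inputs$clock)
    else {
      avail <- sum(.marker_types(dat$panel) == "Neu", na.rm = TRUE)
      ck <- synth_clock(dat$panel, n_cpgs = min(47, avail), seed = cfg$seed)
      write_clock_definition(ck, track(out("clock.csv")))
      ck
    }
  })
  sig <- stage("signature_definition", {
    if (!is.null(cfg$inputs$signature)) read_signature(cfg$inputs$signature)
    else {
      sg <- synth_signature(dat$panel)
      write_signature(sg, track(out("signature.csv")))
      sg
    }
  })

  fractions <- stage("deconvolve", {
    mp <- marker_panel(dat$panel)
    fr <- lapply(dat$cohorts, function(co) {
      if (identical(cfg$deconv$method, "cls"))
        estimate_fractions_cls(co$beta, mp)
      else estimate_fractions_rpc(co$beta, mp, maxit = cfg$deconv$maxit)
    })
    for (id in names(fr))
      write_fraction_matrix(fr[[id]], track(out(sprintf("fractions_%s.csv", id))))
    fr
  })

  scores <- stage("scores", {
    st <- score_table(dat$cohorts, clock = clock, sig = sig)
    write.csv(st, track(out("score_table.csv")), row.names = FALSE)
    st
  })

  ewas_res <- stage("ewas", {
    id <- names(dat$cohorts)[1]
    co <- dat$cohorts[[id]]
    res <- list(
      unadjusted = ewas(co$beta, co$samples$condition,
                        covariates = cbind(sex = co$samples$sex),
                        alpha = cfg$ewas$alpha),
      adjusted = if (isTRUE(cfg$ewas$adjust))
        ewas(co$beta, co$samples$condition,
             covariates = cbind(sex = co$samples$sex),
             adjust_fractions = fractions[[id]], alpha = cfg$ewas$alpha))
    for (nm in names(res)) if (!is.null(res[[nm]]))
      write.csv(as.data.frame(res[[nm]]),
                track(out(sprintf("ewas_%s_%s.csv", id, nm))), row.names = FALSE)
    res
  })

  assoc <- stage("assoc_meta", {
    eaa_ma <- meta_fraction_assoc(scores, fractions, dat$samples,
                                  outcome = "eaa", adjust = "sex")
    infl_ma <- meta_fraction_assoc(scores, fractions, dat$samples,
                                   outcome = "infl_score",
                                   adjust = c("age", "sex"))
    write.csv(eaa_ma$per_cohort, track(out("assoc_eaa.csv")), row.names = FALSE)
    write.csv(eaa_ma$meta, track(out("meta_eaa.csv")), row.names = FALSE)
    write.csv(infl_ma$per_cohort, track(out("assoc_inflscore.csv")),
              row.names = FALSE)
    write.csv(infl_ma$meta, track(out("meta_inflscore.csv")), row.names = FALSE)
    forest <- do.call(rbind, lapply(list(eaa = eaa_ma, infl = infl_ma),
                                    function(ma) {
      per <- ma$per_cohort
      data.frame(term = per$term, cohort = per$cohort, effect = per$effect,
                 ci_low = per$effect - qnorm(0.975) * per$se,
                 ci_high = per$effect + qnorm(0.975) * per$se)
    }))
    write.table(forest, track(out("forest_data.tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
    list(eaa = eaa_ma, infl = infl_ma)
  })

  conc <- stage("concordance", {
    # elastic net for the condition on marker CpGs of the first cohort,
    # compared against per-CpG univariate coefficients
    id <- names(dat$cohorts)[1]
    co <- dat$cohorts[[id]]
    mp <- marker_panel(dat$panel)
    shared <- intersect(rownames(mp), rownames(co$beta))
    Xc <- t(unclass(co$beta)[shared, , drop = FALSE])
    en <- elastic_net_fit(Xc, co$samples$condition,
                          alpha_mix = cfg$concordance$alpha_mix,
                          lambda = cfg$concordance$lambda,
                          family = "binomial")
    uni <- univariate_cpg_regression(
      beta_matrix(unclass(co$beta)[shared, , drop = FALSE]),
      co$samples$condition)
    res <- sign_concordance(en$coefficients, uni$effect)
    jsonlite::write_json(
      list(n_concordant = res$n_concordant, n_discordant = res$n_discordant,
           fisher_p = res$fisher_p, pearson_r = res$pearson_r,
           pearson_p = res$pearson_p),
      track(out("concordance.json")), auto_unbox = TRUE, digits = NA)
    res
  })

  manifest <- list(
    seed = cfg$seed,
    timings_sec = state$timings,
    files = lapply(sort(state$files), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
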