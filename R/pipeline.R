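#' Default pipeline configuration
#'
#' Returns the fully populated configuration list that [run_pipeline]
#' consumes; user configs (lists or YAML files) are merged over these
#' defaults, and the effective configuration is echoed into the output
#' bundle so that no hidden defaults influence a run.
#'
#' @return nested named list.
#' @export
pipeline_defaults <- function() {
  list(
    paths = list(rr_dir = NULL, meta = NULL, covariates = NULL,
                 literature = NULL, out = NULL),
    filter = list(rel_threshold = 0.2, window_beats = 11, abs_bounds = c(300, 2000)),
    frequency = list(window_s = 300, stft_window = 1800, stft_shift = 300,
                     bands = list(ulf = c(0, 1 / 300), vlf = c(1 / 300, 0.04),
                                  lf = c(0.04, 0.15), hf = c(0.15, 0.40))),
    nonlinear = list(),        # overrides for nonlinear_params()
    reference = list(min_n = 20),
    selection = list(top_k = 10, n_trees = 200, min_node_size = 15,
                     min_node_deaths = 3, n_split_candidates = 10),
    adjustment = list(full_covariates = character()),
    outcome = list(time_col = "time_years", event_col = "event"),
    seed = 1L
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full cohort HRV pipeline
#'
#' Executes, in order: eligibility screening, artifact filtering, the
#' 20-marker table, reference ranges with a distribution summary table,
#' literature + survival-forest marker selection, tertile assignments and
#' cumulative-incidence curves for the two top-ranked forest markers, and
#' the standardized linear and Cox model batteries. Every artifact is
#' written to the output directory as CSV/JSON along with the effective
#' configuration, the seed and a per-record rejection log; a stage failure
#' aborts with the stage name.
#'
#' @param config a nested list (see [pipeline_defaults]) or the path to a
#'   YAML file with the same structure. `paths$rr_dir`, `paths$meta`,
#'   `paths$covariates` and `paths$out` are required; `paths$literature` is
#'   optional (selection then uses the forest ranking only).
#' @return invisibly, a list with the in-memory artifacts (`eligibility`,
#'   `markers`, `ranges`, `summary`, `selection`, `battery`, `config`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  for (p in c("rr_dir", "meta", "covariates", "out"))
    if (is.null(cfg$paths[[p]]))
      stop("config paths$", p, " is required", call. = FALSE)
  out_dir <- cfg$paths$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- eligibility -------------------------------------------------------
  elig <- stage("eligibility", {
    meta_df <- utils::read.csv(cfg$paths$meta, stringsAsFactors = FALSE)
    dec <- lapply(seq_len(nrow(meta_df)), function(i) {
      m <- record_meta(meta_df$record_id[i],
                       has_pacemaker = isTRUE(as.logical(meta_df$has_pacemaker[i])),
                       af_fraction = meta_df$af_fraction[i],
                       heart_transplant = isTRUE(as.logical(meta_df$heart_transplant[i])),
                       wearing_time_h = meta_df$wearing_time_h[i])
      check_eligibility(m)
    })
    df <- do.call(rbind, lapply(dec, as.data.frame))
    if (!any(df$included))
      stop("no eligible records remain after exclusion rules")
    df
  })
  utils::write.csv(elig, file.path(out_dir, "eligibility.csv"),
                   row.names = FALSE)
  logf("eligibility: %d of %d records included", sum(elig$included),
       nrow(elig))

  # --- filtering + markers ----------------------------------------------
  fp <- filter_params(cfg$filter$rel_threshold, cfg$filter$window_beats,
                      unlist(cfg$filter$abs_bounds))
  nl <- do.call(nonlinear_params, cfg$nonlinear)
  bands <- do.call(band_scheme, lapply(cfg$frequency$bands, unlist))
  nn_list <- stage("filtering", {
    ids <- elig$record_id[elig$included]
    lapply(ids, function(id) {
      rr <- read_rr_text(file.path(cfg$paths$rr_dir, paste0(id, ".txt")),
                         record_id = id)
      nn <- filter_to_nn(rr, fp)
      logf("filter %s: %d beats rejected", id, nn$rejected_count)
      nn
    })
  })
  markers <- stage("markers", {
    marker_table(nn_list, bands = bands, nl = nl,
                 freq_window_s = cfg$frequency$window_s,
                 stft_window = cfg$frequency$stft_window,
                 stft_shift = cfg$frequency$stft_shift)
  })
  utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)
  reasons <- attr(markers, "reasons")
  names(reasons) <- markers$id
  jsonlite::write_json(reasons, file.path(out_dir, "marker_reasons.json"),
                       auto_unbox = TRUE)

  # --- covariates + reference ranges ------------------------------------
  cov <- stage("covariates", {
    cv <- utils::read.csv(cfg$paths$covariates, stringsAsFactors = FALSE)
    cv <- cv[match(markers$id, cv$id), , drop = FALSE]
    if (anyNA(cv$id)) stop("covariate table lacks some record ids")
    cv
  })
  usable <- names(markers)[-1][colSums(!is.na(markers[-1])) /
                                 nrow(markers) >= 0.5]
  res <- stage("reference_ranges", {
    hm <- healthy_mask(cov)
    ranges <- list()
    summaries <- list()
    for (mk in usable) {
      rg <- tryCatch(
        derive_reference_range(markers, hm, mk,
                               min_n = cfg$reference$min_n),
        error = function(e) NULL)
      if (is.null(rg)) { logf("range %s: skipped (reference floor)", mk); next }
      ranges[[mk]] <- rg
      hf_vals <- markers[[mk]][!hm]
      s_ref <- distribution_summary(markers[[mk]][hm], rg)
      s_hf <- if (sum(!is.na(hf_vals)) > 0)
        distribution_summary(hf_vals, rg) else NULL
      summaries[[mk]] <- data.frame(
        marker = mk, group = c("reference", "heart_failure"),
        n = c(s_ref$n, s_hf$n %||% 0),
        median = c(s_ref$median, s_hf$median %||% NA),
        q1 = c(s_ref$q1, s_hf$q1 %||% NA), q3 = c(s_ref$q3, s_hf$q3 %||% NA),
        p5 = c(s_ref$p5, s_hf$p5 %||% NA),
        p95 = c(s_ref$p95, s_hf$p95 %||% NA),
        pct_below = c(s_ref$pct_below, s_hf$pct_below %||% NA),
        pct_above = c(s_ref$pct_above, s_hf$pct_above %||% NA),
        pct_outside = c(s_ref$pct_outside, s_hf$pct_outside %||% NA))
    }
    list(ranges = ranges, summary = do.call(rbind, summaries))
  })
  if (length(res$ranges)) {
    rng_df <- do.call(rbind, lapply(res$ranges, function(r)
      data.frame(marker = r$marker, lower = r$lower, upper = r$upper,
                 n_reference = r$n_reference, convention = r$convention)))
    utils::write.csv(rng_df, file.path(out_dir, "reference_ranges.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$summary))
    utils::write.csv(res$summary, file.path(out_dir, "summary_table.csv"),
                     row.names = FALSE)

  # --- marker selection --------------------------------------------------
  sel <- stage("selection", {
    k <- cfg$selection$top_k
    X <- as.matrix(markers[, usable, drop = FALSE])
    for (j in seq_len(ncol(X)))  # median imputation for the forest only
      X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
    X <- cbind(X, age = cov$age, sex = cov$sex)
    ok_outcome <- !is.na(cov[[cfg$outcome$time_col]]) &
      !is.na(cov[[cfg$outcome$event_col]])
    forest <- fit_survival_forest(
      X[ok_outcome, , drop = FALSE],
      cov[[cfg$outcome$time_col]][ok_outcome],
      cov[[cfg$outcome$event_col]][ok_outcome],
      forest_params(n_trees = cfg$selection$n_trees,
                    min_node_size = cfg$selection$min_node_size,
                    min_node_deaths = cfg$selection$min_node_deaths,
                    n_split_candidates = cfg$selection$n_split_candidates,
                    seed = cfg$seed),
      forced = c("age", "sex"))
    depth <- minimal_depth_importance(forest)
    forest_ranks <- setdiff(names(depth), c("age", "sex"))
    kf <- min(k, length(forest_ranks))
    if (!is.null(cfg$paths$literature)) {
      lit <- utils::read.csv(cfg$paths$literature, stringsAsFactors = FALSE)
      lit_ranks <- rank_by_hits(lit, min(k, nrow(lit)))
      report <- select_top_union(lit_ranks, forest_ranks,
                                 min(kf, length(lit_ranks)))
    } else {
      report <- data.frame(marker = forest_ranks[seq_len(kf)],
                           source = "forest")
    }
    list(depth = depth, report = report)
  })
  jsonlite::write_json(
    list(minimal_depth = as.list(sel$depth),
         selected = sel$report),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  # --- tertiles + cumulative incidence -----------------------------------
  stage("incidence", {
    top2 <- setdiff(names(sel$depth), c("age", "sex"))[1:2]
    curves <- list()
    for (mk in top2) {
      v <- markers[[mk]]
      ok <- !is.na(v) & !is.na(cov[[cfg$outcome$time_col]])
      if (sum(ok) < 9) next
      tert <- tertile_cutpoints(v[ok])
      curves[[mk]] <- cbind(marker = mk, cumulative_incidence(
        cov[[cfg$outcome$time_col]][ok], cov[[cfg$outcome$event_col]][ok],
        tert$assignment))
    }
    if (length(curves))
      utils::write.csv(do.call(rbind, curves),
                       file.path(out_dir, "cumulative_incidence.csv"),
                       row.names = FALSE)
  })

  # --- model batteries ---------------------------------------------------
  battery <- stage("models", {
    cohort <- cov
    cohort$time <- cohort[[cfg$outcome$time_col]]
    cohort$event <- cohort[[cfg$outcome$event_col]]
    tiers <- list(adjustment_set("age_sex"))
    if (length(cfg$adjustment$full_covariates))
      tiers <- c(tiers, list(adjustment_set("full",
                                            cfg$adjustment$full_covariates)))
    hf <- !healthy_mask(cov)
    mk_df <- markers[hf, usable, drop = FALSE]
    res <- lapply(tiers, function(ad)
      run_model_battery(mk_df, cohort[hf, , drop = FALSE], ad))
    do.call(rbind, res)
  })
  utils::write.csv(battery, file.path(out_dir, "cox_battery.csv"),
                   row.names = FALSE)

  lin <- stage("linear_models", {
    hf <- !healthy_mask(cov)
    covs <- c("age", "sex", cfg$adjustment$full_covariates)
    rows <- lapply(usable, function(mk) {
      v <- markers[[mk]][hf]
      ok <- !is.na(v)
      if (sum(ok) <= length(covs) + 2) return(NULL)
      sdv <- stats::sd(v[ok])
      if (is.na(sdv) || sdv == 0) return(NULL)
      z <- v[ok] / sdv
      Xc <- as.matrix(cov[hf, covs, drop = FALSE])[ok, , drop = FALSE]
      if (any(apply(Xc, 2, stats::sd) == 0)) return(NULL)
      fit <- linear_fit(z, Xc)
      data.frame(marker = mk, covariate = names(fit$beta)[-1],
                 beta = fit$beta[-1], lo = fit$ci95[-1, "lo"],
                 hi = fit$ci95[-1, "hi"], p = fit$p[-1])
    })
    do.call(rbind, rows)
  })
  if (!is.null(lin))
    utils::write.csv(lin, file.path(out_dir, "linear_battery.csv"),
                     row.names = FALSE)

  run_meta <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("hrvcohort")),
                   n_records = nrow(elig), n_included = sum(elig$included),
                   config = cfg)
  jsonlite::write_json(run_meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("pipeline complete")
  invisible(list(eligibility = elig, markers = markers, ranges = res$ranges,
                 summary = res$summary, selection = sel, battery = battery,
                 linear = lin, config = cfg))
}
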