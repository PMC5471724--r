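# End-to-end orchestration: simulate (or ingest) -> screen -> movement
# metrics -> home ranges -> covariates -> per-category predictor screening ->
# one additive mixed model per response x scale x category, plus a tabular
# significance summary. Home-range size is modeled at the monthly and
# overall scales only; daily-scale home ranges are not estimated.

#' Pipeline run configuration
#'
#' All thresholds default to the standard screening and modeling rules:
#' DOP <= 10, nocturnal window 18:00-08:00, >= 2 fixes/day, >= 20 retained
#' days/animal, >= 15 days for monthly eligibility, 95 percent MCP,
#' |r| < 0.5 predictor filter, accuracy-rule epsilon 0.01.
#'
#' @param sim A \code{\link{sim_config}} (used when \code{input_dir} is
#'   NULL).
#' @param input_dir Directory with telemetry.csv / weather.csv /
#'   landscape.csv to ingest instead of simulating.
#' @param responses,scales,categories Grid cells to run.
#' @param hr_method Home-range method modeled as the HR response
#'   (\code{"MCP"} or \code{"sAKDE"}).
#' @param seed Global seed; per-stage seeds are fanned out deterministically.
#' @param max_dop,min_fixes_per_day,min_days,min_days_month Screening rules.
#' @param mhd_target,mhd_window MHD pairing rule (minutes).
#' @param mcp_percent MCP percent parameter.
#' @param corr_threshold,epsilon,rf_trees Predictor-screening parameters
#'   (\code{epsilon = NULL} disables the accuracy stopping rule).
#' @param screen_categories Categories passed through the two-step screen
#'   (the collinear sets; others enter their models in full).
#' @param k,spatial_k Smooth basis sizes.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       responses = c("mxd", "mhd", "hr"),
                       scales = c("daily", "monthly", "overall"),
                       categories = c("individual", "meteorological",
                                      "temporal", "geographic", "landscape"),
                       hr_method = "MCP", seed = 1L,
                       max_dop = 10, min_fixes_per_day = 2, min_days = 20,
                       min_days_month = 15, mhd_target = 60,
                       mhd_window = c(50, 70), mcp_percent = 95,
                       corr_threshold = 0.5, epsilon = 0.01, rf_trees = 300,
                       screen_categories = c("meteorological", "temporal"),
                       k = 10, spatial_k = 8) {
  structure(as.list(environment()), class = "run_config")
}

# applicable scales per response: movement metrics at all three, home-range
# size at monthly and overall only
applicable_scales <- function(response, scales) {
  if (response == "hr") intersect(scales, c("monthly", "overall")) else scales
}

#' Run the full cross-scale analysis pipeline
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress per-stage progress messages.
#' @return A result bundle: screened data, audit, daily/monthly/overall
#'   records, home ranges, covariate tables, screening results, fitted
#'   models (or failure records) and a manifest of counts and seeds.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$input_dir)) {
    say("ingesting telemetry from %s", config$input_dir)
    telemetry <- read_fixes(file.path(config$input_dir, "telemetry.csv"))
    weather <- utils::read.csv(file.path(config$input_dir, "weather.csv"),
                               stringsAsFactors = FALSE)
    weather$timestamp <- as.POSIXct(weather$timestamp,
                                    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    lpath <- file.path(config$input_dir, "landscape.csv")
    landscape <- if (file.exists(lpath)) {
      utils::read.csv(lpath, stringsAsFactors = FALSE)
    } else NULL
  } else {
    say("simulating dataset (preset '%s', seed %d)",
        config$sim$preset, config$sim$seed)
    ds <- simulate_dataset(config$sim)
    telemetry <- ds$telemetry; weather <- ds$weather; landscape <- ds$landscape
  }

  say("screening %d fixes", nrow(telemetry))
  scr <- screen_fixes(telemetry, max_dop = config$max_dop,
                      min_fixes_per_day = config$min_fixes_per_day,
                      min_days = config$min_days,
                      min_days_month = config$min_days_month)
  say("retained %d fixes from %d animals", scr$audit$n_retained,
      scr$audit$n_animals)

  daily <- daily_metrics(scr$fixes, config$mhd_target, config$mhd_window)
  monthly <- aggregate_metrics(daily, "monthly", scr$month_eligibility)
  overall <- aggregate_metrics(daily, "overall")
  say("movement records: %d daily, %d monthly, %d overall",
      nrow(daily), nrow(monthly), nrow(overall))

  hr <- list()
  if ("hr" %in% config$responses) {
    if ("monthly" %in% config$scales) {
      hr$monthly <- home_ranges(scr$fixes, "monthly", scr$month_eligibility,
                                percent = config$mcp_percent)
    }
    if ("overall" %in% config$scales) {
      hr$overall <- home_ranges(scr$fixes, "overall",
                                percent = config$mcp_percent)
    }
    say("home ranges: %d monthly, %d overall estimates",
        if (is.null(hr$monthly)) 0L else nrow(hr$monthly),
        if (is.null(hr$overall)) 0L else nrow(hr$overall))
  }

  covtabs <- list()
  rec_for_scale <- function(scale) switch(scale, daily = daily,
                                          monthly = monthly, overall = overall)
  for (scale in config$scales) {
    covtabs[[scale]] <- attach_covariates(rec_for_scale(scale), scale,
                                          scr$fixes, weather, landscape)
  }

  hr_table <- function(scale) {
    est <- hr[[scale]]
    est <- est[est$method == config$hr_method, , drop = FALSE]
    base <- covtabs[[scale]]
    key_b <- if (scale == "monthly") paste(base$animal_id, base$month) else base$animal_id
    key_e <- if (scale == "monthly") paste(est$animal_id, est$month) else est$animal_id
    base$area_km2 <- est$area_km2[match(key_b, key_e)]
    base
  }

  seeds <- list()
  screenings <- list()
  models <- list()
  for (response in intersect(config$responses, c("mxd", "mhd", "hr"))) {
    for (scale in applicable_scales(response, config$scales)) {
      tab <- if (response == "hr") hr_table(scale) else covtabs[[scale]]
      ycol <- RESPONSE_COLUMNS[[response]]
      wcol <- if (scale == "daily") "n_fixes" else "weight"
      for (category in config$categories) {
        cell <- paste(response, scale, category, sep = ".")
        kept <- NULL
        if (category %in% config$screen_categories) {
          cols <- intersect(attr(tab, "categories")[[category]], names(tab))
          cols <- cols[vapply(cols, function(cl) is.numeric(tab[[cl]]) &&
                                length(unique(stats::na.omit(tab[[cl]]))) > 1,
                              logical(1))]
          ok <- stats::complete.cases(tab[c(ycol, cols)])
          if (length(cols) >= 2 && sum(ok) >= 30) {
            sseed <- seed_for(config$seed, paste0("screen/", cell))
            seeds[[paste0("screen/", cell)]] <- sseed
            sc <- screen_predictors(tab[[ycol]][ok], tab[ok, cols, drop = FALSE],
                                    weights = tab[[wcol]][ok],
                                    threshold = config$corr_threshold,
                                    epsilon = config$epsilon,
                                    n_trees = config$rf_trees, seed = sseed)
            screenings[[cell]] <- sc
            kept <- sc$kept
          }
        }
        spec <- category_spec(tab, response, scale, category, kept = kept,
                              k = config$k, spatial_k = config$spatial_k,
                              weights_col = wcol)
        models[[cell]] <- tryCatch(
          fit_gamm(spec, tab),
          error = function(e) {
            # fallback path: retry with the predictor set halved (importance
            # order) before declaring the cell failed
            fallback <- tryCatch({
              if (!is.null(kept) && length(kept) > 1) {
                spec2 <- category_spec(tab, response, scale, category,
                                       kept = kept[seq_len(ceiling(length(kept) / 2))],
                                       k = config$k, spatial_k = config$spatial_k,
                                       weights_col = wcol)
                f <- fit_gamm(spec2, tab)
                f$fallback <- TRUE
                f
              } else NULL
            }, error = function(e2) NULL)
            if (is.null(fallback)) {
              structure(list(error = conditionMessage(e), spec = spec),
                        class = "gamm_failure")
            } else fallback
          })
        say("model %s: %s", cell,
            if (inherits(models[[cell]], "gamm_failure")) "FAILED" else
              sprintf("adj R^2 = %.3f", models[[cell]]$adj_r2))
      }
    }
  }

  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    n_input_fixes = nrow(telemetry), audit = scr$audit,
    n_daily = nrow(daily), n_monthly = nrow(monthly), n_overall = nrow(overall),
    models_attempted = length(models),
    models_failed = sum(vapply(models, inherits, logical(1), "gamm_failure")),
    timestamp_fields = TELEMETRY_COLUMNS)
  structure(list(screened = scr, daily = daily, monthly = monthly,
                 overall = overall, home_ranges = hr, covariates = covtabs,
                 screenings = screenings, models = models,
                 manifest = manifest, config = config),
            class = "movecap_run")
}

#' Tabular significance summary of a pipeline run
#'
#' One row per fitted term per model: the tabular equivalent of a
#' significant-variable summary across responses, scales and categories.
#' Latitude/longitude smooths and random intercepts are kept but marked as
#' control terms.
#'
#' @param bundle From \code{\link{run_pipeline}}.
#' @param alpha Significance level for the approximate Wald tests.
#' @return Data frame: response, scale, category, term, term_class, edf_or_df,
#'   p_value, significant.
#' @export
summarize_run <- function(bundle, alpha = 0.05) {
  rows <- list()
  control_pat <- "centroid_lat|centroid_lon|animal_id|study_id"
  for (cell in names(bundle$models)) {
    m <- bundle$models[[cell]]
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    if (inherits(m, "gamm_failure")) next
    add <- function(term, df, p) {
      rows[[length(rows) + 1L]] <<- data.frame(
        response = parts[1], scale = parts[2], category = parts[3],
        term = term,
        term_class = if (grepl(control_pat, term)) "control" else "predictor",
        edf_or_df = df, p_value = p, significant = !is.na(p) && p < alpha,
        stringsAsFactors = FALSE)
    }
    st <- m$smooth_table
    if (!is.null(st)) {
      for (i in seq_len(nrow(st))) {
        add(rownames(st)[i], st[i, "edf"], st[i, ncol(st)])
      }
    }
    pt <- m$param_table
    if (!is.null(pt) && nrow(pt) > 0) {
      for (i in seq_len(nrow(pt))) {
        add(rownames(pt)[i], pt[i, "df"], pt[i, ncol(pt)])
      }
    }
    # linear numeric terms (distances, indicators) appear in the coefficient
    # table rather than pTerms when they are single columns
  }
  if (length(rows) == 0) {
    return(data.frame(response = character(), scale = character(),
                      category = character(), term = character(),
                      term_class = character(), edf_or_df = numeric(),
                      p_value = numeric(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
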