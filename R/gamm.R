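# Per-category generalized additive mixed models. One model is fitted per
# response x scale x predictor-category cell: penalized cubic regression
# splines with equally spaced knots (mgcv bs = "cr" plus the select = TRUE
# null-space shrinkage penalty, so uninfluential terms shrink to zero), a
# cyclic basis for month, linear terms for landscape distances, factor terms for
# sex-age / ecoregion / management, random intercepts for animal and study
# (study only at the overall scale), fix-count weights, latitude and
# longitude smooths in every model, and -- at the daily scale --
# Cochrane-Orcutt-style AR(1) residual iteration.

RESPONSE_COLUMNS <- c(mxd = "mxd_km", mhd = "mhd_km", hr = "area_km2")

#' Specify one additive mixed model
#'
#' @param response One of \code{"mxd"}, \code{"mhd"}, \code{"hr"}.
#' @param scale \code{"daily"}, \code{"monthly"} or \code{"overall"}.
#' @param category Predictor category (\code{"individual"},
#'   \code{"meteorological"}, \code{"temporal"}, \code{"geographic"},
#'   \code{"landscape"}).
#' @param smooth_vars Numeric covariates entering as penalized smooths.
#' @param linear_vars Covariates entering linearly (landscape distances,
#'   the management indicator).
#' @param factor_vars Categorical covariates (sex-age, ecoregion).
#' @param k Basis size per smooth (default 10).
#' @param spatial_k Basis size of the latitude/longitude smooths.
#' @param weights_col Column holding the fix-count weights.
#' @param ar1 Apply the AR(1) residual iteration (daily scale only).
#' @param log_link Model log(response) instead of the km-scale response.
#' @return A list of class \code{gamm_spec}.
#' @export
gamm_spec <- function(response, scale, category,
                      smooth_vars = character(0), linear_vars = character(0),
                      factor_vars = character(0), k = 10, spatial_k = 8,
                      weights_col = "weight", ar1 = (scale == "daily"),
                      log_link = FALSE) {
  stopifnot(response %in% names(RESPONSE_COLUMNS),
            scale %in% c("daily", "monthly", "overall"))
  if (ar1 && scale != "daily") stop("AR(1) residuals apply at the daily scale only")
  structure(list(response = response, response_col = RESPONSE_COLUMNS[[response]],
                 scale = scale, category = category,
                 smooth_vars = smooth_vars, linear_vars = linear_vars,
                 factor_vars = factor_vars, k = k, spatial_k = spatial_k,
                 weights_col = weights_col, ar1 = ar1, log_link = log_link),
            class = "gamm_spec")
}

# standard per-category spec from a covariate table's category manifest
category_spec <- function(covtab, response, scale, category, kept = NULL, ...) {
  cats <- attr(covtab, "categories")
  if (is.null(cats)) stop("covariate table lacks a 'categories' attribute")
  cols <- cats[[category]]
  if (!is.null(kept)) cols <- intersect(cols, kept)
  cols <- intersect(cols, names(covtab))
  smooth_vars <- linear_vars <- factor_vars <- character(0)
  if (category == "individual") {
    factor_vars <- intersect("sexage", cols)
    linear_vars <- intersect("managed", cols)
  } else if (category == "geographic") {
    factor_vars <- cols
  } else if (category == "landscape") {
    linear_vars <- cols
  } else {
    smooth_vars <- cols
  }
  gamm_spec(response, scale, category, smooth_vars = smooth_vars,
            linear_vars = linear_vars, factor_vars = factor_vars, ...)
}

#' Build the penalized design for a model specification
#'
#' Assembles the mgcv formula, equally spaced knot sequences, the cleaned
#' model frame (rows with missing values dropped and counted, characters
#' coerced to factors) and the weight vector. Smooth basis sizes are reduced
#' with a warning when a covariate has too few distinct values; single-level
#' factors and constant covariates are dropped with a warning.
#'
#' @param spec A \code{\link{gamm_spec}}.
#' @param data Modeling records with covariates attached
#'   (\code{\link{attach_covariates}}).
#' @return List: \code{formula}, \code{data}, \code{knots}, \code{weights},
#'   \code{n_dropped}, \code{terms} (per-term bookkeeping), \code{notes}.
#' @export
build_design <- function(spec, data) {
  notes <- character(0)
  yname <- spec$response_col
  if (!yname %in% names(data)) stop("response column not found: ", yname)
  vars <- unique(c(yname, spec$smooth_vars, spec$linear_vars, spec$factor_vars,
                   "centroid_lat", "centroid_lon", spec$weights_col,
                   "animal_id", "study_id",
                   if (spec$scale == "daily") "day"))
  vars <- intersect(vars, names(data))
  df <- data[, vars, drop = FALSE]
  if (spec$scale == "daily" && !is.null(df$day)) {
    df <- df[order(df$animal_id, df$day), , drop = FALSE]
  }
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (spec$log_link) df[[yname]] <- log(pmax(df[[yname]], 1e-6))

  smooth_terms <- character(0); knots <- list()
  smooth_vars <- spec$smooth_vars
  for (v in unique(c(smooth_vars, "centroid_lat", "centroid_lon"))) {
    if (!v %in% names(df)) next
    kv <- if (v %in% c("centroid_lat", "centroid_lon")) spec$spatial_k else spec$k
    nd <- length(unique(df[[v]]))
    cyclic <- identical(v, "month_num")
    if (nd < 3 || (cyclic && nd < 5)) {
      if (nd >= 2) {
        spec$linear_vars <- c(spec$linear_vars, v)
        notes <- c(notes, sprintf("smooth '%s' demoted to linear (%d distinct values)", v, nd))
      } else {
        notes <- c(notes, sprintf("covariate '%s' constant, dropped", v))
      }
      next
    }
    if (cyclic) {
      kk <- min(kv, nd)
      smooth_terms <- c(smooth_terms,
                        sprintf("s(month_num, bs = 'cc', k = %d)", kk))
      knots$month_num <- seq(0.5, 12.5, length.out = kk)
    } else {
      if (nd < kv) {
        notes <- c(notes, sprintf("basis for '%s' reduced to %d", v, nd))
        kv <- nd
      }
      smooth_terms <- c(smooth_terms, sprintf("s(%s, bs = 'cr', k = %d)", v, kv))
      knots[[v]] <- seq(min(df[[v]]), max(df[[v]]), length.out = kv)
    }
  }

  linear_terms <- character(0)
  for (v in unique(spec$linear_vars)) {
    if (!v %in% names(df)) next
    if (length(unique(df[[v]])) < 2) {
      notes <- c(notes, sprintf("linear term '%s' constant, dropped", v))
      next
    }
    linear_terms <- c(linear_terms, v)
  }

  factor_terms <- character(0)
  for (v in spec$factor_vars) {
    if (!v %in% names(df)) next
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) {
      notes <- c(notes, sprintf("factor '%s' has one level, dropped", v))
      next
    }
    factor_terms <- c(factor_terms, v)
  }

  re_terms <- character(0)
  df$animal_id <- factor(df$animal_id)
  df$study_id <- factor(df$study_id)
  if (spec$scale != "overall" && nlevels(df$animal_id) > 1) {
    re_terms <- c(re_terms, "s(animal_id, bs = 're')")
  }
  if (nlevels(df$study_id) > 1) {
    re_terms <- c(re_terms, "s(study_id, bs = 're')")
  } else {
    notes <- c(notes, "single study: study random intercept dropped")
  }

  rhs <- c(factor_terms, linear_terms, smooth_terms, re_terms)
  if (length(rhs) == 0) rhs <- "1"
  fml <- stats::as.formula(paste(yname, "~", paste(rhs, collapse = " + ")))
  w <- if (spec$weights_col %in% names(df)) df[[spec$weights_col]] else rep(1, nrow(df))
  for (nt in notes) warning(nt, call. = FALSE)
  list(formula = fml, data = df, knots = knots, weights = w,
       n_dropped = n_dropped,
       terms = list(smooth = smooth_terms, linear = linear_terms,
                    factor = factor_terms, random = re_terms),
       notes = notes)
}

# pooled lag-1 autocorrelation of residuals within unbroken day runs
pooled_lag1 <- function(res, animal, day) {
  ord <- order(animal, day)
  res <- res[ord]; animal <- animal[ord]; day <- as.integer(day[ord])
  n <- length(res)
  if (n < 2) return(0)
  same <- animal[-1] == animal[-n] & (day[-1] - day[-n]) == 1L
  if (!any(same)) return(0)
  num <- sum(res[-1][same] * res[-n][same])
  den <- sum(res^2) * (sum(same) / n)
  if (den <= 0) return(0)
  num / den
}

#' Fit a per-category additive mixed model
#'
#' Penalized weighted fit with REML smoothing selection (mgcv). At the daily
#' scale with \code{spec$ar1}, a Cochrane-Orcutt-style iteration estimates
#' the AR(1) coefficient rho from the pooled lag-1 autocorrelation of
#' within-animal residuals over unbroken day runs, refits with the residual
#' AR(1) model (mgcv::bam prewhitening), and repeats until |delta rho| <
#' 1e-3 (max 20 iterations).
#'
#' @param spec A \code{\link{gamm_spec}}.
#' @param data Modeling records with covariates.
#' @return Object of class \code{gamm_fit}: the mgcv fit plus \code{spec},
#'   \code{design}, \code{rho}, \code{rho_flag}, \code{adj_r2},
#'   \code{variance_components} (random-intercept and smooth sds),
#'   \code{smooth_table}, \code{param_table} (approximate Wald tests),
#'   \code{converged}.
#' @export
fit_gamm <- function(spec, data) {
  des <- suppressWarnings(build_design(spec, data))
  df <- des$data
  df$.w <- des$weights
  rho <- 0; rho_flag <- ""
  if (spec$ar1 && !is.null(df$day)) {
    nr <- nrow(df)
    aid <- as.character(df$animal_id)
    df$.ar_start <- c(TRUE, diff(as.integer(df$day)) != 1L) |
      c(TRUE, aid[-1] != aid[-nr])
    fit <- mgcv::bam(des$formula, data = df, weights = .w, knots = des$knots,
                     method = "fREML", select = TRUE, rho = 0,
                     AR.start = .ar_start)
    for (it in seq_len(20)) {
      res <- df[[spec$response_col]] - stats::fitted(fit)
      rho_new <- pooled_lag1(res, as.character(df$animal_id), df$day)
      if (abs(rho_new) > 0.99) {
        rho_new <- sign(rho_new) * 0.99
        rho_flag <- "rho clipped to (-0.99, 0.99)"
      }
      if (abs(rho_new - rho) < 1e-3) { rho <- rho_new; break }
      rho <- rho_new
      fit <- mgcv::bam(des$formula, data = df, weights = .w, knots = des$knots,
                         method = "fREML", select = TRUE, rho = rho,
                         AR.start = .ar_start)
    }
  } else {
    fit <- mgcv::gam(des$formula, data = df, weights = .w, knots = des$knots,
                     method = "REML", select = TRUE)
  }
  sm <- summary(fit)
  vc <- tryCatch({
    utils::capture.output(v <- mgcv::gam.vcomp(fit, rescale = TRUE))
    if (is.matrix(v)) stats::setNames(v[, "std.dev"], rownames(v)) else v
  }, error = function(e) NULL)
  structure(list(fit = fit, spec = spec, design = des,
                 rho = rho, rho_flag = rho_flag,
                 adj_r2 = sm$r.sq,
                 variance_components = vc,
                 smooth_table = sm$s.table,
                 param_table = sm$pTerms.table,
                 converged = isTRUE(fit$converged) || is.null(fit$converged)),
            class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf("Additive mixed model: %s ~ %s covariates (%s scale)\n",
              x$spec$response_col, x$spec$category, x$spec$scale))
  cat(sprintf("  n = %d, adj R^2 = %.3f, AR(1) rho = %.3f\n",
              nrow(x$design$data), x$adj_r2, x$rho))
  if (!is.null(x$smooth_table)) {
    cat("  smooth terms:\n")
    print(round(x$smooth_table, 4))
  }
  invisible(x)
}

#' Centered partial-effect curve (reaction norm) of one covariate
#'
#' Evaluates the covariate's smooth (or linear) contribution on a grid over
#' its observed range, with a pointwise +/- 2 SE band, and reports shape
#' diagnostics: the location of the curve maximum and a concavity indicator.
#' Concavity is judged from the second differences of the effect curve over
#' the central 50 percent of the grid: the curve is called concave (convex)
#' when the net slope change is negative (positive), its window-scaled
#' magnitude relative to the curve's amplitude exceeds 0.2 (a pure quadratic
#' scores about 2, a line about 0), and at least 70 percent of the second
#' differences share its sign; otherwise \code{"none"}.
#'
#' @param object A \code{\link{fit_gamm}} result.
#' @param covariate Covariate name present in the model.
#' @param n_grid Grid size.
#' @return List: \code{curve} (data frame covariate/effect/se),
#'   \code{argmax}, \code{amplitude} (max - min of the effect),
#'   \code{concavity} (\code{"concave"}, \code{"convex"} or \code{"none"}).
#' @export
reaction_norm <- function(object, covariate, n_grid = 100) {
  stopifnot(inherits(object, "gamm_fit"))
  df <- object$design$data
  if (!covariate %in% names(df)) stop("covariate not in model: ", covariate)
  grid <- seq(min(df[[covariate]]), max(df[[covariate]]), length.out = n_grid)
  nd <- df[rep(1L, n_grid), , drop = FALSE]
  for (nm in names(nd)) {
    if (is.factor(df[[nm]])) {
      lev <- names(sort(table(df[[nm]]), decreasing = TRUE))[1]
      nd[[nm]] <- factor(lev, levels = levels(df[[nm]]))
    } else if (is.numeric(df[[nm]])) {
      nd[[nm]] <- stats::median(df[[nm]])
    }
  }
  nd[[covariate]] <- grid
  pr <- stats::predict(object$fit, newdata = nd, type = "terms", se.fit = TRUE)
  cols <- colnames(pr$fit)
  hit <- cols[grepl(paste0("(^|\\()", covariate, "(,|\\)|$)"), cols)]
  if (length(hit) == 0) stop("no model term found for covariate: ", covariate)
  eff <- rowSums(pr$fit[, hit, drop = FALSE])
  se <- sqrt(rowSums(pr$se.fit[, hit, drop = FALSE]^2))
  eff <- eff - mean(eff)

  mid <- seq.int(ceiling(n_grid * 0.25), floor(n_grid * 0.75))
  d2 <- diff(eff[mid], differences = 2)
  amp <- max(eff) - min(eff)
  concavity <- "none"
  # net curvature = slope change across the window (sum of second
  # differences); scaled by window length / amplitude this index is ~2 for a
  # pure quadratic spanning the grid and ~0 for a line. Require a
  # non-negligible index and a consistent sign along the window, so
  # near-linear fits are not called curved.
  tot <- sum(d2)
  index <- abs(tot) * length(d2) / max(amp, 1e-10)
  if (amp > 1e-10 && index > 0.2 && mean(sign(d2) == sign(tot)) >= 0.7) {
    concavity <- if (tot < 0) "concave" else "convex"
  }
  list(curve = data.frame(covariate = grid, effect = eff, se = se),
       argmax = grid[which.max(eff)],
       amplitude = max(eff) - min(eff),
       concavity = concavity)
}
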