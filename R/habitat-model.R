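# Additive habitat model for maximum daily dive (MDD) depth.
#
# A Gaussian identity-link additive model with penalized cubic regression
# spline smooths per environmental covariate, optional tensor-product
# interactions, and a per-shark random intercept. Structure selection is
# backward elimination on AIC (maximum-likelihood fits), followed by
# linearization of effectively-linear smooths when AIC prefers it, and a
# confirmation prune of terms whose approximate test is not significant --
# plain backward AIC retains spurious smooths at a rate (about
# P(chi^2_1 > 2) ~ 16% per candidate) that makes structure recovery
# unreliable, so retention requires both AIC support and significance.
# The selected structure is refit by REML for reporting and prediction.

#' Build a model frame, discarding deep-dive outliers
#'
#' Rows whose MDD depth is strictly above the empirical `outlier_quantile`
#' of the MDD distribution are removed (ties at the quantile are kept); the
#' removal threshold is attached as `attr(, "outlier_threshold")`.
#'
#' @param dive_days data.frame with `mdd_depth` and matched covariates
#'   (rows with missing covariates among `covariates` are dropped).
#' @param covariates Covariate columns required to be complete; defaults to
#'   every candidate the model considers that is present in the input.
#' @param outlier_quantile Upper MDD quantile retained (default 0.90).
#' @return Filtered data.frame with attributes `outlier_threshold` and
#'   `n_removed`.
#' @export
build_frame <- function(dive_days, covariates = NULL,
                        outlier_quantile = 0.90) {
  if (is.null(covariates))
    covariates <- intersect(c("sst", "temp_100", "sal_surface", "sal_100",
                              "do_100", "npp_100", "chl_surface", "chl_100",
                              "phyto_surface", "phyto_100"),
                            names(dive_days))
  keep <- stats::complete.cases(dive_days[, c("mdd_depth", covariates),
                                          drop = FALSE])
  frame <- dive_days[keep, , drop = FALSE]
  thr <- stats::quantile(frame$mdd_depth, outlier_quantile, names = FALSE)
  out <- frame[frame$mdd_depth <= thr, , drop = FALSE]
  if (nrow(out) == 0) stop("outlier filter removed every row")
  attr(out, "outlier_threshold") <- thr
  attr(out, "n_removed") <- nrow(frame) - nrow(out)
  out
}

term_label <- function(cov, kind) {
  switch(kind, smooth = paste0("s(", cov, ")"), linear = cov,
         tensor = paste0("te(", cov, ")"))
}

build_formula <- function(terms, k) {
  rhs <- vapply(terms, function(t) {
    if (t$kind == "smooth")
      sprintf("s(%s, bs = 'cr', k = %d)", t$cov, k)
    else if (t$kind == "tensor")
      sprintf("te(%s, k = %d)", t$cov, max(4, ceiling(sqrt(k))))
    else t$cov
  }, character(1))
  rhs <- c(rhs, "s(shark_id, bs = 're')")
  stats::as.formula(paste("mdd_depth ~", paste(rhs, collapse = " + ")))
}

fit_gam <- function(terms, frame, k, method) {
  mgcv::gam(build_formula(terms, k), data = frame, method = method,
            family = stats::gaussian())
}

#' Fit the MDD habitat model with backward AIC selection
#'
#' Starts from the full model (one penalized spline per candidate covariate,
#' optional tensor-product interactions `sst x do_100`, `npp_100 x do_100`
#' and `sst x npp_100`, and a per-shark random intercept), then repeatedly
#' removes the term whose removal lowers AIC the most; afterwards each
#' retained smooth is replaced by a linear term when AIC prefers it, and
#' terms whose approximate significance exceeds `alpha` are pruned. The
#' random intercept is never removed. The full selection trace is recorded.
#'
#' @param frame A model frame from [build_frame()] (needs `mdd_depth` and a
#'   factor-coercible `shark_id`; at least 2 sharks and 50 rows).
#' @param candidates Character vector of candidate covariate columns.
#' @param include_tensors Consider the three tensor interactions (default
#'   `FALSE`; they enter the initial full model and are removable like any
#'   term).
#' @param k Spline basis dimension (default 10).
#' @param alpha Significance level of the confirmation prune (default 0.01;
#'   see the package vignette for the choice).
#' @param method Smoothing-parameter criterion for the final refit
#'   (`"REML"`, the default, or `"GCV.Cp"`); selection always uses ML.
#' @return Object of class `mdd_fit`: the final `gam` fit, retained `terms`,
#'   `aic`, `selection_trace` (data.frame), `intercept`, `adj_r2`,
#'   `outlier_threshold` when present on the frame, and post-fit residual
#'   diagnostics (`lag1_autocorrelation`, residual vs fitted slope).
#' @export
fit_mdd_model <- function(frame,
                          candidates = c("sst", "temp_100", "sal_surface",
                                         "sal_100", "do_100", "npp_100",
                                         "chl_surface", "chl_100",
                                         "phyto_surface", "phyto_100"),
                          include_tensors = FALSE, k = 10, alpha = 0.01,
                          method = "REML") {
  frame$shark_id <- as.factor(frame$shark_id)
  if (nlevels(frame$shark_id) < 2) stop("need at least 2 sharks")
  if (nrow(frame) < 50) stop("need at least 50 rows")
  candidates <- intersect(candidates, names(frame))
  terms <- lapply(candidates, function(cc) list(cov = cc, kind = "smooth"))
  if (include_tensors) {
    tens <- list("sst, do_100", "npp_100, do_100", "sst, npp_100")
    for (tt in tens) {
      covs <- trimws(strsplit(tt, ",")[[1]])
      if (all(covs %in% candidates))
        terms <- c(terms, list(list(cov = tt, kind = "tensor")))
    }
  }
  trace <- list()
  note <- function(step, action, term, aic)
    trace[[length(trace) + 1]] <<- data.frame(step = step, action = action,
                                              term = term, aic = aic)
  cur <- fit_gam(terms, frame, k, "ML")
  cur_aic <- stats::AIC(cur)
  note(0L, "full", "(all candidates)", cur_aic)
  step <- 1L

  # backward elimination on AIC
  repeat {
    if (length(terms) == 0) break
    aics <- vapply(seq_along(terms), function(d) {
      f <- try(fit_gam(terms[-d], frame, k, "ML"), silent = TRUE)
      if (inherits(f, "try-error")) Inf else stats::AIC(f)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] < cur_aic) {
      note(step, "drop",
           term_label(terms[[best]]$cov, terms[[best]]$kind), aics[best])
      terms <- terms[-best]
      cur_aic <- aics[best]
      step <- step + 1L
    } else break
  }

  # linear replacement of effectively-linear smooths
  for (d in seq_along(terms)) {
    if (terms[[d]]$kind != "smooth") next
    alt <- terms
    alt[[d]]$kind <- "linear"
    f <- try(fit_gam(alt, frame, k, "ML"), silent = TRUE)
    if (!inherits(f, "try-error") && stats::AIC(f) < cur_aic) {
      note(step, "linearize", term_label(terms[[d]]$cov, "smooth"),
           stats::AIC(f))
      terms <- alt
      cur_aic <- stats::AIC(f)
      step <- step + 1L
    }
  }

  # confirmation prune: drop terms not significant at alpha
  repeat {
    if (length(terms) == 0) break
    fit_ml <- fit_gam(terms, frame, k, "ML")
    pv <- term_p_values(fit_ml, terms)
    worst <- which.max(pv)
    if (is.finite(pv[worst]) && pv[worst] > alpha) {
      lbl <- names(pv)[worst]
      terms <- terms[-worst]
      f2 <- fit_gam(terms, frame, k, "ML")
      note(step, "prune (p > alpha)", lbl, stats::AIC(f2))
      cur_aic <- stats::AIC(f2)
      step <- step + 1L
    } else break
  }

  final <- fit_gam(terms, frame, k, method)
  sm <- summary(final)
  res <- stats::residuals(final)
  fitted_vals <- stats::fitted(final)
  diag <- list(
    lag1_autocorrelation = if (length(res) > 2)
      stats::cor(res[-1], res[-length(res)]) else NA_real_,
    resid_fitted_slope = if (stats::var(fitted_vals) > 0)
      unname(stats::coef(stats::lm(res ~ fitted_vals))[2]) else NA_real_)
  structure(list(fit = final, terms = terms,
                 term_labels = vapply(terms, function(t)
                   term_label(t$cov, t$kind), character(1)),
                 aic = stats::AIC(final), aic_ml = cur_aic,
                 selection_trace = do.call(rbind, trace),
                 intercept = unname(stats::coef(final)[1]),
                 adj_r2 = sm$r.sq, method = method, k = k, alpha = alpha,
                 n = nrow(frame),
                 outlier_threshold = attr(frame, "outlier_threshold"),
                 diagnostics = diag, frame = frame),
            class = "mdd_fit")
}

# approximate p-value per model term (smooth/tensor from the smooth table,
# linear from the parametric table)
term_p_values <- function(fit, terms) {
  sm <- summary(fit)
  pv <- vapply(terms, function(t) {
    if (t$kind %in% c("smooth", "tensor")) {
      lbl <- if (t$kind == "smooth") paste0("s(", t$cov, ")")
      else paste0("te(", gsub(", ", ",", t$cov), ")")
      rn <- rownames(sm$s.table)
      hit <- match(lbl, rn)
      if (is.na(hit)) hit <- grep(t$cov, rn, fixed = TRUE)[1]
      sm$s.table[hit, "p-value"]
    } else {
      rn <- rownames(sm$p.table)
      sm$p.table[match(t$cov, rn), "Pr(>|t|)"]
    }
  }, numeric(1))
  names(pv) <- vapply(terms, function(t) term_label(t$cov, t$kind),
                      character(1))
  pv
}

#' @export
print.mdd_fit <- function(x, ...) {
  cat("Additive MDD habitat model (n =", x$n, ")\n")
  cat("  terms:", if (length(x$term_labels) > 0)
    paste(x$term_labels, collapse = " + ") else "(intercept only)",
    "+ s(shark_id, re)\n")
  cat("  intercept:", round(x$intercept, 2), "m;  AIC:",
      round(x$aic, 1), ";  adj R^2:", round(x$adj_r2, 3), "\n")
  invisible(x)
}

#' Centred partial effect of a retained term
#'
#' @param fit An `mdd_fit`.
#' @param term Covariate name of a retained term (e.g. `"do_100"`).
#' @param values Covariate grid; defaults to 200 points over the observed
#'   range.
#' @return data.frame with `value`, `effect` (centred partial response, m)
#'   and `se`.
#' @export
partial_effect <- function(fit, term, values = NULL) {
  covs <- vapply(fit$terms, `[[`, character(1), "cov")
  if (!term %in% covs)
    stop("term '", term, "' not retained in the fit")
  frame <- fit$frame
  if (is.null(values))
    values <- seq(min(frame[[term]]), max(frame[[term]]), length.out = 200)
  nd <- frame[rep(1, length(values)), , drop = FALSE]
  for (cc in covs) nd[[cc]] <- stats::median(frame[[cc]])
  nd[[term]] <- values
  kind <- fit$terms[[match(term, covs)]]$kind
  lbl <- if (kind == "smooth") paste0("s(", term, ")") else term
  pr <- stats::predict(fit$fit, newdata = nd, type = "terms",
                       se.fit = TRUE)
  col <- match(lbl, colnames(pr$fit))
  if (is.na(col)) col <- grep(term, colnames(pr$fit), fixed = TRUE)[1]
  eff <- pr$fit[, col]
  data.frame(value = values, effect = eff - mean(eff), se = pr$se.fit[, col])
}

#' Estimate the breakpoint of a fitted partial effect
#'
#' Fits a broken-stick (continuous piecewise-linear) model to the partial
#' response curve, scanning candidate knots over the inner 80% of the
#' covariate range and keeping the knot that minimizes the residual sum of
#' squares -- the fitted counterpart of a threshold below which MDD depth
#' starts to shrink.
#'
#' @param fit An `mdd_fit` retaining the term.
#' @param term Covariate name (default `"do_100"`).
#' @return Covariate value of the best-fitting knot.
#' @export
estimate_breakpoint <- function(fit, term = "do_100") {
  pe <- partial_effect(fit, term,
                       values = seq(min(fit$frame[[term]]),
                                    max(fit$frame[[term]]),
                                    length.out = 401))
  x <- pe$value; y <- pe$effect
  lo <- stats::quantile(x, 0.10); hi <- stats::quantile(x, 0.90)
  knots <- seq(lo, hi, length.out = 161)
  rss <- vapply(knots, function(b) {
    h <- pmax(x - b, 0)
    sum(stats::lm.fit(cbind(1, x, h), y)$residuals^2)
  }, numeric(1))
  knots[which.min(rss)]
}

#' Covariate value maximizing a partial effect
#'
#' @param fit An `mdd_fit`.
#' @param term Covariate name (e.g. `"sst"` for the thermal optimum).
#' @return Covariate value at the maximum of the centred partial response.
#' @export
partial_effect_argmax <- function(fit, term) {
  pe <- partial_effect(fit, term)
  pe$value[which.max(pe$effect)]
}

#' Mixed layer depth from a temperature profile
#'
#' Shallowest depth at which temperature falls more than `delta_t` below the
#' temperature at `ref_depth`, linearly interpolated between levels. When
#' the criterion is never met the deepest level is returned with
#' `attr(, "criterion_met") = FALSE`.
#'
#' @param depth Depth levels, m (must span `ref_depth`).
#' @param temp Temperatures at `depth`, degC.
#' @param delta_t Temperature criterion, degC (default 0.2).
#' @param ref_depth Reference depth, m (default 10).
#' @return MLD in metres.
#' @export
compute_mld <- function(depth, temp, delta_t = 0.2, ref_depth = 10) {
  if (min(depth) > ref_depth || max(depth) < ref_depth)
    stop("profile does not span the reference depth")
  t_ref <- stats::approx(depth, temp, xout = ref_depth)$y
  target <- t_ref - delta_t
  below <- depth >= ref_depth
  zz <- depth[below]; tt <- temp[below]
  hit <- which(tt < target)
  if (length(hit) == 0) {
    out <- max(depth)
    attr(out, "criterion_met") <- FALSE
    return(out)
  }
  h <- hit[1]
  if (h == 1) {
    out <- ref_depth
  } else {
    # linear interpolation of the crossing between levels h-1 and h
    z0 <- zz[h - 1]; z1 <- zz[h]; t0 <- tt[h - 1]; t1 <- tt[h]
    out <- if (t0 == t1) z1 else z0 + (t0 - target) / (t0 - t1) * (z1 - z0)
    out <- max(out, ref_depth)
  }
  attr(out, "criterion_met") <- TRUE
  out
}

#' Predict MDD depth on a 1-degree grid, capped at mixed layer depth
#'
#' Box-averages the environment over each cell to obtain the model
#' covariates, predicts MDD depth from the fixed effects (the shark random
#' intercept is excluded), and caps predictions at the local mixed layer
#' depth computed from the cell's temperature profile.
#'
#' @param fit An `mdd_fit`.
#' @param env An [env_grid()].
#' @param cell_size Prediction cell size, degrees (default 1).
#' @param delta_t,ref_depth MLD criterion passed to [compute_mld()].
#' @return data.frame with `cell_lon`, `cell_lat` (lower-left corner),
#'   `predicted_mdd` (m), `mld` (m), and logical `capped`; the number of
#'   predicted cells is `attr(, "n_cells")`.
#' @export
predict_mdd_map <- function(fit, env, cell_size = 1, delta_t = 0.2,
                            ref_depth = 10) {
  lon0 <- seq(floor(min(env$lon)), ceiling(max(env$lon)) - cell_size,
              by = cell_size)
  lat0 <- seq(floor(min(env$lat)), ceiling(max(env$lat)) - cell_size,
              by = cell_size)
  cells <- expand.grid(cell_lon = lon0, cell_lat = lat0)
  covs <- vapply(fit$terms, `[[`, character(1), "cov")
  covs <- unique(trimws(unlist(strsplit(covs, ","))))
  half <- cell_size / 2
  nd <- list(); mld <- numeric(nrow(cells)); okrow <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cx <- cells$cell_lon[i] + half; cy <- cells$cell_lat[i] + half
    if (!env_contains(env, cx, cy)) next
    s <- box_average(env, cx, cy, lat_halfwidth = half,
                     lon_halfwidth = half)
    vals <- lapply(covs, function(cc) s[[cc]])
    if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
      next
    names(vals) <- covs
    nd[[length(nd) + 1]] <- as.data.frame(vals)
    mld[i] <- compute_mld(s$depth, s$temp, delta_t, ref_depth)
    okrow[i] <- TRUE
  }
  cells$predicted_mdd <- NA_real_
  cells$mld <- NA_real_
  cells$capped <- NA
  if (any(okrow)) {
    newdata <- do.call(rbind, nd)
    newdata$shark_id <- factor(levels(fit$frame$shark_id)[1],
                               levels = levels(fit$frame$shark_id))
    pred <- as.numeric(stats::predict(fit$fit, newdata = newdata,
                                      exclude = "s(shark_id)",
                                      newdata.guaranteed = TRUE))
    cells$predicted_mdd[okrow] <- pred
    cells$mld[okrow] <- mld[okrow]
    over <- okrow & cells$predicted_mdd > cells$mld
    cells$capped[okrow] <- FALSE
    cells$capped[over] <- TRUE
    cells$predicted_mdd[over] <- cells$mld[over]
  }
  out <- cells[okrow, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_cells") <- nrow(out)
  out
}
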