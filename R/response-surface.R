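#' Expand a designed experiment into a long observation table
#'
#' One row per (run, sampling time): the run's factor settings repeated over
#' its sampling times, with the measured response. This is the observation
#' table the response-surface model is fitted to.
#'
#' @param design an `ep_design` with a complete response block.
#' @return data frame with columns `run`, `time_h`, one column per factor
#'   (g/100 mL) and `ep_ug_per_L`.
#' @export
#' @examples
#' long <- assemble_long_table(load_design_fixture())
#' nrow(long)  # 10 runs x 4 sampling times
assemble_long_table <- function(design) {
  ep_assert(inherits(design, "ep_design"), "epferm_usage_error",
            "'design' must be an ep_design")
  if (is.null(design$responses) || anyNA(design$responses)) {
    ep_stop("epferm_incomplete_design_error",
            "design has a missing or incomplete response block")
  }
  times <- design$sampling_times
  n <- nrow(design$layout)
  rows <- lapply(seq_len(n), function(i) {
    cbind(
      design$layout[rep(i, length(times)), , drop = FALSE],
      time_h = times,
      ep_ug_per_L = as.numeric(design$responses[i, ]),
      row.names = NULL
    )
  })
  long <- do.call(rbind, rows)
  fac <- setdiff(names(design$layout), "run")
  long[c("run", "time_h", fac, "ep_ug_per_L")]
}

# ---- model object -------------------------------------------------------

#' Build a response-surface model from known coefficients
#'
#' Constructs the mixed quadratic/linear response model
#' \deqn{Y = C + \sum_{i \in Q} (\alpha_i F_i + \beta_i F_i^2) +
#'       \sum_{i \in L} \alpha_i F_i}
#' directly from a coefficient set, e.g. a published coefficient table, so
#' that stationary points, optimum recommendations and predictions can be
#' computed without refitting.
#'
#' @param intercept the constant term `C`.
#' @param quadratic named list; one element per quadratic factor, each a
#'   vector `c(alpha = , beta = )` (linear and squared coefficients).
#' @param linear named numeric vector of coefficients of the linear factors.
#' @param control name of the control variable (the factor that is a process
#'   setting, not a medium component); must be one of the quadratic factors.
#' @return an object of class `ep_rsm`.
#' @export
#' @examples
#' m <- response_model(
#'   intercept = -270.021,
#'   quadratic = list(time_h = c(alpha = 8.617, beta = -0.059),
#'                    glycerol = c(alpha = 50.605, beta = -6.234)),
#'   linear = c(yeast_powder = 15.755, peptone = -43.796, znso4 = -466.113,
#'              mgso4 = 135.518, kh2po4 = 177.269))
#' stationary_point(m, "time_h")
response_model <- function(intercept, quadratic, linear, control = "time_h") {
  ep_assert(is.list(quadratic) && length(names(quadratic)) == length(quadratic),
            "epferm_usage_error", "'quadratic' must be a named list")
  ep_assert(all(vapply(quadratic, function(q)
    all(c("alpha", "beta") %in% names(q)), TRUE)),
    "epferm_usage_error", "each quadratic entry needs alpha and beta")
  ep_assert(is.numeric(linear) && length(names(linear)) == length(linear),
            "epferm_usage_error", "'linear' must be a named numeric vector")
  ep_assert(!any(names(quadratic) %in% names(linear)), "epferm_usage_error",
            "quadratic and linear factor sets must be disjoint")
  ep_assert(control %in% names(quadratic), "epferm_usage_error",
            "'control' must be one of the quadratic factors")
  structure(
    list(intercept = as.numeric(intercept),
         quadratic = lapply(quadratic, function(q) q[c("alpha", "beta")]),
         linear = linear, control = control,
         stats = NULL, fit = NULL),
    class = "ep_rsm"
  )
}

rsm_factors <- function(model) c(names(model$quadratic), names(model$linear))

#' Fit the mixed quadratic/linear response-surface model
#'
#' Ordinary least squares with intercept: the response is quadratic in the
#' control variable and in the first medium factor (by default sampling time
#' and glycerol) and linear in the remaining factors. Per-term standard
#' errors, t and two-sided p values come from the classical linear-model
#' variance estimate; the overall F is regression MS over residual MS.
#'
#' @param table long observation table as from [assemble_long_table()].
#' @param quadratic names of the factors entering with linear + squared terms.
#' @param linear names of the factors entering linearly; default: all other
#'   columns except `run` and the response.
#' @param response response column name.
#' @param control name of the control variable among `quadratic`.
#' @return an `ep_rsm` whose `stats` element carries the coefficient table
#'   (term, estimate, se, t, p), `r2`, `f`, `df`, `p_model` and `n_obs`.
#' @export
#' @examples
#' fit <- fit_response_surface(assemble_long_table(load_design_fixture()))
#' fit$stats$f
fit_response_surface <- function(table,
                                 quadratic = c("time_h", "glycerol"),
                                 linear = NULL,
                                 response = "ep_ug_per_L",
                                 control = quadratic[1]) {
  ep_assert(is.data.frame(table), "epferm_usage_error",
            "'table' must be a data frame")
  if (is.null(linear)) {
    linear <- setdiff(names(table), c("run", response, quadratic))
  }
  miss <- setdiff(c(quadratic, linear, response), names(table))
  ep_assert(length(miss) == 0L, "epferm_data_error",
            sprintf("table misses columns: %s", paste(miss, collapse = ", ")))

  terms <- c(unlist(lapply(quadratic, function(f) c(paste0(f, "^2"), f))),
             linear)
  x <- cbind(
    do.call(cbind, lapply(quadratic, function(f)
      cbind(table[[f]]^2, table[[f]]))),
    as.matrix(table[linear])
  )
  colnames(x) <- terms
  n_obs <- nrow(x)
  p <- ncol(x) + 1L
  if (n_obs <= p) {
    ep_stop("epferm_underdetermined_error",
            sprintf("%d observations cannot identify %d parameters",
                    n_obs, p))
  }
  xi <- cbind("(Intercept)" = 1, x)
  qrx <- qr(xi)
  if (qrx$rank < ncol(xi)) {
    aliased <- colnames(xi)[qrx$pivot[(qrx$rank + 1L):ncol(xi)]]
    ep_stop("epferm_collinearity_error",
            sprintf("model matrix is rank deficient; aliased columns: %s",
                    paste(aliased, collapse = ", ")))
  }

  df <- data.frame(.y = table[[response]], x, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  stats <- list(
    coefficients = data.frame(
      term = c("intercept", terms),
      estimate = unname(co[, 1]), se = unname(co[, 2]),
      t = unname(co[, 3]), p = unname(co[, 4]), row.names = NULL
    ),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    f = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    p_model = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE),
    sigma = sm$sigma, n_obs = n_obs
  )

  est <- setNames(coef(fit), c("(Intercept)", terms))
  quad <- lapply(quadratic, function(f)
    c(alpha = unname(est[f]), beta = unname(est[paste0(f, "^2")])))
  names(quad) <- quadratic
  m <- response_model(unname(est["(Intercept)"]), quad,
                      setNames(unname(est[linear]), linear),
                      control = control)
  m$stats <- stats
  m$fit <- fit
  m
}

#' @export
print.ep_rsm <- function(x, ...) {
  cat(sprintf("<ep_rsm> quadratic in {%s}, linear in {%s}\n",
              paste(names(x$quadratic), collapse = ", "),
              paste(names(x$linear), collapse = ", ")))
  if (!is.null(x$stats)) {
    tab <- x$stats$coefficients
    tab$estimate <- round(tab$estimate, 3)
    tab$se <- round(tab$se, 3)
    tab$t <- round(tab$t, 3)
    tab$p <- round(tab$p, 3)
    print(tab, row.names = FALSE)
    cat(sprintf("R2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n", x$stats$r2,
                x$stats$df[1], x$stats$df[2], x$stats$f, x$stats$p_model))
  } else {
    cat(sprintf("intercept %.3f (coefficients supplied, not fitted)\n",
                x$intercept))
  }
  invisible(x)
}

# ---- stationary point and optimum --------------------------------------

#' Stationary point of a quadratic factor
#'
#' For a factor with response contribution `alpha * F + beta * F^2` the
#' derivative vanishes at `-alpha / (2 beta)`; the point is a maximum when
#' `beta < 0`.
#'
#' @param model an `ep_rsm`.
#' @param factor name of a quadratic factor of the model.
#' @return list with `value` and `curvature` (`"maximum"` or `"minimum"`).
#' @export
stationary_point <- function(model, factor) {
  ep_assert(inherits(model, "ep_rsm"), "epferm_usage_error",
            "'model' must be an ep_rsm")
  q <- model$quadratic[[factor]]
  ep_assert(!is.null(q), "epferm_usage_error",
            sprintf("'%s' is not a quadratic factor of the model", factor))
  if (q[["beta"]] == 0) {
    ep_stop("epferm_no_stationary_point_error",
            sprintf("'%s' has zero curvature: no stationary point", factor))
  }
  list(value = -q[["alpha"]] / (2 * q[["beta"]]),
       curvature = if (q[["beta"]] < 0) "maximum" else "minimum")
}

#' Recommend the optimum factor settings
#'
#' Quadratic factors with negative curvature take their interior stationary
#' point, clamped into the tested range if outside it; a quadratic factor
#' with positive curvature is a boundary case (both endpoints are evaluated
#' and the better one kept, with a warning). Linear factors take the upper
#' end of their tested range when their coefficient is positive and the
#' lower end when negative. The predicted response is the fitted polynomial
#' evaluated at the recommendation.
#'
#' @param model an `ep_rsm`.
#' @param ranges either an `ep_design` (tested ranges and level grids are
#'   taken from its factors, and the sampling times bound the control
#'   variable) or a named list of `c(min, max)` per model factor.
#' @param levels optional named list of tested level grids; interior optima
#'   are additionally reported snapped to the nearest tested level in the
#'   practical medium recipe. Filled automatically from an `ep_design`.
#' @return an object of class `ep_optimum`: a list with `settings` (data
#'   frame of factor, value, provenance), `predicted` (ug/L at the
#'   recommendation), `optimum_time` (h, stationary point of the control
#'   variable) and `recipe_g_per_L` (medium components only, interior optima
#'   snapped to the nearest tested level, converted with [as_g_per_L()]).
#' @export
#' @examples
#' d <- load_design_fixture()
#' fit <- fit_response_surface(assemble_long_table(d))
#' recommend_optimum(fit, d)
recommend_optimum <- function(model, ranges, levels = NULL) {
  ep_assert(inherits(model, "ep_rsm"), "epferm_usage_error",
            "'model' must be an ep_rsm")
  if (inherits(ranges, "ep_design")) {
    design <- ranges
    levels <- lapply(design$factors, `[[`, "levels")
    names(levels) <- vapply(design$factors, `[[`, "", "name")
    ranges <- lapply(levels, range)
    if (!is.null(design$sampling_times)) {
      ranges[[model$control]] <- range(design$sampling_times)
    }
  }
  fac <- rsm_factors(model)
  miss <- setdiff(fac, names(ranges))
  ep_assert(length(miss) == 0L, "epferm_configuration_error",
            sprintf("no tested range for: %s", paste(miss, collapse = ", ")))

  value <- numeric(0)
  provenance <- character(0)
  for (f in names(model$quadratic)) {
    q <- model$quadratic[[f]]
    r <- ranges[[f]]
    if (q[["beta"]] < 0) {
      v <- -q[["alpha"]] / (2 * q[["beta"]])
      if (v < r[1]) {
        v <- r[1]; pr <- "clamped-lower"
      } else if (v > r[2]) {
        v <- r[2]; pr <- "clamped-upper"
      } else pr <- "interior-stationary"
    } else {
      warning(sprintf(
        "quadratic factor '%s' has non-negative curvature; taking the better endpoint",
        f))
      contrib <- q[["alpha"]] * r + q[["beta"]] * r^2
      v <- r[which.max(contrib)]
      pr <- c("clamped-lower", "clamped-upper")[which.max(contrib)]
    }
    value[f] <- v
    provenance[f] <- pr
  }
  for (f in names(model$linear)) {
    r <- ranges[[f]]
    up <- model$linear[[f]] > 0
    value[f] <- if (up) r[2] else r[1]
    provenance[f] <- if (up) "clamped-upper" else "clamped-lower"
  }

  predicted <- evaluate_rsm(model, value)
  medium <- setdiff(fac, model$control)
  recipe <- value[medium]
  if (!is.null(levels)) {
    for (f in intersect(medium, names(levels))) {
      if (provenance[f] == "interior-stationary") {
        grid <- levels[[f]]
        recipe[f] <- grid[which.min(abs(grid - recipe[f]))]
      }
    }
  }

  structure(
    list(
      settings = data.frame(factor = fac, value = unname(value[fac]),
                            provenance = unname(provenance[fac]),
                            row.names = NULL),
      predicted = predicted,
      optimum_time = value[[model$control]],
      recipe_g_per_L = as_g_per_L(recipe)
    ),
    class = "ep_optimum"
  )
}

#' @export
print.ep_optimum <- function(x, ...) {
  cat("<ep_optimum>\n")
  tab <- x$settings
  tab$value <- signif(tab$value, 5)
  print(tab, row.names = FALSE)
  cat(sprintf("optimum time: %.1f h; predicted response: %.2f ug/L\n",
              x$optimum_time, x$predicted))
  cat("medium recipe (g/L, interior optima snapped to the tested grid):\n")
  print(round(x$recipe_g_per_L, 3))
  invisible(x)
}

evaluate_rsm <- function(model, settings) {
  y <- model$intercept
  for (f in names(model$quadratic)) {
    q <- model$quadratic[[f]]
    y <- y + q[["alpha"]] * settings[[f]] + q[["beta"]] * settings[[f]]^2
  }
  for (f in names(model$linear)) {
    y <- y + model$linear[[f]] * settings[[f]]
  }
  y
}

#' Predict the response at given factor settings and times
#'
#' Deterministic evaluation of the fitted polynomial, vectorized over
#' sampling times. Predictions are not clipped at zero: a linear model can
#' extrapolate below zero and a warning flags it when it does.
#'
#' @param model an `ep_rsm`.
#' @param settings named vector or list of medium-factor values (g/100 mL),
#'   covering every model factor except the control variable.
#' @param times control-variable values (h) at which to predict.
#' @return numeric vector of predicted responses (ug/L), one per time.
#' @export
predict_yield <- function(model, settings, times) {
  ep_assert(inherits(model, "ep_rsm"), "epferm_usage_error",
            "'model' must be an ep_rsm")
  settings <- as.list(settings)
  need <- setdiff(rsm_factors(model), model$control)
  miss <- setdiff(need, names(settings))
  ep_assert(length(miss) == 0L, "epferm_configuration_error",
            sprintf("missing factor values: %s", paste(miss, collapse = ", ")))
  y <- vapply(times, function(t0) {
    settings[[model$control]] <- t0
    evaluate_rsm(model, settings)
  }, 1)
  if (any(y < 0)) {
    warning("predicted response is negative at some settings (not clipped)")
  }
  y
}
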