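#' Render a fit result as text and JSON
#'
#' Produces a human-readable coefficient table (values rounded to 3
#' decimals, the display convention of the source tables) and a lossless
#' JSON document (full double precision) from a fitted response-surface
#' model or an integrated-form kinetic fit.
#'
#' @param x an `ep_rsm`, `ep_kinfit` or `ep_kincomp`.
#' @param ... unused.
#' @return an object of class `ep_report`: list with `text` (character
#'   lines) and `json` (a JSON string).
#' @export
render_report <- function(x, ...) UseMethod("render_report")

fmt3 <- function(x) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = 3))
}

coef_lines <- function(tab) {
  header <- sprintf("%-16s %12s %10s %10s", "term", "coefficient", "t", "p")
  rows <- sprintf("%-16s %12s %10s %10s", tab$term, fmt3(tab$estimate),
                  fmt3(tab$t), fmt3(tab$p))
  c(header, rows)
}

new_report <- function(text, payload) {
  structure(
    list(text = text,
         json = jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                 na = "null", pretty = TRUE)),
    class = "ep_report"
  )
}

#' @export
render_report.ep_rsm <- function(x, ...) {
  ep_assert(!is.null(x$stats), "epferm_usage_error",
            "model carries no fit statistics to report")
  st <- x$stats
  text <- c(
    "Response-surface fit (quadratic in time and glycerol, linear otherwise)",
    coef_lines(st$coefficients),
    sprintf("Model: R2 = %s, F(%d, %d) = %s, p = %s", fmt3(st$r2),
            st$df[1], st$df[2], fmt3(st$f), fmt3(st$p_model))
  )
  payload <- list(
    type = "response_surface_fit",
    terms = st$coefficients$term,
    coefficient = st$coefficients$estimate,
    se = st$coefficients$se,
    t = st$coefficients$t,
    p = st$coefficients$p,
    r2 = st$r2, adj_r2 = st$adj_r2, f = st$f,
    df = st$df, p_model = st$p_model, n_obs = st$n_obs
  )
  new_report(text, payload)
}

#' @export
render_report.ep_kinfit <- function(x, ...) {
  text <- c(
    sprintf("Integrated-form kinetic fit: %s model (n = %d)", x$kind,
            x$n_obs),
    coef_lines(x$coefficients),
    sprintf("R2 = %s, adj R2 = %s, F(%d, %d) = %s, p = %s", fmt3(x$r2),
            fmt3(x$adj_r2), x$df[1], x$df[2], fmt3(x$f), fmt3(x$p)),
    sprintf("recovered: %s",
            paste(names(x$parameters)[is.finite(x$parameters)],
                  fmt3(x$parameters[is.finite(x$parameters)]),
                  sep = " = ", collapse = ", "))
  )
  payload <- list(
    type = "kinetic_fit", kind = x$kind,
    terms = x$coefficients$term,
    coefficient = x$coefficients$estimate,
    se = x$coefficients$se,
    t = x$coefficients$t,
    p = x$coefficients$p,
    r2 = x$r2, adj_r2 = x$adj_r2, f = x$f, df = x$df, p = x$p,
    condition_number = x$condition_number,
    C0_eff = x$C0_eff, n_obs = x$n_obs,
    parameters = as.list(x$parameters),
    implausible = x$implausible
  )
  new_report(text, payload)
}

#' @export
render_report.ep_kincomp <- function(x, ...) {
  parts <- lapply(x$fits, function(f) {
    if (inherits(f, "ep_kinfit_failure")) {
      list(text = sprintf("%s model: fit failed (%s)", f$kind, f$message),
           payload = list(kind = f$kind, failed = TRUE,
                          message = f$message))
    } else {
      r <- render_report(f)
      list(text = r$text,
           payload = jsonlite::fromJSON(r$json, simplifyVector = TRUE))
    }
  })
  text <- c(
    "Kinetic model comparison (ranked by adjusted R2)",
    utils::capture.output(print(x$ranking, row.names = FALSE)),
    "",
    unlist(lapply(parts, function(p) c(p$text, "")))
  )
  new_report(text, list(type = "kinetic_comparison",
                        ranking = x$ranking,
                        fits = lapply(parts, `[[`, "payload")))
}

#' @export
print.ep_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a rendered report to disk
#'
#' @param report an `ep_report` from [render_report()].
#' @param prefix output path prefix; `<prefix>.txt` and `<prefix>.json` are
#'   written.
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  ep_assert(inherits(report, "ep_report"), "epferm_usage_error",
            "'report' must come from render_report()")
  txt <- paste0(prefix, ".txt")
  jsn <- paste0(prefix, ".json")
  writeLines(report$text, txt)
  writeLines(report$json, jsn)
  invisible(c(txt, jsn))
}
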