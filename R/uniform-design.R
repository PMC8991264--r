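#' Define a design factor
#'
#' A factor for a U-type uniform design: an ordered set of tested levels for
#' one medium component (g/100 mL) or for the control variable (sampling
#' time, h).
#'
#' @param name factor name, e.g. `"glycerol"`.
#' @param levels strictly increasing vector of positive tested levels.
#' @param units unit string; `"g/100mL"` for medium components, `"h"` for
#'   sampling time.
#' @param role `"medium-component"` or `"control-variable"`.
#' @return an object of class `ep_factor`.
#' @export
#' @examples
#' design_factor("glycerol", seq(2, 6.5, by = 0.5))
design_factor <- function(name, levels,
                          units = "g/100mL",
                          role = c("medium-component", "control-variable")) {
  role <- match.arg(role)
  ep_assert(is.character(name) && length(name) == 1L,
            "epferm_usage_error", "'name' must be a single string")
  ep_assert(is.numeric(levels) && length(levels) >= 2L,
            "epferm_usage_error", "'levels' must be a numeric vector")
  ep_assert(all(levels > 0), "epferm_usage_error",
            sprintf("all levels of '%s' must be positive", name))
  ep_assert(all(diff(levels) > 0), "epferm_usage_error",
            sprintf("levels of '%s' must be strictly increasing", name))
  structure(
    list(name = name, units = units, levels = as.numeric(levels), role = role),
    class = "ep_factor"
  )
}

#' @export
print.ep_factor <- function(x, ...) {
  cat(sprintf("<ep_factor> %s (%s, %s): %s\n", x$name, x$units, x$role,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

# ---- centered L2 discrepancy -------------------------------------------

#' Centered L2 discrepancy of a point set
#'
#' Hickernell's centered L2 discrepancy of `n` points in the `s`-dimensional
#' unit cube, the uniformity criterion used to select good-lattice-point
#' columns. Smaller is more uniform.
#'
#' @param x numeric matrix, `n` rows of points with coordinates in (0, 1).
#' @return the discrepancy (its square root, i.e. CD2 itself).
#' @export
centered_l2_discrepancy <- function(x) {
  x <- as.matrix(x)
  ep_assert(all(is.finite(x)) && all(x > 0 & x < 1), "epferm_usage_error",
            "point coordinates must lie strictly inside (0, 1)")
  n <- nrow(x)
  s <- ncol(x)
  d <- abs(x - 0.5)
  term1 <- (13 / 12)^s
  term2 <- (2 / n) * sum(apply(1 + 0.5 * d - 0.5 * d^2, 1L, prod))
  # pairwise product over dimensions, vectorized one dimension at a time
  m <- matrix(1, n, n)
  for (j in seq_len(s)) {
    dj <- d[, j]
    m <- m * (1 + 0.5 * outer(dj, dj, `+`) -
                0.5 * abs(outer(x[, j], x[, j], `-`)))
  }
  term3 <- sum(m) / n^2
  sqrt(term1 - term2 + term3)
}

# good-lattice-point candidate columns: u[i, h] = (i * h) mod m, with 0
# mapped to m. When Euler's phi(n) provides too few coprime generators for
# the requested number of factors, the leave-one-out variant mod (n + 1) is
# used (rows i = 1..n of the (n + 1)-point lattice), which yields n
# candidate columns whenever n + 1 is prime.
glp_candidates <- function(n_runs, n_factors) {
  coprime <- function(m) Filter(function(h) h < m && gcd2(h, m) == 1L,
                                seq_len(m - 1L))
  hs <- coprime(n_runs)
  modulus <- n_runs
  if (length(hs) < n_factors) {
    modulus <- n_runs + 1L
    hs <- coprime(modulus)
  }
  ep_assert(length(hs) >= n_factors, "epferm_capacity_error",
            sprintf("cannot place %d factors on a %d-run good-lattice design",
                    n_factors, n_runs))
  list(modulus = modulus, generators = hs)
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

glp_column <- function(h, n_runs, modulus) {
  u <- (seq_len(n_runs) * h) %% modulus
  u[u == 0L] <- modulus
  u
}

#' Construct a U-type uniform design
#'
#' Builds a balanced U-design (each factor column a permutation of the level
#' index set) by the good-lattice-point method. Among admissible generator
#' subsets, the one minimizing the centered L2 discrepancy of the induced
#' point set is chosen; for small designs the search is exhaustive.
#'
#' @param n_runs number of runs; must equal the number of levels of every
#'   design factor.
#' @param factors list of [design_factor()] objects with `n_runs` levels each.
#' @param generators optional integer vector of lattice generators (one per
#'   factor); each must be coprime with the lattice modulus. When supplied,
#'   the discrepancy search is skipped.
#' @param max_exhaustive largest number of generator subsets that is searched
#'   exhaustively; beyond it a greedy forward selection is used.
#' @return an object of class `ep_design` with elements `factors`, `layout`
#'   (run-by-factor table of concrete levels), `index` (level indices),
#'   `generators`, `modulus` and `discrepancy`.
#' @export
#' @examples
#' f <- lapply(c("a", "b", "c"), design_factor, levels = 1:7)
#' d <- uniform_design(7, f)
#' d$discrepancy
uniform_design <- function(n_runs, factors, generators = NULL,
                           max_exhaustive = 1e5) {
  ep_assert(is.numeric(n_runs) && length(n_runs) == 1L && n_runs >= 2,
            "epferm_usage_error", "'n_runs' must be a single integer >= 2")
  n_runs <- as.integer(n_runs)
  ep_assert(is.list(factors) && length(factors) >= 1L &&
              all(vapply(factors, inherits, TRUE, "ep_factor")),
            "epferm_usage_error", "'factors' must be a list of ep_factor")
  s <- length(factors)
  ep_assert(s <= n_runs - 1L, "epferm_capacity_error",
            sprintf("at most %d factors fit a %d-run U-design",
                    n_runs - 1L, n_runs))
  n_lev <- vapply(factors, function(f) length(f$levels), 1L)
  ep_assert(all(n_lev == n_runs), "epferm_usage_error",
            "every factor must have exactly n_runs levels")

  cand <- glp_candidates(n_runs, s)
  modulus <- cand$modulus

  if (!is.null(generators)) {
    generators <- as.integer(generators)
    ep_assert(length(generators) == s, "epferm_usage_error",
              "'generators' must supply one generator per factor")
    bad <- generators[vapply(generators, gcd2, 1L, b = modulus) != 1L |
                        generators <= 0L | generators >= modulus]
    if (length(bad)) {
      ep_stop("epferm_invalid_generator_error",
              sprintf("generators not coprime with modulus %d: %s",
                      modulus, paste(bad, collapse = ", ")))
    }
    ep_assert(!anyDuplicated(generators), "epferm_invalid_generator_error",
              "duplicated generators")
    chosen <- generators
  } else {
    hs <- cand$generators
    cols <- vapply(hs, glp_column, integer(n_runs),
                   n_runs = n_runs, modulus = modulus)
    n_subsets <- choose(length(hs), s)
    if (n_subsets <= max_exhaustive) {
      subsets <- combn(length(hs), s)
      disc <- apply(subsets, 2L, function(idx) {
        centered_l2_discrepancy((cols[, idx, drop = FALSE] - 0.5) / n_runs)
      })
      chosen <- hs[subsets[, which.min(disc)]]
    } else {
      # greedy forward selection on the discrepancy
      picked <- integer(0)
      for (k in seq_len(s)) {
        rest <- setdiff(seq_along(hs), picked)
        disc <- vapply(rest, function(j) {
          centered_l2_discrepancy(
            (cols[, c(picked, j), drop = FALSE] - 0.5) / n_runs)
        }, 1)
        picked <- c(picked, rest[which.min(disc)])
      }
      chosen <- hs[picked]
    }
  }

  index <- vapply(chosen, glp_column, integer(n_runs),
                  n_runs = n_runs, modulus = modulus)
  colnames(index) <- vapply(factors, `[[`, "", "name")
  layout <- as.data.frame(
    mapply(function(f, idx) f$levels[idx], factors,
           split(index, col(index)), SIMPLIFY = FALSE),
    col.names = colnames(index)
  )
  layout <- cbind(run = seq_len(n_runs), layout)

  new_ep_design(
    factors = factors, layout = layout, index = index,
    generators = chosen, modulus = modulus,
    discrepancy = centered_l2_discrepancy((index - 0.5) / n_runs)
  )
}

new_ep_design <- function(factors, layout, index = NULL, generators = NULL,
                          modulus = NULL, discrepancy = NULL,
                          sampling_times = NULL, responses = NULL) {
  d <- structure(
    list(factors = factors, layout = layout, index = index,
         generators = generators, modulus = modulus,
         discrepancy = discrepancy, sampling_times = sampling_times,
         responses = responses),
    class = "ep_design"
  )
  validate_ep_design(d)
}

validate_ep_design <- function(d, error_class = "epferm_usage_error") {
  n <- nrow(d$layout)
  for (f in d$factors) {
    col <- d$layout[[f$name]]
    ep_assert(!is.null(col), error_class,
              sprintf("layout misses factor column '%s'", f$name))
    ok <- length(col) == length(f$levels) &&
      isTRUE(all.equal(sort(col), f$levels, tolerance = 1e-8))
    ep_assert(ok, error_class,
              sprintf("column '%s' is not a permutation of its levels (U-design balance violated)",
                      f$name))
  }
  if (!is.null(d$responses)) {
    ep_assert(is.matrix(d$responses) &&
                nrow(d$responses) == n &&
                ncol(d$responses) == length(d$sampling_times),
              error_class, "response block shape does not match the design")
  }
  d
}

#' @export
print.ep_design <- function(x, ...) {
  cat(sprintf("<ep_design> %d runs x %d factors", nrow(x$layout),
              length(x$factors)))
  if (!is.null(x$generators)) {
    cat(sprintf(" (good-lattice generators mod %d: %s; CD2 = %.5f)",
                x$modulus, paste(x$generators, collapse = ", "),
                x$discrepancy))
  }
  cat("\n")
  print(x$layout, row.names = FALSE)
  if (!is.null(x$responses)) {
    cat(sprintf("responses at %s h\n",
                paste(x$sampling_times, collapse = ", ")))
  }
  invisible(x)
}

#' Attach a response block to a design
#'
#' @param design an `ep_design`.
#' @param sampling_times vector of sampling times (h).
#' @param responses numeric matrix, runs x sampling times, of measured
#'   product concentrations (ug/L).
#' @return the design with responses attached.
#' @export
set_design_responses <- function(design, sampling_times, responses) {
  ep_assert(inherits(design, "ep_design"), "epferm_usage_error",
            "'design' must be an ep_design")
  responses <- as.matrix(responses)
  design$sampling_times <- as.numeric(sampling_times)
  design$responses <- responses
  validate_ep_design(design)
}

# ---- packaged design fixture -------------------------------------------

TABLE1_MD5 <- "83823276282963d2f6b6d0077e90775b"

ep_medium_factors <- function() {
  list(
    design_factor("glycerol",     seq(2, 6.5, by = 0.5)),
    design_factor("yeast_powder", seq(0.2, 0.65, by = 0.05)),
    design_factor("peptone",      seq(0.2, 0.65, by = 0.05)),
    design_factor("znso4",        seq(0.005, 0.05, by = 0.005)),
    design_factor("mgso4",        seq(0.06, 0.24, by = 0.02)),
    design_factor("kh2po4",       seq(0.06, 0.24, by = 0.02))
  )
}

#' Load the packaged 10-run uniform-design table
#'
#' Returns the packaged U10(10^6) design: six medium factors at ten levels
#' each (g/100 mL) and the measured ergosterol peroxide responses (ug/L) at
#' the four sampling times 28, 56, 84 and 112 h. The file checksum and the
#' U-design balance are validated on every load.
#'
#' @return an `ep_design` with a complete 10 x 4 response block.
#' @export
#' @examples
#' d <- load_design_fixture()
#' max(d$responses)
load_design_fixture <- function() {
  path <- system.file("extdata", "table1_uniform_design.csv",
                      package = "epferm", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE1_MD5)) {
    ep_stop("epferm_fixture_integrity_error",
            "packaged design table failed its checksum")
  }
  tab <- read.csv(path)
  times <- c(28, 56, 84, 112)
  resp <- as.matrix(tab[paste0("ep_", times, "h")])
  dimnames(resp) <- list(NULL, paste0(times, "h"))
  if (any(!is.finite(resp)) || any(resp <= 0)) {
    ep_stop("epferm_fixture_integrity_error",
            "packaged responses must all be finite and positive")
  }
  d <- tryCatch(
    new_ep_design(
      factors = ep_medium_factors(),
      layout = tab[c("run", "glycerol", "yeast_powder", "peptone",
                     "znso4", "mgso4", "kh2po4")],
      sampling_times = times, responses = resp
    ),
    epferm_error = function(e) {
      ep_stop("epferm_fixture_integrity_error", conditionMessage(e))
    }
  )
  d
}

# ---- design CSV interface ----------------------------------------------

#' Write a design (and any responses) to CSV
#'
#' Header `run,glycerol,yeast_powder,peptone,znso4,mgso4,kh2po4` in
#' g/100 mL, with optional response columns `ep_<time>h` in ug/L. UTF-8,
#' comma separated, `.` decimal.
#'
#' @param design an `ep_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  tab <- design$layout
  if (!is.null(design$responses)) {
    resp <- as.data.frame(design$responses)
    names(resp) <- paste0("ep_", design$sampling_times, "h")
    tab <- cbind(tab, resp)
  }
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design CSV written by [write_design_csv()]
#'
#' @param path file path.
#' @param factors list of [design_factor()] definitions the columns must
#'   match; defaults to the packaged six medium factors.
#' @return an `ep_design`.
#' @export
read_design_csv <- function(path, factors = ep_medium_factors()) {
  tab <- read_checked_csv(path)
  need <- c("run", vapply(factors, `[[`, "", "name"))
  miss <- setdiff(need, names(tab))
  ep_assert(length(miss) == 0L, "epferm_data_error",
            sprintf("design CSV misses columns: %s (found: %s)",
                    paste(miss, collapse = ", "),
                    paste(names(tab), collapse = ", ")))
  resp_cols <- grep("^ep_[0-9]+h$", names(tab), value = TRUE)
  responses <- NULL
  times <- NULL
  if (length(resp_cols)) {
    times <- as.numeric(sub("^ep_([0-9]+)h$", "\\1", resp_cols))
    responses <- as.matrix(tab[resp_cols])
    dimnames(responses) <- list(NULL, paste0(times, "h"))
  }
  new_ep_design(factors = factors, layout = tab[need],
                sampling_times = times, responses = responses)
}
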