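#' Printed per-function complexity measures
#'
#' The packaged table of published complexity values for the 15
#' non-trivial colloid functions (LZ, LZ/n, H, S, D, E), the canonical
#' input for the cross-measure correlation and regression statistics.
#' Two typographically ambiguous rows are stored under the reading
#' consistent with the identity E = H/D and with the published
#' regression lines (f20: D = 0.32, E = 3.4; f37: D = 0.1, E = 12.0).
#' The `arity` column is the comparison-group arity used for the LZ/n
#' normalisation (one four-variable expression, f11, is grouped with the
#' two-argument functions).
#'
#' @return A tibble with columns `id`, `arity`, `LZ`, `LZ_per_n`, `H`,
#'   `S`, `D`, `E`.
#' @export
printed_measures <- function() {
  path <- system.file("extdata", "printed_measures.csv",
                      package = "colloidca", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Group measured functions into a complexity hierarchy
#'
#' Sorts functions by a measure (descending) and merges adjacent values
#' into one level when they differ by less than `tie_frac` of the
#' measure's range over the input; adjacent levels whose boundary gap is
#' at least `strong_frac` of the range are separated by `">>"` (a large
#' jump), others by `">"`. The thresholds are explicit because tie
#' grouping is otherwise ill-defined; both are configurable. The
#' partition is invariant under any positive affine transformation of
#' the measure.
#'
#' @param records A tibble with an `id` column and the measure column.
#' @param measure Column name to rank by (e.g. `"H"`, `"lz_deflate"`).
#' @param tie_frac Fraction of range below which adjacent values merge.
#' @param strong_frac Fraction of range at or above which a level
#'   boundary is marked `">>"`.
#' @return A `ranked_partition`: list with `measure`, `levels` (list of
#'   id vectors, best first), `values` (list of their measure values)
#'   and `seps` (`">"`/`">>"` between consecutive levels).
#' @examples
#' rank_hierarchy(printed_measures()[1:7, ], "H")
#' @export
rank_hierarchy <- function(records, measure, tie_frac = 0.1,
                           strong_frac = 0.3) {
  stopifnot(measure %in% names(records), nrow(records) >= 2L)
  vals <- records[[measure]]
  ids <- records$id
  o <- order(vals, decreasing = TRUE)
  vals <- vals[o]; ids <- ids[o]
  rng <- max(vals) - min(vals)
  if (rng == 0) {
    part <- list(measure = measure, levels = list(ids),
                 values = list(vals), seps = character(0))
    return(structure(part, class = "ranked_partition"))
  }
  gaps <- -diff(vals)                       # >= 0
  breaks <- which(gaps >= tie_frac * rng)   # level boundary after position i
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(vals))
  levels <- purrr::map2(starts, ends, function(a, b) ids[a:b])
  values <- purrr::map2(starts, ends, function(a, b) vals[a:b])
  seps <- vapply(seq_along(breaks), function(j) {
    gap <- vals[breaks[j]] - vals[breaks[j] + 1L]
    if (gap >= strong_frac * rng) ">>" else ">"
  }, character(1))
  structure(list(measure = measure, levels = levels, values = values,
                 seps = seps),
            class = "ranked_partition")
}

#' @export
format.ranked_partition <- function(x, ...) {
  lev <- vapply(x$levels, function(ids) {
    if (length(ids) > 1L) paste0("{", paste(ids, collapse = ", "), "}")
    else ids
  }, character(1))
  out <- lev[1L]
  for (j in seq_along(x$seps))
    out <- paste(out, x$seps[j], lev[j + 1L])
  paste0(x$measure, ": ", out)
}

#' @export
print.ranked_partition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Pearson correlation with a zero-variance guard
#'
#' @param xs,ys Numeric vectors of equal length (at least 3).
#' @return The product-moment correlation coefficient.
#' @export
pearson_r <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(xs, ys)
}

#' Ordinary least-squares fit of one measure on another
#'
#' Fits `data[[y]] ~ data[[x]]` by OLS and returns a `ca_fit` carrying
#' the slope, intercept, Pearson r, R-squared (which equals r^2 for a
#' simple linear regression) and the number of points. [generics::tidy()]
#' and [generics::glance()] methods give the broom-style views.
#'
#' @param data A data frame of measure records.
#' @param y,x Column names of response and predictor.
#' @return A `ca_fit` object.
#' @examples
#' linear_fit(printed_measures(), "S", "H")
#' @export
linear_fit <- function(data, y, x) {
  xs <- data[[x]]; ys <- data[[y]]
  r <- pearson_r(xs, ys)
  fit <- stats::lm(ys ~ xs)
  structure(list(y = y, x = x,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r_squared = r^2, n = length(xs),
                 lm = fit, data = tibble::tibble(x = xs, y = ys)),
            class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, ...) {
  cat(sprintf("<ca_fit> %s = %.6g + %.6g * %s   (r = %.4f, R2 = %.4f, n = %d)\n",
              x$y, x$intercept, x$slope, x$x, x$r, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.ca_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$x),
                 estimate = c(x$intercept, x$slope))
}

#' @importFrom generics glance
#' @export
glance.ca_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r = x$r, r.squared = x$r_squared, n = x$n)
}

#' Cross-measure regression summary
#'
#' Regresses expressiveness E, Simpson diversity S and space filling D
#' on the Shannon entropy H across a table of per-function measures -
#' the package's standing cross-measure consistency check. With the
#' packaged printed-values table this reproduces the published
#' correlation structure: S tracks H strongly, E moderately, and D shows
#' only a very weak negative correlation.
#'
#' @param records A data frame with columns `H`, `E`, `S`, `D` (e.g.
#'   [printed_measures()] or [measure_catalog()] output).
#' @return A tibble with one row per response: `response`, `slope`,
#'   `intercept`, `r`, `r_squared`, `n`.
#' @export
cross_measure_stats <- function(records) {
  purrr::map_dfr(c("E", "S", "D"), function(resp) {
    f <- linear_fit(records, resp, "H")
    tibble::tibble(response = resp, slope = f$slope,
                   intercept = f$intercept, r = f$r,
                   r_squared = f$r_squared, n = f$n)
  })
}

#' Assign a Wolfram behaviour class
#'
#' Operationalises the qualitative taxonomy on the tail of a completed
#' run, ignoring transients: evidence is gathered on the last
#' `max(2 * max_period, 50)` rows. Class I means the automaton has
#' reached a homogeneous fixed point (final row all one state, period 1);
#' Class II covers frozen heterogeneous states and short cycles (detected
#' period at most `max_period`); everything else is Class III
#' (quasi-random). Class IV (interacting gliders) is never auto-assigned:
#' none of the catalogued functions shows it, and glider detection is out
#' of scope.
#'
#' @param diagram A completed `ca_diagram`.
#' @param max_period Largest period accepted as Class II evidence.
#' @return A `wolfram_class`: list with `label` (`"I"`, `"II"` or
#'   `"III"`) and `evidence` (detected period, final-row homogeneity,
#'   final state).
#' @examples
#' d <- ca_evolve("f2", init_random(100, 0.5, seed = 1), steps = 100)
#' classify_wolfram(d)$label   # "I": OR saturates to all ones
#' @export
classify_wolfram <- function(diagram, max_period = 16L) {
  L <- unclass(diagram)
  window <- max(2L * max_period, 50L)
  stopifnot(nrow(L) >= window)
  tail_rows <- L[(nrow(L) - window + 1L):nrow(L), , drop = FALSE]
  period <- detect_period(tail_rows, max_period)
  final <- L[nrow(L), ]
  homogeneous <- length(unique(final)) == 1L
  label <- if (homogeneous && !is.na(period) && period == 1L) "I"
  else if (!is.na(period)) "II"
  else "III"
  structure(list(label = label,
                 evidence = list(period = period,
                                 final_homogeneous = homogeneous,
                                 final_state = if (homogeneous) final[1L] else NA_integer_)),
            class = "wolfram_class")
}

#' @export
print.wolfram_class <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("<wolfram_class> Class %s (period %s, final row %s)\n",
              x$label,
              if (is.na(ev$period)) "none <= max" else ev$period,
              if (ev$final_homogeneous) paste0("all-", ev$final_state)
              else "heterogeneous"))
  invisible(x)
}
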