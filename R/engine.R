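#' Neighbourhood layout for 2-, 4- and 8-input rules
#'
#' Relative cell offsets feeding the rule's variables, in variable order
#' A, B, ...: arity 2 reads (-1, +1), arity 4 reads (-2, -1, +1, +2) and
#' arity 8 reads (-4 ... -1, +1 ... +4). The centre cell is never an
#' input, the offsets are symmetric about 0 and strictly increasing.
#'
#' @param arity 2, 4 or 8.
#' @return Integer vector of offsets, one per variable.
#' @export
neighbourhood_offsets <- function(arity) {
  switch(as.character(arity),
         "2" = c(-1L, 1L),
         "4" = c(-2L, -1L, 1L, 2L),
         "8" = c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L),
         stop("no neighbourhood is defined for arity ", arity, call. = FALSE))
}

shift_row <- function(config, offset, boundary) {
  n <- length(config)
  idx <- seq_len(n) + offset
  if (boundary == "periodic") {
    config[((idx - 1L) %% n) + 1L]
  } else {                      # fixed-zero (absorbing): outside cells are 0
    out <- integer(n)
    ok <- idx >= 1L & idx <= n
    out[ok] <- config[idx[ok]]
    out
  }
}

#' Advance a configuration by one synchronous step
#'
#' Every cell is replaced by the rule-table lookup at its neighbour
#' states. With the `"fixed"` (absorbing) boundary, neighbours beyond the
#' array are read as 0; with `"periodic"`, indices wrap.
#'
#' @param config Integer 0/1 vector, the current row of cell states.
#' @param rule A `rule_table` from [truth_table()] or [get_rule()].
#' @param boundary `"fixed"` (default) or `"periodic"`.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' ca_step(c(0, 0, 1, 0, 0), get_rule("f7"))  # 0 1 0 1 0
#' @export
ca_step <- function(config, rule, boundary = c("fixed", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(rule, "rule_table"))
  offsets <- neighbourhood_offsets(rule$arity)
  config <- as.integer(config)
  if (length(config) < 2L * max(offsets) + 1L)
    stop("configuration shorter than the neighbourhood span", call. = FALSE)
  idx <- integer(length(config))
  for (off in offsets)          # A first, so earlier offsets are high bits
    idx <- idx * 2L + shift_row(config, off, boundary)
  rule$outputs[idx + 1L]
}

#' Evolve a 1D cellular automaton
#'
#' Runs `steps` synchronous updates from `initial` and returns the full
#' space-time diagram: a binary matrix with `steps + 1` rows (row 1 is
#' the initial configuration, time increases downwards) and one column
#' per cell. The default study scale is 500 cells by 500 steps.
#'
#' @param rule A `rule_table`, or a catalogue id string.
#' @param initial Integer 0/1 vector of initial cell states.
#' @param steps Number of updates (>= 0).
#' @param boundary `"fixed"` or `"periodic"`.
#' @param rule_id,init,seed Optional provenance strings recorded in the
#'   diagram's metadata.
#' @return A `ca_diagram`: an integer matrix of class `ca_diagram` with
#'   attributes `rule_id`, `arity`, `boundary`, `init` and `seed`.
#' @examples
#' d <- ca_evolve("f7", init_single_seed(101), steps = 50)
#' dim(d)  # 51 x 101
#' @export
ca_evolve <- function(rule, initial, steps = 500L,
                      boundary = c("fixed", "periodic"),
                      rule_id = NULL, init = NULL, seed = NULL) {
  boundary <- match.arg(boundary)
  if (is.character(rule)) {
    if (is.null(rule_id)) rule_id <- rule
    rule <- get_rule(rule)
  }
  stopifnot(inherits(rule, "rule_table"), steps >= 0L)
  initial <- as.integer(initial)
  stopifnot(all(initial %in% c(0L, 1L)))
  L <- matrix(0L, nrow = steps + 1L, ncol = length(initial))
  L[1L, ] <- initial
  row <- initial
  for (t in seq_len(steps)) {
    row <- ca_step(row, rule, boundary)
    L[t + 1L, ] <- row
  }
  new_ca_diagram(L, rule_id = rule_id, arity = rule$arity,
                 boundary = boundary, init = init, seed = seed)
}

new_ca_diagram <- function(L, rule_id = NULL, arity = NULL,
                           boundary = NULL, init = NULL, seed = NULL) {
  stopifnot(is.matrix(L))
  storage.mode(L) <- "integer"
  structure(L, class = c("ca_diagram", "matrix", "array"),
            rule_id = rule_id, arity = arity, boundary = boundary,
            init = init, seed = seed)
}

#' @export
print.ca_diagram <- function(x, ...) {
  cat(sprintf("<ca_diagram> %d time rows x %d cells", nrow(x), ncol(x)))
  if (!is.null(attr(x, "rule_id"))) cat("  rule:", attr(x, "rule_id"))
  if (!is.null(attr(x, "boundary"))) cat("  boundary:", attr(x, "boundary"))
  cat(sprintf("\n  density of 1s: %.4f\n", mean(x)))
  invisible(x)
}

#' Initial configurations
#'
#' `init_single_seed()` places one '1' at the centre cell `ceiling(n/2)`;
#' `init_two_seeds()` places '1's at centre +/- `offset` (the two-seed
#' fractal-collision experiment uses offset 200 on a 500-cell array);
#' `init_random()` draws i.i.d. Bernoulli(`p`) states from `seed`,
#' reproducibly.
#'
#' @param n Number of cells (>= 1).
#' @param offset Distance of each seed from the centre; must keep both
#'   seeds on the array.
#' @param p Probability a cell starts in state 1.
#' @param seed Integer seed for the random draw.
#' @return Integer 0/1 vector of length `n`.
#' @examples
#' init_single_seed(5)        # 0 0 1 0 0
#' which(init_two_seeds(500, 200) == 1)  # 50 450
#' @export
init_single_seed <- function(n) {
  stopifnot(n >= 1L)
  row <- integer(n)
  row[ceiling(n / 2)] <- 1L
  row
}

#' @rdname init_single_seed
#' @export
init_two_seeds <- function(n, offset = 200L) {
  stopifnot(n >= 1L)
  centre <- ceiling(n / 2)
  lo <- centre - offset
  hi <- centre + offset
  if (offset < 1L || lo < 1L || hi > n)
    stop("offset out of range: seeds at ", lo, " and ", hi,
         " must lie in 1..", n, call. = FALSE)
  row <- integer(n)
  row[c(lo, hi)] <- 1L
  row
}

#' @rdname init_single_seed
#' @export
init_random <- function(n, p = 0.5, seed = NULL) {
  stopifnot(n >= 1L, p >= 0, p <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  as.integer(stats::runif(n) < p)
}

#' Detect a temporal period at the end of a run
#'
#' Finds the smallest period `p <= max_period` such that the final rows
#' repeat with lag `p` over a verification window of `max_period` rows:
#' `row[T - j] == row[T - j - p]` for `j = 0 .. max_period - 1`. A frozen
#' diagram has period 1. Used as the evidence for Class II behaviour.
#'
#' @param diagram A `ca_diagram` (or 0/1 matrix) with at least
#'   `2 * max_period` rows.
#' @param max_period Largest period searched (default 16).
#' @return The period as an integer, or `NA` if none is found.
#' @export
detect_period <- function(diagram, max_period = 16L) {
  L <- unclass(diagram)
  T1 <- nrow(L)
  if (T1 < 2L * max_period)
    stop("diagram needs at least ", 2L * max_period, " rows", call. = FALSE)
  for (p in seq_len(max_period)) {
    ok <- TRUE
    for (j in 0:(max_period - 1L)) {
      if (!identical(L[T1 - j, ], L[T1 - j - p, ])) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  NA_integer_
}
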