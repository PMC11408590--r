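#' Census of 3x3 space-time neighbourhood configurations
#'
#' Scans every position of the space-time matrix whose full 3x3 Moore
#' neighbourhood (centre included) lies inside the matrix and counts how
#' often each of the 512 possible binary configurations occurs. A
#' position is non-quiescent when any of the nine cells is in state 1;
#' eta is the number of non-quiescent positions, so the counts of all
#' non-all-zero configurations sum exactly to eta. The all-zero
#' configuration's count is kept for reference but excluded from the
#' entropy and diversity sums, which is the only reading under which
#' `nu(w)/eta` is a probability distribution.
#'
#' Configuration codes run 0..511: the nine window cells in row-major
#' order (top-left first) form the binary digits of the code, top-left
#' most significant.
#'
#' @param diagram A `ca_diagram` or 0/1 matrix, at least 3x3.
#' @return A `block_histogram`: list with `counts` (integer vector of
#'   length 512, index = code + 1), `eta`, `nu_zero` (count of the
#'   all-zero configuration) and `n_windows`.
#' @export
block_census <- function(diagram) {
  L <- unclass(diagram)
  stopifnot(is.matrix(L))
  if (nrow(L) < 3L || ncol(L) < 3L)
    stop("diagram must be at least 3x3", call. = FALSE)
  nr <- nrow(L) - 2L
  nc <- ncol(L) - 2L
  code <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    code <- code * 2L + L[(2L + dr):(nrow(L) - 1L + dr),
                          (2L + dc):(ncol(L) - 1L + dc)]
  }
  counts <- tabulate(code + 1L, nbins = 512L)
  structure(list(counts = counts,
                 eta = sum(counts[-1L]),
                 nu_zero = counts[1L],
                 n_windows = nr * nc),
            class = "block_histogram")
}

#' @export
print.block_histogram <- function(x, ...) {
  cat("<block_histogram>", x$n_windows, "windows, eta =", x$eta, ",",
      sum(x$counts > 0L) - (x$nu_zero > 0L), "distinct non-zero configurations\n")
  invisible(x)
}

#' Shannon entropy of the block census
#'
#' `H = -sum_w nu(w)/eta * log(nu(w)/eta)` over the non-all-zero
#' configurations with positive count; natural logarithm by default. By
#' convention H = 0 for an all-quiescent diagram (eta = 0).
#'
#' @param hist A [block_census()] result.
#' @param base Logarithm base; `exp(1)` (nats) is the study convention.
#' @return Non-negative entropy value.
#' @export
shannon_entropy <- function(hist, base = exp(1)) {
  stopifnot(inherits(hist, "block_histogram"))
  if (hist$eta == 0L) return(0)
  p <- hist$counts[-1L]
  p <- p[p > 0L] / hist$eta
  -sum(p * log(p, base = base))
}

#' Simpson diversity of the block census
#'
#' `S = sum_w (nu(w)/eta)^2` over non-all-zero configurations: the
#' probability two random non-quiescent positions show the same
#' configuration. S = 1 means a single configuration dominates; the
#' minimum 1/m is reached when m configurations are equally frequent.
#' By convention S = 0 when eta = 0.
#'
#' @param hist A [block_census()] result.
#' @return Value in [0, 1].
#' @export
simpson_diversity <- function(hist) {
  stopifnot(inherits(hist, "block_histogram"))
  if (hist$eta == 0L) return(0)
  p <- hist$counts[-1L] / hist$eta
  sum(p^2)
}

#' Space filling
#'
#' Fraction of cells of the full space-time matrix in state 1.
#'
#' @param diagram A `ca_diagram` or 0/1 matrix.
#' @return Value in [0, 1].
#' @export
space_filling <- function(diagram) {
  mean(unclass(diagram))
}

#' Expressiveness
#'
#' The 'economy of diversity': Shannon entropy divided by space filling,
#' `E = H / D`. Returns 0 (with a warning) when D = 0, where the ratio is
#' undefined.
#'
#' @param H Shannon entropy from [shannon_entropy()].
#' @param D Space filling from [space_filling()].
#' @return Non-negative value.
#' @export
expressiveness <- function(H, D) {
  stopifnot(H >= 0, D >= 0)
  if (D == 0) {
    if (H > 0) warning("expressiveness undefined for D = 0; returning 0")
    return(0)
  }
  H / D
}

# pack a 0/1 vector into bytes, most significant bit first (PBM/PNG order)
pack_bits_msb <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  if (pad) bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}

#' Lempel-Ziv compressibility of a space-time diagram
#'
#' Estimates pattern complexity as the byte size of the diagram under a
#' deflate-family (LZ77-derivative) codec. Two codecs are provided:
#' `"raw-deflate"` compresses the row-major bit-packed matrix (each row
#' padded to a whole byte) with a zlib deflate stream and is the stable
#' choice for cross-platform comparisons and hierarchies; `"png-fixed"`
#' is the byte size of the diagram written as a 1-bit grayscale PNG by
#' the package's pinned encoder (fixed filter 0, no ancillary chunks), so
#' the saved artefact's size equals the reported value.
#'
#' @param diagram A `ca_diagram` or 0/1 matrix.
#' @param codec `"raw-deflate"` (default) or `"png-fixed"`.
#' @return Compressed size in bytes.
#' @export
lz_complexity <- function(diagram, codec = c("raw-deflate", "png-fixed")) {
  codec <- match.arg(codec)
  L <- unclass(diagram)
  stopifnot(is.matrix(L), length(L) > 0L)
  if (codec == "png-fixed") return(length(encode_png_1bit(L)))
  bytes <- unlist(lapply(seq_len(nrow(L)), function(r) pack_bits_msb(L[r, ])))
  length(memCompress(bytes, type = "gzip"))
}

#' Measure one rule's space-time complexity
#'
#' Runs a full simulation for one rule and computes the complete measure
#' vector: both LZ codecs, LZ normalised by the input-string size n (the
#' rule arity), block-census Shannon entropy H, Simpson diversity S,
#' space filling D and expressiveness E = H/D. The default protocol is
#' the study scale - 500 cells, 500 steps, absorbing boundary - with a
#' random Bernoulli(0.5) initial row drawn from `seed` (the measurement
#' protocol is declared here because the original study does not state
#' its initial conditions).
#'
#' @param rule Catalogue id (e.g. `"f7"`) or a `rule_table`.
#' @param cells,steps Lattice width and number of updates.
#' @param boundary `"fixed"` or `"periodic"`.
#' @param init `"random"`, `"single"` or `"two"`.
#' @param p Initial density for `init = "random"`.
#' @param offset Seed offset for `init = "two"`.
#' @param seed Seed for the random initial row.
#' @param lz_norm_arity Arity used for the LZ/n normalisation; defaults
#'   to the rule's own arity (the published comparison groups one
#'   four-variable expression with the two-input family, so the grouping
#'   arity can be overridden).
#' @return A one-row tibble: `id`, `arity`, `lz_deflate`, `lz_png`,
#'   `lz_per_n`, `H`, `S`, `D`, `E`, plus the protocol provenance
#'   (`cells`, `steps`, `boundary`, `init`, `p`, `seed`).
#' @examples
#' measure_rule("f7", cells = 100, steps = 100, seed = 1)
#' @export
measure_rule <- function(rule, cells = 500L, steps = 500L,
                         boundary = c("fixed", "periodic"),
                         init = c("random", "single", "two"),
                         p = 0.5, offset = 200L, seed = 1L,
                         lz_norm_arity = NULL) {
  boundary <- match.arg(boundary)
  init <- match.arg(init)
  id <- if (is.character(rule)) rule else attr(rule, "rule_id") %||% NA_character_
  tab <- if (is.character(rule)) get_rule(rule) else rule
  stopifnot(inherits(tab, "rule_table"))
  row0 <- switch(init,
                 random = init_random(cells, p = p, seed = seed),
                 single = init_single_seed(cells),
                 two = init_two_seeds(cells, offset = offset))
  d <- ca_evolve(tab, row0, steps = steps, boundary = boundary,
                 rule_id = id, init = init, seed = seed)
  hist <- block_census(d)
  H <- shannon_entropy(hist)
  S <- simpson_diversity(hist)
  D <- space_filling(d)
  E <- expressiveness(H, D)
  n <- lz_norm_arity %||% tab$arity
  lzd <- lz_complexity(d, "raw-deflate")
  tibble::tibble(
    id = id, arity = tab$arity,
    lz_deflate = lzd,
    lz_png = lz_complexity(d, "png-fixed"),
    lz_per_n = lzd / n,
    H = H, S = S, D = D, E = E,
    cells = cells, steps = steps, boundary = boundary,
    init = init, p = if (init == "random") p else NA_real_,
    seed = if (init == "random") as.integer(seed) else NA_integer_
  )
}

#' Measure every catalogued function under one protocol
#'
#' Applies [measure_rule()] to each distinct catalogue id with identical
#' simulation parameters (in particular the same seed, so rules of equal
#' arity see the same initial row), returning the full measure table -
#' the package's analogue of the published per-function complexity table.
#'
#' @param ids Character vector of catalogue ids; default all distinct ids.
#' @param ... Passed to [measure_rule()] (protocol parameters).
#' @return A tibble with one row per id.
#' @export
measure_catalog <- function(ids = NULL, ...) {
  if (is.null(ids)) ids <- unique(colloid_catalog()$id)
  purrr::map_dfr(ids, measure_rule, ...)
}
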