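# Independent oracles used across the suite. None of these share code
# with the package implementation they check.

# Brute-force SOP evaluator: substitutes bits textually into the ASCII
# expression and lets R's own logical operators evaluate it.
oracle_eval_sop <- function(text, assignment) {
  expr <- gsub("\\s+", "", text)
  for (v in names(assignment))
    expr <- gsub(v, as.character(as.integer(assignment[[v]])), expr, fixed = TRUE)
  expr <- gsub("*", "&", expr, fixed = TRUE)
  expr <- gsub("+", "|", expr, fixed = TRUE)
  as.integer(as.logical(eval(parse(text = expr))))
}

# Full truth table by brute force, A as the most significant bit.
oracle_truth_table <- function(text, arity) {
  vars <- LETTERS[seq_len(arity)]
  vapply(0:(2^arity - 1L), function(i) {
    bits <- as.integer(intToBits(i))[arity:1]   # A first
    oracle_eval_sop(text, stats::setNames(as.list(bits), vars))
  }, integer(1))
}

# Pascal's triangle mod 2 grown by the additive recurrence: the expected
# single-seed space-time diagram of the two-input XOR rule before any
# boundary contact.
oracle_sierpinski <- function(steps, cells, centre = ceiling(cells / 2)) {
  P <- matrix(0L, steps + 1L, cells)
  P[1L, centre] <- 1L
  for (t in 2:(steps + 1L)) for (c in seq_len(cells)) {
    lft <- if (c > 1L) P[t - 1L, c - 1L] else 0L
    rgt <- if (c < cells) P[t - 1L, c + 1L] else 0L
    P[t, c] <- (lft + rgt) %% 2L
  }
  P
}

# Position-by-position census of 3x3 windows, keyed by the window's
# bit string; returns eta and the sorted positive counts of non-zero
# configurations for multiset comparison.
oracle_census <- function(L) {
  keys <- character(0)
  for (r in 2:(nrow(L) - 1L)) for (c in 2:(ncol(L) - 1L)) {
    w <- L[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
    keys <- c(keys, paste(as.vector(t(w)), collapse = ""))
  }
  zero <- keys == "000000000"
  counts <- table(keys[!zero])
  list(eta = sum(!zero), nu_zero = sum(zero),
       counts = sort(as.integer(counts)))
}

# Per-cell single step via explicit neighbour reads and base-2 index
# assembly (no vectorised shifting).
oracle_step <- function(config, outputs, arity, boundary) {
  offsets <- switch(as.character(arity),
                    "2" = c(-1L, 1L), "4" = c(-2L, -1L, 1L, 2L),
                    "8" = c(-4L:-1L, 1L:4L))
  n <- length(config)
  out <- integer(n)
  for (i in seq_len(n)) {
    bits <- vapply(offsets, function(off) {
      j <- i + off
      if (boundary == "periodic") config[((j - 1L) %% n) + 1L]
      else if (j >= 1L && j <= n) config[j] else 0L
    }, integer(1))
    out[i] <- outputs[strtoi(paste(bits, collapse = ""), base = 2L) + 1L]
  }
  out
}

# Random SOP expression text, contradiction-free by construction.
random_sop_text <- function() {
  arity <- sample(c(2L, 4L, 8L), 1L)
  n_terms <- sample(1:5, 1L)
  terms <- vapply(seq_len(n_terms), function(i) {
    vars <- sample(LETTERS[seq_len(arity)], sample(seq_len(arity), 1L))
    lits <- paste0(ifelse(stats::runif(length(vars)) < 0.5, "!", ""), vars)
    if (length(lits) > 1L) paste0("(", paste(lits, collapse = " * "), ")")
    else lits
  }, character(1))
  list(text = paste(terms, collapse = " + "), arity = arity)
}
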