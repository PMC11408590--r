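#' The catalogue of colloid-derived Boolean functions
#'
#' Loads the packaged catalogue of 46 sum-of-products functions (plus the
#' degenerate constant-false entry `const0`) mined from ZnO nanoparticle
#' colloids, proteinoid colloids and their mixture. Each row is one
#' occurrence of a function in a source table; the same function can
#' recur across substrates (e.g. the two-input OR and AND), so ids repeat
#' across tables but an id always denotes the same Boolean function. The
#' discovery frequency `phi` is experimental metadata and is never used
#' in any computation.
#'
#' Every entry is parsed through [parse_sop()] on load; an unparseable
#' entry aborts with its id. The transcription of the 41-term eight-input
#' function `f21` is audited against its recorded term count.
#'
#' @param path Path to a catalogue file in the tab-separated rule text
#'   format (columns `id`, `arity`, `expression`, `phi`, and optionally
#'   `substrate`, `table`, `uncertain`). Defaults to the packaged file.
#' @param dedup If `TRUE`, keep one row per function id (the first
#'   occurrence) instead of one row per source-table occurrence.
#'
#' @return A tibble with columns `id`, `arity`, `expression`, `phi`,
#'   `substrate`, `table`, `uncertain`, and a list-column `expr` of parsed
#'   `sop_expr` objects.
#' @examples
#' cat46 <- colloid_catalog()
#' dplyr::filter(cat46, id == "f7")
#' @export
colloid_catalog <- function(path = NULL, dedup = FALSE) {
  if (is.null(path))
    path <- system.file("extdata", "colloid_functions.tsv",
                        package = "colloidca", mustWork = TRUE)
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("id", "arity", "expression")
  if (!all(need %in% names(raw)))
    stop("catalogue file must have columns id, arity, expression", call. = FALSE)
  for (opt in c("phi", "substrate", "table", "uncertain"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  out <- tibble::tibble(
    id = as.character(raw$id),
    arity = as.integer(raw$arity),
    expression = as.character(raw$expression),
    phi = suppressWarnings(as.integer(raw$phi)),
    substrate = as.character(raw$substrate),
    table = as.character(raw$table),
    uncertain = !is.na(raw$uncertain) & raw$uncertain %in% c(1, "1", TRUE)
  )
  out$expr <- purrr::map2(out$expression, seq_len(nrow(out)), function(e, i) {
    tryCatch(parse_sop(e, arity = out$arity[i]),
             error = function(err) stop(sprintf(
               "catalogue entry %s does not parse: %s", out$id[i],
               conditionMessage(err)), call. = FALSE))
  })
  # an id must always denote one Boolean function
  canon <- vapply(out$expr, function(e) format(canonical_form(e)), character(1))
  bad <- tapply(canon, out$id, function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop("catalogue id maps to more than one function: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  stopifnot(all(is.na(out$phi) | out$phi >= 0L))
  # transcription audit for the long eight-input entry
  if ("f21" %in% out$id) {
    n21 <- length(out$expr[[match("f21", out$id)]]$terms)
    if (n21 != 41L)
      stop("catalogue audit failed: f21 has ", n21, " terms, expected 41",
           call. = FALSE)
  }
  if (dedup) out <- out[!duplicated(out$id), ]
  out
}

# compiled-rule cache, keyed by id
the_rule_cache <- new.env(parent = emptyenv())

#' Compile a catalogued function to its rule table
#'
#' Looks the id up in the packaged catalogue, compiles its expression with
#' [truth_table()] and caches the result, so repeated lookups are cheap
#' and deterministic.
#'
#' @param id Function id, e.g. `"f7"`, or `"const0"`.
#' @param catalog Optional catalogue tibble from [colloid_catalog()];
#'   defaults to the packaged one (results cached only in that case).
#' @return A `rule_table`.
#' @examples
#' get_rule("f7")$outputs   # 0 1 1 0
#' @export
get_rule <- function(id, catalog = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  packaged <- is.null(catalog)
  if (packaged && !is.null(the_rule_cache[[id]])) return(the_rule_cache[[id]])
  if (is.null(catalog)) catalog <- colloid_catalog()
  hit <- match(id, catalog$id)
  if (is.na(hit))
    stop("unknown rule id: ", id, call. = FALSE)
  tab <- truth_table(catalog$expr[[hit]])
  if (packaged) the_rule_cache[[id]] <- tab
  tab
}

#' Read / write rule files
#'
#' The plain rule text format is one expression per line:
#' `id<TAB>arity<TAB>expression<TAB>phi`, with `phi` optional and lines
#' starting with `#` ignored. [read_rules()] parses each expression;
#' [write_rules()] serialises a catalogue tibble (canonical expression
#' text) back to this format.
#'
#' @param path File path.
#' @return [read_rules()]: a tibble like [colloid_catalog()]'s (without
#'   substrate/table metadata).
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, integer(1))
  if (any(n < 3L))
    stop("rule file line(s) need id<TAB>arity<TAB>expression: line ",
         paste(which(n < 3L), collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    id = vapply(parts, `[[`, character(1), 1L),
    arity = as.integer(vapply(parts, `[[`, character(1), 2L)),
    expression = vapply(parts, `[[`, character(1), 3L),
    phi = vapply(parts, function(p)
      if (length(p) >= 4L && nzchar(p[[4]]))
        suppressWarnings(as.integer(p[[4]])) else NA_integer_, integer(1))
  )
  out$expr <- purrr::map2(out$expression, out$arity, parse_sop)
  out
}

#' @rdname read_rules
#' @param rules A tibble with columns `id`, `arity` and either `expr`
#'   (parsed expressions) or `expression` (text), plus optional `phi`.
#' @export
write_rules <- function(rules, path) {
  expr_text <- if ("expr" %in% names(rules))
    vapply(rules$expr, function(e) format(canonical_form(e)), character(1))
  else rules$expression
  phi <- if ("phi" %in% names(rules)) ifelse(is.na(rules$phi), "", rules$phi)
  else ""
  writeLines(paste(rules$id, rules$arity, expr_text, phi, sep = "\t"), path)
  invisible(path)
}
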