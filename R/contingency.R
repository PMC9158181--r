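#' Joint-enrichment contingency table
#'
#' Cross-tabulation of the enrichment status of a fixed set of `n` GO (or
#' other) terms across two feature lists: `n11` terms enriched in both
#' lists, `n10` only in the first, `n01` only in the second, `n00` in
#' neither. This four-cell table is the sufficient statistic for the
#' Sorensen-Dice dissimilarity between the two lists.
#'
#' @param n11,n10,n01,n00 Non-negative integer cell counts.
#' @return An object of class `enrich_table`: a named integer vector with
#'   elements `n11`, `n10`, `n01`, `n00` and an `n` attribute holding the
#'   total number of terms.
#' @examples
#' tab <- enrich_table(125, 50, 50, 775)
#' tab
#' estimate_probs(tab)
#' @seealso [build_table()], [sorensen_estimate()], [sorensen_equiv_test()]
#' @export
enrich_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = unname(n11)[1], n10 = unname(n10)[1],
             n01 = unname(n01)[1], n00 = unname(n00)[1])
  if (!is.numeric(cells) || length(cells) != 4L || anyNA(cells))
    sq_input_error("all four cell counts must be non-missing numbers")
  if (any(cells < 0))
    sq_input_error(sprintf(
      "cell counts must be non-negative (got %s)",
      paste(names(cells)[cells < 0], "=", cells[cells < 0], collapse = ", ")))
  if (any(cells != round(cells)))
    sq_input_error(sprintf(
      "cell counts must be integers (got %s)",
      paste(names(cells)[cells != round(cells)], "=",
            cells[cells != round(cells)], collapse = ", ")))
  n <- sum(cells)
  if (n < 1) sq_input_error("the table must contain at least one term (n >= 1)")
  structure(as.integer(round(cells)),
            names = names(cells), n = as.integer(n),
            class = "enrich_table")
}

#' @export
print.enrich_table <- function(x, ...) {
  m <- matrix(c(x[["n11"]], x[["n01"]], x[["n10"]], x[["n00"]]), 2L, 2L,
              dimnames = list(`list 1` = c("enriched", "non-enriched"),
                              `list 2` = c("enriched", "non-enriched")))
  cat("Joint-enrichment contingency table (", attr(x, "n"), " terms)\n",
      sep = "")
  print(m)
  invisible(x)
}

#' Coerce to a joint-enrichment contingency table
#'
#' @param x A length-4 numeric vector `(n11, n10, n01, n00)` (named or in
#'   that order), a 2x2 matrix with lists in rows/columns (enriched first),
#'   or an existing `enrich_table`.
#' @return An `enrich_table`.
#' @export
as_enrich_table <- function(x) {
  if (inherits(x, "enrich_table")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2L, 2L)))
    return(enrich_table(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  if (is.numeric(x) && length(x) == 4L) {
    if (!is.null(names(x)) && all(c("n11", "n10", "n01", "n00") %in% names(x)))
      return(enrich_table(x[["n11"]], x[["n10"]], x[["n01"]], x[["n00"]]))
    return(enrich_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  sq_input_error("cannot interpret `x` as a joint-enrichment table")
}

#' Joint-enrichment probability vector
#'
#' The population parameters `(p11, p01, p10, p00)` of the joint enrichment
#' law: `p11` is the probability that a term is enriched in both lists,
#' `p01`/`p10` in only one of them, and `p00 = 1 - (p11 + p01 + p10)` in
#' neither.
#'
#' @param p11,p01,p10 Probabilities in `[0, 1]`.
#' @param p00 Optional; if omitted it is derived as `1 - (p11 + p01 + p10)`.
#'   If supplied, the four values must sum to 1 within `1e-12`.
#' @return An object of class `enrich_probs`: a named numeric vector
#'   `(p11, p01, p10, p00)`.
#' @examples
#' enrich_probs(0.125, 0.05, 0.05)
#' @export
enrich_probs <- function(p11, p01, p10, p00 = NULL) {
  for (nm in c("p11", "p01", "p10"))
    check_number(get(nm), nm, 0, 1)
  s <- p11 + p01 + p10
  if (s > 1 + 1e-12)
    sq_input_error(sprintf("p11 + p01 + p10 = %.15g exceeds 1", s))
  if (is.null(p00)) {
    p00 <- max(0, 1 - s)
  } else {
    check_number(p00, "p00", 0, 1)
    if (abs(s + p00 - 1) > 1e-12)
      sq_input_error(sprintf("probabilities sum to %.15g, not 1", s + p00))
  }
  structure(c(p11 = unname(p11)[1], p01 = unname(p01)[1],
              p10 = unname(p10)[1], p00 = unname(p00)[1]),
            class = "enrich_probs")
}

#' @export
print.enrich_probs <- function(x, digits = 6, ...) {
  cat("Joint-enrichment probabilities\n")
  print(round(unclass(x), digits))
  invisible(x)
}

as_enrich_probs <- function(p) {
  if (inherits(p, "enrich_probs")) return(p)
  if (is.numeric(p) && length(p) %in% c(3L, 4L)) {
    if (!is.null(names(p)) && all(c("p11", "p01", "p10") %in% names(p)))
      return(enrich_probs(p[["p11"]], p[["p01"]], p[["p10"]],
                          if ("p00" %in% names(p)) p[["p00"]] else NULL))
    return(enrich_probs(p[[1]], p[[2]], p[[3]],
                        if (length(p) == 4L) p[[4]] else NULL))
  }
  sq_input_error("cannot interpret `p` as joint-enrichment probabilities")
}

#' Estimate joint-enrichment probabilities from a table
#'
#' Plug-in estimates `p_ij = n_ij / n`.
#'
#' @param table An [enrich_table()] (or anything [as_enrich_table()]
#'   accepts).
#' @return An [enrich_probs()] vector.
#' @examples
#' estimate_probs(enrich_table(125, 50, 50, 775))
#' @export
estimate_probs <- function(table) {
  tab <- as_enrich_table(table)
  n <- attr(tab, "n")
  enrich_probs(tab[["n11"]] / n, tab[["n01"]] / n, tab[["n10"]] / n,
               tab[["n00"]] / n)
}

#' Binary enrichment profile over a fixed term set
#'
#' A terms x lists incidence matrix: entry `(t, l)` is 1 when term `t` is
#' declared enriched in list `l`, 0 otherwise. This is the data structure
#' from which pairwise joint-enrichment tables are built.
#'
#' @param incidence A 0/1 matrix or data frame, terms in rows, lists in
#'   columns; column names identify the lists.
#' @param term_ids Character vector of unique term identifiers, one per
#'   row. Defaults to the row names of `incidence`.
#' @return An object of class `enrich_profile`: an integer 0/1 matrix with
#'   term ids as row names and list ids as column names.
#' @examples
#' prof <- enrich_profile(cbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0)),
#'                        term_ids = paste0("GO:", 1:4))
#' build_table(prof, "A", "B")
#' @export
enrich_profile <- function(incidence, term_ids = rownames(incidence)) {
  m <- as.matrix(incidence)
  if (is.null(term_ids)) term_ids <- paste0("term", seq_len(nrow(m)))
  term_ids <- as.character(term_ids)
  if (length(term_ids) != nrow(m))
    sq_input_error("`term_ids` must have one entry per row of `incidence`")
  if (anyDuplicated(term_ids))
    sq_input_error("term identifiers must be unique")
  if (is.null(colnames(m)))
    sq_input_error("`incidence` must have column names identifying the lists")
  if (!all(m %in% c(0, 1)))
    sq_input_error("incidence entries must be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- term_ids
  structure(m, class = c("enrich_profile", class(m)))
}

#' @export
print.enrich_profile <- function(x, ...) {
  cat("Enrichment profile: ", nrow(x), " terms x ", ncol(x), " lists (",
      paste(colnames(x), collapse = ", "), ")\n", sep = "")
  cat("enriched per list:",
      paste(colnames(x), colSums(x), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build a joint-enrichment table from a profile
#'
#' Cross-tabulates the 0/1 enrichment status of two columns of an
#' enrichment profile. The order of the arguments fixes which list plays
#' the role of "list 1" (the `n10` margin).
#'
#' @param profile An [enrich_profile()].
#' @param list_a,list_b Column (list) identifiers.
#' @return An [enrich_table()].
#' @examples
#' prof <- enrich_profile(cbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0)))
#' build_table(prof, "A", "B")
#' @export
build_table <- function(profile, list_a, list_b) {
  if (!inherits(profile, "enrich_profile"))
    profile <- enrich_profile(profile)
  for (id in c(list_a, list_b))
    if (!id %in% colnames(profile))
      sq_input_error(sprintf("unknown list identifier '%s'", id))
  a <- profile[, list_a]
  b <- profile[, list_b]
  enrich_table(sum(a == 1L & b == 1L), sum(a == 1L & b == 0L),
               sum(a == 0L & b == 1L), sum(a == 0L & b == 0L))
}

#' Read or write a joint-enrichment table
#'
#' Supported formats: `csv`/`tsv` (a header row `n11,n10,n01,n00` and one
#' data row) and `json` (an object with those four keys). The format is
#' sniffed from the file extension unless given explicitly. Writing then
#' reading returns an identical table.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"json"`; default sniffs the
#'   extension.
#' @return `read_enrich_table()` returns an [enrich_table()];
#'   `write_enrich_table()` returns `path` invisibly.
#' @export
read_enrich_table <- function(path, format = c("auto", "csv", "tsv", "json")) {
  format <- sniff_format(path, match.arg(format))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in c("n11", "n10", "n01", "n00"))
      if (is.null(obj[[k]]))
        sq_input_error(sprintf("JSON table is missing field '%s'", k))
    cells <- vapply(c("n11", "n10", "n01", "n00"),
                    function(k) as.numeric(obj[[k]]), numeric(1))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep_of(format))
    missing <- setdiff(c("n11", "n10", "n01", "n00"), names(df))
    if (length(missing))
      sq_input_error(sprintf("table file is missing column(s): %s",
                             paste(missing, collapse = ", ")))
    if (nrow(df) != 1L)
      sq_input_error("table file must contain exactly one data row")
    cells <- vapply(c("n11", "n10", "n01", "n00"), function(k) {
      v <- df[[k]][1]
      if (!is.numeric(v))
        sq_input_error(sprintf("column '%s' does not parse as a number", k))
      v
    }, numeric(1))
  }
  bad <- cells < 0 | cells != round(cells) | is.na(cells)
  if (any(bad))
    sq_input_error(sprintf(
      "invalid cell(s) in %s: %s must be non-negative integers", path,
      paste(c("n11", "n10", "n01", "n00")[bad], "=", cells[bad],
            collapse = ", ")))
  enrich_table(cells[1], cells[2], cells[3], cells[4])
}

#' @rdname read_enrich_table
#' @param table The [enrich_table()] to write.
#' @export
write_enrich_table <- function(table, path,
                               format = c("auto", "csv", "tsv", "json")) {
  tab <- as_enrich_table(table)
  format <- sniff_format(path, match.arg(format))
  if (format == "json") {
    jsonlite::write_json(as.list(unclass(tab)), path, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(t(unclass(tab)))
    utils::write.table(df, path, sep = sep_of(format), row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read or write a binary enrichment profile
#'
#' CSV/TSV layout: terms in rows, a first column of term identifiers
#' (header `term_id`), then one 0/1 column per list with the list name in
#' the header.
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`; default sniffs the extension.
#' @return `read_profile()` returns an [enrich_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path, format = c("auto", "csv", "tsv")) {
  format <- sniff_format(path, match.arg(format))
  if (format == "json")
    sq_input_error("profiles are CSV/TSV only")
  df <- utils::read.table(path, header = TRUE, sep = sep_of(format),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    sq_input_error("a profile needs a term-id column and at least two lists")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  enrich_profile(m, term_ids = ids)
}

#' @rdname read_profile
#' @param profile The [enrich_profile()] to write.
#' @export
write_profile <- function(profile, path, format = c("auto", "csv", "tsv")) {
  if (!inherits(profile, "enrich_profile")) profile <- enrich_profile(profile)
  format <- sniff_format(path, match.arg(format))
  df <- data.frame(term_id = rownames(profile),
                   unclass(profile)[, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep_of(format), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

sniff_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", tab = "tsv", txt = "tsv",
         json = "json",
         "csv")
}

sep_of <- function(format) if (format == "tsv") "\t" else ","
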