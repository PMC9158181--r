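#' Read a gene-set collection in GMT format
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `term-id`, `description`, then the member gene identifiers. Empty sets
#' are rejected; duplicate genes within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors (term id -> genes) with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) sq_input_error(sprintf("no gene sets in %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    sq_input_error(sprintf("GMT line %d has no genes", which(bad)[1]))
  ids <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(
    stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])), ids),
    descriptions = stats::setNames(vapply(parts, `[[`, character(1), 2L), ids))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (term id -> genes).
#' @param descriptions Optional named character vector of term
#'   descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    sq_input_error("`sets` must be a named list of gene vectors")
  if (anyDuplicated(names(sets)))
    sq_input_error("term ids must be unique")
  if (any(vapply(sets, length, integer(1)) == 0L))
    sq_input_error("every gene set must be non-empty")
  structure(lapply(sets, function(g) unique(as.character(g))),
            descriptions = descriptions,
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else id
    paste(c(id, d, collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, length, integer(1))
  cat(sprintf("Gene-set collection: %d sets, sizes %d-%d (median %g)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Over-representation analysis of one gene list
#'
#' For each term (gene set), tests whether the list contains more of the
#' term's genes than expected under random sampling from the universe:
#' the one-sided hypergeometric tail \eqn{P(X \ge a)} with `a` list genes
#' in the term, `K` universe genes in the term, list size `m` and
#' universe size `N` (Fisher's one-sided test). P-values are adjusted
#' across all tested terms (Bonferroni by default) and a term is declared
#' enriched when the adjusted p-value falls at or below `alpha_cutoff`.
#'
#' List genes absent from the universe are dropped with a message; genes
#' of a term outside the universe are ignored.
#'
#' @param gene_list Character vector of gene identifiers.
#' @param universe Character vector: the gene universe.
#' @param sets A [gene_set_collection()] (or named list of gene vectors).
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @param alpha_cutoff Enrichment cutoff on the adjusted p-value.
#'   Default `0.05`.
#' @return A data frame of class `enrichment_calls`, one row per term:
#'   `term_id`, `a`, `K`, `m`, `N`, `p_raw`, `p_adj`, `enriched`.
#' @examples
#' sets <- gene_set_collection(list(T1 = paste0("g", 1:5)))
#' ora_test(paste0("g", 1:5), paste0("g", 1:20), sets)
#' @export
ora_test <- function(gene_list, universe, sets,
                     adjust = c("bonferroni", "bh"), alpha_cutoff = 0.05) {
  adjust <- match.arg(adjust)
  check_alpha(alpha_cutoff)
  if (!inherits(sets, "gene_set_collection"))
    sets <- gene_set_collection(sets)
  universe <- unique(as.character(universe))
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    message(length(outside), " list gene(s) outside the universe dropped")
    gene_list <- intersect(gene_list, universe)
  }
  if (!length(gene_list))
    sq_input_error("the gene list is empty after intersection with the universe")
  N <- length(universe)
  m <- length(gene_list)
  K <- vapply(sets, function(g) length(intersect(g, universe)), integer(1))
  a <- vapply(sets, function(g) length(intersect(g, gene_list)), integer(1))
  # one-sided over-representation: P(X >= a), X ~ Hypergeom(N, K, m)
  p_raw <- stats::phyper(a - 1L, K, N - K, m, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw,
                           method = if (adjust == "bh") "BH" else "bonferroni")
  structure(data.frame(term_id = names(sets), a = a, K = K, m = m, N = N,
                       p_raw = p_raw, p_adj = p_adj,
                       enriched = p_adj <= alpha_cutoff,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("enrichment_calls", "data.frame"))
}

#' Binary enrichment profile from raw gene lists
#'
#' Runs [ora_test()] independently on each list with identical settings
#' and assembles the enriched/non-enriched flags into a terms x lists
#' incidence matrix, the input of [build_table()] and
#' [pairwise_equiv_tests()]. This is the front-end that turns raw feature
#' lists into the joint-enrichment data on which the Sorensen-Dice
#' equivalence machinery operates.
#'
#' @param lists Named list (`>= 2` entries) of character gene vectors.
#' @param universe Character vector: the common gene universe.
#' @param sets A [gene_set_collection()].
#' @inheritParams ora_test
#' @return An [enrich_profile()] over the collection's terms with one
#'   column per list.
#' @export
profile_from_lists <- function(lists, universe, sets,
                               adjust = c("bonferroni", "bh"),
                               alpha_cutoff = 0.05) {
  if (!is.list(lists) || length(lists) < 2L || is.null(names(lists)))
    sq_input_error("`lists` must be a named list of at least two gene lists")
  adjust <- match.arg(adjust)
  if (!inherits(sets, "gene_set_collection"))
    sets <- gene_set_collection(sets)
  inc <- vapply(lists, function(g) {
    as.integer(ora_test(g, universe, sets, adjust = adjust,
                        alpha_cutoff = alpha_cutoff)$enriched)
  }, integer(length(sets)))
  inc <- matrix(inc, nrow = length(sets),
                dimnames = list(NULL, names(lists)))
  enrich_profile(inc, term_ids = names(sets))
}
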