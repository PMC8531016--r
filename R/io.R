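#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: term, description, genes... Lines with
#' fewer than three fields and duplicated term identifiers are format
#' errors (reported with line numbers); duplicated genes within a term are
#' deduplicated with a warning.
#'
#' @param path file path.
#' @return named list of character gene vectors, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_sigrev("empty GMT file", "sigrev_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_sigrev(sprintf("GMT line %d has fewer than 3 fields", short[1]),
                "sigrev_format_error")
  terms <- vapply(fields, `[[`, character(1), 1L)
  dup <- which(duplicated(terms))
  if (length(dup))
    stop_sigrev(sprintf("duplicate GMT term '%s' at line %d", terms[dup[1]], dup[1]),
                "sigrev_format_error")
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicated gene(s) within GMT term '%s' were deduplicated",
                      terms[i]))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- terms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), terms)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors, or a [signature_gene_sets()]
#'   pair (written as two lines, terms `UP` and `DOWN`).
#' @param path output file path.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_pair")) {
    desc <- as.character(sets$origin %||% "na")
    sets <- list(UP = sets$up, DOWN = sets$down)
    descriptions <- c(UP = desc, DOWN = desc)
  }
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, unname(desc[term]), sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-line UP/DOWN GMT as a gene-set pair
#'
#' @param path file path to a GMT with terms `UP` and `DOWN`.
#' @return a `gene_set_pair`.
#' @export
read_gene_set_pair <- function(path) {
  sets <- read_gmt(path)
  if (!all(c("UP", "DOWN") %in% names(sets)))
    stop_sigrev("gene-set-pair GMT must contain terms UP and DOWN",
                "sigrev_format_error")
  structure(list(up = sets$UP, down = sets$DOWN,
                 origin = unname(attr(sets, "descriptions")["UP"])),
            class = "gene_set_pair")
}

#' Read a RNK ranked-list file
#'
#' Two tab-separated columns (gene, statistic), parsed in file order; this
#' function never re-sorts — ordering is the caller's responsibility.
#'
#' @param path file path.
#' @return a `ranked_list` data.frame (gene, stat) in file order.
#' @export
read_rnk <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_sigrev("empty RNK file", "sigrev_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop_sigrev(sprintf("RNK line %d does not have 2 fields", bad[1]),
                "sigrev_format_error")
  stat <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(stat))
    stop_sigrev(sprintf("non-numeric statistic at RNK line %d", which(is.na(stat))[1]),
                "sigrev_format_error")
  structure(data.frame(gene = vapply(fields, `[[`, character(1), 1L),
                       stat = stat, stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Write a ranked list as RNK
#'
#' @param ranked a [ranked_list()] (or data.frame with gene, stat).
#' @param path output file path.
#' @export
write_rnk <- function(ranked, path) {
  writeLines(sprintf("%s\t%s", ranked$gene, format(ranked$stat, digits = 15,
                                                   trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Matrix TSV: first column gene identifiers, remaining columns samples.
#' The companion labels TSV has two columns, sample and group
#' (treated/control), without headers being optional — a header line
#' `sample<TAB>group` is accepted and skipped.
#'
#' @param path matrix TSV path.
#' @param labels_path sample -> group label TSV path.
#' @param counts logical; TRUE for count data.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, labels_path, counts = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  lab <- utils::read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(unlist(lab[1, ])), c("sample", "group"))) lab <- lab[-1, ]
  groups <- stats::setNames(lab[[2]], lab[[1]])
  if (!all(colnames(m) %in% names(groups)))
    stop_sigrev("every sample needs a group label", "sigrev_format_error")
  expression_matrix(m, unname(groups[colnames(m)]), counts = counts)
}

#' Write an expression matrix (and its labels) as TSV
#'
#' @param em an [expression_matrix()].
#' @param path matrix TSV path.
#' @param labels_path labels TSV path (sample, group).
#' @export
write_expression_tsv <- function(em, path, labels_path) {
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(em$groups), group = unname(em$groups)),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a differential signature as TSV
#' @param sig a `differential_signature`.
#' @param path output path.
#' @export
write_signature_tsv <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
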