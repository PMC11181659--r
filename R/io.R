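# Reading, writing and aligning the DepMap-style matrix formats.
#
# All three data types (gene effect / CERES, expression log2(TPM+1), and
# log2 relative copy number) travel as plain numeric matrices oriented
# genes x cell lines, with rownames "SYMBOL (ENTREZ)" keys and colnames
# cell-line IDs. A light "kind" attribute records which quantity a matrix
# holds; the functions never silently coerce one kind into another.

KINDS <- c("fitness", "expression", "copy_number")

#' Construct a genes x cell-lines screen matrix
#'
#' @param values Numeric matrix, rows = genes, columns = cell lines.
#'   Rownames must be gene keys (`"SYMBOL (ENTREZ)"` or plain symbols),
#'   colnames cell-line IDs; both must be unique.
#' @param kind One of `"fitness"` (CERES-scale gene effects, more negative =
#'   stronger fitness defect), `"expression"` (log2(TPM+1), non-negative),
#'   or `"copy_number"` (log2 relative copy number, 0 = neutral).
#' @return The matrix with class `"screen_matrix"` and a `kind` attribute.
#' @examples
#' m <- screen_matrix(matrix(0, 2, 2, dimnames = list(c("A (1)", "B (2)"),
#'                                                    c("ACH-1", "ACH-2"))),
#'                    kind = "fitness")
#' @export
screen_matrix <- function(values, kind = c("fitness", "expression", "copy_number")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("matrix must carry gene rownames and cell-line colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop_data("duplicate gene keys: ", paste(dup_g, collapse = ", "))
  dup_l <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_l))
    stop_data("duplicate cell-line IDs: ", paste(dup_l, collapse = ", "))
  if (kind == "expression") {
    v <- values[is.finite(values)]
    if (any(v < 0))
      stop_data("expression matrix must be non-negative log2(TPM+1)")
  }
  structure(values, kind = kind, class = c("screen_matrix", class(values)))
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix [%s]: %d genes x %d cell lines (%d missing values)\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Parse "SYMBOL (ENTREZ)" header tokens. Returns data.frame(symbol, entrez).
parse_gene_keys <- function(keys) {
  keys <- trimws(keys)
  m <- regmatches(keys, regexec("^(\\S+) \\((\\d+)\\)$", keys))
  bad <- keys[vapply(m, length, 1L) != 3L]
  if (length(bad))
    stop_data("malformed gene header(s), expected \"SYMBOL (ENTREZ)\": ",
              paste(utils::head(bad, 5L), collapse = ", "))
  data.frame(symbol = vapply(m, `[`, "", 2L),
             entrez = as.integer(vapply(m, `[`, "", 3L)))
}

#' Read a DepMap-dialect CSV matrix
#'
#' The DepMap download dialect stores cell lines as rows (first column =
#' line ID) and genes as column headers formatted `"SYMBOL (ENTREZ)"`.
#' `dialect = "genes_as_rows"` reads the transposed layout (gene keys in the
#' first column, cell-line IDs as headers). Either way the result is
#' oriented genes x cell lines. Empty cells become `NA`.
#'
#' @param path CSV file path.
#' @param kind Matrix kind, see [screen_matrix()].
#' @param dialect `"depmap_genes_as_columns"` (default) or `"genes_as_rows"`.
#' @return A [screen_matrix()].
#' @export
read_matrix <- function(path, kind = c("fitness", "expression", "copy_number"),
                        dialect = c("depmap_genes_as_columns", "genes_as_rows")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop_data("matrix file needs one key column plus at least one data column")
  keys <- trimws(df[[1L]])
  headers <- trimws(colnames(df)[-1L]) # before subsetting: keep duplicates as-is
  vals <- as.matrix(df[, -1L, drop = FALSE])
  colnames(vals) <- headers
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals == "" | is.na(vals) | toupper(vals) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop_data(sprintf("non-numeric cell '%s' at row %d (key '%s'), column '%s'",
                      vals[i[1L], i[2L]], i[1L], keys[i[1L]], headers[i[2L]]))
  }
  if (dialect == "depmap_genes_as_columns") {
    parse_gene_keys(headers) # validates the headers
    out <- t(num)
    dimnames(out) <- list(headers, keys)
  } else {
    parse_gene_keys(keys)
    out <- num
    dimnames(out) <- list(keys, headers)
  }
  screen_matrix(out, kind = kind)
}

#' Write a screen matrix as CSV
#'
#' Inverse of [read_matrix()]: round-trips values, gene keys and cell-line
#' IDs exactly in either dialect.
#'
#' @param x A [screen_matrix()] (or plain named matrix).
#' @param path Output CSV path.
#' @param dialect See [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path,
                         dialect = c("depmap_genes_as_columns", "genes_as_rows")) {
  dialect <- match.arg(dialect)
  if (dialect == "depmap_genes_as_columns") {
    df <- data.frame(line = colnames(x), t(unclass(x)), check.names = FALSE)
  } else {
    df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_symbol`, `entrez_id`, `chromosome`,
#' `arm`, `start_bp`, `end_bp`. Arm membership downstream is decided purely
#' by the (chromosome, arm) labels, never by coordinates.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann `data.frame` with columns `gene_symbol`, `entrez_id`,
#'   `chromosome`, `arm`, `start_bp`, `end_bp`.
#' @return `ann`, with `entrez_id` coerced to integer.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_symbol", "entrez_id", "chromosome", "arm", "start_bp", "end_bp")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop_data("annotation lacks column(s): ", paste(miss, collapse = ", "))
  ann$entrez_id <- as.integer(ann$entrez_id)
  key <- paste(ann$gene_symbol, ann$entrez_id)
  if (anyDuplicated(key))
    stop_data("duplicate (gene_symbol, entrez_id) pairs in annotation: ",
              paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(ann$arm %in% c("p", "q")))
    stop_data("annotation 'arm' must be \"p\" or \"q\"")
  if (any(ann$start_bp > ann$end_bp))
    stop_data("annotation has start_bp > end_bp")
  ann
}

#' Read a cell line to lineage map
#'
#' @param path Two-column TSV (`line_id`, `lineage`).
#' @return Named character vector, names = line IDs.
#' @export
read_lineage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), trimws(as.character(df[[1L]])))
}

# Resolve matrix rownames against the annotation; gene identity joins on
# entrez when the rowname carries one, with symbol fallback. Ambiguity is an
# error, not a silent merge.
match_annotation <- function(genes, ann) {
  parsed <- tryCatch(parse_gene_keys(genes), error = function(e) NULL)
  if (!is.null(parsed)) {
    idx <- match(parsed$entrez, ann$entrez_id)
    miss <- is.na(idx)
    idx[miss] <- match(parsed$symbol[miss], ann$gene_symbol)
  } else {
    idx <- match(genes, ann$gene_symbol)
  }
  idx
}

#' Align fitness, expression and copy-number data on shared cell lines
#'
#' Restricts every matrix to the (ordered) intersection of their cell-line
#' sets and records which lines each source lost. Gene sets are left per
#' matrix; downstream stages intersect genes as they need them.
#'
#' @param fitness,expression,copy_number [screen_matrix()] objects (any may
#'   be `NULL`, but at least two must be present for an intersection to be
#'   meaningful).
#' @param annotation Optional annotation `data.frame` (see
#'   [read_annotation()]).
#' @param lineage Optional named character vector mapping line ID to lineage.
#' @return An object of class `"aligned_cohort"`: a list with the aligned
#'   matrices, `lines`, `lineage`, `annotation`, and `dropped` (per-source
#'   character vectors of discarded line IDs).
#' @export
align_cohort <- function(fitness = NULL, expression = NULL, copy_number = NULL,
                         annotation = NULL, lineage = NULL) {
  mats <- list(fitness = fitness, expression = expression, copy_number = copy_number)
  mats <- mats[!vapply(mats, is.null, TRUE)]
  if (!length(mats)) stop_data("no matrices supplied")
  sets <- lapply(mats, colnames)
  shared <- Reduce(intersect, sets)
  if (!length(shared)) stop_data("no cell line is shared by all supplied matrices")
  # keep the order of the first source for reproducibility
  shared <- sets[[1L]][sets[[1L]] %in% shared]
  dropped <- lapply(sets, setdiff, y = shared)
  mats <- lapply(mats, function(m) {
    structure(m[, shared, drop = FALSE], kind = attr(m, "kind"),
              class = class(m))
  })
  if (!is.null(annotation)) annotation <- validate_annotation(annotation)
  if (!is.null(lineage)) lineage <- lineage[shared]
  structure(c(mats,
              list(lines = shared, lineage = lineage,
                   annotation = annotation, dropped = dropped)),
            class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf("aligned_cohort: %d shared cell lines\n", length(x$lines)))
  for (k in KINDS) if (!is.null(x[[k]]))
    cat(sprintf("  %-12s %5d genes, dropped %d line(s)\n",
                k, nrow(x[[k]]), length(x$dropped[[k]])))
  invisible(x)
}
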