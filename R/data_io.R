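#' Read a gene expression matrix from TSV
#'
#' Parses the plain tab-separated convention used throughout the ARACNE
#' family: the first row holds sample identifiers (optionally preceded by a
#' label for the gene-id column), each following row holds one gene
#' identifier and its numeric expression values.  No unit or normalization
#' is assumed: downstream mutual-information estimation is rank-based and
#' therefore invariant to any monotone per-gene transform.
#'
#' @param path Path to the TSV file.
#' @param min_samples Minimum number of sample columns accepted by the
#'   parser (default 2).  A full pipeline run additionally requires at
#'   least 8 samples, the smallest size at which the adaptive partition can
#'   split; [run_pipeline()] enforces that stricter bound.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("Gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t4\t2\t1"), tsv)
#' read_expression(tsv)
#' @seealso [write_expression()], [read_tf_list()]
#' @export
read_expression <- function(path, min_samples = 2L) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file must contain a header row and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]

  nf <- unique(lengths(body))
  if (length(nf) != 1L)
    stop("ragged expression file: rows have differing field counts ",
         "(first offending gene row: '",
         body[[which(lengths(body) != lengths(body)[1L])[1L]]][1L], "')")
  m <- nf - 1L
  if (m < 1L) stop("expression file has no sample columns")

  sample_ids <- if (length(header) == nf) {
    header[-1L]
  } else if (length(header) == m) {
    header
  } else {
    stop(sprintf(
      "header has %d fields but gene rows have %d; expected %d or %d",
      length(header), nf, m, nf))
  }
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ",
         sample_ids[duplicated(sample_ids)][1L])
  if (m < min_samples)
    stop(sprintf("expression matrix has %d samples; at least %d required",
                 m, min_samples))

  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1L])

  values <- matrix(NA_real_, nrow = length(body), ncol = m,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) | !nzchar(trimws(cells)))
    if (length(bad))
      stop(sprintf(
        "non-numeric or missing value for gene '%s', sample '%s'",
        gene_ids[i], sample_ids[bad[1L]]))
    values[i, ] <- num
  }
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: writes a header row of sample ids
#' (preceded by a `Gene` column label) and one row per gene.
#'
#' @param matrix Numeric expression matrix with gene/sample dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  header <- paste(c("Gene", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            format(matrix[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a transcription-factor list and resolve it against a matrix
#'
#' Reads one gene identifier per line (blank lines and lines starting with
#' `#` are ignored) and returns the row indices of those genes in the
#' expression matrix.  Curated TF lists rarely match a given matrix exactly,
#' so listed genes absent from the matrix are skipped with a warning rather
#' than failing; an empty intersection is an error.
#'
#' @param path Path to the TF list file.
#' @param matrix Expression matrix the identifiers refer to.
#' @return Sorted integer vector of row indices (1-based) into `matrix`.
#' @export
read_tf_list <- function(path, matrix) {
  if (!file.exists(path)) stop("TF list file not found: ", path)
  validate_expression(matrix)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(ids)
  if (length(ids) == 0L) stop("TF list is empty")
  idx <- match(ids, rownames(matrix))
  absent <- ids[is.na(idx)]
  if (length(absent))
    warning("TF ids absent from the expression matrix were skipped: ",
            paste(absent, collapse = ", "))
  idx <- sort(idx[!is.na(idx)])
  if (length(idx) == 0L)
    stop("none of the listed TFs are present in the expression matrix")
  idx
}

network_columns <- c("regulator", "target", "mi", "count", "p_adj")

make_network_table <- function(regulator = character(), target = character(),
                               mi = numeric(), count = integer(),
                               p_adj = numeric()) {
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   mi = as.numeric(mi),
                   count = as.integer(count),
                   p_adj = as.numeric(p_adj),
                   stringsAsFactors = FALSE)
  if (any(df$regulator == df$target))
    stop("network table contains self edges")
  key <- paste(df$regulator, df$target, sep = "\r")
  if (anyDuplicated(key))
    stop("network table contains duplicate (regulator, target) rows")
  df
}

#' Write an inferred network as TSV
#'
#' Writes the ARACNE-style five-column table
#' `Regulator  Target  MI  Count  AdjPvalue`.  Rows are sorted by
#' (regulator, target) with byte-wise (radix) ordering and MI is printed
#' with 8 significant digits, so the same network always produces a
#' byte-identical file.  The adjusted p-value column is `NA` for runs
#' without bootstrapping.
#'
#' @param net Network table (data frame with columns `regulator`, `target`,
#'   `mi`, `count`, `p_adj`) as returned by [run_pipeline()] or
#'   [consolidate()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  if (!is.data.frame(net) || !all(network_columns %in% names(net)))
    stop("net must be a network table with columns ",
         paste(network_columns, collapse = ", "))
  header <- "Regulator\tTarget\tMI\tCount\tAdjPvalue"
  if (nrow(net) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(net$regulator, net$target, method = "radix")
  net <- net[ord, , drop = FALSE]
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.8g", x))
  rows <- paste(net$regulator, net$target, fmt_num(net$mi),
                ifelse(is.na(net$count), "NA", as.character(net$count)),
                fmt_num(net$p_adj), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a network TSV written by [write_network()]
#'
#' @param path Path to the network file.
#' @return Network table data frame (possibly with zero rows).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "Regulator\tTarget\tMI\tCount\tAdjPvalue")
    stop("not a network file (unexpected header)")
  if (length(lines) == 1L) return(make_network_table())
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(fields) != 5L)) stop("malformed network row")
  make_network_table(
    regulator = vapply(fields, `[[`, character(1L), 1L),
    target = vapply(fields, `[[`, character(1L), 2L),
    mi = as.numeric(vapply(fields, `[[`, character(1L), 3L)),
    count = suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 4L))),
    p_adj = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 5L))))
}
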