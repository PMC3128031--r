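#' @title SSR genotype tables
#' @name genotype_table
#'
#' @description
#' An SSR (microsatellite) genotype call for one sample at one marker is a
#' *set* of amplicon sizes (base pairs), written `"176/182/186"` in delimited
#' files.  `ssrkit` stores each call as a sorted integer vector (an "allele
#' set"); a missing call is `NULL`.  A `genotype_table` holds the full
#' samples-by-markers grid plus optional class labels.
#'
#' Amplicon sizes are treated as purely qualitative identities: 176 vs 178 is
#' no closer than 176 vs 200.  Duplicate sizes within a call collapse (set
#' semantics), so `"176/176"` is the single-allele set `{176}`.
NULL

MISSING_TOKENS <- c("-", "", "NA")

#' Parse a single genotype cell
#'
#' Parses the slash-separated amplicon-size syntax used in SSR genotype
#' tables (`"177/181"`, `"172"`).  The tokens `"-"`, `""` and `"NA"` denote a
#' missing call.  Allele order in the input is irrelevant; the result is
#' always sorted ascending with duplicates removed.
#'
#' @param text Cell contents, a length-1 character vector.
#' @param context Optional string naming the row/column, used in error
#'   messages.
#' @return A sorted integer vector of allele sizes, or `NULL` for a missing
#'   call.
#' @examples
#' parse_genotype_string("177/181")
#' parse_genotype_string("176/176")   # collapses to 176
#' parse_genotype_string("-")         # NULL (missing)
#' @export
parse_genotype_string <- function(text, context = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (txt %in% MISSING_TOKENS) return(NULL)
  where <- if (is.null(context)) "" else paste0(" at ", context)
  tokens <- trimws(strsplit(txt, "/", fixed = TRUE)[[1L]])
  if (length(tokens) == 0L || any(tokens == "")) {
    stop("malformed genotype cell '", text, "'", where,
         ": empty allele token", call. = FALSE)
  }
  bad <- !grepl("^[0-9]+$", tokens)
  if (any(bad)) {
    stop("malformed genotype cell '", text, "'", where,
         ": non-integer allele token '", tokens[bad][1L], "'", call. = FALSE)
  }
  alleles <- as.integer(tokens)
  if (any(alleles <= 0L)) {
    stop("malformed genotype cell '", text, "'", where,
         ": allele sizes must be positive", call. = FALSE)
  }
  sort(unique(alleles))
}

#' Format an allele set as a genotype string
#'
#' Inverse of [parse_genotype_string()]: alleles ascending, `/`-separated,
#' `"-"` for missing.
#'
#' @param alleles Integer vector of allele sizes, or `NULL` for missing.
#' @return A length-1 character string.
#' @export
format_allele_set <- function(alleles) {
  if (is.null(alleles) || length(alleles) == 0L) return("-")
  paste(sort(unique(as.integer(alleles))), collapse = "/")
}

#' Construct a genotype table
#'
#' @param cells A samples-by-markers matrix of mode `list`; each element a
#'   positive integer vector (an allele set) or `NULL` (missing call).
#'   Character matrices are parsed cell-wise with [parse_genotype_string()].
#' @param sample_ids,marker_ids Unique identifiers; default taken from
#'   `dimnames(cells)`.
#' @param labels Optional class labels, one per sample (any vector coercible
#'   to factor, or `NULL`).
#' @return An object of class `genotype_table` with fields `sample_ids`,
#'   `marker_ids`, `cells` (list-matrix, canonicalized allele sets) and
#'   `labels` (factor or `NULL`).
#' @export
genotype_table <- function(cells, sample_ids = rownames(cells),
                           marker_ids = colnames(cells), labels = NULL) {
  if (!is.matrix(cells)) stop("'cells' must be a matrix", call. = FALSE)
  if (is.character(cells)) {
    parsed <- matrix(vector("list", length(cells)), nrow(cells), ncol(cells))
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(ncol(cells))) {
        parsed[i, j] <- list(parse_genotype_string(
          cells[i, j],
          context = paste0("sample ", i, ", marker ", j)))
      }
    }
    cells <- parsed
  }
  if (!is.list(cells)) stop("'cells' must be a list or character matrix",
                            call. = FALSE)
  n <- nrow(cells); m <- ncol(cells)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(m))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n || length(marker_ids) != m) {
    stop("id lengths do not match the cell grid", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  for (idx in seq_along(cells)) {
    a <- cells[[idx]]
    if (is.null(a) || length(a) == 0L) { cells[idx] <- list(NULL); next }
    if (!is.numeric(a) || any(a != as.integer(a)) || any(a <= 0)) {
      stop("allele sets must be positive integers", call. = FALSE)
    }
    cells[[idx]] <- sort(unique(as.integer(a)))
  }
  dimnames(cells) <- list(sample_ids, marker_ids)
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("'labels' must have one entry per sample", call. = FALSE)
    }
    labels <- factor(as.character(labels))
    if (anyNA(labels)) stop("labels may not be NA", call. = FALSE)
    names(labels) <- sample_ids
  }
  structure(list(sample_ids = sample_ids, marker_ids = marker_ids,
                 cells = cells, labels = labels),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$sample_ids), " samples x ",
      length(x$marker_ids), " markers", sep = "")
  if (!is.null(x$labels)) {
    cat(", ", nlevels(x$labels), " classes", sep = "")
  }
  n_missing <- sum(vapply(x$cells, is.null, logical(1L)))
  cat(", ", n_missing, " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) {
  c(length(x$sample_ids), length(x$marker_ids))
}

#' Subset a genotype table
#'
#' @param x A `genotype_table`.
#' @param samples,markers Indices or ids; `NULL` keeps all.
#' @return A `genotype_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  mi <- if (is.null(markers)) seq_along(x$marker_ids) else markers
  cells <- x$cells[si, mi, drop = FALSE]
  genotype_table(cells,
                 sample_ids = rownames(cells),
                 marker_ids = colnames(cells),
                 labels = if (is.null(x$labels)) NULL else x$labels[si])
}

detect_separator <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t"
  else if (grepl(",", header_line, fixed = TRUE)) ","
  else "\t"
}

#' Read an SSR genotype table from a delimited file
#'
#' Expects a header row of marker names, one row per sample, first column =
#' sample id.  Tab-separated by default with comma auto-detection.  Cells use
#' the `"176/182"` syntax; `"-"`, `""` and `"NA"` read as missing.
#'
#' @param path File path.
#' @param label_column Optional name of the column holding class labels.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated [genotype_table()].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, label_column = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("no sample rows in ", path, call. = FALSE)
  }
  if (is.null(sep)) sep <- detect_separator(lines[1L])
  split_row <- function(line) trimws(strsplit(line, sep, fixed = TRUE)[[1L]])
  header <- split_row(lines[1L])
  if (length(header) < 2L) stop("header must name at least one marker",
                                call. = FALSE)
  col_names <- header[-1L]
  label_idx <- NULL
  if (!is.null(label_column)) {
    label_idx <- match(label_column, col_names)
    if (is.na(label_idx)) {
      stop("label column '", label_column, "' not found in header",
           call. = FALSE)
    }
  }
  marker_ids <- if (is.null(label_idx)) col_names else col_names[-label_idx]
  n_fields <- length(header)
  body <- lines[-1L]
  n <- length(body)
  sample_ids <- character(n)
  labels <- if (is.null(label_idx)) NULL else character(n)
  cells <- matrix(vector("list", n * length(marker_ids)), n,
                  length(marker_ids))
  for (i in seq_len(n)) {
    fields <- split_row(body[i])
    if (length(fields) != n_fields) {
      stop("line ", i + 1L, ": expected ", n_fields, " fields, found ",
           length(fields), call. = FALSE)
    }
    sample_ids[i] <- fields[1L]
    vals <- fields[-1L]
    if (!is.null(label_idx)) {
      labels[i] <- vals[label_idx]
      vals <- vals[-label_idx]
    }
    for (j in seq_along(vals)) {
      cells[i, j] <- list(parse_genotype_string(
        vals[j],
        context = paste0("line ", i + 1L, ", column '", marker_ids[j],
                         "'")))
    }
  }
  genotype_table(cells, sample_ids = sample_ids, marker_ids = marker_ids,
                 labels = labels)
}

#' Write an SSR genotype table to a delimited file
#'
#' Emits the dialect accepted by [read_genotype_table()]: alleles ascending
#' within a cell, missing calls as `"-"`.  If the table carries labels they
#' are written in a final column.
#'
#' @param table A `genotype_table`.
#' @param path Output file path.
#' @param label_column Column name for labels (used only when the table has
#'   labels).
#' @param sep Field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(table, path, label_column = "group",
                                 sep = "\t") {
  stopifnot(inherits(table, "genotype_table"))
  cells_chr <- apply(table$cells, c(1L, 2L),
                     function(a) format_allele_set(a[[1L]]))
  header <- c("sample", table$marker_ids)
  rows <- cbind(table$sample_ids, cells_chr)
  if (!is.null(table$labels)) {
    header <- c(header, label_column)
    rows <- cbind(rows, as.character(table$labels))
  }
  out <- c(paste(header, collapse = sep),
           apply(rows, 1L, paste, collapse = sep))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Per-marker genotype categories
#'
#' For information-theoretic scoring each distinct allele *set* at a marker
#' is one nominal category (the full multi-allele call, not its individual
#' alleles).  Missing calls map to `NA`.
#'
#' @param table A `genotype_table`.
#' @param marker Marker id or index.
#' @return A character vector of length `n_samples` (canonical genotype
#'   strings), `NA` where the call is missing.
#' @export
genotype_categories <- function(table, marker) {
  stopifnot(inherits(table, "genotype_table"))
  col <- table$cells[, marker]
  out <- vapply(col, function(a) {
    if (is.null(a)) NA_character_ else format_allele_set(a)
  }, character(1L))
  unname(out)
}
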