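#' Write counts as Matrix Market with annotation sidecars
#'
#' Writes `matrix.mtx` (coordinate format, nuclei-by-genes), `nuclei.tsv`
#' and `genes.tsv` annotation tables, and optionally `donors.tsv`, under a
#' directory. The round trip through [read_counts()] is lossless for
#' integer counts.
#'
#' @param counts Sparse nuclei-by-genes count matrix.
#' @param path Output directory (created if missing).
#' @param nuclei,genes Annotation data frames (defaults built from
#'   dimnames).
#' @param donors Optional donor table.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, nuclei = NULL, genes = NULL,
                         donors = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "generalMatrix"),
                              "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  if (is.null(nuclei)) {
    nuclei <- data.frame(barcode = rownames(counts) %||%
                           as.character(seq_len(nrow(counts))),
                         stringsAsFactors = FALSE)
  }
  if (is.null(genes)) {
    genes <- data.frame(gene = colnames(counts) %||%
                          as.character(seq_len(ncol(counts))),
                        stringsAsFactors = FALSE)
  }
  if (nrow(nuclei) != nrow(counts) || nrow(genes) != ncol(counts)) {
    stop_config("annotation tables do not match the matrix dimensions")
  }
  utils::write.table(nuclei, file.path(path, "nuclei.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genes, file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(donors)) {
    utils::write.table(donors, file.path(path, "donors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

find_sidecar <- function(path, name) {
  for (f in c(file.path(path, name), file.path(path, paste0(name, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  NULL
}

#' Read counts written by [write_counts()]
#'
#' Accepts plain or gzip-compressed `matrix.mtx`, `nuclei.tsv`, `genes.tsv`
#' (and `donors.tsv` if present); 1-based Matrix Market indices are honored
#' by the reader. A dimension mismatch between the matrix header and the
#' sidecars is a parse error.
#'
#' @param path Directory containing the files.
#' @return A list with `counts` (dgCMatrix with dimnames), `nuclei`,
#'   `genes`, and `donors` (`NULL` if absent).
#' @export
read_counts <- function(path) {
  mtx <- find_sidecar(path, "matrix.mtx")
  nuc <- find_sidecar(path, "nuclei.tsv")
  gen <- find_sidecar(path, "genes.tsv")
  if (is.null(mtx) || is.null(nuc) || is.null(gen)) {
    stop_config("missing matrix.mtx / nuclei.tsv / genes.tsv under %s", path)
  }
  counts <- if (endsWith(mtx, ".gz")) {
    # decompress to a scratch copy; readMM manages plain files natively
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    con <- gzfile(mtx, "rt")
    writeLines(readLines(con), tmp)
    close(con)
    Matrix::readMM(tmp)
  } else {
    Matrix::readMM(mtx)
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"),
                        "CsparseMatrix")
  nuclei <- utils::read.delim(nuc, stringsAsFactors = FALSE)
  genes <- utils::read.delim(gen, stringsAsFactors = FALSE)
  if (nrow(nuclei) != nrow(counts) || nrow(genes) != ncol(counts)) {
    stop_config(
      "matrix is %d x %d but sidecars describe %d nuclei and %d genes",
      nrow(counts), ncol(counts), nrow(nuclei), nrow(genes))
  }
  dimnames(counts) <- list(nuclei[[1]], genes[[1]])
  don <- find_sidecar(path, "donors.tsv")
  donors <- if (!is.null(don)) utils::read.delim(don,
                                                 stringsAsFactors = FALSE)
  list(counts = counts, nuclei = nuclei, genes = genes, donors = donors)
}

#' Read a marker-gene database
#'
#' JSON form: `{"type": {"positive": [...], "negative": [...]}, ...}`.
#' TSV form: three columns `cell_type`, `gene`, `sign`
#' (`positive`/`negative`).
#'
#' @param path File path (`.json` or `.tsv`).
#' @return Named list per cell type with `positive` and `negative`
#'   character vectors.
#' @export
read_marker_db <- function(path) {
  db <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(raw, function(e) {
      if (is.character(e)) e <- list(positive = e)
      list(positive = as.character(e$positive %||% character(0)),
           negative = as.character(e$negative %||% character(0)))
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    split_tab <- split(tab, tab$cell_type)
    lapply(split_tab, function(e) {
      list(positive = e$gene[e$sign == "positive"],
           negative = e$gene[e$sign == "negative"])
    })
  }
  validate_marker_db(db)
  db
}

validate_marker_db <- function(db) {
  for (nm in names(db)) {
    pos <- db[[nm]]$positive
    if (length(pos) == 0) {
      stop_config("cell type '%s' has no positive markers", nm)
    }
    if (anyDuplicated(pos) || anyDuplicated(db[[nm]]$negative)) {
      stop_config("duplicate genes in the marker lists of '%s'", nm)
    }
  }
  invisible(db)
}

#' Write a marker database as JSON
#' @param db Marker database list.
#' @param path Output `.json` path.
#' @export
write_marker_db <- function(db, path) {
  jsonlite::write_json(db, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
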