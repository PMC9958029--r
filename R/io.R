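#' Read a single-cell matrix with its annotation
#'
#' Reads an expression matrix in MatrixMarket (MTX) triplet or dense TSV
#' format together with cell and gene metadata TSVs and assembles a validated
#' [cell_matrix()]. For MTX input, gene and cell ids are taken from the
#' metadata files in file order; for dense TSV input the first column holds
#' gene ids and the header holds cell ids.
#'
#' @param path_matrix path to the `.mtx` or dense `.tsv` matrix.
#' @param path_cell_meta path to a TSV with the cell metadata columns
#'   required by [cell_matrix()].
#' @param path_gene_meta path to a TSV with the gene metadata columns
#'   required by [cell_matrix()]; a `go_terms` column may hold `;`-separated
#'   term ids.
#' @param scale scale tag of the stored values (`"counts"` or `"lognorm"`).
#' @return a [cell_matrix()].
#' @export
read_cell_matrix <- function(path_matrix, path_cell_meta, path_gene_meta,
                             scale = "counts") {
  cell_meta <- read.delim(path_cell_meta, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  gene_meta <- read.delim(path_gene_meta, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  first <- readLines(path_matrix, n = 1)
  if (grepl("^%%MatrixMarket", first)) {
    values <- Matrix::readMM(path_matrix)
    if (nrow(values) != nrow(gene_meta) || ncol(values) != nrow(cell_meta)) {
      stop("shape error: MTX is ", nrow(values), " x ", ncol(values),
           " but metadata describe ", nrow(gene_meta), " genes and ",
           nrow(cell_meta), " cells", call. = FALSE)
    }
    dimnames(values) <- list(as.character(gene_meta$gene_id),
                             as.character(cell_meta$cell_id))
  } else {
    tab <- read.delim(path_matrix, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- gene_ids
    reord <- match(as.character(gene_meta$gene_id), gene_ids)
    if (anyNA(reord)) {
      stop("shape error: dense matrix is missing gene(s) named in gene_meta",
           call. = FALSE)
    }
    values <- values[reord, , drop = FALSE]
    cell_ord <- match(as.character(cell_meta$cell_id), colnames(values))
    if (anyNA(cell_ord)) {
      stop("shape error: dense matrix is missing cell(s) named in cell_meta",
           call. = FALSE)
    }
    values <- values[, cell_ord, drop = FALSE]
  }
  cell_matrix(values, cell_meta, gene_meta, scale = scale)
}

#' Write a tabular result as TSV
#'
#' Writes any data.frame result with a header, unquoted, at full numeric
#' precision (15 significant digits), so that a read-back reproduces values
#' to well under 5e-7.
#'
#' @param result a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  out <- result
  for (nm in names(out)) {
    if (is.list(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], paste, "", collapse = ";")
    } else if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("I/O error writing ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a tabular result written by write_table
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a curated ligand-receptor list
#'
#' @param path TSV with columns `ligand_gene` and `receptor_gene`.
#' @return data.frame with those two character columns.
#' @export
read_lr_list <- function(path) {
  lr <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("ligand_gene", "receptor_gene")
  missing <- setdiff(req, names(lr))
  if (length(missing) > 0) {
    stop("ligand-receptor list is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lr[, req]
}

#' Read survival records
#'
#' @param path TSV with columns `sample_id`, `time`, `event` and optionally
#'   `endpoint` (OS/RFS) and `unit`.
#' @return validated data.frame of survival records.
#' @export
read_survival <- function(path) {
  s <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  missing <- setdiff(req, names(s))
  if (length(missing) > 0) {
    stop("survival table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(s$time < 0)) stop("survival times must be >= 0", call. = FALSE)
  if (!all(s$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  if (!"endpoint" %in% names(s)) s$endpoint <- "OS"
  if (!"unit" %in% names(s)) s$unit <- "months"
  s
}

#' Read a pipeline configuration file
#'
#' JSON is always supported (via jsonlite); YAML is supported when the
#' optional `yaml` package is installed. Fields mirror [pipeline_config()];
#' unknown fields are rejected.
#'
#' @param path path to a `.json`, `.yaml`, or `.yml` file.
#' @return a [pipeline_config()] object.
#' @export
read_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    fields <- yaml::read_yaml(path)
  } else {
    fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, fields)
}
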