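#' Read and write the pipeline's TSV formats
#'
#' Beta (and expression) matrices are TSVs with a `probe_id` / `gene` /
#' row-identifier first column and one column per sample; missing betas are
#' written as `NA`. Sample sheets, annotations and survival tables are
#' plain TSVs with a header row.
#'
#' @param path File path.
#' @param x Object to write.
#' @param id_col Name of the identifier column (default `"probe_id"`).
#' @return Readers return a matrix or tibble; writers return `path`
#'   invisibly.
#' @name methspec-io
NULL

#' @rdname methspec-io
#' @export
write_matrix_tsv <- function(x, path, id_col = "probe_id") {
  df <- tibble::as_tibble(x, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname methspec-io
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname methspec-io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname methspec-io
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' @rdname methspec-io
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    strand = readr::col_character(),
    gene = readr::col_character(),
    tss = readr::col_integer()
  ))
}

#' @rdname methspec-io
#' @export
read_survival_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer(),
    cancer_type = readr::col_character()
  ))
}

#' Write a full synthetic cohort to a directory
#'
#' Writes `beta.tsv`, `sample_sheet.tsv`, `annotation.tsv`,
#' `gpcr_genes.txt` and, when jsonlite is available, `truth.json` with the
#' planted structure.
#'
#' @param cohort A list from [generate_cohort()].
#' @param annotation The matching [generate_annotation()] table.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, annotation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(annotation, file.path(dir, "annotation.tsv"))
  writeLines(cohort$gpcr_genes, file.path(dir, "gpcr_genes.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    truth$baseline <- as.list(truth$baseline)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
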