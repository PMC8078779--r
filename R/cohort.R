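# data_io: matrix/label readers, sample matching, the cohort container.

#' Construct a cohort of matched expression, mutation and stage data
#'
#' A `cohort_dataset` holds the sample-aligned inputs of the pipeline: a
#' continuous (log-scale) expression matrix, a binary gene-level mutation
#' matrix, integer stage labels 1-4 and optional batch labels. Rows of both
#' matrices are samples, in the same order as `sample_ids`.
#'
#' @param expression numeric matrix, samples x genes, with row and column names.
#' @param mutation binary (0/1) matrix, samples x genes, with row and column
#'   names. May cover a different gene set than `expression`.
#' @param stages integer vector with values in 1..4, one per sample. Character
#'   labels such as `"Stage II"` are mapped via [map_stage_labels()].
#' @param sample_ids character vector of unique sample identifiers. Defaults to
#'   the expression row names.
#' @param batch optional vector of batch identifiers, one per sample.
#' @return An object of class `cohort_dataset`: a list with elements
#'   `expression`, `mutation`, `stages`, `sample_ids`, `batch`.
#' @examples
#' expr <- matrix(rnorm(12), 4, 3,
#'                dimnames = list(paste0("S", 1:4), paste0("g", 1:3)))
#' mut <- matrix(rbinom(8, 1, 0.2), 4, 2,
#'               dimnames = list(paste0("S", 1:4), c("TP53", "KRAS")))
#' cohort_dataset(expr, mut, stages = c(1, 2, 3, 4))
#' @export
cohort_dataset <- function(expression, mutation, stages,
                           sample_ids = rownames(expression), batch = NULL) {
  expression <- as.matrix(expression)
  mutation <- as.matrix(mutation)
  if (is.character(stages) || is.factor(stages)) stages <- map_stage_labels(stages)
  stages <- as.integer(stages)
  obj <- structure(
    list(expression = expression, mutation = mutation, stages = stages,
         sample_ids = as.character(sample_ids), batch = batch),
    class = "cohort_dataset"
  )
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  n <- length(x$sample_ids)
  assert_that(nrow(x$expression) == n && nrow(x$mutation) == n &&
                length(x$stages) == n,
              "expression, mutation, stages and sample_ids must agree in length")
  assert_that(!anyDuplicated(x$sample_ids), "duplicate sample identifiers")
  assert_that(!anyDuplicated(colnames(x$expression)),
              "duplicate expression gene identifiers")
  assert_that(!anyDuplicated(colnames(x$mutation)),
              "duplicate mutation gene identifiers")
  assert_that(all(x$stages %in% 1:4), "stage values must be integers in 1..4")
  assert_that(all(x$mutation %in% c(0, 1)), "mutation matrix must be binary 0/1")
  if (!is.null(x$batch)) {
    assert_that(length(x$batch) == n, "batch labels must match sample count")
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d samples, %d expression genes, %d mutation genes\n",
              length(x$sample_ids), ncol(x$expression), ncol(x$mutation)))
  cat("stage counts:", paste(sprintf("%s=%d", names(table(x$stages)),
                                     table(x$stages)), collapse = " "), "\n")
  if (!is.null(x$batch)) {
    cat("batches:", paste(unique(x$batch), collapse = " "), "\n")
  }
  invisible(x)
}

# Subset a cohort to a set of samples (by id), preserving given order.
subset_cohort <- function(cohort, ids) {
  idx <- match(ids, cohort$sample_ids)
  assert_that(!anyNA(idx), "unknown sample identifiers")
  structure(
    list(expression = cohort$expression[idx, , drop = FALSE],
         mutation = cohort$mutation[idx, , drop = FALSE],
         stages = cohort$stages[idx],
         sample_ids = cohort$sample_ids[idx],
         batch = if (is.null(cohort$batch)) NULL else cohort$batch[idx]),
    class = "cohort_dataset"
  )
}

#' Map free-form stage labels to integers 1-4
#'
#' Accepts Roman numerals (`"I"`..`"IV"`), Arabic digits and `"Stage X"`
#' prefixes, case-insensitively. Unmappable labels become `NA` with a warning;
#' downstream matching drops those samples, mirroring the rule that only
#' samples with stage information enter the cohort.
#'
#' @param x character, factor or numeric vector of stage labels.
#' @return integer vector with values in 1..4 or `NA`.
#' @export
map_stage_labels <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(x %in% 1:4, as.integer(x), NA_integer_)
  } else {
    s <- toupper(trimws(as.character(x)))
    s <- sub("^STAGE[ _]*", "", s)
    roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L,
               "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L)
    out <- unname(roman[s])
  }
  if (anyNA(out)) {
    bad <- unique(as.character(x)[is.na(out)])
    warning(sprintf("dropped %d sample(s) with unmappable stage label(s): %s",
                    sum(is.na(out)), paste(bad, collapse = ", ")))
  }
  out
}

#' Read a matrix from a TSV file
#'
#' The first column holds identifiers; the header row holds the other
#' dimension's identifiers. The returned matrix is always oriented
#' samples-in-rows: files stored genes-in-rows are transposed on read.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`,
#'   describing the file on disk.
#' @return numeric matrix with samples in rows.
#' @export
read_matrix_tsv <- function(path,
                            orientation = c("samples_in_rows", "genes_in_rows")) {
  orientation <- match.arg(orientation)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  row_ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !all(is.na(v))) {
        bad <- which(is.na(num) & !is.na(v))[1]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                     v[bad], row_ids[bad], colnames(body)[j], path),
             call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- row_ids
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    dup <- unique(c(rownames(m)[duplicated(rownames(m))],
                    colnames(m)[duplicated(colnames(m))]))
    stop(sprintf("duplicate identifier(s) in %s: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (orientation == "genes_in_rows") m <- t(m)
  m
}

#' Write a matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]; values round-trip exactly (full double
#' precision is written).
#'
#' @param m numeric matrix, samples in rows.
#' @param path output file path.
#' @param orientation orientation to use on disk.
#' @param id_header name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path,
                             orientation = c("samples_in_rows", "genes_in_rows"),
                             id_header = "id") {
  orientation <- match.arg(orientation)
  if (orientation == "genes_in_rows") m <- t(m)
  body <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m),
                 dimnames = dimnames(m))  # 17 significant digits round-trip
  df <- data.frame(rownames(m), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (sample_id, label) TSV
#'
#' @param path file path.
#' @return named character vector, names = sample ids.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "label file needs two columns: sample_id, label")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Match expression, mutation and stage inputs into a cohort
#'
#' Keeps exactly the samples present in all three inputs that carry a valid
#' stage label; samples are ordered by the sorted identifier intersection.
#'
#' @param expr expression matrix, samples in rows, row names = sample ids.
#' @param mut binary mutation matrix, samples in rows.
#' @param stages named vector of stage labels (names = sample ids); free-form
#'   labels are mapped with [map_stage_labels()].
#' @param batch optional named vector of batch labels.
#' @return a [cohort_dataset()].
#' @export
match_and_filter <- function(expr, mut, stages, batch = NULL) {
  stage_int <- if (is.numeric(stages)) {
    stats::setNames(map_stage_labels(stages), names(stages))
  } else {
    stats::setNames(map_stage_labels(stages), names(stages))
  }
  staged_ids <- names(stage_int)[!is.na(stage_int)]
  ids <- sort(intersect(intersect(rownames(expr), rownames(mut)), staged_ids))
  if (length(ids) == 0) {
    stop("no samples shared by expression, mutation and stage inputs",
         call. = FALSE)
  }
  cohort_dataset(
    expression = expr[ids, , drop = FALSE],
    mutation = mut[ids, , drop = FALSE],
    stages = unname(stage_int[ids]),
    sample_ids = ids,
    batch = if (is.null(batch)) NULL else unname(batch[ids])
  )
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `expression.tsv`, `mutation.tsv`, `stages.tsv` and optionally
#' `batch.tsv` in the formats [read_cohort()] and the command-line interface
#' consume.
#'
#' @param cohort a [cohort_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   id_header = "sample_id")
  write_matrix_tsv(cohort$mutation, file.path(dir, "mutation.tsv"),
                   id_header = "sample_id")
  utils::write.table(
    data.frame(sample_id = cohort$sample_ids, stage = cohort$stages),
    file.path(dir, "stages.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$batch)) {
    utils::write.table(
      data.frame(sample_id = cohort$sample_ids, batch = cohort$batch),
      file.path(dir, "batch.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `expression.tsv`, `mutation.tsv`,
#'   `stages.tsv` and optionally `batch.tsv`.
#' @return a [cohort_dataset()].
#' @export
read_cohort <- function(dir) {
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  mut <- read_matrix_tsv(file.path(dir, "mutation.tsv"))
  stages <- read_labels_tsv(file.path(dir, "stages.tsv"))
  batch_path <- file.path(dir, "batch.tsv")
  batch <- if (file.exists(batch_path)) read_labels_tsv(batch_path) else NULL
  match_and_filter(expr, mut, stages, batch)
}
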