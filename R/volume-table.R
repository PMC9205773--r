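#' Construct a subject-by-structure volume table
#'
#' A `volume_table` is a data frame with one row per subject, metadata columns
#' `subject_id`, `strain` and `sex`, and one numeric column per brain
#' structure holding its volume in cubic millimetres. Exactly one strain is
#' designated the wild-type reference; downstream contrasts and effect sizes
#' are expressed relative to it.
#'
#' @param volumes numeric matrix or data frame, subjects x structures, with
#'   column names giving structure names.
#' @param subject_id character vector of unique subject identifiers.
#' @param strain character vector of strain labels, one per subject.
#' @param sex character vector with entries `"F"` or `"M"`.
#' @param wildtype strain label of the pooled wild-type reference group.
#' @param standardised logical; `TRUE` when values are per-structure Z-scores
#'   rather than raw volumes (raw volumes must be strictly positive).
#'
#' @return A data frame of class `volume_table` with attributes `wildtype`
#'   and `standardised`.
#' @export
volume_table <- function(volumes, subject_id, strain, sex, wildtype,
                         standardised = FALSE) {
  volumes <- as.data.frame(volumes, check.names = FALSE)
  n <- nrow(volumes)
  stopifnot(length(subject_id) == n, length(strain) == n, length(sex) == n)
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique")
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!wildtype %in% strain) stop("wild-type strain '", wildtype,
                                  "' not present in the data")
  vm <- as.matrix(volumes)
  if (!is.numeric(vm)) stop("structure columns must be numeric")
  if (anyNA(vm)) stop("volume table contains missing cells")
  if (!standardised && any(vm <= 0)) stop("raw volumes must be positive")
  out <- data.frame(subject_id = as.character(subject_id),
                    strain = as.character(strain),
                    sex = as.character(sex),
                    stringsAsFactors = FALSE)
  out <- cbind(out, volumes)
  structure(out,
            class = c("volume_table", "data.frame"),
            wildtype = wildtype,
            standardised = standardised)
}

#' Structure (value) column names of a volume table
#' @param vt a [volume_table()].
#' @return character vector of structure names.
#' @export
structure_names <- function(vt) {
  setdiff(names(vt), c("subject_id", "strain", "sex"))
}

#' Extract the numeric subject-by-structure matrix
#' @param vt a [volume_table()].
#' @return numeric matrix with subject ids as row names.
#' @export
volume_matrix <- function(vt) {
  m <- as.matrix(vt[, structure_names(vt), drop = FALSE])
  rownames(m) <- vt$subject_id
  m
}

#' Subject metadata of a volume table
#' @param vt a [volume_table()].
#' @return data frame with columns `subject_id`, `strain`, `sex`.
#' @export
subject_info <- function(vt) {
  data.frame(subject_id = vt$subject_id, strain = vt$strain, sex = vt$sex,
             stringsAsFactors = FALSE)
}

#' Wild-type reference strain of a volume table
#' @param vt a [volume_table()].
#' @return character scalar.
#' @export
wildtype_strain <- function(vt) attr(vt, "wildtype")

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf("volume_table: %d subjects x %d structures (%s)\n",
              nrow(x), length(structure_names(x)),
              if (isTRUE(attr(x, "standardised"))) "standardised" else "mm^3"))
  cat(sprintf("  strains: %s (wild-type: %s)\n",
              paste(sort(unique(x$strain)), collapse = ", "),
              attr(x, "wildtype")))
  invisible(x)
}

#' Read / write volume tables as CSV
#'
#' The CSV layout is `subject_id,strain,sex,<structure_1>,...`. The wild-type
#' designation is not part of the tabular data, so it is passed alongside
#' (and recorded in the pipeline configuration rather than the file).
#'
#' @param path file path.
#' @param wildtype wild-type strain label.
#' @param standardised logical, see [volume_table()].
#' @return [read_volume_table()] returns a `volume_table`;
#'   [write_volume_table()] returns `path` invisibly.
#' @export
read_volume_table <- function(path, wildtype, standardised = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("subject_id", "strain", "sex")
  if (!all(req %in% names(df))) stop("missing metadata columns in ", path)
  volume_table(df[, setdiff(names(df), req), drop = FALSE],
               subject_id = df$subject_id, strain = df$strain, sex = df$sex,
               wildtype = wildtype, standardised = standardised)
}

#' @rdname read_volume_table
#' @param vt a [volume_table()].
#' @export
write_volume_table <- function(vt, path) {
  utils::write.csv(as.data.frame(vt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
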