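#' Read a delimited matrix with validation
#'
#' Reads a TSV whose first column is the row identifier and whose header
#' row carries the sample ids, returning a typed matrix. Validation is
#' kind-specific: beta and detection p-values must lie in \[0,1\], counts
#' must be non-negative integers; a violation is reported with its row id
#' and column.
#'
#' @param path file path.
#' @param kind `"beta"`, `"detection_p"`, or `"counts"`.
#' @return numeric (or integer, for counts) matrix with dimnames.
#' @export
read_matrix <- function(path, kind = c("beta", "detection_p", "counts")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 2) stopf("%s: expected an id column plus at least one sample", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stopf("%s: duplicated row id '%s'", path, ids[duplicated(ids)][1])
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    stopf("%s: duplicated sample id '%s'", path,
          colnames(m)[duplicated(colnames(m))][1])
  }
  if (!is.numeric(m)) stopf("%s: non-numeric values in the matrix body", path)
  rownames(m) <- ids
  bad <- if (kind == "counts") {
    which(m < 0 | is.na(m) | m != round(m), arr.ind = TRUE)
  } else {
    which(m < 0 | m > 1 | is.na(m), arr.ind = TRUE)
  }
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("%s: invalid %s value %s at row '%s', column '%s'",
          path, kind, format(m[i, j]), ids[i], colnames(m)[j])
  }
  if (kind == "counts") storage.mode(m) <- "integer"
  m
}

#' Write a matrix as TSV with full-precision numerics
#'
#' Companion of [read_matrix()]: first column holds the row ids under
#' `id_col`, the header the sample ids. Doubles are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_col name for the id column (default "probe_id").
#' @return the path, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "probe_id") {
  if (is.double(m)) {
    body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    body <- m
  }
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- body[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' @param path TSV with one row per patient; must contain `patient_id` and
#'   a binary `outcome` column.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!"patient_id" %in% names(x)) stopf("%s: missing patient_id column", path)
  if (anyDuplicated(x$patient_id)) stopf("%s: duplicated patient ids", path)
  if ("outcome" %in% names(x)) {
    if (anyNA(x$outcome) || !all(x$outcome %in% c(0, 1))) {
      stopf("%s: outcome must be binary 0/1 with no missing values", path)
    }
  }
  x
}

#' Read a probe manifest
#'
#' @param path manifest TSV (see [validate_manifest()] for the contract).
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  validate_manifest(as.data.frame(
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = "chrom"))
  ))
}
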