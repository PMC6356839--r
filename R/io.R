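# Tab-delimited readers/writers for the three pipeline inputs. All files
# carry a header row with the id in the first column; expression is stored
# genes x samples.

#' Write / read an expression matrix as tab-delimited text
#'
#' Genes are rows, samples are columns, with a `gene_id` header column.
#'
#' @param X numeric matrix (genes x samples) with row and column names.
#' @param path file path.
#' @export
write_expression <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @return `read_expression`: the validated numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_data("expression file needs an id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_data("duplicated gene id(s): ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[, -1, drop = FALSE], is.numeric, logical(1)))[1]
    stop_data("non-numeric expression values in column '",
              colnames(df)[-1][bad], "'")
  }
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop_data("missing expression value at gene '", ids[idx[1]],
              "', sample '", colnames(M)[idx[2]], "'")
  }
  if (nrow(M) > 1 && nrow(M) < ncol(M) / 10)
    stop_data("far fewer rows than columns; the matrix looks transposed ",
              "(expected genes as rows, samples as columns)")
  rownames(M) <- ids
  M
}

#' Write / read a survival table as tab-delimited text
#'
#' Columns: `sample_id`, `time` (months, strictly positive), `event`
#' (1 = event observed, 0 = censored).
#'
#' @param surv data.frame with those columns.
#' @param path file path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv[, c("sample_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @return `read_survival`: the validated data.frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_data("survival file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_data("duplicated sample id(s): ",
              paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time <= 0))
    stop_data("survival times must be positive numbers")
  if (!all(df$event %in% c(0, 1)))
    stop_data("event indicator must be 0 (censored) or 1 (event)")
  df[, need]
}

CLINICAL_THERAPY <- c("chemoradiation", "chemotherapy", "radiation", "none")
CLINICAL_SUBTYPE <- c("proneural", "classical", "mesenchymal", "other")

#' Write / read a clinical covariate table as tab-delimited text
#'
#' Columns: `sample_id`, `age`, `gender` (0/1), `kps`, `therapy`
#' (chemoradiation/chemotherapy/radiation/none), `subtype`
#' (proneural/classical/mesenchymal/other), `mgmt`, `gcimp`, `idh_mutation`
#' (all 0/1).
#'
#' @param clinical data.frame with those columns.
#' @param path file path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @return `read_clinical`: the validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "gender", "kps", "therapy", "subtype",
            "mgmt", "gcimp", "idh_mutation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_data("clinical file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_data("duplicated sample id(s)")
  if (!all(df$therapy %in% CLINICAL_THERAPY))
    stop_data("therapy values outside {", paste(CLINICAL_THERAPY, collapse = ", "), "}")
  if (!all(df$subtype %in% CLINICAL_SUBTYPE))
    stop_data("subtype values outside {", paste(CLINICAL_SUBTYPE, collapse = ", "), "}")
  for (nm in c("gender", "mgmt", "gcimp", "idh_mutation"))
    if (!all(df[[nm]] %in% c(0, 1))) stop_data("'", nm, "' must be 0/1")
  df <- df[, need]
  for (nm in c("age", "kps")) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("gender", "mgmt", "gcimp", "idh_mutation"))
    df[[nm]] <- as.integer(df[[nm]])
  df
}
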