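#' Feature-by-sample expression matrix with a group design
#'
#' Thin container for counts or abundances in the four-group oviposition
#' design (virgin `V`, egg-laying `Q`, inhibited `C`, recovery `R`; three
#' queens each by default). Values must be non-negative and every sample
#' must have a group.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames), no negative entries.
#' @param sample_group named character vector mapping every sample id to a
#'   group label.
#' @param kind one of `counts`, `FPKM`, `TPM`, `transformed`.
#' @return A list with class `expr_matrix` (`$values`, `$sample_group`,
#'   `$kind`).
#' @export
expression_matrix <- function(values, sample_group, kind = "counts") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (feature ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique colnames (sample ids)")
  if (!kind %in% c("counts", "FPKM", "TPM", "transformed"))
    stop("unknown expression kind: ", kind)
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  # log-scale transformed values may legitimately dip below zero
  if (kind != "transformed" && any(values < 0))
    stop("expression values must be non-negative")
  storage.mode(values) <- "double"
  sample_group <- sample_group[colnames(values)]
  if (any(is.na(sample_group)) || is.null(names(sample_group)))
    stop("every sample id needs a group in sample_group")
  structure(list(values = values,
                 sample_group = setNames(as.character(sample_group),
                                         colnames(values)),
                 kind = kind), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix %s: %d features x %d samples; groups: %s>\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(sprintf("%s(%d)", names(table(x$sample_group)),
                            table(x$sample_group)), collapse = " ")))
  invisible(x)
}

#' Subset an expression matrix by feature ids and/or sample ids
#' @param em an `expr_matrix`.
#' @param features,samples character vectors (NULL keeps all).
#' @return An `expr_matrix`.
#' @export
subset_expression <- function(em, features = NULL, samples = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  v <- em$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing))
      stop("unknown feature id(s): ", paste(head(missing, 3), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, em$sample_group[colnames(v)], em$kind)
}

#' Read a count table with its sample-to-group map
#'
#' First column feature ids, header row sample ids, all cells numeric and
#' non-negative. Comment lines starting with `#` are skipped.
#'
#' @param path TSV path.
#' @param groups named character vector sample id -> group.
#' @param kind stored matrix kind, default `counts`.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, groups, kind = "counts") {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a feature column plus samples")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table")
  if (any(m < 0)) stop("negative cell(s) in count table")
  rownames(m) <- ids
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing))
    stop("sample(s) without group assignment: ",
         paste(missing, collapse = ", "))
  expression_matrix(m, groups[colnames(m)], kind)
}

#' Write an expression matrix as TSV
#' @param em an `expr_matrix`.
#' @param path output path.
#' @param header optional `#` comment lines to prepend.
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path, header = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(c("feature_id", colnames(em$values)), collapse = "\t"), con)
  body <- apply(em$values, 1L, function(row)
    paste(format(row, scientific = FALSE, trim = TRUE, digits = 15),
          collapse = "\t"))
  writeLines(paste(rownames(em$values), body, sep = "\t"), con)
  invisible(path)
}

#' Contrast between two sample groups
#'
#' The three analyzed oviposition transitions are `Q_V` (egg-laying vs
#' virgin: ovary activation), `C_Q` (inhibited vs egg-laying: oviposition
#' inhibition) and `R_C` (recovery vs inhibited). Fold changes are oriented
#' treatment over reference.
#'
#' @param name contrast label.
#' @param treatment,reference group labels (must differ).
#' @return A list with class `ce_contrast`.
#' @export
contrast <- function(name, treatment, reference) {
  stopifnot(nzchar(name), nzchar(treatment), nzchar(reference))
  if (treatment == reference) stop("treatment and reference must differ")
  structure(list(name = name, treatment = treatment, reference = reference),
            class = "ce_contrast")
}

#' The three default oviposition contrasts
#' @return Named list of [contrast()] objects `Q_V`, `C_Q`, `R_C`.
#' @export
default_contrasts <- function() {
  list(Q_V = contrast("Q_V", "Q", "V"),
       C_Q = contrast("C_Q", "C", "Q"),
       R_C = contrast("R_C", "R", "C"))
}
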