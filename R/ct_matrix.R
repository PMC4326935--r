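#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw qPCR threshold-cycle (Ct) values for a panel of
#' miRNA assays, one row per sample and one column per assay. A cell that
#' failed to amplify within `ct_max` cycles is *censored* and stored as `NA`.
#' Lower Ct means higher abundance; the instrument stops cycling at `ct_max`
#' (conventionally 40), so every finite value must lie in `(0, ct_max]`.
#'
#' @param ct Numeric matrix, samples x miRNAs, with unique rownames (sample
#'   ids) and colnames (miRNA ids). `NA`/`NaN`/`Inf` cells are stored as
#'   censored (`NA`).
#' @param ct_max Detection-limit cycle count (default 40 cycles).
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (numeric matrix, `NA` = censored) and `ct_max`.
#' @seealso [read_ct_table()], [delta_ct()]
#' @export
ct_matrix <- function(ct, ct_max = 40) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x miRNAs)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must carry sample ids as rownames and miRNA ids as colnames")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate miRNA id(s): ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  if (!is.numeric(ct_max) || length(ct_max) != 1L || !is.finite(ct_max) || ct_max <= 0)
    stop("`ct_max` must be a single positive cycle count")
  fin <- is.finite(ct)
  if (any(ct[fin] <= 0))
    stop("finite Ct values must be strictly positive")
  if (any(ct[fin] > ct_max))
    stop("finite Ct values must not exceed ct_max = ", format(ct_max),
         "; coerce above-limit values to censored first (see read_ct_table)")
  ct[!fin] <- NA_real_
  structure(list(ct = ct, ct_max = ct_max), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d samples x %d miRNAs (ct_max = %s cycles)\n",
              nrow(x$ct), ncol(x$ct), format(x$ct_max)))
  cat(sprintf("  censored cells: %d (%.1f%%)\n", sum(is.na(x$ct)),
              100 * mean(is.na(x$ct))))
  invisible(x)
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Read a Ct table from a delimited file
#'
#' Expects a TSV/CSV with a header row of miRNA ids and the first column
#' holding sample ids (or the transpose, see `orientation`). Cells are
#' either numeric Ct values or the censored token emitted by the
#' instrument for assays that never crossed threshold.
#'
#' @param path File path; `.csv` is comma-separated, anything else tab.
#' @param censored_token Text marking a non-amplified cell
#'   (default `"Undetermined"`, the SDS software call). Empty cells are
#'   also treated as censored.
#' @param ct_max Detection limit; finite values above it are coerced to
#'   censored with a warning giving the count.
#' @param orientation `"samples_rows"` (default) or `"mirnas_rows"` if the
#'   file stores miRNAs as rows.
#' @param sep Field separator; default inferred from the file extension.
#' @return A validated [ct_matrix()].
#' @export
read_ct_table <- function(path, censored_token = "Undetermined", ct_max = 40,
                          orientation = c("samples_rows", "mirnas_rows"),
                          sep = NULL) {
  orientation <- match.arg(orientation)
  raw <- read_delim_auto(path, sep)
  if (ncol(raw) < 2L) stop("Ct table needs an id column plus at least one assay column")
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- ids
  colnames(m) <- names(raw)[-1L]  # data.frame subsetting mangles duplicates
  if (anyDuplicated(ids))
    stop("duplicate id(s) in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate id(s) in header: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  cens <- is.na(m) | m == censored_token | m == ""
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(!cens & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 m[bad[1L, 1L], bad[1L, 2L]],
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  num[cens] <- NA_real_
  over <- is.finite(num) & num > ct_max
  if (any(over)) {
    warning(sprintf("%d Ct value(s) above ct_max = %s coerced to censored",
                    sum(over), format(ct_max)))
    num[over] <- NA_real_
  }
  if (orientation == "mirnas_rows") num <- t(num)
  ct_matrix(num, ct_max = ct_max)
}

#' Write a Ct table
#'
#' Inverse of [read_ct_table()]: writes samples as rows, miRNAs as header
#' columns, censored cells as `censored_token`. Finite values are written
#' with 17 significant digits so a round-trip is bit-exact.
#'
#' @param x A [ct_matrix()].
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @param censored_token Token to write for censored cells.
#' @param sep Field separator override.
#' @export
write_ct_table <- function(x, path, censored_token = "Undetermined", sep = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- array(sprintf("%.17g", x$ct), dim = dim(x$ct), dimnames = dimnames(x$ct))
  chr[is.na(x$ct)] <- censored_token
  out <- data.frame(sample_id = rownames(x$ct), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Requires columns `sample_id`, `group` (one of `preterm`, `child`,
#' `adult`), `age` (years; 0 for preterm infants, whose gestational age in
#' weeks may be given in a `gest_weeks` column), and `gender` (`F`/`M`).
#' Any further columns (e.g. clinical flags `PVL`, `BPD`, `schizophrenia`)
#' are kept as-is.
#'
#' @param path File path (TSV, or CSV by extension).
#' @param sep Field separator override.
#' @return A data.frame of per-sample metadata.
#' @export
read_sample_meta <- function(path, sep = NULL) {
  raw <- read_delim_auto(path, sep)
  need <- c("sample_id", "group", "age", "gender")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  raw$age <- as.numeric(raw$age)
  for (cl in setdiff(names(raw), need))
    raw[[cl]] <- utils::type.convert(raw[[cl]], as.is = TRUE)
  validate_sample_meta(raw)
  raw
}

#' Validate sample metadata (optionally against a Ct matrix)
#'
#' @param meta Metadata data.frame as from [read_sample_meta()].
#' @param x Optional [ct_matrix()]; if given, every sample in `x` must have
#'   exactly one metadata row.
#' @return `meta`, invisibly.
#' @export
validate_sample_meta <- function(meta, x = NULL) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_group <- setdiff(unique(meta$group), c("preterm", "child", "adult"))
  if (length(bad_group) > 0L)
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  if (any(!is.na(meta$age) & meta$age < 0)) stop("age must be non-negative")
  if (!is.null(x)) {
    missing_meta <- setdiff(rownames(x$ct), meta$sample_id)
    if (length(missing_meta) > 0L)
      stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  invisible(meta)
}

#' Normalize Ct against the endogenous control (delta-Ct)
#'
#' Computes `dCt[s, m] = Ct[s, m] - Ct[s, control]` for every target assay.
#' The control column is removed from the output (its delta-Ct with itself
#' is identically 0 and would distort downstream class counts). Censoring
#' propagates: a censored target stays censored. The control must have
#' amplified in every sample, otherwise normalization is impossible.
#'
#' @param x A [ct_matrix()].
#' @param control_id Endogenous-control assay id (default `"RNU48"`, the
#'   small nucleolar RNA used on TLDA human panels).
#' @return An object of class `delta_ct_matrix`: list with `delta`
#'   (samples x targets, `NA` = censored), `control_id`, `control_ct`
#'   (per-sample control Ct), and `ct_max`.
#' @export
delta_ct <- function(x, control_id = "RNU48") {
  stopifnot(inherits(x, "ct_matrix"))
  if (!control_id %in% colnames(x$ct))
    stop("control assay '", control_id, "' not present in the Ct matrix")
  ctrl <- x$ct[, control_id]
  if (anyNA(ctrl))
    stop("control '", control_id, "' is censored in sample(s): ",
         paste(rownames(x$ct)[is.na(ctrl)], collapse = ", "),
         "; normalization impossible")
  d <- x$ct[, setdiff(colnames(x$ct), control_id), drop = FALSE] - ctrl
  structure(list(delta = d, control_id = control_id,
                 control_ct = ctrl, ct_max = x$ct_max),
            class = "delta_ct_matrix")
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("delta_ct_matrix: %d samples x %d miRNAs (control: %s)\n",
              nrow(x$delta), ncol(x$delta), x$control_id))
  invisible(x)
}

#' Relative expression from delta-Ct
#'
#' Relative expression is `2^-dCt`: one cycle fewer to threshold doubles
#' the estimated abundance. Strictly positive and strictly decreasing in
#' delta-Ct; censored (`NA`) input stays `NA` (never coerced to zero).
#'
#' @param x Numeric vector/matrix of delta-Ct values, or a
#'   `delta_ct_matrix`.
#' @return Relative-expression values with the same shape.
#' @export
expression_value <- function(x) {
  if (inherits(x, "delta_ct_matrix")) return(2^(-x$delta))
  2^(-x)
}

#' Impute censored delta-Ct values at the detection limit
#'
#' The standard convention for censored qPCR data: a non-amplified target
#' is at or below the abundance detectable at `ct_max`, so its delta-Ct is
#' at least `ct_max - Ct(control)` in that sample. Substituting that limit
#' keeps one-group-heavy miRNAs testable while ranking censored cells
#' below every detected cell of the same sample.
#'
#' @param d A `delta_ct_matrix`.
#' @return Numeric matrix of delta-Ct with censored cells replaced by the
#'   per-sample detection-limit value.
#' @export
impute_censored <- function(d) {
  stopifnot(inherits(d, "delta_ct_matrix"))
  lim <- d$ct_max - d$control_ct
  out <- d$delta
  idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(idx) > 0L) out[idx] <- lim[idx[, 1L]]
  out
}
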