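## deterministic numeric formatting: data carriers get 10 significant digits
## (round-trip fidelity), report tables 6
format_num <- function(x, digits = 10) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- formatC(v, digits = digits, format = "g")
    gsub(" ", "", s)
  }, character(1))
}

#' Write a time-series matrix as TSV
#'
#' Header row `gene_id<TAB>t0<TAB>t1...` with times in minutes, one gene per
#' row. Values are written with 10 significant digits so that a read/write
#' round trip preserves them to better than 1e-9 relative.
#'
#' @param matrix a [time_series_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "time_series_matrix"))
  header <- paste(c("gene_id", format_num(matrix$times)), collapse = "\t")
  rows <- vapply(seq_along(matrix$gene_ids), function(g)
    paste(c(matrix$gene_ids[g], format_num(matrix$values[g, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a time-series matrix from TSV
#'
#' Inverse of [write_matrix()]. Ragged rows, non-numeric cells and duplicate
#' gene ids are rejected with the offending line number.
#'
#' @param path input TSV path.
#' @param condition,replicate metadata attached to the result.
#' @param scale `"linear"` or `"log2rel"` (see [time_series_matrix()]).
#' @return a [time_series_matrix()].
#' @export
read_matrix <- function(path, condition = "WT", replicate = 1L,
                        scale = "linear") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("format error: file has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "gene_id")
    stop("format error (line 1): header must start with 'gene_id'")
  times <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(times))
    stop("format error (line 1): header times must be numeric")
  ncols <- length(header)
  ids <- character(length(lines) - 1L)
  vals <- base::matrix(NA_real_, length(lines) - 1L, ncols - 1L)
  seen <- new.env(parent = emptyenv())
  for (i in 2:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncols)
      stop("format error (line ", i, "): expected ", ncols, " fields, got ",
           length(f))
    id <- f[1]
    if (!is.null(seen[[id]]))
      stop("format error (line ", i, "): duplicate gene id '", id, "'")
    seen[[id]] <- TRUE
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v) && anyNA(suppressWarnings(as.numeric(f[-1][f[-1] != "NA"]))))
      stop("format error (line ", i, "): non-numeric cell")
    if (any(is.na(v) & f[-1] != "NA"))
      stop("format error (line ", i, "): non-numeric cell")
    ids[i - 1L] <- id
    vals[i - 1L, ] <- v
  }
  time_series_matrix(vals, ids, times, condition = condition,
                     replicate = replicate, scale = scale)
}

#' Write a budding curve as two-column TSV
#'
#' @param curve a [budding_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_budding <- function(curve, path) {
  writeLines(c("time\tfraction_budded",
               paste(format_num(curve$times),
                     format_num(curve$fraction_budded), sep = "\t")), path)
  invisible(path)
}

#' Read a budding curve from two-column TSV
#'
#' @param path input path.
#' @return a [budding_curve()].
#' @export
read_budding <- function(path) {
  d <- utils::read.delim(path, header = TRUE)
  budding_curve(d[[1]], d[[2]])
}

#' Read GMT-format gene sets
#'
#' One set per line: `tf_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate set names and empty sets are rejected.
#'
#' @param path GMT file path.
#' @return list of [gene_set_annotation()] objects.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("format error (line ", i, "): GMT line needs name, description ",
           "and >= 1 gene")
    nm <- f[1]
    if (nm %in% vapply(out, function(a) a$tf_name, character(1)))
      stop("format error (line ", i, "): duplicate set name '", nm, "'")
    out[[length(out) + 1L]] <- gene_set_annotation(nm, f[-(1:2)])
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param annotations list of [gene_set_annotation()] objects.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(annotations, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(annotations))
  writeLines(vapply(seq_along(annotations), function(i)
    paste(c(annotations[[i]]$tf_name, descriptions[i],
            annotations[[i]]$targets), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' YAML-style `key: value` lines; `#` comments and blank lines ignored.
#' Values are parsed as numeric, logical, or comma-separated vectors when
#' they look like one, else kept as strings.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("format error: bad config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(nums)) nums
              else if (all(parts %in% c("TRUE", "FALSE", "true", "false")))
                toupper(parts) == "TRUE"
              else if (length(parts) > 1) parts else val
    out[[key]] <- parsed
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config named list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.numeric(v)) format_num(v) else as.character(v)
    paste0(k, ": ", paste(v, collapse = ","))
  }, character(1)), path)
  invisible(path)
}

#' Order genes by peak time
#'
#' Heat-map row ordering: genes sorted by estimated peak time ascending, ties
#' broken lexicographically by gene id. Genes without an estimate are placed
#' in a trailing block sorted by id (attribute `"uncalled"`). The same
#' ordering, derived from one condition, is reused across all conditions so
#' rows stay aligned between heat maps.
#'
#' @param gene_ids character vector of genes to order.
#' @param estimates data.frame with columns `gene_id`, `peak_time`.
#' @return character vector of gene ids with attribute `uncalled`.
#' @export
order_by_peak_time <- function(gene_ids, estimates) {
  idx <- match(gene_ids, estimates$gene_id)
  called <- gene_ids[!is.na(idx)]
  uncalled <- sort(gene_ids[is.na(idx)])
  pt <- estimates$peak_time[idx[!is.na(idx)]]
  o <- order(pt, called)
  out <- c(called[o], uncalled)
  attr(out, "uncalled") <- uncalled
  out
}

## deterministic TSV writer for report tables: 6 significant digits,
## stable column order, no quoting
write_table_tsv <- function(df, path, digits = 6) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- format_num(df2[[j]], digits = digits)
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
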