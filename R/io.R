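#' Read and write the tab-separated interchange tables
#'
#' Readers accept either 0-based half-open coordinates (the package's
#' internal convention, used by all writers) or 1-based inclusive tables
#' via `one_based = TRUE`, which ingestion converts to 0-based half-open.
#' Writers prepend comment headers recording the provenance stamp
#' (seed and a configuration hash) when one is supplied.
#'
#' @param path File path.
#' @param one_based Is the table 1-based inclusive?
#' @return A data.frame.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_reads <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:6] <- c("chrom", "start", "end", "read_id", "score", "strand")
  if (one_based) { df$start <- df$start - 1L }
  df
}

#' @rdname table_io
#' @export
read_calls <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (one_based) df$dyad <- df$dyad - 1L
  df
}

#' @rdname table_io
#' @export
read_genes <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (one_based) {
    df$tss <- df$tss - 1L
    df$orf_end <- df$orf_end - 1L
  }
  df
}

#' @rdname table_io
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(df[[2]], df[[1]])
}

stamp_lines <- function(stamp) {
  if (is.null(stamp)) return(character())
  c(sprintf("# seed=%s config_sha=%s", stamp$seed, stamp$hash),
    "# coordinates: 0-based half-open")
}

#' Write a data.frame as a headered TSV with provenance stamp
#'
#' @param df data.frame.
#' @param path Output path.
#' @param stamp Optional list with `seed` and `hash` recorded in comment
#'   lines.
#' @param col_names Write the header line?
#' @export
write_tsv <- function(df, path, stamp = NULL, col_names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_lines(stamp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
  invisible(path)
}

#' Write a density track as bedGraph
#'
#' Emits runs of equal nonzero weight as bedGraph intervals (0-based
#' half-open), one block per chromosome.
#'
#' @param map A `density_map`.
#' @param path Output path.
#' @param stamp Optional provenance stamp (see [write_tsv()]).
#' @export
write_bedgraph <- function(map, path, stamp = NULL) {
  stopifnot(inherits(map, "density_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_lines(stamp), con)
  writeLines("track type=bedGraph", con)
  for (cn in names(map$tracks)) {
    v <- map$tracks[[cn]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      utils::write.table(
        data.frame(cn, starts[nz], ends[nz], signif(r$values[nz], 8)),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Write a fit report as JSON
#'
#' @param fit A `fit_result` or `scenario_fit` (or a plain list).
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# short deterministic hash of a configuration list (provenance stamp)
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  # polynomial rolling hash; enough to detect config drift in file headers
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
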