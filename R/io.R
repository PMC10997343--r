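# Delimited-text readers/writers and result serialization.  Samples are
# aligned across files by variable label, never by column position.

# sniff comma vs tab from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("file is empty: ", path, call. = FALSE)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_sample_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, colClasses = "character")
  if (!ncol(df)) stop("no columns in ", path, call. = FALSE)
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[j]])))
    if (length(bad))
      stop("non-numeric or missing value in ", path, " at row ", bad[1],
           ", column '", colnames(df)[j], "'", call. = FALSE)
    m[, j] <- v
  }
  m
}

#' Read a two-sample dataset from two delimited files
#'
#' Each file holds one condition: first row variable labels, one observation
#' per row, comma- or tab-delimited (auto-detected).  Columns are matched by
#' label across the two files, so differing column orders are fine;
#' differing label sets are an error.
#'
#' @param path1,path2 Paths to the two sample files.
#' @return A [two_sample_data].
#' @export
read_two_sample <- function(path1, path2) {
  x1 <- read_sample_matrix(path1)
  x2 <- read_sample_matrix(path2)
  if (!setequal(colnames(x1), colnames(x2)))
    stop("variable labels differ between files: ",
         paste(c(setdiff(colnames(x1), colnames(x2)),
                 setdiff(colnames(x2), colnames(x1))), collapse = ", "),
         call. = FALSE)
  two_sample_data(x1, x2[, colnames(x1), drop = FALSE])
}

#' Write a two-sample dataset to two delimited files
#'
#' Inverse of [read_two_sample()] (CSV with header).
#'
#' @param data A [two_sample_data].
#' @param path1,path2 Output paths for the two conditions.
#' @export
write_two_sample <- function(data, path1, path2) {
  utils::write.csv(as.data.frame(data$x1), path1, row.names = FALSE)
  utils::write.csv(as.data.frame(data$x2), path2, row.names = FALSE)
  invisible(data)
}

#' Read an undirected graph from an edge-list file
#'
#' Two delimited columns of node labels, one edge per line; a line with a
#' single field declares an isolated node.  An optional header line
#' (`from,to` / `from<TAB>to`, case-insensitive) is skipped.  Duplicate
#' edges collapse; self-loops are an error.  Endpoints absent from a dataset
#' are only detected later, at test time.
#'
#' @param path Path to the edge list.
#' @return An [undirected_graph].
#' @export
read_graph_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) &&
      grepl("^from[,\t]to$", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) return(undirected_graph(NULL, nodes = character()))
  parts <- strsplit(lines, "[,\t]")
  nfield <- lengths(parts)
  if (any(nfield > 2))
    stop("more than two fields on line ", which(nfield > 2)[1], " of ", path,
         call. = FALSE)
  edges <- do.call(rbind, parts[nfield == 2])
  iso <- unlist(parts[nfield == 1])
  nodes <- unique(c(if (!is.null(edges)) as.vector(t(edges)), iso))
  undirected_graph(edges, nodes = nodes)
}

#' Serialize a test result to JSON or CSV
#'
#' JSON output carries every field of the result plus the package version
#' and an echo of the run configuration; CSV flattens a decomposed test to
#' one row per local term plus a global row.  JSON round-trips through
#' [jsonlite::fromJSON()] without loss.
#'
#' @param result An `lrt_test` or `ggm_test`.
#' @param path Output path.
#' @param format `"json"` (default) or `"csv"`.
#' @param config Optional list echoed into the JSON under `config`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv"),
                         config = NULL) {
  format <- match.arg(format)
  ver <- as.character(utils::packageVersion("ggmlrt"))
  if (format == "csv") {
    tab <- report_rows(result)
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(result, "ggm_test")) {
    list(kind = "decomposed",
         correction = result$correction,
         local = lapply(result$local, unclass),
         global = list(statistic_uncorrected = result$global_statistic,
                       statistic = result$global_corrected,
                       df = result$global_df,
                       p_value = result$global_p_value))
  } else {
    list(kind = "full", result = unclass(result))
  }
  payload$version <- ver
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

report_rows <- function(result) {
  row1 <- function(t, term) data.frame(
    term = term, statistic = t$statistic, df = t$df, p.value = t$p.value,
    correction = t$correction, reference = t$reference,
    subset = paste(t$subset, collapse = ";"),
    conditioning = paste(t$conditioning, collapse = ";"),
    stringsAsFactors = FALSE)
  if (!inherits(result, "ggm_test")) return(row1(result, "full"))
  tab <- do.call(rbind, Map(row1, result$local, names(result$local)))
  glob <- data.frame(term = "global", statistic = result$global_corrected,
                     df = result$global_df, p.value = result$global_p_value,
                     correction = result$correction,
                     reference = "chi_square", subset = "", conditioning = "",
                     stringsAsFactors = FALSE)
  rbind(tab, glob)
}
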