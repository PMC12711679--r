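## Tab-delimited readers/writers with line-numbered validation, GMT gene
## sets, and JSON serialization of cluster networks.  gzip is handled
## transparently by the underlying readers.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all remaining cells must be numeric log2 values.  Duplicate
#' identifiers, ragged rows and non-numeric cells are rejected with the
#' offending line number.
#'
#' @param path file path (plain or gzip TSV).
#' @return numeric genes x samples matrix with dimnames.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1),
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L)
    stop(path, ": need a gene column plus at least one sample column",
         call. = FALSE)
  ids <- dt[[1]]
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(path, ": duplicate gene identifier '", ids[dup[1]], "' at line ",
         dup[1] + 1L, call. = FALSE)
  if (anyDuplicated(names(dt)[-1]))
    stop(path, ": duplicate sample identifier in header (line 1)",
         call. = FALSE)
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_len(ncol(vals))) {
      num <- suppressWarnings(as.numeric(vals[, j]))
      bad <- which(is.na(num) & !is.na(vals[, j]))
      if (length(bad))
        stop(path, ": non-numeric cell '", vals[bad[1], j], "' at line ",
             bad[1] + 1L, ", column ", j + 1L, call. = FALSE)
    }
    storage.mode(vals) <- "numeric"
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(path, ": missing value at line ", bad[1] + 1L, ", column ",
         bad[2] + 1L, call. = FALSE)
  }
  rownames(vals) <- ids
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpression}} (bit-identical round trip up to
#' numeric formatting; full precision is written).
#'
#' @param mat numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @export
writeExpression <- function(mat, path) {
  .check_expression(mat)
  dt <- data.table::data.table(gene_id = rownames(mat), mat)
  data.table::fwrite(dt, path, sep = "\t") # nolint
  invisible(path)
}

#' Read named gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated name, description, then
#' member genes.  Blank lines are skipped with a warning; an entry with no
#' members is an error.  Member order is preserved; unknown genes are kept
#' and validated at the point of use.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      warning(path, ": blank line ", i, " skipped")
      next
    }
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(path, ": line ", i, " has no member genes", call. = FALSE)
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional vector of per-set descriptions.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read per-gene thresholds as TSV
#'
#' @param thresholds data.frame from \code{\link{thresholdMatrix}}.
#' @param path file path.
#' @export
writeThresholds <- function(thresholds, path) {
  data.table::fwrite(thresholds, path, sep = "\t")
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write discovered implications as a TSV edge list
#'
#' @param records data.frame from \code{\link{discoverImplications}}.
#' @param path file path.
#' @export
writeImplications <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

#' @rdname writeImplications
#' @export
readImplications <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(
                                    character = c("gene_a", "gene_b",
                                                  "relation"))))
}

#' Serialize a clustered network to JSON
#'
#' Writes clusters, representatives and the typed edge table.  The inverse
#' reader restores an identical \linkS4class{ClusteredBooleanNetwork}.
#'
#' @param cbin a \linkS4class{ClusteredBooleanNetwork}.
#' @param path JSON file path.
#' @export
writeCBIN <- function(cbin, path) {
  jsonlite::write_json(
    list(clusters = geneClusters(cbin),
         representatives = as.list(representatives(cbin)),
         edges = clusterEdges(cbin)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCBIN
#' @export
readCBIN <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- lapply(x$clusters, as.character)
  edges <- if (length(x$edges)) as.data.frame(x$edges) else
    data.frame(cluster_a = character(), cluster_b = character(),
               relation = character(), support = integer(),
               sampled = integer(), stringsAsFactors = FALSE)
  edges$support <- as.integer(edges$support)
  edges$sampled <- as.integer(edges$sampled)
  new("ClusteredBooleanNetwork", clusters = clusters,
      representatives = unlist(x$representatives), edges = edges)
}

#' Read a survival table (sample_id, time, event) from TSV
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readSurvival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(character = 1)))
  if (!all(c("sample_id", "time", "event") %in% names(d)))
    stop(path, ": columns sample_id, time, event required", call. = FALSE)
  if (any(d$time < 0) || !all(d$event %in% 0:1))
    stop(path, ": time must be >= 0 and event in {0,1}", call. = FALSE)
  d
}
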