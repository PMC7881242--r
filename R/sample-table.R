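#' Construct a SampleTable
#'
#' @param values numeric matrix, samples in rows, variables in columns;
#'   rownames are sample ids, colnames variable names.
#' @param date optional `Date` vector (one per sample) for time-indexed
#'   tables.
#' @param lon,lat optional numeric station coordinates in degrees.
#' @param varType named character vector giving each variable's type
#'   (`"taxon"`, `"group"` or `"env"`); variables not named default to
#'   `"taxon"`.
#' @return A [SampleTable-class] object.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 5, 3, 4), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("Acartia", "SST")))
#' SampleTable(m, date = as.Date("2000-01-01") + 0:2,
#'             varType = c(SST = "env"))
SampleTable <- function(values, date = NULL, lon = NULL, lat = NULL,
                        varType = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  vt <- setNames(rep("taxon", ncol(values)), colnames(values))
  if (!is.null(varType)) {
    unknown <- setdiff(names(varType), colnames(values))
    if (length(unknown))
      stop("varType names unknown variables: ", paste(unknown, collapse = ", "))
    vt[names(varType)] <- varType
  }
  new("SampleTable",
      values = values,
      date = if (is.null(date)) as.Date(character(0)) else as.Date(date),
      lon = if (is.null(lon)) numeric(0) else as.numeric(lon),
      lat = if (is.null(lat)) numeric(0) else as.numeric(lat),
      varType = vt)
}

#' @rdname SampleTable-class
#' @exportMethod sampleValues
setMethod("sampleValues", "SampleTable", function(x) x@values)

#' @rdname SampleTable-class
#' @exportMethod sampleDates
setMethod("sampleDates", "SampleTable", function(x) x@date)

#' @rdname SampleTable-class
#' @exportMethod variableTypes
setMethod("variableTypes", "SampleTable", function(x) x@varType[colnames(x@values)])

#' @rdname SampleTable-class
#' @exportMethod variableNames
setMethod("variableNames", "SampleTable", function(x) colnames(x@values))

#' @rdname SampleTable-class
#' @exportMethod nrow
setMethod("nrow", "SampleTable", function(x) base::nrow(x@values))

#' @describeIn SampleTable-class subset samples (i) and/or variables (j).
#' @param i,j,drop,... subsetting indices (drop is ignored).
#' @exportMethod [
setMethod("[", "SampleTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(i)) i <- match(i, rownames(x@values))
  ii <- seq_len(nrow(x@values))[i]
  v <- x@values[ii, j, drop = FALSE]
  new("SampleTable", values = v,
      date = if (length(x@date)) x@date[ii] else x@date,
      lon = if (length(x@lon)) x@lon[ii] else x@lon,
      lat = if (length(x@lat)) x@lat[ii] else x@lat,
      varType = x@varType[colnames(v)])
})

setMethod("show", "SampleTable", function(object) {
  v <- object@values
  cat(sprintf("SampleTable: %d samples x %d variables\n", nrow(v), ncol(v)))
  tt <- table(factor(object@varType[colnames(v)],
                     levels = c("taxon", "group", "env")))
  cat(sprintf("  variables: %d taxon, %d group, %d env\n",
              tt["taxon"], tt["group"], tt["env"]))
  if (length(object@date))
    cat(sprintf("  dates: %s .. %s\n", min(object@date), max(object@date)))
  if (length(object@lon))
    cat(sprintf("  stations: lon %.2f..%.2f, lat %.2f..%.2f\n",
                min(object@lon), max(object@lon),
                min(object@lat), max(object@lat)))
})

#' Read a SampleTable from delimited text
#'
#' Expects a header row; a column of sample ids, optionally a date column
#' (ISO-8601) and lon/lat columns, and one numeric column per variable.
#'
#' @param path file path of a CSV (or TSV, see `sep`).
#' @param taxa character vector of taxon/abundance column names.
#' @param env character vector of environmental column names (may be empty).
#' @param idColumn,dateColumn,lonColumn,latColumn column names; `NULL` for
#'   absent (id defaults to `"sample_id"`; a missing id column falls back to
#'   row numbers).
#' @param sep field separator, default comma.
#' @return A [SampleTable-class].
#' @export
readSampleTable <- function(path, taxa, env = character(0),
                            idColumn = "sample_id", dateColumn = NULL,
                            lonColumn = NULL, latColumn = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(taxa, env, dateColumn, lonColumn, latColumn))
    if (!col %in% names(df))
      stop("declared column missing from ", path, ": '", col, "'")
  ids <- if (!is.null(idColumn) && idColumn %in% names(df))
    as.character(df[[idColumn]]) else as.character(seq_len(nrow(df)))
  vars <- c(taxa, env)
  vals <- suppressWarnings(
    vapply(df[vars], function(x) as.numeric(x), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(ids, vars))
  badTaxa <- rowSums(is.na(vals[, taxa, drop = FALSE])) > 0
  if (any(badTaxa)) {
    warning(sum(badTaxa), " row(s) with unparseable taxon counts rejected")
    vals <- vals[!badTaxa, , drop = FALSE]
    df <- df[!badTaxa, , drop = FALSE]
    ids <- ids[!badTaxa]
  }
  neg <- which(vals[, taxa, drop = FALSE] < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative count for '", taxa[neg[1, 2]], "' in row '",
         ids[neg[1, 1]], "'")
  SampleTable(vals,
              date = if (!is.null(dateColumn)) as.Date(df[[dateColumn]]),
              lon = if (!is.null(lonColumn)) df[[lonColumn]],
              lat = if (!is.null(latColumn)) df[[latColumn]],
              varType = setNames(rep("env", length(env)), env))
}

#' Write a SampleTable as CSV
#'
#' The writer is bit-stable: identical tables produce identical files.
#'
#' @param x a [SampleTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(x, path) {
  stopifnot(is(x, "SampleTable"))
  df <- data.frame(sample_id = rownames(x@values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (length(x@date)) df$date <- format(x@date, "%Y-%m-%d")
  if (length(x@lon)) { df$lon <- x@lon; df$lat <- x@lat }
  df <- cbind(df, as.data.frame(x@values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
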