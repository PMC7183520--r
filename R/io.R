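LISTMODE_MAGIC <- charToRaw("PETLM1\n")

#' Write a listmode dataset
#'
#' Two dialects: `"text"` -- '#'-prefixed metadata header (JSON) followed
#' by a tab-separated table with a column-name header (units in the
#' names); `"binary"` -- magic bytes, format version, JSON metadata block,
#' then typed little-endian column blocks. The binary dialect round-trips
#' bit-exactly; the text dialect is exact to the printed precision (times
#' are written with 17 significant digits, so doubles survive).
#'
#' @param dataset A [listmode_dataset()].
#' @param path Output path.
#' @param dialect `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(dataset, path, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  rec <- dataset$records
  meta_json <- jsonlite::toJSON(dataset$meta, auto_unbox = TRUE, digits = NA,
                                null = "null")
  if (dialect == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# petlm listmode v1",
                 paste0("# meta ", meta_json),
                 paste(names(rec), collapse = "\t")), con)
    if (nrow(rec)) {
      fmt <- vapply(rec, function(col) {
        if (is.double(col)) "%.17g" else "%s"
      }, character(1))
      lines <- do.call(paste, c(lapply(seq_along(rec), function(k) {
        col <- rec[[k]]
        if (is.double(col)) sprintf(fmt[k], col) else as.character(col)
      }), sep = "\t"))
      writeLines(lines, con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(LISTMODE_MAGIC, con)
    writeBin(1L, con, size = 4, endian = "little")
    mb <- charToRaw(as.character(meta_json))
    writeBin(length(mb), con, size = 4, endian = "little")
    writeBin(mb, con)
    writeBin(nrow(rec), con, size = 4, endian = "little")
    writeBin(ncol(rec), con, size = 4, endian = "little")
    for (nm in names(rec)) {
      col <- rec[[nm]]
      type <- if (is.double(col)) 1L else if (is.integer(col)) 2L else 3L
      nb <- charToRaw(nm)
      writeBin(length(nb), con, size = 4, endian = "little")
      writeBin(nb, con)
      writeBin(type, con, size = 4, endian = "little")
      if (type == 1L) writeBin(col, con, size = 8, endian = "little")
      else if (type == 2L) writeBin(col, con, size = 4, endian = "little")
      else {
        enc <- paste(col, collapse = "\n")
        eb <- charToRaw(enc)
        writeBin(length(eb), con, size = 4, endian = "little")
        writeBin(eb, con)
      }
    }
  }
  invisible(path)
}

#' Read a listmode dataset
#'
#' Auto-detects the dialect from the leading bytes.
#'
#' @param path File written by [write_listmode()].
#' @return A [listmode_dataset()].
#' @export
read_listmode <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head <- readBin(path, "raw", length(LISTMODE_MAGIC))
  if (identical(head, LISTMODE_MAGIC)) read_listmode_bin(path)
  else read_listmode_text(path)
}

read_listmode_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "# petlm listmode"))
    stop("malformed listmode header in ", path)
  meta <- jsonlite::fromJSON(sub("^# meta ", "", lines[2]))
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:3)]
  if (length(body)) {
    rec <- data.table::fread(text = c(lines[3], body), sep = "\t",
                             colClasses = listmode_classes(header))
  } else {
    rec <- empty_coincidences()[, header, with = FALSE]
  }
  structure(list(records = rec, meta = meta), class = "listmode_dataset")
}

listmode_classes <- function(header) {
  proto <- empty_coincidences()
  vapply(header, function(nm) {
    if (nm %in% names(proto)) class(proto[[nm]])[1] else "numeric"
  }, character(1))
}

read_listmode_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(LISTMODE_MAGIC))
  if (!identical(magic, LISTMODE_MAGIC))
    stop("bad magic bytes at offset 0 in ", path)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(ver, 1L)) stop("unsupported listmode version ", ver)
  ml <- readBin(con, "integer", 1, size = 4, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", ml)))
  nr <- readBin(con, "integer", 1, size = 4, endian = "little")
  nc <- readBin(con, "integer", 1, size = 4, endian = "little")
  cols <- vector("list", nc)
  nms <- character(nc)
  for (k in seq_len(nc)) {
    nl <- readBin(con, "integer", 1, size = 4, endian = "little")
    nms[k] <- rawToChar(readBin(con, "raw", nl))
    type <- readBin(con, "integer", 1, size = 4, endian = "little")
    cols[[k]] <- switch(as.character(type),
      "1" = readBin(con, "double", nr, size = 8, endian = "little"),
      "2" = readBin(con, "integer", nr, size = 4, endian = "little"),
      "3" = {
        el <- readBin(con, "integer", 1, size = 4, endian = "little")
        s <- rawToChar(readBin(con, "raw", el))
        if (nr == 0) character(0) else strsplit(s, "\n", fixed = TRUE)[[1]]
      },
      stop("unknown column type ", type, " at byte ", seek(con)))
    if (length(cols[[k]]) != nr)
      stop("truncated column '", nms[k], "' at byte ", seek(con))
  }
  rec <- data.table::as.data.table(stats::setNames(cols, nms))
  structure(list(records = rec, meta = meta), class = "listmode_dataset")
}
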