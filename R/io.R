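## Corpus and embedding I/O --------------------------------------------------
##
## Corpora round-trip through JSONL (one UTF-8 JSON object per line) or TSV
## (header row; unescaped tabs in text are rejected). Embedding matrices are
## stored as raw little-endian float32 with a JSON sidecar carrying n, dim,
## ids, the normalize flag and an encoder fingerprint.

#' Write a sentence corpus to JSONL or TSV
#'
#' @param corpus A `sentence_corpus` data frame (columns `text`, `label`,
#'   `abstract_id`, `sentence_index`; `label` may be `NA`).
#' @param path Output path; format chosen by extension (`.jsonl` or `.tsv`)
#'   unless `format` is given.
#' @param format `"jsonl"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  stopifnot(is.data.frame(corpus))
  need <- c("text", "abstract_id", "sentence_index")
  if (!all(need %in% names(corpus))) {
    stop("corpus must have columns text, abstract_id, sentence_index",
         call. = FALSE)
  }
  if (is.null(corpus$label)) corpus$label <- NA_character_
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(
        text = corpus$text[i],
        label = if (is.na(corpus$label[i])) NULL else corpus$label[i],
        abstract_id = corpus$abstract_id[i],
        sentence_index = as.integer(corpus$sentence_index[i])
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  } else {
    if (any(grepl("\t", corpus$text, fixed = TRUE))) {
      bad <- which(grepl("\t", corpus$text, fixed = TRUE))[1L]
      stop(sprintf("TSV dialect forbids unescaped tabs (record %d)", bad),
           call. = FALSE)
    }
    header <- "text\tlabel\tabstract_id\tsentence_index"
    body <- paste(corpus$text,
                  ifelse(is.na(corpus$label), "", corpus$label),
                  corpus$abstract_id,
                  as.integer(corpus$sentence_index), sep = "\t")
    writeLines(enc2utf8(c(header, body)), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a sentence corpus from JSONL or TSV
#'
#' Malformed lines are reported with their line numbers; no partial corpus is
#' returned silently.
#'
#' @param path Input path.
#' @param format `"jsonl"` or `"tsv"` (default: by extension).
#' @return A `sentence_corpus` data frame.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "jsonl") {
    recs <- vector("list", length(lines))
    bad <- integer(0)
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$text) || is.null(rec$abstract_id) ||
          is.null(rec$sentence_index)) {
        bad <- c(bad, i)
      } else {
        recs[[i]] <- rec
      }
    }
    if (length(bad) > 0L) {
      stop(sprintf("malformed JSONL at line(s): %s",
                   paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    corp <- data.frame(
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      label = vapply(recs, function(r) {
        if (is.null(r$label)) NA_character_ else as.character(r$label)
      }, character(1)),
      abstract_id = vapply(recs, function(r) as.character(r$abstract_id),
                           character(1)),
      sentence_index = vapply(recs, function(r) as.integer(r$sentence_index),
                              integer(1)),
      stringsAsFactors = FALSE
    )
  } else {
    if (length(lines) < 1L) stop("empty TSV file", call. = FALSE)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("text", "label", "abstract_id", "sentence_index")
    if (!all(need %in% header)) {
      stop("TSV header must contain: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    body <- lines[-1L]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    ## a trailing empty label drops the field on split; pad to header width
    fields <- lapply(fields, function(f) c(f, rep("", length(header)))[
      seq_along(header)])
    bad <- which(nf > length(header))
    if (length(bad) > 0L) {
      stop(sprintf("malformed TSV (extra tab?) at line(s): %s",
                   paste(head(bad + 1L, 10L), collapse = ", ")),
           call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    colnames(mat) <- header
    corp <- data.frame(
      text = mat[, "text"],
      label = ifelse(nzchar(mat[, "label"]), mat[, "label"], NA_character_),
      abstract_id = mat[, "abstract_id"],
      sentence_index = as.integer(mat[, "sentence_index"]),
      stringsAsFactors = FALSE
    )
  }
  rownames(corp) <- NULL
  structure(corp, class = c("sentence_corpus", "data.frame"))
}

#' Write an embedding matrix to a float32 store
#'
#' The matrix is written row-major as little-endian float32 to `path`, with a
#' JSON sidecar `<path>.json` recording `n`, `dim`, `ids`, the `normalize`
#' flag and an optional encoder `fingerprint`.
#'
#' @param values Numeric matrix (rows are sentences; rownames used as ids if
#'   `ids` is missing).
#' @param path Output path for the binary block.
#' @param ids Sentence ids (default rownames, else `s000001`, ...).
#' @param normalize Whether rows are unit-normalized.
#' @param fingerprint Free-form encoder fingerprint string.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(values, path, ids = NULL, normalize = TRUE,
                             fingerprint = "") {
  stopifnot(is.matrix(values))
  if (is.null(ids)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- sprintf("s%06d", seq_len(nrow(values)))
  }
  stopifnot(length(ids) == nrow(values))
  con <- file(path, open = "wb")
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  close(con)
  sidecar <- list(n = nrow(values), dim = ncol(values), ids = ids,
                  normalize = normalize, fingerprint = fingerprint)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embeddings()]
#'
#' @param path Path to the binary block (sidecar `<path>.json` must exist).
#' @return A list with `values` (matrix with rownames = ids), `normalize`,
#'   and `fingerprint`.
#' @export
read_embeddings <- function(path) {
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- as.integer(sidecar$n)
  d <- as.integer(sidecar$dim)
  con <- file(path, open = "rb")
  vals <- readBin(con, numeric(), n = n * d, size = 4L, endian = "little")
  close(con)
  values <- matrix(vals, n, d, byrow = TRUE)
  rownames(values) <- sidecar$ids
  list(values = values, normalize = isTRUE(sidecar$normalize),
       fingerprint = as.character(sidecar$fingerprint))
}
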