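## FASTA input/output and the external tables (predictions, annotations).
##
## Coordinate convention: 0-based starts internally, 1-based inclusive
## ranges in every external file; each written table states the convention
## in a '#coords=' header line.

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into an [Biostrings::AAStringSet], validating the
#' alphabet: residues must be one of the 20 standard amino acids or X.
#' Sequences are upper-cased, a single terminal stop character `*` is
#' stripped, record order is preserved and duplicated ids are an error
#' (downstream joins are id-keyed).
#'
#' @param path FASTA file.
#' @return An `AAStringSet` with one element per record.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no sequences in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1L]))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "", fixed = TRUE)[[1]]),
                   c(AA20, "X"))
    if (length(bad))
      stop(sprintf("illegal character '%s' in record '%s'", bad[1L], ids[i]))
    if (!nzchar(seqs[i]))
      stop(sprintf("empty sequence in record '%s'", ids[i]))
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector or `AAStringSet`.
#' @param path output file.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::AAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## Canonical empty motif-call table.
emptyCalls <- function() {
  data.frame(seqid = character(0), motif = character(0),
             start = integer(0), prob = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write motif calls to TSV or JSON
#'
#' Calls use internal 0-based starts; files are written 1-based inclusive
#' (`end = start + motif length - 1`), stated in the `#coords=` header.
#' Rows are grouped by sequence id and ordered by position; probabilities
#' are printed with 4 decimals.
#'
#' @param calls data.frame with columns `seqid`, `motif`, `start` (0-based),
#'   `prob`.
#' @param path output file.
#' @param registry a [MotifRegistry-class] supplying motif lengths.
#' @param format `"tsv"` or `"json"`.
#' @export
writePredictions <- function(calls, path, registry = defaultRegistry(),
                             format = c("tsv", "json")) {
  format <- match.arg(format)
  d <- registryTable(registry)
  calls <- as.data.frame(calls)
  if (nrow(calls)) {
    calls <- calls[order(calls$seqid, calls$start), , drop = FALSE]
    L <- d$length[match(calls$motif, d$name)]
    if (anyNA(L)) stop("calls contain motifs unknown to the registry")
    out <- data.frame(seqid = calls$seqid, motif = calls$motif,
                      start = calls$start + 1L,
                      end = calls$start + L,
                      probability = round(calls$prob, 4),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(seqid = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      probability = numeric(0))
  }
  if (format == "tsv") {
    fout <- out
    fout$probability <- sprintf("%.4f", out$probability)
    if (!nrow(out)) fout$probability <- character(0)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#coords=1-based-inclusive", con)
    utils::write.table(fout, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(coords = "1-based-inclusive", calls = out),
                         path, auto_unbox = TRUE, digits = 4)
  }
  invisible(path)
}

#' Read / write motif annotation tables
#'
#' Annotation tables carry training labels or curated motif positions:
#' columns `seqid`, `motif`, `start`, `end`. Files are 1-based inclusive
#' (declared by the `#coords=` header); in memory starts are 0-based and
#' `end` is dropped (lengths come from the registry).
#'
#' @param path TSV path.
#' @param table data.frame with columns `seqid`, `motif`, `start` (0-based).
#' @param registry registry used to compute `end` on write and to validate
#'   motif names on read.
#' @return `readAnnotationTable` returns a data.frame with 0-based `start`.
#' @export
readAnnotationTable <- function(path, registry = defaultRegistry()) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  coords <- "1-based-inclusive"
  if (length(meta)) {
    tag <- grep("^#coords=", lines[meta], value = TRUE)
    if (length(tag)) coords <- sub("^#coords=", "", tag[1L])
  }
  body <- if (length(meta)) lines[-meta] else lines
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (!all(c("seqid", "motif", "start") %in% names(tab)))
    stop("annotation table needs columns seqid, motif, start")
  unknown <- setdiff(unique(tab$motif), registryTable(registry)$name)
  if (length(unknown))
    stop(sprintf("unknown motif name(s): %s", paste(unknown, collapse = ", ")))
  tab$start <- as.integer(tab$start) -
    if (identical(coords, "1-based-inclusive")) 1L else 0L
  if (any(tab$start < 0L)) stop("negative start after coordinate conversion")
  tab[c("seqid", "motif", "start")]
}

#' @rdname readAnnotationTable
#' @export
writeAnnotationTable <- function(table, path, registry = defaultRegistry()) {
  d <- registryTable(registry)
  L <- d$length[match(table$motif, d$name)]
  if (anyNA(L)) stop("table contains motifs unknown to the registry")
  out <- data.frame(seqid = table$seqid, motif = table$motif,
                    start = table$start + 1L, end = table$start + L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=1-based-inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
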