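#' Read and write the pipeline's on-disk formats
#'
#' Thin, deterministic wrappers around Biostrings and rtracklayer for the
#' standard formats, plus tab-separated tables and flat key-value run
#' configuration files. Writers and readers are mutually inverse on
#' simulator output.
#'
#' @param x Named character vector of sequences.
#' @param path File path; `.gz` suffixes are honored.
#' @return `read_fasta` returns a named character vector.
#' @name io
NULL

#' @rdname io
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname io
#' @export
write_rna_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(x), path)
  invisible(path)
}

#' @rdname io
#' @export
read_rna_fasta <- function(path) {
  ss <- Biostrings::readRNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname io
#' @param reads Named character vector of read sequences (names become read
#'   ids); qualities are written as a constant high score.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    qual <- strrep("I", nchar(reads))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0L) {
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), names(ss))
}

#' @rdname io
#' @param exons Exon table (see [validate_exons()]).
#' @export
write_gtf <- function(exons, path) {
  rtracklayer::export(exons_to_granges(exons), path, format = "gtf")
  invisible(path)
}

#' @rdname io
#' @export
read_gtf <- function(path) {
  granges_to_exons(rtracklayer::import(path, format = "gtf"))
}

#' @rdname io
#' @param df A data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read/write a flat key=value run configuration file
#'
#' Values are stored one per line as `key = value`; vector values are
#' comma-separated and named vectors use `name:value` items
#' (e.g. `groups = healthy:4,patient:6`).
#'
#' @param path File path.
#' @return `read_run_config` returns a named list of character vectors.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stopf("malformed config line: %s", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(grepl(":", items, fixed = TRUE))) {
      parts <- strsplit(items, ":", fixed = TRUE)
      v <- vapply(parts, `[`, "", 2L)
      names(v) <- vapply(parts, `[`, "", 1L)
      out[[key]] <- v
    } else {
      out[[key]] <- items
    }
  }
  out
}

#' @rdname read_run_config
#' @param cfg Named list of scalar or vector values.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    val <- if (!is.null(names(v)) && all(nzchar(names(v)))) {
      paste(paste0(names(v), ":", v), collapse = ",")
    } else {
      paste(v, collapse = ",")
    }
    paste0(k, " = ", val)
  }, "")
  writeLines(fmt, path)
  invisible(path)
}
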