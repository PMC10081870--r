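#' Read sequences from a FASTA file
#'
#' Multi-record FASTA; residues are folded to uppercase and validated
#' against the 15 IUPAC nucleotide codes. Anything else (gaps, `*`, stray
#' symbols) is an error naming the record and offset, unless
#' `coerce = TRUE`, which replaces such symbols by `N`.
#'
#' @param path FASTA file path.
#' @param coerce Replace non-IUPAC symbols by `N` instead of erroring.
#' @return A tibble with columns `seq_id`, `seq` and `length`.
#' @export
read_fasta <- function(path, coerce = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- vapply(seq_along(seqs), function(i) {
    chars <- split_chars(seqs[i])
    bad <- which(!(chars %in% names(IUPAC_MASKS)))
    if (length(bad)) {
      if (!coerce) {
        abort(sprintf(
          "record '%s': symbol '%s' at offset %d is not an IUPAC nucleotide code (use coerce = TRUE to replace with N)",
          ids[i], chars[bad[1]], bad[1]),
          class = "dipwmscan_input_error")
      }
      chars[bad] <- "N"
    }
    paste(chars, collapse = "")
  }, character(1))
  tibble(seq_id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param sequences A tibble with `seq_id` and `seq` columns (or anything
#'   [search_dipwm()] accepts as sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqs <- as_sequences(sequences)
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write occurrences to TSV or BED6
#'
#' TSV: 1-based inclusive coordinates, columns `seq_id`, `start`, `end`,
#' `strand`, `word`, `score` plus `pvalue`/`ambiguous` when present, behind
#' a single `#` header line recording the tool version, matrix name and
#' resolved threshold. BED6: 0-based half-open, with the BED score column
#' the motif score rescaled to `round(1000 * (score - score_min) /
#' (score_max - score_min))`, clamped to `[0, 1000]` (requires `x`).
#'
#' @param occs Occurrence tibble from [search_dipwm()] (possibly
#'   [annotate_occurrences()]d).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param x The [dipwm], needed for the BED score rescaling.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occs, path, format = c("tsv", "bed"), x = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(occs))
  if (format == "tsv") {
    cols <- intersect(c("seq_id", "start", "end", "strand", "word", "score",
                        "pvalue", "ambiguous"), names(occs))
    hdr <- sprintf("# dipwmscan %s\tmatrix=%s\tthreshold=%s",
                   as.character(packageVersion("dipwmscan")),
                   attr(occs, "dipwm_name") %||% "NA",
                   format(attr(occs, "threshold") %||% NA))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(occs)) {
      df <- occs[cols]
      df$score <- formatC(df$score, digits = 10, format = "g")
      if ("pvalue" %in% cols) {
        df$pvalue <- formatC(df$pvalue, digits = 6, format = "g")
      }
      writeLines(do.call(paste, c(as.list(df), sep = "\t")), con)
    }
  } else {
    if (is.null(x)) {
      abort("BED output needs the di-PWM to rescale scores",
            class = "dipwmscan_input_error")
    }
    ex <- score_extrema(x)
    span <- ex[["score_max"]] - ex[["score_min"]]
    bedscore <- if (span > 0) {
      pmin(1000, pmax(0, round(1000 * (occs$score - ex[["score_min"]]) / span)))
    } else rep(0L, nrow(occs))
    df <- data.frame(chrom = occs$seq_id, chromStart = occs$start - 1L,
                     chromEnd = occs$end, name = occs$word,
                     score = as.integer(bedscore), strand = occs$strand)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a TSV occurrence file
#'
#' @param path A file written by [write_occurrences()] in TSV format.
#' @return An occurrence tibble.
#' @export
read_occurrences <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), word = character(), score = numeric()))
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
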