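#' Read a FASTQ file
#'
#' Parses a standard four-line-per-record FASTQ file (Sanger / Phred+33
#' qualities), plain or gzip-compressed, into a data frame with one row per
#' read.
#'
#' @param path Path to a FASTQ file (`.gz` handled transparently).
#' @return A data frame with character columns `read_id` (without the leading
#'   `@`), `sequence` and `quality`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  con <- text_connection(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L)
    stopf("malformed FASTQ '%s': %d lines is not a multiple of 4 (record %d truncated)",
          path, n, n %/% 4L + 1L)
  if (n == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  heads <- lines[seq(1L, n, by = 4L)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stopf("malformed FASTQ '%s': record %d header does not start with '@'",
          path, bad[1L])
  plus <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stopf("malformed FASTQ '%s': record %d separator line does not start with '+'",
          path, bad[1L])
  seqs  <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stopf("malformed FASTQ '%s': record %d sequence and quality lengths differ",
          path, bad[1L])
  data.frame(read_id = substring(heads, 2L), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Count records in a FASTQ file
#'
#' Streams the file in chunks (constant memory) and returns the number of
#' reads, validating the four-line record structure on the way.
#'
#' @inheritParams read_fastq
#' @return Integer: the number of records `k`.
#' @export
count_fastq_reads <- function(path) {
  con <- text_connection(path, "rt")
  on.exit(close(con))
  k <- 0L
  tail_lines <- 0L
  repeat {
    lines <- readLines(con, n = 40000L)   # multiple of 4: records never split
    if (!length(lines)) break
    n <- length(lines)
    full <- n %/% 4L
    if (full) {
      heads <- lines[seq(1L, full * 4L, by = 4L)]
      bad <- which(!startsWith(heads, "@"))
      if (length(bad))
        stopf("malformed FASTQ '%s': record %d header does not start with '@'",
              path, k + bad[1L])
      k <- k + full
    }
    tail_lines <- n %% 4L
  }
  if (tail_lines)
    stopf("malformed FASTQ '%s': trailing partial record %d (%d stray line%s)",
          path, k + 1L, tail_lines, if (tail_lines > 1L) "s" else "")
  k
}

#' Write FASTQ records
#'
#' Writes records in standard four-line format; round-trips losslessly through
#' [read_fastq()]. Records must satisfy the FASTQ invariants: equal sequence
#' and quality length, and a sequence alphabet within `A,C,G,T,N` (either
#' case).
#'
#' @param records Data frame with columns `read_id`, `sequence`, `quality`
#'   (as returned by [read_fastq()]).
#' @param path Output path; a `.gz` suffix compresses the output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("read_id", "sequence", "quality") %in% names(records)))
  if (nrow(records)) {
    bad <- which(nchar(records$sequence) != nchar(records$quality))
    if (length(bad))
      stopf("record %d: sequence and quality lengths differ", bad[1L])
    bad <- which(!grepl("^[ACGTNacgtn]*$", records$sequence))
    if (length(bad))
      stopf("record %d: sequence contains characters outside {A,C,G,T,N}", bad[1L])
  }
  con <- text_connection(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    out <- rbind(paste0("@", records$read_id), records$sequence, "+",
                 records$quality)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Bootstrap sequencing reads from FASTQ files (FB approach)
#'
#' Generates an artificial technical replicate of a sequencing run by drawing
#' `m = round(pi * k)` reads with replacement from the `k` reads of the
#' original FASTQ file. A read can therefore appear several times in the
#' replicate, or not at all. With `pi = 1` the replicate has as many reads as
#' the original file; smaller values of `pi` trade fidelity for speed and
#' storage.
#'
#' The implementation is two-pass and streaming: the first pass counts `k`,
#' then `m` uniform indices are drawn with a seeded generator, and the second
#' pass re-emits each record as many times as it was drawn. Output order is
#' input order, quality strings are carried verbatim, and paired mates share
#' one index sample so pairing is preserved.
#'
#' @param input Path to the (R1) FASTQ file, plain or gzip.
#' @param output Path for the bootstrapped (R1) FASTQ file.
#' @param pi Fraction of reads to draw, in (0, 1]. `round()` (round half to
#'   even) maps `pi * k` to the integer `m`; `m` is at least 1 when `k >= 1`.
#' @param seed Integer seed; identical `(input, pi, seed)` give byte-identical
#'   output.
#' @param input2,output2 Optional mate (R2) files for paired-end data; both
#'   mates are subsampled with the same index vector.
#' @param rename_duplicates When a read is emitted more than once, append
#'   `/bsN` (N = 2, 3, ...) to its id so downstream tools that require unique
#'   ids still work. Set to `FALSE` to keep ids verbatim.
#' @param manifest_path Optional path; when given, the manifest is also
#'   written there as JSON.
#' @return A `bootstrap_manifest` object (list with `strategy`, `k`, `pi`,
#'   `m`, `seed`, `inputs`, `outputs`, `paired`).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(as.vector(rbind(paste0("@r", 1:10), "ACGTACGT", "+", "IIIIIIII")), fq)
#' out <- tempfile(fileext = ".fastq")
#' bootstrap_fastq(fq, out, pi = 0.5, seed = 1)
#' @export
bootstrap_fastq <- function(input, output, pi = 1, seed = 1,
                            input2 = NULL, output2 = NULL,
                            rename_duplicates = TRUE, manifest_path = NULL) {
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi <= 0 || pi > 1)
    stopf("'pi' must be a single number in (0, 1], got %s", format(pi))
  paired <- !is.null(input2)
  if (paired && is.null(output2))
    stopf("paired input requires 'output2'")
  k <- count_fastq_reads(input)
  if (paired) {
    k2 <- count_fastq_reads(input2)
    if (k2 != k)
      stopf("paired FASTQ files have unequal read counts (%d vs %d)", k, k2)
  }
  m <- if (k >= 1L) max(1L, as.integer(round(pi * k))) else 0L
  times <- if (k >= 1L) {
    draws <- with_seed(seed, sample.int(k, m, replace = TRUE))
    tabulate(draws, nbins = k)
  } else integer(0)

  emit <- function(in_path, out_path) {
    con_in  <- text_connection(in_path, "rt")
    on.exit(close(con_in), add = TRUE)
    con_out <- text_connection(out_path, "wt")
    on.exit(close(con_out), add = TRUE)
    at <- 0L
    repeat {
      lines <- readLines(con_in, n = 40000L)
      if (!length(lines)) break
      nrec <- length(lines) %/% 4L
      cnt <- times[at + seq_len(nrec)]
      sel <- which(cnt > 0L)
      if (length(sel)) {
        idx <- rep.int(sel, cnt[sel])              # record index per emission
        occ <- sequence(cnt[sel])                  # occurrence number 1..cnt
        heads <- lines[(idx - 1L) * 4L + 1L]
        if (rename_duplicates && any(occ > 1L)) {
          dup <- which(occ > 1L)
          h <- heads[dup]
          sp <- regexpr(" ", h, fixed = TRUE)
          suffixed <- paste0(substr(h, 1L, ifelse(sp > 0L, sp - 1L, nchar(h))),
                             "/bs", occ[dup],
                             ifelse(sp > 0L, substring(h, sp), ""))
          heads[dup] <- suffixed
        }
        out <- rbind(heads,
                     lines[(idx - 1L) * 4L + 2L],
                     lines[(idx - 1L) * 4L + 3L],
                     lines[(idx - 1L) * 4L + 4L])
        writeLines(as.vector(out), con_out)
      }
      at <- at + nrec
    }
  }
  emit(input, output)
  if (paired) emit(input2, output2)

  manifest <- structure(list(
    strategy = "FB", k = k, pi = pi, m = m, seed = as.integer(seed),
    inputs = c(input, if (paired) input2),
    outputs = c(output, if (paired) output2),
    paired = paired, renamed_duplicates = rename_duplicates),
    class = "bootstrap_manifest")
  if (!is.null(manifest_path))
    jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  manifest
}

#' @export
print.bootstrap_manifest <- function(x, ...) {
  cat(sprintf("FASTQ bootstrap: drew m = %d of k = %d reads (pi = %s, seed = %d%s)\n",
              x$m, x$k, format(x$pi), x$seed,
              if (x$paired) ", paired" else ""))
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}
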