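#' Read genomic intervals from standard formats
#'
#' A single entry point for every on-disk interval format the pipeline
#' touches. BED is consumed as 0-based half-open and GFF3 / RepeatMasker
#' `.out` as 1-based inclusive; all are returned as `GRanges` (1-based
#' closed), so coordinate conventions are resolved at this boundary only.
#' BED, GFF3 and bedGraph parsing is delegated to \pkg{rtracklayer};
#' RepeatMasker output is parsed here (whitespace table after three header
#' lines).
#'
#' @param path File path.
#' @param format One of `"bed"`, `"gff"`, `"bedgraph"`, `"repeatmasker"`.
#' @return A `GRanges`. bedGraph carries a numeric `score` column; GFF
#'   attributes become metadata columns; RepeatMasker rows carry
#'   `repeat_name`, `repeat_class` (e.g. `"SINE/MIR"`) and `repeat_family`
#'   (e.g. `"SINE"`).
#' @export
read_intervals <- function(path, format = c("bed", "gff", "bedgraph", "repeatmasker")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- switch(format,
    bed = rtracklayer::import(path, format = "BED"),
    gff = rtracklayer::import(path, format = "GFF3"),
    bedgraph = rtracklayer::import(path, format = "bedGraph"),
    repeatmasker = read_repeatmasker(path)
  )
  if (any(width(gr) < 1L)) {
    stop("interval with end <= start after coordinate conversion in ", path)
  }
  gr
}

read_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("RepeatMasker file too short: ", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf < 11L)
  if (length(bad)) {
    stop("malformed RepeatMasker line ", bad[1] + 3L,
         ": expected >= 11 fields, found ", nf[bad[1]])
  }
  chrom <- vapply(fields, `[[`, character(1), 5L)
  begin <- as.integer(vapply(fields, `[[`, character(1), 6L))
  end <- as.integer(vapply(fields, `[[`, character(1), 7L))
  if (anyNA(begin) || anyNA(end)) {
    stop("malformed RepeatMasker coordinates (fields 6-7) in ", path)
  }
  strand <- vapply(fields, `[[`, character(1), 9L)
  strand[strand == "C"] <- "-"
  strand[!strand %in% c("+", "-")] <- "*"
  cls <- vapply(fields, `[[`, character(1), 11L)
  GRanges(chrom, IRanges(begin, end), strand = strand,
          repeat_name = vapply(fields, `[[`, character(1), 10L),
          repeat_class = cls,
          repeat_family = sub("/.*$", "", cls),
          score = as.numeric(vapply(fields, `[[`, character(1), 1L)))
}

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "numeric"))
  if (any(tab$size <= 0)) stop("non-positive chromosome size in ", path)
  setNames(tab$size, tab$chrom)
}

#' @rdname read_chrom_sizes
#' @param genome Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(paste(names(genome), format_num(genome), sep = "\t"), path)
  invisible(path)
}

# fixed-notation number formatting shared by all writers (determinism,
# no scientific notation in genomic coordinates)
format_num <- function(x, digits = NULL) {
  if (!is.numeric(x)) return(as.character(x))
  if (!is.null(digits)) x <- round(x, digits)
  format(x, trim = TRUE, scientific = FALSE, justify = "none")
}

#' Write intervals as BED (0-based half-open)
#'
#' Emits canonical BED3 for bare intervals, BED6 when any of name, score or
#' strand is informative, and appends any `extra_cols` from `mcols` after
#' column 6. Deterministic, byte-stable output.
#'
#' @param x A `GRanges`. `mcols(x)$name` and `mcols(x)$score` populate BED
#'   columns 4-5 when present.
#' @param path Output path.
#' @param extra_cols Character vector of `mcols` column names to append.
#' @export
write_bed <- function(x, path, extra_cols = character()) {
  chrom <- as.character(seqnames(x))
  out <- paste(chrom, format_num(start(x) - 1L), format_num(end(x)), sep = "\t")
  has_name <- !is.null(mcols(x)$name)
  has_score <- !is.null(mcols(x)$score)
  has_strand <- any(as.character(strand(x)) != "*")
  if (has_name || has_score || has_strand || length(extra_cols)) {
    nm <- if (has_name) as.character(mcols(x)$name) else rep(".", length(x))
    sc <- if (has_score) format_num(mcols(x)$score, digits = 4) else rep("0", length(x))
    st <- as.character(strand(x))
    st[st == "*"] <- "."
    out <- paste(out, nm, sc, st, sep = "\t")
  }
  for (col in extra_cols) {
    out <- paste(out, format_num(mcols(x)[[col]], digits = 4), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as GFF3 (1-based inclusive)
#'
#' @param x A `GRanges`; metadata columns named in `attr_cols` are written
#'   into column 9 as `key=value` pairs, after an `ID`.
#' @param path Output path.
#' @param source,type GFF columns 2 and 3.
#' @param attr_cols `mcols` columns to serialise as attributes.
#' @export
write_gff <- function(x, path, source = "sebodymap", type = "enhancer",
                      attr_cols = intersect(c("state", "signal"), names(mcols(x)))) {
  st <- as.character(strand(x))
  st[st == "*"] <- "."
  score <- if (!is.null(mcols(x)$signal)) format_num(mcols(x)$signal, digits = 4) else "."
  attrs <- paste0("ID=", type, "_", seq_along(x))
  for (col in attr_cols) {
    attrs <- paste0(attrs, ";", col, "=", format_num(mcols(x)[[col]], digits = 4))
  }
  lines <- paste(as.character(seqnames(x)), source, type,
                 format_num(start(x)), format_num(end(x)),
                 score, st, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' @param x A `GRanges` with a numeric `score` (or `signal`) column.
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  val <- mcols(x)$score
  if (is.null(val)) val <- mcols(x)$signal
  if (is.null(val)) stop("no 'score' or 'signal' column to write")
  lines <- paste(as.character(seqnames(x)),
                 format_num(start(x) - 1L), format_num(end(x)),
                 format_num(val, digits = 4), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals in RepeatMasker .out layout
#'
#' Three header lines followed by the whitespace-delimited table; only the
#' columns the pipeline consumes (coordinates, repeat name and class) carry
#' information.
#'
#' @param x A `GRanges` with `repeat_name` and `repeat_class` columns.
#' @param path Output path.
#' @export
write_repeatmasker <- function(x, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)  repeat    class/family  begin  end (left) ID",
    ""
  )
  st <- as.character(strand(x))
  st[st == "-"] <- "C"
  st[!st %in% c("+", "C")] <- "+"
  lines <- paste(" 1000", "10.0", "0.0", "0.0",
                 as.character(seqnames(x)),
                 format_num(start(x)), format_num(end(x)), "(0)",
                 st,
                 as.character(mcols(x)$repeat_name),
                 as.character(mcols(x)$repeat_class),
                 "1", format_num(width(x)), "(0)",
                 format_num(seq_along(x)))
  writeLines(c(header, lines), path)
  invisible(path)
}
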