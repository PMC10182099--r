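#' Write alignments as SAM
#'
#' Minimal SAM dialect: the 11 mandatory columns, an `@SQ` header per
#' chromosome, and FLAG bits for paired / strand / unmapped / mate
#' unmapped only. Coordinates are converted to the 1-based convention of
#' the format.
#'
#' @param aln alignment tibble from [map_reads()]; an optional `seq`
#'   column supplies the read sequence, and an optional `mate` column
#'   (1 or 2) sets the paired-end flag bits.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)),
              "@PG\tID:resectr\tPN:resectr")
  flag <- integer(nrow(aln))
  if (!is.null(aln[["mate"]])) {
    flag <- flag + 1L +                     # paired
      ifelse(aln[["mate"]] == 1L, 64L, 128L)
  }
  flag <- flag + ifelse(aln$mapped, 0L, 4L) +
    ifelse(!is.na(aln$strand) & aln$strand == "-", 16L, 0L)
  seq <- aln[["seq"]] %||% rep("*", nrow(aln))
  qual <- ifelse(seq == "*", "*", strrep("I", nchar(seq)))
  k <- ifelse(seq == "*", NA_integer_, nchar(seq))
  body <- paste(aln$read_id, flag,
                ifelse(aln$mapped, aln$chromosome, "*"),
                ifelse(aln$mapped, aln$start + 1L, 0L),
                ifelse(aln$mapped, ifelse(aln$unique, 255L, 0L), 0L),
                ifelse(aln$mapped, paste0(ifelse(is.na(k), 75L, k), "M"), "*"),
                "*", 0L, 0L, seq, qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Parses the 11 mandatory columns; optional tags are ignored. Malformed
#' records abort with the offending line number.
#'
#' @param path SAM path.
#' @return tibble (read_id, flag, mapped, chromosome, start, strand, seq)
#'   with 0-based `start`; attribute `chrom_lengths` from the `@SQ`
#'   header lines.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty SAM file")
  hdr <- startsWith(lines, "@")
  sq <- lines[hdr & startsWith(lines, "@SQ")]
  chrom_lengths <- NULL
  if (length(sq) > 0) {
    sn <- sub(".*SN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
    chrom_lengths <- setNames(ln, sn)
  }
  body <- lines[!hdr]
  if (length(body) == 0) abort("SAM file contains no alignment records")
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11)) {
    bad_line <- which(!hdr)[which(nf < 11)[1L]]
    abort(sprintf("truncated SAM record at line %d", bad_line))
  }
  flag <- as.integer(vapply(parts, `[[`, "", 2L))
  pos <- as.integer(vapply(parts, `[[`, "", 4L))
  rname <- vapply(parts, `[[`, "", 3L)
  mapped <- !bitwAnd(flag, 4L) & rname != "*"
  out <- tibble(
    read_id = vapply(parts, `[[`, "", 1L),
    flag = flag,
    mapped = mapped,
    mapq = as.integer(vapply(parts, `[[`, "", 5L)),
    chromosome = ifelse(mapped, rname, NA_character_),
    start = ifelse(mapped, pos - 1L, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
                    NA_character_),
    seq = vapply(parts, `[[`, "", 10L)
  )
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' Write / read a per-base coverage track as BedGraph
#'
#' Runs of equal coverage are written as 0-based half-open intervals.
#'
#' @param track a `coverage_track`.
#' @param path file path.
#' @return `write_bedgraph()` the path invisibly; `read_bedgraph()` a
#'   `coverage_track`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track$data)) {
    r <- rle(track$data[[nm]])
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", nm, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_lengths named vector of chromosome lengths for
#'   reconstruction.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "value"),
                    stringsAsFactors = FALSE)
  data <- lapply(setNames(names(chrom_lengths), names(chrom_lengths)),
                 function(nm) numeric(chrom_lengths[nm]))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$chrom[i]
    data[[nm]][(tab$start[i] + 1L):tab$end[i]] <- tab$value[i]
  }
  new_coverage_track(data, scaled = FALSE)
}
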