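# Reference model: sequence records, plasmid maps, coordinate conventions,
# and the small set of text formats shared by every stage.
#
# All internal coordinates are 0-based half-open [start, end); conversion to
# the 1-based inclusive coordinates used in reports happens only at the
# reporting boundary (to_one_based()).

VALID_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are upper-cased on read and restricted to the A/C/G/T/N
#' alphabet; anything else (e.g. RNA `U`, IUPAC ambiguity codes) is rejected
#' so downstream k-mer arithmetic never meets an unexpected symbol.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (upper-case character).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    offending <- gsub("[ACGTN]", "", seqs[which(bad)[1]])
    stop("record '", ids[which(bad)[1]], "' contains characters outside ",
         "A/C/G/T/N (e.g. '", substr(offending, 1, 1), "')")
  }
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", path)
  tibble(id = ids, seq = unname(seqs))
}

#' Write a sequence tibble (or named character vector) as FASTA
#'
#' @param x tibble with `id`/`seq` columns, or a named character vector.
#' @param path output path.
#' @param width line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  x <- as_seq_tbl(x)
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# accept tibble(id, seq) or named character vector
as_seq_tbl <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(tibble(id = names(x), seq = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  as_tibble(x)
}

seq_vec <- function(x) {
  x <- as_seq_tbl(x)
  setNames(x$seq, x$id)
}

#' Reverse-complement a DNA string
#' @param seq character scalar over A/C/G/T/N.
#' @return the reverse complement.
#' @export
revcomp <- function(seq) cpp_revcomp(seq)

#' Parse a plasmid FASTA plus element interval table into a plasmid map
#'
#' The element table is a TSV with columns `name`, `start`, `end`, `strand`
#' (0-based half-open coordinates on the plasmid). Exactly one row must be
#' named `T-DNA`; the plasmid backbone is derived as the circular complement
#' of the T-DNA interval.
#'
#' @param fasta_path single-record plasmid FASTA.
#' @param elements_tsv path to the element table.
#' @return a `plasmid_map` object: list with `id`, `seq`, `length`, `tdna`
#'   (c(start, end)), `elements` tibble and `backbone` interval tibble.
#' @export
parse_plasmid_map <- function(fasta_path, elements_tsv) {
  fa <- read_fasta(fasta_path)
  if (nrow(fa) != 1) stop("plasmid FASTA must contain exactly one record")
  el <- utils::read.table(elements_tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  plasmid_map(fa$seq[1], el, id = fa$id[1])
}

#' Build a plasmid map from in-memory pieces
#'
#' @param seq plasmid sequence (circular).
#' @param elements data frame with `name`, `start`, `end`, `strand`;
#'   one row must be named `T-DNA`.
#' @param id plasmid identifier.
#' @return a `plasmid_map` object.
#' @export
plasmid_map <- function(seq, elements, id = "plasmid") {
  stopifnot(all(c("name", "start", "end", "strand") %in% names(elements)))
  el <- as_tibble(elements)
  L <- nchar(seq)
  if (any(el$start < 0 | el$end > L | el$start >= el$end)) {
    stop("element interval out of plasmid bounds [0, ", L, ")")
  }
  td <- el[el$name == "T-DNA", ]
  if (nrow(td) != 1) stop("element table must contain exactly one T-DNA row")
  tdna <- c(start = td$start, end = td$end)
  backbone <- circular_complement(td$start, td$end, L)
  structure(
    list(id = id, seq = toupper(seq), length = L, tdna = tdna,
         elements = el[el$name != "T-DNA", ], backbone = backbone),
    class = "plasmid_map")
}

# complement of [start, end) on a circle of size L, as a tibble of 0 or
# more linear intervals
circular_complement <- function(start, end, L) {
  if (end - start >= L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  if (start == 0) {
    tibble(start = end, end = L)
  } else if (end == L) {
    tibble(start = 0L, end = start)
  } else {
    s <- start
    e <- end
    tibble(start = c(e, 0L), end = c(L, s))
  }
}

#' @export
print.plasmid_map <- function(x, ...) {
  cat("<plasmid_map> ", x$id, ": ", x$length, " bp, T-DNA [",
      x$tdna[["start"]], ",", x$tdna[["end"]], "), ",
      nrow(x$elements), " annotated elements, backbone ",
      sum(x$backbone$end - x$backbone$start), " bp\n", sep = "")
  invisible(x)
}

#' Convert internal 0-based half-open intervals to reported 1-based ones
#'
#' Reported loci (e.g. an integration locus printed in a characterization
#' report) are 1-based inclusive; internally everything is 0-based
#' half-open, so start moves by +1 and end is unchanged.
#'
#' @param interval data frame with `start`, `end` (0-based half-open), or a
#'   length-2 numeric `c(start, end)`.
#' @return same shape with `start` incremented; a 1-based inclusive interval.
#' @export
to_one_based <- function(interval) {
  if (is.numeric(interval) && length(interval) == 2) {
    return(c(start = unname(interval[1]) + 1, end = unname(interval[2])))
  }
  stopifnot(all(c("start", "end") %in% names(interval)))
  interval$start <- interval$start + 1
  interval
}

#' Write intervals as BED6
#'
#' @param x data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (0-based half-open, BED-native).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bed <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# merged IRanges from start/end columns (0-based half-open -> IRanges is
# 1-based closed internally; shift once here and once back)
to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

from_iranges <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
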