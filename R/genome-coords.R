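# Coordinate projection between the genomic frame and the coding (c.) frame.
# c.1 is the A of the start codon; numbering covers the CDS only (stop codon
# included). For minus-strand transcripts the coding frame runs in
# transcription direction, i.e. genomic-descending.

# genomic positions of CDS bases in transcription order (integer vector)
cds_genomic_positions <- function(t) {
  ex <- t$exons[[1]]
  cs <- t$cds_start
  ce <- t$cds_end
  if (is.na(cs)) abort(paste0("transcript has no CDS: ", t$transcript_id))
  segs <- lapply(seq_len(nrow(ex)), function(i) {
    s <- max(ex$start[i], cs)
    e <- min(ex$end[i], ce)
    if (s > e) NULL else seq.int(s, e)
  })
  pos <- unlist(segs)
  pos <- sort(pos)
  if (t$strand == "-") pos <- rev(pos)
  pos
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS-overlapping exon segments in transcription order;
#' minus-strand models are reverse-complemented so the result reads
#' 5' to 3' on the coding strand.
#'
#' @param t One row of a transcript tibble (see [read_transcripts()]).
#' @param genome A `ref_genome`.
#' @return DNA string of the CDS (stop codon included for valid models).
#' @export
spliced_cds <- function(t, genome) {
  t <- as_transcript_row(t)
  ex <- t$exons[[1]]
  cs <- t$cds_start
  ce <- t$cds_end
  if (is.na(cs)) abort(paste0("transcript has no CDS: ", t$transcript_id))
  chunks <- character(0)
  for (i in seq_len(nrow(ex))) {
    s <- max(ex$start[i], cs)
    e <- min(ex$end[i], ce)
    if (s <= e) chunks <- c(chunks, slice_seq(genome, t$contig, s, e))
  }
  fwd <- paste(chunks, collapse = "")
  if (t$strand == "-") revcomp(fwd) else fwd
}

as_transcript_row <- function(t) {
  if (is_tibble(t) || is.data.frame(t)) {
    if (nrow(t) != 1) abort("expected a single transcript row")
    return(t)
  }
  abort("expected a transcript tibble row")
}

#' Project a genomic position into the coding frame
#'
#' @param t One transcript row.
#' @param gpos Genomic position (1-based).
#' @return A list with `region` (one of `"cds"`, `"intronic"`, `"utr"`,
#'   `"intergenic"`), `c_pos` (coding position, `NA` outside the CDS) and
#'   `offset` (distance to the nearest exon boundary for intronic positions).
#' @export
genomic_to_cds <- function(t, gpos) {
  t <- as_transcript_row(t)
  map <- cds_genomic_positions(t)
  k <- match(gpos, map)
  if (!is.na(k)) {
    return(list(region = "cds", c_pos = as.integer(k), offset = 0L))
  }
  ex <- t$exons[[1]]
  in_exon <- any(gpos >= ex$start & gpos <= ex$end)
  if (in_exon) {
    return(list(region = "utr", c_pos = NA_integer_, offset = 0L))
  }
  if (gpos >= min(ex$start) && gpos <= max(ex$end)) {
    bounds <- c(ex$start, ex$end)
    off <- min(abs(gpos - bounds))
    return(list(region = "intronic", c_pos = NA_integer_, offset = as.integer(off)))
  }
  list(region = "intergenic", c_pos = NA_integer_, offset = 0L)
}

#' Project a coding position back to the genome
#'
#' Inverse of [genomic_to_cds()] on CDS positions.
#'
#' @param t One transcript row.
#' @param c_pos Coding position (1 = A of the start codon).
#' @return Genomic position (integer).
#' @export
cds_to_genomic <- function(t, c_pos) {
  t <- as_transcript_row(t)
  map <- cds_genomic_positions(t)
  if (any(c_pos < 1 | c_pos > length(map))) {
    abort(sprintf("coding position out of range 1-%d", length(map)))
  }
  map[c_pos]
}

# wild-type protein length in aa (terminal stop excluded)
wt_protein_length <- function(t, genome) {
  tr <- translate_cds(spliced_cds(t, genome))
  nchar(tr$protein)
}
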