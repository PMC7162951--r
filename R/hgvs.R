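# HGVS-like rendering and parsing. Genomic (g.) descriptions follow the
# left-aligned VCF representation; coding (c.) descriptions follow the HGVS
# 3'-rule on the transcript strand, with the inserted sequence given in
# transcript orientation. The two conventions shift the same indel in
# opposite directions on a minus-strand gene, which is why both renderings
# are provided.

variant_shape <- function(ref, alt) {
  nr <- nchar(ref); na_ <- nchar(alt)
  if (nr == 1 && na_ == 1) return("snv")
  if (na_ > nr && nr == 1 && substr(alt, 1, 1) == ref) return("ins")
  if (nr > na_ && na_ == 1 && substr(ref, 1, 1) == alt) return("del")
  "delins"
}

# project a genomic variant into the coding frame of one transcript.
# Returns NULL when the edit does not touch the CDS; otherwise a list with
# kind, c_start/c_end, wt, seq (transcript orientation), mut_cds, net and
# partial (TRUE when an indel only partially overlaps the CDS).
transcript_edit <- function(contig, pos, ref, alt, t, genome, ctx = NULL) {
  if (contig != t$contig) return(NULL)
  ctx <- ctx %||% tx_context(t, genome)
  map <- ctx$map
  cds <- ctx$cds
  strand <- t$strand
  orient <- function(s) if (strand == "-") revcomp(s) else s
  nr <- nchar(ref); na_ <- nchar(alt)
  ncds <- nchar(cds)
  shape <- variant_shape(ref, alt)

  if (shape == "snv") {
    k <- match(pos, map)
    if (is.na(k)) return(NULL)
    mut_base <- orient(alt)
    list(kind = "snv", c_start = k, c_end = k,
         wt = substr(cds, k, k), seq = mut_base,
         mut_cds = paste0(substr(cds, 1, k - 1), mut_base,
                          substr(cds, k + 1, ncds)),
         net = 0L, partial = FALSE)
  } else if (shape == "ins") {
    ins <- substr(alt, 2, na_)
    k1 <- match(pos, map)
    k2 <- match(pos + 1, map)
    if (is.na(k1) || is.na(k2) || abs(k1 - k2) != 1) return(NULL)
    kmin <- min(k1, k2)
    iseq <- orient(ins)
    list(kind = "ins", c_start = kmin, c_end = kmin + 1L,
         wt = "", seq = iseq,
         mut_cds = paste0(substr(cds, 1, kmin), iseq,
                          substr(cds, kmin + 1, ncds)),
         net = nchar(iseq), partial = FALSE)
  } else if (shape == "del") {
    del_g <- seq.int(pos + 1, pos + nr - 1)
    ks <- match(del_g, map)
    kk <- sort(ks[!is.na(ks)])
    if (length(kk) == 0) return(NULL)
    keep <- setdiff(seq_len(ncds), kk)
    list(kind = "del", c_start = min(kk), c_end = max(kk),
         wt = substr(cds, min(kk), max(kk)), seq = "",
         mut_cds = paste(strsplit(cds, "", fixed = TRUE)[[1]][keep],
                         collapse = ""),
         net = -length(kk), partial = length(kk) < length(del_g))
  } else {
    rng <- seq.int(pos, pos + nr - 1)
    ks <- match(rng, map)
    kk <- sort(ks[!is.na(ks)])
    if (length(kk) == 0) return(NULL)
    if (length(kk) < length(rng)) {
      # partial CDS overlap: the in-CDS bases are lost; classify as deletion
      keep <- setdiff(seq_len(ncds), kk)
      return(list(kind = "del", c_start = min(kk), c_end = max(kk),
                  wt = substr(cds, min(kk), max(kk)), seq = "",
                  mut_cds = paste(strsplit(cds, "", fixed = TRUE)[[1]][keep],
                                  collapse = ""),
                  net = -length(kk), partial = TRUE))
    }
    iseq <- orient(alt)
    list(kind = "delins", c_start = min(kk), c_end = max(kk),
         wt = substr(cds, min(kk), max(kk)), seq = iseq,
         mut_cds = paste0(substr(cds, 1, min(kk) - 1), iseq,
                          substr(cds, max(kk) + 1, ncds)),
         net = na_ - nr, partial = FALSE)
  }
}

#' Render a variant in genomic (g.) notation
#'
#' Uses the left-aligned VCF representation directly (insertions at their
#' leftmost equivalent genomic placement).
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt` (normalised).
#' @return Character vector of `contig:g.` descriptions.
#' @examples
#' # an 8-bp insertion between two genomic positions:
#' # "chr3:g.91534556_91534557insGGGGGCCG"
#' @export
hgvs_g <- function(variants) {
  purrr::pmap_chr(
    list(variants$contig, variants$pos, variants$ref, variants$alt),
    function(contig, pos, ref, alt) {
      shape <- variant_shape(ref, alt)
      if (shape == "snv") {
        sprintf("%s:g.%d%s>%s", contig, pos, ref, alt)
      } else if (shape == "ins") {
        sprintf("%s:g.%d_%dins%s", contig, pos, pos + 1L,
                substr(alt, 2, nchar(alt)))
      } else if (shape == "del") {
        d <- nchar(ref) - 1L
        if (d == 1) {
          sprintf("%s:g.%ddel", contig, pos + 1L)
        } else {
          sprintf("%s:g.%d_%ddel", contig, pos + 1L, pos + d)
        }
      } else {
        if (nchar(ref) == 1) {
          sprintf("%s:g.%ddelins%s", contig, pos, alt)
        } else {
          sprintf("%s:g.%d_%ddelins%s", contig, pos,
                  pos + nchar(ref) - 1L, alt)
        }
      }
    }
  )
}

#' Render a coding-frame (c.) description for one transcript
#'
#' Insertions and deletions are shifted to their most 3' equivalent position
#' on the transcript strand (HGVS 3'-rule); the inserted sequence is reported
#' in transcript orientation, i.e. the reverse complement of the genomic
#' allele for minus-strand genes.
#'
#' @param variant One-row tibble (or list) with `contig`, `pos`, `ref`, `alt`.
#' @param t One transcript row.
#' @param genome A `ref_genome`.
#' @param ctx Optional precomputed transcript context (internal caching).
#' @return A `c.` description string; errors when the variant does not touch
#'   the CDS.
#' @export
hgvs_c <- function(variant, t, genome, ctx = NULL) {
  t <- as_transcript_row(t)
  ctx <- ctx %||% tx_context(t, genome)
  edit <- transcript_edit(variant$contig, variant$pos, variant$ref,
                          variant$alt, t, genome, ctx)
  if (is.null(edit)) {
    abort(sprintf("variant %s:%d %s>%s is outside the CDS of %s",
                  variant$contig, variant$pos, variant$ref, variant$alt,
                  t$transcript_id))
  }
  cds <- ctx$cds
  if (edit$kind == "snv") {
    sprintf("c.%d%s>%s", edit$c_start, edit$wt, edit$seq)
  } else if (edit$kind == "ins") {
    pl <- enumerate_placements(cds, edit$c_start, edit$seq)
    p <- max(pl$positions)
    sprintf("c.%d_%dins%s", p, p + 1L, pl$insert_at_3p)
  } else if (edit$kind == "del") {
    i <- edit$c_start; j <- edit$c_end
    n <- nchar(cds)
    while (j < n && substr(cds, i, i) == substr(cds, j + 1, j + 1)) {
      i <- i + 1L; j <- j + 1L
    }
    if (i == j) sprintf("c.%ddel", i) else sprintf("c.%d_%ddel", i, j)
  } else {
    sprintf("c.%d_%ddelins%s", edit$c_start, edit$c_end, edit$seq)
  }
}

#' Parse an HGVS-like coding description
#'
#' Supports SNVs (`c.5A>G`), insertions (`c.19_20insCGGCCCCC`), deletions
#' (`c.10del`, `c.10_12del`) and deletion-insertions (`c.10_12delinsAA`).
#'
#' @param s A `c.` description string.
#' @return A list with `kind` and the positions/sequences of the edit.
#' @export
parse_hgvs_c <- function(s) {
  s <- trimws(s)
  m <- str_match(s, "^c\\.([0-9]+)([ACGT])>([ACGT])$")
  if (!is.na(m[1, 1])) {
    return(list(kind = "snv", c_start = as.integer(m[1, 2]),
                c_end = as.integer(m[1, 2]), wt = m[1, 3], seq = m[1, 4]))
  }
  m <- str_match(s, "^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$")
  if (!is.na(m[1, 1])) {
    p1 <- as.integer(m[1, 2]); p2 <- as.integer(m[1, 3])
    if (p2 != p1 + 1) {
      abort(paste0("insertion positions must be adjacent in: ", s))
    }
    return(list(kind = "ins", c_start = p1, c_end = p2, wt = "",
                seq = m[1, 4]))
  }
  m <- str_match(s, "^c\\.([0-9]+)(?:_([0-9]+))?del(?:ins([ACGT]+))?$")
  if (!is.na(m[1, 1])) {
    p1 <- as.integer(m[1, 2])
    p2 <- if (is.na(m[1, 3])) p1 else as.integer(m[1, 3])
    if (p2 < p1) abort(paste0("descending position range in: ", s))
    if (!is.na(m[1, 4])) {
      return(list(kind = "delins", c_start = p1, c_end = p2, wt = NA,
                  seq = m[1, 4]))
    }
    return(list(kind = "del", c_start = p1, c_end = p2, wt = NA, seq = ""))
  }
  abort(paste0("cannot parse HGVS c. description: '", s, "'"))
}

#' Apply a parsed coding edit to a CDS string
#'
#' @param cds Wild-type coding sequence.
#' @param edit A parsed edit from [parse_hgvs_c()].
#' @return The mutant coding sequence.
#' @export
apply_cds_edit <- function(cds, edit) {
  n <- nchar(cds)
  if (edit$c_end > n + (edit$kind == "ins")) {
    abort("edit positions beyond CDS length")
  }
  if (edit$kind == "snv") {
    wt <- substr(cds, edit$c_start, edit$c_start)
    if (!is.null(edit$wt) && !is.na(edit$wt) && wt != edit$wt) {
      abort(sprintf("reference base mismatch at c.%d: CDS has %s, edit says %s",
                    edit$c_start, wt, edit$wt))
    }
    paste0(substr(cds, 1, edit$c_start - 1), edit$seq,
           substr(cds, edit$c_start + 1, n))
  } else if (edit$kind == "ins") {
    paste0(substr(cds, 1, edit$c_start), edit$seq,
           substr(cds, edit$c_start + 1, n))
  } else if (edit$kind == "del") {
    paste0(substr(cds, 1, edit$c_start - 1), substr(cds, edit$c_end + 1, n))
  } else {
    paste0(substr(cds, 1, edit$c_start - 1), edit$seq,
           substr(cds, edit$c_end + 1, n))
  }
}

# genomic VCF-style variant corresponding to a coding edit on a transcript
coding_edit_to_variant <- function(edit, t, genome) {
  t <- as_transcript_row(t)
  map <- cds_genomic_positions(t)
  orient <- function(s) if (t$strand == "-") revcomp(s) else s
  base_at <- function(p) slice_seq(genome, t$contig, p, p)
  if (edit$kind == "snv") {
    g <- map[edit$c_start]
    return(tibble(contig = t$contig, pos = as.integer(g),
                  ref = base_at(g), alt = orient(edit$seq)))
  }
  if (edit$kind == "ins") {
    g1 <- map[edit$c_start]; g2 <- map[edit$c_start + 1]
    anchor <- min(g1, g2)
    return(tibble(contig = t$contig, pos = as.integer(anchor),
                  ref = base_at(anchor),
                  alt = paste0(base_at(anchor), orient(edit$seq))))
  }
  gs <- map[seq.int(edit$c_start, edit$c_end)]
  lo <- min(gs); hi <- max(gs)
  anchor <- lo - 1L
  if (anchor < 1) abort("cannot anchor deletion at contig start")
  ref <- slice_seq(genome, t$contig, anchor, hi)
  alt <- if (edit$kind == "del") base_at(anchor) else
    paste0(base_at(anchor), orient(edit$seq))
  tibble(contig = t$contig, pos = as.integer(anchor), ref = ref, alt = alt)
}

# precomputed per-transcript context: spliced CDS, genomic position map and
# wild-type translation; cached across many variants in annotate_callset()
tx_context <- function(t, genome, cache = NULL) {
  key <- t$transcript_id
  if (!is.null(cache) && !is.na(key) && !is.null(cache[[key]])) {
    return(cache[[key]])
  }
  ctx <- if (is.na(t$cds_start)) {
    list(cds = NULL, map = integer(0), wt = NULL)
  } else {
    cds <- spliced_cds(t, genome)
    list(cds = cds, map = cds_genomic_positions(t),
         wt = tryCatch(translate_cds(cds), error = function(e) NULL))
  }
  if (!is.null(cache) && !is.na(key)) cache[[key]] <- ctx
  ctx
}
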