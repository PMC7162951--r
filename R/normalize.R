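# Variant normalisation. Two conventions deliberately coexist:
#   * VCF-style left alignment (leftmost equivalent placement, single anchor
#     base) — used for storage and for matching against the control panel;
#   * HGVS-style 3' shifting on the transcript strand — used for reporting
#     (see hgvs.R).
# In repetitive sequence an insertion admits a contiguous run of equivalent
# placements; enumerate_placements() computes that run.

left_align_one <- function(contig, pos, ref, alt, genome) {
  seqlen <- contig_length(genome, contig)
  obs <- slice_seq(genome, contig, pos, pos + nchar(ref) - 1)
  if (obs != ref) {
    abort(sprintf(
      "REF mismatch at %s:%d (VCF says %s, genome has %s); wrong reference build?",
      contig, pos, ref, obs))
  }
  if (identical(ref, alt)) abort("ref and alt are identical")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1, nr - 1)
      alt <- substr(alt, 1, na - 1)
    } else if (nr == 0 || na == 0) {
      if (pos > 1) {
        b <- slice_seq(genome, contig, pos - 1, pos - 1)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1
      } else {
        # contig start: anchor on the base following the event instead
        e <- pos + nchar(ref)
        if (e > seqlen) abort("cannot normalise variant at contig edge")
        b <- slice_seq(genome, contig, e, e)
        ref <- paste0(ref, b)
        alt <- paste0(alt, b)
        break
      }
    } else {
      break
    }
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Left-align and trim variants against the reference
#'
#' Shared suffixes are trimmed, indels are shifted to their leftmost
#' equivalent genomic placement with a single anchor base, and shared
#' prefixes beyond the anchor are removed. SNVs pass through unchanged.
#' The operation is idempotent and preserves the alternate haplotype.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt` (extra columns
#'   are carried through; `key` is recomputed).
#' @param genome A `ref_genome`; an error is raised when the REF allele does
#'   not match the genome (a wrong-reference-build signal).
#' @return The input tibble with normalised `pos`, `ref`, `alt`, `key`.
#' @export
left_align <- function(variants, genome) {
  if (nrow(variants) == 0) return(variants)
  norm <- purrr::pmap(
    list(variants$contig, variants$pos, variants$ref, variants$alt),
    function(c, p, r, a) left_align_one(c, p, r, a, genome)
  )
  out <- variants
  out$pos <- purrr::map_int(norm, "pos")
  out$ref <- purrr::map_chr(norm, "ref")
  out$alt <- purrr::map_chr(norm, "alt")
  if ("key" %in% names(out) || TRUE) {
    out$key <- variant_key(out$contig, out$pos, out$ref, out$alt)
  }
  out
}

#' Enumerate equivalent placements of an insertion
#'
#' Given a sequence context and an insertion after position `after`, returns
#' every position after which inserting (a rotation of) the allele yields a
#' byte-identical alternate sequence. In repetitive sequence this is a
#' contiguous run; elsewhere it is the single input position. Positions are
#' interpreted in whatever frame `context` is supplied in (genomic slice or
#' coding sequence).
#'
#' @param context DNA string covering the repeat neighbourhood.
#' @param after Position (0 to `nchar(context)`) after which the insertion
#'   is placed.
#' @param insert Inserted allele (pure insertion).
#' @return A list with `positions` (contiguous integer run of equivalent
#'   placements), `insert_at_3p` (the rotated allele as placed at the
#'   3'-most position) and `insert_at_5p` (rotation at the 5'-most position).
#' @export
enumerate_placements <- function(context, after, insert) {
  if (is.na(insert) || !nzchar(insert)) {
    abort("enumerate_placements(): not an insertion (empty allele)")
  }
  n <- nchar(context)
  if (after < 0 || after > n) abort("insertion point outside context")
  # roll left: placement after p-1 is equivalent iff context[p] equals the
  # last base of the current rotation
  p <- after; s <- insert
  while (p >= 1 && substr(context, p, p) == substr(s, nchar(s), nchar(s))) {
    s <- rot_right(s)
    p <- p - 1
  }
  lo <- p; s5 <- s
  # roll right symmetrically
  p <- after; s <- insert
  while (p < n && substr(context, p + 1, p + 1) == substr(s, 1, 1)) {
    s <- rot_left(s)
    p <- p + 1
  }
  hi <- p; s3 <- s
  list(positions = seq.int(lo, hi), insert_at_3p = s3, insert_at_5p = s5)
}

# apply a (pos, ref, alt) substitution to a sequence string (1-based)
apply_variant_to_seq <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}
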