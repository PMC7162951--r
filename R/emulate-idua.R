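# A synthetic transcript engineered to reproduce the published molecular
# anatomy of the canine alpha-L-iduronidase frameshift: a 655-codon coding
# sequence whose first 19 bases carry two tandem copies of the 8-mer
# CGGCCCCC (so an insertion of that 8-mer reported after c.19 is equivalently
# placeable after any of c.3-c.19), and whose shifted reading frame first
# stops at mutant codon 109 (truncated protein of 108 aa against 655 wild
# type, divergence from residue 7). The sequence is synthetic: only the
# repeat context and frame anatomy are modelled, not the real gene.

IDUA_INSERT_TX <- "CGGCCCCC"
IDUA_INSERT_GENOMIC <- "GGGGGCCG"   # reverse complement, minus-strand gene

#' Synthetic coding sequence emulating the canine IDUA frameshift context
#'
#' Deterministically builds a 1968-bp CDS (655 codons plus stop) such that
#' inserting `CGGCCCCC` between c.19 and c.20 (i) preserves exactly the
#' first 6 amino acids, (ii) truncates the protein to 108 residues at a
#' premature stop, and (iii) is equivalently placeable after any base from
#' c.3 to c.19 because bases 4-19 are two tandem copies of the insert.
#'
#' @return A DNA string of length 1968.
#' @export
emulate_idua_cds <- function() {
  with_seed(20200416L, {
    n_codons <- 655L
    prefix <- paste0("ATG", IDUA_INSERT_TX, IDUA_INSERT_TX)  # bases 1..19
    # base 20 must break the 3' roll (not C) and codon 7 (c19-c21) must not
    # encode the mutant codon-7 amino acid (CCG = Pro)
    b20_21 <- "AC"                                           # codon 7 = CAC
    body <- sample(NONSTOP_CODONS, n_codons - 7L, replace = TRUE)
    cds <- paste0(prefix, b20_21, paste(body, collapse = ""), "TAA")
    stopifnot(nchar(cds) == 3L * (n_codons + 1L))

    set_base <- function(s, i, b) {
      substr(s, i, i) <- b
      s
    }
    code <- Biostrings::GENETIC_CODE
    codon_at <- function(s, i) substr(s, i, i + 2L)

    # enforce: shifted-frame codons 10..108 (cds bases 20..316 read in the
    # +8 frame) are stop-free; shifted codon 109 (bases 317..319) is TAA
    for (i in 317:319) cds <- set_base(cds, i, c("T", "A", "A")[i - 316])
    repeat {
      ok <- TRUE
      for (j in 10:108) {
        b <- 3L * j - 10L               # first cds base of shifted codon j
        cod <- codon_at(cds, b)
        if (is_stop_codon(cod)) {
          ok <- FALSE
          # resample the original-frame codon containing the middle base,
          # keeping the original frame stop-free
          mid <- b + 1L
          oj <- ceiling(mid / 3)
          os <- 3L * oj - 2L
          if (os <= 21L || os >= 316L) {
            # inside the fixed prefix/stop assignment: flip a safe base
            cds <- set_base(cds, b, setdiff(c("A", "C", "G", "T"),
                                            substr(cds, b, b))[1])
          } else {
            cds <- paste0(substr(cds, 1, os - 1),
                          sample(NONSTOP_CODONS, 1),
                          substr(cds, os + 3L, nchar(cds)))
          }
          break
        }
      }
      if (ok) break
    }
    # original frame must remain stop-free up to codon 655
    repeat {
      ok <- TRUE
      for (j in 2:n_codons) {
        os <- 3L * j - 2L
        if (is_stop_codon(codon_at(cds, os))) {
          ok <- FALSE
          if (os >= 316L && os <= 321L) {
            abort("internal error: immovable stop codon")
          }
          cds <- paste0(substr(cds, 1, os - 1),
                        sample(NONSTOP_CODONS, 1),
                        substr(cds, os + 3L, nchar(cds)))
          break
        }
      }
      if (ok) {
        # re-check the shifted frame after any original-frame fix
        shifted_ok <- all(!vapply(10:108, function(j)
          is_stop_codon(codon_at(cds, 3L * j - 10L)), logical(1)))
        if (shifted_ok) break
      }
    }

    wt <- translate_cds(cds)
    stopifnot(!wt$no_stop, nchar(wt$protein) == 655L)
    mut <- translate_cds(apply_cds_edit(
      cds, list(kind = "ins", c_start = 19L, c_end = 20L,
                seq = IDUA_INSERT_TX)))
    stopifnot(nchar(mut$protein) == 108L)
    cds
  })
}

#' Synthetic minus-strand world carrying the emulated IDUA gene
#'
#' Places the [emulate_idua_cds()] transcript on the minus strand of a small
#' synthetic contig (mirroring the real gene's orientation, where the
#' transcript-strand insert `CGGCCCCC` appears as `GGGGGCCG` on the genomic
#' plus strand) and returns the causal insertion in VCF representation.
#'
#' @return List with `genome`, `transcript` (one-row tibble), `cds`,
#'   `variant` (raw VCF-style genomic insertion anchored at the transcript
#'   placement) and `variant_left` (the same insertion left-aligned).
#' @export
emulate_idua_world <- function() {
  cds <- emulate_idua_cds()
  with_seed(20200417L, {
    flank5 <- random_bases(150)   # genomic left of the gene
    utr <- list(u5 = random_bases(12), u3 = random_bases(12))
    tx_seq <- paste0(utr$u5, cds, utr$u3)
    contig_seq <- paste0(flank5, revcomp(tx_seq), random_bases(150))
    genome <- structure(c(chr3_syn = contig_seq), class = "ref_genome")
    exon_start <- nchar(flank5) + 1L
    exon_end <- nchar(flank5) + nchar(tx_seq)
    cds_start <- exon_start + 12L
    cds_end <- exon_end - 12L
    t <- tibble(
      transcript_id = "IDUA_syn.t1", gene_id = "IDUA_syn",
      gene_symbol = "IDUA", contig = "chr3_syn", strand = "-",
      cds_start = cds_start, cds_end = cds_end,
      exons = list(data.frame(start = exon_start, end = exon_end)),
      valid = TRUE, invalid_reason = NA_character_
    )
    v <- coding_edit_to_variant(
      list(kind = "ins", c_start = 19L, seq = IDUA_INSERT_TX), t, genome)
    list(genome = genome, transcript = t, cds = cds,
         variant = v, variant_left = left_align(v, genome))
  })
}
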