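# Coding consequence prediction. Each (variant, transcript) pair receives
# exactly one Sequence-Ontology-style category and an impact tier. Coding
# categories are decided by editing the spliced CDS in transcript
# orientation and translating to the first stop, so frameshift anatomy
# (first divergent residue, premature stop, truncated length) falls out of
# the same computation.

#' Impact tier for each consequence category
#'
#' The mapping is fixed: HIGH covers frameshift, stop_gained, stop_lost,
#' start_lost and the two splice-site categories; MODERATE covers in-frame
#' indels and missense; LOW synonymous; MODIFIER the non-coding categories.
#'
#' @return Named character vector mapping category to tier.
#' @export
impact_table <- function() {
  c(frameshift = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
    start_lost = "HIGH", splice_donor = "HIGH", splice_acceptor = "HIGH",
    inframe_insertion = "MODERATE", inframe_deletion = "MODERATE",
    missense = "MODERATE", synonymous = "LOW",
    intronic = "MODIFIER", utr = "MODIFIER", intergenic = "MODIFIER")
}

IMPACT_ORDER <- c(MODIFIER = 0L, LOW = 1L, MODERATE = 2L, HIGH = 3L)

impact_rank <- function(x) unname(IMPACT_ORDER[x])

# donor/acceptor genomic positions (2 intronic bases each side) for introns
# lying within the CDS span
splice_site_positions <- function(t) {
  ex <- t$exons[[1]]
  n <- nrow(ex)
  if (n < 2) return(list(donor = integer(0), acceptor = integer(0)))
  donor <- integer(0); acceptor <- integer(0)
  for (i in seq_len(n - 1)) {
    istart <- ex$end[i] + 1L
    iend <- ex$start[i + 1] - 1L
    if (istart > iend) next
    if (is.na(t$cds_start) ||
        iend < t$cds_start || istart > t$cds_end) next
    left <- c(istart, min(istart + 1L, iend))
    right <- c(max(iend - 1L, istart), iend)
    if (t$strand == "+") {
      donor <- c(donor, left)
      acceptor <- c(acceptor, right)
    } else {
      donor <- c(donor, right)
      acceptor <- c(acceptor, left)
    }
  }
  list(donor = unique(donor), acceptor = unique(acceptor))
}

#' Classify one variant against one transcript
#'
#' Splice categories cover the two intronic bases at each CDS-flanking
#' junction; variants overlapping the CDS are classified through mutant
#' translation; variants spanning an exon/intron boundary take the most
#' severe overlapped context (coding first, then splice).
#'
#' @param variant One-row tibble with `contig`, `pos`, `ref`, `alt`
#'   (left-aligned).
#' @param t One transcript row.
#' @param genome A `ref_genome`.
#' @param ctx Optional precomputed transcript context (internal caching).
#' @return One-row tibble: `key`, `transcript_id`, `gene_id`, `gene_symbol`,
#'   `category`, `impact`, `hgvs_c`, `hgvs_g`, `wt_protein_length`,
#'   `mut_protein_length`, `first_divergent_residue`, `premature_stop`.
#' @export
classify_variant <- function(variant, t, genome, ctx = NULL) {
  t <- as_transcript_row(t)
  v <- variant
  imp <- impact_table()
  base_row <- function(category, hc = NA_character_, wt_len = NA_integer_,
                       mut_len = NA_integer_, fdr = NA_integer_,
                       pstop = NA) {
    tibble::new_tibble(list(
      contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
      key = variant_key(v$contig, v$pos, v$ref, v$alt),
      transcript_id = t$transcript_id, gene_id = t$gene_id,
      gene_symbol = t$gene_symbol,
      category = category, impact = unname(imp[category]),
      hgvs_c = hc,
      hgvs_g = hgvs_g(list(contig = v$contig, pos = v$pos,
                           ref = v$ref, alt = v$alt)),
      wt_protein_length = as.integer(wt_len),
      mut_protein_length = as.integer(mut_len),
      first_divergent_residue = as.integer(fdr),
      premature_stop = as.logical(pstop)
    ), nrow = 1L)
  }

  if (!v$contig %in% names(genome) || v$contig != t$contig) {
    return(base_row("intergenic"))
  }
  ex <- t$exons[[1]]
  span_lo <- min(ex$start); span_hi <- max(ex$end)
  shape <- variant_shape(v$ref, v$alt)
  g_lo <- v$pos
  g_hi <- if (shape == "ins") v$pos + 1L else v$pos + nchar(v$ref) - 1L
  if (g_hi < span_lo - 2L || g_lo > span_hi + 2L) {
    return(base_row("intergenic"))
  }

  if (is.null(ctx) && !is.na(t$cds_start)) ctx <- tx_context(t, genome)
  edit <- transcript_edit(v$contig, v$pos, v$ref, v$alt, t, genome, ctx)
  # genomic positions actually changed (excludes indel anchor base)
  changed <- switch(shape,
    snv = g_lo,
    ins = numeric(0),
    del = seq.int(v$pos + 1L, g_hi),
    delins = seq.int(g_lo, g_hi)
  )
  ss <- splice_site_positions(t)
  hits_donor <- any(changed %in% ss$donor)
  hits_acceptor <- any(changed %in% ss$acceptor)
  if (shape == "ins" && length(changed) == 0) {
    # insertion between two bases: splice-relevant if the gap interrupts a
    # donor/acceptor dinucleotide
    gap <- c(v$pos, v$pos + 1L)
    hits_donor <- all(gap %in% ss$donor)
    hits_acceptor <- all(gap %in% ss$acceptor)
  }

  if (!is.null(edit)) {
    wt_tr <- ctx$wt %||% translate_cds(ctx$cds)
    wt_prot <- wt_tr$protein
    frameshifty <- edit$net %% 3 != 0
    if (frameshifty &&
        !(edit$kind == "del" && edit$partial) &&
        edit$kind != "snv") {
      cat_fs <- "frameshift"
    } else {
      cat_fs <- NULL
    }
    if (nchar(edit$mut_cds) < 3) {
      return(base_row("start_lost", wt_len = nchar(wt_prot), mut_len = 0L,
                      fdr = 1L, pstop = FALSE))
    }
    mut_tr <- translate_cds(edit$mut_cds)
    mut_prot <- mut_tr$protein
    fdr <- first_divergence(wt_prot, mut_prot)
    wt_len <- nchar(wt_prot)
    mut_len <- nchar(mut_prot)
    pstop <- !mut_tr$no_stop && mut_len < wt_len
    hc <- tryCatch(hgvs_c(v, t, genome, ctx), error = function(e) NA_character_)

    start_hit <- edit$c_start <= 3 && edit$kind != "ins"
    if (start_hit && substr(edit$mut_cds, 1, 3) != "ATG") {
      return(base_row("start_lost", hc, wt_len, 0L, 1L, FALSE))
    }
    category <- if (!is.null(cat_fs)) {
      cat_fs
    } else if (frameshifty) {
      # partial-CDS deletion with out-of-frame loss
      "frameshift"
    } else if (identical(wt_prot, mut_prot) && shape == "snv") {
      "synonymous"
    } else if (identical(wt_prot, mut_prot)) {
      if (edit$net > 0) "inframe_insertion"
      else if (edit$net < 0) "inframe_deletion"
      else "synonymous"
    } else if (pstop && edit$net == 0) {
      "stop_gained"
    } else if (mut_tr$no_stop && !wt_tr$no_stop) {
      "stop_lost"
    } else if (edit$net > 0) {
      if (pstop) "stop_gained" else "inframe_insertion"
    } else if (edit$net < 0) {
      if (pstop) "stop_gained" else "inframe_deletion"
    } else {
      "missense"
    }
    return(base_row(category, hc, wt_len, mut_len, fdr, pstop))
  }

  if (hits_donor) return(base_row("splice_donor"))
  if (hits_acceptor) return(base_row("splice_acceptor"))
  touched <- if (length(changed) == 0) c(v$pos, v$pos + 1L) else changed
  in_exon <- any(vapply(touched, function(p)
    any(p >= ex$start & p <= ex$end), logical(1)))
  if (in_exon) return(base_row("utr"))
  if (g_hi >= span_lo && g_lo <= span_hi) return(base_row("intronic"))
  base_row("intergenic")
}

#' Mutant protein induced by a coding variant
#'
#' Applies the variant to the spliced CDS in transcript orientation and
#' translates to the first stop codon.
#'
#' @param variant One-row tibble with `contig`, `pos`, `ref`, `alt`.
#' @param t One transcript row.
#' @param genome A `ref_genome`.
#' @return List with `protein`, `first_divergent_residue` (0 when the mutant
#'   equals wild type), `premature_stop`, `wt_length`, `mut_length`,
#'   `no_stop`.
#' @export
mutant_protein <- function(variant, t, genome) {
  t <- as_transcript_row(t)
  edit <- transcript_edit(variant$contig, variant$pos, variant$ref,
                          variant$alt, t, genome)
  if (is.null(edit)) {
    abort("variant does not overlap the CDS of this transcript")
  }
  cds <- spliced_cds(t, genome)
  wt <- translate_cds(cds)
  if (nchar(edit$mut_cds) < 3) {
    return(list(protein = "", first_divergent_residue = 1L,
                premature_stop = FALSE, wt_length = nchar(wt$protein),
                mut_length = 0L, no_stop = FALSE))
  }
  mut <- translate_cds(edit$mut_cds)
  list(
    protein = mut$protein,
    first_divergent_residue = first_divergence(wt$protein, mut$protein),
    premature_stop = !mut$no_stop && nchar(mut$protein) < nchar(wt$protein),
    wt_length = nchar(wt$protein),
    mut_length = nchar(mut$protein),
    no_stop = mut$no_stop
  )
}

#' Annotate a callset against a transcript set
#'
#' Every variant is classified against every transcript it overlaps
#' (gene span plus 2 bp of splice context); variants overlapping no
#' transcript receive a single `intergenic` call. Calls are tagged with
#' `source` so two annotation sources can be compared downstream.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt` (left-aligned).
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param genome A `ref_genome`.
#' @param source_label Label recorded in the `source` column.
#' @return Tibble of consequence calls (one row per variant x transcript).
#' @export
annotate_callset <- function(variants, transcripts, genome,
                             source_label = "sourceA") {
  if (nrow(variants) == 0) {
    return(dplyr::mutate(classify_empty(), source = character(0)))
  }
  uniq <- dplyr::distinct(variants, contig, pos, ref, alt)
  spans <- if (nrow(transcripts) == 0) {
    tibble(idx = integer(0), contig = character(0),
           lo = integer(0), hi = integer(0))
  } else {
    purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
      ex <- transcripts$exons[[i]]
      tibble(idx = i, contig = transcripts$contig[i],
             lo = min(ex$start) - 2L, hi = max(ex$end) + 2L)
    })
  }
  # precompute per-transcript rows and contexts once for the whole callset
  tx_rows <- purrr::map(seq_len(nrow(transcripts)),
                        function(i) transcripts[i, ])
  ctx_cache <- purrr::map(tx_rows, function(t) {
    if (is.na(t$cds_start)) NULL else tx_context(t, genome)
  })
  calls <- purrr::map_dfr(seq_len(nrow(uniq)), function(i) {
    v <- uniq[i, ]
    g_hi <- v$pos + max(1L, nchar(v$ref) - 1L)
    hit <- spans$idx[spans$contig == v$contig &
                       spans$lo <= g_hi & spans$hi >= v$pos]
    if (length(hit) == 0) {
      return(classify_variant(v, intergenic_transcript(), genome))
    }
    purrr::map_dfr(hit, function(j)
      classify_variant(v, tx_rows[[j]], genome, ctx_cache[[j]]))
  })
  dplyr::mutate(calls, source = source_label)
}

classify_empty <- function() {
  tibble(contig = character(0), pos = integer(0), ref = character(0),
         alt = character(0), key = character(0),
         transcript_id = character(0), gene_id = character(0),
         gene_symbol = character(0), category = character(0),
         impact = character(0), hgvs_c = character(0),
         hgvs_g = character(0), wt_protein_length = integer(0),
         mut_protein_length = integer(0),
         first_divergent_residue = integer(0), premature_stop = logical(0))
}

# sentinel transcript used to emit an intergenic call
intergenic_transcript <- function() {
  tibble(transcript_id = NA_character_, gene_id = NA_character_,
         gene_symbol = NA_character_, contig = "__none__", strand = "+",
         cds_start = NA_integer_, cds_end = NA_integer_,
         exons = list(data.frame(start = integer(0), end = integer(0))))
}
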