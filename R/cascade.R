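# The filtration cascade for a recessive single-proband analysis:
# control-panel subtraction -> high-impact filtering (primary annotation
# source) -> zygosity partition -> phase-aware compound-het gene logic ->
# assembly-error gene exclusion -> dual-source concordance -> candidate-gene
# intersection. Every step appends a conservation-checked row to the audit
# ledger (in = kept + removed).

new_ledger <- function() {
  tibble(step = character(0), variants_in = integer(0),
         variants_removed = integer(0), variants_kept = integer(0),
         genes_in = integer(0), genes_kept = integer(0))
}

ledger_add <- function(ledger, step, n_in, n_kept, genes_in, genes_kept) {
  stopifnot(n_in >= n_kept)
  dplyr::bind_rows(ledger, tibble(
    step = step, variants_in = as.integer(n_in),
    variants_removed = as.integer(n_in - n_kept),
    variants_kept = as.integer(n_kept),
    genes_in = as.integer(genes_in), genes_kept = as.integer(genes_kept)
  ))
}

# gene ids touched by a set of variant keys, via consequence calls
genes_of <- function(keys, consequences) {
  g <- consequences$gene_id[consequences$key %in% keys &
                              !is.na(consequences$gene_id)]
  unique(g)
}

#' Remove variants common in a control panel
#'
#' Variants whose left-aligned key matches a panel site with minor allele
#' frequency strictly greater than `maf_threshold` are removed; variants
#' absent from the panel are proband-unique and kept.
#'
#' @param variants Tibble with a `key` column (left-aligned).
#' @param panel Panel tibble from [read_panel()].
#' @param maf_threshold MAF cutoff in `[0, 0.5]`; default 0.01 (the
#'   "MAF > 1%" rule).
#' @return List with `kept` and `removed` tibbles.
#' @export
panel_subtract <- function(variants, panel, maf_threshold = 0.01) {
  if (maf_threshold < 0 || maf_threshold > 0.5) {
    abort("maf_threshold must lie in [0, 0.5]")
  }
  common <- panel$key[panel$maf > maf_threshold]
  list(kept = dplyr::filter(variants, !key %in% common),
       removed = dplyr::filter(variants, key %in% common))
}

# per-variant worst impact rank under one source
worst_impact <- function(consequences) {
  if (nrow(consequences) == 0) {
    return(tibble(key = character(0), max_rank = integer(0)))
  }
  consequences |>
    dplyr::group_by(key) |>
    dplyr::summarise(max_rank = max(c(0L, impact_rank(impact)), na.rm = TRUE),
                     .groups = "drop")
}

#' Partition surviving variants by recessive-model zygosity
#'
#' Keeps variants with at least one consequence at or above `impact_floor`
#' under the supplied (primary-source) annotation, split into homozygous
#' candidates and a heterozygous pool for compound-het analysis. Hom-ref and
#' missing/half-call genotypes are discarded.
#'
#' @param variants Tibble with `key` and `zygosity`.
#' @param consequences Consequence calls for the same variants.
#' @param impact_floor Minimum impact tier, default `"HIGH"`.
#' @return List with `hom_candidates`, `het_pool`, `removed`.
#' @export
recessive_partition <- function(variants, consequences,
                                impact_floor = "HIGH") {
  floor_rank <- impact_rank(impact_floor)
  wi <- worst_impact(consequences)
  v <- dplyr::left_join(variants, wi, by = "key")
  v$max_rank[is.na(v$max_rank)] <- 0L
  qualifying <- v$max_rank >= floor_rank
  hom <- v[qualifying & v$zygosity == "hom_alt", ]
  het <- v[qualifying & v$zygosity == "het", ]
  removed <- v[!(qualifying & v$zygosity %in% c("hom_alt", "het")), ]
  list(hom_candidates = dplyr::select(hom, -max_rank),
       het_pool = dplyr::select(het, -max_rank),
       removed = dplyr::select(removed, -max_rank))
}

# haplotype side carrying the alternate allele: 1, 2 or NA
alt_side <- function(a1, a2) {
  if (is.na(a1) || is.na(a2)) return(NA_integer_)
  if (a1 == 1 && a2 == 0) return(1L)
  if (a1 == 0 && a2 == 1) return(2L)
  NA_integer_
}

pair_configuration <- function(va, vb) {
  if (!isTRUE(va$phased) || !isTRUE(vb$phased) ||
      is.na(va$phase_set) || is.na(vb$phase_set) ||
      va$phase_set != vb$phase_set) {
    return("unresolved")
  }
  sa <- alt_side(va$allele1, va$allele2)
  sb <- alt_side(vb$allele1, vb$allele2)
  if (is.na(sa) || is.na(sb)) return("unresolved")
  if (sa != sb) "trans" else "cis"
}

#' Compound-heterozygous gene analysis
#'
#' A gene is retained when it carries at least two qualifying heterozygous
#' variants and at least one pair is in trans (alternate alleles on opposite
#' haplotypes of the same phase set) or of unknown relative phase
#' (flagged `"unresolved"`, never silently promoted to trans). Genes whose
#' pairs are all in cis are excluded.
#'
#' @param het_pool Het variants from [recessive_partition()] (columns `key`,
#'   `allele1`, `allele2`, `phased`, `phase_set`).
#' @param consequences Consequence calls providing gene assignment.
#' @return Tibble of retained pairs: `gene_id`, `key_a`, `key_b`,
#'   `configuration` (`"trans"` or `"unresolved"`).
#' @export
compound_het_genes <- function(het_pool, consequences) {
  empty <- tibble(gene_id = character(0), key_a = character(0),
                  key_b = character(0), configuration = character(0))
  if (nrow(het_pool) == 0) return(empty)
  gene_map <- consequences |>
    dplyr::filter(key %in% het_pool$key, !is.na(gene_id)) |>
    dplyr::distinct(key, gene_id)
  out <- list()
  for (g in unique(gene_map$gene_id)) {
    ks <- gene_map$key[gene_map$gene_id == g]
    vs <- het_pool[match(ks, het_pool$key), ]
    if (nrow(vs) < 2) next
    for (i in seq_len(nrow(vs) - 1)) {
      for (j in seq.int(i + 1, nrow(vs))) {
        cfg <- pair_configuration(vs[i, ], vs[j, ])
        if (cfg %in% c("trans", "unresolved")) {
          out[[length(out) + 1]] <- tibble(
            gene_id = g, key_a = vs$key[i], key_b = vs$key[j],
            configuration = cfg
          )
        }
      }
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Exclude variants confined to assembly-error genes
#'
#' A variant is removed only when every gene it touches is flagged; variants
#' also touching an unflagged gene are kept.
#'
#' @param variants Tibble with `key`.
#' @param consequences Consequence calls providing gene assignment.
#' @param flags Character vector of flagged gene ids (or symbols).
#' @return List with `kept` and `removed`.
#' @export
exclude_assembly_errors <- function(variants, consequences, flags) {
  if (length(flags) == 0 || nrow(variants) == 0) {
    return(list(kept = variants, removed = variants[0, ]))
  }
  flagged <- function(gid, gsym) {
    gid %in% flags | gsym %in% flags
  }
  gm <- consequences |>
    dplyr::filter(key %in% variants$key, !is.na(gene_id)) |>
    dplyr::group_by(key) |>
    dplyr::summarise(all_flagged = all(flagged(gene_id, gene_symbol)),
                     .groups = "drop")
  bad <- gm$key[gm$all_flagged]
  list(kept = dplyr::filter(variants, !key %in% bad),
       removed = dplyr::filter(variants, key %in% bad))
}

#' Require high impact under both annotation sources
#'
#' @param variants Tibble with `key`.
#' @param calls_a,calls_b Consequence calls from the two sources.
#' @param impact_floor Minimum tier that must be met under each source.
#' @return List with `kept` and `removed`.
#' @export
concordance_filter <- function(variants, calls_a, calls_b,
                               impact_floor = "HIGH") {
  if (is.null(calls_a)) abort("missing annotation source: sourceA")
  if (is.null(calls_b)) abort("missing annotation source: sourceB")
  floor_rank <- impact_rank(impact_floor)
  ok_a <- worst_impact(calls_a)
  ok_b <- worst_impact(calls_b)
  good <- intersect(ok_a$key[ok_a$max_rank >= floor_rank],
                    ok_b$key[ok_b$max_rank >= floor_rank])
  list(kept = dplyr::filter(variants, key %in% good),
       removed = dplyr::filter(variants, !key %in% good))
}

#' Restrict to candidate disease genes
#'
#' Matching is by gene id first, then case-insensitive gene symbol.
#'
#' @param variants Tibble with `key`.
#' @param consequences Consequence calls providing gene assignment.
#' @param candidate_genes Non-empty character vector of gene ids/symbols.
#' @return List with `kept` and `removed`.
#' @export
candidate_gene_filter <- function(variants, consequences, candidate_genes) {
  if (length(candidate_genes) == 0) {
    abort("candidate gene set is empty but candidate filtering is enabled")
  }
  cand <- toupper(candidate_genes)
  hits <- consequences |>
    dplyr::filter(key %in% variants$key,
                  toupper(gene_id) %in% cand |
                    toupper(gene_symbol) %in% cand)
  list(kept = dplyr::filter(variants, key %in% hits$key),
       removed = dplyr::filter(variants, !key %in% hits$key))
}

#' Run the full filtration cascade
#'
#' Executes panel subtraction, dual-source annotation, high-impact filtering
#' (primary source), zygosity partition, compound-het gene logic,
#' assembly-error exclusion, dual-source concordance and (optionally)
#' candidate-gene intersection, recording an audit ledger after every step.
#' Fully deterministic given its inputs.
#'
#' @param proband Proband callset tibble from [read_proband_vcf()].
#' @param panel Panel tibble from [read_panel()].
#' @param transcripts_a,transcripts_b Transcript tibbles for the two
#'   annotation sources.
#' @param genome A `ref_genome`.
#' @param flags Character vector of assembly-error gene ids (may be empty).
#' @param candidate_genes Character vector of candidate gene ids/symbols.
#' @param maf_threshold Panel MAF cutoff, default 0.01.
#' @param impact_floor Minimum impact tier, default `"HIGH"`.
#' @param use_candidate_filter Disable to obtain the genome-wide candidate
#'   table.
#' @param use_concordance,use_assembly_filter Stage toggles.
#' @return An object of class `cascade_result`: a list with `candidates`
#'   (final tibble), `ledger`, `calls_a`, `calls_b`, `comphet_pairs`,
#'   and `params`.
#' @export
run_cascade <- function(proband, panel, transcripts_a, transcripts_b,
                        genome, flags = character(0),
                        candidate_genes = character(0),
                        maf_threshold = 0.01, impact_floor = "HIGH",
                        use_candidate_filter = TRUE,
                        use_concordance = TRUE,
                        use_assembly_filter = TRUE) {
  ledger <- new_ledger()
  v0 <- left_align(proband, genome)

  ps <- panel_subtract(v0, panel, maf_threshold)
  calls_a <- annotate_callset(ps$kept, transcripts_a, genome, "sourceA")
  calls_b <- annotate_callset(ps$kept, transcripts_b, genome, "sourceB")
  genes_all <- function(keys) length(genes_of(keys, calls_a))
  ledger <- ledger_add(ledger, "panel_subtract", nrow(v0), nrow(ps$kept),
                       NA_integer_, genes_all(ps$kept$key))

  part <- recessive_partition(ps$kept, calls_a, impact_floor)
  pool <- dplyr::bind_rows(part$hom_candidates, part$het_pool)
  ledger <- ledger_add(ledger, "high_impact_recessive",
                       nrow(ps$kept), nrow(pool),
                       genes_all(ps$kept$key), genes_all(pool$key))

  pairs <- compound_het_genes(part$het_pool, calls_a)
  het_kept_keys <- unique(c(pairs$key_a, pairs$key_b))
  het_kept <- dplyr::filter(part$het_pool, key %in% het_kept_keys)
  pool2 <- dplyr::bind_rows(part$hom_candidates, het_kept)
  ledger <- ledger_add(ledger, "compound_het", nrow(pool), nrow(pool2),
                       genes_all(pool$key), genes_all(pool2$key))

  if (use_assembly_filter) {
    ae <- exclude_assembly_errors(pool2, calls_a, flags)
    ledger <- ledger_add(ledger, "assembly_errors", nrow(pool2),
                         nrow(ae$kept), genes_all(pool2$key),
                         genes_all(ae$kept$key))
    pool3 <- ae$kept
  } else {
    pool3 <- pool2
  }

  if (use_concordance) {
    cc <- concordance_filter(pool3, calls_a, calls_b, impact_floor)
    ledger <- ledger_add(ledger, "dual_source_concordance", nrow(pool3),
                         nrow(cc$kept), genes_all(pool3$key),
                         genes_all(cc$kept$key))
    pool4 <- cc$kept
  } else {
    pool4 <- pool3
  }

  if (use_candidate_filter) {
    cg <- candidate_gene_filter(pool4, calls_a, candidate_genes)
    ledger <- ledger_add(ledger, "candidate_genes", nrow(pool4),
                         nrow(cg$kept), genes_all(pool4$key),
                         genes_all(cg$kept$key))
    final <- cg$kept
  } else {
    final <- pool4
  }

  candidates <- final |>
    dplyr::left_join(
      calls_a |>
        dplyr::filter(impact_rank(impact) >= impact_rank(impact_floor)) |>
        dplyr::group_by(key) |>
        dplyr::slice_max(impact_rank(impact), n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::select(key, gene_id, gene_symbol, transcript_id, category,
                      impact, hgvs_c, hgvs_g, wt_protein_length,
                      mut_protein_length, first_divergent_residue,
                      premature_stop),
      by = "key"
    ) |>
    dplyr::arrange(contig, pos, alt)

  structure(
    list(candidates = candidates, ledger = ledger,
         calls_a = calls_a, calls_b = calls_b, comphet_pairs = pairs,
         params = list(maf_threshold = maf_threshold,
                       impact_floor = impact_floor,
                       use_candidate_filter = use_candidate_filter,
                       use_concordance = use_concordance,
                       use_assembly_filter = use_assembly_filter)),
    class = "cascade_result"
  )
}

#' Run the cascade from file paths
#'
#' Convenience wrapper loading all inputs with the package readers.
#'
#' @param vcf,panel,fasta,gff_a,gff_b File paths.
#' @param flags,candidates Paths to one-gene-per-line text files (optional).
#' @param ... Passed to [run_cascade()].
#' @return A `cascade_result`.
#' @export
run_cascade_files <- function(vcf, panel, fasta, gff_a, gff_b,
                              flags = NULL, candidates = NULL, ...) {
  genome <- read_genome(fasta)
  run_cascade(
    proband = read_proband_vcf(vcf),
    panel = read_panel(panel),
    transcripts_a = read_transcripts(gff_a, genome),
    transcripts_b = read_transcripts(gff_b, genome),
    genome = genome,
    flags = if (is.null(flags)) character(0) else read_gene_list(flags),
    candidate_genes = if (is.null(candidates)) character(0)
    else read_gene_list(candidates),
    ...
  )
}

#' Read a one-gene-per-line text file
#'
#' @param path File path; blank lines and `#` comments ignored.
#' @return Character vector of gene ids/symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("gene list not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
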