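# Deterministic synthetic test worlds: a reference FASTA, two GFF3
# annotation sources, a control-panel allele-frequency table, a proband VCF
# with a planted causal variant plus structured decoys, assembly-error and
# candidate gene lists, and a ground-truth manifest. Each decoy class is
# built to be removed by exactly one cascade step:
#   common_high        panel MAF > threshold           -> panel_subtract
#   private_low        synonymous (LOW impact)         -> high_impact_recessive
#   singleton_het_high single qualifying het per gene  -> compound_het
#   cis_het_pair       two hets phased onto one haplotype -> compound_het
#   flagged_gene       hom HIGH confined to a flagged gene -> assembly_errors
#   source_discordant  HIGH under source A only        -> dual_source_concordance
#   noncandidate_survivor hom HIGH outside candidates  -> candidate_genes

NONSTOP_CODONS <- local({
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free open reading frame: ATG + (n_codons - 1) non-stop codons + stop,
# built by codon-level rejection (sampling only from non-stop codons)
random_orf <- function(n_codons) {
  body <- sample(NONSTOP_CODONS, n_codons - 1, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

#' Scenario configuration for the synthetic world generator
#'
#' Defaults describe the study conditions the generator emulates: a
#' 100-individual control panel, a proband callset of a few hundred variants
#' and a causal homozygous frameshift insertion planted in a candidate gene
#' amid decoy classes targeting each cascade filter.
#'
#' @param seed Integer seed; identical configurations are byte-reproducible.
#' @param n_contigs,contig_length Reference layout.
#' @param n_genes Total gene count (roles are assigned internally:
#'   candidate, assembly-flagged, annotation-discordant, plain).
#' @param n_candidate_genes,n_flagged_genes,n_discordant_genes Role counts.
#' @param panel_samples Number of panel individuals (2N chromosomes).
#' @param n_proband_variants Total proband variants including the causal one.
#' @param mix Named fractions of the decoy classes (sum <= 1; the remainder
#'   is assigned to `private_low`).
#' @param causal One of `"hom_frameshift"`, `"compound_het_trans"`, `"none"`.
#' @param maf_threshold The downstream panel cutoff the classes are built
#'   around (common decoys get MAF above it, rare panel sites at or below).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            n_contigs = 2L,
                            contig_length = 60000L,
                            n_genes = 24L,
                            n_candidate_genes = 3L,
                            n_flagged_genes = 3L,
                            n_discordant_genes = 3L,
                            panel_samples = 100L,
                            n_proband_variants = 200L,
                            mix = c(common_high = 0.30,
                                    private_low = 0.30,
                                    singleton_het_high = 0.04,
                                    cis_het_pair = 0.03,
                                    flagged_gene = 0.04,
                                    source_discordant = 0.04,
                                    noncandidate_survivor = 0.02),
                            causal = c("hom_frameshift",
                                       "compound_het_trans", "none"),
                            maf_threshold = 0.01) {
  causal <- match.arg(causal)
  if (sum(mix) > 1 + 1e-9) abort("decoy mix fractions must sum to <= 1")
  if (any(mix < 0)) abort("decoy mix fractions must be non-negative")
  structure(
    list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
         contig_length = as.integer(contig_length),
         n_genes = as.integer(n_genes),
         n_candidate_genes = as.integer(n_candidate_genes),
         n_flagged_genes = as.integer(n_flagged_genes),
         n_discordant_genes = as.integer(n_discordant_genes),
         panel_samples = as.integer(panel_samples),
         n_proband_variants = as.integer(n_proband_variants),
         mix = mix, causal = causal, maf_threshold = maf_threshold),
    class = "scenario_config"
  )
}

# ---- gene construction -----------------------------------------------------

# build one gene in a slot [slot_start, slot_end]; returns a transcript row
# and the genomic sequence chunk to splice into the contig
build_gene <- function(gene_id, symbol, contig, slot_start, slot_end,
                       strand, n_codons, n_exons) {
  cds <- random_orf(n_codons)
  utr5 <- random_bases(12)
  utr3 <- random_bases(12)
  tx_seq <- paste0(utr5, cds, utr3)  # exonic sequence, transcription order
  tx_len <- nchar(tx_seq)
  # split exonic sequence into n_exons chunks (cuts away from CDS ends)
  if (n_exons > 1) {
    cuts <- sort(sample(seq(30L, tx_len - 30L), n_exons - 1))
  } else {
    cuts <- integer(0)
  }
  bounds <- c(0L, cuts, tx_len)
  intron_lens <- if (n_exons > 1) sample(80:150, n_exons - 1, replace = TRUE)
  else integer(0)

  # assemble pre-mRNA (transcription order) with GT...AG introns
  chunks <- character(0)
  exon_tx <- list()  # transcript-order exon offsets within pre-mRNA
  off <- 0L
  for (i in seq_len(n_exons)) {
    ex_seq <- substr(tx_seq, bounds[i] + 1L, bounds[i + 1L])
    chunks <- c(chunks, ex_seq)
    exon_tx[[i]] <- c(off + 1L, off + nchar(ex_seq))
    off <- off + nchar(ex_seq)
    if (i < n_exons) {
      il <- intron_lens[i]
      intron <- paste0("GT", random_bases(il - 4L), "AG")
      chunks <- c(chunks, intron)
      off <- off + il
    }
  }
  pre <- paste(chunks, collapse = "")
  glen <- nchar(pre)
  if (slot_start + glen - 1L > slot_end) {
    abort("infeasible config: gene does not fit its contig slot")
  }
  gstart <- slot_start

  # map transcript-order offsets to genomic intervals
  to_genomic <- function(o1, o2) {
    if (strand == "+") c(gstart + o1 - 1L, gstart + o2 - 1L)
    else c(gstart + glen - o2, gstart + glen - o1)
  }
  ex_g <- lapply(exon_tx, function(e) to_genomic(e[1], e[2]))
  exons <- do.call(rbind, lapply(ex_g, function(e)
    data.frame(start = as.integer(e[1]), end = as.integer(e[2]))))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds_tx <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds))
  # CDS genomic extremes: map the two transcript end offsets of the CDS
  # through the exon structure
  # o is an offset in the exonic (spliced) sequence; map via the exon that
  # contains it into pre-mRNA coordinates, then to the genome
  tx_to_g <- function(o) {
    for (i in seq_len(n_exons)) {
      if (o > bounds[i] && o <= bounds[i + 1]) {
        pre_off <- exon_tx[[i]][1] + (o - bounds[i] - 1L)
        return(to_genomic(pre_off, pre_off)[1])
      }
    }
    abort("offset not exonic")
  }
  g1 <- tx_to_g(cds_tx[1]); g2 <- tx_to_g(cds_tx[2])
  seq_genomic <- if (strand == "+") pre else revcomp(pre)

  list(
    row = tibble(
      transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
      gene_symbol = symbol, contig = contig, strand = strand,
      cds_start = as.integer(min(g1, g2)), cds_end = as.integer(max(g1, g2)),
      exons = list(exons), valid = TRUE, invalid_reason = NA_character_
    ),
    gstart = gstart, gend = gstart + glen - 1L, seq = seq_genomic
  )
}

# ---- variant builders (transcript frame -> genomic VCF representation) -----

tx_codon <- function(cds, j) substr(cds, 3 * j - 2, 3 * j)

# Enumerate every single-base coding edit in [lo, hi] (codon indices) that
# satisfies `pred(wt_codon, mut_codon)`; rows are returned shuffled so a
# caller can walk them until one is placeable.
enumerate_codon_snvs <- function(cds, codon_range, pred) {
  rows <- list()
  for (j in seq.int(codon_range[1], codon_range[2])) {
    cod <- tx_codon(cds, j)
    for (p in 1:3) {
      wt_b <- substr(cod, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), wt_b)) {
        mut <- cod
        substr(mut, p, p) <- b
        if (pred(cod, mut)) {
          rows[[length(rows) + 1]] <- list(c_start = 3L * (j - 1L) + p,
                                           seq = b)
        }
      }
    }
  }
  if (length(rows) == 0) return(rows)
  rows[sample.int(length(rows))]
}


stop_gain_pred <- function(wt, mut) is_stop_codon(mut) && !is_stop_codon(wt)

synonymous_pred <- local({
  code <- NULL
  function(wt, mut) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    !is_stop_codon(wt) && !is_stop_codon(mut) && code[[wt]] == code[[mut]]
  }
})

#' Plant an out-of-frame insertion in a gene
#'
#' Draws a random insertion allele of the requested (out-of-frame) length,
#' placed after coding position `c_anchor`, resampling until the mutant
#' protein diverges at the first affected codon and is truncated by a
#' premature stop. The expected divergence anatomy is returned as ground
#' truth.
#'
#' @param t One transcript row (the host gene).
#' @param genome A `ref_genome`.
#' @param ins_length Insertion length; must not be a multiple of 3.
#' @param c_anchor Coding position after which the insertion is placed.
#' @return List with `variant` (genomic VCF-style tibble), `insert_tx`
#'   (allele in transcript orientation), `expected` (list with
#'   `first_divergent_residue` and `preserved_prefix_aa`).
#' @export
plant_frameshift <- function(t, genome, ins_length = 8L, c_anchor = 19L) {
  if (ins_length %% 3 == 0) {
    abort("ins_length must not be a multiple of 3 (in-frame insertion)")
  }
  t <- as_transcript_row(t)
  cds <- spliced_cds(t, genome)
  if (nchar(cds) <= c_anchor + 3) abort("CDS too short for this anchor")
  first_codon <- as.integer(ceiling((c_anchor + 1) / 3))
  wt <- translate_cds(cds)
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > 1000L) {
      # a CDS whose shifted frame is stop-free downstream of the anchor
      # admits no truncating insertion of this length class
      abort("no truncating insertion found for this CDS and anchor")
    }
    ins <- random_bases(ins_length)
    mut_cds <- apply_cds_edit(cds, list(kind = "ins", c_start = c_anchor,
                                        c_end = c_anchor + 1L, seq = ins))
    mut <- translate_cds(mut_cds)
    fdr <- first_divergence(wt$protein, mut$protein)
    truncated <- !mut$no_stop && nchar(mut$protein) < nchar(wt$protein)
    if (fdr == first_codon && truncated) break
  }
  variant <- coding_edit_to_variant(
    list(kind = "ins", c_start = c_anchor, seq = ins), t, genome)
  list(variant = variant, insert_tx = ins,
       expected = list(first_divergent_residue = first_codon,
                       preserved_prefix_aa = first_codon - 1L))
}

# ---- panel -----------------------------------------------------------------

#' Assign panel allele frequencies to a pool of sites
#'
#' Sites draw a minor allele frequency from a fixed grid spanning absent,
#' below-threshold, boundary (exactly the threshold) and common categories;
#' allele counts are exact over `2 * panel_samples` chromosomes.
#'
#' @param cfg A `scenario_config` (uses `panel_samples`).
#' @param site_pool Tibble with `contig`, `pos`, `ref`, `alt`.
#' @param weights Mixture weights over the MAF grid
#'   `c(0, 0.005, 0.01, 0.02, 0.05, 0.25)`.
#' @return Panel tibble with `allele_count`, `allele_number`, `maf`, `key`.
#' @export
build_panel <- function(cfg, site_pool,
                        weights = c(0.10, 0.20, 0.20, 0.20, 0.15, 0.15)) {
  grid <- c(0, 0.005, 0.01, 0.02, 0.05, 0.25)
  an <- 2L * cfg$panel_samples
  maf <- sample(grid, nrow(site_pool), replace = TRUE, prob = weights)
  ac <- as.integer(round(maf * an))
  dplyr::mutate(site_pool,
                key = variant_key(contig, pos, ref, alt),
                allele_count = ac, allele_number = an,
                maf = ac / an)
}

# ---- world assembly --------------------------------------------------------

#' Generate a self-contained synthetic test world
#'
#' Builds a reference genome with valid multi-exon gene models on both
#' strands, a control panel, and a proband callset containing the configured
#' causal variant and decoy classes, then writes all files (FASTA, two GFF3
#' sources, panel TSV, proband VCF, gene lists, ground-truth JSON) to `dir`.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list with file `paths`, in-memory objects (`genome`,
#'   `transcripts_a`, `transcripts_b`, `proband`, `panel`, `flags`,
#'   `candidates`) and the ground-`truth` manifest.
#' @export
simulate_world <- function(cfg, dir = tempfile("world")) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- with_seed(cfg$seed, build_world(cfg))
  paths <- write_world(world, dir)
  invisible(c(world, list(paths = paths, dir = dir)))
}

build_world <- function(cfg) {
  n_plain <- cfg$n_genes - cfg$n_candidate_genes - cfg$n_flagged_genes -
    cfg$n_discordant_genes
  if (n_plain < 0) abort("infeasible config: gene roles exceed n_genes")
  per_contig <- ceiling(cfg$n_genes / cfg$n_contigs)
  slot <- cfg$contig_length %/% per_contig
  if (slot < 1500) abort("infeasible config: more genes than fit contigs")

  contigs <- paste0("ctg", seq_len(cfg$n_contigs))
  backgrounds <- lapply(contigs, function(x) random_bases(cfg$contig_length))
  names(backgrounds) <- contigs

  roles <- c(rep("candidate", cfg$n_candidate_genes),
             rep("flagged", cfg$n_flagged_genes),
             rep("discordant", cfg$n_discordant_genes),
             rep("plain", n_plain))
  roles <- sample(roles)  # scatter roles across the genome

  tx_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    ctg <- contigs[((i - 1) %/% per_contig) + 1]
    slot_idx <- (i - 1) %% per_contig
    slot_start <- slot_idx * slot + 200L
    g <- build_gene(
      gene_id = sprintf("gene%02d", i),
      symbol = sprintf("SYN%02d", i),
      contig = ctg, slot_start = slot_start,
      slot_end = slot_idx * slot + slot - 200L,
      strand = sample(c("+", "-"), 1),
      n_codons = sample(120:180, 1),
      n_exons = sample(1:3, 1)
    )
    substr(backgrounds[[ctg]], g$gstart, g$gend) <- g$seq
    tx_rows[[i]] <- dplyr::mutate(g$row, role = roles[i])
  }
  genome <- structure(unlist(backgrounds), class = "ref_genome")
  names(genome) <- contigs
  tx_a <- dplyr::bind_rows(tx_rows)

  # source B: same models except discordant genes lose 45 bp of 3' CDS
  tx_b <- tx_a
  for (i in which(tx_a$role == "discordant")) {
    t <- tx_a[i, ]
    map <- cds_genomic_positions(t)
    keep <- map[seq_len(length(map) - 120L)]
    tx_b$cds_start[i] <- min(keep)
    tx_b$cds_end[i] <- max(keep)
  }

  genes <- dplyr::mutate(tx_a, n_codons = purrr::map_int(
    seq_len(dplyr::n()), function(i)
      as.integer(nchar(spliced_cds(tx_a[i, ], genome)) / 3 - 1)))

  counts <- decoy_counts(cfg)
  check_feasible(counts, genes)

  used <- new.env(parent = emptyenv())
  claim <- function(v) {
    # reserve the variant's footprint so classes never collide
    ks <- paste0(v$contig, ":", seq(v$pos - 1L, v$pos + nchar(v$ref) + 1L))
    if (any(vapply(ks, function(k) !is.null(used[[k]]), logical(1)))) {
      return(FALSE)
    }
    for (k in ks) used[[k]] <- TRUE
    TRUE
  }

  gene_rows <- function(role) which(genes$role == role)
  plain <- gene_rows("plain")
  candidate <- gene_rows("candidate")
  flaggedg <- gene_rows("flagged")
  discordant <- gene_rows("discordant")

  mid_range <- function(i) c(10L, genes$n_codons[i] - 20L)

  # per-gene transcript contexts and lazily-enumerated SNV pools; each pool
  # is computed once and consumed as variants are claimed
  ctxs <- purrr::map(seq_len(nrow(tx_a)),
                     function(i) tx_context(tx_a[i, ], genome))
  preds <- list(stop = stop_gain_pred, syn = synonymous_pred)
  snv_pool <- new.env(parent = emptyenv())
  snv_from <- function(gi, c_start, b) {
    g <- ctxs[[gi]]$map[c_start]
    ref <- slice_seq(genome, tx_a$contig[gi], g, g)
    alt <- if (tx_a$strand[gi] == "-") revcomp(b) else b
    tibble(contig = tx_a$contig[gi], pos = as.integer(g), ref = ref,
           alt = alt)
  }
  pool_draw <- function(gi, range, pred_name) {
    k <- paste(gi, pred_name, range[1], range[2])
    if (is.null(snv_pool[[k]])) {
      snv_pool[[k]] <- enumerate_codon_snvs(ctxs[[gi]]$cds, range,
                                            preds[[pred_name]])
    }
    lst <- snv_pool[[k]]
    while (length(lst) > 0) {
      e <- lst[[1]]
      lst <- lst[-1]
      v <- snv_from(gi, e$c_start, e$seq)
      if (claim(v)) {
        snv_pool[[k]] <- lst
        return(v)
      }
    }
    snv_pool[[k]] <- lst
    NULL
  }
  must_draw <- function(gi, range, pred_name) {
    v <- pool_draw(gi, range, pred_name)
    if (is.null(v)) {
      abort("infeasible config: no free site left for a decoy variant")
    }
    v
  }
  late_range <- function(i) {
    n <- genes$n_codons[i]
    c(n - 38L, n - 5L)  # inside the 120 bp removed from source B's CDS
  }

  variants <- list()
  truth_classes <- list()
  add_var <- function(v, class, gt, ps = NA_integer_) {
    v <- dplyr::mutate(v, gt = gt, ps = ps, class = class)
    variants[[length(variants) + 1]] <<- v
    key <- variant_key(v$contig, v$pos, v$ref, v$alt)
    truth_classes[[class]] <<- c(truth_classes[[class]], key)
    v
  }

  # decoys removable earlier may sit in any gene; restrict to non-candidate
  # hosts so single-class scenarios stay clean for the candidate filter too
  host_any <- c(plain, flaggedg, discordant)

  for (i in seq_len(counts$common_high)) {
    gi <- host_any[1 + (i - 1) %% length(host_any)]
    v <- must_draw(gi, mid_range(gi), "stop")
    add_var(v, "common_high", sample(c("0/1", "1/1"), 1))
  }
  for (i in seq_len(counts$private_low)) {
    gi <- host_any[1 + (i - 1) %% length(host_any)]
    v <- must_draw(gi, mid_range(gi), "syn")
    add_var(v, "private_low", sample(c("0/1", "1/1"), 1))
  }
  singles <- plain[seq_len(counts$singleton_het_high)]
  for (gi in singles) {
    v <- must_draw(gi, mid_range(gi), "stop")
    add_var(v, "singleton_het_high", "0/1")
  }
  cis_hosts <- setdiff(plain, singles)[seq_len(counts$cis_pairs)]
  ps_counter <- 1000L
  for (gi in cis_hosts) {
    ps_counter <- ps_counter + 1L
    for (r in 1:2) {
      v <- must_draw(gi, mid_range(gi), "stop")
      add_var(v, "cis_het_pair", "0|1", ps = ps_counter)
    }
  }
  for (i in seq_len(counts$flagged_gene)) {
    gi <- flaggedg[1 + (i - 1) %% length(flaggedg)]
    v <- must_draw(gi, mid_range(gi), "stop")
    add_var(v, "flagged_gene", "1/1")
  }
  for (i in seq_len(counts$source_discordant)) {
    # rotate over the discordant genes; the late window of any one gene can
    # run out of placeable stop-gain sites
    order_gi <- discordant[1 + ((i - 1) + seq_along(discordant) - 1) %%
                             length(discordant)]
    v <- NULL
    for (gi in order_gi) {
      v <- pool_draw(gi, late_range(gi), "stop")
      if (!is.null(v)) break
    }
    if (is.null(v)) {
      abort("infeasible config: discordant-gene windows exhausted")
    }
    add_var(v, "source_discordant", "1/1")
  }
  nc_hosts <- setdiff(plain, c(singles, cis_hosts))
  for (i in seq_len(counts$noncandidate_survivor)) {
    gi <- nc_hosts[1 + (i - 1) %% length(nc_hosts)]
    v <- must_draw(gi, mid_range(gi), "stop")
    add_var(v, "noncandidate_survivor", "1/1")
  }

  truth <- list(causal_keys = character(0), causal_gene = NA_character_,
                expected_final = character(0))
  # plant in the first candidate gene whose CDS admits a truncating
  # insertion (a CDS whose shifted frame is stop-free cannot truncate)
  plant_in_candidates <- function() {
    for (gi in candidate) {
      p <- tryCatch(plant_frameshift(tx_a[gi, ], genome),
                    error = function(e) NULL)
      if (!is.null(p) && claim(p$variant)) {
        return(list(p = p, gi = gi))
      }
    }
    abort("infeasible config: no candidate gene admits the causal insertion")
  }
  if (cfg$causal == "hom_frameshift") {
    pl <- plant_in_candidates()
    v <- add_var(pl$p$variant, "causal", "1/1")
    truth$causal_keys <- variant_key(v$contig, v$pos, v$ref, v$alt)
    truth$causal_gene <- genes$gene_id[pl$gi]
    truth$expected_final <- truth$causal_keys
    truth$expected_anatomy <- pl$p$expected
  } else if (cfg$causal == "compound_het_trans") {
    ps_counter <- ps_counter + 1L
    pl <- plant_in_candidates()
    v1 <- add_var(pl$p$variant, "causal", "0|1", ps = ps_counter)
    v2 <- must_draw(pl$gi, mid_range(pl$gi), "stop")
    v2 <- add_var(v2, "causal", "1|0", ps = ps_counter)
    truth$causal_keys <- c(variant_key(v1$contig, v1$pos, v1$ref, v1$alt),
                           variant_key(v2$contig, v2$pos, v2$ref, v2$alt))
    truth$causal_gene <- genes$gene_id[pl$gi]
    truth$expected_final <- truth$causal_keys
    truth$expected_anatomy <- pl$p$expected
  }

  proband <- dplyr::bind_rows(variants) |>
    dplyr::mutate(pos = as.integer(pos)) |>
    dplyr::arrange(contig, pos, alt)
  # ground-truth keys use the left-aligned representation (the cascade's
  # matching convention); planted indels can shift in repetitive context
  raw_keys <- variant_key(proband$contig, proband$pos, proband$ref,
                          proband$alt)
  aligned <- left_align(proband[, c("contig", "pos", "ref", "alt")], genome)
  keymap <- stats::setNames(aligned$key, raw_keys)
  remap <- function(x) unname(keymap[x])
  truth$causal_keys <- remap(truth$causal_keys)
  truth$expected_final <- remap(truth$expected_final)
  truth_classes <- purrr::map(truth_classes, remap)
  # mirror the read_proband_vcf() schema so the in-memory callset is
  # directly consumable by the cascade
  gtp <- purrr::map(proband$gt, function(g) {
    a <- as.integer(strsplit(g, "[/|]")[[1]])
    list(a1 = a[1], a2 = a[2], phased = grepl("|", g, fixed = TRUE))
  })
  proband <- proband |>
    dplyr::mutate(
      key = variant_key(contig, pos, ref, alt),
      info = NA_character_, sample_id = "proband",
      allele1 = purrr::map_int(gtp, "a1"),
      allele2 = purrr::map_int(gtp, "a2"),
      phased = purrr::map_lgl(gtp, "phased"),
      phase_set = ifelse(is.na(ps), NA_character_, as.character(ps)),
      zygosity = dplyr::case_when(
        allele1 == 1L & allele2 == 1L ~ "hom_alt",
        allele1 + allele2 == 1L ~ "het",
        TRUE ~ "hom_ref"
      )
    )

  # panel: every common_high site (MAF above threshold), a slice of
  # private_low sites at/below threshold, plus background-only sites
  pr_keys <- variant_key(proband$contig, proband$pos, proband$ref,
                         proband$alt)
  an <- 2L * cfg$panel_samples
  panel_rows <- list()
  ph <- proband[proband$class == "common_high", ]
  if (nrow(ph) > 0) {
    panel_rows$common <- ph |>
      dplyr::transmute(contig, pos, ref, alt,
                       allele_count = as.integer(
                         sample(c(0.02, 0.05, 0.25) * an, dplyr::n(),
                                replace = TRUE)),
                       allele_number = an)
  }
  pl <- proband[proband$class == "private_low", ]
  n_rare <- min(nrow(pl), 10L)
  if (n_rare > 0) {
    panel_rows$rare <- pl[seq_len(n_rare), ] |>
      dplyr::transmute(contig, pos, ref, alt,
                       allele_count = as.integer(
                         sample(c(0.005, 0.01) * an, n_rare,
                                replace = TRUE)),
                       allele_number = an)
  }
  bg <- background_sites(genome, 60L, used)
  panel_rows$background <- build_panel(cfg, bg) |>
    dplyr::select(contig, pos, ref, alt, allele_count, allele_number)
  panel <- dplyr::bind_rows(panel_rows) |>
    dplyr::mutate(key = variant_key(contig, pos, ref, alt),
                  maf = pmin(allele_count / allele_number,
                             1 - allele_count / allele_number)) |>
    dplyr::arrange(contig, pos, alt)

  flags <- genes$gene_id[genes$role == "flagged"]
  candidates <- genes$gene_id[genes$role == "candidate"]
  truth$classes <- truth_classes

  list(genome = genome, transcripts_a = tx_a, transcripts_b = tx_b,
       genes = genes, proband = proband, panel = panel, flags = flags,
       candidates = candidates, truth = truth, cfg = cfg)
}

decoy_counts <- function(cfg) {
  n <- cfg$n_proband_variants
  n_causal <- switch(cfg$causal, hom_frameshift = 1L,
                     compound_het_trans = 2L, none = 0L)
  frac <- function(f) {
    v <- unname(cfg$mix[f])
    if (length(v) == 0 || is.na(v)) 0 else v
  }
  common_high <- as.integer(round(frac("common_high") * n))
  singleton <- as.integer(round(frac("singleton_het_high") * n))
  cis_pairs <- as.integer(floor(frac("cis_het_pair") * n / 2))
  flagged <- as.integer(round(frac("flagged_gene") * n))
  discordant <- as.integer(round(frac("source_discordant") * n))
  nc <- as.integer(round(frac("noncandidate_survivor") * n))
  fixed <- common_high + singleton + 2L * cis_pairs + flagged + discordant +
    nc + n_causal
  private_low <- n - fixed
  if (private_low < 0) abort("infeasible config: decoy counts exceed total")
  list(common_high = common_high, private_low = private_low,
       singleton_het_high = singleton, cis_pairs = cis_pairs,
       flagged_gene = flagged, source_discordant = discordant,
       noncandidate_survivor = nc)
}

check_feasible <- function(counts, genes) {
  plain <- sum(genes$role == "plain")
  need <- counts$singleton_het_high + counts$cis_pairs +
    min(counts$noncandidate_survivor, 1L)
  if (need > plain) {
    abort("infeasible config: not enough plain genes for het/survivor classes")
  }
  if (counts$flagged_gene > 0 && sum(genes$role == "flagged") == 0) {
    abort("infeasible config: flagged decoys but no flagged genes")
  }
  if (counts$source_discordant > 0 && sum(genes$role == "discordant") == 0) {
    abort("infeasible config: discordant decoys but no discordant genes")
  }
  invisible(TRUE)
}

# panel-only SNV sites at unused positions
background_sites <- function(genome, n, used) {
  rows <- list()
  contigs <- names(genome)
  while (length(rows) < n) {
    ctg <- sample(contigs, 1)
    p <- sample(seq.int(100L, contig_length(genome, ctg) - 100L), 1)
    k <- paste0(ctg, ":", p)
    if (!is.null(used[[k]])) next
    used[[k]] <- TRUE
    ref <- slice_seq(genome, ctg, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    rows[[length(rows) + 1]] <- tibble(contig = ctg, pos = p,
                                       ref = ref, alt = alt)
  }
  dplyr::bind_rows(rows)
}

# ---- file output -----------------------------------------------------------

write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

write_gff3 <- function(tx, path, source = "varprior_sim") {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    ex <- t$exons[[1]]
    span <- c(min(ex$start), max(ex$end))
    gid <- t$gene_id
    tid <- t$transcript_id
    lines <- c(lines,
      paste(t$contig, source, "gene", span[1], span[2], ".", t$strand, ".",
            sprintf("ID=%s;gene_id=%s;gene_symbol=%s", gid, gid,
                    t$gene_symbol), sep = "\t"),
      paste(t$contig, source, "mRNA", span[1], span[2], ".", t$strand, ".",
            sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(t$contig, source, "exon", ex$start[j], ex$end[j], ".",
              t$strand, ".", sprintf("Parent=%s", tid), sep = "\t"))
    }
    # CDS segments with phase, in transcription order
    segs <- list()
    for (j in seq_len(nrow(ex))) {
      s <- max(ex$start[j], t$cds_start)
      e <- min(ex$end[j], t$cds_end)
      if (s <= e) segs[[length(segs) + 1]] <- c(s, e)
    }
    if (t$strand == "-") segs <- rev(segs)
    cum <- 0L
    for (sg in segs) {
      phase <- (3L - (cum %% 3L)) %% 3L
      lines <- c(lines,
        paste(t$contig, source, "CDS", sg[1], sg[2], ".", t$strand, phase,
              sprintf("Parent=%s", tid), sep = "\t"))
      cum <- cum + (sg[2] - sg[1] + 1L)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_world <- function(world, dir) {
  p <- function(f) file.path(dir, f)
  paths <- list(
    fasta = p("genome.fa"), gff_a = p("annotation_sourceA.gff3"),
    gff_b = p("annotation_sourceB.gff3"), panel = p("panel.tsv"),
    proband = p("proband.vcf"), flags = p("flagged_genes.txt"),
    candidates = p("candidate_genes.txt"), truth = p("truth.json")
  )
  write_fasta(world$genome, paths$fasta)
  write_gff3(world$transcripts_a, paths$gff_a)
  write_gff3(world$transcripts_b, paths$gff_b)
  write_panel_tsv(world$panel, paths$panel)
  write_vcf_file(world$proband, paths$proband,
                 contig_lengths = vapply(names(world$genome), function(x)
                   contig_length(world$genome, x), integer(1)))
  writeLines(world$flags, paths$flags)
  writeLines(world$candidates, paths$candidates)
  jsonlite::write_json(world$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE)
  paths
}
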