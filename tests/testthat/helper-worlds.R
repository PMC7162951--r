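# Shared fixtures and independent brute-force oracles. Oracles are written
# from first principles (string surgery, exhaustive enumeration, Biostrings
# as an external reference) and never call the code paths they check.

toy_genome <- function(...) {
  seqs <- c(...)
  structure(seqs, class = "ref_genome")
}

toy_transcript <- function(contig, strand, exons, cds_start, cds_end,
                           transcript_id = "tx1", gene_id = "gene1",
                           gene_symbol = "GENE1") {
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id,
    gene_symbol = gene_symbol, contig = contig, strand = strand,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    exons = list(data.frame(start = as.integer(exons[, 1]),
                            end = as.integer(exons[, 2]))),
    valid = TRUE, invalid_reason = NA_character_
  )
}

# a random stop-free ORF (ATG + non-stop codons + TAA) as plain string;
# independent of the package's generator
oracle_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
  pool <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(pool, n_codons - 1, replace = TRUE),
                      collapse = ""), "TAA")
}

# single-contig plus-strand world around an ORF, for coding-variant tests
orf_world <- function(n_codons = 100, flank = 30) {
  cds <- oracle_orf(n_codons)
  seq <- paste0(paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                      collapse = ""),
                cds,
                paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                      collapse = ""))
  genome <- toy_genome(chrT = seq)
  t <- toy_transcript("chrT", "+",
                      matrix(c(flank + 1, flank + nchar(cds)), ncol = 2),
                      flank + 1, flank + nchar(cds))
  list(genome = genome, t = t, cds = cds, cds_offset = flank)
}

# --- oracles ---------------------------------------------------------------

# Biostrings-based translation to first stop (external reference)
oracle_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n)),
    if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

# Exhaustive equivalent-placement enumeration. A placement after position p
# is equivalent when SOME inserted allele there (necessarily
# target[p+1..p+L]) reproduces the alternate haplotype, i.e. when the
# reference prefix up to p and the suffix after p match the target around
# the inserted block. This admits rotated alleles, matching the biology of
# an insertion arising anywhere in a tandem repeat.
oracle_placements <- function(context, after, insert) {
  n <- nchar(context)
  L <- nchar(insert)
  target <- paste0(substr(context, 1, after), insert,
                   substr(context, after + 1, n))
  which(vapply(0:n, function(p) {
    substr(context, 1, p) == substr(target, 1, p) &&
      substr(context, p + 1, n) == substr(target, p + L + 1, n + L)
  }, logical(1))) - 1L
}

# leftmost anchor of an insertion's VCF representation = the 5'-most
# equivalent placement
oracle_leftmost_insertion <- function(context, after, insert) {
  min(oracle_placements(context, after, insert))
}

# apply a VCF-style variant to a genome slice (independent of the package)
oracle_apply <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# brute-force compound-het gene retention: nested loops over all pairs
oracle_comphet <- function(het, gene_map) {
  side <- function(a1, a2) {
    if (a1 == 1 && a2 == 0) 1L else if (a1 == 0 && a2 == 1) 2L else NA_integer_
  }
  kept <- list()
  for (g in unique(gene_map$gene_id)) {
    ks <- gene_map$key[gene_map$gene_id == g]
    vs <- het[het$key %in% ks, ]
    if (nrow(vs) < 2) next
    for (i in seq_len(nrow(vs) - 1)) {
      for (j in (i + 1):nrow(vs)) {
        a <- vs[i, ]; b <- vs[j, ]
        cfg <- if (a$phased && b$phased && !is.na(a$phase_set) &&
                   !is.na(b$phase_set) && a$phase_set == b$phase_set) {
          sa <- side(a$allele1, a$allele2)
          sb <- side(b$allele1, b$allele2)
          if (is.na(sa) || is.na(sb)) "unresolved"
          else if (sa != sb) "trans" else "cis"
        } else {
          "unresolved"
        }
        if (cfg != "cis") {
          kept[[length(kept) + 1]] <- data.frame(
            gene_id = g, key_a = a$key, key_b = b$key,
            configuration = cfg)
        }
      }
    }
  }
  if (length(kept) == 0) {
    data.frame(gene_id = character(0), key_a = character(0),
               key_b = character(0), configuration = character(0))
  } else {
    do.call(rbind, kept)
  }
}

# random het-pool fixture for compound-het tests
random_het_fixture <- function(n_genes = 10, max_per_gene = 4) {
  rows <- list()
  keys <- 0L
  gm <- list()
  for (g in seq_len(n_genes)) {
    gid <- paste0("g", g)
    nv <- sample(1:max_per_gene, 1)
    ps <- sample(c(NA_character_, "100", "200"), 1)
    for (v in seq_len(nv)) {
      keys <- keys + 1L
      key <- paste0("k", keys)
      phased <- runif(1) < 0.6
      this_ps <- if (phased) sample(c("100", "200"), 1) else NA_character_
      a <- if (runif(1) < 0.5) c(0L, 1L) else c(1L, 0L)
      rows[[keys]] <- tibble::tibble(
        key = key, allele1 = a[1], allele2 = a[2], phased = phased,
        phase_set = this_ps, zygosity = "het",
        contig = "c", pos = keys, ref = "A", alt = "T")
      gm[[keys]] <- tibble::tibble(key = key, gene_id = gid)
    }
  }
  list(het = dplyr::bind_rows(rows), gene_map = dplyr::bind_rows(gm))
}

# small cached default worlds so multiple test files can share them
.world_cache <- new.env(parent = emptyenv())
cached_world <- function(seed, ...) {
  key <- paste(seed, ..., sep = "_")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- simulate_world(scenario_config(seed = seed, ...))
  }
  .world_cache[[key]]
}

run_cascade_mem <- function(w, ...) {
  run_cascade(w$proband, w$panel, w$transcripts_a, w$transcripts_b,
              w$genome, w$flags, w$candidates, ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
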