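# Consequence classification and mutant-protein computation, checked
# against an independent apply-then-translate oracle.

test_that("out-of-frame insertions are frameshift HIGH, in-frame are MODERATE", {
  set.seed(31)
  w <- orf_world(80)
  g10 <- cds_to_genomic(w$t, 10)
  # 8-bp insertion inside the CDS (length mod 3 = 2)
  v8 <- tibble::tibble(contig = "chrT", pos = g10,
                       ref = substr(w$cds, 10, 10),
                       alt = paste0(substr(w$cds, 10, 10), "CGGCCCCC"))
  c8 <- classify_variant(v8, w$t, w$genome)
  expect_identical(c8$category, "frameshift")
  expect_identical(c8$impact, "HIGH")

  # 3-bp insertion at a codon boundary (after c.12)
  g12 <- cds_to_genomic(w$t, 12)
  v3 <- tibble::tibble(contig = "chrT", pos = g12,
                       ref = substr(w$cds, 12, 12),
                       alt = paste0(substr(w$cds, 12, 12), "GCT"))
  c3 <- classify_variant(v3, w$t, w$genome)
  expect_identical(c3$category, "inframe_insertion")
  expect_identical(c3$impact, "MODERATE")
})

test_that("splice-site SNVs at the two intronic junction bases are HIGH", {
  set.seed(32)
  cds <- oracle_orf(40)
  # two exons split inside the CDS, plus strand; intron of 100 bp
  ex1_seq <- substr(cds, 1, 60)
  ex2_seq <- substr(cds, 61, nchar(cds))
  intron <- paste0("GT", random_dna(96), "AG")
  genome <- toy_genome(c1 = paste0(random_dna(20), ex1_seq, intron,
                                   ex2_seq, random_dna(20)))
  ex <- matrix(c(21, 80, 181, 180 + nchar(ex2_seq)), ncol = 2, byrow = TRUE)
  t <- toy_transcript("c1", "+", ex, 21, 180 + nchar(ex2_seq))

  donor1 <- tibble::tibble(contig = "c1", pos = 81L, ref = "G", alt = "T")
  cd <- classify_variant(donor1, t, genome)
  expect_identical(cd$category, "splice_donor")
  expect_identical(cd$impact, "HIGH")

  acc <- tibble::tibble(contig = "c1", pos = 180L, ref = "G", alt = "C")
  ca <- classify_variant(acc, t, genome)
  expect_identical(ca$category, "splice_acceptor")

  deep <- tibble::tibble(contig = "c1", pos = 120L,
                         ref = substr(genome[["c1"]], 120, 120),
                         alt = setdiff(c("A", "C", "G", "T"),
                                       substr(genome[["c1"]], 120, 120))[1])
  expect_identical(classify_variant(deep, t, genome)$category, "intronic")
})

test_that("stop-gain, synonymous, missense and start-loss SNVs classify by translation", {
  # hand-built CDS: ATG GCC TAT AAA CTG ... TAA
  cds <- paste0("ATGGCCTATAAACTG", strrep("GAC", 10), "TAA")
  genome <- toy_genome(c1 = paste0(strrep("A", 10), cds, strrep("A", 10)))
  t <- toy_transcript("c1", "+", matrix(c(11, 10 + nchar(cds)), ncol = 2),
                      11, 10 + nchar(cds))
  at <- function(k) 10L + k
  # TAT -> TAA (c.9 T>A): stop gained
  v <- tibble::tibble(contig = "c1", pos = at(9), ref = "T", alt = "A")
  cc <- classify_variant(v, t, genome)
  expect_identical(cc$category, "stop_gained")
  expect_true(cc$premature_stop)
  expect_equal(cc$mut_protein_length, 2)
  # GCC -> GCG (c.6 C>G): synonymous, never HIGH
  v <- tibble::tibble(contig = "c1", pos = at(6), ref = "C", alt = "G")
  cc <- classify_variant(v, t, genome)
  expect_identical(cc$category, "synonymous")
  expect_identical(cc$impact, "LOW")
  expect_equal(cc$first_divergent_residue, 0)
  # GCC -> GTC (c.5 C>T): missense at residue 2
  v <- tibble::tibble(contig = "c1", pos = at(5), ref = "C", alt = "T")
  cc <- classify_variant(v, t, genome)
  expect_identical(cc$category, "missense")
  expect_equal(cc$first_divergent_residue, 2)
  # ATG -> ATC (c.3 G>C): start lost, zero-length product
  v <- tibble::tibble(contig = "c1", pos = at(3), ref = "G", alt = "C")
  cc <- classify_variant(v, t, genome)
  expect_identical(cc$category, "start_lost")
  expect_equal(cc$mut_protein_length, 0)
  # terminal TAA -> CAA: stop lost
  v <- tibble::tibble(contig = "c1", pos = at(nchar(cds) - 2),
                      ref = "T", alt = "C")
  expect_identical(classify_variant(v, t, genome)$category, "stop_lost")
})

test_that("mutant proteins equal the apply-then-translate oracle on random deletions", {
  set.seed(33)
  for (i in 1:500) {
    w <- if (i %% 50 == 1) orf_world(100) else w   # reuse worlds in blocks
    k <- sample(2:(nchar(w$cds) - 5), 1)
    g <- cds_to_genomic(w$t, k)
    # 1-bp deletion: anchor at the previous base
    v <- tibble::tibble(
      contig = "chrT", pos = g - 1L,
      ref = substr(w$genome[["chrT"]], g - 1L, g),
      alt = substr(w$genome[["chrT"]], g - 1L, g - 1L)
    )
    mp <- mutant_protein(v, w$t, w$genome)
    mut_cds <- paste0(substr(w$cds, 1, k - 1),
                      substr(w$cds, k + 1, nchar(w$cds)))
    expect_identical(mp$protein, oracle_translate(mut_cds))
  }
})

test_that("consequences are invariant across equivalent insertion placements", {
  set.seed(34)
  for (rep in 1:20) {
    unit <- random_dna(sample(1:3, 1))
    cds <- paste0("ATG", strrep(unit, 4),
                  oracle_orf(40) |> substr(4, 999))
    cds <- substr(cds, 1, nchar(cds) - nchar(cds) %% 3)
    genome0 <- paste0(random_dna(15), cds, random_dna(15))
    genome <- toy_genome(c1 = genome0)
    t <- toy_transcript("c1", "+", matrix(c(16, 15 + nchar(cds)), ncol = 2),
                        16, 15 + nchar(cds))
    ins <- unit  # same repeat unit: guaranteed multi-placement run
    anchor <- 3 + nchar(unit)
    pl <- enumerate_placements(cds, anchor, ins)
    # one fixed alternate haplotype; each placement inserts its rotation
    target <- paste0(substr(cds, 1, anchor), ins,
                     substr(cds, anchor + 1, nchar(cds)))
    prots <- unique(vapply(pl$positions, function(p) {
      if (p == 0) return(NA_character_)
      g <- cds_to_genomic(t, p)
      rot <- substr(target, p + 1, p + nchar(ins))
      v <- tibble::tibble(contig = "c1", pos = g,
                          ref = substr(cds, p, p),
                          alt = paste0(substr(cds, p, p), rot))
      mutant_protein(v, t, genome)$protein
    }, character(1)))
    prots <- prots[!is.na(prots)]
    expect_length(prots, 1)
  }
})

test_that("annotation is per-source and empty transcript sets give intergenic", {
  w <- cached_world(301, n_proband_variants = 40L, contig_length = 30000L)
  v <- w$proband[1:5, c("contig", "pos", "ref", "alt", "key")]
  empty_tx <- w$transcripts_a[0, ]
  calls <- annotate_callset(v, empty_tx, w$genome, "none")
  expect_true(all(calls$category == "intergenic"))
  expect_true(all(calls$source == "none"))

  # discordant genes: HIGH under source A, not under source B
  disc <- w$truth$classes$source_discordant
  ca <- annotate_callset(w$proband[w$proband$key %in% disc, ],
                         w$transcripts_a, w$genome, "sourceA")
  cb <- annotate_callset(w$proband[w$proband$key %in% disc, ],
                         w$transcripts_b, w$genome, "sourceB")
  worst <- function(x) tapply(x$impact, x$key, function(i)
    max(c(MODIFIER = 0, LOW = 1, MODERATE = 2, HIGH = 3)[i]))
  expect_true(all(worst(ca) == 3))
  expect_true(all(worst(cb) < 3))
})

test_that("coding indels with length not divisible by 3 are always frameshift", {
  set.seed(35)
  w <- orf_world(90)
  for (i in 1:100) {
    k <- sample(5:(nchar(w$cds) - 10), 1)
    g <- cds_to_genomic(w$t, k)
    L <- sample(c(1, 2, 4, 5, 7, 8), 1)
    cc <- if (runif(1) < 0.5) {
      v <- tibble::tibble(contig = "chrT", pos = g,
                          ref = substr(w$cds, k, k),
                          alt = paste0(substr(w$cds, k, k), random_dna(L)))
      classify_variant(v, w$t, w$genome)
    } else {
      if (k + L > nchar(w$cds) - 3) next
      v <- tibble::tibble(
        contig = "chrT", pos = g,
        ref = substr(w$genome[["chrT"]], g, g + L),
        alt = substr(w$genome[["chrT"]], g, g)
      )
      classify_variant(v, w$t, w$genome)
    }
    expect_identical(cc$category, "frameshift")
  }
})
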