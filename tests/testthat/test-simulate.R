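# Synthetic-world generator: reproducibility, file validity, decoy-class
# faithfulness and the planted-frameshift anatomy.

test_that("identical configurations produce byte-identical worlds", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- scenario_config(seed = 5, n_proband_variants = 40L,
                         contig_length = 30000L)
  w1 <- simulate_world(cfg, d1)
  w2 <- simulate_world(cfg, d2)
  for (f in names(w1$paths)) {
    expect_identical(unname(tools::md5sum(w1$paths[[f]])),
                     unname(tools::md5sum(w2$paths[[f]])),
                     info = f)
  }
  # a different seed changes the world
  w3 <- simulate_world(scenario_config(seed = 6,
                                       n_proband_variants = 40L,
                                       contig_length = 30000L),
                       withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(w1$paths$proband)),
                         unname(tools::md5sum(w3$paths$proband))))
})

test_that("generated files parse with the package readers and stay consistent", {
  w <- cached_world(302, n_proband_variants = 40L, contig_length = 30000L)
  genome <- read_genome(w$paths$fasta)
  expect_identical(names(genome), names(w$genome))
  tx <- read_transcripts(w$paths$gff_a, genome)
  expect_equal(nrow(tx), nrow(w$transcripts_a))
  expect_true(all(tx$valid))
  m <- match(w$transcripts_a$transcript_id, tx$transcript_id)
  expect_identical(tx$cds_start[m], w$transcripts_a$cds_start)
  expect_identical(tx$strand[m], w$transcripts_a$strand)
  # source B truncates discordant CDS ends and is flagged accordingly
  txb <- read_transcripts(w$paths$gff_b, genome)
  disc <- w$genes$transcript_id[w$genes$role == "discordant"]
  expect_true(all(!txb$valid[txb$transcript_id %in% disc]))
  panel <- read_panel(w$paths$panel)
  expect_true(all(panel$maf >= 0 & panel$maf <= 0.5))
  expect_identical(read_gene_list(w$paths$flags), w$flags)
  expect_identical(read_gene_list(w$paths$candidates), w$candidates)
})

test_that("every proband variant belongs to exactly one ground-truth class", {
  w <- cached_world(303)
  cls <- w$truth$classes
  all_keys <- sort(unlist(cls, use.names = FALSE))
  expect_identical(sort(w$proband$key), all_keys)
  expect_false(any(duplicated(all_keys)))
})

test_that("each decoy class alone is fully removed at its targeted step", {
  targets <- c(common_high = "panel_subtract",
               private_low = "high_impact_recessive",
               singleton_het_high = "compound_het",
               cis_het_pair = "compound_het",
               flagged_gene = "assembly_errors",
               source_discordant = "dual_source_concordance",
               noncandidate_survivor = "candidate_genes")
  for (cl in names(targets)) {
    # the whole callset drawn from a single class (remainder classes zero)
    mix <- stats::setNames(rep(0, length(targets)), names(targets))
    mix[cl] <- 1.0
    w <- simulate_world(scenario_config(
      seed = 400 + match(cl, names(targets)), causal = "none",
      n_proband_variants = 12L, contig_length = 30000L, mix = mix))
    res <- run_cascade_mem(w)
    expect_equal(nrow(res$candidates), 0, info = cl)
    led <- res$ledger
    n_class <- length(w$truth$classes[[cl]])
    expect_gt(n_class, 0)
    expect_equal(led$variants_removed[led$step == targets[[cl]]],
                 n_class, info = cl)
    other <- led$variants_removed[led$step != targets[[cl]]]
    expect_true(all(other == 0), info = cl)
  }
})

test_that("planted frameshifts have the configured divergence anatomy", {
  set.seed(61)
  expect_error({
    w <- orf_world(60)
    plant_frameshift(w$t, w$genome, ins_length = 6L)
  }, "multiple of 3")

  done <- 0
  while (done < 100) {
    if (done %% 20 == 0) w <- orf_world(80)
    len <- sample(c(1, 2, 4, 5, 7, 8), 1)
    anchor <- sample(7:60, 1)
    # an ORF whose shifted frame is stop-free cannot truncate: regenerate
    p <- tryCatch(
      plant_frameshift(w$t, w$genome, ins_length = len, c_anchor = anchor),
      error = function(e) NULL)
    if (is.null(p)) {
      w <- orf_world(80)
      next
    }
    cc <- classify_variant(p$variant, w$t, w$genome)
    expect_identical(cc$category, "frameshift")
    expect_equal(cc$first_divergent_residue,
                 p$expected$first_divergent_residue)
    expect_equal(p$expected$preserved_prefix_aa,
                 p$expected$first_divergent_residue - 1L)
    done <- done + 1
  }
})

test_that("panel allele frequencies follow the configured mixture with boundary sites", {
  # AC=2/AN=200 is exactly the 1% boundary and must survive the strict rule
  cfg <- scenario_config(seed = 9)
  site <- tibble::tibble(contig = "c1", pos = 100L, ref = "A", alt = "T")
  an <- 2L * cfg$panel_samples
  expect_equal(2 / an, 0.01)

  set.seed(62)
  pool <- tibble::tibble(contig = "c1", pos = seq_len(10000L),
                         ref = "A", alt = "T")
  weights <- c(0.10, 0.20, 0.20, 0.20, 0.15, 0.15)
  panel <- build_panel(cfg, pool, weights = weights)
  expect_true(all(panel$allele_number == an))
  grid <- c(0, 0.005, 0.01, 0.02, 0.05, 0.25)
  obs <- as.numeric(table(factor(panel$maf, levels = grid))) / nrow(panel)
  # multinomial tolerance: 4 standard errors per category
  se <- sqrt(weights * (1 - weights) / nrow(panel))
  expect_true(all(abs(obs - weights) < 4 * se))
  # boundary and below-threshold sites are kept by the strict > rule
  ps <- panel_subtract(
    dplyr::mutate(pool, key = variant_key(contig, pos, ref, alt)),
    panel, cfg$maf_threshold)
  expect_setequal(ps$kept$key, panel$key[panel$maf <= 0.01])
})

test_that("infeasible configurations fail with a clear error", {
  expect_error(scenario_config(mix = c(common_high = 0.9,
                                       private_low = 0.2)),
               "sum to <= 1")
  expect_error(
    simulate_world(scenario_config(seed = 1, n_genes = 4L,
                                   n_candidate_genes = 3L,
                                   n_flagged_genes = 3L,
                                   n_discordant_genes = 3L)),
    "infeasible")
  expect_error(
    simulate_world(scenario_config(seed = 1, contig_length = 2000L)),
    "infeasible")
})

test_that("the compound-het causal mode is recovered through the het branch", {
  w <- simulate_world(scenario_config(seed = 77,
                                      causal = "compound_het_trans"))
  res <- run_cascade_mem(w)
  expect_setequal(res$candidates$key, w$truth$causal_keys)
  expect_equal(nrow(res$candidates), 2)
  expect_true(all(res$candidates$zygosity == "het"))
  expect_true(w$truth$causal_gene %in% res$candidates$gene_id)
  pairs <- res$comphet_pairs
  expect_true(any(pairs$gene_id == w$truth$causal_gene &
                    pairs$configuration == "trans"))
})
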