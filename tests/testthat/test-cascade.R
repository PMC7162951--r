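# Filtration-cascade stages and their invariants.

test_that("panel subtraction removes strictly above the MAF threshold", {
  panel <- tibble::tibble(
    contig = "c1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    key = variant_key("c1", c(10L, 20L, 30L), "A", "T"),
    allele_count = c(10L, 2L, 3L), allele_number = 200L,
    maf = c(0.05, 0.01, 0.015)
  )
  v <- tibble::tibble(contig = "c1", pos = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "T") |>
    dplyr::mutate(key = variant_key(contig, pos, ref, alt))
  r <- panel_subtract(v, panel, 0.01)
  expect_identical(r$removed$pos, c(10L, 30L))     # maf 0.05 and 0.015
  expect_identical(r$kept$pos, c(20L, 40L))        # boundary 0.01 and absent
  expect_error(panel_subtract(v, panel, 0.7), "0, 0.5")
  expect_error(panel_subtract(v, panel, -0.1), "0, 0.5")
})

test_that("recessive partition keeps hom and het variants at the impact floor", {
  v <- tibble::tibble(
    key = paste0("k", 1:4),
    zygosity = c("hom_alt", "het", "hom_alt", "hom_ref")
  )
  cons <- tibble::tibble(
    key = paste0("k", 1:4),
    impact = c("HIGH", "HIGH", "LOW", "HIGH")
  )
  p <- recessive_partition(v, cons, "HIGH")
  expect_identical(p$hom_candidates$key, "k1")
  expect_identical(p$het_pool$key, "k2")
  expect_setequal(p$removed$key, c("k3", "k4"))
})

test_that("compound-het genes need >=2 hets and a non-cis configuration", {
  het <- tibble::tibble(
    key = c("a", "b", "c", "d", "e", "f"),
    allele1 = c(0L, 1L, 0L, 0L, 0L, 0L),
    allele2 = c(1L, 0L, 1L, 1L, 1L, 1L),
    phased = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    phase_set = c("1", "1", "2", "2", NA, NA)
  )
  cons <- tibble::tibble(
    key = c("a", "b", "c", "d", "e", "f"),
    gene_id = c("gT", "gT", "gC", "gC", "gU", "gU")
  )
  pairs <- compound_het_genes(het, cons)
  expect_identical(sort(unique(pairs$gene_id)), c("gT", "gU"))
  expect_identical(pairs$configuration[pairs$gene_id == "gT"], "trans")
  expect_identical(pairs$configuration[pairs$gene_id == "gU"], "unresolved")
  # gC (cis pair, same phase set, same haplotype) is excluded entirely
  expect_false("gC" %in% pairs$gene_id)
})

test_that("compound-het retention equals brute-force pairwise enumeration", {
  set.seed(51)
  for (i in 1:50) {
    fx <- random_het_fixture(n_genes = 8)
    got <- compound_het_genes(fx$het, fx$gene_map)
    want <- oracle_comphet(fx$het, fx$gene_map)
    key <- function(d) sort(paste(d$gene_id, d$key_a, d$key_b,
                                  d$configuration))
    expect_identical(key(got), key(want))
  }
})

test_that("assembly-error exclusion removes only variants confined to flagged genes", {
  v <- tibble::tibble(key = c("k1", "k2", "k3"))
  cons <- tibble::tibble(
    key = c("k1", "k2", "k2", "k3"),
    gene_id = c("gBad", "gBad", "gOk", "gOk"),
    gene_symbol = NA_character_
  )
  r <- exclude_assembly_errors(v, cons, "gBad")
  expect_identical(r$removed$key, "k1")          # only flagged gene
  expect_setequal(r$kept$key, c("k2", "k3"))     # k2 also touches gOk
  r0 <- exclude_assembly_errors(v, cons, character(0))
  expect_identical(r0$kept, v)                   # empty flag set is identity
})

test_that("assembly-error removal matches a direct set intersection on a fixture", {
  set.seed(52)
  genes <- paste0("g", 1:20)
  flagged <- sample(genes, 5)
  v <- tibble::tibble(key = paste0("k", 1:40))
  cons <- tibble::tibble(
    key = v$key, gene_id = sample(genes, 40, replace = TRUE),
    gene_symbol = NA_character_
  )
  r <- exclude_assembly_errors(v, cons, flagged)
  expect_setequal(r$removed$key, cons$key[cons$gene_id %in% flagged])
})

test_that("concordance keeps variants HIGH under both annotation sources", {
  keys <- paste0("k", 1:12)
  v <- tibble::tibble(key = keys)
  ca <- tibble::tibble(key = keys, impact = "HIGH")
  # controlled disagreement in 3 of 12 variants
  cb <- tibble::tibble(key = keys,
                       impact = c(rep("HIGH", 9), rep("MODIFIER", 3)))
  r <- concordance_filter(v, ca, cb, "HIGH")
  expect_equal(nrow(r$kept), 9)
  expect_setequal(r$removed$key, keys[10:12])
  expect_error(concordance_filter(v, NULL, cb), "sourceA")
  expect_error(concordance_filter(v, ca, NULL), "sourceB")
})

test_that("candidate filtering matches gene id first, then case-insensitive symbol", {
  v <- tibble::tibble(key = c("k1", "k2", "k3"))
  cons <- tibble::tibble(
    key = c("k1", "k2", "k3"),
    gene_id = c("gene01", "gene02", "gene03"),
    gene_symbol = c("IDUA", "OTHER", "GUSB")
  )
  r <- candidate_gene_filter(v, cons, c("gene02"))
  expect_identical(r$kept$key, "k2")
  r2 <- candidate_gene_filter(v, cons, c("idua", "gusb"))
  expect_setequal(r2$kept$key, c("k1", "k3"))
  expect_error(candidate_gene_filter(v, cons, character(0)), "empty")
})

test_that("the cascade ledger conserves counts and the funnel is monotone", {
  w <- cached_world(303)
  res <- run_cascade_mem(w)
  led <- res$ledger
  expect_true(all(led$variants_in ==
                    led$variants_removed + led$variants_kept))
  expect_true(all(diff(led$variants_kept) <= 0 |
                    led$variants_in[-1] == led$variants_kept[-nrow(led)]))
  expect_identical(led$variants_in[-1], led$variants_kept[-nrow(led)])
})

test_that("assembly-error and concordance filters commute", {
  w <- cached_world(303)
  base <- list(w$proband, w$panel, w$transcripts_a, w$transcripts_b,
               w$genome)
  v0 <- left_align(w$proband, w$genome)
  ps <- panel_subtract(v0, w$panel, 0.01)
  ca <- annotate_callset(ps$kept, w$transcripts_a, w$genome, "A")
  cb <- annotate_callset(ps$kept, w$transcripts_b, w$genome, "B")
  part <- recessive_partition(ps$kept, ca, "HIGH")
  pool <- dplyr::bind_rows(part$hom_candidates, part$het_pool)

  ab <- concordance_filter(
    exclude_assembly_errors(pool, ca, w$flags)$kept, ca, cb, "HIGH")$kept
  ba <- exclude_assembly_errors(
    concordance_filter(pool, ca, cb, "HIGH")$kept, ca, w$flags)$kept
  expect_setequal(ab$key, ba$key)
})

test_that("disabling the candidate filter exposes the genome-wide survivors", {
  w <- cached_world(303)
  res <- run_cascade_mem(w, use_candidate_filter = FALSE)
  nc <- w$truth$classes$noncandidate_survivor
  expect_true(all(nc %in% res$candidates$key))
  expect_true(all(w$truth$causal_keys %in% res$candidates$key))
  res2 <- run_cascade_mem(w)
  expect_false(any(nc %in% res2$candidates$key))
})

test_that("tidy, glance and autoplot summarise a cascade result", {
  w <- cached_world(303)
  res <- run_cascade_mem(w)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("key", "gene_id", "hgvs_g", "category") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_candidates, nrow(res$candidates))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
  rep <- render_report(res)
  expect_true(any(grepl("Final candidates", rep)))
})
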