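# VCF input (via vcfR) and plain-text VCF output used by the synthetic
# generator. Multi-allelic records are split into bi-allelic variants with
# genotype indices remapped; the phased separator '|' and the PS tag are
# preserved. Breakends/symbolic ALTs are skipped with a logged count;
# half-calls are treated as missing genotypes.

parse_gt_string <- function(gt, ps) {
  # returns list(allele1, allele2, phased, phase_set, missing)
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(list(a1 = NA_integer_, a2 = NA_integer_, phased = FALSE,
                ps = NA_character_, missing = TRUE))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  if (length(parts) != 2 || any(parts == ".")) {
    return(list(a1 = NA_integer_, a2 = NA_integer_, phased = phased,
                ps = NA_character_, missing = TRUE))
  }
  a <- suppressWarnings(as.integer(parts))
  if (anyNA(a)) {
    return(list(a1 = NA_integer_, a2 = NA_integer_, phased = phased,
                ps = NA_character_, missing = TRUE))
  }
  list(a1 = a[1], a2 = a[2], phased = phased,
       ps = if (phased && !is.na(ps) && ps != ".") as.character(ps) else NA_character_,
       missing = FALSE)
}

#' Read a proband callset from VCF
#'
#' Reads a VCF 4.2 file with a GT FORMAT field. Multi-allelic records are
#' split into bi-allelic variants (genotype indices remapped so that the
#' alternate allele under consideration is 1 and all others fold to 0).
#' Symbolic/breakend ALT alleles are skipped and counted; half-calls are
#' returned as `zygosity = "missing"`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param sample Sample name to extract; default first sample.
#' @return Tibble with one row per bi-allelic variant: `contig`, `pos`,
#'   `ref`, `alt`, `key`, `info`, `sample_id`, `allele1`, `allele2`,
#'   `phased`, `phase_set`, `zygosity`. The number of skipped records is
#'   attached as attribute `skipped`.
#' @export
read_proband_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), key = character(), info = character(),
                  sample_id = character(), allele1 = integer(),
                  allele2 = integer(), phased = logical(),
                  phase_set = character(), zygosity = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  if (ncol(v@gt) < 2) abort(paste0("VCF has no sample columns: ", path))
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort(paste0("missing GT in FORMAT: ", path))
  }
  samples <- colnames(v@gt)[-1]
  sample <- sample %||% samples[1]
  if (!sample %in% samples) abort(paste0("sample not in VCF: ", sample))
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  ps_mat <- if (any(grepl("(^|:)PS(:|$)", fmt))) {
    vcfR::extract.gt(v, element = "PS")
  } else {
    matrix(NA_character_, nrow = nrow(gt_mat), ncol = ncol(gt_mat),
           dimnames = dimnames(gt_mat))
  }

  skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    if (is.na(pos) || is.na(ref) || !grepl("^[ACGTN]+$", ref)) {
      abort(sprintf("malformed VCF record %d (%s:%s)", i,
                    fix$CHROM[i], fix$POS[i]))
    }
    g <- parse_gt_string(gt_mat[i, sample], ps_mat[i, sample])
    sub <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (!grepl("^[ACGTN]+$", alt)) {
        skipped <- skipped + 1L   # symbolic ALT, breakend, spanning deletion
        next
      }
      remap <- function(a) {
        if (is.na(a)) NA_integer_ else if (a == j) 1L else 0L
      }
      a1 <- remap(g$a1); a2 <- remap(g$a2)
      zyg <- if (g$missing || is.na(a1) || is.na(a2)) "missing"
      else if (a1 == 1 && a2 == 1) "hom_alt"
      else if (a1 + a2 == 1) "het"
      else "hom_ref"
      sub[[j]] <- tibble(
        contig = fix$CHROM[i], pos = pos, ref = ref, alt = alt,
        info = fix$INFO[i] %||% NA_character_,
        sample_id = sample, allele1 = a1, allele2 = a2,
        phased = g$phased, phase_set = g$ps, zygosity = zyg
      )
    }
    rows[[i]] <- dplyr::bind_rows(sub)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, key = variant_key(contig, pos, ref, alt),
                       .after = "alt")
  if (skipped > 0) {
    inform(sprintf("read_proband_vcf: skipped %d unsupported ALT allele(s)",
                   skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read a control-panel allele-frequency table
#'
#' Accepts either a TSV with columns `contig`, `pos`, `ref`, `alt`,
#' `allele_count`, `allele_number`, or a VCF whose INFO field carries
#' `AC` and `AN` (per-sample genotypes are counted when AC/AN are absent).
#' Minor-allele frequency is folded to `[0, 0.5]`.
#'
#' @param path Path to the panel file.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `key`,
#'   `allele_count`, `allele_number`, `maf`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    ac <- suppressWarnings(as.integer(
      stringr::str_match(fix$INFO, "(?:^|;)AC=([0-9]+)")[, 2]))
    an <- suppressWarnings(as.integer(
      stringr::str_match(fix$INFO, "(?:^|;)AN=([0-9]+)")[, 2]))
    if (anyNA(ac) || anyNA(an)) {
      gt <- vcfR::extract.gt(v, element = "GT")
      alleles <- apply(gt, 1, function(r) {
        a <- unlist(strsplit(r[!is.na(r)], "[/|]"))
        a <- a[a != "."]
        c(sum(a == "1"), length(a))
      })
      ac <- alleles[1, ]
      an <- alleles[2, ]
    }
    out <- tibble(contig = fix$CHROM,
                  pos = as.integer(fix$POS),
                  ref = toupper(fix$REF), alt = toupper(fix$ALT),
                  allele_count = ac, allele_number = an)
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("contig", "pos", "ref", "alt", "allele_count", "allele_number")
    if (!all(need %in% names(out))) {
      abort(paste0("panel TSV must have columns: ",
                   paste(need, collapse = ", ")))
    }
    out <- dplyr::select(out, dplyr::all_of(need))
  }
  af <- out$allele_count / out$allele_number
  dplyr::mutate(out,
                key = variant_key(contig, pos, ref, alt), .after = "alt",
                maf = pmin(af, 1 - af))
}

# minimal plain-text VCF 4.2 writer used by the synthetic generator
# variants: tibble contig,pos,ref,alt + gt (string like "0/1" or "0|1"),
# optional ps
write_vcf_file <- function(variants, path, sample = "proband",
                           contig_lengths = NULL, info = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              unname(contig_lengths))
    },
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")
  )
  v <- dplyr::arrange(variants, contig, pos, alt)
  has_ps <- "ps" %in% names(v) && any(!is.na(v$ps))
  recs <- vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    inf <- if (is.null(info)) "." else info[[i]] %||% "."
    fmt <- if (has_ps && !is.na(r$ps)) "GT:PS" else "GT"
    smp <- if (has_ps && !is.na(r$ps)) paste0(r$gt, ":", r$ps) else r$gt
    paste(r$contig, r$pos, ".", r$ref, r$alt, ".", "PASS", inf, fmt, smp,
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# sites-only panel writers
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(
    dplyr::select(panel, contig, pos, ref, alt,
                  allele_count, allele_number),
    path
  )
  invisible(path)
}
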