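# Reference genome and transcript-model input. The genome is a named
# character vector (one uppercase DNA string per contig) with class
# "ref_genome"; transcript models are a tibble with one row per mRNA and a
# list-column of exon intervals.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and restricted to the alphabet `{A,C,G,T,N}`;
#' IUPAC ambiguity codes other than `N` are rejected, as are duplicate
#' record names.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named character vector of contig sequences, class `ref_genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[[1]], ">")) {
    abort(paste0("malformed FASTA (line 1): expected '>' header in ", path))
  }
  bad <- which(!startsWith(lines, ">") &
                 grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0) {
    abort(paste0(
      "malformed FASTA sequence (line ", bad[1], "): characters outside ",
      "{A,C,G,T,N} in ", path
    ))
  }
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name: ", nm[duplicated(nm)][1]))
  }
  seqs <- toupper(as.character(dss))
  names(seqs) <- nm
  if (any(!nzchar(seqs))) {
    abort(paste0("empty FASTA record: ", nm[!nzchar(seqs)][1]))
  }
  structure(seqs, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x), " contig(s)\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  }
  invisible(x)
}

contig_length <- function(genome, contig) {
  if (!contig %in% names(genome)) abort(paste0("unknown contig: ", contig))
  nchar(genome[[contig]])
}

# 1-based inclusive slice of a contig
slice_seq <- function(genome, contig, start, end) {
  n <- contig_length(genome, contig)
  if (start < 1 || end > n || start > end) {
    abort(sprintf("slice %s:%d-%d outside contig bounds (1-%d)",
                  contig, start, end, n))
  }
  substr(genome[[contig]], start, end)
}

gff3_attr <- function(meta, row, keys) {
  for (k in keys) {
    if (k %in% names(meta)) {
      v <- meta[[k]][row]
      if (is.list(v)) v <- unlist(v)
      v <- v[!is.na(v)]
      if (length(v) > 0) return(as.character(v[[1]]))
    }
  }
  NA_character_
}

#' Read transcript models from GFF3
#'
#' Assembles one transcript model per mRNA feature from gene/mRNA/exon/CDS
#' records linked by `ID`/`Parent`. Models that violate CDS invariants
#' (CDS not contained in exons, length not a multiple of 3, missing start or
#' terminal stop codon, internal stop) are returned with `valid = FALSE` and
#' a reason, not dropped. GFF3 dialects that exclude the stop codon from the
#' CDS are normalised to stop-inclusive when the three transcript bases past
#' the annotated CDS end form a stop codon.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `ref_genome` (used for bounds checks and CDS validation).
#' @return Tibble with columns `transcript_id`, `gene_id`, `gene_symbol`,
#'   `contig`, `strand`, `cds_start`, `cds_end`, `exons` (list of data frames
#'   with `start`,`end`), `valid`, `invalid_reason`.
#' @export
read_transcripts <- function(path, genome) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  meta <- df
  n <- nrow(df)
  get_parent <- function(i) gff3_attr(meta, i, "Parent")

  types <- as.character(df$type)
  gene_rows <- which(types == "gene")
  mrna_rows <- which(types %in% c("mRNA", "transcript"))
  exon_rows <- which(types == "exon")
  cds_rows  <- which(types == "CDS")

  gene_info <- list()
  for (i in gene_rows) {
    gid <- gff3_attr(meta, i, c("ID", "gene_id"))
    gene_info[[gid]] <- list(
      gene_id = gff3_attr(meta, i, c("gene_id", "ID")),
      symbol  = gff3_attr(meta, i, c("gene_symbol", "Name", "gene_name", "ID"))
    )
  }

  mrna_ids <- character(0)
  mrna_meta <- list()
  for (i in mrna_rows) {
    tid <- gff3_attr(meta, i, c("ID", "transcript_id"))
    parent <- get_parent(i)
    mrna_ids <- c(mrna_ids, tid)
    mrna_meta[[tid]] <- list(
      contig = as.character(df$seqnames[i]),
      strand = as.character(df$strand[i]),
      parent = parent
    )
  }

  child_tx <- function(i, what) {
    p <- get_parent(i)
    if (is.na(p)) abort(paste0("orphan ", what, " feature (no Parent) in ", path))
    if (!p %in% mrna_ids) {
      abort(paste0("orphan ", what, " feature: Parent '", p,
                   "' is not an mRNA in ", path))
    }
    p
  }

  exons_by_tx <- list()
  for (i in exon_rows) {
    p <- child_tx(i, "exon")
    exons_by_tx[[p]] <- rbind(
      exons_by_tx[[p]],
      data.frame(start = df$start[i], end = df$end[i])
    )
  }
  cds_by_tx <- list()
  for (i in cds_rows) {
    p <- child_tx(i, "CDS")
    cds_by_tx[[p]] <- rbind(
      cds_by_tx[[p]],
      data.frame(start = df$start[i], end = df$end[i])
    )
  }

  # bounds check against genome
  for (i in seq_len(n)) {
    ctg <- as.character(df$seqnames[i])
    if (ctg %in% names(genome) && df$end[i] > contig_length(genome, ctg)) {
      abort(sprintf("GFF3 feature beyond contig end: %s:%d-%d",
                    ctg, df$start[i], df$end[i]))
    }
  }

  rows <- purrr::map(mrna_ids, function(tid) {
    mm <- mrna_meta[[tid]]
    ginfo <- gene_info[[mm$parent]] %||%
      list(gene_id = mm$parent %||% tid, symbol = mm$parent %||% tid)
    ex <- exons_by_tx[[tid]]
    cd <- cds_by_tx[[tid]]
    if (is.null(ex) && !is.null(cd)) ex <- cd
    if (is.null(ex)) return(NULL)
    ex <- ex[order(ex$start), , drop = FALSE]
    tibble(
      transcript_id = tid,
      gene_id = ginfo$gene_id %||% NA_character_,
      gene_symbol = ginfo$symbol %||% NA_character_,
      contig = mm$contig,
      strand = mm$strand,
      cds_start = if (is.null(cd)) NA_integer_ else min(cd$start),
      cds_end = if (is.null(cd)) NA_integer_ else max(cd$end),
      exons = list(ex)
    )
  })
  tx <- dplyr::bind_rows(rows)
  if (nrow(tx) == 0) abort(paste0("no mRNA features found in ", path))
  validate_transcripts(tx, genome)
}

# check invariants, normalise stop-inclusive CDS, set valid/invalid_reason
validate_transcripts <- function(tx, genome) {
  res <- purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    reason <- NA_character_
    ex <- t$exons[[1]]
    ok_contig <- t$contig %in% names(genome)
    if (!ok_contig) {
      return(dplyr::mutate(t, valid = FALSE,
                           invalid_reason = "unknown contig"))
    }
    if (nrow(ex) > 1) {
      if (any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        reason <- "overlapping exons"
      }
    }
    if (is.na(t$cds_start)) {
      reason <- reason %|na|% "no CDS"
    }
    if (is.na(reason)) {
      in_exon <- function(p) any(p >= ex$start & p <= ex$end)
      cds_pos <- cds_genomic_positions(t)
      if (!all(vapply(range(cds_pos), in_exon, logical(1)))) {
        reason <- "CDS outside exons"
      } else {
        cds <- spliced_cds(t, genome)
        # stop-exclusive dialect: extend by one codon when the next three
        # transcript bases form a stop
        if (!is_stop_codon(substr(cds, nchar(cds) - 2, nchar(cds)))) {
          ext <- try_stop_extension(t, genome)
          if (!is.null(ext)) {
            t <- ext
            cds <- spliced_cds(t, genome)
          }
        }
        if (nchar(cds) %% 3 != 0) {
          reason <- "CDS length not a multiple of 3"
        } else if (substr(cds, 1, 3) != "ATG") {
          reason <- "CDS does not begin with ATG"
        } else if (!is_stop_codon(substr(cds, nchar(cds) - 2, nchar(cds)))) {
          reason <- "CDS does not end with a stop codon"
        } else {
          tr <- translate_cds(cds)
          if (nchar(tr$protein) != nchar(cds) / 3 - 1) {
            reason <- "internal stop codon in CDS"
          }
        }
      }
    }
    dplyr::mutate(t, valid = is.na(reason), invalid_reason = reason)
  })
  res
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

# try to extend the CDS by 3 transcript bases (stop-exclusive GFF3 dialect);
# returns the adjusted row or NULL
try_stop_extension <- function(t, genome) {
  ex <- t$exons[[1]]
  if (t$strand == "+") {
    pos <- exonic_positions_after(ex, t$cds_end, 3L, ascending = TRUE)
  } else {
    pos <- exonic_positions_after(ex, t$cds_start, 3L, ascending = FALSE)
  }
  if (length(pos) < 3) return(NULL)
  bases <- vapply(pos, function(p) substr(genome[[t$contig]], p, p), character(1))
  codon <- if (t$strand == "+") paste(bases, collapse = "") else
    revcomp(paste(rev(bases), collapse = ""))
  if (!is_stop_codon(codon)) return(NULL)
  if (t$strand == "+") t$cds_end <- max(pos) else t$cds_start <- min(pos)
  t
}

# next k exonic genomic positions strictly after (ascending) or before
# (descending) the given position
exonic_positions_after <- function(ex, from, k, ascending) {
  all_pos <- unlist(lapply(seq_len(nrow(ex)),
                           function(i) seq.int(ex$start[i], ex$end[i])))
  all_pos <- sort(all_pos)
  res <- if (ascending) all_pos[all_pos > from] else rev(all_pos[all_pos < from])
  head(res, k)
}
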