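# Low-level DNA string helpers. All sequences are plain uppercase character
# strings over {A,C,G,T,N}; coordinates are 1-based inclusive throughout
# (GFF3/VCF convention).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("CGGCCCCC") # "GGGGGCCG"
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return("")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- comp[ch]
    if (anyNA(out)) {
      abort(paste0("non-DNA character in sequence: ", s))
    }
    paste(rev(out), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# rotate a string: move last char to front / first char to end
rot_right <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  paste0(substr(s, n, n), substr(s, 1, n - 1))
}

rot_left <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  paste0(substr(s, 2, n), substr(s, 1, 1))
}

#' Translate a coding sequence to protein
#'
#' Translation uses the standard genetic code, starts at the first base, and
#' stops at (and excludes) the first stop codon. A trailing partial codon is
#' ignored. Codons containing `N` translate to `X`.
#'
#' @param cds DNA string, length >= 3.
#' @return A list with `protein` (amino-acid string, stop excluded) and
#'   `no_stop` (`TRUE` if no stop codon was encountered before the end).
#' @examples
#' translate_cds("ATGTAA")$protein    # "M"
#' translate_cds("ATGGCCAAA")$no_stop # TRUE
#' @export
translate_cds <- function(cds) {
  if (is.na(cds) || !nzchar(cds)) abort("translate_cds(): empty input")
  n <- nchar(cds)
  if (n < 3) abort("translate_cds(): input shorter than one codon")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  code <- genetic_code()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- ifelse(grepl("N", codons[is.na(aa)], fixed = TRUE), "X", NA)
  if (anyNA(aa)) abort("translate_cds(): non-DNA codon encountered")
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) {
    k <- stop_at[1]
    list(protein = paste(aa[seq_len(k - 1)], collapse = ""), no_stop = FALSE)
  } else {
    list(protein = paste(aa, collapse = ""), no_stop = TRUE)
  }
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# first index at which two protein strings differ; 0 when identical.
# When one is a prefix of the other the first divergent residue is the
# position just past the shared prefix.
first_divergence <- function(a, b) {
  if (identical(a, b)) return(0L)
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n > 0) {
    va <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
    vb <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
    d <- which(va != vb)
    if (length(d) > 0) return(d[1])
  }
  n + 1L
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Canonical variant identity key
#'
#' Variants are matched (against the control panel and across annotation
#' sources) on `contig:pos:ref:alt` after left alignment.
#'
#' @param contig,pos,ref,alt Vectors describing variants (VCF convention).
#' @return Character vector of keys.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# cached copy of the standard genetic code table
genetic_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    code
  }
})
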