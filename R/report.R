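# Reporting: a human-readable step table plus machine-readable JSON twin,
# broom-style tidy()/glance() accessors and a ggplot2 funnel for the ledger.

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a cascade report
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @return Character vector of report lines (step table, candidate table or
#'   an explicit negative finding).
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  led <- result$ledger
  lines <- c("Filtration cascade", "")
  lines <- c(lines, sprintf("%-24s %9s %9s %9s %7s", "step", "in",
                            "removed", "kept", "genes"))
  for (i in seq_len(nrow(led))) {
    lines <- c(lines, sprintf(
      "%-24s %9d %9d %9d %7s", led$step[i], led$variants_in[i],
      led$variants_removed[i], led$variants_kept[i],
      ifelse(is.na(led$genes_kept[i]), ".",
             as.character(led$genes_kept[i]))))
  }
  lines <- c(lines, "")
  cand <- result$candidates
  if (nrow(cand) == 0) {
    lines <- c(lines, "No candidate variant survives the cascade.")
  } else {
    lines <- c(lines, sprintf("Final candidates (%d):", nrow(cand)))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, ]
      prot <- if (!is.na(r$wt_protein_length)) {
        sprintf(" protein %d->%d aa, divergence at residue %s",
                r$wt_protein_length, r$mut_protein_length,
                ifelse(is.na(r$first_divergent_residue), "?",
                       r$first_divergent_residue))
      } else ""
      lines <- c(lines, sprintf(
        "  %s  %s  %s  %s [%s]%s", r$gene_symbol %||% r$gene_id,
        r$zygosity, r$hgvs_g,
        ifelse(is.na(r$hgvs_c), "-", r$hgvs_c), r$category, prot))
    }
  }
  lines
}

#' Write all cascade outputs to a directory
#'
#' Writes `ledger.json`, `candidates.tsv` and `report.txt` with
#' deterministic ordering (contig, position, alt).
#'
#' @param result A `cascade_result`.
#' @param dir Output directory.
#' @return Invisible named list of paths.
#' @export
write_cascade_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ledger = file.path(dir, "ledger.json"),
                candidates = file.path(dir, "candidates.tsv"),
                report = file.path(dir, "report.txt"))
  jsonlite::write_json(
    list(steps = result$ledger,
         n_candidates = nrow(result$candidates),
         params = result$params),
    paths$ledger, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  out <- result$candidates
  out$exons <- NULL
  readr::write_tsv(out, paths$candidates)
  writeLines(render_report(result), paths$report)
  invisible(paths)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the final candidate table of a cascade
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return Tibble of final candidate variants with gene, HGVS and protein
#'   effect columns.
#' @export
tidy.cascade_result <- function(x, ...) {
  as_tibble(x$candidates)
}

#' One-row summary of a cascade run
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return One-row tibble: variants in/out, steps, final genes.
#' @export
glance.cascade_result <- function(x, ...) {
  led <- x$ledger
  tibble(
    n_steps = nrow(led),
    variants_in = led$variants_in[1],
    variants_final = led$variants_kept[nrow(led)],
    n_candidates = nrow(x$candidates),
    final_genes = paste(sort(unique(stats::na.omit(
      x$candidates$gene_id))), collapse = ",")
  )
}

#' Funnel plot of the filtration ledger
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot showing variants entering and surviving each step.
#' @export
autoplot.cascade_result <- function(object, ...) {
  led <- object$ledger
  led$step <- factor(led$step, levels = led$step)
  df <- tidyr::pivot_longer(
    dplyr::select(led, step, variants_in, variants_kept),
    cols = c("variants_in", "variants_kept"),
    names_to = "what", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = step, y = count, fill = what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(variants_in = "grey65", variants_kept = "steelblue"),
      labels = c(variants_in = "entering", variants_kept = "surviving"),
      name = NULL
    ) +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Variant filtration cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
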