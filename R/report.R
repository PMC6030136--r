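# P-value presentation and report serialization (CSV + JSON), with
# deterministic ordering and byte-stable output.

#' Format a p-value in 3-significant-figure scientific notation
#'
#' Matches the `3.91E-10` presentation style. When the value itself has
#' underflowed to 0 but a finite `log10_p` is available (products of many
#' tiny p-values), the mantissa and exponent are reconstructed from the
#' log10 value so the formatted string stays exact.
#'
#' @param p probability in \[0, 1\], or 0 when only `log10_p` is exact.
#' @param log10_p optional log10 of the value; used when `p` underflowed.
#' @return A string like `"3.91E-10"`.
#' @export
format_pvalue <- function(p, log10_p = NULL) {
  if (is.na(p) || p < 0) {
    cmx_domain_error("p must be a non-negative probability")
  }
  if (p > 0) {
    return(sprintf("%.2E", p))
  }
  if (is.null(log10_p) || !is.finite(log10_p)) {
    return("0.00E+00")
  }
  e <- floor(log10_p)
  m <- 10^(log10_p - e)  # mantissa in [1, 10)
  m_str <- sprintf("%.2f", m)
  if (m_str == "10.00") {  # rounding carried into the next decade
    m_str <- "1.00"
    e <- e + 1
  }
  sprintf("%sE%+03d", m_str, e)
}

# full-precision decimal that round-trips a double exactly
format_full <- function(x) sprintf("%.17g", x)

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

venn_to_list <- function(venn) {
  list(
    labels = as.list(venn$labels),
    regions = lapply(venn$regions, as.list)
  )
}

shared_terms_frame <- function(report, ns) {
  joint <- report$shared[[ns]]$joint
  ids <- report$chemicals$chemical_id
  cols <- list(term_id = character(0), description = character(0))
  for (cid in ids) {
    cols[[paste0("adj_p_", cid)]] <- character(0)
    cols[[paste0("adj_p_", cid, "_fmt")]] <- character(0)
  }
  cols$joint_p <- character(0)
  cols$joint_p_fmt <- character(0)
  cols$log10_joint_p <- character(0)
  if (length(joint) == 0L) {
    return(do.call(data.frame,
                   c(cols, list(stringsAsFactors = FALSE))))
  }
  first_tab <- report$enrichment[[ids[[1L]]]][[ns]]
  rows <- lapply(joint, function(j) {
    row <- list(
      term_id = j$term_id,
      description = first_tab$description[match(j$term_id,
                                                first_tab$term_id)]
    )
    for (cid in ids) {
      p <- unname(j$per_chemical_adj_p[[cid]])
      row[[paste0("adj_p_", cid)]] <- format_full(p)
      row[[paste0("adj_p_", cid, "_fmt")]] <- format_pvalue(p)
    }
    row$joint_p <- format_full(j$joint_p)
    row$joint_p_fmt <- format_pvalue(j$joint_p, log10_p = j$log10_joint_p)
    row$log10_joint_p <- format_full(j$log10_joint_p)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

target_detail_frame <- function(ts) {
  if (is.null(ts$detail) || nrow(ts$detail) == 0L) {
    return(data.frame(
      protein_id = character(0), gene_symbol = character(0),
      gene_id = character(0), gene_name = character(0),
      combined_score = integer(0), stringsAsFactors = FALSE
    ))
  }
  d <- ts$detail[order(ts$detail$protein_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a mixture report to disk
#'
#' Writes, under `outdir`: `chemicals.csv`; per-chemical target detail
#' CSVs (`targets_<chemical>.csv` with protein id, gene symbol, gene id,
#' gene name, interaction score); `venn_regions.json` covering the target
#' Venn and each namespace's significant-term Venn;
#' `enrichment_<chemical>_<ns>.csv`; `shared_terms_<ns>.csv` (per-chemical
#' adjusted p-values plus the joint p-value, full-precision and
#' 3-significant-figure columns); `overall_<ns>.csv` for the union-based
#' overall effect; and `manifest.json` listing everything written.
#' Output is deterministic: writing the same report twice is
#' byte-identical.
#'
#' @param report a `mixture_report` from [analyze_mixture()].
#' @param outdir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "mixture_report"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2L) != 0L) {
    cmx_io_error(sprintf("cannot write to output directory '%s'", outdir))
  }
  files <- character(0)
  add <- function(name) {
    files[[length(files) + 1L]] <<- name
    file.path(outdir, name)
  }

  write_csv_file(report$chemicals, add("chemicals.csv"))
  ids <- report$chemicals$chemical_id
  for (cid in ids) {
    write_csv_file(target_detail_frame(report$target_sets[[cid]]),
                   add(sprintf("targets_%s.csv", cid)))
  }
  namespaces <- names(report$shared)
  venn_json <- list(
    targets = venn_to_list(report$target_venn),
    terms = lapply(report$shared[namespaces],
                   function(s) venn_to_list(s$term_venn))
  )
  writeLines(
    jsonlite::toJSON(venn_json, auto_unbox = TRUE, pretty = TRUE),
    add("venn_regions.json")
  )
  for (cid in ids) {
    for (ns in namespaces) {
      write_enrichment_csv(report$enrichment[[cid]][[ns]],
                           add(sprintf("enrichment_%s_%s.csv", cid, ns)))
    }
  }
  for (ns in namespaces) {
    write_csv_file(shared_terms_frame(report, ns),
                   add(sprintf("shared_terms_%s.csv", ns)))
    write_enrichment_csv(report$overall[[ns]],
                         add(sprintf("overall_%s.csv", ns)))
  }
  manifest <- list(
    chemicals = as.list(ids),
    level = report$level$name,
    alpha = report$alpha,
    namespaces = as.list(namespaces),
    files = as.list(sort(c(files, "manifest.json")))
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
    file.path(outdir, "manifest.json")
  )
  files <- sort(c(files, "manifest.json"))
  invisible(file.path(outdir, files))
}
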