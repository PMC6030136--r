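# Hypergeometric over-representation analysis of a target gene set
# against one annotation catalog, with Benjamini-Hochberg correction.
#
# Parameterization used throughout: of N background genes, K carry the
# annotation; n target genes are in the background; k of them carry the
# annotation. The test is the one-sided upper tail P(X >= k).

#' Upper-tail hypergeometric probability
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability
#' that a uniform draw of `n` genes from a background of `N`, of which `K`
#' are annotated to a term, contains at least `k` annotated genes.
#' Computed via the survival function of [stats::phyper()] (log-gamma
#' based), not naive factorials.
#'
#' @param k observed overlap (target genes annotated to the term).
#' @param K term size within the background.
#' @param n number of target genes present in the background.
#' @param N background size.
#' @return A probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(is.na(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
    cmx_domain_error("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) {
    cmx_domain_error(sprintf("need K <= N and n <= N (got K=%d n=%d N=%d)",
                             K, n, N))
  }
  if (k < max(0, n + K - N) || k > min(K, n)) {
    cmx_domain_error(sprintf(
      "k=%d outside feasible range [%d, %d] for K=%d n=%d N=%d",
      k, max(0, n + K - N), min(K, n), K, n, N
    ))
  }
  # P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' With order statistics `p_(1) <= ... <= p_(m)`, the adjusted value for
#' rank `i` is `min_{j >= i} (p_(j) * m / j)` capped at 1, mapped back to
#' the input order. Output has the same length and order as the input.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    cmx_domain_error("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))  # min over j >= i
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Construct an enrichment table
#'
#' @param records data frame with columns `term_id, description, k, K, n,
#'   N, p_raw, p_adj, significant`.
#' @param label the gene-set label (a chemical id or `"union"`).
#' @param namespace catalog namespace the table was computed against.
#' @param alpha significance threshold used.
#' @param n_dropped number of target genes absent from the background.
#' @return Data frame of class `enrichment_table`, sorted by
#'   `(p_adj, term_id)`.
#' @export
enrichment_table <- function(records, label, namespace, alpha = 0.05,
                             n_dropped = 0L) {
  required <- c("term_id", "description", "k", "K", "n", "N",
                "p_raw", "p_adj", "significant")
  stopifnot(all(required %in% names(records)))
  records <- records[order(records$p_adj, records$term_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
    label = label, namespace = namespace, alpha = alpha,
    n_dropped = as.integer(n_dropped),
    class = c("enrichment_table", "data.frame")
  )
}

#' Hypergeometric over-representation of a gene set in a catalog
#'
#' Tests every term of one catalog for over-representation in
#' `target_genes`, with BH correction across all of that catalog's terms.
#' The background universe is the catalog's own gene universe (the union
#' of its term gene sets); target genes outside the background are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param target_genes character vector of gene symbols.
#' @param catalog an [annotation_catalog()].
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param label label stored on the result (chemical id or `"union"`).
#' @return An [enrichment_table()]. If no target gene is in the
#'   background, an empty-records table flagged `no_testable_genes`.
#' @export
enrich <- function(target_genes, catalog, alpha = 0.05, label = "targets") {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    cmx_domain_error("alpha must be a probability in (0, 1]")
  }
  targets <- unique(as.character(target_genes))
  effective <- intersect(targets, catalog$background)
  n_dropped <- length(targets) - length(effective)
  N <- length(catalog$background)
  n <- length(effective)
  term_ids <- sort(names(catalog$terms))
  if (n == 0L) {
    empty <- data.frame(
      term_id = character(0), description = character(0),
      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
      p_raw = numeric(0), p_adj = numeric(0), significant = logical(0),
      stringsAsFactors = FALSE
    )
    tab <- enrichment_table(empty, label, catalog$namespace, alpha,
                            n_dropped = n_dropped)
    attr(tab, "no_testable_genes") <- TRUE
    return(tab)
  }
  K <- vapply(catalog$terms[term_ids], length, integer(1))
  k <- vapply(catalog$terms[term_ids],
              function(g) length(intersect(effective, g)), integer(1))
  p_raw <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  p_adj <- bh_adjust(p_raw)
  records <- data.frame(
    term_id = term_ids,
    description = unname(catalog$descriptions[term_ids]),
    k = as.integer(k), K = as.integer(K),
    n = rep.int(n, length(term_ids)), N = rep.int(N, length(term_ids)),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
  enrichment_table(records, label, catalog$namespace, alpha,
                   n_dropped = n_dropped)
}

#' Significant term ids of an enrichment table
#'
#' @param table an [enrichment_table()].
#' @return Character vector of term ids with `significant == TRUE`.
#' @export
significant_terms <- function(table) {
  stopifnot(inherits(table, "enrichment_table"))
  table$term_id[table$significant]
}

#' Write an enrichment table as CSV
#'
#' Columns: `term_id, description, k, K, n, N, p_raw, p_adj, significant`
#' plus formatted 3-significant-figure columns `p_raw_fmt, p_adj_fmt`.
#'
#' @param table an [enrichment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_csv <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  out <- as.data.frame(table)
  out$p_raw_fmt <- vapply(out$p_raw, format_pvalue, character(1))
  out$p_adj_fmt <- vapply(out$p_adj, format_pvalue, character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "Enrichment of '%s' in namespace '%s': %d terms tested, %d significant (alpha=%g)\n",
    attr(x, "label"), attr(x, "namespace"), nrow(x),
    sum(x$significant), attr(x, "alpha")
  ))
  if (attr(x, "n_dropped") > 0L) {
    cat(sprintf("  %d target gene(s) outside background dropped\n",
                attr(x, "n_dropped")))
  }
  NextMethod()
}
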