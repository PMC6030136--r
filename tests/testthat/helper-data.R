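# Shared helpers: tiny on-disk fixtures built in code at test time.

# keep pipeline logging out of test output; tests that assert on log
# messages re-enable it locally
options(chemmix.verbose = FALSE)

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

links_file <- function(rows, header = "chemical\tprotein\tcombined_score") {
  write_tmp(c(header, rows))
}

# a 20-gene background split over two terms: T = g1..g5, REST = g6..g20
toy_catalog <- function(namespace = "DO") {
  genes <- sprintf("g%d", 1:20)
  annotation_catalog(
    namespace,
    terms = list(T1 = genes[1:5], REST = genes[6:20]),
    descriptions = c(T1 = "toy term", REST = "everything else")
  )
}

# random catalog for property-style loops
random_catalog <- function(n_genes = 30, n_terms = 6, namespace = "NS") {
  genes <- sprintf("g%03d", seq_len(n_genes))
  terms <- lapply(seq_len(n_terms), function(i) {
    sample(genes, sample(3:10, 1))
  })
  names(terms) <- sprintf("%s:%03d", namespace, seq_len(n_terms))
  annotation_catalog(namespace, terms)
}

# hand-built enrichment table (for shared-term analysis without enrich())
manual_enrichment <- function(term_ids, p_adj, label, namespace = "DO",
                              alpha = 0.05) {
  enrichment_table(
    data.frame(
      term_id = term_ids,
      description = term_ids,
      k = 1L, K = 2L, n = 3L, N = 10L,
      p_raw = p_adj, p_adj = p_adj,
      significant = p_adj < alpha,
      stringsAsFactors = FALSE
    ),
    label = label, namespace = namespace, alpha = alpha
  )
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw n from N where the first K are marked; P(#marked >= k)
enum_upper_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= K)
  mean(marked >= k)
}

# literal step-up definition of BH, independent of bh_adjust's cummin form
bh_definition <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# normalize a venn_regions object for order-independent comparison
venn_canonical <- function(venn) {
  keys <- names(venn$regions)
  canon <- vapply(strsplit(keys, "+", fixed = TRUE),
                  function(k) paste(sort(k), collapse = "+"), character(1))
  regions <- lapply(venn$regions, sort)
  names(regions) <- canon
  regions[order(names(regions))]
}
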