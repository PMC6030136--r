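# Readers and writers for the on-disk chemogenomics bundle:
# STITCH-shaped link TSVs, chemical alias tables, protein->gene maps and
# GMT annotation catalogs. All identifiers are opaque, case-sensitive
# strings once parsed; only alias lookup is case-folded.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    cmx_io_error(sprintf("file not found: '%s'", path), path = path)
  }
  con <- gzfile(path, open = "rt")  # transparently reads plain or gzip
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

#' Construct a chemical-protein interaction table
#'
#' An `interaction_table` is a data frame with columns `chemical_id`,
#' `protein_id` and `combined_score` (integer confidence in \[0, 1000\],
#' the STITCH convention where 150/400/700 mark low/medium/high
#' confidence). Duplicate (chemical, protein) pairs are collapsed to the
#' maximum score, the conservative choice for threshold filtering.
#'
#' @param chemical_id,protein_id character vectors of equal length.
#' @param combined_score integer vector in \[0, 1000\].
#' @param source_version free-text provenance tag (e.g. `"v5"`).
#' @return A data frame of class `interaction_table` with one row per
#'   unique (chemical, protein) pair.
#' @export
interaction_table <- function(chemical_id, protein_id, combined_score,
                              source_version = "") {
  chemical_id <- as.character(chemical_id)
  protein_id <- as.character(protein_id)
  if (any(!nzchar(chemical_id)) || any(!nzchar(protein_id))) {
    cmx_domain_error("chemical_id and protein_id must be non-empty strings")
  }
  score <- as.integer(combined_score)
  if (any(is.na(score)) || any(score < 0L) || any(score > 1000L)) {
    cmx_domain_error("combined_score must be an integer in [0, 1000]")
  }
  df <- data.frame(
    chemical_id = chemical_id, protein_id = protein_id,
    combined_score = score, stringsAsFactors = FALSE
  )
  # max-collapse duplicates, then fix a deterministic row order
  if (nrow(df) > 0L) {
    key <- paste(df$chemical_id, df$protein_id, sep = "\r")
    ord <- order(key, -df$combined_score)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df,
    source_version = source_version,
    class = c("interaction_table", "data.frame")
  )
}

#' Read a STITCH-shaped chemical-protein links file
#'
#' Expects a tab-separated file (optionally gzip-compressed) whose header
#' names a chemical column, a protein column and a combined-score column,
#' as in STITCH `protein_chemical.links` dumps.
#'
#' @param path path to the TSV (may be `.gz`).
#' @param chemical_filter optional character vector; when given, only rows
#'   whose `chemical_id` is in this set are kept. Equivalent to reading
#'   everything and filtering afterwards.
#' @param source_version provenance tag stored on the result.
#' @return An [interaction_table()].
#' @export
read_stitch_links <- function(path, chemical_filter = NULL,
                              source_version = "") {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    cmx_format_error(sprintf("'%s': empty links file", path))
  }
  header <- split_fields(lines[[1L]])
  chem_col <- grep("chem", header, ignore.case = TRUE)[1L]
  prot_col <- grep("protein", header, ignore.case = TRUE)[1L]
  score_col <- grep("score", header, ignore.case = TRUE)[1L]
  if (is.na(chem_col) || is.na(prot_col) || is.na(score_col)) {
    cmx_format_error(sprintf(
      "'%s': header must name chemical, protein and score columns (got: %s)",
      path, paste(header, collapse = ", ")
    ))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  need <- max(chem_col, prot_col, score_col)
  chems <- character(length(body))
  prots <- character(length(body))
  scores <- integer(length(body))
  for (i in seq_along(body)) {
    f <- split_fields(body[[i]])
    lineno <- i + 1L  # header is line 1
    if (length(f) < need) {
      cmx_format_error(sprintf(
        "'%s' line %d: expected at least %d tab-separated fields, got %d",
        path, lineno, need, length(f)
      ))
    }
    s <- suppressWarnings(as.integer(f[[score_col]]))
    if (is.na(s) || f[[score_col]] != as.character(s) ||
        s < 0L || s > 1000L) {
      cmx_format_error(sprintf(
        "'%s' line %d: combined score '%s' is not an integer in [0, 1000]",
        path, lineno, f[[score_col]]
      ))
    }
    chems[[i]] <- f[[chem_col]]
    prots[[i]] <- f[[prot_col]]
    scores[[i]] <- s
  }
  if (!is.null(chemical_filter)) {
    keep <- chems %in% chemical_filter
    chems <- chems[keep]; prots <- prots[keep]; scores <- scores[keep]
  }
  interaction_table(chems, prots, scores, source_version = source_version)
}

#' Write an interaction table as a STITCH-shaped TSV
#'
#' @param table an [interaction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stitch_links <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  lines <- c(
    "chemical\tprotein\tcombined_score",
    sprintf("%s\t%s\t%d", table$chemical_id, table$protein_id,
            table$combined_score)
  )
  writeLines(lines, path)
  invisible(path)
}

normalize_alias <- function(x) {
  # trim + case-fold; deterministic, no fuzzy matching. CAS numbers are
  # digits and dashes so folding is a no-op for them.
  tolower(trimws(x))
}

#' Read a chemical alias table
#'
#' Two-column TSV of `(chemical_id, alias)` rows; aliases are names or CAS
#' numbers. The first alias listed for a chemical becomes its display
#' name. An alias mapping to two distinct chemicals is recorded as a
#' conflict and fails loudly at resolution time.
#'
#' @param path path to the alias TSV (optional `chemical_id` header line).
#' @return An object of class `chem_alias_index`.
#' @export
read_alias_table <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    cmx_format_error(sprintf("'%s': empty alias table", path))
  }
  if (normalize_alias(split_fields(lines[[1L]])[[1L]]) == "chemical_id") {
    lines <- lines[-1L]
  }
  entries <- list()        # normalized alias -> chemical_id
  conflicts <- list()      # normalized alias -> candidate chemical_ids
  display <- character(0)  # chemical_id -> preferred name
  for (i in seq_along(lines)) {
    f <- split_fields(lines[[i]])
    if (length(f) < 2L) {
      cmx_format_error(sprintf(
        "'%s' line %d: expected chemical_id<TAB>alias", path, i
      ))
    }
    cid <- trimws(f[[1L]])
    alias <- normalize_alias(f[[2L]])
    if (!nzchar(cid) || !nzchar(alias)) next
    if (!cid %in% names(display)) display[[cid]] <- trimws(f[[2L]])
    prev <- entries[[alias]]
    if (is.null(prev)) {
      entries[[alias]] <- cid
    } else if (!identical(prev, cid)) {
      conflicts[[alias]] <- sort(unique(c(conflicts[[alias]], prev, cid)))
    }
  }
  structure(
    list(entries = entries, conflicts = conflicts, display_names = display),
    class = "chem_alias_index"
  )
}

#' Resolve a chemical query to its identifier
#'
#' Exact match on a normalized (trimmed, case-folded) name or CAS number;
#' no prefix or fuzzy matching.
#'
#' @param query chemical name or CAS number.
#' @param index a `chem_alias_index` from [read_alias_table()].
#' @return The chemical id (string).
#' @export
resolve_chemical <- function(query, index) {
  stopifnot(inherits(index, "chem_alias_index"))
  key <- normalize_alias(query)
  cand <- index$conflicts[[key]]
  if (!is.null(cand)) {
    cmx_ambiguity_error(
      sprintf("alias '%s' is ambiguous between: %s",
              query, paste(cand, collapse = ", ")),
      candidates = cand
    )
  }
  hit <- index$entries[[key]]
  if (is.null(hit)) {
    cmx_not_found_error(sprintf("no chemical matches '%s'", query),
                        query = query)
  }
  hit
}

#' Construct an annotation catalog
#'
#' A catalog is one namespace (e.g. GO, KEGG, Reactome, SMPDB, DO,
#' DOLite) mapping term ids to gene sets. The enrichment background
#' universe is the union of all term gene sets.
#'
#' @param namespace namespace label.
#' @param terms named list: term id -> character vector of gene symbols.
#' @param descriptions named character vector: term id -> description.
#' @return An object of class `annotation_catalog` with elements
#'   `namespace`, `terms`, `descriptions`, `background`.
#' @export
annotation_catalog <- function(namespace, terms, descriptions = NULL) {
  if (length(terms) == 0L) {
    cmx_domain_error("catalog must contain at least one term")
  }
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    cmx_domain_error("terms must be a named list keyed by term id")
  }
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (any(lengths(terms) == 0L)) {
    cmx_domain_error("every term's gene set must be non-empty")
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(names(terms), names(terms))
  }
  descriptions <- descriptions[names(terms)]
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(terms)
  structure(
    list(
      namespace = as.character(namespace),
      terms = terms,
      descriptions = descriptions,
      background = sort(unique(unlist(terms, use.names = FALSE)))
    ),
    class = "annotation_catalog"
  )
}

#' Read a GMT gene-set file into an annotation catalog
#'
#' Standard GMT dialect: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Terms listed more
#' than once are merged by union; lines carrying zero genes are dropped.
#' Both situations are logged to stderr.
#'
#' @param path path to the GMT file.
#' @param namespace namespace label for the catalog.
#' @return An [annotation_catalog()].
#' @export
read_gmt <- function(path, namespace) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    cmx_format_error(sprintf("'%s': empty GMT file", path))
  }
  terms <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    f <- split_fields(lines[[i]])
    if (length(f) < 2L) {
      cmx_format_error(sprintf(
        "'%s' line %d: GMT lines need term_id<TAB>description", path, i
      ))
    }
    id <- f[[1L]]
    genes <- f[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      cmx_log("read_gmt: dropping term '%s' with zero genes ('%s' line %d)",
              id, path, i)
      next
    }
    if (!is.null(terms[[id]])) {
      cmx_log("read_gmt: merging duplicate term '%s' by union ('%s' line %d)",
              id, path, i)
      terms[[id]] <- union(terms[[id]], genes)
    } else {
      terms[[id]] <- genes
      descriptions[[id]] <- f[[2L]]
    }
  }
  if (length(terms) == 0L) {
    cmx_format_error(sprintf("'%s': no terms with genes in GMT file", path))
  }
  annotation_catalog(namespace, terms, descriptions)
}

#' Read a protein-to-gene mapping table
#'
#' Four-column TSV: `protein_id, gene_symbol, gene_id, gene_name`.
#' Duplicate rows that agree are deduplicated silently; a protein id
#' mapped to conflicting gene symbols is an error.
#'
#' @param path path to the mapping TSV (optional `protein_id` header).
#' @return A data frame of class `protein_gene_map`.
#' @export
read_protein_gene_map <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    cmx_format_error(sprintf("'%s': empty protein-gene map", path))
  }
  if (split_fields(lines[[1L]])[[1L]] == "protein_id") lines <- lines[-1L]
  rows <- lapply(seq_along(lines), function(i) {
    f <- split_fields(lines[[i]])
    if (length(f) < 4L) {
      cmx_format_error(sprintf(
        "'%s' line %d: expected 4 columns (protein_id, gene_symbol, gene_id, gene_name)",
        path, i
      ))
    }
    f[1:4]
  })
  m <- do.call(rbind, rows)
  df <- data.frame(
    protein_id = m[, 1L], gene_symbol = m[, 2L],
    gene_id = m[, 3L], gene_name = m[, 4L], stringsAsFactors = FALSE
  )
  df <- unique(df)
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup) > 0L) {
    cmx_format_error(sprintf(
      "'%s': conflicting mappings for protein(s): %s",
      path, paste(dup, collapse = ", ")
    ))
  }
  df <- df[order(df$protein_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("protein_gene_map", "data.frame"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("Interaction table: %d links, %d chemicals, %d proteins",
              nrow(x), length(unique(x$chemical_id)),
              length(unique(x$protein_id))))
  sv <- attr(x, "source_version")
  if (nzchar(sv)) cat(sprintf(" (source %s)", sv))
  cat("\n")
  NextMethod()
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("Annotation catalog '%s': %d terms, background of %d genes\n",
              x$namespace, length(x$terms), length(x$background)))
  invisible(x)
}

#' @export
print.chem_alias_index <- function(x, ...) {
  cat(sprintf("Chemical alias index: %d aliases, %d chemicals, %d conflicts\n",
              length(x$entries), length(x$display_names),
              length(x$conflicts)))
  invisible(x)
}
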