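# The mixture-interaction engine: confidence filtering, target
# extraction, Venn partitioning of targets and of enriched term sets,
# joint p-values for shared terms, and union-based overall enrichment.

#' STITCH-convention confidence score thresholds
#'
#' Minimum combined scores defining low, medium and high confidence
#' interactions (150/400/700, the STITCH convention).
#'
#' @return Named integer vector `c(low = 150, medium = 400, high = 700)`.
#' @export
confidence_thresholds <- function() {
  c(low = 150L, medium = 400L, high = 700L)
}

#' Resolve a confidence level
#'
#' @param level `"low"`, `"medium"`, `"high"`, or an explicit integer
#'   minimum combined score in \[0, 1000\].
#' @return List with `name` and `min_score`.
#' @export
confidence_level <- function(level = "high") {
  if (is.numeric(level)) {
    thr <- as.integer(level)
    if (is.na(thr) || thr < 0L || thr > 1000L) {
      cmx_domain_error("explicit score threshold must be in [0, 1000]")
    }
    return(list(name = sprintf("custom(>=%d)", thr), min_score = thr))
  }
  thresholds <- confidence_thresholds()
  if (!level %in% names(thresholds)) {
    cmx_contract_error(sprintf(
      "unknown confidence level '%s' (use low, medium, high or a score)",
      level
    ))
  }
  list(name = level, min_score = unname(thresholds[[level]]))
}

#' Extract a chemical's confidence-filtered target gene set
#'
#' Keeps the chemical's links with `combined_score >= min_score` and maps
#' the surviving proteins to gene symbols. Several proteins mapping to
#' one gene collapse to the maximum score; proteins without a mapping are
#' recorded in `unmapped_proteins` and excluded from `genes`.
#'
#' @param table an [interaction_table()].
#' @param chemical_id chemical identifier present in `table`.
#' @param level a [confidence_level()] (or a name/score accepted by it).
#' @param map a `protein_gene_map` from [read_protein_gene_map()].
#' @return Object of class `target_set` with elements `chemical_id`,
#'   `level`, `genes` (sorted character), `per_gene_score` (named
#'   integer), `unmapped_proteins`.
#' @export
select_targets <- function(table, chemical_id, level, map) {
  stopifnot(inherits(table, "interaction_table"),
            inherits(map, "protein_gene_map"))
  if (!is.list(level)) level <- confidence_level(level)
  rows <- table[table$chemical_id == chemical_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    cmx_not_found_error(
      sprintf("chemical '%s' has no links in the interaction table",
              chemical_id),
      query = chemical_id
    )
  }
  rows <- rows[rows$combined_score >= level$min_score, , drop = FALSE]
  idx <- match(rows$protein_id, map$protein_id)
  unmapped <- sort(unique(rows$protein_id[is.na(idx)]))
  mapped_idx <- idx[!is.na(idx)]
  mapped <- rows[!is.na(idx), , drop = FALSE]
  symbols <- map$gene_symbol[mapped_idx]
  per_gene <- stats::setNames(integer(0), character(0))
  if (nrow(mapped) > 0L) {
    per_gene <- vapply(split(mapped$combined_score, symbols), max, integer(1))
    per_gene <- per_gene[sort(names(per_gene))]
  }
  detail <- data.frame(
    protein_id = mapped$protein_id,
    gene_symbol = symbols,
    gene_id = map$gene_id[mapped_idx],
    gene_name = map$gene_name[mapped_idx],
    combined_score = mapped$combined_score,
    stringsAsFactors = FALSE
  )
  detail <- detail[order(detail$protein_id), , drop = FALSE]
  rownames(detail) <- NULL
  structure(
    list(
      chemical_id = chemical_id,
      level = level,
      genes = names(per_gene),
      per_gene_score = per_gene,
      unmapped_proteins = unmapped,
      detail = detail
    ),
    class = "target_set"
  )
}

#' Partition 2-4 labeled sets into disjoint Venn regions
#'
#' Every element of the union is assigned to exactly one region, keyed by
#' the subset of labels whose sets contain it. All `2^n - 1` regions are
#' present, empty ones with empty member vectors. Region names join the
#' labels with `"+"` in input-label order.
#'
#' @param labeled_sets named list of 2-4 character vectors.
#' @return Object of class `venn_regions` with elements `labels` and
#'   `regions` (named list of sorted character vectors).
#' @export
venn_partition <- function(labeled_sets) {
  n <- length(labeled_sets)
  if (n < 2L || n > 4L) {
    cmx_contract_error(sprintf(
      "Venn partitioning needs between 2 and 4 sets, got %d", n
    ))
  }
  labels <- names(labeled_sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    cmx_contract_error("labeled_sets must have unique non-empty names")
  }
  sets <- lapply(labeled_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  if (length(universe) == 0L) {
    membership <- matrix(logical(0), nrow = 0L, ncol = n)
  }
  # all non-empty label subsets, in binary-counter order
  regions <- list()
  for (mask in seq_len(2L^n - 1L)) {
    in_subset <- as.logical(bitwAnd(mask, 2L^(seq_len(n) - 1L)))
    key <- paste(labels[in_subset], collapse = "+")
    hit <- rep(TRUE, length(universe))
    for (j in seq_len(n)) {
      hit <- hit & (membership[, j] == in_subset[j])
    }
    regions[[key]] <- universe[hit]
  }
  structure(list(labels = labels, regions = regions),
            class = "venn_regions")
}

#' Full-intersection region of a Venn partition
#'
#' @param venn a `venn_regions` object.
#' @return Members of the region where all sets overlap.
#' @export
venn_intersection <- function(venn) {
  stopifnot(inherits(venn, "venn_regions"))
  venn$regions[[paste(venn$labels, collapse = "+")]]
}

#' Joint p-value for a term shared by several chemicals
#'
#' The mixture-prioritization statistic: the product of the per-chemical
#' BH-adjusted p-values of a term enriched for every chemical,
#' `p_j = prod_i p_i`. Accumulated in log10 space so that products far
#' below the double-precision floor keep an exact `log10_joint_p` even
#' when `joint_p` itself underflows to 0.
#'
#' @param per_chemical_adj_p named numeric vector (chemical -> adjusted
#'   p-value in \[0, 1\]).
#' @param term_id optional term identifier carried on the result.
#' @return Object of class `joint_pvalue` with elements `term_id`,
#'   `per_chemical_adj_p`, `joint_p`, `log10_joint_p`, `underflow`, and
#'   `zero_input` flagging a degenerate 0 input.
#' @export
joint_pvalue <- function(per_chemical_adj_p, term_id = NA_character_) {
  p <- as.numeric(per_chemical_adj_p)
  if (length(p) < 1L) {
    cmx_domain_error("at least one chemical's p-value is required")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    cmx_domain_error("adjusted p-values must lie in [0, 1]")
  }
  zero_input <- any(p == 0)
  if (zero_input) {
    log10_joint <- -Inf
    joint <- 0
  } else {
    log10_joint <- sum(log10(p))
    joint <- 10^log10_joint  # 0-clamped by IEEE underflow when < ~1e-308
  }
  structure(
    list(
      term_id = term_id,
      per_chemical_adj_p = stats::setNames(p, names(per_chemical_adj_p)),
      joint_p = joint,
      log10_joint_p = log10_joint,
      underflow = is.finite(log10_joint) && joint == 0,
      zero_input = zero_input
    ),
    class = "joint_pvalue"
  )
}

#' Shared-term analysis across chemicals for one namespace
#'
#' Builds the Venn partition of the chemicals' significant term-id sets
#' and computes a joint p-value for every term in the full-intersection
#' region (significant for all chemicals), using each chemical's own
#' BH-adjusted p-value for that term. Joint p-values are reported for the
#' full intersection only; partial-overlap regions appear in the Venn
#' without a joint p.
#'
#' @param tables named list (chemical id -> [enrichment_table()]), all
#'   for the same namespace; 2-4 chemicals.
#' @return List with `term_venn` (a `venn_regions` over significant term
#'   ids) and `joint` (list of [joint_pvalue()] sorted by ascending
#'   `log10_joint_p`, ties by term id).
#' @export
shared_term_analysis <- function(tables) {
  if (length(tables) < 2L || length(tables) > 4L) {
    cmx_contract_error("shared-term analysis needs 2-4 chemicals")
  }
  ns <- unique(vapply(tables, function(t) attr(t, "namespace"), character(1)))
  if (length(ns) != 1L) {
    cmx_contract_error(sprintf(
      "all tables must share one namespace, got: %s",
      paste(ns, collapse = ", ")
    ))
  }
  sig_sets <- lapply(tables, significant_terms)
  venn <- venn_partition(sig_sets)
  shared <- venn_intersection(venn)
  joint <- lapply(shared, function(tid) {
    p <- vapply(tables, function(t) t$p_adj[match(tid, t$term_id)],
                numeric(1))
    joint_pvalue(p, term_id = tid)
  })
  if (length(joint) > 0L) {
    ord <- order(vapply(joint, function(j) j$log10_joint_p, numeric(1)),
                 vapply(joint, function(j) j$term_id, character(1)))
    joint <- joint[ord]
  }
  list(term_venn = venn, joint = joint)
}

#' Overall-effect enrichment on the union of target sets
#'
#' Treats the mixture as a single exposure: enrichment of the union of
#' all chemicals' target genes, labeled `"union"`.
#'
#' @param target_sets list of `target_set` objects (length >= 1).
#' @param catalog an [annotation_catalog()].
#' @param alpha significance threshold.
#' @return An [enrichment_table()] labeled `"union"`.
#' @export
overall_enrichment <- function(target_sets, catalog, alpha = 0.05) {
  if (length(target_sets) < 1L) {
    cmx_contract_error("at least one target set is required")
  }
  genes <- sort(unique(unlist(lapply(target_sets, `[[`, "genes"),
                              use.names = FALSE)))
  enrich(genes, catalog, alpha = alpha, label = "union")
}

#' Run the full mixture-interaction analysis
#'
#' Orchestrates the pipeline for 2-4 chemicals: resolve queries ->
#' confidence-filtered target extraction -> target Venn -> per-chemical
#' enrichment per namespace -> term Venn and joint p-values per namespace
#' -> union-based overall enrichment. Deterministic for fixed inputs.
#' A chemical whose target set is empty after filtering is retained with
#' empty outputs so mixtures degrade gracefully.
#'
#' @param chemicals 2-4 chemical queries (names, CAS numbers, or raw
#'   chemical ids when `bundle$aliases` is `NULL`).
#' @param bundle list with elements `links` ([interaction_table()]),
#'   `aliases` (`chem_alias_index` or `NULL`), `map`
#'   (`protein_gene_map`), `catalogs` (named list of
#'   [annotation_catalog()]); see [read_bundle()].
#' @param level confidence level name or explicit integer threshold.
#' @param namespaces catalogs to analyze (default: all in the bundle).
#' @param alpha BH-adjusted significance threshold.
#' @return Object of class `mixture_report` with elements `chemicals`
#'   (data frame of query/id/display name), `level`, `alpha`,
#'   `target_sets`, `target_venn`, `enrichment` (nested chemical ->
#'   namespace -> table), `shared` (namespace -> shared_term_analysis
#'   result), `overall` (namespace -> union table).
#' @export
analyze_mixture <- function(chemicals, bundle, level = "high",
                            namespaces = names(bundle$catalogs),
                            alpha = 0.05) {
  if (length(chemicals) < 2L || length(chemicals) > 4L) {
    cmx_contract_error(sprintf(
      "between 2 and 4 chemicals can be analyzed simultaneously, got %d",
      length(chemicals)
    ))
  }
  stopifnot(inherits(bundle$links, "interaction_table"),
            inherits(bundle$map, "protein_gene_map"))
  if (length(namespaces) == 0L ||
      !all(namespaces %in% names(bundle$catalogs))) {
    cmx_contract_error("requested namespaces missing from the bundle")
  }
  lvl <- confidence_level(level)

  ids <- vapply(chemicals, function(q) {
    if (is.null(bundle$aliases)) q else resolve_chemical(q, bundle$aliases)
  }, character(1))
  if (anyDuplicated(ids)) {
    cmx_contract_error(sprintf(
      "queries resolve to duplicate chemicals: %s",
      paste(ids[duplicated(ids)], collapse = ", ")
    ))
  }
  display <- if (is.null(bundle$aliases)) {
    stats::setNames(ids, ids)
  } else {
    d <- bundle$aliases$display_names[ids]
    d[is.na(d)] <- ids[is.na(d)]
    stats::setNames(d, ids)
  }
  chem_df <- data.frame(
    query = as.character(chemicals), chemical_id = unname(ids),
    display_name = unname(display[ids]), stringsAsFactors = FALSE
  )
  cmx_log("resolved %d chemicals: %s", length(ids),
          paste(sprintf("%s -> %s", chem_df$query, chem_df$chemical_id),
                collapse = ", "))

  target_sets <- lapply(ids, function(cid) {
    ts <- select_targets(bundle$links, cid, lvl, bundle$map)
    cmx_log("chemical %s: %d target genes at %s confidence (%d unmapped proteins)",
            cid, length(ts$genes), lvl$name, length(ts$unmapped_proteins))
    ts
  })
  names(target_sets) <- ids

  target_venn <- venn_partition(lapply(target_sets, `[[`, "genes"))

  enrichment <- lapply(target_sets, function(ts) {
    tabs <- lapply(namespaces, function(ns) {
      enrich(ts$genes, bundle$catalogs[[ns]], alpha = alpha,
             label = ts$chemical_id)
    })
    names(tabs) <- namespaces
    tabs
  })
  for (cid in ids) {
    counts <- vapply(enrichment[[cid]],
                     function(t) sum(t$significant), integer(1))
    cmx_log("chemical %s significant terms: %s", cid,
            paste(sprintf("%s=%d", namespaces, counts), collapse = ", "))
  }

  shared <- lapply(namespaces, function(ns) {
    shared_term_analysis(lapply(enrichment, `[[`, ns))
  })
  names(shared) <- namespaces

  overall <- lapply(namespaces, function(ns) {
    overall_enrichment(target_sets, bundle$catalogs[[ns]], alpha = alpha)
  })
  names(overall) <- namespaces

  structure(
    list(
      chemicals = chem_df,
      level = lvl,
      alpha = alpha,
      target_sets = target_sets,
      target_venn = target_venn,
      enrichment = enrichment,
      shared = shared,
      overall = overall
    ),
    class = "mixture_report"
  )
}

#' @export
print.venn_regions <- function(x, ...) {
  cat(sprintf("Venn partition of %d sets (%s): %d regions\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              length(x$regions)))
  for (key in names(x$regions)) {
    cat(sprintf("  [%s] %d member(s)\n", key, length(x$regions[[key]])))
  }
  invisible(x)
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf(
    "Target set for %s at %s confidence: %d genes, %d unmapped proteins\n",
    x$chemical_id, x$level$name, length(x$genes),
    length(x$unmapped_proteins)
  ))
  invisible(x)
}

#' @export
print.joint_pvalue <- function(x, ...) {
  cat(sprintf("Joint p-value%s: %s (log10 = %.4f) from %d chemicals\n",
              if (is.na(x$term_id)) "" else sprintf(" for %s", x$term_id),
              format_pvalue(x$joint_p, log10_p = x$log10_joint_p),
              x$log10_joint_p, length(x$per_chemical_adj_p)))
  invisible(x)
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf("Mixture analysis of %d chemicals at %s confidence (alpha=%g)\n",
              nrow(x$chemicals), x$level$name, x$alpha))
  for (i in seq_len(nrow(x$chemicals))) {
    cid <- x$chemicals$chemical_id[i]
    cat(sprintf("  %s (%s): %d target genes\n", cid,
                x$chemicals$display_name[i],
                length(x$target_sets[[cid]]$genes)))
  }
  inter <- venn_intersection(x$target_venn)
  cat(sprintf("  shared target genes: %d\n", length(inter)))
  for (ns in names(x$shared)) {
    cat(sprintf("  namespace %s: %d shared significant term(s)\n",
                ns, length(x$shared[[ns]]$joint)))
  }
  invisible(x)
}
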