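# Seeded synthetic-data generator: produces a complete, internally
# consistent bundle (links, aliases, protein-gene map, GMT catalogs) with
# planted shared targets and planted co-enriched terms, so the whole
# pipeline is testable offline. This stands in for real STITCH/GO/DO
# snapshots; it makes no attempt at statistical realism of STITCH score
# distributions.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the documented reference fixture: seed 42, two
#' chemicals, a 200-gene universe, 20 terms of size 8-15 per namespace,
#' 30 target links per chemical, 3 planted shared target genes, and one
#' disease-namespace term planted at fraction 1.0 (all of its genes
#' forced into every chemical's target set at high-confidence scores).
#'
#' @param seed integer RNG seed (single pseudo-random stream).
#' @param n_chemicals number of chemicals, 2-4.
#' @param n_background_genes size of the synthetic gene universe.
#' @param n_terms_per_namespace terms sampled per catalog.
#' @param term_size_range `c(min, max)` genes per term.
#' @param targets_per_chemical link rows generated per chemical.
#' @param n_planted_shared_targets genes forced into every chemical's
#'   high-confidence target set.
#' @param namespaces catalog namespaces to generate.
#' @param planted_terms list of `list(namespace =, fraction =)` entries;
#'   for each, one term of that namespace has `fraction` of its genes
#'   forced into every chemical's target set. Fraction must be in (0, 1].
#' @param planted_score_range score band for planted links (clears the
#'   high-confidence threshold by default).
#' @param filler_score_range score band for random filler links (spans
#'   all three confidence levels so filtering is exercised).
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42L,
                           n_chemicals = 2L,
                           n_background_genes = 200L,
                           n_terms_per_namespace = 20L,
                           term_size_range = c(8L, 15L),
                           targets_per_chemical = 30L,
                           n_planted_shared_targets = 3L,
                           namespaces = c("GO", "DO"),
                           planted_terms = list(
                             list(namespace = "DO", fraction = 1.0)
                           ),
                           planted_score_range = c(700L, 1000L),
                           filler_score_range = c(150L, 1000L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chemicals = as.integer(n_chemicals),
    n_background_genes = as.integer(n_background_genes),
    n_terms_per_namespace = as.integer(n_terms_per_namespace),
    term_size_range = as.integer(term_size_range),
    targets_per_chemical = as.integer(targets_per_chemical),
    n_planted_shared_targets = as.integer(n_planted_shared_targets),
    namespaces = as.character(namespaces),
    planted_terms = planted_terms,
    planted_score_range = as.integer(planted_score_range),
    filler_score_range = as.integer(filler_score_range)
  )
  if (cfg$n_chemicals < 2L || cfg$n_chemicals > 4L) {
    cmx_config_error("n_chemicals must be between 2 and 4")
  }
  if (length(cfg$term_size_range) != 2L ||
      cfg$term_size_range[1L] > cfg$term_size_range[2L] ||
      cfg$term_size_range[1L] < 1L) {
    cmx_config_error("term_size_range must be c(min, max) with 1 <= min <= max")
  }
  if (cfg$term_size_range[2L] > cfg$n_background_genes) {
    cmx_config_error("term sizes exceed the background gene universe")
  }
  if (cfg$n_planted_shared_targets > cfg$targets_per_chemical) {
    cmx_config_error(
      "n_planted_shared_targets cannot exceed targets_per_chemical"
    )
  }
  for (pt in cfg$planted_terms) {
    if (is.null(pt$namespace) || !pt$namespace %in% cfg$namespaces) {
      cmx_config_error("planted term namespace not in configured namespaces")
    }
    if (is.null(pt$fraction) || pt$fraction <= 0 || pt$fraction > 1) {
      cmx_config_error("planted fraction must be in (0, 1]")
    }
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a synthetic chemogenomics data bundle
#'
#' Writes, under `dir`: `links.tsv` (STITCH-shaped), `aliases.tsv`,
#' `protein_gene_map.tsv`, one `<namespace>.gmt` per catalog, and
#' `manifest.json` recording the resolved config and the ground truth
#' (planted shared genes and planted term ids). Each chemical's target
#' genes are the planted shared genes, plus the planted-term genes, plus
#' random fill up to `targets_per_chemical`; planted links draw scores
#' that clear the high-confidence threshold. Deterministic: the same
#' config always produces byte-identical files.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if missing).
#' @return Object of class `fixture_bundle`: `dir`, `files` (named
#'   absolute paths), `manifest` (config + ground truth).
#' @export
generate_fixture <- function(config = fixture_config(), dir = tempfile("fixture")) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  # sample() on a length-1 numeric vector would sample 1:x; avoid that
  resample <- function(x, n, replace = FALSE) {
    x[sample.int(length(x), n, replace = replace)]
  }

  genes <- sprintf("G%04d", seq_len(config$n_background_genes))
  proteins <- sprintf("9606.ENSP%08d", seq_len(config$n_background_genes))
  gene_of_protein <- stats::setNames(genes, proteins)
  protein_of_gene <- stats::setNames(proteins, genes)

  # catalogs: sampled term gene sets per namespace
  catalogs <- list()
  for (ns in config$namespaces) {
    terms <- list()
    descriptions <- character(0)
    for (j in seq_len(config$n_terms_per_namespace)) {
      id <- sprintf("%s:%04d", ns, j)
      size <- resample(seq(config$term_size_range[1L],
                           config$term_size_range[2L]), 1L)
      terms[[id]] <- sort(resample(genes, size))
      descriptions[[id]] <- sprintf("synthetic %s term %d", ns, j)
    }
    catalogs[[ns]] <- annotation_catalog(ns, terms, descriptions)
  }

  # ground truth: planted shared genes and planted term gene subsets
  planted_shared <- sort(resample(genes, config$n_planted_shared_targets))
  planted_terms <- lapply(config$planted_terms, function(pt) {
    cat_terms <- catalogs[[pt$namespace]]$terms
    tid <- resample(names(cat_terms), 1L)
    members <- cat_terms[[tid]]
    n_forced <- max(1L, ceiling(pt$fraction * length(members)))
    list(
      namespace = pt$namespace,
      term_id = tid,
      fraction = pt$fraction,
      forced_genes = sort(resample(members, n_forced))
    )
  })
  forced_genes <- sort(unique(unlist(
    lapply(planted_terms, `[[`, "forced_genes"), use.names = FALSE
  )))

  base_targets <- sort(unique(c(planted_shared, forced_genes)))
  if (length(base_targets) > config$targets_per_chemical) {
    cmx_config_error(sprintf(
      "planted genes (%d) exceed targets_per_chemical (%d)",
      length(base_targets), config$targets_per_chemical
    ))
  }

  chem_ids <- sprintf("CIDm%08d", seq_len(config$n_chemicals))
  chem_names <- sprintf("chem%02d", seq_len(config$n_chemicals))
  chem_cas <- sprintf("%d-%02d-%d",
                      1000L + seq_len(config$n_chemicals),
                      seq_len(config$n_chemicals), 5L)

  rint <- function(n, range) {
    as.integer(resample(seq(range[1L], range[2L]), n, replace = TRUE))
  }

  link_rows <- character(0)
  chem_targets <- list()
  for (i in seq_len(config$n_chemicals)) {
    n_fill <- config$targets_per_chemical - length(base_targets)
    fill <- resample(setdiff(genes, base_targets), n_fill)
    targets <- c(base_targets, sort(fill))
    planted_flag <- targets %in% base_targets
    scores <- integer(length(targets))
    scores[planted_flag] <- rint(sum(planted_flag),
                                 config$planted_score_range)
    scores[!planted_flag] <- rint(sum(!planted_flag),
                                  config$filler_score_range)
    chem_targets[[chem_ids[i]]] <- targets
    link_rows <- c(link_rows, sprintf(
      "%s\t%s\t%d", chem_ids[i], protein_of_gene[targets], scores
    ))
  }

  files <- c(
    links = "links.tsv",
    aliases = "aliases.tsv",
    map = "protein_gene_map.tsv",
    stats::setNames(sprintf("%s.gmt", config$namespaces),
                    paste0("gmt_", config$namespaces)),
    manifest = "manifest.json"
  )
  paths <- stats::setNames(file.path(dir, files), names(files))

  writeLines(c("chemical\tprotein\tcombined_score", link_rows),
             paths[["links"]])
  alias_rows <- character(0)
  for (i in seq_len(config$n_chemicals)) {
    alias_rows <- c(alias_rows,
                    sprintf("%s\t%s", chem_ids[i], chem_names[i]),
                    sprintf("%s\t%s", chem_ids[i], chem_cas[i]))
  }
  writeLines(alias_rows, paths[["aliases"]])
  writeLines(sprintf("%s\t%s\t%d\t%s", proteins, genes,
                     100000L + seq_along(genes),
                     sprintf("synthetic protein for %s", genes)),
             paths[["map"]])
  for (ns in config$namespaces) {
    cat_ns <- catalogs[[ns]]
    writeLines(vapply(names(cat_ns$terms), function(tid) {
      paste(c(tid, cat_ns$descriptions[[tid]], cat_ns$terms[[tid]]),
            collapse = "\t")
    }, character(1)), paths[[paste0("gmt_", ns)]])
  }

  manifest <- list(
    config = unclass(config),
    chemicals = lapply(seq_len(config$n_chemicals), function(i) {
      list(chemical_id = chem_ids[i], name = chem_names[i],
           cas = chem_cas[i])
    }),
    ground_truth = list(
      planted_shared_genes = as.list(planted_shared),
      planted_terms = planted_terms,
      targets_per_chemical = lapply(chem_targets, as.list)
    ),
    files = as.list(unname(files))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths[["manifest"]])

  structure(list(dir = dir, files = paths, manifest = manifest),
            class = "fixture_bundle")
}

#' Load an analysis bundle from its on-disk files
#'
#' @param links path to the STITCH-shaped links TSV.
#' @param map path to the protein-gene mapping TSV.
#' @param gmt named character vector, namespace -> GMT path.
#' @param aliases optional path to the alias TSV; when `NULL`, chemical
#'   queries are treated as raw chemical ids.
#' @return A bundle list (`links`, `aliases`, `map`, `catalogs`) as
#'   consumed by [analyze_mixture()].
#' @export
read_bundle <- function(links, map, gmt, aliases = NULL) {
  if (is.null(names(gmt)) || any(!nzchar(names(gmt)))) {
    cmx_contract_error("gmt must be a named vector: namespace = path")
  }
  list(
    links = read_stitch_links(links),
    aliases = if (is.null(aliases)) NULL else read_alias_table(aliases),
    map = read_protein_gene_map(map),
    catalogs = stats::setNames(
      lapply(names(gmt), function(ns) read_gmt(gmt[[ns]], ns)),
      names(gmt)
    )
  )
}

#' Load a generated fixture bundle for analysis
#'
#' @param bundle a `fixture_bundle` from [generate_fixture()], or the
#'   directory such a bundle was written to.
#' @return A bundle list as consumed by [analyze_mixture()].
#' @export
read_fixture_bundle <- function(bundle) {
  if (is.character(bundle)) {
    manifest_path <- file.path(bundle, "manifest.json")
    if (!file.exists(manifest_path)) {
      cmx_io_error(sprintf("no manifest.json under '%s'", bundle))
    }
    manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
    dir <- bundle
  } else {
    stopifnot(inherits(bundle, "fixture_bundle"))
    manifest <- bundle$manifest
    dir <- bundle$dir
  }
  namespaces <- unlist(manifest$config$namespaces)
  read_bundle(
    links = file.path(dir, "links.tsv"),
    map = file.path(dir, "protein_gene_map.tsv"),
    gmt = stats::setNames(file.path(dir, sprintf("%s.gmt", namespaces)),
                          namespaces),
    aliases = file.path(dir, "aliases.tsv")
  )
}

#' Check that planted terms are recovered by the full pipeline
#'
#' Runs [analyze_mixture()] on a generated bundle at high confidence and
#' verifies, for every planted term, that it is significant
#' (`p_adj < alpha`) for each chemical and present in the shared-term
#' set. Returns a report rather than erroring.
#'
#' @param config the [fixture_config()] the bundle was generated from.
#' @param bundle the corresponding `fixture_bundle`.
#' @param alpha significance threshold (default 0.05).
#' @return Data frame with one row per planted term: `namespace`,
#'   `term_id`, `significant_in_all`, `in_shared_terms`, `pass`. Empty
#'   when no terms were planted. The full `mixture_report` is attached
#'   as attribute `"report"`.
#' @export
expected_planted_significance <- function(config, bundle, alpha = 0.05) {
  stopifnot(inherits(config, "fixture_config"),
            inherits(bundle, "fixture_bundle"))
  data <- read_fixture_bundle(bundle)
  chem_names <- vapply(bundle$manifest$chemicals, `[[`, character(1), "name")
  report <- analyze_mixture(chem_names, data, level = "high", alpha = alpha)
  planted <- bundle$manifest$ground_truth$planted_terms
  if (length(planted) == 0L) {
    out <- data.frame(
      namespace = character(0), term_id = character(0),
      significant_in_all = logical(0), in_shared_terms = logical(0),
      pass = logical(0), stringsAsFactors = FALSE
    )
    attr(out, "report") <- report
    return(out)
  }
  rows <- lapply(planted, function(pt) {
    ns <- pt$namespace
    tid <- pt$term_id
    sig_each <- vapply(report$enrichment, function(tabs) {
      tab <- tabs[[ns]]
      i <- match(tid, tab$term_id)
      !is.na(i) && tab$significant[i]
    }, logical(1))
    shared_ids <- vapply(report$shared[[ns]]$joint, `[[`, character(1),
                         "term_id")
    data.frame(
      namespace = ns, term_id = tid,
      significant_in_all = all(sig_each),
      in_shared_terms = tid %in% shared_ids,
      pass = all(sig_each) && tid %in% shared_ids,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}
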