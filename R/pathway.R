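# Metabolic pathway analysis: hypergeometric over-representation plus
# out-degree-centrality topology impact over small packaged pathway-graph
# libraries.

#' Load a pathway library
#'
#' Two toy libraries ship with the package: `"toy-hsa"` (11 pathways in the
#' style of the better-annotated Homo sapiens collection) and `"toy-bta"`
#' (its smaller Bos taurus counterpart). A library holds, per pathway, a
#' named directed compound graph (nodes = compounds, edges = reactions),
#' plus a synonym table; the compound universe is the union of all pathway
#' compounds.
#'
#' A library's compound universe is the union of its pathway compounds and
#' its background pool (compounds known to the library but belonging to
#' pathways outside the modelled set) — the reference tool's convention,
#' where the enrichment background is the whole compound collection, not
#' the measured panel.
#'
#' @param name `"toy-hsa"`, `"toy-bta"`, or a path to a library JSON file.
#' @return object of class `"pathway_library"`: `name`, `pathways` (each
#'   with `name`, `compounds`, `graph` (igraph)), `synonyms` (named
#'   character vector, lower-cased names), `universe`.
#' @export
load_pathway_library <- function(name = "toy-hsa") {
  path <- if (file.exists(name)) name else {
    file <- switch(name,
                   "toy-hsa" = "pathway_toy_hsa.json",
                   "toy-bta" = "pathway_toy_bta.json",
                   stop("unknown pathway library: ", name))
    system.file("extdata", file, package = "ovimetab", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  pathways <- lapply(raw$pathways, function(p) {
    compounds <- as.character(unlist(p$compounds))
    if (!length(compounds)) stop("pathway ", p$name, " has no compounds")
    if (anyDuplicated(compounds))
      stop("pathway ", p$name, " has duplicate compounds")
    edges <- if (length(p$edges))
      matrix(unlist(p$edges), ncol = 2, byrow = TRUE) else NULL
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(compounds)
    if (!is.null(edges)) {
      if (!all(edges %in% compounds))
        stop("pathway ", p$name, " has edges to unlisted compounds")
      g <- igraph::add_edges(g, t(edges))
    }
    list(name = p$name, compounds = compounds, graph = g)
  })
  synonyms <- unlist(raw$synonyms)
  if (length(synonyms)) names(synonyms) <- tolower(names(synonyms))
  universe <- sort(unique(c(unlist(lapply(pathways, `[[`, "compounds")),
                            as.character(unlist(raw$background_compounds)))))
  structure(list(name = raw$name, pathways = pathways,
                 synonyms = synonyms, universe = universe),
            class = "pathway_library")
}

#' Match metabolite names against a pathway library
#'
#' Case-insensitive matching of names (and library synonyms) against the
#' library's compound universe. Unmatched names (e.g. unknown metabolites
#' "U1", "U2") are reported and excluded from enrichment.
#'
#' @param metabolites character vector of metabolite names.
#' @param library a [load_pathway_library()] object.
#' @return list `matched` (canonical compound names), `unmatched`.
#' @export
map_metabolites <- function(metabolites, library) {
  if (!length(metabolites)) stop("empty metabolite list")
  uni <- library$universe
  lower_uni <- tolower(uni)
  canon <- vapply(metabolites, function(m) {
    lm <- tolower(m)
    i <- match(lm, lower_uni)
    if (!is.na(i)) return(uni[i])
    s <- library$synonyms[lm]
    if (!is.na(s)) {
      j <- match(tolower(s), lower_uni)
      if (!is.na(j)) return(uni[j])
    }
    NA_character_
  }, "")
  unmatched <- metabolites[is.na(canon)]
  if (length(unmatched) == length(metabolites))
    warning("no metabolites matched the library universe")
  list(matched = unique(unname(canon[!is.na(canon)])), unmatched = unmatched)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of observing `k` or more pathway
#' compounds among `n` matched metabolites drawn from a universe of `N`
#' compounds of which `K` belong to the pathway. `k = 0` gives P = 1.
#'
#' @param k hits in the pathway.
#' @param K pathway size.
#' @param n matched metabolite list size.
#' @param N universe size.
#' @return the enrichment p-value.
#' @export
enrich_hypergeometric <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway topology impact from out-degree centrality
#'
#' `impact = sum(out-degree of hit compounds) / sum(out-degree of all
#' compounds)` in the pathway graph, landing in `[0, 1]`; a graph with no
#' edges has impact 0.
#'
#' @param pathway one element of a pathway library (with `graph`).
#' @param hits character vector of hit compound names.
#' @return impact score.
#' @export
pathway_impact <- function(pathway, hits) {
  deg <- igraph::degree(pathway$graph, mode = "out")
  total <- sum(deg)
  if (total == 0) return(0)
  sum(deg[names(deg) %in% hits]) / total
}

#' Pathway enrichment analysis
#'
#' Maps the significant metabolites into the library, computes the
#' hypergeometric enrichment p-value and the out-degree topology impact
#' for every pathway, and summarizes with fold-enrichment scores
#' `-ln(P)` and the raw `P < 0.05` significance rule (no cross-pathway
#' correction by default, matching the reporting convention of the
#' enrichment tool the analysis emulates; BH across pathways available).
#'
#' @param metabolites significant metabolite names.
#' @param library a [load_pathway_library()] object (or library name).
#' @param universe `"library"` (default: all compounds in the library) or
#'   `"measured"` (restrict to `measured`).
#' @param measured measured-panel compound names for
#'   `universe = "measured"`.
#' @param adjust apply BH across pathways (default FALSE).
#' @return data frame of class `"enrichment_result"`, sorted by P:
#'   `pathway`, `hits`, `k`, `K`, `n`, `N`, `p_value`, `fold_enrichment`
#'   (-ln P), `impact`, `significant`; the unmatched metabolites are
#'   attached as attribute `"unmatched"`.
#' @export
run_enrichment <- function(metabolites, library = "toy-hsa",
                           universe = c("library", "measured"),
                           measured = NULL, adjust = FALSE) {
  universe <- match.arg(universe)
  if (is.character(library)) library <- load_pathway_library(library)
  mm <- map_metabolites(metabolites, library)
  uni <- library$universe
  if (universe == "measured") {
    if (is.null(measured)) stop("measured universe requested without a panel")
    uni <- intersect(uni, map_metabolites(measured, library)$matched)
  }
  hits_all <- intersect(mm$matched, uni)
  rows <- lapply(library$pathways, function(p) {
    cmp <- intersect(p$compounds, uni)
    hit <- intersect(hits_all, cmp)
    pval <- enrich_hypergeometric(length(hit), length(cmp),
                                  length(hits_all), length(uni))
    data.frame(pathway = p$name,
               hits = paste(sort(hit), collapse = ";"),
               k = length(hit), K = length(cmp),
               n = length(hits_all), N = length(uni),
               p_value = pval, impact = pathway_impact(p, hit),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust) res$p_value_adj <- bh_adjust(res$p_value)
  res <- summarize_enrichment(res)
  attr(res, "unmatched") <- mm$unmatched
  res
}

#' Rank and flag enrichment results
#'
#' Sorts pathways by ascending p-value, attaches the fold-enrichment score
#' `-ln(P)` and flags pathways with raw P < 0.05 — the triplets
#' (impact, -ln P, flag) are what the conventional enrichment bubble plot
#' displays.
#'
#' @param results data frame with at least `pathway`, `p_value`, `impact`.
#' @param alpha significance threshold.
#' @return the sorted, annotated data frame (class `"enrichment_result"`).
#' @export
summarize_enrichment <- function(results, alpha = 0.05) {
  results$fold_enrichment <- -log(results$p_value)
  results$significant <- results$p_value < alpha
  results <- results[order(results$p_value, results$pathway), ]
  rownames(results) <- NULL
  class(results) <- c("enrichment_result", "data.frame")
  results
}
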