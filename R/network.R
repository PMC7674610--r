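#' Ties-adjusted Spearman correlation matrix of a trait table
#'
#' All trait pairs with pairwise-complete observations, using [spearman()]
#' for the coefficient and its exact small-sample p-value. Constant traits
#' are flagged and their rows/columns set to `NA` rather than failing the
#' whole matrix.
#'
#' @param table a [trait_table()].
#' @param exact_n_max,n_perm,seed passed to [spearman()].
#' @return An object of class `trait_corr`: matrices `rho`, `p`, `n`,
#'   `method`, the trait class map, and `constant_traits`.
#' @export
correlation_matrix <- function(table, exact_n_max = 10, n_perm = 99999,
                               seed = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (nrow(table) < 3)
    st_stop("st_insufficient_data", "need >= 3 accessions")
  traits <- names(table)
  k <- length(traits)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  method <- matrix(NA_character_, k, k, dimnames = list(traits, traits))
  const <- vapply(traits, function(tr) {
    v <- table[[tr]]; stats::sd(v[is.finite(v)]) == 0
  }, TRUE)
  diag(rho) <- ifelse(const, NA_real_, 1)
  diag(p) <- ifelse(const, NA_real_, 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) next
    sp <- tryCatch(
      spearman(table[[i]], table[[j]], exact_n_max = exact_n_max,
               n_perm = n_perm, seed = seed),
      st_undefined_correlation = function(e) NULL,
      st_insufficient_data = function(e) NULL)
    if (is.null(sp)) next
    rho[i, j] <- rho[j, i] <- sp$rho
    p[i, j] <- p[j, i] <- sp$p
    nmat[i, j] <- nmat[j, i] <- sp$n
    method[i, j] <- method[j, i] <- sp$method
  }
  structure(list(rho = rho, p = p, n = nmat, method = method,
                 traits = traits, classes = attr(table, "trait_class"),
                 constant_traits = traits[const]),
            class = "trait_corr")
}

#' @export
print.trait_corr <- function(x, digits = 3, ...) {
  cat(sprintf("<trait_corr> %d traits; p-value methods: %s\n",
              length(x$traits),
              paste(sort(unique(stats::na.omit(as.vector(x$method)))),
                    collapse = ", ")))
  if (length(x$constant_traits))
    cat("  constant (undefined) traits:",
        paste(x$constant_traits, collapse = ", "), "\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Significance-filtered trait network
#'
#' Builds an undirected graph whose nodes are traits and whose edges are the
#' significant correlations: `(u, v)` is an edge iff `p(u, v) <= alpha` and
#' the pair is admissible. Geographical-geographical and
#' geographical-climate pairs are excluded from the analysis outright (site
#' geography and site climate correlate trivially with each other); every
#' other pairing may enter. Edge weight is `-log10(p)`, so stronger
#' evidence gives heavier edges.
#'
#' @param cm a `trait_corr` from [correlation_matrix()].
#' @param alpha significance threshold on the (optionally adjusted) p-value,
#'   default 0.05.
#' @param adjust `"none"` (raw p, default) or `"BH"` for a
#'   Benjamini-Hochberg adjustment across admissible pairs.
#' @return An object of class `trait_network`: `nodes` (name, class,
#'   degree, community), `edges` (from, to, rho, p, weight,
#'   within_community), `alpha`, and the underlying `igraph` graph.
#'   Community fields are filled by [girvan_newman()].
#' @export
build_network <- function(cm, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(cm, "trait_corr"))
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    st_stop("st_domain_error", "alpha must lie in (0, 1)")
  traits <- cm$traits
  cls <- cm$classes
  pairs <- which(upper.tri(cm$p), arr.ind = TRUE)
  u <- traits[pairs[, 1]]; v <- traits[pairs[, 2]]
  excluded <- cls[u] == "geographical" & cls[v] %in% c("geographical", "climate") |
              cls[v] == "geographical" & cls[u] %in% c("geographical", "climate")
  pvals <- cm$p[pairs]
  admissible <- !excluded & !is.na(pvals)
  padj <- pvals
  if (adjust == "BH")
    padj[admissible] <- stats::p.adjust(pvals[admissible], "BH")
  keep <- admissible & padj <= alpha
  edges <- data.frame(
    from = u[keep], to = v[keep],
    rho = cm$rho[pairs][keep], p = pvals[keep],
    weight = -log10(pmax(padj[keep], .Machine$double.xmin)),
    within_community = rep(NA, sum(keep)), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = traits, class = unname(cls)))
  nodes <- data.frame(
    name = traits, class = unname(cls),
    degree = igraph::degree(g)[traits],
    community = NA_integer_, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 adjust = adjust, graph = g,
                 communities = NULL, modularity = NA_real_),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf("<trait_network> %d traits, %d significant edges (alpha = %g%s)\n",
              nrow(x$nodes), nrow(x$edges), x$alpha,
              if (x$adjust != "none") paste0(", ", x$adjust) else ""))
  if (!is.null(x$communities))
    cat(sprintf("  %d communities (Girvan-Newman), modularity %.3f\n",
                length(x$communities), x$modularity))
  invisible(x)
}

#' Edge betweenness of a trait network
#'
#' For each edge, the number of shortest paths between all node pairs that
#' traverse it, with paths split equally among tied shortest routes.
#' Shortest paths are unweighted: the significance weights are display
#' attributes, not distances.
#'
#' @param net a `trait_network` (or an `igraph` graph).
#' @return A data frame `from, to, betweenness`, one row per edge.
#' @export
edge_betweenness <- function(net) {
  g <- if (inherits(net, "trait_network")) net$graph else net
  if (igraph::ecount(g) == 0)
    st_stop("st_validation_error", "graph has no edges")
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  ends <- igraph::as_edgelist(g)
  data.frame(from = ends[, 1], to = ends[, 2], betweenness = eb,
             stringsAsFactors = FALSE)
}

#' Girvan-Newman community detection on a trait network
#'
#' Iteratively removes the edge of highest (unweighted) edge betweenness,
#' recomputing after each removal, and returns the partition along the
#' removal sequence that maximises Newman modularity of the original
#' (unweighted) graph. Isolated traits take no part: communities partition
#' exactly the connected (non-isolated) nodes.
#'
#' @param net a `trait_network` from [build_network()].
#' @return The network with `communities` (an `igraph` communities object
#'   on the non-isolated subgraph), `modularity`, node `community` labels,
#'   and the edge `within_community` flag filled in.
#' @export
girvan_newman <- function(net) {
  stopifnot(inherits(net, "trait_network"))
  g <- net$graph
  connected <- names(which(igraph::degree(g) > 0))
  if (length(connected) < 2) {
    net$communities <- NULL
    net$modularity <- NA_real_
    return(net)
  }
  sg <- igraph::induced_subgraph(g, connected)
  comm <- igraph::cluster_edge_betweenness(
    sg, weights = NA, directed = FALSE, modularity = TRUE)
  memb <- igraph::membership(comm)
  net$communities <- comm
  net$modularity <- igraph::modularity(sg, memb)
  net$nodes$community <- unname(memb[net$nodes$name])
  if (nrow(net$edges) > 0)
    net$edges$within_community <-
      net$nodes$community[match(net$edges$from, net$nodes$name)] ==
      net$nodes$community[match(net$edges$to, net$nodes$name)]
  net
}

#' Export a trait network to CSV and JSON documents
#'
#' Writes `<stem>_nodes.csv` (name, class, community, degree),
#' `<stem>_edges.csv` (from, to, rho, p, weight, within_community) and
#' `<stem>.json` (a single graph document with nodes, edges and
#' modularity).
#'
#' @param net a `trait_network`.
#' @param stem output path stem (no extension).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "trait_network"))
  paths <- paste0(stem, c("_nodes.csv", "_edges.csv", ".json"))
  write.csv(net$nodes, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(net$edges, paths[2], row.names = FALSE, quote = FALSE)
  doc <- list(alpha = net$alpha, modularity = net$modularity,
              n_communities = if (is.null(net$communities)) 0L
                              else length(net$communities),
              nodes = net$nodes, edges = net$edges)
  jsonlite::write_json(doc, paths[3], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
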