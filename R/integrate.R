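# Transcript-metabolite association: a two-block latent-variable model in
# canonical mode yields paired component scores; the similarity between a
# transcript and a metabolite is the sum over components of the products of
# their correlations with the paired scores. Thresholding the similarity
# matrix gives an exportable bipartite relevance network.

#' Latent-variable association scores between two omics blocks
#'
#' Fits a two-block PLS in canonical mode (NIPALS) on the standardized
#' blocks and returns the similarity matrix
#' `s_jk = sum_h cor(x_j, t_h) * cor(y_k, u_h)`, clipped to `[-1, 1]`.
#'
#' @param x Transcript matrix, features x samples.
#' @param y Metabolite matrix, features x samples (same samples, same
#'   order).
#' @param n_components Number of latent component pairs.
#' @return Numeric matrix transcripts x metabolites of similarity weights.
#' @export
latent_association_scores <- function(x, y, n_components = 2) {
  if (ncol(x) != ncol(y) ||
      (!is.null(colnames(x)) && !is.null(colnames(y)) &&
       !identical(colnames(x), colnames(y))))
    stop("input error: blocks must share the same samples in the same order")
  X <- scale(t(x)); Y <- scale(t(y))
  if (anyNA(X) || anyNA(Y))
    stop("input error: constant features cannot be standardized")
  A <- n_components
  Tm <- matrix(0, nrow(X), A); Um <- matrix(0, nrow(X), A)
  Xd <- X; Yd <- Y
  for (a in seq_len(A)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    w <- rep(0, ncol(Xd))
    for (it in 1:500) {
      w_new <- crossprod(Xd, u)[, 1]
      w_new <- w_new / sqrt(sum(w_new^2))
      tt <- Xd %*% w_new
      cq <- crossprod(Yd, tt)[, 1]
      cq <- cq / sqrt(sum(cq^2))
      u <- Yd %*% cq
      if (sum((w_new - w)^2) < 1e-20) { w <- w_new; break }
      w <- w_new
    }
    tt <- Xd %*% w
    u <- Yd %*% cq
    Tm[, a] <- tt; Um[, a] <- u
    # canonical-mode deflation: each block on its own scores
    Xd <- Xd - tt %*% t(crossprod(Xd, tt) / sum(tt^2))
    Yd <- Yd - u %*% t(crossprod(Yd, u) / sum(u^2))
  }
  s <- matrix(0, ncol(X), ncol(Y), dimnames = list(rownames(x), rownames(y)))
  for (a in seq_len(A)) {
    cx <- stats::cor(X, Tm[, a])[, 1]
    cy <- stats::cor(Y, Um[, a])[, 1]
    s <- s + outer(cx, cy)
  }
  pmin(pmax(s, -1), 1)
}

#' Threshold association scores into a bipartite network
#'
#' @param weights Matrix from [latent_association_scores()] (transcripts x
#'   metabolites).
#' @param threshold Absolute-weight cutoff in `(0, 1)`.
#' @param node_attrs Optional data.frame of node attributes with columns
#'   `node`, `biotype`, `log2_fc` (attached to exports).
#' @return Object of class `association_network`: `edges` data.frame
#'   (`metabolite`, `transcript`, `weight`), `threshold`, `node_attrs`;
#'   attribute `empty` flags a network with no retained edge.
#' @export
build_network <- function(weights, threshold = 0.7, node_attrs = NULL) {
  if (!(threshold > 0 && threshold < 1) && threshold != 1)
    stop("input error: threshold must lie in (0, 1]")
  idx <- which(abs(weights) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    metabolite = colnames(weights)[idx[, 2]],
    transcript = rownames(weights)[idx[, 1]],
    weight = weights[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$metabolite, edges$transcript), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(edges = edges, threshold = threshold,
                        node_attrs = node_attrs),
                   class = "association_network")
  attr(net, "empty") <- nrow(edges) == 0
  net
}

#' Export an association network
#'
#' Writes SIF (`source TAB relationship TAB target`) or GraphML with
#' `weight`, `biotype` and `log2_fc` attributes. GraphML round-trips through
#' [read_network_graphml()] with edges and weights intact.
#'
#' @param net An `association_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  if (!inherits(net, "association_network"))
    stop("input error: not an association_network")
  if (length(format) == 1 && !format %in% c("sif", "graphml"))
    stop("input error: unknown format '", format,
         "'; supported formats: sif, graphml")
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    lines <- if (nrow(e))
      sprintf("%s\tassociates\t%s", e$metabolite, e$transcript) else character()
    writeLines(lines, path)
    return(invisible(path))
  }
  attrs <- net$node_attrs
  node_attr <- function(id, col) {
    if (is.null(attrs) || !id %in% attrs$node) return(NULL)
    v <- attrs[[col]][match(id, attrs$node)]
    if (is.null(v) || is.na(v)) NULL else v
  }
  nodes <- unique(c(e$metabolite, e$transcript))
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="biotype" for="node" attr.name="biotype" attr.type="string"/>',
    '  <key id="log2_fc" for="node" attr.name="log2_fc" attr.type="double"/>',
    '  <graph id="assoc" edgedefault="undirected">')
  for (nd in nodes) {
    bt <- node_attr(nd, "biotype"); fc <- node_attr(nd, "log2_fc")
    inner <- c(
      if (!is.null(bt)) sprintf('      <data key="biotype">%s</data>', bt),
      if (!is.null(fc)) sprintf('      <data key="log2_fc">%.17g</data>', fc))
    xml <- c(xml,
             if (length(inner))
               c(sprintf('    <node id="%s">', nd), inner, "    </node>")
             else sprintf('    <node id="%s"/>', nd))
  }
  if (nrow(e))
    xml <- c(xml, sprintf(
      '    <edge source="%s" target="%s"><data key="weight">%.17g</data></edge>',
      e$metabolite, e$transcript, e$weight))
  xml <- c(xml, "  </graph>", "</graphml>")
  writeLines(xml, path)
  invisible(path)
}

#' Read a GraphML association network back
#'
#' @param path GraphML file written by [export_network()].
#' @return data.frame with `metabolite` (source), `transcript` (target),
#'   `weight`.
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  data.frame(
    metabolite = xml2::xml_attr(edges, "source"),
    transcript = xml2::xml_attr(edges, "target"),
    weight = as.numeric(xml2::xml_text(
      xml2::xml_find_first(edges, ".//g:data[@key='weight']", ns))),
    stringsAsFactors = FALSE)
}
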