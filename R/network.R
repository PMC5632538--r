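#' Classify lncRNAs as miRNA targets or decoys
#'
#' Standard ceRNA logic over (lncRNA, miRNA) pairs that carry binding-site
#' evidence (the lncRNA harbors a retained site for the miRNA):
#' \itemize{
#'   \item role \emph{target}: `r(lnc, mir) <= -r_pair` — the miRNA
#'     represses the lncRNA;
#'   \item role \emph{decoy}: `r(lnc, mir) > -r_pair` AND the lncRNA
#'     correlates at `>= +r_pair` with at least one mRNA among that miRNA's
#'     mRNA pairing candidates — the lncRNA sponges the miRNA, co-varying
#'     with the relieved target;
#'   \item otherwise: no edge.
#' }
#' Pairs with an undefined (zero-variance) correlation are dropped.
#'
#' @param lnc_sites data.frame with columns `mirna_id`, `target_id` (the
#'   lncRNA) — retained binding sites on lncRNA sequences.
#' @param lnc_em,mir_em,mrna_em [expression_matrix()] objects on shared
#'   samples (typically log expression).
#' @param mir_mrna_edges data.frame with columns `mirna_id`, `mrna_id` —
#'   the miRNA-mRNA pairing candidates (site plus correlation, from
#'   [mir_mrna_candidates()]).
#' @param cfg a [ce_config()].
#' @return data.frame of lncRNA-miRNA edges: `lnc_id`, `mirna_id`,
#'   `edge_type` (`lnc_mir_target` / `lnc_mir_decoy`), `r`.
#' @export
classify_lncrna_roles <- function(lnc_sites, lnc_em, mir_em, mrna_em,
                                  mir_mrna_edges, cfg = ce_config()) {
  empty <- data.frame(lnc_id = character(), mirna_id = character(),
                      edge_type = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(lnc_sites)) return(empty)
  pairs <- unique(lnc_sites[, c("mirna_id", "target_id")])
  shared <- Reduce(intersect, list(colnames(lnc_em$values),
                                   colnames(mir_em$values),
                                   colnames(mrna_em$values)))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  out <- empty
  for (k in seq_len(nrow(pairs))) {
    lnc <- pairs$target_id[k]; mir <- pairs$mirna_id[k]
    if (!lnc %in% rownames(lnc_em$values) ||
        !mir %in% rownames(mir_em$values)) next
    x <- lnc_em$values[lnc, shared]; y <- mir_em$values[mir, shared]
    if (sd(x) == 0 || sd(y) == 0) next
    r_lm <- unname(cor(x, y))
    if (r_lm <= -cfg$r_pair) {
      out <- rbind(out, data.frame(lnc_id = lnc, mirna_id = mir,
                                   edge_type = "lnc_mir_target", r = r_lm,
                                   stringsAsFactors = FALSE))
      next
    }
    mrnas <- mir_mrna_edges$mrna_id[mir_mrna_edges$mirna_id == mir]
    mrnas <- intersect(mrnas, rownames(mrna_em$values))
    is_decoy <- FALSE
    for (g in mrnas) {
      gy <- mrna_em$values[g, shared]
      if (sd(gy) == 0) next
      if (unname(cor(x, gy)) >= cfg$r_pair) { is_decoy <- TRUE; break }
    }
    if (is_decoy)
      out <- rbind(out, data.frame(lnc_id = lnc, mirna_id = mir,
                                   edge_type = "lnc_mir_decoy", r = r_lm,
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' miRNA-mRNA pairing candidates (site evidence plus correlation)
#'
#' Annotates each retained miRNA-mRNA binding-site pair with the Pearson
#' correlation of the two expression profiles across shared samples.
#'
#' @param mrna_sites data.frame with columns `mirna_id`, `target_id` (the
#'   mRNA) — retained binding sites on mRNA scan regions.
#' @param mir_em,mrna_em [expression_matrix()] objects on shared samples.
#' @return data.frame: `mirna_id`, `mrna_id`, `r`, `site_evidence = TRUE`.
#' @export
mir_mrna_candidates <- function(mrna_sites, mir_em, mrna_em) {
  empty <- data.frame(mirna_id = character(), mrna_id = character(),
                      r = numeric(), site_evidence = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(mrna_sites)) return(empty)
  pairs <- unique(mrna_sites[, c("mirna_id", "target_id")])
  shared <- intersect(colnames(mir_em$values), colnames(mrna_em$values))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  keep <- pairs$mirna_id %in% rownames(mir_em$values) &
    pairs$target_id %in% rownames(mrna_em$values)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  r <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- mir_em$values[pairs$mirna_id[k], shared]
    y <- mrna_em$values[pairs$target_id[k], shared]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else unname(cor(x, y))
  }, numeric(1))
  out <- data.frame(mirna_id = pairs$mirna_id, mrna_id = pairs$target_id,
                    r = r, site_evidence = TRUE, stringsAsFactors = FALSE)
  out[!is.na(out$r), , drop = FALSE]
}

#' Assemble the ceRNA network
#'
#' A miRNA-mRNA edge is admitted iff it has site evidence (unless
#' `cfg$require_site` is FALSE), `|r| > r_pair` (either sign), and both
#' endpoints are differentially expressed; a lncRNA-miRNA edge (from
#' [classify_lncrna_roles()]) is admitted iff both endpoints are DE. Nodes
#' with no admitted edge are dropped, so every node of the result sits in
#' at least one lncRNA-miRNA or miRNA-mRNA pair.
#'
#' @param de_ids character vector of DE feature ids (by default the union
#'   over the three contrasts, see [de_union()]).
#' @param lnc_mir_edges data.frame from [classify_lncrna_roles()].
#' @param mir_mrna_cand data.frame from [mir_mrna_candidates()].
#' @param cfg a [ce_config()].
#' @return A `ce_network`: list with `nodes` (id, node_type, role) and
#'   `edges` (a, b, edge_type, r, site_evidence).
#' @export
build_network <- function(de_ids, lnc_mir_edges, mir_mrna_cand,
                          cfg = ce_config()) {
  mm <- mir_mrna_cand
  mm <- mm[(mm$site_evidence | !cfg$require_site) &
             abs(mm$r) > cfg$r_pair &
             mm$mirna_id %in% de_ids & mm$mrna_id %in% de_ids, ,
           drop = FALSE]
  lm <- lnc_mir_edges
  lm <- lm[lm$lnc_id %in% de_ids & lm$mirna_id %in% de_ids, , drop = FALSE]
  edges <- rbind(
    if (nrow(lm)) data.frame(a = lm$lnc_id, b = lm$mirna_id,
                             edge_type = lm$edge_type, r = lm$r,
                             site_evidence = TRUE, stringsAsFactors = FALSE),
    if (nrow(mm)) data.frame(a = mm$mirna_id, b = mm$mrna_id,
                             edge_type = "mir_mrna", r = mm$r,
                             site_evidence = mm$site_evidence,
                             stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(a = character(), b = character(),
                        edge_type = character(), r = numeric(),
                        site_evidence = logical(), stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("a", "b", "edge_type")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges)) warning("empty network: no admissible edges")
  lnc_ids <- unique(edges$a[edges$edge_type != "mir_mrna"])
  mir_ids <- unique(c(edges$b[edges$edge_type != "mir_mrna"],
                      edges$a[edges$edge_type == "mir_mrna"]))
  mrna_ids <- unique(edges$b[edges$edge_type == "mir_mrna"])
  lnc_role <- vapply(lnc_ids, function(id) {
    # a lncRNA with any target-type edge is reported as a miRNA target
    if (any(edges$a == id & edges$edge_type == "lnc_mir_target"))
      "mir_target_lnc" else "decoy_lnc"
  }, character(1))
  node_df <- function(ids, type, role)
    data.frame(id = ids, node_type = rep(type, length(ids)),
               role = rep_len(role, length(ids)), stringsAsFactors = FALSE)
  nodes <- rbind(node_df(lnc_ids, "lncRNA", unname(lnc_role)),
                 node_df(mir_ids, "miRNA", "mirna"),
                 node_df(mrna_ids, "mRNA", "target_mrna"))
  nodes <- nodes[order(nodes$node_type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  net <- structure(list(nodes = nodes, edges = edges), class = "ce_network")
  validate_network(net)
  net
}

#' Validate ceRNA-network invariants
#'
#' Checks that every node appears in at least one edge, edge endpoints have
#' compatible node types, there are no self-edges and no duplicate
#' undirected edges.
#' @param net a `ce_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "ce_network"))
  e <- net$edges; n <- net$nodes
  if (any(e$a == e$b)) stop("network has self-edge(s)")
  key <- apply(cbind(pmin(e$a, e$b), pmax(e$a, e$b)), 1L, paste,
               collapse = "\r")
  if (anyDuplicated(key)) stop("duplicate undirected edge(s)")
  in_edge <- unique(c(e$a, e$b))
  if (length(setdiff(n$id, in_edge)))
    stop("node(s) outside any pair: ",
         paste(head(setdiff(n$id, in_edge), 3), collapse = ", "))
  if (length(setdiff(in_edge, n$id)))
    stop("edge endpoint(s) missing from node table")
  type_of <- setNames(n$node_type, n$id)
  lm <- e$edge_type != "mir_mrna"
  if (any(type_of[e$a[lm]] != "lncRNA") || any(type_of[e$b[lm]] != "miRNA"))
    stop("lncRNA-miRNA edge with incompatible endpoint types")
  if (any(type_of[e$a[!lm]] != "miRNA") || any(type_of[e$b[!lm]] != "mRNA"))
    stop("miRNA-mRNA edge with incompatible endpoint types")
  invisible(net)
}

#' @export
print.ce_network <- function(x, ...) {
  cat(sprintf("<ce_network: %d nodes (%s), %d edges (%s)>\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(table(x$nodes$node_type)),
                            table(x$nodes$node_type)), collapse = ", "),
              nrow(x$edges),
              paste(sprintf("%s %d", names(table(x$edges$edge_type)),
                            table(x$edges$edge_type)), collapse = ", ")))
  invisible(x)
}

#' Bridge genes: mRNAs linking several miRNAs
#'
#' mRNA nodes with at least `min_mirna_degree` distinct miRNA neighbors,
#' sorted by descending miRNA degree then ascending id.
#'
#' @param net a `ce_network`.
#' @param min_mirna_degree minimum number of distinct miRNA neighbors.
#' @return data.frame: `mrna_id`, `mirna_degree`, `mirnas` (comma-joined).
#' @export
find_bridges <- function(net, min_mirna_degree = 2L) {
  stopifnot(inherits(net, "ce_network"))
  mm <- net$edges[net$edges$edge_type == "mir_mrna", , drop = FALSE]
  if (!nrow(mm))
    return(data.frame(mrna_id = character(), mirna_degree = integer(),
                      mirnas = character(), stringsAsFactors = FALSE))
  deg <- tapply(mm$a, mm$b, function(x) sort(unique(x)), simplify = FALSE)
  out <- data.frame(mrna_id = names(deg),
                    mirna_degree = vapply(deg, length, integer(1)),
                    mirnas = vapply(deg, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$mirna_degree >= min_mirna_degree, , drop = FALSE]
  out <- out[order(-out$mirna_degree, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge-induced subnetwork around a node whitelist
#'
#' Keeps edges with at least one endpoint in `keep_ids` (e.g. a
#' reproduction-associated gene list plus QTL members), then drops nodes
#' left without edges.
#' @param net a `ce_network`.
#' @param keep_ids character vector of node ids.
#' @return A `ce_network`.
#' @export
subnetwork <- function(net, keep_ids) {
  stopifnot(inherits(net, "ce_network"))
  e <- net$edges[net$edges$a %in% keep_ids | net$edges$b %in% keep_ids, ,
                 drop = FALSE]
  ids <- unique(c(e$a, e$b))
  structure(list(nodes = net$nodes[net$nodes$id %in% ids, , drop = FALSE],
                 edges = e), class = "ce_network")
}

#' Write a network as SIF plus a node-attribute table
#'
#' One line per edge, `source <tab> relation <tab> target`, relation in
#' `{lnc_mir_target, lnc_mir_decoy, mir_mrna}`; lines sorted
#' lexicographically by (source, relation, target) so output is
#' byte-identical across runs. The companion node table carries node type
#' and lncRNA role.
#'
#' @param net a `ce_network`.
#' @param path SIF output path.
#' @param node_attr_path optional node-attribute TSV path.
#' @param header optional `#` comment lines (node table only; SIF has no
#'   comment syntax).
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path, node_attr_path = NULL,
                              header = NULL) {
  stopifnot(inherits(net, "ce_network"))
  e <- net$edges
  lines <- character()
  if (nrow(e)) {
    lines <- paste(e$a, e$edge_type, e$b, sep = "\t")
    lines <- sort(lines, method = "radix")
  }
  writeLines(lines, path)
  if (!is.null(node_attr_path)) {
    con <- file(node_attr_path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    writeLines("id\tnode_type\trole", con)
    n <- net$nodes[order(net$nodes$id), , drop = FALSE]
    if (nrow(n))
      writeLines(paste(n$id, n$node_type, n$role, sep = "\t"), con)
  }
  invisible(path)
}
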