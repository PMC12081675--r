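#' Taxonomy tree
#'
#' A small NCBI-nodes-like taxonomy: one row per node with `taxid`,
#' `parent_taxid`, `rank` and `name`. The root is its own parent. This is
#' the hierarchy over which lowest-common-ancestor (LCA) read assignment
#' operates; reference genomes map to leaves (usually rank `species`).
#'
#' @param nodes data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`. `taxid` must be unique, every `parent_taxid` must exist, and
#'   exactly one node (the root) must have `parent_taxid == taxid`.
#' @return the validated data.frame with class `taxonomy_tree`.
#' @export
#' @examples
#' tax <- taxonomy_tree(data.frame(
#'   taxid = 1:3, parent_taxid = c(1, 1, 2),
#'   rank = c("order", "family", "species"),
#'   name = c("Carnivora", "Phocidae", "Pusa hispida")
#' ))
taxonomy_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  req <- c("taxid", "parent_taxid", "rank", "name")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols)) {
    stop("taxonomy is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[req]
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent_taxid <- as.integer(nodes$parent_taxid)
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxid in taxonomy")
  if (!all(nodes$parent_taxid %in% nodes$taxid)) {
    stop("taxonomy has parent_taxid values with no node")
  }
  roots <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root node")
  # acyclicity: every node must reach the root
  parent <- stats::setNames(nodes$parent_taxid, nodes$taxid)
  for (t in nodes$taxid) {
    cur <- t
    for (i in seq_len(nrow(nodes) + 1L)) {
      p <- parent[[as.character(cur)]]
      if (p == cur) break
      cur <- p
    }
    if (parent[[as.character(cur)]] != cur) stop("taxonomy contains a cycle")
  }
  structure(nodes, class = c("taxonomy_tree", "data.frame"))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x), "nodes;",
      "ranks:", paste(unique(x$rank), collapse = ", "), "\n")
  invisible(x)
}

tax_parent_map <- function(tax) stats::setNames(tax$parent_taxid, tax$taxid)

#' Root-to-node lineage of a taxon
#'
#' @param tax a [taxonomy_tree()].
#' @param taxid a single taxid present in `tax`.
#' @return integer vector of taxids from the root down to `taxid`.
#' @export
tax_lineage <- function(tax, taxid) {
  parent <- tax_parent_map(tax)
  taxid <- as.integer(taxid)
  if (!as.character(taxid) %in% names(parent)) {
    stop("taxid ", taxid, " is not in the taxonomy")
  }
  path <- taxid
  cur <- taxid
  repeat {
    p <- parent[[as.character(cur)]]
    if (p == cur) break
    path <- c(p, path)
    cur <- p
  }
  path
}

tax_depth <- function(tax, taxid) length(tax_lineage(tax, taxid)) - 1L

#' Lowest common ancestor of a set of taxa
#'
#' Pairwise climb: the deeper node is walked up until both nodes sit at the
#' same depth, then both are walked up together until they meet. Reduced
#' left-to-right over the input set.
#'
#' @param tax a [taxonomy_tree()].
#' @param taxids integer vector of taxids present in `tax`.
#' @return the taxid of the lowest common ancestor.
#' @export
tax_lca <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (!length(taxids)) stop("tax_lca needs at least one taxid")
  parent <- tax_parent_map(tax)
  depth_of <- function(t) {
    d <- 0L
    while (parent[[as.character(t)]] != t) {
      t <- parent[[as.character(t)]]
      d <- d + 1L
    }
    d
  }
  lca2 <- function(a, b) {
    da <- depth_of(a); db <- depth_of(b)
    while (da > db) { a <- parent[[as.character(a)]]; da <- da - 1L }
    while (db > da) { b <- parent[[as.character(b)]]; db <- db - 1L }
    while (a != b) {
      a <- parent[[as.character(a)]]
      b <- parent[[as.character(b)]]
    }
    a
  }
  Reduce(lca2, taxids)
}

#' Ancestor of a taxon at a given rank
#'
#' @param tax a [taxonomy_tree()].
#' @param taxid taxid whose lineage is searched.
#' @param rank rank name (e.g. `"family"`).
#' @return the taxid of the ancestor-or-self with that rank, or `NA` if the
#'   lineage has no node of that rank.
#' @export
tax_ancestor_at_rank <- function(tax, taxid, rank) {
  path <- tax_lineage(tax, taxid)
  ranks <- tax$rank[match(path, tax$taxid)]
  hit <- which(ranks == rank)
  if (!length(hit)) return(NA_integer_)
  path[hit[length(hit)]]
}

#' Is a taxon prokaryotic?
#'
#' A taxon is treated as prokaryotic when its lineage contains a node named
#' `Bacteria` or `Archaea` (the convention used to exclude prokaryote
#' assignments from eukaryote detection tables).
#'
#' @param tax a [taxonomy_tree()].
#' @param taxid taxid(s) to classify.
#' @return logical vector.
#' @export
tax_is_prokaryote <- function(tax, taxid) {
  vapply(as.integer(taxid), function(t) {
    path <- tax_lineage(tax, t)
    any(tax$name[match(path, tax$taxid)] %in% c("Bacteria", "Archaea"))
  }, logical(1))
}

#' Read / write a 4-column taxonomy TSV
#'
#' Columns: `taxid`, `parent_taxid`, `rank`, `name`.
#'
#' @param path file path.
#' @return [read_taxonomy()] returns a [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param tax a [taxonomy_tree()].
#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
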