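# Newick/TSV I/O and shared tree helpers. Trees are ape "phylo" objects;
# reconciliation and likelihood operations additionally require them to
# be rooted and binary.

#' Read a rooted tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validity checks the
#' downstream operations rely on: a single tree, unique leaf labels and
#' non-negative branch lengths when present. Quoted labels are accepted
#' and bracketed comments stripped by the underlying parser.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree found in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected exactly one tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("Newick parse error: duplicate leaf labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("Newick parse error: negative branch lengths")
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

assert_rooted_binary <- function(tree, what = "tree") {
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  if (!ape::is.binary(tree)) stop(what, " must be binary (no multifurcations)")
  invisible(tree)
}

# Parent lookup: integer vector over all node ids, 0 at the root.
node_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# Depth in edges from the root for every node (robust to edge order).
node_edge_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- node_parents(tree)
  root <- root_node(tree)
  vapply(seq_len(n), function(v) {
    d <- 0L
    while (v != root) {
      v <- par[v]
      d <- d + 1L
      if (d > n) stop("tree has a cycle or disconnected node")
    }
    d
  }, integer(1))
}

# Node label -> node id over tips and internal labels.
node_by_label <- function(tree, label) {
  hit <- match(label, tree$tip.label)
  if (!is.na(hit)) return(hit)
  if (!is.null(tree$node.label)) {
    hit <- match(label, tree$node.label)
    if (!is.na(hit)) return(ape::Ntip(tree) + hit)
  }
  stop("unknown node label: ", label)
}

#' Read a leaf-to-species map from a two-column TSV
#'
#' @param path TSV with header columns `leaf` and `species`.
#' @return Named character vector mapping gene-tree leaf labels to
#'   species labels.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("leaf", "species") %in% names(df)))
    stop("species map must have columns 'leaf' and 'species'")
  stats::setNames(as.character(df$species), as.character(df$leaf))
}

#' Write a typed table to TSV
#'
#' Deterministic column order from `schema`; doubles serialised at six
#' significant digits; `NA`/`NaN` written as `NA`.
#'
#' @param rows Data frame conforming to `schema`.
#' @param schema Named character vector column -> type, types in
#'   `c("chr", "int", "dbl", "lgl")`. Defaults to a schema derived from
#'   `rows`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, schema = NULL, path) {
  if (is.null(schema)) {
    schema <- vapply(rows, function(col) {
      if (is.character(col) || is.factor(col)) "chr"
      else if (is.logical(col)) "lgl"
      else if (is.integer(col)) "int"
      else "dbl"
    }, character(1))
  }
  if (!all(names(schema) %in% names(rows)))
    stop("schema mismatch: missing columns ",
         paste(setdiff(names(schema), names(rows)), collapse = ", "))
  bad_type <- setdiff(schema, c("chr", "int", "dbl", "lgl"))
  if (length(bad_type) > 0) stop("schema mismatch: unknown types ",
                                 paste(bad_type, collapse = ", "))
  out <- lapply(names(schema), function(cn) {
    col <- rows[[cn]]
    tp <- schema[[cn]]
    if (tp == "dbl") {
      if (!is.numeric(col)) stop("schema mismatch: column ", cn, " not numeric")
      ifelse(is.na(col), "NA", formatC(signif(col, 6), format = "g",
                                       digits = 6))
    } else if (tp == "int") {
      if (!is.numeric(col)) stop("schema mismatch: column ", cn, " not numeric")
      ifelse(is.na(col), "NA", format(as.integer(col), scientific = FALSE))
    } else if (tp == "lgl") {
      ifelse(is.na(col), "NA", ifelse(as.logical(col), "TRUE", "FALSE"))
    } else {
      ifelse(is.na(col), "NA", as.character(col))
    }
  })
  names(out) <- names(schema)
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path TSV path.
#' @return Data frame with `"NA"` parsed as missing.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
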