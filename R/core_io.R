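#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist glm hclust p.adjust plogis prcomp
#'   quantile rbinom rlnorm rnbinom rpois runif setNames binomial cmdscale
#'   coef qnorm sd
#' @importFrom utils combn read.delim write.table packageVersion
NULL

# ---- calibrated trees -------------------------------------------------------

#' Node ages of a rooted tree with branch lengths
#'
#' Ages are times before present: the root age equals the maximum
#' root-to-tip path length and every tip of an ultrametric tree has age 0.
#'
#' @param tree an [ape::phylo] tree with edge lengths.
#' @return numeric vector of ages for all nodes (tips first, then internal
#'   nodes, in `ape` node numbering).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Read a time-calibrated (ultrametric) tree
#'
#' Parses a Newick file with branch lengths and derives node ages from
#' root-to-tip path lengths (the Newick format has no age field). Trees whose
#' tip ages spread more than `tol * root_age` are rejected: slicing an
#' almost-but-not ultrametric tree silently misassigns clades, so
#' reconciliation is refused rather than attempted.
#'
#' @param path path to a Newick file, or a Newick string.
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @return a `calibrated_tree`: an [ape::phylo] with a `node_age` attribute.
#' @export
read_calibrated_tree <- function(path, tol = 1e-6) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tree)) stop("malformed Newick in ", path)
  as_calibrated_tree(tree, tol = tol)
}

#' Validate a phylo object as a calibrated tree
#'
#' @param tree an [ape::phylo].
#' @param tol relative ultrametricity tolerance.
#' @return the tree with class `calibrated_tree` prepended and ages attached.
#' @export
as_calibrated_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  age <- node_ages(tree)
  ntip <- length(tree$tip.label)
  tip_age <- age[seq_len(ntip)]
  root_age <- max(age)
  spread <- max(tip_age) - min(tip_age)
  if (root_age > 0 && spread > tol * root_age) {
    bad <- tree$tip.label[abs(tip_age - stats::median(tip_age)) >
                            tol * root_age / 2]
    stop("tree is not ultrametric (tip age spread ", format(spread),
         "); offending tips: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  # snap tip ages to zero so downstream slicing sees an exact ultrametric tree
  age[seq_len(ntip)] <- 0
  attr(tree, "node_age") <- age
  class(tree) <- c("calibrated_tree", class(tree))
  tree
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat("Time-calibrated tree:", length(x$tip.label), "leaves, root age",
      format(max(attr(x, "node_age"))), "\n")
  invisible(x)
}

#' Root age of a calibrated tree
#' @param tree a `calibrated_tree`.
#' @return the root age (time before present).
#' @export
root_age <- function(tree) max(node_ages(tree))

#' Write a tree to Newick
#' @param tree a phylo/calibrated tree.
#' @param path output file.
#' @export
write_calibrated_tree <- function(tree, path) {
  cls <- class(tree)
  class(tree) <- "phylo"
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# ---- distance matrices ------------------------------------------------------

#' Construct a labelled host distance matrix
#'
#' @param m square numeric matrix with matching dimnames.
#' @param what label used in validation messages.
#' @return the validated matrix (symmetric, zero diagonal, non-negative).
#' @export
host_distance_matrix <- function(m, what = "distance matrix") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(what, " is not square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry host labels")
  if (!identical(rownames(m), colnames(m))) stop(what, " labels disagree")
  if (any(m < 0)) stop(what, " has negative entries")
  if (max(abs(m - t(m))) > 1e-12) stop(what, " is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop(what, " has nonzero diagonal")
  diag(m) <- 0
  m
}

#' Cophenetic (tree-path) distances between leaves
#'
#' Entry (i, j) is the sum of branch lengths along the path between leaves
#' i and j; on an ultrametric tree this is twice the age of their most recent
#' common ancestor.
#'
#' @param tree a phylo with branch lengths and at least two leaves.
#' @return a symmetric host distance matrix.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("need at least two leaves")
  host_distance_matrix(ape::cophenetic.phylo(tree), "cophenetic matrix")
}

#' Host ecology distance matrix
#'
#' Encodes the domestication-transition contrast used for ancient canid
#' microbiomes: distance 1 between a dog and a wolf, 0 within dogs or within
#' wolves, and 0.5 between an ancient host and every modern one (the ancient
#' hosts are treated as an ecological intermediate between wild wolves and
#' modern dogs). Ancient-ancient pairs get 0; only ancient-vs-modern is
#' specified by the coding rule, and identical ecological state is the
#' natural extension.
#'
#' @param meta a `host_meta` data frame (see [host_meta()]), or any data
#'   frame with columns `host` and `group`.
#' @return a host distance matrix with values in \{0, 0.5, 1\}.
#' @export
ecology_distance_matrix <- function(meta) {
  meta <- host_meta(meta)
  g <- meta$group
  n <- nrow(meta)
  d <- matrix(0, n, n, dimnames = list(meta$host, meta$host))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gi <- g[i]; gj <- g[j]
    d[i, j] <- if (gi == gj) 0
      else if ("ancient" %in% c(gi, gj)) 0.5
      else 1
  }
  host_distance_matrix(d, "ecology matrix")
}

#' Host metadata table
#'
#' @param x data frame with columns `host`, `group` (one of `wolf`, `dog`,
#'   `ancient`) and optionally diet-fraction columns.
#' @return validated data frame of class `host_meta`.
#' @export
host_meta <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("host", "group") %in% names(x)))
    stop("host meta needs columns 'host' and 'group'")
  if (anyDuplicated(x$host)) stop("duplicated host ids")
  bad <- setdiff(unique(x$group), c("wolf", "dog", "ancient"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  diet <- setdiff(names(x), c("host", "group"))
  if (length(diet)) {
    dm <- as.matrix(x[diet])
    if (any(dm < 0 | dm > 1, na.rm = TRUE)) stop("diet fractions must lie in [0, 1]")
  }
  class(x) <- unique(c("host_meta", class(x)))
  x
}

# ---- abundance tables -------------------------------------------------------

#' Validate a hosts-by-taxa abundance table
#'
#' @param m numeric matrix, hosts in rows, taxa in columns, with dimnames.
#' @return validated matrix of class `abundance_table`.
#' @export
abundance_table <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundance table must carry host and taxon ids")
  if (anyDuplicated(rownames(m)))
    stop("duplicated host id: ", rownames(m)[duplicated(rownames(m))][1])
  if (anyDuplicated(colnames(m)))
    stop("duplicated taxon id: ", colnames(m)[duplicated(colnames(m))][1])
  if (any(!is.finite(m)) || any(m < 0)) stop("abundance table has negative or non-finite entries")
  class(m) <- c("abundance_table", class(m))
  m
}

#' Read an abundance table from TSV
#'
#' The file must be rectangular with a header row and a first id column.
#' Orientation is explicit because taxa-major tables are common upstream and
#' a silently transposed table is fatal downstream.
#'
#' @param path TSV file.
#' @param orientation `"hosts_in_rows"` (default) or `"taxa_in_rows"`.
#' @return an `abundance_table` (hosts x taxa).
#' @export
read_abundance_table <- function(path,
                                 orientation = c("hosts_in_rows", "taxa_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  if (orientation == "taxa_in_rows") m <- t(m)
  abundance_table(m)
}

#' Write an abundance table as TSV (hosts in rows)
#' @param table abundance table.
#' @param path output file.
#' @param id_name header of the id column.
#' @export
write_abundance_table <- function(table, path, id_name = "host") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled distance matrix (full symmetric TSV body)
#' @param path TSV file with id column and header.
#' @return host distance matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  host_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m distance matrix to write.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(host = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- calibration set --------------------------------------------------------

#' External 16S calibration set for divergence-time estimation
#'
#' Builds the roster of external 16S rRNA sequences used to anchor node ages
#' when calibrating a bacterial phylogeny: lineages with fossil/biomarker
#' minimum ages (in My before present) that are added for dating and removed
#' before analysis. Defaults follow the standard four-group design
#' (Cyanobacteria > 2500 My, Rickettsiales > 1600 My, Chlorobium > 1640 My,
#' Chromatiales > 1640 My).
#'
#' @param cyanobacteria,rickettsiales,chlorobium,chromatiales sequence counts
#'   per calibration group.
#' @return data frame with one row per external sequence (`id`, `group`,
#'   `min_age_my`).
#' @export
calibration_set <- function(cyanobacteria = 50, rickettsiales = 50,
                            chlorobium = 15, chromatiales = 15) {
  counts <- c(cyanobacteria = cyanobacteria, rickettsiales = rickettsiales,
              chlorobium = chlorobium, chromatiales = chromatiales)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("group counts must be non-negative integers")
  ages <- c(cyanobacteria = 2500, rickettsiales = 1600,
            chlorobium = 1640, chromatiales = 1640)
  group <- rep(names(counts), counts)
  data.frame(
    id = paste0(group, "_", unlist(lapply(counts, seq_len), use.names = FALSE)),
    group = group,
    min_age_my = ages[group],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
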