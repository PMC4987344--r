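#' Column z-standardization of a feature matrix
#'
#' Transforms each selected feature to zero mean and unit sample standard
#' deviation (n-1 denominator), storing the transform for reporting.
#'
#' @param mat numeric matrix or data frame, cells in rows.
#' @return Numeric matrix of z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(mat) {
  m <- as.matrix(mat)
  if (!is.numeric(m)) stop("feature matrix must be numeric")
  if (nrow(m) < 2) stop("standardization needs at least 2 cells")
  if (anyNA(m))
    stop("invalid (missing) feature values in columns: ",
         paste(colnames(m)[apply(is.na(m), 2, any)], collapse = ", "))
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  if (any(scl == 0))
    stop("cannot standardize constant feature(s): ",
         paste(colnames(m)[scl == 0], collapse = ", "))
  z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Ward's agglomerative clustering
#'
#' Hierarchical clustering of a standardized feature matrix with Ward's
#' minimum-variance criterion on Euclidean distances (the `ward.D2`
#' formulation, i.e. Lance-Williams updates on squared distances with
#' heights on the distance scale). Merge heights are checked for
#' monotonicity on every run.
#'
#' @param z standardized numeric matrix (cells in rows).
#' @return An `hclust` object; leaf labels are the row names of `z`.
#' @export
ward_linkage <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("clustering needs at least 2 cells")
  h <- stats::hclust(stats::dist(z, method = "euclidean"),
                     method = "ward.D2")
  if (any(diff(h$height) < -1e-8))
    stop("non-monotone merge heights; Ward linkage on Euclidean distances ",
         "should be monotone")
  h
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges of the dendrogram.
#'
#' @param dendrogram an `hclust` object.
#' @param k number of clusters, 1..n.
#' @return A `cluster_assignment`: list with `labels` (named integer vector
#'   cell -> cluster) and `k`.
#' @export
cluster_cut <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k))
    stop("k must be an integer in 1..", n)
  structure(list(labels = stats::cutree(dendrogram, k = k), k = k),
            class = "cluster_assignment")
}

#' Misclassification count against known labels
#'
#' Counts the cells whose cluster does not match their true class under the
#' best one-to-one matching of clusters to classes (the confusion-matrix
#' off-diagonal minimised over label permutations). With more clusters than
#' classes, unmatched clusters count entirely as misclassified.
#'
#' @param labels integer cluster labels.
#' @param truth true class labels (same length).
#' @return List with `count`, `misclassified` (indices) and the cluster ->
#'   class `mapping` used.
#' @export
misclassification <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  cl <- sort(unique(labels))
  classes <- sort(unique(as.character(truth)))
  tab <- table(factor(labels, levels = cl),
               factor(as.character(truth), levels = classes))
  # assign each cluster a class by exhaustive matching (small k)
  perms <- perms_of(classes, length(cl))
  best <- NULL
  best_err <- Inf
  for (p in perms) {
    err <- sum(tab) - sum(tab[cbind(seq_along(cl), match(p, classes))],
                          na.rm = TRUE)
    if (err < best_err) { best_err <- err; best <- p }
  }
  mapping <- stats::setNames(best, cl)
  mis <- which(mapping[as.character(labels)] != as.character(truth))
  list(count = length(mis), misclassified = mis, mapping = mapping)
}

# all assignments of classes to k slots (with repetition allowed when
# k exceeds the number of classes, without repetition otherwise)
perms_of <- function(classes, k) {
  if (k <= length(classes)) {
    idx <- utils::combn(length(classes), k, simplify = FALSE)
    out <- list()
    for (cmb in idx)
      out <- c(out, lapply(perms_list(cmb), function(o) classes[o]))
    out
  } else {
    # map surplus clusters to NA (unmatched)
    base <- perms_of(classes, length(classes))
    slots <- utils::combn(k, length(classes), simplify = FALSE)
    out <- list()
    for (sl in slots) for (p in base) {
      v <- rep(NA_character_, k)
      v[sl] <- p
      out <- c(out, list(v))
    }
    out
  }
}

perms_list <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perms_list(x[-i]), function(p) c(x[i], p)))
  out
}

#' Sequential re-clustering with group removal
#'
#' Runs a staged classification: at each stage the named groups are
#' removed, z-scores are recalculated on the remaining cells, Ward
#' clustering is re-run and cut at the stage's k. A full audit trail of
#' every stage is retained.
#'
#' @param records data frame with a `group` column (identity labels used
#'   for exclusion), optional `cell_id`, and the feature columns.
#' @param stage_plan list of stages; each stage is a list with `features`
#'   (character vector of feature columns), `exclude_groups` (character,
#'   possibly empty) and `k`.
#' @return List of stages, each with `kept` (row indices into `records`),
#'   `z`, `tree` (hclust) and `assignment`.
#' @export
sequential_cluster <- function(records, stage_plan) {
  stopifnot(is.data.frame(records), "group" %in% names(records))
  excluded <- character(0)
  lapply(stage_plan, function(stage) {
    excluded <<- union(excluded, stage$exclude_groups)
    keep <- which(!(records$group %in% excluded))
    if (!length(keep)) stop("a stage excluded all cells")
    m <- as.matrix(records[keep, stage$features, drop = FALSE])
    rownames(m) <- if ("cell_id" %in% names(records))
      records$cell_id[keep] else as.character(keep)
    z <- standardize(m)
    tree <- ward_linkage(z)
    list(kept = keep, features = stage$features, z = z, tree = tree,
         assignment = cluster_cut(tree, stage$k))
  })
}

#' Name clusters from benchmark cells and count misclassification
#'
#' Each cluster containing benchmark cells is named by the majority
#' benchmark class (a tie is an error prompting explicit naming, never a
#' silent tie-break). Cells of a known class assigned to a cluster named
#' otherwise, or to an unnamed cluster, are counted as misclassified.
#'
#' @param assignment a `cluster_assignment`.
#' @param benchmark_labels character vector (NA for non-benchmark cells),
#'   aligned with `assignment$labels`.
#' @param known_labels optional character vector of true classes for
#'   non-benchmark cells (NA when unknown); defaults to
#'   `benchmark_labels`.
#' @return The assignment augmented with `cluster_names`, `misclassified`
#'   (indices) and `n_misclassified`.
#' @export
benchmark_assign <- function(assignment, benchmark_labels,
                             known_labels = benchmark_labels) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            length(benchmark_labels) == length(assignment$labels))
  labs <- assignment$labels
  if (all(is.na(benchmark_labels))) stop("at least one benchmark cell is required")
  cl <- sort(unique(labs))
  nm <- stats::setNames(rep(NA_character_, length(cl)), cl)
  for (g in cl) {
    b <- benchmark_labels[labs == g]
    b <- b[!is.na(b)]
    if (!length(b)) next
    tab <- sort(table(b), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2])
      stop("benchmark majority tie in cluster ", g,
           "; name this cluster explicitly")
    nm[as.character(g)] <- names(tab)[1]
  }
  known <- known_labels
  mis <- which(unname(!is.na(known) &
                        (is.na(nm[as.character(labs)]) |
                           nm[as.character(labs)] != known)))
  assignment$cluster_names <- nm
  assignment$misclassified <- mis
  assignment$n_misclassified <- length(mis)
  assignment
}

#' Export a dendrogram as a Newick string or file
#'
#' Merge heights become branch lengths (via the standard hclust-to-phylo
#' conversion).
#'
#' @param tree an `hclust` object.
#' @param file optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
export_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
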