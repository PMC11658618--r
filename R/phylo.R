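#' Pairwise binary distances between samples of a presence matrix
#'
#' Hamming distance over PAM sites: the number of sites at which exactly one
#' of the two samples carries the PAM, counted over sites where neither entry
#' is `no_coverage` (pairwise deletion).
#'
#' @param pm a [presence_matrix()].
#' @param samples samples to compare; default all tumor samples (normal
#'   excluded).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
binary_distance <- function(pm, samples = NULL) {
  if (is.null(samples)) {
    samples <- pm$samples$sample[pm$samples$role != "normal"]
  }
  if (length(samples) < 2) stop("need at least 2 samples")
  st <- pm$status[, samples, drop = FALSE]
  pres <- st == "present"
  nc <- st == "no_coverage"
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !nc[, i] & !nc[, j]
      if (!any(ok)) {
        stop("no comparable sites for pair ", samples[i], " / ", samples[j])
      }
      d[i, j] <- d[j, i] <- sum(pres[ok, i] != pres[ok, j])
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: iteratively
#' merge the closest pair of clusters; the distance from the merged cluster
#' to any other is the size-weighted average of its members' distances, and
#' the merge node sits at height distance/2 (so the tree is ultrametric).
#' Ties are broken deterministically: among equally close pairs, the pair
#' whose lexicographically sorted, concatenated member names sort first is
#' merged.
#'
#' @param d symmetric distance matrix with dimnames (or a `dist`).
#' @return an ultrametric `ape::phylo` tree.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 samples")
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);", labels[1],
                                         d[1, 2] / 2, labels[2], d[1, 2] / 2)))
  }
  members <- as.list(labels)
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  dm <- d
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1):length(idx)) {
        a <- idx[ii]; b <- idx[jj]
        dd <- dm[a, b]
        key <- paste(sort(c(members[[a]], members[[b]])), collapse = "|")
        if (dd < best_d - 1e-12 ||
            (abs(dd - best_d) <= 1e-12 && !is.null(best_key) && key < best_key)) {
          best <- c(a, b); best_d <- dd; best_key <- key
        } else if (is.null(best)) {
          best <- c(a, b); best_d <- dd; best_key <- key
        }
      }
    }
    a <- best[1]; b <- best[2]
    h <- best_d / 2
    new_newick <- sprintf("(%s:%.12g,%s:%.12g)", newick[a], h - height[a],
                          newick[b], h - height[b])
    # size-weighted average distances to the merged cluster
    for (k in idx) {
      if (k == a || k == b) next
      dm[a, k] <- dm[k, a] <- (size[a] * dm[a, k] + size[b] * dm[b, k]) /
        (size[a] + size[b])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    newick[a] <- new_newick
    height[a] <- h
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
  }
  root <- which(active)
  ape::read.tree(text = paste0(newick[root], ";"))
}

#' Re-root a sample tree at the least-derived primary
#'
#' Selects the primary sample with the fewest unique PAMs (PAMs present in
#' it and in no other sample of the matrix) and places the root on the
#' branch leading to it. With a single primary that primary is the root
#' outgroup; ties are broken lexicographically (logged via `message`).
#' Without any primary the tree is returned unchanged with a warning.
#'
#' @param tree an `ape::phylo` tree whose tips are sample names.
#' @param pm the [presence_matrix()] the tree was built from.
#' @return re-rooted `ape::phylo`.
#' @export
reroot_at_primary <- function(tree, pm) {
  prim <- intersect(samples_of_role(pm, "primary"), tree$tip.label)
  if (!length(prim)) {
    warning("no primary sample in tree; returning unrooted tree")
    return(tree)
  }
  if (length(prim) == 1) {
    sel <- prim
  } else {
    uniq <- vapply(prim, function(p) unique_pam_count(pm, p, tree$tip.label), 1L)
    best <- min(uniq)
    cands <- sort(names(uniq)[uniq == best])
    if (length(cands) > 1) {
      message("tie in unique-PAM counts (", paste(cands, collapse = ", "),
              "); rooting at ", cands[1])
    }
    sel <- cands[1]
  }
  ape::root(tree, outgroup = sel, resolve.root = TRUE)
}

# PAMs present in sample p and in no other sample of `scope`.
unique_pam_count <- function(pm, p, scope) {
  st <- pm$status[, intersect(scope, colnames(pm$status)), drop = FALSE]
  others <- setdiff(colnames(st), p)
  sum(st[, p] == "present" &
        rowSums(st[, others, drop = FALSE] == "present") == 0)
}
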