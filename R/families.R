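#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix: repeatedly
#' join the pair minimising `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (with `R`
#' the row sums over active nodes), using the standard rate-corrected
#' branch lengths. Ties in Q are broken by the lexicographically smallest
#' id pair. Negative branch-length estimates are clamped to zero with the
#' deficit transferred to the sibling branch. The result exactly fits any
#' additive input matrix.
#'
#' @param d Symmetric numeric matrix with ids as dimnames (e.g. from
#'   [ibs_distance()]), at least 3 leaves, finite entries.
#' @return An unrooted tree of class `phylo` (ape).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 leaves")
  if (!isSymmetric(unname(d), tol = 1e-10))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  ## active nodes are nested subtree structures:
  ## list(label=) for a leaf, list(children=list(list(node, len), ...))
  nodes <- lapply(ids, function(x) list(label = x))
  key <- ids  # smallest leaf id in each subtree, for deterministic ties

  while (length(nodes) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    pair_key <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- min(pick); j <- max(pick)

    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)

    new_node <- list(children = list(list(node = nodes[[i]], len = li),
                                     list(node = nodes[[j]], len = lj)))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    key <- c(key[keep], min(key[c(i, j)]))
  }

  ## resolve the final three nodes around a central vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  root <- list(children = list(list(node = nodes[[1L]], len = max(la, 0)),
                               list(node = nodes[[2L]], len = max(lb, 0)),
                               list(node = nodes[[3L]], len = max(lc, 0))))
  tree <- ape::read.tree(text = node_to_newick(root))
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  tree
}

## serialise a nested subtree structure to Newick (full precision)
node_to_newick <- function(node) {
  paste0(subtree_string(node), ";")
}

subtree_string <- function(node) {
  if (!is.null(node$label)) return(quote_newick_label(node$label))
  inner <- vapply(node$children, function(ch) {
    paste0(subtree_string(ch$node), ":", sprintf("%.15g", ch$len))
  }, character(1L))
  paste0("(", paste(inner, collapse = ","), ")")
}

quote_newick_label <- function(x) {
  if (grepl("[][ (){},;:'\t]", x))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

## ape::read.tree keeps the quotes of quoted labels; strip them back off
unquote_newick_label <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
  x
}

#' Serialise a tree to Newick
#'
#' Writes branch lengths at full precision, quotes labels containing
#' Newick-reserved characters, and terminates with `;`. Re-parsing
#' reproduces topology and branch lengths.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rec <- function(node) {
    if (node <= n) return(quote_newick_label(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    inner <- vapply(kids, function(e) {
      child <- tree$edge[e, 2L]
      len <- if (is.null(tree$edge.length)) "" else
        paste0(":", sprintf("%.15g", tree$edge.length[e]))
      paste0(rec(child), len)
    }, character(1L))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Build conservation families from genomic kinship
#'
#' Implements the herd-conservation family rule: (1) bulls whose pairwise
#' genomic kinship (off-diagonal G entry) is at or above the threshold are
#' connected; connected components form the families, labelled "Family 1",
#' "Family 2", ... in discovery order (input order of the first bull);
#' (2) each cow joins the family of her maximum-kinship bull when that
#' kinship reaches the threshold, otherwise she is assigned to the "other"
#' category. Ties between bulls of different families go to the
#' lexicographically smaller bull id.
#'
#' @param G A `grm` object or symmetric kinship matrix with sample ids.
#' @param sex Named character vector ("male"/"female") or a data frame with
#'   `id` and `sex` columns covering every sample in `G`.
#' @param threshold Kinship threshold (default 0.1).
#' @return A list of class `family_assignment`: `families` (list of
#'   `label`, `bulls`, `cows`), `other` (cow ids), `threshold`,
#'   `assignments` (data frame: id, sex, family).
#' @export
build_families <- function(G, sex, threshold = 0.1) {
  if (inherits(G, "grm")) G <- G$G
  ids <- rownames(G)
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$id)
  sex <- sex[ids]
  if (any(is.na(sex) | !(sex %in% c("male", "female"))))
    stop("a male/female sex label is required for every sample")
  bulls <- ids[sex == "male"]
  cows <- ids[sex == "female"]
  if (!length(bulls)) stop("no bulls in the cohort")

  nb <- length(bulls)
  Gb <- G[bulls, bulls, drop = FALSE]
  edges <- which(upper.tri(Gb) & Gb >= threshold, arr.ind = TRUE)
  comp <- connected_components(nb, edges)
  fam_of_bull <- match(comp, unique(comp))  # discovery order
  k <- max(fam_of_bull)

  fam_cows <- vector("list", k)
  other <- character()
  for (cw in cows) {
    kin <- G[cw, bulls]
    best <- max(kin)
    if (best >= threshold) {
      cand <- bulls[kin >= best - 1e-15]
      bull <- sort(cand)[1L]
      f <- fam_of_bull[match(bull, bulls)]
      fam_cows[[f]] <- c(fam_cows[[f]], cw)
    } else other <- c(other, cw)
  }

  families <- lapply(seq_len(k), function(f) {
    list(label = paste("Family", f),
         bulls = bulls[fam_of_bull == f],
         cows = if (is.null(fam_cows[[f]])) character() else fam_cows[[f]])
  })
  assignments <- data.frame(
    id = c(bulls, cows),
    sex = c(rep("male", length(bulls)), rep("female", length(cows))),
    family = c(paste("Family", fam_of_bull),
               vapply(cows, function(cw) {
                 hit <- which(vapply(fam_cows, function(x) cw %in% x,
                                     logical(1L)))
                 if (length(hit)) paste("Family", hit[1L]) else "other"
               }, character(1L))),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(families = families, other = other, threshold = threshold,
                 assignments = assignments),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("Conservation families (kinship threshold ", x$threshold, ")\n",
      sep = "")
  for (f in x$families)
    cat("  ", f$label, ": ", length(f$bulls), " bulls, ",
        length(f$cows), " cows\n", sep = "")
  cat("  other: ", length(x$other), " cows\n", sep = "")
  invisible(x)
}
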