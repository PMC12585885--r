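#' Pairwise allele-sharing difference matrix
#'
#' `d(i, j)` is the mean over pairwise-complete sites of
#' `|dosage_i - dosage_j| / 2`: identical genotypes contribute 0, opposite
#' homozygotes 1, and a heterozygote differs from either homozygote by 0.5
#' per site. Computed directly from dosages, which for biallelic SNPs on
#' homozygote-only subsets is equivalent to a sequence-based difference
#' matrix. Note this distance can violate the triangle inequality.
#'
#' @param gm a [genotype_matrix()].
#' @param region optional `list(chrom=, start=, end=)` (0-based half-open).
#' @param samples optional sample subset.
#' @return Symmetric matrix with zero diagonal and sample-id dimnames.
#' @export
diff_matrix <- function(gm, region = NULL, samples = NULL) {
  if (!is.null(region)) {
    gm <- gm_region(gm, region$chrom, region$start %||% 0L,
                    region$end %||% Inf)
  }
  if (!is.null(samples)) gm <- gm_subset(gm, samples = samples)
  if (nrow(gm$sites) == 0) stop("empty region")
  d <- gm$dosage
  M <- !is.na(d)
  I0 <- (d == 0L) & M; I1 <- (d == 1L) & M; I2 <- (d == 2L) & M
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  Mm <- M; storage.mode(Mm) <- "double"
  # sum |gi - gj| decomposed over dosage-pair combinations
  S <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  n_complete <- tcrossprod(Mm)
  out <- S / (2 * n_complete)
  out[n_complete == 0] <- NA
  diag(out) <- 0
  dimnames(out) <- list(gm$samples, gm$samples)
  out
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lowest (row, column) index pair. A
#' negative branch length arising at a join is set to zero and its length
#' transferred to the sister branch, preserving the path length between the
#' joined taxa.
#'
#' @param dist symmetric distance matrix with taxon dimnames (or a `dist`
#'   object); at least 3 taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # each active node is represented by a newick fragment
  frag <- labs
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < bq - 1e-12) {
          bq <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- paste0("(", frag[active[i]], ":", fmt(vi), ",",
                      frag[active[j]], ":", fmt(vj), ")")
    du <- (Dm[i, -c(i, j)] + Dm[j, -c(i, j)] - Dm[i, j]) / 2
    keep <- active[-c(i, j)]
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, keep] <- du; D[keep, u] <- du
    frag <- c(frag, newfrag)
    active <- c(keep, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- D[a, b] - va
  vc <- D[a, c3] - va
  adj <- function(v) max(v, 0)
  nwk <- paste0("(", frag[a], ":", fmt(adj(va)), ",",
                frag[b], ":", fmt(adj(vb)), ",",
                frag[c3], ":", fmt(adj(vc)), ");")
  ape::read.tree(text = nwk)
}

#' Restrict to homokaryote samples
#'
#' Keeps samples called homozygous for a haplotype (`00`, `11`, or doubled
#' third-haplotype codes such as `1a1a`); heterokaryotes and unassigned
#' samples are excluded.
#'
#' @param gm a [genotype_matrix()] (used to preserve sample order).
#' @param calls a `karyotype_calls` data.frame.
#' @return Character vector of retained sample ids (warning when empty).
#' @export
subset_homokaryotes <- function(gm, calls) {
  g <- calls$genotype
  homo <- function(x) {
    if (x %in% c("00", "11")) return(TRUE)
    if (x == "unassigned" || x == "01") return(FALSE)
    h <- nchar(x) / 2
    h == floor(h) && substr(x, 1, h) == substr(x, h + 1, 2 * h)
  }
  ids <- calls$sample_id[vapply(g, homo, logical(1))]
  ids <- gm$samples[gm$samples %in% ids]
  if (length(ids) == 0) warning("no homokaryote samples retained")
  ids
}

# internal: adjacency representation of a phylo tree
.tree_adj <- function(tree) {
  e <- tree$edge
  len <- tree$edge.length
  n_nodes <- max(e)
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, len[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, len[k]))
  }
  adj
}

# internal: newick fragment of the subtree away from 'from', starting 'at'
.nwk_from <- function(adj, tips, at, from) {
  nb <- adj[[at]]
  nb <- nb[nb[, 1] != from, , drop = FALSE]
  if (nrow(nb) == 0) return(tips[at])
  parts <- vapply(seq_len(nrow(nb)), function(i) {
    paste0(.nwk_from(adj, tips, nb[i, 1], at), ":",
           sprintf("%.15g", nb[i, 2]))
  }, "")
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Root a tree on the branch separating two groups
#'
#' Finds the edge whose removal bipartitions the tips into exactly
#' (`groupA`, `groupB`) and roots the tree at that edge's midpoint. An error
#' (listing conflicting tips) is raised when no such edge exists.
#'
#' @param tree an unrooted `phylo` tree covering exactly the two groups.
#' @param groupA,groupB disjoint, non-empty tip-label sets.
#' @return A rooted `phylo` tree.
#' @export
root_between_groups <- function(tree, groupA, groupB) {
  tips <- tree$tip.label
  stopifnot(length(groupA) > 0, length(groupB) > 0,
            length(intersect(groupA, groupB)) == 0)
  if (!setequal(tips, union(groupA, groupB))) {
    stop("groups must cover the tree's tips exactly")
  }
  ntip <- length(tips)
  adj <- .tree_adj(tree)
  # tip sets on the child side of each edge, via one DFS per edge endpoint
  side_tips <- function(at, from) {
    nb <- adj[[at]]; nb <- nb[nb[, 1] != from, , drop = FALSE]
    if (at <= ntip) return(tips[at])
    unlist(lapply(nb[, 1], side_tips, from = at))
  }
  e <- tree$edge
  best_conflict <- NULL; best_bad <- Inf
  for (k in seq_len(nrow(e))) {
    side <- side_tips(e[k, 2], e[k, 1])
    if (setequal(side, groupA) || setequal(side, groupB)) {
      # root at the midpoint of this edge
      L <- tree$edge.length[k]
      a <- e[k, 1]; b <- e[k, 2]
      sub_a <- .nwk_from(adj, c(tips, rep("", length(adj) - ntip)), a, b)
      sub_b <- .nwk_from(adj, c(tips, rep("", length(adj) - ntip)), b, a)
      nwk <- paste0("(", sub_a, ":", sprintf("%.15g", L / 2), ",",
                    sub_b, ":", sprintf("%.15g", L / 2), ");")
      return(ape::read.tree(text = nwk))
    }
    bad <- length(c(setdiff(side, groupA), setdiff(groupA, side)))
    if (bad < best_bad) { best_bad <- bad; best_conflict <- side }
  }
  stop("no edge separates the two groups; closest bipartition conflicts on ",
       "tips: ",
       paste(utils::head(c(setdiff(best_conflict, groupA),
                           setdiff(groupA, best_conflict)), 5),
             collapse = ", "))
}

#' Root a tree on a named outgroup tip
#'
#' @param tree a `phylo` tree.
#' @param tip tip label to use as outgroup.
#' @return A rooted `phylo` tree.
#' @export
root_on_tip <- function(tree, tip) {
  if (!tip %in% tree$tip.label) stop("no such tip: ", tip)
  ape::root(tree, outgroup = tip, resolve.root = TRUE)
}

#' Branch-length contrast between two tip groups
#'
#' For a tree rooted between the groups (see [root_between_groups()]):
#' the inter-group stem length (path between the two group MRCAs), the mean
#' within-group depth (MRCA-to-tip distance), and their ratio. Divergent SV
#' haplotypes yield a long stem relative to shallow within-group depths;
#' freely recombining regions yield a ratio near or below 1.
#'
#' @param tree a rooted `phylo` tree.
#' @param groupA,groupB tip-label sets.
#' @return List `stem_length`, `mean_depth_A`, `mean_depth_B`, `ratio`.
#' @export
branch_summary <- function(tree, groupA, groupB) {
  dn <- ape::dist.nodes(tree)
  tips <- tree$tip.label
  node_of <- function(g) {
    i <- match(g, tips)
    if (length(i) == 1) i else ape::getMRCA(tree, i)
  }
  ma <- node_of(groupA); mb <- node_of(groupB)
  stem <- dn[ma, mb]
  depth <- function(m, g) mean(dn[m, match(g, tips)])
  da <- depth(ma, groupA); db <- depth(mb, groupB)
  wd <- mean(c(dn[ma, match(groupA, tips)], dn[mb, match(groupB, tips)]))
  list(stem_length = stem, mean_depth_A = da, mean_depth_B = db,
       ratio = if (wd > 0) stem / wd else Inf)
}
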