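#' Detect co-expression modules by dynamic hybrid tree cutting
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity followed by a dynamic hybrid branch decomposition.  A
#' branch of the dendrogram becomes a module when (i) it holds at least
#' `min_module_size` proteins, (ii) its core merge heights are low
#' relative to the height range (core scatter), and (iii) it stays
#' separate from the rest of the tree over a sufficient height interval
#' before attaching (gap).  The `deep_split` setting maps onto the four
#' documented sensitivity presets: higher values tolerate looser cores
#' and smaller gaps, producing more and finer modules.  An optional PAM
#' stage then assigns leftover proteins to the nearest module (by average
#' dissimilarity), restricted to modules within the protein's own
#' dendrogram branch below the cut height.  Proteins in no module are
#' labelled "grey".
#'
#' On structureless data the merge heights concentrate near the top of
#' the tree, no branch attains a low core scatter, and (nearly) all
#' proteins stay grey; this is the intended null behaviour.
#'
#' @param dissim symmetric dissimilarity matrix, typically `1 - TOM`.
#' @param params a [network_params()] bundle (`deep_split`,
#'   `min_module_size`, `pam_stage` are used).
#' @return list with `labels` (character; "1", "2", ... and "grey") and
#'   `dendrogram` (the `hclust` object).
#' @export
detect_modules <- function(dissim, params = network_params()) {
  n <- nrow(dissim)
  if (n < params$min_module_size) {
    warning("fewer proteins than min_module_size; all proteins labelled grey")
    return(list(labels = rep("grey", n), dendrogram = NULL))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  lab <- cut_tree_hybrid(hc, dissim,
                         deep_split = params$deep_split,
                         min_size = params$min_module_size,
                         pam_stage = params$pam_stage)
  labels <- ifelse(lab == 0L, "grey", as.character(lab))
  names(labels) <- rownames(dissim)
  list(labels = labels, dendrogram = hc)
}

# deep_split 0..4 -> (maxCoreScatter, minGap) sensitivity presets
deep_split_presets <- function(deep_split) {
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_core_scatter = mcs, min_gap = (1 - mcs) * 3 / 4)
}

# Hybrid branch decomposition of an hclust tree.  Returns integer labels,
# 0 = unassigned.
cut_tree_hybrid <- function(hc, dissim, deep_split = 4, min_size = 12,
                            pam_stage = TRUE) {
  n <- length(hc$order)
  m <- hc$merge
  h <- hc$height
  nm <- nrow(m)

  ref_h <- stats::quantile(h, 0.05, names = FALSE)
  hmax <- max(h)
  denom <- hmax - ref_h
  cut_h <- ref_h + 0.99 * denom
  if (denom < 1e-12) {
    # degenerate tree: every merge at one height.  A uniformly tight tree
    # (low absolute dissimilarity) is one module; a uniformly loose one
    # has no structure.
    if (stats::median(h) < 0.3) return(rep(1L, n)) else return(rep(0L, n))
  }
  norm_h <- function(x) pmin(pmax((x - ref_h) / denom, 0), 1)
  preset <- deep_split_presets(deep_split)

  # per-node subtree members and internal merge heights
  members <- vector("list", nm)
  hts <- vector("list", nm)
  for (k in seq_len(nm)) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    pick_h <- function(j) if (j < 0) numeric(0) else hts[[j]]
    members[[k]] <- c(pick(m[k, 1]), pick(m[k, 2]))
    hts[[k]] <- c(pick_h(m[k, 1]), pick_h(m[k, 2]), h[k])
  }
  sizes <- lengths(members)

  core_scatter <- function(k) {
    s <- sizes[k]
    ncore <- min(s - 1, min_size + floor(sqrt(max(0, s - min_size))))
    mean(sort(hts[[k]])[seq_len(max(1, ncore))])
  }
  parent <- rep(NA_integer_, nm)
  for (k in seq_len(nm)) for (j in m[k, ]) if (j > 0) parent[j] <- k

  # Height at which the lineage of node k first merges with another branch
  # of substantial size (>= min_size).  Stray attachments of single
  # proteins or tiny twigs do not end a branch; a module's distinctness is
  # its height margin below the point where it joins real structure.
  attach_height <- function(k) {
    cur <- k
    p <- parent[k]
    while (!is.na(p)) {
      if (h[p] > cut_h) break
      sib <- m[p, ][m[p, ] != cur][1]
      sib_size <- if (sib < 0) 1L else sizes[sib]
      if (sib_size >= min_size) return(h[p])
      cur <- p
      p <- parent[p]
    }
    cut_h
  }
  # Core scatter is judged relative to the tree's height range (a branch
  # must be tight relative to this dataset); the gap is judged on the raw
  # dissimilarity scale, which for 1 - TOM is already normalized to
  # [0, 1].  An absolute gap keeps structureless data grey: in noise the
  # merge heights concentrate near the top of the tree and no branch
  # separates from its surroundings by a material dissimilarity margin.
  qualifies <- function(k) {
    sizes[k] >= min_size &&
      norm_h(core_scatter(k)) <= preset$max_core_scatter &&
      (attach_height(k) - h[k]) >= preset$min_gap
  }
  # returns list of node indices that become modules within subtree k
  collect <- function(k) {
    if (k < 0 || sizes[k] < min_size) return(integer(0))
    sub <- c(collect(m[k, 1]), collect(m[k, 2]))
    if (length(sub)) return(sub)
    if (qualifies(k)) return(k)
    integer(0)
  }

  # dendrogram components below the cut height: nodes at/below the cut
  # that are not children of another node at/below the cut
  below <- which(h <= cut_h)
  is_child <- rep(FALSE, nm)
  for (k in below) for (j in m[k, ]) if (j > 0) is_child[j] <- TRUE
  comp_roots <- below[!is_child[below]]

  labels <- integer(n)
  component <- integer(n)
  next_lab <- 0L
  for (r in comp_roots) {
    component[members[[r]]] <- r
    for (k in collect(r)) {
      next_lab <- next_lab + 1L
      labels[members[[k]]] <- next_lab
    }
  }

  if (pam_stage && next_lab > 0L) {
    mods <- seq_len(next_lab)
    mod_comp <- vapply(mods, function(l) component[which(labels == l)[1]],
                       integer(1))
    for (i in which(labels == 0L)) {
      cand <- mods[mod_comp == component[i]]
      if (!length(cand) || component[i] == 0L) next
      d <- vapply(cand, function(l) mean(dissim[i, labels == l]), numeric(1))
      if (min(d) < cut_h) labels[i] <- cand[which.min(d)]
    }
  }
  labels
}
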