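#' Binary multiregion mutation matrix
#'
#' Samples (rows) by variants (columns), entries 0/1 presence calls, with one
#' sample designated the germline normal (typically an all-zero row).
#'
#' @param calls numeric/integer matrix with row and column names.
#' @param normal row name of the germline normal sample.
#' @return An object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(calls, normal) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("mutation matrix needs sample (row) and variant (column) names")
  }
  if (anyDuplicated(rownames(calls)) || anyDuplicated(colnames(calls))) {
    stop("duplicate sample or variant labels")
  }
  if (!all(calls %in% c(0, 1))) stop("mutation matrix entries must be 0/1")
  if (!normal %in% rownames(calls)) stop("normal sample '", normal, "' not found")
  structure(
    list(calls = calls, samples = rownames(calls), variants = colnames(calls), normal = normal),
    class = "mutation_matrix"
  )
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(
    "<mutation_matrix> ", length(x$samples), " samples x ", length(x$variants),
    " variants (normal: ", x$normal, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Read a mutation matrix from TSV (samples x variants, 0/1)
#' @param path TSV with sample names in the first column.
#' @param normal normal-sample row name.
#' @return a [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path, normal) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  mutation_matrix(as.matrix(df), normal = normal)
}

#' Write a mutation matrix to TSV
#' @param M a [mutation_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(M, path) {
  utils::write.table(
    data.frame(sample = rownames(M$calls), M$calls, check.names = FALSE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Manhattan (Hamming) distance between samples of a binary call matrix
#'
#' For 0/1 rows the Manhattan distance equals the Hamming distance: the
#' number of variants with differing calls.
#'
#' @param M a [mutation_matrix()] (or plain 0/1 matrix with rownames).
#' @return symmetric numeric matrix with a `metric` attribute.
#' @export
manhattan_distance <- function(M) {
  calls <- if (inherits(M, "mutation_matrix")) M$calls else as.matrix(M)
  if (!all(calls %in% c(0, 1))) stop("non-binary entry in call matrix")
  if (nrow(calls) < 2L) stop("need at least 2 samples")
  D <- as.matrix(stats::dist(calls, method = "manhattan"))
  attr(D, "metric") <- "manhattan"
  D
}

# ---- exhaustive OLS minimum-evolution tree search -------------------------

# Enumerate all unrooted binary topologies over n >= 3 labelled leaves by
# stepwise addition. Each topology is an edge matrix over nodes 1..(2n-2)
# (leaves 1..n, internals above). n topologies: 1, 3, 15, 105, 945, 10395.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3L)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
  topos <- list(list(edges = base, next_node = n + 2L))
  if (n == 3L) {
    return(lapply(topos, `[[`, "edges"))
  }
  for (leaf in 4:n) {
    topos <- unlist(lapply(topos, function(tp) {
      lapply(seq_len(nrow(tp$edges)), function(e) {
        u <- tp$edges[e, 1]
        v <- tp$edges[e, 2]
        w <- tp$next_node
        edges <- rbind(tp$edges[-e, , drop = FALSE], c(u, w), c(w, v), c(w, leaf))
        list(edges = edges, next_node = w + 1L)
      })
    }), recursive = FALSE)
  }
  lapply(topos, `[[`, "edges")
}

# Edge indicator matrix: rows = leaf pairs (i<j), cols = edges; A[p, e] = 1
# iff edge e lies on the path between the pair's leaves.
path_indicator <- function(edges, n) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]
    v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  # parent pointers from a DFS rooted at leaf 1
  parent <- integer(n_nodes)
  parent_edge <- integer(n_nodes)
  depth <- integer(n_nodes)
  visited <- logical(n_nodes)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[node]]
    for (k in seq_len(nrow(nb))) {
      m <- nb[k, 1]
      if (!visited[m]) {
        visited[m] <- TRUE
        parent[m] <- node
        parent_edge[m] <- nb[k, 2]
        depth[m] <- depth[node] + 1L
        stack <- c(stack, m)
      }
    }
  }
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    while (i != j) {
      if (depth[i] >= depth[j]) {
        A[p, parent_edge[i]] <- 1
        i <- parent[i]
      } else {
        A[p, parent_edge[j]] <- 1
        j <- parent[j]
      }
    }
  }
  A
}

# Canonical encoding of an unrooted topology: sorted strings of the smaller
# side of every split. Used for deterministic tie-breaking.
topology_encoding <- function(edges, labels) {
  n <- length(labels)
  A <- path_indicator(edges, n)
  splits <- vapply(seq_len(nrow(edges)), function(e) {
    # leaves i with A[pair(1,i), e] == 1 are on the far side from leaf 1
    far <- c(FALSE, vapply(2:n, function(i) {
      p <- pair_index(1L, i, n)
      A[p, e] == 1
    }, logical(1)))
    side <- labels[if (sum(far) <= n - sum(far)) far else !far]
    paste(sort(side), collapse = ",")
  }, character(1))
  paste(sort(splits), collapse = "|")
}

pair_index <- function(i, j, n) {
  if (i > j) {
    tmp <- i
    i <- j
    j <- tmp
  }
  (i - 1L) * n - i * (i - 1L) / 2L + (j - i)
}

#' Rooted tree by exhaustive OLS minimum evolution
#'
#' Searches all unrooted binary topologies over the samples (exact for
#' n <= `exhaustive_max`), fits branch lengths to the distance matrix by
#' ordinary least squares, selects the topology minimizing the total fitted
#' tree length, and roots the result at `root_label` (the germline normal).
#' Ties on total length (beyond `1e-9`) are broken by the lexicographically
#' smallest topology encoding and flagged.
#'
#' Negative OLS branch lengths are retained in the fit and reported; a
#' zero-clamped copy is used for display/newick export.
#'
#' For n above `exhaustive_max` an agglomerative (neighbor-joining) starting
#' topology is OLS-fitted instead -- a documented approximation, enabled only
#' with `allow_heuristic = TRUE`.
#'
#' @param D symmetric distance matrix with dimnames (see
#'   [manhattan_distance()]).
#' @param root_label sample to root at (placed as outgroup).
#' @param exhaustive_max exhaustive-search size limit (default 8).
#' @param allow_heuristic permit the heuristic path for larger n.
#' @return a list of class `me_tree`: `tree` (rooted `ape::phylo`, fitted
#'   branch lengths), `tree_clamped` (branch lengths clamped at 0),
#'   `total_length`, `residual` (OLS sum of squares), `tied` (logical),
#'   `n_topologies`.
#' @export
ols_me_tree <- function(D, root_label, exhaustive_max = 8L, allow_heuristic = FALSE) {
  D <- as.matrix(D)
  labels <- rownames(D)
  n <- length(labels)
  stopifnot(n >= 3L, identical(labels, colnames(D)))
  if (!root_label %in% labels) stop("root label '", root_label, "' not in distance matrix")
  d <- D[t(utils::combn(n, 2))]
  if (n > exhaustive_max) {
    if (!allow_heuristic) {
      stop(
        "n = ", n, " exceeds exhaustive_max = ", exhaustive_max,
        "; set allow_heuristic = TRUE for an agglomerative starting tree"
      )
    }
    nj <- ape::unroot(ape::nj(D))
    edges <- nj$edge
    # relabel leaves to 1..n in `labels` order
    perm <- match(nj$tip.label, labels)
    leaf <- edges <= n
    edges[leaf] <- perm[edges[leaf]]
    topologies <- list(edges)
  } else {
    topologies <- enumerate_topologies(n)
  }
  best <- NULL
  tied <- FALSE
  for (edges in topologies) {
    A <- path_indicator(edges, n)
    fit <- stats::lm.fit(A, d)
    total <- sum(fit$coefficients)
    if (is.null(best) || total < best$total - 1e-9) {
      best <- list(edges = edges, lengths = fit$coefficients, total = total,
        residual = sum(fit$residuals^2))
      tied <- FALSE
    } else if (abs(total - best$total) <= 1e-9) {
      enc_new <- topology_encoding(edges, labels)
      enc_old <- topology_encoding(best$edges, labels)
      if (enc_new < enc_old) {
        best <- list(edges = edges, lengths = fit$coefficients, total = total,
          residual = sum(fit$residuals^2))
      }
      tied <- TRUE
    }
  }
  phy <- unrooted_phylo(best$edges, best$lengths, labels)
  rooted <- ape::root(phy, outgroup = root_label, resolve.root = TRUE)
  clamped <- rooted
  clamped$edge.length <- pmax(clamped$edge.length, 0)
  structure(
    list(
      tree = rooted, tree_clamped = clamped,
      total_length = best$total, residual = best$residual,
      tied = tied, n_topologies = length(topologies)
    ),
    class = "me_tree"
  )
}

#' @export
print.me_tree <- function(x, ...) {
  cat(sprintf(
    "<me_tree> %d leaves, total length %.4g, OLS residual %.4g (%d topologies searched%s)\n",
    length(x$tree$tip.label), x$total_length, x$residual, x$n_topologies,
    if (x$tied) ", tie broken deterministically" else ""
  ))
  invisible(x)
}

# Convert an edge matrix + OLS lengths into an ape phylo object, via a
# recursively emitted newick string (ape owns all subsequent tree handling).
unrooted_phylo <- function(edges, lengths, labels) {
  n <- length(labels)
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]
    v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  emit <- function(node, from) {
    nb <- adj[[node]]
    children <- nb[nb[, 1] != from, , drop = FALSE]
    if (node <= n) {
      return(labels[node])
    }
    parts <- vapply(seq_len(nrow(children)), function(k) {
      child <- children[k, 1]
      paste0(emit(child, node), ":", format(lengths[children[k, 2]], digits = 15))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n + 1L
  nb <- adj[[root]]
  parts <- vapply(seq_len(nrow(nb)), function(k) {
    paste0(emit(nb[k, 1], root), ":", format(lengths[nb[k, 2]], digits = 15))
  }, character(1))
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Assign mutations to tree edges by sample-presence pattern
#'
#' Groups variants by their tumor-sample presence pattern and maps each
#' pattern to the unique tree edge whose descendant (tumor) leaf set equals
#' the pattern. The pattern present in every tumor sample is the truncal
#' cluster. Patterns with no matching edge are homoplasy-flagged and assigned
#' to the minimal edge whose descendant set covers them.
#'
#' @param M a [mutation_matrix()].
#' @param fit an `me_tree` from [ols_me_tree()] (or a rooted `ape::phylo`).
#' @return list: `clusters` (data.frame pattern / n / edge label / truncal /
#'   homoplasy), `assignments` (per-variant data.frame), `edge_counts`
#'   (mutations per edge).
#' @export
assign_mutations <- function(M, fit) {
  stopifnot(inherits(M, "mutation_matrix"))
  phy <- if (inherits(fit, "me_tree")) fit$tree else fit
  if (!setequal(phy$tip.label, M$samples)) {
    stop("tree leaves and matrix samples differ")
  }
  tumors <- setdiff(M$samples, M$normal)
  calls <- M$calls[tumors, , drop = FALSE]
  pattern_of <- apply(calls, 2, paste, collapse = "")
  # descendant tumor-leaf set per edge
  n_tip <- length(phy$tip.label)
  desc <- descendant_tips(phy)
  edge_sets <- lapply(seq_len(nrow(phy$edge)), function(e) {
    tips <- phy$tip.label[desc[[phy$edge[e, 2]]]]
    sort(setdiff(tips, M$normal))
  })
  edge_label <- vapply(seq_len(nrow(phy$edge)), function(e) {
    child <- phy$edge[e, 2]
    if (child <= n_tip) {
      phy$tip.label[child]
    } else {
      paste0("clade{", paste(edge_sets[[e]], collapse = ","), "}")
    }
  }, character(1))
  edge_key <- vapply(edge_sets, paste, character(1), collapse = ",")
  patterns <- unique(pattern_of)
  rows <- lapply(patterns, function(p) {
    present <- sort(tumors[strsplit(p, "")[[1]] == "1"])
    if (!length(present)) {
      return(data.frame(
        pattern = p, n = sum(pattern_of == p), edge = NA_character_,
        truncal = FALSE, homoplasy = FALSE, stringsAsFactors = FALSE
      ))
    }
    key <- paste(present, collapse = ",")
    hit <- which(edge_key == key)
    # prefer the deepest matching edge (trunk edge and the root-side edge of
    # the full tumor clade share a descendant set when the normal is outgroup)
    if (length(hit)) {
      hit <- hit[which.max(lengths(edge_sets[hit]) - 0)] # deterministic
      return(data.frame(
        pattern = p, n = sum(pattern_of == p), edge = edge_label[hit],
        truncal = setequal(present, tumors), homoplasy = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    covering <- which(vapply(edge_sets, function(s) all(present %in% s), logical(1)))
    minimal <- covering[which.min(lengths(edge_sets[covering]))]
    data.frame(
      pattern = p, n = sum(pattern_of == p), edge = edge_label[minimal],
      truncal = FALSE, homoplasy = TRUE, stringsAsFactors = FALSE
    )
  })
  clusters <- do.call(rbind, rows)
  assignments <- data.frame(
    variant = M$variants,
    pattern = pattern_of,
    edge = clusters$edge[match(pattern_of, clusters$pattern)],
    homoplasy = clusters$homoplasy[match(pattern_of, clusters$pattern)],
    stringsAsFactors = FALSE
  )
  counts <- stats::aggregate(n ~ edge, data = clusters[!is.na(clusters$edge), ], FUN = sum)
  list(
    clusters = clusters, assignments = assignments,
    edge_counts = stats::setNames(counts$n, counts$edge),
    tumor_order = tumors
  )
}

# list of descendant tip indices per node (tips included)
descendant_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_nodes <- n_tip + phy$Nnode
  desc <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- phy$edge[order(phy$edge[, 1], decreasing = TRUE), , drop = FALSE]
  # postorder accumulation: children have higher numbers than... not
  # guaranteed, iterate until fixed point (trees are tiny)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]
      child <- edges[e, 2]
      if (is.null(desc[[child]])) next
      merged <- sort(unique(c(desc[[parent]], desc[[child]])))
      if (!identical(merged, desc[[parent]])) {
        desc[[parent]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  desc
}

#' Write a fitted tree as newick
#'
#' @param fit an `me_tree` from [ols_me_tree()].
#' @param path output file.
#' @param clamp write zero-clamped branch lengths (default `TRUE`); the
#'   unclamped OLS fit may contain small negative lengths.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(fit, path, clamp = TRUE) {
  phy <- if (clamp) fit$tree_clamped else fit$tree
  ape::write.tree(phy, file = path)
  invisible(path)
}
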