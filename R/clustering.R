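#' Minkowski distance matrix over summary vectors
#'
#' Pairwise distances `d(u, v) = (sum_k |u_k - v_k|^p)^(1/p)` over the six
#' components of the lifetime summary vectors. The default `p = 1`
#' (Manhattan) is the order used to compare experimental conditions; the
#' resulting heights are then in nanoseconds.
#'
#' @param vectors numeric matrix with one summary vector per row (rownames
#'   become leaf labels), or a list of [summary_vector()]s.
#' @param p Minkowski order, >= 1.
#' @return a [stats::dist] object with labels.
#' @export
minkowski_distance_matrix <- function(vectors, p = 1) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need >= 2 vectors", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1 || p < 1) {
    stop("`p` must be a single number >= 1", call. = FALSE)
  }
  dist(vectors, method = "minkowski", p = p)
}

as_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12 * (1 + max(abs(m))))) {
    stop("distance input must be a symmetric matrix or dist", call. = FALSE)
  }
  if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(diag(m) != 0)) stop("distance diagonal must be zero", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  m
}

#' Ward.D2 agglomerative clustering
#'
#' Agglomerates leaves by the Ward criterion applied to squared
#' dissimilarities via the Lance-Williams recurrence
#' `d2(uv, w) = ((n_u + n_w) d2(u, w) + (n_v + n_w) d2(v, w)
#'   - n_w d2(u, v)) / (n_u + n_v + n_w)`,
#' reporting merge heights on the square-root scale (the Ward.D2
#' convention, so heights keep the units of the input distances). At each
#' step the pair with the smallest squared distance is merged; exact cost
#' ties are broken deterministically toward the pair whose smallest
#' original leaf indices are lexicographically least.
#'
#' @param d a [stats::dist] object or symmetric non-negative matrix with
#'   zero diagonal.
#' @return object of class `lifetime_dendrogram`: a list with `merge`
#'   (hclust-coded merge table), `height` (non-decreasing, in input
#'   units), `labels`, and `order` (leaf display order, lower-index
#'   subtree first).
#' @seealso [cophenetic_matrix()], [export_newick()],
#'   [as.hclust.lifetime_dendrogram()]
#' @export
ward_d2_linkage <- function(d) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 leaves", call. = FALSE)
  labels <- rownames(m)
  D2 <- m^2
  active <- seq_len(n)          # column indices into D2 still live
  id <- -seq_len(n)             # hclust codes of live clusters
  size <- rep(1L, n)
  minorig <- seq_len(n)         # smallest original leaf index per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; best_val <- Inf; best_key <- c(Inf, Inf)
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        v <- D2[active[i], active[j]]
        key <- sort(c(minorig[i], minorig[j]))
        if (v < best_val - 1e-15 * (1 + abs(best_val)) ||
            (abs(v - best_val) <= 1e-15 * (1 + abs(best_val)) &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(i, j); best_val <- v; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    pair <- sort(c(id[i], id[j]))
    # hclust convention: singletons (negative codes) first
    merge[step, ] <- if (pair[1] < 0) pair else sort(c(id[i], id[j]))
    height[step] <- sqrt(max(best_val, 0))
    ai <- active[i]; aj <- active[j]
    nu <- size[i]; nv <- size[j]
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      al <- active[l]; nw <- size[l]
      newd <- ((nu + nw) * D2[ai, al] + (nv + nw) * D2[aj, al] -
                 nw * best_val) / (nu + nv + nw)
      D2[ai, al] <- D2[al, ai] <- newd
    }
    id[i] <- step
    size[i] <- nu + nv
    minorig[i] <- min(minorig[i], minorig[j])
    active <- active[-j]; id <- id[-j]; size <- size[-j]
    minorig <- minorig[-j]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = dendrogram_order(merge, minorig_rule = TRUE),
                 method = "ward.D2"),
            class = "lifetime_dendrogram")
}

# Leaf display order: recursive, subtree containing the smaller original
# leaf index first. Cosmetic only.
dendrogram_order <- function(merge, minorig_rule = TRUE) {
  n <- nrow(merge) + 1
  leaves <- function(k) {
    if (k < 0) return(-k)
    unlist(lapply(merge[k, ], leaves))
  }
  expand <- function(k) {
    if (k < 0) return(-k)
    a <- merge[k, 1]; b <- merge[k, 2]
    if (min(leaves(a)) > min(leaves(b))) { tmp <- a; a <- b; b <- tmp }
    c(expand(a), expand(b))
  }
  expand(n - 1)
}

#' @export
print.lifetime_dendrogram <- function(x, ...) {
  cat("lifetime_dendrogram (", x$method, "): ", length(x$labels),
      " leaves, root height ", format(max(x$height)), "\n", sep = "")
  invisible(x)
}

#' Convert a lifetime dendrogram to an hclust object
#'
#' @param x a `lifetime_dendrogram`.
#' @param ... unused.
#' @return a [stats::hclust] object (for plotting, `cutree`, etc.).
#' @export
as.hclust.lifetime_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "minkowski"),
            class = "hclust")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the height of the lowest merge that joins leaves i and
#' j; the matrix is ultrametric (for any triple, the largest two of the
#' three pairwise values are equal).
#'
#' @param dendrogram a `lifetime_dendrogram` from [ward_d2_linkage()].
#' @return symmetric numeric matrix with zero diagonal, labelled like the
#'   dendrogram leaves.
#' @export
cophenetic_matrix <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "lifetime_dendrogram"))
  n <- nrow(dendrogram$merge) + 1
  cm <- matrix(0, n, n, dimnames = list(dendrogram$labels, dendrogram$labels))
  members <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    side <- lapply(dendrogram$merge[k, ], function(code) {
      if (code < 0) -code else members[[code]]
    })
    cm[side[[1]], side[[2]]] <- dendrogram$height[k]
    cm[side[[2]], side[[1]]] <- dendrogram$height[k]
    members[[k]] <- c(side[[1]], side[[2]])
  }
  cm
}

#' Summary vectors for each condition cell of a dataset
#'
#' Helper producing the clustering feature matrix: one six-number
#' [summary_vector()] per combination of the grouping factors, labelled
#' e.g. `"0%_5min_in"`.
#'
#' @param dataset a [lifetime_dataset()].
#' @param by character vector of grouping columns among `regime`,
#'   `time_post_admin`, `location`.
#' @param location_filter optional `"in"`/`"out"` pre-filter.
#' @return numeric matrix, rows = condition cells present in the dataset.
#' @export
condition_summary_vectors <- function(dataset,
                                      by = c("regime", "time_post_admin",
                                             "location"),
                                      location_filter = NULL) {
  stopifnot(inherits(dataset, "lifetime_dataset"))
  by <- match.arg(by, c("regime", "time_post_admin", "location"),
                  several.ok = TRUE)
  if (!is.null(location_filter)) {
    dataset <- dataset[dataset$location == location_filter, , drop = FALSE]
  }
  if (nrow(dataset) == 0) stop("no records in scope", call. = FALSE)
  fmt <- list(regime = function(v) paste0(v, "%"),
              time_post_admin = function(v) paste0(v, "min"),
              location = identity)
  key <- interaction(dataset[by], drop = TRUE, lex.order = TRUE)
  groups <- split(dataset$tau, key)
  labs <- vapply(strsplit(names(groups), ".", fixed = TRUE), function(parts) {
    paste(mapply(function(f, v) f(v), fmt[by], parts), collapse = "_")
  }, character(1))
  out <- t(vapply(groups, summary_vector, numeric(6)))
  rownames(out) <- labs
  out
}

#' Per-level dendrograms over data subsets
#'
#' Splits the dataset by one factor (oxygen regime or administration time),
#' and for each level builds a Ward.D2 dendrogram over the summary vectors
#' of the *other* factor's levels (e.g. grouping by regime yields, per
#' regime, a dendrogram whose leaves are the administration times). Levels
#' whose subset is empty, or leaves fewer than two leaf cells, are skipped
#' with a warning.
#'
#' @param dataset a [lifetime_dataset()].
#' @param group_by `"regime"` or `"time_post_admin"`.
#' @param location_filter `"in"` or `"out"`.
#' @param p Minkowski order for the leaf distances.
#' @return named list of `lifetime_dendrogram`s (one per factor level).
#' @export
subset_dendrograms <- function(dataset,
                               group_by = c("regime", "time_post_admin"),
                               location_filter = c("in", "out"), p = 1) {
  stopifnot(inherits(dataset, "lifetime_dataset"))
  group_by <- match.arg(group_by)
  location_filter <- match.arg(location_filter)
  leaf_by <- setdiff(c("regime", "time_post_admin"), group_by)
  lvls <- levels(dataset[[group_by]])
  out <- list()
  for (lv in lvls) {
    sub <- dataset[dataset[[group_by]] == lv &
                     dataset$location == location_filter, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("empty subset for ", group_by, " = ", lv, "; skipped",
              call. = FALSE)
      next
    }
    vecs <- condition_summary_vectors(sub, by = leaf_by)
    if (nrow(vecs) < 2) {
      warning("fewer than 2 leaf cells for ", group_by, " = ", lv,
              "; skipped", call. = FALSE)
      next
    }
    out[[paste0(lv, if (group_by == "regime") "%" else "min")]] <-
      ward_d2_linkage(minkowski_distance_matrix(vecs, p = p))
  }
  out
}

quote_newick_label <- function(x) {
  needs <- grepl("[] ():;,'[]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Export a dendrogram as a Newick string
#'
#' Writes an ultrametric Newick tree in which each internal node sits at
#' half its merge height, so two leaves joined at height `h` read
#' `(A:h/2,B:h/2);` and the cophenetic distance is twice the depth to the
#' lowest common ancestor. Labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param dendrogram a `lifetime_dendrogram`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string (terminated by `;`).
#' @export
export_newick <- function(dendrogram, digits = 12) {
  stopifnot(inherits(dendrogram, "lifetime_dendrogram"))
  lab <- quote_newick_label(dendrogram$labels)
  fmt <- function(x) sprintf("%.*g", digits, x)
  node <- function(code, parent_h) {
    if (code < 0) {
      return(paste0(lab[-code], ":", fmt(parent_h / 2)))
    }
    h <- dendrogram$height[code]
    kids <- vapply(dendrogram$merge[code, ], node, character(1), parent_h = h)
    paste0("(", paste(kids, collapse = ","), "):", fmt((parent_h - h) / 2))
  }
  root <- nrow(dendrogram$merge)
  h <- dendrogram$height[root]
  kids <- vapply(dendrogram$merge[root, ], node, character(1), parent_h = h)
  paste0("(", paste(kids, collapse = ","), ");")
}

#' Write a dendrogram merge table as JSON
#'
#' Serialises `merges` (1-based leaf/merge codes as in the hclust
#' convention), `heights` and `labels`.
#'
#' @param dendrogram a `lifetime_dendrogram`.
#' @param path output path.
#' @export
write_dendrogram_json <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "lifetime_dendrogram"))
  jsonlite::write_json(
    list(merges = unclass(dendrogram$merge),
         heights = dendrogram$height,
         labels = dendrogram$labels),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a labelled distance matrix as delimited text
#'
#' @param d a `dist` or symmetric matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as_distance_matrix(d)
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
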