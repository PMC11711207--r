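#' Node degree of an edge mask
#'
#' Degree = number of mask edges incident to each node. Summed over nodes,
#' degrees equal twice the mask size.
#'
#' @param x A logical edge mask (canonical order) or a `cpm_model` (both
#'   signs are summarized).
#' @param n_nodes Node count; inferred from the mask length when omitted.
#' @return For a mask: tibble with `node`, `degree`. For a model: long tibble
#'   with `node`, `sign`, `degree`.
#' @export
node_degree <- function(x, n_nodes = NULL) {
  if (inherits(x, "cpm_model")) {
    nn <- if (is.null(n_nodes)) x$n_nodes else n_nodes
    if (is.na(nn)) abort("cannot infer node count from the model")
    return(bind_rows(
      node_degree(x$positive, nn) %>% mutate(sign = "positive"),
      node_degree(x$negative, nn) %>% mutate(sign = "negative")
    ) %>% select("node", "sign", "degree"))
  }
  if (!is.logical(x)) abort("expected a logical mask or cpm_model")
  if (is.null(n_nodes)) n_nodes <- nodes_from_edges(length(x))
  if (length(x) != n_edges(n_nodes)) abort("mask length does not match node count")
  pairs <- edge_index(n_nodes)
  idx <- which(x)
  tibble(
    node = seq_len(n_nodes),
    degree = tabulate(c(pairs$node_i[idx], pairs$node_j[idx]), nbins = n_nodes)
  )
}

#' Count mask edges within and between labelled networks
#'
#' Cross-tabulates the mask's edges by the network labels of their endpoint
#' nodes (e.g. the 10 WASHU networks). Cell (A, B) counts edges with one
#' endpoint in A and the other in B; the diagonal holds within-network counts.
#' Nodes without an assignment are tracked as their own `"unassigned"` row and
#' column. The upper triangle plus diagonal sums to the mask size.
#'
#' @param mask Logical edge mask in canonical order.
#' @param labels Character vector of network names, one per node (use
#'   `"unassigned"` for unlabelled nodes), or a data frame with `node_id` and
#'   `network` columns (see [read_network_labels()]).
#' @return Symmetric integer matrix with network names as dimnames.
#' @export
network_pair_counts <- function(mask, labels) {
  if (!is.logical(mask)) abort("mask must be logical")
  if (is.data.frame(labels)) {
    if (!all(c("node_id", "network") %in% names(labels))) {
      abort("label table needs node_id and network columns")
    }
    labels <- labels$network[order(labels$node_id)]
  }
  labels[is.na(labels) | labels == ""] <- "unassigned"
  n_nodes <- length(labels)
  if (length(mask) != n_edges(n_nodes)) {
    abort(sprintf(
      "mask implies %d nodes but %d labels were supplied (unknown node in mask)",
      nodes_from_edges(length(mask)), n_nodes
    ))
  }
  nets <- sort(unique(labels))
  f <- factor(labels, levels = nets)
  pairs <- edge_index(n_nodes)
  idx <- which(mask)
  m <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  if (length(idx) > 0) {
    a <- as.integer(f[pairs$node_i[idx]])
    b <- as.integer(f[pairs$node_j[idx]])
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    tab <- table(factor(lo, levels = seq_along(nets)),
                 factor(hi, levels = seq_along(nets)))
    upper <- matrix(as.integer(tab), length(nets), length(nets))
    m <- upper + t(upper)
    diag(m) <- diag(upper)
    dimnames(m) <- list(nets, nets)
  }
  m
}

#' Export a model's masks as a viewer-compatible edge list
#'
#' Writes a TSV with columns `node_i`, `node_j`, `sign`, `weight` (always 1)
#' in canonical edge order — a plain interchange format in place of surface
#' or connectogram rendering. [read_edge_list()] reproduces the masks exactly.
#'
#' @param x A `cpm_model` (both signs) or a logical mask.
#' @param path Output TSV path.
#' @param sign Sign tag used when `x` is a bare mask (default `"positive"`).
#' @param n_nodes Node count for a bare mask; inferred when possible.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(x, path, sign = "positive", n_nodes = NULL) {
  if (inherits(x, "cpm_model")) {
    nn <- if (is.null(n_nodes)) x$n_nodes else n_nodes
    if (is.na(nn)) abort("cannot infer node count from the model")
    pairs <- edge_index(nn)
    rows <- bind_rows(
      pairs[x$positive, ] %>% mutate(sign = "positive"),
      pairs[x$negative, ] %>% mutate(sign = "negative")
    )
  } else {
    if (is.null(n_nodes)) n_nodes <- nodes_from_edges(length(x))
    pairs <- edge_index(n_nodes)
    rows <- pairs[x, ] %>% mutate(sign = sign)
  }
  rows <- rows %>%
    arrange(.data$edge) %>%
    transmute(.data$node_i, .data$node_j, .data$sign, weight = 1)
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read an edge list back into logical masks
#'
#' @param path TSV written by [write_edge_list()].
#' @param n_nodes Node count of the edge space.
#' @return List with logical masks `positive` and `negative`.
#' @export
read_edge_list <- function(path, n_nodes) {
  el <- readr::read_tsv(path, show_col_types = FALSE)
  pairs <- edge_index(n_nodes)
  E <- n_edges(n_nodes)
  key <- function(i, j) (pmin(i, j) - 1) * n_nodes + pmax(i, j)
  lookup <- setNames(pairs$edge, key(pairs$node_i, pairs$node_j))
  out <- list(positive = logical(E), negative = logical(E))
  if (nrow(el) > 0) {
    if (any(el$node_i > n_nodes | el$node_j > n_nodes)) {
      abort("edge list references nodes beyond n_nodes")
    }
    idx <- lookup[as.character(key(el$node_i, el$node_j))]
    for (s in c("positive", "negative")) {
      out[[s]][idx[el$sign == s]] <- TRUE
    }
  }
  out
}

#' Read a node-to-network label table
#'
#' @param path CSV with columns `node_id`, `network` and optionally MNI
#'   coordinates `x`, `y`, `z`.
#' @return Tibble sorted by `node_id`, with empty/missing networks set to
#'   `"unassigned"`.
#' @export
read_network_labels <- function(path) {
  lab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("node_id", "network") %in% names(lab))) {
    abort("label file needs node_id and network columns")
  }
  lab$network[is.na(lab$network) | lab$network == ""] <- "unassigned"
  lab %>% arrange(.data$node_id)
}
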