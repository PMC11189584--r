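#' Hypergraphs and simplicial complexes as interaction tensors
#'
#' A `hyper_structure` stores the connectivity of a system of `n_nodes`
#' coupled units as a set of weighted hyperedges, one coefficient
#' `a^(d)_[i; j1..jd]` per stored entry: the strength with which the group of
#' nodes `(j1, ..., jd)` acts on the focal node `i`. Order `d = 1` entries
#' form the ordinary adjacency matrix; order `d = 2` entries are three-body
#' interactions, and so on up to `max_order`.
#'
#' Entries with the focal node repeated among the neighbors, or with repeated
#' neighbors, are disallowed: such terms reduce to a lower-order tensor.
#' Under the `"unordered"` convention (interaction invariant under
#' permutation of the neighbors, as in product-form couplings) each neighbor
#' tuple is stored once, sorted strictly increasing; under `"ordered"` the
#' full tuple is meaningful. `directed = FALSE` declares that cross-node
#' symmetry (`a^(1)_[i;j] == a^(1)_[j;i]` and its higher-order analogues)
#' holds; it is validated at construction.
#'
#' @param n_nodes number of nodes `N` (>= 2).
#' @param max_order largest interaction order `D` (group size minus one).
#' @param entries `data.frame` with columns `order`, `node` (focal node),
#'   `n1`, ..., `nD` (neighbor indices, `NA` beyond the entry's order) and
#'   `weight`. `NULL` means an empty structure.
#' @param convention `"unordered"` or `"ordered"` neighbor tuples.
#' @param directed logical; `FALSE` asserts cross-node symmetry.
#' @return An object of class `hyper_structure`.
#' @seealso [count_unknowns()], [flatten()], [build_karate_complex()],
#'   [build_lv_hypergraph()]
#' @examples
#' e <- data.frame(order = 1, node = 1, n1 = 2, weight = 0.5)
#' hyper_structure(2, 1, e)
#' @export
hyper_structure <- function(n_nodes, max_order = 1L, entries = NULL,
                            convention = c("unordered", "ordered"),
                            directed = TRUE) {
  convention <- match.arg(convention)
  n_nodes <- as.integer(n_nodes)
  max_order <- as.integer(max_order)
  if (n_nodes < 2L) stop("`n_nodes` must be at least 2", call. = FALSE)
  if (max_order < 1L || max_order >= n_nodes) {
    stop("`max_order` must satisfy 1 <= max_order <= n_nodes - 1", call. = FALSE)
  }
  entries <- normalize_entries(entries, n_nodes, max_order, convention)
  hs <- structure(
    list(n_nodes = n_nodes, max_order = max_order, entries = entries,
         convention = convention, directed = !isFALSE(directed)),
    class = "hyper_structure"
  )
  if (isFALSE(directed)) {
    hs$directed <- FALSE
    asym <- structure_asymmetry(hs)
    if (asym > 1e-12) {
      stop(sprintf(
        "undirected structure violates cross-node symmetry (max asymmetry %.3g)",
        asym), call. = FALSE)
    }
  }
  hs
}

neighbor_cols <- function(max_order) paste0("n", seq_len(max_order))

empty_entries <- function(max_order) {
  cols <- c(list(order = integer(), node = integer()),
            stats::setNames(rep(list(integer()), max_order),
                            neighbor_cols(max_order)),
            list(weight = numeric()))
  as.data.frame(cols)
}

normalize_entries <- function(entries, n_nodes, max_order, convention) {
  if (is.null(entries) || nrow(entries) == 0L) {
    return(empty_entries(max_order))
  }
  entries <- as.data.frame(entries)
  ncols <- neighbor_cols(max_order)
  missing_n <- setdiff(ncols, names(entries))
  for (nm in missing_n) entries[[nm]] <- NA_integer_
  req <- c("order", "node", ncols, "weight")
  if (!all(c("order", "node", "weight") %in% names(entries))) {
    stop("entries must have columns `order`, `node`, neighbor columns and `weight`",
         call. = FALSE)
  }
  entries <- entries[, req]
  entries$order <- as.integer(entries$order)
  entries$node <- as.integer(entries$node)
  for (nm in ncols) entries[[nm]] <- as.integer(entries[[nm]])
  entries$weight <- as.numeric(entries$weight)

  if (any(entries$order < 1L) || any(entries$order > max_order)) {
    stop("entry `order` outside [1, max_order]", call. = FALSE)
  }
  if (any(!is.finite(entries$weight))) stop("non-finite weights", call. = FALSE)
  for (r in seq_len(nrow(entries))) {
    d <- entries$order[r]
    nb <- as.integer(entries[r, ncols[seq_len(d)]])
    if (anyNA(nb) || (max_order > d && !all(is.na(entries[r, ncols[-seq_len(d)]])))) {
      stop(sprintf("entry %d: neighbor columns inconsistent with its order", r),
           call. = FALSE)
    }
    idx <- c(entries$node[r], nb)
    if (any(idx < 1L) || any(idx > n_nodes)) {
      stop(sprintf("entry %d: node index outside [1, n_nodes]", r), call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop(sprintf("entry %d: repeated node index (such components vanish)", r),
           call. = FALSE)
    }
    if (convention == "unordered" && d > 1L && any(diff(nb) <= 0L)) {
      stop(sprintf("entry %d: unordered neighbor tuples must be strictly increasing", r),
           call. = FALSE)
    }
  }
  keys <- entry_keys(entries, max_order)
  if (anyDuplicated(keys)) stop("duplicate hyperedge entries", call. = FALSE)
  rownames(entries) <- NULL
  entries
}

entry_keys <- function(entries, max_order) {
  ncols <- neighbor_cols(max_order)
  nb <- do.call(paste, c(lapply(ncols, function(nm) entries[[nm]]), sep = ","))
  paste0("d", entries$order, ":", entries$node, "<-", nb)
}

# largest within-group weight spread over focal-node rotations of each hyperedge
structure_asymmetry <- function(hs) {
  e <- hs$entries
  if (nrow(e) == 0L) return(0)
  ncols <- neighbor_cols(hs$max_order)
  grp <- vapply(seq_len(nrow(e)), function(r) {
    d <- e$order[r]
    members <- sort(c(e$node[r], as.integer(e[r, ncols[seq_len(d)]])))
    paste0("d", d, ":", paste(members, collapse = ","))
  }, character(1))
  spread <- tapply(e$weight, grp, function(w) max(w) - min(w))
  max(spread)
}

#' @export
print.hyper_structure <- function(x, ...) {
  per_order <- vapply(seq_len(x$max_order),
                      function(d) sum(x$entries$order == d), integer(1))
  cat(sprintf("<hyper_structure> %d nodes, max order %d, %s, %s\n",
              x$n_nodes, x$max_order, x$convention,
              if (x$directed) "directed" else "undirected"))
  cat("  entries per order:",
      paste(sprintf("d=%d: %d", seq_along(per_order), per_order), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of unknown interaction coefficients per node
#'
#' For a system of `N` nodes with interactions up to order `D`, each node's
#' coefficient vector has `H` entries: `sum_d choose(N-1, d)` when neighbor
#' tuples are unordered (permutation-invariant couplings) or
#' `sum_d (N-1)(N-2)...(N-d)` when ordered tuples are distinct unknowns.
#'
#' @param n_nodes number of nodes `N` (>= 2).
#' @param max_order maximum interaction order `D`, with `D <= N - 1`.
#' @param convention `"unordered"` or `"ordered"`.
#' @return Integer-valued count `H`.
#' @examples
#' count_unknowns(7, 2, "unordered")  # 6 + 15 = 21
#' count_unknowns(34, 2, "unordered") # 33 + 528 = 561
#' @export
count_unknowns <- function(n_nodes, max_order,
                           convention = c("unordered", "ordered")) {
  convention <- match.arg(convention)
  n_nodes <- as.integer(n_nodes)
  max_order <- as.integer(max_order)
  if (n_nodes < 2L) stop("`n_nodes` must be at least 2", call. = FALSE)
  if (max_order < 1L || max_order >= n_nodes) {
    stop("`max_order` must satisfy 1 <= max_order <= n_nodes - 1", call. = FALSE)
  }
  d <- seq_len(max_order)
  h <- if (convention == "unordered") {
    sum(choose(n_nodes - 1L, d))
  } else {
    sum(vapply(d, function(dd) prod(n_nodes - 1L - seq_len(dd) + 1L), numeric(1)))
  }
  as.integer(round(h))
}

# all ordered d-tuples of distinct elements of v, lexicographic
ordered_tuples <- function(v, d) {
  if (d == 1L) return(matrix(v, ncol = 1L))
  out <- NULL
  for (x in v) {
    sub <- ordered_tuples(setdiff(v, x), d - 1L)
    out <- rbind(out, cbind(x, sub))
  }
  unname(out)
}

#' Column layout of a node's coefficient vector
#'
#' Returns the ordered list of hyperedge slots making up the coefficient
#' vector of `node`: first all order-1 neighbors in ascending order (skipping
#' the focal node), then order-2 tuples in lexicographic order, and so on up
#' to `max_order`. This layout is part of the public contract: design-matrix
#' columns, [flatten()] output and fitted coefficient vectors all use it.
#'
#' @inheritParams count_unknowns
#' @param node focal node index.
#' @return `data.frame` with columns `order`, `n1`, ..., `nD` and `label`,
#'   one row per coefficient, `count_unknowns()` rows in total.
#' @export
column_index <- function(n_nodes, max_order, node,
                         convention = c("unordered", "ordered")) {
  convention <- match.arg(convention)
  others <- setdiff(seq_len(n_nodes), node)
  ncols <- neighbor_cols(max_order)
  blocks <- lapply(seq_len(max_order), function(d) {
    tuples <- if (convention == "unordered") {
      if (length(others) < d) {
        matrix(integer(), 0, d)
      } else if (length(others) == d) {
        matrix(others, 1, d)  # combn() would misread a scalar as a count
      } else {
        t(utils::combn(others, d))
      }
    } else {
      ordered_tuples(others, d)
    }
    blk <- as.data.frame(matrix(NA_integer_, nrow(tuples), max_order,
                                dimnames = list(NULL, ncols)))
    if (nrow(tuples)) blk[, seq_len(d)] <- tuples
    cbind(data.frame(order = rep(d, nrow(tuples))), blk)
  })
  out <- do.call(rbind, blocks)
  for (nm in ncols) out[[nm]] <- as.integer(out[[nm]])
  lab_nb <- vapply(seq_len(nrow(out)), function(r) {
    d <- out$order[r]
    paste(out[r, ncols[seq_len(d)]], collapse = ",")
  }, character(1))
  out$label <- paste0("d", out$order, ":", lab_nb)
  rownames(out) <- NULL
  out
}

#' Flatten a node's interactions to a coefficient vector (and back)
#'
#' `flatten()` extracts the coefficient vector of one focal node from a
#' structure, in [column_index()] order, with absent hyperedges appearing as
#' explicit zeros. `unflatten()` inverts the operation, turning a coefficient
#' vector back into an entry table (zero coefficients are dropped). The two
#' are mutual inverses.
#'
#' @param structure a [hyper_structure()].
#' @param node focal node index.
#' @return `flatten()`: a named numeric vector of length `count_unknowns()`.
#' @examples
#' hs <- build_lv_hypergraph(seed = 1)
#' v <- flatten(hs, 2)
#' v["d2:3,7"]  # printed three-body coupling on species 2
#' @export
flatten <- function(structure, node) {
  stopifnot(inherits(structure, "hyper_structure"))
  ci <- column_index(structure$n_nodes, structure$max_order, node,
                     structure$convention)
  vals <- stats::setNames(numeric(nrow(ci)), ci$label)
  e <- structure$entries
  e <- e[e$node == node, , drop = FALSE]
  if (nrow(e)) {
    keys <- sub("^d(\\d+):\\d+<-", "d\\1:", entry_keys(e, structure$max_order))
    keys <- gsub(",NA", "", keys)
    pos <- match(keys, ci$label)
    if (anyNA(pos)) stop("entry not representable in the column layout", call. = FALSE)
    vals[pos] <- e$weight
  }
  vals
}

#' @rdname flatten
#' @param values numeric coefficient vector in [column_index()] order.
#' @inheritParams count_unknowns
#' @param drop_zero drop exactly-zero coefficients from the entry table.
#' @return `unflatten()`: an entry `data.frame` suitable for
#'   [hyper_structure()].
#' @export
unflatten <- function(values, node, n_nodes, max_order,
                      convention = c("unordered", "ordered"),
                      drop_zero = TRUE) {
  convention <- match.arg(convention)
  ci <- column_index(n_nodes, max_order, node, convention)
  if (length(values) != nrow(ci)) {
    stop(sprintf("`values` has length %d; expected H = %d",
                 length(values), nrow(ci)), call. = FALSE)
  }
  keep <- if (drop_zero) values != 0 else rep(TRUE, length(values))
  out <- ci[keep, setdiff(names(ci), "label"), drop = FALSE]
  out <- cbind(order = out$order, node = rep(node, nrow(out)),
               out[, neighbor_cols(max_order), drop = FALSE],
               weight = as.numeric(values[keep]))
  rownames(out) <- NULL
  out
}

#' Bundled Zachary karate-club edge list
#'
#' The canonical 34-node, 78-edge undirected friendship network, shipped as a
#' plain-text fixture and used as the pairwise backbone of the coupled
#' Rossler-oscillator case study.
#'
#' @return `data.frame` with columns `from`, `to` (1-based, `from < to`).
#' @export
karate_club_edges <- function() {
  path <- system.file("extdata", "zachary_karate_edges.tsv", package = "hordyn")
  if (path == "") stop("bundled karate edge list not found", call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Brute-force triangle census of an undirected edge list
#'
#' Enumerates all node triples and returns those whose three edges are all
#' present. Intended for moderate `n_nodes` (the enumeration is cubic).
#'
#' @param edges `data.frame` with columns `from`, `to` (1-based).
#' @param n_nodes number of nodes.
#' @return Integer matrix with one row per triangle, columns `i < j < k`.
#' @export
triangle_census <- function(edges, n_nodes) {
  a <- matrix(FALSE, n_nodes, n_nodes)
  a[cbind(edges$from, edges$to)] <- TRUE
  a[cbind(edges$to, edges$from)] <- TRUE
  tri <- list()
  for (i in seq_len(n_nodes - 2L)) {
    for (j in seq.int(i + 1L, n_nodes - 1L)) {
      if (!a[i, j]) next
      ks <- seq.int(j + 1L, n_nodes)
      hit <- ks[a[i, ks] & a[j, ks]]
      for (k in hit) tri[[length(tri) + 1L]] <- c(i, j, k)
    }
  }
  out <- if (length(tri)) do.call(rbind, tri) else matrix(integer(), 0, 3)
  colnames(out) <- c("i", "j", "k")
  out
}

#' Karate-club simplicial complex with promoted triangles
#'
#' Builds the undirected simplicial complex used in the coupled-oscillator
#' case study: all 78 links of the karate-club graph as order-1 entries
#' (weight 1, both directions) and a randomly chosen fraction `delta` of its
#' 45 triangles promoted to 2-simplices (order-2 entries of weight 1, one per
#' focal node of each promoted triangle). Because promoted triangles are
#' triangles of the graph, simplicial closure holds by construction. The
#' number promoted is `delta * 45` rounded half-up.
#'
#' @param delta fraction of triangles promoted, in `[0, 1]`.
#' @param seed optional RNG seed for the triangle draw.
#' @return An undirected, unweighted [hyper_structure()] with `max_order = 2`.
#' @examples
#' hs <- build_karate_complex(1)
#' sum(hs$entries$order == 2) / 3  # 45 two-simplices
#' @export
build_karate_complex <- function(delta = 1, seed = NULL) {
  stop_if_not_scalar_number(delta, "delta")
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  edges <- karate_club_edges()
  n <- 34L
  tri <- triangle_census(edges, n)
  n_promote <- round_half_up(delta * nrow(tri))
  pick <- with_seed(seed, sample.int(nrow(tri), n_promote))
  e1 <- data.frame(order = 1L,
                   node = c(edges$from, edges$to),
                   n1 = c(edges$to, edges$from),
                   n2 = NA_integer_, weight = 1)
  e2 <- empty_entries(2L)
  if (n_promote > 0L) {
    t2 <- tri[pick, , drop = FALSE]
    e2 <- data.frame(
      order = 2L,
      node = c(t2[, 1], t2[, 2], t2[, 3]),
      n1 = c(t2[, 2], t2[, 1], t2[, 1]),
      n2 = c(t2[, 3], t2[, 3], t2[, 2]),
      weight = 1)
  }
  hyper_structure(n, 2L, rbind(e1, e2), convention = "unordered",
                  directed = FALSE)
}

# Fixed 8-arrow pairwise topology of the 7-species ecosystem fixture:
# influence of column `from` on column `on`; `sign` +1 cooperative,
# -1 antagonistic. An approximate repo constant (the reference ecosystem's
# weights are not available); magnitudes are drawn at build time.
lv_pairwise_topology <- function() {
  data.frame(
    on   = c(2L, 2L, 4L, 4L, 1L, 3L, 5L, 6L),
    from = c(3L, 7L, 1L, 6L, 5L, 6L, 7L, 2L),
    sign = c(1, 1, 1, 1, -1, -1, -1, -1)
  )
}

#' Seven-species Lotka-Volterra hypergraph fixture
#'
#' The weighted directed hypergraph of the microbial-ecosystem case study:
#' eight pairwise interactions (four cooperative, positive; four
#' antagonistic, negative) and exactly two cooperative three-body
#' interactions, `a^(2)_[2; 3,7] = 0.0062` and `a^(2)_[4; 1,6] = 0.0016`.
#' The pairwise topology is a fixed, approximate repo constant and the
#' pairwise magnitudes are sampled uniformly in `(0, weight_scale]` (the
#' reference ecosystem's weights are not available); the two three-body
#' weights are the case study's reference values.
#'
#' @param weight_scale upper bound of the sampled pairwise magnitudes;
#'   default `0.01`, the order of magnitude of the three-body weights.
#' @param seed optional RNG seed for the magnitude draw.
#' @return A directed weighted [hyper_structure()] on 7 nodes, `max_order = 2`.
#' @examples
#' hs <- build_lv_hypergraph(seed = 1)
#' subset(hs$entries, order == 2)
#' @export
build_lv_hypergraph <- function(weight_scale = 0.01, seed = NULL) {
  stop_if_not_scalar_number(weight_scale, "weight_scale")
  if (weight_scale <= 0) stop("`weight_scale` must be positive", call. = FALSE)
  topo <- lv_pairwise_topology()
  mag <- with_seed(seed, stats::runif(nrow(topo), 0, weight_scale))
  e1 <- data.frame(order = 1L, node = topo$on, n1 = topo$from,
                   n2 = NA_integer_, weight = topo$sign * mag)
  e2 <- data.frame(order = 2L, node = c(2L, 4L), n1 = c(3L, 1L),
                   n2 = c(7L, 6L), weight = c(0.0062, 0.0016))
  hyper_structure(7L, 2L, rbind(e1, e2), convention = "unordered",
                  directed = TRUE)
}

#' Read and write hyperedge-list TSV files
#'
#' Plain-text exchange format for structures: tab-separated columns `order`,
#' `focal_node`, `neighbor_1` ... `neighbor_D` (empty beyond an entry's
#' order) and `weight`, with a header line and 1-based node indices.
#'
#' @param structure a [hyper_structure()].
#' @param path file path.
#' @return `write_hyperedge_tsv()` returns `path` invisibly;
#'   `read_hyperedge_tsv()` returns a [hyper_structure()].
#' @export
write_hyperedge_tsv <- function(structure, path) {
  stopifnot(inherits(structure, "hyper_structure"))
  e <- structure$entries
  out <- data.frame(order = e$order, focal_node = e$node)
  for (d in seq_len(structure$max_order)) {
    out[[paste0("neighbor_", d)]] <- e[[paste0("n", d)]]
  }
  out$weight <- format(e$weight, digits = 17, scientific = TRUE, trim = TRUE)
  header <- paste(names(out), collapse = "\t")
  meta <- sprintf("# hordyn hyperedges v1\tn_nodes=%d\tmax_order=%d\tconvention=%s\tdirected=%s",
                  structure$n_nodes, structure$max_order,
                  structure$convention, structure$directed)
  cells <- lapply(out, function(col) {
    s <- as.character(col)
    s[is.na(col)] <- ""  # unused neighbor slots written empty
    s
  })
  writeLines(c(meta, header,
               do.call(paste, c(cells, sep = "\t"))[seq_len(nrow(out))]),
             path)
  invisible(path)
}

#' @rdname write_hyperedge_tsv
#' @export
read_hyperedge_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# hordyn hyperedges")) {
    stop("not a hordyn hyperedge TSV (missing metadata line)", call. = FALSE)
  }
  kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           colClasses = NA)
  max_order <- as.integer(meta[["max_order"]])
  entries <- data.frame(order = as.integer(tab$order),
                        node = as.integer(tab$focal_node))
  for (d in seq_len(max_order)) {
    entries[[paste0("n", d)]] <- as.integer(tab[[paste0("neighbor_", d)]])
  }
  entries$weight <- as.numeric(tab$weight)
  if (nrow(tab) == 0L) entries <- NULL
  hyper_structure(as.integer(meta[["n_nodes"]]), max_order, entries,
                  convention = meta[["convention"]],
                  directed = identical(meta[["directed"]], "TRUE"))
}

#' JSON serialization of a structure
#'
#' Versioned JSON schema carrying the node count, conventions and the full
#' entry table of a [hyper_structure()].
#'
#' @param structure a [hyper_structure()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `structure_to_json()`: a JSON string (or `path`, invisibly);
#'   `structure_from_json()`: a [hyper_structure()].
#' @export
structure_to_json <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "hyper_structure"))
  obj <- list(schema = "hordyn/hyper_structure/v1",
              n_nodes = structure$n_nodes,
              max_order = structure$max_order,
              convention = structure$convention,
              directed = structure$directed,
              entries = structure$entries)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname structure_to_json
#' @param json JSON string or file path produced by `structure_to_json()`.
#' @export
structure_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$schema, "hordyn/hyper_structure/v1")) {
    stop("unrecognized hyper_structure JSON schema", call. = FALSE)
  }
  entries <- if (length(obj$entries) == 0) NULL else as.data.frame(obj$entries)
  hyper_structure(obj$n_nodes, obj$max_order, entries,
                  convention = obj$convention, directed = obj$directed)
}
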