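ELEMENT_TYPES <- c("artery", "arteriole", "capillary", "venule", "vein")

# allowed downstream successor types along the flow direction
TYPE_SUCCESSORS <- list(
  artery = c("artery", "arteriole"),
  arteriole = "capillary",
  capillary = "venule",
  venule = "vein",
  vein = "vein"
)

#' Validate a vascular network
#'
#' Checks table structure, id uniqueness, reference integrity, positive
#' radii/lengths, the artery-arteriole-capillary-venule-vein ordering along
#' the flow direction, single inlet/outlet, connectivity, and acyclicity of
#' the arterial and venous trees. Errors carry row-level diagnostics.
#'
#' @param network a `vascular_network`
#' @return the network, invisibly
#' @export
validate_network <- function(network) {
  nd <- network$nodes
  el <- network$elements
  fail <- function(...) stop("invalid network: ", ..., call. = FALSE)

  dup <- nd$id[duplicated(nd$id)]
  if (length(dup)) fail("duplicated node id(s): ", paste(unique(dup), collapse = ", "))
  dup <- el$id[duplicated(el$id)]
  if (length(dup)) fail("duplicated element id(s): ", paste(unique(dup), collapse = ", "))

  bad <- which(!(el$type %in% ELEMENT_TYPES))
  if (length(bad))
    fail("unknown element type in elements row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(el$type[bad]), collapse = ", "))
  bad <- which(!(el$node_in %in% nd$id) | !(el$node_out %in% nd$id))
  if (length(bad))
    fail("element row(s) ", paste(bad, collapse = ", "), " reference unknown nodes")
  bad <- which(!is.finite(el$length_mm) | el$length_mm <= 0)
  if (length(bad))
    fail("non-positive length in elements row(s) ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(el$radius0_mm) | el$radius0_mm <= 0)
  if (length(bad))
    fail("non-positive radius in elements row(s) ", paste(bad, collapse = ", "))

  if (length(network$inlet_element) != 1 || !(network$inlet_element %in% el$id))
    fail("inlet_element must name exactly one element")
  if (length(network$outlet_element) != 1 || !(network$outlet_element %in% el$id))
    fail("outlet_element must name exactly one element")

  # type ordering along flow: every downstream neighbour must be an allowed
  # successor of the upstream element's type
  idx_by_in <- split(seq_len(nrow(el)), el$node_in)
  for (ty in ELEMENT_TYPES) {
    rows <- which(el$type == ty)
    if (!length(rows)) next
    succ_rows <- idx_by_in[as.character(el$node_out[rows])]
    n_succ <- lengths(succ_rows)
    src <- rep(rows, n_succ)
    succ <- unlist(succ_rows, use.names = FALSE)
    if (length(succ)) {
      bad <- which(!(el$type[succ] %in% TYPE_SUCCESSORS[[ty]]))
      if (length(bad))
        fail("illegal type transition ", ty, " -> ", el$type[succ[bad[1]]],
             " at elements row ", succ[bad[1]])
    }
  }

  # capillary units: exactly one arteriole parent and one venule child
  cap <- which(el$type == "capillary")
  if (length(cap)) {
    n_par <- vapply(cap, function(i)
      sum(el$type == "arteriole" & el$node_out == el$node_in[i]), integer(1))
    n_chl <- vapply(cap, function(i)
      sum(el$type == "venule" & el$node_in == el$node_out[i]), integer(1))
    bad <- which(n_par != 1L | n_chl != 1L)
    if (length(bad))
      fail("capillary at elements row ", cap[bad[1]],
           " lacks a unique arteriole parent / venule child")
  }

  # connectivity (undirected) from the inlet node
  n_nodes <- nrow(nd)
  node_pos <- match(c(el$node_in, el$node_out), nd$id)
  adj <- split(c(match(el$node_out, nd$id), match(el$node_in, nd$id)),
               node_pos)
  seen <- logical(n_nodes)
  start <- match(el$node_in[el$id == network$inlet_element], nd$id)
  frontier <- start
  seen[start] <- TRUE
  while (length(frontier)) {
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  if (!all(seen))
    fail(sum(!seen), " node(s) unreachable from the inlet, e.g. node id ",
         nd$id[which(!seen)[1]])

  # arterial/venous subgraphs are trees: acyclic <=> edges = nodes - 1 for a
  # connected subgraph; here check each non-root node has exactly one parent
  for (side in c("artery", "vein")) {
    rows <- which(el$type == side)
    if (!length(rows)) next
    kids <- if (side == "artery") el$node_out[rows] else el$node_in[rows]
    dup <- kids[duplicated(kids)]
    if (length(dup))
      fail(side, " subgraph is not a tree: node ", dup[1],
           " has multiple ", side, " parents")
  }
  invisible(network)
}

#' Write a network to a directory
#'
#' Writes `nodes.csv` (id, x_mm, y_mm, z_mm), `elements.csv`
#' (id, node_in, node_out, type, radius0_mm, length_mm) and `header.json`
#' naming the inlet/outlet elements, terminal-unit count, domain semi-axes
#' and the axis conventions.
#'
#' @param network a valid `vascular_network`
#' @param path directory (created if needed)
#' @return `path`, invisibly
#' @export
write_network <- function(network, path) {
  validate_network(network)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # %.17g round-trips doubles exactly through text
  fmt <- function(df) {
    for (cl in names(df))
      if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
    df
  }
  utils::write.csv(fmt(network$nodes), file.path(path, "nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(network$elements), file.path(path, "elements.csv"),
                   row.names = FALSE, quote = FALSE)
  header <- list(
    format = "pulmoasl-network-v1",
    inlet_element = network$inlet_element,
    outlet_element = network$outlet_element,
    n_terminal_units = network$n_terminal_units,
    domain_semi_axes_mm = network$domain$semi_axes,
    hilum_mm = network$domain$hilum,
    axes = network$domain$axes
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network from a directory
#'
#' Inverse of [write_network()]; the round trip is an identity on the node
#' and element tables. Malformed tables are rejected with row-level
#' diagnostics.
#'
#' @param path directory containing `nodes.csv`, `elements.csv`, `header.json`
#' @return a validated `vascular_network`
#' @export
read_network <- function(path) {
  for (f in c("nodes.csv", "elements.csv", "header.json"))
    if (!file.exists(file.path(path, f)))
      stop("missing network file: ", file.path(path, f))
  nodes <- utils::read.csv(file.path(path, "nodes.csv"), stringsAsFactors = FALSE)
  elements <- utils::read.csv(file.path(path, "elements.csv"), stringsAsFactors = FALSE)
  header <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(nodes)))
    stop("nodes.csv lacks column(s): ", paste(setdiff(need, names(nodes)), collapse = ", "))
  need <- c("id", "node_in", "node_out", "type", "radius0_mm", "length_mm")
  if (!all(need %in% names(elements)))
    stop("elements.csv lacks column(s): ", paste(setdiff(need, names(elements)), collapse = ", "))
  net <- structure(list(
    nodes = nodes,
    elements = elements,
    inlet_element = as.integer(header$inlet_element),
    outlet_element = as.integer(header$outlet_element),
    n_terminal_units = as.integer(header$n_terminal_units),
    domain = lung_domain(as.numeric(header$domain_semi_axes_mm),
                         hilum_y_frac = as.numeric(header$hilum_mm[2]) /
                           as.numeric(header$domain_semi_axes_mm[2])),
    config = NULL
  ), class = "vascular_network")
  validate_network(net)
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  tab <- table(x$elements$type)
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " elements (", paste(names(tab), tab, sep = ": ", collapse = ", "),
      "), ", x$n_terminal_units, " terminal units\n", sep = "")
  invisible(x)
}
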