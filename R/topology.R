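#' @useDynLib empstem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif median setNames kmeans prcomp hclust cutree dist
#'   sd quantile IQR wilcox.test t.test p.adjust mahalanobis
#' @importFrom utils read.table write.table
NULL

#' Construct a circuit topology
#'
#' A `circuit_topology` holds the nodes and signed, directed regulatory edges
#' of a gene circuit. Node order is fixed and determines the layout of state
#' vectors everywhere downstream.
#'
#' @param nodes Character vector of unique node names, in canonical order.
#' @param edges Data frame with columns `source`, `target` (node names) and
#'   `sign` (`"activation"` or `"inhibition"`).
#' @param name Identifier for the circuit.
#' @return An object of class `circuit_topology`: a list with elements
#'   `name`, `nodes` and `edges`.
#' @export
circuit_topology <- function(nodes, edges, name = "circuit") {
  stopifnot(is.character(nodes), is.data.frame(edges))
  edges <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    sign = as.character(edges$sign),
    stringsAsFactors = FALSE
  )
  topo <- structure(
    list(name = name, nodes = nodes, edges = edges),
    class = "circuit_topology"
  )
  diag <- validate_topology(topo)
  if (length(diag) > 0L) {
    stop("invalid topology: ", paste(diag, collapse = "; "))
  }
  topo
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf(
    "<circuit_topology '%s'>: %d nodes, %d edges\n",
    x$name, length(x$nodes), nrow(x$edges)
  ))
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  arrow <- ifelse(x$edges$sign == "activation", "->", "-|")
  cat("  edges:", paste0(x$edges$source, arrow, x$edges$target, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a circuit topology
#'
#' Checks the structural invariants: unique node names, every edge endpoint
#' declared, at most one edge per ordered (source, target) pair, and a valid
#' regulation sign. Self-edges are allowed.
#'
#' @param topo A `circuit_topology` (or a list shaped like one).
#' @return Character vector of human-readable diagnostics; empty if the
#'   topology is valid.
#' @export
validate_topology <- function(topo) {
  diag <- character(0)
  if (anyDuplicated(topo$nodes)) {
    diag <- c(diag, sprintf(
      "duplicate node name(s): %s",
      paste(unique(topo$nodes[duplicated(topo$nodes)]), collapse = ", ")
    ))
  }
  if (nrow(topo$edges) == 0L) {
    diag <- c(diag, "topology has no edges")
  }
  bad_sign <- !topo$edges$sign %in% c("activation", "inhibition")
  if (any(bad_sign)) {
    diag <- c(diag, sprintf("invalid edge sign in %d edge(s)", sum(bad_sign)))
  }
  unknown <- setdiff(c(topo$edges$source, topo$edges$target), topo$nodes)
  for (u in unknown) diag <- c(diag, sprintf("unknown node '%s' referenced by an edge", u))
  key <- paste(topo$edges$source, topo$edges$target)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      diag <- c(diag, sprintf("duplicate edge %s", sub(" ", " -> ", k)))
    }
  }
  diag
}

#' Read a circuit topology from a `.topo` file
#'
#' The `.topo` dialect is whitespace-delimited text with one edge per line:
#' `Source Target Type`, where Type 1 is activation and Type 2 inhibition.
#' An optional header line `Source Target Type` is tolerated. Nodes are
#' inferred in order of first appearance in the edge list.
#'
#' @param path Path to a `.topo` file.
#' @param name Circuit name; defaults to the file name without extension.
#' @return A `circuit_topology`.
#' @export
load_topology <- function(path, name = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) > 0L && grepl("^source\\s+target\\s+type$", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (length(lines) == 0L) stop("topology file has no edges: ", path)
  parts <- strsplit(lines, "\\s+")
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    stop(sprintf(
      "malformed .topo line %d (expected 3 fields, got %d): '%s'",
      line_no[which(nfield != 3L)[1L]], nfield[nfield != 3L][1L],
      lines[which(nfield != 3L)[1L]]
    ))
  }
  src <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  type <- vapply(parts, `[[`, "", 3L)
  if (!all(type %in% c("1", "2"))) {
    bad <- which(!type %in% c("1", "2"))[1L]
    stop(sprintf("unknown regulation Type code '%s' on line %d (expected 1 or 2)",
                 type[bad], line_no[bad]))
  }
  nodes <- unique(c(rbind(src, tgt)))
  edges <- data.frame(
    source = src, target = tgt,
    sign = ifelse(type == "1", "activation", "inhibition"),
    stringsAsFactors = FALSE
  )
  circuit_topology(nodes, edges, name = name)
}

#' Write a circuit topology to a `.topo` file
#'
#' Always writes the `Source Target Type` header; edges in stored order.
#' `load_topology(save_topology(topo))` reproduces `topo` whenever node order
#' follows first appearance in the edge list.
#'
#' @param topo A `circuit_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_topology <- function(topo, path) {
  type <- ifelse(topo$edges$sign == "activation", 1L, 2L)
  lines <- c("Source Target Type",
             paste(topo$edges$source, topo$edges$target, type))
  writeLines(lines, path)
  invisible(path)
}

.builtin_circuit_names <- c("base", "uncoupled", "grhl2", "grhl2_kd", "ovol", "nrf2")

.canonical_node_order <- function(nodes) {
  core <- c("miR200", "ZEB", "SNAIL", "LIN28", "let7", "NFkB")
  c(core[core %in% nodes], setdiff(nodes, core))
}

#' Bundled EMP-stemness circuits
#'
#' Returns one of the six bundled circuit topologies. `base` is the 6-node,
#' 14-edge coupled EMP-stemness circuit (miR-200/ZEB toggle with ZEB
#' self-activation, SNAIL input, LIN28/let-7 toggle with self-activations and
#' NF-kB input, coupled by the miR-200 -| LIN28 and let-7 -| ZEB links).
#' `uncoupled` removes the two coupling links. `grhl2`, `ovol` and `nrf2` add
#' one phenotypic stability factor node each; `grhl2_kd` is the GRHL2 circuit
#' without the GRHL2 -> miR-200 activation, differing from `ovol` only in the
#' sign of the PSF self-edge (after renaming the PSF node).
#'
#' @param name One of `"base"`, `"uncoupled"`, `"grhl2"`, `"grhl2_kd"`,
#'   `"ovol"`, `"nrf2"`.
#' @return A `circuit_topology` with nodes in canonical order
#'   (miR200, ZEB, SNAIL, LIN28, let7, NFkB, then the PSF node).
#' @export
builtin_circuit <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% .builtin_circuit_names) {
    stop("unknown circuit name '", paste(name, collapse = ","),
         "'; valid names: ", paste(.builtin_circuit_names, collapse = ", "))
  }
  path <- system.file("extdata", "circuits", paste0(name, ".topo"),
                      package = "empstem", mustWork = TRUE)
  topo <- load_topology(path, name = name)
  circuit_topology(.canonical_node_order(topo$nodes), topo$edges, name = name)
}

# Index helpers used by the sampler and dynamics code ------------------------

.node_index <- function(topo) setNames(seq_along(topo$nodes), topo$nodes)

# Edge endpoints as 1-based indices into topo$nodes.
.edge_indices <- function(topo) {
  idx <- .node_index(topo)
  list(
    src = unname(idx[topo$edges$source]),
    tgt = unname(idx[topo$edges$target]),
    activating = topo$edges$sign == "activation"
  )
}
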