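#' Load the circulation topology
#'
#' Reads a declarative topology description (compartment list plus
#' directed flow connections) and validates it: compartment names are
#' unique, every connection references a known compartment, and the graph
#' is a single closed loop network in which every compartment can reach,
#' and be reached from, every other (so no blood can pool outside the
#' circulation).
#'
#' The packaged default mirrors the reduced closed-loop model: four heart
#' chambers and four valves, pulmonary artery and vein, aortic and
#' carotid/cerebral arterial compartments, seven named terminal beds
#' (leg, brachial, anterior/external/middle/posterior carotid-cerebral,
#' trunk), and upper/lower venous compartments with their caval returns.
#'
#' @param path JSON file; defaults to the packaged topology.
#' @return A list of class `cvs_topology` with tibbles `compartments`
#'   and `connections`.
#' @export
cvs_topology <- function(path = system.file("extdata", "topology.json",
                                            package = "cvscalib")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- structure(list(name = raw$name,
                         compartments = tibble::as_tibble(raw$compartments),
                         connections = tibble::as_tibble(raw$connections)),
                    class = "cvs_topology")
  validate_topology(topo)
  topo
}

#' @rdname cvs_topology
#' @param topo A `cvs_topology` object.
#' @export
validate_topology <- function(topo) {
  comp <- topo$compartments$name
  if (anyDuplicated(comp)) stop("duplicate compartment names")
  conn <- topo$connections
  unknown <- setdiff(c(conn$from, conn$to), comp)
  if (length(unknown) > 0) {
    stop("connection references unknown compartment(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  reach <- function(start, edges) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- setdiff(edges$to[edges$from %in% frontier], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  fwd <- reach(comp[1], conn)
  rev_edges <- tibble::tibble(from = conn$to, to = conn$from)
  bwd <- reach(comp[1], rev_edges)
  stranded <- setdiff(comp, intersect(fwd, bwd))
  if (length(stranded) > 0) {
    stop("not a single closed loop; compartment(s) outside the cycle: ",
         paste(stranded, collapse = ", "))
  }
  invisible(topo)
}

#' @export
print.cvs_topology <- function(x, ...) {
  cat("<cvs_topology>", x$name, "-", nrow(x$compartments),
      "compartments,", nrow(x$connections), "connections\n")
  invisible(x)
}
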