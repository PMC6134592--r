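#' Bipartite organism-metabolite web for one environment
#'
#' The web view of an environment: organisms around a pool of metabolite
#' nodes, with an edge for every increase (red) or decrease (blue) assertion.
#' A metabolite node's degree is the number of organisms interacting with it
#' (increase or decrease only — no-change cells draw nothing) and controls
#' its circle size; nodes are filled when the metabolite was detected in the
#' untransformed control pool and hollow when it appeared only after
#' microbial transformation. Control-pool metabolites are kept even with no
#' interactions; metabolites neither in the control nor interacting are
#' absent.
#'
#' @param cube a [datacube()].
#' @param environment environment name.
#' @return An object of class `"web_graph"`: list with `environment`,
#'   `metabolites` (data frame `name`, `degree`, `in_control`), `organisms`
#'   (data frame `name`) and `edges` (data frame `organism`, `metabolite`,
#'   `action`, `shade`), all lexicographically ordered.
#' @seealso [export_graph()], [one_environment()]
#' @examples
#' web <- build_web(worked_example_fixture(), "R2A")
#' head(web$metabolites)
#' @export
build_web <- function(cube, environment) {
  stopifnot(inherits(cube, "datacube"))
  if (!environment %in% cube$environments$name)
    stop("unknown environment: ", environment, call. = FALSE)
  obs <- cube$observations[cube$observations$environment == environment, ,
                           drop = FALSE]
  ctrl <- obs$organism == control_name()
  in_control <- .lex_sort(obs$metabolite[ctrl & obs$action == "detected"])

  inter <- obs[!ctrl & obs$action %in% c("increased", "decreased"), ,
               drop = FALSE]
  edges <- data.frame(organism = inter$organism, metabolite = inter$metabolite,
                      action = inter$action, shade = inter$confidence / 5,
                      stringsAsFactors = FALSE)
  edges <- edges[.lex_order(edges$organism, edges$metabolite), , drop = FALSE]
  rownames(edges) <- NULL

  met_names <- .lex_sort(union(in_control, edges$metabolite))
  deg <- table(factor(edges$metabolite, levels = met_names))
  metabolites <- data.frame(name = met_names,
                            degree = as.integer(deg[met_names]),
                            in_control = met_names %in% in_control,
                            stringsAsFactors = FALSE)
  organisms <- data.frame(
    name = .lex_sort(setdiff(unique(obs$organism), control_name())),
    stringsAsFactors = FALSE)
  structure(list(environment = environment, metabolites = metabolites,
                 organisms = organisms, edges = edges),
            class = "web_graph")
}

#' @export
print.web_graph <- function(x, ...) {
  cat(sprintf(
    "interaction web (%s): %d metabolites (%d in control), %d organisms, %d edges\n",
    x$environment, nrow(x$metabolites), sum(x$metabolites$in_control),
    nrow(x$organisms), nrow(x$edges)))
  invisible(x)
}

#' Export an interaction web
#'
#' Writes a [build_web()] graph either as node-link JSON (`nodes` with `id`,
#' `type`, `degree`, `in_control`; `links` with `source` organism, `target`
#' metabolite, `action`, `shade`) or as GraphML with the same attributes.
#' Ordering is deterministic. JSON exports round-trip through
#' [import_graph()].
#'
#' @param graph a `"web_graph"`.
#' @param path file to write.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("json", "graphml")) {
  stopifnot(inherits(graph, "web_graph"))
  format <- match.arg(format)
  node_table <- function(id_name) {
    met <- graph$metabolites
    org <- graph$organisms
    nodes <- rbind(
      data.frame(id = met$name,
                 type = rep("metabolite", nrow(met)), degree = met$degree,
                 in_control = met$in_control, stringsAsFactors = FALSE),
      data.frame(id = org$name, type = rep("organism", nrow(org)),
                 degree = rep(NA_integer_, nrow(org)),
                 in_control = rep(NA, nrow(org)), stringsAsFactors = FALSE))
    names(nodes)[1] <- id_name
    nodes
  }
  if (format == "json") {
    nodes <- node_table("id")
    links <- data.frame(source = graph$edges$organism,
                        target = graph$edges$metabolite,
                        action = graph$edges$action,
                        shade = graph$edges$shade, stringsAsFactors = FALSE)
    payload <- list(environment = graph$environment, nodes = nodes,
                    links = links)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    nodes <- node_table("name")
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("organism", "metabolite", "action", "shade")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a node-link JSON web export
#'
#' Inverse of [export_graph()]'s JSON writer; restores the `"web_graph"`
#' structure (node and edge multisets are preserved exactly).
#'
#' @param path JSON file written by [export_graph()].
#' @return A `"web_graph"`.
#' @export
import_graph <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
  links <- as.data.frame(payload$links, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = character(), type = character(),
                        degree = integer(), in_control = logical(),
                        stringsAsFactors = FALSE)
  met <- nodes[nodes$type == "metabolite", , drop = FALSE]
  org <- nodes[nodes$type == "organism", , drop = FALSE]
  edges <- if (nrow(links) > 0)
    data.frame(organism = links$source, metabolite = links$target,
               action = links$action, shade = as.numeric(links$shade),
               stringsAsFactors = FALSE)
  else data.frame(organism = character(), metabolite = character(),
                  action = character(), shade = numeric(),
                  stringsAsFactors = FALSE)
  structure(list(environment = payload$environment,
                 metabolites = data.frame(
                   name = as.character(met$id),
                   degree = as.integer(met$degree),
                   in_control = as.logical(met$in_control),
                   stringsAsFactors = FALSE),
                 organisms = data.frame(name = as.character(org$id),
                                        stringsAsFactors = FALSE),
                 edges = edges),
            class = "web_graph")
}
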