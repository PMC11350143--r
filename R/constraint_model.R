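#' Hierarchical proportion-constraint models
#'
#' A constraint model is a tree of cell populations. Each node carries a
#' `[min, max]` proportion *relative to its parental population*; the root
#' is the whole admixture, split into cancer, leukocyte and non-leukocyte
#' stromal compartments. Flattening multiplies bounds down each path, giving
#' one absolute linear inequality pair per leaf.
#'
#' @name constraint_model
NULL

.validate_node <- function(node, path = "root") {
  if (is.null(node$min) || is.null(node$max)) {
    stop("constraint node '", path, "' lacks min/max")
  }
  if (node$min > node$max) {
    stop("constraint node '", path, "' has min > max")
  }
  for (nm in names(node$children)) {
    .validate_node(node$children[[nm]], paste(path, nm, sep = "/"))
  }
  invisible(TRUE)
}

#' Read a hierarchical constraint model from a YAML file
#'
#' The file holds a nested mapping: each node has `min`, `max` and an
#' optional `children` mapping. Bounds are relative to the parent node.
#'
#' @param path YAML file path.
#' @return A list of class `constraint_model` with a single `root` node.
#' @export
read_constraint_model <- function(path) {
  model <- yaml::read_yaml(path)
  if (is.null(model$root)) stop("constraint model must have a 'root' node")
  .validate_node(model$root)
  structure(model, class = "constraint_model")
}

.leaf_bounds <- function(node, acc_min = 1, acc_max = 1, name = "root") {
  lo <- acc_min * node$min
  hi <- acc_max * node$max
  if (is.null(node$children) || length(node$children) == 0L) {
    return(data.frame(population = name, min = lo, max = hi,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(node$children), function(nm) {
    .leaf_bounds(node$children[[nm]], lo, hi, nm)
  }))
}

#' Flatten a hierarchical model to absolute per-leaf bounds
#'
#' @param model a `constraint_model`.
#' @param populations optional character vector restricting (and ordering)
#'   the returned leaves, e.g. an admixture panel.
#' @return data.frame with columns `population`, `min`, `max` (absolute
#'   fractions of the whole admixture).
#' @export
flatten_model <- function(model, populations = NULL) {
  stopifnot(inherits(model, "constraint_model"))
  bounds <- .leaf_bounds(model$root)
  if (anyDuplicated(bounds$population)) {
    stop("constraint model leaves are not disjoint: ",
         paste(bounds$population[duplicated(bounds$population)], collapse = ", "))
  }
  if (!is.null(populations)) {
    missing <- setdiff(populations, bounds$population)
    if (length(missing)) {
      stop("populations missing from constraint model: ",
           paste(missing, collapse = ", "))
    }
    bounds <- bounds[match(populations, bounds$population), ]
    rownames(bounds) <- NULL
  }
  bounds
}

.combine_nodes <- function(a, b, floor, path = "root") {
  if (!setequal(names(a$children), names(b$children))) {
    stop("mismatched leaves under '", path, "': ",
         paste(union(setdiff(names(a$children), names(b$children)),
                     setdiff(names(b$children), names(a$children))),
               collapse = ", "))
  }
  node <- list(min = max(min(a$min, b$min), floor),
               max = max(a$max, b$max))
  if (length(a$children)) {
    node$children <- stats::setNames(lapply(names(a$children), function(nm) {
      .combine_nodes(a$children[[nm]], b$children[[nm]], floor,
                     paste(path, nm, sep = "/"))
    }), names(a$children))
  }
  node
}

#' Combine two hierarchical constraint models
#'
#' Per population, the combined maximum is the larger of the two maxima and
#' the combined minimum the smaller of the two minima, raised to `floor`
#' (default 0.01) when below it.
#'
#' @param model_a,model_b `constraint_model`s sharing the same tree.
#' @param floor lower floor applied to combined minima.
#' @return A `constraint_model`.
#' @export
combine_models <- function(model_a, model_b, floor = 0.01) {
  stopifnot(inherits(model_a, "constraint_model"),
            inherits(model_b, "constraint_model"))
  root <- .combine_nodes(model_a$root, model_b$root, floor)
  root$min <- min(model_a$root$min, model_b$root$min)  # root floor not raised
  root$max <- max(model_a$root$max, model_b$root$max)
  structure(list(root = root), class = "constraint_model")
}

#' Default biological constraint model
#'
#' Combines the two illustrative hierarchical models shipped with the
#' package (one styled on bulk pan-cancer compartment estimates, one on
#' single-cell tumor-atlas compositions) into a single final model, flooring
#' minima at 0.01.
#'
#' @return A `constraint_model`.
#' @export
default_biological_model <- function() {
  a <- read_constraint_model(system.file("extdata", "constraints_bulk_reference.yaml",
                                         package = "admixbench", mustWork = TRUE))
  b <- read_constraint_model(system.file("extdata", "constraints_sc_reference.yaml",
                                         package = "admixbench", mustWork = TRUE))
  combine_models(a, b, floor = 0.01)
}
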