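#' Build a logic tree from node specifications
#'
#' A logic tree is a rooted DAG of named nodes evaluated cell-by-cell:
#' \describe{
#'   \item{input}{a leaf bound to a raw input variable; if a `conversion` is
#'     present the raw layer is normalized with [convert_linear()], otherwise
#'     the supplied layer must already be fuzzy.}
#'   \item{convert}{applies a [conversion_spec()] to exactly one child.}
#'   \item{and / or / union}{fuzzy minimum / maximum / mean of two or more
#'     children ([fuzzy_and()], [fuzzy_or()], [fuzzy_union()]).}
#' }
#'
#' @param nodes List of node specs; each is a list with fields `name`,
#'   `kind`, and (by kind) `statement`, `children`, `conversion`
#'   (list with `false` and `true` thresholds), `input_variable`.
#' @return A validated object of class `logic_tree` with elements `nodes`
#'   (named list), `root` (name of the single root), and `order` (topological
#'   evaluation order).
#' @export
logic_tree <- function(nodes) {
  if (length(nodes) == 0L) stop("empty tree")
  names(nodes) <- vapply(nodes, function(n) as.character(n$name), "")
  if (anyDuplicated(names(nodes))) stop("duplicate node names")
  kinds <- c("input", "convert", "and", "or", "union")

  for (n in nodes) {
    if (!n$kind %in% kinds) stop("unknown node kind: ", n$kind)
    ch <- n$children
    if (n$kind == "input") {
      if (length(ch)) stop("input node '", n$name, "' must not have children")
      if (is.null(n$input_variable)) {
        stop("input node '", n$name, "' lacks input_variable")
      }
    } else {
      if (is.null(ch) || !length(ch)) stop("node '", n$name, "' has no children")
      bad <- setdiff(unlist(ch), names(nodes))
      if (length(bad)) stop("dangling child reference: ", paste(bad, collapse = ", "))
      if (n$kind == "convert" && length(unlist(ch)) != 1L) {
        stop("arity: convert node '", n$name, "' must have exactly 1 child")
      }
      if (n$kind %in% c("and", "or", "union") && length(unlist(ch)) < 2L) {
        stop("arity: operator node '", n$name, "' needs at least 2 children")
      }
    }
    if (!is.null(n$conversion)) {
      conversion_spec(n$conversion$false, n$conversion$true)  # validates
    } else if (n$kind == "convert") {
      stop("convert node '", n$name, "' lacks a conversion")
    }
  }

  # Topological sort (Kahn); detects cycles.
  children_of <- lapply(nodes, function(n) as.character(unlist(n$children)))
  remaining <- names(nodes)
  order <- character(0)
  done <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      all(children_of[[nm]] %in% done)
    }, TRUE)]
    if (!length(ready)) stop("cycle detected in logic tree")
    order <- c(order, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }

  referenced <- unique(unlist(children_of))
  roots <- setdiff(names(nodes), referenced)
  if (length(roots) != 1L) {
    stop("tree must have a single root, found: ", paste(roots, collapse = ", "))
  }
  structure(list(nodes = nodes, root = roots, order = order),
            class = "logic_tree")
}

#' @export
print.logic_tree <- function(x, ...) {
  cat(sprintf("<logic_tree> %d nodes (%d inputs), root '%s'\n",
              length(x$nodes),
              sum(vapply(x$nodes, function(n) n$kind == "input", TRUE)),
              x$root))
  invisible(x)
}

#' Load a logic tree from a JSON configuration file
#'
#' The file holds a list under `nodes`, each entry with the fields described
#' in [logic_tree()]; conversions are serialized as `{"false": v, "true": v}`.
#' The default biomass-loss-risk tree ships with the package
#' (`system.file("extdata", "biomass_loss_risk_tree.json", package = "fuzzyrisk")`).
#'
#' @param path Path to the JSON config.
#' @param thresholds Optional named list overriding input-node conversions:
#'   `variable name -> list(false =, true =)` (e.g. a derived threshold
#'   profile from [derive_thresholds()]).
#' @return A [logic_tree()].
#' @export
load_tree <- function(path, thresholds = NULL) {
  if (!file.exists(path)) stop("tree config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- cfg$nodes
  if (is.null(nodes)) stop("config has no 'nodes' entry")
  if (!is.null(thresholds)) {
    for (i in seq_along(nodes)) {
      v <- nodes[[i]]$input_variable
      if (!is.null(v) && v %in% names(thresholds)) {
        nodes[[i]]$conversion <- thresholds[[v]]
      }
    }
  }
  logic_tree(nodes)
}

#' Names of the raw input variables a tree consumes
#'
#' @param tree A [logic_tree()].
#' @return Character vector of `input_variable` names.
#' @export
tree_input_variables <- function(tree) {
  unname(vapply(Filter(function(n) n$kind == "input", tree$nodes),
                function(n) n$input_variable, ""))
}

#' Evaluate a logic tree on raw input layers
#'
#' Bottom-up, memoized evaluation in topological order; every cell is
#' computed independently of all other cells, and cells masked in any input
#' are masked in every output (via the shared grid mask).
#'
#' @param tree A [logic_tree()].
#' @param inputs Named list mapping each input variable to a [raster_layer()]
#'   (raw, when the input node carries a conversion) or [fuzzy_layer()].
#' @return An object of class `tree_result`: list with `layers` (node name ->
#'   [fuzzy_layer()]) and `attributions` (node name -> [attribution_layer()],
#'   And/Or nodes only).
#' @export
evaluate <- function(tree, inputs) {
  stopifnot(inherits(tree, "logic_tree"))
  need <- tree_input_variables(tree)
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    stop("missing input variable(s): ", paste(missing, collapse = ", "))
  }
  grid <- inputs[[need[1L]]]$grid
  for (v in need) stop_if_grid_mismatch(grid, inputs[[v]]$grid, "input layers")

  layers <- list()
  attributions <- list()
  for (nm in tree$order) {
    n <- tree$nodes[[nm]]
    if (n$kind == "input") {
      raw <- inputs[[n$input_variable]]
      layers[[nm]] <- if (!is.null(n$conversion)) {
        convert_linear(raw, conversion_spec(n$conversion$false, n$conversion$true),
                       statement = nm)
      } else {
        as_fuzzy(raw)
      }
    } else {
      ch <- lapply(as.character(unlist(n$children)), function(c) layers[[c]])
      if (n$kind == "convert") {
        layers[[nm]] <- convert_linear(
          ch[[1L]], conversion_spec(n$conversion$false, n$conversion$true),
          statement = nm)
      } else if (n$kind == "union") {
        layers[[nm]] <- fuzzy_union(ch)
      } else {
        res <- if (n$kind == "and") fuzzy_and(ch) else fuzzy_or(ch)
        res$attribution$input_names <- as.character(unlist(n$children))
        layers[[nm]] <- res$layer
        attributions[[nm]] <- res$attribution
      }
      layers[[nm]]$variable_name <- nm
    }
  }
  structure(list(layers = layers, attributions = attributions,
                 root = tree$root, grid = grid),
            class = "tree_result")
}

#' Evaluate a logic tree for every ensemble member
#'
#' The tree is evaluated independently per member — no cross-member mixing
#' happens before an explicit reduction ([reduce_stack()] etc.). Shared
#' inputs (e.g. the observed-biomass layer) are broadcast to all members.
#'
#' @param tree A [logic_tree()].
#' @param stacks Named list mapping input variables to [ensemble_stack()]s;
#'   all stacks must carry identical `member_ids` in identical order.
#' @param shared_inputs Named list mapping input variables to single
#'   [raster_layer()]s used for every member.
#' @return Named list `member_id -> tree_result`.
#' @export
evaluate_ensemble <- function(tree, stacks, shared_inputs = list()) {
  stopifnot(length(stacks) >= 1L)
  ids <- stacks[[1L]]$member_ids
  for (s in stacks) {
    if (!identical(s$member_ids, ids)) {
      stop("member-id mismatch between input stacks")
    }
  }
  results <- vector("list", length(ids))
  names(results) <- ids
  for (m in seq_along(ids)) {
    inputs <- c(lapply(stacks, stack_member, member = m), shared_inputs)
    results[[m]] <- evaluate(tree, inputs)
  }
  results
}

#' Collect one node's layers across member results into a stack
#'
#' @param results Named list of `tree_result`s from [evaluate_ensemble()].
#' @param node Node name; default the root.
#' @return An [ensemble_stack()] of that node across members.
#' @export
node_stack <- function(results, node = NULL) {
  stopifnot(length(results) >= 1L)
  if (is.null(node)) node <- results[[1L]]$root
  layers_to_stack(lapply(results, function(r) r$layers[[node]]),
                  variable_name = node, units = "fuzzy truth")
}
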